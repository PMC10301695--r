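test_that("model dimensions follow the ontology layout", {
  g <- toy_graph()
  onto <- trim_ontology(g, bottom = 2, top = 4)   # B, C at depth 0
  x <- matrix(runif(12), 4, 3,
              dimnames = list(NULL, c("g2", "g3", "g4")))
  m <- pathvae(x, onto, k = 3, hidden_dim = 8, epochs = 0, seed = 1)
  expect_equal(m$layout$latent_dim, 6L)
  expect_length(m$masks$decoder, 0L)
  expect_equal(dim(m$params$rec_W), c(3L, 6L))
})

test_that("chain ontology consumes one decoder mask per extra depth", {
  onto <- chain_ontology()                        # P depth 0, C depth 1
  x <- matrix(runif(8), 4, 2, dimnames = list(NULL, c("gP", "gC")))
  m <- pathvae(x, onto, k = 1, hidden_dim = 4, epochs = 0, seed = 1)
  expect_equal(m$layout$latent_dim, 1L)
  expect_length(m$masks$decoder, 1L)
  expect_equal(dim(m$params$dec_W1), c(1L, 1L))
})

test_that("identical spec and seed give bit-identical models", {
  fx <- trained_toy_model()
  x <- fx$sim$data
  m1 <- pathvae(x, fx$onto, k = 2, hidden_dim = 16, epochs = 3,
                batch_size = 32, seed = 42)
  m2 <- pathvae(x, fx$onto, k = 2, hidden_dim = 16, epochs = 3,
                batch_size = 32, seed = 42)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  m0a <- pathvae(x, fx$onto, epochs = 0, seed = 7)
  m0b <- pathvae(x, fx$onto, epochs = 0, seed = 7)
  expect_identical(m0a$params, m0b$params)
})

test_that("closed-form KL is zero at the prior and 1/2 at unit mean shift", {
  expect_equal(kl_divergence(rep(0, 5), rep(0, 5)), 0)
  expect_equal(kl_divergence(1, 0), 0.5)
  expect_error(kl_divergence(NaN, 0), "non-finite")
})

test_that("closed-form KL matches a Monte-Carlo estimate", {
  set.seed(31)
  mu <- rnorm(4); lv <- rnorm(4, sd = 0.5)
  n <- 2e5
  z <- matrix(rnorm(4 * n), n, 4, byrow = TRUE)
  z <- sweep(sweep(z, 2, exp(0.5 * lv), "*"), 2, mu, "+")
  # log q(z) - log p(z), averaged over draws from q
  lq <- sapply(1:4, function(j) dnorm(z[, j], mu[j], exp(0.5 * lv[j]), log = TRUE))
  lp <- sapply(1:4, function(j) dnorm(z[, j], log = TRUE))
  diffs <- rowSums(lq - lp)
  se <- sd(diffs) / sqrt(n)
  expect_lt(abs(kl_divergence(mu, lv) - mean(diffs)), 3 * se)
})

test_that("hand-set chain model reproduces a pencil-and-paper forward pass", {
  m <- hand_chain_model()
  z <- matrix(c(1, -0.5), 2, 1)
  dec <- decode_latent(m, z)
  # C = 2 * P + 0.5; gC = 3*C + 0.1 (first gene row is gC); gP = 1*P + 0.2
  expect_equal(unname(dec$term_activities[, "P"]), c(1, -0.5))
  expect_equal(unname(dec$term_activities[, "C"]), c(2.5, -0.5))
  expect_equal(unname(dec$reconstruction[, "gC"]), c(7.6, -1.4))
  expect_equal(unname(dec$reconstruction[, "gP"]), c(1.2, -0.3))
})

test_that("zero weights and biases decode to the zero vector", {
  m <- hand_chain_model()
  m$params$dec_W1[] <- 0; m$params$dec_b1[] <- 0
  m$params$rec_W[] <- 0; m$params$rec_b[] <- 0
  dec <- decode_latent(m, matrix(c(3, -2, 0.5), 3, 1))
  expect_equal(unname(dec$reconstruction), matrix(0, 3, 2))
})

test_that("skip-concatenation decoding equals the dense linear-solve oracle", {
  set.seed(99)
  for (s in 1:6) {
    g <- random_dag(12, p_edge = 0.3, seed = 300 + s)
    onto <- trim_ontology(g, 1, 100)
    k <- sample(1:3, 1)
    x <- matrix(runif(5 * length(onto$genes)), 5,
                dimnames = list(NULL, onto$genes))
    m <- pathvae(x, onto, k = k, hidden_dim = 6, epochs = 0, seed = s)
    # random positive masked weights and nonzero biases
    for (d in seq_len(m$layout$D)) {
      nm <- paste0("dec_W", d)
      m$params[[nm]] <- matrix(runif(length(m$params[[nm]])),
                               nrow(m$params[[nm]])) * m$masks$decoder[[d]]
      m$params[[paste0("dec_b", d)]] <- rnorm(length(m$params[[paste0("dec_b", d)]]))
    }
    Z <- matrix(rnorm(4 * m$layout$latent_dim), 4)
    got <- decode_latent(m, Z)
    want <- oracle_dense_decode(m, Z)
    expect_equal(got$neurons, want$full, tolerance = 1e-6)
    expect_equal(unname(got$reconstruction), unname(want$xhat), tolerance = 1e-6)
  }
})

test_that("elbo on the hand-set chain model equals the hand computation", {
  m <- hand_chain_model()
  # deterministic path: z = mu; compute mu by hand from encoder params
  x <- m$x
  H <- pmax(x %*% m$params$enc_W1 + rep(m$params$enc_b1, each = 2), 0)
  mu <- H %*% m$params$enc_Wmu + rep(m$params$enc_bmu, each = 2)
  lv <- H %*% m$params$enc_Wlv + rep(m$params$enc_blv, each = 2)
  C <- 2 * mu + 0.5
  xhat <- cbind(3 * C + 0.1, 1 * mu + 0.2)
  colnames(xhat) <- c("gC", "gP")
  rec <- sum((xhat - x[, c("gC", "gP")])^2) / 2
  kl <- sum(0.5 * (mu^2 + exp(lv) - 1 - lv)) / 2
  got <- elbo(m, x)
  expect_equal(got$reconstruction, rec)
  expect_equal(got$kl, kl)
  expect_equal(got$objective, -rec - m$spec$beta * kl)
  expect_gte(got$kl, 0)
})

test_that("elbo with beta = 0 reduces to the reconstruction loss", {
  m <- hand_chain_model()
  m$spec$beta <- 0
  got <- elbo(m, m$x)
  expect_equal(got$loss, got$reconstruction)
  # stochastic path is reproducible under a fixed seed
  a <- elbo(m, m$x, training = TRUE, seed = 5)
  b <- elbo(m, m$x, training = TRUE, seed = 5)
  expect_identical(a, b)
})

test_that("training reduces validation loss and respects constraints", {
  fx <- trained_toy_model()
  h <- fx$model$history
  expect_lt(h$val_loss[nrow(h)], h$val_loss[1])
  expect_true(all(h$min_decoder_weight >= 0))
  expect_true(all(h$max_masked_abs == 0))
  par <- fx$model$params
  for (nm in pathvae:::pv_decoder_weight_names(fx$model$layout)) {
    expect_gte(min(par[[nm]]), 0)
  }
  expect_identical(which.min(h$val_loss), as.integer(fx$model$best_epoch))
})

test_that("monotone propagation: raising a latent coordinate never lowers activities", {
  fx <- trained_toy_model()
  m <- fx$model
  for (d in seq_len(m$layout$D)) m$params[[paste0("dec_b", d)]][] <- 0
  m$params$rec_b[] <- 0
  set.seed(4)
  z0 <- matrix(rnorm(m$layout$latent_dim), 1)
  base <- decode_latent(m, z0)
  for (j in sample(m$layout$latent_dim, 3)) {
    z1 <- z0; z1[j] <- z1[j] + 0.5
    up <- decode_latent(m, z1)
    expect_true(all(up$neurons - base$neurons >= -1e-12))
    expect_true(all(up$reconstruction - base$reconstruction >= -1e-12))
  }
})

test_that("with beta ~ 0 a toy model drives training MSE down over epochs", {
  onto <- chain_ontology()
  set.seed(21)
  a <- 2 * abs(rnorm(100))
  x <- cbind(gP = a + rnorm(100, sd = 0.1), gC = 2 * a + rnorm(100, sd = 0.1))
  m <- pathvae(x, onto, k = 1, hidden_dim = 16, beta = 0, epochs = 150,
               batch_size = 25, learning_rate = 1e-3, dropout_hidden = 0,
               dropout_latent = 0, seed = 3)
  h <- m$history
  expect_lt(mean(tail(h$train_loss, 10)), 0.25 * h$train_loss[1])
})

test_that("save/load round-trips the model and validates integrity", {
  fx <- trained_toy_model()
  f <- tempfile(fileext = ".rds")
  save_pathvae(fx$model, f)
  m2 <- load_pathvae(f)
  z <- matrix(seq_len(fx$model$layout$latent_dim) / 10, 1)
  expect_identical(decode_latent(fx$model, z), decode_latent(m2, z))
  expect_identical(m2$params, fx$model$params)
  # tampered ontology hash is rejected
  obj <- readRDS(f)
  obj$ontology_hash <- "0000"
  f2 <- tempfile(fileext = ".rds")
  saveRDS(obj, f2)
  expect_error(load_pathvae(f2), "hash mismatch")
  # truncated file is a parse error, not silent garbage
  raw <- readBin(f, "raw", file.size(f))
  f3 <- tempfile(fileext = ".rds")
  writeBin(raw[seq_len(100)], f3)
  expect_error(load_pathvae(f3), "cannot parse|not a pathvae")
  f4 <- tempfile(fileext = ".rds")
  saveRDS(list(format = "pathvae-checkpoint", version = 99L, model = list()), f4)
  expect_error(load_pathvae(f4), "version")
})

test_that("training refuses degenerate inputs", {
  onto <- chain_ontology()
  x1 <- matrix(1, 1, 2, dimnames = list(NULL, c("gP", "gC")))
  expect_error(pathvae(x1, onto, epochs = 1), "at least 2 samples")
  x <- matrix(runif(10), 5, 2, dimnames = list(NULL, c("aa", "bb")))
  expect_error(pathvae(x, onto, epochs = 1), "no overlap")
})
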