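#' Closed-form KL divergence from a diagonal Gaussian to the standard normal
#'
#' Computes \eqn{\sum_i (\mu_i^2 + \sigma_i^2 - 1 - \log\sigma_i^2)/2},
#' the Kullback-Leibler divergence of \eqn{N(\mu, diag(\sigma^2))} from
#' \eqn{N(0, I)}.  Matrix inputs (samples in rows) are summed over all
#' entries.
#'
#' @param mu Mean vector or matrix.
#' @param logvar Log-variance vector or matrix, same shape as \code{mu}.
#' @return Non-negative scalar.
#' @export
kl_divergence <- function(mu, logvar) {
  if (any(!is.finite(mu)) || any(!is.finite(logvar))) {
    stop("kl_divergence: non-finite input")
  }
  sum(0.5 * (mu^2 + exp(logvar) - 1 - logvar))
}

# column layout of the concatenated decoder state (latent + all layers)
decoder_layout <- function(onto, k) {
  terms <- onto$terms
  depth <- onto$depth
  D <- max(depth)
  n_by_depth <- vapply(0:D, function(d) sum(depth == d), 1L)
  if (n_by_depth[1L] == 0L) stop("configuration error: empty depth-0 layer")
  width <- k * length(terms)
  # terms are ordered by depth then lexicographically, so each depth's
  # neuron columns are contiguous
  ends <- cumsum(n_by_depth) * k
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  avg <- matrix(0, width, length(terms))
  for (i in seq_along(terms)) avg[(i - 1L) * k + seq_len(k), i] <- 1 / k
  list(k = as.integer(k), D = D, width = width,
       latent_dim = k * n_by_depth[1L],
       slice = lapply(seq_len(D + 1L), function(i) seq.int(starts[i], ends[i])),
       in_cols = lapply(seq_len(D + 1L), function(i) {
         if (i == 1L) integer(0) else seq_len(starts[i] - 1L)
       }),
       avg = avg)
}

add_bias <- function(A, b) A + rep(b, each = nrow(A))

# initial parameters; decoder weights |fan-in uniform| * mask, biases zero
pv_init_params <- function(n_genes, hidden_dim, layout, masks) {
  runif_mat <- function(nr, nc, fan_in) {
    s <- 1 / sqrt(fan_in)
    matrix(stats::runif(nr * nc, -s, s), nr, nc)
  }
  par <- list(
    enc_W1 = runif_mat(n_genes, hidden_dim, n_genes),
    enc_b1 = stats::runif(hidden_dim, -1 / sqrt(n_genes), 1 / sqrt(n_genes)),
    enc_Wmu = runif_mat(hidden_dim, layout$latent_dim, hidden_dim),
    enc_bmu = stats::runif(layout$latent_dim, -1 / sqrt(hidden_dim), 1 / sqrt(hidden_dim)),
    enc_Wlv = runif_mat(hidden_dim, layout$latent_dim, hidden_dim),
    enc_blv = stats::runif(layout$latent_dim, -1 / sqrt(hidden_dim), 1 / sqrt(hidden_dim))
  )
  for (d in seq_len(layout$D)) {
    M <- masks$decoder[[d]]
    par[[paste0("dec_W", d)]] <- abs(runif_mat(nrow(M), ncol(M), ncol(M))) * M
    par[[paste0("dec_b", d)]] <- numeric(nrow(M))
  }
  Mr <- masks$reconstruction
  par$rec_W <- abs(runif_mat(nrow(Mr), ncol(Mr), ncol(Mr))) * Mr
  par$rec_b <- numeric(nrow(Mr))
  par
}

pv_decoder_weight_names <- function(layout) {
  c(if (layout$D > 0) paste0("dec_W", seq_len(layout$D)), "rec_W")
}

# decoder forward: Z (n x latent) -> list(full = n x width, xhat = n x genes)
pv_decode <- function(par, masks, layout, Z) {
  n <- nrow(Z)
  full <- matrix(0, n, layout$width)
  full[, layout$slice[[1L]]] <- Z
  for (d in seq_len(layout$D)) {
    Wm <- par[[paste0("dec_W", d)]] * masks$decoder[[d]]
    out <- add_bias(full[, layout$in_cols[[d + 1L]], drop = FALSE] %*% t(Wm),
                    par[[paste0("dec_b", d)]])
    if (any(!is.finite(out))) stop("non-finite values in decoder layer ", d)
    full[, layout$slice[[d + 1L]]] <- out
  }
  xhat <- add_bias(full %*% t(par$rec_W * masks$reconstruction), par$rec_b)
  if (any(!is.finite(xhat))) stop("non-finite values in reconstruction layer")
  list(full = full, xhat = xhat)
}

# full forward pass; when training, applies dropout and samples z
pv_forward <- function(par, masks, layout, X, training, spec) {
  n <- nrow(X)
  H_pre <- add_bias(X %*% par$enc_W1, par$enc_b1)
  Hr <- pmax(H_pre, 0)
  if (training && spec$dropout_hidden > 0) {
    mh <- matrix(stats::rbinom(length(Hr), 1L, 1 - spec$dropout_hidden) /
                   (1 - spec$dropout_hidden), n)
    Hd <- Hr * mh
  } else {
    mh <- NULL
    Hd <- Hr
  }
  mu <- add_bias(Hd %*% par$enc_Wmu, par$enc_bmu)
  lv <- add_bias(Hd %*% par$enc_Wlv, par$enc_blv)
  if (training) {
    eps <- matrix(stats::rnorm(length(mu)), n)
    sd_ <- exp(0.5 * lv)
    z <- mu + sd_ * eps
    if (spec$dropout_latent > 0) {
      mz <- matrix(stats::rbinom(length(z), 1L, 1 - spec$dropout_latent) /
                     (1 - spec$dropout_latent), n)
      zd <- z * mz
    } else {
      mz <- NULL
      zd <- z
    }
  } else {
    eps <- NULL; sd_ <- NULL; mz <- NULL
    zd <- mu
  }
  dec <- pv_decode(par, masks, layout, zd)
  list(H_pre = H_pre, Hd = Hd, mh = mh, mu = mu, lv = lv, eps = eps,
       sd_ = sd_, mz = mz, zd = zd, full = dec$full, xhat = dec$xhat)
}

pv_loss_parts <- function(fw, X, beta) {
  n <- nrow(X)
  rec <- sum((fw$xhat - X)^2) / n
  kl <- kl_divergence(fw$mu, fw$lv) / n
  list(reconstruction = rec, kl = kl, loss = rec + beta * kl,
       objective = -rec - beta * kl)
}

# gradients of loss = reconstruction MSE (sum over genes, mean over batch)
# + beta * KL (mean over batch)
pv_backward <- function(par, masks, layout, X, fw, beta, spec) {
  n <- nrow(X)
  g <- list()
  G_xhat <- 2 * (fw$xhat - X) / n
  g$rec_W <- (crossprod(G_xhat, fw$full)) * masks$reconstruction
  g$rec_b <- colSums(G_xhat)
  G_full <- G_xhat %*% (par$rec_W * masks$reconstruction)
  for (d in rev(seq_len(layout$D))) {
    G_out <- G_full[, layout$slice[[d + 1L]], drop = FALSE]
    inp <- fw$full[, layout$in_cols[[d + 1L]], drop = FALSE]
    Wm <- par[[paste0("dec_W", d)]] * masks$decoder[[d]]
    g[[paste0("dec_W", d)]] <- crossprod(G_out, inp) * masks$decoder[[d]]
    g[[paste0("dec_b", d)]] <- colSums(G_out)
    G_full[, layout$in_cols[[d + 1L]]] <-
      G_full[, layout$in_cols[[d + 1L]], drop = FALSE] + G_out %*% Wm
  }
  G_zd <- G_full[, layout$slice[[1L]], drop = FALSE]
  G_z <- if (is.null(fw$mz)) G_zd else G_zd * fw$mz
  G_mu <- G_z + beta * fw$mu / n
  G_lv <- G_z * fw$eps * 0.5 * fw$sd_ + beta * 0.5 * (exp(fw$lv) - 1) / n
  g$enc_Wmu <- crossprod(fw$Hd, G_mu)
  g$enc_bmu <- colSums(G_mu)
  g$enc_Wlv <- crossprod(fw$Hd, G_lv)
  g$enc_blv <- colSums(G_lv)
  G_Hd <- G_mu %*% t(par$enc_Wmu) + G_lv %*% t(par$enc_Wlv)
  G_Hr <- if (is.null(fw$mh)) G_Hd else G_Hd * fw$mh
  G_Hpre <- G_Hr * (fw$H_pre > 0)
  g$enc_W1 <- crossprod(X, G_Hpre)
  g$enc_b1 <- colSums(G_Hpre)
  g
}

adamw_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0),
       t = 0L)
}

# decoupled weight decay (AdamW); decay applies to weight matrices only
adamw_step <- function(par, grad, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grad)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grad[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grad[[nm]]^2
    step <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    wd <- if (grepl("_W", nm)) weight_decay else 0
    par[[nm]] <- par[[nm]] - lr * (step + wd * par[[nm]])
  }
  list(par = par, state = state)
}

pv_clamp <- function(par, masks, layout) {
  for (d in seq_len(layout$D)) {
    nm <- paste0("dec_W", d)
    par[[nm]] <- pmax(par[[nm]], 0) * masks$decoder[[d]]
  }
  par$rec_W <- pmax(par$rec_W, 0) * masks$reconstruction
  par
}

#' Align an expression matrix to a model's gene list
#'
#' Keeps genes shared with \code{genes}, zero-fills ontology genes missing
#' from the data and drops data genes unknown to the ontology, reporting
#' both counts.
#'
#' @param x Samples x genes numeric matrix with gene colnames.
#' @param genes Ordered character vector of model genes.
#' @param quiet Suppress the alignment message.
#' @return Samples x \code{length(genes)} matrix, columns in \code{genes}
#'   order.
#' @export
align_genes <- function(x, genes, quiet = FALSE) {
  if (is.null(colnames(x))) stop("expression matrix must have gene colnames")
  common <- intersect(genes, colnames(x))
  if (length(common) == 0L) stop("no overlap between data genes and model genes")
  out <- matrix(0, nrow(x), length(genes),
                dimnames = list(rownames(x), genes))
  out[, common] <- x[, common]
  n_fill <- length(genes) - length(common)
  n_drop <- ncol(x) - length(common)
  if (!quiet && (n_fill > 0 || n_drop > 0)) {
    message("align_genes: zero-filled ", n_fill,
            " missing gene(s), dropped ", n_drop, " unknown gene(s)")
  }
  out
}

#' Fit an ontology-guided variational autoencoder
#'
#' Couples a one-hidden-layer non-linear encoder to a linear decoder whose
#' sparsity pattern mirrors a trimmed ontology: the latent space holds the
#' depth-0 terms (k neurons per term), each decoder layer holds the terms
#' of one depth, connections exist only along parent-to-child edges and
#' from terms to their directly annotated genes, and all decoder weights
#' are constrained to be non-negative so that neuron activations can be
#' read as pathway activities.  Skip concatenation passes every earlier
#' layer's output to each later layer, which is how edges that jump depth
#' levels are realized.
#'
#' Training maximizes the evidence lower bound with a Gaussian (mean
#' squared error) reconstruction term and the closed-form KL divergence of
#' the diagonal-Gaussian posterior from the standard-normal prior, weighted
#' by \code{beta}.  The optimizer is AdamW; after every optimizer step the
#' decoder weights are clamped at zero and re-masked, so the constraints
#' hold exactly throughout training.  Samples are split into training and
#' validation sets and the parameter snapshot with the lowest validation
#' loss (evaluated deterministically, at the posterior mean with dropout
#' off) is returned; ties go to the earliest epoch.
#'
#' @param x Samples x genes expression matrix (non-negative, log-scale),
#'   with gene colnames.  Genes are aligned to \code{ontology$genes}
#'   (missing ones zero-filled, extra ones dropped, both reported).
#' @param ontology A \code{trimmed_ontology}.
#' @param k Neurons per ontology term (default 3).
#' @param hidden_dim Width of the encoder hidden layer (default 512).
#' @param dropout_hidden Dropout rate in the encoder hidden layer
#'   (default 0.2, training only).
#' @param dropout_latent Dropout rate on the sampled latent vector
#'   (default 0.5, training only).
#' @param beta Weight of the KL term in the loss (default 1e-4).
#' @param learning_rate AdamW learning rate (default 1e-4).
#' @param weight_decay AdamW decoupled weight decay (default 0.01,
#'   weights only).
#' @param batch_size Minibatch size (default 128).
#' @param epochs Maximum training epochs (default 300); \code{epochs = 0}
#'   returns the initialized, untrained model.
#' @param validation_fraction Fraction of samples held out for validation
#'   (default 0.2).
#' @param seed Integer seed controlling the split, the initialization and
#'   all stochastic training draws.
#' @param verbose Print per-epoch losses.
#' @return An object of class \code{pathvae}; see [predict.pathvae()],
#'   [activities()], [screen_genes()].
#' @export
pathvae <- function(x, ontology, k = 3, hidden_dim = 512,
                    dropout_hidden = 0.2, dropout_latent = 0.5,
                    beta = 1e-4, learning_rate = 1e-4, weight_decay = 0.01,
                    batch_size = 128, epochs = 300,
                    validation_fraction = 0.2, seed = 1, verbose = FALSE) {
  stopifnot(inherits(ontology, "trimmed_ontology"),
            k >= 1, hidden_dim >= 1,
            dropout_hidden >= 0, dropout_hidden < 1,
            dropout_latent >= 0, dropout_latent < 1,
            beta >= 0, learning_rate > 0, batch_size >= 1, epochs >= 0,
            validation_fraction > 0, validation_fraction < 1)
  spec <- list(k = as.integer(k), hidden_dim = as.integer(hidden_dim),
               dropout_hidden = dropout_hidden, dropout_latent = dropout_latent,
               beta = beta, learning_rate = learning_rate,
               weight_decay = weight_decay, batch_size = as.integer(batch_size),
               epochs = as.integer(epochs),
               validation_fraction = validation_fraction,
               seed = as.integer(seed), input_genes = ontology$genes)
  X <- align_genes(x, ontology$genes)
  if (nrow(X) < 2 && epochs > 0) stop("need at least 2 samples to train")
  masks <- build_masks(ontology, k)
  layout <- decoder_layout(ontology, k)
  set.seed(seed)
  par <- pv_init_params(length(ontology$genes), hidden_dim, layout, masks)
  par <- pv_clamp(par, masks, layout)
  model <- structure(list(
    spec = spec, ontology = ontology, masks = masks, layout = layout,
    params = par, history = NULL, best_epoch = NA_integer_, x = X,
    trained = FALSE), class = "pathvae")
  if (epochs == 0) return(model)

  n <- nrow(X)
  n_val <- max(1L, round(validation_fraction * n))
  if (n_val >= n) stop("validation split leaves no training samples")
  perm <- sample.int(n)
  val_idx <- perm[seq_len(n_val)]
  train_idx <- perm[-seq_len(n_val)]
  Xtr <- X[train_idx, , drop = FALSE]
  Xval <- X[val_idx, , drop = FALSE]

  opt <- adamw_init(par)
  best <- list(loss = Inf, par = par, epoch = NA_integer_)
  hist <- data.frame(epoch = seq_len(epochs), train_loss = NA_real_,
                     val_loss = NA_real_, min_decoder_weight = NA_real_,
                     max_masked_abs = NA_real_)
  dec_names <- pv_decoder_weight_names(layout)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(nrow(Xtr))
    batch_losses <- numeric(0)
    for (b0 in seq(1L, nrow(Xtr), by = batch_size)) {
      idx <- ord[seq.int(b0, min(b0 + batch_size - 1L, nrow(Xtr)))]
      Xb <- Xtr[idx, , drop = FALSE]
      fw <- pv_forward(par, masks, layout, Xb, training = TRUE, spec = spec)
      parts <- pv_loss_parts(fw, Xb, beta)
      if (!is.finite(parts$loss)) stop("non-finite loss at epoch ", ep)
      batch_losses <- c(batch_losses, parts$loss)
      grad <- pv_backward(par, masks, layout, Xb, fw, beta, spec)
      upd <- adamw_step(par, grad, opt, learning_rate, weight_decay)
      par <- pv_clamp(upd$par, masks, layout)
      opt <- upd$state
    }
    fv <- pv_forward(par, masks, layout, Xval, training = FALSE, spec = spec)
    val_loss <- pv_loss_parts(fv, Xval, beta)$loss
    hist$train_loss[ep] <- mean(batch_losses)
    hist$val_loss[ep] <- val_loss
    hist$min_decoder_weight[ep] <- min(vapply(dec_names, function(nm) min(par[[nm]]), 1))
    hist$max_masked_abs[ep] <- max(vapply(dec_names, function(nm) {
      M <- if (nm == "rec_W") masks$reconstruction else
        masks$decoder[[as.integer(sub("dec_W", "", nm))]]
      if (all(M == 1)) 0 else max(abs(par[[nm]][M == 0]))
    }, 1))
    if (val_loss < best$loss) best <- list(loss = val_loss, par = par, epoch = ep)
    if (verbose) {
      cat(sprintf("epoch %3d  train %.4f  val %.4f\n",
                  ep, hist$train_loss[ep], val_loss))
    }
  }
  model$params <- best$par
  model$final_params <- par
  model$history <- hist
  model$best_epoch <- best$epoch
  model$val_idx <- val_idx
  model$trained <- TRUE
  model
}

#' Evidence-lower-bound components of a model on a data batch
#'
#' Returns the Gaussian reconstruction loss (mean squared error summed over
#' genes, averaged over samples), the closed-form KL divergence (averaged
#' over samples), the weighted loss minimized in training and the ELBO
#' objective under the sign convention \code{objective = -reconstruction -
#' beta * kl}.
#'
#' @param model A \code{pathvae} model.
#' @param x Samples x genes matrix.
#' @param training Use the stochastic training path (dropout + sampled z)?
#' @param seed Optional seed making the stochastic path reproducible.
#' @return List with \code{reconstruction}, \code{kl}, \code{loss},
#'   \code{objective}.
#' @export
elbo <- function(model, x, training = FALSE, seed = NULL) {
  stopifnot(inherits(model, "pathvae"))
  X <- align_genes(x, model$spec$input_genes, quiet = TRUE)
  if (!is.null(seed)) set.seed(seed)
  fw <- pv_forward(model$params, model$masks, model$layout, X,
                   training = training, spec = model$spec)
  pv_loss_parts(fw, X, model$spec$beta)
}

#' Run the decoder on latent vectors
#'
#' Propagates latent vectors through the masked linear decoder with skip
#' concatenation and returns every term neuron's activation alongside the
#' reconstruction.  No nonlinearity, sampling or dropout is involved, so
#' the map is exactly linear.
#'
#' @param model A \code{pathvae} model.
#' @param z Matrix (samples x latent dim) or a single latent vector.
#' @return List with \code{neurons} (samples x k*terms activation matrix),
#'   \code{term_activities} (samples x terms, k-neuron averages) and
#'   \code{reconstruction} (samples x genes).
#' @export
decode_latent <- function(model, z) {
  stopifnot(inherits(model, "pathvae"))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (ncol(z) != model$layout$latent_dim) {
    stop("latent vector has length ", ncol(z), ", expected ",
         model$layout$latent_dim)
  }
  dec <- pv_decode(model$params, model$masks, model$layout, z)
  act <- dec$full %*% model$layout$avg
  colnames(act) <- model$ontology$terms
  colnames(dec$xhat) <- model$ontology$genes
  list(neurons = dec$full, term_activities = act, reconstruction = dec$xhat)
}
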