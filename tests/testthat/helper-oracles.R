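# Independent brute-force oracles used across the suite.  These never call
# the code paths they are checking.

# longest path from any parentless node, by exhaustive DFS over all paths
oracle_longest_path <- function(terms, edges) {
  pm <- setNames(vector("list", length(terms)), terms)
  if (nrow(edges)) {
    sp <- split(edges[, 1L], edges[, 2L])
    pm[names(sp)] <- sp
  }
  longest <- function(t) {
    ps <- pm[[t]]
    if (length(ps) == 0L) return(0L)
    max(vapply(ps, function(p) longest(p) + 1L, 1L))
  }
  setNames(vapply(terms, longest, 1L), terms)
}

# boolean reachability matrix (strict: u reaches v via >= 1 edge) by
# repeated squaring of the adjacency matrix
oracle_transitive_closure <- function(terms, edges) {
  n <- length(terms)
  A <- matrix(FALSE, n, n, dimnames = list(terms, terms))
  if (nrow(edges)) A[cbind(edges[, 1L], edges[, 2L])] <- TRUE
  R <- A
  repeat {
    R2 <- R | (R %*% A > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

# k-expanded adjacency over the full concatenated neuron space, built by a
# plain edge-list scan; decoder masks are slices of this matrix
oracle_full_adjacency <- function(onto, k) {
  terms <- onto$terms
  width <- k * length(terms)
  block <- function(i) (i - 1L) * k + seq_len(k)
  A <- matrix(0, width, width)
  idx <- setNames(seq_along(terms), terms)
  for (e in seq_len(nrow(onto$edges))) {
    A[block(idx[[onto$edges[e, 2L]]]), block(idx[[onto$edges[e, 1L]]])] <- 1
  }
  A
}

# dense formulation of the linear skip-concatenation decoder:
# full = (I - L)^{-1} (E z + b), with L the masked block strictly-lower-
# triangular weight matrix acting on the concatenated state
oracle_dense_decode <- function(model, Z) {
  layout <- model$layout
  par <- model$params
  masks <- model$masks
  W <- matrix(0, layout$width, layout$width)
  b <- numeric(layout$width)
  for (d in seq_len(layout$D)) {
    W[layout$slice[[d + 1L]], layout$in_cols[[d + 1L]]] <-
      par[[paste0("dec_W", d)]] * masks$decoder[[d]]
    b[layout$slice[[d + 1L]]] <- par[[paste0("dec_b", d)]]
  }
  Zpad <- matrix(0, nrow(Z), layout$width)
  Zpad[, layout$slice[[1L]]] <- Z
  full <- t(solve(diag(layout$width) - W, t(Zpad) + b))
  xhat <- full %*% t(par$rec_W * masks$reconstruction) +
    rep(par$rec_b, each = nrow(Z))
  list(full = full, xhat = xhat)
}

# exact rank-sum p-value by enumerating all group assignments of the
# pooled sample (permutation distribution of the rank sum)
oracle_rank_sum_p <- function(x, y, alternative) {
  pooled <- c(x, y)
  N <- length(pooled)
  n1 <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  e <- n1 * (N + 1) / 2
  sets <- utils::combn(N, n1)
  stat <- apply(sets, 2L, function(id) sum(r[id]))
  switch(alternative,
         greater = mean(stat >= obs),
         less = mean(stat <= obs),
         two.sided = mean(abs(stat - e) >= abs(obs - e) - 1e-12))
}

# exact signed-rank p-value by enumerating all sign assignments of the
# nonzero differences
oracle_signed_rank_p <- function(pre, post, alternative) {
  d <- post - pre
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  stat <- as.vector(signs %*% r)
  e <- m * (m + 1) / 4
  switch(alternative,
         greater = mean(stat >= obs),
         less = mean(stat <= obs),
         two.sided = mean(abs(stat - e) >= abs(obs - e) - 1e-12))
}

# hypergeometric upper-tail p by enumerating all draws of the hit set
oracle_hypergeom_p <- function(n_bg, n_term, n_hits, overlap) {
  draws <- utils::combn(n_bg, n_hits)
  in_term <- draws <= n_term          # label genes 1..n_term as term genes
  mean(colSums(in_term) >= overlap)
}

# random sparse DAG (parent always earlier in term order) for oracle tests
random_dag <- function(n, p_edge = 0.15, seed = 1) {
  set.seed(seed)
  terms <- sprintf("N%03d", seq_len(n))
  edges <- NULL
  for (i in seq_len(n)[-1L]) {
    n_par <- min(i - 1L, 1L + stats::rbinom(1L, 1L, p_edge))
    ps <- sample(terms[seq_len(i - 1L)], n_par)
    edges <- rbind(edges, cbind(parent = ps, child = terms[i]))
  }
  if (is.null(edges)) edges <- matrix(character(0), 0, 2,
                                      dimnames = list(NULL, c("parent", "child")))
  genes <- sprintf("G%03d", seq_len(2L * n))
  ann <- setNames(lapply(seq_len(n), function(i) {
    sort(sample(genes, sample(1:4, 1L)))
  }), terms)
  pathvae:::new_ontology_graph(terms, edges, ann)
}
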