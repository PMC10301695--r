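# Shared fixtures, built in code.

# toy DAG: A is parent of B and C; D is child of both B and C
toy_graph <- function() {
  edges <- rbind(c("A", "B"), c("A", "C"), c("B", "D"), c("C", "D"))
  colnames(edges) <- c("parent", "child")
  pathvae:::new_ontology_graph(
    c("A", "B", "C", "D"), edges,
    list(A = "g1", B = c("g2", "g3"), C = c("g3", "g4"), D = "g5"))
}

# two-term chain P -> C with one gene each, handy for pencil-and-paper
# forward passes at k = 1
chain_ontology <- function() {
  edges <- rbind(c("P", "C"))
  colnames(edges) <- c("parent", "child")
  g <- pathvae:::new_ontology_graph(c("P", "C"), edges,
                                    list(P = "gP", C = "gC"))
  trim_ontology(g, bottom = 1, top = 10)
}

# untrained chain model with every weight overwritten by hand
hand_chain_model <- function() {
  onto <- chain_ontology()
  x <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(c("s1", "s2"), c("gP", "gC")))
  m <- pathvae(x, onto, k = 1, hidden_dim = 2, epochs = 0, seed = 1,
               dropout_hidden = 0, dropout_latent = 0)
  m$params$dec_W1 <- matrix(2)        # C neuron = 2 * P neuron
  m$params$dec_b1 <- 0.5
  # gene rows are sorted (gC, gP); term columns are (P, C)
  m$params$rec_W <- matrix(c(0, 1, 3, 0), 2, 2) * m$masks$reconstruction
  m$params$rec_b <- c(0.1, 0.2)
  m
}

# small trained model on synthetic data, trained once per session
.fixture_env <- new.env()
trained_toy_model <- function() {
  if (is.null(.fixture_env$model)) {
    spec <- synthetic_spec(n_terms = 16, max_depth = 3, n_genes = 50,
                           genes_per_term_range = c(3, 5), n_samples = 120,
                           noise_sd = 0.5, seed = 11)
    g <- simulate_ontology(spec)
    sim <- simulate_expression(g, spec)
    onto <- trim_ontology(g, bottom = 3, top = 30)
    .fixture_env$sim <- sim
    .fixture_env$onto <- onto
    .fixture_env$model <- pathvae(sim$data, onto, k = 3, hidden_dim = 64,
                                  epochs = 60, batch_size = 32, seed = 2)
  }
  list(model = .fixture_env$model, sim = .fixture_env$sim,
       onto = .fixture_env$onto)
}
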