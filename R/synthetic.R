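#' Specification for synthetic ontology + expression data
#'
#' Bundles the parameters of the seeded generator used to validate the
#' whole pipeline without external downloads: a random single-root term
#' DAG with per-term gene annotations, and expression in which each gene
#' is a noisy non-negative combination of latent term activities.
#'
#' @param n_terms Number of ontology terms (>= max_depth + 1).
#' @param max_depth Maximum term depth (root has depth 0).
#' @param n_genes Size of the gene pool terms draw their annotations from.
#' @param genes_per_term_range Integer range (min, max) of genes directly
#'   annotated per term.
#' @param n_samples Number of samples to simulate.
#' @param n_groups Number of sample groups (1 = no group structure).
#' @param effect_size Activity shift added to one signal term (and hence
#'   propagated to its descendants) in every group beyond the first.
#' @param noise_sd Standard deviation of the Gaussian gene-level noise.
#' @param seed Integer seed; every draw in the generator flows from it.
#' @return A list of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_terms = 50, max_depth = 4, n_genes = 300,
                           genes_per_term_range = c(4, 8), n_samples = 500,
                           n_groups = 1, effect_size = 0, noise_sd = 0.5,
                           seed = 1) {
  stopifnot(n_terms >= max_depth + 1, max_depth >= 0, n_genes >= 1,
            length(genes_per_term_range) == 2,
            genes_per_term_range[1] >= 1,
            genes_per_term_range[2] >= genes_per_term_range[1],
            n_samples >= 1, n_groups >= 1, effect_size >= 0, noise_sd > 0)
  structure(list(n_terms = as.integer(n_terms), max_depth = as.integer(max_depth),
                 n_genes = as.integer(n_genes),
                 genes_per_term_range = as.integer(genes_per_term_range),
                 n_samples = as.integer(n_samples), n_groups = as.integer(n_groups),
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Simulate a random annotated ontology DAG
#'
#' Generates a single-root DAG: every non-root term receives one parent
#' one depth above it (which pins its longest-path depth) and, with
#' probability 0.4, a second parent at any strictly smaller depth.  Each
#' term is annotated with a uniform number of genes drawn from the shared
#' gene pool, so genes may be annotated to several terms.
#'
#' @param spec A [synthetic_spec()].
#' @return An annotated \code{ontology_graph}.
#' @export
simulate_ontology <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_terms
  terms <- sprintf("T%04d", seq_len(n))
  depth <- integer(n)
  if (spec$max_depth > 0 && n > 1) {
    # pin one term per depth so every layer is occupied, then assign the
    # rest uniformly over 1..max_depth
    pinned <- 2L:(spec$max_depth + 1L)
    depth[pinned] <- seq_len(spec$max_depth)
    rest <- setdiff(seq_len(n), c(1L, pinned))
    if (length(rest)) {
      depth[rest] <- sample.int(spec$max_depth, length(rest), replace = TRUE)
    }
  }
  edges <- NULL
  for (i in seq_len(n)[-1L]) {
    d <- depth[i]
    above <- which(depth == d - 1L)
    p1 <- terms[above[sample.int(length(above), 1L)]]
    ps <- p1
    lower <- which(depth < d)
    lower <- setdiff(lower, match(p1, terms))
    if (length(lower) && stats::runif(1) < 0.4) {
      ps <- c(ps, terms[lower[sample.int(length(lower), 1L)]])
    }
    edges <- rbind(edges, cbind(parent = ps, child = terms[i]))
  }
  if (is.null(edges)) edges <- matrix(character(0), 0, 2,
                                      dimnames = list(NULL, c("parent", "child")))
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  rng <- spec$genes_per_term_range
  ann <- stats::setNames(lapply(seq_len(n), function(i) {
    ng <- if (rng[1] == rng[2]) rng[1] else sample(seq.int(rng[1], rng[2]), 1L)
    sort(sample(genes, min(ng, spec$n_genes)))
  }), terms)
  new_ontology_graph(terms, edges, ann)
}

#' Simulate expression driven by latent term activities
#'
#' Each sample draws a half-normal activity for the root; every other
#' term's activity is a positively weighted average of its parents'
#' activities plus a half-normal innovation of its own, so the stored
#' per-term ground truth is informative for every term.  A gene's value is
#' the positively weighted sum of the activities of the terms it is
#' annotated to, plus Gaussian noise, truncated at zero (mimicking
#' non-negative log-scale expression).  With \code{n_groups > 1} and a
#' positive \code{effect_size}, one depth-1 "signal term" has the shift
#' added for every group beyond the first before propagation, so the
#' effect cascades through that branch.
#'
#' @param graph An annotated \code{ontology_graph} from [simulate_ontology()].
#' @param spec The same [synthetic_spec()].
#' @return List with \code{data} (samples x genes matrix),
#'   \code{activities} (samples x terms ground-truth matrix),
#'   \code{labels} (group factor) and \code{signal_term} (NA when no group
#'   structure was requested).
#' @export
simulate_expression <- function(graph, spec) {
  stopifnot(inherits(graph, "ontology_graph"), inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1000003L)
  n <- spec$n_samples
  terms <- topo_sort_terms(graph$terms, graph$edges)
  pm <- parents_map(graph)
  labels <- factor(rep(seq_len(spec$n_groups), length.out = n))
  depth <- compute_depths(graph$edges, graph$terms)
  signal_term <- NA_character_
  if (spec$n_groups > 1 && spec$effect_size > 0) {
    d1 <- sort(graph$terms[depth == min(depth[depth > 0])])
    signal_term <- d1[1L]
  }
  act <- matrix(0, n, length(graph$terms),
                dimnames = list(sprintf("s%04d", seq_len(n)), graph$terms))
  for (t in terms) {
    p <- pm[[t]]
    a <- if (length(p) == 0L) {
      2 * abs(stats::rnorm(n))
    } else {
      base <- if (length(p) == 1L) act[, p] else rowMeans(act[, p, drop = FALSE])
      0.6 * base + abs(stats::rnorm(n, sd = 0.5))
    }
    if (!is.na(signal_term) && t == signal_term) {
      a <- a + spec$effect_size * (as.integer(labels) > 1L)
    }
    act[, t] <- a
  }
  genes <- sort(unique(unlist(graph$annotations)))
  x <- matrix(0, n, length(genes),
              dimnames = list(rownames(act), genes))
  # fixed positive term->gene weights
  for (t in graph$terms) {
    gs <- graph$annotations[[t]]
    if (!length(gs)) next
    w <- stats::runif(length(gs), 0.5, 1.5)
    x[, gs] <- x[, gs] + act[, t] %o% w
  }
  x <- x + matrix(stats::rnorm(n * length(genes), sd = spec$noise_sd), n)
  x <- pmax(x, 0)
  list(data = x, activities = act, labels = labels, signal_term = signal_term)
}

#' Simulate a single-driver-gene scenario
#'
#' Constructs a small two-branch ontology in which one branch's learnable
#' signal is carried exclusively by a single driver gene: the driver
#' tracks the branch-root activity almost noiselessly, while the other
#' genes annotated in that branch are pure noise.  The sibling branch
#' behaves like a regular [simulate_expression()] branch.  Knocking out
#' the driver is then the only input perturbation that can move the
#' branch's activity, which makes the scenario a ground truth for
#' perturbation screens.
#'
#' @param n_samples Number of samples.
#' @param genes_per_branch Number of ordinary genes annotated per branch.
#' @param seed Integer seed.
#' @return List with \code{graph} (annotated \code{ontology_graph}),
#'   \code{data}, \code{activities}, \code{driver_gene}, \code{branch_terms}
#'   (the driven branch, including its depth-1 root) and
#'   \code{other_terms}.
#' @export
simulate_driver_scenario <- function(n_samples = 150, genes_per_branch = 8,
                                     seed = 1) {
  set.seed(seed)
  # root -> branches X, Y; each branch root has a 4-term subtree
  terms <- c("ROOT", "TX00", "TY00",
             sprintf("TX%02d", 1:4), sprintf("TY%02d", 1:4))
  edges <- rbind(
    cbind("ROOT", c("TX00", "TY00")),
    cbind("TX00", c("TX01", "TX02")),
    cbind("TX01", "TX03"), cbind("TX02", "TX04"),
    cbind("TY00", c("TY01", "TY02")),
    cbind("TY01", "TY03"), cbind("TY02", "TY04"))
  colnames(edges) <- c("parent", "child")
  gx <- sprintf("gx%02d", seq_len(genes_per_branch))
  gy <- sprintf("gy%02d", seq_len(genes_per_branch))
  driver <- "gDRV"
  split_genes <- function(g) split(g, rep(1:5, length.out = length(g)))
  sx <- split_genes(gx); sy <- split_genes(gy)
  ann <- list(ROOT = character(0),
              TX00 = c(driver, sx[[1]]), TX01 = sx[[2]], TX02 = sx[[3]],
              TX03 = sx[[4]], TX04 = sx[[5]],
              TY00 = sy[[1]], TY01 = sy[[2]], TY02 = sy[[3]],
              TY03 = sy[[4]], TY04 = sy[[5]])
  graph <- new_ontology_graph(terms, edges, ann)
  n <- n_samples
  act <- matrix(0, n, length(terms), dimnames = list(sprintf("s%04d", seq_len(n)), terms))
  act[, "ROOT"] <- 2 * abs(stats::rnorm(n))
  for (b in c("TX", "TY")) {
    act[, paste0(b, "00")] <- 2 * abs(stats::rnorm(n))
    act[, paste0(b, "01")] <- 0.8 * act[, paste0(b, "00")] + abs(stats::rnorm(n, sd = 0.3))
    act[, paste0(b, "02")] <- 0.8 * act[, paste0(b, "00")] + abs(stats::rnorm(n, sd = 0.3))
    act[, paste0(b, "03")] <- 0.8 * act[, paste0(b, "01")] + abs(stats::rnorm(n, sd = 0.3))
    act[, paste0(b, "04")] <- 0.8 * act[, paste0(b, "02")] + abs(stats::rnorm(n, sd = 0.3))
  }
  genes <- c(driver, gx, gy)
  x <- matrix(0, n, length(genes), dimnames = list(rownames(act), genes))
  x[, driver] <- act[, "TX00"] + stats::rnorm(n, sd = 0.05)
  # X-branch ordinary genes: uninformative noise
  x[, gx] <- abs(matrix(stats::rnorm(n * length(gx), sd = 0.5), n))
  # Y-branch genes: track their terms as usual
  for (t in c("TY00", sprintf("TY%02d", 1:4))) {
    gs <- ann[[t]]
    if (!length(gs)) next
    w <- stats::runif(length(gs), 0.8, 1.2)
    x[, gs] <- x[, gs] + act[, t] %o% w
  }
  x <- pmax(x + matrix(stats::rnorm(length(x), sd = 0.2), n), 0)
  list(graph = graph, data = x, activities = act, driver_gene = driver,
       branch_terms = c("TX00", sprintf("TX%02d", 1:4)),
       other_terms = c("TY00", sprintf("TY%02d", 1:4)))
}

#' Write a synthetic dataset in the package's on-disk formats
#'
#' Emits the OBO file, the two-column annotation TSV, the expression TSV
#' and the ground-truth activity TSV, so fixtures exercise the same
#' readers as real data.
#'
#' @param graph,sim Results of [simulate_ontology()] and
#'   [simulate_expression()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_simulation <- function(graph, sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(obo = file.path(dir, "ontology.obo"),
             annotations = file.path(dir, "annotations.tsv"),
             expression = file.path(dir, "expression.tsv"),
             activities = file.path(dir, "true_activities.tsv"))
  write_obo(graph, paths[["obo"]])
  write_annotations(graph, paths[["annotations"]])
  write_expression(sim$data, paths[["expression"]])
  write_expression(sim$activities, paths[["activities"]])
  paths
}
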