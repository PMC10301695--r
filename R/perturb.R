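#' Define a single-gene perturbation
#'
#' A knockout sets a gene's input value to 0; a stimulation raises it to a
#' fixed positive value for every sample (mimicking drug-induced
#' activation).  Perturbations act on the model input only, one gene at a
#' time.
#'
#' @param gene Gene identifier.
#' @param mode \code{"knockout"} or \code{"stimulate"}.
#' @param value Input value for stimulation (> 0); ignored for knockouts
#'   (always 0).  When \code{NULL}, functions that receive a model default
#'   to the maximum training-data expression rounded up to the next
#'   integer.
#' @return Object of class \code{perturbation}.
#' @export
perturbation <- function(gene, mode = c("knockout", "stimulate"), value = NULL) {
  mode <- match.arg(mode)
  if (mode == "knockout") {
    value <- 0
  } else if (!is.null(value) && value <= 0) {
    stop("stimulation value must be positive")
  }
  structure(list(gene = gene, mode = mode, value = value),
            class = "perturbation")
}

#' @export
print.perturbation <- function(x, ...) {
  cat("perturbation:", x$mode, "of", x$gene,
      if (!is.null(x$value)) paste0("(value ", x$value, ")") else "(default value)",
      "\n")
  invisible(x)
}

resolve_value <- function(p, model) {
  if (!is.null(p$value)) return(p$value)
  if (p$mode == "knockout") return(0)
  ceiling(max(model$x))
}

#' Apply a perturbation to an expression matrix
#'
#' Returns a copy of the matrix with the perturbed gene's column set to
#' the perturbation value for all samples; everything else is untouched.
#'
#' @param x Samples x genes matrix with gene colnames.
#' @param p A [perturbation()] with a resolved \code{value}.
#' @return Perturbed copy of \code{x}.
#' @export
perturb_expression <- function(x, p) {
  stopifnot(inherits(p, "perturbation"))
  if (!p$gene %in% colnames(x)) stop("unknown gene: ", p$gene)
  value <- if (is.null(p$value)) stop("perturbation value unresolved") else p$value
  x[, p$gene] <- value
  x
}

node_activity <- function(model, x, node) {
  if (node %in% model$ontology$terms) {
    activities(model, x)[, node]
  } else if (node %in% model$ontology$genes) {
    reconstruction(model, x)[, node]
  } else {
    stop("unknown node (neither term nor gene): ", node)
  }
}

#' Paired pre/post comparison of one node under a perturbation
#'
#' Computes the node's activity before and after perturbing the input and
#' runs a one-tailed paired Wilcoxon signed-rank test over samples.  For
#' stimulations with \code{exclude_zero_cells = TRUE}, samples whose
#' unperturbed expression of the gene is zero are excluded (they carry no
#' evidence that raising the gene changes anything).  Fewer than 2 usable
#' pairs, or all-zero differences, yield an untestable result (\code{p =
#' NA}) rather than an error.
#'
#' @param model A trained \code{pathvae} model.
#' @param x Samples x genes matrix.
#' @param p A [perturbation()].
#' @param node Term ID (latent/decoder node) or gene ID (reconstruction
#'   node).
#' @param alternative \code{"less"} (activity drops post-perturbation) or
#'   \code{"greater"}.
#' @param exclude_zero_cells Drop zero-expression samples (stimulation
#'   only)?
#' @param pre Optional precomputed pre-perturbation node activities
#'   (vector over all samples of \code{x}), e.g. from a screen.
#' @return One-row data frame: node, gene, mode, statistic (z), p_value,
#'   alternative, n_used.
#' @export
compare_node <- function(model, x, p, node,
                         alternative = c("less", "greater"),
                         exclude_zero_cells = FALSE, pre = NULL) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(model, "pathvae"), inherits(p, "perturbation"))
  if (nrow(x) == 0L) stop("empty data")
  p$value <- resolve_value(p, model)
  if (!p$gene %in% model$ontology$genes) stop("gene not in model input: ", p$gene)
  X <- align_genes(x, model$spec$input_genes, quiet = TRUE)
  keep <- rep(TRUE, nrow(X))
  if (exclude_zero_cells && p$mode == "stimulate") {
    keep <- X[, p$gene] != 0
  }
  if (is.null(pre)) pre <- node_activity(model, X, node)
  post <- node_activity(model, perturb_expression(X, p), node)
  pre_k <- pre[keep]; post_k <- post[keep]
  if (sum(keep) < 2) {
    rt <- list(statistic = NA_real_, p_value = NA_real_, n_pairs = sum(keep))
  } else {
    rt <- signed_rank_test(pre_k, post_k, alternative = alternative)
  }
  data.frame(node = node, gene = p$gene, mode = p$mode,
             statistic = rt$statistic, p_value = rt$p_value,
             alternative = alternative, n_used = rt$n_pairs)
}

#' Screen genes one-by-one at a node
#'
#' Applies the same single-gene perturbation independently to every gene
#' in the list, testing the chosen node each time with a one-tailed paired
#' signed-rank test.  Pre-perturbation activities are computed once and
#' reused.  Results are ranked by ascending p-value, ties broken by
#' descending statistic magnitude then gene ID; untestable genes rank
#' last.
#'
#' @param model A trained \code{pathvae} model.
#' @param x Samples x genes matrix.
#' @param genes Character vector of genes to perturb, or \code{"all"} for
#'   every model gene.
#' @param node Term or gene ID at which to test.
#' @param mode \code{"knockout"} or \code{"stimulate"}.
#' @param value Stimulation value (default: max training expression
#'   rounded up).
#' @param alternative \code{"less"} or \code{"greater"} (post vs pre).
#' @param exclude_zero_cells Drop zero-expression samples (stimulation)?
#' @return Data frame of class \code{perturbation_screen} with columns
#'   gene, statistic, p_value, n_used, rank; sorted by rank.
#' @export
screen_genes <- function(model, x, genes = "all", node,
                         mode = c("knockout", "stimulate"), value = NULL,
                         alternative = c("less", "greater"),
                         exclude_zero_cells = FALSE) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  stopifnot(inherits(model, "pathvae"))
  if (identical(genes, "all")) genes <- model$ontology$genes
  if (length(genes) == 0L) stop("empty gene list")
  if (!all(genes %in% model$ontology$genes)) {
    stop("genes not in model input: ",
         paste(utils::head(setdiff(genes, model$ontology$genes), 5), collapse = ", "))
  }
  X <- align_genes(x, model$spec$input_genes, quiet = TRUE)
  pre <- node_activity(model, X, node)
  rows <- lapply(genes, function(g) {
    p <- perturbation(g, mode, value)
    p$value <- resolve_value(p, model)
    compare_node(model, X, p, node, alternative = alternative,
                 exclude_zero_cells = exclude_zero_cells, pre = pre)
  })
  res <- do.call(rbind, rows)
  ord <- order(res$p_value, -abs(res$statistic), res$gene, na.last = TRUE)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  class(res) <- c("perturbation_screen", "data.frame")
  res
}

#' Term-level, gene-level and ORA analysis of one perturbation
#'
#' Runs the paired one-tailed signed-rank test at every ontology term
#' (latent space and decoder) and at every reconstruction gene, then
#' performs hypergeometric over-representation analysis of each term's
#' descendant gene set within the \code{top_k} most significantly affected
#' genes (background: all model genes), with Benjamini-Hochberg
#' correction.
#'
#' @param model A trained \code{pathvae} model.
#' @param x Samples x genes matrix.
#' @param p A [perturbation()].
#' @param top_k Number of top genes fed into ORA (default 100; capped at
#'   the number of genes with a warning).
#' @param alternative \code{"less"} or \code{"greater"} (post vs pre).
#' @param exclude_zero_cells Drop zero-expression samples (stimulation)?
#' @return List of class \code{perturbation_analysis} with data frames
#'   \code{terms} (term, statistic, p_value, n_used, rank), \code{genes}
#'   (likewise) and \code{ora} (term, overlap, term_size, p_value, fdr),
#'   each sorted by significance.
#' @export
term_and_gene_level_analysis <- function(model, x, p, top_k = 100,
                                         alternative = c("less", "greater"),
                                         exclude_zero_cells = FALSE) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(model, "pathvae"), inherits(p, "perturbation"))
  p$value <- resolve_value(p, model)
  X <- align_genes(x, model$spec$input_genes, quiet = TRUE)
  keep <- rep(TRUE, nrow(X))
  if (exclude_zero_cells && p$mode == "stimulate") keep <- X[, p$gene] != 0
  Xp <- perturb_expression(X, p)
  act_pre <- activities(model, X)[keep, , drop = FALSE]
  act_post <- activities(model, Xp)[keep, , drop = FALSE]
  rec_pre <- reconstruction(model, X)[keep, , drop = FALSE]
  rec_post <- reconstruction(model, Xp)[keep, , drop = FALSE]
  test_cols <- function(pre, post) {
    rows <- lapply(colnames(pre), function(cn) {
      rt <- signed_rank_test(pre[, cn], post[, cn], alternative = alternative)
      data.frame(target = cn, statistic = rt$statistic, p_value = rt$p_value,
                 n_used = rt$n_pairs)
    })
    res <- do.call(rbind, rows)
    res <- res[order(res$p_value, -abs(res$statistic), res$target,
                     na.last = TRUE), , drop = FALSE]
    res$rank <- seq_len(nrow(res))
    rownames(res) <- NULL
    res
  }
  term_tab <- test_cols(act_pre, act_post)
  names(term_tab)[1L] <- "term"
  gene_tab <- test_cols(rec_pre, rec_post)
  names(gene_tab)[1L] <- "gene"
  background <- model$ontology$genes
  if (top_k > length(background)) {
    warning("top_k exceeds the number of genes; capping at ", length(background))
    top_k <- length(background)
  }
  top <- gene_tab$gene[seq_len(top_k)]
  ora_rows <- lapply(model$ontology$terms, function(tm) {
    tg <- intersect(model$ontology$descendant_genes[[tm]], background)
    pv <- if (length(tg)) hypergeom_ora(top, tg, background) else NA_real_
    data.frame(term = tm, overlap = length(intersect(top, tg)),
               term_size = length(tg), p_value = pv)
  })
  ora <- do.call(rbind, ora_rows)
  ora$fdr <- bh_fdr(ora$p_value)
  ora <- ora[order(ora$p_value, -ora$overlap, ora$term, na.last = TRUE), ]
  rownames(ora) <- NULL
  structure(list(terms = term_tab, genes = gene_tab, ora = ora,
                 perturbation = p, alternative = alternative),
            class = "perturbation_analysis")
}

#' @export
print.perturbation_analysis <- function(x, ...) {
  cat("perturbation_analysis:", x$perturbation$mode, "of",
      x$perturbation$gene, "(alternative:", x$alternative, ")\n")
  cat("top terms:\n")
  print(utils::head(x$terms, 5))
  cat("top genes:\n")
  print(utils::head(x$genes, 5))
  invisible(x)
}
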