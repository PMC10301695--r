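#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-group comparison on ranks.  The p-value comes from
#' [stats::wilcox.test()]: the exact null distribution when both groups
#' are small and untied, otherwise the tie-corrected normal approximation.
#' The reported statistic is the centered, standardized rank-sum
#' (a z-score computed with midranks and tie correction), which is 0 for
#' identically distributed ranks.
#'
#' @param x,y Numeric sample vectors (each non-empty).
#' @param alternative \code{"two.sided"}, \code{"greater"} (x tends larger)
#'   or \code{"less"}.
#' @return List of class \code{rank_test} with \code{statistic} (z),
#'   \code{W} (Mann-Whitney U of x), \code{p_value}, \code{alternative},
#'   \code{n1}, \code{n2}.
#' @export
rank_sum_test <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- n1 * n2 / 12 * ((N + 1) - tie_term)
  z <- if (v > 0) (R1 - n1 * (N + 1) / 2) / sqrt(v) else 0
  if (all(c(x, y) == c(x, y)[1L])) {
    p <- 1
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = alternative)$p.value)
  }
  structure(list(statistic = z, W = R1 - n1 * (n1 + 1) / 2, p_value = p,
                 alternative = alternative, n1 = n1, n2 = n2),
            class = "rank_test")
}

#' Paired Wilcoxon signed-rank test
#'
#' Tests paired differences \code{post - pre}.  Zero differences are
#' dropped before ranking (the standard treatment); if every difference is
#' zero the pair set is untestable and \code{p_value} is \code{NA} with
#' \code{untestable = TRUE}.  The p-value comes from
#' [stats::wilcox.test()] (exact for small untied samples, tie-corrected
#' normal approximation with continuity correction otherwise); the
#' statistic reported is the centered, standardized signed-rank sum.
#'
#' @param pre,post Equal-length numeric vectors of paired observations.
#' @param alternative \code{"two.sided"}, \code{"greater"} (post tends
#'   larger than pre) or \code{"less"}.
#' @return List of class \code{rank_test} with \code{statistic} (z),
#'   \code{V} (sum of positive ranks), \code{p_value}, \code{alternative},
#'   \code{n_pairs} (pairs used after zero removal), \code{untestable}.
#' @export
signed_rank_test <- function(pre, post,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(pre) == length(post))
  d <- post - pre
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) {
    return(structure(list(statistic = NA_real_, V = NA_real_,
                          p_value = NA_real_, alternative = alternative,
                          n_pairs = 0L, untestable = TRUE),
                     class = "rank_test"))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- table(r)
  v <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (v > 0) (V - m * (m + 1) / 4) / sqrt(v) else 0
  p <- suppressWarnings(
    stats::wilcox.test(d, alternative = alternative, mu = 0)$p.value)
  structure(list(statistic = z, V = V, p_value = p,
                 alternative = alternative, n_pairs = m, untestable = FALSE),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  lab <- if (!is.null(x$n_pairs)) "signed-rank (paired)" else "rank-sum"
  cat("Wilcoxon", lab, "test\n")
  if (isTRUE(x$untestable)) {
    cat("  untestable: all paired differences are zero\n")
  } else {
    cat("  z =", format(x$statistic, digits = 4),
        " p =", format(x$p_value, digits = 4),
        " alternative:", x$alternative, "\n")
  }
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a thin validated wrapper over
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \code{[0, 1]} (NA allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability of drawing at least the observed overlap between
#' a hit list and a term's gene set when sampling \code{length(hits)} genes
#' from the background without replacement.
#'
#' @param hits Character vector of selected genes (subset of background).
#' @param term_genes Character vector of the term's genes (subset of
#'   background).
#' @param background Character vector, the gene universe.
#' @return P-value in \code{[0, 1]}.
#' @export
hypergeom_ora <- function(hits, term_genes, background) {
  background <- unique(background)
  if (length(background) == 0L) stop("empty background gene set")
  hits <- unique(hits); term_genes <- unique(term_genes)
  if (!all(hits %in% background) || !all(term_genes %in% background)) {
    stop("hits and term genes must be subsets of the background")
  }
  q <- length(intersect(hits, term_genes))
  stats::phyper(q - 1, length(term_genes),
                length(background) - length(term_genes),
                length(hits), lower.tail = FALSE)
}

#' Jaccard similarity of two terms' descendant gene sets
#'
#' Intersection over union of the descendant gene sets; defined as 0 when
#' the union is empty.
#'
#' @param graph An \code{ontology_graph} or \code{trimmed_ontology}.
#' @param a,b Term identifiers.
#' @return Numeric in \code{[0, 1]}.
#' @export
jaccard_similarity <- function(graph, a, b) {
  sa <- descendant_genes(graph, a)
  sb <- descendant_genes(graph, b)
  u <- union(sa, sb)
  if (length(u) == 0L) return(0)
  length(intersect(sa, sb)) / length(u)
}

#' Rank sample groups per term by pairwise activity wins
#'
#' For every term and every ordered pair of groups, a one-sided rank-sum
#' test asks whether the term is more active in the first group; a win at
#' \code{p <= p_cutoff} counts as a hit.  Per term, groups are ranked by
#' hit count (most hits = rank 1, ties broken by group label order).  Per
#' group, terms are sorted by (rank ascending, hits descending, median
#' pairwise z-statistic descending), giving the "top terms" table for that
#' group.
#'
#' @param act Samples x terms activity matrix (term colnames).
#' @param labels Group label per sample (factor or character).  Groups with
#'   fewer than 2 samples are excluded with a warning.
#' @param p_cutoff Hit threshold on the uncorrected one-sided p-value
#'   (default 0.05).
#' @return Object of class \code{term_ranking}: list with \code{table}
#'   (long data frame: term, group, hits, rank, median_statistic) and
#'   \code{by_group} (named list of per-group sorted data frames).
#' @export
rank_terms_for_groups <- function(act, labels, p_cutoff = 0.05) {
  labels <- as.factor(labels)
  stopifnot(nrow(act) == length(labels))
  sizes <- table(labels)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding group(s) with < 2 samples: ", paste(small, collapse = ", "))
    keep <- !(labels %in% small)
    act <- act[keep, , drop = FALSE]
    labels <- droplevels(labels[keep])
  }
  groups <- levels(labels)
  if (length(groups) < 2) stop("need at least 2 groups with >= 2 samples")
  terms <- colnames(act)
  rows <- list()
  for (tm in terms) {
    hits <- stats::setNames(integer(length(groups)), groups)
    med <- stats::setNames(numeric(length(groups)), groups)
    for (g in groups) {
      zs <- numeric(0)
      for (h in setdiff(groups, g)) {
        rt <- rank_sum_test(act[labels == g, tm], act[labels == h, tm],
                            alternative = "greater")
        zs <- c(zs, rt$statistic)
        if (!is.na(rt$p_value) && rt$p_value <= p_cutoff) {
          hits[g] <- hits[g] + 1L
        }
      }
      med[g] <- stats::median(zs)
    }
    rk <- integer(length(groups))
    rk[order(-hits, seq_along(groups))] <- seq_along(groups)
    rows[[tm]] <- data.frame(term = tm, group = groups, hits = unname(hits),
                             rank = rk, median_statistic = unname(med))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  by_group <- lapply(groups, function(g) {
    sub <- tab[tab$group == g, , drop = FALSE]
    sub <- sub[order(sub$rank, -sub$hits, -sub$median_statistic), ]
    rownames(sub) <- NULL
    sub
  })
  names(by_group) <- groups
  structure(list(table = tab, by_group = by_group, groups = groups,
                 p_cutoff = p_cutoff),
            class = "term_ranking")
}

#' @export
print.term_ranking <- function(x, ...) {
  cat("term_ranking:", length(unique(x$table$term)), "terms x",
      length(x$groups), "groups (hit cutoff p <=", x$p_cutoff, ")\n")
  invisible(x)
}
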