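#' Parse an OBO ontology file
#'
#' Reads an OBO 1.2/1.4 flat file and returns the term DAG restricted to
#' \code{is_a} relationships.  Other relationship types (\code{part_of},
#' \code{regulates}, ...) are deliberately ignored: only subsumption edges
#' carry the parent/child semantics the masked decoder relies on.  Obsolete
#' terms are dropped, as are edges pointing at terms outside the retained
#' set (e.g. after namespace filtering).
#'
#' @param path Path to an OBO file.
#' @param namespace Optional namespace filter, e.g. \code{"biological_process"};
#'   only terms whose \code{namespace:} tag matches are kept.
#' @return An object of class \code{ontology_graph}: a list with
#'   \code{terms} (ordered character vector), \code{edges} (two-column
#'   character matrix, columns \code{parent}, \code{child}),
#'   \code{annotations} (named list term -> character vector of genes,
#'   empty at this stage) and \code{term_names} (named character vector).
#' @seealso [parse_annotations()], [trim_ontology()]
#' @export
parse_obo <- function(path, namespace = NULL) {
  if (!file.exists(path)) {
    stop("cannot read OBO file: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  # stanza boundaries
  starts <- grep("^\\[", lines)
  if (length(starts) == 0L) {
    stop("no stanzas found in OBO file: ", path)
  }
  ends <- c(starts[-1L] - 1L, length(lines))
  ids <- character(0)
  nms <- character(0)
  parent_of <- list()  # child id -> character vector of parents
  for (s in seq_along(starts)) {
    if (lines[starts[s]] != "[Term]") next
    block <- lines[seq.int(starts[s], ends[s])]
    tag_val <- function(tag) {
      hit <- grep(paste0("^", tag, ": "), block, value = TRUE)
      sub(paste0("^", tag, ": "), "", hit)
    }
    id <- tag_val("id")
    if (length(id) != 1L) next
    if (any(grepl("^is_obsolete: *true", block))) next
    if (!is.null(namespace)) {
      ns <- tag_val("namespace")
      if (length(ns) == 0L || ns[1L] != namespace) next
    }
    nm <- tag_val("name")
    is_a <- tag_val("is_a")
    # strip trailing "! comment" and whitespace
    is_a <- trimws(sub("!.*$", "", is_a))
    ids <- c(ids, id)
    nms <- c(nms, if (length(nm)) nm[1L] else id)
    if (length(is_a)) parent_of[[id]] <- is_a
  }
  if (length(ids) == 0L) {
    stop("no (matching) [Term] stanzas in OBO file: ", path)
  }
  edges <- do.call(rbind, lapply(names(parent_of), function(ch) {
    p <- parent_of[[ch]]
    p <- p[p %in% ids]   # drop edges to filtered/obsolete terms
    if (length(p) == 0L) return(NULL)
    cbind(parent = p, child = ch)
  }))
  if (is.null(edges)) edges <- matrix(character(0), 0, 2,
                                      dimnames = list(NULL, c("parent", "child")))
  names(nms) <- ids
  g <- new_ontology_graph(ids, edges, stats::setNames(vector("list", length(ids)), ids), nms)
  # validation (errors on cycles, naming one member)
  topo_sort_terms(g$terms, g$edges)
  g
}

new_ontology_graph <- function(terms, edges, annotations, term_names = NULL) {
  annotations <- annotations[names(annotations) %in% terms]
  missing <- setdiff(terms, names(annotations))
  if (length(missing)) {
    annotations <- c(annotations, stats::setNames(vector("list", length(missing)), missing))
  }
  annotations <- annotations[terms]
  annotations <- lapply(annotations, function(g) sort(unique(as.character(g))))
  if (is.null(term_names)) term_names <- stats::setNames(terms, terms)
  if (nrow(edges)) {
    bad <- !(edges[, 1L] %in% terms & edges[, 2L] %in% terms)
    if (any(bad)) stop("edge references unknown term: ",
                       paste(unique(c(edges[bad, ])), collapse = ", "))
    edges <- edges[!duplicated(paste(edges[, 1L], edges[, 2L])), , drop = FALSE]
  }
  structure(list(terms = terms, edges = edges, annotations = annotations,
                 term_names = term_names),
            class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  n_ann <- sum(lengths(x$annotations) > 0)
  cat("ontology_graph:", length(x$terms), "terms,", nrow(x$edges), "is_a edges,",
      n_ann, "terms with direct annotations,",
      length(unique(unlist(x$annotations))), "genes\n")
  invisible(x)
}

# Kahn topological sort; stops with one cycle member named on failure.
topo_sort_terms <- function(terms, edges) {
  n <- length(terms)
  idx <- stats::setNames(seq_len(n), terms)
  indeg <- integer(n)
  children <- vector("list", n)
  if (nrow(edges)) {
    pi <- idx[edges[, 1L]]
    ci <- idx[edges[, 2L]]
    for (e in seq_along(pi)) {
      children[[pi[e]]] <- c(children[[pi[e]]], ci[e])
      indeg[ci[e]] <- indeg[ci[e]] + 1L
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (w in children[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) < n) {
    member <- terms[which(indeg > 0L)[1L]]
    stop("ontology graph contains a cycle involving term ", member)
  }
  terms[out]
}

#' Parse gene annotations (GAF or two-column TSV)
#'
#' Reads a term-to-gene annotation table.  GAF 2.1/2.2 files (17 columns,
#' comment lines starting with \code{!}) use column 2 as the gene symbol,
#' column 4 as the qualifier and column 5 as the term ID; rows carrying a
#' \code{NOT} qualifier are excluded.  Generic two-column TSVs are read as
#' (term, gene) pairs.  Duplicate pairs are collapsed; rows with empty
#' fields are dropped with a reported count.
#'
#' @param path Path to the annotation file.
#' @param format One of \code{"auto"}, \code{"gaf"}, \code{"tsv"}.
#' @return Named list mapping term ID to a sorted character vector of genes.
#' @export
parse_annotations <- function(path, format = c("auto", "gaf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (length(lines) == 0L) stop("annotation file has zero parsable rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (format == "auto") {
    format <- if (stats::median(ncols) >= 15) "gaf" else "tsv"
  }
  if (format == "gaf") {
    ok <- ncols >= 5
    rows <- fields[ok]
    qual <- vapply(rows, `[`, "", 4L)
    keep <- !grepl("(^|\\|)NOT($|\\|)", qual)
    gene <- vapply(rows, `[`, "", 2L)[keep]
    term <- vapply(rows, `[`, "", 5L)[keep]
  } else {
    ok <- ncols >= 2
    rows <- fields[ok]
    term <- vapply(rows, `[`, "", 1L)
    gene <- vapply(rows, `[`, "", 2L)
  }
  good <- nzchar(term) & nzchar(gene)
  n_rejected <- sum(!ok) + sum(!good)
  if (n_rejected > 0) {
    message("parse_annotations: rejected ", n_rejected, " malformed row(s)")
  }
  term <- term[good]; gene <- gene[good]
  if (length(term) == 0L) stop("annotation file has zero usable rows: ", path)
  ann <- split(gene, term)
  lapply(ann, function(g) sort(unique(g)))
}

#' Attach direct annotations to an ontology graph
#'
#' @param graph An \code{ontology_graph}.
#' @param annotations Named list term -> gene vector, e.g. from
#'   [parse_annotations()].  Entries for unknown terms are dropped with a
#'   reported count.
#' @return The graph with \code{annotations} filled in.
#' @export
set_annotations <- function(graph, annotations) {
  stopifnot(inherits(graph, "ontology_graph"))
  unknown <- setdiff(names(annotations), graph$terms)
  if (length(unknown)) {
    message("set_annotations: dropping ", length(unknown),
            " annotation term(s) absent from the graph")
    annotations <- annotations[setdiff(names(annotations), unknown)]
  }
  new_ontology_graph(graph$terms, graph$edges, annotations, graph$term_names)
}

# child adjacency list (term -> character vector of children)
children_map <- function(graph) {
  cm <- stats::setNames(vector("list", length(graph$terms)), graph$terms)
  if (nrow(graph$edges)) {
    sp <- split(graph$edges[, 2L], graph$edges[, 1L])
    cm[names(sp)] <- sp
  }
  cm
}

parents_map <- function(graph) {
  pm <- stats::setNames(vector("list", length(graph$terms)), graph$terms)
  if (nrow(graph$edges)) {
    sp <- split(graph$edges[, 1L], graph$edges[, 2L])
    pm[names(sp)] <- sp
  }
  pm
}

#' Descendant gene set of a term
#'
#' The set of genes annotated directly to a term or to any term reachable
#' from it through child edges.  This is the gene-set notion used both for
#' ontology trimming and for over-representation analysis.
#'
#' @param graph An \code{ontology_graph} (or \code{trimmed_ontology}).
#' @param term Term identifier.
#' @return Sorted character vector of gene identifiers.
#' @export
descendant_genes <- function(graph, term) {
  if (inherits(graph, "trimmed_ontology")) {
    if (!term %in% graph$terms) stop("unknown term: ", term)
    return(graph$descendant_genes[[term]])
  }
  stopifnot(inherits(graph, "ontology_graph"))
  if (!term %in% graph$terms) stop("unknown term: ", term)
  all_descendant_genes(graph)[[term]]
}

# all terms' descendant gene sets in one reverse-topological sweep
all_descendant_genes <- function(graph) {
  ord <- topo_sort_terms(graph$terms, graph$edges)
  cm <- children_map(graph)
  sets <- stats::setNames(vector("list", length(graph$terms)), graph$terms)
  for (t in rev(ord)) {
    s <- graph$annotations[[t]]
    for (ch in cm[[t]]) s <- c(s, sets[[ch]])
    sets[[t]] <- sort(unique(s))
  }
  sets
}

#' Longest-path depths in a term DAG
#'
#' Depth of a term is the length of the longest directed path from any
#' parentless term down to it; parentless terms have depth 0.  The depth
#' decides which decoder layer a term occupies.
#'
#' @param edges Two-column matrix (parent, child).
#' @param terms Character vector of term IDs (the node set).
#' @return Named integer vector of depths.
#' @export
compute_depths <- function(edges, terms) {
  ord <- topo_sort_terms(terms, edges)
  depth <- stats::setNames(integer(length(terms)), terms)
  pm <- stats::setNames(vector("list", length(terms)), terms)
  if (nrow(edges)) {
    sp <- split(edges[, 1L], edges[, 2L])
    pm[names(sp)] <- sp
  }
  for (t in ord) {
    p <- pm[[t]]
    depth[t] <- if (length(p)) max(depth[p]) + 1L else 0L
  }
  depth
}

#' Trim an ontology by descendant-gene counts
#'
#' Removes terms whose descendant-gene count (computed on the untrimmed
#' graph) lies outside \code{[bottom, top]}: very generic terms (too many
#' genes, including the root) and very specific ones (too few).  Children
#' of a removed term are rewired to its closest kept ancestors (edge
#' contraction), so ancestry among kept terms is preserved.  Depths are
#' recomputed on the contracted graph; the model's gene list is rebuilt
#' from the direct annotations of kept terms.
#'
#' @param graph An annotated \code{ontology_graph}.
#' @param bottom,top Inclusive bounds on descendant-gene counts
#'   (defaults 30 and 1000).
#' @return An object of class \code{trimmed_ontology} with fields
#'   \code{terms} (ordered by depth, then lexicographically), \code{edges},
#'   \code{depth}, \code{n_layers}, \code{layer_terms}, \code{genes},
#'   \code{annotations} (direct), \code{descendant_genes} (on the trimmed
#'   graph), \code{trim_counts} (original-graph counts of kept terms) and
#'   \code{trim_thresholds}.
#' @export
trim_ontology <- function(graph, bottom = 30, top = 1000) {
  stopifnot(inherits(graph, "ontology_graph"), bottom >= 0, top > bottom)
  sets <- all_descendant_genes(graph)
  counts <- lengths(sets)
  kept <- graph$terms[counts[graph$terms] >= bottom & counts[graph$terms] <= top]
  if (length(kept) == 0L) {
    qs <- stats::quantile(counts, c(0, .25, .5, .75, 1))
    stop("no terms survive trimming with [", bottom, ", ", top,
         "]; descendant-gene count quantiles: ",
         paste(names(qs), round(qs), sep = "=", collapse = ", "))
  }
  keep <- stats::setNames(graph$terms %in% kept, graph$terms)
  pm <- parents_map(graph)
  # contracted parents of a kept term: kept ancestors reachable through
  # removed terms only
  contract_edges <- lapply(kept, function(ch) {
    stack <- pm[[ch]]
    seen <- character(0)
    res <- character(0)
    while (length(stack)) {
      p <- stack[[1L]]; stack <- stack[-1L]
      if (p %in% seen) next
      seen <- c(seen, p)
      if (keep[[p]]) res <- c(res, p) else stack <- c(stack, pm[[p]])
    }
    if (length(res)) cbind(parent = sort(unique(res)), child = ch) else NULL
  })
  edges <- do.call(rbind, contract_edges)
  if (is.null(edges)) edges <- matrix(character(0), 0, 2,
                                      dimnames = list(NULL, c("parent", "child")))
  depth <- compute_depths(edges, kept)
  ord <- kept[order(depth[kept], kept)]
  depth <- depth[ord]
  genes <- sort(unique(unlist(graph$annotations[ord])))
  ann <- graph$annotations[ord]
  sub <- new_ontology_graph(ord, edges, ann, graph$term_names[ord])
  desc <- all_descendant_genes(sub)[ord]
  layer_terms <- split(ord, depth)
  structure(list(
    terms = ord,
    edges = edges,
    depth = depth,
    n_layers = max(depth) + 1L,
    layer_terms = layer_terms,
    genes = genes,
    annotations = ann,
    term_names = graph$term_names[ord],
    descendant_genes = desc,
    trim_counts = counts[ord],
    trim_thresholds = c(bottom = bottom, top = top)
  ), class = "trimmed_ontology")
}

#' @export
print.trimmed_ontology <- function(x, ...) {
  cat("trimmed_ontology:", length(x$terms), "terms in", x$n_layers,
      "layers,", nrow(x$edges), "edges,", length(x$genes), "genes\n")
  cat("  layer sizes:", paste(lengths(x$layer_terms), collapse = ", "), "\n")
  cat("  trim thresholds: [", x$trim_thresholds[["bottom"]], ", ",
      x$trim_thresholds[["top"]], "]\n", sep = "")
  invisible(x)
}

#' Build binary connectivity masks for the decoder
#'
#' For each decoder depth \code{d} in \code{1..D} a mask of shape
#' (k * terms at depth d) x (k * terms at depths < d) carrying a k x k
#' all-ones block wherever a parent -> child edge exists, plus a
#' reconstruction mask of shape genes x (k * all terms) with a 1 x k block
#' where a gene is directly annotated to a term.  Column blocks follow the
#' global term order (ascending depth, lexicographic within a depth), which
#' is also the order in which decoder layer outputs are concatenated.
#'
#' @param onto A \code{trimmed_ontology}.
#' @param k Neurons per term (>= 1; default 3).
#' @return List with \code{decoder} (list of 0/1 matrices, one per depth
#'   1..D; empty when D = 0) and \code{reconstruction} (0/1 matrix).
#' @export
build_masks <- function(onto, k = 3) {
  stopifnot(inherits(onto, "trimmed_ontology"), k >= 1)
  k <- as.integer(k)
  terms <- onto$terms
  depth <- onto$depth
  t_idx <- stats::setNames(seq_along(terms), terms)
  if (nrow(onto$edges)) {
    dp <- depth[onto$edges[, 1L]]
    dc <- depth[onto$edges[, 2L]]
    if (any(dp >= dc)) stop("internal error: edge with depth(parent) >= depth(child)")
  }
  D <- max(depth)
  dec <- list()
  if (D >= 1) {
    for (d in seq_len(D)) {
      rows_t <- terms[depth == d]
      cols_t <- terms[depth < d]        # global order preserved
      M <- matrix(0, nrow = k * length(rows_t), ncol = k * length(cols_t))
      ri <- stats::setNames(seq_along(rows_t), rows_t)
      ci <- stats::setNames(seq_along(cols_t), cols_t)
      sel <- depth[onto$edges[, 2L]] == d
      es <- onto$edges[sel, , drop = FALSE]
      for (e in seq_len(nrow(es))) {
        r0 <- (ri[[es[e, 2L]]] - 1L) * k
        c0 <- (ci[[es[e, 1L]]] - 1L) * k
        M[r0 + seq_len(k), c0 + seq_len(k)] <- 1
      }
      dec[[d]] <- M
    }
  }
  R <- matrix(0, nrow = length(onto$genes), ncol = k * length(terms),
              dimnames = list(onto$genes, NULL))
  for (t in terms) {
    g <- onto$annotations[[t]]
    if (length(g)) {
      c0 <- (t_idx[[t]] - 1L) * k
      R[g, c0 + seq_len(k)] <- 1
    }
  }
  list(decoder = dec, reconstruction = R)
}
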