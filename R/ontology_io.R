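#' Write / read a trimmed ontology as JSON
#'
#' The JSON artifact stores terms, edges, depths, genes, direct
#' annotations, term names and the trim bookkeeping; [read_trimmed_ontology()]
#' restores a bit-identical \code{trimmed_ontology}.
#'
#' @param onto A \code{trimmed_ontology}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_trimmed_ontology <- function(onto, path) {
  stopifnot(inherits(onto, "trimmed_ontology"))
  obj <- list(
    format = "pathvae-trimmed-ontology",
    version = 1L,
    terms = onto$terms,
    edges = if (nrow(onto$edges)) apply(onto$edges, 1L, as.list, simplify = FALSE) else list(),
    depth = as.list(onto$depth),
    genes = onto$genes,
    annotations = onto$annotations,
    term_names = as.list(onto$term_names),
    trim_counts = as.list(onto$trim_counts),
    trim_thresholds = as.list(onto$trim_thresholds)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_trimmed_ontology
#' @export
read_trimmed_ontology <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$format) || obj$format != "pathvae-trimmed-ontology") {
    stop("not a pathvae trimmed-ontology file: ", path)
  }
  terms <- unlist(obj$terms)
  edges <- if (length(obj$edges)) {
    do.call(rbind, lapply(obj$edges, function(e) c(parent = e[[1]], child = e[[2]])))
  } else matrix(character(0), 0, 2, dimnames = list(NULL, c("parent", "child")))
  depth <- stats::setNames(vapply(obj$depth, as.integer, 1L), names(obj$depth))[terms]
  genes <- unlist(obj$genes)
  ann <- lapply(obj$annotations, function(g) sort(unique(unlist(g))))
  ann <- stats::setNames(lapply(terms, function(t) {
    v <- ann[[t]]
    if (is.null(v)) character(0) else v
  }), terms)
  sub <- new_ontology_graph(terms, edges, ann,
                            stats::setNames(unlist(obj$term_names)[terms], terms))
  desc <- all_descendant_genes(sub)[terms]
  structure(list(
    terms = terms,
    edges = edges,
    depth = depth,
    n_layers = max(depth) + 1L,
    layer_terms = split(terms, depth),
    genes = genes,
    annotations = ann,
    term_names = stats::setNames(unlist(obj$term_names)[terms], terms),
    descendant_genes = desc,
    trim_counts = stats::setNames(vapply(obj$trim_counts, as.integer, 1L),
                                  names(obj$trim_counts))[terms],
    trim_thresholds = c(bottom = as.numeric(obj$trim_thresholds$bottom),
                        top = as.numeric(obj$trim_thresholds$top))
  ), class = "trimmed_ontology")
}

#' Write / read connectivity masks in coordinate sparse text form
#'
#' One row per nonzero entry: \code{layer i j} where layer 0 is the
#' reconstruction mask and layers 1..D the decoder masks.  A header line
#' records the dimensions so the round trip is lossless.
#'
#' @param masks Result of [build_masks()].
#' @param path Output TSV file.
#' @return \code{path}, invisibly.
#' @export
write_masks <- function(masks, path) {
  dims <- lapply(c(list(masks$reconstruction), masks$decoder), dim)
  hdr <- paste0("# pathvae-masks v1 dims=",
                paste(vapply(dims, function(d) paste(d, collapse = "x"), ""),
                      collapse = ";"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("layer\ti\tj", con)
  mats <- c(list(masks$reconstruction), masks$decoder)
  for (l in seq_along(mats)) {
    nz <- which(mats[[l]] != 0, arr.ind = TRUE)
    if (nrow(nz)) {
      writeLines(paste(l - 1L, nz[, 1L], nz[, 2L], sep = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname write_masks
#' @export
read_masks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^# pathvae-masks v1 dims=", lines[1L])) {
    stop("not a pathvae mask file: ", path)
  }
  dims <- strsplit(sub("^# pathvae-masks v1 dims=", "", lines[1L]), ";")[[1]]
  dims <- lapply(strsplit(dims, "x"), as.integer)
  tab <- utils::read.delim(text = lines[-1L], header = TRUE)
  mats <- lapply(dims, function(d) matrix(0, d[1L], d[2L]))
  for (l in seq_along(mats)) {
    sel <- tab$layer == (l - 1L)
    if (any(sel)) mats[[l]][cbind(tab$i[sel], tab$j[sel])] <- 1
  }
  list(reconstruction = mats[[1L]], decoder = mats[-1L])
}

#' Write an ontology graph in OBO format
#'
#' Minimal OBO 1.2 writer (id, name, is_a tags) used mainly so that
#' synthetic ontologies exercise the same reader as real ones.
#'
#' @param graph An \code{ontology_graph}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_obo <- function(graph, path) {
  stopifnot(inherits(graph, "ontology_graph"))
  pm <- parents_map(graph)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in graph$terms) {
    writeLines(c("[Term]",
                 paste0("id: ", t),
                 paste0("name: ", graph$term_names[[t]]),
                 paste0("is_a: ", pm[[t]]),
                 ""), con)
  }
  invisible(path)
}

#' Write term-gene annotations as a two-column TSV
#'
#' @param annotations Named list term -> gene vector (or an
#'   \code{ontology_graph}, whose direct annotations are used).
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  if (inherits(annotations, "ontology_graph")) annotations <- annotations$annotations
  rows <- unlist(lapply(names(annotations), function(t) {
    g <- annotations[[t]]
    if (length(g)) paste(t, g, sep = "\t") else character(0)
  }))
  writeLines(rows, path)
  invisible(path)
}

#' Read / write a samples-by-genes expression matrix as delimited text
#'
#' Tab-separated, first column sample IDs, header row gene IDs.  Values are
#' assumed to be non-negative, log-scale continuous expression.
#'
#' @param path File path.
#' @return Numeric matrix with sample rownames and gene colnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, row.names = 1L, check.names = FALSE,
                          comment.char = "#")
  as.matrix(df)
}

#' @rdname read_expression
#' @param x Numeric matrix, samples in rows, genes in columns.
#' @param header_lines Optional character vector written as leading
#'   \code{#} comment lines (provenance).
#' @export
write_expression <- function(x, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  writeLines(paste(c("sample", colnames(x)), collapse = "\t"), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}
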