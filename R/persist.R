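ontology_hash <- function(onto) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(list(terms = onto$terms, edges = onto$edges, genes = onto$genes,
               annotations = onto$annotations, depth = onto$depth),
          tmp, version = 2L, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Save / load a pathvae model checkpoint
#'
#' The checkpoint stores the hyperparameter spec, the weights, the training
#' history and the embedded trimmed ontology together with a content hash
#' of the ontology; loading verifies the format version and the hash, so a
#' corrupted or mismatched checkpoint fails loudly.  A loaded model
#' reproduces [decode_latent()] outputs bit-identically.
#'
#' @param model A \code{pathvae} model.
#' @param path Checkpoint file path.
#' @return \code{path} invisibly for \code{save_pathvae}; the restored
#'   model for \code{load_pathvae}.
#' @export
save_pathvae <- function(model, path) {
  stopifnot(inherits(model, "pathvae"))
  obj <- list(format = "pathvae-checkpoint", version = 1L,
              ontology_hash = ontology_hash(model$ontology),
              model = unclass(model))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_pathvae
#' @export
load_pathvae <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot parse checkpoint file ", path, ": ", conditionMessage(e))
  })
  if (!is.list(obj) || is.null(obj$format) || obj$format != "pathvae-checkpoint") {
    stop("not a pathvae checkpoint: ", path)
  }
  if (obj$version != 1L) {
    stop("unsupported checkpoint version ", obj$version, " (expected 1)")
  }
  model <- structure(obj$model, class = "pathvae")
  if (!identical(ontology_hash(model$ontology), obj$ontology_hash)) {
    stop("ontology hash mismatch in checkpoint ", path)
  }
  model
}
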