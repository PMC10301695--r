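#' Pathway activities of samples under a trained model
#'
#' Runs samples through the encoder deterministically (posterior mean, no
#' sampling, dropout off) and through the masked linear decoder, then
#' averages the k neurons representing each term.  Depth-0 terms therefore
#' report the average of their latent posterior-mean components.  Repeated
#' calls are bit-identical.
#'
#' @param model A \code{pathvae} model.
#' @param x Samples x genes matrix; defaults to the training data.
#' @return Samples x terms numeric matrix (term IDs as colnames).
#' @export
activities <- function(model, x = NULL) {
  stopifnot(inherits(model, "pathvae"))
  if (!isTRUE(model$trained)) {
    warning("model is untrained; activities reflect the initialization")
  }
  if (is.null(x)) x <- model$x
  X <- align_genes(x, model$spec$input_genes, quiet = TRUE)
  fw <- pv_forward(model$params, model$masks, model$layout, X,
                   training = FALSE, spec = model$spec)
  act <- fw$full %*% model$layout$avg
  dimnames(act) <- list(rownames(X), model$ontology$terms)
  act
}

#' Reconstructed gene values of samples under a trained model
#'
#' Same deterministic forward pass as [activities()] but reads out the
#' reconstruction layer.
#'
#' @inheritParams activities
#' @return Samples x genes numeric matrix.
#' @export
reconstruction <- function(model, x = NULL) {
  stopifnot(inherits(model, "pathvae"))
  if (!isTRUE(model$trained)) {
    warning("model is untrained; reconstruction reflects the initialization")
  }
  if (is.null(x)) x <- model$x
  X <- align_genes(x, model$spec$input_genes, quiet = TRUE)
  fw <- pv_forward(model$params, model$masks, model$layout, X,
                   training = FALSE, spec = model$spec)
  dimnames(fw$xhat) <- list(rownames(X), model$ontology$genes)
  fw$xhat
}

#' Write an activity (or reconstruction) matrix as TSV
#'
#' @param act Samples x terms (or genes) matrix.
#' @param path Output file.
#' @param header_lines Optional provenance comment lines.
#' @return \code{path}, invisibly.
#' @export
write_activities <- function(act, path, header_lines = NULL) {
  write_expression(act, path, header_lines = header_lines)
}
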