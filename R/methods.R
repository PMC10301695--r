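#' @export
print.pathvae <- function(x, ...) {
  s <- x$spec
  cat("pathvae model: ", length(x$ontology$terms), " ontology terms in ",
      x$layout$D + 1L, " layers, ", length(s$input_genes), " genes\n", sep = "")
  cat("  latent dim ", x$layout$latent_dim, " (", s$k, " neurons/term), encoder hidden ",
      s$hidden_dim, "\n", sep = "")
  if (isTRUE(x$trained)) {
    cat("  trained ", nrow(x$history), " epochs; best validation loss ",
        format(min(x$history$val_loss), digits = 6), " at epoch ",
        x$best_epoch, "\n", sep = "")
  } else {
    cat("  untrained (initialized only)\n")
  }
  invisible(x)
}

#' @export
summary.pathvae <- function(object, ...) {
  s <- object$spec
  out <- list(
    n_terms = length(object$ontology$terms),
    n_layers = object$layout$D + 1L,
    layer_sizes = lengths(object$ontology$layer_terms),
    n_genes = length(s$input_genes),
    latent_dim = object$layout$latent_dim,
    k = s$k,
    hyperparameters = s[c("hidden_dim", "dropout_hidden", "dropout_latent",
                          "beta", "learning_rate", "weight_decay",
                          "batch_size", "validation_fraction", "seed")],
    trained = isTRUE(object$trained),
    best_epoch = object$best_epoch,
    best_val_loss = if (isTRUE(object$trained)) min(object$history$val_loss) else NA_real_,
    n_parameters = sum(vapply(object$params, length, 1L))
  )
  class(out) <- "summary.pathvae"
  out
}

#' @export
print.summary.pathvae <- function(x, ...) {
  cat("pathvae model summary\n")
  cat("  terms:", x$n_terms, " layers:", x$n_layers,
      "(", paste(x$layer_sizes, collapse = "/"), ")\n")
  cat("  genes:", x$n_genes, " latent dim:", x$latent_dim,
      " neurons/term:", x$k, "\n")
  cat("  parameters:", x$n_parameters, "\n")
  h <- x$hyperparameters
  cat("  encoder hidden:", h$hidden_dim, " dropout:", h$dropout_hidden,
      "/", h$dropout_latent, "(latent)\n")
  cat("  beta:", h$beta, " lr:", h$learning_rate, " batch:", h$batch_size, "\n")
  if (x$trained) {
    cat("  best epoch:", x$best_epoch, " val loss:",
        format(x$best_val_loss, digits = 6), "\n")
  } else cat("  untrained\n")
  invisible(x)
}

#' Decoder coefficients of a fitted model
#'
#' Returns the masked non-negative decoder weights: one matrix per decoder
#' depth (child-term neurons x ancestor-term neurons) and the
#' reconstruction matrix (genes x term neurons).
#'
#' @param object A \code{pathvae} model.
#' @param ... Unused.
#' @return List with \code{decoder} (list of matrices) and
#'   \code{reconstruction}.
#' @export
coef.pathvae <- function(object, ...) {
  dec <- lapply(seq_len(object$layout$D), function(d) {
    object$params[[paste0("dec_W", d)]]
  })
  list(decoder = dec, reconstruction = object$params$rec_W)
}

#' Predict method for pathvae models
#'
#' @param object A \code{pathvae} model.
#' @param newdata Samples x genes matrix; defaults to the training data.
#' @param type \code{"activities"} (samples x terms),
#'   \code{"reconstruction"} (samples x genes) or \code{"latent"}
#'   (samples x latent-dim posterior means).
#' @param ... Unused.
#' @return Numeric matrix.
#' @export
predict.pathvae <- function(object, newdata = NULL,
                            type = c("activities", "reconstruction", "latent"),
                            ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$x
  if (type == "activities") return(activities(object, newdata))
  if (type == "reconstruction") return(reconstruction(object, newdata))
  X <- align_genes(newdata, object$spec$input_genes, quiet = TRUE)
  fw <- pv_forward(object$params, object$masks, object$layout, X,
                   training = FALSE, spec = object$spec)
  rownames(fw$mu) <- rownames(X)
  fw$mu
}

#' @export
fitted.pathvae <- function(object, ...) {
  reconstruction(object, object$x)
}

#' @export
residuals.pathvae <- function(object, ...) {
  object$x - reconstruction(object, object$x)
}

#' Draw new expression profiles from the generative model
#'
#' Samples latent vectors from the standard-normal prior and decodes them,
#' i.e. draws from the model's generative distribution (reconstruction
#' means; no observation noise is added).
#'
#' @param object A \code{pathvae} model.
#' @param nsim Number of samples.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return \code{nsim} x genes matrix.
#' @export
simulate.pathvae <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(stats::rnorm(nsim * object$layout$latent_dim), nsim)
  decode_latent(object, z)$reconstruction
}

#' Plot the training history of a pathvae model
#'
#' @param x A trained \code{pathvae} model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.pathvae <- function(x, ...) {
  if (!isTRUE(x$trained)) stop("model is untrained; nothing to plot")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}
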