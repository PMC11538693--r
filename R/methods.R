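#' @export
print.hgt_fit <- function(x, ...) {
  cat("Heterogeneous graph transformer fit\n")
  cat("Call: "); print(x$call)
  s <- graph_summary(x$graph)
  cat(sprintf("Graph: %d species, %d samples; %d abundance / %d metabolic / %d phylogenetic edges\n",
              s$species, s$samples, s$abundance_edges, s$metabolic,
              s$phylogenetic))
  cat(sprintf("Classes: %s\n", paste(x$labels$classes, collapse = ", ")))
  n <- nrow(x$loss_trace)
  cat(sprintf("Training: %d epochs, final loss %.5f (focal %.5f, kl %.4f)\n",
              n, x$loss_trace$total[n], x$loss_trace$focal[n],
              x$loss_trace$kl[n]))
  cat(sprintf("Training accuracy: %.3f\n", x$accuracy))
  invisible(x)
}

#' @export
summary.hgt_fit <- function(object, ...) {
  cm <- table(truth = object$labels$labels, predicted = object$predicted)
  out <- list(fit = object, confusion = cm,
              class_sizes = table(factor(object$labels$labels,
                                         levels = object$labels$classes)),
              accuracy = object$accuracy,
              control = object$control)
  class(out) <- "summary.hgt_fit"
  out
}

#' @export
print.summary.hgt_fit <- function(x, ...) {
  print(x$fit)
  cat("\nConfusion matrix (transductive):\n")
  print(x$confusion)
  ctl <- x$control
  cat(sprintf("\nModel: d = %d, h = %d heads, L = %d layers, gamma = %g, reg_alpha = %g\n",
              ctl$d, ctl$h, ctl$L, ctl$gamma, ctl$reg_alpha))
  invisible(x)
}

#' Interpretable scalar coefficients of a fit
#'
#' Returns the trained meta-relation priors (`mu`, the adaptive scaling of
#' each source-type/edge-type/target-type attention channel) and the residual
#' gates (`theta`, how much each node type's update relies on aggregated
#' messages versus its previous embedding), per layer.
#'
#' @param object An `"hgt_fit"`.
#' @param ... Unused.
#' @return Data frame with one row per layer x parameter.
#' @export
coef.hgt_fit <- function(object, ...) {
  rows <- lapply(seq_along(object$params$layers), function(l) {
    p <- object$params$layers[[l]]
    data.frame(layer = l,
               parameter = c(paste0("mu.", names(p$mu)),
                             paste0("theta.", names(p$theta))),
               value = c(unname(p$mu), unname(p$theta)))
  })
  do.call(rbind, rows)
}

#' @export
fitted.hgt_fit <- function(object, ...) object$probs

#' Predicted class probabilities or labels
#'
#' The model is transductive (trained on all labelled samples); predictions
#' are the fitted class distribution of the training samples.
#'
#' @param object An `"hgt_fit"`.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Character vector of classes or the N x C probability matrix.
#' @export
predict.hgt_fit <- function(object, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (type == "prob") object$probs else object$predicted
}

#' @export
residuals.hgt_fit <- function(object, ...) {
  object$labels$onehot - object$probs
}

#' Plot the training loss trace
#'
#' @param x An `"hgt_fit"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.hgt_fit <- function(x, ...) {
  tr <- x$loss_trace
  graphics::matplot(tr$epoch, cbind(tr$total, tr$focal),
                    type = "l", lty = 1, col = c("black", "steelblue"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("total", "focal"), lty = 1,
                   col = c("black", "steelblue"), bty = "n")
  invisible(x)
}

#' Export the fitted attention tensor in long format
#'
#' @param fit An `"hgt_fit"` or [attention_tensor()].
#' @param path Output TSV path (`head`, `species_id`, `sample_id`,
#'   `attention`).
#' @return `path`, invisibly.
#' @export
write_attention <- function(fit, path) {
  att <- if (inherits(fit, "hgt_fit")) fit$attention else fit
  stopifnot(inherits(att, "attention_tensor"))
  n_e <- nrow(att$edges)
  df <- data.frame(
    head = rep(seq_len(att$h), each = n_e),
    species_id = rep(att$species_ids[att$edges[, 1L]], att$h),
    sample_id = rep(att$sample_ids[att$edges[, 2L]], att$h),
    attention = as.vector(att$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
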