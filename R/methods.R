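#' @export
print.clic <- function(x, ...) {
  cat("Co-expression partition of", length(x$membership), "query genes over",
      length(x$zdata$dataset_ids), "dataset(s)\n")
  if (x$no_partition) cat("  (partition step disabled: single-CEM ablation)\n")
  cat("  CEMs found:", x$k_hat, "  null genes:", sum(x$membership == 0L), "\n")
  for (k in seq_len(x$k_hat)) {
    lab <- if (x$phi[k] > 1) "strongly co-expressed"
           else if (x$phi[k] > 0.1) "co-expressed" else "weak"
    cat(sprintf("  CEM %d: %d genes, phi = %.2f (%s)\n",
                k, length(x$cems[[k]]), x$phi[k], lab))
  }
  cat(sprintf("  log posterior (unnormalized): %.2f\n", x$log_posterior))
  invisible(x)
}

#' Summarize a fitted co-expression partition
#'
#' @param object A `"clic"` fit.
#' @param n_top Number of top-weighted datasets to report per CEM.
#' @param ... Unused.
#' @return An object of class `"summary.clic"`.
#' @export
summary.clic <- function(object, n_top = 5L, ...) {
  top <- lapply(seq_len(object$k_hat), function(k) {
    w <- object$weights[, k]
    ord <- order(-w)[seq_len(min(n_top, length(w)))]
    data.frame(dataset_id = rownames(object$weights)[ord], weight = w[ord],
               theta_hat = object$theta_hat[ord, k],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  structure(list(fit = object, top_datasets = top), class = "summary.clic")
}

#' @export
print.summary.clic <- function(x, ...) {
  print(x$fit)
  for (k in seq_len(x$fit$k_hat)) {
    cat("\n  CEM", k, "genes:", paste(x$fit$cems[[k]], collapse = ", "), "\n")
    cat("  top-weighted datasets:\n")
    df <- x$top_datasets[[k]]
    for (r in seq_len(nrow(df)))
      cat(sprintf("    %s  p_hat = %.3f  theta_hat = %.2f\n",
                  df$dataset_id[r], df$weight[r], df$theta_hat[r]))
  }
  invisible(x)
}

#' Extract CEM parameter estimates
#'
#' @param object A `"clic"` fit.
#' @param ... Unused.
#' @return List with D x K matrices `theta_hat`, `sigma_sq_hat` and
#'   `weights`, and the vector `phi`.
#' @export
coef.clic <- function(object, ...) {
  list(theta_hat = object$theta_hat, sigma_sq_hat = object$sigma_sq_hat,
       weights = object$weights, phi = object$phi)
}

#' Plot a fitted co-expression partition
#'
#' Left: CEM strengths phi on a log axis with the co-expression (0.1) and
#' strong co-expression (1) reference lines. Right: the dataset-selection
#' weight matrix (datasets x CEMs).
#'
#' @param x A `"clic"` fit.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.clic <- function(x, ...) {
  if (x$k_hat == 0L) {
    warning("no CEMs to plot")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::barplot(pmax(x$phi, 1e-3), names.arg = paste0("CEM", seq_len(x$k_hat)),
                    log = "y", ylab = "CEM strength phi", ...)
  graphics::abline(h = c(0.1, 1), lty = 2, col = "grey40")
  graphics::image(t(x$weights), axes = FALSE, col = grDevices::hcl.colors(25),
                  xlab = "CEM", ylab = "dataset", main = "selection weights")
  graphics::axis(1, at = seq(0, 1, length.out = x$k_hat),
                 labels = seq_len(x$k_hat))
  invisible(x)
}
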