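# Base-graphics diagnostics for fits and PR curves.

#' Plot training curves
#'
#' Loss per epoch and, where evaluated, mAP@0.5 and mAP@0.5:0.95.
#'
#' @param x a "cryolo_fit"
#' @param ... passed to [graphics::plot()]
#' @return invisibly, `x`
#' @export
plot.cryolo_fit <- function(x, ...) {
  m <- x$metrics
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(m$epoch, m$loss, type = "l", xlab = "epoch", ylab = "loss",
       main = "training loss", ...)
  has_map <- !is.na(m$map50)
  if (any(has_map)) {
    plot(m$epoch[has_map], m$map50[has_map], type = "b", pch = 16,
         ylim = c(0, 1), xlab = "epoch", ylab = "mAP",
         main = "validation mAP", col = "steelblue", ...)
    graphics::lines(m$epoch[has_map], m$map50_95[has_map], type = "b",
                    pch = 1, col = "firebrick")
    graphics::legend("bottomright", legend = c("mAP@0.5", "mAP@0.5:0.95"),
                     col = c("steelblue", "firebrick"), pch = c(16, 1),
                     bty = "n")
  }
  invisible(x)
}

#' Plot a precision-recall curve
#'
#' Draws the raw PR points and the integrated precision envelope.
#'
#' @param x a "cryolo_pr" from [average_precision()]
#' @param ... passed to [graphics::plot()]
#' @return invisibly, `x`
#' @export
plot.cryolo_pr <- function(x, ...) {
  plot(c(0, x$recall), c(1, x$precision), type = "s", xlim = c(0, 1),
       ylim = c(0, 1), xlab = "recall", ylab = "precision",
       main = sprintf("PR curve (AP = %.3f)", x$ap), ...)
  env <- rev(cummax(rev(x$precision)))
  graphics::lines(c(0, x$recall), c(if (length(env)) env[1] else 1, env),
                  type = "s", col = "firebrick", lty = 2)
  invisible(x)
}
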