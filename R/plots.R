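#' Plot a derived signal channel with its annotations
#'
#' Time-series plot of one signal-bank channel with the annotated turn (grey)
#' and FOG (red) spans shaded — the quickest way to eyeball whether, e.g., a
#' left-right distance collapses in the turn or heel speed dies during FOG.
#'
#' @param x A \code{derived_signals} object.
#' @param channel Channel name (default the shoulder x-distance).
#' @param ann Optional \code{annotation_track} to shade.
#' @param ... Passed to \code{plot}.
#' @export
plot.derived_signals <- function(x, channel = "pairdiff_shoulders_x",
                                 ann = NULL, ...) {
  stopifnot(channel %in% colnames(x$data))
  v <- x$data[, channel]
  t <- (seq_along(v) - 1) / x$fps
  graphics::plot(t, v, type = "n", xlab = "time (s)", ylab = channel, ...)
  if (!is.null(ann)) {
    shade <- function(iv, col) {
      if (nrow(iv)) for (i in seq_len(nrow(iv)))
        graphics::rect(iv[i, 1] / x$fps, graphics::par("usr")[3],
                       iv[i, 2] / x$fps, graphics::par("usr")[4],
                       col = col, border = NA)
    }
    shade(ann$turn, grDevices::adjustcolor("grey40", 0.2))
    shade(ann$fog, grDevices::adjustcolor("firebrick", 0.2))
  }
  graphics::lines(t, v)
  invisible(x)
}

#' Plot per-fold LOSO metrics
#'
#' Dot plot of the per-fold episode sensitivity and specificity with the
#' pooled values as horizontal lines.
#'
#' @param x A \code{fog_loso} result.
#' @param ... Unused.
#' @export
plot.fog_loso <- function(x, ...) {
  sens <- vapply(x$folds, function(f) f$episode$sensitivity, numeric(1))
  spec <- vapply(x$folds, function(f) f$episode$specificity, numeric(1))
  n <- length(sens)
  graphics::plot(seq_len(n), sens, pch = 19, col = "firebrick", ylim = c(0, 1),
                 xaxt = "n", xlab = "held-out subject",
                 ylab = "episode-level rate", ...)
  graphics::axis(1, at = seq_len(n), labels = names(x$folds), las = 2,
                 cex.axis = 0.7)
  graphics::points(seq_len(n), spec, pch = 17, col = "steelblue")
  graphics::abline(h = x$pooled$episode$sensitivity, col = "firebrick", lty = 2)
  graphics::abline(h = x$pooled$episode$specificity, col = "steelblue", lty = 2)
  graphics::legend("bottomleft", c("sensitivity", "specificity"),
                   pch = c(19, 17), col = c("firebrick", "steelblue"),
                   bty = "n")
  invisible(x)
}
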