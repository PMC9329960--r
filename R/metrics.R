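#' Geometric mean of sensitivity and specificity
#'
#' \code{sqrt(sensitivity * specificity)}; balances the two rates and
#' penalizes imbalanced pairs.
#'
#' @param sensitivity,specificity Rates in [0, 1] (vectorized).
#' @return The geometric mean.
#' @export
geometric_mean <- function(sensitivity, specificity) {
  sqrt(sensitivity * specificity)
}

#' Rank-based AUC with midrank tie handling
#'
#' The probability that a random positive scores above a random negative,
#' computed from the Wilcoxon rank-sum statistic with ties assigned their
#' midrank. Constant scores give 0.5.
#'
#' @param scores Numeric scores, higher means more positive.
#' @param labels Binary truth labels (the larger/second level is positive,
#'   or pass 0/1).
#' @return AUC in [0, 1]; \code{NA} when a class is absent.
#' @export
auc_midrank <- function(scores, labels) {
  y <- as_binary(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Window-level classification metrics
#'
#' Confusion-matrix rates over scored windows; windows with truth label
#' \code{unknown} are excluded. When a truth class is absent the affected
#' rates are \code{NA} and the report is flagged.
#'
#' @param truth Truth labels per window.
#' @param pred Predicted labels per window.
#' @param scores Optional numeric scores for AUC.
#' @param positive Positive class label.
#' @return A \code{fog_metrics} list: sensitivity, specificity, accuracy,
#'   gm, auc, counts (tp, fp, tn, fn) and a \code{degenerate} flag.
#' @export
window_metrics <- function(truth, pred, scores = NULL, positive = "fog") {
  keep <- truth != "unknown"
  truth <- truth[keep]; pred <- pred[keep]
  if (!is.null(scores)) scores <- scores[keep]
  tp <- sum(truth == positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  sens <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  acc <- (tp + tn) / max(1L, length(truth))
  auc <- if (is.null(scores)) NA_real_ else
    auc_midrank(scores, as.integer(truth == positive))
  structure(list(sensitivity = sens, specificity = spec, accuracy = acc,
                 gm = geometric_mean(sens, spec), auc = auc,
                 counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 level = "window", degenerate = is.na(sens) || is.na(spec)),
            class = "fog_metrics")
}

#' Episode-level FOG metrics
#'
#' Event-level scoring of FOG recognition:
#' \itemize{
#'   \item a truth FOG episode counts as detected when at least one
#'     predicted-FOG window's span overlaps it (sensitivity = detected / all
#'     truth FOG episodes);
#'   \item a truth non-FOG episode counts as correct when no predicted-FOG
#'     window falls in it, a window being "in" an episode when its full span
#'     lies inside the episode (specificity = clean / all truth non-FOG
#'     episodes). Containment, not mere overlap, keeps the 2-s windows that
#'     straddle a true FOG boundary — which genuinely contain freezing —
#'     from being charged against the flanking non-FOG episode;
#'   \item accuracy = correct episodes / all episodes; GM as usual.
#' }
#'
#' @param pred_windows Window predictions (\code{subject_id}, \code{test_id},
#'   \code{t_start}, \code{t_end}, \code{fog_pred}).
#' @param truth_eps Truth episode table from \code{\link{truth_episodes}}.
#' @return A \code{fog_metrics} list with episode counts.
#' @export
episode_metrics <- function(pred_windows, truth_eps) {
  fogw <- pred_windows[pred_windows$fog_pred == "fog", , drop = FALSE]
  key_w <- paste(fogw$subject_id, fogw$test_id, sep = "/")
  key_e <- paste(truth_eps$subject_id, truth_eps$test_id, sep = "/")
  tp <- fn <- tn <- fp <- 0L
  for (i in seq_len(nrow(truth_eps))) {
    w <- which(key_w == key_e[i])
    if (truth_eps$label[i] == "fog") {
      hit <- any(fogw$t_start[w] < truth_eps$t_end[i] - 1e-9 &
                   fogw$t_end[w] > truth_eps$t_start[i] + 1e-9)
      if (hit) tp <- tp + 1L else fn <- fn + 1L
    } else {
      inside <- any(fogw$t_start[w] >= truth_eps$t_start[i] - 1e-9 &
                      fogw$t_end[w] <= truth_eps$t_end[i] + 1e-9)
      if (inside) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  sens <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  acc <- (tp + tn) / max(1L, nrow(truth_eps))
  structure(list(sensitivity = sens, specificity = spec, accuracy = acc,
                 gm = geometric_mean(sens, spec), auc = NA_real_,
                 counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 level = "episode", degenerate = is.na(sens) || is.na(spec)),
            class = "fog_metrics")
}

#' @export
print.fog_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "  NA  " else sprintf("%6.2f%%", 100 * v)
  cat(sprintf("<fog_metrics> (%s-level)%s\n", x$level,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  cat(sprintf("  sensitivity %s  specificity %s  accuracy %s  GM %s  AUC %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$accuracy),
              fmt(x$gm), fmt(x$auc)))
  cat(sprintf("  counts: TP %d  FP %d  TN %d  FN %d\n",
              x$counts["tp"], x$counts["fp"], x$counts["tn"], x$counts["fn"]))
  invisible(x)
}

#' Per-subject paired Wilcoxon signed-rank test on a window feature
#'
#' Windowed features are autocorrelated within a subject, so windows are not
#' independent observations. The test therefore first averages the feature
#' within each subject and group, then runs a paired Wilcoxon signed-rank
#' test on the per-subject group means. Subjects missing either group are
#' dropped and counted.
#'
#' @param fm Feature matrix.
#' @param feature Feature column name.
#' @param group_col Label column defining the two groups
#'   (default \code{"fog_label"}).
#' @param groups Character vector of the two group labels
#'   (default \code{c("fog", "nonfog")}).
#' @return List with \code{p_value}, \code{n_pairs}, \code{n_dropped},
#'   \code{statistic} and \code{degenerate} (TRUE when all paired
#'   differences are zero, in which case p = 1).
#' @export
paired_subject_wilcoxon <- function(fm, feature, group_col = "fog_label",
                                    groups = c("fog", "nonfog")) {
  stopifnot(feature %in% names(fm), group_col %in% names(fm))
  g <- fm[[group_col]]
  means <- function(lab) tapply(fm[[feature]][g == lab], fm$subject_id[g == lab],
                                mean)
  a <- means(groups[1]); b <- means(groups[2])
  common <- intersect(names(a), names(b))
  n_dropped <- length(union(names(a), names(b))) - length(common)
  if (length(common) < 5L)
    stop("paired Wilcoxon needs at least 5 subjects with windows in both groups",
         " (got ", length(common), ")")
  d <- a[common] - b[common]
  if (all(d == 0))
    return(list(p_value = 1, n_pairs = length(common), n_dropped = n_dropped,
                statistic = NA_real_, degenerate = TRUE))
  wt <- suppressWarnings(stats::wilcox.test(a[common], b[common], paired = TRUE))
  list(p_value = wt$p.value, n_pairs = length(common), n_dropped = n_dropped,
       statistic = unname(wt$statistic), degenerate = FALSE)
}
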