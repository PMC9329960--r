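#' Merge window predictions into episodes
#'
#' Maximal runs of windows with equal FOG prediction become episodes; an
#' episode spans from the first window's start to the last window's end.
#' A gap between consecutive window starts larger than the sliding step
#' splits episodes. Works per recording (\code{subject_id} x \code{test_id}).
#'
#' @param preds Window predictions (needs \code{subject_id}, \code{test_id},
#'   \code{t_start}, \code{t_end}, \code{fog_pred}), time-ordered within each
#'   recording.
#' @return Data frame of episodes: \code{subject_id}, \code{test_id},
#'   \code{label}, \code{t_start}, \code{t_end}.
#' @export
windows_to_episodes <- function(preds) {
  pieces <- lapply(split(preds, paste(preds$subject_id, preds$test_id, sep = "/")),
                   episodes_one_recording)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

episodes_one_recording <- function(w) {
  w <- w[order(w$t_start), , drop = FALSE]
  n <- nrow(w)
  step <- if (n > 1L) stats::median(diff(w$t_start)) else Inf
  new_run <- c(TRUE, w$fog_pred[-1] != w$fog_pred[-n] |
                     diff(w$t_start) > step + 1e-6)
  run <- cumsum(new_run)
  data.frame(subject_id = w$subject_id[!duplicated(run)],
             test_id = w$test_id[!duplicated(run)],
             label = w$fog_pred[!duplicated(run)],
             t_start = tapply(w$t_start, run, min)[unique(run)],
             t_end = tapply(w$t_end, run, max)[unique(run)],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Minimum-duration postprocessing of predicted episodes
#'
#' Short spurious FOG detections are removed: every FOG episode shorter than
#' \code{min_dur_s} is relabeled non-FOG and merged with its neighbors. The
#' operation is idempotent and never increases the FOG episode count.
#'
#' @param eps Episode table from \code{\link{windows_to_episodes}}.
#' @param min_dur_s Minimum FOG episode duration in seconds.
#' @return The postprocessed episode table.
#' @export
postprocess_episodes <- function(eps, min_dur_s) {
  stopifnot(min_dur_s >= 0)
  if (nrow(eps) == 0L || min_dur_s == 0) return(eps)
  short <- eps$label == "fog" & (eps$t_end - eps$t_start) < min_dur_s - 1e-9
  eps$label[short] <- "nonfog"
  merge_adjacent_episodes(eps)
}

merge_adjacent_episodes <- function(eps) {
  pieces <- lapply(split(eps, paste(eps$subject_id, eps$test_id, sep = "/")),
    function(e) {
      e <- e[order(e$t_start), , drop = FALSE]
      n <- nrow(e)
      new_run <- c(TRUE, e$label[-1] != e$label[-n] |
                         e$t_start[-1] > e$t_end[-n] + 1e-6)
      run <- cumsum(new_run)
      data.frame(subject_id = e$subject_id[!duplicated(run)],
                 test_id = e$test_id[!duplicated(run)],
                 label = e$label[!duplicated(run)],
                 t_start = tapply(e$t_start, run, min)[unique(run)],
                 t_end = tapply(e$t_end, run, max)[unique(run)],
                 row.names = NULL, stringsAsFactors = FALSE)
    })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Postprocess window predictions through the episode duration threshold
#'
#' Applies \code{\link{postprocess_episodes}} at the window level: windows
#' belonging to a predicted FOG episode shorter than \code{min_dur_s} have
#' their prediction flipped to non-FOG, so downstream window and episode
#' scoring see the cleaned predictions.
#'
#' @param preds Window predictions.
#' @param min_dur_s Minimum FOG episode duration in seconds.
#' @return The window predictions with cleaned \code{fog_pred}.
#' @export
postprocess_window_predictions <- function(preds, min_dur_s) {
  if (min_dur_s <= 0 || nrow(preds) == 0L) return(preds)
  eps <- windows_to_episodes(preds)
  short <- eps[eps$label == "fog" &
                 (eps$t_end - eps$t_start) < min_dur_s - 1e-9, , drop = FALSE]
  if (nrow(short) == 0L) return(preds)
  key_p <- paste(preds$subject_id, preds$test_id, sep = "/")
  for (i in seq_len(nrow(short))) {
    hit <- key_p == paste(short$subject_id[i], short$test_id[i], sep = "/") &
      preds$t_start >= short$t_start[i] - 1e-9 &
      preds$t_end <= short$t_end[i] + 1e-9 &
      preds$fog_pred == "fog"
    preds$fog_pred[hit] <- "nonfog"
  }
  preds
}

#' Ground-truth episodes from a frame-based annotation track
#'
#' FOG intervals become FOG episodes; the complement of FOG and unknown
#' spans becomes non-FOG episodes; unknown spans belong to neither.
#'
#' @param ann An \code{annotation_track}.
#' @param fps Frames per second.
#' @param n_frames Number of frames in the recording.
#' @param subject_id,test_id Identifiers attached to the output rows.
#' @return Episode table (\code{label} in \code{fog}/\code{nonfog}).
#' @export
truth_episodes <- function(ann, fps, n_frames, subject_id = "S", test_id = "TUG") {
  total <- n_frames / fps
  fog <- ann$fog / fps
  unk <- ann$unknown / fps
  covered <- rbind(if (nrow(fog)) cbind(fog, 1) else NULL,
                   if (nrow(unk)) cbind(unk, 0) else NULL)
  eps <- list()
  if (!is.null(covered)) {
    covered <- covered[order(covered[, 1]), , drop = FALSE]
    cursor <- 0
    for (i in seq_len(nrow(covered))) {
      if (covered[i, 1] > cursor + 1e-9)
        eps[[length(eps) + 1L]] <- c("nonfog", cursor, covered[i, 1])
      if (covered[i, 3] == 1)
        eps[[length(eps) + 1L]] <- c("fog", covered[i, 1], covered[i, 2])
      cursor <- max(cursor, covered[i, 2])
    }
    if (cursor < total - 1e-9)
      eps[[length(eps) + 1L]] <- c("nonfog", cursor, total)
  } else {
    eps[[1L]] <- c("nonfog", 0, total)
  }
  data.frame(subject_id = subject_id, test_id = test_id,
             label = vapply(eps, `[`, "", 1),
             t_start = as.numeric(vapply(eps, `[`, "", 2)),
             t_end = as.numeric(vapply(eps, `[`, "", 3)),
             stringsAsFactors = FALSE)
}

#' Write episodes as a BED-like TSV (label, start_s, end_s)
#'
#' @param eps Episode table.
#' @param path Output path.
#' @export
write_episodes_tsv <- function(eps, path) {
  utils::write.table(eps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
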