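#' Sliding-window segmentation of a signal bank
#'
#' Windows of length \code{window_s} seconds start at 0, \code{step_s},
#' 2 \code{step_s}, ... and never extend past the signal; the window count is
#' \code{floor((T - window_s) / step_s) + 1} for signal duration \code{T}.
#'
#' @param signals A \code{derived_signals} object (or anything with
#'   \code{fps} and a \code{data} matrix).
#' @param window_s Window length in seconds (default 2).
#' @param step_s Step between window starts in seconds (default 0.1).
#' @return Data frame with one row per window: \code{t_start}, \code{t_end}
#'   (seconds), \code{i_start} (1-based first sample) and \code{n} (samples
#'   per window). Zero rows, with a warning, when the signal is shorter than
#'   one window.
#' @export
slide_windows <- function(signals, window_s = 2, step_s = 0.1) {
  fps <- signals$fps
  nf <- nrow(signals$data)
  dur <- nf / fps
  n <- as.integer(round(window_s * fps))
  if (dur < window_s - 1e-9) {
    warning("signal duration ", signif(dur, 4), " s is shorter than one window")
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      i_start = integer(0), n = integer(0)))
  }
  count <- floor((dur - window_s) / step_s + 1e-9) + 1
  t_start <- (seq_len(count) - 1) * step_s
  i_start <- as.integer(round(t_start * fps)) + 1L
  keep <- i_start + n - 1L <= nf
  data.frame(t_start = t_start[keep], t_end = t_start[keep] + window_s,
             i_start = i_start[keep], n = n)
}

#' Label windows from a frame-based annotation track
#'
#' Stage label: \code{turn} when more than half of the window's frames fall
#' inside a turn interval, else \code{walk}. FOG label: \code{unknown} when
#' the window touches any unknown-annotated frame; otherwise \code{fog} when
#' the FOG frame fraction is at least \code{fog_frac_min}, else \code{nonfog}.
#'
#' @param windows Window table from \code{\link{slide_windows}}.
#' @param ann An \code{annotation_track}.
#' @param fps Frames per second of the underlying sequence.
#' @param n_frames Number of frames in the sequence.
#' @param fog_frac_min Minimum FOG frame fraction for a \code{fog} label
#'   (default 0.5).
#' @return The window table with columns \code{stage_label},
#'   \code{fog_label}, \code{frac_turn}, \code{frac_fog}, \code{frac_unknown}
#'   appended.
#' @export
label_windows <- function(windows, ann, fps, n_frames, fog_frac_min = 0.5) {
  in_turn <- interval_mask(ann$turn, n_frames)
  in_fog <- interval_mask(ann$fog, n_frames)
  in_unk <- interval_mask(ann$unknown, n_frames)
  frac_in <- function(mask, i0, n) {
    cs <- c(0, cumsum(mask))
    (cs[i0 + n] - cs[i0]) / n
  }
  windows$frac_turn <- frac_in(in_turn, windows$i_start, windows$n)
  windows$frac_fog <- frac_in(in_fog, windows$i_start, windows$n)
  windows$frac_unknown <- frac_in(in_unk, windows$i_start, windows$n)
  windows$stage_label <- ifelse(windows$frac_turn > 0.5, "turn", "walk")
  windows$fog_label <- ifelse(windows$frac_unknown > 0, "unknown",
                              ifelse(windows$frac_fog >= fog_frac_min,
                                     "fog", "nonfog"))
  windows
}

# logical frame mask from 0-based half-open [start, end) intervals
interval_mask <- function(iv, n_frames) {
  mask <- logical(n_frames)
  if (nrow(iv) > 0L)
    for (i in seq_len(nrow(iv)))
      mask[(iv[i, 1] + 1L):min(iv[i, 2], n_frames)] <- TRUE
  mask
}
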