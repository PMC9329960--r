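#' Per-frame scale normalization via the expanded enclosing rectangle
#'
#' 2D video suffers from perspective scaling: a subject walking toward the
#' camera appears larger frame by frame. Each frame is therefore rescaled
#' independently: (1) the minimum axis-aligned rectangle enclosing all
#' keypoints with positive confidence is computed; (2) its width and height
#' are each expanded by \code{expand_frac}, symmetrically about the rectangle
#' center; (3) coordinates are translated so the expanded rectangle's
#' upper-left corner becomes the origin; (4) everything is multiplied by the
#' scale factor \code{s = target_height / expanded height}, so the normalized
#' expanded rectangle has height \code{target_height} in every frame.
#'
#' The result is invariant to any positive isotropic scaling and translation
#' of the input frame.
#'
#' @param seq A \code{pose_sequence}.
#' @param expand_frac Fractional expansion of rectangle width and height
#'   (default 0.30).
#' @param target_height Normalized height of the expanded rectangle
#'   (default 80).
#' @return A \code{normalized_sequence}: the sequence with normalized
#'   coordinates plus a \code{rect} matrix (frames x 5: origin x, origin y,
#'   expanded width, expanded height, scale factor s).
#' @export
normalize_sequence <- function(seq, expand_frac = 0.30, target_height = 80) {
  stopifnot(expand_frac >= 0, target_height > 0)
  nf <- n_frames(seq)
  rect <- matrix(NA_real_, nf, 5,
                 dimnames = list(NULL, c("ox", "oy", "width", "height", "s")))
  for (i in seq_len(nf)) {
    vis <- seq$conf[i, ] > 0
    if (!any(vis)) stop("frame ", seq$frame_index[i],
                        ": no keypoint with positive confidence")
    rx <- range(seq$x[i, vis]); ry <- range(seq$y[i, vis])
    w <- diff(rx); h <- diff(ry)
    we <- w * (1 + expand_frac); he <- h * (1 + expand_frac)
    if (he <= 0) stop("frame ", seq$frame_index[i],
                      ": degenerate enclosing rectangle (height 0)")
    ox <- mean(rx) - we / 2
    oy <- mean(ry) - he / 2
    s <- target_height / he
    seq$x[i, ] <- (seq$x[i, ] - ox) * s
    seq$y[i, ] <- (seq$y[i, ] - oy) * s
    rect[i, ] <- c(ox, oy, we, he, s)
  }
  seq$rect <- rect
  class(seq) <- c("normalized_sequence", "pose_sequence")
  seq
}

#' Derive the kinematic signal bank from a normalized sequence
#'
#' From the normalized keypoint positions, builds the per-frame signal bank:
#' \itemize{
#'   \item \code{pos_<kp>_<axis>}: normalized position, 25 keypoints x (x, y);
#'   \item \code{speed_<kp>_<axis>}: forward first difference of position
#'     times fps (units/s), last sample replicated;
#'   \item \code{acc_<kp>_<axis>}: forward first difference of speed times
#'     fps (units/s^2);
#'   \item \code{knee_angle_L}, \code{knee_angle_R}: interior angle at the
#'     knee between the knee-to-hip and knee-to-ankle vectors, in degrees;
#'   \item \code{pairdiff_<pair>_x}: absolute left-right x-coordinate
#'     difference for the 8 pairs hips, knees, ankles, big toes, shoulders,
#'     elbows, wrists, ears.
#' }
#'
#' @param nseq A \code{normalized_sequence} with at least 3 frames.
#' @param lowpass_hz Optional low-pass corner frequency (Hz); if non-NULL the
#'   positions are filtered with a zero-phase 4th-order Butterworth filter
#'   before differencing. Default \code{NULL} (no filtering).
#' @return A \code{derived_signals} object: list with \code{fps},
#'   \code{subject_id}, \code{test_id} and \code{data}, a frames x channels
#'   numeric matrix with named columns.
#' @export
derive_signals <- function(nseq, lowpass_hz = NULL) {
  nf <- n_frames(nseq)
  if (nf < 3L) stop("derive_signals needs at least 3 frames")
  fps <- nseq$fps
  X <- nseq$x; Y <- nseq$y
  if (!is.null(lowpass_hz)) {
    stopifnot(lowpass_hz > 0, lowpass_hz < fps / 2)
    bf <- signal::butter(4, lowpass_hz / (fps / 2), type = "low")
    X <- apply(X, 2, function(v) signal::filtfilt(bf, v))
    Y <- apply(Y, 2, function(v) signal::filtfilt(bf, v))
  }
  fdiff <- function(m) {           # forward difference * fps, last sample replicated
    d <- diff(m) * fps
    rbind(d, d[nf - 1, , drop = FALSE])
  }
  spX <- fdiff(X); spY <- fdiff(Y)
  acX <- fdiff(spX); acY <- fdiff(spY)

  cn <- function(prefix, axis) paste0(prefix, "_", BODY25, "_", axis)
  colnames(X) <- cn("pos", "x");  colnames(Y) <- cn("pos", "y")
  colnames(spX) <- cn("speed", "x"); colnames(spY) <- cn("speed", "y")
  colnames(acX) <- cn("acc", "x");  colnames(acY) <- cn("acc", "y")
  out <- cbind(X, Y, spX, spY, acX, acY)

  knee <- cbind(
    knee_angle_L = knee_angle(X, Y, "LHip", "LKnee", "LAnkle"),
    knee_angle_R = knee_angle(X, Y, "RHip", "RKnee", "RAnkle"))
  pd <- vapply(BODY25_PAIRS, function(pr) {
    abs(X[, body25_index(pr[1])] - X[, body25_index(pr[2])])
  }, numeric(nf))
  colnames(pd) <- paste0("pairdiff_", names(BODY25_PAIRS), "_x")

  structure(list(fps = fps, subject_id = nseq$subject_id, test_id = nseq$test_id,
                 data = cbind(out, knee, pd)),
            class = "derived_signals")
}

# interior angle at the knee, degrees; degenerate frames (coincident points)
# carry the previous valid value forward (or the next valid one at the start)
knee_angle <- function(X, Y, hip, knee, ankle) {
  ih <- body25_index(hip); ik <- body25_index(knee); ia <- body25_index(ankle)
  ux <- X[, ih] - X[, ik]; uy <- Y[, ih] - Y[, ik]
  vx <- X[, ia] - X[, ik]; vy <- Y[, ia] - Y[, ik]
  nu <- sqrt(ux^2 + uy^2); nv <- sqrt(vx^2 + vy^2)
  cosang <- (ux * vx + uy * vy) / (nu * nv)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  bad <- !is.finite(ang)
  if (any(bad)) {
    if (all(bad)) stop("knee angle undefined in every frame (", knee, ")")
    ang <- fill_forward(ang)
  }
  ang
}

fill_forward <- function(v) {
  ok <- is.finite(v)
  idx <- cumsum(ok)
  first <- which(ok)[1]
  filled <- v[ok][pmax(idx, 1)]
  filled[seq_len(first - 1)] <- v[first]
  filled
}

#' @export
print.derived_signals <- function(x, ...) {
  cat(sprintf("<derived_signals> subject %s, test %s: %d frames x %d channels @ %g fps\n",
              x$subject_id, x$test_id, nrow(x$data), ncol(x$data), x$fps))
  invisible(x)
}

#' Write a derived signal bank to a wide TSV (frame, one column per channel)
#'
#' @param signals A \code{derived_signals} object.
#' @param path Output TSV path.
#' @export
write_signals_tsv <- function(signals, path) {
  df <- data.frame(frame = seq_len(nrow(signals$data)) - 1L, signals$data,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
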