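#' Construct a pose sequence
#'
#' A \code{pose_sequence} holds per-frame 2D coordinates and detection
#' confidences for the 25 BODY_25 keypoints of one recording.
#'
#' @param x,y Numeric matrices, frames x 25, pixel coordinates.
#' @param conf Numeric matrix, frames x 25, detection confidence in [0, 1].
#' @param fps Frame rate in frames per second (default 30).
#' @param subject_id,test_id Identifiers of the subject and the gait test
#'   (e.g. \code{"TUG"} or \code{"Narrow"}).
#' @param frame_index Integer vector of 0-based frame indices; defaults to
#'   \code{0:(nrow(x) - 1)}.
#' @return An object of class \code{pose_sequence}.
#' @export
pose_sequence <- function(x, y, conf, fps = 30, subject_id = "S", test_id = "TUG",
                          frame_index = NULL) {
  x <- as.matrix(x); y <- as.matrix(y); conf <- as.matrix(conf)
  if (is.null(frame_index)) frame_index <- seq_len(nrow(x)) - 1L
  seq <- structure(
    list(subject_id = as.character(subject_id), test_id = as.character(test_id),
         fps = fps, frame_index = as.integer(frame_index),
         x = x, y = y, conf = conf),
    class = "pose_sequence")
  validate_pose_sequence(seq)
}

validate_pose_sequence <- function(seq) {
  stopifnot(is.numeric(seq$fps), seq$fps > 0)
  for (m in c("x", "y", "conf")) {
    if (ncol(seq[[m]]) != 25L)
      stop("pose_sequence: '", m, "' must have exactly 25 keypoint columns")
  }
  if (nrow(seq$x) != length(seq$frame_index) ||
      nrow(seq$y) != nrow(seq$x) || nrow(seq$conf) != nrow(seq$x))
    stop("pose_sequence: frame dimensions disagree")
  if (anyDuplicated(seq$frame_index))
    stop("pose_sequence: duplicated frame_index")
  if (is.unsorted(seq$frame_index))
    stop("pose_sequence: frames must be ordered by frame_index")
  if (any(seq$conf < 0 | seq$conf > 1, na.rm = TRUE))
    stop("pose_sequence: confidence outside [0, 1]")
  bad <- seq$conf > 0 & (!is.finite(seq$x) | !is.finite(seq$y))
  if (any(bad))
    stop("pose_sequence: non-finite coordinates with positive confidence")
  colnames(seq$x) <- colnames(seq$y) <- colnames(seq$conf) <- BODY25
  invisible(seq)
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf("<pose_sequence> subject %s, test %s: %d frames @ %g fps (%.1f s)\n",
              x$subject_id, x$test_id, nrow(x$x), x$fps, nrow(x$x) / x$fps))
  invisible(x)
}

n_frames <- function(seq) nrow(seq$x)

#' Read an OpenPose keypoint sequence
#'
#' Reads a directory of per-frame OpenPose JSON files (one file per frame,
#' each with \code{people[].pose_keypoints_2d} as flat x, y, confidence
#' triplets in BODY_25 order) into a \code{pose_sequence}. When a frame holds
#' several detected persons, one is selected by \code{person_policy}.
#'
#' @param path Directory containing \code{*_keypoints.json} files (or any
#'   \code{*.json}); files are taken in lexicographic order, one frame each.
#' @param subject_id,test_id,fps Sequence metadata.
#' @param person_policy Person selection rule; only \code{"largest_bbox"} is
#'   implemented: the person with the largest keypoint bounding-box area among
#'   persons with at least 13 keypoints of positive confidence.
#' @param allow_empty If \code{TRUE}, a frame with zero detected persons
#'   yields an all-zero-confidence frame instead of an error.
#' @return A \code{pose_sequence}.
#' @export
read_openpose_sequence <- function(path, subject_id = "S", test_id = "TUG",
                                   fps = 30, person_policy = "largest_bbox",
                                   allow_empty = FALSE) {
  person_policy <- match.arg(person_policy, "largest_bbox")
  files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
  if (length(files) == 0L) stop("no JSON frame files found under ", path)
  nf <- length(files)
  x <- y <- conf <- matrix(0, nf, 25)
  for (i in seq_len(nf)) {
    rec <- tryCatch(jsonlite::fromJSON(files[i], simplifyVector = FALSE),
                    error = function(e)
                      stop("malformed keypoint record in frame file ",
                           basename(files[i]), ": ", conditionMessage(e)))
    people <- rec$people
    if (is.null(people) || length(people) == 0L) {
      if (allow_empty) next   # leave the all-zero-confidence frame
      stop("zero persons detected in frame file ", basename(files[i]))
    }
    kps <- lapply(people, function(p) {
      v <- unlist(p$pose_keypoints_2d)
      if (length(v) != 75L)
        stop("malformed keypoint record in frame file ", basename(files[i]),
             ": expected 75 values per person, got ", length(v))
      matrix(v, ncol = 3, byrow = TRUE)
    })
    sel <- select_person(kps)
    x[i, ] <- sel[, 1]; y[i, ] <- sel[, 2]; conf[i, ] <- sel[, 3]
  }
  pose_sequence(x, y, conf, fps = fps, subject_id = subject_id, test_id = test_id)
}

# largest keypoint bounding-box area among persons with >= 13 confident keypoints
select_person <- function(kps) {
  area <- vapply(kps, function(m) {
    ok <- m[, 3] > 0
    if (sum(ok) < 13L) return(-Inf)
    diff(range(m[ok, 1])) * diff(range(m[ok, 2]))
  }, numeric(1))
  if (all(!is.finite(area))) {
    # no person passes the visibility requirement: fall back to raw area
    area <- vapply(kps, function(m) {
      ok <- m[, 3] > 0
      if (!any(ok)) return(0)
      diff(range(m[ok, 1])) * diff(range(m[ok, 2]))
    }, numeric(1))
  }
  kps[[which.max(area)]]
}

#' Write / read a pose sequence as a plain CSV table
#'
#' The consolidated sequence format is one long table with columns
#' \code{subject_id, test_id, fps, frame, keypoint, x, y, confidence}
#' (one row per frame and keypoint), readable by any tabular tool.
#'
#' @param seq A \code{pose_sequence}.
#' @param path Output (input) CSV path.
#' @return \code{write_pose_csv} returns \code{path} invisibly;
#'   \code{read_pose_csv} returns a \code{pose_sequence}.
#' @export
write_pose_csv <- function(seq, path) {
  nf <- n_frames(seq)
  df <- data.frame(
    subject_id = seq$subject_id, test_id = seq$test_id, fps = seq$fps,
    frame = rep(seq$frame_index, times = 25),
    keypoint = rep(BODY25, each = nf),
    x = as.vector(seq$x), y = as.vector(seq$y),
    confidence = as.vector(seq$conf))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pose_csv
#' @export
read_pose_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "test_id", "fps", "frame", "keypoint", "x", "y", "confidence")
  if (!all(need %in% names(df))) stop("not a pose CSV: missing columns")
  frames <- sort(unique(df$frame))
  nf <- length(frames)
  ik <- body25_index(df$keypoint)
  ifr <- match(df$frame, frames)
  x <- y <- conf <- matrix(NA_real_, nf, 25)
  x[cbind(ifr, ik)] <- df$x
  y[cbind(ifr, ik)] <- df$y
  conf[cbind(ifr, ik)] <- df$confidence
  if (anyNA(conf)) stop("pose CSV is missing frame/keypoint cells")
  pose_sequence(x, y, conf, fps = df$fps[1],
                subject_id = df$subject_id[1], test_id = df$test_id[1],
                frame_index = frames)
}

#' Construct a frame-based annotation track
#'
#' Frame intervals are 0-based and half-open \code{[start, end)}.
#'
#' @param turn,fog,unknown Two-column integer matrices (or NULL) of
#'   \code{[start_frame, end_frame)} intervals for the turning stage, FOG
#'   episodes, and spans whose FOG status could not be decided.
#' @param n_frames Optional sequence length for bounds validation.
#' @return An object of class \code{annotation_track}.
#' @export
annotation_track <- function(turn = NULL, fog = NULL, unknown = NULL, n_frames = NULL) {
  as_iv <- function(m) {
    if (is.null(m) || length(m) == 0L) return(matrix(integer(0), 0, 2,
      dimnames = list(NULL, c("start", "end"))))
    m <- matrix(as.integer(m), ncol = 2, dimnames = list(NULL, c("start", "end")))
    if (any(m[, 1] >= m[, 2])) stop("annotation interval with start >= end")
    if (any(m[, 1] < 0)) stop("annotation interval with negative start")
    m[order(m[, 1]), , drop = FALSE]
  }
  ann <- structure(list(turn = as_iv(turn), fog = as_iv(fog), unknown = as_iv(unknown)),
                   class = "annotation_track")
  if (intervals_overlap(ann$fog, ann$unknown))
    stop("fog and unknown annotation intervals overlap")
  if (!is.null(n_frames)) {
    hi <- max(0L, ann$turn[, 2], ann$fog[, 2], ann$unknown[, 2])
    if (hi > n_frames) stop("annotation interval extends past the sequence end")
  }
  ann
}

intervals_overlap <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(FALSE)
  for (i in seq_len(nrow(a)))
    if (any(a[i, 1] < b[, 2] & b[, 1] < a[i, 2])) return(TRUE)
  FALSE
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("<annotation_track> %d turn, %d fog, %d unknown interval(s)\n",
              nrow(x$turn), nrow(x$fog), nrow(x$unknown)))
  invisible(x)
}

#' Read / write frame-based annotations
#'
#' Native annotation format: a TSV with columns \code{label} (one of
#' \code{turn}, \code{fog}, \code{unknown}), \code{start_frame},
#' \code{end_frame}; intervals are 0-based half-open \code{[start, end)}.
#' An empty file (header only, or zero bytes) yields an empty track.
#'
#' @param path Annotation TSV path.
#' @param n_frames Optional sequence length for bounds validation.
#' @return An \code{annotation_track}.
#' @export
read_annotations <- function(path, n_frames = NULL) {
  if (file.size(path) == 0L)
    return(annotation_track(n_frames = n_frames))
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(annotation_track(n_frames = n_frames))
  need <- c("label", "start_frame", "end_frame")
  if (!all(need %in% names(df))) stop("not an annotation TSV: need columns ",
                                      paste(need, collapse = ", "))
  bad <- setdiff(unique(df$label), c("turn", "fog", "unknown"))
  if (length(bad)) stop("unknown annotation label(s): ", paste(bad, collapse = ", "))
  pick <- function(lab) as.matrix(df[df$label == lab, c("start_frame", "end_frame")])
  annotation_track(turn = pick("turn"), fog = pick("fog"),
                   unknown = pick("unknown"), n_frames = n_frames)
}

#' @rdname read_annotations
#' @param ann An \code{annotation_track} to write.
#' @export
write_annotations <- function(ann, path) {
  rows <- do.call(rbind, lapply(c("turn", "fog", "unknown"), function(lab) {
    m <- ann[[lab]]
    if (nrow(m) == 0L) return(NULL)
    data.frame(label = lab, start_frame = m[, 1], end_frame = m[, 2])
  }))
  if (is.null(rows))
    rows <- data.frame(label = character(0), start_frame = integer(0),
                       end_frame = integer(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Repair low-confidence keypoints by temporal interpolation
#'
#' For each keypoint channel, frames whose detection confidence falls below
#' \code{conf_min} get their coordinates linearly interpolated in time between
#' the nearest flanking frames with confidence at or above the threshold;
#' leading and trailing gaps take the nearest valid value. Repaired frames
#' have their confidence set to \code{conf_min}, which makes the operation
#' idempotent. The fraction of repaired keypoint-frames is attached as
#' attribute \code{"repair_fraction"}.
#'
#' @param seq A \code{pose_sequence}.
#' @param conf_min Confidence threshold in [0, 1); default 0.1.
#' @return The repaired \code{pose_sequence}.
#' @export
interpolate_low_confidence <- function(seq, conf_min = 0.1) {
  stopifnot(conf_min >= 0, conf_min < 1)
  nf <- n_frames(seq)
  t <- seq$frame_index
  repaired <- 0L
  for (k in seq_len(25L)) {
    ok <- seq$conf[, k] >= conf_min
    if (!any(ok)) stop("keypoint channel '", BODY25[k],
                       "' has no frame with confidence >= ", conf_min)
    if (all(ok)) next
    bad <- which(!ok)
    repaired <- repaired + length(bad)
    for (m in c("x", "y")) {
      v <- seq[[m]][, k]
      seq[[m]][bad, k] <- stats::approx(t[ok], v[ok], xout = t[bad],
                                        method = "linear", rule = 2)$y
    }
    seq$conf[bad, k] <- conf_min
  }
  attr(seq, "repair_fraction") <- repaired / (nf * 25)
  seq
}
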