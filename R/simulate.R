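#' Simulation parameters for the synthetic gait cohort
#'
#' The simulator produces stylized 25-keypoint walking recordings carrying
#' the statistical signatures the recognition pipeline relies on: locomotor
#' (0.5-3 Hz) limb oscillation during walking with forward translation
#' rendered as smooth apparent-scale change; turning as a collapse and
#' re-expansion of the left-right keypoint x-separations; freezing of gait
#' as suppressed locomotor oscillation, 6-8 Hz lower-limb tremor and
#' arrested progression; plus keypoint jitter and confidence dropouts.
#'
#' @param n_subjects Number of subjects (default 12).
#' @param fog_prevalence Fraction of subjects with FOG; ceiling applied
#'   (default 0.26, i.e. 4 of 12 subjects).
#' @param fps Frames per second (default 30).
#' @param cadence_hz Range of the per-subject locomotor oscillation
#'   frequency (default 0.8-1.2 Hz).
#' @param tremor_hz Range of the FOG leg-tremor frequency (default 6-8 Hz).
#' @param gait_amp Range of the per-subject gait oscillation amplitude,
#'   template pixels (default 12-18).
#' @param tremor_amp Range of the FOG tremor amplitude, template pixels
#'   (default 3-5).
#' @param approach_scale_range Apparent-size multiplier from clip start to
#'   end (default 0.7 to 1.3).
#' @param noise_sd Gaussian keypoint jitter, image pixels (default 0.5).
#' @param dropout_rate Per keypoint-frame probability of a zero-confidence
#'   dropout (default 0.01).
#' @param walk_s Range of each straight-walk segment duration, seconds
#'   (default 18-22).
#' @param turn_s Range of the turn duration, seconds (default 2.5-4).
#' @param fog_duration_s Range of FOG episode durations, seconds
#'   (default 1-15).
#' @param fog_episodes_range Episodes per affected subject (default 1-4).
#' @param turn_fog_prob Probability that an episode falls in the turning
#'   stage (default 0.25; at most one per recording).
#' @param seed Cohort seed (default 0).
#' @return A \code{sim_params} list.
#' @export
sim_params <- function(n_subjects = 12L, fog_prevalence = 0.26, fps = 30,
                       cadence_hz = c(0.8, 1.2), tremor_hz = c(6, 8),
                       gait_amp = c(12, 18), tremor_amp = c(3, 5),
                       approach_scale_range = c(0.7, 1.3), noise_sd = 0.5,
                       dropout_rate = 0.01, walk_s = c(18, 22),
                       turn_s = c(2.5, 4), fog_duration_s = c(1, 15),
                       fog_episodes_range = c(1L, 4L), turn_fog_prob = 0.25,
                       seed = 0L) {
  stopifnot(fog_prevalence >= 0, fog_prevalence <= 1, dropout_rate >= 0,
            dropout_rate <= 1, turn_fog_prob >= 0, turn_fog_prob <= 1,
            max(cadence_hz) < fps / 2, max(tremor_hz) < fps / 2, fps > 0)
  structure(as.list(environment()), class = "sim_params")
}

# template skeleton, scale-1 "body pixels", y grows downward, x from midline
body25_template <- function() {
  tmpl <- rbind(
    Nose = c(0, 10), Neck = c(0, 35), RShoulder = c(-20, 38),
    RElbow = c(-25, 65), RWrist = c(-27, 90), LShoulder = c(20, 38),
    LElbow = c(25, 65), LWrist = c(27, 90), MidHip = c(0, 105),
    RHip = c(-12, 105), RKnee = c(-13, 150), RAnkle = c(-14, 192),
    LHip = c(12, 105), LKnee = c(13, 150), LAnkle = c(14, 192),
    REye = c(-4, 6), LEye = c(4, 6), REar = c(-8, 9), LEar = c(8, 9),
    LBigToe = c(16, 200), LSmallToe = c(19, 199), LHeel = c(13, 196),
    RBigToe = c(-16, 200), RSmallToe = c(-19, 199), RHeel = c(-13, 196))
  tmpl[BODY25, ]
}

LEG_KPS <- c("RKnee", "RAnkle", "RHeel", "RBigToe", "RSmallToe",
             "LKnee", "LAnkle", "LHeel", "LBigToe", "LSmallToe")

#' Simulate one gait recording
#'
#' Builds a walk - turn - walk recording for one subject, with optional FOG
#' episodes inserted into the walking and/or turning segments (a frozen turn
#' pauses the turn's progress; a frozen walk arrests forward translation).
#' Annotations match the generated regimes exactly by construction.
#'
#' @param params A \code{\link{sim_params}}.
#' @param subject_seed Integer distinguishing recordings; together with
#'   \code{params$seed} it fully determines the output.
#' @param subject_id,test_id Identifiers for the output sequence.
#' @param with_fog Whether this subject produces FOG episodes.
#' @return A \code{sim_recording}: list with \code{sequence}
#'   (\code{pose_sequence}), \code{annotations} (\code{annotation_track})
#'   and \code{log} (segment table and drawn parameters).
#' @export
simulate_recording <- function(params, subject_seed = 1L, subject_id = "S01",
                               test_id = "TUG", with_fog = FALSE) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed((params$seed %% 65536L) * 32749L + subject_seed %% 32749L)
  fps <- params$fps
  runif2 <- function(r) stats::runif(1, r[1], r[2])

  cadence <- runif2(params$cadence_hz)
  gait_amp <- runif2(params$gait_amp)
  tremor_hz <- runif2(params$tremor_hz)
  tremor_amp <- runif2(params$tremor_amp)

  segs <- plan_segments(params, with_fog)
  nseg <- nrow(segs)
  segs$frames <- pmax(1L, as.integer(round(segs$dur * fps)))
  nf <- sum(segs$frames)
  if (nf < 2L * as.integer(round(2 * fps)))
    stop("segment plan shorter than 2 windows")

  stage <- rep(segs$stage, segs$frames)     # walk / turn
  frozen <- rep(segs$kind == "fog", segs$frames)
  tvec <- (seq_len(nf) - 1) / fps

  activity <- ifelse(frozen, 0.05, 1)
  phase <- cumsum(2 * pi * cadence * activity / fps)

  # forward progression: advances only while actually walking
  adv <- as.numeric(stage == "walk" & !frozen)
  prog <- cumsum(adv) / max(1, sum(adv))
  scl <- params$approach_scale_range[1] +
    diff(params$approach_scale_range) * prog

  # turn progress u in [0, 1] per contiguous turn run; frozen frames hold u
  compress <- rep(1, nf)
  r <- rle(stage == "turn")
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    idx <- starts[j]:ends[j]
    act <- as.numeric(!frozen[idx])
    u <- cumsum(act) / max(1, sum(act))
    compress[idx] <- abs(cos(pi * u))
  }

  tmpl <- body25_template()
  Ox <- matrix(0, nf, 25, dimnames = list(NULL, BODY25))
  Oy <- matrix(0, nf, 25, dimnames = list(NULL, BODY25))
  legosc <- gait_amp * sin(phase) * activity
  lift <- 0.4 * gait_amp * activity
  add_x <- function(kps, v) for (k in kps) Ox[, k] <<- Ox[, k] + v
  add_y <- function(kps, v) for (k in kps) Oy[, k] <<- Oy[, k] + v
  # foot swing stays below the ankle half-separation so left-right
  # x-distances only collapse during turns, not at every stride
  add_x(c("LAnkle", "LHeel", "LBigToe", "LSmallToe"), 0.45 * legosc)
  add_x(c("RAnkle", "RHeel", "RBigToe", "RSmallToe"), -0.45 * legosc)
  add_x("LKnee", 0.3 * legosc); add_x("RKnee", -0.3 * legosc)
  add_x("LWrist", -0.6 * legosc); add_x("RWrist", 0.6 * legosc)
  add_x("LElbow", -0.3 * legosc); add_x("RElbow", 0.3 * legosc)
  add_y(c("LAnkle", "LHeel", "LBigToe", "LSmallToe"),
        -lift * pmax(0, sin(phase)))
  add_y(c("RAnkle", "RHeel", "RBigToe", "RSmallToe"),
        -lift * pmax(0, -sin(phase)))
  bob <- 0.15 * gait_amp * sin(2 * phase) * activity
  Oy <- Oy + bob

  if (any(frozen)) {
    tr <- tremor_amp * sin(2 * pi * tremor_hz * tvec +
                             stats::runif(1, 0, 2 * pi)) * frozen
    for (k in LEG_KPS) {
      sgn <- if (startsWith(k, "L")) 1 else -1
      Ox[, k] <- Ox[, k] + sgn * tr
      Oy[, k] <- Oy[, k] + 0.7 * tr
    }
  }

  Xb <- sweep(compress * sweep(Ox, 2, tmpl[, 1], `+`), 1, rep(0, nf), `+`)
  Yb <- sweep(Oy, 2, tmpl[, 2], `+`)
  X <- 272 + scl * Xb + stats::rnorm(nf * 25, sd = params$noise_sd)
  Y <- 200 + scl * Yb + stats::rnorm(nf * 25, sd = params$noise_sd)
  conf <- matrix(stats::runif(nf * 25, 0.5, 0.95), nf, 25)
  drop <- matrix(stats::runif(nf * 25) < params$dropout_rate, nf, 25)
  conf[drop] <- 0; X[drop] <- 0; Y[drop] <- 0

  seq <- pose_sequence(X, Y, conf, fps = fps, subject_id = subject_id,
                       test_id = test_id)
  ann <- annotations_from_segments(segs, fps, nf)
  structure(list(sequence = seq, annotations = ann,
                 log = list(segments = segs, cadence_hz = cadence,
                            gait_amp = gait_amp, tremor_hz = tremor_hz,
                            tremor_amp = tremor_amp, with_fog = with_fog)),
            class = "sim_recording")
}

# ordered segment table: kind (walk/turn/fog), stage (walk/turn), dur (s)
plan_segments <- function(params, with_fog) {
  runif2 <- function(r) stats::runif(1, r[1], r[2])
  w1 <- runif2(params$walk_s); w2 <- runif2(params$walk_s)
  td <- runif2(params$turn_s)
  n_ep <- if (with_fog)
    sample(seq(params$fog_episodes_range[1], params$fog_episodes_range[2]), 1)
  else 0L
  durs <- if (n_ep > 0) stats::runif(n_ep, params$fog_duration_s[1],
                                     params$fog_duration_s[2]) else numeric(0)
  in_turn <- if (n_ep > 0) stats::runif(n_ep) < params$turn_fog_prob
             else logical(0)
  if (sum(in_turn) > 1L) in_turn[which(in_turn)[-1]] <- FALSE  # one per turn
  walk_durs <- durs[!in_turn]
  turn_dur <- durs[in_turn]

  # distribute walk episodes over the two walk segments
  seg_of <- sample(c(1L, 2L), length(walk_durs), replace = TRUE)
  walk_piece <- function(D, eps) {
    if (length(eps) == 0L)
      return(data.frame(kind = "walk", stage = "walk", dur = D))
    k <- length(eps)
    cuts <- (seq_len(k) / (k + 1)) * D + stats::runif(k, -0.4, 0.4)
    cuts <- pmin(pmax(sort(cuts), 1.5), D - 1.5)
    out <- list()
    prev <- 0
    for (j in seq_len(k)) {
      out[[length(out) + 1L]] <- data.frame(kind = "walk", stage = "walk",
                                            dur = max(0.5, cuts[j] - prev))
      out[[length(out) + 1L]] <- data.frame(kind = "fog", stage = "walk",
                                            dur = eps[j])
      prev <- cuts[j]
    }
    out[[length(out) + 1L]] <- data.frame(kind = "walk", stage = "walk",
                                          dur = max(0.5, D - prev))
    do.call(rbind, out)
  }
  turn_piece <- if (length(turn_dur)) rbind(
    data.frame(kind = "turn", stage = "turn", dur = td / 2),
    data.frame(kind = "fog", stage = "turn", dur = turn_dur[1]),
    data.frame(kind = "turn", stage = "turn", dur = td / 2))
  else data.frame(kind = "turn", stage = "turn", dur = td)

  segs <- rbind(walk_piece(w1, walk_durs[seg_of == 1L]), turn_piece,
                walk_piece(w2, walk_durs[seg_of == 2L]))
  rownames(segs) <- NULL
  segs
}

annotations_from_segments <- function(segs, fps, nf) {
  ends <- cumsum(segs$frames)
  starts <- c(0L, ends[-length(ends)])
  iv <- function(sel) {
    if (!any(sel)) return(NULL)
    m <- cbind(starts[sel], ends[sel])
    # merge touching intervals (e.g. turn pieces around a frozen turn)
    keep <- list(m[1, ])
    if (nrow(m) > 1L) for (i in 2:nrow(m)) {
      last <- keep[[length(keep)]]
      if (m[i, 1] <= last[2]) keep[[length(keep)]] <- c(last[1], m[i, 2])
      else keep[[length(keep) + 1L]] <- m[i, ]
    }
    do.call(rbind, keep)
  }
  annotation_track(turn = iv(segs$stage == "turn"),
                   fog = iv(segs$kind == "fog"), n_frames = nf)
}

#' @export
print.sim_recording <- function(x, ...) {
  cat("<sim_recording>\n  ")
  print(x$sequence)
  cat("  ")
  print(x$annotations)
  invisible(x)
}

#' Simulate a cohort of subjects
#'
#' Draws per-subject gait parameters, marks
#' \code{ceiling(fog_prevalence * n_subjects)} subjects as FOG-affected
#' (each receiving 1-4 episodes), and simulates one recording per subject.
#'
#' @param params A \code{\link{sim_params}}.
#' @return A \code{sim_cohort}: list with \code{recordings} (list of
#'   \code{sim_recording}), \code{manifest} (per-subject data frame) and
#'   \code{params}.
#' @export
simulate_cohort <- function(params = sim_params()) {
  n <- params$n_subjects
  stopifnot(n >= 2L)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(params$seed %% 2147483L + 11L)
  n_fog <- ceiling(params$fog_prevalence * n)
  fog_subjects <- sort(sample.int(n, n_fog))
  ids <- sprintf("S%02d", seq_len(n))
  recordings <- lapply(seq_len(n), function(i)
    simulate_recording(params, subject_seed = i, subject_id = ids[i],
                       test_id = "TUG", with_fog = i %in% fog_subjects))
  manifest <- data.frame(
    subject_id = ids, test_id = "TUG", with_fog = seq_len(n) %in% fog_subjects,
    n_fog_episodes = vapply(recordings, function(r) nrow(r$annotations$fog), 0L),
    n_frames = vapply(recordings, function(r) n_frames(r$sequence), 0L),
    cadence_hz = vapply(recordings, function(r) r$log$cadence_hz, 0),
    tremor_hz = vapply(recordings, function(r) r$log$tremor_hz, 0))
  structure(list(recordings = recordings, manifest = manifest, params = params),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d subject(s), %d with FOG, %d episode(s) total\n",
              nrow(x$manifest), sum(x$manifest$with_fog),
              sum(x$manifest$n_fog_episodes)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' One pose CSV and one annotation TSV per recording, plus a YAML manifest.
#'
#' @param cohort A \code{sim_cohort}.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$recordings) {
    base <- file.path(dir, paste0(rec$sequence$subject_id, "_",
                                  rec$sequence$test_id))
    write_pose_csv(rec$sequence, paste0(base, "_pose.csv"))
    write_annotations(rec$annotations, paste0(base, "_annotations.tsv"))
  }
  yaml::write_yaml(list(params = unclass(cohort$params),
                        subjects = split(cohort$manifest,
                                         seq_len(nrow(cohort$manifest)))),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}
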