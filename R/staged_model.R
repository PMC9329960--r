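#' Fit the multi-stage FOG recognition model
#'
#' Trains the three gradient-boosted-tree classifiers that make up the
#' staged pipeline: a motion model (walk vs turn, all labeled windows), a
#' Walk-FOG model (walking-stage windows) and a Turn-FOG model
#' (turning-stage windows). Each FOG model goes through transition-window
#' removal, SMOTE balancing, gain ranking, forward feature selection, and
#' subject-grouped grid search. Windows labeled \code{unknown} are excluded
#' from all training. The minimum-duration threshold for episode
#' postprocessing is the 10\% linear-interpolation quantile of the annotated
#' FOG episode durations in the training data.
#'
#' A stage with no FOG training windows gets a constant non-FOG predictor,
#' flagged in the returned object.
#'
#' @param fm Feature matrix from \code{\link{build_feature_matrix}}
#'   (training rows only).
#' @param annotations Named list of \code{annotation_track}s keyed by
#'   \code{"<subject_id>/<test_id>"} for the training recordings.
#' @param config A \code{\link{fog_model_config}}.
#' @return An object of class \code{fog_staged_model}.
#' @export
fog_staged_fit <- function(fm, annotations, config = fog_model_config()) {
  fcols <- feature_cols(fm)
  fps <- attr(fm, "fps")
  stopifnot(!is.null(fcols), !is.null(fps))
  fm <- canonical_order(fm)
  known <- fm[fm$fog_label != "unknown", , drop = FALSE]
  if (length(unique(known$stage_label)) < 2L)
    stop("training windows must span both motion stages")
  bounds <- fog_boundaries(annotations, fps)

  motion <- train_task(known, fcols, known$stage_label, config,
                       cap = config$max_features[["motion"]],
                       positive = "turn", smote = FALSE)
  walk_fog <- train_fog_task(known[known$stage_label == "walk", , drop = FALSE],
                             fm, bounds, fcols, config,
                             cap = config$max_features[["walk"]])
  turn_fog <- train_fog_task(known[known$stage_label == "turn", , drop = FALSE],
                             fm, bounds, fcols, config,
                             cap = config$max_features[["turn"]])

  thr <- fog_duration_threshold(annotations, fps)

  structure(list(motion = motion, walk_fog = walk_fog, turn_fog = turn_fog,
                 fog_duration_threshold_s = thr, config = config, fps = fps,
                 training_subjects = sort(unique(fm$subject_id)),
                 training_fingerprint = training_fingerprint(fm)),
            class = "fog_staged_model")
}

#' Minimum-duration threshold from annotated FOG episode durations
#'
#' The 10\% linear-interpolation quantile of the annotated FOG episode
#' durations (seconds); 0 when there are none. Predicted FOG episodes
#' shorter than this are discarded during postprocessing.
#'
#' @param annotations Named list of \code{annotation_track}s.
#' @param fps Frames per second.
#' @param prob Quantile level (default 0.10).
#' @return Threshold in seconds.
#' @export
fog_duration_threshold <- function(annotations, fps, prob = 0.10) {
  durs <- unlist(lapply(annotations, function(ann)
    (ann$fog[, 2] - ann$fog[, 1]) / fps), use.names = FALSE)
  if (!length(durs)) return(0)
  unname(stats::quantile(durs, prob, type = 7))
}

# canonical training-row order: results must not depend on input row order
canonical_order <- function(fm) {
  keep_attrs(fm[order(fm$subject_id, fm$test_id, fm$t_start), , drop = FALSE],
             fm)
}

# sorted row keys of the training windows: proof of what the fit saw
training_fingerprint <- function(fm) {
  sort(paste(fm$subject_id, fm$test_id, sprintf("%.4f", fm$t_start), sep = "|"))
}

# shared task trainer: ranking -> forward selection -> grid search;
# `positive` is the class the model scores toward 1
train_task <- function(rows, fcols, y, config, cap, positive, smote = FALSE) {
  X <- as.matrix(rows[, fcols, drop = FALSE])
  subj <- rows$subject_id
  if (smote) {
    bal <- smote_balance(X, y, k = config$smote_k, seed = config$seed)
    # synthetic rows inherit the subject of their base minority row for grouping
    minority <- names(which.min(table(y)))
    extra <- nrow(bal$X) - nrow(X)
    subj <- c(subj, rep_len(subj[y == minority], extra))
    X <- bal$X; y <- bal$y
  }
  y01 <- as_binary(y, positive)
  ranked <- rank_features_by_gain(X, y01, config)
  sel <- forward_select(X, y01, subj, ranked, config, cap = cap)
  fit <- tryCatch(grid_search_train(X, y01, subj, config, features = sel$features),
                  error = function(e) {
                    warning("grid search degenerate (", conditionMessage(e),
                            "); fitting at the grid center")
                    ctr <- grid_center(config$grid)
                    list(model = fit_xgb(X[, sel$features, drop = FALSE],
                                         y01, ctr, config$seed),
                         best = ctr, grid_table = NULL)
                  })
  list(model = fit$model, selected = sel, best = fit$best,
       grid_table = fit$grid_table, positive = positive, constant = FALSE)
}

train_fog_task <- function(rows, fm_all, bounds, fcols, config, cap) {
  if (nrow(rows) == 0L || sum(rows$fog_label == "fog") == 0L) {
    warning("stage has no FOG training windows; using a constant non-FOG predictor")
    return(list(model = NULL, selected = NULL, best = NULL,
                positive = "fog", constant = TRUE))
  }
  rows <- remove_transition_windows(keep_attrs(rows, fm_all), bounds,
                                    config$transition_margin_s)
  n_fog <- sum(rows$fog_label == "fog")
  if (n_fog < 2L || n_fog == nrow(rows)) {
    warning("too few usable FOG training windows after transition removal; ",
            "using a constant non-FOG predictor")
    return(list(model = NULL, selected = NULL, best = NULL,
                positive = "fog", constant = TRUE))
  }
  train_task(rows, fcols, rows$fog_label, config, cap,
             positive = "fog", smote = TRUE)
}

#' @export
print.fog_staged_model <- function(x, ...) {
  cat("<fog_staged_model>\n")
  for (nm in c("motion", "walk_fog", "turn_fog")) {
    m <- x[[nm]]
    if (isTRUE(m$constant)) {
      cat(sprintf("  %-9s constant non-FOG predictor\n", nm))
    } else {
      cat(sprintf("  %-9s %d features, depth %d, %d trees, eta %g\n", nm,
                  length(m$selected$features), m$best$max_depth,
                  m$best$n_estimators, m$best$learning_rate))
    }
  }
  cat(sprintf("  FOG episode duration threshold: %.2f s\n",
              x$fog_duration_threshold_s))
  cat(sprintf("  trained on %d subject(s)\n", length(x$training_subjects)))
  invisible(x)
}

#' @export
summary.fog_staged_model <- function(object, ...) {
  print(object)
  cat("\nSelected features:\n")
  for (nm in c("motion", "walk_fog", "turn_fog")) {
    m <- object[[nm]]
    if (isTRUE(m$constant)) next
    cat(sprintf("  [%s]\n", nm))
    cat(paste0("    ", m$selected$features, collapse = "\n"), "\n")
  }
  invisible(object)
}

#' Predict with the multi-stage model
#'
#' Each window first receives a motion-stage prediction; the stage then
#' routes the window to the Walk-FOG or Turn-FOG model for its FOG score.
#' The FOG decision applies the configured probability cutoff (0.5).
#'
#' @param object A \code{fog_staged_model}.
#' @param newdata Feature matrix rows carrying all features the model
#'   selected (plus window metadata).
#' @param ... Unused.
#' @return Data frame with the window metadata plus \code{stage_pred},
#'   \code{fog_score}, \code{fog_pred}.
#' @export
predict.fog_staged_model <- function(object, newdata, ...) {
  check_features(object, newdata)
  thr <- object$config$decision_threshold
  mp <- predict_xgb(object$motion$model,
                    newdata[, object$motion$selected$features, drop = FALSE])
  stage_pred <- ifelse(mp >= 0.5, object$motion$positive,
                       setdiff(c("walk", "turn"), object$motion$positive))
  score <- numeric(nrow(newdata))
  for (st in c("walk", "turn")) {
    m <- if (st == "walk") object$walk_fog else object$turn_fog
    rows <- which(stage_pred == st)
    if (length(rows) == 0L) next
    score[rows] <- if (isTRUE(m$constant)) 0 else
      predict_xgb(m$model, newdata[rows, m$selected$features, drop = FALSE])
  }
  out <- newdata[, intersect(c("subject_id", "test_id", "t_start", "t_end",
                               "stage_label", "fog_label"), names(newdata)),
                 drop = FALSE]
  out$stage_pred <- stage_pred
  out$motion_score <- mp
  out$fog_score <- score
  out$fog_pred <- ifelse(score >= thr, "fog", "nonfog")
  rownames(out) <- NULL
  out
}

check_features <- function(object, newdata) {
  need <- unique(c(object$motion$selected$features,
                   if (!isTRUE(object$walk_fog$constant)) object$walk_fog$selected$features,
                   if (!isTRUE(object$turn_fog$constant)) object$turn_fog$selected$features))
  missing <- setdiff(need, names(newdata))
  if (length(missing))
    stop("newdata is missing required feature column(s): ",
         paste(missing, collapse = ", "))
}

#' Fit the non-staged (single) FOG recognition model
#'
#' Reference model for the staged-vs-non-staged comparison: one FOG
#' classifier trained on all labeled windows regardless of motion stage,
#' with the same transition removal, SMOTE, feature selection and grid
#' search as the staged FOG models.
#'
#' @inheritParams fog_staged_fit
#' @return An object of class \code{fog_single_model}.
#' @export
fog_single_fit <- function(fm, annotations, config = fog_model_config()) {
  fcols <- feature_cols(fm)
  fps <- attr(fm, "fps")
  fm <- canonical_order(fm)
  known <- fm[fm$fog_label != "unknown", , drop = FALSE]
  bounds <- fog_boundaries(annotations, fps)
  fog <- train_fog_task(keep_attrs(known, fm), fm, bounds, fcols, config,
                        cap = config$max_features[["walk"]])
  thr <- fog_duration_threshold(annotations, fps)
  structure(list(fog = fog, fog_duration_threshold_s = thr, config = config,
                 fps = fps, training_subjects = sort(unique(fm$subject_id)),
                 training_fingerprint = training_fingerprint(fm)),
            class = "fog_single_model")
}

#' @export
predict.fog_single_model <- function(object, newdata, ...) {
  thr <- object$config$decision_threshold
  m <- object$fog
  score <- if (isTRUE(m$constant)) rep(0, nrow(newdata)) else
    predict_xgb(m$model, newdata[, m$selected$features, drop = FALSE])
  out <- newdata[, intersect(c("subject_id", "test_id", "t_start", "t_end",
                               "stage_label", "fog_label"), names(newdata)),
                 drop = FALSE]
  out$fog_score <- score
  out$fog_pred <- ifelse(score >= thr, "fog", "nonfog")
  rownames(out) <- NULL
  out
}

#' @export
print.fog_single_model <- function(x, ...) {
  cat("<fog_single_model>\n")
  m <- x$fog
  if (isTRUE(m$constant)) cat("  constant non-FOG predictor\n")
  else cat(sprintf("  %d features, depth %d, %d trees\n",
                   length(m$selected$features), m$best$max_depth,
                   m$best$n_estimators))
  cat(sprintf("  FOG episode duration threshold: %.2f s\n",
              x$fog_duration_threshold_s))
  invisible(x)
}
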