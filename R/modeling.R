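#' Hyperparameter grid for the boosted-tree models
#'
#' @param scale \code{"small"} (default): a 4-point grid suitable for
#'   leave-one-subject-out experiments at desk scale; \code{"full"}: the
#'   108-point grid crossing learning_rate {0.05, 0.1, 0.3}, n_estimators
#'   {50, 100, 200}, max_depth {3, 5, 7}, subsample {0.8, 1} and
#'   colsample_bytree {0.8, 1}.
#' @return Data frame, one row per grid point.
#' @export
fog_grid <- function(scale = c("small", "full")) {
  scale <- match.arg(scale)
  if (scale == "small") {
    expand.grid(learning_rate = 0.1, n_estimators = 50L, max_depth = c(3L, 5L),
                subsample = 1, colsample_bytree = c(0.8, 1),
                KEEP.OUT.ATTRS = FALSE)
  } else {
    expand.grid(learning_rate = c(0.05, 0.1, 0.3), n_estimators = c(50L, 100L, 200L),
                max_depth = c(3L, 5L, 7L), subsample = c(0.8, 1),
                colsample_bytree = c(0.8, 1), KEEP.OUT.ATTRS = FALSE)
  }
}

#' Model configuration for staged FOG recognition
#'
#' @param grid Hyperparameter grid (data frame, see \code{\link{fog_grid}}).
#' @param metric Selection metric; only \code{"gm"} (geometric mean of
#'   sensitivity and specificity) is implemented.
#' @param seed Random seed controlling SMOTE and tree fitting.
#' @param max_features Named integer vector: feature-count caps for the
#'   motion, walk-FOG and turn-FOG models (defaults 50, 20, 12).
#' @param smote_k SMOTE neighbor count (default 5).
#' @param transition_margin_s Half-width in seconds of the transition zone
#'   around FOG boundaries removed from training windows (default 0.5).
#' @param inner_folds Number of subject-grouped folds used for forward
#'   selection and grid search on the training subjects (default 3).
#' @param decision_threshold Probability cutoff for the FOG decision
#'   (default 0.5).
#' @return A \code{fog_model_config} list.
#' @export
fog_model_config <- function(grid = fog_grid("small"), metric = "gm", seed = 1L,
                             max_features = c(motion = 50L, walk = 20L, turn = 12L),
                             smote_k = 5L, transition_margin_s = 0.5,
                             inner_folds = 3L, decision_threshold = 0.5) {
  stopifnot(nrow(grid) >= 1L, transition_margin_s >= 0, smote_k >= 1L,
            all(c("motion", "walk", "turn") %in% names(max_features)))
  metric <- match.arg(metric, "gm")
  structure(list(grid = grid, metric = metric, seed = as.integer(seed),
                 max_features = max_features, smote_k = as.integer(smote_k),
                 transition_margin_s = transition_margin_s,
                 inner_folds = as.integer(inner_folds),
                 decision_threshold = decision_threshold),
            class = "fog_model_config")
}

# ---- xgboost helpers --------------------------------------------------------

xgb_params <- function(row, seed) {
  list(objective = "binary:logistic", eta = row$learning_rate,
       max_depth = row$max_depth, subsample = row$subsample,
       colsample_bytree = row$colsample_bytree, nthread = 1L,
       seed = as.integer(seed))
}

fit_xgb <- function(X, y01, row, seed) {
  dm <- xgboost::xgb.DMatrix(as.matrix(X), label = y01)
  xgboost::xgb.train(params = xgb_params(row, seed), data = dm,
                     nrounds = row$n_estimators, verbose = 0)
}

predict_xgb <- function(model, X) {
  stats::predict(model, xgboost::xgb.DMatrix(as.matrix(X)))
}

# middle value of each grid dimension: the "grid center" used for gain ranking
grid_center <- function(grid) {
  ctr <- lapply(grid, function(v) {
    u <- sort(unique(v))
    u[ceiling(length(u) / 2)]
  })
  as.data.frame(ctr)
}

#' Rank features by boosted-tree split gain
#'
#' Fits a single gradient-boosted-tree ensemble at the grid-center
#' hyperparameters and ranks the features by their total split gain
#' (descending). Features the ensemble never splits on receive gain 0 and are
#' ranked last, alphabetically.
#'
#' @param X Numeric feature matrix (data frame or matrix) with named columns.
#' @param y Binary labels (factor, character or 0/1).
#' @param config A \code{\link{fog_model_config}}.
#' @return A \code{fog_selected} list: \code{features} (ordered names),
#'   \code{gain} (same order).
#' @export
rank_features_by_gain <- function(X, y, config = fog_model_config()) {
  y01 <- as_binary(y)
  if (length(unique(y01)) < 2L) stop("feature ranking needs both classes present")
  model <- fit_xgb(X, y01, grid_center(config$grid), config$seed)
  imp <- xgboost::xgb.importance(model = model)
  gain <- stats::setNames(rep(0, ncol(X)), colnames(X))
  if (!is.null(imp) && nrow(imp) > 0L) gain[imp$Feature] <- imp$Gain
  used <- names(sort(gain[gain > 0], decreasing = TRUE))
  unused <- sort(names(gain)[gain == 0])
  ord <- c(used, unused)
  structure(list(features = ord, gain = unname(gain[ord])),
            class = "fog_selected")
}

as_binary <- function(y, positive = NULL) {
  if (!is.null(positive)) return(as.integer(as.character(y) == positive))
  if (is.numeric(y)) return(as.integer(y != 0))
  u <- sort(unique(as.character(y)))
  if (length(u) > 2L) stop("labels are not binary: ", paste(u, collapse = ", "))
  as.integer(as.character(y) == u[length(u)])
}

# deterministic subject-grouped fold assignment, round robin; when positive
# counts are supplied, subjects are spread by positive count so each fold has
# a chance of carrying both classes
grouped_folds <- function(subject_ids, k, y01 = NULL) {
  subj <- sort(unique(subject_ids))
  if (!is.null(y01)) {
    pos <- vapply(subj, function(s) sum(y01[subject_ids == s]), numeric(1))
    subj <- subj[order(-pos, subj)]
  }
  k <- max(2L, min(k, length(subj)))
  fold_of <- stats::setNames(rep_len(seq_len(k), length(subj)), subj)
  unname(fold_of[subject_ids])
}

# mean GM over subject-grouped folds at a fixed feature set + hyperparameters
cv_gm <- function(X, y01, subject_ids, features, row, config) {
  fold <- grouped_folds(subject_ids, config$inner_folds, y01)
  gms <- c()
  for (f in sort(unique(fold))) {
    tr <- fold != f; te <- !tr
    if (length(unique(y01[tr])) < 2L || !any(te)) next
    model <- fit_xgb(X[tr, features, drop = FALSE], y01[tr], row, config$seed)
    p <- predict_xgb(model, X[te, features, drop = FALSE])
    pred <- as.integer(p >= config$decision_threshold)
    tp <- sum(pred == 1 & y01[te] == 1); fn <- sum(pred == 0 & y01[te] == 1)
    tn <- sum(pred == 0 & y01[te] == 0); fp <- sum(pred == 1 & y01[te] == 0)
    sens <- if (tp + fn == 0) NA else tp / (tp + fn)
    spec <- if (tn + fp == 0) NA else tn / (tn + fp)
    g <- geometric_mean(sens, spec)
    if (is.finite(g)) gms <- c(gms, g)
  }
  if (length(gms) == 0L) return(NA_real_)
  mean(gms)
}

#' Gain-ordered forward feature selection
#'
#' Adds features one at a time in gain order; after each addition the
#' candidate prefix is scored by subject-grouped cross-validated GM; the
#' prefix with the highest score is kept (ties break toward the smaller
#' prefix), capped at \code{cap} features.
#'
#' @param X,y Feature matrix and binary labels.
#' @param subject_ids Subject identifier per row (grouping for the inner CV).
#' @param ranked A \code{fog_selected} ranking from
#'   \code{\link{rank_features_by_gain}}.
#' @param config A \code{\link{fog_model_config}}.
#' @param cap Maximum number of selected features.
#' @return A \code{fog_selected} with the chosen prefix and its selection
#'   trace (attribute \code{"trace"}: prefix size vs CV GM).
#' @export
forward_select <- function(X, y, subject_ids, ranked,
                           config = fog_model_config(), cap = 20L) {
  stopifnot(length(ranked$features) >= 1L)
  y01 <- as_binary(y)
  row <- grid_center(config$grid)
  kmax <- min(cap, length(ranked$features))
  trace <- numeric(kmax)
  for (k in seq_len(kmax)) {
    trace[k] <- cv_gm(X, y01, subject_ids, ranked$features[seq_len(k)], row, config)
  }
  if (all(is.na(trace))) {
    warning("no usable inner fold for forward selection; ",
            "keeping the gain ranking up to the cap")
    best <- max(1L, min(kmax, sum(ranked$gain > 0)))
  } else {
    best <- which(trace >= max(trace, na.rm = TRUE) - 1e-12)[1]  # ties: smallest prefix
  }
  sel <- structure(list(features = ranked$features[seq_len(best)],
                        gain = ranked$gain[seq_len(best)]),
                   class = "fog_selected")
  attr(sel, "trace") <- data.frame(size = seq_len(kmax), gm = trace)
  sel
}

#' Remove transition windows around FOG boundaries (training only)
#'
#' Windows whose start time lies within \code{margin_s} seconds (either side)
#' of any FOG/non-FOG annotation boundary carry ambiguous labels and are
#' dropped before training. Test windows are never filtered.
#'
#' @param fm Feature matrix rows (needs \code{subject_id}, \code{test_id},
#'   \code{t_start}).
#' @param boundaries Named list keyed by \code{"<subject_id>/<test_id>"},
#'   each a numeric vector of FOG boundary times in seconds.
#' @param margin_s Margin half-width in seconds (default 0.5).
#' @return The filtered feature matrix.
#' @export
remove_transition_windows <- function(fm, boundaries, margin_s = 0.5) {
  if (margin_s <= 0 || length(boundaries) == 0L) return(fm)
  key <- paste0(fm$subject_id, "/", fm$test_id)
  drop <- logical(nrow(fm))
  for (k in names(boundaries)) {
    b <- boundaries[[k]]
    if (length(b) == 0L) next
    rows <- which(key == k)
    if (length(rows) == 0L) next
    near <- vapply(fm$t_start[rows],
                   function(t) any(abs(t - b) <= margin_s + 1e-9), logical(1))
    drop[rows[near]] <- TRUE
  }
  keep_attrs(fm[!drop, , drop = FALSE], fm)
}

keep_attrs <- function(new, old) {
  attr(new, "feature_cols") <- attr(old, "feature_cols")
  attr(new, "fps") <- attr(old, "fps")
  new
}

# boundary times (s) of the FOG intervals of each recording's annotations
fog_boundaries <- function(annotations, fps) {
  lapply(annotations, function(ann) {
    if (nrow(ann$fog) == 0L) return(numeric(0))
    sort(c(ann$fog[, 1], ann$fog[, 2])) / fps
  })
}

#' SMOTE minority oversampling
#'
#' Oversamples the minority class to parity with the majority by synthetic
#' minority oversampling: each synthetic point is a convex combination of a
#' minority sample and one of its \code{k} nearest minority neighbors
#' (Euclidean), at a uniform random fraction. Deterministic under
#' \code{seed}; the majority class is untouched.
#'
#' @param X Numeric feature matrix.
#' @param y Binary labels (any two-level coding).
#' @param k Neighbor count (default 5); reduced with a warning when the
#'   minority class has fewer than \code{k + 1} members.
#' @param seed Random seed.
#' @return List with balanced \code{X} (matrix) and \code{y} (same coding as
#'   input), original rows first.
#' @export
smote_balance <- function(X, y, k = 5L, seed = 1L) {
  X <- as.matrix(X)
  u <- sort(unique(as.character(y)))
  stopifnot(length(u) == 2L)
  counts <- table(factor(as.character(y), levels = u))
  if (counts[1] == counts[2]) return(list(X = X, y = y))
  minority <- u[which.min(counts)]
  n_new <- as.integer(max(counts) - min(counts))
  idx_min <- which(as.character(y) == minority)
  if (length(idx_min) < 2L) stop("SMOTE needs at least 2 minority samples")
  if (length(idx_min) < k + 1L) {
    k <- length(idx_min) - 1L
    warning("SMOTE neighbor count reduced to ", k,
            " (minority class has only ", length(idx_min), " samples)")
  }
  M <- X[idx_min, , drop = FALSE]
  d <- as.matrix(stats::dist(M))
  diag(d) <- Inf
  ord <- apply(d, 1, function(r) order(r)[seq_len(k)])
  nn <- if (k == 1L) matrix(ord, ncol = 1L) else t(ord)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  base_i <- rep_len(seq_along(idx_min), n_new)
  pick <- nn[cbind(base_i, sample.int(k, n_new, replace = TRUE))]
  lam <- stats::runif(n_new)
  Xnew <- M[base_i, , drop = FALSE] +
    lam * (M[pick, , drop = FALSE] - M[base_i, , drop = FALSE])
  ynew <- if (is.factor(y)) factor(rep(minority, n_new), levels = levels(y))
          else rep(minority, n_new)
  list(X = rbind(X, Xnew), y = c(as.character(y), as.character(ynew)))
}

#' Grid search with subject-grouped validation
#'
#' Scores every grid point by mean GM over subject-grouped folds of the
#' training subjects, then refits on all rows at the best point (ties break
#' toward the first row in grid order).
#'
#' @param X,y Feature matrix and binary labels.
#' @param subject_ids Subject identifier per row.
#' @param config A \code{\link{fog_model_config}}.
#' @param features Feature subset to use (default: all columns).
#' @return List with \code{model} (xgboost handle), \code{best} (grid row),
#'   \code{grid_table} (grid with a \code{cv_gm} column) and
#'   \code{features}.
#' @export
grid_search_train <- function(X, y, subject_ids, config = fog_model_config(),
                              features = colnames(X)) {
  y01 <- as_binary(y)
  if (length(unique(subject_ids)) < 2L && nrow(config$grid) > 1L)
    stop("grid search needs at least 2 training subjects")
  scores <- vapply(seq_len(nrow(config$grid)), function(i)
    cv_gm(X, y01, subject_ids, features, config$grid[i, , drop = FALSE], config),
    numeric(1))
  if (all(is.na(scores)))
    stop("all grid points degenerate (no fold had both classes)")
  best_i <- which(scores >= max(scores, na.rm = TRUE) - 1e-12 & !is.na(scores))[1]
  best <- config$grid[best_i, , drop = FALSE]
  model <- fit_xgb(X[, features, drop = FALSE], y01, best, config$seed)
  list(model = model, best = best,
       grid_table = cbind(config$grid, cv_gm = scores), features = features)
}
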