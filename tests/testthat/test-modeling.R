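# small separable classification fixture: f1 separates, rest is noise
make_class_data <- function(n = 120, n_noise = 9, seed = 5) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  X <- cbind(f1 = y * 2 + stats::rnorm(n, sd = 0.2),
             matrix(stats::rnorm(n * n_noise), n,
                    dimnames = list(NULL, paste0("noise", seq_len(n_noise)))))
  subj <- rep(sprintf("P%02d", 1:6), length.out = n)
  list(X = X, y = y, subj = subj)
}

test_that("gain ranking puts the separating feature first, noise last", {
  d <- make_class_data()
  cfg <- tiny_config()
  ranked <- rank_features_by_gain(d$X, d$y, cfg)
  expect_equal(ranked$features[1], "f1")
  expect_true(all(diff(ranked$gain[ranked$gain > 0]) <= 1e-12))
  # determinism under a fixed seed, also with a duplicated column
  X2 <- cbind(d$X, f1_copy = d$X[, "f1"])
  r1 <- rank_features_by_gain(X2, d$y, cfg)
  r2 <- rank_features_by_gain(X2, d$y, cfg)
  expect_identical(r1, r2)
  expect_error(rank_features_by_gain(d$X, rep(1, nrow(d$X)), cfg),
               "both classes")
})

test_that("forward selection keeps one informative feature among noise", {
  d <- make_class_data()
  cfg <- tiny_config()
  ranked <- rank_features_by_gain(d$X, d$y, cfg)
  sel <- forward_select(d$X, d$y, d$subj, ranked, cfg, cap = 10)
  # brute-force oracle: score every prefix with the same CV and take the best
  trace <- attr(sel, "trace")
  oracle <- vapply(seq_len(10), function(k)
    fogvision:::cv_gm(d$X, d$y, d$subj, ranked$features[seq_len(k)],
                      fogvision:::grid_center(cfg$grid), cfg), numeric(1))
  expect_equal(trace$gm, oracle)
  expect_equal(length(sel$features),
               which(oracle >= max(oracle, na.rm = TRUE) - 1e-12)[1])
  expect_equal(sel$features[1], "f1")
  expect_lte(length(sel$features), 3)   # noise prefixes cannot beat f1 alone

  # identical copies of one signal: tie broken toward the smallest prefix
  Xc <- d$X[, c("f1", "f1", "f1")]
  colnames(Xc) <- c("a", "b", "c")
  rc <- structure(list(features = c("a", "b", "c"), gain = c(3, 2, 1)),
                  class = "fog_selected")
  selc <- forward_select(Xc, d$y, d$subj, rc, cfg, cap = 3)
  expect_equal(length(selc$features), 1)

  # cap limits the prefix length
  sel3 <- forward_select(d$X, d$y, d$subj, ranked, cfg, cap = 1)
  expect_equal(sel3$features, "f1")
})

test_that("transition-window removal drops starts near FOG boundaries only", {
  fm <- data.frame(subject_id = "S1", test_id = "TUG",
                   t_start = seq(0, 20, by = 0.1))
  attr(fm, "feature_cols") <- character(0); attr(fm, "fps") <- 30
  b <- list("S1/TUG" = 10.0)
  out <- remove_transition_windows(fm, b, margin_s = 0.5)
  dropped <- setdiff(fm$t_start, out$t_start)
  expect_equal(sort(dropped), seq(9.5, 10.5, by = 0.1), tolerance = 1e-9)
  # margin 0 and no-boundary cases are identities
  expect_equal(remove_transition_windows(fm, b, margin_s = 0)$t_start,
               fm$t_start)
  expect_equal(remove_transition_windows(fm, list("S1/TUG" = numeric(0)),
                                         0.5)$t_start, fm$t_start)
  # training row count is monotone non-increasing in the margin
  ns <- vapply(c(0, 0.2, 0.5, 1, 2),
               function(m) nrow(remove_transition_windows(fm, b, m)), 0)
  expect_true(all(diff(ns) <= 0))
  # other recordings untouched
  fm2 <- fm; fm2$subject_id <- "S2"
  expect_equal(nrow(remove_transition_windows(fm2, b, 0.5)), nrow(fm2))
})

test_that("SMOTE balances to parity with convex minority combinations", {
  set.seed(3)
  # already balanced: identity
  Xb <- matrix(stats::rnorm(40), 20)
  yb <- rep(c("a", "b"), 10)
  out <- smote_balance(Xb, yb, k = 3, seed = 1)
  expect_equal(out$X, Xb)

  # 100 majority vs 10 minority -> 100/100, new rows convex in the minority
  X <- rbind(matrix(stats::rnorm(200), 100), matrix(stats::rnorm(20) + 5, 10))
  y <- c(rep("nonfog", 100), rep("fog", 10))
  out <- suppressWarnings(smote_balance(X, y, k = 5, seed = 2))
  expect_equal(unname(table(out$y)["fog"]), 100)
  expect_equal(unname(table(out$y)["nonfog"]), 100)
  newX <- out$X[111:200, , drop = FALSE]
  minX <- X[101:110, , drop = FALSE]
  # each synthetic point lies on a segment between two minority points:
  # brute-force over all pairs, solve for lambda per pair, check residual
  on_segment <- function(p) {
    for (i in 1:9) for (j in (i + 1):10) {
      d <- minX[j, ] - minX[i, ]
      lam <- sum((p - minX[i, ]) * d) / sum(d * d)
      if (lam >= -1e-9 && lam <= 1 + 1e-9 &&
          sqrt(sum((minX[i, ] + lam * d - p)^2)) < 1e-9) return(TRUE)
    }
    FALSE
  }
  expect_true(all(apply(newX, 1, on_segment)))
  # deterministic under seed
  out2 <- suppressWarnings(smote_balance(X, y, k = 5, seed = 2))
  expect_identical(out$X, out2$X)

  # two-point minority: every synthetic point on segment [a, b]
  X2 <- rbind(matrix(stats::rnorm(60), 30), c(0, 0), c(1, 2))
  y2 <- c(rep("n", 30), "f", "f")
  out3 <- suppressWarnings(smote_balance(X2, y2, k = 5, seed = 4))
  syn <- out3$X[33:nrow(out3$X), , drop = FALSE]
  lam <- syn[, 2] / 2
  expect_equal(syn[, 1], lam * 1, tolerance = 1e-9)
  expect_true(all(lam >= 0 & lam <= 1))

  expect_error(smote_balance(X2[1:31, ], y2[1:31], 5, 1), "at least 2")
})

test_that("grid search picks the stronger setting and is reproducible", {
  d <- make_class_data(n = 180, n_noise = 3)
  cfg <- tiny_config()
  # grid of one: equivalent to a single fit
  fit1 <- grid_search_train(d$X, d$y, d$subj, cfg)
  direct <- fogvision:::fit_xgb(d$X, d$y, cfg$grid[1, ], cfg$seed)
  expect_equal(fogvision:::predict_xgb(fit1$model, d$X),
               fogvision:::predict_xgb(direct, d$X))

  # crippled vs healthy setting: healthy wins
  grid2 <- rbind(
    data.frame(learning_rate = 1e-4, n_estimators = 1L, max_depth = 1L,
               subsample = 1, colsample_bytree = 1),
    data.frame(learning_rate = 0.1, n_estimators = 50L, max_depth = 3L,
               subsample = 1, colsample_bytree = 1))
  cfg2 <- fog_model_config(grid = grid2, seed = 1, inner_folds = 2L)
  fit2 <- grid_search_train(d$X, d$y, d$subj, cfg2)
  expect_equal(fit2$best$n_estimators, 50L)
  expect_equal(nrow(fit2$grid_table), 2)
  # identical rerun: identical choice and predictions
  fit2b <- grid_search_train(d$X, d$y, d$subj, cfg2)
  expect_equal(fit2$best, fit2b$best)
  expect_equal(fogvision:::predict_xgb(fit2$model, d$X),
               fogvision:::predict_xgb(fit2b$model, d$X))
})

test_that("the duration threshold is the 10% interpolated quantile", {
  anns <- list(
    "A/TUG" = annotation_track(fog = cbind(c(0, 60), c(30, 120))),     # 1, 2 s
    "B/TUG" = annotation_track(fog = cbind(c(0, 300, 600),
                                           c(120, 540, 900))))         # 4, 8, 10 s
  expect_equal(fog_duration_threshold(anns, fps = 30), 1.4)
  expect_equal(fog_duration_threshold(list("A/TUG" = annotation_track()), 30), 0)
})
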