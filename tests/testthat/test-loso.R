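# one shared small cohort for the model-level tests
local({
  ch <- simulate_cohort(tiny_sim_params(n_subjects = 4, seed = 7))
  ex <- extract_cohort_features(ch$recordings, small_feature_spec())
  assign("loso_ex", ex, envir = topenv())
})

test_that("the staged fit trains, respects caps, and predicts deterministically", {
  cfg <- tiny_config()
  fit <- suppressWarnings(fog_staged_fit(loso_ex$fm, loso_ex$annotations, cfg))
  expect_s3_class(fit, "fog_staged_model")
  expect_lte(length(fit$motion$selected$features), cfg$max_features[["motion"]])
  if (!isTRUE(fit$walk_fog$constant))
    expect_lte(length(fit$walk_fog$selected$features),
               cfg$max_features[["walk"]])
  # threshold equals the quantile of this cohort's annotated durations
  expect_equal(fit$fog_duration_threshold_s,
               fog_duration_threshold(loso_ex$annotations, 30))
  expect_output(print(fit), "fog_staged_model")

  preds <- predict(fit, loso_ex$fm)
  expect_equal(nrow(preds), nrow(loso_ex$fm))
  expect_true(all(preds$fog_pred == ifelse(preds$fog_score >= 0.5,
                                           "fog", "nonfog")))
  # duplicated windows get duplicated identical predictions
  dup <- rbind(loso_ex$fm[1:5, ], loso_ex$fm[1:5, ])
  pd <- predict(fit, dup)
  expect_equal(pd[1:5, ], pd[6:10, ], ignore_attr = TRUE)
  # missing feature column errors by name
  nd <- loso_ex$fm
  gone <- fit$motion$selected$features[1]
  nd[[gone]] <- NULL
  expect_error(predict(fit, nd), gone)
})

test_that("an all-FOG-free training set yields constant non-FOG predictors", {
  ch <- simulate_cohort({p <- tiny_sim_params(n_subjects = 3); p$fog_prevalence <- 0; p})
  ex <- extract_cohort_features(ch$recordings, small_feature_spec())
  w <- testthat::capture_warnings(
    fit <- fog_staged_fit(ex$fm, ex$annotations, tiny_config()))
  expect_true(any(grepl("constant non-FOG", w)))
  expect_true(fit$walk_fog$constant)
  expect_true(fit$turn_fog$constant)
  expect_equal(fit$fog_duration_threshold_s, 0)
  preds <- predict(fit, ex$fm)
  expect_true(all(preds$fog_pred == "nonfog"))
})

test_that("LOSO keeps one fold per subject with no held-out leakage", {
  cfg <- tiny_config()
  res <- suppressWarnings(loso_evaluate(loso_ex, cfg, model = "staged"))
  subjects <- sort(unique(loso_ex$fm$subject_id))
  expect_equal(sort(names(res$folds)), subjects)
  # leakage fingerprints: the held-out subject never appears in training rows
  for (s in names(res$folds)) {
    fp <- res$folds[[s]]$training_fingerprint
    expect_false(any(startsWith(fp, paste0(s, "|"))))
    expect_setequal(unique(sub("\\|.*$", "", fp)), setdiff(subjects, s))
  }
  # pooled held-out windows partition the dataset
  expect_equal(nrow(res$predictions), nrow(loso_ex$fm))
  key <- function(df) sort(paste(df$subject_id, df$t_start))
  expect_equal(key(res$predictions), key(loso_ex$fm))
  # GM identity in every report
  for (m in list(res$pooled$window, res$pooled$episode, res$pooled$motion))
    if (!m$degenerate)
      expect_equal(m$gm^2, m$sensitivity * m$specificity, tolerance = 1e-12)
  # the per-fold dot plot renders without error
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off(), add = TRUE)
  expect_invisible(plot(res))
})

test_that("subject order does not change pooled LOSO metrics", {
  cfg <- tiny_config()
  res1 <- suppressWarnings(loso_evaluate(loso_ex, cfg))
  ex_rev <- loso_ex
  ex_rev$fm <- fogvision:::keep_attrs(
    loso_ex$fm[rev(seq_len(nrow(loso_ex$fm))), ], loso_ex$fm)
  ex_rev$annotations <- rev(loso_ex$annotations)
  ex_rev$n_frames <- rev(loso_ex$n_frames)
  res2 <- suppressWarnings(loso_evaluate(ex_rev, cfg))
  expect_equal(res1$pooled$episode$counts, res2$pooled$episode$counts)
  expect_equal(res1$pooled$window$counts, res2$pooled$window$counts)
})

test_that("the single-model and experiment wrapper produce a comparison", {
  dir <- withr::local_tempdir()
  cfg <- tiny_config()
  out <- suppressWarnings(run_loso_experiment(
    tiny_sim_params(n_subjects = 4, seed = 7), cfg,
    feature_spec = small_feature_spec(), out_dir = dir))
  expect_equal(nrow(out$comparison), 2)
  expect_setequal(out$comparison$model, c("multi-stage", "non-staged"))
  for (i in 1:2)
    expect_equal(out$comparison$gm[i]^2,
                 out$comparison$sensitivity[i] * out$comparison$specificity[i],
                 tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "metrics.json")))
  expect_true(file.exists(file.path(dir, "comparison.csv")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  # rerun reproducibility: byte-identical metrics JSON
  dir2 <- withr::local_tempdir()
  out2 <- suppressWarnings(run_loso_experiment(
    tiny_sim_params(n_subjects = 4, seed = 7), cfg,
    feature_spec = small_feature_spec(), out_dir = dir2))
  expect_identical(readLines(file.path(dir, "metrics.json")),
                   readLines(file.path(dir2, "metrics.json")))
})
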