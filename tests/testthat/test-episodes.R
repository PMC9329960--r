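mk_preds <- function(labels, step = 0.1, win = 2) {
  t0 <- (seq_along(labels) - 1) * step
  data.frame(subject_id = "S", test_id = "T", t_start = t0, t_end = t0 + win,
             fog_pred = labels, stringsAsFactors = FALSE)
}

test_that("windows merge into episodes by the run rule", {
  eps <- windows_to_episodes(mk_preds(c("nonfog", "nonfog", "fog", "fog",
                                        "fog", "nonfog")))
  fog <- eps[eps$label == "fog", ]
  expect_equal(nrow(fog), 1)
  expect_equal(fog$t_start, 0.2)
  expect_equal(fog$t_end, 2.4)
  expect_equal(nrow(eps), 3)

  # all non-FOG: a single episode covering the whole span
  eps1 <- windows_to_episodes(mk_preds(rep("nonfog", 30)))
  expect_equal(nrow(eps1), 1)
  expect_equal(eps1$t_end - eps1$t_start, 0.1 * 29 + 2)

  # alternating labels: one episode per window
  eps4 <- windows_to_episodes(mk_preds(c("fog", "nonfog", "fog", "nonfog")))
  expect_equal(nrow(eps4), 4)

  # a gap larger than the step splits an otherwise continuous run
  p <- mk_preds(rep("fog", 6))
  p$t_start[4:6] <- p$t_start[4:6] + 1.0
  p$t_end <- p$t_start + 2
  expect_equal(nrow(windows_to_episodes(p)), 2)
})

test_that("duration postprocessing removes short FOG episodes and merges", {
  eps <- data.frame(subject_id = "S", test_id = "T",
                    label = c("nonfog", "fog", "nonfog", "fog", "nonfog"),
                    t_start = c(0, 5, 5.3, 10, 15),
                    t_end = c(5, 5.3, 10, 15, 20), stringsAsFactors = FALSE)
  out <- postprocess_episodes(eps, 1.0)
  expect_equal(out$label, c("nonfog", "fog", "nonfog"))
  expect_equal(out$t_start, c(0, 10, 15))
  # relabeled short episode merged with both neighbors
  triple <- eps[1:3, ]
  out2 <- postprocess_episodes(triple, 1.0)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$label, "nonfog")
  expect_equal(c(out2$t_start, out2$t_end), c(0, 10))
  # threshold 0 is the identity
  expect_equal(postprocess_episodes(eps, 0), eps)
  # idempotence
  expect_equal(postprocess_episodes(out, 1.0), out)
  # monotone: a larger threshold never yields more FOG episodes
  thr <- c(0, 0.5, 2, 6, 100)
  nfog <- vapply(thr, function(m) sum(postprocess_episodes(eps, m)$label == "fog"), 0)
  expect_true(all(diff(nfog) <= 0))
})

test_that("window-level postprocessing flips exactly the short-episode windows", {
  labels <- c(rep("nonfog", 5), "fog", rep("nonfog", 5), rep("fog", 10))
  p <- mk_preds(labels)
  out <- postprocess_window_predictions(p, 2.5)
  # the isolated window's 2.0-s episode goes; the 2.9-s run stays
  expect_equal(out$fog_pred[6], "nonfog")
  expect_equal(out$fog_pred[12:21], rep("fog", 10))
  expect_equal(postprocess_window_predictions(p, 0), p)
})

test_that("truth episodes complement FOG and unknown spans", {
  ann <- annotation_track(fog = cbind(300, 600), unknown = cbind(750, 900))
  te <- truth_episodes(ann, fps = 30, n_frames = 1200, subject_id = "Z")
  expect_equal(te$label, c("nonfog", "fog", "nonfog", "nonfog"))
  expect_equal(te$t_start, c(0, 10, 20, 30))
  expect_equal(te$t_end, c(10, 20, 25, 40))
  # no annotations: one non-FOG episode over the whole recording
  te0 <- truth_episodes(annotation_track(), 30, 300)
  expect_equal(nrow(te0), 1)
  expect_equal(te0$t_end, 10)
})

test_that("episode metrics agree with the frame-rasterizing oracle", {
  for (seed in 1:12) {
    inst <- random_prediction_instance(seed)
    m <- episode_metrics(inst$preds, inst$truth)
    o <- oracle_episode_metrics(inst$preds, inst$truth)
    expect_equal(m$sensitivity, o$sens, info = paste("seed", seed))
    expect_equal(m$specificity, o$spec, info = paste("seed", seed))
    if (!m$degenerate)
      expect_equal(m$gm^2, m$sensitivity * m$specificity, tolerance = 1e-12)
  }
})

test_that("episode metric edge cases follow their definitions", {
  truth <- data.frame(subject_id = "S", test_id = "T",
                      label = rep(c("fog", "nonfog"), 8)[1:16],
                      t_start = (0:15) * 10, t_end = (0:15) * 10 + 10,
                      stringsAsFactors = FALSE)
  # detect 7 of the 8 FOG episodes
  hits <- truth[truth$label == "fog", ][1:7, ]
  preds <- data.frame(subject_id = "S", test_id = "T",
                      t_start = hits$t_start + 4, t_end = hits$t_start + 6,
                      fog_pred = "fog", stringsAsFactors = FALSE)
  m <- episode_metrics(preds, truth)
  expect_equal(m$sensitivity, 0.875)
  expect_equal(m$specificity, 1)
  # no predicted FOG anywhere: sensitivity 0, specificity 1
  none <- preds; none$fog_pred <- "nonfog"
  m0 <- episode_metrics(none, truth)
  expect_equal(m0$sensitivity, 0)
  expect_equal(m0$specificity, 1)
  # no truth FOG episodes: sensitivity undefined and flagged
  mna <- episode_metrics(none, truth[truth$label == "nonfog", ])
  expect_true(is.na(mna$sensitivity))
  expect_true(mna$degenerate)
})
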