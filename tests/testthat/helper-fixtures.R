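# Shared fixture builders. Everything is generated in code; nothing binary.

# minimal deterministic pose sequence: template skeleton, optional per-frame
# isotropic scale and translation, no noise
make_pose_seq <- function(n = 10, fps = 30, scale = 1, dx = 0, dy = 0,
                          subject_id = "S", test_id = "TUG") {
  tmpl <- fogvision:::body25_template()
  x <- matrix(rep(tmpl[, 1], each = n), n, 25) * scale + dx
  y <- matrix(rep(tmpl[, 2], each = n), n, 25) * scale + dy
  conf <- matrix(0.9, n, 25)
  pose_sequence(x, y, conf, fps = fps, subject_id = subject_id,
                test_id = test_id)
}

# fast small-cohort simulation parameters (short recordings, fewer subjects)
tiny_sim_params <- function(n_subjects = 4, seed = 7, ...) {
  sim_params(n_subjects = n_subjects, fog_prevalence = 0.5, seed = seed,
             walk_s = c(8, 10), turn_s = c(2.5, 3),
             fog_duration_s = c(2.5, 5), fog_episodes_range = c(1L, 2L), ...)
}

# small, fast model configuration for unit tests
tiny_config <- function(seed = 1) {
  fog_model_config(grid = fog_grid("small")[1, , drop = FALSE], seed = seed,
                   max_features = c(motion = 5L, walk = 4L, turn = 3L),
                   inner_folds = 2L)
}

# narrow feature spec (keeps extraction cheap where the full bank is overkill)
small_feature_spec <- function() {
  fog_feature_spec(
    channels = c("pairdiff_shoulders_x", "pairdiff_ankles_x",
                 "speed_RHeel_y", "speed_LHeel_y", "pos_LAnkle_y"),
    statistics = c("min", "max", "mean_abs", "crest", "p90",
                   "band_0p5_3", "band_1_1p5", "fi", "amp_peak"))
}

# independent brute-force DFT: direct summation, no fft()
naive_dft_power <- function(x, fs) {
  n <- length(x)
  xc <- x - mean(x)
  nfreq <- n %/% 2 + 1
  freq <- (seq_len(nfreq) - 1) * fs / n
  amp <- vapply(seq_len(nfreq) - 1, function(k) {
    re <- sum(xc * cos(-2 * pi * k * (seq_len(n) - 1) / n))
    im <- sum(xc * sin(-2 * pi * k * (seq_len(n) - 1) / n))
    sqrt(re^2 + im^2)
  }, numeric(1))
  sided <- rep(2, nfreq); sided[1] <- 1
  if (n %% 2 == 0) sided[nfreq] <- 1
  list(frequencies = freq, power = sided * amp^2 / (n^2 * (fs / n)),
       amplitude = amp)
}

# trapezoid band integral with edge interpolation, written independently
naive_band_area <- function(freq, power, lo, hi) {
  hi <- min(hi, max(freq)); lo <- max(lo, 0)
  if (lo >= hi) return(0)
  g <- sort(unique(c(lo, hi, freq[freq > lo & freq < hi])))
  vals <- stats::approx(freq, power, xout = g)$y
  sum(diff(g) * (head(vals, -1) + tail(vals, -1)) / 2)
}

# frame-rasterizing episode-metric oracle: paints predicted-FOG window spans
# onto a fine time grid and scans the truth episodes frame by frame
oracle_episode_metrics <- function(pred_windows, truth_eps, dt = 0.01) {
  total <- max(truth_eps$t_end)
  grid <- seq(0, total, by = dt)
  fogw <- pred_windows[pred_windows$fog_pred == "fog", , drop = FALSE]
  painted <- rep(FALSE, length(grid))
  for (i in seq_len(nrow(fogw)))
    painted[grid >= fogw$t_start[i] + dt / 2 & grid <= fogw$t_end[i] - dt / 2] <- TRUE
  tp <- fn <- tn <- fp <- 0
  for (i in seq_len(nrow(truth_eps))) {
    sel <- grid >= truth_eps$t_start[i] & grid <= truth_eps$t_end[i]
    if (truth_eps$label[i] == "fog") {
      if (any(painted[sel])) tp <- tp + 1 else fn <- fn + 1
    } else {
      # containment: some predicted-FOG window entirely inside this episode
      contained <- any(fogw$t_start >= truth_eps$t_start[i] - 1e-9 &
                         fogw$t_end <= truth_eps$t_end[i] + 1e-9)
      if (contained) fp <- fp + 1 else tn <- tn + 1
    }
  }
  list(sens = if (tp + fn == 0) NA else tp / (tp + fn),
       spec = if (tn + fp == 0) NA else tn / (tn + fp))
}

# random window-prediction instance for the oracle comparison
random_prediction_instance <- function(seed, n_windows = 50) {
  set.seed(seed)
  step <- 0.1; win <- 2
  t_start <- (seq_len(n_windows) - 1) * step
  preds <- data.frame(subject_id = "S", test_id = "T", t_start = t_start,
                      t_end = t_start + win,
                      fog_pred = sample(c("fog", "nonfog"), n_windows, TRUE,
                                        prob = c(0.3, 0.7)))
  total <- max(preds$t_end)
  nb <- sample(1:3, 1)
  cuts <- sort(stats::runif(nb * 2, 0.5, total - 0.5))
  fog_iv <- matrix(cuts, ncol = 2, byrow = TRUE)
  fog_iv <- fog_iv[fog_iv[, 2] - fog_iv[, 1] > 0.3, , drop = FALSE]
  ann <- annotation_track(fog = round(fog_iv * 30))
  truth <- truth_episodes(ann, fps = 30, n_frames = ceiling(total * 30),
                          subject_id = "S", test_id = "T")
  list(preds = preds, truth = truth)
}
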