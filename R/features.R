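#' Time-domain window features
#'
#' Computes the time-domain statistic bank of a single window:
#' \describe{
#'   \item{min, max, mean, ptp}{extrema, mean, peak-to-peak (max - min)}
#'   \item{mean_abs}{mean of absolute values}
#'   \item{mse}{mean of squared values}
#'   \item{min_sq}{minimum of squared values}
#'   \item{p90}{90th percentile: the order statistic at position
#'     \code{1 + 0.9 (n - 1)}, linearly interpolated}
#'   \item{skewness}{third standardized central moment (population moments);
#'     0 when the window is constant}
#'   \item{kurtosis}{non-central fourth-moment coefficient, mean of
#'     \code{x^4} (not the standardized excess kurtosis)}
#'   \item{crest}{crest factor max(x) / RMS; 0 when RMS is 0}
#'   \item{clearance}{clearance factor max(|x|) / (mean sqrt(|x|))^2; 0 when
#'     the denominator is 0. With \code{clearance_literal = TRUE} the crest
#'     factor is returned instead (some feature tables define the two
#'     identically).}
#'   \item{entropy}{Shannon entropy (nats) of a 10-bin histogram of the
#'     window values; 0 for a constant window}
#' }
#'
#' @param x Numeric window samples, length at least 2, finite.
#' @param clearance_literal Use the crest-factor formula for the clearance
#'   factor (default \code{FALSE}).
#' @return Named numeric vector of the statistics above.
#' @export
time_features <- function(x, clearance_literal = FALSE) {
  n <- length(x)
  stopifnot(n >= 2L, all(is.finite(x)))
  mn <- min(x); mx <- max(x); mu <- mean(x)
  mse <- mean(x^2)
  rms <- sqrt(mse)
  sd_pop <- sqrt(mean((x - mu)^2))
  skew <- if (sd_pop == 0) 0 else mean(((x - mu) / sd_pop)^3)
  crest <- if (rms == 0) 0 else mx / rms
  clr_den <- mean(sqrt(abs(x)))^2
  clearance <- if (clearance_literal) crest
               else if (clr_den == 0) 0 else max(abs(x)) / clr_den
  c(min = mn, max = mx, mean = mu, mean_abs = mean(abs(x)), mse = mse,
    min_sq = min(x^2), ptp = mx - mn, p90 = percentile_interp(x, 0.9),
    skewness = skew, kurtosis = mean(x^4), crest = crest,
    clearance = clearance, entropy = hist_entropy(x, 10L))
}

# order statistic at position 1 + p (n - 1), linear interpolation
percentile_interp <- function(x, p) {
  xs <- sort(x)
  pos <- 1 + p * (length(x) - 1)
  lo <- floor(pos); hi <- ceiling(pos)
  xs[lo] + (pos - lo) * (xs[hi] - xs[lo])
}

hist_entropy <- function(x, bins = 10L) {
  if (max(x) == min(x)) return(0)
  cuts <- seq(min(x), max(x), length.out = bins + 1L)
  cnt <- tabulate(pmin(findInterval(x, cuts, rightmost.closed = TRUE), bins),
                  nbins = bins)
  p <- cnt[cnt > 0] / length(x)
  -sum(p * log(p))
}

#' Sample entropy (SampEn)
#'
#' Conventional sample entropy of a window: the negative log of the
#' conditional probability that sequences matching for \code{m} points
#' (Chebyshev distance within \code{r}) also match for \code{m + 1} points.
#' Offered as an alternative to the histogram entropy in
#' \code{\link{time_features}}.
#'
#' @param x Numeric vector.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance; default 0.2 times the window standard deviation.
#' @return Sample entropy (nats); \code{Inf} when no template matches extend.
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  if (n <= m + 1L || !is.finite(r) || r <= 0) return(NA_real_)
  count_matches <- function(mm) {
    emb <- stats::embed(x, mm)        # rows are length-mm templates
    nt <- nrow(emb)
    cnt <- 0L
    for (i in seq_len(nt - 1L)) {
      d <- abs(emb[(i + 1L):nt, , drop = FALSE] -
                 matrix(emb[i, ], nt - i, mm, byrow = TRUE))
      cnt <- cnt + sum(apply(d, 1, max) <= r)
    }
    cnt
  }
  B <- count_matches(m); A <- count_matches(m + 1L)
  if (B == 0L) return(NA_real_)
  if (A == 0L) return(Inf)
  -log(A / B)
}

#' Periodogram spectrum of a window
#'
#' Mean-removed, untapered (rectangular window) real discrete Fourier
#' transform. The one-sided power densities are scaled so that
#' \code{sum(power) * df} equals the window's (population) variance, with
#' \code{df = fs / n} (Parseval-consistent periodogram).
#'
#' @param x Numeric window samples, length at least 4.
#' @param fs Sampling frequency (Hz).
#' @return A \code{fog_spectrum}: list with \code{frequencies} (Hz, from 0 to
#'   the Nyquist frequency), \code{power} (density, power per Hz),
#'   \code{amplitude} (DFT coefficient magnitudes) and \code{fs}, \code{n}.
#' @export
spectrum_window <- function(x, fs) {
  n <- length(x)
  stopifnot(n >= 4L)
  X <- stats::fft(x - mean(x))
  nfreq <- n %/% 2L + 1L
  freq <- (seq_len(nfreq) - 1) * fs / n
  amp <- Mod(X[seq_len(nfreq)])
  df <- fs / n
  sided <- rep(2, nfreq)
  sided[1] <- 1
  if (n %% 2L == 0L) sided[nfreq] <- 1
  power <- sided * amp^2 / (n^2 * df)
  structure(list(frequencies = freq, power = power, amplitude = amp,
                 fs = fs, n = n), class = "fog_spectrum")
}

#' Integrated power over a frequency band
#'
#' Trapezoidal integral of the power density over [lo, hi] Hz, with linear
#' interpolation of the density at the band edges; bands reaching past the
#' Nyquist frequency are clipped with a warning. Additive:
#' \code{band_area(a, b) + band_area(b, c) == band_area(a, c)}.
#'
#' @param spec A \code{fog_spectrum}.
#' @param lo,hi Band edges in Hz.
#' @return Band power (units^2).
#' @export
band_area <- function(spec, lo, hi) {
  f <- spec$frequencies; p <- spec$power
  nyq <- f[length(f)]
  if (hi > nyq + 1e-12) {
    warning("band upper edge ", hi, " Hz clipped to the Nyquist frequency ",
            nyq, " Hz")
    hi <- nyq
  }
  lo <- max(lo, 0)
  if (lo >= hi) return(0)
  sum(band_weights(f, lo, hi) * p)
}

# weights w such that the edge-interpolated trapezoidal integral of p over
# [lo, hi] equals sum(w * p); linear in p, so bands stay exactly additive
band_weights <- function(f, lo, hi) {
  grid <- sort(unique(c(lo, hi, f[f > lo & f < hi])))
  W <- numeric(length(f))
  # interpolation operator: value at g is a convex combination of two p's
  for (seg in seq_len(length(grid) - 1L)) {
    a <- grid[seg]; b <- grid[seg + 1L]
    h <- (b - a) / 2
    for (g in c(a, b)) {
      j <- findInterval(g, f)
      if (j >= length(f)) {
        W[length(f)] <- W[length(f)] + h
      } else if (f[j] == g) {
        W[j] <- W[j] + h
      } else {
        t <- (g - f[j]) / (f[j + 1L] - f[j])
        W[j] <- W[j] + h * (1 - t)
        W[j + 1L] <- W[j + 1L] + h * t
      }
    }
  }
  W
}

#' Spectral window features
#'
#' \describe{
#'   \item{amp_peak}{maximum DFT amplitude}
#'   \item{avg_freq}{power-weighted mean frequency (0 for an all-zero
#'     spectrum); also the "center frequency"}
#'   \item{second_power_peak}{second-largest interior local maximum of the
#'     power density (0 when there is none)}
#' }
#'
#' @param spec A \code{fog_spectrum}.
#' @return Named numeric vector.
#' @export
spectral_features <- function(spec) {
  p <- spec$power; f <- spec$frequencies
  tot <- sum(p)
  avg <- if (tot == 0) 0 else sum(f * p) / tot
  c(amp_peak = max(spec$amplitude), avg_freq = avg,
    second_power_peak = second_local_max(p))
}

second_local_max <- function(p) {
  n <- length(p)
  if (n < 3L) return(0)
  is_max <- c(p[1] > p[2],
              p[2:(n - 1)] > p[1:(n - 2)] & p[2:(n - 1)] > p[3:n],
              p[n] > p[n - 1])
  peaks <- sort(p[is_max], decreasing = TRUE)
  if (length(peaks) < 2L) 0 else peaks[2]
}

#' Freezing index of a window
#'
#' Power in the 3-8 Hz "freeze" band divided by power in the 0.5-3 Hz
#' "locomotor" band. During freezing of gait, locomotor-band power collapses
#' while leg trembling adds freeze-band power, so the index rises sharply.
#'
#' @param x Window samples.
#' @param fs Sampling frequency (Hz).
#' @param freeze_band,locomotor_band Band edges in Hz.
#' @param cap Value returned when the locomotor power is below 1e-12
#'   (default 1e6).
#' @return The freezing index (unitless ratio).
#' @export
freezing_index <- function(x, fs, freeze_band = c(3, 8),
                           locomotor_band = c(0.5, 3), cap = 1e6) {
  spec <- spectrum_window(x, fs)
  num <- band_area(spec, freeze_band[1], freeze_band[2])
  den <- band_area(spec, locomotor_band[1], locomotor_band[2])
  if (den < 1e-12) return(cap)
  min(num / den, cap)
}

# ---- feature registry -------------------------------------------------------

TIME_STATS <- c("min", "max", "mean", "mean_abs", "mse", "min_sq", "ptp",
                "p90", "skewness", "kurtosis", "crest", "clearance", "entropy")
SPECTRAL_STATS <- c("amp_peak", "avg_freq", "second_power_peak",
                    "band_0p5_3", "band_1_1p5", "band_3p5_15", "fi")
BAND_DEFS <- list(band_0p5_3 = c(0.5, 3), band_1_1p5 = c(1, 1.5),
                  band_3p5_15 = c(3.5, 15))

#' Feature specification
#'
#' A feature spec is a data frame with columns \code{statistic} and
#' \code{channel}; every pair becomes one feature column named
#' \code{"<statistic>__<channel>"}. \code{fog_feature_spec()} builds the
#' default bank: the full statistic set on the 8 left-right distance
#' channels and on lower-limb speed/acceleration/position channels plus the
#' knee angles.
#'
#' @param channels Character vector of signal-bank channel names; default as
#'   described above.
#' @param statistics Character vector of statistic names; defaults to all
#'   time and spectral statistics.
#' @return Data frame with columns \code{statistic}, \code{channel}.
#' @export
fog_feature_spec <- function(channels = NULL, statistics = NULL) {
  if (is.null(channels)) {
    channels <- c(
      paste0("pairdiff_", names(BODY25_PAIRS), "_x"),
      paste0("speed_", rep(c("RHeel", "LHeel", "RAnkle", "LAnkle"), each = 2),
             "_", c("x", "y")),
      paste0("acc_", rep(c("RHeel", "LHeel"), each = 2), "_", c("x", "y")),
      paste0("pos_", rep(c("LAnkle", "LHeel"), each = 1), "_y"),
      "knee_angle_L", "knee_angle_R")
  }
  if (is.null(statistics)) statistics <- c(TIME_STATS, SPECTRAL_STATS)
  bad <- setdiff(statistics, c(TIME_STATS, SPECTRAL_STATS, "sampen"))
  if (length(bad)) stop("unknown statistic name(s): ", paste(bad, collapse = ", "))
  expand.grid(statistic = statistics, channel = channels,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Read / write a feature spec as YAML
#'
#' The YAML file is a list of \code{{statistic, channel}} pairs.
#'
#' @param path YAML file path.
#' @export
read_feature_spec <- function(path) {
  lst <- yaml::read_yaml(path)
  data.frame(statistic = vapply(lst, `[[`, "", "statistic"),
             channel = vapply(lst, `[[`, "", "channel"),
             stringsAsFactors = FALSE)
}

#' @rdname read_feature_spec
#' @param spec Feature spec data frame.
#' @export
write_feature_spec <- function(spec, path) {
  yaml::write_yaml(lapply(seq_len(nrow(spec)), function(i)
    list(statistic = spec$statistic[i], channel = spec$channel[i])), path)
  invisible(path)
}

#' Build the window feature matrix for one or more recordings
#'
#' For every labeled window of every recording, computes all
#' (statistic, channel) pairs in the feature spec and returns one data frame
#' with the window metadata columns (\code{subject_id}, \code{test_id},
#' \code{t_start}, \code{t_end}, labels and label fractions) followed by one
#' column per feature, named \code{"<statistic>__<channel>"}. The feature
#' columns are recorded in the \code{"feature_cols"} attribute and the frame
#' rate in \code{"fps"}.
#'
#' @param dataset A list of recordings; each element a list with
#'   \code{signals} (a \code{derived_signals}) and \code{windows} (a labeled
#'   window table from \code{\link{label_windows}}).
#' @param feature_spec Feature spec from \code{\link{fog_feature_spec}}.
#' @param clearance_literal Passed to \code{\link{time_features}}.
#' @return The feature matrix data frame.
#' @export
build_feature_matrix <- function(dataset, feature_spec = fog_feature_spec(),
                                 clearance_literal = FALSE) {
  pieces <- lapply(dataset, function(rec)
    feature_matrix_recording(rec$signals, rec$windows, feature_spec,
                             clearance_literal))
  fm <- do.call(rbind, pieces)
  rownames(fm) <- NULL
  attr(fm, "feature_cols") <- paste0(feature_spec$statistic, "__",
                                     feature_spec$channel)
  attr(fm, "fps") <- dataset[[1]]$signals$fps
  fm
}

#' Feature columns of a feature matrix
#' @param fm Feature matrix from \code{\link{build_feature_matrix}}.
#' @return Character vector of feature column names.
#' @export
feature_cols <- function(fm) attr(fm, "feature_cols")

feature_matrix_recording <- function(signals, windows, feature_spec,
                                     clearance_literal = FALSE) {
  stopifnot(nrow(windows) > 0L)
  missing_ch <- setdiff(unique(feature_spec$channel), colnames(signals$data))
  if (length(missing_ch))
    stop("feature spec names unknown channel(s): ",
         paste(missing_ch, collapse = ", "))
  fs <- signals$fps
  W <- nrow(windows)
  fnames <- paste0(feature_spec$statistic, "__", feature_spec$channel)
  out <- matrix(NA_real_, W, nrow(feature_spec), dimnames = list(NULL, fnames))
  n <- windows$n[1]
  idx <- outer(seq_len(n) - 1L, windows$i_start, `+`)   # n x W sample indices
  for (ch in unique(feature_spec$channel)) {
    stats_ch <- feature_spec$statistic[feature_spec$channel == ch]
    M <- matrix(signals$data[idx, ch], n, W)
    if (any(stats_ch %in% TIME_STATS)) {
      tf <- apply(M, 2, time_features, clearance_literal = clearance_literal)
      for (s in intersect(stats_ch, TIME_STATS))
        out[, paste0(s, "__", ch)] <- tf[s, ]
    }
    if ("sampen" %in% stats_ch)
      out[, paste0("sampen__", ch)] <- apply(M, 2, function(v) {
        se <- sample_entropy(v)
        if (!is.finite(se)) 0 else se
      })
    sp_ch <- intersect(stats_ch, SPECTRAL_STATS)
    if (length(sp_ch)) {
      sp <- spectral_feature_block(M, fs, sp_ch)
      for (s in sp_ch) out[, paste0(s, "__", ch)] <- sp[[s]]
    }
  }
  if (anyNA(out)) stop("feature extraction produced missing values")
  meta <- data.frame(subject_id = signals$subject_id, test_id = signals$test_id,
                     windows[, c("t_start", "t_end", "stage_label", "fog_label",
                                 "frac_turn", "frac_fog", "frac_unknown")],
                     stringsAsFactors = FALSE)
  cbind(meta, as.data.frame(out, check.names = FALSE))
}

# vectorized spectral statistics over the columns of a window matrix
spectral_feature_block <- function(M, fs, stats_wanted) {
  n <- nrow(M)
  nfreq <- n %/% 2L + 1L
  f <- (seq_len(nfreq) - 1) * fs / n
  df <- fs / n
  Mc <- sweep(M, 2, colMeans(M))
  A <- Mod(stats::mvfft(Mc))[seq_len(nfreq), , drop = FALSE]
  sided <- rep(2, nfreq); sided[1] <- 1
  if (n %% 2L == 0L) sided[nfreq] <- 1
  P <- A^2 * sided / (n^2 * df)
  res <- list()
  if ("amp_peak" %in% stats_wanted) res$amp_peak <- apply(A, 2, max)
  if ("avg_freq" %in% stats_wanted) {
    tot <- colSums(P)
    res$avg_freq <- ifelse(tot == 0, 0, colSums(f * P) / tot)
  }
  if ("second_power_peak" %in% stats_wanted)
    res$second_power_peak <- apply(P, 2, second_local_max)
  bands <- intersect(stats_wanted, names(BAND_DEFS))
  need_fi <- "fi" %in% stats_wanted
  band_vals <- list()
  for (b in unique(c(bands, if (need_fi) c("band_0p5_3")))) {
    eds <- BAND_DEFS[[b]]
    hi <- min(eds[2], f[nfreq])
    band_vals[[b]] <- as.vector(band_weights(f, eds[1], hi) %*% P)
  }
  for (b in bands) res[[b]] <- band_vals[[b]]
  if (need_fi) {
    frz <- as.vector(band_weights(f, 3, min(8, f[nfreq])) %*% P)
    loc <- band_vals[["band_0p5_3"]]
    res$fi <- ifelse(loc < 1e-12, 1e6, pmin(frz / loc, 1e6))
  }
  res
}
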