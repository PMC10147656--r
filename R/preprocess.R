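# Trajectory cleaning: drift removal and single-frequency "line" noise
# notching, applied before any MSD/NPAF statistics.

new_filter_report <- function(detrend_model = NULL,
                              removed_peak_frequencies = numeric(),
                              removed_peak_amplitudes = numeric()) {
  structure(list(detrend_model = detrend_model,
                 removed_peak_frequencies = removed_peak_frequencies,
                 removed_peak_amplitudes = removed_peak_amplitudes),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filter report\n")
  if (!is.null(x$detrend_model))
    cat("  detrend:", x$detrend_model$description, "\n")
  if (length(x$removed_peak_frequencies)) {
    cat(sprintf("  removed %d spectral line(s): %s Hz (amplitudes %s m)\n",
                length(x$removed_peak_frequencies),
                paste(signif(x$removed_peak_frequencies, 4), collapse = ", "),
                paste(signif(x$removed_peak_amplitudes, 3), collapse = ", ")))
  } else cat("  no spectral lines removed\n")
  invisible(x)
}

#' Remove long-term drift from a trajectory
#'
#' Instrument drift (stage creep, thermal expansion) adds a slow
#' deterministic component to the recorded positions that inflates
#' long-lag statistics. The default model subtracts a per-axis linear
#' trend; polynomial and centred moving-mean alternatives are available.
#' The residual trajectory has (numerically) zero mean on every axis.
#'
#' @param traj A [trajectory()] with at least 10 samples.
#' @param model `"linear"`, `"polynomial"` or `"moving_mean"`.
#' @param degree Polynomial degree (for `model = "polynomial"`).
#' @param window Window length in samples (for `model = "moving_mean"`),
#'   must be smaller than the series length.
#' @return List with elements `trajectory` (residual) and `report`
#'   (a `filter_report` recording the model and its coefficients).
#' @export
detrend <- function(traj, model = c("linear", "polynomial", "moving_mean"),
                    degree = 2L, window = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  model <- match.arg(model)
  n <- length(traj$t)
  if (n < 10L) stop("detrending needs at least 10 samples")
  tt <- traj$t - traj$t[1L]
  coefs <- list()
  res <- traj$positions
  for (ax in colnames(res)) {
    x <- res[, ax]
    if (model == "linear") {
      fit <- stats::lm.fit(cbind(1, tt), x)
      coefs[[ax]] <- stats::setNames(fit$coefficients,
                                     c("intercept", "slope_m_per_s"))
      r <- fit$residuals
    } else if (model == "polynomial") {
      X <- stats::poly(tt, degree = degree, raw = TRUE)
      fit <- stats::lm.fit(cbind(1, X), x)
      coefs[[ax]] <- fit$coefficients
      r <- fit$residuals
    } else {
      if (is.null(window) || window >= n)
        stop("'window' must be given and smaller than the series length")
      k <- if (window %% 2L == 0L) window + 1L else window
      trend <- stats::filter(x, rep(1 / k, k), sides = 2)
      # edges: shrink the window rather than drop samples
      half <- (k - 1L) %/% 2L
      for (i in which(is.na(trend))) {
        lo <- max(1L, i - half); hi <- min(n, i + half)
        trend[i] <- mean(x[lo:hi])
      }
      coefs[[ax]] <- c(window = k)
      r <- x - as.numeric(trend)
    }
    res[, ax] <- r - mean(r)
  }
  out <- traj
  out$positions <- res
  out$provenance <- sprintf("detrend(%s) | %s", model, traj$provenance)
  list(trajectory = out,
       report = new_filter_report(detrend_model = list(
         description = sprintf("%s detrend", model), coefficients = coefs)))
}

# Single-sided amplitude spectrum (metres) of one axis and its fft.
axis_spectrum <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  half <- seq_len(floor(n / 2) + 1L)          # DC .. Nyquist
  amp <- Mod(X[half]) * 2 / n
  amp[1L] <- Mod(X[1L]) / n
  if (n %% 2L == 0L) amp[length(half)] <- Mod(X[length(half)]) / n
  list(X = X, amp = amp, half = half)
}

#' Notch out single-frequency instrument noise lines
#'
#' Electrical and mechanical interference shows up in the position
#' spectrum as sharp peaks of essentially single-frequency width. Each
#' axis is Fourier transformed; isolated peaks -- contiguous groups of at
#' most `max_peak_bins` bins whose single-sided amplitude exceeds both the
#' absolute `amplitude_threshold` and `prominence` times the running
#' median of their `neighbourhood`-bin surroundings -- are notched by
#' scaling the offending bins down to the local background level
#' (zeroing would delete legitimate Brownian power). All removals are
#' reported. With no qualifying peaks the data pass through unchanged,
#' and a second pass removes nothing (idempotence).
#'
#' @param traj A uniformly sampled [trajectory()].
#' @param amplitude_threshold Minimum single-sided amplitude (metres) for
#'   a peak to be removed; default `2e-10` m.
#' @param max_peak_bins Maximum width (FFT bins) of a removable peak.
#' @param neighbourhood Width (bins) of the running-median background
#'   window.
#' @param prominence Required ratio of peak amplitude to local background.
#' @return List with elements `trajectory` and `report`.
#' @export
filter_noise_peaks <- function(traj, amplitude_threshold = 2e-10,
                               max_peak_bins = 3L, neighbourhood = 50L,
                               prominence = 5) {
  stopifnot(inherits(traj, "trajectory"))
  n <- length(traj$t)
  fs <- traj$frame_rate
  res <- traj$positions
  freqs_rm <- amps_rm <- numeric()
  k <- if (neighbourhood %% 2L == 0L) neighbourhood + 1L else neighbourhood
  for (ax in colnames(res)) {
    sp <- axis_spectrum(res[, ax])
    amp <- sp$amp
    bg <- stats::runmed(amp, k, endrule = "median")
    cand <- which(amp >= amplitude_threshold & amp >= prominence * bg)
    cand <- cand[cand > 1L]                    # never touch DC
    if (!length(cand)) next
    groups <- split(cand, cumsum(c(1L, diff(cand) != 1L)))
    X <- sp$X
    changed <- FALSE
    for (g in groups) {
      if (length(g) > max_peak_bins) next      # broadband feature, keep
      peak <- g[which.max(amp[g])]
      freqs_rm <- c(freqs_rm, (peak - 1L) * fs / n)
      amps_rm <- c(amps_rm, amp[peak])
      scale <- bg[g] / amp[g]                  # shrink to local background
      X[g] <- X[g] * scale
      conj_idx <- n - g + 2L                   # matching negative freqs
      keep <- conj_idx >= 1L & conj_idx <= n & conj_idx != g
      X[conj_idx[keep]] <- X[conj_idx[keep]] * scale[keep]
      changed <- TRUE
    }
    if (changed) res[, ax] <- Re(stats::fft(X, inverse = TRUE)) / n
  }
  out <- traj
  out$positions <- res
  if (length(freqs_rm))
    out$provenance <- sprintf("filter_noise_peaks(%d lines) | %s",
                              length(freqs_rm), traj$provenance)
  list(trajectory = out,
       report = new_filter_report(removed_peak_frequencies = freqs_rm,
                                  removed_peak_amplitudes = amps_rm))
}
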