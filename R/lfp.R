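# LFP analyses: ripple-band event detection and spectral summaries.

#' Ripple-band envelope of an LFP signal
#'
#' Band-pass 100-250 Hz (4th-order Butterworth, zero-phase), rectified and
#' smoothed with a 4 ms Gaussian.
#' @param x numeric LFP samples.
#' @param fs sampling rate (Hz); must be >= 600 so the band is resolvable.
#' @param band ripple band in Hz.
#' @return envelope, same length as `x`.
#' @export
ripple_envelope <- function(x, fs, band = c(100, 250)) {
  if (fs < 600) stop("LFP sampling rate too low for ripple-band filtering",
                     call. = FALSE)
  if (length(x) < 4 * fs / band[1])
    stop("LFP segment shorter than the filter warm-up", call. = FALSE)
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, x)
  smooth_sigma <- 0.004 * fs
  half <- ceiling(3 * smooth_sigma)
  k <- stats::dnorm(seq(-half, half), sd = smooth_sigma)
  k <- k / sum(k)
  env <- stats::filter(abs(filt), k, sides = 2)
  env <- as.numeric(env)
  env[is.na(env)] <- abs(filt)[is.na(env)]
  env
}

#' Detect sharp-wave-ripple events
#'
#' The ripple-band envelope is z-scored against the whole-session mean and
#' SD. Events are intervals whose envelope peak reaches `peak_thresh_sd`,
#' with boundaries at the surrounding `edge_thresh_sd` crossings; events
#' separated by less than `merge_gap_s` are merged, and events outside the
#' `duration_s` range are discarded. Note the duration is the span of the
#' 2.5 SD crossing, which for a physiological 50-400 ms ripple is
#' considerably shorter than the oscillation itself -- hence the 20 ms
#' operational minimum.
#'
#' @param lfp an `lfp_trace` (list with `values`, `fs`, `t0`).
#' @param peak_thresh_sd envelope peak threshold (SD units).
#' @param edge_thresh_sd boundary threshold (SD units).
#' @param merge_gap_s merge gap (s).
#' @param duration_s admissible event duration range (s).
#' @return data frame: `start_s`, `end_s`, `peak_s`, `peak_z`.
#' @export
detect_ripple_events <- function(lfp, peak_thresh_sd = 4, edge_thresh_sd = 2.5,
                                 merge_gap_s = 0.03,
                                 duration_s = c(0.02, 0.4)) {
  env <- ripple_envelope(lfp$values, lfp$fs)
  z <- (env - mean(env)) / stats::sd(env)
  above <- z >= edge_thresh_sd
  out <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    peak_s = numeric(0), peak_z = numeric(0))
  if (!any(above)) return(out)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  iv <- cbind(starts[r$values], ends[r$values])
  # merge across short gaps
  if (nrow(iv) > 1) {
    merged <- list(iv[1, ])
    for (i in 2:nrow(iv)) {
      prev <- merged[[length(merged)]]
      if ((iv[i, 1] - prev[2]) / lfp$fs < merge_gap_s) {
        merged[[length(merged)]] <- c(prev[1], iv[i, 2])
      } else merged[[length(merged) + 1]] <- iv[i, ]
    }
    iv <- do.call(rbind, merged)
  }
  tt <- lfp$t0 + (seq_along(env) - 1) / lfp$fs
  for (i in seq_len(nrow(iv))) {
    seg <- iv[i, 1]:iv[i, 2]
    pk <- seg[which.max(z[seg])]
    if (z[pk] < peak_thresh_sd) next
    dur <- (iv[i, 2] - iv[i, 1] + 1) / lfp$fs
    if (dur < duration_s[1] || dur > duration_s[2]) next
    out <- rbind(out, data.frame(start_s = tt[iv[i, 1]], end_s = tt[iv[i, 2]],
                                 peak_s = tt[pk], peak_z = z[pk]))
  }
  rownames(out) <- NULL
  out
}

#' Spectrogram and power spectral density of an LFP
#'
#' Power is computed every 0.5 Hz and every 25 ms with 1 s Hann windows
#' (zero-padded FFT). The PSD averages spectrogram columns whose window
#' centres fall inside the supplied intervals; a normalised variant divides
#' by the total power in 0.5-400 Hz.
#'
#' @param lfp an `lfp_trace`.
#' @param intervals optional data frame (`start_s`, `end_s`); default whole
#'   trace. Each interval must be at least 1 s long.
#' @param freq_step_hz frequency resolution (Hz).
#' @param time_step_s spectrogram time step (s).
#' @param window_s analysis window length (s).
#' @param max_freq_hz highest frequency retained (Hz).
#' @return list with `freq_hz`, `times_s`, `spectrogram` (freq x time),
#'   `psd`, `psd_norm` (sums to 1 over 0.5-400 Hz).
#' @export
lfp_spectra <- function(lfp, intervals = NULL, freq_step_hz = 0.5,
                        time_step_s = 0.025, window_s = 1,
                        max_freq_hz = 400) {
  fs <- lfp$fs
  x <- lfp$values
  nwin <- round(window_s * fs)
  if (length(x) < nwin) stop("LFP shorter than one analysis window", call. = FALSE)
  nfft <- max(nwin, round(fs / freq_step_hz))
  step <- max(1L, round(time_step_s * fs))
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nwin - 1) / (nwin - 1))
  freq <- (seq_len(nfft) - 1) * fs / nfft
  keep <- freq <= max_freq_hz
  spec <- matrix(NA_real_, sum(keep), length(starts))
  for (j in seq_along(starts)) {
    seg <- x[starts[j] + seq_len(nwin) - 1] * win
    p <- abs(stats::fft(c(seg, rep(0, nfft - nwin))))^2 / (sum(win^2) * fs)
    spec[, j] <- p[keep]
  }
  times <- lfp$t0 + (starts - 1 + nwin / 2) / fs
  if (is.null(intervals)) {
    use <- rep(TRUE, length(times))
  } else {
    if (any(intervals$end_s - intervals$start_s < window_s))
      stop("spectral intervals must be at least one window long", call. = FALSE)
    use <- in_intervals(times, intervals)
  }
  psd <- rowMeans(spec[, use, drop = FALSE])
  f <- freq[keep]
  band_total <- sum(psd[f >= 0.5 & f <= 400])
  list(freq_hz = f, times_s = times, spectrogram = spec,
       psd = psd, psd_norm = psd / band_total)
}

#' Band power from a PSD
#' @param spectra result of [lfp_spectra()].
#' @param band numeric length-2 band limits (Hz).
#' @return total power in the band.
#' @export
band_power <- function(spectra, band) {
  sel <- spectra$freq_hz >= band[1] & spectra$freq_hz <= band[2]
  sum(spectra$psd[sel])
}
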