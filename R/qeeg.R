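# Quantitative EEG auxiliary labels: per-second relative spectral power in
# the delta (0.5-4), theta (4-8), alpha (8-13) and beta (13-30 Hz) bands,
# computed from C4-M1 EEG by short-time Welch spectra.

qeeg_bands <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
                   beta = c(13, 30))

#' Construct an EEG signal object
#'
#' @param samples numeric EEG trace.
#' @param fs sampling rate in Hz; must be at least 60 so the 13-30 Hz beta
#'   band lies below Nyquist.
#' @param channel channel label (convention: `"C4-M1"`).
#' @return object of class `eeg_signal`.
#' @export
eeg_signal <- function(samples, fs, channel = "C4-M1") {
  stopifnot(fs >= 60, is.numeric(samples), length(samples) > 0L)
  structure(list(samples = as.numeric(samples), fs = fs, channel = channel,
                 duration_s = length(samples) / fs), class = "eeg_signal")
}

#' Load an EEG channel from an EDF file
#'
#' Convenience wrapper over the EDF layer: reads the named channel and
#' returns it as an [eeg_signal()] at its native sampling rate.
#'
#' @param path EDF file.
#' @param channel channel label (default `"C4-M1"`).
#' @return an [eeg_signal()].
#' @export
load_eeg <- function(path, channel = "C4-M1") {
  e <- read_edf(path, channels = channel)
  eeg_signal(e$signals[[1L]], fs = e$fs[[1L]], channel = channel)
}

hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

# One-sided Welch power spectrum of a short segment: Hann sub-windows of
# length seg samples with the given fractional overlap, averaged |FFT|^2.
welch_psd <- function(x, fs, seg, overlap_frac) {
  hop <- max(1L, as.integer(round(seg * (1 - overlap_frac))))
  starts <- seq.int(1L, length(x) - seg + 1L, by = hop)
  w <- hann(seg)
  acc <- numeric(seg %/% 2L + 1L)
  for (s in starts) {
    v <- x[s:(s + seg - 1L)] * w
    sp <- Mod(stats::fft(v))^2
    acc <- acc + sp[seq_len(seg %/% 2L + 1L)]
  }
  freq <- (seq_len(seg %/% 2L + 1L) - 1L) * fs / seg
  list(freq = freq, power = acc / length(starts))
}

band_sums <- function(freq, power) {
  vapply(qeeg_bands, function(be) sum(power[freq >= be[1L] & freq < be[2L]]),
         numeric(1))
}

#' Per-second relative EEG band powers
#'
#' For each second of the recording, a `window_s`-long window centered on
#' that second (edge windows are clamped inside the night) is analyzed with
#' Welch's method (Hann sub-windows of half the window length, fractional
#' overlap `overlap_frac`); power is summed over each band's half-open
#' \[lo, hi) edges and normalized by the total over the four bands only.
#'
#' @param eeg an [eeg_signal()].
#' @param window_s analysis window in seconds (>= 2, default 4).
#' @param overlap_frac Welch sub-window overlap (default 0.5).
#' @return matrix (`floor(duration_s)` x 4), columns
#'   delta/theta/alpha/beta, rows on the simplex.
#' @export
compute_band_powers <- function(eeg, window_s = 4, overlap_frac = 0.5) {
  stopifnot(window_s >= 2)
  fs <- eeg$fs
  n <- length(eeg$samples)
  win <- as.integer(round(window_s * fs))
  if (n < win) stop("night shorter than one analysis window")
  seg <- win %/% 2L
  n_sec <- floor(eeg$duration_s)
  out <- matrix(0, n_sec, 4L, dimnames = list(NULL, names(qeeg_bands)))
  for (i in seq_len(n_sec)) {
    center <- (i - 0.5) * fs
    start <- as.integer(round(center - win / 2)) + 1L
    start <- min(max(start, 1L), n - win + 1L)
    psd <- welch_psd(eeg$samples[start:(start + win - 1L)], fs, seg, overlap_frac)
    bp <- band_sums(psd$freq, psd$power)
    tot <- sum(bp)
    out[i, ] <- if (tot > 0) bp / tot else rep(0.25, 4L)
  }
  out
}

#' Align a qEEG series to the decoder output length
#'
#' Pads (edge replication) or truncates the per-second series to exactly
#' `n_target` seconds; the padded tail is flagged in the returned mask so it
#' can be excluded from the loss. Mismatches beyond 8 s are an error.
#'
#' @param q seconds x 4 relative-power matrix.
#' @param n_target decoder output length in seconds.
#' @return list with `rel_power` (n_target x 4) and `mask` (logical, TRUE
#'   where the label is genuine).
#' @export
align_qeeg_to_features <- function(q, n_target) {
  n <- nrow(q)
  if (abs(n - n_target) > 8L) {
    stop("qEEG/feature length mismatch beyond 8 s: ", n, " vs ", n_target)
  }
  mask <- rep(TRUE, n_target)
  if (n > n_target) {
    q <- q[seq_len(n_target), , drop = FALSE]
  } else if (n < n_target) {
    q <- rbind(q, q[rep(n, n_target - n), , drop = FALSE])
    mask[(n + 1L):n_target] <- FALSE
  }
  list(rel_power = q, mask = mask)
}

#' Write / read a qEEG series as TSV (second, delta, theta, alpha, beta)
#'
#' @param q seconds x 4 matrix.
#' @param path file path.
#' @export
write_qeeg <- function(q, path) {
  df <- data.frame(second = seq_len(nrow(q)), q)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_qeeg
#' @export
read_qeeg <- function(path) {
  df <- utils::read.delim(path)
  as.matrix(df[, c("delta", "theta", "alpha", "beta")])
}

#' Synthesize an EEG realization from a qEEG series (synthetic stand-in)
#'
#' Emits, for each second, a sum of random-phase sinusoids per band with
#' amplitudes proportional to the square root of the target relative power.
#' Used to exercise the EEG-to-qEEG path end to end; it is a synthetic
#' construction, not a physiological EEG model.
#'
#' @param q seconds x 4 relative-power matrix.
#' @param fs output sampling rate (Hz).
#' @param tones_per_band sinusoids drawn per band per second.
#' @return an [eeg_signal()].
#' @export
synth_eeg_from_qeeg <- function(q, fs = 100, tones_per_band = 3L) {
  n_sec <- nrow(q)
  x <- numeric(n_sec * fs)
  tt <- seq_len(fs) / fs
  for (i in seq_len(n_sec)) {
    seg <- numeric(fs)
    for (b in seq_len(4L)) {
      be <- qeeg_bands[[b]]
      fr <- stats::runif(tones_per_band, be[1L], be[2L] * 0.98)
      ph <- stats::runif(tones_per_band, 0, 2 * pi)
      amp <- sqrt(q[i, b] / tones_per_band)
      for (j in seq_len(tones_per_band)) {
        seg <- seg + amp * sin(2 * pi * fr[j] * ((i - 1L) + tt) + ph[j])
      }
    }
    x[((i - 1L) * fs + 1L):(i * fs)] <- seg
  }
  eeg_signal(x, fs)
}
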