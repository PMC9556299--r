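# Night-level breathing data model and on-disk formats: EDF belt channels,
# a plain columnar night format with JSON sidecar, the cohort manifest TSV,
# screening rules and the clip/normalize preprocessing.

#' Construct a breathing night
#'
#' @param subject_id opaque subject identifier.
#' @param night_date calendar date (`Date` or ISO-8601 string).
#' @param domain acquisition domain, `"belt"` or `"wireless"`.
#' @param signal numeric respiratory-effort trace.
#' @param f_b sampling frequency in Hz (10 by default).
#' @return object of class `breathing_night`.
#' @export
breathing_night <- function(subject_id, night_date, domain = c("belt", "wireless"),
                            signal, f_b = 10) {
  domain <- match.arg(domain)
  stopifnot(f_b > 0, is.numeric(signal), length(signal) > 0L)
  structure(list(subject_id = as.character(subject_id),
                 night_date = as.Date(night_date),
                 domain = domain,
                 signal = as.numeric(signal),
                 f_b = f_b,
                 duration_s = length(signal) / f_b),
            class = "breathing_night")
}

#' @export
print.breathing_night <- function(x, ...) {
  cat(sprintf("<breathing_night %s %s [%s] %.2f h @ %g Hz>\n", x$subject_id,
              format(x$night_date), x$domain, x$duration_s / 3600, x$f_b))
  invisible(x)
}

## ---- minimal EDF layer (16-bit continuous recordings) ----

edf_pad <- function(s, n) {
  s <- substr(s, 1L, n)
  sprintf(paste0("%-", n, "s"), s)
}

#' Write signals to a minimal EDF file
#'
#' Continuous 16-bit EDF with one-second data records; enough of the format
#' to round-trip belt PSG channels in tests and small exports.
#'
#' @param path output file.
#' @param signals named list of numeric vectors.
#' @param fs sampling rates (Hz, recycled) — must be integers per 1 s record.
#' @param start_date,start_time header strings `dd.mm.yy` / `hh.mm.ss`.
#' @export
write_edf <- function(path, signals, fs, start_date = "01.01.20",
                      start_time = "00.00.00") {
  ns <- length(signals)
  fs <- rep_len(as.integer(fs), ns)
  n_rec <- min(floor(lengths(signals) / fs))
  stopifnot(n_rec >= 1L)
  phys_min <- phys_max <- numeric(ns)
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- signals[[i]][seq_len(n_rec * fs[i])]
    lo <- min(x); hi <- max(x)
    if (hi - lo < 1e-12) hi <- lo + 1
    phys_min[i] <- lo; phys_max[i] <- hi
    dig[[i]] <- as.integer(round((x - lo) / (hi - lo) * 65535 - 32768))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(edf_pad("0", 8L), edf_pad("synthetic", 80L),
                edf_pad("synthetic", 80L), edf_pad(start_date, 8L),
                edf_pad(start_time, 8L), edf_pad(as.character(256L * (ns + 1L)), 8L),
                edf_pad("", 44L), edf_pad(as.character(n_rec), 8L),
                edf_pad("1", 8L), edf_pad(as.character(ns), 4L))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, w) writeChar(paste0(vapply(vals, edf_pad, "", w),
                                            collapse = ""), con, eos = NULL)
  fld(names(signals), 16L)
  fld(rep("", ns), 80L)
  fld(rep("uV", ns), 8L)
  fld(formatC(phys_min, format = "g", digits = 6), 8L)
  fld(formatC(phys_max, format = "g", digits = 6), 8L)
  fld(rep("-32768", ns), 8L)
  fld(rep("32767", ns), 8L)
  fld(rep("", ns), 80L)
  fld(as.character(fs), 8L)
  fld(rep("", ns), 32L)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      writeBin(dig[[i]][((r - 1L) * fs[i] + 1L):(r * fs[i])], con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read a minimal EDF file
#'
#' @param path EDF file.
#' @param channels channel labels to read (default all).
#' @return list with `signals` (named numeric list) and `fs` (named Hz).
#' @export
read_edf <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rdc <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rdc(8L); rdc(80L); rdc(80L); rdc(8L); rdc(8L)
  rdc(8L); rdc(44L)
  n_rec <- as.integer(rdc(8L))
  rec_s <- as.numeric(rdc(8L))
  ns <- as.integer(rdc(4L))
  if (is.na(ns) || ns < 1L) stop("unreadable EDF header")
  labs <- vapply(seq_len(ns), function(i) rdc(16L), "")
  for (i in seq_len(ns)) rdc(80L)
  for (i in seq_len(ns)) rdc(8L)
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rdc(8L), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rdc(8L), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rdc(8L), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rdc(8L), ""))
  for (i in seq_len(ns)) rdc(80L)
  spr <- as.integer(vapply(seq_len(ns), function(i) rdc(8L), ""))
  for (i in seq_len(ns)) rdc(32L)
  keep <- if (is.null(channels)) seq_len(ns) else match(channels, labs)
  if (anyNA(keep)) stop("channel(s) not found: ",
                        paste(channels[is.na(keep)], collapse = ", "))
  sig <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                   endian = "little")
      sig[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <- v
    }
  }
  out <- lapply(keep, function(i) {
    (sig[[i]] - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i]) + pmin[i]
  })
  names(out) <- labs[keep]
  fs <- spr[keep] / rec_s
  names(fs) <- labs[keep]
  list(signals = out, fs = fs)
}

## ---- resampling ----

#' Resample a signal to a new rate (polyphase FIR)
#'
#' Rational-factor polyphase resampling: zero-stuff by p, apply a windowed-
#' sinc (Hamming) anti-aliasing low-pass at the tighter Nyquist, take every
#' q-th sample.
#'
#' @param x numeric signal.
#' @param from,to source and target sampling rates in Hz.
#' @return resampled numeric vector of length `round(length(x) * to / from)`.
#' @export
resample_signal <- function(x, from, to) {
  if (abs(from - to) < 1e-12) return(x)
  r <- to / from
  fr <- as.integer(c(numerator_denominator(r)))
  p <- fr[1L]; q <- fr[2L]
  n_out <- round(length(x) * r)
  up <- numeric(length(x) * p)
  up[seq.int(1L, length(up), by = p)] <- x * p
  fc <- 0.5 / max(p, q)                      # cutoff in upsampled cycles/sample
  half <- 10L * max(p, q)
  t <- seq.int(-half, half)
  h <- 2 * fc * sinc(2 * fc * t) * (0.54 + 0.46 * cos(pi * t / half))
  h <- h / sum(h) * 1
  y <- stats::filter(c(up, numeric(half)), h, sides = 2L)
  y <- as.numeric(y)
  y <- y[seq_len(length(up))]
  y[is.na(y)] <- 0
  out <- y[seq.int(1L, by = q, length.out = n_out)]
  out
}

sinc <- function(x) ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))

numerator_denominator <- function(r, max_den = 1000L) {
  # best rational approximation by continued fractions
  best <- c(1L, 1L)
  err <- Inf
  for (den in seq_len(max_den)) {
    num <- round(r * den)
    if (num < 1) next
    e <- abs(r - num / den)
    if (e < err - 1e-15) {
      err <- e
      best <- c(as.integer(num), as.integer(den))
      if (e < 1e-12) break
    }
  }
  best
}

## ---- night loading / saving ----

#' Load one night of breathing
#'
#' Columnar format: a text file with one sample per line plus a JSON sidecar
#' (`subject_id`, `date`, `domain`, `f_b`) at the same path with extension
#' `.json`. EDF format: the named respiratory channel is read and resampled
#' to 10 Hz when the source rate differs; metadata comes from the sidecar if
#' present, else from the arguments.
#'
#' @param path file path.
#' @param format `"columnar"` or `"edf"`.
#' @param channel EDF channel label holding respiratory effort.
#' @param subject_id,night_date,domain metadata fallbacks when no sidecar.
#' @param f_b target sampling rate (Hz).
#' @return a `breathing_night`.
#' @export
load_night <- function(path, format = c("columnar", "edf"),
                       channel = "THOR RES", subject_id = NULL,
                       night_date = NULL, domain = NULL, f_b = 10) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  subject_id <- subject_id %||% meta$subject_id %||% tools::file_path_sans_ext(basename(path))
  night_date <- night_date %||% meta$date %||% "1970-01-01"
  domain <- domain %||% meta$domain %||% "belt"
  if (format == "columnar") {
    src_fb <- as.numeric(meta$f_b %||% f_b)
    x <- scan(path, what = numeric(), quiet = TRUE)
    if (length(x) == 0L) stop("empty signal file: ", path)
    if (abs(src_fb - f_b) > 1e-9) x <- resample_signal(x, src_fb, f_b)
  } else {
    e <- read_edf(path, channels = channel)
    x <- e$signals[[1L]]
    src_fb <- e$fs[[1L]]
    if (length(x) == 0L) stop("empty EDF channel: ", channel)
    if (is.na(src_fb) || src_fb <= 0) stop("missing sampling rate in EDF")
    if (abs(src_fb - f_b) > 1e-9) x <- resample_signal(x, src_fb, f_b)
  }
  breathing_night(subject_id, night_date, domain, x, f_b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a night in the columnar format (+ JSON sidecar)
#'
#' @param night a `breathing_night`.
#' @param path output `.txt` path; the sidecar goes to the matching `.json`.
#' @export
save_night <- function(night, path) {
  writeLines(formatC(night$signal, format = "g", digits = 17), path)
  jsonlite::write_json(
    list(subject_id = night$subject_id, date = format(night$night_date),
         domain = night$domain, f_b = night$f_b),
    paste0(tools::file_path_sans_ext(path), ".json"), auto_unbox = TRUE)
  invisible(path)
}

## ---- screening ----

#' Default distortion-screen configuration
#'
#' A night is called distorted when more than `clip_frac` of raw samples sit
#' at the clip bound, when more than `flat_max_frac` of 30-s windows have a
#' standard deviation below `flat_sd_frac` times the median window s.d.
#' (flat-line), or when no spectral peak in the respiratory band
#' (0.1-0.5 Hz) exceeds `peak_ratio` times the 1-5 Hz noise floor.
#'
#' @param clip_range raw-unit clip bounds.
#' @param clip_frac maximum tolerated fraction of clipped samples.
#' @param flat_window_s flat-line window length (s).
#' @param flat_sd_frac flat threshold relative to the median window s.d.
#' @param flat_max_frac maximum tolerated fraction of flat windows.
#' @param peak_ratio required respiratory-peak to noise-floor power ratio.
#' @param spectral_check disable to skip the spectral rule.
#' @export
distortion_config <- function(clip_range = c(-6, 6), clip_frac = 0.2,
                              flat_window_s = 30, flat_sd_frac = 0.05,
                              flat_max_frac = 0.25, peak_ratio = 3,
                              spectral_check = TRUE) {
  list(clip_range = clip_range, clip_frac = clip_frac,
       flat_window_s = flat_window_s, flat_sd_frac = flat_sd_frac,
       flat_max_frac = flat_max_frac, peak_ratio = peak_ratio,
       spectral_check = spectral_check)
}

#' Screen a raw night for usability
#'
#' Applies, in order: the absent rule (constant signal), the minimum-length
#' rule (default 2 h) and the distortion rules of [distortion_config()].
#'
#' @param night raw (pre-normalization) `breathing_night`.
#' @param min_hours minimum night length in hours.
#' @param distortion_cfg see [distortion_config()].
#' @return list with `keep` (logical) and `reason`
#'   (`ok`/`too_short`/`distorted`/`absent`).
#' @export
screen_night <- function(night, min_hours = 2, distortion_cfg = distortion_config()) {
  x <- night$signal
  decision <- function(keep, reason) list(keep = keep, reason = reason)
  if (stats::sd(x) < 1e-12) return(decision(FALSE, "absent"))
  if (night$duration_s < min_hours * 3600) return(decision(FALSE, "too_short"))
  dc <- distortion_cfg
  at_bound <- mean(x <= dc$clip_range[1L] | x >= dc$clip_range[2L])
  if (at_bound > dc$clip_frac) return(decision(FALSE, "distorted"))
  w <- as.integer(dc$flat_window_s * night$f_b)
  nw <- length(x) %/% w
  if (nw >= 2L) {
    sds <- vapply(seq_len(nw), function(i) stats::sd(x[((i - 1L) * w + 1L):(i * w)]),
                  numeric(1))
    med <- stats::median(sds)
    if (med > 0 && mean(sds < dc$flat_sd_frac * med) > dc$flat_max_frac) {
      return(decision(FALSE, "distorted"))
    }
  }
  if (isTRUE(dc$spectral_check)) {
    # Welch-averaged spectrum (60-s segments) so the respiratory peak is
    # judged against a stable noise floor rather than periodogram maxima
    n <- min(length(x), 2L^17L)
    seg_len <- min(as.integer(60 * night$f_b), n)
    psd <- welch_psd(x[seq_len(n)] - mean(x[seq_len(n)]), night$f_b,
                     seg_len, 0.5)
    resp <- psd$power[psd$freq >= 0.1 & psd$freq <= 0.5]
    floor_pw <- psd$power[psd$freq >= 1 & psd$freq <= 5]
    if (length(resp) && length(floor_pw) &&
        max(resp) < dc$peak_ratio * mean(floor_pw)) {
      return(decision(FALSE, "distorted"))
    }
  }
  decision(TRUE, "ok")
}

#' Clip and z-normalize a screened night
#'
#' Clips the raw signal to `clip_range` (default \[-6, +6\]), subtracts the
#' mean of the clipped signal and divides by its population standard
#' deviation (divide-by-n convention).
#'
#' @param night a `breathing_night` that passed [screen_night()].
#' @param clip_range symmetric clip bounds in raw units.
#' @return normalized `breathing_night`.
#' @export
preprocess_night <- function(night, clip_range = c(-6, 6)) {
  x <- pmin(pmax(night$signal, clip_range[1L]), clip_range[2L])
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s < 1e-12) stop("unusable night: zero standard deviation after clipping")
  night$signal <- (x - m) / s
  night
}

## ---- cohort manifest ----

manifest_cols <- c("subject_id", "domain", "pd_status", "mds_updrs_total",
                   "updrs_1", "updrs_2", "updrs_3", "updrs_4", "hy_stage",
                   "baseline_date", "m6_date", "m12_date")

#' Read a cohort manifest TSV
#'
#' UTF-8 tab-separated file with header columns `subject_id, domain,
#' pd_status, mds_updrs_total, updrs_1..4, hy_stage, baseline_date, m6_date,
#' m12_date`; dates are ISO-8601 and missing values are empty strings.
#'
#' @param path manifest file.
#' @return data.frame, one row per subject.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "", colClasses = "character",
                          fileEncoding = "UTF-8")
  missing <- setdiff(manifest_cols, names(df))
  if (length(missing)) stop("manifest missing columns: ",
                            paste(missing, collapse = ", "))
  for (col in c("mds_updrs_total", "updrs_1", "updrs_2", "updrs_3", "updrs_4",
                "hy_stage")) df[[col]] <- as.numeric(df[[col]])
  df
}

#' Write a cohort manifest TSV
#'
#' @param manifest data.frame in the [read_manifest()] layout.
#' @param path output file.
#' @export
write_manifest <- function(manifest, path) {
  out <- manifest[, manifest_cols]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Impute missing control severity labels
#'
#' Control subjects with missing MDS-UPDRS (total or subparts) or H&Y
#' receive the mean of the observed control values; PD subjects are never
#' imputed.
#'
#' @param manifest cohort manifest data.frame.
#' @return manifest with imputed control rows.
#' @export
impute_control_labels <- function(manifest) {
  ctrl <- manifest$pd_status == "control"
  if (!any(ctrl & !is.na(manifest$mds_updrs_total))) {
    stop("no control subject has an observed MDS-UPDRS")
  }
  for (col in c("mds_updrs_total", "updrs_1", "updrs_2", "updrs_3", "updrs_4",
                "hy_stage")) {
    obs <- manifest[[col]][ctrl & !is.na(manifest[[col]])]
    if (!length(obs)) next
    fill <- ctrl & is.na(manifest[[col]])
    manifest[[col]][fill] <- mean(obs)
  }
  manifest
}
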