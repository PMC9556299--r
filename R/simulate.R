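# Synthetic polysomnography simulator. Generates multi-night cohorts with
# the statistical structure the method assumes: two acquisition domains with
# different noise and prevalence, disease-dependent breathing dynamics
# (breathing-rate variability, arousal bursts, amplitude irregularity, all
# scaled by severity), stage-dependent qEEG band powers with a PD effect
# (delta down, beta up), Markov-chain hypnograms and longitudinal severity
# drift. Ground-truth generating parameters are stored alongside the data.

sim_stages <- c("Wake", "N1", "N2", "N3", "REM")

sim_stage_templates <- rbind(
  Wake = c(0.15, 0.20, 0.35, 0.30),
  N1   = c(0.25, 0.35, 0.25, 0.15),
  N2   = c(0.45, 0.30, 0.15, 0.10),
  N3   = c(0.70, 0.18, 0.08, 0.04),
  REM  = c(0.30, 0.30, 0.22, 0.18)
)
colnames(sim_stage_templates) <- c("delta", "theta", "alpha", "beta")

sim_base_transition <- rbind(
  Wake = c(0.50, 0.40, 0.10, 0.00, 0.00),
  N1   = c(0.10, 0.40, 0.45, 0.03, 0.02),
  N2   = c(0.03, 0.05, 0.75, 0.12, 0.05),
  N3   = c(0.01, 0.02, 0.15, 0.80, 0.02),
  REM  = c(0.05, 0.10, 0.10, 0.01, 0.74)
)

#' Simulator configuration
#'
#' Defaults define the standard test-bench conditions: balanced belt-domain
#' cohorts of 30-minute nights with a strong severity-scaled disease effect
#' on breathing-rate variability, arousal-event rate and amplitude
#' irregularity, and a delta-down/beta-up qEEG modulation.
#'
#' @param n_pd,n_control subjects per class in the belt domain.
#' @param n_pd_wireless,n_control_wireless subjects per class in the
#'   wireless domain (0 for a single-domain cohort).
#' @param nights_per_subject nights per subject around each visit.
#' @param night_hours night length in hours (0.5 for desk-scale runs).
#' @param f_b breathing sampling rate (Hz).
#' @param base_rate mean breathing rate (Hz, ~15 breaths/min).
#' @param rate_sd stationary s.d. of the instantaneous-rate OU process (Hz).
#' @param ou_tau OU correlation time (s).
#' @param rate_var_gain multiplier on `rate_sd` at severity 100.
#' @param arousal_rate_control arousal events per hour for a healthy subject.
#' @param arousal_rate_gain extra events per hour at severity 100.
#' @param amp_irregularity_gain amplitude-modulation gain at severity 100.
#' @param pd_severity_range,control_severity_range uniform MDS-UPDRS ranges.
#' @param eeg_delta_drop,eeg_beta_gain fractional qEEG modulation at
#'   severity 100.
#' @param frag_gain hypnogram fragmentation blend toward Wake/N1 at
#'   severity 100.
#' @param wireless_noise_sd,wireless_amp_scale wireless-domain coloured
#'   noise s.d. and amplitude scale.
#' @param dirichlet_conc concentration of the per-second qEEG Dirichlet noise.
#' @param progression_rate severity drift in MDS-UPDRS points per year.
#' @param months 0 for baseline only; >= 6 adds month-6 (and >= 12 month-12)
#'   visits with `nights_per_subject` nights each.
#' @param effect_scale global multiplier on all disease effect channels
#'   (0 gives a null cohort with no class signal).
#' @param qeeg_domains domains whose nights carry qEEG labels (PSG-style
#'   belt recordings by default).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_pd = 20L, n_control = 20L, n_pd_wireless = 0L,
                       n_control_wireless = 0L, nights_per_subject = 3L,
                       night_hours = 0.5, f_b = 10, base_rate = 0.25,
                       rate_sd = 0.02, ou_tau = 60, rate_var_gain = 2.5,
                       arousal_rate_control = 2, arousal_rate_gain = 25,
                       amp_irregularity_gain = 2, pd_severity_range = c(20, 80),
                       control_severity_range = c(0, 10), eeg_delta_drop = 0.3,
                       eeg_beta_gain = 0.8, frag_gain = 0.5,
                       wireless_noise_sd = 1.5, wireless_amp_scale = 0.8,
                       dirichlet_conc = 60, progression_rate = 0, months = 0,
                       effect_scale = 1, qeeg_domains = "belt") {
  cfg <- as.list(environment())
  stopifnot(cfg$f_b > 0, cfg$night_hours > 0, cfg$nights_per_subject >= 1L,
            cfg$base_rate > 0, cfg$effect_scale >= 0)
  class(cfg) <- "sim_config"
  cfg
}

# Severity-scaled effect channels; effect_scale = 0 removes all class signal.
sim_subject_params <- function(cfg, severity, domain) {
  s <- cfg$effect_scale * severity / 100
  list(
    severity = severity, domain = domain,
    rate_sd = cfg$rate_sd * (1 + cfg$rate_var_gain * s),
    arousal_rate = cfg$arousal_rate_control + cfg$arousal_rate_gain * s,
    amp_irr = 0.10 * (1 + cfg$amp_irregularity_gain * s),
    delta_drop = cfg$eeg_delta_drop * s,
    beta_gain = cfg$eeg_beta_gain * s,
    frag = cfg$frag_gain * s
  )
}

sim_hypnogram <- function(n_epochs, frag) {
  P <- (1 - frag) * sim_base_transition +
    frag * matrix(rep(c(0.5, 0.5, 0, 0, 0), each = 5L), 5L)
  st <- integer(n_epochs)
  st[1L] <- 2L  # start the night at N1
  for (i in seq_len(n_epochs - 1L)) {
    st[i + 1L] <- sample.int(5L, 1L, prob = P[st[i], ])
  }
  sim_stages[st]
}

sim_qeeg <- function(hypno, night_len_s, pars, conc) {
  n_sec <- as.integer(night_len_s)
  stage_per_sec <- rep(hypno, each = 30L)[seq_len(n_sec)]
  tmpl <- sim_stage_templates[stage_per_sec, , drop = FALSE]
  tmpl[, "delta"] <- tmpl[, "delta"] * (1 - pars$delta_drop)
  tmpl[, "beta"] <- tmpl[, "beta"] * (1 + pars$beta_gain)
  tmpl <- tmpl / rowSums(tmpl)
  g <- matrix(stats::rgamma(n_sec * 4L, shape = conc * tmpl), n_sec, 4L)
  q <- g / rowSums(g)
  colnames(q) <- colnames(sim_stage_templates)
  q
}

# AR(1) discretization of an Ornstein-Uhlenbeck path (exact at step dt).
sim_ou <- function(n, dt, mu, sd, tau) {
  phi <- exp(-dt / tau)
  innov <- stats::rnorm(n, sd = sd * sqrt(1 - phi^2))
  mu + as.numeric(stats::filter(innov, phi, method = "recursive",
                                init = stats::rnorm(1, sd = sd)))
}

#' Simulate one night of polysomnography
#'
#' Breathing is an amplitude-modulated quasi-sinusoid whose instantaneous
#' rate follows an OU process around the base rate, with severity-rate-scaled
#' arousal bursts (brief rate and amplitude excursions) placed inside
#' Wake/N1 epochs, plus domain noise for wireless nights. The hypnogram
#' comes from a severity-fragmented Markov chain; per-second qEEG relative
#' powers are the stage template perturbed by Dirichlet noise and the PD
#' delta/beta modulation.
#'
#' @param pars subject parameter slice from the simulator (severity, domain,
#'   effect channels); see [sim_config()].
#' @param cfg a [sim_config()].
#' @param seed integer seed; identical seeds give bit-identical nights.
#' @param subject_id,night_date metadata for the emitted night.
#' @return list with `night` (a `breathing_night`), `hypnogram` (stage per
#'   30-s epoch), `qeeg` (seconds x 4 or NULL outside `qeeg_domains`) and
#'   `truth` (the generating parameters).
#' @export
simulate_night <- function(pars, cfg, seed, subject_id = "S0",
                           night_date = "2020-01-01") {
  set.seed(seed)
  night_len_s <- cfg$night_hours * 3600
  n <- as.integer(night_len_s * cfg$f_b)
  dt <- 1 / cfg$f_b
  n_epochs <- max(1L, as.integer(ceiling(night_len_s / 30)))
  hypno <- sim_hypnogram(n_epochs, pars$frag)
  qeeg <- if (pars$domain %in% cfg$qeeg_domains) {
    sim_qeeg(hypno, night_len_s, pars, cfg$dirichlet_conc)
  }
  rate <- sim_ou(n, dt, cfg$base_rate, pars$rate_sd, cfg$ou_tau)
  amp <- 1 + sim_ou(n, dt, 0, pars$amp_irr, 20)
  # arousal bursts inside Wake/N1 epochs
  n_events <- stats::rpois(1L, pars$arousal_rate * cfg$night_hours)
  event_mask <- logical(n)
  if (n_events > 0L) {
    light <- which(rep(hypno, each = 30L * cfg$f_b)[seq_len(n)] %in% c("Wake", "N1"))
    cand <- if (length(light)) light else seq_len(n)
    starts <- sample(cand, min(n_events, length(cand)))
    for (s0 in starts) {
      len <- as.integer(stats::runif(1, 10, 20) * cfg$f_b)
      idx <- s0:min(s0 + len - 1L, n)
      event_mask[idx] <- TRUE
    }
  }
  rate[event_mask] <- rate[event_mask] + 0.12
  amp[event_mask] <- amp[event_mask] * 1.6
  phase <- 2 * pi * cumsum(rate) * dt
  x <- amp * sin(phase) + 0.15 * amp * sin(2 * phase)
  x[event_mask] <- x[event_mask] + stats::rnorm(sum(event_mask), sd = 0.4)
  x <- x + stats::rnorm(n, sd = 0.05)
  if (pars$domain == "wireless") {
    # contactless acquisition: band-limited (3-sample smoothing) with
    # added coloured noise from residual environmental reflections
    x <- as.numeric(stats::filter(x, rep(1 / 7, 7), sides = 2L))
    x[is.na(x)] <- 0
    coloured <- as.numeric(stats::filter(stats::rnorm(n, sd = cfg$wireless_noise_sd),
                                         0.95, method = "recursive"))
    x <- cfg$wireless_amp_scale * x + coloured * sqrt(1 - 0.95^2)
  }
  night <- breathing_night(subject_id, night_date, pars$domain, x, cfg$f_b)
  list(night = night, hypnogram = hypno, qeeg = qeeg,
       truth = c(pars[c("severity", "rate_sd", "arousal_rate", "amp_irr")],
                 list(n_events = n_events)))
}

night_key <- function(subject_id, date) paste(subject_id, format(as.Date(date)), sep = "_")

#' Simulate a full cohort
#'
#' Draws per-subject severities (PD uniform over `pd_severity_range`,
#' controls over `control_severity_range`), generates every night with
#' [simulate_night()], and assembles the manifest, hypnograms, qEEG labels
#' and ground truth. With `months >= 6` each subject gets month-6 (and,
#' with `months >= 12`, month-12) visits whose true severity has drifted by
#' `progression_rate` points per year.
#'
#' @param cfg a [sim_config()].
#' @param seed integer master seed.
#' @return object of class `breathpd_cohort`: list with `manifest`,
#'   `nights`, `hypnograms`, `qeeg` (keyed by subject/date), `truth`
#'   (per-night data.frame with true severity at each night) and `cfg`.
#' @export
simulate_cohort <- function(cfg, seed = 1L) {
  set.seed(seed)
  spec <- data.frame(
    pd = c(rep(c(TRUE, FALSE), c(cfg$n_pd, cfg$n_control)),
           rep(c(TRUE, FALSE), c(cfg$n_pd_wireless, cfg$n_control_wireless))),
    domain = rep(c("belt", "wireless"),
                 c(cfg$n_pd + cfg$n_control,
                   cfg$n_pd_wireless + cfg$n_control_wireless)),
    stringsAsFactors = FALSE
  )
  n_sub <- nrow(spec)
  if (n_sub < 1L) stop("empty cohort configuration")
  ids <- sprintf("S%03d", seq_len(n_sub))
  sev0 <- ifelse(spec$pd,
                 stats::runif(n_sub, cfg$pd_severity_range[1L], cfg$pd_severity_range[2L]),
                 stats::runif(n_sub, cfg$control_severity_range[1L],
                              cfg$control_severity_range[2L]))
  baseline <- as.Date("2020-01-01")
  visit_offsets <- c(0L, if (cfg$months >= 6) 183L, if (cfg$months >= 12) 365L)
  manifest <- data.frame(
    subject_id = ids, domain = spec$domain,
    pd_status = ifelse(spec$pd, "PD", "control"),
    mds_updrs_total = round(sev0, 1),
    updrs_1 = round(sev0 * 0.15, 1), updrs_2 = round(sev0 * 0.25, 1),
    updrs_3 = round(sev0 * 0.5, 1), updrs_4 = round(sev0 * 0.1, 1),
    hy_stage = pmin(5, round(sev0 / 20)),
    baseline_date = format(baseline),
    m6_date = if (cfg$months >= 6) format(baseline + 183L) else NA_character_,
    m12_date = if (cfg$months >= 12) format(baseline + 365L) else NA_character_,
    stringsAsFactors = FALSE
  )
  nights <- list(); hypnograms <- list(); qeeg <- list()
  truth <- list()
  night_seed <- function(i, v, k) (seed * 997L + i * 131L + v * 17L + k) %% .Machine$integer.max
  for (i in seq_len(n_sub)) {
    for (v in seq_along(visit_offsets)) {
      for (k in seq_len(cfg$nights_per_subject)) {
        date <- baseline + visit_offsets[v] + (k - 1L)
        years <- as.numeric(date - baseline) / 365
        sev_t <- max(0, sev0[i] + cfg$progression_rate * years)
        pars <- sim_subject_params(cfg, sev_t, spec$domain[i])
        sim <- simulate_night(pars, cfg, night_seed(i, v, k), ids[i], date)
        key <- night_key(ids[i], date)
        nights[[key]] <- sim$night
        hypnograms[[key]] <- sim$hypnogram
        if (!is.null(sim$qeeg)) qeeg[[key]] <- sim$qeeg
        truth[[key]] <- data.frame(subject_id = ids[i], night_date = format(date),
                                   true_severity = sev_t, pd = spec$pd[i],
                                   n_events = sim$truth$n_events,
                                   arousal_rate = sim$truth$arousal_rate,
                                   stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(manifest = manifest, nights = nights, hypnograms = hypnograms,
                 qeeg = qeeg, truth = do.call(rbind, truth), cfg = cfg,
                 seed = seed),
            class = "breathpd_cohort")
}

#' @export
print.breathpd_cohort <- function(x, ...) {
  cat(sprintf("<breathpd cohort: %d subjects (%d PD), %d nights, %d with qEEG>\n",
              nrow(x$manifest), sum(x$manifest$pd_status == "PD"),
              length(x$nights), length(x$qeeg)))
  invisible(x)
}

#' Write a cohort to the on-disk layout
#'
#' Emits `manifest.tsv`, one columnar night file + JSON sidecar per night
#' under `nights/`, hypnogram TSVs under `hypnograms/` and qEEG TSVs under
#' `qeeg/` — exactly the formats the I/O layer reads back.
#'
#' @param cohort a `breathpd_cohort`.
#' @param dir output directory.
#' @export
write_cohort <- function(cohort, dir) {
  for (d in c("", "nights", "hypnograms", "qeeg")) {
    dir.create(file.path(dir, d), showWarnings = FALSE, recursive = TRUE)
  }
  write_manifest(cohort$manifest, file.path(dir, "manifest.tsv"))
  for (key in names(cohort$nights)) {
    save_night(cohort$nights[[key]], file.path(dir, "nights", paste0(key, ".txt")))
    write_hypnogram(cohort$hypnograms[[key]],
                    file.path(dir, "hypnograms", paste0(key, ".tsv")))
    if (!is.null(cohort$qeeg[[key]])) {
      write_qeeg(cohort$qeeg[[key]], file.path(dir, "qeeg", paste0(key, ".tsv")))
    }
  }
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory produced by [write_cohort()].
#' @return a `breathpd_cohort` (without the simulator config).
#' @export
read_cohort <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.tsv"))
  nights <- list(); hypnograms <- list(); qeeg <- list()
  for (f in list.files(file.path(dir, "nights"), pattern = "\\.txt$")) {
    key <- tools::file_path_sans_ext(f)
    nights[[key]] <- load_night(file.path(dir, "nights", f), "columnar")
    hf <- file.path(dir, "hypnograms", paste0(key, ".tsv"))
    if (file.exists(hf)) hypnograms[[key]] <- read_hypnogram(hf)
    qf <- file.path(dir, "qeeg", paste0(key, ".tsv"))
    if (file.exists(qf)) qeeg[[key]] <- read_qeeg(qf)
  }
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    utils::read.delim(truth_path, stringsAsFactors = FALSE)
  }
  structure(list(manifest = manifest, nights = nights, hypnograms = hypnograms,
                 qeeg = qeeg, truth = truth, cfg = NULL, seed = NULL),
            class = "breathpd_cohort")
}

#' Simulate nightly measurement series for aggregation studies
#'
#' Generates per-night values as a subject-level latent plus i.i.d. nightly
#' noise — the measurement model under which window aggregation and
#' test-retest reliability are studied in isolation from network training.
#'
#' @param n_subjects number of subjects.
#' @param n_nights nights per subject (consecutive dates).
#' @param between_sd s.d. of subject latents.
#' @param within_sd s.d. of nightly noise.
#' @param mean latent mean.
#' @param seed integer seed.
#' @return data.frame `subject_id, night_date, value, latent`.
#' @export
simulate_nightly_values <- function(n_subjects, n_nights, between_sd,
                                    within_sd, mean = 0, seed = 1L) {
  set.seed(seed)
  lat <- stats::rnorm(n_subjects, mean, between_sd)
  df <- expand.grid(night = seq_len(n_nights), subject = seq_len(n_subjects))
  data.frame(
    subject_id = sprintf("S%03d", df$subject),
    night_date = format(as.Date("2020-01-01") + df$night - 1L),
    value = lat[df$subject] + stats::rnorm(nrow(df), 0, within_sd),
    latent = lat[df$subject],
    stringsAsFactors = FALSE
  )
}

#' Simulate noisy per-night severity predictions from cohort ground truth
#'
#' Produces prediction records whose severity equals the night's true
#' severity plus Gaussian noise — the harness used to study progression
#' power and aggregation independently of network training.
#'
#' @param cohort a `breathpd_cohort` with stored truth.
#' @param noise_sd nightly prediction noise s.d. (MDS-UPDRS points).
#' @param seed integer seed.
#' @return data.frame `subject_id, night_date, severity_pred`.
#' @export
simulate_severity_predictions <- function(cohort, noise_sd = 8, seed = 1L) {
  set.seed(seed)
  tr <- cohort$truth
  data.frame(subject_id = tr$subject_id, night_date = tr$night_date,
             severity_pred = tr$true_severity + stats::rnorm(nrow(tr), 0, noise_sd),
             stringsAsFactors = FALSE)
}

#' Simulate a longitudinal prediction harness for progression power studies
#'
#' Builds, without generating raw signals, a cohort of PD subjects whose true
#' severity drifts linearly over a year, plus noisy per-night severity
#' predictions in the month after the baseline, month-6 and month-12 visits.
#' Used to study how window aggregation affects progression detection.
#'
#' @param n_subjects number of PD subjects.
#' @param drift_per_year true severity increase (MDS-UPDRS points/year).
#' @param noise_sd nightly prediction noise s.d.
#' @param nights_per_window nights recorded in each visit window.
#' @param baseline_range uniform range of baseline severities.
#' @param seed integer seed.
#' @return list with `manifest` (visit dates) and `records` (per-night
#'   `severity_pred`).
#' @export
simulate_progression_harness <- function(n_subjects = 12L, drift_per_year = 6,
                                         noise_sd = 8, nights_per_window = 30L,
                                         baseline_range = c(20, 60), seed = 1L) {
  set.seed(seed)
  base_date <- as.Date("2020-01-01")
  ids <- sprintf("P%03d", seq_len(n_subjects))
  sev0 <- stats::runif(n_subjects, baseline_range[1L], baseline_range[2L])
  manifest <- data.frame(
    subject_id = ids, domain = "wireless", pd_status = "PD",
    mds_updrs_total = round(sev0, 1), updrs_1 = NA_real_, updrs_2 = NA_real_,
    updrs_3 = NA_real_, updrs_4 = NA_real_, hy_stage = NA_real_,
    baseline_date = format(base_date), m6_date = format(base_date + 183L),
    m12_date = format(base_date + 365L), stringsAsFactors = FALSE
  )
  offs <- c(0L, 183L, 365L)
  rows <- vector("list", n_subjects * 3L * nights_per_window)
  idx <- 0L
  for (i in seq_len(n_subjects)) {
    for (v in offs) {
      for (k in seq_len(nights_per_window)) {
        date <- base_date + v + (k - 1L)
        tru <- sev0[i] + drift_per_year * as.numeric(date - base_date) / 365
        idx <- idx + 1L
        rows[[idx]] <- data.frame(
          subject_id = ids[i], night_date = format(date),
          severity_pred = tru + stats::rnorm(1L, 0, noise_sd),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(manifest = manifest, records = do.call(rbind, rows))
}
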