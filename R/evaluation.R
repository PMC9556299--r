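# Evaluation methodology: ROC/AUC, sensitivity/specificity with exact
# binomial CIs, the Pearson correlation in its textbook summation form,
# median multi-night aggregation, one-way random-effects ICC test-retest
# reliability, cross-validation schemes, nonparametric group tests and the
# longitudinal progression analysis.

#' ROC curve and AUC
#'
#' AUC equals the Mann-Whitney concordance probability: the proportion of
#' positive-negative pairs where the positive scores higher, ties counted
#' one half (computed via midranks).
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (1 positive / 0 negative), both classes
#'   required.
#' @return list with `auc` and `curve` (data.frame `threshold, tpr, fpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required for ROC analysis")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    threshold = th,
    tpr = vapply(th, function(t) mean(scores[labels == 1L] >= t), numeric(1)),
    fpr = vapply(th, function(t) mean(scores[labels == 0L] >= t), numeric(1))
  )
  list(auc = auc, curve = curve)
}

clopper_pearson <- function(x, n, conf = 0.95) {
  a <- 1 - conf
  lo <- if (x == 0L) 0 else stats::qbeta(a / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(lo, hi)
}

wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Sensitivity and specificity with confidence intervals
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP); 95% CIs are
#' Clopper-Pearson exact by default (Wilson available).
#'
#' @param tp,fn,tn,fp confusion counts at the 0.5 threshold.
#' @param conf confidence level.
#' @param method `"clopper-pearson"` or `"wilson"`.
#' @return list with `sensitivity`, `specificity` and their CIs.
#' @export
sens_spec <- function(tp, fn, tn, fp, conf = 0.95,
                      method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  if (tp + fn == 0L || tn + fp == 0L) stop("zero denominator in confusion counts")
  ci <- switch(method, "clopper-pearson" = clopper_pearson, wilson = wilson_ci)
  list(sensitivity = tp / (tp + fn), sensitivity_ci = ci(tp, tp + fn, conf),
       specificity = tn / (tn + fp), specificity_ci = ci(tn, tn + fp, conf))
}

#' Confusion counts at a score threshold
#'
#' @param scores numeric scores; predicted positive when score > `threshold`.
#' @param labels binary labels.
#' @param threshold decision threshold (0.5 per the calibrated convention).
#' @return list with `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  pred <- scores > threshold
  list(tp = sum(pred & labels == 1L), fn = sum(!pred & labels == 1L),
       tn = sum(!pred & labels == 0L), fp = sum(pred & labels == 0L))
}

#' Pearson correlation (summation formula)
#'
#' Implements R = (N * sum(uv) - sum(u) sum(v)) /
#' sqrt((N * sum(u^2) - sum(u)^2) (N * sum(v^2) - sum(v)^2)).
#'
#' @param u,v numeric vectors of equal length >= 2.
#' @return correlation coefficient.
#' @export
pearson <- function(u, v) {
  n <- length(u)
  stopifnot(n >= 2L, length(v) == n)
  num <- n * sum(u * v) - sum(u) * sum(v)
  den2 <- (n * sum(u^2) - sum(u)^2) * (n * sum(v^2) - sum(v)^2)
  if (den2 <= 0) stop("zero variance in Pearson correlation")
  num / sqrt(den2)
}

## ---- aggregation ----

#' Aggregate per-night predictions to one value per subject
#'
#' The subject-level value is the median (mean-of-middle convention for even
#' counts) of the nightly values, optionally restricted to a per-subject
#' date window.
#'
#' @param records data.frame with `subject_id`, `night_date` and the value
#'   column.
#' @param value name of the value column (e.g. `"pd_score"`).
#' @param windows optional data.frame `subject_id, start, end` restricting
#'   each subject's nights to \[start, end\].
#' @param stat aggregation statistic (default [stats::median]).
#' @return data.frame `subject_id, value, n_nights`.
#' @export
aggregate_subjects <- function(records, value = "pd_score", windows = NULL,
                               stat = stats::median) {
  if (!is.null(windows)) {
    records <- merge(records, windows, by = "subject_id")
    d <- as.Date(records$night_date)
    records <- records[d >= as.Date(records$start) & d <= as.Date(records$end), ]
  }
  if (!nrow(records)) stop("no nights inside the aggregation window")
  agg <- stats::aggregate(records[[value]], by = list(subject_id = records$subject_id),
                          FUN = stat)
  cnt <- stats::aggregate(records[[value]], by = list(subject_id = records$subject_id),
                          FUN = length)
  data.frame(subject_id = agg$subject_id, value = agg$x, n_nights = cnt$x,
             stringsAsFactors = FALSE)
}

#' Per-subject one-month windows after a visit
#'
#' @param manifest cohort manifest.
#' @param visit `"baseline"`, `"m6"` or `"m12"`.
#' @param days window length in days.
#' @return data.frame `subject_id, start, end`.
#' @export
month_window <- function(manifest, visit = c("baseline", "m6", "m12"),
                         days = 30L) {
  visit <- match.arg(visit)
  col <- c(baseline = "baseline_date", m6 = "m6_date", m12 = "m12_date")[[visit]]
  d <- as.Date(manifest[[col]])
  keep <- !is.na(d)
  data.frame(subject_id = manifest$subject_id[keep], start = format(d[keep]),
             end = format(d[keep] + days - 1L), stringsAsFactors = FALSE)
}

## ---- test-retest reliability ----

#' One-way random-effects intraclass correlation, ICC(1,1)
#'
#' Variance-components form from the one-way ANOVA mean squares:
#' ICC = (MSB - MSW) / (MSB + (k0 - 1) MSW), with k0 the average group size
#' adjusted for imbalance.
#'
#' @param subject grouping vector.
#' @param value numeric measurements.
#' @return ICC estimate in \[-1, 1\].
#' @export
icc_oneway <- function(subject, value) {
  subject <- as.character(subject)
  ni <- table(subject)
  a <- length(ni)
  n <- length(value)
  stopifnot(a >= 2L, n > a)
  gm <- mean(value)
  mi <- tapply(value, subject, mean)
  ssb <- sum(ni * (mi[names(ni)] - gm)^2)
  ssw <- sum((value - mi[subject])^2)
  msb <- ssb / (a - 1)
  msw <- ssw / (n - a)
  k0 <- (n - sum(ni^2) / n) / (a - 1)
  (msb - msw) / (msb + (k0 - 1) * msw)
}

#' Test-retest reliability of window-aggregated predictions
#'
#' Splits each subject's nights (inside the month after baseline) into
#' consecutive non-overlapping windows of `window_n_nights`, aggregates each
#' window with the median, and computes the one-way ICC across subjects
#' treating windows as repeated measurements. The CI is a subject-level
#' bootstrap.
#'
#' @param records prediction records (`subject_id, night_date`, value column).
#' @param window_n_nights nights aggregated per window.
#' @param value value column name.
#' @param min_windows minimum windows required per subject (default 2).
#' @param n_boot bootstrap resamples for the CI (0 to skip).
#' @param conf confidence level.
#' @return list with `icc`, `ci`, `n_subjects`, `windows_per_subject`.
#' @export
test_retest_icc <- function(records, window_n_nights, value = "pd_score",
                            min_windows = 2L, n_boot = 1000L, conf = 0.95) {
  sp <- split(records, records$subject_id)
  rows <- list()
  for (id in names(sp)) {
    r <- sp[[id]][order(as.Date(sp[[id]]$night_date)), ]
    nw <- nrow(r) %/% window_n_nights
    if (nw < min_windows) next
    for (w in seq_len(nw)) {
      idx <- ((w - 1L) * window_n_nights + 1L):(w * window_n_nights)
      rows[[length(rows) + 1L]] <- data.frame(subject_id = id, window = w,
                                              value = stats::median(r[[value]][idx]))
    }
  }
  if (length(rows) < 4L) stop("insufficient windows for ICC")
  df <- do.call(rbind, rows)
  if (length(unique(df$subject_id)) < 5L) stop("need at least 5 subjects for ICC")
  est <- icc_oneway(df$subject_id, df$value)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    ids <- unique(df$subject_id)
    bt <- vapply(seq_len(n_boot), function(b) {
      take <- sample(ids, length(ids), replace = TRUE)
      parts <- lapply(seq_along(take), function(j) {
        d <- df[df$subject_id == take[j], ]
        d$subject_id <- sprintf("B%03d", j)
        d
      })
      d <- do.call(rbind, parts)
      tryCatch(icc_oneway(d$subject_id, d$value), error = function(e) NA_real_)
    }, numeric(1))
    ci <- unname(stats::quantile(bt, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                                 na.rm = TRUE))
  }
  list(icc = est, ci = ci, n_subjects = length(unique(df$subject_id)),
       windows_per_subject = table(df$subject_id))
}

## ---- cross-validation ----

#' Subject-level cross-validation assignments
#'
#' All nights of a subject share a fold. `kfold4` stratifies by PD status
#' and acquisition domain; `loo` is leave-one-subject-out;
#' `cross_institution` returns one train/test configuration per institution
#' tag; `external_holdout` holds out a stratified fraction of subjects.
#'
#' @param manifest cohort manifest.
#' @param scheme one of `"kfold4"`, `"loo"`, `"cross_institution"`,
#'   `"external_holdout"`.
#' @param institution institution tag per manifest row (required for
#'   `cross_institution`).
#' @param holdout_frac held-out fraction for `external_holdout`.
#' @param seed shuffling seed.
#' @return for fold schemes, data.frame `subject_id, fold`; for
#'   `cross_institution`/`external_holdout`, list of
#'   `list(train_ids, test_ids, test_institution)`.
#' @export
crossval <- function(manifest, scheme = c("kfold4", "loo", "cross_institution",
                                          "external_holdout"),
                     institution = NULL, holdout_frac = 0.25, seed = 1L) {
  scheme <- match.arg(scheme)
  set.seed(seed)
  if (scheme == "kfold4") {
    fold <- integer(nrow(manifest))
    strata <- interaction(manifest$pd_status, manifest$domain, drop = TRUE)
    offset <- 0L
    for (s in levels(strata)) {
      idx <- which(strata == s)
      fold[idx][sample.int(length(idx))] <-
        (offset + seq_along(idx) - 1L) %% 4L + 1L
      offset <- offset + length(idx)
    }
    return(data.frame(subject_id = manifest$subject_id, fold = fold,
                      stringsAsFactors = FALSE))
  }
  if (scheme == "loo") {
    return(data.frame(subject_id = manifest$subject_id,
                      fold = seq_len(nrow(manifest)), stringsAsFactors = FALSE))
  }
  if (scheme == "cross_institution") {
    if (is.null(institution)) stop("cross_institution requires institution tags")
    lapply(unique(institution), function(inst) {
      list(test_institution = inst,
           train_ids = manifest$subject_id[institution != inst],
           test_ids = manifest$subject_id[institution == inst])
    })
  } else {
    test <- c()
    for (cl in unique(manifest$pd_status)) {
      ids <- manifest$subject_id[manifest$pd_status == cl]
      test <- c(test, sample(ids, max(1L, round(length(ids) * holdout_frac))))
    }
    list(list(test_institution = NA_character_,
              train_ids = setdiff(manifest$subject_id, test), test_ids = test))
  }
}

## ---- group comparisons ----

#' Nonparametric group comparisons
#'
#' Wraps the Wilcoxon rank-sum (one-tailed), Kruskal-Wallis, and one-sample
#' Wilcoxon signed-rank (one-tailed) tests; exact null distributions are
#' used for small samples without ties (the default of the underlying
#' implementations), normal approximation with tie correction otherwise.
#'
#' @param values_a first group (for Kruskal-Wallis, a list of groups).
#' @param values_b second group (rank-sum only).
#' @param test `"rank_sum_one_tailed"`, `"kruskal_wallis"` or
#'   `"signed_rank_one_sample"`.
#' @param alternative direction of `values_a` relative to `values_b` (or to
#'   `mu`): `"greater"` or `"less"`.
#' @param mu null location for the one-sample signed-rank test.
#' @return list with `statistic` and `p`.
#' @export
group_compare <- function(values_a, values_b = NULL,
                          test = c("rank_sum_one_tailed", "kruskal_wallis",
                                   "signed_rank_one_sample"),
                          alternative = c("greater", "less"), mu = 0) {
  test <- match.arg(test)
  alternative <- match.arg(alternative)
  if (test == "rank_sum_one_tailed") {
    stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
    ht <- stats::wilcox.test(values_a, values_b, alternative = alternative)
  } else if (test == "kruskal_wallis") {
    groups <- if (is.list(values_a)) values_a else list(values_a, values_b)
    stopifnot(all(lengths(groups) >= 2L))
    ht <- stats::kruskal.test(groups)
  } else {
    stopifnot(length(values_a) >= 1L)
    if (all(values_a == mu)) {
      # no nonzero differences: the one-tailed test carries no evidence
      return(list(statistic = 0, p = 1))
    }
    ht <- stats::wilcox.test(values_a, mu = mu, alternative = alternative)
  }
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

## ---- progression ----

#' Longitudinal progression analysis
#'
#' For each subject with the required visits, aggregates the severity
#' predictions over the month following baseline and the month following
#' the month-6 (and/or month-12) visit, forms the change
#' (later minus baseline, positive = worsening) and tests it against zero
#' with the one-tailed one-sample Wilcoxon signed-rank test. The
#' single-night variant uses the first night of each window instead of the
#' median.
#'
#' @param records prediction records with `severity_pred`.
#' @param manifest cohort manifest (visit dates).
#' @param months which follow-up visits to analyze (subset of c(6, 12)).
#' @param window_days aggregation window length.
#' @param single_night use one night per window instead of the median.
#' @return list per month: `changes` (per-subject data.frame), `p`
#'   (signed-rank, alternative greater-than-zero), `n`.
#' @export
progression_analysis <- function(records, manifest, months = c(6, 12),
                                 window_days = 30L, single_night = FALSE) {
  stat <- if (single_night) function(x) x[1L] else stats::median
  agg_window <- function(visit) {
    w <- month_window(manifest, visit, days = window_days)
    r <- merge(records, w, by = "subject_id")
    d <- as.Date(r$night_date)
    r <- r[d >= as.Date(r$start) & d <= as.Date(r$end), ]
    r <- r[order(r$subject_id, as.Date(r$night_date)), ]
    stats::aggregate(r$severity_pred, by = list(subject_id = r$subject_id),
                     FUN = stat)
  }
  base <- agg_window("baseline")
  out <- list()
  for (m in months) {
    visit <- paste0("m", m)
    if (all(is.na(manifest[[paste0(visit, "_date")]]))) next
    later <- agg_window(visit)
    mg <- merge(base, later, by = "subject_id", suffixes = c("_base", "_later"))
    if (!nrow(mg)) stop("no qualifying subjects for month-", m, " progression")
    changes <- data.frame(subject_id = mg$subject_id,
                          change = mg$x_later - mg$x_base)
    p <- group_compare(changes$change, test = "signed_rank_one_sample",
                       alternative = "greater")$p
    out[[visit]] <- list(changes = changes, p = p, n = nrow(changes))
  }
  if (!length(out)) stop("no qualifying subjects for progression analysis")
  out
}

## ---- end-to-end fold evaluation ----

#' Cross-validated detection evaluation on a cohort
#'
#' Trains one model per fold on the training subjects and scores the
#' held-out subjects' nights; subject-level scores are the per-subject
#' median nightly score. Returns the pooled held-out AUC at subject level.
#'
#' @param cohort a `breathpd_cohort`.
#' @param cfg a [model_config()].
#' @param epochs training epochs per fold.
#' @param seed seed for fold assignment and training.
#' @param ... forwarded to [train_model()].
#' @return list with `auc`, `subject_scores` (data.frame) and `records`.
#' @export
evaluate_detection_cv <- function(cohort, cfg = model_config(), epochs = 30L,
                                  seed = 1L, ...) {
  manifest <- cohort$manifest
  folds <- crossval(manifest, "kfold4", seed = seed)
  records <- list()
  for (k in sort(unique(folds$fold))) {
    test_ids <- folds$subject_id[folds$fold == k]
    train_ids <- setdiff(manifest$subject_id, test_ids)
    member <- train_model(cohort, cfg, subjects = train_ids, epochs = epochs,
                          seed = seed + k, ...)
    records[[k]] <- predict_cohort(member, cohort, subjects = test_ids,
                                   calibrated = FALSE)
  }
  records <- do.call(rbind, records)
  subj <- aggregate_subjects(records, value = "pd_score")
  subj$label <- as.integer(manifest$pd_status[match(subj$subject_id,
                                                    manifest$subject_id)] == "PD")
  list(auc = roc_auc(subj$value, subj$label)$auc, subject_scores = subj,
       records = records)
}

## ---- domain-invariance probe ----

#' Post-hoc domain probe on pooled features
#'
#' Freshly trains a logistic probe to predict the acquisition domain from
#' the model's pooled global features, using every subject's earlier nights,
#' and reports its accuracy on each subject's held-out last night. Low probe
#' accuracy means the encoder's representation is domain invariant.
#'
#' @param member trained member or bundle (first member used).
#' @param cohort a `breathpd_cohort` with both domains.
#' @param subjects subject ids to probe (default all); each must have at
#'   least two nights so one can be held out.
#' @return held-out probe accuracy in \[0, 1\].
#' @export
domain_probe_accuracy <- function(member, cohort, subjects = NULL) {
  m <- first_member(member)
  keys <- names(cohort$nights)
  sid <- vapply(keys, function(k) cohort$nights[[k]]$subject_id, "")
  if (!is.null(subjects)) {
    keys <- keys[sid %in% subjects]
    sid <- sid[sid %in% subjects]
  }
  dates <- as.Date(vapply(keys, function(k) format(cohort$nights[[k]]$night_date), ""))
  is_test <- vapply(seq_along(keys), function(i) {
    dates[i] == max(dates[sid == sid[i]])
  }, logical(1))
  g <- t(vapply(keys, function(k) {
    sig <- preprocess_night(cohort$nights[[k]])$signal
    tape <- tape_new()
    pe <- pnode_env(tape, m$params)
    as.numeric(network_forward(tape, pe, m$cfg, sig, want = "cls")$g$val)
  }, numeric(m$cfg$d)))
  y <- as.integer(vapply(keys, function(k) cohort$nights[[k]]$domain == "belt",
                         logical(1)))
  if (length(unique(y[!is_test])) < 2L) {
    stop("probe training set has one domain only")
  }
  df <- data.frame(y = y, g)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df[!is_test, ],
                                     family = stats::binomial()))
  pred <- suppressWarnings(stats::predict(fit, newdata = df[is_test, ],
                                          type = "response"))
  mean((pred > 0.5) == (y[is_test] == 1L))
}
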