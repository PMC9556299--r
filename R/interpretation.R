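# Attention-based interpretation: spread each attention step over the
# seconds it covers, aggregate by sleep stage or by dominant EEG band, and
# contrast the PD and control distributions per category.

#' Write / read a hypnogram TSV (epoch_index, stage)
#'
#' Stages are `Wake, N1, N2, N3, REM`, one row per 30-s epoch.
#'
#' @param hypnogram character vector of stages.
#' @param path file path.
#' @export
write_hypnogram <- function(hypnogram, path) {
  utils::write.table(data.frame(epoch_index = seq_along(hypnogram),
                                stage = hypnogram),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)$stage
}

# Spread step-level attention uniformly over covered seconds.
attention_per_second <- function(attention, step_seconds, n_seconds) {
  w <- rep(attention / step_seconds, each = step_seconds)
  length(w) <- n_seconds                 # truncate or NA-pad
  w[is.na(w)] <- 0
  w
}

#' Aggregate an attention profile by sleep stage or EEG band
#'
#' Attention steps (8 s at the default encoder stride) are spread uniformly
#' over their covered seconds; each second is assigned its 30-s hypnogram
#' stage (mode `"stage"`) or its argmax relative-power band with ties broken
#' toward the lower-frequency band (mode `"band"`); the per-category scores
#' are the attention mass in each category, renormalized over the
#' categories present.
#'
#' @param attention nonnegative step weights summing to 1.
#' @param labels a hypnogram (stage per 30-s epoch) for mode `"stage"`, or a
#'   seconds x 4 qEEG relative-power matrix for mode `"band"`.
#' @param mode `"stage"` or `"band"`.
#' @param step_seconds seconds covered by one attention step.
#' @return named numeric vector of category scores summing to 1.
#' @export
attention_by_category <- function(attention, labels, mode = c("stage", "band"),
                                  step_seconds = 8L) {
  mode <- match.arg(mode)
  if (mode == "stage") {
    cats <- rep(labels, each = 30L)
    levels <- sim_stages
  } else {
    cats <- colnames(labels)[max.col(labels, ties.method = "first")]
    levels <- colnames(labels)
  }
  n_sec <- min(length(cats), length(attention) * step_seconds)
  if (n_sec == 0L) stop("no overlap between attention support and labels")
  w <- attention_per_second(attention, step_seconds, n_sec)
  cats <- cats[seq_len(n_sec)]
  score <- vapply(levels, function(l) sum(w[cats == l]), numeric(1))
  tot <- sum(score)
  if (tot <= 0) stop("attention mass is zero over the labelled period")
  score / tot
}

#' Contrast attention summaries between PD and control nights
#'
#' For each category, picks the direction in which the PD group's
#' normalized attention differs from the control group's (by median) and
#' reports the one-tailed Wilcoxon rank-sum p-value in that direction.
#'
#' @param summaries_pd,summaries_control matrices (nights x categories) of
#'   per-night normalized attention scores, equal column sets.
#' @return data.frame `category, direction ("pd_higher"/"pd_lower"), p`.
#' @export
cohort_attention_contrast <- function(summaries_pd, summaries_control) {
  if (nrow(summaries_pd) < 3L || nrow(summaries_control) < 3L) {
    stop("need at least 3 nights per group")
  }
  stopifnot(identical(colnames(summaries_pd), colnames(summaries_control)))
  rows <- lapply(colnames(summaries_pd), function(cat) {
    a <- summaries_pd[, cat]; b <- summaries_control[, cat]
    if (all(is.na(a)) || all(is.na(b))) stop("empty category: ", cat)
    pd_higher <- stats::median(a) >= stats::median(b)
    p <- group_compare(a, b, test = "rank_sum_one_tailed",
                       alternative = if (pd_higher) "greater" else "less")$p
    data.frame(category = cat,
               direction = if (pd_higher) "pd_higher" else "pd_lower",
               p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-night attention summaries for a cohort
#'
#' Convenience wrapper: computes attention profiles for the given nights
#' and aggregates each by stage or band using the cohort's hypnograms/qEEG.
#'
#' @param model trained model or bundle.
#' @param cohort a `breathpd_cohort`.
#' @param keys night keys (default: all nights with the needed labels).
#' @param mode `"stage"` or `"band"`.
#' @return matrix (nights x categories) with night keys as row names.
#' @export
cohort_attention_summaries <- function(model, cohort, keys = NULL,
                                       mode = c("stage", "band")) {
  mode <- match.arg(mode)
  if (is.null(keys)) {
    keys <- if (mode == "stage") names(cohort$hypnograms) else names(cohort$qeeg)
  }
  prof <- attention_profiles(model, cohort, keys)
  step <- first_member(model)$cfg$stride_total / first_member(model)$cfg$f_b
  out <- t(vapply(keys, function(k) {
    labels <- if (mode == "stage") cohort$hypnograms[[k]] else cohort$qeeg[[k]]
    attention_by_category(prof[[k]], labels, mode, step_seconds = step)
  }, numeric(if (mode == "stage") 5L else 4L)))
  rownames(out) <- keys
  out
}
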