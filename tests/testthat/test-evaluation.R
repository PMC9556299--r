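test_that("AUC equals exhaustive pairwise concordance", {
  # perfectly separated
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  # all scores tied
  expect_equal(roc_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  # six-point fixture with a tie, against the enumeration oracle
  s <- c(0.1, 0.4, 0.4, 0.35, 0.8, 0.7)
  l <- c(0, 0, 1, 0, 1, 1)
  expect_equal(roc_auc(s, l)$auc, auc_pairwise(s, l))
  # random fixtures up to 12 points
  set.seed(51)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    l <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 2)   # rounding forces occasional ties
    expect_equal(roc_auc(s, l)$auc, auc_pairwise(s, l), tolerance = 1e-12)
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(52)
  s <- runif(40)
  l <- rbinom(40, 1, 0.5)
  ref <- as.numeric(suppressMessages(pROC::auc(l, s, direction = "<")))
  expect_equal(roc_auc(s, l)$auc, ref, tolerance = 1e-12)
})

test_that("sensitivity/specificity follow the count formulas with exact CIs", {
  r <- sens_spec(tp = 8, fn = 2, tn = 5, fp = 5)
  expect_equal(r$sensitivity, 0.8)
  expect_equal(r$specificity, 0.5)
  expect_equal(sens_spec(tp = 1, fn = 0, tn = 0, fp = 5)$specificity, 0)

  # Clopper-Pearson bounds vs the binomial-tail bisection oracle
  r2 <- sens_spec(tp = 73, fn = 18, tn = 50, fp = 10)
  expect_equal(r2$sensitivity_ci, cp_bisect(73, 91), tolerance = 1e-6)
  expect_equal(r2$specificity_ci, cp_bisect(50, 60), tolerance = 1e-6)
  # edge counts
  expect_equal(sens_spec(tp = 10, fn = 0, tn = 5, fp = 0)$sensitivity_ci,
               cp_bisect(10, 10), tolerance = 1e-6)
  expect_error(sens_spec(tp = 0, fn = 0, tn = 3, fp = 1), "denominator")

  w <- sens_spec(tp = 73, fn = 18, tn = 50, fp = 10, method = "wilson")
  expect_true(w$sensitivity_ci[1] > r2$sensitivity_ci[1])  # Wilson is narrower
})

test_that("Pearson implements the summation formula", {
  expect_equal(pearson(1:10, 1:10), 1)
  expect_equal(pearson(1:10, -(1:10) + 7), -1)
  # hand-computed fixture
  expect_equal(pearson(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  # cross-check against the standard implementation on random data
  set.seed(53)
  u <- rnorm(50); v <- 0.3 * u + rnorm(50)
  expect_equal(pearson(u, v), cor(u, v), tolerance = 1e-12)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("subject aggregation takes the median with mean-of-middle ties", {
  rec <- data.frame(subject_id = c("a", "a", "a", "b", "c", "c"),
                    night_date = format(as.Date("2020-01-01") + 0:5),
                    pd_score = c(0.2, 0.9, 0.7, 0.6, 0.2, 0.4))
  agg <- aggregate_subjects(rec, "pd_score")
  expect_equal(agg$value[agg$subject_id == "a"], 0.7)
  expect_equal(agg$value[agg$subject_id == "b"], 0.6)   # single night
  expect_equal(agg$value[agg$subject_id == "c"], 0.3)   # even count
  # sorting oracle for the even-count convention
  expect_equal(agg$value[agg$subject_id == "c"], mean(sort(c(0.2, 0.4))[1:2]))

  # window restriction
  win <- data.frame(subject_id = "a", start = "2020-01-01", end = "2020-01-02")
  expect_equal(aggregate_subjects(rec[rec$subject_id == "a", ], "pd_score",
                                  windows = win)$value, 0.55)
  expect_error(aggregate_subjects(rec[rec$subject_id == "b", ], "pd_score",
                                  windows = win), "no nights")
})

test_that("one-way ICC matches ANOVA mean squares and known structures", {
  # identical window aggregates per subject, subjects differ -> ICC 1
  df <- data.frame(subject = rep(letters[1:6], each = 2),
                   value = rep(c(1, 3, 5, 7, 9, 11), each = 2))
  expect_equal(icc_oneway(df$subject, df$value), 1)

  # ANOVA cross-check on random balanced data
  set.seed(54)
  df2 <- data.frame(subject = rep(sprintf("s%d", 1:8), each = 3),
                    value = rnorm(24))
  av <- anova(lm(value ~ subject, data = df2))
  msb <- av$`Mean Sq`[1]; msw <- av$`Mean Sq`[2]
  expect_equal(icc_oneway(df2$subject, df2$value),
               (msb - msw) / (msb + 2 * msw), tolerance = 1e-12)

  # pure noise: ICC near zero at 50 subjects
  nul <- simulate_nightly_values(50, 4, between_sd = 0, within_sd = 1,
                                 seed = 55L)
  icc0 <- icc_oneway(nul$subject_id, nul$value)
  expect_lt(abs(icc0), 0.1)
})

test_that("test-retest ICC recovers the variance-components target", {
  # between:within 9:1 per window aggregate
  df <- simulate_nightly_values(200, 12, between_sd = 3, within_sd = 1,
                                seed = 56L)
  names(df)[names(df) == "value"] <- "pd_score"
  r <- test_retest_icc(df, window_n_nights = 1L, n_boot = 200L)
  expect_lt(abs(r$icc - 0.9), 0.05)
  expect_true(r$ci[1] < r$icc & r$icc < r$ci[2])
  expect_error(test_retest_icc(df[df$subject_id %in% c("S001", "S002"), ],
                               window_n_nights = 1L), "5 subjects")
})

test_that("cross-validation schemes partition at the subject level", {
  man <- data.frame(subject_id = sprintf("s%d", 1:8),
                    domain = rep(c("belt", "wireless"), 4),
                    pd_status = rep(c("PD", "control"), each = 4),
                    stringsAsFactors = FALSE)
  f <- crossval(man, "kfold4", seed = 2L)
  expect_equal(as.integer(sort(table(f$fold))), rep(2L, 4L))
  expect_setequal(f$subject_id, man$subject_id)

  loo <- crossval(man, "loo")
  expect_equal(length(unique(loo$fold)), 8L)

  inst <- crossval(man, "cross_institution",
                   institution = c("A", "A", "B", "B", "C", "C", "C", "A"))
  expect_length(inst, 3L)
  for (cfg in inst) {
    expect_length(intersect(cfg$train_ids, cfg$test_ids), 0L)
  }
  expect_error(crossval(man, "cross_institution"), "institution")

  hold <- crossval(man, "external_holdout", holdout_frac = 0.25, seed = 3L)
  expect_length(intersect(hold[[1]]$train_ids, hold[[1]]$test_ids), 0L)
  expect_equal(length(hold[[1]]$test_ids), 2L)
})

test_that("rank tests match exhaustive enumeration for small samples", {
  # one-tailed rank-sum: all mass in one tail -> 1 / choose(6, 3) = 1/20
  r <- group_compare(c(1, 2, 3), c(4, 5, 6), "rank_sum_one_tailed",
                     alternative = "less")
  expect_equal(r$p, 0.05)
  expect_equal(r$p, ranksum_exact_p(c(1, 2, 3), c(4, 5, 6)))

  # interleaved groups with no shift: one-tailed p at least 0.5
  expect_gte(group_compare(c(1, 4, 5, 8), c(2, 3, 6, 7),
                           "rank_sum_one_tailed")$p, 0.5)

  # signed-rank, all positive: 1/2^4
  s <- group_compare(c(1, 2, 3, 4), test = "signed_rank_one_sample",
                     alternative = "greater")
  expect_equal(s$p, 1 / 16)
  expect_equal(s$p, signedrank_exact_p(c(1, 2, 3, 4)))

  # random small fixtures against both enumeration oracles
  set.seed(57)
  for (i in 1:10) {
    a <- sample(1:50, sample(3:4, 1))
    b <- sample(1:50, sample(3:4, 1)) + 0.5   # never ties with a
    expect_equal(group_compare(a, b, "rank_sum_one_tailed",
                               alternative = "less")$p,
                 ranksum_exact_p(a, b), tolerance = 1e-12)
    x <- sample(1:20, 6) * sample(c(-1, 1), 6, replace = TRUE)
    expect_equal(group_compare(x, test = "signed_rank_one_sample",
                               alternative = "greater")$p,
                 signedrank_exact_p(x), tolerance = 1e-12)
  }

  # Kruskal-Wallis wiring
  kw <- group_compare(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)),
                      test = "kruskal_wallis")
  expect_equal(kw$p, kruskal.test(list(c(1, 2, 3), c(4, 5, 6),
                                       c(7, 8, 9)))$p.value)
})

test_that("progression analysis signs changes as later minus baseline", {
  h <- simulate_progression_harness(n_subjects = 8L, drift_per_year = 12,
                                    noise_sd = 0.1, nights_per_window = 5L,
                                    seed = 58L)
  res <- progression_analysis(h$records, h$manifest)
  expect_true(all(res$m6$changes$change > 0))     # worsening is positive
  expect_lt(res$m6$p, 0.05)
  expect_lt(res$m12$p, 0.05)
  expect_gt(mean(res$m12$changes$change), mean(res$m6$changes$change))

  # zero drift and zero noise: all changes zero -> p = 1 one-tailed
  h0 <- simulate_progression_harness(n_subjects = 6L, drift_per_year = 0,
                                     noise_sd = 0, nights_per_window = 3L,
                                     seed = 59L)
  res0 <- progression_analysis(h0$records, h0$manifest, months = 6)
  expect_equal(res0$m6$p, 1)
})
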