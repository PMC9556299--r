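test_that("loss terms drop out exactly when their labels are absent", {
  set.seed(31)
  q <- matrix(1 / 4, 16, 4)
  outs <- list(list(cls_logit = 0.3, sev = 25, qeeg = q + 0.01,
                    disc_pd_logit = 0.2, disc_ctl_logit = -0.1))
  w <- model_config()$weights

  # PD label only: no severity, no qEEG -> cls + adv remain
  lb <- composite_loss(outs, list(y = 1L, sev = NA_real_, domain_is_belt = 1),
                       weights = w)
  expect_true(all(lb$available == c(TRUE, FALSE, FALSE, TRUE, FALSE)))
  expect_equal(lb$l_sev, 0)
  expect_equal(lb$l_qeeg, 0)
  expect_equal(lb$total, w$cls * lb$l_cls + w$adv * lb$l_adv, tolerance = 1e-12)

  # everything labelled, two nights -> all five terms, weighted total
  outs2 <- list(
    list(cls_logit = 0.3, sev = 25,
         qeeg = list(rel_power = q, mask = rep(TRUE, 16))$rel_power),
    list(cls_logit = -0.2, sev = 31, qeeg = NULL)
  )
  lb2 <- composite_loss(
    outs2,
    list(y = 1L, sev = 28, domain_is_belt = 1,
         qeeg = list(list(rel_power = q + 0.02, mask = rep(TRUE, 16)), NULL)),
    weights = w)
  expect_true(all(lb2$available[c(1, 2, 3, 5)]))
  expect_equal(lb2$total,
               w$cls * lb2$l_cls + w$sev * lb2$l_sev + w$qeeg * lb2$l_qeeg +
                 w$cons * lb2$l_cons,
               tolerance = 1e-12)

  # a perfect qEEG prediction zeroes its term
  lb3 <- composite_loss(
    list(list(cls_logit = 0, sev = NA, qeeg = q)),
    list(y = 0L, sev = NA_real_, domain_is_belt = 1,
         qeeg = list(list(rel_power = q, mask = rep(TRUE, 16)))),
    weights = w)
  expect_equal(lb3$l_qeeg, 0)

  expect_error(composite_loss(list(list(cls_logit = 0.1)),
                              list(y = NA_integer_, sev = NA_real_),
                              weights = w),
               "no loss term")
})

test_that("consistency loss is the population variance of nightly predictions", {
  expect_equal(consistency_loss(c(10, 10, 10)), 0)
  expect_equal(consistency_loss(c(0, 2)), 1)          # population convention
  expect_equal(consistency_loss(c(3, 1, 7)), mean((c(3, 1, 7) - 11 / 3)^2))
  expect_equal(consistency_loss(c(3, 1, 7)), consistency_loss(c(7, 3, 1)))
  single <- consistency_loss(5)
  expect_equal(as.numeric(single), 0)
  expect_true(attr(single, "not_applicable"))
})

test_that("parameters with no label receive exactly zero gradient", {
  ns <- asNamespace("breathpd")
  cfg <- model_config(seed = 9L)
  params <- init_params(cfg)
  set.seed(32)
  sig <- rnorm(2000)
  batch <- list(signals = list(sig), qeeg = list(NULL), y = 1L,
                sev = NA_real_, domain_is_belt = 1L)
  opts <- list(use_adv = FALSE, use_cons = TRUE, w_class = c(1, 1),
               w_dom = c(1, 1))
  stp <- ns$batch_step(params, cfg, batch, opts)
  # no qEEG label, no severity label: decoder and severity head untouched
  expect_length(stp$grads[grep("^dec|^qout|^sev", names(stp$grads))], 0L)
  # finite-difference check: perturbing a decoder weight leaves the loss fixed
  p2 <- params
  p2$dec2.d2.W[1, 1] <- p2$dec2.d2.W[1, 1] + 0.37
  stp2 <- ns$batch_step(p2, cfg, batch, opts)
  expect_identical(stp$total, stp2$total)
})

test_that("Platt scaling recovers known calibration parameters", {
  set.seed(33)
  n <- 2000
  z0 <- rnorm(n, 0, 2)
  y <- rbinom(n, 1, plogis(z0))

  # scores generated through a known distortion z = 2*z0 - 1: the fit must
  # invert it, A ~ 0.5, B ~ 0.5
  fit <- platt_fit(2 * z0 - 1, y)
  expect_lt(abs(fit[["A"]] - 0.5), 0.1)
  expect_lt(abs(fit[["B"]] - 0.5), 0.1)

  # already-calibrated input: identity map
  fit0 <- platt_fit(z0, y)
  expect_lt(abs(fit0[["A"]] - 1), 0.1)
  expect_lt(abs(fit0[["B"]]), 0.1)

  # calibration never increases cross-entropy on the calibration subset
  ce <- function(p) -mean(y * log(p) + (1 - y) * log(1 - p))
  z_dist <- 2 * z0 - 1
  expect_lte(ce(plogis(fit[["A"]] * z_dist + fit[["B"]])),
             ce(plogis(z_dist)) + 1e-12)

  expect_error(platt_fit(rnorm(10), rep(1, 10)), "one class")
})

test_that("ensemble scores average the members' calibrated outputs", {
  cfg <- model_config(seed = 2L)
  base <- list(params = init_params(cfg), cfg = cfg)
  # with A = 0 the calibrated score is plogis(B) regardless of the night,
  # so four members can be pinned at known scores
  targets <- c(0.2, 0.4, 0.6, 0.8)
  members <- lapply(targets, function(p) {
    m <- base
    m$calib <- c(A = 0, B = qlogis(p))
    m
  })
  bundle <- breathpd:::new_bundle(members, cfg, seed = 1L)
  night <- breathing_night("s", "2020-01-01", "belt", rnorm(2000))
  expect_equal(predict_night(bundle, night)$pd_score, 0.5, tolerance = 1e-12)

  # four identical members give the single-member score
  same <- breathpd:::new_bundle(rep(list(members[[2]]), 4L), cfg, seed = 1L)
  expect_equal(predict_night(same, night)$pd_score, 0.4, tolerance = 1e-12)
})

test_that("training is deterministic given a seed and learns a tiny cohort", {
  cohort <- tiny_cohort(n_pd = 2L, n_control = 2L, nights = 2L,
                        night_hours = 1 / 18, seed = 41L)
  m1 <- train_model(cohort, model_config(), epochs = 2L, seed = 77L,
                    use_qeeg = FALSE)
  m2 <- train_model(cohort, model_config(), epochs = 2L, seed = 77L,
                    use_qeeg = FALSE)
  expect_identical(m1$params, m2$params)
  expect_length(m1$history, 2L)
  expect_true(is.finite(m1$history[[2]]$l_cls))
})

test_that("the four-fold ensemble partitions subjects and calibrates each fold", {
  cohort <- tiny_cohort(n_pd = 4L, n_control = 4L, nights = 1L,
                        night_hours = 1 / 18, seed = 42L)
  bundle <- build_ensemble(cohort, model_config(), epochs = 1L, seed = 5L,
                           use_qeeg = FALSE)
  expect_s3_class(bundle, "breathpd_model")
  expect_length(bundle$members, 4L)
  for (m in bundle$members) {
    expect_true(all(is.finite(m$calib)))
    expect_true(m$fold_id %in% 1:4)
  }
  rec <- predict_cohort(bundle, cohort)
  expect_true(all(rec$pd_score > 0 & rec$pd_score < 1))
  expect_equal(nrow(rec), 8L)
})

test_that("subject-level splits keep every night of a subject together", {
  cohort <- tiny_cohort(n_pd = 4L, n_control = 4L, nights = 3L,
                        night_hours = 1 / 18, seed = 43L)
  folds <- crossval(cohort$manifest, "kfold4", seed = 1L)
  expect_equal(as.integer(sort(table(folds$fold))), rep(2L, 4L))
  expect_equal(anyDuplicated(folds$subject_id), 0L)
  # prediction records inherit the subject id, so all nights follow the fold
  rec <- simulate_severity_predictions(cohort, noise_sd = 1, seed = 1L)
  merged <- merge(rec, folds, by = "subject_id")
  per_subject <- tapply(merged$fold, merged$subject_id, function(f) {
    length(unique(f))
  })
  expect_true(all(per_subject == 1L))
})

test_that("head substitution trains a subpart head on its own labels", {
  cohort <- tiny_cohort(n_pd = 3L, n_control = 3L, nights = 2L,
                        night_hours = 1 / 18, seed = 44L)
  m <- train_model(cohort, model_config(), epochs = 2L, seed = 6L,
                   use_qeeg = FALSE, parts = "II")
  # the part-II head exists and produces finite estimates
  night <- cohort$nights[[1L]]
  f <- encode_breathing(preprocess_night(night), m)
  g <- attend_pool(f, m)$g
  expect_true(is.finite(predict_severity(g, m, part = "II")))
  # and the total head was never created
  expect_error(predict_severity(g, m, part = "total"), "not trained")
})
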