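cfg <- model_config(seed = 3L)
member <- list(params = init_params(cfg), cfg = cfg)

random_night <- function(len, seed = 1L) {
  set.seed(seed)
  x <- rnorm(len)
  n <- breathing_night("s", "2020-01-01", "belt", x)
  preprocess_night(n)
}

test_that("encoder output length is ceil(length / stride) across lengths", {
  expect_equal(cfg$stride_total, 80L)
  n <- random_night(72000)  # a 2 h night
  f <- encode_breathing(n, member)
  expect_equal(nrow(f), 900L)
  expect_equal(ncol(f), cfg$d)
  expect_equal(attr(f, "step_seconds"), 8)
  expect_true(all(is.finite(f)))

  set.seed(21)
  for (len in sample(640:20000, 20L)) {
    f1 <- encode_breathing(random_night(len), member)
    expect_equal(nrow(f1), as.integer(ceiling(len / 80)))
    # doubling the input length doubles the number of steps
    f2 <- encode_breathing(random_night(2L * len), member)
    expect_equal(nrow(f2), as.integer(ceiling(2 * len / 80)))
  }
})

test_that("nights shorter than the receptive field are rejected", {
  expect_error(encode_breathing(random_night(400), member))
})

test_that("attention weights sum to one and pooling matches brute force", {
  n <- random_night(4000, seed = 5L)
  f <- encode_breathing(n, member)
  ap <- attend_pool(f, member)
  expect_equal(sum(ap$attention), 1, tolerance = 1e-6)
  expect_true(all(ap$attention >= 0))
  # brute-force weighted sum oracle
  manual <- colSums(unclass(f) * ap$attention)
  expect_equal(as.numeric(ap$g), manual, tolerance = 1e-9)
})

test_that("forced attention weights reproduce mean and selection pooling", {
  ns <- asNamespace("breathpd")
  set.seed(22)
  feats <- matrix(rnorm(5 * 4), 5, 4)
  pool_with_scores <- function(scores) {
    tape <- ns$tape_new()
    out <- ns$op_attention_pool(tape, ns$ad_leaf(tape, feats),
                                ns$ad_leaf(tape, matrix(scores, ncol = 1)))
    out$val
  }
  # equal scores -> softmax uniform -> arithmetic mean
  expect_equal(as.numeric(pool_with_scores(rep(0, 5))), colMeans(feats),
               tolerance = 1e-6)
  # a dominant score -> effectively one-hot selection of that step
  expect_equal(as.numeric(pool_with_scores(c(0, 0, 60, 0, 0))), feats[3, ],
               tolerance = 1e-6)
  # random weights equal the explicit weighted sum
  sc <- rnorm(5)
  a <- exp(sc - max(sc)); a <- a / sum(a)
  expect_equal(as.numeric(pool_with_scores(sc)), colSums(feats * a),
               tolerance = 1e-9)
})

test_that("the PD classifier is a sigmoid over three dense layers", {
  # zero weights give logit 0 -> score exactly 0.5
  zero <- member
  for (nm in grep("^cls", names(zero$params), value = TRUE)) {
    zero$params[[nm]][] <- 0
  }
  expect_equal(classify_pd(rnorm(cfg$d), zero), 0.5)

  # toy 3-d network against a hand-rolled forward pass
  toy <- list(cfg = cfg, params = list(
    cls1.W = matrix(c(1, 0, -1, 0.5, 2, 1), 3, 2),
    cls1.b = matrix(c(0.1, -0.2), 1),
    cls2.W = matrix(c(1, -1, 0.5, 0.25), 2, 2),
    cls2.b = matrix(c(0, 0.3), 1),
    cls3.W = matrix(c(2, -1), 2, 1),
    cls3.b = matrix(0.05, 1)
  ))
  g <- c(0.3, -0.6, 1.2)
  h1 <- pmax(as.numeric(g %*% toy$params$cls1.W) + as.numeric(toy$params$cls1.b), 0)
  h2 <- pmax(as.numeric(h1 %*% toy$params$cls2.W) + as.numeric(toy$params$cls2.b), 0)
  z <- as.numeric(h2 %*% toy$params$cls3.W) + as.numeric(toy$params$cls3.b)
  expect_equal(classify_pd(g, toy), plogis(z), tolerance = 1e-12)
  expect_gt(classify_pd(g, toy), 0)
  expect_lt(classify_pd(g, toy), 1)
})

test_that("the severity head is linear-output over four dense layers", {
  zero <- member
  for (nm in grep("^sev_total", names(zero$params), value = TRUE)) {
    zero$params[[nm]][] <- 0
  }
  expect_equal(predict_severity(rnorm(cfg$d), zero), 0)

  expect_error(predict_severity(rnorm(cfg$d), member, part = "II"),
               "not trained")

  toy <- list(cfg = cfg, params = list(
    sev_total1.W = matrix(c(1, -0.5, 0.2, 0.7), 2, 2),
    sev_total1.b = matrix(c(0.1, 0), 1),
    sev_total2.W = matrix(c(0.5, 1, -1, 0.3), 2, 2),
    sev_total2.b = matrix(c(0, -0.1), 1),
    sev_total3.W = matrix(c(1, 0.5, -0.2, 0.4), 2, 2),
    sev_total3.b = matrix(c(0.2, 0), 1),
    sev_total4.W = matrix(c(3, -2), 2, 1),
    sev_total4.b = matrix(1, 1)
  ))
  g <- c(0.4, -0.9)
  h <- g
  for (i in 1:3) {
    h <- as.numeric(h %*% toy$params[[paste0("sev_total", i, ".W")]]) +
      as.numeric(toy$params[[paste0("sev_total", i, ".b")]])
    h <- pmax(h, 0)
  }
  expected <- as.numeric(h %*% toy$params$sev_total4.W) +
    as.numeric(toy$params$sev_total4.b)
  expect_equal(predict_severity(g, toy), expected, tolerance = 1e-12)
})

test_that("qEEG predictions are per-second simplex vectors at 8x upsampling", {
  n <- random_night(7200, seed = 8L)  # 12 min -> 90 steps -> 720 seconds
  q <- predict_qeeg(n, member)
  expect_equal(nrow(q), 8L * 90L)
  expect_equal(colnames(q), c("delta", "theta", "alpha", "beta"))
  expect_true(all(abs(rowSums(q) - 1) < 1e-5))
  expect_true(all(q > 0))

  # ablating the skip connections changes the output
  q_noskip <- predict_qeeg(n, member, use_skips = FALSE)
  expect_gt(max(abs(q - q_noskip)), 1e-6)
})

test_that("domain discriminators start at 0.5 and route by group", {
  zero <- member
  for (nm in grep("^disc", names(zero$params), value = TRUE)) {
    zero$params[[nm]][] <- 0
  }
  g <- rnorm(cfg$d)
  expect_equal(discriminate_domain(g, zero, "PD"), 0.5)
  expect_equal(discriminate_domain(g, zero, "control"), 0.5)

  # PD routing never touches D_Control parameters (gradient isolation)
  ns <- asNamespace("breathpd")
  batch <- list(signals = list(random_night(2000, 9L)$signal),
                qeeg = list(NULL), y = 1L, sev = NA_real_, domain_is_belt = 1L)
  opts <- list(use_adv = TRUE, use_cons = FALSE, w_class = c(1, 1),
               w_dom = c(1, 1))
  stp <- ns$batch_step(member$params, cfg, batch, opts)
  ctl_grads <- stp$grads[grep("^discCTL", names(stp$grads))]
  expect_true(length(ctl_grads) == 0 ||
                all(vapply(ctl_grads, function(g) is.null(g) || all(g == 0),
                           logical(1))))
  expect_false(is.null(stp$grads[["discPD1.W"]]))
})

test_that("the forward pass is deterministic in evaluation mode", {
  n <- random_night(6000, seed = 10L)
  p1 <- predict_night(member, breathing_night("s", "2020-01-01", "belt",
                                              n$signal))
  p2 <- predict_night(member, breathing_night("s", "2020-01-01", "belt",
                                              n$signal))
  expect_identical(p1$pd_score, p2$pd_score)
  expect_identical(p1$severity, p2$severity)
  expect_identical(p1$attention, p2$attention)
})

test_that("model bundles round-trip through disk bit-identically", {
  m2 <- member
  m2$calib <- c(A = 1.3, B = -0.4)
  m2$fold_id <- 2L
  bundle <- breathpd:::new_bundle(list(m2, member), cfg, seed = 5L)
  dir <- file.path(tempdir(), "bundle")
  save_model(bundle, dir)
  rt <- load_model(dir)
  expect_equal(length(rt$members), 2L)
  expect_identical(rt$members[[1]]$calib, m2$calib)
  set.seed(30)
  for (i in 1:5) {
    sig <- rnorm(sample(2000:6000, 1))
    night <- breathing_night("s", "2020-01-01", "belt", sig)
    expect_identical(predict_night(bundle, night)$pd_score,
                     predict_night(rt, night)$pd_score)
    expect_identical(predict_night(bundle, night)$severity,
                     predict_night(rt, night)$severity)
  }
})
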