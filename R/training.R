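# Multitask/adversarial training: composite loss with per-term availability
# masking, Adam optimization over subject-night batches, Platt-scaled
# four-fold ensemble calibration, and cohort prediction.

## ---- losses ----

#' Transductive consistency loss
#'
#' Population variance of one subject's per-night severity predictions
#' within a short window; zero iff all nights agree. A single night returns
#' 0 with attribute `not_applicable`.
#'
#' @param preds numeric vector of per-night severity predictions.
#' @return nonnegative scalar.
#' @export
consistency_loss <- function(preds) {
  if (length(preds) < 2L) {
    return(structure(0, not_applicable = TRUE))
  }
  mean((preds - mean(preds))^2)
}

# Core composite loss over one subject batch, built on a tape. `outs` is a
# list (one element per night) of head nodes; `lab` carries y, sev, domain,
# qeeg targets. Terms with no label contribute exactly zero and no gradient
# (the head is simply never evaluated).
composite_loss_nodes <- function(tape, outs, lab, weights,
                                 w_class = c(1, 1), w_dom = 1,
                                 use_cons = TRUE) {
  n <- length(outs)
  terms <- list()
  if (!is.na(lab$y) && !is.null(outs[[1L]]$cls_logit)) {
    ls <- lapply(outs, function(o) {
      loss_bce_logit(tape, o$cls_logit, lab$y, w_class[lab$y + 1L])
    })
    terms$l_cls <- op_sum_scalars(tape, ls, rep(1 / n, n))
  }
  sev_nodes <- NULL
  if (!is.na(lab$sev) && !is.null(outs[[1L]]$sev)) {
    sev_nodes <- lapply(outs, `[[`, "sev")
    ls <- lapply(sev_nodes, function(o) {
      loss_mse(tape, o, matrix(lab$sev, 1L), weight = w_dom)
    })
    terms$l_sev <- op_sum_scalars(tape, ls, rep(1 / n, n))
  }
  qeeg_idx <- which(vapply(seq_len(n), function(i) {
    !is.null(lab$qeeg[[i]]) && !is.null(outs[[i]]$qeeg)
  }, logical(1)))
  if (length(qeeg_idx)) {
    ls <- lapply(qeeg_idx, function(i) {
      tgt <- lab$qeeg[[i]]
      loss_mse(tape, outs[[i]]$qeeg, tgt$rel_power, mask = tgt$mask * 1)
    })
    terms$l_qeeg <- op_sum_scalars(tape, ls, rep(1 / length(ls), length(ls)))
  }
  if (!is.na(lab$y) && !is.null(outs[[1L]]$disc_pd_logit)) {
    ls <- lapply(outs, function(o) {
      lgt <- if (lab$y == 1L) o$disc_pd_logit else o$disc_ctl_logit
      loss_bce_logit(tape, lgt, lab$domain_is_belt)
    })
    terms$l_adv <- op_sum_scalars(tape, ls, rep(1 / n, n))
  }
  if (use_cons && !is.null(sev_nodes) && length(sev_nodes) >= 2L) {
    terms$l_cons <- loss_variance(tape, sev_nodes)
  }
  if (!length(terms)) stop("no loss term available for this batch")
  wmap <- c(l_cls = weights$cls, l_sev = weights$sev, l_qeeg = weights$qeeg,
            l_adv = weights$adv, l_cons = weights$cons)
  total <- op_sum_scalars(tape, unname(terms), unname(wmap[names(terms)]))
  list(total = total,
       terms = vapply(terms, function(t) as.numeric(t$val), numeric(1)))
}

#' Composite multitask loss breakdown
#'
#' Evaluates the weighted total training loss for one subject's nights from
#' already-computed head outputs, excluding every term whose label is
#' unavailable (the excluded term contributes exactly zero).
#'
#' @param outputs list, one element per night, each with any of
#'   `cls_logit`, `sev` (scalars), `qeeg` (seconds x 4 matrix),
#'   `disc_pd_logit`, `disc_ctl_logit`.
#' @param labels list with `y` (1 PD / 0 control / NA), `sev` (MDS-UPDRS or
#'   NA), `domain_is_belt` (1/0), `qeeg` (list per night of
#'   `list(rel_power, mask)` or NULL).
#' @param weights named loss weights, default from [model_config()].
#' @param use_cons include the transductive consistency term.
#' @return list with per-term values, `total`, and the availability mask.
#' @export
composite_loss <- function(outputs, labels,
                           weights = model_config()$weights, use_cons = TRUE) {
  tape <- tape_new()
  outs <- lapply(outputs, function(o) {
    lapply(o, function(v) {
      if (is.null(v)) NULL else ad_leaf(tape, if (is.matrix(v)) v else matrix(v, 1L))
    })
  })
  if (is.null(labels$qeeg)) labels$qeeg <- vector("list", length(outputs))
  if (is.null(labels$domain_is_belt)) labels$domain_is_belt <- 1
  res <- composite_loss_nodes(tape, outs, labels, weights, use_cons = use_cons)
  all_terms <- c("l_cls", "l_sev", "l_qeeg", "l_adv", "l_cons")
  vals <- stats::setNames(rep(0, 5L), all_terms)
  vals[names(res$terms)] <- res$terms
  c(as.list(vals), list(total = as.numeric(res$total$val),
                        available = all_terms %in% names(res$terms)))
}

## ---- optimizer ----

adam_new <- function() {
  st <- new.env(parent = emptyenv())
  st$m <- list(); st$v <- list(); st$t <- 0L
  st
}

adam_step <- function(st, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    m <- st$m[[nm]]; v <- st$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    st$m[[nm]] <- m; st$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  params
}

## ---- training data preparation ----

sev_label_col <- c(total = "mds_updrs_total", I = "updrs_1", II = "updrs_2",
                   III = "updrs_3", IV = "updrs_4")

# Groups a subject's nights into consistency windows (gaps > 31 days split);
# severity labels attach to the baseline window only.
prep_subject_batches <- function(cohort, manifest_row, cfg, use_qeeg,
                                 part = "total") {
  id <- manifest_row$subject_id
  keys <- names(cohort$nights)[vapply(cohort$nights, function(n) {
    n$subject_id == id
  }, logical(1))]
  if (!length(keys)) return(list())
  dates <- as.Date(vapply(keys, function(k) format(cohort$nights[[k]]$night_date), ""))
  ord <- order(dates)
  keys <- keys[ord]; dates <- dates[ord]
  win <- cumsum(c(1L, diff(dates) > 31))
  y <- switch(manifest_row$pd_status, PD = 1L, control = 0L, NA_integer_)
  lapply(unique(win), function(w) {
    ks <- keys[win == w]
    base_win <- abs(as.numeric(dates[win == w][1L] -
                               as.Date(manifest_row$baseline_date))) <= 31
    sev <- if (base_win) manifest_row[[sev_label_col[[part]]]] else NA_real_
    sigs <- lapply(ks, function(k) preprocess_night(cohort$nights[[k]])$signal)
    qeeg <- lapply(ks, function(k) {
      q <- if (use_qeeg) cohort$qeeg[[k]] else NULL
      if (is.null(q)) return(NULL)
      n_sec <- 8L * as.integer(ceiling(length(cohort$nights[[k]]$signal) /
                                       cfg$stride_total))
      align_qeeg_to_features(q, n_sec)
    })
    list(subject_id = id, keys = ks, signals = sigs, qeeg = qeeg,
         y = y, sev = if (is.null(sev)) NA_real_ else sev,
         domain_is_belt = as.integer(manifest_row$domain == "belt"))
  })
}

# One gradient step over a subject batch; returns grads + term values.
batch_step <- function(params, cfg, batch, opts) {
  tape <- tape_new()
  pe <- pnode_env(tape, params)
  outs <- lapply(seq_along(batch$signals), function(i) {
    want <- "cls"
    if (!is.na(batch$sev)) want <- c(want, "sev")
    if (!is.null(batch$qeeg[[i]])) want <- c(want, "qeeg")
    if (opts$use_adv && !is.na(batch$y)) want <- c(want, "disc")
    network_forward(tape, pe, cfg, batch$signals[[i]], want = want,
                    part = opts$part)
  })
  res <- composite_loss_nodes(tape, outs, batch, cfg$weights,
                              w_class = opts$w_class, w_dom = opts$w_dom[
                                batch$domain_is_belt + 1L],
                              use_cons = opts$use_cons)
  ad_backward(tape, res$total)
  grads <- list()
  for (nm in ls(pe$nodes)) grads[[nm]] <- get(nm, envir = pe$nodes)$grad
  gs <- if (opts$use_adv) lapply(outs, function(o) o$g$val)
  list(grads = grads, terms = res$terms, total = as.numeric(res$total$val),
       pooled = gs)
}

# Extra discriminator-only refinement on detached pooled features, so the
# group discriminator stays strong enough for the reversed gradient to be
# informative (alternating-update half of the adversarial scheme).
disc_step <- function(params, cfg, pooled, y, domain_is_belt) {
  nm <- if (y == 1L) "discPD" else "discCTL"
  tape <- tape_new()
  pe <- pnode_env(tape, params)
  ls_nodes <- lapply(pooled, function(g) {
    lgt <- mlp_forward(tape, pe, ad_leaf(tape, g), nm, 2L)
    loss_bce_logit(tape, lgt, domain_is_belt)
  })
  total <- op_sum_scalars(tape, ls_nodes, rep(1 / length(ls_nodes),
                                              length(ls_nodes)))
  ad_backward(tape, total)
  grads <- list()
  for (p in ls(pe$nodes)) grads[[p]] <- get(p, envir = pe$nodes)$grad
  grads
}

## ---- training loop ----

#' Train a single multitask model
#'
#' Optimizes the composite objective (weighted cross-entropy PD
#' classification, weighted MDS-UPDRS regression, L2 qEEG prediction,
#' gradient-reversal adversarial domain loss, transductive consistency)
#' with Adam. One optimization step processes all nights of one subject
#' within a consistency window; unavailable labels drop their terms.
#'
#' @param cohort a `breathpd_cohort`.
#' @param cfg a [model_config()].
#' @param subjects subject ids to train on (default all).
#' @param epochs passes over the training subjects.
#' @param seed integer seed controlling initialization and batch order.
#' @param use_qeeg,use_adv,use_cons enable the auxiliary, adversarial and
#'   consistency terms (`use_adv = NULL` auto-enables when both acquisition
#'   domains are present).
#' @param class_weighting weight the classification cross-entropy by inverse
#'   class frequency of the training split.
#' @param parts severity heads to create; the first entry is the head that
#'   is trained (head substitution: a subpart head is supervised by the
#'   matching manifest column, e.g. `parts = "II"` trains on `updrs_2`).
#' @param log_file optional JSON-lines per-epoch loss log.
#' @param verbose print per-epoch losses.
#' @return a trained member (list with `params`, `cfg`, `history`).
#' @export
train_model <- function(cohort, cfg = model_config(), subjects = NULL,
                        epochs = 30L, seed = cfg$seed, use_qeeg = TRUE,
                        use_adv = NULL, use_cons = TRUE,
                        class_weighting = TRUE, parts = "total",
                        log_file = NULL, verbose = FALSE) {
  manifest <- impute_control_labels(cohort$manifest)
  if (!is.null(subjects)) manifest <- manifest[manifest$subject_id %in% subjects, ]
  n_class <- table(factor(manifest$pd_status, levels = c("control", "PD")))
  if (any(n_class < 2L)) stop("need at least 2 subjects per class")
  set.seed(seed)
  params <- init_params(cfg, parts = parts, init_seed = NULL)
  if (is.null(use_adv)) use_adv <- length(unique(manifest$domain)) > 1L
  w_class <- if (class_weighting) {
    as.numeric(sum(n_class) / (2 * n_class))       # (control, PD)
  } else c(1, 1)
  n_dom <- table(factor(manifest$domain, levels = c("wireless", "belt")))
  w_dom <- if (all(n_dom > 0)) as.numeric(sum(n_dom) / (2 * n_dom)) else c(1, 1)
  part <- parts[1L]
  stopifnot(part %in% names(sev_label_col))
  opts <- list(use_adv = use_adv, use_cons = use_cons, w_class = w_class,
               w_dom = w_dom, part = part)
  batches <- list()
  for (i in seq_len(nrow(manifest))) {
    batches <- c(batches, prep_subject_batches(cohort, manifest[i, ], cfg,
                                               use_qeeg, part = part))
  }
  if (!length(batches)) stop("no training nights")
  st <- adam_new()
  st_disc <- adam_new()
  history <- list()
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(batches))
    acc <- c(l_cls = 0, l_sev = 0, l_qeeg = 0, l_adv = 0, l_cons = 0)
    cnt <- acc
    for (b in ord) {
      stp <- batch_step(params, cfg, batches[[b]], opts)
      if (!is.finite(stp$total)) {
        stop("training diverged (non-finite loss) at epoch ", ep)
      }
      params <- adam_step(st, params, stp$grads, cfg$lr)
      if (opts$use_adv && !is.null(stp$pooled) && !is.na(batches[[b]]$y)) {
        for (k in seq_len(3L)) {
          dg <- disc_step(params, cfg, stp$pooled, batches[[b]]$y,
                          batches[[b]]$domain_is_belt)
          params <- adam_step(st_disc, params, dg, cfg$lr)
        }
      }
      acc[names(stp$terms)] <- acc[names(stp$terms)] + stp$terms
      cnt[names(stp$terms)] <- cnt[names(stp$terms)] + 1
    }
    ep_log <- as.list(ifelse(cnt > 0, acc / pmax(cnt, 1), NA))
    history[[ep]] <- c(list(epoch = ep), ep_log)
    if (!is.null(log_file)) {
      cat(jsonlite::toJSON(history[[ep]], auto_unbox = TRUE, digits = 6, na = "null"),
          "\n", file = log_file, append = ep > 1L, sep = "")
    }
    if (verbose) {
      message(sprintf("epoch %d: %s", ep,
                      paste(sprintf("%s=%.4f", names(acc), acc / pmax(cnt, 1)),
                            collapse = " ")))
    }
  }
  list(params = params, cfg = cfg, history = history, seed = seed)
}

## ---- calibration ----

#' Fit Platt scaling scalars by Newton iterations
#'
#' Finds (A, B) minimizing the cross-entropy of `plogis(A * z + B)` against
#' binary labels; the fit is convex and iterated to gradient norm < `tol`.
#' `z` is the classifier's pre-sigmoid logit.
#'
#' @param z numeric logits.
#' @param y binary labels (0/1), both classes required.
#' @return named vector `c(A, B)`.
#' @param tol gradient-infinity-norm convergence tolerance.
#' @param max_iter Newton iteration cap.
#' @export
platt_fit <- function(z, y, tol = 1e-8, max_iter = 100L) {
  if (length(unique(y)) < 2L) stop("calibration subset contains one class only")
  X <- cbind(z, 1)
  nll <- function(b) {
    eta <- as.numeric(X %*% b)
    sum(pmax(eta, 0) - eta * y + log1p(exp(-abs(eta))))
  }
  beta <- c(0, 0)
  f0 <- nll(beta)
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(as.numeric(X %*% beta))
    g <- crossprod(X, p - y)
    if (max(abs(g)) < tol) break
    W <- p * (1 - p)
    H <- crossprod(X * W, X) + diag(1e-10, 2L)
    step <- solve(H, g)
    # damped Newton: backtrack until the convex objective decreases
    t <- 1
    repeat {
      cand <- beta - t * as.numeric(step)
      f1 <- nll(cand)
      if (f1 <= f0 - 1e-4 * t * sum(g * step) || t < 1e-8) break
      t <- t / 2
    }
    beta <- cand
    f0 <- f1
  }
  c(A = beta[1L], B = beta[2L])
}

# Uncalibrated classifier logit for one preprocessed signal.
member_logit <- function(member, signal) {
  tape <- tape_new()
  pe <- pnode_env(tape, member$params)
  out <- network_forward(tape, pe, member$cfg, signal, want = "cls")
  as.numeric(out$cls_logit$val)
}

#' Platt-calibrate a trained member on a calibration subset
#'
#' Computes per-night classifier logits for the calibration subjects and
#' fits the two calibration scalars (A, B) by [platt_fit()].
#'
#' @param member trained member from [train_model()].
#' @param cohort the cohort holding the calibration nights.
#' @param subjects calibration subject ids (both classes required).
#' @param fold_id stored fold index.
#' @return the member with `$calib = c(A, B)` attached.
#' @export
platt_calibrate <- function(member, cohort, subjects, fold_id = NA_integer_) {
  manifest <- cohort$manifest[cohort$manifest$subject_id %in% subjects, ]
  z <- c(); y <- c()
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$subject_id[i]
    yy <- switch(manifest$pd_status[i], PD = 1L, control = 0L, NA_integer_)
    if (is.na(yy)) next
    for (k in names(cohort$nights)) {
      if (cohort$nights[[k]]$subject_id != id) next
      z <- c(z, member_logit(member, preprocess_night(cohort$nights[[k]])$signal))
      y <- c(y, yy)
    }
  }
  member$calib <- platt_fit(z, y)
  member$fold_id <- fold_id
  member
}

#' Train the Platt-scaled four-fold calibrated ensemble
#'
#' Splits the training subjects into four subject-level subsets (stratified
#' by PD status), trains on three and calibrates on the held-out subset,
#' rotating so each subset calibrates once; the final prediction is the
#' arithmetic mean of the four members' calibrated scores.
#'
#' @inheritParams train_model
#' @param ... forwarded to [train_model()].
#' @return a `breathpd_model` bundle with four calibrated members.
#' @export
build_ensemble <- function(cohort, cfg = model_config(), subjects = NULL,
                           epochs = 30L, seed = cfg$seed, ...) {
  manifest <- cohort$manifest
  if (!is.null(subjects)) manifest <- manifest[manifest$subject_id %in% subjects, ]
  if (nrow(manifest) < 8L) stop("need at least 8 subjects for the 4-fold ensemble")
  set.seed(seed)
  fold <- integer(nrow(manifest))
  for (cl in unique(manifest$pd_status)) {
    idx <- which(manifest$pd_status == cl)
    fold[idx] <- (sample.int(length(idx)) - 1L) %% 4L + 1L
  }
  members <- vector("list", 4L)
  for (k in 1:4) {
    calib_ids <- manifest$subject_id[fold == k]
    train_ids <- manifest$subject_id[fold != k]
    m <- train_model(cohort, cfg, subjects = train_ids, epochs = epochs,
                     seed = seed + k, ...)
    members[[k]] <- platt_calibrate(m, cohort, calib_ids, fold_id = k)
  }
  new_bundle(members, cfg, seed)
}

## ---- prediction ----

#' Predict one night
#'
#' Runs every ensemble member on the preprocessed night; the PD score is the
#' arithmetic mean of the members' (calibrated, when available) sigmoid
#' scores, the severity estimate the mean of the head outputs, and the
#' attention profile comes from the first member.
#'
#' @param model a `breathpd_model` bundle or single member.
#' @param night a `breathing_night` (raw; preprocessing applied here).
#' @param part severity head.
#' @param calibrated use Platt-calibrated scores where fitted.
#' @return list with `pd_score`, `severity`, `attention`.
#' @export
predict_night <- function(model, night, part = "total", calibrated = TRUE) {
  members <- if (inherits(model, "breathpd_model")) model$members else list(model)
  sig <- preprocess_night(night)$signal
  scores <- numeric(length(members))
  sevs <- numeric(length(members))
  attention <- NULL
  for (i in seq_along(members)) {
    m <- members[[i]]
    tape <- tape_new()
    pe <- pnode_env(tape, m$params)
    out <- network_forward(tape, pe, m$cfg, sig, want = c("cls", "sev"),
                           part = part)
    z <- as.numeric(out$cls_logit$val)
    scores[i] <- if (calibrated && !is.null(m$calib)) {
      stats::plogis(m$calib[["A"]] * z + m$calib[["B"]])
    } else stats::plogis(z)
    sevs[i] <- as.numeric(out$sev$val)
    if (i == 1L) attention <- out$attn
  }
  list(pd_score = mean(scores), severity = mean(sevs), attention = attention)
}

#' Predict every night of a cohort
#'
#' @param model a `breathpd_model` or member.
#' @param cohort a `breathpd_cohort`.
#' @param subjects subject ids to score (default all).
#' @param part severity head.
#' @param calibrated use calibrated scores where fitted.
#' @return data.frame of prediction records: `subject_id, night_date,
#'   pd_score, severity_pred`.
#' @export
predict_cohort <- function(model, cohort, subjects = NULL, part = "total",
                           calibrated = TRUE) {
  keys <- names(cohort$nights)
  if (!is.null(subjects)) {
    keys <- keys[vapply(keys, function(k) {
      cohort$nights[[k]]$subject_id %in% subjects
    }, logical(1))]
  }
  rows <- lapply(keys, function(k) {
    n <- cohort$nights[[k]]
    p <- predict_night(model, n, part = part, calibrated = calibrated)
    data.frame(subject_id = n$subject_id, night_date = format(n$night_date),
               pd_score = p$pd_score, severity_pred = p$severity,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Attention profiles for a set of nights
#'
#' @param model a `breathpd_model` or member.
#' @param cohort a `breathpd_cohort`.
#' @param keys night keys (default all).
#' @return named list of attention weight vectors (one per feature step).
#' @export
attention_profiles <- function(model, cohort, keys = names(cohort$nights)) {
  m <- first_member(model)
  out <- lapply(keys, function(k) {
    sig <- preprocess_night(cohort$nights[[k]])$signal
    tape <- tape_new()
    pe <- pnode_env(tape, m$params)
    network_forward(tape, pe, m$cfg, sig, want = "cls")$attn
  })
  names(out) <- keys
  out
}
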