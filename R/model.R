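# Network definition: breathing encoder E (1D bottleneck residual blocks +
# simple recurrent units), attention-pooling PD encoder G, PD classifier M,
# severity predictor N, UNet-style qEEG decoder F and the two domain
# discriminators D_PD / D_Control.

#' Model configuration
#'
#' Builds the hyperparameter set of the breathing network. The temporal
#' layout is fixed by design: a stride-5 stem followed by eight bottleneck
#' residual blocks with stride 2 at blocks 1, 3, 5 and 7 gives a total
#' encoder stride of S = 80 samples per feature step, i.e. a feature rate of
#' 0.125 Hz at the 10 Hz input rate; three x2 upsampling blocks in the qEEG
#' decoder then restore exactly the 1 Hz label resolution.
#'
#' @param block_channels output channels of the eight bottleneck blocks.
#' @param hidden hidden size of the three simple-recurrent-unit layers (must
#'   equal the last block width so the highway skip is an identity).
#' @param d dimension of the pooled global feature.
#' @param attn_width channels of the first attention convolution.
#' @param cls_widths hidden widths of the three-layer PD classifier.
#' @param sev_widths hidden widths of the four-layer severity predictor.
#' @param disc_width hidden width of each domain discriminator.
#' @param dec_channels output channels of the three deconvolution blocks.
#' @param qeeg_fc_width width of the first of the two fully connected output
#'   layers of the qEEG predictor.
#' @param lr Adam learning rate.
#' @param weights named list of loss weights (`cls`, `sev`, `qeeg`, `adv`,
#'   `cons`).
#' @param grl_lambda gradient-reversal coefficient of the adversarial term.
#' @param seed integer used for weight initialization.
#' @return an object of class `breathpd_config`.
#' @export
model_config <- function(block_channels = c(6L, 6L, 8L, 8L, 12L, 12L, 12L, 12L),
                         hidden = 12L, d = 12L, attn_width = 8L,
                         cls_widths = c(12L, 8L), sev_widths = c(12L, 8L, 6L),
                         disc_width = 8L, dec_channels = c(10L, 8L, 6L),
                         qeeg_fc_width = 6L, lr = 1e-3,
                         weights = list(cls = 1, sev = 0.05, qeeg = 1,
                                        adv = 0.1, cons = 0.1),
                         grl_lambda = 1, seed = 1L) {
  stopifnot(length(block_channels) == 8L, length(dec_channels) == 3L,
            hidden == block_channels[8L], d == hidden)
  cfg <- list(
    f_b = 10, stem_kernel = 7L, stem_stride = 5L, stem_channels = block_channels[1L],
    block_channels = as.integer(block_channels),
    block_strides = c(2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L),
    expansion = 2L, sru_layers = 3L, hidden = as.integer(hidden), d = as.integer(d),
    attn_width = as.integer(attn_width), cls_widths = as.integer(cls_widths),
    sev_widths = as.integer(sev_widths), disc_width = as.integer(disc_width),
    dec_channels = as.integer(dec_channels), qeeg_fc_width = as.integer(qeeg_fc_width),
    lr = lr, weights = weights, grl_lambda = grl_lambda, seed = as.integer(seed)
  )
  cfg$stride_total <- cfg$stem_stride * prod(cfg$block_strides)  # S = 80
  cfg$feature_rate <- cfg$f_b / cfg$stride_total                  # 0.125 Hz
  stopifnot(abs(cfg$feature_rate * 2^3 - 1) < 1e-12)
  class(cfg) <- "breathpd_config"
  cfg
}

## ---- parameter initialization ----

he_init <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)

conv_par <- function(p, name, k, cin, cout) {
  p[[paste0(name, ".W")]] <- he_init(k * cin, cout)
  p[[paste0(name, ".b")]] <- matrix(0, 1L, cout)
  p
}

norm_par <- function(p, name, c) {
  p[[paste0(name, ".g")]] <- matrix(1, 1L, c)
  p[[paste0(name, ".beta")]] <- matrix(0, 1L, c)
  p
}

fc_par <- function(p, name, cin, cout) {
  p[[paste0(name, ".W")]] <- he_init(cin, cout)
  p[[paste0(name, ".b")]] <- matrix(0, 1L, cout)
  p
}

mlp_par <- function(p, name, widths) {
  for (i in seq_len(length(widths) - 1L)) {
    p <- fc_par(p, paste0(name, i), widths[i], widths[i + 1L])
  }
  p
}

#' Initialize network parameters
#'
#' Randomly initializes every trainable array of the network (He-scaled
#' normals for weights, zeros for biases, unit gain for normalization).
#'
#' @param cfg a [model_config()].
#' @param parts character vector of severity heads to create
#'   (`"total"`, `"I"`..`"IV"`).
#' @param init_seed seed for the draws (`NULL` to use the current RNG state).
#' @return named list of parameter matrices.
#' @export
init_params <- function(cfg, parts = "total", init_seed = cfg$seed) {
  if (!is.null(init_seed)) set.seed(init_seed)
  p <- list()
  p <- conv_par(p, "stem", cfg$stem_kernel, 1L, cfg$stem_channels)
  p <- norm_par(p, "stem.n", cfg$stem_channels)
  cin <- cfg$stem_channels
  for (i in 1:8) {
    co <- cfg$block_channels[i]
    mid <- max(co %/% cfg$expansion, 4L)
    nm <- paste0("blk", i)
    p <- conv_par(p, paste0(nm, ".c1"), 1L, cin, mid)
    p <- norm_par(p, paste0(nm, ".n1"), mid)
    p <- conv_par(p, paste0(nm, ".c2"), 3L, mid, mid)
    p <- norm_par(p, paste0(nm, ".n2"), mid)
    p <- conv_par(p, paste0(nm, ".c3"), 1L, mid, co)
    p <- norm_par(p, paste0(nm, ".n3"), co)
    if (cfg$block_strides[i] != 1L || cin != co) {
      p <- conv_par(p, paste0(nm, ".sc"), 1L, cin, co)
      p <- norm_par(p, paste0(nm, ".scn"), co)
    }
    cin <- co
  }
  h <- cfg$hidden
  for (l in 1:3) {
    nm <- paste0("sru", l)
    p[[paste0(nm, ".W")]] <- he_init(h, 3L * h) * 0.5
    p[[paste0(nm, ".bf")]] <- matrix(0, 1L, h)
    p[[paste0(nm, ".br")]] <- matrix(0, 1L, h)
  }
  p <- conv_par(p, "attn.c1", 3L, cfg$d, cfg$attn_width)
  p <- conv_par(p, "attn.c2", 3L, cfg$attn_width, 1L)
  p <- mlp_par(p, "cls", c(cfg$d, cfg$cls_widths, 1L))
  for (part in parts) {
    p <- mlp_par(p, paste0("sev_", part), c(cfg$d, cfg$sev_widths, 1L))
  }
  p <- mlp_par(p, "discPD", c(cfg$d, cfg$disc_width, 1L))
  p <- mlp_par(p, "discCTL", c(cfg$d, cfg$disc_width, 1L))
  # qEEG decoder: block i doubles time; skips concatenate SRU-layer outputs
  dc <- cfg$dec_channels
  dec_in <- c(h, dc[1L] + h, dc[2L] + h)
  for (i in 1:3) {
    nm <- paste0("dec", i)
    p <- conv_par(p, paste0(nm, ".d1"), 3L, dec_in[i], dc[i])
    p <- norm_par(p, paste0(nm, ".n1"), dc[i])
    p <- conv_par(p, paste0(nm, ".d2"), 3L, dc[i], dc[i])
    p <- norm_par(p, paste0(nm, ".n2"), dc[i])
    p <- conv_par(p, paste0(nm, ".d3"), 3L, dc[i], dc[i])
    p <- norm_par(p, paste0(nm, ".n3"), dc[i])
    p <- conv_par(p, paste0(nm, ".sc"), 1L, dec_in[i], dc[i])
  }
  p <- fc_par(p, "qout1", dc[3L], cfg$qeeg_fc_width)
  p <- fc_par(p, "qout2", cfg$qeeg_fc_width, 4L)
  p
}

## ---- forward pass ----

# Parameter-node cache: wraps raw matrices as tape leaves once per pass.
pnode_env <- function(tape, params) {
  env <- new.env(parent = emptyenv())
  env$tape <- tape
  env$params <- params
  env$nodes <- new.env(parent = emptyenv())
  env
}

P <- function(pe, name) {
  nd <- pe$nodes[[name]]
  if (is.null(nd)) {
    val <- pe$params[[name]]
    if (is.null(val)) stop("unknown parameter: ", name)
    nd <- ad_leaf(pe$tape, val)
    assign(name, nd, envir = pe$nodes)
  }
  nd
}

conv_norm_relu <- function(tape, pe, x, name, nname, k, stride = 1L, relu = TRUE) {
  op_conv_norm(tape, x, P(pe, paste0(name, ".W")), P(pe, paste0(name, ".b")),
               P(pe, paste0(nname, ".g")), P(pe, paste0(nname, ".beta")),
               k, stride, relu = relu)
}

bottleneck_block <- function(tape, pe, x, i, cfg) {
  nm <- paste0("blk", i)
  s <- cfg$block_strides[i]
  y <- conv_norm_relu(tape, pe, x, paste0(nm, ".c1"), paste0(nm, ".n1"), 1L)
  y <- conv_norm_relu(tape, pe, y, paste0(nm, ".c2"), paste0(nm, ".n2"), 3L, s)
  y <- conv_norm_relu(tape, pe, y, paste0(nm, ".c3"), paste0(nm, ".n3"), 1L,
                      relu = FALSE)
  sc <- if (!is.null(pe$params[[paste0(nm, ".sc.W")]])) {
    conv_norm_relu(tape, pe, x, paste0(nm, ".sc"), paste0(nm, ".scn"), 1L, s,
                   relu = FALSE)
  } else {
    x
  }
  op_add_relu(tape, y, sc)
}

mlp_forward <- function(tape, pe, x, name, n_layers) {
  for (i in seq_len(n_layers)) {
    x <- op_fc(tape, x, P(pe, paste0(name, i, ".W")), P(pe, paste0(name, i, ".b")))
    if (i < n_layers) x <- op_relu(tape, x)
  }
  x
}

dec_block <- function(tape, pe, x, i) {
  nm <- paste0("dec", i)
  y <- op_zero_upsample(tape, x, 2L)
  y <- conv_norm_relu(tape, pe, y, paste0(nm, ".d1"), paste0(nm, ".n1"), 3L)
  y <- conv_norm_relu(tape, pe, y, paste0(nm, ".d2"), paste0(nm, ".n2"), 3L)
  y <- conv_norm_relu(tape, pe, y, paste0(nm, ".d3"), paste0(nm, ".n3"), 3L,
                      relu = FALSE)
  sc <- op_nearest_upsample(tape, x, 2L)
  sc <- op_conv1d(tape, sc, P(pe, paste0(nm, ".sc.W")), P(pe, paste0(nm, ".sc.b")), 1L)
  op_add_relu(tape, y, sc)
}

# Full differentiable forward pass over one night's preprocessed signal.
# `want` selects which heads are evaluated; returns tape nodes.
network_forward <- function(tape, pe, cfg, signal,
                            want = c("cls"), part = "total",
                            use_skips = TRUE) {
  stopifnot(length(signal) >= 8L * cfg$stride_total)
  x <- ad_leaf(tape, matrix(signal, ncol = 1L))
  y <- conv_norm_relu(tape, pe, x, "stem", "stem.n", cfg$stem_kernel,
                      cfg$stem_stride)
  for (i in 1:8) y <- bottleneck_block(tape, pe, y, i, cfg)
  sru_outs <- vector("list", cfg$sru_layers)
  for (l in seq_len(cfg$sru_layers)) {
    nm <- paste0("sru", l)
    y <- op_sru(tape, y, P(pe, paste0(nm, ".W")), P(pe, paste0(nm, ".bf")),
                P(pe, paste0(nm, ".br")))
    sru_outs[[l]] <- y
  }
  feats <- y
  out <- list(feats = feats)
  if (identical(want, "feats")) return(out)

  a1 <- op_relu(tape, op_conv1d(tape, feats, P(pe, "attn.c1.W"),
                                P(pe, "attn.c1.b"), 3L))
  scores <- op_conv1d(tape, a1, P(pe, "attn.c2.W"), P(pe, "attn.c2.b"), 3L)
  pooled <- op_attention_pool(tape, feats, scores)
  out$g <- pooled
  out$attn <- pooled$attn

  if ("cls" %in% want) out$cls_logit <- mlp_forward(tape, pe, pooled, "cls", 3L)
  if ("sev" %in% want) {
    head <- paste0("sev_", part)
    if (is.null(pe$params[[paste0(head, "1.W")]])) {
      stop("severity head not trained for part: ", part)
    }
    out$sev <- mlp_forward(tape, pe, pooled, head, 4L)
  }
  if ("disc" %in% want) {
    rev <- op_grad_reverse(tape, pooled, cfg$grl_lambda)
    out$disc_pd_logit <- mlp_forward(tape, pe, rev, "discPD", 2L)
    out$disc_ctl_logit <- mlp_forward(tape, pe, rev, "discCTL", 2L)
  }
  if ("qeeg" %in% want) {
    z <- feats
    for (i in 1:3) {
      if (i > 1L) {
        skip <- op_nearest_upsample(tape, sru_outs[[4L - i]], 2L^(i - 1L))
        if (!use_skips) {
          # ablation hook: keep the layer shapes, silence the skip content
          skip <- ad_leaf(tape, skip$val * 0)
        }
        z <- op_concat_cols(tape, z, skip)
      }
      z <- dec_block(tape, pe, z, i)
    }
    z <- op_relu(tape, op_fc(tape, z, P(pe, "qout1.W"), P(pe, "qout1.b")))
    z <- op_fc(tape, z, P(pe, "qout2.W"), P(pe, "qout2.b"))
    out$qeeg <- op_row_softmax(tape, z)
  }
  out
}

## ---- user-facing operations on a trained member ----

#' Encode a night of breathing into the temporal feature sequence
#'
#' Runs the breathing encoder E (stem + eight bottleneck residual blocks +
#' three SRU layers) on a preprocessed night. One feature step covers
#' S / f_b = 8 seconds of signal.
#'
#' @param night a `breathing_night` (preprocessed).
#' @param model a single trained member or a model bundle (first member used).
#' @return matrix (time steps x channels) with attribute `step_seconds`.
#' @export
encode_breathing <- function(night, model) {
  m <- first_member(model)
  tape <- tape_new()
  pe <- pnode_env(tape, m$params)
  f <- network_forward(tape, pe, m$cfg, night$signal, want = "feats")$feats$val
  attr(f, "step_seconds") <- m$cfg$stride_total / m$cfg$f_b
  f
}

#' Attention-pool a feature sequence into the global PD feature
#'
#' The PD encoder G: two stride-1 convolutions score each feature step, a
#' softmax over time normalizes the scores, and the pooled feature is the
#' attention-weighted time average of the features.
#'
#' @param feats feature matrix from [encode_breathing()].
#' @param model trained member or bundle.
#' @return list with `g` (1 x d global feature) and `attention`
#'   (nonnegative weights summing to 1).
#' @export
attend_pool <- function(feats, model) {
  m <- first_member(model)
  tape <- tape_new()
  pe <- pnode_env(tape, m$params)
  fnode <- ad_leaf(tape, unclass(feats))
  a1 <- op_relu(tape, op_conv1d(tape, fnode, P(pe, "attn.c1.W"),
                                P(pe, "attn.c1.b"), 3L))
  scores <- op_conv1d(tape, a1, P(pe, "attn.c2.W"), P(pe, "attn.c2.b"), 3L)
  pooled <- op_attention_pool(tape, fnode, scores)
  list(g = pooled$val, attention = pooled$attn)
}

#' PD classification score from a global feature
#'
#' The PD classifier M: three fully connected layers and a sigmoid. A
#' subject is called PD when the score exceeds 0.5.
#'
#' @param g 1 x d global feature.
#' @param model trained member or bundle.
#' @return score strictly inside (0, 1).
#' @export
classify_pd <- function(g, model) {
  m <- first_member(model)
  tape <- tape_new()
  pe <- pnode_env(tape, m$params)
  z <- mlp_forward(tape, pe, ad_leaf(tape, matrix(g, 1L)), "cls", 3L)
  plogis(as.numeric(z$val))
}

#' MDS-UPDRS severity estimate from a global feature
#'
#' The severity predictor N: four fully connected layers, linear output on
#' the MDS-UPDRS scale of the trained head (`total` or a subpart).
#'
#' @param g 1 x d global feature.
#' @param model trained member or bundle.
#' @param part which trained head to use: `"total"`, `"I"`, `"II"`, `"III"`, `"IV"`.
#' @return unbounded real severity estimate.
#' @export
predict_severity <- function(g, model, part = "total") {
  m <- first_member(model)
  head <- paste0("sev_", part)
  if (is.null(m$params[[paste0(head, "1.W")]])) {
    stop("severity head not trained for part: ", part)
  }
  tape <- tape_new()
  pe <- pnode_env(tape, m$params)
  z <- mlp_forward(tape, pe, ad_leaf(tape, matrix(g, 1L)), head, 4L)
  as.numeric(z$val)
}

#' Domain probability from a global feature
#'
#' Applies the group-specific discriminator (D_PD for PD subjects,
#' D_Control for controls) and returns the probability that the feature
#' came from the belt domain.
#'
#' @param g 1 x d global feature.
#' @param model trained member or bundle.
#' @param group `"PD"` or `"control"`.
#' @return probability in (0, 1).
#' @export
discriminate_domain <- function(g, model, group = c("PD", "control")) {
  group <- match.arg(group)
  m <- first_member(model)
  tape <- tape_new()
  pe <- pnode_env(tape, m$params)
  nm <- if (group == "PD") "discPD" else "discCTL"
  z <- mlp_forward(tape, pe, ad_leaf(tape, matrix(g, 1L)), nm, 2L)
  plogis(as.numeric(z$val))
}

#' Predict the per-second qEEG relative band powers from breathing
#'
#' The qEEG predictor F: three x2 deconvolution blocks with UNet-style skip
#' connections from the SRU layers, two fully connected output layers and a
#' per-second softmax over the four bands.
#'
#' @param night a preprocessed `breathing_night`.
#' @param model trained member or bundle.
#' @param use_skips set `FALSE` to ablate the skip connections.
#' @return matrix (seconds x 4) of predicted relative powers, columns
#'   delta/theta/alpha/beta, each row summing to 1.
#' @export
predict_qeeg <- function(night, model, use_skips = TRUE) {
  m <- first_member(model)
  tape <- tape_new()
  pe <- pnode_env(tape, m$params)
  out <- network_forward(tape, pe, m$cfg, night$signal, want = c("qeeg"),
                         use_skips = use_skips)
  q <- out$qeeg$val
  colnames(q) <- c("delta", "theta", "alpha", "beta")
  q
}

## ---- bundles and serialization ----

first_member <- function(model) {
  if (inherits(model, "breathpd_model")) return(model$members[[1L]])
  if (!is.null(model$params)) return(model)
  stop("not a trained model or bundle")
}

new_bundle <- function(members, cfg, seed) {
  structure(list(members = members, cfg = cfg, seed = seed),
            class = "breathpd_model")
}

#' @export
print.breathpd_model <- function(x, ...) {
  cal <- vapply(x$members, function(m) !is.null(m$calib), logical(1))
  cat(sprintf("<breathpd model: %d member(s), %d calibrated, d = %d>\n",
              length(x$members), sum(cal), x$cfg$d))
  invisible(x)
}

#' Save a trained model bundle to a directory
#'
#' Writes the configuration and calibration scalars as JSON and every
#' parameter array to a single portable little-endian binary file with a
#' JSON shape index, so a reload reproduces predictions bit-identically.
#'
#' @param model a `breathpd_model`.
#' @param dir output directory (created if needed).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    cfg = model$cfg[setdiff(names(model$cfg), "weights")],
    loss_weights = model$cfg$weights,
    seed = model$seed,
    members = lapply(model$members, function(m) {
      list(calib = if (is.null(m$calib)) NULL else as.list(m$calib),
           fold_id = m$fold_id)
    })
  )
  jsonlite::write_json(meta, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  con <- file(file.path(dir, "params.bin"), "wb")
  on.exit(close(con))
  index <- list()
  for (i in seq_along(model$members)) {
    p <- model$members[[i]]$params
    for (nm in names(p)) {
      writeBin(as.numeric(p[[nm]]), con, size = 8L, endian = "little")
      index[[length(index) + 1L]] <- list(member = i, name = nm,
                                          dim = dim(p[[nm]]))
    }
  }
  jsonlite::write_json(index, file.path(dir, "index.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Load a model bundle saved by [save_model()]
#'
#' @param dir directory written by [save_model()].
#' @return a `breathpd_model`.
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"))
  index <- jsonlite::read_json(file.path(dir, "index.json"))
  cfg <- meta$cfg
  for (nm in c("block_channels", "block_strides", "cls_widths", "sev_widths",
               "dec_channels")) cfg[[nm]] <- as.integer(unlist(cfg[[nm]]))
  cfg$weights <- lapply(meta$loss_weights, as.numeric)
  class(cfg) <- "breathpd_config"
  n_members <- length(meta$members)
  members <- vector("list", n_members)
  con <- file(file.path(dir, "params.bin"), "rb")
  on.exit(close(con))
  for (ent in index) {
    d <- as.integer(unlist(ent$dim))
    v <- readBin(con, "numeric", n = prod(d), size = 8L, endian = "little")
    i <- ent$member
    if (is.null(members[[i]])) members[[i]] <- list(params = list(), cfg = cfg)
    members[[i]]$params[[ent$name]] <- matrix(v, d[1L], d[2L])
  }
  for (i in seq_len(n_members)) {
    cal <- meta$members[[i]]$calib
    if (!is.null(cal)) members[[i]]$calib <- c(A = cal$A, B = cal$B)
    members[[i]]$fold_id <- meta$members[[i]]$fold_id
  }
  new_bundle(members, cfg, meta$seed)
}
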