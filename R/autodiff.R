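# Minimal reverse-mode automatic differentiation on a dynamic tape.
# Values are numeric matrices (time x channels, or 1 x k for vectors/scalars).
# A node is an environment holding $val, $grad, $parents and a $bw closure
# returning gradients aligned with $parents. The tape records creation order;
# ad_backward() walks it in reverse, accumulating into leaf $grad slots.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$head <- NULL   # linked list, most recent node first
  tp$n <- 0L
  tp
}

ad_node <- function(tape, val, parents = list(), bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$bw <- bw
  tape$head <- list(nd = nd, prev = tape$head)
  tape$n <- tape$n + 1L
  nd
}

ad_leaf <- function(tape, val) ad_node(tape, val)

# Walk the tape newest-to-oldest (reverse topological order by construction).
ad_backward <- function(tape, root) {
  stopifnot(length(root$val) == 1L)
  root$grad <- 1
  cell <- tape$head
  while (!is.null(cell)) {
    nd <- cell$nd
    if (!is.null(nd$grad) && !is.null(nd$bw)) {
      gs <- nd$bw(nd$grad)
      ps <- nd$parents
      for (j in seq_along(ps)) {
        g <- gs[[j]]
        if (!is.null(g)) {
          p <- ps[[j]]
          p$grad <- if (is.null(p$grad)) g else p$grad + g
        }
      }
    }
    cell <- cell$prev
  }
  invisible(NULL)
}

## ---- elementwise / linear ops ----

op_add <- function(tape, a, b) {
  ad_node(tape, a$val + b$val, list(a, b), function(g) list(g, g))
}

op_scale <- function(tape, a, s) {
  ad_node(tape, a$val * s, list(a), function(g) list(g * s))
}

op_relu <- function(tape, a) {
  m <- a$val > 0
  ad_node(tape, a$val * m, list(a), function(g) list(g * m))
}

# Residual join fused with ReLU: relu(a + b).
op_add_relu <- function(tape, a, b) {
  y <- cpp_addrelu_fw(a$val, b$val)
  ad_node(tape, y, list(a, b), function(g) {
    ga <- cpp_addrelu_bw(y, g)
    list(ga, ga)
  })
}

op_fc <- function(tape, x, W, b) {
  # x: (n x in), W: (in x out), b: (1 x out)
  y <- x$val %*% W$val
  y <- y + rep(as.numeric(b$val), each = nrow(y))
  ad_node(tape, y, list(x, W, b), function(g) {
    list(g %*% t(W$val), crossprod(x$val, g), matrix(colSums(g), 1L))
  })
}

op_concat_cols <- function(tape, a, b) {
  na <- ncol(a$val)
  ad_node(tape, cbind(a$val, b$val), list(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE], g[, -seq_len(na), drop = FALSE])
  })
}

op_grad_reverse <- function(tape, a, lambda = 1) {
  ad_node(tape, a$val, list(a), function(g) list(-lambda * g))
}

## ---- convolution / recurrence (Rcpp kernels) ----

op_conv1d <- function(tape, x, W, b, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  if (k == 1L) {
    # pointwise convolution: no patch matrix needed
    y <- cpp_conv1d_fw(x$val, W$val, as.numeric(b$val), k, stride, pad)
    return(ad_node(tape, y, list(x, W, b), function(g) {
      gr <- cpp_conv1d_bw(x$val, W$val, g, k, stride, pad)
      list(gr$gX, gr$gW, matrix(gr$gb, 1L))
    }))
  }
  xcol <- cpp_im2col(x$val, k, stride, pad)  # cached for the backward pass
  y <- xcol %*% W$val
  y <- y + rep(as.numeric(b$val), each = nrow(y))
  ad_node(tape, y, list(x, W, b), function(g) {
    gxcol <- tcrossprod(g, W$val)
    list(cpp_col2im(gxcol, nrow(x$val), ncol(x$val), k, stride, pad),
         crossprod(xcol, g), matrix(colSums(g), 1L))
  })
}

op_sru <- function(tape, x, W, bf, br) {
  U <- x$val %*% W$val
  fw <- cpp_sru_fw(x$val, U, as.numeric(bf$val), as.numeric(br$val))
  ad_node(tape, fw$H, list(x, W, bf, br), function(g) {
    bw <- cpp_sru_bw(x$val, U, as.numeric(bf$val), as.numeric(br$val), fw$C, g)
    gX <- bw$gX + bw$gU %*% t(W$val)
    list(gX, crossprod(x$val, bw$gU), matrix(bw$gbf, 1L), matrix(bw$gbr, 1L))
  })
}

## ---- normalization ----

# Per-channel normalization over time with learnable affine (instance-norm
# style; statistics come from the input itself so evaluation is
# deterministic), optionally fused with a trailing ReLU.
op_time_norm <- function(tape, x, gamma, beta, eps = 1e-5, relu = FALSE) {
  fw <- cpp_tnorm_fw(x$val, as.numeric(gamma$val), as.numeric(beta$val), eps,
                     relu)
  ad_node(tape, fw$Y, list(x, gamma, beta), function(g) {
    bw <- cpp_tnorm_bw(fw$Xhat, fw$inv, as.numeric(gamma$val), fw$Y, g, relu)
    list(bw$gX, matrix(bw$ggamma, 1L), matrix(bw$gbeta, 1L))
  })
}

# Fused conv1d -> per-channel time normalization -> optional ReLU; the
# patch matrix and normalized activations are stashed for the backward pass.
op_conv_norm <- function(tape, x, W, b, gamma, beta, k, stride = 1L,
                         pad = (k - 1L) %/% 2L, eps = 1e-5, relu = TRUE) {
  fw <- cpp_cnr_fw(x$val, W$val, as.numeric(b$val), as.numeric(gamma$val),
                   as.numeric(beta$val), k, stride, pad, eps, relu)
  ad_node(tape, fw$Y, list(x, W, b, gamma, beta), function(g) {
    bw <- cpp_cnr_bw(x$val, as.numeric(b$val), fw$mu, fw$inv, W$val,
                     as.numeric(gamma$val), fw$Y, g, nrow(x$val), ncol(x$val),
                     k, stride, pad, relu)
    list(bw$gX, bw$gW, matrix(bw$gb, 1L), matrix(bw$ggamma, 1L),
         matrix(bw$gbeta, 1L))
  })
}

## ---- resampling along time ----

op_zero_upsample <- function(tape, x, factor = 2L) {
  tn <- nrow(x$val)
  idx <- seq.int(1L, factor * tn, by = factor)
  y <- matrix(0, factor * tn, ncol(x$val))
  y[idx, ] <- x$val
  ad_node(tape, y, list(x), function(g) list(g[idx, , drop = FALSE]))
}

op_nearest_upsample <- function(tape, x, factor = 2L) {
  tn <- nrow(x$val)
  rep_idx <- rep(seq_len(tn), each = factor)
  ad_node(tape, x$val[rep_idx, , drop = FALSE], list(x), function(g) {
    list(rowsum(g, group = rep_idx, reorder = TRUE))
  })
}

## ---- attention pooling / softmax ----

# scores: (T x 1) unnormalized; feats: (T x d). Returns the pooled (1 x d)
# global feature; the softmax weights are stashed on the node as $attn.
op_attention_pool <- function(tape, feats, scores) {
  s <- as.numeric(scores$val)
  a <- exp(s - max(s))
  a <- a / sum(a)
  g <- matrix(a, 1L) %*% feats$val
  nd <- ad_node(tape, g, list(feats, scores), function(gg) {
    gfeats <- a %o% as.numeric(gg)
    ga <- as.numeric(feats$val %*% t(gg))
    gscore <- matrix(a * (ga - sum(a * ga)), ncol = 1L)
    list(gfeats, gscore)
  })
  nd$attn <- a
  nd
}

op_row_softmax <- function(tape, x) {
  n <- nrow(x$val)
  rmax <- x$val[cbind(seq_len(n), max.col(x$val, ties.method = "first"))]
  e <- exp(x$val - rmax)
  p <- e / rowSums(e)
  ad_node(tape, p, list(x), function(g) {
    s <- rowSums(g * p)
    list(p * (g - s))
  })
}

## ---- scalar losses ----

# Numerically stable binary cross-entropy on a logit node (1 x 1).
loss_bce_logit <- function(tape, logit, y, weight = 1) {
  z <- as.numeric(logit$val)
  l <- weight * (max(z, 0) - z * y + log1p(exp(-abs(z))))
  ad_node(tape, l, list(logit), function(g) {
    list(matrix(g * weight * (1 / (1 + exp(-z)) - y), 1L))
  })
}

# Mean squared error between a node and a fixed target (same shape).
loss_mse <- function(tape, pred, target, weight = 1, mask = NULL) {
  d <- pred$val - target
  if (!is.null(mask)) d <- d * mask
  n <- if (is.null(mask)) length(d) else max(sum(mask), 1)
  l <- weight * sum(d * d) / n
  ad_node(tape, l, list(pred), function(g) list(g * weight * 2 * d / n))
}

# Population variance of a set of scalar prediction nodes (the transductive
# consistency penalty); zero iff all predictions agree.
loss_variance <- function(tape, preds, weight = 1) {
  v <- vapply(preds, function(p) as.numeric(p$val), numeric(1))
  n <- length(v)
  m <- mean(v)
  l <- weight * mean((v - m)^2)
  ad_node(tape, l, preds, function(g) {
    lapply(seq_len(n), function(i) matrix(g * weight * 2 * (v[i] - m) / n, 1L))
  })
}

op_sum_scalars <- function(tape, nodes, weights = rep(1, length(nodes))) {
  tot <- sum(vapply(seq_along(nodes), function(i) {
    weights[i] * as.numeric(nodes[[i]]$val)
  }, numeric(1)))
  ad_node(tape, tot, nodes, function(g) {
    lapply(weights, function(w) g * w)
  })
}
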