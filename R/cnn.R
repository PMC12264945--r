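# Small native convolutional network for map-to-map contact prediction.
# The processed attention stack is treated as an S x S image with L*H
# channels; a stack of 3x3 dilated convolutions emits a per-pixel contact
# probability. Convolutions are computed as im2col + matrix products so the
# heavy lifting stays in BLAS; training is Adam on a class-weighted binary
# cross-entropy restricted to eligible (off-band, in-length) pixels, and the
# output is symmetrized as (P + t(P)) / 2 so predicted maps are symmetric by
# construction.

# source index vectors for a 3x3 kernel at dilation d on an S x S grid:
# list of 9 integer vectors (length S^2), NA marking out-of-bounds taps
conv_offsets <- function(S, d) {
  rc <- expand.grid(r = seq_len(S), c = seq_len(S))
  offs <- expand.grid(dr = c(-d, 0L, d), dc = c(-d, 0L, d))
  lapply(seq_len(9), function(o) {
    r <- rc$r + offs$dr[o]; c <- rc$c + offs$dc[o]
    ok <- r >= 1 & r <= S & c >= 1 & c <= S
    ifelse(ok, (c - 1L) * S + r, NA_integer_)
  })
}

im2col <- function(Xmat, src) {
  # Xmat: S^2 x Cin; returns S^2 x 9*Cin
  Cin <- ncol(Xmat)
  M <- matrix(0, nrow(Xmat), 9L * Cin)
  for (o in seq_len(9)) {
    s <- src[[o]]; ok <- !is.na(s)
    M[ok, ((o - 1L) * Cin + 1L):(o * Cin)] <- Xmat[s[ok], , drop = FALSE]
  }
  M
}

col2im <- function(dM, src, Cin, S2) {
  dX <- matrix(0, S2, Cin)
  for (o in seq_len(9)) {
    s <- src[[o]]; ok <- !is.na(s)
    blk <- dM[ok, ((o - 1L) * Cin + 1L):(o * Cin), drop = FALSE]
    # accumulate: several offsets may write the same source pixel
    dX[s[ok], ] <- dX[s[ok], ] + blk
  }
  dX
}

cnn_init <- function(C_in, channels, seed) {
  chans <- c(C_in, channels)
  withr::with_seed(seed, lapply(seq_along(channels), function(l) {
    fan_in <- 9L * chans[l]
    list(W = matrix(stats::rnorm(fan_in * chans[l + 1L], sd = sqrt(2 / fan_in)),
                    fan_in, chans[l + 1L]),
         b = rep(0, chans[l + 1L]))
  }))
}

cnn_forward <- function(Xmat, params, srcs, S2) {
  acts <- vector("list", length(params))
  A <- Xmat
  for (l in seq_along(params)) {
    M <- im2col(A, srcs[[l]])
    Z <- sweep(M %*% params[[l]]$W, 2L, params[[l]]$b, "+")
    A <- if (l < length(params)) pmax(Z, 0) else Z  # ReLU; last layer linear
    acts[[l]] <- list(M = M, Z = Z)
  }
  list(logits = A[, 1L], acts = acts)
}

# returns gradient list and the (symmetrized) probabilities
cnn_backward <- function(Xmat, params, srcs, S2, fwd, target, wmask) {
  L <- length(params)
  logitm <- matrix(fwd$logits, sqrt(S2), sqrt(S2))
  p_sym <- 1 / (1 + exp(-(logitm + t(logitm)) / 2))
  # d(loss)/d(sym logit); symmetrization backprop sends (G + t(G)) / 2 to logits
  G <- wmask * (p_sym - target)
  dZ <- as.numeric((G + t(G)) / 2)
  grads <- vector("list", L)
  dA <- matrix(dZ, S2, 1L)
  for (l in rev(seq_len(L))) {
    Zl <- fwd$acts[[l]]$Z
    dZl <- if (l < L) dA * (Zl > 0) else dA
    grads[[l]] <- list(W = crossprod(fwd$acts[[l]]$M, dZl), b = colSums(dZl))
    if (l > 1L) {
      dM <- dZl %*% t(params[[l]]$W)
      dA <- col2im(dM, srcs[[l]], ncol(fwd$acts[[l - 1L]]$Z), S2)
    }
  }
  list(grads = grads, p_sym = p_sym)
}

stack_to_image <- function(stack, S) {
  C <- stack$L * stack$H
  Xmat <- matrix(0, S * S, C)
  col <- 0L
  idx <- seq_len(stack$n)
  for (l in seq_len(stack$L)) for (h in seq_len(stack$H)) {
    col <- col + 1L
    img <- matrix(0, S, S)
    img[idx, idx] <- stack$weights[l, h, , ]
    Xmat[, col] <- as.numeric(img)
  }
  Xmat
}

#' Train the convolutional map-to-map predictor
#'
#' Takes whole processed attention stacks as multi-channel images and learns
#' a per-pixel contact probability map. All molecules are zero-padded to a
#' common size; the loss is binary cross-entropy over eligible pixels only
#' (off the exclusion band and inside the true length), with the contact
#' class up-weighted by the background/contact ratio so the network does not
#' collapse to the majority class. The output map is symmetrized inside the
#' network, so predictions are symmetric by construction.
#'
#' @param stacks List of processed [attention_stack()]s (equal L, H).
#' @param maps Named list of [contact_map()]s aligned by molecule id.
#' @param spec A [predictor_spec()] with \code{kind = "cnn"}. Recognized
#'   hyperparameters: \code{channels} (default \code{c(64, 64, 32)} hidden
#'   widths before the 1-channel output), \code{dilations} (default
#'   \code{c(1, 2, 4, 1)}), \code{epochs} (default 30), \code{lr} (default
#'   1e-3), \code{max_len} (default: longest molecule), \code{window}
#'   (default: maps' window).
#' @return An \code{attn_predictor} usable with [predict_contact_map()].
#' @export
train_cnn <- function(stacks, maps, spec) {
  stopifnot(inherits(spec, "predictor_spec"), spec$kind == "cnn")
  ids <- vapply(stacks, `[[`, character(1), "molecule_id")
  if (!is.null(names(maps))) maps <- maps[ids]
  L <- stacks[[1]]$L; H <- stacks[[1]]$H; C <- L * H
  for (st in stacks) {
    if (!st$processed) stop_attn("cnn training requires processed stacks", "attn_state_error")
    if (st$L * st$H != C) stop_attn("stacks disagree on channel count", "attn_shape_error")
  }
  hy <- spec$hyper
  hidden <- hy$channels %||% c(64L, 64L, 32L)
  channels <- c(hidden, 1L)
  dil <- hy$dilations %||% c(1L, 2L, 4L, 1L)
  if (length(dil) != length(channels))
    stop_attn("need one dilation per conv layer", "attn_config_error")
  epochs <- hy$epochs %||% 30L
  lr <- hy$lr %||% 1e-3
  S <- as.integer(hy$max_len %||% max(vapply(stacks, `[[`, integer(1), "n")))
  window <- as.integer(hy$window %||% maps[[1]]$window)
  if (any(vapply(stacks, `[[`, integer(1), "n") > S))
    stop_attn("a molecule exceeds max_len", "attn_shape_error")
  srcs <- lapply(dil, function(d) conv_offsets(S, d))
  S2 <- S * S

  inputs <- lapply(stacks, stack_to_image, S = S)
  targets <- lapply(seq_along(stacks), function(k) {
    tg <- matrix(0, S, S)
    idx <- seq_len(stacks[[k]]$n)
    tg[idx, idx] <- maps[[k]]$matrix
    tg
  })
  wmasks <- lapply(seq_along(stacks), function(k) {
    n <- stacks[[k]]$n
    m <- matrix(FALSE, S, S)
    m[seq_len(n), seq_len(n)] <- eligible_mask(n, window)
    pos <- sum(targets[[k]][m]); neg <- sum(m) - pos
    w <- matrix(0, S, S)
    w[m] <- ifelse(targets[[k]][m] == 1, ifelse(pos > 0, neg / pos, 1), 1)
    w / max(sum(w), 1)  # normalize so per-molecule gradients are comparable
  })

  params <- cnn_init(C, channels, spec$seed)
  adam <- lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                          mb = p$b * 0, vb = p$b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0L
  order_seed <- derive_seed(spec$seed, "cnn_order")
  for (ep in seq_len(epochs)) {
    ord <- withr::with_seed(order_seed + ep, sample(seq_along(stacks)))
    for (k in ord) {
      fwd <- cnn_forward(inputs[[k]], params, srcs, S2)
      bwd <- cnn_backward(inputs[[k]], params, srcs, S2, fwd, targets[[k]], wmasks[[k]])
      t <- t + 1L
      for (l in seq_along(params)) {
        g <- bwd$grads[[l]]
        adam[[l]]$mW <- b1 * adam[[l]]$mW + (1 - b1) * g$W
        adam[[l]]$vW <- b2 * adam[[l]]$vW + (1 - b2) * g$W^2
        adam[[l]]$mb <- b1 * adam[[l]]$mb + (1 - b1) * g$b
        adam[[l]]$vb <- b2 * adam[[l]]$vb + (1 - b2) * g$b^2
        mhW <- adam[[l]]$mW / (1 - b1^t); vhW <- adam[[l]]$vW / (1 - b2^t)
        mhb <- adam[[l]]$mb / (1 - b1^t); vhb <- adam[[l]]$vb / (1 - b2^t)
        params[[l]]$W <- params[[l]]$W - lr * mhW / (sqrt(vhW) + eps)
        params[[l]]$b <- params[[l]]$b - lr * mhb / (sqrt(vhb) + eps)
      }
    }
  }
  structure(list(
    spec = spec,
    fit = list(params = params, dilations = dil, channels = channels,
               max_len = S, C = C, L = L, H = H, window = window),
    feature_names = feature_names_for(L, H),
    provenance = list(n_samples = length(stacks), balanced = NA,
                      window = window, dataset_hash = rlang::hash(ids),
                      hyper = spec$hyper)
  ), class = "attn_predictor")
}

cnn_predict_map <- function(model, stack, window) {
  fit <- model$fit
  if (stack$L * stack$H != fit$C)
    stop_attn("stack channel count does not match the cnn", "attn_feature_error")
  if (stack$n > fit$max_len)
    stop_attn("molecule longer than the cnn's maximum length", "attn_shape_error")
  S <- fit$max_len
  srcs <- lapply(fit$dilations, function(d) conv_offsets(S, d))
  fwd <- cnn_forward(stack_to_image(stack, S), fit$params, srcs, S * S)
  logitm <- matrix(fwd$logits, S, S)
  p <- 1 / (1 + exp(-(logitm + t(logitm)) / 2))
  idx <- seq_len(stack$n)
  p[idx, idx, drop = FALSE]
}
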