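# Minimal neural-network toolkit: dense and 1-D convolution layers with
# leaky-rectifier activations, manual backpropagation, and Adam. Sized for
# the small encoders used by the artificial fish; all heavy lifting is BLAS
# matrix multiplication. Inputs are row-major batches; retina inputs use the
# interleaved layout of [obs_to_vec()] (ray-major, channels fastest).

layer_dense <- function(n_in, n_out) {
  list(type = "dense",
       W = matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = rep(0, n_out), n_in = n_in, n_out = n_out)
}

layer_lrelu <- function(alpha = 0.01) list(type = "lrelu", alpha = alpha)

layer_conv1d <- function(L_in, C_in, C_out, k, stride) {
  L_out <- (L_in - k) %/% stride + 1L
  stopifnot(L_out >= 1)
  kc <- k * C_in
  # gather index: blocks of k*C_in input columns per output position
  idx <- integer(L_out * kc)
  m <- 1L
  for (p in seq_len(L_out)) {
    start <- (p - 1L) * stride
    for (kk in seq_len(k)) {
      base <- (start + kk - 1L) * C_in
      idx[m:(m + C_in - 1L)] <- base + seq_len(C_in)
      m <- m + C_in
    }
  }
  # scatter groups: for each input column, which gathered columns map to it
  groups <- split(seq_along(idx), idx)
  list(type = "conv1d",
       W = matrix(rnorm(kc * C_out, sd = sqrt(2 / kc)), kc, C_out),
       b = rep(0, C_out),
       L_in = L_in, C_in = C_in, C_out = C_out, k = k, stride = stride,
       L_out = L_out, idx = idx, groups = groups)
}

fwd_layer <- function(ly, X) {
  switch(ly$type,
    dense = {
      out <- X %*% ly$W
      out <- out + rep(ly$b, each = nrow(out))
      list(out = out, cache = X)
    },
    lrelu = {
      mask <- X > 0
      list(out = X * (ly$alpha + (1 - ly$alpha) * mask), cache = mask)
    },
    conv1d = {
      B <- nrow(X)
      kc <- ly$k * ly$C_in
      if (B == 1L) {
        Xmat <- matrix(X[, ly$idx], ly$L_out, kc, byrow = TRUE)
        Y <- Xmat %*% ly$W + rep(ly$b, each = ly$L_out)
        out <- matrix(as.vector(t(Y)), 1L)
      } else {
        Xc <- X[, ly$idx, drop = FALSE]
        Xmat <- matrix(aperm(array(Xc, c(B, kc, ly$L_out)), c(1, 3, 2)),
                       B * ly$L_out, kc)
        Y <- Xmat %*% ly$W
        Y <- Y + rep(ly$b, each = nrow(Y))
        out <- matrix(aperm(array(Y, c(B, ly$L_out, ly$C_out)), c(1, 3, 2)),
                      B, ly$L_out * ly$C_out)
      }
      list(out = out, cache = Xmat)
    },
    stop("unknown layer type"))
}

bwd_layer <- function(ly, cache, dOut) {
  switch(ly$type,
    dense = {
      list(dX = dOut %*% t(ly$W),
           grads = list(W = crossprod(cache, dOut), b = colSums(dOut)))
    },
    lrelu = {
      list(dX = dOut * (ly$alpha + (1 - ly$alpha) * cache), grads = NULL)
    },
    conv1d = {
      B <- nrow(dOut)
      kc <- ly$k * ly$C_in
      dY <- matrix(aperm(array(dOut, c(B, ly$C_out, ly$L_out)), c(1, 3, 2)),
                   B * ly$L_out, ly$C_out)
      dW <- crossprod(cache, dY)
      db <- colSums(dY)
      dXmat <- dY %*% t(ly$W)
      dXc <- matrix(aperm(array(dXmat, c(B, ly$L_out, kc)), c(1, 3, 2)),
                    B, ly$L_out * kc)
      dX <- matrix(0, B, ly$L_in * ly$C_in)
      for (cname in names(ly$groups)) {
        cols <- ly$groups[[cname]]
        c0 <- as.integer(cname)
        dX[, c0] <- if (length(cols) == 1L) dXc[, cols]
                    else rowSums(dXc[, cols, drop = FALSE])
      }
      list(dX = dX, grads = list(W = dW, b = db))
    },
    stop("unknown layer type"))
}

# A network is a mutable environment holding a layer list plus Adam state.
net_new <- function(layers, frozen = FALSE) {
  e <- new.env(parent = emptyenv())
  e$layers <- layers
  e$frozen <- frozen
  e$adam <- NULL
  e$t <- 0L
  class(e) <- "curiofish_net"
  e
}

net_forward <- function(net, X, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(net$layers)) else NULL
  out <- X
  for (i in seq_along(net$layers)) {
    r <- fwd_layer(net$layers[[i]], out)
    out <- r$out
    if (keep_cache) caches[[i]] <- r$cache
  }
  list(out = out, caches = caches)
}

net_backward <- function(net, caches, dOut) {
  n <- length(net$layers)
  grads <- vector("list", n)
  d <- dOut
  for (i in rev(seq_len(n))) {
    r <- bwd_layer(net$layers[[i]], caches[[i]], d)
    d <- r$dX
    grads[i] <- list(r$grads)   # keep NULL placeholders for no-param layers
  }
  list(grads = grads, dX = d)
}

grads_zero_like <- function(net) {
  lapply(net$layers, function(ly)
    if (!is.null(ly$W)) list(W = ly$W * 0, b = ly$b * 0) else NULL)
}

grads_add <- function(g1, g2) {
  for (i in seq_along(g1)) {
    if (is.null(g2[[i]])) next
    if (is.null(g1[[i]])) { g1[[i]] <- g2[[i]]; next }
    g1[[i]]$W <- g1[[i]]$W + g2[[i]]$W
    g1[[i]]$b <- g1[[i]]$b + g2[[i]]$b
  }
  g1
}

# in-place Adam step; errors on frozen networks (contract: frozen components
# are never updated)
net_apply_grads <- function(net, grads, lr, beta1 = 0.9, beta2 = 0.999,
                            eps = 1e-8) {
  if (isTRUE(net$frozen))
    stop("contract violation: attempt to update a frozen network")
  if (lr == 0) return(invisible(net))
  if (is.null(net$adam)) {
    net$adam <- lapply(net$layers, function(ly)
      if (!is.null(ly$W)) list(mW = ly$W * 0, vW = ly$W * 0,
                               mb = ly$b * 0, vb = ly$b * 0) else NULL)
  }
  net$t <- net$t + 1L
  bc1 <- 1 - beta1^net$t
  bc2 <- 1 - beta2^net$t
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    st <- net$adam[[i]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$W
    st$vW <- beta2 * st$vW + (1 - beta2) * g$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$b
    st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
    net$adam[[i]] <- st
    net$layers[[i]]$W <- net$layers[[i]]$W -
      lr * (st$mW / bc1) / (sqrt(st$vW / bc2) + eps)
    net$layers[[i]]$b <- net$layers[[i]]$b -
      lr * (st$mb / bc1) / (sqrt(st$vb / bc2) + eps)
  }
  invisible(net)
}

net_clone <- function(net) {
  e <- net_new(net$layers, frozen = net$frozen)
  e$adam <- net$adam
  e$t <- net$t
  e
}

net_params <- function(net) lapply(net$layers, function(ly)
  if (!is.null(ly$W)) list(W = ly$W, b = ly$b) else NULL)

#' Build the shared visual encoder
#'
#' Two 1-D convolution stages with leaky-rectifier activations over the ray
#' retina, followed by two fully connected stages of 128 units, producing a
#' 128-dimensional representation. The same architecture is used by the
#' policy trunk and by every intrinsic-motivation algorithm.
#'
#' @param n_rays retina length (input has `3 * n_rays` features)
#' @param c1,c2 channels of the two convolution stages
#' @param frozen if `TRUE` the encoder is frozen at initialization
#' @return a network object with 128-dimensional output
#' @export
build_encoder <- function(n_rays, c1 = 8, c2 = 16, frozen = FALSE) {
  k1 <- min(5L, n_rays)
  conv1 <- layer_conv1d(n_rays, 3L, c1, k1, 2L)
  k2 <- min(3L, conv1$L_out)
  conv2 <- layer_conv1d(conv1$L_out, c1, c2, k2, 2L)
  flat <- conv2$L_out * c2
  net <- net_new(list(conv1, layer_lrelu(), conv2, layer_lrelu(),
                      layer_dense(flat, 128), layer_lrelu(),
                      layer_dense(128, 128)),
                 frozen = frozen)
  net$n_rays <- n_rays
  net
}

softmax_rows <- function(Z) {
  mx <- Z[, 1]
  for (j in 2:ncol(Z)) mx <- pmax(mx, Z[, j])
  E <- exp(Z - mx)
  E / rowSums(E)
}

sample_categorical_rows <- function(P) {
  # one draw per row of a row-stochastic matrix (2 or 3 columns)
  u <- runif(nrow(P))
  if (ncol(P) == 2L) {
    1L + (u > P[, 1])
  } else {
    c1 <- P[, 1]; c2 <- c1 + P[, 2]
    1L + (u > c1) + (u > c2)
  }
}
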