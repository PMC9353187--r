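# Layer primitives with hand-written forward/backward passes, in plain R
# matrix algebra. Conventions: batches are the first array dimension;
# dense inputs are (B, D) matrices; 1-D convolution inputs are
# (B, L, C) arrays (length x channels). Every *_fw returns a cache that
# its *_bw consumes; analytic gradients are verified against central
# differences in the test suite.

## ---- dense -----------------------------------------------------------

dense_fw <- function(x, W, b) {
  out <- x %*% W
  out <- sweep(out, 2, b, `+`)
  list(out = out, cache = list(x = x))
}

dense_bw <- function(dout, cache, W) {
  list(dx = dout %*% t(W),
       dW = crossprod(cache$x, dout),
       db = colSums(dout))
}

## ---- relu ------------------------------------------------------------

relu_fw <- function(x) {
  out <- x
  out[out < 0] <- 0
  list(out = out, cache = list(pos = x > 0))
}

relu_bw <- function(dout, cache) dout * cache$pos

## ---- batch normalization --------------------------------------------

# Operates on a 2-D matrix (N, C), normalizing each column. For
# convolutional maps, callers fold (B, L) into N so statistics are per
# channel. Training mode uses batch statistics (biased variance) and
# updates the running estimates; inference mode uses the running ones.
bn_fw <- function(x, gamma, beta, running, training,
                  momentum = 0.9, eps = 1e-5) {
  if (training) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu, `-`)
    v <- colMeans(xc^2)
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * v
  } else {
    mu <- running$mean
    v <- running$var
    xc <- sweep(x, 2, mu, `-`)
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv_sd, `*`)
  out <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(out = out, running = running,
       cache = list(xhat = xhat, xc = xc, inv_sd = inv_sd,
                    training = training))
}

bn_bw <- function(dout, cache, gamma) {
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, gamma, `*`)
  if (cache$training) {
    n <- nrow(dout)
    # dx = inv_sd/N * (N*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dx <- sweep(dxhat * n, 2, s1, `-`) -
      sweep(cache$xhat, 2, s2, `*`)
    dx <- sweep(dx, 2, cache$inv_sd / n, `*`)
  } else {
    dx <- sweep(dxhat, 2, cache$inv_sd, `*`)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- 1-D convolution (valid, stride 1) -------------------------------

# x: (B, L, Cin); W: (fl * Cin, F) with rows ordered offset-major
# (offset k = 1..fl, channel c = 1..Cin -> row (k-1)*Cin + c); b: length F.
conv1d_fw <- function(x, W, b, fl) {
  d <- dim(x); B <- d[1]; L <- d[2]; Cin <- d[3]
  Lout <- L - fl + 1L
  assert_that(Lout >= 1, "input shorter than the convolution filter")
  Xc <- matrix(0, B * Lout, fl * Cin)
  for (k in seq_len(fl)) {
    slab <- x[, k:(k + Lout - 1L), , drop = FALSE]
    dim(slab) <- c(B * Lout, Cin)
    Xc[, ((k - 1L) * Cin + 1L):(k * Cin)] <- slab
  }
  Z <- sweep(Xc %*% W, 2, b, `+`)
  out <- array(Z, dim = c(B, Lout, ncol(W)))
  list(out = out, cache = list(Xc = Xc, dims = c(B, L, Cin), fl = fl))
}

conv1d_bw <- function(dout, cache, W) {
  dims <- cache$dims; B <- dims[1]; L <- dims[2]; Cin <- dims[3]
  fl <- cache$fl
  Fno <- dim(dout)[3]; Lout <- dim(dout)[2]
  dZ <- dout
  dim(dZ) <- c(B * Lout, Fno)
  dW <- crossprod(cache$Xc, dZ)
  db <- colSums(dZ)
  dXc <- dZ %*% t(W)
  dx <- array(0, dim = dims)
  for (k in seq_len(fl)) {
    slab <- dXc[, ((k - 1L) * Cin + 1L):(k * Cin)]
    dim(slab) <- c(B, Lout, Cin)
    dx[, k:(k + Lout - 1L), ] <- dx[, k:(k + Lout - 1L), , drop = FALSE] +
      slab
  }
  list(dx = dx, dW = dW, db = db)
}

## ---- non-overlapping max pooling -------------------------------------

maxpool_fw <- function(x, p) {
  d <- dim(x); B <- d[1]; L <- d[2]; C <- d[3]
  Lp <- L %/% p
  assert_that(Lp >= 1, "input shorter than the pooling window")
  xr <- x[, seq_len(Lp * p), , drop = FALSE]
  dim(xr) <- c(B, p, Lp, C)
  out <- xr[, 1, , , drop = FALSE]
  dim(out) <- c(B, Lp, C)
  amax <- array(1L, dim = c(B, Lp, C))
  if (p > 1) for (j in 2:p) {
    slab <- xr[, j, , , drop = FALSE]
    dim(slab) <- c(B, Lp, C)
    upd <- slab > out
    out[upd] <- slab[upd]
    amax[upd] <- j
  }
  list(out = out, cache = list(amax = amax, dims = d, p = p, Lp = Lp))
}

maxpool_bw <- function(dout, cache) {
  d <- cache$dims; B <- d[1]; C <- d[3]
  p <- cache$p; Lp <- cache$Lp
  dxr <- array(0, dim = c(B, p, Lp, C))
  for (j in seq_len(p)) {
    sel <- cache$amax == j
    slab <- array(0, dim = c(B, Lp, C))
    slab[sel] <- dout[sel]
    dxr[, j, , ] <- slab
  }
  dx <- array(0, dim = d)
  dim(dxr) <- c(B, p * Lp, C)
  dx[, seq_len(p * Lp), ] <- dxr
  dx
}

## ---- GRU (single direction) ------------------------------------------

# Parameters: W (D, 3H), U (H, 3H), b (3H), gate blocks ordered [r | z | n].
# Update: r = sig(xW_r + hU_r + b_r); z = sig(xW_z + hU_z + b_z);
# n = tanh(xW_n + b_n + r * (h U_n)); h' = (1 - z) * n + z * h.
gru_fw <- function(xs, W, U, b) {
  H <- ncol(U)
  stopifnot(H %% 3 == 0)
  H <- H %/% 3
  B <- nrow(xs[[1]])
  h <- matrix(0, B, H)
  steps <- vector("list", length(xs))
  ir <- seq_len(H); iz <- H + ir; inn <- 2L * H + ir
  for (t in seq_along(xs)) {
    gx <- sweep(xs[[t]] %*% W, 2, b, `+`)
    gh <- h %*% U[, c(ir, iz), drop = FALSE]
    r <- sigmoid(gx[, ir, drop = FALSE] + gh[, ir, drop = FALSE])
    z <- sigmoid(gx[, iz, drop = FALSE] + gh[, H + ir, drop = FALSE])
    hn <- h %*% U[, inn, drop = FALSE]
    n <- tanh(gx[, inn, drop = FALSE] + r * hn)
    h_new <- (1 - z) * n + z * h
    steps[[t]] <- list(x = xs[[t]], h_prev = h, r = r, z = z, n = n,
                       hn = hn)
    h <- h_new
  }
  list(out = h, cache = list(steps = steps, H = H))
}

gru_bw <- function(dh_final, cache, W, U) {
  H <- cache$H
  ir <- seq_len(H); iz <- H + ir; inn <- 2L * H + ir
  dW <- matrix(0, nrow(W), ncol(W))
  dU <- matrix(0, nrow(U), ncol(U))
  db <- numeric(3L * H)
  dxs <- vector("list", length(cache$steps))
  dh <- dh_final
  for (t in rev(seq_along(cache$steps))) {
    st <- cache$steps[[t]]
    dz <- dh * (st$h_prev - st$n)
    dn <- dh * (1 - st$z)
    dh_prev <- dh * st$z
    dn_pre <- dn * (1 - st$n^2)
    dr <- dn_pre * st$hn
    dhn <- dn_pre * st$r
    dh_prev <- dh_prev + dhn %*% t(U[, inn, drop = FALSE])
    dU[, inn] <- dU[, inn] + crossprod(st$h_prev, dhn)
    dr_pre <- dr * st$r * (1 - st$r)
    dz_pre <- dz * st$z * (1 - st$z)
    dg <- cbind(dr_pre, dz_pre, dn_pre)
    dW <- dW + crossprod(st$x, dg)
    db <- db + colSums(dg)
    dxs[[t]] <- dg %*% t(W)
    dgh <- cbind(dr_pre, dz_pre)
    dU[, c(ir, iz)] <- dU[, c(ir, iz)] + crossprod(st$h_prev, dgh)
    dh_prev <- dh_prev + dgh %*% t(U[, c(ir, iz), drop = FALSE])
    dh <- dh_prev
  }
  list(dxs = dxs, dW = dW, dU = dU, db = db)
}

## ---- two-class softmax ------------------------------------------------

# Logits (B, 2); column 2 is the methylated class. Returns probabilities
# normalized to sum to 1 per row.
softmax2_fw <- function(z) {
  zs <- z - apply(z, 1, max)
  e <- exp(zs)
  p <- e / rowSums(e)
  list(p = p, cache = list(p2 = p[, 2]))
}

# Gradient of the methylated-class probability: given dL/dp2, return
# dL/dlogits using p2 = sigmoid(z2 - z1).
softmax2_bw <- function(dp2, cache) {
  g <- dp2 * cache$p2 * (1 - cache$p2)
  cbind(-g, g)
}

## ---- parameter initialization ----------------------------------------

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}
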