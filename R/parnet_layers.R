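# Layer primitives for the shallow parallel CNN.
#
# Activations are dense arrays with dimensions (H, W, C, N): height, width,
# channels, batch. Convolutions are computed by tap-wise im2col: the padded
# input is gathered into a (kh*kw*C) x (outH*outW*N) matrix so that the
# convolution itself is a single BLAS matrix multiply; gradients reverse the
# gather. Padding is "same" with ceil(H / stride) output size.

conv_out_len <- function(n, stride) as.integer(ceiling(n / stride))

conv_pad <- function(n, k, stride) {
  out <- conv_out_len(n, stride)
  total <- max((out - 1L) * stride + k - n, 0L)
  c(before = total %/% 2L, total = total)
}

# parameter container for a conv layer; Wm is (cout) x (kh*kw*cin) with
# columns ordered tap-major (tap = (ki-1)*kw + kj), channel-fast within tap
conv_init <- function(kh, kw, cin, cout, stride = 1L) {
  fan_in <- kh * kw * cin
  list(k = c(kh, kw), cin = cin, cout = cout, stride = as.integer(stride),
       Wm = matrix(stats::rnorm(cout * fan_in, 0, sqrt(2 / fan_in)),
                   cout, fan_in),
       b = numeric(cout))
}

# memoised flat gather indices for im2col, keyed by padded shape x kernel;
# one cached integer vector per distinct layer geometry
.conv_idx_cache <- new.env(parent = emptyenv())

conv_gather_idx <- function(hp, wp, cc, nn, kh, kw, stride, out_h, out_w) {
  key <- paste(hp, wp, cc, nn, kh, kw, stride, sep = "_")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  plane <- hp * wp
  vol <- plane * cc
  # row offsets: tap-major (ki outer, kj inner per kernel row order), channel
  # fastest within a tap -- matches the Wm column layout
  taps <- expand.grid(c = seq_len(cc) - 1L, kj = seq_len(kw) - 1L,
                      ki = seq_len(kh) - 1L)
  rowoff <- taps$ki + taps$kj * hp + taps$c * plane
  # column offsets: output row fastest, then output col, then batch index
  cols <- expand.grid(oh = seq_len(out_h) - 1L, ow = seq_len(out_w) - 1L,
                      n = seq_len(nn) - 1L)
  coloff <- cols$oh * stride + cols$ow * stride * hp + cols$n * vol
  idx <- outer(as.integer(rowoff), as.integer(coloff), "+") + 1L
  storage.mode(idx) <- "integer"
  .conv_idx_cache[[key]] <- idx
  idx
}

conv_fwd <- function(x, ly) {
  d <- dim(x)
  kh <- ly$k[1]
  kw <- ly$k[2]
  s <- ly$stride
  out_h <- conv_out_len(d[1], s)
  out_w <- conv_out_len(d[2], s)
  ph <- conv_pad(d[1], kh, s)
  pw <- conv_pad(d[2], kw, s)
  if (ph["total"] > 0 || pw["total"] > 0) {
    xp <- array(0, c(d[1] + ph["total"], d[2] + pw["total"], d[3], d[4]))
    xp[ph["before"] + seq_len(d[1]), pw["before"] + seq_len(d[2]), , ] <- x
  } else {
    xp <- x
  }
  pd <- dim(xp)
  idx <- conv_gather_idx(pd[1], pd[2], d[3], d[4], kh, kw, s, out_h, out_w)
  dim(xp) <- NULL
  xcol <- xp[idx]
  dim(xcol) <- dim(idx)
  dim(xp) <- pd
  y <- ly$Wm %*% xcol + ly$b
  list(y = aperm(array(y, c(ly$cout, out_h, out_w, d[4])), c(2, 3, 1, 4)),
       cache = list(xcol = xcol, in_dim = d, pad_dim = pd, idx = idx,
                    ph = ph, pw = pw, out_h = out_h, out_w = out_w))
}

conv_bwd <- function(dy, ly, cache) {
  kh <- ly$k[1]
  kw <- ly$k[2]
  cc <- ly$cin
  dym <- matrix(aperm(dy, c(3, 1, 2, 4)), nrow = ly$cout)
  dW <- tcrossprod(dym, cache$xcol)
  db <- rowSums(dym)
  dxcol <- crossprod(ly$Wm, dym)
  dxp <- numeric(prod(cache$pad_dim))
  # scatter-add one tap at a time: indices are collision-free within a tap
  for (tap in seq_len(kh * kw)) {
    rows <- ((tap - 1L) * cc + 1L):(tap * cc)
    iv <- cache$idx[rows, ]
    dxp[iv] <- dxp[iv] + dxcol[rows, ]
  }
  dim(dxp) <- cache$pad_dim
  dx <- dxp[cache$ph["before"] + seq_len(cache$in_dim[1]),
            cache$pw["before"] + seq_len(cache$in_dim[2]), , , drop = FALSE]
  list(dx = dx, dWm = dW, db = db)
}

bn_init <- function(c_out) {
  list(gamma = rep(1, c_out), beta = numeric(c_out),
       rmean = numeric(c_out), rvar = rep(1, c_out),
       momentum = 0.9, eps = 1e-5)
}

# batch norm works on the (H*W) x (C*N) matrix view of the activation
# (channel fastest among columns), which needs no transposition; channel
# statistics are column statistics pooled over the batch
channel_sum <- function(colstat, cc) rowSums(matrix(colstat, cc))

bn_fwd <- function(x, bn, training) {
  d <- dim(x)
  cc <- d[3]
  nn <- d[4]
  m <- d[1] * d[2] * nn
  xm <- matrix(x, d[1] * d[2])
  if (training) {
    mu <- channel_sum(colMeans(xm), cc) / nn
    v <- channel_sum(colMeans(xm * xm), cc) / nn - mu^2
    v[v < 0] <- 0
    bn$rmean <- bn$momentum * bn$rmean + (1 - bn$momentum) * mu
    bn$rvar <- bn$momentum * bn$rvar + (1 - bn$momentum) * v
  } else {
    mu <- bn$rmean
    v <- bn$rvar
  }
  inv <- 1 / sqrt(v + bn$eps)
  xh <- sweep(sweep(xm, 2, rep(mu, nn)), 2, rep(inv, nn), "*")
  ym <- sweep(sweep(xh, 2, rep(bn$gamma, nn), "*"), 2, rep(bn$beta, nn), "+")
  list(y = array(ym, d), bn = bn,
       cache = list(xh = xh, inv = inv, d = d, m = m))
}

bn_bwd <- function(dy, bn, cache) {
  d <- cache$d
  cc <- d[3]
  nn <- d[4]
  m <- cache$m
  dym <- matrix(dy, d[1] * d[2])
  dgamma <- channel_sum(colSums(dym * cache$xh), cc)
  dbeta <- channel_sum(colSums(dym), cc)
  dxh <- sweep(dym, 2, rep(bn$gamma, nn), "*")
  s1 <- channel_sum(colSums(dxh), cc) / m
  s2 <- channel_sum(colSums(dxh * cache$xh), cc) / m
  t1 <- sweep(dxh, 2, rep(s1, nn))
  t2 <- sweep(cache$xh, 2, rep(s2, nn), "*")
  dxm <- sweep(t1 - t2, 2, rep(cache$inv, nn), "*")
  list(dx = array(dxm, d), dgamma = dgamma, dbeta = dbeta)
}

silu_fwd <- function(z) {
  s <- 1 / (1 + exp(-z))
  list(y = z * s, cache = list(z = z, s = s))
}

silu_bwd <- function(dy, cache) {
  dy * (cache$s * (1 + cache$z * (1 - cache$s)))
}

# global average pool to (C, N)
gap_fwd <- function(x) {
  d <- dim(x)
  matrix(colMeans(matrix(x, nrow = d[1] * d[2])), d[3], d[4])
}

gap_bwd <- function(dg, d) {
  hw <- d[1] * d[2]
  array(rep(as.vector(dg) / hw, each = hw), d)
}

se_init <- function(c_out) {
  list(V = matrix(stats::rnorm(c_out * c_out, 0, sqrt(1 / c_out)),
                  c_out, c_out),
       b = numeric(c_out))
}

# squeeze-excitation skip gate: y = x * sigmoid(V gap(x) + b), per channel
se_fwd <- function(x, se) {
  d <- dim(x)
  g <- gap_fwd(x)
  s <- 1 / (1 + exp(-(se$V %*% g + se$b)))
  xm <- matrix(x, nrow = d[1] * d[2])
  ym <- sweep(xm, 2, as.vector(s), "*")
  list(y = array(ym, d), cache = list(g = g, s = s, d = d))
}

se_bwd <- function(dy, x, se, cache) {
  d <- cache$d
  hw <- d[1] * d[2]
  dym <- matrix(dy, nrow = hw)
  xm <- matrix(x, nrow = hw)
  dx1 <- sweep(dym, 2, as.vector(cache$s), "*")
  ds <- matrix(colSums(dym * xm), d[3], d[4])
  da <- ds * cache$s * (1 - cache$s)
  dV <- da %*% t(cache$g)
  db <- rowSums(da)
  dg <- crossprod(se$V, da)
  dxm <- dx1 + matrix(rep(as.vector(dg) / hw, each = hw), nrow = hw)
  list(dx = array(dxm, d), dV = dV, db = db)
}

softmax_probs <- function(scores) {
  z <- sweep(scores, 2, apply(scores, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# mean cross-entropy and gradient wrt scores; y_idx in 1..n_classes
softmax_ce <- function(scores, y_idx) {
  n <- ncol(scores)
  p <- softmax_probs(scores)
  loss <- -mean(log(pmax(p[cbind(y_idx, seq_len(n))], 1e-12)))
  hot <- matrix(0, nrow(scores), n)
  hot[cbind(y_idx, seq_len(n))] <- 1
  list(loss = loss, dscores = (p - hot) / n, probs = p)
}

# Adam update applied recursively over parallel lists of numeric tensors
adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.numeric(params)) {
    if (is.null(state)) state <- list(m = params * 0, v = params * 0)
    state$m <- beta1 * state$m + (1 - beta1) * grads
    state$v <- beta2 * state$v + (1 - beta2) * grads^2
    mhat <- state$m / (1 - beta1^t)
    vhat <- state$v / (1 - beta2^t)
    params <- params - lr * mhat / (sqrt(vhat) + eps)
    return(list(params = params, state = state))
  }
  if (is.null(state)) state <- list()
  for (nm in names(grads)) {
    if (is.null(grads[[nm]]) || is.null(params[[nm]])) next
    upd <- adam_step(params[[nm]], grads[[nm]],
                     if (nm %in% names(state)) state[[nm]] else NULL,
                     lr, t, beta1, beta2, eps)
    params[[nm]] <- upd$params
    state[[nm]] <- upd$state
  }
  list(params = params, state = state)
}
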