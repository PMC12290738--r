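# Differentiable layers for the noise-prediction network.  Feature maps are
# H x W x C x N arrays; each layer has a *_fw returning list(out, cache) and
# a *_bw returning the input gradient plus parameter gradients.  Backward
# passes are verified against central finite differences in the test suite.

## ---- parameter initialisation -------------------------------------------

init_conv <- function(k, cin, cout, zero = FALSE) {
  w <- if (zero) matrix(0, k * k * cin, cout) else
    matrix(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
           k * k * cin, cout)
  list(W = w, b = numeric(cout), k = as.integer(k), cin = as.integer(cin),
       cout = as.integer(cout))
}

init_dense <- function(din, dout, zero = FALSE) {
  w <- if (zero) matrix(0, dout, din) else
    matrix(stats::rnorm(dout * din, sd = sqrt(1 / din)), dout, din)
  list(W = w, b = numeric(dout))
}

init_gn <- function(c) list(gamma = rep(1, c), beta = numeric(c))

## ---- convolution ---------------------------------------------------------

conv2d_fw <- function(x, p, stride = 1L) {
  d <- dim(x)
  pad <- (p$k - 1L) %/% 2L
  Ho <- (d[1] + 2L * pad - p$k) %/% stride + 1L
  Wo <- (d[2] + 2L * pad - p$k) %/% stride + 1L
  cols <- im2col_hwcn(x, d[1], d[2], d[3], d[4], p$k, stride, pad)
  outm <- cols %*% p$W
  outm <- outm + rep(p$b, each = nrow(outm))
  dim(outm) <- c(Ho, Wo, d[4], p$cout)
  list(out = aperm(outm, c(1, 2, 4, 3)),
       cache = list(cols = cols, d = d, stride = stride, pad = pad,
                    Ho = Ho, Wo = Wo))
}

conv2d_bw <- function(dout, p, cache, need_dx = TRUE) {
  dm <- aperm(dout, c(1, 2, 4, 3))
  dim(dm) <- c(cache$Ho * cache$Wo * cache$d[4], p$cout)
  dW <- crossprod(cache$cols, dm)
  db <- colSums(dm)
  dx <- NULL
  if (need_dx) {
    dcols <- tcrossprod(dm, p$W)
    dx <- col2im_hwcn(dcols, cache$d[1], cache$d[2], cache$d[3], cache$d[4],
                      p$k, cache$stride, cache$pad)
    dim(dx) <- cache$d
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

## ---- group normalisation -------------------------------------------------

GN_EPS <- 1e-5

groupnorm_fw <- function(x, p, groups) {
  d <- dim(x); C <- d[3]; N <- d[4]
  cg <- C %/% groups
  m <- d[1] * d[2] * cg
  xm <- x; dim(xm) <- c(m, groups * N)
  mu <- .colMeans(xm, m, groups * N)
  v <- .colMeans(xm * xm, m, groups * N) - mu^2
  sig <- sqrt(pmax(v, 0) + GN_EPS)
  xhat <- (xm - rep(mu, each = m)) / rep(sig, each = m)
  gam <- rep(rep(p$gamma, each = d[1] * d[2]), times = N)
  bet <- rep(rep(p$beta, each = d[1] * d[2]), times = N)
  out <- xhat * gam + bet
  dim(out) <- d
  list(out = out, cache = list(xhat = xhat, sig = sig, d = d, m = m,
                               groups = groups, gam = gam))
}

groupnorm_bw <- function(dout, p, cache) {
  d <- cache$d; m <- cache$m; gn <- cache$groups * d[4]
  dy <- dout; dim(dy) <- NULL
  dxhat <- dy * cache$gam
  dim(dxhat) <- c(m, gn)
  mh <- .colMeans(dxhat, m, gn)
  mh2 <- .colMeans(dxhat * cache$xhat, m, gn)
  dx <- (dxhat - rep(mh, each = m) - cache$xhat * rep(mh2, each = m)) /
    rep(cache$sig, each = m)
  dim(dx) <- d
  a <- dy * as.vector(cache$xhat)
  dim(a) <- c(d[1] * d[2], d[3] * d[4])
  dgamma <- rowSums(matrix(colSums(a), d[3], d[4]))
  dim(dy) <- c(d[1] * d[2], d[3] * d[4])
  dbeta <- rowSums(matrix(colSums(dy), d[3], d[4]))
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

## ---- activations ---------------------------------------------------------

silu_fw <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(out = x * s, cache = list(x = x, s = s))
}

silu_bw <- function(dout, cache) {
  # d/dx [x s(x)] = s(x) (1 + x (1 - s(x)))
  s <- cache$cache$s
  dout * (s * (1 + cache$cache$x * (1 - s)))
}

## ---- dense ---------------------------------------------------------------

dense_fw <- function(x, p) list(out = p$W %*% x + p$b, cache = x)

dense_bw <- function(dout, p, cache) {
  list(dx = crossprod(p$W, dout),
       grads = list(W = tcrossprod(dout, cache), b = rowSums(dout)))
}

## ---- nearest-neighbour resampling ---------------------------------------

upsample2_fw <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

upsample2_bw <- function(dout) {
  d <- dim(dout)
  i1 <- seq(1L, d[1], by = 2L); i2 <- seq(2L, d[1], by = 2L)
  j1 <- seq(1L, d[2], by = 2L); j2 <- seq(2L, d[2], by = 2L)
  dout[i1, j1, , , drop = FALSE] + dout[i1, j2, , , drop = FALSE] +
    dout[i2, j1, , , drop = FALSE] + dout[i2, j2, , , drop = FALSE]
}

## ---- single-head self-attention ------------------------------------------

attn_fw <- function(x, p, groups) {
  d <- dim(x); hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  gn <- groupnorm_fw(x, p$gn, groups)
  per <- vector("list", N)
  out <- x
  scale <- 1 / sqrt(C)
  for (n in seq_len(N)) {
    xn <- gn$out[, , , n]; dim(xn) <- c(hw, C)
    q <- xn %*% p$Wq + rep(p$bq, each = hw)
    k <- xn %*% p$Wk + rep(p$bk, each = hw)
    v <- xn %*% p$Wv + rep(p$bv, each = hw)
    lg <- tcrossprod(q, k) * scale
    lg <- lg - lg[cbind(seq_len(hw), max.col(lg, ties.method = "first"))]
    A <- exp(lg); A <- A / rowSums(A)
    o <- A %*% v
    y <- o %*% p$Wo + rep(p$bo, each = hw)
    out[, , , n] <- out[, , , n] + array(y, dim = c(d[1], d[2], C))
    per[[n]] <- list(xn = xn, q = q, k = k, v = v, A = A, o = o)
  }
  list(out = out, cache = list(gn = gn, per = per, d = d, scale = scale))
}

attn_bw <- function(dout, p, cache) {
  d <- cache$d; hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  g <- list(gn = NULL,
            Wq = matrix(0, C, C), bq = numeric(C),
            Wk = matrix(0, C, C), bk = numeric(C),
            Wv = matrix(0, C, C), bv = numeric(C),
            Wo = matrix(0, C, C), bo = numeric(C))
  dgn_out <- array(0, dim = d)
  for (n in seq_len(N)) {
    cc <- cache$per[[n]]
    dy <- dout[, , , n]; dim(dy) <- c(hw, C)
    g$Wo <- g$Wo + crossprod(cc$o, dy)
    g$bo <- g$bo + colSums(dy)
    do <- tcrossprod(dy, p$Wo)
    dA <- tcrossprod(do, cc$v)
    dv <- crossprod(cc$A, do)
    dlg <- cc$A * (dA - rowSums(dA * cc$A))
    dq <- (dlg %*% cc$k) * cache$scale
    dk <- (crossprod(dlg, cc$q)) * cache$scale
    g$Wq <- g$Wq + crossprod(cc$xn, dq); g$bq <- g$bq + colSums(dq)
    g$Wk <- g$Wk + crossprod(cc$xn, dk); g$bk <- g$bk + colSums(dk)
    g$Wv <- g$Wv + crossprod(cc$xn, dv); g$bv <- g$bv + colSums(dv)
    dxn <- tcrossprod(dq, p$Wq) + tcrossprod(dk, p$Wk) + tcrossprod(dv, p$Wv)
    dgn_out[, , , n] <- array(dxn, dim = c(d[1], d[2], C))
  }
  gb <- groupnorm_bw(dgn_out, p$gn, cache$gn$cache)
  g$gn <- gb$grads
  list(dx = dout + gb$dx, grads = g)   # residual branch passes dout through
}

init_attn <- function(C) {
  sdv <- sqrt(1 / C)
  list(gn = init_gn(C),
       Wq = matrix(stats::rnorm(C * C, sd = sdv), C, C), bq = numeric(C),
       Wk = matrix(stats::rnorm(C * C, sd = sdv), C, C), bk = numeric(C),
       Wv = matrix(stats::rnorm(C * C, sd = sdv), C, C), bv = numeric(C),
       Wo = matrix(0, C, C), bo = numeric(C))
}

## ---- residual block ------------------------------------------------------

init_resblock <- function(cin, cout, temb_dim) {
  list(gn1 = init_gn(cin),
       conv1 = init_conv(3L, cin, cout),
       temb = init_dense(temb_dim, cout),
       gn2 = init_gn(cout),
       conv2 = init_conv(3L, cout, cout, zero = TRUE),
       skip = if (cin != cout) init_conv(1L, cin, cout) else NULL)
}

resblock_fw <- function(x, temb, p, groups) {
  n1 <- groupnorm_fw(x, p$gn1, min(groups, dim(x)[3]))
  a1 <- silu_fw(n1$out)
  c1 <- conv2d_fw(a1$out, p$conv1)
  ts <- silu_fw(temb)
  tp <- dense_fw(ts$out, p$temb)          # cout x N
  d <- dim(c1$out)
  # broadcast the per-channel time projection over H and W
  h <- c1$out + array(rep(tp$out, each = d[1] * d[2]), dim = d)
  n2 <- groupnorm_fw(h, p$gn2, min(groups, d[3]))
  a2 <- silu_fw(n2$out)
  c2 <- conv2d_fw(a2$out, p$conv2)
  if (is.null(p$skip)) {
    out <- c2$out + x
    sk <- NULL
  } else {
    sk <- conv2d_fw(x, p$skip)
    out <- c2$out + sk$out
  }
  list(out = out,
       cache = list(n1 = n1, a1 = a1, c1 = c1, ts = ts, tp = tp, n2 = n2,
                    a2 = a2, c2 = c2, sk = sk, d = d, groups = groups))
}

resblock_bw <- function(dout, p, cache) {
  d <- cache$d
  c2b <- conv2d_bw(dout, p$conv2, cache$c2$cache)
  da2 <- silu_bw(c2b$dx, cache$a2)
  n2b <- groupnorm_bw(da2, p$gn2, cache$n2$cache)
  dh <- n2b$dx
  # time-embedding branch: sum the broadcast over H, W
  dtp <- dh; dim(dtp) <- c(d[1] * d[2], d[3] * d[4])
  dtp <- matrix(colSums(dtp), d[3], d[4])
  tpb <- dense_bw(dtp, p$temb, cache$tp$cache)
  dtemb <- silu_bw(tpb$dx, cache$ts)
  c1b <- conv2d_bw(dh, p$conv1, cache$c1$cache)
  da1 <- silu_bw(c1b$dx, cache$a1)
  n1b <- groupnorm_bw(da1, p$gn1, cache$n1$cache)
  if (is.null(p$skip)) {
    dx <- n1b$dx + dout
    skg <- NULL
  } else {
    skb <- conv2d_bw(dout, p$skip, cache$sk$cache)
    dx <- n1b$dx + skb$dx
    skg <- skb$grads
  }
  list(dx = dx, dtemb = dtemb,
       grads = list(gn1 = n1b$grads, conv1 = c1b$grads, temb = tpb$grads,
                    gn2 = n2b$grads, conv2 = c2b$grads, skip = skg))
}

## ---- sinusoidal timestep embedding ---------------------------------------

time_embedding <- function(t, dim) {
  half <- dim %/% 2L
  freqs <- exp(-log(10000) * (seq_len(half) - 1) / max(half - 1, 1))
  ang <- outer(freqs, as.numeric(t))       # half x N
  rbind(sin(ang), cos(ang))                # dim x N
}
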