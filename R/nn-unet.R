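#' Specification of the noise-prediction network
#'
#' Describes a UNet-style 2D encoder--decoder over unit channel stacks: per
#' resolution level one residual block (two 3x3 convolutions with group
#' normalisation, SiLU activations, a shortcut connection, and an injected
#' timestep embedding), optional single-head self-attention, stride-2
#' convolution downsampling and nearest-neighbour upsampling, and a
#' sinusoidal timestep embedding passed through two fully-connected layers.
#'
#' For a layout with unit channel count \eqn{C = K(2J+1)} the output has
#' \eqn{C} channels and the input has \eqn{(1 + n_{cond}) C} channels for the
#' diffusion model (noisy target plus condition stacks) or
#' \eqn{n_{cond} C} for the autoencoder comparator.
#'
#' @param in_channels,out_channels input/output channel counts.
#' @param H,W spatial size of a unit; both must be divisible by
#'   \code{2^(depth - 1)}.
#' @param base_channels channel multiplier (the reference configurations use
#'   64 for past-conditioned and 128 for past-and-following-conditioned
#'   models; the "tiny" desk-scale preset uses 16).
#' @param depth number of resolution levels.
#' @param channel_mult per-level channel multipliers (default
#'   \code{2^(0:(depth-1))}).
#' @param groups group-normalisation group count.
#' @param time_embed_dim width of the timestep embedding (even).
#' @param attention_levels levels receiving self-attention (default: lowest
#'   resolution only).
#' @return An object of class \code{"denoiser_spec"}.
#' @export
denoiser_spec <- function(in_channels, out_channels, H, W,
                          base_channels = 16L, depth = 2L,
                          channel_mult = NULL, groups = 8L,
                          time_embed_dim = 4L * base_channels,
                          attention_levels = depth) {
  if (in_channels < 1 || out_channels < 1)
    stop("channel counts must be positive")
  if (is.null(channel_mult)) channel_mult <- 2^(seq_len(depth) - 1)
  if (length(channel_mult) != depth)
    stop("'channel_mult' must have one entry per level")
  down <- 2^(depth - 1)
  if (H %% down != 0 || W %% down != 0)
    stop(sprintf("H and W must be divisible by 2^(depth-1) = %d", down))
  if (time_embed_dim %% 2L != 0L) stop("'time_embed_dim' must be even")
  ch <- as.integer(base_channels * channel_mult)
  if (any(ch %% groups != 0))
    stop("per-level channel counts must be multiples of 'groups'")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 H = as.integer(H), W = as.integer(W),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth), channels = ch,
                 groups = as.integer(groups),
                 time_embed_dim = as.integer(time_embed_dim),
                 attention_levels = as.integer(attention_levels)),
            class = "denoiser_spec")
}

#' Desk-scale and reference network presets
#'
#' \code{"tiny"} is the configuration used throughout the test suite
#' (16 base channels, 2 levels); \code{"reference-p"} and \code{"reference-pf"}
#' mirror the reference channel multipliers (64 and 128) at depth 4.
#'
#' @param preset one of \code{"tiny"}, \code{"reference-p"}, \code{"reference-pf"}.
#' @param layout a [unit_layout()] providing the unit channel count and H, W.
#' @param conditioning \code{"p"} (past visit) or \code{"pf"} (past and
#'   following visits).
#' @param ae logical; if \code{TRUE} the input carries condition stacks only
#'   (autoencoder comparator), otherwise the noisy target plus conditions.
#' @return A \code{"denoiser_spec"}.
#' @export
denoiser_preset <- function(preset = c("tiny", "reference-p", "reference-pf"),
                            layout, conditioning = c("pf", "p"), ae = FALSE) {
  preset <- match.arg(preset)
  conditioning <- match.arg(conditioning)
  C <- layout$K * layout$clip_len
  n_cond <- if (conditioning == "pf") 2L else 1L
  in_ch <- if (ae) n_cond * C else (1L + n_cond) * C
  switch(preset,
    tiny = denoiser_spec(in_ch, C, layout$H, layout$W, base_channels = 16L,
                         depth = 2L),
    `reference-p` = denoiser_spec(in_ch, C, layout$H, layout$W,
                              base_channels = 64L, depth = 4L),
    `reference-pf` = denoiser_spec(in_ch, C, layout$H, layout$W,
                               base_channels = 128L, depth = 4L))
}

#' Build a denoiser with seeded random initialisation
#'
#' Initialises all weights (He-scaled convolutions; the closing convolution
#' of every residual block, the attention output projection, and the final
#' output convolution start at zero so the untrained network predicts zero
#' noise).  Uses R's global RNG stream: seed the session for reproducible
#' initialisation.
#'
#' @param spec a [denoiser_spec()].
#' @return Object of class \code{"denoiser"}: list with \code{spec},
#'   \code{params}, and the training \code{step} counter.
#' @export
build_denoiser <- function(spec) {
  d <- spec$time_embed_dim
  ch <- spec$channels
  D <- spec$depth
  enc <- vector("list", D)
  dec <- vector("list", D)
  for (lev in seq_len(D)) {
    cin <- if (lev == 1L) ch[1] else ch[lev - 1L]
    enc[[lev]] <- list(
      res = init_resblock(cin, ch[lev], d),
      attn = if (lev %in% spec$attention_levels) init_attn(ch[lev]) else NULL,
      down = if (lev < D) init_conv(3L, ch[lev], ch[lev]) else NULL)
    dec[[lev]] <- list(
      res = init_resblock(2L * ch[lev], ch[lev], d),
      attn = if (lev %in% spec$attention_levels) init_attn(ch[lev]) else NULL,
      up = if (lev > 1L) init_conv(3L, ch[lev], ch[lev - 1L]) else NULL)
  }
  params <- list(
    tmlp1 = init_dense(d, d), tmlp2 = init_dense(d, d),
    conv_in = init_conv(3L, spec$in_channels, ch[1]),
    enc = enc,
    mid = list(res1 = init_resblock(ch[D], ch[D], d),
               attn = init_attn(ch[D]),
               res2 = init_resblock(ch[D], ch[D], d)),
    dec = dec,
    gn_out = init_gn(ch[1]),
    conv_out = init_conv(3L, ch[1], spec$out_channels, zero = TRUE))
  structure(list(spec = spec, params = params, step = 0L), class = "denoiser")
}

#' @export
print.denoiser <- function(x, ...) {
  cat(sprintf(
    "Denoiser: %d -> %d channels, %d x %d units, %d levels (%s ch), %d params\n",
    x$spec$in_channels, x$spec$out_channels, x$spec$H, x$spec$W, x$spec$depth,
    paste(x$spec$channels, collapse = "/"), n_params(x$params)))
  cat(sprintf("  training step: %d\n", x$step))
  invisible(x)
}

n_params <- function(p) length(flatten_tree(p))

## ---- forward -------------------------------------------------------------

unet_fw <- function(params, spec, x, t) {
  D <- spec$depth; g <- spec$groups
  te0 <- time_embedding(t, spec$time_embed_dim)
  if (ncol(te0) == 1L && dim(x)[4] > 1L)
    te0 <- te0[, rep(1L, dim(x)[4]), drop = FALSE]
  t1 <- dense_fw(te0, params$tmlp1)
  ta <- silu_fw(t1$out)
  t2 <- dense_fw(ta$out, params$tmlp2)
  temb <- t2$out
  ci <- conv2d_fw(x, params$conv_in)
  h <- ci$out
  enc_cache <- vector("list", D)
  skips <- vector("list", D)
  for (lev in seq_len(D)) {
    p <- params$enc[[lev]]
    rb <- resblock_fw(h, temb, p$res, g); h <- rb$out
    ab <- NULL
    if (!is.null(p$attn)) { ab <- attn_fw(h, p$attn, g); h <- ab$out }
    skips[[lev]] <- h
    db <- NULL
    if (!is.null(p$down)) { db <- conv2d_fw(h, p$down, stride = 2L); h <- db$out }
    enc_cache[[lev]] <- list(rb = rb, ab = ab, db = db)
  }
  m1 <- resblock_fw(h, temb, params$mid$res1, g)
  ma <- attn_fw(m1$out, params$mid$attn, g)
  m2 <- resblock_fw(ma$out, temb, params$mid$res2, g)
  h <- m2$out
  dec_cache <- vector("list", D)
  for (lev in seq(D, 1L)) {
    p <- params$dec[[lev]]
    h <- bind_channels(h, skips[[lev]])
    rb <- resblock_fw(h, temb, p$res, g); h <- rb$out
    ab <- NULL
    if (!is.null(p$attn)) { ab <- attn_fw(h, p$attn, g); h <- ab$out }
    ub <- NULL
    if (!is.null(p$up)) {
      hu <- upsample2_fw(h)
      ub <- conv2d_fw(hu, p$up); h <- ub$out
    }
    dec_cache[[lev]] <- list(rb = rb, ab = ab, ub = ub)
  }
  no <- groupnorm_fw(h, params$gn_out, g)
  ao <- silu_fw(no$out)
  co <- conv2d_fw(ao$out, params$conv_out)
  list(out = co$out,
       cache = list(t1 = t1, ta = ta, t2 = t2, ci = ci, enc = enc_cache,
                    mid = list(m1 = m1, ma = ma, m2 = m2), dec = dec_cache,
                    no = no, ao = ao, co = co, spec = spec))
}

## ---- backward ------------------------------------------------------------

unet_bw <- function(params, spec, cache, dout) {
  D <- spec$depth
  grads <- list(enc = vector("list", D), dec = vector("list", D))
  dtemb <- 0

  cob <- conv2d_bw(dout, params$conv_out, cache$co$cache)
  grads$conv_out <- cob$grads
  dao <- silu_bw(cob$dx, cache$ao)
  nob <- groupnorm_bw(dao, params$gn_out, cache$no$cache)
  grads$gn_out <- nob$grads
  dh <- nob$dx
  dskips <- vector("list", D)
  for (lev in seq_len(D)) {            # reverse of the decoder loop
    p <- params$dec[[lev]]; cc <- cache$dec[[lev]]
    glev <- list()
    if (!is.null(p$up)) {
      ub <- conv2d_bw(dh, p$up, cc$ub$cache)
      glev$up <- ub$grads
      dh <- upsample2_bw(ub$dx)
    }
    if (!is.null(p$attn)) {
      ab <- attn_bw(dh, p$attn, cc$ab$cache)
      glev$attn <- ab$grads
      dh <- ab$dx
    }
    rb <- resblock_bw(dh, p$res, cc$rb$cache)
    glev$res <- rb$grads
    dtemb <- dtemb + rb$dtemb
    nch <- dim(rb$dx)[3] %/% 2L
    dh <- rb$dx[, , seq_len(nch), , drop = FALSE]
    dskips[[lev]] <- rb$dx[, , nch + seq_len(nch), , drop = FALSE]
    grads$dec[[lev]] <- glev
  }
  m2 <- resblock_bw(dh, params$mid$res2, cache$mid$m2$cache)
  dtemb <- dtemb + m2$dtemb
  ma <- attn_bw(m2$dx, params$mid$attn, cache$mid$ma$cache)
  m1 <- resblock_bw(ma$dx, params$mid$res1, cache$mid$m1$cache)
  dtemb <- dtemb + m1$dtemb
  grads$mid <- list(res1 = m1$grads, attn = ma$grads, res2 = m2$grads)
  dh <- m1$dx
  for (lev in seq(D, 1L)) {            # reverse of the encoder loop
    p <- params$enc[[lev]]; cc <- cache$enc[[lev]]
    glev <- list()
    if (!is.null(p$down)) {
      db <- conv2d_bw(dh, p$down, cc$db$cache)
      glev$down <- db$grads
      dh <- db$dx
    }
    dh <- dh + dskips[[lev]]
    if (!is.null(p$attn)) {
      ab <- attn_bw(dh, p$attn, cc$ab$cache)
      glev$attn <- ab$grads
      dh <- ab$dx
    }
    rb <- resblock_bw(dh, p$res, cc$rb$cache)
    glev$res <- rb$grads
    dtemb <- dtemb + rb$dtemb
    dh <- rb$dx
    grads$enc[[lev]] <- glev
  }
  cib <- conv2d_bw(dh, params$conv_in, cache$ci$cache, need_dx = FALSE)
  grads$conv_in <- cib$grads
  t2b <- dense_bw(dtemb, params$tmlp2, cache$t2$cache)
  grads$tmlp2 <- t2b$grads
  dta <- silu_bw(t2b$dx, cache$ta)
  t1b <- dense_bw(dta, params$tmlp1, cache$t1$cache)
  grads$tmlp1 <- t1b$grads
  list(grads = grads, dx = cib$dx)
}

#' Predict the added noise for a (noisy target, conditions) stack
#'
#' @param model a [build_denoiser()] object, or a plain
#'   \code{function(input, t)} implementing the same contract (useful for
#'   analytic reference models such as a zero predictor).
#' @param input H x W x in_channels array (or H x W x C x N batch): the noisy
#'   target unit concatenated with the clean condition units along channels
#'   (condition stacks only for the autoencoder comparator).
#' @param t timestep(s): scalar or one per batch sample.
#' @return Array of shape H x W x out_channels (x N), the predicted noise.
#' @export
denoiser_predict <- function(model, input, t) {
  if (is.function(model)) return(model(input, t))
  was3d <- length(dim(input)) == 3L
  if (was3d) dim(input) <- c(dim(input), 1L)
  d <- dim(input)
  if (d[1] != model$spec$H || d[2] != model$spec$W)
    stop("input spatial size does not match the denoiser spec")
  if (d[3] != model$spec$in_channels)
    stop(sprintf("input has %d channels but the denoiser expects %d",
                 d[3], model$spec$in_channels))
  out <- unet_fw(model$params, model$spec, input, t)$out
  if (was3d) dim(out) <- dim(out)[1:3]
  out
}

## ---- parameter-tree utilities and Adam -----------------------------------

# layer metadata living beside weight arrays; never treated as parameters
TREE_META <- c("k", "cin", "cout")

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    nms <- names(a)
    for (i in seq_along(a)) {
      nm <- if (!is.null(nms)) nms[i] else ""
      if (nm %in% TREE_META) next
      if (is.null(a[[i]])) next        # assigning NULL would drop the slot
      bi <- if (nzchar(nm) && !is.null(names(b))) b[[nm]] else b[[i]]
      if (is.null(bi)) next
      out[[i]] <- tree_map2(f, a[[i]], bi)
    }
    out
  } else if (is.numeric(a)) f(a, b) else a
}

tree_zeros <- function(a) {
  tree_map2(function(p, q) p * 0, a, a)
}

flatten_tree <- function(a) {
  out <- numeric(0)
  walk <- function(q) {
    nms <- names(q)
    for (i in seq_along(q)) {
      if (!is.null(nms) && nms[i] %in% TREE_META) next
      e <- q[[i]]
      if (is.list(e)) walk(e) else if (is.numeric(e)) out <<- c(out, as.numeric(e))
    }
  }
  walk(a)
  out
}

adam_init <- function(params) {
  list(m = tree_zeros(params), v = tree_zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(function(p, u) p - u, params, upd)
  list(params = params, state = state)
}
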