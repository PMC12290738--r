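#' Closed-form forward diffusion to an arbitrary step
#'
#' Draws the diffused state \eqn{x_t} directly from the clean data:
#' \eqn{x_t = \sqrt{\bar\alpha_t}\, x_0 + \sqrt{1 - \bar\alpha_t}\, \epsilon}.
#'
#' @param x0 clean data (any numeric array).
#' @param t diffusion step in \code{[1, T]}.
#' @param eps standard-normal noise, same shape as \code{x0}.
#' @param sched a [diffusion_schedule()].
#' @return Array shaped like \code{x0}, with attribute \code{"t"}.
#' @export
forward_sample <- function(x0, t, eps, sched) {
  t <- check_t(t, sched)
  if (length(eps) != length(x0)) stop("'eps' must be shaped like 'x0'")
  ab <- sched$alpha_bar[t]
  out <- sqrt(ab) * x0 + sqrt(1 - ab) * eps
  attr(out, "t") <- t
  out
}

#' Single-step forward diffusion kernel
#'
#' One application of \eqn{q(x_t \mid x_{t-1}) =
#' N(\sqrt{1-\beta_t}\, x_{t-1}, \beta_t I)}.
#'
#' @param x_prev state at step \code{t - 1}.
#' @param t diffusion step in \code{[1, T]}.
#' @param noise standard-normal noise shaped like \code{x_prev}.
#' @param sched a [diffusion_schedule()].
#' @return Array shaped like \code{x_prev}.
#' @export
forward_step <- function(x_prev, t, noise, sched) {
  t <- check_t(t, sched)
  if (length(noise) != length(x_prev))
    stop("'noise' must be shaped like 'x_prev'")
  b <- sched$beta[t]
  out <- sqrt(1 - b) * x_prev + sqrt(b) * noise
  attr(out, "t") <- t
  out
}

#' Recover the clean-data estimate from a noise prediction
#'
#' Algebraic inversion of the closed-form forward draw:
#' \eqn{\hat x_0 = (x_t - \sqrt{1 - \bar\alpha_t}\,\hat\epsilon) /
#' \sqrt{\bar\alpha_t}}.
#'
#' @param x_t diffused state at step \code{t}.
#' @param t diffusion step in \code{[1, T]}.
#' @param eps_pred predicted (or true) noise shaped like \code{x_t}.
#' @param sched a [diffusion_schedule()].
#' @return Estimate of the clean data, shaped like \code{x_t}.
#' @export
estimate_x0 <- function(x_t, t, eps_pred, sched) {
  t <- check_t(t, sched)
  if (length(eps_pred) != length(x_t))
    stop("'eps_pred' must be shaped like 'x_t'")
  ab <- sched$alpha_bar[t]
  (x_t - sqrt(1 - ab) * eps_pred) / sqrt(ab)
}

#' Mean and variance of the reverse (denoising) transition
#'
#' Parameters of \eqn{p_\theta(x_{t-1} \mid x_t, C)}: the posterior mean
#' \deqn{\tilde\mu = \frac{\sqrt{\bar\alpha_{t-1}}\,\beta_t}{1-\bar\alpha_t}
#'  \hat x_0 + \frac{\sqrt{\alpha_t}(1-\bar\alpha_{t-1})}{1-\bar\alpha_t} x_t}
#' with \eqn{\hat x_0} from [estimate_x0()], and variance
#' \eqn{\tilde\beta_t}.  The conditioning enters only through the noise
#' prediction \code{eps_pred}, which the denoiser produced from the
#' concatenation of \code{x_t} with the condition images.  At \code{t = 1}
#' (with \eqn{\bar\alpha_0 = 1}) the \eqn{x_t} coefficient vanishes and the
#' variance is zero: the final transition returns \eqn{\hat x_0}.
#'
#' @inheritParams estimate_x0
#' @param x0_clip optional length-2 range to which the intermediate clean
#'   estimate \eqn{\hat x_0} is clamped (e.g. \code{c(0, 1)} for min-max
#'   normalised images).  Clamping is the standard sampler stabiliser: it
#'   keeps the reverse chain inside the data range so that imperfect noise
#'   predictions cannot compound into divergence.  \code{NULL} (default)
#'   leaves the estimate untouched.
#' @return List with elements \code{mean} (array shaped like \code{x_t}) and
#'   \code{var} (non-negative scalar \eqn{\tilde\beta_t}).
#' @export
posterior_params <- function(x_t, t, eps_pred, sched, x0_clip = NULL) {
  t <- check_t(t, sched)
  x0_hat <- estimate_x0(x_t, t, eps_pred, sched)
  if (!is.null(x0_clip))
    x0_hat <- pmin(pmax(x0_hat, x0_clip[1]), x0_clip[2])
  ab <- sched$alpha_bar[t]
  ab_prev <- sched$alpha_bar_prev[t]
  b <- sched$beta[t]
  a <- sched$alpha[t]
  coef0 <- sqrt(ab_prev) * b / (1 - ab)
  coeft <- sqrt(a) * (1 - ab_prev) / (1 - ab)
  list(mean = coef0 * x0_hat + coeft * x_t, var = sched$posterior_var[t])
}

#' One ancestral denoising step
#'
#' Draws \eqn{x_{t-1} \sim N(\tilde\mu, \tilde\beta_t I)} from the reverse
#' transition, using the denoiser's noise prediction under the given
#' condition set.  No noise is injected at \code{t = 1}, so the last step is
#' deterministic.  Uses R's global RNG stream; seed the session for
#' reproducibility.
#'
#' @param x_t current state (H x W x C unit array).
#' @param t diffusion step in \code{[1, T]}.
#' @param model a denoiser built by [build_denoiser()].
#' @param cond condition unit array (H x W x n_cond*C), extracted at the same
#'   slice indices as the target unit.
#' @param sched a [diffusion_schedule()].
#' @param x0_clip see [posterior_params()]; the pipeline samples with
#'   \code{c(0, 1)}.
#' @return State at step \code{t - 1}, shaped like \code{x_t}.
#' @export
denoise_step <- function(x_t, t, model, cond, sched, x0_clip = NULL) {
  t <- check_t(t, sched)
  inp <- bind_channels(x_t, cond)
  eps_pred <- denoiser_predict(model, inp, t)
  pp <- posterior_params(x_t, t, eps_pred, sched, x0_clip = x0_clip)
  if (t == 1L || pp$var == 0) {
    out <- pp$mean
  } else {
    out <- pp$mean + sqrt(pp$var) * array(stats::rnorm(length(pp$mean)),
                                          dim = dim(pp$mean))
  }
  attr(out, "t") <- t - 1L
  out
}

# concatenate H x W x C arrays (or batches H x W x C x N) along the channel axis
bind_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (length(da) != length(db) || !all(da[-3] == db[-3]))
    stop("channel concatenation requires matching spatial/batch dimensions")
  if (length(da) == 3L) {
    out <- array(0, dim = c(da[1], da[2], da[3] + db[3]))
    out[, , seq_len(da[3])] <- a
    out[, , da[3] + seq_len(db[3])] <- b
  } else {
    out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
    out[, , seq_len(da[3]), ] <- a
    out[, , da[3] + seq_len(db[3]), ] <- b
  }
  out
}

#' Generate a full volume by ordered ancestral sampling
#'
#' For every ordered generation unit of the layout, starts from
#' standard-normal noise and runs the reverse diffusion from \eqn{t = T} down
#' to 1, conditioning each step on the condition volumes extracted at the
#' target unit's slice indices; reassembles all generated units into an
#' L x H x W volume (replicated padding slices are dropped).
#'
#' @param model a denoiser built by [build_denoiser()] whose input channel
#'   count matches \code{1 + length(cond_volumes)} unit stacks.
#' @param cond_volumes list of one (past) or two (past, following) condition
#'   volumes, each L x H x W.
#' @param layout a [unit_layout()].
#' @param sched a [diffusion_schedule()].
#' @param x0_clip range for clamping the intermediate clean estimate; the
#'   default \code{c(0, 1)} matches min-max normalised volumes.  Set to
#'   \code{NULL} for the unclamped transition.
#' @return Imputed L x H x W volume.
#' @export
sample_volume <- function(model, cond_volumes, layout, sched,
                          x0_clip = c(0, 1)) {
  stopifnot(is.list(cond_volumes), length(cond_volumes) %in% 1:2)
  for (cv in cond_volumes)
    if (!all(dim(cv) == c(layout$L, layout$H, layout$W)))
      stop("condition volume shape does not match layout")
  gus <- generation_units(layout)
  C <- layout$K * layout$clip_len
  nunit <- length(gus)
  # batch all units of the volume through the network together
  x <- array(stats::rnorm(layout$H * layout$W * C * nunit),
             dim = c(layout$H, layout$W, C, nunit))
  cond <- array(0, dim = c(layout$H, layout$W, C * length(cond_volumes), nunit))
  for (i in seq_len(nunit)) {
    cu <- lapply(cond_volumes, extract_unit, indices = gus[[i]]$indices)
    cond[, , , i] <- if (length(cu) == 1L) cu[[1]] else
      bind_channels(cu[[1]], cu[[2]])
  }
  for (t in seq(sched$n_steps, 1L)) {
    eps_pred <- denoiser_predict(model, bind_channels(x, cond),
                                 rep(t, nunit))
    pp <- posterior_params(x, t, eps_pred, sched, x0_clip = x0_clip)
    x <- pp$mean
    if (t > 1L && pp$var > 0)
      x <- x + sqrt(pp$var) * array(stats::rnorm(length(x)), dim = dim(x))
  }
  units <- lapply(seq_len(nunit), function(i) {
    u <- array(x[, , , i], dim = c(layout$H, layout$W, C))
    attr(u, "indices") <- gus[[i]]$indices
    u
  })
  assemble_units(units, layout)
}

#' Noise-prediction training loss
#'
#' The simplified diffusion objective: diffuse the target unit to step
#' \code{t} with noise \code{eps}, concatenate the clean condition units
#' (conditions are never diffused), and score the denoiser's noise prediction
#' by mean squared error
#' \eqn{\| \epsilon - \epsilon_\theta(\sqrt{\bar\alpha_t} x_0 +
#' \sqrt{1-\bar\alpha_t}\epsilon,\, t,\, C) \|^2 / d}.
#'
#' @param model a denoiser built by [build_denoiser()].
#' @param target_unit clean unit extracted from the missing-visit image
#'   (H x W x C, or batched H x W x C x N).
#' @param cond_units condition unit stack (H x W x n_cond*C, batched alike).
#' @param t diffusion step(s) in \code{[1, T]} (scalar or one per sample).
#' @param eps standard-normal noise shaped like \code{target_unit}.
#' @param sched a [diffusion_schedule()].
#' @return Non-negative scalar loss.
#' @export
training_loss <- function(model, target_unit, cond_units, t, eps, sched) {
  if (length(eps) != length(target_unit))
    stop("'eps' must be shaped like 'target_unit'")
  nd <- length(dim(target_unit))
  n <- if (nd == 4L) dim(target_unit)[4] else 1L
  t <- check_t(t, sched, len = n)
  ab <- sched$alpha_bar[t]
  if (nd == 4L && length(ab) > 1L) {
    per <- prod(dim(target_unit)[1:3])
    ab <- rep(ab, each = per)
  }
  x_t <- array(sqrt(ab) * target_unit + sqrt(1 - ab) * eps,
               dim = dim(target_unit))
  pred <- denoiser_predict(model, bind_channels(x_t, cond_units), t)
  mean((eps - pred)^2)
}
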