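#' Variance schedule for the diffusion process
#'
#' Builds the fixed variance schedule \eqn{\beta_1, \ldots, \beta_T} of a
#' denoising diffusion probabilistic model together with all derived
#' quantities: \eqn{\alpha_t = 1 - \beta_t}, the cumulative signal-retention
#' products \eqn{\bar\alpha_t = \prod_{s \le t} \alpha_s}, and the reverse
#' posterior variances
#' \eqn{\tilde\beta_t = \beta_t (1 - \bar\alpha_{t-1}) / (1 - \bar\alpha_t)}
#' under the convention \eqn{\bar\alpha_0 = 1} (so \eqn{\tilde\beta_1 = 0} and
#' the final reverse transition is deterministic in its mean).
#'
#' The default (\code{T = 1000}, \eqn{\beta} linear from \code{1e-4} to
#' \code{0.02}) is the standard linear schedule; it drives
#' \eqn{\bar\alpha_T} below \code{1e-4}, i.e. the fully diffused state is
#' numerically indistinguishable from a standard normal.  When fewer steps are
#' used (desk-scale runs), the \eqn{\beta} range should be scaled up by
#' \code{1000/T} to preserve the terminal signal-to-noise ratio; see
#' [tiny_schedule()].
#'
#' @param n_steps number of diffusion steps \eqn{T} (positive integer).
#' @param beta_start,beta_end endpoints of the linearly spaced schedule; both
#'   must lie in (0, 1) with \code{beta_start <= beta_end}.
#' @param kind schedule family; only \code{"linear"} is supported.
#' @return An object of class \code{"diffusion_schedule"}: a list with
#'   elements \code{n_steps}, \code{beta}, \code{alpha}, \code{alpha_bar},
#'   \code{posterior_var}, each of length \code{n_steps}.
#' @examples
#' sch <- diffusion_schedule(10, 1e-4, 0.2)
#' sch$alpha_bar
#' @export
diffusion_schedule <- function(n_steps = 1000L, beta_start = 1e-4,
                               beta_end = 0.02, kind = c("linear")) {
  kind <- match.arg(kind)
  if (length(n_steps) != 1L || !is.finite(n_steps) || n_steps < 1 ||
      n_steps != round(n_steps))
    stop("'n_steps' must be a positive integer")
  if (!is.finite(beta_start) || beta_start <= 0 || beta_start >= 1)
    stop("'beta_start' must lie in (0, 1)")
  if (!is.finite(beta_end) || beta_end <= 0 || beta_end >= 1)
    stop("'beta_end' must lie in (0, 1)")
  if (beta_start > beta_end)
    stop("'beta_start' must not exceed 'beta_end'")
  n_steps <- as.integer(n_steps)
  beta <- if (n_steps == 1L) beta_start else
    seq(beta_start, beta_end, length.out = n_steps)
  alpha <- 1 - beta
  alpha_bar <- cumprod(alpha)
  alpha_bar_prev <- c(1, alpha_bar[-n_steps])   # alpha_bar[0] := 1
  posterior_var <- (1 - alpha_bar_prev) / (1 - alpha_bar) * beta
  structure(list(n_steps = n_steps, beta = beta, alpha = alpha,
                 alpha_bar = alpha_bar, alpha_bar_prev = alpha_bar_prev,
                 posterior_var = posterior_var, kind = kind),
            class = "diffusion_schedule")
}

#' @export
print.diffusion_schedule <- function(x, ...) {
  cat(sprintf("Diffusion schedule (%s): T = %d, beta in [%g, %g]\n",
              x$kind, x$n_steps, x$beta[1], x$beta[x$n_steps]))
  cat(sprintf("  terminal signal retention alpha_bar[T] = %.3g\n",
              x$alpha_bar[x$n_steps]))
  invisible(x)
}

#' Desk-scale schedule with preserved terminal signal-to-noise
#'
#' Short schedules reuse the default linear shape with the \eqn{\beta} range
#' scaled by \code{1000/n_steps}, so the fully diffused state remains close to
#' a standard normal even at small \eqn{T}.
#'
#' @param n_steps number of diffusion steps (default 50).
#' @return A \code{"diffusion_schedule"}.
#' @export
tiny_schedule <- function(n_steps = 50L) {
  scale <- 1000 / n_steps
  diffusion_schedule(n_steps, beta_start = min(1e-4 * scale, 0.5),
                     beta_end = min(0.02 * scale, 0.5))
}

check_t <- function(t, sched, len = NULL) {
  if (any(!is.finite(t)) || any(t < 1) || any(t > sched$n_steps) ||
      any(t != round(t)))
    stop("timestep 't' out of range [1, T]")
  if (!is.null(len) && !(length(t) %in% c(1L, len)))
    stop("'t' must be scalar or one value per sample")
  as.integer(t)
}
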