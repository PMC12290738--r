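# Independent reference implementations used as oracles.

# 1-D conjugate-Gaussian posterior q(x_{t-1} | x_t, x0_hat): the product of
# the single-step kernel N(x_t; sqrt(alpha_t) x_{t-1}, beta_t) and the
# closed-form marginal N(x_{t-1}; sqrt(alpha_bar_{t-1}) x0, 1 - alpha_bar_{t-1}),
# derived by completing the square (alpha_bar_0 = 1).
conjugate_posterior_1d <- function(x_t, x0, t, sched) {
  a <- sched$alpha[t]
  b <- sched$beta[t]
  ab_prev <- if (t == 1L) 1 else sched$alpha_bar[t - 1L]
  prior_var <- 1 - ab_prev
  if (prior_var == 0) return(list(mean = sqrt(ab_prev) * x0, var = 0))
  prec <- a / b + 1 / prior_var
  mean <- (sqrt(a) * x_t / b + sqrt(ab_prev) * x0 / prior_var) / prec
  list(mean = mean, var = 1 / prec)
}

# scalar SSIM for constant-within-window images (variances and covariance
# vanish, leaving the luminance term)
ssim_constant_scalar <- function(mx, my, data_range = 1, K1 = 0.01, K2 = 0.03) {
  C1 <- (K1 * data_range)^2
  (2 * mx * my + C1) / (mx^2 + my^2 + C1)
}

# tiny cohort used by several pipeline tests: 16^3, fast to generate/train on
tiny_cohort <- function(n_subjects = 4, n_visits = 5, noise_sd = 0.02,
                        seed = 3, rho = 0.95) {
  generate_cohort(cohort_spec(n_subjects = n_subjects, n_visits = n_visits,
                              shape = c(16, 16, 16), rho = rho,
                              noise_sd = noise_sd), seed = seed)
}

tiny_layout <- function() unit_layout(16, 16, 16, K = 2, J = 1)

# denoiser spec small enough for gradient checks and short training runs
tiny_net_spec <- function(in_ch, out_ch, HW = 16L)
  denoiser_spec(in_ch, out_ch, HW, HW, base_channels = 8L, depth = 2L,
                groups = 4L, time_embed_dim = 16L)

# perturb every parameter so zero-initialised closing layers do not silence
# gradient or time-sensitivity checks
jitter_params <- function(model, sd = 0.05) {
  model$params <- diffimpute:::tree_map2(
    function(p, q) p + stats::rnorm(length(p), sd = sd),
    model$params, model$params)
  model
}
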