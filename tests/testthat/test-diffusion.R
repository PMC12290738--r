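test_that("closed-form forward sampling matches its definition", {
  s2 <- diffusion_schedule(2, 0.1, 0.2)
  x0 <- array(rnorm(24), c(2, 3, 4))
  z <- array(0, dim(x0))
  expect_equal(forward_sample(x0, 2, z, s2),
               sqrt(0.72) * x0, ignore_attr = TRUE)
  eps <- array(rnorm(24), dim(x0))
  expect_equal(forward_sample(z, 2, eps, s2),
               sqrt(1 - 0.72) * eps, ignore_attr = TRUE)
  # scalar arithmetic case
  expect_equal(as.numeric(forward_sample(1, 2, 1, s2)),
               sqrt(0.72) + sqrt(0.28), tolerance = 1e-12)
  expect_error(forward_sample(x0, 3, eps, s2), "out of range")
  expect_error(forward_sample(x0, 1, rnorm(5), s2), "shaped like")
})

test_that("single-step kernel is sqrt(1-beta_t) x + sqrt(beta_t) noise", {
  s <- diffusion_schedule(2, 0.1, 0.19)
  expect_equal(as.numeric(forward_step(2, 2, 0, s)), sqrt(0.81) * 2)
  # beta -> 0 limit: the kernel degenerates to the identity
  s0 <- diffusion_schedule(1, 1e-12, 1e-12)
  expect_equal(as.numeric(forward_step(1.5, 1, 1, s0)), 1.5,
               tolerance = 1e-5)
})

test_that("iterated single steps reproduce the closed-form moments", {
  # Monte-Carlo oracle: 1e5 scalar trajectories through t = 50 steps
  sched <- diffusion_schedule(50, 1e-4, 0.02)
  set.seed(101)
  n <- 1e5
  x <- rep(1, n)
  for (t in 1:50) x <- forward_step(x, t, rnorm(n), sched)
  ab <- sched$alpha_bar[50]
  mu_th <- sqrt(ab) * 1
  var_th <- 1 - ab
  se_mu <- sd(x) / sqrt(n)
  se_var <- var_th * sqrt(2 / (n - 1))
  expect_lt(abs(mean(x) - mu_th), 3 * se_mu)
  expect_lt(abs(var(x) - var_th), 3 * se_var)
})

test_that("x0 estimation exactly inverts forward sampling", {
  sched <- diffusion_schedule(40, 1e-3, 0.3)
  set.seed(7)
  for (i in 1:25) {
    x0 <- array(rnorm(60, sd = 2), c(5, 4, 3))
    eps <- array(rnorm(60), c(5, 4, 3))
    t <- sample(40, 1)
    xt <- forward_sample(x0, t, eps, sched)
    expect_equal(estimate_x0(xt, t, eps, sched), x0, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  # eps_pred = 0 reduces to rescaling
  xt <- array(1, c(2, 2, 1))
  expect_equal(estimate_x0(xt, 3, xt * 0, sched),
               xt / sqrt(sched$alpha_bar[3]), ignore_attr = TRUE)
})

test_that("posterior parameters match the conjugate-Gaussian derivation", {
  sched <- diffusion_schedule(30, 5e-3, 0.25)
  grid <- expand.grid(x_t = seq(-2, 2, length.out = 5),
                      x0 = seq(-1.5, 1.5, length.out = 5),
                      t = c(1L, 2L, 7L, 15L, 30L))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    # choose eps_pred so that estimate_x0 returns exactly g$x0
    ab <- sched$alpha_bar[g$t]
    eps_pred <- (g$x_t - sqrt(ab) * g$x0) / sqrt(1 - ab)
    pp <- posterior_params(g$x_t, g$t, eps_pred, sched)
    or <- conjugate_posterior_1d(g$x_t, g$x0, g$t, sched)
    expect_equal(as.numeric(pp$mean), or$mean, tolerance = 1e-8)
    expect_equal(pp$var, or$var, tolerance = 1e-8)
  }
})

test_that("the final reverse step is deterministic and returns x0_hat", {
  sched <- diffusion_schedule(10, 1e-3, 0.2)
  x1 <- array(rnorm(8), c(2, 2, 2))
  eps_pred <- array(rnorm(8), c(2, 2, 2))
  pp <- posterior_params(x1, 1, eps_pred, sched)
  expect_equal(pp$var, 0)
  expect_equal(pp$mean, estimate_x0(x1, 1, eps_pred, sched),
               ignore_attr = TRUE)
  # via denoise_step with a model function returning the fixed prediction
  model <- function(input, t) eps_pred
  cond <- array(0, c(2, 2, 2))
  out <- denoise_step(x1, 1, model, cond, sched)
  expect_equal(out, pp$mean, ignore_attr = TRUE)
})

test_that("reverse sampling is reproducible under a fixed seed", {
  sched <- diffusion_schedule(5, 0.05, 0.3)
  model <- function(input, t) input[, , 1:2, drop = FALSE] * 0.1
  x <- array(rnorm(8), c(2, 2, 2))
  cond <- array(0.5, c(2, 2, 2))
  set.seed(42); a <- denoise_step(x, 4, model, cond, sched)
  set.seed(42); b <- denoise_step(x, 4, model, cond, sched)
  expect_identical(a, b)
})

test_that("a one-step sampler with a zero model rescales pure noise", {
  # at T = 1 the sampler collapses to estimate_x0 on the initial noise
  lay <- unit_layout(6, 4, 4, K = 1, J = 1)   # 3-slice units, 2 per volume
  s1 <- diffusion_schedule(1, 0.1, 0.1)
  zero_model <- function(input, t) {
    d <- dim(input)                       # batched input: H x W x 2C x N
    array(0, dim = c(d[1], d[2], d[3] %/% 2L, d[4]))
  }
  cond <- list(array(0.3, c(6, 4, 4)))
  set.seed(9)
  vol <- sample_volume(zero_model, cond, lay, s1, x0_clip = NULL)
  set.seed(9)
  noise_units <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  gus <- generation_units(lay)
  expected <- array(NA_real_, c(6, 4, 4))
  for (i in 1:2) for (j in 1:3)
    expected[gus[[i]]$indices[j], , ] <- noise_units[, , j, i] / sqrt(0.9)
  expect_equal(vol, expected)
  expect_equal(dim(vol), c(6L, 4L, 4L))
})

test_that("training loss is the mean squared noise-prediction error", {
  sched <- diffusion_schedule(10, 1e-3, 0.2)
  x0 <- array(runif(32), c(4, 4, 2))
  cond <- array(runif(32), c(4, 4, 2))
  eps <- array(rnorm(32), c(4, 4, 2))
  oracle <- function(input, t) eps
  expect_equal(training_loss(oracle, x0, cond, 4, eps, sched), 0)
  zero <- function(input, t) eps * 0
  expect_equal(training_loss(zero, x0, cond, 4, eps, sched), mean(eps^2))
  expect_gte(training_loss(function(input, t) eps + 0.1, x0, cond, 4, eps,
                           sched), 0)
})

test_that("zero-model loss averages to one over noise draws", {
  # E ||eps||^2 / d = 1 for standard normal noise
  sched <- diffusion_schedule(10, 1e-3, 0.2)
  x0 <- array(0.5, c(4, 4, 2))
  cond <- x0
  zero <- function(input, t) x0 * 0
  set.seed(11)
  losses <- replicate(300, training_loss(
    zero, x0, cond, sample(10, 1), array(rnorm(32), c(4, 4, 2)), sched))
  expect_equal(mean(losses), 1, tolerance = 0.05)
})
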