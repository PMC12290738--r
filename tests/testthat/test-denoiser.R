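test_that("channel accounting follows the layout and conditioning kind", {
  lay <- unit_layout(32, 16, 16, K = 5, J = 1)
  sp <- denoiser_preset("tiny", lay, conditioning = "p")
  expect_equal(sp$in_channels, 30L)      # (1 + 1) * K(2J+1)
  expect_equal(sp$out_channels, 15L)
  sf <- denoiser_preset("tiny", lay, conditioning = "pf")
  expect_equal(sf$in_channels, 45L)      # (1 + 2) * K(2J+1)
  sa <- denoiser_preset("tiny", lay, conditioning = "pf", ae = TRUE)
  expect_equal(sa$in_channels, 30L)      # conditions only, no noisy target
  # reference presets carry the published channel multipliers
  expect_equal(denoiser_preset("reference-p", lay, "p")$base_channels, 64L)
  expect_equal(denoiser_preset("reference-pf", lay, "pf")$base_channels, 128L)
})

test_that("invalid network shapes are rejected", {
  expect_error(denoiser_spec(4, 2, 10, 10, depth = 3), "divisible")
  expect_error(denoiser_spec(0, 2, 16, 16), "positive")
  sp <- denoiser_spec(4, 2, 16, 16, base_channels = 8, groups = 4,
                      time_embed_dim = 16)
  m <- build_denoiser(sp)
  expect_error(denoiser_predict(m, array(0, c(16, 16, 5)), 1), "channels")
  expect_error(denoiser_predict(m, array(0, c(8, 8, 4)), 1), "spatial")
})

test_that("prediction has the unit shape and is deterministic in the seed", {
  sp <- tiny_net_spec(6L, 2L)
  set.seed(31); m1 <- build_denoiser(sp)
  set.seed(31); m2 <- build_denoiser(sp)
  x <- array(rnorm(16 * 16 * 6), c(16, 16, 6))
  expect_identical(denoiser_predict(m1, x, 3), denoiser_predict(m2, x, 3))
  out <- denoiser_predict(m1, x, 3)
  expect_equal(dim(out), c(16L, 16L, 2L))
  expect_true(all(is.finite(out)))
  xb <- array(rnorm(16 * 16 * 6 * 3), c(16, 16, 6, 3))
  expect_equal(dim(denoiser_predict(m1, xb, c(1, 5, 9))), c(16L, 16L, 2L, 3L))
})

test_that("predictions depend on the timestep embedding", {
  set.seed(8)
  m <- jitter_params(build_denoiser(tiny_net_spec(6L, 2L)))
  x <- array(rnorm(16 * 16 * 6), c(16, 16, 6))
  p1 <- denoiser_predict(m, x, 1)
  pT <- denoiser_predict(m, x, 20)
  expect_gt(max(abs(p1 - pT)), 1e-6)
})

test_that("analytic gradients match central finite differences", {
  set.seed(14)
  spec <- denoiser_spec(6L, 2L, 8L, 8L, base_channels = 8L, depth = 2L,
                        groups = 4L, time_embed_dim = 8L)
  m <- jitter_params(build_denoiser(spec))
  x <- array(rnorm(8 * 8 * 6 * 2), c(8, 8, 6, 2))
  tt <- c(3, 7)
  tgt <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  loss_of <- function(params) {
    out <- diffimpute:::unet_fw(params, spec, x, tt)$out
    mean((out - tgt)^2)
  }
  fw <- diffimpute:::unet_fw(m$params, spec, x, tt)
  dout <- 2 * (fw$out - tgt) / length(tgt)
  gr <- diffimpute:::unet_bw(m$params, spec, fw$cache, dout)$grads

  leaves <- list(c("conv_in", "W"), c("tmlp1", "W"), c("gn_out", "gamma"),
                 c("conv_out", "b"))
  get_leaf <- function(tree, path) {
    for (k in path) tree <- tree[[k]]
    tree
  }
  for (path in leaves) {
    lp <- get_leaf(m$params, path)
    lg <- get_leaf(gr, path)
    i <- which.max(abs(lg))            # check the most informative entry
    h <- 1e-5
    bump <- function(delta) {
      p2 <- m$params
      leaf <- get_leaf(p2, path)
      leaf[i] <- leaf[i] + delta
      if (length(path) == 2) p2[[path[1]]][[path[2]]] <- leaf
      p2
    }
    num <- (loss_of(bump(h)) - loss_of(bump(-h))) / (2 * h)
    expect_equal(lg[i], num, tolerance = 1e-4)
  }
  # deeper leaves: attention and residual-block parameters
  assign_at <- function(params, path, i, delta) {
    ref <- paste(sprintf("[['%s']]", path), collapse = "")
    eval(parse(text = sprintf("params%s[i] <- params%s[i] + delta",
                              ref, ref)))
    params
  }
  deep <- list(c("mid", "attn", "Wq"),
               c("mid", "res1", "conv1", "W"),
               c("mid", "res1", "temb", "W"))
  for (path in deep) {
    lg <- get_leaf(gr, path)
    i <- which.max(abs(lg))
    h <- 1e-5
    num <- (loss_of(assign_at(m$params, path, i, h)) -
              loss_of(assign_at(m$params, path, i, -h))) / (2 * h)
    expect_equal(lg[i], num, tolerance = 1e-4)
  }
})

test_that("a tiny network overfits one subject below the zero-model loss", {
  # zero-prediction baseline loss is E||eps||^2/d = 1; a trained denoiser
  # must do substantially better on a single repeated phantom
  coh <- tiny_cohort(n_subjects = 1, noise_sd = 0.01)
  coh <- apply_missingness(coh, "pf")
  lay <- tiny_layout()
  fit <- diffimpute(coh, method = "ddpm", conditioning = "pf", layout = lay,
                    schedule = tiny_schedule(20),
                    network = denoiser_preset("tiny", lay, "pf"),
                    control = train_control(lr = 1e-3, batch_size = 4,
                                            max_steps = 400, log_every = 50),
                    seed = 2)
  late <- mean(utils::tail(fit$loss_history$loss, 2))
  early <- fit$loss_history$loss[1]
  expect_lt(late, 0.8)
  expect_lt(late, early)
})
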