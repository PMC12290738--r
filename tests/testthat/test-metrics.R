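test_that("SSIM is 1 for identical volumes, symmetric, and mask-local", {
  set.seed(3)
  x <- array(runif(16^3), c(16, 16, 16))
  y <- array(runif(16^3), c(16, 16, 16))
  mask <- array(FALSE, c(16, 16, 16)); mask[8:12, 8:12, 8:12] <- TRUE
  expect_equal(ssim_masked(x, x, mask), 1)
  expect_equal(ssim_masked(x, y, mask), ssim_masked(y, x, mask))
  # content outside the mask cannot change the score when it lies beyond the
  # Gaussian window radius (5) of every mask voxel
  y2 <- y
  y2[1, 1, 1] <- 9
  expect_equal(ssim_masked(x, y, mask), ssim_masked(x, y2, mask))
  expect_error(ssim_masked(x, y, mask * 0), "empty mask")
  expect_error(ssim_masked(x, y[1:8, , ], mask), "shape|dims")
})

test_that("constant-image SSIM equals the scalar luminance term", {
  mask <- array(TRUE, c(12, 12, 12))
  x <- array(0.4, c(12, 12, 12))
  y <- array(0.4 + 0.5, c(12, 12, 12))   # offset data_range / 2
  expect_equal(ssim_masked(x, y, mask, data_range = 1),
               ssim_constant_scalar(0.4, 0.9), tolerance = 1e-10)
})

test_that("one-voxel-window SSIM matches the direct per-voxel formula", {
  set.seed(8)
  x <- array(runif(5^3), c(5, 5, 5))
  y <- array(runif(5^3), c(5, 5, 5))
  mask <- array(TRUE, c(5, 5, 5))
  C1 <- 1e-4; C2 <- 9e-4
  direct <- mean((2 * x * y + C1) / (x^2 + y^2 + C1))
  expect_equal(ssim_masked(x, y, mask, size = 1), direct, tolerance = 1e-6)
})

test_that("PSNR follows its closed form in the masked MSE", {
  x <- array(0, c(8, 8, 8))
  y <- array(0.5, c(8, 8, 8))            # masked MSE 0.25
  mask <- array(TRUE, c(8, 8, 8))
  expect_equal(psnr_masked(x, y, mask, data_range = 1), 20 * log10(1 / 0.5),
               tolerance = 1e-10)
  expect_equal(psnr_masked(x, y, mask), 6.0206, tolerance = 1e-4)
  expect_identical(psnr_masked(x, x, mask), Inf)
  # halving the MSE raises PSNR by 10 log10(2) ~ 3.0103 dB
  y2 <- array(0.5 / sqrt(2), c(8, 8, 8))
  expect_equal(psnr_masked(x, y2, mask) - psnr_masked(x, y, mask),
               10 * log10(2), tolerance = 1e-10)
})

test_that("region volumes count labelled voxels times the voxel volume", {
  lab <- array(0L, c(10, 10, 10))
  lab[1:4, 1:5, 1:5] <- 3L
  expect_equal(region_volumes(lab), c(`3` = 100))
  expect_equal(region_volumes(lab, voxel_volume = 2), c(`3` = 200))
  expect_error(region_volumes(lab * 0L), "no non-zero")
  # rasterised ellipsoid volume matches the analytic value within 5% at 32^3
  m <- diffimpute:::ellipsoid_mask(c(32, 32, 32), c(16.5, 16.5, 16.5),
                                   c(10, 8, 6))
  expect_equal(sum(m), 4 / 3 * pi * 10 * 8 * 6, tolerance = 0.05)
})

test_that("error and progression rates are relative and scale-invariant", {
  obs <- c(a = 100, b = 200)
  expect_equal(error_rate(c(a = 100, b = 200), obs), c(a = 0, b = 0))
  expect_equal(error_rate(c(a = 90, b = 220), obs), c(a = 0.1, b = 0.1))
  expect_equal(error_rate(c(a = 110, b = 180), obs), c(a = 0.1, b = 0.1))
  expect_equal(error_rate(3 * c(a = 90, b = 220), 3 * obs),
               error_rate(c(a = 90, b = 220), obs))
  expect_equal(progression_rate(c(a = 95), c(a = 100)), c(a = 0.05))
  expect_equal(progression_rate(c(a = 100), c(a = 100)), c(a = 0))
  expect_equal(abs(progression_rate(c(a = 105), c(a = 100)) -
                     progression_rate(c(a = 104), c(a = 100))),
               c(a = 0.01), tolerance = 1e-12)
  expect_error(error_rate(c(a = 1), c(b = 1)), "cover")
})

test_that("annualized atrophy scenarios behave as the trajectories dictate", {
  regions <- c("r1", "r2")
  subj <- 1:3
  lin <- expand.grid(subject = subj, visit = 1:3, region = regions)
  v0 <- ifelse(lin$region == "r1", 1000, 500)
  k <- ifelse(lin$region == "r1", 30, 10)          # linear decline per visit
  lin$volume <- v0 - k * (lin$visit - 1)
  out <- annualized_atrophy_comparison(lin)
  expect_equal(out$dev_doubled, rep(0, nrow(out)), tolerance = 1e-12)

  # oracle imputation reproduces the complete-data rate exactly
  imp <- lin[lin$visit == 3, c("subject", "region", "volume")]
  out2 <- annualized_atrophy_comparison(lin, imputed = imp)
  expect_equal(out2$dev_imputed, rep(0, nrow(out2)), tolerance = 1e-12)

  # exponential decline: doubling the 6-month rate overestimates atrophy
  expo <- lin
  expo$volume <- v0 * 0.9^(expo$visit - 1)
  out3 <- annualized_atrophy_comparison(expo,
    imputed = expo[expo$visit == 3, c("subject", "region", "volume")])
  expect_true(all(out3$dev_doubled > 0))
  expect_equal(out3$dev_imputed, rep(0, nrow(out3)), tolerance = 1e-12)
  expect_error(annualized_atrophy_comparison(lin[lin$visit < 3, ]), "cover")
})

test_that("aggregation averages regions within subject before subjects", {
  rep1 <- data.frame(imputer = "m", subject = 1, visit = 2, region = "a",
                     metric = "error_rate", value = 0.9)
  expect_equal(aggregate_report(rep1)$sd, 0)
  rep2 <- rbind(rep1,
                data.frame(imputer = "m", subject = 2, visit = 2,
                           region = "a", metric = "error_rate", value = 1.0))
  agg <- aggregate_report(rep2)
  expect_equal(agg$mean, 0.95)
  expect_equal(aggregate_report(rep2[2:1, ])$mean, agg$mean)
  # within-subject averaging over regions first
  rep3 <- rbind(rep1,
                data.frame(imputer = "m", subject = 1, visit = 2,
                           region = c("b", "c"), metric = "error_rate",
                           value = c(0.1, 0.2)),
                data.frame(imputer = "m", subject = 2, visit = 2,
                           region = "a", metric = "error_rate", value = 0.6))
  agg3 <- aggregate_report(rep3)
  expect_equal(agg3$mean, mean(c(mean(c(0.9, 0.1, 0.2)), 0.6)))
})
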