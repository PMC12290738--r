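# Masked image-similarity metrics and regional volumetrics.

gauss_kernel <- function(sigma, size) {
  r <- (size - 1) %/% 2
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  g / sum(g)
}

# Separable Gaussian filtering along each axis of a 3D array.  Edge rows of
# the convolution matrix are renormalised so weights always sum to one.
gaussian_filter3 <- function(vol, sigma = 1.5, size = NULL) {
  d <- dim(vol)
  if (is.null(size)) size <- min(11L, 2L * floor((min(d) - 1) / 2) + 1L)
  if (size %% 2 == 0) stop("'size' must be odd")
  r <- (size - 1L) %/% 2L
  g <- gauss_kernel(sigma, size)
  conv_mat <- function(n) {
    G <- matrix(0, n, n)
    for (o in -r:r) {
      i <- seq_len(n)
      j <- i + o
      ok <- j >= 1 & j <= n
      G[cbind(i[ok], j[ok])] <- g[o + r + 1]
    }
    G / rowSums(G)
  }
  x <- vol
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    x <- aperm(x, perm)
    dp <- dim(x)
    dim(x) <- c(dp[1], dp[2] * dp[3])
    x <- conv_mat(dp[1]) %*% x
    dim(x) <- dp
    x <- aperm(x, order(perm))
  }
  x
}

#' Masked structural similarity (SSIM) of two volumes
#'
#' Standard SSIM combining luminance, contrast, and structure terms, computed
#' voxelwise with a 3D Gaussian window (sigma 1.5, size 11 or the largest odd
#' size fitting the volume) and averaged over the mask voxels only, so the
#' score is invariant to content outside the mask (e.g. skull or background).
#' Returns 1 for identical volumes; the range is [-1, 1].
#'
#' @param x,y volumes of identical shape.
#' @param mask logical/0-1 volume of the same shape; metric voxels.
#' @param data_range dynamic range of the data (1 for min-max normalised
#'   images).
#' @param sigma,size Gaussian window parameters.
#' @param K1,K2 SSIM stabilisation constants.
#' @return Scalar SSIM.
#' @export
ssim_masked <- function(x, y, mask = NULL, data_range = 1, sigma = 1.5,
                        size = NULL, K1 = 0.01, K2 = 0.03) {
  if (!all(dim(x) == dim(y))) stop("'x' and 'y' must have the same shape")
  if (data_range <= 0) stop("'data_range' must be positive")
  if (is.null(mask)) mask <- array(TRUE, dim = dim(x))
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  f <- function(v) gaussian_filter3(v, sigma = sigma, size = size)
  mu_x <- f(x); mu_y <- f(y)
  var_x <- pmax(f(x * x) - mu_x^2, 0)
  var_y <- pmax(f(y * y) - mu_y^2, 0)
  cov_xy <- f(x * y) - mu_x * mu_y
  num <- (2 * mu_x * mu_y + C1) * (2 * cov_xy + C2)
  den <- (mu_x^2 + mu_y^2 + C1) * (var_x + var_y + C2)
  mean((num / den)[mask])
}

#' Masked peak signal-to-noise ratio in decibels
#'
#' \eqn{20 \log_{10}(\mathrm{range}) - 10 \log_{10}(\mathrm{MSE})} with the
#' mean squared error taken over mask voxels.  Identical inputs give
#' \code{Inf}.
#'
#' @inheritParams ssim_masked
#' @return Scalar PSNR in dB (\code{Inf} for identical masked content).
#' @export
psnr_masked <- function(x, y, mask = NULL, data_range = 1) {
  mse <- mse_masked(x, y, mask)
  if (mse == 0) return(Inf)
  20 * log10(data_range) - 10 * log10(mse)
}

#' Masked mean squared error
#'
#' @inheritParams ssim_masked
#' @return Scalar mean squared error over mask voxels.
#' @export
mse_masked <- function(x, y, mask = NULL) {
  if (!all(dim(x) == dim(y))) stop("'x' and 'y' must have the same shape")
  if (is.null(mask)) mask <- array(TRUE, dim = dim(x))
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  mean((x[mask] - y[mask])^2)
}

#' Regional volumes from a label map
#'
#' @param labelmap integer volume; 0 is background, positive labels are
#'   regions.
#' @param voxel_volume physical volume of one voxel in mm^3.
#' @return Named numeric vector of volumes (mm^3) per label.
#' @export
region_volumes <- function(labelmap, voxel_volume = 1) {
  labs <- sort(unique(labelmap[labelmap > 0]))
  if (length(labs) == 0) stop("label map has no non-zero labels")
  stats::setNames(vapply(labs, function(l) sum(labelmap == l) * voxel_volume,
                         0), as.character(labs))
}

#' Regional volumes from an intensity image by nearest-class labelling
#'
#' A synthetic stand-in for an external segmentation pipeline: every voxel
#' inside the mask is assigned to the nominal intensity class (tissue or one
#' of the labelled regions) nearest to its value, and region volumes are
#' voxel counts times the voxel volume.  Suitable for phantoms whose class
#' intensities are well separated; real images require a proper segmentation
#' whose volume tables can be imported instead.
#'
#' @param image intensity volume in [0, 1].
#' @param mask logical volume restricting the labelling.
#' @param intensities named vector of class intensities; the first entry is
#'   treated as unlabelled tissue, the rest as regions.
#' @param voxel_volume physical volume of one voxel in mm^3.
#' @return Named numeric vector of region volumes (mm^3).
#' @export
region_volumes_from_image <- function(image, mask, intensities,
                                      voxel_volume = 1) {
  v <- image[mask > 0]
  cls <- apply(abs(outer(v, intensities, `-`)), 1, which.min)
  out <- vapply(seq_along(intensities)[-1], function(i)
    sum(cls == i) * voxel_volume, 0)
  stats::setNames(out, names(intensities)[-1])
}

#' Regional volume error rate
#'
#' \eqn{|\hat y - y| / y} per region: the relative disagreement between the
#' volume measured on an imputed image and on the observed image.
#'
#' @param imputed,observed named vectors of regional volumes over the same
#'   region set.
#' @return Named vector of per-region error rates.
#' @export
error_rate <- function(imputed, observed) {
  observed <- observed[names(imputed)]
  if (any(is.na(observed)) || any(observed <= 0))
    stop("'observed' must cover the regions of 'imputed' with positive volumes")
  abs(imputed - observed) / observed
}

#' Regional volume progression rate
#'
#' \eqn{|v_i - v_{i-1}| / v_{i-1}}: the relative regional volume change
#' between adjacent visits.  Computed with an imputed current volume it
#' measures imputed atrophy; its absolute difference from the observed rate
#' (the progression gap) measures atrophy-tracking fidelity.
#'
#' @param current,previous named vectors of regional volumes.
#' @return Named vector of per-region progression rates.
#' @export
progression_rate <- function(current, previous) {
  previous <- previous[names(current)]
  if (any(is.na(previous)) || any(previous <= 0))
    stop("'previous' must cover the regions of 'current' with positive volumes")
  abs(current - previous) / previous
}

#' Annualized atrophy rates under three missing-data scenarios
#'
#' Per subject and region, compares 1-year (two-interval) atrophy rates:
#' scenario 1 uses complete data (baseline and 12-month volumes); scenario 2
#' doubles the 6-month rate (linear extrapolation, as if the 12-month visit
#' were missing); scenario 3 substitutes the imputed 12-month volume.  For
#' volume trajectories linear in time, scenario 2 matches scenario 1 exactly;
#' under non-linear (e.g. exponential) atrophy it does not, while an accurate
#' imputation keeps scenario 3 close to scenario 1.
#'
#' @param volumes data frame with columns \code{subject}, \code{visit},
#'   \code{region}, \code{volume}: observed volumes at the baseline visit and
#'   the two following visits.
#' @param imputed optional data frame with columns \code{subject},
#'   \code{region}, \code{volume}: imputed volumes at the 12-month visit.
#' @param baseline_visit visit number of the baseline.
#' @return Data frame with one row per subject x region: the three rates and
#'   the absolute deviations of scenarios 2 and 3 from scenario 1.
#' @export
annualized_atrophy_comparison <- function(volumes, imputed = NULL,
                                          baseline_visit = 1L) {
  need <- baseline_visit + 0:2
  if (!all(need %in% volumes$visit))
    stop("volumes must cover the baseline, 6-month, and 12-month visits")
  v0 <- volumes[volumes$visit == need[1], ]
  v6 <- volumes[volumes$visit == need[2], ]
  v12 <- volumes[volumes$visit == need[3], ]
  key <- function(d) paste(d$subject, d$region)
  v6 <- v6[match(key(v0), key(v6)), ]
  v12 <- v12[match(key(v0), key(v12)), ]
  out <- data.frame(subject = v0$subject, region = v0$region,
                    rate_complete = abs(v12$volume - v0$volume) / v0$volume,
                    rate_doubled6mo = 2 * abs(v6$volume - v0$volume) / v0$volume)
  out$dev_doubled <- abs(out$rate_doubled6mo - out$rate_complete)
  if (!is.null(imputed)) {
    im <- imputed[match(key(v0), paste(imputed$subject, imputed$region)), ]
    out$rate_imputed <- abs(im$volume - v0$volume) / v0$volume
    out$dev_imputed <- abs(out$rate_imputed - out$rate_complete)
  }
  out
}

#' Read or write a regional volume table
#'
#' The canonical exchange format for volumes measured by external
#' segmentation pipelines: tab-separated text with columns \code{subject},
#' \code{visit}, \code{region}, \code{volume} (mm^3).
#'
#' @param path file path.
#' @param volumes data frame with the four canonical columns.
#' @return \code{read_volume_table} returns the data frame;
#'   \code{write_volume_table} returns \code{path} invisibly.
#' @export
read_volume_table <- function(path) {
  v <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("subject", "visit", "region", "volume")
  if (!all(need %in% names(v)))
    stop("volume table must have columns subject, visit, region, volume")
  v
}

#' @rdname read_volume_table
#' @export
write_volume_table <- function(volumes, path) {
  utils::write.table(volumes, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Aggregate a tidy metric table into mean +/- sd summaries
#'
#' Regional metrics are first averaged across regions within subject, then
#' mean and standard deviation are taken across subjects; when a \code{fold}
#' column is present, subject means are further averaged within fold and the
#' spread is across folds.
#'
#' @param report data frame with columns \code{metric}, \code{value},
#'   \code{subject}, and optionally \code{region}, \code{fold},
#'   \code{imputer}.
#' @return Data frame with columns \code{imputer} (if present),
#'   \code{metric}, \code{mean}, \code{sd}, \code{n}.
#' @export
aggregate_report <- function(report) {
  stopifnot(all(c("metric", "value", "subject") %in% names(report)))
  grp_cols <- intersect(c("imputer", "metric"), names(report))
  split_by <- interaction(report[grp_cols], drop = TRUE)
  res <- lapply(split(report, split_by), function(d) {
    per_subj <- tapply(d$value, d$subject, mean)   # regions -> subject mean
    if ("fold" %in% names(d) && length(unique(d$fold)) > 1) {
      sub_fold <- unique(d[c("subject", "fold")])
      fold_of <- stats::setNames(sub_fold$fold, sub_fold$subject)
      per_unit <- tapply(per_subj, fold_of[names(per_subj)], mean)
    } else per_unit <- per_subj
    out <- d[1, grp_cols, drop = FALSE]
    out$mean <- mean(per_unit)
    out$sd <- if (length(per_unit) > 1) stats::sd(per_unit) else 0
    out$n <- length(per_unit)
    out
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res
}
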