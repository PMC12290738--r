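#' Specification of a synthetic longitudinal brain-phantom cohort
#'
#' Phantoms emulate the data regime of a fixed-interval longitudinal T1
#' study: per subject, a brain-shaped ellipsoid (optionally wrapped in a
#' bright skull shell) containing a small set of ellipsoidal "regions" whose
#' semi-axes shrink (atrophy) or grow (ventricle-like expansion) by a fixed
#' factor per visit, plus a smooth per-subject texture field and per-visit
#' Gaussian acquisition noise.  Images are min-max normalised to [0, 1] over
#' the non-zero (head) voxels, with exactly-zero background.  Ground-truth
#' regional volumes (analytic ellipsoid volume and rasterised voxel count)
#' and per-visit label maps are recorded for volumetric evaluation.
#'
#' @param n_subjects number of subjects.
#' @param n_visits visits per subject at a nominal fixed interval.
#' @param shape volume dimensions c(L, H, W); default 32^3 desk scale.
#' @param rho per-visit semi-axis scale factor of the atrophying regions
#'   (volume scales as \code{rho^3} per visit).  The ventricle-like region
#'   expands with factor \code{2 - rho}.
#' @param noise_sd per-visit Gaussian noise sd (intensity units).
#' @param background_texture amplitude of the smooth per-subject texture.
#' @param skull_shell add a bright shell outside the brain mask.
#' @param jitter relative per-subject jitter of region geometry.
#' @param voxel_size voxel spacing in mm (length 3).
#' @param visit_interval_months nominal visit spacing; metadata only, no
#'   computation uses it.
#' @param regions optional list overriding the default three regions; each
#'   element is \code{list(name, center, semi, intensity, rho)} with
#'   \code{center}/\code{semi} in voxel units.  A region's \code{rho} may
#'   also be a vector of per-visit cumulative semi-axis factors, which allows
#'   non-geometric volume trajectories (e.g. linear in time).
#' @return An object of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(n_subjects = 24L, n_visits = 5L, shape = c(32L, 32L, 32L),
                        rho = 0.95, noise_sd = 0.02, background_texture = 0.03,
                        skull_shell = TRUE, jitter = 0.05,
                        voxel_size = c(1, 1, 1), visit_interval_months = 6,
                        regions = NULL) {
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (any(shape < 8)) stop("'shape' too small for a brain phantom")
  if (rho <= 0) stop("'rho' must be positive")
  s <- as.numeric(shape)
  if (is.null(regions)) {
    regions <- list(
      list(name = "hippocampus_like", center = s * c(0.36, 0.42, 0.40),
           semi = s * c(0.120, 0.100, 0.090), intensity = 0.80, rho = rho),
      list(name = "parahippocampal_like", center = s * c(0.66, 0.42, 0.38),
           semi = s * c(0.100, 0.090, 0.080), intensity = 0.95, rho = rho),
      list(name = "ventricle_like", center = s * c(0.50, 0.64, 0.55),
           semi = s * c(0.085, 0.115, 0.085), intensity = 0.12, rho = 2 - rho))
  }
  brain <- list(center = s * 0.5 + 0.5, semi = s * c(0.40, 0.38, 0.36),
                intensity = 0.55)
  for (r in regions) {
    rel <- (abs(r$center - brain$center) + r$semi) / brain$semi
    if (any(rel > 1)) stop(sprintf("region '%s' extends outside the brain",
                                   r$name))
    if (any(r$semi <= 0)) stop("region semi-axes must be positive")
    if (!length(r$rho) %in% c(1L, n_visits) || any(r$rho <= 0))
      stop("region 'rho' must be a positive scalar or one factor per visit")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_visits = as.integer(n_visits),
                 shape = as.integer(shape), rho = rho, noise_sd = noise_sd,
                 background_texture = background_texture,
                 skull_shell = isTRUE(skull_shell), jitter = jitter,
                 voxel_size = as.numeric(voxel_size),
                 visit_interval_months = visit_interval_months,
                 brain = brain, regions = regions),
            class = "cohort_spec")
}

# cumulative semi-axis scale at a visit: scalar rho means geometric decline
# rho^(v-1); a vector gives the per-visit cumulative factors directly (e.g.
# (1 - k (v-1))^(1/3) for volume trajectories linear in time)
region_scale <- function(rho, v) {
  if (length(rho) == 1L) rho^(v - 1) else rho[v]
}

ellipsoid_mask <- function(shape, center, semi) {
  gx <- (seq_len(shape[1]) - center[1]) / semi[1]
  gy <- (seq_len(shape[2]) - center[2]) / semi[2]
  gz <- (seq_len(shape[3]) - center[3]) / semi[3]
  d2 <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
  d2 <= 1
}

smooth_field <- function(shape, sigma = 2) {
  x <- array(stats::rnorm(prod(shape)), dim = shape)
  x <- gaussian_filter3(x, sigma = sigma)
  x / stats::sd(x)
}

#' Generate a synthetic longitudinal phantom cohort
#'
#' A pure function of \code{(spec, seed)}: the same inputs always produce the
#' same cohort.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed for all randomness (geometry jitter, texture,
#'   noise).
#' @return Object of class \code{"phantom_cohort"}: list with \code{records}
#'   (one \code{"longitudinal_record"} per subject) and the \code{spec}.
#'   Each record holds \code{visits} (list of \code{image} in [0,1] and
#'   \code{existence} flag), the static brain \code{mask}, per-visit
#'   \code{labelmaps}, a \code{volumes} data frame (analytic and rasterised
#'   ground truth per region and visit), and the nominal class
#'   \code{intensities}.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_subjects = 2, n_visits = 3,
#'                                    shape = c(16, 16, 16)), seed = 1)
#' coh$records[[1]]$volumes[1:3, ]
#' @export
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  shape <- spec$shape
  records <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    jit <- function(x, rel) x * (1 + stats::runif(length(x), -rel, rel))
    brain_c <- spec$brain$center + stats::runif(3, -0.5, 0.5)
    brain_s <- jit(spec$brain$semi, spec$jitter / 2)
    regs <- lapply(spec$regions, function(r) {
      r$center <- r$center + stats::runif(3, -0.5, 0.5)
      r$semi <- jit(r$semi, spec$jitter)
      r
    })
    brain <- ellipsoid_mask(shape, brain_c, brain_s)
    skull <- if (spec$skull_shell)
      ellipsoid_mask(shape, brain_c, brain_s * 1.12) &
        !ellipsoid_mask(shape, brain_c, brain_s * 1.04) else
      array(FALSE, dim = shape)
    texture <- smooth_field(shape) * spec$background_texture
    visits <- vector("list", spec$n_visits)
    labelmaps <- vector("list", spec$n_visits)
    vols <- NULL
    for (v in seq_len(spec$n_visits)) {
      img <- array(0, dim = shape)
      img[brain] <- spec$brain$intensity
      img[skull] <- 0.85
      lab <- array(0L, dim = shape)
      for (i in seq_along(regs)) {
        r <- regs[[i]]
        semi_v <- r$semi * region_scale(r$rho, v)
        rm <- ellipsoid_mask(shape, r$center, semi_v)
        img[rm] <- r$intensity
        lab[rm] <- i
        vols <- rbind(vols, data.frame(
          subject = s, visit = v, region = r$name,
          volume_analytic = 4 / 3 * pi * prod(semi_v) * prod(spec$voxel_size),
          volume_voxel = sum(rm) * prod(spec$voxel_size)))
      }
      support <- brain | skull
      img[support] <- img[support] + texture[support]
      if (spec$noise_sd > 0)
        img[support] <- img[support] +
          stats::rnorm(sum(support), sd = spec$noise_sd)
      img[img < 0] <- 0
      rng <- range(img[support])
      if (rng[2] > rng[1])
        img[support] <- (img[support] - rng[1]) / (rng[2] - rng[1])
      visits[[v]] <- list(image = img, existence = 1L)
      labelmaps[[v]] <- lab
    }
    intensities <- c(tissue = spec$brain$intensity,
                     stats::setNames(vapply(regs, `[[`, 0, "intensity"),
                                     vapply(regs, `[[`, "", "name")))
    records[[s]] <- structure(
      list(subject_id = s, visits = visits, mask = brain,
           labelmaps = labelmaps, volumes = vols, intensities = intensities,
           voxel_size = spec$voxel_size,
           visit_interval_months = spec$visit_interval_months),
      class = "longitudinal_record")
  }
  structure(list(records = records, spec = spec, seed = seed),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("Phantom cohort: %d subjects x %d visits, %s volume\n",
              length(x$records), x$spec$n_visits,
              paste(x$spec$shape, collapse = " x ")))
  miss <- sum(vapply(x$records, function(r)
    sum(vapply(r$visits, function(v) v$existence == 0L, TRUE)), 0L))
  cat(sprintf("  designated-missing visits: %d\n", miss))
  invisible(x)
}

#' Apply a longitudinal missingness pattern
#'
#' Pattern \code{"p"} marks every second visit as missing (imputable from
#' the past visit); pattern \code{"pf"} marks the middle visit of every
#' consecutive observed triple (imputable from past and following visits).
#' Images are retained in place as evaluation targets; only the existence
#' flags change.
#'
#' @param cohort a \code{"phantom_cohort"} (or list of records).
#' @param pattern \code{"p"} or \code{"pf"}.
#' @return The cohort with updated existence flags.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_subjects = 1, n_visits = 4,
#'                                    shape = c(16, 16, 16)), seed = 1)
#' coh <- apply_missingness(coh, "p")
#' vapply(coh$records[[1]]$visits, `[[`, 0L, "existence")  # 1 0 1 0
#' @export
apply_missingness <- function(cohort, pattern = c("p", "pf")) {
  pattern <- match.arg(pattern)
  recs <- if (inherits(cohort, "phantom_cohort")) cohort$records else cohort
  R <- length(recs[[1]]$visits)
  if (pattern == "p" && R < 2) stop("pattern 'p' needs at least 2 visits")
  if (pattern == "pf" && R < 3) stop("pattern 'pf' needs at least 3 visits")
  missing_at <- if (pattern == "p") seq(2L, R, by = 2L) else
    seq(2L, R - 1L, by = 2L)
  for (i in seq_along(recs)) {
    for (v in seq_len(R))
      recs[[i]]$visits[[v]]$existence <-
        if (v %in% missing_at) 0L else 1L
  }
  if (inherits(cohort, "phantom_cohort")) {
    cohort$records <- recs
    cohort$pattern <- pattern
    cohort
  } else recs
}

#' Write a longitudinal record to a directory of NIfTI files
#'
#' One NIfTI volume per visit plus the brain mask and per-visit label maps,
#' a JSON sidecar with subject metadata and existence flags, and the
#' ground-truth volume table as tab-separated text.
#'
#' @param record a \code{"longitudinal_record"}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_record <- function(record, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(arr, file) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- record$voxel_size
    RNifti::writeNifti(img, file.path(dir, file), datatype = "double")
  }
  for (v in seq_along(record$visits)) {
    wr(record$visits[[v]]$image, sprintf("visit_%02d.nii.gz", v))
    wr(record$labelmaps[[v]] + 0, sprintf("labelmap_%02d.nii.gz", v))
  }
  wr(record$mask + 0, "mask.nii.gz")
  meta <- list(subject_id = record$subject_id,
               existence = vapply(record$visits, `[[`, 0L, "existence"),
               intensities = as.list(record$intensities),
               voxel_size = record$voxel_size,
               visit_interval_months = record$visit_interval_months)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dir, "record.json"))
  utils::write.table(record$volumes, file.path(dir, "volumes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a longitudinal record written by [write_record()]
#'
#' @param dir directory containing the record files.
#' @return A \code{"longitudinal_record"}.
#' @export
read_record <- function(dir) {
  mf <- file.path(dir, "record.json")
  if (!file.exists(mf)) stop(sprintf("no record found in '%s'", dir))
  meta <- jsonlite::fromJSON(mf)
  nv <- length(meta$existence)
  rd <- function(file) {
    img <- RNifti::readNifti(file.path(dir, file))
    structure(as.array(img), pixdim = RNifti::pixdim(img))
  }
  visits <- vector("list", nv)
  labelmaps <- vector("list", nv)
  for (v in seq_len(nv)) {
    visits[[v]] <- list(image = unclass_arr(rd(sprintf("visit_%02d.nii.gz", v))),
                        existence = as.integer(meta$existence[v]))
    labelmaps[[v]] <- array(as.integer(
      round(rd(sprintf("labelmap_%02d.nii.gz", v)))),
      dim = dim(visits[[v]]$image))
  }
  maskf <- rd("mask.nii.gz")
  spacing <- attr(maskf, "pixdim")[1:3]
  structure(list(subject_id = meta$subject_id, visits = visits,
                 mask = unclass_arr(maskf) > 0.5,
                 labelmaps = labelmaps,
                 volumes = utils::read.table(file.path(dir, "volumes.tsv"),
                                             header = TRUE, sep = "\t"),
                 intensities = unlist(meta$intensities),
                 voxel_size = as.numeric(meta$voxel_size),
                 visit_interval_months = meta$visit_interval_months),
            class = "longitudinal_record")
}

unclass_arr <- function(x) {
  y <- as.numeric(x)
  dim(y) <- dim(x)
  y
}
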