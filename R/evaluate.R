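#' Evaluate imputed visits against retained true images
#'
#' For every imputed visit, computes masked SSIM, PSNR and MSE against the
#' retained true image, and — via nearest-intensity-class labelling of both
#' the imputed and the observed image (see [region_volumes_from_image()]) —
#' per-region volume error rates, the imputed and observed progression rates
#' relative to the previous observed visit, and their absolute difference
#' (the progression gap).
#'
#' @param imputations result of [predict.diffimpute()].
#' @param cohort the cohort holding the retained true images.
#' @param imputer label stored in the report (e.g. \code{"ddpm-pf"},
#'   \code{"naive-p"}).
#' @param fold optional fold label.
#' @return Tidy data frame with columns \code{imputer}, \code{subject},
#'   \code{visit}, \code{region} (\code{NA} for whole-image metrics),
#'   \code{metric}, \code{value} (and \code{fold} if given).  Aggregate with
#'   [aggregate_report()].
#' @export
evaluate_imputation <- function(imputations, cohort, imputer = "model",
                                fold = NULL) {
  records <- if (inherits(cohort, "phantom_cohort")) cohort$records else cohort
  recmap <- stats::setNames(seq_along(records),
                            vapply(records, `[[`, 0, "subject_id"))
  rows <- list()
  add <- function(subject, visit, region, metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      imputer = imputer, subject = subject, visit = visit, region = region,
      metric = metric, value = value)
  for (im in imputations) {
    rec <- records[[recmap[[as.character(im$subject_id)]]]]
    truth <- rec$visits[[im$visit]]$image
    mask <- rec$mask
    vv <- prod(rec$voxel_size)
    add(im$subject_id, im$visit, NA, "ssim",
        ssim_masked(im$volume, truth, mask))
    add(im$subject_id, im$visit, NA, "psnr",
        psnr_masked(im$volume, truth, mask))
    add(im$subject_id, im$visit, NA, "mse",
        mse_masked(im$volume, truth, mask))
    vol_imp <- region_volumes_from_image(im$volume, mask, rec$intensities, vv)
    vol_obs <- region_volumes_from_image(truth, mask, rec$intensities, vv)
    er <- error_rate(vol_imp, vol_obs)
    for (r in names(er)) add(im$subject_id, im$visit, r, "error_rate", er[[r]])
    if (im$visit > 1) {
      prev <- region_volumes_from_image(rec$visits[[im$visit - 1]]$image,
                                        mask, rec$intensities, vv)
      pr_imp <- progression_rate(vol_imp, prev)
      pr_obs <- progression_rate(vol_obs, prev)
      for (r in names(pr_imp)) {
        add(im$subject_id, im$visit, r, "progression_rate", pr_imp[[r]])
        add(im$subject_id, im$visit, r, "progression_gap",
            abs(pr_imp[[r]] - pr_obs[[r]]))
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(fold)) out$fold <- fold
  out
}

#' Write an evaluation report to disk
#'
#' Tab-separated per-visit table plus a JSON aggregate summary.
#'
#' @param report data frame from [evaluate_imputation()].
#' @param path output path without extension; writes \code{<path>.tsv} and
#'   \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.table(report, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  agg <- aggregate_report(report)
  writeLines(jsonlite::toJSON(agg, dataframe = "rows", digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' Cross-validation fold plan over subjects
#'
#' Randomly partitions subjects into \code{n_folds} disjoint folds.  For each
#' fold taken as the test set, the remaining subjects are split into training
#' and validation sets in an 8:1 ratio.  All visits of a subject stay
#' together.
#'
#' @param subject_ids vector of subject identifiers.
#' @param n_folds number of folds (reference protocol: 10).
#' @param seed integer seed.
#' @return Object of class \code{"fold_plan"}: list with \code{assignment}
#'   (fold per subject) and \code{folds}, a list of
#'   \code{list(train, validation, test)} subject-id vectors.
#' @export
make_folds <- function(subject_ids, n_folds = 10L, seed = 1L) {
  n <- length(subject_ids)
  if (n_folds < 2 || n_folds > n)
    stop("'n_folds' must be between 2 and the number of subjects")
  set.seed(seed)
  assignment <- sample(rep(seq_len(n_folds), length.out = n))
  folds <- lapply(seq_len(n_folds), function(k) {
    test <- subject_ids[assignment == k]
    rest <- subject_ids[assignment != k]
    rest <- sample(rest)
    n_val <- max(1L, round(length(rest) / 9))
    list(train = sort(rest[-seq_len(n_val)]),
         validation = sort(rest[seq_len(n_val)]),
         test = sort(test))
  })
  structure(list(n_folds = as.integer(n_folds),
                 assignment = stats::setNames(assignment,
                                              as.character(subject_ids)),
                 folds = folds),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("Fold plan: %d folds over %d subjects (8:1 train:validation)\n",
              x$n_folds, length(x$assignment)))
  invisible(x)
}
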