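#' Forward-fill imputation
#'
#' Predicts the missing visit to be identical to the most recent past
#' observed image (last image carried forward).  Parameter- and
#' training-free.
#'
#' @param past the past observed volume.
#' @return A copy of \code{past}.
#' @export
impute_naive_p <- function(past) {
  if (!all(is.finite(past))) stop("'past' must be finite")
  past
}

#' Adjacent-visit averaging imputation
#'
#' Predicts the missing visit as the voxelwise mean of the adjacent past and
#' following observed images.
#'
#' @param past,following volumes of identical shape.
#' @return Voxelwise \code{(past + following) / 2}.
#' @export
impute_naive_pf <- function(past, following) {
  if (!all(dim(past) == dim(following)))
    stop("'past' and 'following' must have the same shape")
  (past + following) / 2
}
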