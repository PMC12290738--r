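#' Impute missing visits of a cohort
#'
#' For every visit flagged missing whose required neighbours are observed,
#' runs the fitted imputer: ancestral diffusion sampling (\code{"ddpm"}),
#' deterministic unit-wise regression (\code{"ae"}), forward filling or
#' adjacent-visit averaging (\code{"naive"}).  Visits whose required
#' neighbours are themselves missing are skipped.
#'
#' @param object a fitted [diffimpute()] model.
#' @param newdata a \code{"phantom_cohort"} or list of records.
#' @param subjects optional record indices to impute.
#' @param seed seed for the stochastic sampler (ddpm); deterministic methods
#'   ignore it.
#' @param ... unused.
#' @return List of class \code{"diffimpute_imputations"}: one element per
#'   imputed visit with \code{subject_id}, \code{visit}, and \code{volume}.
#' @export
predict.diffimpute <- function(object, newdata, subjects = NULL, seed = 1L,
                               ...) {
  records <- if (inherits(newdata, "phantom_cohort")) newdata$records else
    newdata
  if (!is.null(subjects)) records <- records[subjects]
  set.seed(seed)
  idx <- target_index(records, object$conditioning)
  if (is.null(idx)) return(structure(list(), class = "diffimpute_imputations"))
  if (object$method != "naive") {
    dims <- dim(records[[1]]$visits[[1]]$image)
    n_cond <- if (object$conditioning == "pf") 2L else 1L
    want <- (if (object$method == "ddpm") 1L + n_cond else n_cond) *
      object$layout$K * object$layout$clip_len
    if (object$model$spec$in_channels != want)
      stop(sprintf("checkpointed network expects %d input channels, not %d",
                   object$model$spec$in_channels, want))
  }
  out <- vector("list", nrow(idx))
  for (j in seq_len(nrow(idx))) {
    rec <- records[[idx[j, 1]]]
    v <- idx[j, 2]
    cvs <- cond_volumes_for(rec, v, object$conditioning)
    vol <- switch(object$method,
      naive = if (object$conditioning == "p") impute_naive_p(cvs[[1]]) else
        impute_naive_pf(cvs[[1]], cvs[[2]]),
      ae = (ae_impute(object$model, lapply(cvs, function(v) 2 * v - 1),
                      object$layout) + 1) / 2,
      ddpm = (sample_volume(object$model, lapply(cvs, function(v) 2 * v - 1),
                            object$layout, object$schedule,
                            x0_clip = c(-1, 1)) + 1) / 2)
    out[[j]] <- list(subject_id = rec$subject_id, visit = v, volume = vol)
  }
  structure(out, class = "diffimpute_imputations")
}

# deterministic unit-wise regression over the ordered generation units
ae_impute <- function(model, cond_volumes, layout) {
  gus <- generation_units(layout)
  C <- layout$K * layout$clip_len
  nunit <- length(gus)
  cond <- array(0, dim = c(layout$H, layout$W,
                           C * length(cond_volumes), nunit))
  for (i in seq_len(nunit)) {
    cu <- lapply(cond_volumes, extract_unit, indices = gus[[i]]$indices)
    cond[, , , i] <- if (length(cu) == 1L) cu[[1]] else
      bind_channels(cu[[1]], cu[[2]])
  }
  pred <- denoiser_predict(model, cond, rep(0, nunit))
  units <- lapply(seq_len(nunit), function(i) {
    u <- array(pred[, , , i], dim = c(layout$H, layout$W, C))
    attr(u, "indices") <- gus[[i]]$indices
    u
  })
  assemble_units(units, layout)
}

#' Draw repeated stochastic imputations
#'
#' For the diffusion imputer each draw is an independent ancestral sample
#' from the learned conditional distribution of the missing image;
#' deterministic imputers return identical copies.
#'
#' @param object a fitted [diffimpute()] model.
#' @param nsim number of imputation draws.
#' @param seed integer seed.
#' @param newdata cohort or record list to impute.
#' @param ... passed to [predict.diffimpute()].
#' @return List of length \code{nsim} of imputation sets.
#' @export
simulate.diffimpute <- function(object, nsim = 1, seed = 1L, newdata, ...) {
  lapply(seq_len(nsim), function(i)
    predict(object, newdata, seed = seed + i - 1L, ...))
}

#' Residual volumes of imputed visits
#'
#' Differences (imputed minus observed) at each imputed visit, restricted to
#' the record's brain mask, using the retained true images as reference.
#'
#' @param object a fitted [diffimpute()] model.
#' @param newdata cohort or record list with retained true images.
#' @param imputations optional precomputed [predict.diffimpute()] result.
#' @param seed passed to predict when imputations are not supplied.
#' @param ... unused.
#' @return List per imputed visit: \code{subject_id}, \code{visit},
#'   \code{residual} (masked difference volume, zero outside the mask), and
#'   \code{rmse}.
#' @export
residuals.diffimpute <- function(object, newdata, imputations = NULL,
                                 seed = 1L, ...) {
  records <- if (inherits(newdata, "phantom_cohort")) newdata$records else
    newdata
  if (is.null(imputations)) imputations <- predict(object, newdata, seed = seed)
  recmap <- stats::setNames(seq_along(records),
                            vapply(records, `[[`, 0, "subject_id"))
  lapply(imputations, function(im) {
    rec <- records[[recmap[[as.character(im$subject_id)]]]]
    truth <- rec$visits[[im$visit]]$image
    res <- (im$volume - truth) * (rec$mask > 0)
    list(subject_id = im$subject_id, visit = im$visit, residual = res,
         rmse = sqrt(mse_masked(im$volume, truth, rec$mask)))
  })
}

#' @export
coef.diffimpute <- function(object, ...) {
  if (is.null(object$model)) numeric(0) else flatten_tree(object$model$params)
}

#' @export
print.diffimpute <- function(x, ...) {
  lab <- switch(x$method, ddpm = "conditional diffusion",
                ae = "autoencoder (l2)", naive = if (x$conditioning == "p")
                  "forward filling" else "adjacent-visit averaging")
  cat(sprintf("Longitudinal imputation model: %s, conditioning on %s\n",
              lab, if (x$conditioning == "p") "past visit" else
                "past + following visits"))
  if (!is.null(x$model)) {
    cat(sprintf("  network: %d parameters, trained %d steps\n",
                n_params(x$model$params), x$model$step))
    if (x$method == "ddpm")
      cat(sprintf("  schedule: T = %d, beta in [%g, %g]\n",
                  x$schedule$n_steps, x$schedule$beta[1],
                  x$schedule$beta[x$schedule$n_steps]))
    if (!is.null(x$loss_history) && nrow(x$loss_history))
      cat(sprintf("  final running loss: %.5f\n",
                  utils::tail(x$loss_history$loss, 1)))
  }
  invisible(x)
}

#' @export
summary.diffimpute <- function(object, ...) {
  out <- list(method = object$method, conditioning = object$conditioning,
              layout = object$layout,
              n_params = if (is.null(object$model)) 0L else
                n_params(object$model$params),
              steps = if (is.null(object$model)) 0L else object$model$step,
              n_train_pairs = object$n_train_pairs,
              loss_history = object$loss_history)
  class(out) <- "summary.diffimpute"
  out
}

#' @export
print.summary.diffimpute <- function(x, ...) {
  cat(sprintf("Method: %s (%s conditioning)\n", x$method,
              toupper(x$conditioning)))
  cat(sprintf("Unit layout: K = %d segments, clip length %d (%d x %d x %d)\n",
              x$layout$K, x$layout$clip_len, x$layout$L, x$layout$H,
              x$layout$W))
  cat(sprintf("Training pairs: %d; parameters: %d; steps: %d\n",
              x$n_train_pairs, x$n_params, x$steps))
  if (!is.null(x$loss_history) && nrow(x$loss_history) > 1) {
    cat("Loss trajectory (running mean):\n")
    print(utils::tail(x$loss_history, 5), row.names = FALSE)
  }
  invisible(x)
}

#' Plot the training-loss trajectory of a fitted imputer
#'
#' @param x a fitted [diffimpute()] model.
#' @param log logarithmic y axis (default TRUE).
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.diffimpute <- function(x, log = TRUE, ...) {
  if (is.null(x$loss_history) || !nrow(x$loss_history))
    stop("no training history to plot")
  graphics::plot(x$loss_history$step, x$loss_history$loss, type = "l",
                 xlab = "step", ylab = "running loss",
                 log = if (log) "y" else "", ...)
  invisible(x)
}
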