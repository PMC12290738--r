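#' Training control parameters
#'
#' @param lr Adam learning rate (reference setting 1e-4; the tiny desk-scale
#'   preset trains for few steps and uses 1e-3).
#' @param lr_decay_at,lr_decay_factor optional step decay: multiply the
#'   learning rate by \code{lr_decay_factor} once \code{lr_decay_at} steps
#'   are reached (0 = no decay).
#' @param batch_size units per training step (reference setting 16).
#' @param max_steps maximum optimisation steps (reference setting 200,000;
#'   desk default 2,000).
#' @param ae_plateau_window,ae_plateau_tol autoencoder stopping rule: stop
#'   when the running-mean loss over \code{ae_plateau_window} steps improves
#'   by less than \code{ae_plateau_tol} (relative) twice consecutively.
#' @param checkpoint_every write a checkpoint every this many steps
#'   (0 = never).
#' @param checkpoint_path file path for checkpoints.
#' @param resume_from checkpoint file to resume training from.
#' @param log_every record the running loss every this many steps.
#' @param verbose print progress lines.
#' @return List of class \code{"train_control"}.
#' @export
train_control <- function(lr = 1e-4, batch_size = 16L, max_steps = 2000L,
                          lr_decay_at = 0L, lr_decay_factor = 0.3,
                          ae_plateau_window = 500L, ae_plateau_tol = 1e-3,
                          checkpoint_every = 0L, checkpoint_path = NULL,
                          resume_from = NULL, log_every = 50L,
                          verbose = FALSE) {
  if (lr <= 0 || batch_size < 1 || max_steps < 1)
    stop("'lr', 'batch_size' and 'max_steps' must be positive")
  structure(list(lr = lr, lr_decay_at = as.integer(lr_decay_at),
                 lr_decay_factor = lr_decay_factor,
                 batch_size = as.integer(batch_size),
                 max_steps = as.integer(max_steps),
                 ae_plateau_window = as.integer(ae_plateau_window),
                 ae_plateau_tol = ae_plateau_tol,
                 checkpoint_every = as.integer(checkpoint_every),
                 checkpoint_path = checkpoint_path,
                 resume_from = resume_from,
                 log_every = as.integer(log_every), verbose = verbose),
            class = "train_control")
}

# (record index, visit) pairs imputable/trainable under a conditioning kind:
# the target visit is flagged missing and its required neighbours observed
target_index <- function(records, conditioning) {
  out <- NULL
  for (i in seq_along(records)) {
    e <- vapply(records[[i]]$visits, `[[`, 0L, "existence")
    R <- length(e)
    for (v in seq_len(R)) {
      if (e[v] != 0L) next
      ok <- if (conditioning == "p") v > 1 && e[v - 1] == 1L else
        v > 1 && v < R && e[v - 1] == 1L && e[v + 1] == 1L
      if (ok) out <- rbind(out, c(i, v))
    }
  }
  out
}

cond_volumes_for <- function(record, v, conditioning) {
  if (conditioning == "p") list(record$visits[[v - 1]]$image) else
    list(record$visits[[v - 1]]$image, record$visits[[v + 1]]$image)
}

#' Fit a longitudinal MRI imputation model
#'
#' The main fitting interface.  Given a cohort of longitudinal records with
#' designated-missing visits (see [apply_missingness()]), fits one of three
#' imputers:
#' \describe{
#'   \item{\code{"ddpm"}}{a conditional denoising diffusion model: a
#'     noise-prediction UNet is trained on local-continuous units of the
#'     missing-visit image diffused to a random step and concatenated with
#'     the clean condition units (the past visit, or past and following
#'     visits); imputation runs ancestral sampling from pure noise.}
#'   \item{\code{"ae"}}{an autoencoder comparator with the same backbone,
#'     mapping condition units directly to the target unit under an l2
#'     objective, trained until the loss plateaus.}
#'   \item{\code{"naive"}}{training-free forward filling (conditioning
#'     \code{"p"}) or adjacent-visit averaging (conditioning \code{"pf"}).}
#' }
#'
#' All randomness (initialisation, batch sampling, diffusion noise) is drawn
#' from R's RNG seeded with \code{seed}, so a fit is reproducible from
#' \code{(arguments, seed)}.
#'
#' @param cohort a \code{"phantom_cohort"} or list of
#'   \code{"longitudinal_record"} objects with existence flags set.
#' @param method imputer type: \code{"ddpm"}, \code{"ae"}, or
#'   \code{"naive"}.
#' @param conditioning \code{"pf"} (past and following visits) or \code{"p"}
#'   (past visit only).
#' @param layout a [unit_layout()]; default K = 5 segments, J = 1 neighbour
#'   slice (clips of three consecutive slices) over the record's volume
#'   shape.
#' @param schedule a [diffusion_schedule()]; default the standard 1000-step
#'   linear schedule.  Desk-scale runs use [tiny_schedule()].
#' @param network a [denoiser_spec()] or preset name for
#'   [denoiser_preset()] (\code{"tiny"}, \code{"reference-p"},
#'   \code{"reference-pf"}).
#' @param control a [train_control()].
#' @param subjects optional subset of record indices to train on.
#' @param seed integer seed.
#' @return An object of class \code{"diffimpute"} with components
#'   \code{method}, \code{conditioning}, \code{layout}, \code{schedule},
#'   \code{model} (the trained network, \code{NULL} for naive),
#'   \code{loss_history} (data frame of step and running loss), and the
#'   \code{call}.  Use [predict.diffimpute()] to impute missing visits.
#' @seealso [evaluate_imputation()], [generate_cohort()]
#' @export
diffimpute <- function(cohort, method = c("ddpm", "ae", "naive"),
                       conditioning = c("pf", "p"), layout = NULL,
                       schedule = NULL, network = "tiny",
                       control = train_control(), subjects = NULL,
                       seed = 1L) {
  method <- match.arg(method)
  conditioning <- match.arg(conditioning)
  records <- if (inherits(cohort, "phantom_cohort")) cohort$records else cohort
  if (!length(records)) stop("empty cohort")
  if (!is.null(subjects)) records <- records[subjects]
  dims <- dim(records[[1]]$visits[[1]]$image)
  if (is.null(layout)) layout <- unit_layout(dims[1], dims[2], dims[3])
  if (is.null(schedule)) schedule <- diffusion_schedule()
  cl <- match.call()
  set.seed(seed)

  fit <- structure(list(method = method, conditioning = conditioning,
                        layout = layout, schedule = schedule, model = NULL,
                        loss_history = NULL, control = control, seed = seed,
                        n_train_pairs = 0L, call = cl),
                   class = "diffimpute")
  if (method == "naive") return(fit)

  idx <- target_index(records, conditioning)
  if (is.null(idx)) stop("no trainable (missing visit, neighbours) pairs; ",
                         "did you call apply_missingness()?")
  fit$n_train_pairs <- nrow(idx)

  spec <- if (inherits(network, "denoiser_spec")) network else
    denoiser_preset(network, layout, conditioning, ae = (method == "ae"))
  state <- NULL
  if (!is.null(control$resume_from)) {
    ck <- readRDS(control$resume_from)
    if (!identical(ck$spec$in_channels, spec$in_channels))
      stop(sprintf(
        "checkpoint expects %d input channels but this fit needs %d",
        ck$spec$in_channels, spec$in_channels))
    state <- ck
    assign(".Random.seed", ck$rng_state, envir = globalenv())
  }
  trained <- train_network(records, idx, layout, schedule, spec, method,
                           conditioning, control, state)
  fit$model <- trained$model
  fit$loss_history <- trained$loss_history
  fit
}

train_network <- function(records, idx, layout, schedule, spec, method,
                          conditioning, control, state = NULL) {
  C <- layout$K * layout$clip_len
  n_cond <- if (conditioning == "pf") 2L else 1L
  if (is.null(state)) {
    model <- build_denoiser(spec)
    adam <- adam_init(model$params)
    step0 <- 0L
    loss_hist <- data.frame(step = integer(0), loss = numeric(0))
  } else {
    model <- structure(list(spec = state$spec, params = state$params,
                            step = state$step), class = "denoiser")
    adam <- state$adam
    step0 <- state$step
    loss_hist <- state$loss_history
  }
  H <- layout$H; W <- layout$W; nb <- control$batch_size
  running <- numeric(0)
  win_means <- numeric(0)
  plateau_hits <- 0L
  for (step in seq_len(control$max_steps - step0) + step0) {
    pick <- idx[sample.int(nrow(idx), nb, replace = TRUE), , drop = FALSE]
    x0 <- array(0, c(H, W, C, nb))
    cond <- array(0, c(H, W, C * n_cond, nb))
    for (b in seq_len(nb)) {
      rec <- records[[pick[b, 1]]]
      v <- pick[b, 2]
      u <- sample_training_unit(rec$visits[[v]]$image, layout)
      x0[, , , b] <- u
      cvs <- cond_volumes_for(rec, v, conditioning)
      cu <- lapply(cvs, extract_unit, indices = attr(u, "indices"))
      cond[, , , b] <- if (n_cond == 1L) cu[[1]] else
        bind_channels(cu[[1]], cu[[2]])
    }
    # network operates on intensities affinely mapped from [0,1] to [-1,1],
    # matching the unit variance of the diffusion noise
    x0 <- 2 * x0 - 1
    cond <- 2 * cond - 1
    if (method == "ddpm") {
      tt <- sample.int(schedule$n_steps, nb, replace = TRUE)
      eps <- array(stats::rnorm(length(x0)), dim = dim(x0))
      ab <- rep(schedule$alpha_bar[tt], each = H * W * C)
      x_t <- array(sqrt(ab) * x0 + sqrt(1 - ab) * eps, dim = dim(x0))
      inp <- bind_channels(x_t, cond)
      fw <- unet_fw(model$params, spec, inp, tt)
      loss <- mean((eps - fw$out)^2)
      dout <- 2 * (fw$out - eps) / length(eps)
    } else {
      inp <- cond
      fw <- unet_fw(model$params, spec, inp, rep(0, nb))
      loss <- mean((fw$out - x0)^2)
      dout <- 2 * (fw$out - x0) / length(x0)
    }
    bw <- unet_bw(model$params, spec, fw$cache, dout)
    lr_now <- if (control$lr_decay_at > 0L && step > control$lr_decay_at)
      control$lr * control$lr_decay_factor else control$lr
    upd <- adam_step(model$params, bw$grads, adam, lr = lr_now)
    model$params <- upd$params
    adam <- upd$state
    model$step <- step
    running <- c(running, loss)
    if (step %% control$log_every == 0L || step == control$max_steps) {
      loss_hist <- rbind(loss_hist,
                         data.frame(step = step, loss = mean(running)))
      if (control$verbose)
        message(sprintf("step %6d  loss %.5f", step, mean(running)))
      if (method != "ae") running <- numeric(0)
    }
    if (control$checkpoint_every > 0L && !is.null(control$checkpoint_path) &&
        step %% control$checkpoint_every == 0L)
      save_checkpoint(model, adam, loss_hist, control$checkpoint_path)
    if (method == "ae" && length(running) >= control$ae_plateau_window) {
      wm <- mean(utils::tail(running, control$ae_plateau_window))
      if (length(win_means)) {
        imp <- (utils::tail(win_means, 1) - wm) /
          max(utils::tail(win_means, 1), 1e-12)
        plateau_hits <- if (imp < control$ae_plateau_tol)
          plateau_hits + 1L else 0L
      }
      win_means <- c(win_means, wm)
      running <- numeric(0)
      if (plateau_hits >= 2L) break
    }
  }
  if (control$checkpoint_every > 0L && !is.null(control$checkpoint_path))
    save_checkpoint(model, adam, loss_hist, control$checkpoint_path)
  list(model = model, loss_history = loss_hist)
}

save_checkpoint <- function(model, adam, loss_history, path) {
  saveRDS(list(format = "diffimpute-checkpoint-1", spec = model$spec,
               params = model$params, step = model$step, adam = adam,
               loss_history = loss_history,
               rng_state = get(".Random.seed", envir = globalenv())),
          path)
  invisible(path)
}
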