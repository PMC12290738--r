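test_that("imputation covers exactly the missing visits with neighbours", {
  coh <- tiny_cohort(n_subjects = 3, n_visits = 5)
  coh <- apply_missingness(coh, "pf")      # visits 2 and 4 missing
  fit <- diffimpute(coh, method = "naive", conditioning = "pf")
  imp <- predict(fit, coh)
  expect_length(imp, 3 * 2)
  expect_setequal(unique(vapply(imp, `[[`, 0, "visit")), c(2, 4))
  # p-conditioned naive imputer works on the same flags (past always exists)
  fit_p <- diffimpute(coh, method = "naive", conditioning = "p")
  expect_length(predict(fit_p, coh), 6)
  # a last-visit missing flag is skipped under pf conditioning
  coh2 <- apply_missingness(tiny_cohort(n_subjects = 1, n_visits = 4), "p")
  fit2 <- diffimpute(coh2, method = "naive", conditioning = "pf")
  expect_length(predict(fit2, coh2), 1)    # visit 4 has no following visit
})

test_that("fitting requires designated-missing training pairs", {
  coh <- tiny_cohort(n_subjects = 2)       # no missingness applied
  expect_error(diffimpute(coh, method = "ddpm", conditioning = "pf",
                          schedule = tiny_schedule(10)),
               "apply_missingness")
})

test_that("training runs, logs, checkpoints, and resumes deterministically", {
  coh <- apply_missingness(tiny_cohort(n_subjects = 2), "pf")
  lay <- tiny_layout()
  ckpt <- file.path(tempdir(), "ck.rds")
  sch <- tiny_schedule(10)
  ctl <- function(n, resume = NULL)
    train_control(lr = 1e-3, batch_size = 2, max_steps = n, log_every = 5,
                  checkpoint_every = 10, checkpoint_path = ckpt,
                  resume_from = resume)
  fit10 <- diffimpute(coh, method = "ddpm", conditioning = "pf", layout = lay,
                      schedule = sch, control = ctl(10), seed = 77)
  expect_true(file.exists(ckpt))
  ck <- readRDS(ckpt)
  expect_equal(ck$step, 10L)
  expect_equal(ck$format, "diffimpute-checkpoint-1")
  fit20r <- diffimpute(coh, method = "ddpm", conditioning = "pf",
                       layout = lay, schedule = sch,
                       control = ctl(20, resume = ckpt), seed = 77)
  fit20 <- diffimpute(coh, method = "ddpm", conditioning = "pf", layout = lay,
                      schedule = sch, control = ctl(20), seed = 77)
  expect_equal(coef(fit20r), coef(fit20), tolerance = 1e-12)
  expect_equal(fit20$model$step, 20L)
  expect_gt(nrow(fit20$loss_history), 1)
  unlink(ckpt)
})

test_that("condition-kind mismatches are refused with a channel error", {
  coh <- apply_missingness(tiny_cohort(n_subjects = 2), "pf")
  lay <- tiny_layout()
  fit_p <- diffimpute(coh, method = "ddpm", conditioning = "p", layout = lay,
                      schedule = tiny_schedule(5),
                      control = train_control(lr = 1e-3, batch_size = 2,
                                              max_steps = 3), seed = 1)
  # a pf imputer built around a p-shaped network must refuse to run
  fit_bad <- fit_p
  fit_bad$conditioning <- "pf"
  expect_error(predict(fit_bad, coh), "channels")
  # resuming with an incompatible checkpoint fails before training
  ckpt <- file.path(tempdir(), "ckp.rds")
  diffimpute:::save_checkpoint(fit_p$model, diffimpute:::adam_init(
    fit_p$model$params), fit_p$loss_history, ckpt)
  expect_error(
    diffimpute(coh, method = "ddpm", conditioning = "pf", layout = lay,
               schedule = tiny_schedule(5),
               control = train_control(max_steps = 3, resume_from = ckpt)),
    "channels")
  unlink(ckpt)
})

test_that("fold plans are disjoint, exhaustive, seeded, and 8:1 split", {
  ids <- sprintf("s%02d", 1:30)
  fp <- make_folds(ids, n_folds = 10, seed = 4)
  expect_equal(fp$n_folds, 10L)
  tests <- unlist(lapply(fp$folds, `[[`, "test"))
  expect_setequal(tests, ids)
  expect_equal(length(tests), length(ids))            # each exactly once
  for (f in fp$folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$validation, f$test), 0)
    expect_length(intersect(f$train, f$validation), 0)
    expect_setequal(c(f$train, f$validation, f$test), ids)
    expect_equal(length(f$validation), round(length(c(f$train,
                                                      f$validation)) / 9))
  }
  fp2 <- make_folds(ids, n_folds = 10, seed = 4)
  expect_identical(fp$assignment, fp2$assignment)
  fp10 <- make_folds(1:10, n_folds = 10, seed = 1)
  expect_true(all(vapply(fp10$folds, function(f) length(f$test), 0L) == 1L))
  expect_error(make_folds(1:5, n_folds = 10), "between")
})

test_that("evaluating truth as imputation gives perfect scores", {
  coh <- apply_missingness(tiny_cohort(n_subjects = 1), "pf")
  rec <- coh$records[[1]]
  imp <- structure(list(list(subject_id = rec$subject_id, visit = 2,
                             volume = rec$visits[[2]]$image)),
                   class = "diffimpute_imputations")
  rep <- evaluate_imputation(imp, coh, imputer = "oracle")
  expect_equal(rep$value[rep$metric == "ssim"], 1)
  expect_identical(rep$value[rep$metric == "psnr"], Inf)
  expect_true(all(rep$value[rep$metric == "error_rate"] == 0))
  expect_true(all(rep$value[rep$metric == "progression_gap"] == 0))
})

test_that("reports aggregate and serialise to TSV + JSON", {
  coh <- apply_missingness(tiny_cohort(n_subjects = 2), "pf")
  fit <- diffimpute(coh, method = "naive", conditioning = "pf")
  rep <- evaluate_imputation(predict(fit, coh), coh, imputer = "naive-pf",
                             fold = 1)
  path <- file.path(tempdir(), "rep")
  write_report(rep, path)
  expect_true(file.exists(paste0(path, ".tsv")))
  expect_true(file.exists(paste0(path, ".json")))
  back <- utils::read.table(paste0(path, ".tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(rep))
  agg <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_true(all(c("metric", "mean", "sd", "n") %in% names(agg)))
  unlink(paste0(path, c(".tsv", ".json")))
})

test_that("model objects print, summarise, and expose coefficients", {
  coh <- apply_missingness(tiny_cohort(n_subjects = 2), "pf")
  fit <- diffimpute(coh, method = "ddpm", conditioning = "pf",
                    layout = tiny_layout(), schedule = tiny_schedule(5),
                    control = train_control(lr = 1e-3, batch_size = 2,
                                            max_steps = 4, log_every = 2),
                    seed = 3)
  expect_output(print(fit), "conditional diffusion")
  expect_output(print(summary(fit)), "Training pairs")
  expect_gt(length(coef(fit)), 1e4)
  expect_equal(length(coef(diffimpute(coh, method = "naive",
                                      conditioning = "p"))), 0)
  res <- residuals(fit, coh, imputations = predict(fit, coh, subjects = 1,
                                                   seed = 2))
  expect_length(res, 2)
  expect_true(all(vapply(res, function(r) is.finite(r$rmse), TRUE)))
  # stochastic imputation is bit-reproducible from the seed
  i1 <- predict(fit, coh, subjects = 1, seed = 2)
  i2 <- predict(fit, coh, subjects = 1, seed = 2)
  expect_identical(i1[[1]]$volume, i2[[1]]$volume)
  i3 <- simulate(fit, nsim = 2, seed = 2, newdata = coh, subjects = 1)
  expect_identical(i3[[1]][[1]]$volume, i1[[1]]$volume)
  expect_false(identical(i3[[2]][[1]]$volume, i1[[1]]$volume))
})
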