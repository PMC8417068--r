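# Straddle-style acquisition and the two-stage training schedule

#' Candidate pool for acquisition
#'
#' 1,000 (by default) Latin-hypercube points in the block plane.
#'
#' @param n pool size.
#' @param seed RNG seed.
#' @param bounds per-axis bounds.
#' @return n x 2 matrix with columns `beta_cal`, `beta_kr`.
#' @export
candidate_pool <- function(n = 1000, seed = 1, bounds = c(0, 0.95)) {
  latin_hypercube(n, 2, bounds, seed)
}

#' Training schedule for the two-stage classifier
#'
#' Defaults follow the two-stage budget: 25 low-fidelity Latin-hypercube
#' samples + 25 low-fidelity active-learning samples, then 10 high-fidelity
#' Latin-hypercube samples + 15 high-fidelity active-learning samples, with
#' retraining after every acquisition.
#'
#' @param n_low_lhs,n_low_al,n_high_lhs,n_high_al stage sample counts.
#' @param retrain retrain after each acquisition (always TRUE in this
#'   implementation; recorded for provenance).
#' @return A `training_schedule`.
#' @export
training_schedule <- function(n_low_lhs = 25, n_low_al = 25, n_high_lhs = 10,
                              n_high_al = 15, retrain = TRUE) {
  counts <- c(n_low_lhs, n_low_al, n_high_lhs, n_high_al)
  if (any(counts < 0)) stop("schedule counts must be non-negative",
                            call. = FALSE)
  structure(list(n_low_lhs = n_low_lhs, n_low_al = n_low_al,
                 n_high_lhs = n_high_lhs, n_high_al = n_high_al,
                 retrain = retrain), class = "training_schedule")
}

#' Acquire the next sample near the decision boundary
#'
#' Straddle-style rule: over the candidate pool, minimize
#' `|mu(x)| / Sigma(x)`, where `mu` and `Sigma` are Monte-Carlo estimates of
#' the mean and variance of the latent `f(x)` (pre-sigmoid). Points closer
#' than `dedup_tol` to an already-evaluated input are excluded. Deterministic
#' given the draws and the pool.
#'
#' @param draws a `gp_posterior`.
#' @param pool candidate matrix (n x 2).
#' @param n_pred_draws posterior draws used in the Monte-Carlo estimate.
#' @param dedup_tol exclusion radius around evaluated points.
#' @return The selected point (length-2 named vector) with attribute `index`.
#' @export
acquire_next <- function(draws, pool, n_pred_draws = 200, dedup_tol = 1e-6) {
  pool <- as.matrix(pool)
  if (nrow(pool) == 0) stop("candidate pool is empty", call. = FALSE)
  keep <- rep(TRUE, nrow(pool))
  for (i in seq_len(nrow(draws$X_raw))) {
    d2 <- (pool[, 1] - draws$X_raw[i, 1])^2 + (pool[, 2] - draws$X_raw[i, 2])^2
    keep <- keep & d2 > dedup_tol^2
  }
  if (!any(keep)) stop("all candidates coincide with evaluated points",
                       call. = FALSE)
  fs <- latent_samples(draws, pool[keep, , drop = FALSE], n_pred_draws)
  mu <- rowMeans(fs)
  v <- apply(fs, 1, stats::var)
  crit <- abs(mu) / pmax(v, 1e-12)
  idx_kept <- which(keep)[which.min(crit)]
  out <- pool[idx_kept, ]
  names(out) <- c("beta_cal", "beta_kr")
  attr(out, "index") <- unname(idx_kept)
  attr(out, "criterion") <- min(crit)
  out
}

#' Run the two-stage active-learning training loop
#'
#' Stage 1: `n_low_lhs` Latin-hypercube low-fidelity evaluations, a
#' single-fidelity fit, then `n_low_al` one-at-a-time acquisitions with
#' retraining after each. Stage 2 (when a high-fidelity evaluator is given):
#' `n_high_lhs` Latin-hypercube high-fidelity evaluations, a multi-fidelity
#' fit, then `n_high_al` acquisitions with retraining. A fresh seeded
#' candidate pool is generated for every acquisition. Evaluator failures are
#' logged and the iteration skipped with a warning.
#'
#' @param low_evaluator function(point) -> binary label (the cheap labeler).
#' @param high_evaluator optional function(point) -> binary label (the
#'   expensive labeler); when NULL only stage 1 runs.
#' @param schedule a [training_schedule()].
#' @param seed RNG seed governing all sampling.
#' @param sampler list of MCMC settings passed to the fits
#'   (`n_chains`, `n_draws`, `n_tune`).
#' @param pool_size candidate-pool size per acquisition.
#' @return list with `data` (labeled_dataset of all evaluations), `draws`
#'   (final `gp_posterior`), and `log` (per-iteration acquisition record).
#' @export
run_active_learning <- function(low_evaluator, high_evaluator = NULL,
                                schedule = training_schedule(), seed = 1,
                                sampler = list(n_chains = 2, n_draws = 1000,
                                               n_tune = 1000),
                                pool_size = 1000) {
  fit_args <- function(extra_seed)
    c(list(seed = seed + extra_seed), sampler)
  eval_safe <- function(f, x, what, log) {
    y <- tryCatch(f(x), error = function(e) {
      warning(sprintf("%s evaluator failed at (%.3f, %.3f): %s; skipped",
                      what, x[1], x[2], conditionMessage(e)), call. = FALSE)
      NA_integer_
    })
    y
  }
  log <- data.frame(stage = character(0), iteration = integer(0),
                    beta_cal = numeric(0), beta_kr = numeric(0),
                    label = integer(0), criterion = numeric(0))
  # stage 1: low-fidelity LHS
  XL <- latin_hypercube(schedule$n_low_lhs, 2, seed = seed)
  yL <- integer(0); keepL <- logical(0)
  for (i in seq_len(nrow(XL))) {
    lab <- eval_safe(low_evaluator, XL[i, ], "low", log)
    keepL[i] <- !is.na(lab); yL[i] <- lab
    log <- rbind(log, data.frame(stage = "low_lhs", iteration = i,
                                 beta_cal = XL[i, 1], beta_kr = XL[i, 2],
                                 label = lab, criterion = NA_real_))
  }
  XL <- XL[keepL, , drop = FALSE]; yL <- yL[keepL]
  dl <- labeled_dataset(XL, yL, "low")
  draws <- do.call(fit_single_fidelity, c(list(data = dl), fit_args(0L)))
  # stage 1: low-fidelity active learning
  for (i in seq_len(schedule$n_low_al)) {
    pool <- candidate_pool(pool_size, seed = seed + 10000L + i)
    x_new <- acquire_next(draws, pool)
    lab <- eval_safe(low_evaluator, x_new, "low", log)
    log <- rbind(log, data.frame(stage = "low_al", iteration = i,
                                 beta_cal = x_new[1], beta_kr = x_new[2],
                                 label = lab,
                                 criterion = attr(x_new, "criterion")))
    if (is.na(lab)) next
    XL <- rbind(XL, x_new); yL <- c(yL, lab)
    dl <- labeled_dataset(XL, yL, "low")
    draws <- do.call(fit_single_fidelity, c(list(data = dl), fit_args(i)))
  }
  if (is.null(high_evaluator) ||
      (schedule$n_high_lhs == 0 && schedule$n_high_al == 0)) {
    data <- labeled_dataset(XL, yL, "low")
    return(list(data = data, draws = draws, log = log))
  }
  # stage 2: high-fidelity LHS
  XH <- latin_hypercube(schedule$n_high_lhs, 2, seed = seed + 500L)
  yH <- integer(0); keepH <- logical(0)
  for (i in seq_len(nrow(XH))) {
    lab <- eval_safe(high_evaluator, XH[i, ], "high", log)
    keepH[i] <- !is.na(lab); yH[i] <- lab
    log <- rbind(log, data.frame(stage = "high_lhs", iteration = i,
                                 beta_cal = XH[i, 1], beta_kr = XH[i, 2],
                                 label = lab, criterion = NA_real_))
  }
  XH <- XH[keepH, , drop = FALSE]; yH <- yH[keepH]
  dl <- labeled_dataset(XL, yL, "low")
  dh <- labeled_dataset(XH, yH, "high")
  draws <- do.call(fit_multi_fidelity,
                   c(list(data_low = dl, data_high = dh), fit_args(100L)))
  # stage 2: high-fidelity active learning
  for (i in seq_len(schedule$n_high_al)) {
    pool <- candidate_pool(pool_size, seed = seed + 20000L + i)
    x_new <- acquire_next(draws, pool)
    lab <- eval_safe(high_evaluator, x_new, "high", log)
    log <- rbind(log, data.frame(stage = "high_al", iteration = i,
                                 beta_cal = x_new[1], beta_kr = x_new[2],
                                 label = lab,
                                 criterion = attr(x_new, "criterion")))
    if (is.na(lab)) next
    XH <- rbind(XH, x_new); yH <- c(yH, lab)
    dh <- labeled_dataset(XH, yH, "high")
    draws <- do.call(fit_multi_fidelity,
                     c(list(data_low = dl, data_high = dh),
                       fit_args(100L + i)))
  }
  data <- rbind(labeled_dataset(XL, yL, "low"), labeled_dataset(XH, yH, "high"))
  class(data) <- c("labeled_dataset", "data.frame")
  list(data = data, draws = draws, log = log)
}
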