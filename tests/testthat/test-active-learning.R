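test_that("acquisition minimizes |mu|/variance over the pool (brute force)", {
  prob <- synthetic_problem(noise_low = 0)
  ds <- gen_two_fidelity_dataset(prob, 25, 0, seed = 21)
  fit <- suppressWarnings(do.call(fit_single_fidelity,
                                  c(list(data = ds$low), fast_sampler,
                                    list(seed = 22))))
  pool <- candidate_pool(100, seed = 23)
  x <- acquire_next(fit, pool, n_pred_draws = 150)
  # independent full scan with the same posterior draws
  fs <- cardiosex:::latent_samples(fit, pool, n_pred_draws = 150)
  crit <- abs(rowMeans(fs)) / pmax(apply(fs, 1, var), 1e-12)
  expect_equal(attr(x, "index"), unname(which.min(crit)))
  expect_equal(as.numeric(x), unname(pool[which.min(crit), ]))
  expect_error(acquire_next(fit, pool[0, , drop = FALSE]), "empty")
})

test_that("straddle ordering: smaller |mu| wins at equal spread, larger
          spread wins at equal |mu|", {
  # one-point training sets place the posterior mean near the label's sign;
  # use a stub posterior with constant hyperparameters so mu and the
  # variance are controlled by distance from the single training point
  psi <- c(log_eta = log(1), log_ell1 = log(0.5), log_ell2 = log(0.5))
  st <- stub_posterior("single", matrix(c(0.4, 0.4), 1, 2), 1, f = 2,
                       psi_row = psi, n_draws = 500)
  # candidate A on the training point: |mu| = 2, tiny variance
  # candidate B far away: mu ~ 0, prior variance
  pool <- rbind(A = c(0.4, 0.4), B = c(0.9, 0.05))
  x <- acquire_next(st, pool, n_pred_draws = 500, dedup_tol = 0)
  expect_equal(unname(attr(x, "index")), 2L)  # near-boundary AND uncertain wins
})

test_that("acquisition never returns an already-evaluated point", {
  prob <- synthetic_problem(noise_low = 0)
  ds <- gen_two_fidelity_dataset(prob, 20, 0, seed = 24)
  fit <- suppressWarnings(do.call(fit_single_fidelity,
                                  c(list(data = ds$low), fast_sampler,
                                    list(seed = 25))))
  # a pool made ONLY of evaluated points must error; with one fresh point it
  # must pick the fresh point
  evaluated <- as.matrix(ds$low[, 1:2])
  expect_error(acquire_next(fit, evaluated, dedup_tol = 1e-9), "coincide")
  pool <- rbind(evaluated, fresh = c(0.47, 0.51))
  x <- acquire_next(fit, pool, n_pred_draws = 100, dedup_tol = 1e-9)
  expect_equal(as.numeric(x), c(0.47, 0.51))
})

test_that("zero active-learning steps yield a pure LHS dataset; fixed seed
          reproduces the acquisition sequence", {
  toy <- toy_cell_params()
  ev <- function(x) toy_screen(toy, matrix(x, ncol = 2))
  sched0 <- training_schedule(12, 0, 0, 0)
  r0 <- run_active_learning(ev, NULL, sched0, seed = 26,
                            sampler = fast_sampler)
  expect_equal(nrow(r0$data), 12)
  expect_identical(as.matrix(r0$data[, 1:2]),
                   latin_hypercube(12, 2, seed = 26),
                   ignore_attr = TRUE)
  sched <- training_schedule(10, 3, 0, 0)
  r1 <- suppressWarnings(run_active_learning(ev, NULL, sched, seed = 27,
                                             sampler = fast_sampler))
  r2 <- suppressWarnings(run_active_learning(ev, NULL, sched, seed = 27,
                                             sampler = fast_sampler))
  expect_identical(r1$log, r2$log)
  expect_equal(nrow(r1$data), 13)
  expect_equal(sum(r1$log$stage == "low_al"), 3)
})

test_that("failing evaluator iterations are skipped with a warning", {
  calls <- 0
  ev <- function(x) {  # balanced labels regardless of which call crashes
    calls <<- calls + 1
    if (calls == 2) stop("simulated crash")
    as.integer(x[2] > 0.45)
  }
  w <- capture_warnings(
    r <- run_active_learning(ev, NULL, training_schedule(10, 0, 0, 0),
                             seed = 28, sampler = fast_sampler))
  expect_true(any(grepl("failed", w)))
  expect_equal(nrow(r$data), 9)  # the crashed evaluation is dropped
})

test_that("active learning beats random sampling at equal budget and shrinks
          posterior uncertainty (20 seeded repetitions)", {
  toy <- toy_cell_params()
  truth <- function(b) toy_boundary(toy, b)
  ev <- function(x) toy_screen(toy, matrix(x, ncol = 2))
  tiny <- list(n_chains = 1, n_draws = 200, n_tune = 200)
  score <- function(fit) {
    g <- probability_grid(fit, resolution = 41, n_pred_draws = 100)
    boundary_displacement(extract_boundary(g), truth)
  }
  n_lhs <- 12; n_al <- 8
  wins <- 0; sd_drop <- 0
  for (s in 1:20) {
    al <- suppressWarnings(run_active_learning(
      ev, NULL, training_schedule(n_lhs, n_al, 0, 0), seed = 300 + s,
      sampler = tiny))
    X_r <- latin_hypercube(n_lhs + n_al, 2, seed = 300 + s)
    rnd <- suppressWarnings(do.call(fit_single_fidelity,
      c(list(data = labeled_dataset(X_r, toy_screen(toy, X_r))), tiny,
        list(seed = 300 + s))))
    e_al <- score(al$draws); e_rnd <- score(rnd)
    if (!is.na(e_al) && !is.na(e_rnd) && e_al <= e_rnd) wins <- wins + 1
    # posterior predictive spread: final AL fit vs its pure-LHS start
    start <- suppressWarnings(do.call(fit_single_fidelity,
      c(list(data = labeled_dataset(al$data[seq_len(n_lhs), 1:2],
                                    al$data$label[seq_len(n_lhs)])), tiny,
        list(seed = 300 + s))))
    G <- latin_hypercube(60, 2, seed = 999)
    sd0 <- mean(predict_probability(start, G, n_pred_draws = 100)$sd)
    sd1 <- mean(predict_probability(al$draws, G, n_pred_draws = 100)$sd)
    if (sd1 < sd0) sd_drop <- sd_drop + 1
  }
  expect_gte(wins, 16)      # >= 80% of 20 repetitions
  expect_gte(sd_drop, 14)   # uncertainty shrinks with added samples
})
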