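test_that("ARD squared-exponential kernel identities", {
  expect_equal(ard_sqexp_kernel(c(1, 2), c(1, 2), eta = 3.7, ell = c(1, 2)),
               3.7)
  expect_equal(ard_sqexp_kernel(c(0, 0), c(1, 1), eta = 1, ell = c(1, 1)),
               exp(-1))
  set.seed(2)
  for (k in 1:5) {
    x <- runif(3); xp <- runif(3); ell <- runif(3, 0.5, 2)
    expect_equal(ard_sqexp_kernel(x, xp, 2, ell),
                 ard_sqexp_kernel(xp, x, 2, ell))
  }
  expect_error(ard_sqexp_kernel(1, 1, -1, 1), "positive")
  expect_error(ard_sqexp_kernel(c(1, 2), 1, 1, 1), "dim")
})

test_that("labeled datasets validate bounds and labels", {
  X <- latin_hypercube(10, 2, seed = 1)
  d <- labeled_dataset(X, rep(c(0, 1), 5), "low")
  expect_s3_class(d, "labeled_dataset")
  expect_error(labeled_dataset(X + 1, rep(0, 10)), "outside")
  expect_error(labeled_dataset(X, rep(0, 3)), "nrow")
})

test_that("single-class data is rejected; empty low side is rejected", {
  X <- latin_hypercube(8, 2, seed = 2)
  expect_error(fit_single_fidelity(labeled_dataset(X, rep(1, 8))), "classes")
  dh <- labeled_dataset(X, rep(c(0, 1), 4), "high")
  empty <- labeled_dataset(matrix(numeric(0), 0, 2), integer(0), "low")
  expect_error(fit_multi_fidelity(empty, dh), "low-fidelity")
})

test_that("symmetric two-point problem predicts 0.5 at the midpoint", {
  d <- list(X = matrix(c(-0.5, 0.5), ncol = 1), y = c(0, 1))
  fit <- suppressWarnings(do.call(fit_single_fidelity,
                                  c(list(data = d), fast_sampler,
                                    list(seed = 3))))
  p <- predict_probability(fit, matrix(0, 1, 1), n_pred_draws = 400)
  expect_equal(p$mean, 0.5, tolerance = 0.06)
})

test_that("probabilities are bounded, reproducible and data-respecting", {
  prob <- synthetic_problem(noise_low = 0)
  ds <- gen_two_fidelity_dataset(prob, 40, 0, seed = 4)
  fit <- suppressWarnings(do.call(fit_single_fidelity,
                                  c(list(data = ds$low), fast_sampler,
                                    list(seed = 5))))
  g1 <- probability_grid(fit, resolution = 21, n_pred_draws = 100)
  g2 <- probability_grid(fit, resolution = 21, n_pred_draws = 100)
  expect_identical(g1$mean, g2$mean)   # fixed derived seed
  expect_true(all(g1$mean >= 0 & g1$mean <= 1))
  expect_false(anyNA(g1$mean))
  # training point deep in class 1 has mean > 0.5
  x1 <- ds$low[ds$low$label == 1, c("beta_cal", "beta_kr")]
  deep <- x1[which.max(x1$beta_kr), , drop = FALSE]
  expect_gt(predict_probability(fit, as.matrix(deep),
                                n_pred_draws = 200)$mean, 0.5)
  # predictive spread at a training input <= far outside the data
  p_in <- predict_probability(fit, as.matrix(ds$low[1, 1:2]),
                              n_pred_draws = 300)
  p_far <- predict_probability(fit, matrix(c(3, 3), 1, 2),
                               n_pred_draws = 300)
  expect_lte(p_in$sd, p_far$sd + 0.05)
})

test_that("label swap mirrors the probability field about one half", {
  prob <- synthetic_problem(noise_low = 0)
  ds <- gen_two_fidelity_dataset(prob, 30, 0, seed = 6)
  flipped <- ds$low
  flipped$label <- 1L - flipped$label
  f1 <- suppressWarnings(do.call(fit_single_fidelity,
                                 c(list(data = ds$low), fast_sampler,
                                   list(seed = 7))))
  f2 <- suppressWarnings(do.call(fit_single_fidelity,
                                 c(list(data = flipped), fast_sampler,
                                   list(seed = 7))))
  G <- latin_hypercube(25, 2, seed = 8)
  p1 <- predict_probability(f1, G, n_pred_draws = 300)$mean
  p2 <- predict_probability(f2, G, n_pred_draws = 300)$mean
  expect_equal(p1, 1 - p2, tolerance = 0.08)
})

test_that("boundary recovery on a known logistic boundary", {
  # 40 points labeled by a noiseless linear boundary
  prob <- synthetic_problem(low_shift = 0, noise_low = 0)
  ds <- gen_two_fidelity_dataset(prob, 40, 0, seed = 9)
  fit <- suppressWarnings(fit_single_fidelity(ds$low, seed = 10))
  g <- probability_grid(fit, resolution = 61, n_pred_draws = 200)
  b <- extract_boundary(g)
  expect_gt(nrow(b), 5)
  expect_lt(boundary_displacement(b, prob), 0.05)
})

test_that("zero cross-fidelity correlation decouples the high level", {
  # stub posteriors with fixed hyperparameters: with rho = 0 the
  # multi-fidelity prediction must equal the single-fidelity prediction
  # built from the high block alone
  set.seed(11)
  XL <- latin_hypercube(12, 2, seed = 12)
  XH <- latin_hypercube(7, 2, seed = 13)
  fH <- rnorm(7); fL <- rnorm(12)
  psi_m <- c(log_eta_L = log(1.3), log_ell_L1 = 0, log_ell_L2 = 0.2,
             log_eta_H = log(0.8), log_ell_H1 = -0.1, log_ell_H2 = 0.1,
             rho = 0)
  psi_s <- c(log_eta = log(0.8), log_ell1 = -0.1, log_ell2 = 0.1)
  mf <- stub_posterior("multi", rbind(XL, XH), c(rep(0, 12), rep(1, 7)),
                       c(fL, fH), psi_m, n_low = 12, n_draws = 400)
  sf <- stub_posterior("single", XH, rep(1, 7), fH, psi_s, n_draws = 400)
  G <- latin_hypercube(15, 2, seed = 14)
  pm <- predict_probability(mf, G, n_pred_draws = 400)$mean
  ps <- predict_probability(sf, G, n_pred_draws = 400)$mean
  expect_equal(pm, ps, tolerance = 0.05)
})

test_that("multi-fidelity with identical labels concentrates rho away from 0", {
  prob <- synthetic_problem(low_shift = 0, noise_low = 0, noise_high = 0)
  ds <- gen_two_fidelity_dataset(prob, 30, 15, seed = 15)
  fit <- suppressWarnings(do.call(fit_multi_fidelity,
                                  c(list(data_low = ds$low,
                                         data_high = ds$high),
                                    fast_sampler, list(seed = 16))))
  rho <- fit$psi[, "rho"]
  expect_gt(mean(abs(rho) > 0.1), 0.8)
  expect_gt(mean(rho), 0)  # same-sign labels imply positive correlation
})

test_that("boundary extraction on analytic fields", {
  gx <- seq(0, 0.95, length.out = 101)
  mk_grid <- function(f) structure(
    list(x = gx, y = gx, mean = outer(gx, gx, f), sd = outer(gx, gx, f) * 0),
    class = "probability_grid")
  # vertical line at beta_kr = 0.5 (y axis carries beta_kr)
  g <- mk_grid(function(cal, kr) plogis(10 * (kr - 0.5)))
  b <- extract_boundary(g)
  expect_true(all(abs(b$beta_kr - 0.5) < 1e-6))
  # all below the level -> empty, not an error
  g0 <- mk_grid(function(cal, kr) 0.2 + 0 * kr)
  expect_equal(nrow(extract_boundary(g0)), 0)
  # tilted boundary beta_kr = 0.4 + 0.3 beta_cal: recover the slope
  gt <- mk_grid(function(cal, kr) plogis(8 * (kr - 0.4 - 0.3 * cal)))
  bt <- extract_boundary(gt)
  co <- coef(lm(beta_kr ~ beta_cal, bt))
  expect_equal(unname(co[2]), 0.3, tolerance = 1e-3)
  expect_equal(unname(co[1]), 0.4, tolerance = 1e-3)
})

test_that("multi-fidelity fusion corrects the biased low-fidelity boundary", {
  prob <- synthetic_problem()  # low boundary shifted +0.1 from truth
  score <- function(fit) {
    g <- probability_grid(fit, resolution = 61, n_pred_draws = 100)
    boundary_displacement(extract_boundary(g), prob)
  }
  wins <- 0
  for (s in 1:6) {
    ds <- gen_two_fidelity_dataset(prob, 50, 10, seed = 200 + s)
    mf <- suppressWarnings(fit_multi_fidelity(ds$low, ds$high, seed = s,
                                              n_draws = 500, n_tune = 500))
    lo <- suppressWarnings(fit_single_fidelity(ds$low, seed = s,
                                               n_draws = 500, n_tune = 500))
    if (score(mf) < score(lo)) wins <- wins + 1
  }
  # adding 10 unbiased high-fidelity labels moves the boundary toward truth
  expect_gte(wins, 4)
})
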