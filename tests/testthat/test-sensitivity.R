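test_that("Latin hypercube is stratified per dimension and seed-reproducible", {
  s <- latin_hypercube(4, 1, c(0, 0.95), seed = 5)
  expect_equal(sort(floor(s / (0.95 / 4))), 0:3)
  s2 <- latin_hypercube(100, 7, seed = 11)
  expect_equal(dim(s2), c(100L, 7L))
  for (j in 1:7) {
    bins <- floor(s2[, j] / (0.95 / 100))
    bins[bins == 100] <- 99
    expect_equal(sort(bins), 0:99)
  }
  expect_identical(latin_hypercube(50, 7, seed = 3),
                   latin_hypercube(50, 7, seed = 3))
  expect_error(latin_hypercube(0, 2), ">= 1")
  expect_error(latin_hypercube(5, 2, bounds = c(1, 0)), "bounds")
})

test_that("abnormality detector criteria: plateau, EAD slope, clean beat", {
  # plateau at -20 mV to the end of the beat: never below -40 -> abnormal
  t <- seq(0, 1000, by = 1)
  v <- ifelse(t < 1, -85, -20)
  expect_true(detect_abnormality(cardiosex:::new_ap_trace(t, v, 0, 1000)))
  # clean repolarizing beat -> normal
  expect_false(detect_abnormality(linear_decay_trace()))
  # secondary depolarization of slope +0.5 mV/ms at t = 600 -> abnormal
  v2 <- ifelse(t < 1, -85, pmax(40 - (125 / 300) * (t - 1), -85))
  bump <- ifelse(t >= 600 & t < 640, 0.5 * (t - 600),
                 ifelse(t >= 640 & t < 680, 20 - 0.5 * (t - 640), 0))
  expect_true(detect_abnormality(cardiosex:::new_ap_trace(t, v2 + bump, 0, 1000)))
  # ordinary repolarization slopes must NOT trip the (signed) criterion
  expect_false(detect_abnormality(linear_decay_trace(decay_ms = 150)))
  expect_error(detect_abnormality(
    cardiosex:::new_ap_trace(0:100, rep(-85, 101), 0, 1000)), "shorter")
})

test_that("logistic fit recovers known coefficients and the null", {
  set.seed(42)
  n <- 50000
  X <- matrix(runif(n * 3), n, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  b_true <- c(-1, 2, -3, 0.8)
  p <- plogis(b_true[1] + X %*% b_true[-1])
  y <- rbinom(n, 1, p)
  fit <- fit_logistic(X, y)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), b_true, tolerance = 0.05)
  # labels independent of X: slopes indistinguishable from zero
  y0 <- rbinom(n, 1, 0.3)
  fit0 <- fit_logistic(X, y0)
  expect_true(all(abs(fit0$coefficients[-1]) < 0.1))
})

test_that("constant columns are dropped with a warning", {
  set.seed(1)
  X <- cbind(a = runif(200), b = rep(0.5, 200))
  y <- rbinom(200, 1, plogis(-1 + 2 * X[, 1]))
  expect_warning(fit <- fit_logistic(X, y), "constant")
  expect_false("b" %in% names(fit$coefficients))
})

test_that("normalized marginal effects equal b_j / sum|b_k| and sum to one", {
  set.seed(7)
  X <- matrix(runif(400 * 2), 400, 2, dimnames = list(NULL, c("u", "v")))
  fit <- list(coefficients = c("(Intercept)" = 0.3, u = 2, v = -1),
              converged = TRUE, ridge = FALSE)
  me <- normalized_marginal_effects(fit, X)
  # the common factor mean(p(1-p)) cancels exactly in the ratio
  expect_equal(unname(me), c(2 / 3, -1 / 3), tolerance = 1e-12)
  expect_equal(sum(abs(me)), 1, tolerance = 1e-12)
  # single covariate: effect is its sign
  fit1 <- list(coefficients = c("(Intercept)" = 1, u = -4),
               converged = TRUE, ridge = FALSE)
  expect_equal(unname(normalized_marginal_effects(fit1,
                                                  X[, 1, drop = FALSE])), -1)
})

test_that("feature selection picks the opposing extremes with fixed tie-break", {
  me <- c(IKr = 0.5, INa = 0.1, ICaL = -0.5)
  sel <- select_features(me)
  expect_equal(sel, list(anti = "ICaL", pro = "IKr"))
  # tie on the positive side: IKr precedes IKs in the canonical order
  me2 <- c(IKs = 0.3, IKr = 0.3, ICaL = -0.4)
  expect_equal(select_features(me2)$pro, "IKr")
  expect_error(select_features(c(IKr = 0.6, IKs = 0.4)), "opposing")
})

test_that("screen labels baseline as normal and supports checkpoint resume", {
  m <- build_myocyte("male", "mid")
  S <- matrix(0, 3, 7, dimnames = list(NULL, cardiosex:::block_channels()))
  proto <- pacing_protocol(n_prepace = 3, n_beats = 1)
  ck <- withr::local_tempfile(fileext = ".csv")
  res <- screen(m, S, proto, cache = TRUE, checkpoint = ck)
  expect_false(any(res$abnormal))
  expect_false(any(res$failed))
  # resume: previously computed rows are reused verbatim
  res2 <- screen(m, S, proto, cache = TRUE, checkpoint = ck)
  expect_identical(res2$abnormal, res$abnormal)
  expect_error(screen(apply_block(m, block_vector(IKr = 0.5)), S, proto),
               "unblocked")
})
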