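test_that("toy labels match the closed-form boundary exactly", {
  toy <- toy_cell_params()
  expect_equal(toy_screen(toy, matrix(c(0, 0), 1)), 0L)
  # points straddling the analytic boundary flip labels
  for (bc in c(0, 0.3, 0.6)) {
    bk <- toy_boundary(toy, bc)
    if (bk < 0.94) {
      expect_equal(toy_screen(toy, matrix(c(bc, bk + 0.01), 1)), 1L)
      expect_equal(toy_screen(toy, matrix(c(bc, bk - 0.01), 1)), 0L)
    }
  }
  expect_error(toy_screen(toy, matrix(c(0, 1), 1)), "outside")
  expect_error(toy_cell_params(a = -1), "> 0")
})

test_that("generated AP trace kinds drive the detector as constructed", {
  expect_false(detect_abnormality(gen_ap_trace("normal")))
  expect_true(detect_abnormality(gen_ap_trace("ead")))
  expect_true(detect_abnormality(gen_ap_trace("repol_failure")))
})

test_that("two-fidelity generator: noiseless labels equal the boundary sign,
          seeds reproduce, scoring identity", {
  prob <- synthetic_problem(noise_low = 0, noise_high = 0)
  ds <- gen_two_fidelity_dataset(prob, 50, 20, seed = 41)
  X <- as.matrix(ds$low[, 1:2])
  expect_equal(ds$low$label,
               as.integer(X[, 2] > prob$true_boundary(X[, 1]) +
                            prob$low_shift))
  XH <- as.matrix(ds$high[, 1:2])
  expect_equal(ds$high$label,
               as.integer(XH[, 2] > prob$true_boundary(XH[, 1])))
  ds2 <- gen_two_fidelity_dataset(prob, 50, 20, seed = 41)
  expect_identical(ds, ds2)
  # a perfect boundary polyline scores zero displacement
  bc <- seq(0, 0.95, length.out = 50)
  perfect <- data.frame(beta_cal = bc, beta_kr = prob$true_boundary(bc),
                        piece = 1L)
  expect_equal(boundary_displacement(perfect, prob), 0)
  expect_true(is.na(boundary_displacement(perfect[0, ], prob)))
  expect_error(synthetic_problem(noise_low = 0.7), "0.5")
})

test_that("label noise flips approximately the requested fraction", {
  prob0 <- synthetic_problem(noise_low = 0)
  prob3 <- synthetic_problem(noise_low = 0.3)
  d0 <- gen_two_fidelity_dataset(prob0, 400, 0, seed = 42)$low
  d3 <- gen_two_fidelity_dataset(prob3, 400, 0, seed = 42)$low
  frac <- mean(d0$label != d3$label)
  expect_gt(frac, 0.2); expect_lt(frac, 0.4)
})

test_that("female toy analogue is abnormal at lower beta_Kr everywhere", {
  male <- toy_cell_params(); female <- toy_cell_female()
  bc <- seq(0, 0.95, length.out = 40)
  expect_true(all(toy_boundary(female, bc) < toy_boundary(male, bc)))
})

test_that("toy screen agrees with trace synthesis plus the detector", {
  toy <- toy_cell_params()
  S <- latin_hypercube(100, 2, seed = 43)
  labels <- toy_screen(toy, S)
  detected <- vapply(seq_len(nrow(S)), function(i) {
    apd <- toy_apd(toy, S[i, , drop = FALSE])
    kind <- if (apd > toy$apd_ead) "ead" else "normal"
    detect_abnormality(gen_ap_trace(kind, toy, apd = min(apd, 800)))
  }, logical(1))
  expect_equal(detected, labels == 1L)
})

test_that("make_fixtures writes reproducible fixture files", {
  d <- withr::local_tempdir()
  paths <- make_fixtures(d, seed = 44)
  expect_true(all(file.exists(file.path(
    d, c("trace_normal.csv", "trace_ead.csv", "trace_repol_failure.csv",
         "two_fidelity_dataset.csv", "toy_screen.csv")))))
  tr <- read_ap_trace(file.path(d, "trace_ead.csv"))
  expect_true(detect_abnormality(tr))
})
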