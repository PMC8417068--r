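# analytic classifiers (probability as a function of the block plane) let the
# concentration search be checked against closed-form inversions

vertical_boundary <- function(level) {
  function(X) plogis(40 * (X[, 2] - level))
}

test_that("bisection reproduces the analytic Hill inversion at the boundary", {
  # boundary beta_Kr = 0.5; drug blocks only IKr with h = 1, IC50 = 10 C_eff:
  # beta = 0.5 exactly at C = IC50, i.e. at 10x the therapeutic concentration
  drug <- drug_definition("ikr10", c_eff = 1,
                          channels = list(IKr = hill_block(10, 1)))
  a <- critical_concentration(drug, vertical_boundary(0.5))
  expect_false(a$safe)
  expect_equal(a$critical_multiple, 10, tolerance = 0.011)
  expect_equal(unname(a$crossing[2]), 0.5, tolerance = 0.01)
  # independent oracle: dense grid search agrees with the bisection
  mult <- seq(0.1, 100, by = 0.01)
  beta <- mult / (mult + 10)
  p <- plogis(40 * (beta - 0.5))
  expect_equal(a$critical_multiple, mult[which(p >= 0.5)[1]],
               tolerance = 0.011)
})

test_that("drugs moving along the protective axis are safe", {
  drug <- drug_definition("ical_only", c_eff = 1,
                          channels = list(ICaL = hill_block(5, 1)))
  a <- critical_concentration(drug, vertical_boundary(0.5))
  expect_true(a$safe)
  expect_true(is.na(a$critical_multiple))
  no_plane <- drug_definition("iks_only", c_eff = 1,
                              channels = list(IKs = hill_block(5, 1)))
  expect_error(critical_concentration(no_plane, vertical_boundary(0.5)),
               "classifier plane")
  mixed <- drug_definition("mixed", c_eff = 1,
                           channels = list(IKr = hill_block(10, 1),
                                           INa = hill_block(50, 1)))
  expect_warning(critical_concentration(mixed, vertical_boundary(0.5)),
                 "ignoring")
})

test_that("shrinking the arrhythmogenic region raises the critical multiple", {
  drug <- drug_definition("ikr10", c_eff = 1,
                          channels = list(IKr = hill_block(10, 1)))
  crits <- vapply(c(0.4, 0.5, 0.6, 0.7), function(lv)
    critical_concentration(drug, vertical_boundary(lv))$critical_multiple,
    numeric(1))
  expect_true(all(diff(crits) > 0))
})

test_that("sex comparison reports ratios and asymmetries", {
  mk <- function(safe, crit) structure(
    list(drug = "d", safe = safe, critical_multiple = crit, crossing = NULL,
         p_max = 0.4), class = "risk_assessment")
  r <- compare_sexes(mk(FALSE, 26.0), mk(FALSE, 3.5))
  expect_equal(r$ratio, 3.5 / 26.0, tolerance = 1e-12)
  expect_match(r$summary, "lower concentration")
  both <- compare_sexes(mk(TRUE, NA), mk(TRUE, NA))
  expect_match(both$summary, "safe for both")
  asym <- compare_sexes(mk(TRUE, NA), mk(FALSE, 80.1))
  expect_match(asym$summary, "safe for males; females at risk")
  other <- mk(FALSE, 2); other$drug <- "e"
  expect_error(compare_sexes(mk(FALSE, 2), other), "different drugs")
})

test_that("stratification works end-to-end against a fitted classifier", {
  prob <- synthetic_problem(low_shift = 0, noise_low = 0)
  ds <- gen_two_fidelity_dataset(prob, 40, 0, seed = 31)
  fit <- suppressWarnings(do.call(fit_single_fidelity,
                                  c(list(data = ds$low), fast_sampler,
                                    list(seed = 32))))
  drug <- drug_definition("ikr_strong", c_eff = 1,
                          channels = list(IKr = hill_block(8, 1.2)))
  a <- critical_concentration(drug, fit, n_pred_draws = 100)
  expect_false(a$safe)
  # trajectory stays on the beta_Kr axis; boundary there is ~0.45
  beta_crit <- a$crossing[2]
  expect_equal(unname(beta_crit), prob$true_boundary(0), tolerance = 0.08)
})
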