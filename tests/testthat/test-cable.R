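test_that("connexin43 sex scaling of conductivity and isometric factor", {
  base <- conductivity(0.090, 0.012)
  expect_equal(sex_scaled_conductivity(base, "male")$d_par, 0.108)
  expect_equal(sex_scaled_conductivity(base, "female")$d_par, 0.072)
  expect_equal(sex_scaled_conductivity(base, "male")$d_perp, 0.0144)
  expect_equal(sex_scaled_conductivity(base, "female")$d_perp, 0.0096)
  # male = 1.5 x female with mean = baseline
  expect_equal(sex_scaled_conductivity(base, "male")$d_par /
                 sex_scaled_conductivity(base, "female")$d_par, 1.5)
  expect_equal(isometric_scale_factor(0.72), 0.72^(1 / 3))
  expect_equal(round(isometric_scale_factor(0.72), 2), 0.90)
  expect_equal(isometric_scale_factor(1), 1)
  expect_equal(isometric_scale_factor(0.512), 0.8)
  expect_error(isometric_scale_factor(-1), "positive")
  expect_error(conductivity(0.01, 0.02), "d_par >= d_perp")
})

test_that("cable domain honors the 20/30/50 arrangement within one node", {
  d <- cable_domain("male", n_nodes = 165)
  counts <- table(factor(d$layers, c("endo", "mid", "epi")))
  expect_true(abs(counts[["endo"]] - 0.2 * 165) <= 1)
  expect_true(abs(counts[["mid"]] - 0.3 * 165) <= 1)
  expect_true(abs(counts[["epi"]] - 0.5 * 165) <= 1)
  expect_equal(as.character(d$layers[1]), "endo")
  expect_equal(as.character(d$layers[165]), "epi")
  # female cable isometrically shortened
  df <- cable_domain("female")
  expect_equal(df$n_nodes, as.integer(round(165 * 0.72^(1 / 3))))
})

test_that("explicit stability bound is enforced with the required step", {
  d <- cable_domain("male", n_nodes = 20)
  expect_error(
    solve_monodomain_cable(d, dt = 0.08, duration = 10, prepace_cycles = 0),
    "dt <=")
})

test_that("an unstimulated uniform cable stays uniform with zero pseudo-ECG", {
  d <- cable_domain("male", n_nodes = 15, n_stim_nodes = 0)
  d$layers <- rep("mid", 15)  # uniform tissue: no transmural heterogeneity
  res <- solve_monodomain_cable(d, duration = 40, dt = 0.02, cl = 1000,
                                prepace_cycles = 0)
  # all nodes share the resting trajectory
  expect_lt(max(apply(res$vm, 1, function(r) diff(range(r)))), 1e-6)
  ecg <- pseudo_ecg(res)
  expect_lt(max(abs(ecg$phi)), 1e-9)
})

test_that("pseudo-ECG matches the closed-form two-node kernel", {
  d <- cable_domain("male", n_nodes = 2, dx = 0.5, electrode_distance = 10)
  res <- structure(list(time = 0, vm = matrix(c(-80, 20), 1, 2),
                        stim_times = 0, domain = d, dt = 0.005, cl = 1000),
                   class = "cable_result")
  ecg <- pseudo_ecg(res)
  # hand-computed: dV/dx = 200 mV/mm at the midpoint x = 0.5;
  # d(1/r)/dx = (1/10.25 - 1/10.75)/0.5; quadrature weight dx = 0.5
  expect_equal(ecg$phi, -0.90754396, tolerance = 1e-6)
  expect_lt(ecg$phi, 0)
  expect_error(pseudo_ecg(res, x_e = 0.5), "inside")
})

test_that("doubling conductivity speeds conduction by about sqrt(2)", {
  cv <- function(D) {
    d <- cable_domain("male", n_nodes = 60, n_stim_nodes = 8)
    d$layers <- rep("endo", 60)  # uniform tissue for a clean plane wave
    res <- solve_monodomain_cable(d, cond = conductivity(D, D / 7.5),
                                  duration = 60, dt = 0.005, cl = 1000,
                                  prepace_cycles = 0, sample_dt = 0.25)
    act <- function(j) {  # interpolated -20 mV crossing time
      i <- which(res$vm[, j] > -20)[1]
      v0 <- res$vm[i - 1, j]; v1 <- res$vm[i, j]
      res$time[i - 1] + (-20 - v0) / (v1 - v0) *
        (res$time[i] - res$time[i - 1])
    }
    (40 - 20) * d$dx / (act(40) - act(20))
  }
  r <- cv(0.108 * 2) / cv(0.108)
  expect_equal(r, sqrt(2), tolerance = 0.08)
})

test_that("vanishing conductivity reduces every node to the single cell", {
  nn <- 5
  d <- cable_domain("male", n_nodes = nn, n_stim_nodes = nn)
  d$layers <- rep("mid", nn)
  res <- solve_monodomain_cable(d, cond = conductivity(1e-7, 1e-8),
                                duration = 350, dt = 0.005, cl = 1000,
                                prepace_cycles = 0)
  m <- build_myocyte("male", "mid")
  m$solver$dt_coarse <- 0.005  # match the cable's fixed step
  tr <- simulate_ap(m, initial_state(m),
                    pacing_protocol(n_prepace = 0, n_beats = 1))
  idx <- match(res$time, tr$time)
  for (j in seq_len(nn))
    expect_equal(res$vm[, j], tr$vm[idx], tolerance = 1e-4)
})

test_that("arrhythmogenicity labeling fires on extra activations and on
          period-doubled ECG peaks", {
  d <- cable_domain("male", n_nodes = 8, dx = 0.5)
  mk_result <- function(vm, stim) structure(
    list(time = seq(0, by = 1, length.out = nrow(vm)), vm = vm,
         stim_times = stim, domain = d, dt = 0.005, cl = 1000),
    class = "cable_result")
  # 7 upstrokes at one node over 5 stimuli -> arrhythmogenic by construction
  t <- seq(0, 4999)
  v_reg <- -85 + 70 * (sin(2 * pi * t / 1000) > 0.95)     # 5 activations
  v_bad <- -85 + 70 * (sin(2 * pi * t / 700) > 0.95)      # 7 activations
  vm <- matrix(rep(v_reg, 8), ncol = 8)
  vm[, 4] <- v_bad
  expect_true(label_arrhythmogenic(mk_result(vm, seq(0, 4000, 1000))))
  # regular field is not flagged
  vm_ok <- matrix(rep(v_reg, 8), ncol = 8)
  expect_false(label_arrhythmogenic(mk_result(vm_ok, seq(0, 4000, 1000))))
  # period-doubled ECG peak timing: alternate beats with shifted gradients
  vstep <- function(shift) {
    v <- rep(-85, 1000)
    v[(300 + shift):(420 + shift)] <- 20
    v
  }
  one <- cbind(rep(-85, 1000), vstep(0), rep(-85, 1000), vstep(0),
               rep(-85, 1000), vstep(0), rep(-85, 1000), vstep(0))
  two <- cbind(rep(-85, 1000), vstep(250), rep(-85, 1000), vstep(250),
               rep(-85, 1000), vstep(250), rep(-85, 1000), vstep(250))
  vm_pd <- rbind(one, two, one, two, one)
  expect_true(label_arrhythmogenic(mk_result(vm_pd, seq(0, 4000, 1000))))
  expect_error(label_arrhythmogenic(mk_result(vm_ok[1:2000, ],
                                              c(0, 1000))), ">= 5")
})
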