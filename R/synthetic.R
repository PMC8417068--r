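# Seeded generators: toy algebraic cell, synthetic AP traces, and
# two-fidelity classification problems with known boundaries

#' Toy algebraic myocyte for fast classifier tests
#'
#' An algebraic stand-in for the midwall myocyte: the action potential
#' duration responds to block as
#' `APD(beta) = APD0 * (1 + a * beta_Kr) * (1 - b * beta_CaL)` and a trace is
#' abnormal (gets an injected early-afterdepolarization bump) when
#' `APD > apd_ead`. The abnormality boundary is available in closed form, so
#' Gaussian-process and active-learning machinery can be tested in seconds.
#' The default female analogue has a larger `a` (stronger IKr-block
#' sensitivity) and smaller `b` (weaker ICaL-block protection), mirroring the
#' qualitative sex asymmetry of the physiological screen.
#'
#' @param apd0 baseline APD (ms).
#' @param a IKr-block prolongation coefficient (> 0).
#' @param b ICaL-block shortening coefficient (> 0).
#' @param apd_ead APD threshold above which an EAD is injected (ms).
#' @param v_rest,v_peak resting/peak potentials (mV) of generated traces.
#' @return A `toy_cell_params` object.
#' @export
toy_cell_params <- function(apd0 = 300, a = 0.8, b = 0.35, apd_ead = 375,
                            v_rest = -85, v_peak = 40) {
  if (apd0 <= 0 || a <= 0 || b <= 0) stop("apd0, a, b must be > 0",
                                          call. = FALSE)
  structure(list(apd0 = apd0, a = a, b = b, apd_ead = apd_ead,
                 v_rest = v_rest, v_peak = v_peak),
            class = "toy_cell_params")
}

#' @rdname toy_cell_params
#' @export
toy_cell_female <- function() toy_cell_params(a = 1.2, b = 0.2)

#' Toy APD response and closed-form abnormality boundary
#'
#' `toy_apd` evaluates the algebraic APD; `toy_boundary` returns, for each
#' `beta_cal`, the critical `beta_kr` at which `APD = apd_ead` (may exceed the
#' screening range when the cell is protected).
#'
#' @param params [toy_cell_params()].
#' @param beta matrix/vector with columns (beta_cal, beta_kr).
#' @return numeric APDs (ms).
#' @export
toy_apd <- function(params, beta) {
  beta <- matrix(beta, ncol = 2)
  params$apd0 * (1 + params$a * beta[, 2]) * (1 - params$b * beta[, 1])
}

#' @rdname toy_apd
#' @param beta_cal vector of ICaL block fractions.
#' @export
toy_boundary <- function(params, beta_cal) {
  r <- params$apd_ead / params$apd0
  (r / (1 - params$b * beta_cal) - 1) / params$a
}

#' Label block samples with the toy cell
#'
#' @param params [toy_cell_params()].
#' @param samples n x 2 matrix in \[0, 0.95\]^2.
#' @return Integer labels: 1 when `APD(beta) > apd_ead`.
#' @export
toy_screen <- function(params, samples) {
  samples <- matrix(samples, ncol = 2)
  if (any(samples < 0 | samples > 0.95))
    stop("samples outside [0, 0.95]^2", call. = FALSE)
  as.integer(toy_apd(params, samples) > params$apd_ead)
}

#' Generate a synthetic action-potential trace
#'
#' Deterministic piecewise traces for exercising the abnormality detector:
#' `normal` repolarizes smoothly below -40 mV with no depolarizing slope above
#' 0.1 mV/ms after 50 ms; `ead` adds a secondary depolarizing bump (peak
#' slope ~0.5 mV/ms) at `ead_time`; `repol_failure` holds the plateau above
#' -40 mV to the end of the beat.
#'
#' @param kind "normal", "ead" or "repol_failure".
#' @param params [toy_cell_params()].
#' @param apd APD of the underlying beat (ms); default the params baseline.
#' @param cl beat length (ms).
#' @param ead_time center of the EAD bump (ms after the upstroke).
#' @param seed unused for the deterministic kinds; kept for interface
#'   stability.
#' @return An `ap_trace` sampled at 1 ms.
#' @export
gen_ap_trace <- function(kind = c("normal", "ead", "repol_failure"),
                         params = toy_cell_params(), apd = NULL, cl = 1000,
                         ead_time = 600, seed = 1) {
  kind <- match.arg(kind)
  if (is.null(apd)) apd <- params$apd0
  t <- seq(0, cl, by = 1)
  vr <- params$v_rest; vp <- params$v_peak
  amp <- vp - vr
  v <- rep(vr, length(t))
  if (kind == "repol_failure") {
    # instantaneous upstroke, then a slow plateau that stays above -40 mV
    plateau_end <- vr + 0.55 * amp   # ~ -16 mV for the defaults
    v[t >= 1] <- vp - (vp - plateau_end) * (t[t >= 1] - 1) / (cl - 1)
  } else {
    # smooth repolarization reaching 90% at `apd`: cosine half-wave
    dur <- apd / 0.9                 # full return to rest
    ph <- pmin((t - 1) / dur, 1)
    v[t >= 1] <- vr + amp * (0.5 + 0.5 * cos(pi * ph[t >= 1]))
    if (kind == "ead") {
      # gaussian bump, peak positive slope ~0.5 mV/ms
      sigma <- 25
      bump_amp <- 0.5 * sigma * exp(0.5)  # slope max = amp/(sigma e^-1/2)
      v <- v + bump_amp * exp(-(t - ead_time)^2 / (2 * sigma^2))
    }
  }
  new_ap_trace(t, v, 0, cl)
}

#' Two-fidelity synthetic classification problem with a known boundary
#'
#' The high-fidelity label is 1 above the true boundary curve
#' `beta_kr = true_boundary(beta_cal)`; the low-fidelity labeler uses the same
#' curve shifted by `low_shift` in `beta_kr` (the built-in low-fidelity bias).
#' Labels are flipped independently with the per-fidelity noise rates.
#'
#' @param true_boundary function(beta_cal) -> critical beta_kr.
#' @param low_shift bias of the low-fidelity boundary (input units).
#' @param noise_low,noise_high label-flip probabilities in \[0, 0.5).
#' @return A `synthetic_problem`.
#' @export
synthetic_problem <- function(true_boundary = function(b) 0.45 + 0.30 * b,
                              low_shift = 0.10, noise_low = 0.05,
                              noise_high = 0) {
  if (noise_low < 0 || noise_low >= 0.5 || noise_high < 0 || noise_high >= 0.5)
    stop("noise rates must lie in [0, 0.5)", call. = FALSE)
  structure(list(true_boundary = true_boundary, low_shift = low_shift,
                 noise_low = noise_low, noise_high = noise_high),
            class = "synthetic_problem")
}

problem_label <- function(problem, x, fidelity) {
  shift <- if (fidelity == "low") problem$low_shift else 0
  as.integer(x[, 2] > problem$true_boundary(x[, 1]) + shift)
}

#' Generate a two-fidelity labeled dataset
#'
#' Latin-hypercube inputs per fidelity; labels from the fidelity's boundary
#' plus Bernoulli label noise. Fully reproducible under `seed`.
#'
#' @param problem a [synthetic_problem()].
#' @param n_low,n_high sample counts.
#' @param seed RNG seed.
#' @return list(low = labeled_dataset, high = labeled_dataset).
#' @export
gen_two_fidelity_dataset <- function(problem, n_low = 50, n_high = 25,
                                     seed = 1) {
  out <- list()
  XL <- if (n_low > 0) latin_hypercube(n_low, 2, seed = seed) else
    matrix(numeric(0), 0, 2)
  XH <- if (n_high > 0) latin_hypercube(n_high, 2, seed = seed + 1L) else
    matrix(numeric(0), 0, 2)
  set.seed(seed + 2L)
  yL <- problem_label(problem, XL, "low")
  if (nrow(XL) && problem$noise_low > 0) {
    flip <- stats::runif(nrow(XL)) < problem$noise_low
    yL[flip] <- 1L - yL[flip]
  }
  yH <- problem_label(problem, XH, "high")
  if (nrow(XH) && problem$noise_high > 0) {
    flip <- stats::runif(nrow(XH)) < problem$noise_high
    yH[flip] <- 1L - yH[flip]
  }
  list(low = labeled_dataset(XL, yL, "low"),
       high = labeled_dataset(XH, yH, "high"))
}

#' Mean absolute displacement of an extracted boundary from the truth
#'
#' For every vertex of the extracted 0.5-level polyline, the vertical
#' (beta_Kr) distance to the true boundary curve is computed; the mean over
#' vertices is returned. A perfect classifier on the truth scores 0.
#'
#' @param boundary data.frame from [extract_boundary()].
#' @param problem a [synthetic_problem()] (or a boundary function).
#' @return Mean absolute displacement (input units); `NA` for an empty
#'   boundary.
#' @export
boundary_displacement <- function(boundary, problem) {
  fb <- if (inherits(problem, "synthetic_problem")) problem$true_boundary
        else problem
  if (!nrow(boundary)) return(NA_real_)
  mean(abs(boundary$beta_kr - fb(boundary$beta_cal)))
}

#' Write all synthetic fixtures as CSV
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed.
#' @return Paths of the written files, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (kind in c("normal", "ead", "repol_failure")) {
    tr <- gen_ap_trace(kind, seed = seed)
    p <- file.path(dir, paste0("trace_", kind, ".csv"))
    write_ap_trace(tr, p)
    paths <- c(paths, p)
  }
  ds <- gen_two_fidelity_dataset(synthetic_problem(), 50, 25, seed)
  p <- file.path(dir, "two_fidelity_dataset.csv")
  utils::write.csv(rbind(ds$low, ds$high), p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  toy <- toy_cell_params()
  S <- latin_hypercube(200, 2, seed = seed + 3L)
  p <- file.path(dir, "toy_screen.csv")
  utils::write.csv(data.frame(S, label = toy_screen(toy, S)), p,
                   row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
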