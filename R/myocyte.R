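# Sex- and layer-specific ventricular myocyte construction, pacing and APD

# canonical drug-blockable channels, fixed order (also the tie-break order)
block_channels <- function() {
  c("IKr", "INa", "INaL", "ICaL", "IKs", "Ito", "IK1")
}

#' Build a sex- and layer-specific ventricular myocyte model
#'
#' Constructs a human ventricular cardiomyocyte model: the O'Hara-Rudy
#' endocardial formulation with the fast sodium current replaced by the
#' ten Tusscher (2006) formulation (38 state variables, 15 ionic currents),
#' with each of the twelve activity-table targets multiplied by its
#' (sex, layer) factor. Factors are applied to the baseline endocardial
#' parameters; the only built-in layer dependences retained are the L-type
#' permeability (x2.5 midwall, x1.2 epicardial) and the epicardial
#' transient-outward inactivation-kinetics modifier, which the table does not
#' cover. An all-ones table therefore reproduces the baseline endocardial
#' model exactly.
#'
#' @param sex "male" or "female".
#' @param layer "endo", "mid" or "epi".
#' @param table activity scaling table; default [channel_scaling_table()].
#' @param stim_amplitude stimulus current (uA/uF); negative depolarizes.
#' @param stim_duration stimulus duration (ms).
#' @return An object of class `myocyte_model`.
#' @examples
#' m <- build_myocyte("male", "endo")
#' m$factors[["IKr"]]  # 1.10
#' @export
build_myocyte <- function(sex, layer, table = channel_scaling_table(),
                          stim_amplitude = -80, stim_duration = 0.5) {
  if (!is.character(sex) || !sex %in% c("male", "female"))
    stop("unknown sex: ", deparse(substitute(sex)), call. = FALSE)
  if (!is.character(layer) || !layer %in% c("endo", "mid", "epi"))
    stop("unknown layer: ", deparse(substitute(layer)), call. = FALSE)
  validate_scaling_table(table)
  fac <- scaling_factors(table, sex, layer)
  structure(list(
    sex = sex, layer = layer, factors = fac,
    block = stats::setNames(numeric(7), block_channels()),
    stim_amplitude = stim_amplitude, stim_duration = stim_duration,
    solver = list(dt_fine = 0.005, dt_coarse = 0.04, vdot_switch = 1.0)
  ), class = "myocyte_model")
}

#' Baseline endocardial myocyte (all scaling factors 1)
#'
#' @param layer transmural layer for the built-in layer-dependent pieces.
#' @inheritParams build_myocyte
#' @return A `myocyte_model`.
#' @export
baseline_myocyte <- function(layer = "endo", stim_amplitude = -80,
                             stim_duration = 0.5) {
  layer <- match.arg(layer, c("endo", "mid", "epi"))
  structure(list(
    sex = "baseline", layer = layer,
    factors = stats::setNames(rep(1, 12), scaling_targets()),
    block = stats::setNames(numeric(7), block_channels()),
    stim_amplitude = stim_amplitude, stim_duration = stim_duration,
    solver = list(dt_fine = 0.005, dt_coarse = 0.04, vdot_switch = 1.0)
  ), class = "myocyte_model")
}

#' @export
print.myocyte_model <- function(x, ...) {
  cat(sprintf("<myocyte_model> %s %scardial cell\n", x$sex,
              sub("endo", "endo", x$layer)))
  cat("  activity factors:",
      paste(sprintf("%s=%.2f", names(x$factors), x$factors), collapse = " "),
      "\n")
  if (any(x$block > 0))
    cat("  drug block:",
        paste(sprintf("%s=%.2f", names(x$block)[x$block > 0],
                      x$block[x$block > 0]), collapse = " "), "\n")
  invisible(x)
}

# 17-element parameter vector consumed by the compiled kernels
model_params <- function(model) {
  f <- model$factors
  b <- model$block
  layer_code <- match(model$layer, c("endo", "mid", "epi")) - 1L
  c(
    1 - b[["INa"]],
    f[["INaL"]] * (1 - b[["INaL"]]),
    f[["Ito"]] * (1 - b[["Ito"]]),
    f[["IpCa"]],
    f[["IKr"]] * (1 - b[["IKr"]]),
    f[["IKs"]] * (1 - b[["IKs"]]),
    f[["IK1"]] * (1 - b[["IK1"]]),
    f[["INaCa"]], f[["INaK"]], f[["IKb"]],
    f[["Jrel"]], f[["Jup"]], f[["CMDN"]],
    layer_code, model$stim_amplitude, model$stim_duration,
    1 - b[["ICaL"]]
  )
}

#' Resting initial state vector
#'
#' Gating variables at their resting-potential steady state, physiological
#' resting concentrations. 38 state variables; gates in \[0,1\],
#' concentrations positive.
#'
#' @param model a `myocyte_model` (unused except for class check; the resting
#'   state is model-independent and conditioning is done by prepacing).
#' @return Numeric vector of length 38.
#' @export
initial_state <- function(model = NULL) {
  if (!is.null(model) && !inherits(model, "myocyte_model"))
    stop("model must be a myocyte_model", call. = FALSE)
  cell_initial_state_cpp()
}

#' Pacing protocol
#'
#' @param cl S1 cycle length (ms).
#' @param n_prepace number of prepacing cycles.
#' @param n_beats number of recorded beats.
#' @param s2_di optional S2 diastolic interval (ms).
#' @return A `pacing_protocol` object.
#' @export
pacing_protocol <- function(cl = 1000, n_prepace = 1000, n_beats = 5,
                            s2_di = NULL) {
  if (cl <= 0) stop("cycle length must be positive", call. = FALSE)
  if (n_prepace < 0 || n_beats < 0)
    stop("cycle counts must be non-negative", call. = FALSE)
  if (!is.null(s2_di) && s2_di < 0)
    stop("diastolic interval must be >= 0", call. = FALSE)
  structure(list(cl = cl, n_prepace = n_prepace, n_beats = n_beats,
                 s2_di = s2_di), class = "pacing_protocol")
}

check_protocol <- function(model, protocol) {
  if (!inherits(protocol, "pacing_protocol"))
    stop("protocol must be a pacing_protocol", call. = FALSE)
  if (protocol$cl <= model$stim_duration)
    stop("cycle length must exceed the stimulus duration", call. = FALSE)
}

# in-session cache of prepaced states (keyed by model parameters + protocol)
.prepace_cache <- new.env(parent = emptyenv())

prepace_cache_key <- function(model, n_prepace, cl) {
  paste(c(format(model_params(model), digits = 17), model$solver$dt_fine,
          model$solver$dt_coarse, model$solver$vdot_switch, n_prepace, cl),
        collapse = "|")
}

#' Prepace a myocyte to (approximate) steady state
#'
#' Paces the cell for `protocol$n_prepace` cycles at cycle length
#' `protocol$cl`, returning the end-of-train state together with the per-cycle
#' APD90 of the final (up to) 10 cycles as a drift report. With
#' `n_prepace = 0` the supplied state is returned unchanged.
#'
#' @param model a `myocyte_model`.
#' @param protocol a [pacing_protocol()].
#' @param state initial state; default [initial_state()].
#' @param cache reuse an in-session cache keyed by model + protocol (only used
#'   when `state` is the default resting state).
#' @return List with `state` (38-vector), `apd_drift` (numeric, per-cycle
#'   APD90 of the recorded tail cycles) and `drift` (max absolute successive
#'   difference, ms).
#' @export
prepace <- function(model, protocol = pacing_protocol(),
                    state = initial_state(model), cache = FALSE) {
  check_protocol(model, protocol)
  n <- protocol$n_prepace
  if (n == 0L)
    return(list(state = state, apd_drift = numeric(0), drift = NA_real_))
  key <- if (cache) prepace_cache_key(model, n, protocol$cl) else NULL
  if (!is.null(key) && !is.null(.prepace_cache[[key]]))
    return(.prepace_cache[[key]])
  res <- cell_prepace_cpp(model_params(model), state, as.integer(n),
                          protocol$cl, as.integer(min(10L, n)),
                          model$solver$dt_fine, model$solver$dt_coarse,
                          model$solver$vdot_switch)
  if (!isTRUE(res$ok))
    stop(sprintf("integration failure during prepacing at cycle %d",
                 res$fail_cycle), call. = FALSE)
  tr <- new_ap_trace(res$time, res$vm, res$stim_times, protocol$cl)
  apds <- suppressWarnings(vapply(seq_along(res$stim_times), function(b) {
    tryCatch(apd90(tr, b), error = function(e) NA_real_)
  }, numeric(1)))
  out <- list(state = res$state, apd_drift = apds,
              drift = if (sum(!is.na(apds)) > 1)
                max(abs(diff(apds[!is.na(apds)]))) else NA_real_)
  if (!is.null(key)) .prepace_cache[[key]] <- out
  out
}

new_ap_trace <- function(time, vm, stim_times, cl) {
  stopifnot(length(time) == length(vm))
  structure(list(time = as.numeric(time), vm = as.numeric(vm),
                 stim_times = as.numeric(stim_times), cl = cl),
            class = "ap_trace")
}

#' Simulate recorded action-potential beats
#'
#' Simulates `protocol$n_beats` paced beats from `state` (plus an optional S2
#' extrasystolic beat when `protocol$s2_di` is set: the S2 stimulus is
#' delivered at the end of the preceding S1 beat's APD90 plus the diastolic
#' interval). Membrane potential is sampled at `sample_dt` (<= 1 ms); internal
#' stepping is adaptive.
#'
#' @inheritParams prepace
#' @param sample_dt output sampling interval (ms), at most 1 ms.
#' @return An `ap_trace` with fields `time`, `vm`, `stim_times`.
#' @export
simulate_ap <- function(model, state, protocol = pacing_protocol(),
                        sample_dt = 1) {
  check_protocol(model, protocol)
  if (sample_dt > 1) stop("sample_dt must be <= 1 ms", call. = FALSE)
  n <- protocol$n_beats
  if (n == 0L)
    return(new_ap_trace(numeric(0), numeric(0), numeric(0), protocol$cl))
  stim <- (seq_len(n) - 1) * protocol$cl
  t_end <- n * protocol$cl
  res <- cell_run_cpp(model_params(model), state, stim, t_end, sample_dt,
                      model$solver$dt_fine, model$solver$dt_coarse,
                      model$solver$vdot_switch)
  if (!isTRUE(res$ok))
    stop(sprintf("integration failure (non-finite Vm) at t = %.1f ms",
                 res$fail_time), call. = FALSE)
  tr <- new_ap_trace(res$time, res$vm, stim, protocol$cl)
  if (!is.null(protocol$s2_di)) {
    # S2 delivered at end of the last S1 beat's APD90 + DI
    a <- apd90(tr, n)
    up <- attr(a, "upstroke_time")
    s2_time <- up + as.numeric(a) + protocol$s2_di
    t_end2 <- s2_time + protocol$cl
    res <- cell_run_cpp(model_params(model), state, c(stim, s2_time), t_end2,
                        sample_dt, model$solver$dt_fine,
                        model$solver$dt_coarse, model$solver$vdot_switch)
    if (!isTRUE(res$ok))
      stop(sprintf("integration failure (non-finite Vm) at t = %.1f ms",
                   res$fail_time), call. = FALSE)
    tr <- new_ap_trace(res$time, res$vm, c(stim, s2_time), protocol$cl)
  }
  tr
}

#' @export
print.ap_trace <- function(x, ...) {
  cat(sprintf("<ap_trace> %d samples, %.0f ms, %d beat(s)\n",
              length(x$time),
              if (length(x$time)) max(x$time) else 0, length(x$stim_times)))
  invisible(x)
}

beat_window <- function(trace, beat) {
  nb <- length(trace$stim_times)
  if (beat < 1 || beat > nb) stop("beat index out of range", call. = FALSE)
  t0 <- trace$stim_times[beat]
  t1 <- if (beat < nb) trace$stim_times[beat + 1] else max(trace$time)
  which(trace$time >= t0 & trace$time <= t1)
}

#' Action potential duration at 90% repolarization
#'
#' Duration from the time of maximum upstroke velocity to the first downward
#' crossing of `V_peak - 0.9 (V_peak - V_rest)`, where `V_rest` is the
#' pre-stimulus membrane potential of the beat and `V_peak` the beat maximum.
#' Sub-sample precision by linear interpolation.
#'
#' @param trace an `ap_trace`.
#' @param beat beat index (1-based).
#' @return APD90 in ms, with attribute `upstroke_time`. If the beat never
#'   recrosses the 90% level before the next beat, returns `NA` with attribute
#'   `repolarization_failure = TRUE` (a flag, not a duration). If no upstroke
#'   is present (voltage excursion < 10 mV), an error of class
#'   `no_action_potential` is thrown.
#' @export
apd90 <- function(trace, beat = 1L) {
  idx <- beat_window(trace, beat)
  t <- trace$time[idx]; v <- trace$vm[idx]
  if (length(t) < 3) stop("beat window too short", call. = FALSE)
  if (diff(range(v)) < 10)
    stop(structure(
      list(message = "no action potential (voltage excursion < 10 mV)",
           call = NULL),
      class = c("no_action_potential", "error", "condition")))
  n <- length(v)
  dv <- (v[3:n] - v[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])  # central differences
  iup <- which.max(dv) + 1L
  t_up <- t[iup]
  v_rest <- v[1]
  v_peak <- max(v)
  thr <- v_peak - 0.9 * (v_peak - v_rest)
  i_peak <- which.max(v)
  cross <- which(v[-1] < thr & seq_along(v[-1]) >= i_peak)
  if (!length(cross)) {
    out <- NA_real_
    attr(out, "repolarization_failure") <- TRUE
    attr(out, "upstroke_time") <- t_up
    return(out)
  }
  i2 <- cross[1] + 1L
  tc <- t[i2 - 1] + (thr - v[i2 - 1]) / (v[i2] - v[i2 - 1]) * (t[i2] - t[i2 - 1])
  out <- tc - t_up
  attr(out, "upstroke_time") <- t_up
  out
}

#' S1-S2 action potential duration restitution curve
#'
#' For each diastolic interval: prepace with S1 at `protocol$cl`, deliver a
#' single S2 stimulus at (end of the S1 beat's APD90) + DI, and report the S2
#' beat's APD90. Non-capturing S2 beats (voltage excursion < 10 mV) are
#' reported with `captured = FALSE` and `apd90 = NA`.
#'
#' @param model a `myocyte_model`.
#' @param diastolic_intervals numeric vector of DIs in \[0, 1000\] ms.
#' @param protocol S1 pacing protocol (prepacing cycles, cycle length).
#' @param cache reuse cached prepaced states.
#' @return data.frame with columns `di`, `apd90`, `captured`.
#' @export
restitution_curve <- function(model, diastolic_intervals,
                              protocol = pacing_protocol(), cache = FALSE) {
  if (any(diastolic_intervals < 0 | diastolic_intervals > 1000))
    stop("diastolic intervals must lie in [0, 1000] ms", call. = FALSE)
  pp <- prepace(model, protocol, cache = cache)
  out <- data.frame(di = diastolic_intervals, apd90 = NA_real_,
                    captured = NA)
  for (k in seq_along(diastolic_intervals)) {
    di <- diastolic_intervals[k]
    tr <- simulate_ap(model, pp$state,
                      pacing_protocol(cl = protocol$cl, n_prepace = 0,
                                      n_beats = 1, s2_di = di))
    a <- tryCatch(apd90(tr, 2L), no_action_potential = function(e) NULL)
    if (is.null(a)) {
      out$captured[k] <- FALSE
    } else {
      out$captured[k] <- TRUE
      out$apd90[k] <- as.numeric(a)
    }
  }
  out
}

#' Write / read an AP trace (CSV + beat-marker sidecar JSON)
#'
#' @param trace an `ap_trace`.
#' @param path CSV path; the sidecar is `<path>.json`.
#' @return `path` (write) or an `ap_trace` (read).
#' @export
write_ap_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_ms = trace$time, vm_mV = trace$vm),
                   path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(stim_times = trace$stim_times, cl = trace$cl),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ap_trace
#' @export
read_ap_trace <- function(path) {
  d <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_ap_trace(d$time_ms, d$vm_mV, side$stim_times, side$cl)
}
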