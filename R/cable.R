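# Desk-scale high-fidelity stage: 1-D transmural monodomain cable,
# sex-scaled conductivity, pseudo-ECG, automated arrhythmogenicity labeling

#' Anisotropic conductivity pair
#'
#' @param d_par conductivity parallel to the fiber direction (mm^2/ms).
#' @param d_perp cross-fiber conductivity (mm^2/ms); must not exceed `d_par`.
#' @return A `conductivity` object.
#' @export
conductivity <- function(d_par = 0.090, d_perp = 0.012) {
  if (!(d_par >= d_perp && d_perp > 0))
    stop("require d_par >= d_perp > 0", call. = FALSE)
  structure(list(d_par = d_par, d_perp = d_perp), class = "conductivity")
}

#' Sex-scaled tissue conductivity
#'
#' The baseline conductivity is taken as a 50/50 male/female average. The 50%
#' higher connexin43 expression in male vs. female myocardium then fixes the
#' scalings uniquely (male = 1.5 x female with mean = baseline): male = 1.2 x
#' baseline, female = 0.8 x baseline.
#'
#' @param baseline a [conductivity()] (50/50 average heart).
#' @param sex "male" or "female".
#' @return Scaled [conductivity()].
#' @examples
#' sex_scaled_conductivity(conductivity(0.090, 0.012), "male")$d_par  # 0.108
#' @export
sex_scaled_conductivity <- function(baseline, sex) {
  sex <- match.arg(sex, c("male", "female"))
  s <- if (sex == "male") 1.2 else 0.8
  conductivity(baseline$d_par * s, baseline$d_perp * s)
}

#' Isometric linear scale factor from a mass ratio
#'
#' Geometrically similar scaling: a volume (mass) ratio `r` corresponds to a
#' linear factor `r^(1/3)`; the reported female/male left-ventricular mass
#' ratio of 0.72 gives a factor of 0.896 (90% to the nearest percent).
#'
#' @param mass_ratio positive mass (volume) ratio.
#' @return Linear scale factor.
#' @export
isometric_scale_factor <- function(mass_ratio) {
  if (!is.numeric(mass_ratio) || any(mass_ratio <= 0))
    stop("mass ratio must be positive", call. = FALSE)
  mass_ratio^(1 / 3)
}

#' Transmural cable domain
#'
#' One-dimensional transmural cable, endocardial end first, with a
#' 20% endo / 30% mid / 50% epi layer arrangement (within one node). The
#' female cable is isometrically shortened by the scale factor from the 0.72
#' mass ratio. Stimuli are delivered at the endocardial-end node(s); the
#' pseudo-ECG electrode sits `electrode_distance` beyond the epicardial end.
#'
#' @param sex "male" or "female".
#' @param n_nodes node count for the male cable; the female cable defaults to
#'   `round(n_nodes * isometric_scale_factor(0.72))`.
#' @param dx node spacing (mm).
#' @param fractions endo/mid/epi layer fractions (sum 1).
#' @param electrode_distance electrode offset beyond the epicardial end (mm).
#' @param n_stim_nodes number of stimulated endocardial-end nodes.
#' @return A `cable_domain`.
#' @export
cable_domain <- function(sex, n_nodes = 165, dx = 0.1,
                         fractions = c(endo = 0.2, mid = 0.3, epi = 0.5),
                         electrode_distance = 20, n_stim_nodes = 5) {
  sex <- match.arg(sex, c("male", "female"))
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("layer fractions must sum to 1", call. = FALSE)
  if (dx <= 0) stop("dx must be positive", call. = FALSE)
  nn <- if (sex == "female" && missing(n_nodes))
    as.integer(round(n_nodes * isometric_scale_factor(0.72))) else
    as.integer(n_nodes)
  n_endo <- round(fractions[["endo"]] * nn)
  n_mid <- round(fractions[["mid"]] * nn)
  n_epi <- nn - n_endo - n_mid
  layers <- c(rep("endo", n_endo), rep("mid", n_mid), rep("epi", n_epi))
  structure(list(
    sex = sex, n_nodes = nn, dx = dx, layers = layers,
    stim_nodes = seq_len(min(n_stim_nodes, nn)),
    electrode_x = nn * dx + electrode_distance
  ), class = "cable_domain")
}

#' @export
print.cable_domain <- function(x, ...) {
  cat(sprintf("<cable_domain> %s, %d nodes x %.2f mm (%.1f mm wall), %s\n",
              x$sex, x$n_nodes, x$dx, x$n_nodes * x$dx,
              paste(sprintf("%s=%d", c("endo", "mid", "epi"),
                            tabulate(factor(x$layers,
                                            c("endo", "mid", "epi")))),
                    collapse = "/")))
  invisible(x)
}

#' Solve the monodomain equation on a transmural cable
#'
#' Explicit finite-difference solution of the 1-D monodomain
#' reaction-diffusion equation with no-flux ends, per-node myocyte models
#' built from the activity table for the domain's sex and each node's layer
#' (with the drug block applied), and endocardial-end stimulation every `cl`
#' ms. Node states are initialized from the layer-wise prepaced single-cell
#' steady states. The explicit stability condition `dt <= dx^2 / (2 D)` is
#' verified up front.
#'
#' @param domain a [cable_domain()].
#' @param table activity scaling table.
#' @param cond a [conductivity()] for this sex (the cable uses `d_par`).
#' @param block block vector applied to every node (default: no block).
#' @param duration total simulated time (ms).
#' @param cl stimulation cycle length (ms).
#' @param dt time step (ms).
#' @param sample_dt output sampling step (ms), at most 1 ms.
#' @param prepace_cycles single-cell prepacing cycles used for the per-layer
#'   initial states.
#' @param cache reuse cached prepaced states.
#' @return A `cable_result` with fields `time`, `vm` (time x node matrix),
#'   `stim_times`, `domain`, `dt`, `cl`.
#' @export
solve_monodomain_cable <- function(domain, table = channel_scaling_table(),
                                   cond = sex_scaled_conductivity(
                                     conductivity(), domain$sex),
                                   block = block_vector(), duration = 5000,
                                   cl = 1000, dt = 0.005, sample_dt = 1,
                                   prepace_cycles = 1000, cache = TRUE) {
  if (!inherits(domain, "cable_domain"))
    stop("domain must be a cable_domain", call. = FALSE)
  D <- cond$d_par
  dt_max <- domain$dx^2 / (2 * D)
  if (dt > dt_max)
    stop(sprintf("explicit stability violated: need dt <= %.4g ms", dt_max),
         call. = FALSE)
  if (sample_dt > 1) stop("sample_dt must be <= 1 ms", call. = FALSE)
  layers <- unique(domain$layers)
  par_by_layer <- list(); state_by_layer <- list()
  for (l in layers) {
    m <- if (domain$sex %in% c("male", "female"))
      build_myocyte(domain$sex, l, table) else baseline_myocyte(l)
    pp <- prepace(m, pacing_protocol(cl = cl, n_prepace = prepace_cycles),
                  cache = cache)
    m <- apply_block(m, block)
    par_by_layer[[l]] <- model_params(m)
    state_by_layer[[l]] <- pp$state
  }
  nn <- domain$n_nodes
  P <- vapply(domain$layers, function(l) par_by_layer[[l]],
              numeric(length(par_by_layer[[1]])))
  S <- vapply(domain$layers, function(l) state_by_layer[[l]],
              numeric(length(state_by_layer[[1]])))
  stim_times <- seq(0, duration - 1, by = cl)
  res <- cable_run_cpp(P, S, D, domain$dx, dt,
                       as.integer(domain$stim_nodes - 1L), stim_times,
                       duration, sample_dt)
  if (!isTRUE(res$ok))
    stop(sprintf("integration failure (non-finite field) at t = %.1f ms",
                 res$fail_time), call. = FALSE)
  structure(list(time = res$time, vm = res$vm, stim_times = stim_times,
                 domain = domain, dt = dt, cl = cl),
            class = "cable_result")
}

#' @export
print.cable_result <- function(x, ...) {
  cat(sprintf("<cable_result> %s cable, %d nodes, %.0f ms (%d beats)\n",
              x$domain$sex, ncol(x$vm), max(x$time), length(x$stim_times)))
  invisible(x)
}

#' Pseudo-electrocardiogram of a cable simulation
#'
#' Far-field potential at the electrode:
#' `phi_e(t) = -integral dV/dx * d(1/r)/dx dx`, discretized by midpoint
#' quadrature on the node spacing, with `r` the distance from the electrode
#' (beyond the epicardial end) to each point. A spatially uniform field gives
#' identically zero potential.
#'
#' @param result a `cable_result`.
#' @param x_e electrode position (mm, measured from the endocardial end);
#'   defaults to the domain's electrode. Must lie outside the cable.
#' @return An `ecg_trace` with fields `time`, `phi`, `stim_times`, `cl`.
#' @export
pseudo_ecg <- function(result, x_e = NULL) {
  dom <- result$domain
  if (is.null(x_e)) x_e <- dom$electrode_x
  nn <- ncol(result$vm)
  xs <- (seq_len(nn) - 0.5) * dom$dx
  if (x_e >= 0 && x_e <= nn * dom$dx)
    stop("electrode lies inside the cable domain (singular kernel)",
         call. = FALSE)
  xm <- (xs[-1] + xs[-nn]) / 2            # midpoints where dV/dx lives
  kern <- diff(1 / abs(x_e - xs)) / dom$dx  # d(1/r)/dx at midpoints
  dvdx <- (result$vm[, -1, drop = FALSE] -
           result$vm[, -nn, drop = FALSE]) / dom$dx
  phi <- -as.numeric(dvdx %*% (kern * dom$dx))
  structure(list(time = result$time, phi = phi, x_e = x_e,
                 stim_times = result$stim_times, cl = result$cl),
            class = "ecg_trace")
}

#' QRS duration and QT interval of a pseudo-ECG
#'
#' Per beat: QRS spans the first to last time `|dphi/dt|` exceeds 5% of its
#' beat maximum within 150 ms of the stimulus; QT runs from QRS onset to the
#' T-wave end located by the tangent method (steepest descent of `|phi|`
#' after the T peak, extrapolated to the baseline).
#'
#' @param ecg an `ecg_trace`.
#' @return data.frame with one row per beat: `beat`, `qrs`, `qt`.
#' @export
ecg_intervals <- function(ecg) {
  out <- data.frame(beat = seq_along(ecg$stim_times), qrs = NA_real_,
                    qt = NA_real_)
  for (b in seq_along(ecg$stim_times)) {
    t0 <- ecg$stim_times[b]
    t1 <- t0 + ecg$cl
    idx <- which(ecg$time >= t0 & ecg$time < t1)
    if (length(idx) < 10) next
    t <- ecg$time[idx]; phi <- ecg$phi[idx]
    dphi <- c(0, abs(diff(phi) / diff(t)))
    early <- t - t0 <= 150
    if (!any(early)) next
    thr <- 0.05 * max(dphi[early])
    hot <- which(early & dphi > thr)
    if (length(hot) < 2) next
    qrs_on <- t[hot[1]]; qrs_off <- t[hot[length(hot)]]
    out$qrs[b] <- qrs_off - qrs_on
    # T wave: largest |phi| deflection after QRS offset
    late <- which(t > qrs_off + 20)
    if (length(late) < 5) next
    ip <- late[which.max(abs(phi[late]))]
    sgn <- sign(phi[ip])
    after <- ip:length(t)
    if (length(after) < 3) next
    slopes <- diff(sgn * phi[after]) / diff(t[after])
    is_ <- which.min(slopes)  # steepest return to baseline
    i_tan <- after[is_]
    base <- 0
    t_end <- t[i_tan] + (base - sgn * phi[i_tan]) / slopes[is_]
    out$qt[b] <- t_end - qrs_on
  }
  out
}

#' Automated arrhythmogenicity label for a cable simulation
#'
#' TRUE when, over the last `n_beats` stimulus intervals, any node shows more
#' upstroke crossings of `upstroke_threshold` than delivered stimuli
#' (re-entrant/triggered extra activations), or the beat-to-beat deviation of
#' the pseudo-ECG main-peak time exceeds `peak_dev_frac` of the cycle length
#' (the non-regular, twisting-complex signature).
#'
#' @param result a `cable_result` with at least `n_beats` stimulated beats.
#' @param n_beats number of trailing beats to inspect.
#' @param upstroke_threshold voltage threshold for counting activations (mV).
#' @param peak_dev_frac allowed relative deviation of ECG peak timing.
#' @return TRUE/FALSE.
#' @export
label_arrhythmogenic <- function(result, n_beats = 5,
                                 upstroke_threshold = -20,
                                 peak_dev_frac = 0.1) {
  ns <- length(result$stim_times)
  if (ns < n_beats)
    stop(sprintf("need >= %d stimulated beats, have %d", n_beats, ns),
         call. = FALSE)
  t_start <- result$stim_times[ns - n_beats + 1]
  idx <- which(result$time >= t_start)
  vm <- result$vm[idx, , drop = FALSE]
  # activation counts per node
  up <- vm[-1, , drop = FALSE] > upstroke_threshold &
        vm[-nrow(vm), , drop = FALSE] <= upstroke_threshold
  if (any(colSums(up) > n_beats)) return(TRUE)
  # pseudo-ECG peak-time regularity
  ecg <- pseudo_ecg(result)
  peaks <- rep(NA_real_, n_beats)
  for (k in seq_len(n_beats)) {
    b <- ns - n_beats + k
    t0 <- result$stim_times[b]
    jj <- which(ecg$time >= t0 & ecg$time < t0 + result$cl)
    if (!length(jj)) next
    peaks[k] <- ecg$time[jj[which.max(abs(ecg$phi[jj]))]] - t0
  }
  peaks <- peaks[!is.na(peaks)]
  if (length(peaks) >= 2 &&
      max(peaks) - min(peaks) > peak_dev_frac * result$cl) return(TRUE)
  FALSE
}
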