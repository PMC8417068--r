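# Critical drug-concentration stratification against a classifier boundary

#' Critical drug concentration from a trained risk classifier
#'
#' Maps the drug's concentration-block trajectory (Hill equation per channel)
#' into the (beta_CaL, beta_Kr) classifier plane and finds the smallest
#' concentration whose predicted mean arrhythmogenicity probability reaches
#' 0.5. A dense 200-point log-spaced pre-scan brackets the first crossing
#' (robust to non-monotone probability profiles); bisection then refines it to
#' relative tolerance `tol`. If the probability stays below 0.5 up to
#' `c_max_multiple` times the effective free therapeutic plasma concentration,
#' the drug is reported safe. Channels blocked by the drug outside
#' {ICaL, IKr} are ignored with a warning (the classifier plane is 2-D).
#'
#' @param drug a [drug_definition()] with Hill data for ICaL and/or IKr.
#' @param draws a `gp_posterior` trained on (beta_CaL, beta_Kr), or any
#'   classifier accepted by [predict_probability()] (e.g. an analytic
#'   probability function).
#' @param c_max_multiple largest concentration multiple scanned.
#' @param tol relative tolerance of the critical multiple.
#' @param n_scan pre-scan grid size.
#' @param n_pred_draws posterior draws used per probability evaluation.
#' @return A `risk_assessment`: list with `drug`, `safe`, `critical_multiple`
#'   (NA when safe), `crossing` (beta_CaL, beta_Kr at the critical point),
#'   and `p_max` (largest mean probability seen in the scan).
#' @export
critical_concentration <- function(drug, draws, c_max_multiple = 1000,
                                   tol = 0.01, n_scan = 200,
                                   n_pred_draws = 200) {
  if (!inherits(drug, "drug_definition"))
    stop("drug must be a drug_definition", call. = FALSE)
  plane <- c("ICaL", "IKr")
  if (!any(plane %in% names(drug$channels)))
    stop("trajectory undefined in classifier plane: drug has no ICaL or IKr ",
         "Hill data", call. = FALSE)
  extra <- setdiff(names(drug$channels), plane)
  if (length(extra))
    warning("ignoring channels outside the classifier plane: ",
            paste(extra, collapse = ", "), call. = FALSE)
  point_at <- function(mult) {
    beta <- vapply(plane, function(ch) {
      if (ch %in% names(drug$channels))
        min(fractional_block(mult * drug$c_eff, drug$channels[[ch]]), 0.95)
      else 0
    }, numeric(1))
    matrix(beta, ncol = 2, dimnames = list(NULL, c("beta_cal", "beta_kr")))
  }
  p_at <- function(mult)
    predict_probability(draws, point_at(mult), n_pred_draws)$mean
  # dense log-spaced pre-scan (plus the origin)
  mults <- c(0, 10^seq(-2, log10(c_max_multiple), length.out = n_scan - 1))
  X <- do.call(rbind, lapply(mults, point_at))
  p <- predict_probability(draws, X, n_pred_draws)$mean
  cross <- which(p >= 0.5)
  if (!length(cross)) {
    return(structure(list(drug = drug$name, safe = TRUE,
                          critical_multiple = NA_real_, crossing = NULL,
                          p_max = max(p)), class = "risk_assessment"))
  }
  i <- cross[1]
  if (i == 1) {
    lo <- 0; hi <- mults[1]
  } else {
    lo <- mults[i - 1]; hi <- mults[i]
  }
  # bisection to relative tolerance
  while ((hi - lo) > tol * max(hi, 1e-12)) {
    mid <- (lo + hi) / 2
    if (p_at(mid) >= 0.5) hi <- mid else lo <- mid
  }
  crit <- (lo + hi) / 2
  structure(list(drug = drug$name, safe = FALSE, critical_multiple = crit,
                 crossing = stats::setNames(as.numeric(point_at(crit)),
                                            c("beta_cal", "beta_kr")),
                 p_max = max(p)), class = "risk_assessment")
}

#' @export
print.risk_assessment <- function(x, ...) {
  if (x$safe)
    cat(sprintf("<risk_assessment> %s: safe (p_max = %.2f)\n", x$drug, x$p_max))
  else
    cat(sprintf(
      "<risk_assessment> %s: critical concentration %.3gx C_eff at (beta_CaL = %.3f, beta_Kr = %.3f)\n",
      x$drug, x$critical_multiple, x$crossing[1], x$crossing[2]))
  invisible(x)
}

#' Compare male and female risk assessments for one drug
#'
#' @param assess_male,assess_female `risk_assessment`s for the same drug.
#' @return list with `drug`, `ratio` (female/male critical multiple, NA when
#'   either is safe) and a human-readable `summary`.
#' @export
compare_sexes <- function(assess_male, assess_female) {
  if (!identical(assess_male$drug, assess_female$drug))
    stop("assessments are for different drugs", call. = FALSE)
  drug <- assess_male$drug
  if (assess_male$safe && assess_female$safe) {
    return(list(drug = drug, ratio = NA_real_,
                summary = sprintf("%s: safe for both sexes", drug)))
  }
  if (assess_male$safe && !assess_female$safe) {
    return(list(drug = drug, ratio = NA_real_,
                summary = sprintf(
                  "%s: safe for males; females at risk above %.3gx C_eff",
                  drug, assess_female$critical_multiple)))
  }
  if (!assess_male$safe && assess_female$safe) {
    return(list(drug = drug, ratio = NA_real_,
                summary = sprintf(
                  "%s: safe for females; males at risk above %.3gx C_eff",
                  drug, assess_male$critical_multiple)))
  }
  ratio <- assess_female$critical_multiple / assess_male$critical_multiple
  list(drug = drug, ratio = ratio,
       summary = sprintf(
         "%s: female critical concentration is %.2fx the male one (female at risk at ~%.1f-fold lower concentration)",
         drug, ratio, 1 / ratio))
}
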