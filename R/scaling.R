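# Sex- and layer-specific channel activity scaling

#' Canonical channel/flux/buffer targets of the activity scaling table
#'
#' Order fixes tie-breaks and the parameter layout passed to the solver.
#' @keywords internal
scaling_targets <- function() {
  c("INaL", "Ito", "IpCa", "IKr", "IKs", "IK1", "INaCa", "INaK", "IKb",
    "Jrel", "Jup", "CMDN")
}

#' Sex-specific subcellular ion channel activity table
#'
#' Multiplicative activity factors, per sex and transmural layer, for twelve
#' channel, pump, flux and buffer targets, expressed relative to the baseline
#' endocardial ventricular myocyte model. The baseline model is regarded as a
#' 56% male / 44% female mixture, so for every endocardial target
#' `0.56 * male + 0.44 * female = 1` (within rounding). `INaCa` applies to both
#' the myoplasmic and subspace sodium-calcium exchange currents; `Jrel` and
#' `Jup` scale the sarcoplasmic-reticulum calcium release and uptake fluxes;
#' `CMDN` scales the calmodulin buffer concentration.
#'
#' @return A data.frame with columns `sex` ("male"/"female"), `layer`
#'   ("endo"/"mid"/"epi"), `channel` and `factor`.
#' @examples
#' tab <- channel_scaling_table()
#' subset(tab, sex == "male" & layer == "endo" & channel == "IKr")
#' @export
channel_scaling_table <- function() {
  ch <- scaling_targets()
  # columns: male epi, male mid, male endo, female epi, female mid, female endo
  vals <- rbind(
    INaL  = c(0.77, 1.06, 1.06, 0.65, 0.93, 0.93),
    Ito   = c(4.00, 4.00, 1.00, 4.00, 4.00, 1.00),
    IpCa  = c(0.70, 1.97, 0.79, 1.26, 3.17, 1.27),
    IKr   = c(1.20, 0.88, 1.10, 0.96, 0.70, 0.87),
    IKs   = c(1.16, 1.10, 1.10, 0.93, 0.88, 0.88),
    IK1   = c(1.07, 1.39, 1.07, 0.76, 1.18, 0.91),
    INaCa = c(1.10, 1.41, 1.01, 1.07, 1.38, 0.99),
    INaK  = c(0.92, 0.70, 1.00, 0.87, 0.70, 1.00),
    IKb   = c(0.82, 1.25, 1.25, 0.42, 0.68, 0.68),
    Jrel  = c(1.13, 1.68, 0.99, 0.89, 1.72, 1.01),
    Jup   = c(1.33, 0.94, 0.94, 1.85, 1.08, 1.08),
    CMDN  = c(0.97, 0.92, 0.92, 1.28, 1.11, 1.11)
  )
  stopifnot(identical(rownames(vals), ch))
  out <- data.frame(
    sex     = rep(rep(c("male", "female"), each = 3L), each = length(ch)),
    layer   = rep(rep(c("epi", "mid", "endo"), 2L), each = length(ch)),
    channel = rep(ch, 6L),
    factor  = as.vector(apply(vals, 2, identity)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  validate_scaling_table(out)
  out
}

#' Validate a channel scaling table
#'
#' Checks completeness (both sexes, all three layers, all twelve targets),
#' positivity of every factor, and the endocardial mixture rule
#' `0.56 * male + 0.44 * female` within `[0.99, 1.01]` for every target.
#'
#' @param tab data.frame as returned by [channel_scaling_table()].
#' @return `tab`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_scaling_table <- function(tab) {
  need <- c("sex", "layer", "channel", "factor")
  if (!is.data.frame(tab) || !all(need %in% names(tab)))
    stop("scaling table must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(!is.finite(tab$factor)) || any(tab$factor <= 0))
    stop("all scaling factors must be positive and finite", call. = FALSE)
  ch <- scaling_targets()
  for (s in c("male", "female")) for (l in c("endo", "mid", "epi")) {
    got <- tab$channel[tab$sex == s & tab$layer == l]
    if (!setequal(got, ch) || anyDuplicated(got))
      stop(sprintf("scaling table incomplete for (%s, %s)", s, l),
           call. = FALSE)
  }
  m <- scaling_factors(tab, "male", "endo")
  f <- scaling_factors(tab, "female", "endo")
  mix <- 0.56 * m + 0.44 * f
  bad <- ch[mix < 0.99 | mix > 1.01]
  if (length(bad))
    stop("endocardial 56/44 mixture outside [0.99, 1.01] for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(tab)
}

#' Extract the factor vector for one (sex, layer) cell type
#'
#' @param tab scaling table data.frame.
#' @param sex "male" or "female".
#' @param layer "endo", "mid" or "epi".
#' @return Named numeric vector over the twelve targets, in canonical order.
#' @export
scaling_factors <- function(tab, sex, layer) {
  sex <- match.arg(sex, c("male", "female"))
  layer <- match.arg(layer, c("endo", "mid", "epi"))
  sub <- tab[tab$sex == sex & tab$layer == layer, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop(sprintf("no entries for (%s, %s) in scaling table", sex, layer),
         call. = FALSE)
  out <- stats::setNames(sub$factor[match(scaling_targets(), sub$channel)],
                         scaling_targets())
  if (anyNA(out))
    stop(sprintf("scaling table missing targets for (%s, %s)", sex, layer),
         call. = FALSE)
  out
}

#' Read / write a scaling table as CSV
#'
#' CSV columns: `sex`, `layer`, `channel`, `factor`.
#' @param path file path.
#' @return `read_scaling_table` returns a validated table;
#'   `write_scaling_table` returns `path` invisibly.
#' @export
read_scaling_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_scaling_table(tab)
  tab
}

#' @rdname read_scaling_table
#' @param tab scaling table data.frame.
#' @export
write_scaling_table <- function(tab, path) {
  validate_scaling_table(tab)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
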