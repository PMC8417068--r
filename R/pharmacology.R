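# Hill-equation concentration-block conversion and drug application

#' Hill concentration-block parameters for one channel
#'
#' @param ic50 concentration achieving 50% block (same units as the
#'   concentrations later passed to [fractional_block()]).
#' @param h Hill exponent (> 0).
#' @return A `hill_block` object.
#' @export
hill_block <- function(ic50, h = 1) {
  if (!is.numeric(ic50) || ic50 <= 0) stop("ic50 must be > 0", call. = FALSE)
  if (!is.numeric(h) || h <= 0) stop("h must be > 0", call. = FALSE)
  structure(list(ic50 = ic50, h = h), class = "hill_block")
}

#' Fractional channel block at a concentration
#'
#' `beta = C^h / (IC50^h + C^h)`: 0 at `C = 0`, exactly 0.5 at `C = IC50` for
#' any exponent, strictly increasing, approaching 1 as `C` grows.
#'
#' @param conc drug concentration(s), >= 0.
#' @param hill a [hill_block()].
#' @return Fractional block(s) in \[0, 1).
#' @examples
#' fractional_block(3, hill_block(ic50 = 1, h = 1))  # 0.75
#' @export
fractional_block <- function(conc, hill) {
  if (!inherits(hill, "hill_block")) stop("hill must be a hill_block",
                                          call. = FALSE)
  if (any(conc < 0)) stop("concentration must be >= 0", call. = FALSE)
  # work on the log-ratio scale so large C^h cannot overflow
  r <- (conc / hill$ic50)^hill$h
  ifelse(is.infinite(r), 1 - .Machine$double.eps, r / (1 + r))
}

canonical_channel <- function(x) {
  ch <- block_channels()
  i <- match(tolower(x), tolower(ch))
  if (anyNA(i))
    stop("unknown channel(s): ", paste(x[is.na(i)], collapse = ", "),
         "; expected one of ", paste(ch, collapse = ", "), call. = FALSE)
  ch[i]
}

#' Drug definition: per-channel Hill parameters and therapeutic concentration
#'
#' @param name drug name.
#' @param c_eff effective free therapeutic plasma concentration (> 0), the
#'   unit in which exposure multiples are expressed.
#' @param channels named list of [hill_block()] objects; names are channel
#'   symbols (case-insensitive) among IKr, INa, INaL, ICaL, IKs, Ito, IK1.
#' @return A `drug_definition`.
#' @export
drug_definition <- function(name, c_eff, channels) {
  if (!is.numeric(c_eff) || c_eff <= 0) stop("c_eff must be > 0", call. = FALSE)
  if (!is.list(channels) || length(channels) == 0L)
    stop("at least one channel must be parameterized", call. = FALSE)
  if (is.null(names(channels)) || any(names(channels) == ""))
    stop("channels must be a named list", call. = FALSE)
  names(channels) <- canonical_channel(names(channels))
  ok <- vapply(channels, inherits, logical(1), "hill_block")
  if (!all(ok)) stop("every channel entry must be a hill_block", call. = FALSE)
  structure(list(name = name, c_eff = c_eff, channels = channels),
            class = "drug_definition")
}

#' @export
print.drug_definition <- function(x, ...) {
  cat(sprintf("<drug_definition> %s (C_eff = %g)\n", x$name, x$c_eff))
  for (ch in names(x$channels))
    cat(sprintf("  %-5s IC50 = %g, h = %g\n", ch, x$channels[[ch]]$ic50,
                x$channels[[ch]]$h))
  invisible(x)
}

#' Block vector over the seven screened channels
#'
#' @param ... named fractional blocks in \[0, 0.95\] (e.g. `IKr = 0.5`);
#'   unspecified channels default to 0.
#' @return Named numeric vector over (IKr, INa, INaL, ICaL, IKs, Ito, IK1).
#' @export
block_vector <- function(...) {
  args <- list(...)
  out <- stats::setNames(numeric(7), block_channels())
  if (length(args)) {
    if (is.null(names(args)) || any(names(args) == ""))
      stop("block components must be named", call. = FALSE)
    nm <- canonical_channel(names(args))
    vals <- unlist(args, use.names = FALSE)
    check_block_bounds(vals)
    out[nm] <- vals
  }
  out
}

check_block_bounds <- function(beta) {
  if (any(!is.finite(beta)) || any(beta < 0) || any(beta > 0.95))
    stop("fractional blocks must lie in [0, 0.95]", call. = FALSE)
  invisible(beta)
}

#' Apply (or remove) a drug block to a myocyte model
#'
#' Each targeted current is scaled by `(1 - beta)`; composition with the
#' sex/layer activity scaling is multiplicative, so applying and then removing
#' a block restores the baseline parameters exactly.
#'
#' @param model a `myocyte_model`.
#' @param blocks a [block_vector()] (or named numeric over its channels).
#' @return The blocked (or unblocked) model.
#' @export
apply_block <- function(model, blocks) {
  if (!inherits(model, "myocyte_model"))
    stop("model must be a myocyte_model", call. = FALSE)
  if (is.null(names(blocks))) {
    if (length(blocks) != 7)
      stop("unnamed block vector must have length 7", call. = FALSE)
    names(blocks) <- block_channels()
  }
  full <- stats::setNames(numeric(7), block_channels())
  full[canonical_channel(names(blocks))] <- blocks
  check_block_bounds(full)
  model$block <- full
  model
}

#' @rdname apply_block
#' @export
remove_block <- function(model) {
  apply_block(model, stats::setNames(numeric(7), block_channels()))
}

#' Concentration-block trajectory of a drug
#'
#' Evaluates the per-channel fractional block at each concentration (given as
#' multiples of the drug's effective free therapeutic plasma concentration).
#' Channels without Hill data stay at 0. Values above the 0.95 screening cap
#' are clipped with a warning.
#'
#' @param drug a [drug_definition()].
#' @param multiples non-negative, sorted concentration multiples of `c_eff`.
#' @return data.frame with column `multiple` and one column per channel.
#' @export
concentration_trajectory <- function(drug, multiples) {
  if (!inherits(drug, "drug_definition"))
    stop("drug must be a drug_definition", call. = FALSE)
  if (length(multiples) == 0L)
    stop("concentration list must be non-empty", call. = FALSE)
  if (any(multiples < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (is.unsorted(multiples))
    stop("concentrations must be sorted increasingly", call. = FALSE)
  out <- data.frame(multiple = multiples)
  clipped <- FALSE
  for (ch in block_channels()) {
    if (ch %in% names(drug$channels)) {
      beta <- fractional_block(multiples * drug$c_eff, drug$channels[[ch]])
      if (any(beta > 0.95)) { clipped <- TRUE; beta <- pmin(beta, 0.95) }
      out[[ch]] <- beta
    } else out[[ch]] <- 0
  }
  if (clipped)
    warning("fractional block exceeded the 0.95 screening cap and was clipped",
            call. = FALSE)
  out
}

#' Read a drug library from JSON
#'
#' Format: `{ "<name>": {"c_eff": ..., "channels": {"IKr": {"ic50":..., "h":...}, ...}}, ...}`.
#' Channel keys are case-insensitive. The example file shipped under
#' `inst/extdata/drugs_example.json` carries illustrative placeholder values,
#' not measured Hill parameters.
#'
#' @param path JSON file path.
#' @return Named list of [drug_definition()] objects.
#' @export
read_drug_library <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  raw <- raw[!startsWith(names(raw), "_")]  # "_comment" and similar metadata
  out <- lapply(names(raw), function(nm) {
    d <- raw[[nm]]
    chans <- lapply(d$channels, function(cc) hill_block(cc$ic50, cc$h))
    drug_definition(nm, d$c_eff, chans)
  })
  stats::setNames(out, names(raw))
}
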