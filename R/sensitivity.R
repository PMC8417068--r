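# Low-fidelity 7-D block-space screening: LHS sampling, abnormality
# detection, logistic regression, normalized marginal effects

#' Latin hypercube sample
#'
#' Stratified design: in every dimension exactly one sample falls in each of
#' `n` equal-width bins of the bounds. Reproducible under `seed`.
#'
#' @param n number of samples (>= 1).
#' @param d number of dimensions (>= 1).
#' @param bounds length-2 lower/upper bound applied to every dimension.
#' @param seed RNG seed.
#' @return `n x d` matrix; columns named after the screened channels when
#'   `d == 7`, or (`beta_cal`, `beta_kr`) when `d == 2`.
#' @export
latin_hypercube <- function(n, d, bounds = c(0, 0.95), seed = 1) {
  if (n < 1 || d < 1) stop("n and d must be >= 1", call. = FALSE)
  if (length(bounds) != 2 || bounds[2] <= bounds[1])
    stop("bounds must be an increasing length-2 vector", call. = FALSE)
  set.seed(seed)
  u <- lhs::randomLHS(as.integer(n), as.integer(d))
  x <- bounds[1] + u * (bounds[2] - bounds[1])
  colnames(x) <- if (d == 7) block_channels()
                 else if (d == 2) c("beta_cal", "beta_kr")
                 else paste0("x", seq_len(d))
  x
}

#' Detect de- or repolarization abnormalities in an AP trace
#'
#' A beat is abnormal when, strictly inside the (50, 1000) ms window after its
#' stimulus, the membrane potential either rises faster than
#' `dvdt_threshold` (a depolarizing slope: the early-afterdepolarization
#' signature) or never drops below `vm_floor` (repolarization failure). The
#' derivative is estimated by central differences on the <= 1 ms output grid.
#'
#' @param trace an `ap_trace` with at least one complete beat.
#' @param window time window (ms) after each stimulus to inspect.
#' @param dvdt_threshold depolarizing-slope threshold (mV/ms).
#' @param vm_floor repolarization floor (mV).
#' @return TRUE if any beat is abnormal.
#' @export
detect_abnormality <- function(trace, window = c(50, 1000),
                               dvdt_threshold = 0.1, vm_floor = -40) {
  if (!inherits(trace, "ap_trace")) stop("trace must be an ap_trace",
                                         call. = FALSE)
  if (length(trace$stim_times) < 1 ||
      max(trace$time) < trace$stim_times[1] + min(window[2], trace$cl) - 1)
    stop("trace shorter than one complete beat", call. = FALSE)
  for (b in seq_along(trace$stim_times)) {
    t0 <- trace$stim_times[b]
    idx <- which(trace$time > t0 + window[1] & trace$time < t0 + window[2])
    if (length(idx) < 3) next
    v <- trace$vm[idx]; t <- trace$time[idx]
    if (min(v) > vm_floor) return(TRUE)
    n <- length(v)
    dvdt <- (v[3:n] - v[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
    if (any(dvdt > dvdt_threshold)) return(TRUE)
  }
  FALSE
}

#' Screen block samples on a myocyte model
#'
#' For each row of `samples`: apply the block to `model`, simulate
#' `protocol$n_beats` beats from the prepaced unblocked steady state, and run
#' [detect_abnormality()]. The unblocked model is prepaced once
#' (`protocol$n_prepace` cycles); the drug block is applied acutely at that
#' steady state. Integration failures (a repolarization catastrophe) are
#' labeled abnormal with a distinct `failed` flag.
#'
#' @param model unblocked `myocyte_model` (typically a midwall cell).
#' @param samples matrix of block vectors, columns named after channels (a
#'   subset of the seven screened channels; unnamed 7-column matrices are
#'   taken in canonical order).
#' @param protocol pacing protocol (prepacing cycles + recorded beats).
#' @param cache reuse the in-session prepaced-state cache.
#' @param checkpoint optional CSV path; finished rows are appended and reused
#'   on resume.
#' @return data.frame: the sample columns plus `abnormal` and `failed`.
#' @export
screen <- function(model, samples, protocol = pacing_protocol(), cache = TRUE,
                   checkpoint = NULL) {
  if (is.null(colnames(samples))) {
    if (ncol(samples) != 7)
      stop("unnamed sample matrix must have 7 columns", call. = FALSE)
    colnames(samples) <- block_channels()
  }
  if (any(model$block > 0))
    stop("screen expects an unblocked base model", call. = FALSE)
  pp <- prepace(model, protocol, cache = cache)
  n <- nrow(samples)
  done <- 0L
  res <- data.frame(samples, abnormal = NA, failed = NA)
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    prev <- utils::read.csv(checkpoint)
    done <- min(nrow(prev), n)
    if (done > 0) {
      res$abnormal[seq_len(done)] <- as.logical(prev$abnormal[seq_len(done)])
      res$failed[seq_len(done)] <- as.logical(prev$failed[seq_len(done)])
    }
  }
  beat_proto <- pacing_protocol(cl = protocol$cl, n_prepace = 0,
                                n_beats = protocol$n_beats)
  for (i in seq_len(n)) {
    if (i <= done) next
    blocked <- apply_block(model, samples[i, ])
    tr <- tryCatch(simulate_ap(blocked, pp$state, beat_proto),
                   error = function(e) NULL)
    if (is.null(tr)) {
      res$abnormal[i] <- TRUE; res$failed[i] <- TRUE
    } else {
      res$abnormal[i] <- detect_abnormality(tr); res$failed[i] <- FALSE
    }
    if (!is.null(checkpoint))
      utils::write.csv(res[seq_len(i), ], checkpoint, row.names = FALSE)
  }
  res
}

#' Multivariable logistic regression of abnormality on block fractions
#'
#' Maximum-likelihood fit of `P(y = 1 | x) = logistic(b0 + b . x)`. Constant
#' columns are dropped with a warning. Under complete separation (or other
#' non-convergence) the fit falls back to an L2 ridge (lambda = 1e-4) with a
#' warning.
#'
#' @param X numeric design matrix (n x d, named columns).
#' @param y binary labels (logical or 0/1) with both classes present.
#' @return List with `coefficients` (intercept first), `converged`, `ridge`.
#' @export
fit_logistic <- function(X, y) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2)
    stop("both classes must be present", call. = FALSE)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- apply(X, 2, function(col) stats::var(col) > 0)
  if (!all(keep)) {
    warning("dropping constant column(s): ",
            paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  dat <- data.frame(y = y, X)
  fit <- suppressWarnings(stats::glm(y ~ ., data = dat,
                                     family = stats::binomial()))
  separated <- !fit$converged || any(abs(stats::coef(fit)[-1]) > 50)
  if (separated) {
    warning("possible complete separation; refitting with L2 ridge (1e-4)",
            call. = FALSE)
    if (!requireNamespace("glmnet", quietly = TRUE))
      stop("glmnet required for the ridge fallback", call. = FALSE)
    gfit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                           lambda = 1e-4, standardize = FALSE)
    co <- c(as.numeric(gfit$a0), as.numeric(gfit$beta))
    names(co) <- c("(Intercept)", colnames(X))
    return(list(coefficients = co, converged = TRUE, ridge = TRUE))
  }
  list(coefficients = stats::coef(fit), converged = fit$converged,
       ridge = FALSE)
}

#' Normalized average marginal effects of channel block
#'
#' Average marginal effect of channel `j`: `mean_i b_j p_i (1 - p_i)`,
#' normalized by the sum of absolute effects so the magnitudes sum to one.
#' Positive values are pro-arrhythmic, negative anti-arrhythmic. Because the
#' factor `mean_i p_i (1 - p_i)` is common to all channels, the normalized
#' effect equals `b_j / sum_k |b_k|` exactly.
#'
#' @param fit result of [fit_logistic()].
#' @param X design matrix the fit was computed on.
#' @return Named numeric vector; `sum(abs(.)) == 1`.
#' @export
normalized_marginal_effects <- function(fit, X) {
  b <- fit$coefficients
  if (anyNA(b) || length(b) < 2) stop("degenerate fit", call. = FALSE)
  X <- as.matrix(X)[, names(b)[-1], drop = FALSE]
  p <- stats::plogis(b[1] + X %*% b[-1])
  ame <- vapply(seq_along(b[-1]), function(j) mean(b[j + 1] * p * (1 - p)),
                numeric(1))
  names(ame) <- names(b)[-1]
  s <- sum(abs(ame))
  if (s == 0) stop("degenerate fit: all marginal effects are zero",
                   call. = FALSE)
  ame / s
}

#' Select the leading anti- and pro-arrhythmic channels
#'
#' `anti` is the most negative normalized marginal effect, `pro` the most
#' positive. Ties are broken by the fixed channel order
#' (IKr, INa, INaL, ICaL, IKs, Ito, IK1).
#'
#' @param effects named vector from [normalized_marginal_effects()].
#' @return list(anti = channel, pro = channel).
#' @export
select_features <- function(effects) {
  ord <- intersect(block_channels(), names(effects))
  effects <- effects[ord]
  if (all(effects >= 0) || all(effects <= 0))
    stop("no opposing anti-/pro-arrhythmic pair: all effects share one sign",
         call. = FALSE)
  list(anti = names(effects)[which.min(effects)],
       pro = names(effects)[which.max(effects)])
}

#' Write screen results to CSV
#'
#' @param results data.frame from [screen()].
#' @param path CSV path.
#' @param seed seed recorded alongside the rows.
#' @return `path`, invisibly.
#' @export
write_screen_results <- function(results, path, seed = NA) {
  results$seed <- seed
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
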