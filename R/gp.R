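# Single- and multi-fidelity Gaussian-process classification of the
# (beta_CaL, beta_Kr) block plane.
#
# Model: latent f ~ GP(0, k_ARD), y_i ~ Bernoulli(sigmoid(f_i)); for two
# fidelities f_H(x) = rho * f_L(x) + delta(x) with independent GP priors on
# f_L and delta. Exact MCMC: the latents are whitened (f = L u, K = L L') and
# updated by elliptical slice sampling; the kernel hyperparameters (and rho)
# by adaptive random-walk Metropolis. Priors: eta ~ HalfNormal(sigma = 5),
# ell_m ~ Gamma(2, 2), rho ~ Normal(0, 10).

#' Automatic-relevance-determination squared-exponential kernel
#'
#' `k(x, x') = eta * exp(-sum_m (x_m - x'_m)^2 / (2 ell_m^2))`; symmetric,
#' with `k(x, x) = eta`.
#'
#' @param x,xp numeric vectors of equal length M.
#' @param eta kernel amplitude (> 0). Note: the amplitude multiplies the
#'   exponential directly (it is a variance-scale parameter).
#' @param ell length scales, length M or 1 (> 0).
#' @return Covariance value.
#' @examples
#' ard_sqexp_kernel(c(0, 0), c(1, 1), eta = 1, ell = c(1, 1))  # exp(-1)
#' @export
ard_sqexp_kernel <- function(x, xp, eta, ell) {
  if (length(x) != length(xp)) stop("dim(x) != dim(xp)", call. = FALSE)
  if (any(eta <= 0) || any(ell <= 0))
    stop("kernel hyperparameters must be positive", call. = FALSE)
  if (length(ell) == 1) ell <- rep(ell, length(x))
  eta * exp(-sum((x - xp)^2 / (2 * ell^2)))
}

# dense kernel matrix between row sets
kernel_matrix <- function(X, Xp, eta, ell) {
  X <- as.matrix(X); Xp <- as.matrix(Xp)
  M <- ncol(X)
  if (length(ell) == 1) ell <- rep(ell, M)
  d2 <- matrix(0, nrow(X), nrow(Xp))
  for (m in seq_len(M)) {
    dm <- outer(X[, m], Xp[, m], "-") / ell[m]
    d2 <- d2 + dm * dm
  }
  eta * exp(-0.5 * d2)
}

#' Labeled dataset in the 2-D block plane
#'
#' @param x n x 2 matrix of (beta_CaL, beta_Kr) points in \[0, 0.95\]^2.
#' @param y binary labels (0/1 or logical).
#' @param fidelity "low" or "high" (recycled).
#' @return A `labeled_dataset` data.frame with columns `beta_cal`, `beta_kr`,
#'   `label`, `fidelity`.
#' @export
labeled_dataset <- function(x, y, fidelity = "low") {
  x <- as.matrix(x)
  if (ncol(x) != 2) stop("x must have two columns", call. = FALSE)
  if (any(x < 0 | x > 0.95)) stop("x outside [0, 0.95]^2", call. = FALSE)
  y <- as.integer(as.logical(y))
  if (length(y) != nrow(x)) stop("length(y) != nrow(x)", call. = FALSE)
  fidelity <- rep(match.arg(fidelity, c("low", "high")), length.out = nrow(x))
  out <- data.frame(beta_cal = x[, 1], beta_kr = x[, 2], label = y,
                    fidelity = fidelity, stringsAsFactors = FALSE)
  class(out) <- c("labeled_dataset", "data.frame")
  out
}

# ---- internal MCMC machinery ------------------------------------------------

bern_loglik <- function(f, y) {
  # sum log sigmoid((2y-1) f), numerically stable
  s <- (2 * y - 1) * f
  -sum(log1p(exp(-abs(s))) + pmax(-s, 0))
}

# log prior for a hyperparameter vector psi on the sampling scale
# psi = c(log_eta..., log_ell..., rho?); layout described by `spec`
hyper_logprior <- function(psi, spec) {
  lp <- 0
  for (k in seq_along(spec$kind)) {
    v <- psi[k]
    lp <- lp + switch(spec$kind[k],
      log_eta = { e <- exp(v); -e^2 / 50 + v },       # HalfNormal(5) + Jacobian
      log_ell = { 2 * v - 2 * exp(v) },               # Gamma(2,2) + Jacobian
      rho     = { -v^2 / 200 })                       # Normal(0,10)
  }
  lp
}

# build covariance (with jitter) from psi for either model type
build_cov <- function(psi, spec, Xs, n_low) {
  M <- spec$M
  if (spec$type == "single") {
    eta <- exp(psi[1]); ell <- exp(psi[2:(1 + M)])
    K <- kernel_matrix(Xs, Xs, eta, ell)
  } else {
    eta_l <- exp(psi[1]); ell_l <- exp(psi[2:(1 + M)])
    eta_h <- exp(psi[M + 2]); ell_h <- exp(psi[(M + 3):(2 * M + 2)])
    rho <- psi[2 * M + 3]
    XL <- Xs[seq_len(n_low), , drop = FALSE]
    XH <- Xs[-seq_len(n_low), , drop = FALSE]
    KL <- kernel_matrix(XL, XL, eta_l, ell_l)
    KLH <- rho * kernel_matrix(XL, XH, eta_l, ell_l)
    KH <- rho^2 * kernel_matrix(XH, XH, eta_l, ell_l) +
      kernel_matrix(XH, XH, eta_h, ell_h)
    K <- rbind(cbind(KL, KLH), cbind(t(KLH), KH))
  }
  K + diag(spec$jitter, nrow(K))
}

ess_update <- function(u, Lc, y, loglik) {
  n <- length(u)
  nu <- stats::rnorm(n)
  logy <- loglik(as.numeric(Lc %*% u), y) + log(stats::runif(1))
  ang <- stats::runif(1, 0, 2 * pi)
  lo <- ang - 2 * pi; hi <- ang
  repeat {
    up <- u * cos(ang) + nu * sin(ang)
    if (loglik(as.numeric(Lc %*% up), y) > logy) return(up)
    if (ang < 0) lo <- ang else hi <- ang
    ang <- stats::runif(1, lo, hi)
    if (hi - lo < 1e-12) return(u)  # degenerate slice; keep current point
  }
}

run_gp_mcmc <- function(Xs, y, spec, n_chains, n_draws, n_tune, seed) {
  n <- nrow(Xs)
  npsi <- length(spec$kind)
  draws_psi <- array(NA_real_, c(n_draws, n_chains, npsi))
  draws_f <- array(NA_real_, c(n, n_chains * n_draws))
  accept <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(seed + 1000 * ch)
    psi <- vapply(spec$kind, function(k)
      switch(k, log_eta = log(1), log_ell = log(1), rho = 1), numeric(1))
    u <- stats::rnorm(n, 0, 0.1)
    K <- build_cov(psi, spec, Xs, spec$n_low)
    Lc <- t(chol(K))
    lp <- hyper_logprior(psi, spec) + bern_loglik(as.numeric(Lc %*% u), y)
    step <- rep(0.15, npsi)
    n_acc <- 0L
    total <- n_tune + n_draws
    for (it in seq_len(total)) {
      # latent update (whitened elliptical slice)
      u <- ess_update(u, Lc, y, bern_loglik)
      lp <- hyper_logprior(psi, spec) + bern_loglik(as.numeric(Lc %*% u), y)
      # joint random-walk Metropolis on the hyperparameters
      psi_p <- psi + stats::rnorm(npsi) * step
      Kp <- build_cov(psi_p, spec, Xs, spec$n_low)
      ch_ok <- TRUE
      Lp <- tryCatch(t(chol(Kp)), error = function(e) { ch_ok <<- FALSE; NULL })
      if (ch_ok) {
        lp_p <- hyper_logprior(psi_p, spec) +
          bern_loglik(as.numeric(Lp %*% u), y)
        if (log(stats::runif(1)) < lp_p - lp) {
          psi <- psi_p; Lc <- Lp; lp <- lp_p
          if (it > n_tune) n_acc <- n_acc + 1L
          acc <- 1
        } else acc <- 0
      } else acc <- 0
      if (it <= n_tune)  # Robbins-Monro adaptation toward 25% acceptance
        step <- step * exp((acc - 0.25) / sqrt(it / 5 + 1))
      if (it > n_tune) {
        j <- it - n_tune
        draws_psi[j, ch, ] <- psi
        draws_f[, (ch - 1) * n_draws + j] <- as.numeric(Lc %*% u)
      }
    }
    accept[ch] <- n_acc / n_draws
  }
  list(psi = draws_psi, f = draws_f, accept = accept)
}

split_rhat <- function(x) {
  # x: iterations x chains
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n <- floor(nrow(x) / 2)
  if (n < 2) return(NA_real_)
  halves <- cbind(x[seq_len(n), , drop = FALSE],
                  x[(nrow(x) - n + 1):nrow(x), , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves); vars <- apply(halves, 2, stats::var)
  B <- n * stats::var(means); W <- mean(vars)
  if (W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

finish_posterior <- function(mc, spec, Xs, y, Xraw, mu, sdv, n_low, seed,
                             n_chains, n_draws) {
  rhats <- vapply(seq_along(spec$kind), function(k)
    split_rhat(mc$psi[, , k, drop = TRUE]), numeric(1))
  if (any(rhats > 1.05, na.rm = TRUE))
    warning(sprintf("sampler convergence suspect: max split-Rhat = %.3f",
                    max(rhats, na.rm = TRUE)), call. = FALSE)
  psi_flat <- do.call(rbind, lapply(seq_len(dim(mc$psi)[2]), function(ch)
    mc$psi[, ch, ]))
  colnames(psi_flat) <- spec$names
  structure(list(
    type = spec$type, M = spec$M, psi = psi_flat, f = mc$f,
    X = Xs, y = y, X_raw = Xraw, n_low = n_low,
    center = mu, scale = sdv, jitter = spec$jitter, seed = seed,
    n_chains = n_chains, n_draws = n_draws,
    diagnostics = list(rhat = stats::setNames(rhats, spec$names),
                       accept_rate = mc$accept, n_divergent = 0L)
  ), class = "gp_posterior")
}

#' @export
print.gp_posterior <- function(x, ...) {
  cat(sprintf("<gp_posterior> %s-fidelity, %d training points, %d draws (%d chains)\n",
              x$type, nrow(x$X), nrow(x$psi), x$n_chains))
  cat(sprintf("  max split-Rhat %.3f, mean MH acceptance %.2f\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              mean(x$diagnostics$accept_rate)))
  invisible(x)
}

# ---- fitting ----------------------------------------------------------------

standardize_x <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(Xs = sweep(sweep(X, 2, mu), 2, sdv, "/"), mu = mu, sd = sdv)
}

dataset_xy <- function(data) {
  if (inherits(data, "labeled_dataset") || is.data.frame(data))
    list(X = as.matrix(data[, c("beta_cal", "beta_kr")]), y = data$label)
  else if (is.list(data) && !is.null(data$X))
    list(X = as.matrix(data$X), y = as.integer(data$y))
  else stop("data must be a labeled_dataset or list(X, y)", call. = FALSE)
}

#' Fit a single-fidelity Gaussian-process classifier
#'
#' Latent-GP Bernoulli classification with an ARD squared-exponential kernel;
#' joint posterior over (eta, ell, latents) sampled exactly by whitened
#' elliptical slice sampling (latents) plus adaptive random-walk Metropolis
#' (hyperparameters). Inputs are standardized internally; the constants are
#' stored with the draws.
#'
#' @param data a [labeled_dataset()] (or `list(X, y)`); both classes must be
#'   present.
#' @param n_chains,n_draws,n_tune MCMC configuration (default 2 chains x 1000
#'   draws after 1000 tuning iterations).
#' @param seed RNG seed.
#' @param jitter diagonal stabilization added to every covariance.
#' @return A `gp_posterior` with hyperparameter and latent draws, sampler
#'   diagnostics (split-Rhat, acceptance rates) and standardization constants.
#' @export
fit_single_fidelity <- function(data, n_chains = 2, n_draws = 1000,
                                n_tune = 1000, seed = 1, jitter = 1e-6) {
  d <- dataset_xy(data)
  if (length(unique(d$y)) < 2)
    stop("both classes must be present", call. = FALSE)
  st <- standardize_x(d$X)
  M <- ncol(d$X)
  spec <- list(type = "single", M = M, jitter = jitter, n_low = nrow(d$X),
               kind = c("log_eta", rep("log_ell", M)),
               names = c("log_eta", paste0("log_ell", seq_len(M))))
  mc <- run_gp_mcmc(st$Xs, d$y, spec, n_chains, n_draws, n_tune, seed)
  finish_posterior(mc, spec, st$Xs, d$y, d$X, st$mu, st$sd, nrow(d$X), seed,
                   n_chains, n_draws)
}

#' Fit a multi-fidelity Gaussian-process classifier
#'
#' Autoregressive two-fidelity latent model `f_H(x) = rho f_L(x) + delta(x)`
#' with independent ARD squared-exponential GP priors on `f_L` and the
#' discrepancy `delta`, and a scalar correlation `rho ~ Normal(0, 10)`.
#' Low-fidelity rows use `f_L`, high-fidelity rows `f_H`; predictions target
#' the high-fidelity level.
#'
#' @param data_low,data_high [labeled_dataset()]s for the two fidelities;
#'   `data_low` must be non-empty.
#' @inheritParams fit_single_fidelity
#' @return A `gp_posterior` (type "multi").
#' @export
fit_multi_fidelity <- function(data_low, data_high, n_chains = 2,
                               n_draws = 1000, n_tune = 1000, seed = 1,
                               jitter = 1e-6) {
  dl <- dataset_xy(data_low); dh <- dataset_xy(data_high)
  if (nrow(dl$X) == 0)
    stop("the low-fidelity set must be non-empty: the multi-fidelity model ",
         "infers the high level through the low-fidelity surface; use ",
         "fit_single_fidelity() for a high-only classifier", call. = FALSE)
  if (nrow(dh$X) == 0) stop("high-fidelity set is empty", call. = FALSE)
  if (length(unique(c(dl$y, dh$y))) < 2)
    stop("both classes must be present", call. = FALSE)
  if (length(unique(dh$y)) < 2)
    warning("high-fidelity set contains a single class", call. = FALSE)
  X <- rbind(dl$X, dh$X); y <- c(dl$y, dh$y)
  st <- standardize_x(X)
  M <- ncol(X)
  spec <- list(type = "multi", M = M, jitter = jitter, n_low = nrow(dl$X),
               kind = c("log_eta", rep("log_ell", M),
                        "log_eta", rep("log_ell", M), "rho"),
               names = c("log_eta_L", paste0("log_ell_L", seq_len(M)),
                         "log_eta_H", paste0("log_ell_H", seq_len(M)), "rho"))
  mc <- run_gp_mcmc(st$Xs, y, spec, n_chains, n_draws, n_tune, seed)
  finish_posterior(mc, spec, st$Xs, y, X, st$mu, st$sd, nrow(dl$X), seed,
                   n_chains, n_draws)
}

# ---- prediction -------------------------------------------------------------

# cross-covariance between prediction points (standardized) and training rows,
# plus the prior variance at the prediction points, for one psi draw
cross_cov <- function(psi, spec_type, M, Xs_star, Xs, n_low) {
  if (spec_type == "single") {
    eta <- exp(psi[1]); ell <- exp(psi[2:(1 + M)])
    list(C = kernel_matrix(Xs_star, Xs, eta, ell), v0 = eta)
  } else {
    eta_l <- exp(psi[1]); ell_l <- exp(psi[2:(1 + M)])
    eta_h <- exp(psi[M + 2]); ell_h <- exp(psi[(M + 3):(2 * M + 2)])
    rho <- psi[2 * M + 3]
    XL <- Xs[seq_len(n_low), , drop = FALSE]
    XH <- Xs[-seq_len(n_low), , drop = FALSE]
    CL <- rho * kernel_matrix(Xs_star, XL, eta_l, ell_l)
    CH <- rho^2 * kernel_matrix(Xs_star, XH, eta_l, ell_l) +
      kernel_matrix(Xs_star, XH, eta_h, ell_h)
    list(C = cbind(CL, CH), v0 = rho^2 * eta_l + eta_h)
  }
}

# sampled latent values f*(x) per retained draw: npoints x n_kept matrix
latent_samples <- function(draws, X_star, n_pred_draws = 200, seed = NULL) {
  if (ncol(as.matrix(X_star)) != draws$M)
    stop("prediction points have wrong dimensionality", call. = FALSE)
  if (is.null(seed)) seed <- draws$seed + 77L
  set.seed(seed)
  Xs_star <- sweep(sweep(as.matrix(X_star), 2, draws$center), 2, draws$scale,
                   "/")
  total <- nrow(draws$psi)
  keep <- unique(round(seq(1, total, length.out = min(n_pred_draws, total))))
  np <- nrow(Xs_star)
  out <- matrix(NA_real_, np, length(keep))
  for (k in seq_along(keep)) {
    psi <- draws$psi[keep[k], ]
    K <- build_cov_from_names(psi, draws, draws$X)
    Lc <- t(chol(K))
    f <- draws$f[, keep[k]]
    cc <- cross_cov(psi, draws$type, draws$M, Xs_star, draws$X, draws$n_low)
    A <- forwardsolve(Lc, t(cc$C))            # n x np
    mu <- as.numeric(crossprod(A, forwardsolve(Lc, f)))
    v <- pmax(cc$v0 + draws$jitter - colSums(A^2), 1e-12)
    out[, k] <- mu + sqrt(v) * stats::rnorm(np)
  }
  out
}

build_cov_from_names <- function(psi, draws, Xs) {
  M <- draws$M
  kind <- if (draws$type == "single") c("log_eta", rep("log_ell", M))
          else c("log_eta", rep("log_ell", M), "log_eta",
                 rep("log_ell", M), "rho")
  spec <- list(type = draws$type, M = M, jitter = draws$jitter, kind = kind)
  build_cov(psi, spec, Xs, draws$n_low)
}

#' Posterior class probabilities at new points
#'
#' For each retained posterior draw the latent `f*` is sampled from its GP
#' predictive conditional and passed through the logistic sigmoid; the
#' function returns the Monte-Carlo mean and standard deviation of the class
#' probability at each point. Multi-fidelity posteriors predict the
#' high-fidelity level.
#'
#' @param classifier a `gp_posterior`, or a plain function mapping an
#'   `n x 2` matrix to class probabilities (useful as an analytic stand-in).
#' @param X_star points (n x 2 matrix, original input scale).
#' @param n_pred_draws number of posterior draws used (thinned evenly).
#' @param seed RNG seed for the predictive sampling (default: derived from the
#'   fit seed, so repeated calls are identical).
#' @param ... passed to methods.
#' @return data.frame with columns `mean`, `sd`.
#' @export
predict_probability <- function(classifier, X_star, ...) {
  UseMethod("predict_probability")
}

#' @rdname predict_probability
#' @export
predict_probability.gp_posterior <- function(classifier, X_star,
                                             n_pred_draws = 200, seed = NULL,
                                             ...) {
  fs <- latent_samples(classifier, X_star, n_pred_draws, seed)
  p <- stats::plogis(fs)
  data.frame(mean = rowMeans(p), sd = apply(p, 1, stats::sd))
}

#' @rdname predict_probability
#' @export
predict_probability.function <- function(classifier, X_star, ...) {
  data.frame(mean = classifier(as.matrix(X_star)), sd = 0)
}

#' Class-probability grid over the block plane
#'
#' @param draws a `gp_posterior`.
#' @param resolution grid resolution per axis.
#' @param bounds lower/upper bound of both axes.
#' @inheritParams predict_probability
#' @return A `probability_grid`: list with `x` (beta_CaL axis), `y` (beta_Kr
#'   axis), `mean`, `sd` (resolution x resolution matrices, x indexing rows).
#' @export
probability_grid <- function(draws, resolution = 101, bounds = c(0, 0.95),
                             n_pred_draws = 200, seed = NULL) {
  gx <- seq(bounds[1], bounds[2], length.out = resolution)
  gy <- seq(bounds[1], bounds[2], length.out = resolution)
  G <- as.matrix(expand.grid(beta_cal = gx, beta_kr = gy))
  pr <- predict_probability(draws, G, n_pred_draws, seed)
  structure(list(x = gx, y = gy,
                 mean = matrix(pr$mean, resolution, resolution),
                 sd = matrix(pr$sd, resolution, resolution)),
            class = "probability_grid")
}

#' Extract the decision boundary from a probability grid
#'
#' Marching-squares contour of the mean-probability field at `level`,
#' returned as ordered polyline(s). An empty data.frame (zero rows) is
#' returned when the level is never crossed.
#'
#' @param grid a [probability_grid()].
#' @param level probability level (default 0.5).
#' @return data.frame with columns `beta_cal`, `beta_kr`, `piece`.
#' @export
extract_boundary <- function(grid, level = 0.5) {
  cl <- grDevices::contourLines(grid$x, grid$y, grid$mean, levels = level)
  if (!length(cl))
    return(data.frame(beta_cal = numeric(0), beta_kr = numeric(0),
                      piece = integer(0)))
  do.call(rbind, lapply(seq_along(cl), function(i)
    data.frame(beta_cal = cl[[i]]$x, beta_kr = cl[[i]]$y, piece = i)))
}
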