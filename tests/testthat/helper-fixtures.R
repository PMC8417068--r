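# shared fixtures: cheap sampler settings and hand-built traces

fast_sampler <- list(n_chains = 2, n_draws = 250, n_tune = 250)

# instantaneous upstroke from v_rest to v_peak at t = 1 ms, then linear decay
# back to rest over `decay_ms`; sampled at 1 ms
linear_decay_trace <- function(v_rest = -85, v_peak = 40, decay_ms = 300,
                               cl = 1000) {
  t <- seq(0, cl, by = 1)
  v <- ifelse(t < 1, v_rest,
              pmax(v_peak - (v_peak - v_rest) / decay_ms * (t - 1), v_rest))
  cardiosex:::new_ap_trace(t, v, 0, cl)
}

flat_trace <- function(level = -85, cl = 1000) {
  t <- seq(0, cl, by = 1)
  cardiosex:::new_ap_trace(t, rep(level, length(t)), 0, cl)
}

# fast pacing protocol for solver-level unit tests
tiny_protocol <- function(n_prepace = 3, n_beats = 1)
  pacing_protocol(cl = 1000, n_prepace = n_prepace, n_beats = n_beats)

# gp_posterior with hand-chosen constant hyperparameters and latents, used to
# test the prediction equations independently of MCMC
stub_posterior <- function(type, X, y, f, psi_row, n_low = nrow(X),
                           n_draws = 50, seed = 123) {
  Xm <- as.matrix(X)
  structure(list(
    type = type, M = ncol(Xm),
    psi = matrix(rep(psi_row, each = n_draws), nrow = n_draws,
                 dimnames = list(NULL, names(psi_row))),
    f = matrix(rep(f, n_draws), ncol = n_draws),
    X = Xm, y = y, X_raw = Xm, n_low = n_low,
    center = rep(0, ncol(Xm)), scale = rep(1, ncol(Xm)),
    jitter = 1e-6, seed = seed, n_chains = 1, n_draws = n_draws,
    diagnostics = list(rhat = NA, accept_rate = 1, n_divergent = 0L)
  ), class = "gp_posterior")
}
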