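# Shared fixtures: synthetic observers and small studies, built in code.

make_observers <- function(n, phi = 0.75, sigma_i = 0.15, sigma_meta = 0.5) {
  obs <- lapply(seq_len(n), function(s) {
    observer_params(phi = phi, sigma_i1 = sigma_i, sigma_i2 = sigma_i,
                    sigma_meta = sigma_meta)
  })
  names(obs) <- sprintf("S%02d", seq_len(n))
  obs
}

make_study <- function(n_subjects = 3, n_trials = 60, seed = 1,
                       total_duration = 1.5, ...) {
  simulate_study(make_observers(n_subjects, ...),
                 total_duration = total_duration,
                 schedule = schedule_spec(n_trials = n_trials,
                                          block_size = n_trials),
                 seed = seed)
}

# A minimal fit-shaped object with hand-set posterior draws, for deterministic
# tests of draw-based summaries (DIC composition, midpoint summaries,
# posterior-predictive limits) without running MCMC.
fake_fit <- function(draws, subjects, conditions, total_duration = 1.5,
                     spec = hier_model_spec()) {
  structure(list(draws = draws, chain = rep(1L, nrow(draws)),
                 samples = NULL, summary = NULL, rhat = NULL,
                 max_rhat = 1, converged = TRUE, subjects = subjects,
                 conditions = conditions, true_mid = total_duration / 2,
                 total_duration = total_duration, spec = spec,
                 mcmc = mcmc_control()),
            class = "bisect_fit")
}

# Draw matrix in the fit's parameter naming for constant parameter values.
constant_draws <- function(n_draws, mid, sigma_i1, sigma_i2, sigma_meta,
                           subjects, conditions) {
  S <- length(subjects); C <- length(conditions)
  cols <- c(sprintf("mid[%d]", seq_len(C)))
  vals <- as.numeric(mid)
  for (s in seq_len(S)) for (r in 1:3) for (c in seq_len(C)) {
    cols <- c(cols, sprintf("sigma[%d,%d,%d]", s, r, c))
    sig <- switch(r, `1` = sigma_i1, `2` = sigma_i2, `3` = sigma_meta)
    vals <- c(vals, if (length(sig) == C) sig[c] else sig)
  }
  matrix(rep(vals, each = n_draws), nrow = n_draws,
         dimnames = list(NULL, cols))
}
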