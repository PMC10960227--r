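#' Hierarchical model specification
#'
#' Configures the hierarchical Bayesian measurement model of bisection and
#' metacognitive precision. The `full` variant estimates, for every subject,
#' one precision per condition and role (interval 1, interval 2,
#' metacognitive), coupled across conditions through a multivariate normal on
#' the log-precision scale with a shared coupling scale and a subject-specific
#' correlation `rho[s] ~ Uniform(0, 1)`; the `constrained` variant forces each
#' subject's precisions to be equal across the V/A/AV conditions. Group-level
#' precision means carry Uniform priors on the precision (1/sigma^2) scale, as
#' do the midpoint spread precisions. Condition midpoints are drawn around a
#' grand subjective midpoint, itself centred on the veridical midpoint.
#'
#' @param variant `"full"` (condition-specific precisions) or `"constrained"`
#'   (shared across conditions).
#' @param error_type `"absolute"` (perceived error `|I - phi|`, default) or
#'   `"signed"` (`I - phi`, sensitivity analysis).
#' @param mvn_scale Scale on which the subject-level cross-condition coupling
#'   acts: `"log"` (default; log precisions, positivity by construction) or
#'   `"precision"` (literal precision scale, floored at 1e-4).
#' @param epsilon Diagonal regulariser added to the coupling covariance so it
#'   stays positive definite (default 0.1).
#' @param prior_precision_max Upper bound of the uniform precision priors
#'   (default 100). The lower bound is 1e-6 rather than 0 so the log of a
#'   group mean precision is always defined.
#' @param rhat_threshold Convergence flag threshold on the maximum split
#'   rank-normalised R-hat (default 1.05).
#' @return An object of class `"hier_model_spec"`.
#' @export
hier_model_spec <- function(variant = c("full", "constrained"),
                            error_type = c("absolute", "signed"),
                            mvn_scale = c("log", "precision"),
                            epsilon = 0.1, prior_precision_max = 100,
                            rhat_threshold = 1.05) {
  stopifnot(epsilon > 0, prior_precision_max > 0)
  structure(list(variant = match.arg(variant),
                 error_type = match.arg(error_type),
                 mvn_scale = match.arg(mvn_scale),
                 epsilon = epsilon,
                 prior_precision_max = prior_precision_max,
                 rhat_threshold = rhat_threshold),
            class = "hier_model_spec")
}

#' MCMC settings
#'
#' Defaults mirror the reference sampling plan: two chains, 2000 burn-in
#' iterations, 5000 sampling iterations thinned every 20th draw.
#'
#' @param n_chains Number of chains (default 2).
#' @param burn_in Burn-in iterations per chain (default 2000).
#' @param n_samples Sampling iterations per chain before thinning
#'   (default 5000).
#' @param thin Thinning interval (default 20).
#' @param n_adapt Adaptation iterations (default 500).
#' @param seed Integer seed; chain-level RNG seeds are derived from it.
#' @return An object of class `"mcmc_control"`.
#' @export
mcmc_control <- function(n_chains = 2, burn_in = 2000, n_samples = 5000,
                         thin = 20, n_adapt = 500, seed = 1) {
  stopifnot(n_chains >= 1, burn_in >= 0, n_samples >= thin, thin >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in),
                 n_samples = as.integer(n_samples),
                 thin = as.integer(thin), n_adapt = as.integer(n_adapt),
                 seed = as.integer(seed)),
            class = "mcmc_control")
}

# Build the JAGS model string for a given spec and number of conditions.
.jags_model_string <- function(spec, n_cond) {
  err <- if (spec$error_type == "absolute") {
    "abs(%s)"
  } else {
    "(%s)"
  }
  e1 <- sprintf(err, "I1[i] - mid[cond[i]]")
  e2 <- sprintf(err, "I2[i] - mid[cond[i]]")
  pmax_ <- spec$prior_precision_max
  head <- sprintf("
model {
  tau_mid ~ dunif(1.0E-6, %g)
  tau_cond ~ dunif(1.0E-6, %g)
  mid_overall ~ dnorm(true_mid, tau_mid)
  for (c in 1:C) { mid[c] ~ dnorm(mid_overall, tau_cond) }
  sigma_mid_overall <- 1 / sqrt(tau_mid)
  sigma_mid_cond <- 1 / sqrt(tau_cond)
  tau_couple ~ dunif(1.0E-2, %g)
  sc2 <- 1 / tau_couple
", pmax_, pmax_, pmax_)

  group_full <- sprintf("
  for (r in 1:3) { for (c in 1:C) {
    mu_tau[r, c] ~ dunif(1.0E-6, %g)
    lmu[r, c] <- log(mu_tau[r, c])
    sigma_group[r, c] <- 1 / sqrt(mu_tau[r, c])
  } }
", pmax_)

  subj_full_log <- if (n_cond >= 2) "
  for (s in 1:S) {
    rho[s] ~ dunif(0, 1)
    for (j in 1:C) { for (k in 1:C) {
      Sig[s, j, k] <- sc2 * ((1 - rho[s]) * equals(j, k) + rho[s]) +
        epsilon * equals(j, k)
    } }
    Omega[s, 1:C, 1:C] <- inverse(Sig[s, 1:C, 1:C])
    for (r in 1:3) {
      ltau[s, r, 1:C] ~ dmnorm(lmu[r, 1:C], Omega[s, 1:C, 1:C])
      for (c in 1:C) {
        tau[s, r, c] <- exp(ltau[s, r, c])
        sigma[s, r, c] <- 1 / sqrt(tau[s, r, c])
      }
    }
  }
" else "
  for (s in 1:S) {
    rho[s] ~ dunif(0, 1)
    for (r in 1:3) {
      ltau[s, r, 1] ~ dnorm(lmu[r, 1], 1 / (sc2 + epsilon))
      tau[s, r, 1] <- exp(ltau[s, r, 1])
      sigma[s, r, 1] <- 1 / sqrt(tau[s, r, 1])
    }
  }
"

  subj_full_prec <- if (n_cond >= 2) "
  for (s in 1:S) {
    rho[s] ~ dunif(0, 1)
    for (j in 1:C) { for (k in 1:C) {
      Sig[s, j, k] <- sc2 * ((1 - rho[s]) * equals(j, k) + rho[s]) +
        epsilon * equals(j, k)
    } }
    Omega[s, 1:C, 1:C] <- inverse(Sig[s, 1:C, 1:C])
    for (r in 1:3) {
      traw[s, r, 1:C] ~ dmnorm(mu_tau[r, 1:C], Omega[s, 1:C, 1:C])
      for (c in 1:C) {
        tau[s, r, c] <- max(traw[s, r, c], 1.0E-4)
        sigma[s, r, c] <- 1 / sqrt(tau[s, r, c])
      }
    }
  }
" else "
  for (s in 1:S) {
    rho[s] ~ dunif(0, 1)
    for (r in 1:3) {
      traw[s, r, 1] ~ dnorm(mu_tau[r, 1], 1 / (sc2 + epsilon))
      tau[s, r, 1] <- max(traw[s, r, 1], 1.0E-4)
      sigma[s, r, 1] <- 1 / sqrt(tau[s, r, 1])
    }
  }
"

  group_constrained <- sprintf("
  for (r in 1:3) {
    mu_tau[r] ~ dunif(1.0E-6, %g)
    lmu[r] <- log(mu_tau[r])
    sigma_group[r] <- 1 / sqrt(mu_tau[r])
  }
  for (s in 1:S) {
    for (r in 1:3) {
      ltau0[s, r] ~ dnorm(lmu[r], 1 / (sc2 + epsilon))
      for (c in 1:C) {
        tau[s, r, c] <- exp(ltau0[s, r])
        sigma[s, r, c] <- 1 / sqrt(tau[s, r, c])
      }
    }
  }
", pmax_)

  lik <- sprintf("
  for (i in 1:N) {
    I1[i] ~ dnorm(mid[cond[i]], tau[subj[i], 1, cond[i]])
    I2[i] ~ dnorm(mid[cond[i]], tau[subj[i], 2, cond[i]])
    d1[i] <- %s
    d2[i] <- %s
    praw[i] <- phi((d2[i] - d1[i]) * sqrt(tau[subj[i], 3, cond[i]]))
    p[i] <- max(min(praw[i], 1 - 1.0E-12), 1.0E-12)
    y[i] ~ dbern(p[i])
  }
}
", e1, e2)

  mid_block <- if (spec$variant == "constrained") {
    group_constrained
  } else if (spec$mvn_scale == "log") {
    paste0(group_full, subj_full_log)
  } else {
    paste0(group_full, subj_full_prec)
  }
  paste0(head, mid_block, lik)
}

# Data-driven initial values for one chain.
.jags_inits <- function(data, spec, subjects, conditions, chain_seed) {
  S <- length(subjects)
  C <- length(conditions)
  emp_tau <- array(1, dim = c(S, 3, C))
  for (s in seq_len(S)) for (c in seq_len(C)) {
    cell <- data[data$subject_id == subjects[s] &
                   data$condition == conditions[c], ]
    if (nrow(cell) >= 2) {
      emp_tau[s, 1, c] <- min(max(1 / var(cell$estimate1), 1e-3), 99)
      emp_tau[s, 2, c] <- min(max(1 / var(cell$estimate2), 1e-3), 99)
    }
    emp_tau[s, 3, c] <- 1
  }
  mids <- vapply(conditions, function(cc) {
    cell <- data[data$condition == cc, ]
    mean(c(cell$estimate1, cell$estimate2))
  }, numeric(1))
  inits <- list(
    .RNG.name = "base::Mersenne-Twister",
    .RNG.seed = chain_seed,
    tau_mid = 50, tau_cond = 50, tau_couple = 25,
    mid_overall = mean(mids), mid = as.numeric(mids)
  )
  mu <- apply(emp_tau, c(2, 3), mean)
  mu <- pmin(pmax(mu, 1e-3), 99)
  if (spec$variant == "constrained") {
    inits$mu_tau <- rowMeans(mu)
    lt0 <- matrix(0, S, 3)
    for (s in seq_len(S)) lt0[s, ] <- log(rowMeans(mu))
    inits$ltau0 <- lt0
  } else {
    inits$mu_tau <- mu
    inits$rho <- rep(0.5, S)
    if (spec$mvn_scale == "log") {
      inits$ltau <- log(emp_tau)
    } else {
      inits$traw <- emp_tau
    }
  }
  inits
}

#' Fit the hierarchical bisection/metacognition model
#'
#' Samples the posterior of the measurement model by MCMC (JAGS). The
#' likelihood of each trial combines two normal densities for the bisection
#' estimates, centred on the condition's subjective midpoint with
#' subject-by-condition precisions, and a Bernoulli mass for the metacognitive
#' choice whose probability is the probit read-out of the perceived error
#' difference (see [choice_probability()]). Each duration condition is fitted
#' separately: the input must contain a single `total_duration`.
#'
#' Convergence is assessed with the split rank-normalised R-hat ([rhat()]) on
#' every monitored parameter; a fit whose maximum R-hat exceeds the spec's
#' threshold is flagged (`converged = FALSE`) with a warning, never returned
#' silently.
#'
#' @param data Validated session data frame, one duration condition.
#' @param spec A [hier_model_spec()].
#' @param mcmc An [mcmc_control()].
#' @param quiet Suppress JAGS progress output (default `TRUE`).
#' @return An object of class `"bisect_fit"`: list with `draws` (matrix,
#'   retained draws by parameter), `chain` (chain index per draw), `samples`
#'   (the underlying [coda::mcmc.list]), `summary` (parameter, mean, sd,
#'   `hdi_low`, `hdi_high`, `rhat`), `rhat`, `max_rhat`, `converged`,
#'   `subjects`, `conditions`, `true_mid`, `total_duration`, `spec`, `mcmc`.
#' @export
fit_hier_model <- function(data, spec = hier_model_spec(),
                           mcmc = mcmc_control(), quiet = TRUE) {
  validate_trials(data)
  if (nrow(data) < 2) stop("insufficient data: need at least 2 trials",
                           call. = FALSE)
  dur <- unique(data$total_duration)
  if (length(dur) != 1) {
    stop("fit each duration condition separately: ",
         "data contain multiple total_duration values", call. = FALSE)
  }
  subjects <- sort(unique(data$subject_id))
  conditions <- intersect(.conditions, unique(data$condition))
  per_cell <- table(data$subject_id, data$condition)
  if (any(per_cell[per_cell > 0] < 2)) {
    stop("insufficient data: need at least 2 trials per subject-condition",
         call. = FALSE)
  }
  true_mid <- dur / 2

  jdata <- list(
    N = nrow(data), S = length(subjects), C = length(conditions),
    I1 = data$estimate1, I2 = data$estimate2,
    y = as.integer(data$meta_choice == 1L),
    subj = match(data$subject_id, subjects),
    cond = match(data$condition, conditions),
    true_mid = true_mid, epsilon = spec$epsilon
  )

  set.seed(mcmc$seed)
  chain_seeds <- sample.int(.Machine$integer.max %/% 2, mcmc$n_chains)
  inits <- lapply(chain_seeds, function(cs) {
    .jags_inits(data, spec, subjects, conditions, cs)
  })

  monitors <- c("mid", "mid_overall", "sigma", "sigma_group",
                "sigma_mid_overall", "sigma_mid_cond", "tau_couple")
  if (spec$variant == "full") monitors <- c(monitors, "rho")

  model_txt <- .jags_model_string(spec, length(conditions))
  run <- function() {
    jm <- rjags::jags.model(textConnection(model_txt), data = jdata,
                            inits = inits, n.chains = mcmc$n_chains,
                            n.adapt = mcmc$n_adapt, quiet = quiet)
    if (mcmc$burn_in > 0) {
      update(jm, n.iter = mcmc$burn_in,
             progress.bar = if (quiet) "none" else "text")
    }
    rjags::coda.samples(jm, variable.names = monitors,
                        n.iter = mcmc$n_samples, thin = mcmc$thin,
                        progress.bar = if (quiet) "none" else "text")
  }
  samples <- if (quiet) suppressWarnings(run()) else run()

  draws <- do.call(rbind, lapply(samples, as.matrix))
  chain <- rep(seq_along(samples), vapply(samples, nrow, integer(1)))

  rh <- vapply(colnames(draws), function(pn) {
    m <- vapply(samples, function(ch) as.matrix(ch)[, pn], numeric(nrow(samples[[1]])))
    tryCatch(rhat(m), error = function(e) NA_real_)
  }, numeric(1))
  max_rhat <- max(rh, na.rm = TRUE)
  converged <- is.finite(max_rhat) && max_rhat <= spec$rhat_threshold

  summ <- data.frame(parameter = colnames(draws),
                     mean = colMeans(draws),
                     sd = apply(draws, 2, sd),
                     t(apply(draws, 2, function(x) {
                       h <- hdi(x)
                       c(hdi_low = h[1], hdi_high = h[2])
                     })),
                     rhat = rh, row.names = NULL)

  fit <- structure(list(draws = draws, chain = chain, samples = samples,
                        summary = summ, rhat = rh, max_rhat = max_rhat,
                        converged = converged, subjects = subjects,
                        conditions = conditions, true_mid = true_mid,
                        total_duration = dur, spec = spec, mcmc = mcmc),
                   class = "bisect_fit")
  if (!converged) {
    warning(sprintf("fit flagged: max R-hat %.4f exceeds threshold %.2f",
                    max_rhat, spec$rhat_threshold))
  }
  fit
}

#' @export
print.bisect_fit <- function(x, ...) {
  cat(sprintf("Hierarchical bisection/metacognition fit (%s variant)\n",
              x$spec$variant))
  cat(sprintf("  %d subjects, conditions %s, total duration %.3f s\n",
              length(x$subjects), paste(x$conditions, collapse = "/"),
              x$total_duration))
  cat(sprintf("  %d retained draws over %d chains; max R-hat %.4f (%s)\n",
              nrow(x$draws), length(x$samples), x$max_rhat,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# Extract per-draw structured parameters from a fit: group midpoints and the
# subject-by-role-by-condition SD array.
.draw_params <- function(fit, d) {
  S <- length(fit$subjects)
  C <- length(fit$conditions)
  draws <- fit$draws
  mid_name <- function(c) {
    nm <- sprintf("mid[%d]", c)
    if (nm %in% colnames(draws)) nm else "mid"
  }
  mid <- setNames(vapply(seq_len(C), function(c) {
    draws[d, mid_name(c)]
  }, numeric(1)), fit$conditions)
  sig <- array(NA_real_, dim = c(S, 3, C),
               dimnames = list(fit$subjects, c("i1", "i2", "meta"),
                               fit$conditions))
  for (s in seq_len(S)) for (r in 1:3) for (c in seq_len(C)) {
    sig[s, r, c] <- draws[d, sprintf("sigma[%d,%d,%d]", s, r, c)]
  }
  role <- function(r) {
    m <- sig[, r, , drop = FALSE]
    dim(m) <- c(S, C)
    dimnames(m) <- list(fit$subjects, fit$conditions)
    m
  }
  list(mid = mid, sigma_i1 = role(1), sigma_i2 = role(2),
       sigma_meta = role(3))
}
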