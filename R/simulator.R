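#' Trial-schedule specification
#'
#' Describes the session structure of the paradigm: 500 trial-pairs presented
#' in blocks of 100, a random pre-stimulus delay of 0-250 ms on each interval,
#' a 500 ms inter-stimulus interval, and auditory feedback on whether the
#' chosen interval was closest to the veridical midpoint. The jitter and ISI
#' are schedule metadata: they shape the session's timing, not the estimates.
#'
#' @param n_trials Number of trial-pairs (default 500).
#' @param block_size Trials per block (default 100); `n_trials` must be a
#'   multiple of `block_size`.
#' @param jitter_range Pre-stimulus delay range in seconds (default 0-0.25).
#' @param isi Inter-stimulus interval in seconds (default 0.5).
#' @param feedback Whether correctness feedback is given (default `TRUE`).
#' @return An object of class `"schedule_spec"`.
#' @export
schedule_spec <- function(n_trials = 500, block_size = 100,
                          jitter_range = c(0, 0.250), isi = 0.500,
                          feedback = TRUE) {
  stopifnot(n_trials >= 0, block_size >= 1, length(jitter_range) == 2,
            jitter_range[1] >= 0, diff(jitter_range) >= 0, isi >= 0)
  if (n_trials %% block_size != 0) {
    stop("n_trials must be a multiple of block_size", call. = FALSE)
  }
  structure(list(n_trials = as.integer(n_trials),
                 block_size = as.integer(block_size),
                 jitter_range = as.numeric(jitter_range),
                 isi = as.numeric(isi),
                 feedback = isTRUE(feedback)),
            class = "schedule_spec")
}

#' Generative parameters of a synthetic observer
#'
#' One observer is characterised, per modality condition, by a subjective
#' midpoint `phi` (the internal estimate of half the interval, seconds),
#' interval-specific bisection SDs `sigma_i1`/`sigma_i2`, and a metacognitive
#' SD `sigma_meta` governing how noisily the error difference between the two
#' estimates is read out. `rho` is the cross-condition coupling used when
#' observers are drawn hierarchically. An optional `drift` gives the early
#' "guessing" phase of a session: the effective midpoint starts offset from
#' `phi` and decays exponentially toward it.
#'
#' @param phi Subjective midpoint(s), seconds: a scalar recycled across
#'   conditions or a vector named by condition.
#' @param sigma_i1,sigma_i2 Bisection estimate SD(s), seconds.
#' @param sigma_meta Metacognitive SD(s), seconds.
#' @param rho Cross-condition coupling in `[0, 1]` (used by
#'   [sample_observers()]).
#' @param drift `NULL` (static midpoint, the default) or
#'   `list(offset = <s>, decay = <trials>)`.
#' @param conditions Condition labels (default `c("V", "A", "AV")`).
#' @return An object of class `"observer_params"`.
#' @export
observer_params <- function(phi, sigma_i1, sigma_i2, sigma_meta, rho = 0,
                            drift = NULL, conditions = .conditions) {
  expand <- function(x, name) {
    if (length(x) == 1) x <- setNames(rep(as.numeric(x), length(conditions)),
                                      conditions)
    if (is.null(names(x))) names(x) <- conditions
    if (!all(conditions %in% names(x))) {
      stop(name, " must cover every condition", call. = FALSE)
    }
    x[conditions]
  }
  phi <- expand(phi, "phi")
  sigma_i1 <- expand(sigma_i1, "sigma_i1")
  sigma_i2 <- expand(sigma_i2, "sigma_i2")
  sigma_meta <- expand(sigma_meta, "sigma_meta")
  if (any(phi <= 0)) stop("phi must be positive", call. = FALSE)
  if (any(c(sigma_i1, sigma_i2, sigma_meta) < 0)) {
    stop("SD parameters must be nonnegative", call. = FALSE)
  }
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]", call. = FALSE)
  if (!is.null(drift)) {
    stopifnot(is.list(drift), all(c("offset", "decay") %in% names(drift)),
              drift$decay > 0)
  }
  structure(list(phi = phi, sigma_i1 = sigma_i1, sigma_i2 = sigma_i2,
                 sigma_meta = sigma_meta, rho = rho, drift = drift,
                 conditions = conditions),
            class = "observer_params")
}

#' Probability of judging interval 1 the more accurate
#'
#' The observer compares the perceived errors of the two bisection attempts.
#' With `delta1` and `delta2` the (absolute) errors of intervals 1 and 2, the
#' perceived error difference is normally distributed around
#' `delta1 - delta2` with SD `sigma_meta`; interval 1 is chosen when the
#' perceived difference is negative, so the choice probability is the mass of
#' that normal below zero: `pnorm(-(delta1 - delta2) / sigma_meta)`.
#'
#' In the ideal-observer limit `sigma_meta == 0` the rule is deterministic:
#' probability 1 when `delta1 < delta2`, 0 when `delta1 > delta2`, and 1/2 at
#' exact ties.
#'
#' @param delta1,delta2 Numeric vectors of perceived errors (seconds).
#' @param sigma_meta Metacognitive SD (seconds), scalar or vector; `>= 0`.
#' @return Probability (vector) of choosing interval 1.
#' @export
choice_probability <- function(delta1, delta2, sigma_meta) {
  if (any(sigma_meta < 0)) stop("sigma_meta must be >= 0", call. = FALSE)
  ddelta <- delta1 - delta2
  p <- pnorm(-ddelta / sigma_meta)
  limit <- sigma_meta == 0
  if (any(limit)) {
    dl <- rep_len(ddelta, length(p))
    p[limit & dl < 0] <- 1
    p[limit & dl > 0] <- 0
    p[limit & dl == 0] <- 0.5
  }
  p
}

# Truncated-normal estimates by resampling: a button release cannot precede
# stimulus onset or follow its offset.
.sim_estimates <- function(n, mean, sd, lower, upper) {
  if (length(mean) == 1) mean <- rep(mean, n)
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean[bad], sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' Simulate a single trial-pair
#'
#' Draws the two bisection estimates from normals centred on the observer's
#' subjective midpoint (truncated to `[0, total_duration]`), compares their
#' perceived errors through [choice_probability()], and draws the
#' metacognitive choice as a Bernoulli outcome.
#'
#' @param obs An [observer_params()] object.
#' @param condition Condition label.
#' @param total_duration Total stimulus duration (seconds).
#' @param trial_index Trial number within the session.
#' @param subject_id Subject label.
#' @param error_type `"absolute"` (default): perceived errors are
#'   `|I - phi|`; `"signed"`: `I - phi` (sensitivity analysis only).
#' @return A one-row trial data frame (see [session_data()]).
#' @export
simulate_trial <- function(obs, condition, total_duration, trial_index = 1L,
                           subject_id = "S1",
                           error_type = c("absolute", "signed")) {
  ses <- simulate_session(obs, condition, total_duration,
                          schedule = schedule_spec(n_trials = 1,
                                                   block_size = 1),
                          subject_id = subject_id, error_type = error_type)
  ses$trial_index <- as.integer(trial_index)
  ses
}

#' Simulate a full session for one observer in one condition
#'
#' Runs the generative model forward for `schedule$n_trials` trial-pairs:
#' `I1 ~ Normal(phi_eff, sigma_i1)`, `I2 ~ Normal(phi_eff, sigma_i2)` (both
#' truncated to `[0, total_duration]` by resampling), perceived errors
#' `|I - phi|`, and the metacognitive choice Bernoulli with
#' [choice_probability()]. `feedback_correct` records whether the choice
#' matched the interval closest to the veridical midpoint; it does not alter
#' the observer. With a `drift` spec the effective midpoint on trial `t` is
#' `phi + offset * exp(-(t - 1) / decay)`.
#'
#' @inheritParams simulate_trial
#' @param schedule A [schedule_spec()].
#' @param seed Optional integer seed; identical seeds give identical sessions.
#' @return A validated session data frame with the schedule attached.
#' @export
simulate_session <- function(obs, condition, total_duration,
                             schedule = schedule_spec(), subject_id = "S1",
                             seed = NULL,
                             error_type = c("absolute", "signed")) {
  error_type <- match.arg(error_type)
  stopifnot(inherits(obs, "observer_params"), total_duration > 0)
  if (!condition %in% obs$conditions) {
    stop("condition not covered by observer parameters", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- schedule$n_trials
  if (n == 0) {
    return(session_data(data.frame(subject_id = character(),
                                   condition = character(),
                                   total_duration = numeric(),
                                   trial_index = integer(),
                                   estimate1 = numeric(),
                                   estimate2 = numeric(),
                                   meta_choice = integer()),
                        schedule = schedule))
  }
  phi <- obs$phi[[condition]]
  phi_eff <- rep(phi, n)
  if (!is.null(obs$drift)) {
    phi_eff <- phi + obs$drift$offset * exp(-(seq_len(n) - 1) / obs$drift$decay)
  }
  i1 <- .sim_estimates(n, phi_eff, obs$sigma_i1[[condition]], 0, total_duration)
  i2 <- .sim_estimates(n, phi_eff, obs$sigma_i2[[condition]], 0, total_duration)
  err <- function(x) if (error_type == "absolute") abs(x) else x
  p1 <- choice_probability(err(i1 - phi), err(i2 - phi),
                           obs$sigma_meta[[condition]])
  choice <- ifelse(runif(n) < p1, 1L, 2L)
  session_data(data.frame(subject_id = subject_id, condition = condition,
                          total_duration = total_duration,
                          trial_index = seq_len(n),
                          estimate1 = i1, estimate2 = i2,
                          meta_choice = choice),
               schedule = schedule)
}

#' Simulate a multi-subject, multi-condition study
#'
#' @param observers A named list of [observer_params()] (names are subject
#'   ids) as returned by [sample_observers()].
#' @param conditions Conditions to run (default all the observers cover).
#' @param total_duration Total stimulus duration (seconds).
#' @param schedule A [schedule_spec()].
#' @param seed Optional integer seed for the whole study.
#' @inheritParams simulate_trial
#' @return A validated session data frame stacking all subject-condition
#'   sessions.
#' @export
simulate_study <- function(observers, conditions = NULL, total_duration,
                           schedule = schedule_spec(), seed = NULL,
                           error_type = c("absolute", "signed")) {
  error_type <- match.arg(error_type)
  if (is.null(names(observers))) {
    names(observers) <- sprintf("S%02d", seq_along(observers))
  }
  if (is.null(conditions)) conditions <- observers[[1]]$conditions
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (sid in names(observers)) {
    for (cond in conditions) {
      out[[paste(sid, cond)]] <- simulate_session(
        observers[[sid]], cond, total_duration, schedule,
        subject_id = sid, seed = NULL, error_type = error_type)
    }
  }
  session_data(do.call(rbind, out), schedule = schedule)
}

#' Draw observers from a group-level distribution
#'
#' Subject-level SDs are drawn, per role (interval 1, interval 2,
#' metacognitive), from a log-normal centred on the group SD with
#' between-subject spread `subject_lsd` on the log scale, coupled across the
#' conditions with correlation `rho` (the repeated-measures coupling: an
#' observer precise in one modality tends to be precise in the others).
#' Subjective midpoints are drawn from `Normal(phi, phi_sd)` truncated to
#' positive values. Positivity of every parameter is guaranteed by
#' construction.
#'
#' @param group A list with elements `phi`, `sigma_i1`, `sigma_i2`,
#'   `sigma_meta` (group-level values, scalar or per-condition named vectors,
#'   seconds), and optionally `phi_sd` (default 0), `subject_lsd` (default
#'   0.2), `rho` (default 0.6).
#' @param n_subjects Number of observers to draw.
#' @param seed Optional integer seed.
#' @param conditions Condition labels.
#' @return A named list of [observer_params()].
#' @export
sample_observers <- function(group, n_subjects, seed = NULL,
                             conditions = .conditions) {
  stopifnot(n_subjects >= 1)
  if (!is.null(seed)) set.seed(seed)
  phi_sd <- if (is.null(group$phi_sd)) 0 else group$phi_sd
  lsd <- if (is.null(group$subject_lsd)) 0.2 else group$subject_lsd
  rho <- if (is.null(group$rho)) 0.6 else group$rho
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]", call. = FALSE)
  expand <- function(x) {
    if (length(x) == 1) x <- setNames(rep(x, length(conditions)), conditions)
    x[conditions]
  }
  # equicorrelated normal via a shared and a private component
  corr_norm <- function(nc) {
    z0 <- rnorm(1)
    sqrt(rho) * z0 + sqrt(1 - rho) * rnorm(nc)
  }
  out <- list()
  for (s in seq_len(n_subjects)) {
    phi_s <- expand(group$phi) + if (phi_sd > 0) {
      x <- rnorm(length(conditions), 0, phi_sd)
      x
    } else 0
    while (any(phi_s <= 0)) {
      bad <- phi_s <= 0
      phi_s[bad] <- expand(group$phi)[bad] + rnorm(sum(bad), 0, phi_sd)
    }
    draw_sigma <- function(mu) exp(log(expand(mu)) + lsd *
                                     corr_norm(length(conditions)))
    out[[sprintf("S%02d", s)]] <- observer_params(
      phi = phi_s,
      sigma_i1 = draw_sigma(group$sigma_i1),
      sigma_i2 = draw_sigma(group$sigma_i2),
      sigma_meta = draw_sigma(group$sigma_meta),
      rho = rho, conditions = conditions)
  }
  out
}
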