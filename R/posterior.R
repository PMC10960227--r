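#' Split rank-normalised R-hat
#'
#' Gelman-Rubin potential scale reduction factor in its split, rank-normalised
#' form: each chain is split in half, the pooled draws are rank-normalised
#' through the inverse normal CDF, and the classic between/within variance
#' ratio is computed on the normalised draws. Values near 1 indicate the
#' chains agree; the package flags fits above 1.05.
#'
#' @param x Matrix of draws, iterations by chains (at least 2 chains with at
#'   least 4 iterations each).
#' @return Scalar R-hat (`>= 1` up to numerical tolerance).
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- ncol(x)
  if (m < 2) stop("R-hat needs at least 2 chains", call. = FALSE)
  if (n < 4) stop("R-hat needs at least 4 draws per chain", call. = FALSE)
  if (all(apply(x, 2, var) == 0)) {
    stop("R-hat undefined: zero within-chain variance", call. = FALSE)
  }
  half <- n %/% 2
  split_x <- cbind(x[seq_len(half), , drop = FALSE],
                   x[half + seq_len(half), , drop = FALSE])
  z <- qnorm((rank(split_x, ties.method = "average") - 3 / 8) /
               (length(split_x) + 1 / 4))
  dim(z) <- dim(split_x)
  w <- mean(apply(z, 2, var))
  if (w == 0) stop("R-hat undefined: zero within-chain variance",
                   call. = FALSE)
  b <- half * var(colMeans(z))
  var_plus <- (half - 1) / half * w + b / half
  sqrt(var_plus / w)
}

#' Highest density interval
#'
#' The shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws — the usual sample HDI, which handles skewed posteriors better
#' than equal-tail intervals.
#'
#' @param x Numeric vector of draws (`n >= 2`).
#' @param mass Probability mass (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @export
hdi <- function(x, mass = 0.95) {
  stopifnot(length(x) >= 2, mass > 0, mass < 1)
  xs <- sort(x)
  n <- length(xs)
  k <- ceiling(mass * n)
  if (k >= n) return(c(xs[1], xs[n]))
  widths <- xs[k:n] - xs[seq_len(n - k + 1)]
  i <- which.min(widths)
  c(xs[i], xs[i + k - 1])
}

#' Log-likelihood of trial data under the measurement model
#'
#' Sums, over trials, the normal log-densities of the two bisection estimates
#' around the condition midpoint and the Bernoulli log-mass of the
#' metacognitive choice, whose probability is the probit read-out of the
#' perceived error difference ([choice_probability()]). Choice probabilities
#' are floored at 1e-12 (and capped at 1 - 1e-12) before taking logs; a
#' warning is raised if a clamped probability contradicts an observed choice.
#'
#' @param data Validated session data frame (single duration condition).
#' @param params List with `mid` (named numeric by condition, seconds),
#'   and `sigma_i1`, `sigma_i2`, `sigma_meta` (matrices subject x condition
#'   with dimnames, seconds).
#' @param error_type `"absolute"` (default) or `"signed"` perceived errors.
#' @param quiet Suppress the clamping warning (default `FALSE`).
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(data, params,
                           error_type = c("absolute", "signed"),
                           quiet = FALSE) {
  error_type <- match.arg(error_type)
  s_idx <- data$subject_id
  c_idx <- data$condition
  mid <- params$mid[c_idx]
  pick <- function(m) m[cbind(match(s_idx, rownames(m)),
                              match(c_idx, colnames(m)))]
  sd1 <- pick(params$sigma_i1)
  sd2 <- pick(params$sigma_i2)
  sdm <- pick(params$sigma_meta)
  err <- function(x) if (error_type == "absolute") abs(x) else x
  p1 <- choice_probability(err(data$estimate1 - mid),
                           err(data$estimate2 - mid), sdm)
  floor_ <- 1e-12
  clamped <- p1 < floor_ | p1 > 1 - floor_
  pc <- pmin(pmax(p1, floor_), 1 - floor_)
  chose1 <- data$meta_choice == 1L
  if (!quiet && any(clamped & ((p1 < floor_ & chose1) |
                                 (p1 > 1 - floor_ & !chose1)))) {
    warning("choice probability clamped at the 1e-12 floor against an ",
            "observed choice")
  }
  sum(dnorm(data$estimate1, mid, sd1, log = TRUE)) +
    sum(dnorm(data$estimate2, mid, sd2, log = TRUE)) +
    sum(log(ifelse(chose1, pc, 1 - pc)))
}

# Per-draw log-likelihood vector for a fit.
.draw_loglik <- function(fit, data) {
  vapply(seq_len(nrow(fit$draws)), function(d) {
    log_likelihood(data, .draw_params(fit, d),
                   error_type = fit$spec$error_type, quiet = TRUE)
  }, numeric(1))
}

#' Deviance information criterion
#'
#' Deviance is `D(theta) = -2 log L(y | theta)`. The default composition is
#' the one printed in the source analysis: `DIC = Dbar + 2 * p_D` with
#' `p_D = 2 * var[log L]`. Because that composition doubles the usual
#' complexity penalty, the standard conventions are available as switches:
#' `"gelman"` (`DIC = Dbar + p_D`, `p_D = 2 var[log L]`) and
#' `"spiegelhalter"` (`DIC = Dbar + p_D`, `p_D = Dbar - D(posterior mean)`).
#' Only relative orderings between model variants matter for model selection;
#' the orderings agree across conventions in the regimes exercised here.
#'
#' @param fit A [fit_hier_model()] result.
#' @param data The data the model was fitted to.
#' @param convention `"paper"` (default), `"gelman"`, or `"spiegelhalter"`.
#' @return An object of class `"dic_result"`: list with `dbar`, `p_d`, `dic`,
#'   `convention`, `n_draws`.
#' @export
dic <- function(fit, data, convention = c("paper", "gelman",
                                          "spiegelhalter")) {
  convention <- match.arg(convention)
  stopifnot(inherits(fit, "bisect_fit"))
  if (nrow(fit$draws) < 2) stop("DIC needs at least 2 draws", call. = FALSE)
  ll <- .draw_loglik(fit, data)
  dbar <- mean(-2 * ll)
  if (convention == "spiegelhalter") {
    mean_params <- .posterior_mean_params(fit)
    d_hat <- -2 * log_likelihood(data, mean_params,
                                 error_type = fit$spec$error_type,
                                 quiet = TRUE)
    p_d <- dbar - d_hat
    dic_val <- dbar + p_d
  } else {
    p_d <- 2 * var(ll)
    dic_val <- if (convention == "paper") dbar + 2 * p_d else dbar + p_d
  }
  structure(list(dbar = dbar, p_d = p_d, dic = dic_val,
                 convention = convention, n_draws = length(ll)),
            class = "dic_result")
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("DIC (%s): %.2f  [Dbar %.2f, p_D %.2f, %d draws]\n",
              x$convention, x$dic, x$dbar, x$p_d, x$n_draws))
  invisible(x)
}

# Posterior-mean structured parameters (for the Spiegelhalter p_D).
.posterior_mean_params <- function(fit) {
  means <- colMeans(fit$draws)
  mean_fit <- fit
  mean_fit$draws <- matrix(means, nrow = 1,
                           dimnames = list(NULL, names(means)))
  .draw_params(mean_fit, 1)
}

#' Posterior-predictive Metacognitive Index
#'
#' For each retained posterior draw, simulates a fresh session per subject and
#' condition from that draw's parameters (via the forward model in
#' [simulate_session()]), computes each subject's MCI exactly as done for
#' data, and averages across subjects — yielding a posterior-predictive
#' distribution of the group MCI per condition. Draws on which the MCI is
#' degenerate (zero variance in a denominator) are dropped and counted.
#'
#' @param fit A [fit_hier_model()] result.
#' @param schedule A [schedule_spec()] for the simulated sessions (default the
#'   standard 500-trial session).
#' @param n_draws Number of posterior draws to push through the forward model
#'   (default 100, evenly spaced over the retained draws; `NULL` = all).
#' @param seed Optional integer seed.
#' @return List per condition with elements `draws` (predictive MCI values),
#'   `mean`, `hdi` (95%), and `dropped` (degenerate draw count).
#' @export
posterior_predictive_mci <- function(fit, schedule = schedule_spec(),
                                     n_draws = 100, seed = NULL) {
  stopifnot(inherits(fit, "bisect_fit"))
  if (!is.null(seed)) set.seed(seed)
  total <- nrow(fit$draws)
  idx <- if (is.null(n_draws) || n_draws >= total) {
    seq_len(total)
  } else {
    unique(round(seq(1, total, length.out = n_draws)))
  }
  out <- list()
  for (cond in fit$conditions) {
    vals <- numeric(0)
    dropped <- 0L
    for (d in idx) {
      pars <- .draw_params(fit, d)
      subj_mci <- vapply(fit$subjects, function(s) {
        obs <- observer_params(phi = pars$mid[[cond]],
                               sigma_i1 = pars$sigma_i1[s, cond],
                               sigma_i2 = pars$sigma_i2[s, cond],
                               sigma_meta = pars$sigma_meta[s, cond],
                               conditions = cond)
        ses <- simulate_session(obs, cond, fit$total_duration, schedule,
                                subject_id = s,
                                error_type = fit$spec$error_type)
        tryCatch(mci(ses, true_mid = fit$true_mid)$mci,
                 error = function(e) NA_real_)
      }, numeric(1))
      if (anyNA(subj_mci)) {
        dropped <- dropped + 1L
      } else {
        vals <- c(vals, mean(subj_mci))
      }
    }
    out[[cond]] <- list(draws = vals, mean = mean(vals),
                        hdi = if (length(vals) >= 2) hdi(vals) else
                          c(NA_real_, NA_real_),
                        dropped = dropped)
  }
  out
}

#' Posterior summaries of the subjective midpoints
#'
#' Posterior mean and 95% HDI of each condition's subjective midpoint and of
#' the overall midpoint (the across-condition average, computed per draw). In
#' relative mode the summaries are divided by the total stimulus duration, so
#' 0.5 marks veridical bisection.
#'
#' @param fit A [fit_hier_model()] result.
#' @param relative Divide by total duration (default `FALSE`).
#' @return Data frame with columns `condition`, `mean`, `hdi_low`,
#'   `hdi_high`; the final row is the overall (across-modality) mean.
#' @export
summarize_midpoints <- function(fit, relative = FALSE) {
  stopifnot(inherits(fit, "bisect_fit"))
  C <- length(fit$conditions)
  cols <- vapply(seq_len(C), function(c) {
    nm <- sprintf("mid[%d]", c)
    if (nm %in% colnames(fit$draws)) nm else "mid"
  }, character(1))
  mids <- fit$draws[, cols, drop = FALSE]
  overall <- rowMeans(mids)
  scale_ <- if (relative) fit$total_duration else 1
  one <- function(x, label) {
    h <- hdi(x / scale_)
    data.frame(condition = label, mean = mean(x) / scale_,
               hdi_low = h[1], hdi_high = h[2])
  }
  rows <- lapply(seq_len(C), function(c) one(mids[, c], fit$conditions[c]))
  rows[[C + 1]] <- one(overall, "overall")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
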