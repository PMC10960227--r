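#' Re-sort trial pairs by the observer's own choice
#'
#' Each trial-pair contributes one estimate to the "subjective best" set (the
#' interval the observer judged closer to the target) and the other to the
#' "subjective worst" set. Re-sorting permutes estimates between sets; it
#' never alters a value.
#'
#' @param trials Session data frame for a single subject-condition (see
#'   [session_data()]).
#' @return An object of class `"sorted_estimates"`: list with `best`, `worst`
#'   (numeric vectors, one entry per trial, in trial order), `true_mid`, and
#'   `type = "subjective"`.
#' @export
sort_subjective <- function(trials) {
  if (nrow(trials) == 0) stop("no trials to sort", call. = FALSE)
  chose1 <- trials$meta_choice == 1L
  structure(list(
    best = ifelse(chose1, trials$estimate1, trials$estimate2),
    worst = ifelse(chose1, trials$estimate2, trials$estimate1),
    true_mid = unique(trials$total_duration)[1] / 2,
    type = "subjective"), class = "sorted_estimates")
}

#' Re-sort trial pairs as the ideal observer would
#'
#' The ideal observer always labels as "best" the estimate of the pair with
#' the smaller absolute deviation from the veridical midpoint, so the "ideal
#' worst" set collects the tails of the estimate distribution. Exact ties go
#' to interval 1 (a measure-zero event for continuous estimates).
#'
#' @param trials Session data frame for a single subject-condition.
#' @param true_mid Veridical midpoint (seconds); defaults to
#'   `total_duration / 2`.
#' @return A `"sorted_estimates"` object with `type = "ideal"`.
#' @export
sort_ideal <- function(trials, true_mid = NULL) {
  if (nrow(trials) == 0) stop("no trials to sort", call. = FALSE)
  if (is.null(true_mid)) true_mid <- unique(trials$total_duration)[1] / 2
  stopifnot(true_mid > 0)
  best1 <- abs(trials$estimate2 - true_mid) < abs(trials$estimate1 - true_mid)
  structure(list(
    best = ifelse(best1, trials$estimate2, trials$estimate1),
    worst = ifelse(best1, trials$estimate1, trials$estimate2),
    true_mid = true_mid,
    type = "ideal"), class = "sorted_estimates")
}

#' Metacognitive Index
#'
#' The MCI for one subject-condition is the ratio of the ideal best/worst
#' variance ratio to the subjective best/worst variance ratio:
#' \deqn{MCI = (V_{i.best}/V_{i.worst}) / (V_{s.best}/V_{s.worst})}
#' An observer with perfect insight sorts exactly as the ideal observer does
#' and scores 1; an observer whose choices carry no information about accuracy
#' has subjective ratio near 1 and scores near the (small) ideal ratio,
#' approaching 0. Variances are unbiased (n-1) sample variances.
#'
#' @param sorted_subj A subjective [sort_subjective()] result.
#' @param sorted_ideal An ideal [sort_ideal()] result over the same trials.
#' @return An object of class `"mci_result"`: list with the four variances
#'   (`v_subj_best`, `v_subj_worst`, `v_ideal_best`, `v_ideal_worst`, s^2)
#'   and `mci`.
#' @export
compute_mci <- function(sorted_subj, sorted_ideal) {
  stopifnot(inherits(sorted_subj, "sorted_estimates"),
            inherits(sorted_ideal, "sorted_estimates"))
  n <- length(sorted_subj$best)
  if (n != length(sorted_ideal$best)) {
    stop("sortings cover different trial sets", call. = FALSE)
  }
  if (n < 2) stop("need at least 2 trials to form variances", call. = FALSE)
  v <- list(v_subj_best = var(sorted_subj$best),
            v_subj_worst = var(sorted_subj$worst),
            v_ideal_best = var(sorted_ideal$best),
            v_ideal_worst = var(sorted_ideal$worst))
  if (v$v_ideal_worst == 0 || v$v_subj_best == 0 || v$v_subj_worst == 0) {
    stop("degenerate variance: MCI undefined for this trial set",
         call. = FALSE)
  }
  mci <- (v$v_ideal_best / v$v_ideal_worst) / (v$v_subj_best / v$v_subj_worst)
  structure(c(v, list(mci = mci)), class = "mci_result")
}

#' Metacognitive Index straight from a trial table
#'
#' Convenience wrapper: subjective and ideal sortings plus [compute_mci()].
#'
#' @inheritParams sort_ideal
#' @return An `"mci_result"` object.
#' @export
mci <- function(trials, true_mid = NULL) {
  compute_mci(sort_subjective(trials), sort_ideal(trials, true_mid))
}

#' Coefficient of variation
#'
#' Sample SD divided by sample mean. Constancy of the CV across base durations
#' is the scalar-timing (Weber's law) signature for interval estimates.
#'
#' @param x Numeric vector of estimates.
#' @return Nonnegative scalar.
#' @export
coefficient_of_variation <- function(x) {
  m <- mean(x)
  if (m == 0) stop("coefficient of variation undefined for zero mean",
                   call. = FALSE)
  sd(x) / m
}

#' Binned trial-series means with confidence intervals
#'
#' Bins consecutive trials (default bins of 50) and returns per-bin means with
#' t-based confidence intervals, for inspecting learning or drift across a
#' session. Bin centers are placed at the middle of each bin's trial range. A
#' final partial bin is retained and flagged.
#'
#' @param estimates Numeric vector ordered by trial index.
#' @param bin_size Trials per bin (`>= 2`, default 50).
#' @param level Confidence level (default 0.95).
#' @return Data frame with columns `bin`, `center`, `n`, `mean`, `ci_low`,
#'   `ci_high`, `partial`.
#' @export
binned_series <- function(estimates, bin_size = 50, level = 0.95) {
  n <- length(estimates)
  stopifnot(bin_size >= 2, level > 0, level < 1, n >= 1)
  if (bin_size > n) {
    warning("bin_size exceeds series length; returning a single bin")
    bin_size <- n
  }
  nb <- ceiling(n / bin_size)
  bin <- factor(ceiling(seq_len(n) / bin_size), levels = seq_len(nb))
  out <- data.frame(bin = seq_len(nb))
  out$n <- as.vector(table(bin))
  starts <- (out$bin - 1) * bin_size
  out$center <- starts + out$n / 2
  out$mean <- as.vector(tapply(estimates, bin, mean))
  sds <- as.vector(tapply(estimates, bin, sd))
  half <- ifelse(out$n > 1,
                 qt(1 - (1 - level) / 2, out$n - 1) * sds / sqrt(out$n), NA)
  out$ci_low <- out$mean - half
  out$ci_high <- out$mean + half
  out$partial <- out$n < bin_size
  out
}

#' Histogram of bisection estimates
#'
#' Equal-width bins (default 150) spanning zero to the total stimulus
#' duration. Bins are half-open `[e_i, e_{i+1})` except the last, which is
#' closed so that an estimate exactly at the upper limit is counted.
#'
#' @param estimates Numeric vector in `[0, upper]`.
#' @param n_bins Number of bins (default 150).
#' @param upper Upper edge, normally the total stimulus duration (seconds).
#' @return List with `edges` (length `n_bins + 1`), `mids`, and integer
#'   `counts` summing to `length(estimates)`.
#' @export
estimate_histogram <- function(estimates, n_bins = 150, upper) {
  stopifnot(upper > 0, n_bins >= 1)
  edges <- seq(0, upper, length.out = n_bins + 1)
  if (length(estimates) == 0) {
    counts <- integer(n_bins)
  } else {
    if (any(estimates < 0 | estimates > upper)) {
      stop("estimates outside [0, upper]", call. = FALSE)
    }
    idx <- findInterval(estimates, edges, rightmost.closed = TRUE)
    counts <- tabulate(idx, nbins = n_bins)
  }
  list(edges = edges, mids = (edges[-1] + edges[-(n_bins + 1)]) / 2,
       counts = counts)
}

#' Trial-series autocorrelation
#'
#' Pearson correlation between the series and its lag-k shift (overlapping
#' segments), for lags 0 through `max_lag`; lag 0 is 1 by construction. This
#' is the lagged-scatter convention (a perfectly alternating series scores
#' exactly -1 at lag 1), not the n-divisor estimator used by [stats::acf()].
#'
#' @param estimates Numeric vector ordered by trial index.
#' @param max_lag Largest lag (`< length(estimates)`).
#' @return Named numeric vector of correlations for lags `0:max_lag`.
#' @export
trial_autocorrelation <- function(estimates, max_lag) {
  n <- length(estimates)
  stopifnot(max_lag >= 0, max_lag < n)
  if (max_lag >= 1 && var(estimates) == 0) {
    stop("autocorrelation undefined beyond lag 0 for a constant series",
         call. = FALSE)
  }
  r <- vapply(0:max_lag, function(k) {
    if (k == 0) return(1)
    cor(estimates[seq_len(n - k)], estimates[seq_len(n - k) + k])
  }, numeric(1))
  names(r) <- paste0("lag", 0:max_lag)
  r
}

#' Per-cell summary of a study
#'
#' One row per subject-condition-duration cell: trial count, interval means,
#' the four re-sorted variances, the Metacognitive Index, per-interval
#' coefficients of variation, and the mean relative bisection
#' (mean estimate / total duration; 0.5 is veridical).
#'
#' @param trials Session data frame (possibly many subjects/conditions).
#' @return A data frame, one row per cell.
#' @export
describe_session <- function(trials) {
  validate_trials(trials)
  key <- interaction(trials$subject_id, trials$condition,
                     trials$total_duration, drop = TRUE)
  rows <- lapply(split(trials, key), function(cell) {
    m <- mci(cell)
    est <- c(cell$estimate1, cell$estimate2)
    data.frame(subject_id = cell$subject_id[1],
               condition = cell$condition[1],
               total_duration = cell$total_duration[1],
               n_trials = nrow(cell),
               mean1 = mean(cell$estimate1), mean2 = mean(cell$estimate2),
               v_subj_best = m$v_subj_best, v_subj_worst = m$v_subj_worst,
               v_ideal_best = m$v_ideal_best, v_ideal_worst = m$v_ideal_worst,
               mci = m$mci,
               cv1 = coefficient_of_variation(cell$estimate1),
               cv2 = coefficient_of_variation(cell$estimate2),
               relative_bisection = mean(est) / cell$total_duration[1])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$subject_id, out$condition, out$total_duration), ]
}
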