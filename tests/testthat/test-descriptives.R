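trial_row <- function(e1, e2, choice, dur = 1.5) {
  session_data(data.frame(subject_id = "S1", condition = "V",
                          total_duration = dur,
                          trial_index = seq_along(e1),
                          estimate1 = e1, estimate2 = e2,
                          meta_choice = as.integer(choice)))
}

test_that("subjective sorting routes the chosen estimate to 'best'", {
  s <- sort_subjective(trial_row(0.70, 0.90, 1))
  expect_equal(s$best, 0.70)
  expect_equal(s$worst, 0.90)
  s <- sort_subjective(trial_row(0.70, 0.90, 2))
  expect_equal(s$best, 0.90)
  expect_equal(s$worst, 0.70)
  empty <- session_data(data.frame(subject_id = character(),
                                   condition = character(),
                                   total_duration = numeric(),
                                   trial_index = integer(),
                                   estimate1 = numeric(),
                                   estimate2 = numeric(),
                                   meta_choice = integer()))
  expect_error(sort_subjective(empty), "no trials")
  expect_error(sort_ideal(empty, 0.75), "no trials")
})

test_that("ideal sorting keys on distance to the veridical midpoint", {
  s <- sort_ideal(trial_row(0.70, 0.90, 1), true_mid = 0.75)
  expect_equal(s$best, 0.70)   # |0.70-0.75| < |0.90-0.75|
  expect_equal(s$worst, 0.90)
  # equal distances: interval 1 wins the tie
  s <- sort_ideal(trial_row(0.74, 0.76, 2), true_mid = 0.75)
  expect_equal(s$best, 0.74)
})

test_that("re-sorting permutes but never alters the estimates", {
  obs <- observer_params(0.75, 0.15, 0.18, 0.3)
  ses <- simulate_session(obs, "V", 1.5, schedule_spec(), seed = 21)
  all_est <- sort(c(ses$estimate1, ses$estimate2))
  for (s in list(sort_subjective(ses), sort_ideal(ses))) {
    expect_equal(sort(c(s$best, s$worst)), all_est)
    expect_length(s$best, nrow(ses))
  }
  si <- sort_ideal(ses)
  expect_true(all(abs(si$best - 0.75) <= abs(si$worst - 0.75)))
})

test_that("ideal-best selection minimizes MSE among all per-pair selections", {
  # exhaustive oracle over the 2^n possible selections
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(5:11, 1)
    ses <- trial_row(runif(n, 0, 1.5), runif(n, 0, 1.5),
                     sample(1:2, n, TRUE))
    best <- sort_ideal(ses, true_mid = 0.75)$best
    mse <- function(x) mean((x - 0.75)^2)
    picks <- expand.grid(rep(list(1:2), n))
    oracle <- min(apply(picks, 1, function(pk) {
      mse(ifelse(pk == 1, ses$estimate1, ses$estimate2))
    }))
    expect_equal(mse(best), oracle, tolerance = 1e-12)
  }
})

test_that("MCI is exactly 1 for an ideal chooser and matches its formula", {
  obs <- observer_params(0.75, 0.15, 0.15, sigma_meta = 0)  # ideal chooser
  ses <- simulate_session(obs, "A", 1.5, schedule_spec(), seed = 8)
  m <- mci(ses)
  expect_identical(m$mci, 1)

  # formula check against direct computation on a noisy chooser
  obs2 <- observer_params(0.75, 0.15, 0.15, sigma_meta = 0.4)
  ses2 <- simulate_session(obs2, "A", 1.5, schedule_spec(), seed = 9)
  m2 <- mci(ses2)
  ss <- sort_subjective(ses2); si <- sort_ideal(ses2)
  expect_equal(m2$mci, (var(si$best) / var(si$worst)) /
                 (var(ss$best) / var(ss$worst)))
  expect_lt(m2$mci, 1)
})

test_that("MCI is invariant to joint affine rescaling of estimates", {
  obs <- observer_params(0.75, 0.15, 0.15, 0.4)
  ses <- simulate_session(obs, "V", 1.5, schedule_spec(n_trials = 200,
                                                       block_size = 200),
                          seed = 3)
  m0 <- mci(ses, true_mid = 0.75)$mci
  for (a in c(2, 0.5)) {
    scaled <- ses
    scaled$estimate1 <- ses$estimate1 * a
    scaled$estimate2 <- ses$estimate2 * a
    scaled$total_duration <- 1.5 * a
    scaled <- session_data(scaled)
    scaled$meta_choice <- ses$meta_choice  # same choices
    expect_equal(mci(scaled, true_mid = 0.75 * a)$mci, m0, tolerance = 1e-12)
  }
})

test_that("degenerate variances raise errors, not infinities", {
  ses <- trial_row(rep(0.75, 5), rep(0.75, 5), rep(1, 5))
  expect_error(mci(ses), "degenerate variance")
  expect_error(compute_mci(sort_subjective(ses[1, ]),
                           sort_ideal(ses[1, ])), "at least 2")
})

test_that("coefficient of variation follows its definition", {
  expect_equal(coefficient_of_variation(rep(3, 10)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 0.5)  # mean 2, sd 1
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("CV is constant across proportionally-scaled durations (Weber)", {
  # sigma proportional to duration => same CV, the scalar-timing signature
  sch <- schedule_spec(n_trials = 500, block_size = 500)
  s1 <- simulate_session(observer_params(0.75, 0.15, 0.15, 0.5), "V", 1.5,
                         sch, seed = 11)
  s2 <- simulate_session(observer_params(1.50, 0.30, 0.30, 0.5), "V", 3.0,
                         sch, seed = 12)
  cv1 <- coefficient_of_variation(s1$estimate1)
  cv2 <- coefficient_of_variation(s2$estimate1)
  expect_equal(cv1, cv2, tolerance = 0.1)  # Monte-Carlo tolerance
})

test_that("binned series matches brute-force re-binning", {
  b <- binned_series(rep(1.0, 100), bin_size = 50)
  expect_equal(nrow(b), 2)
  expect_equal(b$ci_low, b$mean)
  expect_equal(b$ci_high, b$mean)

  b <- binned_series(rnorm(500), bin_size = 50)
  expect_equal(b$center, seq(25, 475, by = 50))

  set.seed(4)
  x <- rnorm(173)
  b <- binned_series(x, bin_size = 50)
  expect_equal(nrow(b), 4)
  expect_true(b$partial[4] && !any(b$partial[1:3]))
  for (i in 1:4) {
    lo <- (i - 1) * 50 + 1
    seg <- x[lo:min(i * 50, 173)]
    expect_equal(b$mean[i], mean(seg))
    if (length(seg) > 1) {
      half <- qt(0.975, length(seg) - 1) * sd(seg) / sqrt(length(seg))
      expect_equal(b$ci_high[i] - b$mean[i], half)
    }
  }
  expect_warning(binned_series(rnorm(10), bin_size = 50), "single bin")
})

test_that("estimate histogram uses half-open bins with a closed last bin", {
  h <- estimate_histogram(rep(1.5, 7), n_bins = 150, upper = 1.5)
  expect_equal(h$counts[150], 7)
  expect_equal(sum(h$counts), 7)

  h <- estimate_histogram(numeric(0), n_bins = 150, upper = 1.5)
  expect_equal(sum(h$counts), 0)
  expect_length(h$edges, 151)

  # independent digitize-and-tally oracle
  set.seed(6)
  x <- runif(400, 0, 1.5)
  h <- estimate_histogram(x, n_bins = 23, upper = 1.5)
  edges <- seq(0, 1.5, length.out = 24)
  oracle <- integer(23)
  for (v in x) {
    for (b in 1:23) {
      if (v >= edges[b] && (v < edges[b + 1] || (b == 23 && v <= edges[24]))) {
        oracle[b] <- oracle[b] + 1L
        break
      }
    }
  }
  expect_equal(h$counts, oracle)
})

test_that("trial autocorrelation has the expected limiting values", {
  x <- rnorm(100)
  r <- trial_autocorrelation(x, max_lag = 5)
  expect_equal(unname(r[1]), 1)

  alt <- rep(c(1, -1), 50)
  expect_equal(unname(trial_autocorrelation(alt, 1)[2]), -1)

  set.seed(13)
  wn <- rnorm(2000)
  r <- trial_autocorrelation(wn, max_lag = 10)
  expect_true(all(abs(r[-1]) < 3 / sqrt(2000)))

  expect_error(trial_autocorrelation(rep(1, 10), 2), "constant")
})

test_that("describe_session yields one row per subject-condition cell", {
  study <- make_study(n_subjects = 2, n_trials = 50, seed = 2)
  d <- describe_session(study)
  expect_equal(nrow(d), 6)  # 2 subjects x 3 conditions
  expect_true(all(d$mci > 0))
  expect_true(all(abs(d$relative_bisection - 0.5) < 0.05))
})
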