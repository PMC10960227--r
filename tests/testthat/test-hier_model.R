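simple_params <- function(mid = 0.75, s1 = 0.15, s2 = 0.15, sm = 0.5,
                          subjects = "S1", conditions = "V") {
  m <- function(v) matrix(v, length(subjects), length(conditions),
                          dimnames = list(subjects, conditions))
  list(mid = setNames(rep(mid, length(conditions)), conditions),
       sigma_i1 = m(s1), sigma_i2 = m(s2), sigma_meta = m(sm))
}

test_that("log-likelihood reduces to log(0.5) for a zero error difference", {
  ses <- session_data(data.frame(subject_id = "S1", condition = "V",
                                 total_duration = 1.5, trial_index = 1L,
                                 estimate1 = 0.75, estimate2 = 0.75,
                                 meta_choice = 1L))
  p <- simple_params()
  ll <- log_likelihood(ses, p)
  expect_equal(ll, 2 * dnorm(0.75, 0.75, 0.15, log = TRUE) + log(0.5),
               tolerance = 1e-12)
})

test_that("log-likelihood is additive over trials", {
  obs <- observer_params(0.75, 0.15, 0.15, 0.5)
  ses <- simulate_session(obs, "V", 1.5, schedule_spec(10, 10), seed = 3)
  p <- simple_params()
  doubled <- session_data(rbind(ses, transform(ses, trial_index = 11:20)))
  expect_equal(log_likelihood(doubled, p), 2 * log_likelihood(ses, p),
               tolerance = 1e-12)
})

test_that("log-likelihood matches a term-by-term oracle", {
  set.seed(44)
  ses <- session_data(data.frame(
    subject_id = c("S1", "S1", "S2"), condition = c("V", "A", "V"),
    total_duration = 1.5, trial_index = c(1L, 1L, 1L),
    estimate1 = runif(3, 0.5, 1), estimate2 = runif(3, 0.5, 1),
    meta_choice = sample(1:2, 3, TRUE)))
  p <- simple_params(mid = c(0.72, 0.78), s1 = c(0.1, 0.2, 0.15, 0.25),
                     s2 = c(0.12, 0.22, 0.17, 0.27),
                     sm = c(0.4, 0.6, 0.5, 0.7),
                     subjects = c("S1", "S2"), conditions = c("V", "A"))
  oracle <- 0
  for (i in 1:3) {
    s <- ses$subject_id[i]; cc <- ses$condition[i]
    mu <- p$mid[[cc]]
    d1 <- abs(ses$estimate1[i] - mu); d2 <- abs(ses$estimate2[i] - mu)
    p1 <- pnorm(-(d1 - d2) / p$sigma_meta[s, cc])
    oracle <- oracle +
      dnorm(ses$estimate1[i], mu, p$sigma_i1[s, cc], log = TRUE) +
      dnorm(ses$estimate2[i], mu, p$sigma_i2[s, cc], log = TRUE) +
      log(if (ses$meta_choice[i] == 1) p1 else 1 - p1)
  }
  expect_equal(log_likelihood(ses, p), oracle, tolerance = 1e-10)
})

test_that("extreme choice probabilities are clamped with a warning", {
  ses <- session_data(data.frame(subject_id = "S1", condition = "V",
                                 total_duration = 1.5, trial_index = 1L,
                                 estimate1 = 1.4,  # far worse than interval 2
                                 estimate2 = 0.75, meta_choice = 1L))
  p <- simple_params(sm = 1e-4)
  expect_warning(ll <- log_likelihood(ses, p), "clamped")
  expect_true(is.finite(ll))
  expect_equal(suppressWarnings(
    log_likelihood(ses, p) -
      dnorm(1.4, 0.75, 0.15, log = TRUE) -
      dnorm(0.75, 0.75, 0.15, log = TRUE)),
    log(1e-12))
})

test_that("hdi equals the exhaustive window-scan oracle", {
  expect_equal(hdi(rep(2.5, 10)), c(2.5, 2.5))
  for (seed in 1:5) {
    set.seed(seed)
    x <- rexp(201)  # skewed on purpose
    h <- hdi(x, mass = 0.9)
    xs <- sort(x)
    k <- ceiling(0.9 * length(xs))
    widths <- vapply(seq_len(length(xs) - k + 1),
                     function(i) xs[i + k - 1] - xs[i], numeric(1))
    i <- which.min(widths)
    expect_equal(h, c(xs[i], xs[i + k - 1]))
  }
  set.seed(10)
  h <- hdi(rnorm(1e5))
  expect_lt(abs(h[1] + 1.96), 0.05)
  expect_lt(abs(h[2] - 1.96), 0.05)
})

test_that("R-hat detects agreement and divergence between chains", {
  set.seed(2)
  same <- cbind(rnorm(5000), rnorm(5000))
  expect_lt(abs(rhat(same) - 1), 0.01)

  # rank normalisation bounds the statistic, but separation is still flagged
  disjoint <- cbind(rnorm(200), rnorm(200) + 50)
  expect_gt(rhat(disjoint), 1.5)

  expect_error(rhat(cbind(1, 2)), "draws")
  expect_error(rhat(matrix(1, 10, 2)), "zero within-chain variance")
  expect_error(rhat(matrix(rnorm(10), 10, 1)), "chains")
})

test_that("DIC composition follows the printed formula and its variants", {
  subjects <- "S1"; conditions <- "V"
  ses <- simulate_session(observer_params(0.75, 0.15, 0.15, 0.5), "V", 1.5,
                          schedule_spec(20, 20), seed = 6)
  # posterior concentrated at one theta: p_D = 0 and DIC = D(theta)
  d0 <- constant_draws(5, 0.75, 0.15, 0.15, 0.5, subjects, conditions)
  f0 <- fake_fit(d0, subjects, conditions)
  r0 <- dic(f0, ses)
  expect_equal(r0$p_d, 0)
  expect_equal(r0$dic, -2 * log_likelihood(ses, simple_params()),
               tolerance = 1e-10)

  # draw-by-draw oracle for a dispersed posterior
  set.seed(9)
  draws <- constant_draws(40, 0.75, 0.15, 0.15, 0.5, subjects, conditions)
  draws[, "mid[1]"] <- draws[, "mid[1]"] + rnorm(40, 0, 0.01)
  draws[, "sigma[1,1,1]"] <- draws[, "sigma[1,1,1]"] * exp(rnorm(40, 0, 0.1))
  f <- fake_fit(draws, subjects, conditions)
  ll <- vapply(1:40, function(d) {
    p <- simple_params(mid = draws[d, "mid[1]"],
                       s1 = draws[d, "sigma[1,1,1]"])
    log_likelihood(ses, p, quiet = TRUE)
  }, numeric(1))
  r <- dic(f, ses)
  expect_equal(r$dbar, mean(-2 * ll), tolerance = 1e-8)
  expect_equal(r$p_d, 2 * var(ll), tolerance = 1e-8)
  expect_equal(r$dic, mean(-2 * ll) + 4 * var(ll), tolerance = 1e-8)
  rg <- dic(f, ses, convention = "gelman")
  expect_equal(rg$dic, rg$dbar + rg$p_d)
  rs <- dic(f, ses, convention = "spiegelhalter")
  expect_equal(rs$dic, rs$dbar + rs$p_d)
  expect_gte(rs$p_d, 0)
})

test_that("fit contracts reject unusable inputs instead of crashing", {
  obs <- observer_params(0.75, 0.15, 0.15, 0.5)
  one <- simulate_session(obs, "V", 1.5, schedule_spec(1, 1), seed = 1)
  expect_error(fit_hier_model(one), "at least 2")

  two_dur <- rbind(simulate_session(obs, "V", 1.5, schedule_spec(5, 5),
                                    seed = 1),
                   simulate_session(obs, "V", 3.0, schedule_spec(5, 5),
                                    seed = 2))
  expect_error(fit_hier_model(session_data(two_dur)), "separately")
})

test_that("a tiny single-condition fit runs and reports diagnostics", {
  obs <- observer_params(0.75, 0.15, 0.15, 0.5)
  ses <- simulate_session(obs, "V", 1.5, schedule_spec(40, 40), seed = 12)
  fit <- suppressWarnings(
    fit_hier_model(ses, hier_model_spec(),
                   mcmc_control(n_chains = 2, burn_in = 200, n_samples = 400,
                                thin = 2, seed = 5)))
  expect_s3_class(fit, "bisect_fit")
  expect_true(all(c("mid", "sigma[1,1,1]", "sigma[1,3,1]") %in%
                    colnames(fit$draws)))
  expect_equal(summarize_midpoints(fit, relative = TRUE)$condition,
               c("V", "overall"))
  expect_true(is.finite(fit$max_rhat))
  expect_equal(nrow(fit$draws), 400)
  expect_output(print(fit), "1 subjects")
})

test_that("midpoint summaries are exact for degenerate posteriors", {
  subjects <- c("S1", "S2"); conditions <- c("V", "A", "AV")
  draws <- constant_draws(10, c(0.75, 0.75, 0.75), 0.15, 0.15, 0.5,
                          subjects, conditions)
  f <- fake_fit(draws, subjects, conditions, total_duration = 1.5)
  s <- summarize_midpoints(f, relative = TRUE)
  expect_equal(s$mean, rep(0.5, 4))  # phi == true_mid => relative 0.5

  draws2 <- constant_draws(10, c(0.70, 0.75, 0.80), 0.15, 0.15, 0.5,
                           subjects, conditions)
  f2 <- fake_fit(draws2, subjects, conditions)
  s2 <- summarize_midpoints(f2)
  expect_equal(s2$mean[s2$condition == "overall"],
               mean(c(0.70, 0.75, 0.80)))
})

test_that("posterior-predictive MCI concentrates at 1 for ideal readers", {
  subjects <- c("S1", "S2"); conditions <- "V"
  draws <- constant_draws(6, 0.75, 0.15, 0.15, sigma_meta = 0,
                          subjects, conditions)
  f <- fake_fit(draws, subjects, conditions)
  ppc <- posterior_predictive_mci(f, schedule_spec(100, 100), n_draws = 5,
                                  seed = 3)
  expect_true(all(ppc$V$draws == 1))
  expect_equal(ppc$V$dropped, 0)
})
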