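#' Run the simulate - describe - fit - compare - predict pipeline
#'
#' End-to-end orchestration of a synthetic (or pre-existing) study: simulate a
#' multi-subject session table, compute per-cell descriptives (variances, MCI,
#' CV, relative bisection), fit the hierarchical measurement model, compare
#' the full and constrained variants by DIC, and derive posterior-predictive
#' MCI distributions. Every artifact lands in `config$output_dir`, alongside a
#' `manifest.json` echoing the configuration, the seeds used, the package
#' version, and the fit's R-hat summary, which together suffice to reproduce
#' the run.
#'
#' @param config A list, or path to a YAML file, with elements:
#'   \describe{
#'     \item{output_dir}{Directory for artifacts (created if needed).}
#'     \item{seed}{Integer seed used for every stochastic stage.}
#'     \item{input}{Optional path to an existing trials CSV; when given the
#'       simulate stage is skipped.}
#'     \item{simulate}{List: `n_subjects`, `total_duration` (s), `n_trials`,
#'       `conditions`, and `group` (see [sample_observers()]).}
#'     \item{fit}{List: `variant`, `n_chains`, `burn_in`, `n_samples`,
#'       `thin`, plus optional [hier_model_spec()] fields.}
#'     \item{stages}{Character vector of stages to run; default all of
#'       `simulate`, `describe`, `fit`, `compare`, `ppc`.}
#'     \item{ppc}{List: `n_draws` (default 100), `n_trials` (default 500).}
#'   }
#' @param quiet Suppress sampler progress (default `TRUE`).
#' @return Invisibly, a list with the artifact paths and in-memory results.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$output_dir)) stop("config$output_dir is required",
                                       call. = FALSE)
  if (is.null(config$seed)) stop("config$seed is required (every stochastic ",
                                 "stage needs a seed)", call. = FALSE)
  seed <- as.integer(config$seed)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% c("simulate", "describe", "fit", "compare",
                                 "ppc")
  res <- list(artifacts = character(0))
  manifest <- list(config = config, seed = seed,
                   package_version = as.character(
                     utils::packageVersion("bisectmeta")),
                   stages_completed = character(0))
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  stage <- function(name, expr) {
    if (!name %in% stages) return(invisible(NULL))
    tryCatch(expr, error = function(e) {
      manifest$incomplete <<- name
      write_manifest()
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    manifest$stages_completed <<- c(manifest$stages_completed, name)
    invisible(NULL)
  }

  trials <- NULL
  stage("simulate", {
    if (!is.null(config$input)) {
      trials <- read_trials(config$input)
    } else {
      sim <- config$simulate %||% list()
      n_subjects <- sim$n_subjects %||% 5
      total_duration <- sim$total_duration %||% 1.5
      conditions <- sim$conditions %||% .conditions
      n_trials <- sim$n_trials %||% 500
      group <- sim$group %||% list(phi = total_duration / 2, phi_sd = 0.02,
                                   sigma_i1 = 0.15, sigma_i2 = 0.15,
                                   sigma_meta = 0.5, rho = 0.6)
      obs <- sample_observers(group, n_subjects, seed = seed,
                              conditions = conditions)
      sched <- schedule_spec(n_trials = n_trials,
                             block_size = min(n_trials, 100))
      trials <- simulate_study(obs, conditions, total_duration, sched,
                                seed = seed + 1L)
    }
    path <- file.path(out_dir, "trials.csv")
    write_trials(trials, path)
    res$artifacts <- c(res$artifacts, path)
    res$trials <- trials
  })
  if (is.null(trials) && !is.null(config$input)) trials <- read_trials(config$input)

  stage("describe", {
    desc <- describe_session(trials)
    path <- file.path(out_dir, "descriptives.csv")
    utils::write.csv(desc, path, row.names = FALSE)
    res$artifacts <- c(res$artifacts, path)
    res$descriptives <- desc
  })

  fit <- NULL
  fit_cfg <- config$fit %||% list()
  mcmc <- mcmc_control(n_chains = fit_cfg$n_chains %||% 2,
                       burn_in = fit_cfg$burn_in %||% 2000,
                       n_samples = fit_cfg$n_samples %||% 5000,
                       thin = fit_cfg$thin %||% 20,
                       seed = seed + 2L)
  spec <- hier_model_spec(variant = fit_cfg$variant %||% "full",
                          error_type = fit_cfg$error_type %||% "absolute",
                          epsilon = fit_cfg$epsilon %||% 0.1)
  stage("fit", {
    fit <- fit_hier_model(trials, spec, mcmc, quiet = quiet)
    path <- file.path(out_dir, "posterior_summary.csv")
    utils::write.csv(fit$summary, path, row.names = FALSE)
    mids <- summarize_midpoints(fit)
    utils::write.csv(mids, file.path(out_dir, "midpoints.csv"),
                     row.names = FALSE)
    res$artifacts <- c(res$artifacts, path,
                        file.path(out_dir, "midpoints.csv"))
    res$fit <- fit
    manifest$max_rhat <- fit$max_rhat
    manifest$converged <- fit$converged
  })

  stage("compare", {
    if (is.null(fit)) fit <- fit_hier_model(trials, spec, mcmc, quiet = quiet)
    other <- hier_model_spec(
      variant = if (spec$variant == "full") "constrained" else "full",
      error_type = spec$error_type, epsilon = spec$epsilon)
    fit2 <- fit_hier_model(trials, other, mcmc, quiet = quiet)
    d1 <- dic(fit, trials)
    d2 <- dic(fit2, trials)
    cmp <- list(
      list(variant = fit$spec$variant, dbar = d1$dbar, p_d = d1$p_d,
           dic = d1$dic),
      list(variant = other$variant, dbar = d2$dbar, p_d = d2$p_d,
           dic = d2$dic))
    path <- file.path(out_dir, "dic.json")
    jsonlite::write_json(cmp, path, auto_unbox = TRUE, digits = NA)
    res$artifacts <- c(res$artifacts, path)
    res$dic <- cmp
  })

  stage("ppc", {
    if (is.null(fit)) fit <- fit_hier_model(trials, spec, mcmc, quiet = quiet)
    ppc_cfg <- config$ppc %||% list()
    sched <- schedule_spec(n_trials = ppc_cfg$n_trials %||% 500,
                           block_size = min(ppc_cfg$n_trials %||% 500, 100))
    ppc <- posterior_predictive_mci(fit, sched,
                                    n_draws = ppc_cfg$n_draws %||% 100,
                                    seed = seed + 3L)
    path <- file.path(out_dir, "ppc_mci.json")
    jsonlite::write_json(
      lapply(ppc, function(x) list(mean = x$mean, hdi = x$hdi,
                                   n_draws = length(x$draws),
                                   dropped = x$dropped)),
      path, auto_unbox = TRUE, digits = NA)
    res$artifacts <- c(res$artifacts, path)
    res$ppc <- ppc
  })

  write_manifest()
  res$manifest <- manifest
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
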