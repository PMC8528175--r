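#' QUEST staircase configuration
#'
#' Bayesian adaptive staircase over the log10 probe numerosity, after Watson
#' and Pelli's QUEST. The posterior over the candidate point of subjective
#' equality (PSE) lives on a regular log10 grid centred on the reference
#' numerosity; each probe recommendation is the posterior mean perturbed by
#' Gaussian noise of 0.15 log10 units, back-transformed and rounded to an
#' integer dot count.
#'
#' @param reference_numerosity Reference dot count of the session.
#' @param prior_mean Prior mean in log10 units (default
#'   `log10(reference_numerosity)`).
#' @param prior_sd Prior SD, log10 units (default 0.3).
#' @param grid_halfwidth Grid half-extent around `prior_mean`, log10 units
#'   (default 0.6; must cover the prior's central two SDs).
#' @param grid_step Grid resolution, log10 units (default 0.005).
#' @param assumed_slope_sd Slope of the assumed cumulative-Gaussian
#'   psychometric likelihood, log10 units (default 0.12).
#' @param perturbation_sd SD of the Gaussian probe-placement perturbation,
#'   log10 units (default 0.15).
#' @param n_trials Trials per session (default 180).
#' @param seed Optional integer seed for [run_session()].
#' @return An object of class `quest_config`.
#' @export
quest_config <- function(reference_numerosity,
                         prior_mean = log10(reference_numerosity),
                         prior_sd = 0.3,
                         grid_halfwidth = 0.6,
                         grid_step = 0.005,
                         assumed_slope_sd = 0.12,
                         perturbation_sd = 0.15,
                         n_trials = 180L,
                         seed = NULL) {
  stopifnot(
    reference_numerosity >= 1,
    prior_sd > 0, grid_step > 0, grid_halfwidth > 0,
    assumed_slope_sd > 0, perturbation_sd >= 0, n_trials >= 1
  )
  if (grid_halfwidth < 2 * prior_sd)
    stop("grid must cover the prior +/- 2 SD: increase grid_halfwidth",
         call. = FALSE)
  structure(as.list(environment()), class = "quest_config")
}

#' Initialise a QUEST posterior
#'
#' Discretises a Normal(prior_mean, prior_sd) over the log10 grid and
#' normalises it.
#'
#' @param config A [quest_config()].
#' @return A `quest_state`: list with `grid` (log10 candidates), `posterior`
#'   (probability masses summing to one), and `trial` counter.
#' @export
quest_init <- function(config) {
  stopifnot(inherits(config, "quest_config"))
  grid <- seq(config$prior_mean - config$grid_halfwidth,
              config$prior_mean + config$grid_halfwidth,
              by = config$grid_step)
  if (length(grid) < 3) stop("degenerate grid", call. = FALSE)
  mass <- stats::dnorm(grid, config$prior_mean, config$prior_sd)
  structure(
    list(grid = grid, posterior = mass / sum(mass), trial = 0L,
         assumed_slope_sd = config$assumed_slope_sd),
    class = "quest_state"
  )
}

#' Bayesian update of the QUEST posterior after one response
#'
#' The likelihood of a "probe more numerous" response given a candidate PSE
#' `c` is `pnorm((probe_log - c) / assumed_slope_sd)`; its complement for a
#' "reference more numerous" response. Posterior mass is multiplied
#' elementwise and renormalised.
#'
#' @param state A `quest_state`.
#' @param probe_log Probe numerosity in log10 units.
#' @param response `"probe_more"` or `"ref_more"`.
#' @return The updated `quest_state`.
#' @export
quest_update <- function(state, probe_log,
                         response = c("probe_more", "ref_more")) {
  stopifnot(inherits(state, "quest_state"), is.finite(probe_log))
  response <- match.arg(response)
  p <- stats::pnorm((probe_log - state$grid) / state$assumed_slope_sd)
  lik <- if (response == "probe_more") p else 1 - p
  mass <- state$posterior * lik
  tot <- sum(mass)
  if (tot <= 0 || !is.finite(tot))
    stop(sprintf(
      "QUEST posterior update produced zero total mass (probe_log = %.3f, response = %s)",
      probe_log, response
    ), call. = FALSE)
  state$posterior <- mass / tot
  state$trial <- state$trial + 1L
  state
}

#' Posterior mean of a QUEST state, log10 units
#'
#' @param state A `quest_state`.
#' @return Scalar posterior mean.
#' @export
quest_mean <- function(state) sum(state$grid * state$posterior)

#' Recommend the next integer probe numerosity
#'
#' Posterior mean plus a Gaussian perturbation (SD `perturbation_sd` log10
#' units), back-transformed from log10 and rounded to the nearest integer,
#' floored at 1. Uses the current RNG stream.
#'
#' @param state A `quest_state`.
#' @param config The session's [quest_config()].
#' @return Integer probe numerosity >= 1.
#' @export
quest_recommend <- function(state, config) {
  stopifnot(inherits(state, "quest_state"), inherits(config, "quest_config"))
  x <- quest_mean(state) + stats::rnorm(1, 0, config$perturbation_sd)
  max(1L, as.integer(round(10^x)))
}

#' Run one simulated QUEST session
#'
#' The full per-cell loop: recommend a probe, generate the stimuli (the
#' reference connected or isolated according to `condition`; the probe always
#' isolated), collect the simulated observer's 2AFC decision, and update the
#' posterior. Fresh stimuli are generated on every trial. With a seed in
#' `config` the whole session is reproducible.
#'
#' @param observer One cohort row ([sample_cohort()]).
#' @param reference_numerosity Reference dot count.
#' @param condition `"isolated"` or `"connected"` (reference stimulus).
#' @param task `"single"` or `"dual"`.
#' @param config A [quest_config()]; its `reference_numerosity` must agree.
#' @param stim_config Optional [stimulus_config()] template for geometry
#'   defaults; its `numerosity`, `connect_fraction` and `seed` fields are
#'   overridden per stimulus.
#' @param band_threshold Passed to the observer model.
#' @return A tibble of trial records: `observer_id`, `task`, `condition`,
#'   `reference_numerosity`, `trial_index`, `probe_numerosity`, `response`,
#'   `distractor_correct`, `session_seed`.
#' @export
run_session <- function(observer, reference_numerosity,
                        condition = c("isolated", "connected"),
                        task = c("single", "dual"),
                        config = quest_config(reference_numerosity),
                        stim_config = NULL,
                        band_threshold = 25) {
  condition <- match.arg(condition)
  task <- match.arg(task)
  stopifnot(inherits(config, "quest_config"),
            config$reference_numerosity == reference_numerosity)
  base_cfg <- if (is.null(stim_config)) {
    stimulus_config(numerosity = reference_numerosity)
  } else {
    stim_config
  }

  run <- function() {
    make_cfg <- function(n, f) {
      cfg <- base_cfg
      cfg$numerosity <- as.integer(n)
      cfg$connect_fraction <- f
      cfg$seed <- NULL
      cfg
    }
    ref_f <- if (condition == "connected") base_cfg$connect_fraction else 0
    state <- quest_init(config)
    nt <- config$n_trials
    probe_n <- integer(nt)
    response <- character(nt)
    distractor <- rep(NA, nt)
    for (t in seq_len(nt)) {
      pn <- quest_recommend(state, config)
      ref_pat <- if (condition == "connected") {
        generate_connected(make_cfg(reference_numerosity, ref_f))
      } else {
        generate_isolated(make_cfg(reference_numerosity, 0))
      }
      probe_pat <- generate_isolated(make_cfg(pn, 0))
      dec <- decide_trial(ref_pat, probe_pat, observer, task, band_threshold)
      probe_n[t] <- pn
      response[t] <- dec$choice
      distractor[t] <- dec$distractor_correct
      state <- quest_update(state, log10(pn), dec$choice)
    }
    tibble::tibble(
      observer_id = observer$observer_id,
      task = task,
      condition = condition,
      reference_numerosity = as.integer(reference_numerosity),
      trial_index = seq_len(nt),
      probe_numerosity = probe_n,
      response = response,
      distractor_correct = distractor,
      session_seed = if (is.null(config$seed)) NA_integer_ else as.integer(config$seed)
    )
  }
  if (!is.null(config$seed)) withr::with_seed(config$seed, run()) else run()
}

#' Write / read trial logs as CSV
#'
#' The interchange format consumed by the psychometric-fitting stage:
#' `observer_id, task, condition, reference_numerosity, trial_index,
#' probe_numerosity, response, distractor_correct, session_seed`.
#'
#' @param trials Trial tibble from [run_session()] (rows from several
#'   sessions may be concatenated).
#' @param path File path.
#' @return `path` (write) or a trial tibble (read).
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
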