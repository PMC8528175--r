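# Frozen calibration constants for the synthetic cohort.
#
# AQ scores follow a skew-normal whose parameters were fit once by quantile
# matching: the median is pinned at exactly 13.5 and the quartiles (8, 22)
# are matched in least squares (the skew-normal family cannot reproduce that
# quartile asymmetry exactly; the fitted quartiles are 7.69 and 21.27).
# Grouping-probability coupling constants were calibrated once by simulation
# so that, in expectation over a large cohort, the single-task low-numerosity
# bias is -20%, the dual-task bias -7%, and the AQ-bias correlations 0.59
# (single) and 0.30 (dual). See the methods vignette for the procedure.
.aq_sn <- list(location = 2.486878, scale = 16.328078, shape = 22.269382)
.aq_sn$delta <- .aq_sn$shape / sqrt(1 + .aq_sn$shape^2)
.aq_sn$mean <- .aq_sn$location + .aq_sn$scale * .aq_sn$delta * sqrt(2 / pi)
.aq_sn$sd <- .aq_sn$scale * sqrt(1 - 2 * .aq_sn$delta^2 / pi)

.coupling <- list(
  p_group_base = 0.998170,
  slope = 0.006,
  noise_sd = 0.008229,
  dual_attenuation = 0.351756,
  dual_noise_sd = 0.004044,
  p_group_high_mean = 0.40,
  p_group_high_sd = 0.02
)

# Skew-normal draws via the delta representation:
# Z = delta*|U0| + sqrt(1-delta^2)*U1, X = location + scale*Z.
rskewnorm <- function(n, location, scale, shape) {
  delta <- shape / sqrt(1 + shape^2)
  location + scale * (delta * abs(stats::rnorm(n)) +
                        sqrt(1 - delta^2) * stats::rnorm(n))
}

#' Configuration of the synthetic observer cohort
#'
#' Defaults emulate the reference sample: 18 observers whose Autistic
#' Quotient (AQ) scores follow a right-skewed distribution with median 13.5
#' and quartiles near 8 and 22, and whose probability of perceiving a
#' connected dot pair as a single object decreases with AQ under full
#' attention. Under divided attention the grouping probability is attenuated
#' multiplicatively; at high numerosity (N = 100) grouping is weak and
#' task-independent. Internal precision is a Weber fraction that increases
#' by 50% under divided attention.
#'
#' @param n_observers Cohort size (default 18).
#' @param aq_location,aq_scale,aq_skew Skew-normal parameters of the AQ
#'   sampling distribution (calibrated defaults; scores are rounded and
#'   clipped to 0..50).
#' @param p_group_base Baseline grouping probability (low numerosity, single
#'   task) at the population-average AQ.
#' @param coupling_slope Decrease in grouping probability per standard
#'   deviation of AQ.
#' @param coupling_noise_sd SD of observer-level noise on the single-task
#'   grouping probability.
#' @param dual_attenuation Multiplicative reduction of grouping probability
#'   under the dual task (0..1).
#' @param dual_noise_sd SD of observer-level noise added to the dual-task
#'   grouping probability.
#' @param p_group_high_mean,p_group_high_sd Mean and SD of the
#'   task-independent grouping probability at high numerosity.
#' @param w_single_mean,w_single_sd Mean and SD of the single-task internal
#'   Weber fraction.
#' @param w_dual_over_single Ratio of dual- to single-task internal Weber
#'   fraction (default 1.5, the attentional precision cost).
#' @param distractor_accuracy Probability of a correct response to the
#'   central distractor in dual-task trials (default 0.85).
#' @param lapse Probability of a uniformly random numerosity response
#'   (default 0).
#' @param seed Optional integer seed for [sample_cohort()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_observers = 18L,
                          aq_location = .aq_sn$location,
                          aq_scale = .aq_sn$scale,
                          aq_skew = .aq_sn$shape,
                          p_group_base = .coupling$p_group_base,
                          coupling_slope = .coupling$slope,
                          coupling_noise_sd = .coupling$noise_sd,
                          dual_attenuation = .coupling$dual_attenuation,
                          dual_noise_sd = .coupling$dual_noise_sd,
                          p_group_high_mean = .coupling$p_group_high_mean,
                          p_group_high_sd = .coupling$p_group_high_sd,
                          w_single_mean = 0.2,
                          w_single_sd = 0.02,
                          w_dual_over_single = 1.5,
                          distractor_accuracy = 0.85,
                          lapse = 0,
                          seed = NULL) {
  stopifnot(
    n_observers >= 2, aq_scale > 0,
    p_group_base >= 0, p_group_base <= 1,
    coupling_noise_sd >= 0, dual_noise_sd >= 0,
    dual_attenuation >= 0, dual_attenuation <= 1,
    p_group_high_mean >= 0, p_group_high_mean <= 1, p_group_high_sd >= 0,
    w_single_mean > 0, w_single_sd >= 0, w_dual_over_single > 0,
    distractor_accuracy >= 0, distractor_accuracy <= 1,
    lapse >= 0, lapse <= 1
  )
  structure(as.list(environment()), class = "cohort_config")
}

#' Sample a synthetic observer cohort
#'
#' Draws AQ scores from the calibrated skew-normal (rounded and clipped to
#' 0..50) and derives each observer's grouping probabilities and internal
#' Weber fractions. The single-task low-numerosity grouping probability is
#' `clip(base - slope * z(AQ) + noise)`, where `z(AQ)` standardises the raw
#' (unrounded) score by the population moments of the AQ distribution; the
#' dual-task value is `clip(attenuation * single + noise)`; the
#' high-numerosity value is task-independent.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per observer: `observer_id`, `aq`,
#'   `p_group_low_single`, `p_group_low_dual`, `p_group_high`, `w_single`,
#'   `w_dual`, `lapse`, `distractor_accuracy`.
#' @export
sample_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  draw <- function() {
    n <- config$n_observers
    x <- rskewnorm(n, config$aq_location, config$aq_scale, config$aq_skew)
    aq <- as.integer(pmin(pmax(round(x), 0), 50))
    z <- (x - .aq_sn$mean) / .aq_sn$sd
    clip01 <- function(v) pmin(pmax(v, 0), 1)
    p_single <- clip01(config$p_group_base - config$coupling_slope * z +
                         stats::rnorm(n, 0, config$coupling_noise_sd))
    p_dual <- clip01(config$dual_attenuation * p_single +
                       stats::rnorm(n, 0, config$dual_noise_sd))
    p_high <- clip01(stats::rnorm(n, config$p_group_high_mean,
                                  config$p_group_high_sd))
    w_single <- pmax(stats::rnorm(n, config$w_single_mean, config$w_single_sd),
                     0.05)
    tibble::tibble(
      observer_id = sprintf("obs%03d", seq_len(n)),
      aq = aq,
      p_group_low_single = p_single,
      p_group_low_dual = p_dual,
      p_group_high = p_high,
      w_single = w_single,
      w_dual = w_single * config$w_dual_over_single,
      lapse = config$lapse,
      distractor_accuracy = config$distractor_accuracy
    )
  }
  if (!is.null(config$seed)) withr::with_seed(config$seed, draw()) else draw()
}

#' Expected percent bias from pairwise grouping
#'
#' Under the object-removal account, each connected pair perceived as one
#' object removes one countable item, so with a fraction `f` of dots joined
#' pairwise and per-pair grouping probability `p` the expected percent change
#' in perceived numerosity is `-100 * (f / 2) * p`: -20% for f = 0.4 with
#' obligatory grouping, -7% when grouping succeeds on 35% of pairs.
#'
#' @param connect_fraction Fraction of dots joined pairwise (0..1).
#' @param p_group Per-pair grouping probability (0..1).
#' @return Expected bias in percent (non-positive).
#' @examples
#' expected_bias_percent(0.4, 1.0)  # -20
#' expected_bias_percent(0.4, 0.35) # -7
#' @export
expected_bias_percent <- function(connect_fraction, p_group) {
  if (any(connect_fraction < 0 | connect_fraction > 1))
    stop("connect_fraction must lie in [0, 1]", call. = FALSE)
  if (any(p_group < 0 | p_group > 1))
    stop("p_group must lie in [0, 1]", call. = FALSE)
  -100 * (connect_fraction / 2) * p_group
}

#' Grouping probability of an observer in a given cell
#'
#' Dispatches on the numerosity band: at or below `band_threshold`
#' (default 25) the task-specific low-numerosity probability applies; above
#' it the task-independent high-numerosity probability applies.
#'
#' @param profile One row of a cohort tibble (or an equivalent list).
#' @param task `"single"` or `"dual"`.
#' @param numerosity Reference numerosity.
#' @param band_threshold Upper edge of the low-numerosity band (default 25).
#' @return Grouping probability in \code{[0, 1]}.
#' @export
effective_grouping_prob <- function(profile, task = c("single", "dual"),
                                    numerosity, band_threshold = 25) {
  task <- match.arg(task)
  if (numerosity <= band_threshold) {
    if (task == "single") profile$p_group_low_single else profile$p_group_low_dual
  } else {
    profile$p_group_high
  }
}

#' Internal numerosity estimate for a stimulus
#'
#' Each connector groups its pair into one perceived object with the
#' observer's effective grouping probability, so the effective count is
#' `N - Binomial(n_connectors, p)`. The returned estimate is Gaussian around
#' the effective count with SD `w * N_eff` (the internal Weber noise on the
#' linear numerosity scale), truncated at zero. Uses the current RNG stream.
#'
#' @param pattern A `dot_pattern`.
#' @param profile Observer row as in [sample_cohort()].
#' @param task `"single"` or `"dual"`.
#' @param band_threshold Passed to [effective_grouping_prob()].
#' @return A non-negative numeric scalar.
#' @export
perceive_pattern <- function(pattern, profile, task = c("single", "dual"),
                             band_threshold = 25) {
  task <- match.arg(task)
  n <- nrow(pattern$dots)
  k <- nrow(pattern$connectors)
  p <- effective_grouping_prob(profile, task, n, band_threshold)
  n_eff <- n - if (k > 0) stats::rbinom(1, k, p) else 0
  w <- if (task == "single") profile$w_single else profile$w_dual
  max(0, stats::rnorm(1, n_eff, w * n_eff))
}

#' Simulate one 2AFC trial decision
#'
#' With probability `lapse` the observer responds at random; otherwise the
#' probe is chosen when its internal estimate exceeds the reference's
#' (ties, which have probability zero under the noise model, go to the
#' reference). Dual-task trials additionally emit a Bernoulli distractor
#' response with the observer's `distractor_accuracy`. Uses the current RNG
#' stream.
#'
#' @param ref_pattern,probe_pattern `dot_pattern` stimuli; the probe is
#'   always isolated in the standard design.
#' @param profile Observer row as in [sample_cohort()].
#' @param task `"single"` or `"dual"`.
#' @param band_threshold Passed to [effective_grouping_prob()].
#' @return A list with `choice` (`"probe_more"` or `"ref_more"`) and
#'   `distractor_correct` (logical, `NA` for single-task trials).
#' @export
decide_trial <- function(ref_pattern, probe_pattern, profile,
                         task = c("single", "dual"), band_threshold = 25) {
  task <- match.arg(task)
  if (stats::runif(1) < profile$lapse) {
    choice <- if (stats::runif(1) < 0.5) "probe_more" else "ref_more"
  } else {
    est_ref <- perceive_pattern(ref_pattern, profile, task, band_threshold)
    est_probe <- perceive_pattern(probe_pattern, profile, task, band_threshold)
    choice <- if (est_probe > est_ref) "probe_more" else "ref_more"
  }
  distractor <- if (task == "dual") {
    stats::runif(1) < profile$distractor_accuracy
  } else {
    NA
  }
  list(choice = choice, distractor_correct = distractor)
}

#' Write / read a cohort as CSV
#'
#' One row per observer with all profile fields; the sampling seed (when
#' known) is recorded in a `#`-prefixed header comment.
#'
#' @param cohort Cohort tibble from [sample_cohort()].
#' @param path File path.
#' @param seed Optional seed to record in the header.
#' @return `path` (write) or the cohort tibble (read).
#' @export
write_cohort_csv <- function(cohort, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# numgroup cohort; seed=%s",
                     if (is.null(seed)) "NA" else seed), con)
  utils::write.csv(cohort, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}
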