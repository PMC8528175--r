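#' Aggregate trial records into per-level response tallies
#'
#' Groups trials by experimental cell (observer, task, condition, reference
#' numerosity) and probe level, tallying "probe more numerous" responses.
#'
#' @param records Trial tibble as produced by [run_session()].
#' @return A tibble with columns `observer_id`, `task`, `condition`,
#'   `reference_numerosity`, `probe_numerosity`, `n_probe_more`, `n_total`.
#' @export
aggregate_responses <- function(records) {
  if (nrow(records) == 0) stop("no trial records to aggregate", call. = FALSE)
  records |>
    dplyr::group_by(.data$observer_id, .data$task, .data$condition,
                    .data$reference_numerosity, .data$probe_numerosity) |>
    dplyr::summarise(
      n_probe_more = sum(.data$response == "probe_more"),
      n_total = dplyr::n(),
      .groups = "drop"
    )
}

# Negative log-likelihood of the cumulative-Gaussian psychometric function,
# parameterised as (mu, log sigma) for unconstrained optimisation.
.cg_nll <- function(par, x, k, n) {
  mu <- par[1]
  sigma <- exp(par[2])
  p <- stats::pnorm((x - mu) / sigma)
  eps <- 1e-10
  p <- pmin(pmax(p, eps), 1 - eps)
  -sum(k * log(p) + (n - k) * log(1 - p))
}

# Trial-weighted squared error on the proportion scale.
.cg_wls <- function(par, x, k, n) {
  mu <- par[1]
  sigma <- exp(par[2])
  sum(n * (k / n - stats::pnorm((x - mu) / sigma))^2)
}

#' Fit a cumulative-Gaussian psychometric function
#'
#' Fits `P(probe judged more numerous) = pnorm((x - mu) / sigma)` on the
#' probe-numerosity axis, optimised over `(mu, log sigma)` from several
#' starting points: a probit-regression start, a moment-based start, and a
#' coarse grid.
#'
#' Two objectives are available. The default `"wls"` minimises the squared
#' error between observed and predicted proportions, weighted by the number
#' of trials per level -- the classical proportion-space fit of the
#' psychophysics literature, which tracks the central part of the function
#' where the median (PSE) is defined. `"ml"` is Bernoulli maximum
#' likelihood. For an observer with scalar (Weber-like) internal noise the
#' true choice curve is mildly asymmetric around its median; maximum
#' likelihood, dominated by the near-saturated tail trials an adaptive
#' staircase still produces, absorbs that asymmetry into an upward-shifted
#' location and inflated spread, whereas the proportion fit does not (see
#' the methods vignette). On data genuinely generated from a cumulative
#' Gaussian the two estimators agree.
#'
#' Complete separation (a threshold splitting all-"reference" from
#' all-"probe" levels with no mixed level) is flagged as non-converged with
#' sigma clamped at a small positive value; a response set with no variation
#' at all is an error.
#'
#' @param data One cell of [aggregate_responses()] output (columns
#'   `probe_numerosity`, `n_probe_more`, `n_total`), or any data frame with
#'   those columns.
#' @param reference Reference numerosity of the cell. Taken from a
#'   `reference_numerosity` column when present.
#' @param method `"wls"` (trial-weighted least squares on proportions,
#'   default) or `"ml"` (Bernoulli maximum likelihood).
#' @return An object of class `psychometric_fit`: list with `mu`, `sigma`,
#'   `log_likelihood` (Bernoulli log-likelihood at the estimate, whichever
#'   objective was optimised), `converged`, `n_trials`, `reference`, and the
#'   derived indices `pse`, `jnd` (`qnorm(0.75) * sigma`), `weber_fraction`
#'   (JND / PSE) and `bias_percent` (`100 * (pse - reference) / reference`).
#' @export
fit_cumulative_gaussian <- function(data, reference = NULL,
                                    method = c("wls", "ml")) {
  method <- match.arg(method)
  x <- data$probe_numerosity
  k <- data$n_probe_more
  n <- data$n_total
  stopifnot(all(k >= 0), all(k <= n))
  if (is.null(reference)) {
    if (!"reference_numerosity" %in% names(data))
      stop("reference numerosity not supplied", call. = FALSE)
    reference <- unique(data$reference_numerosity)
    stopifnot(length(reference) == 1)
  }
  if (length(unique(x)) < 2)
    stop("need at least 2 distinct probe levels for fitting", call. = FALSE)
  if (sum(k) == 0 || sum(k) == sum(n))
    stop("degenerate responses: no variation to fit", call. = FALSE)

  # complete separation: no mixed level and a clean threshold
  o <- order(x)
  prop <- (k / n)[o]
  mixed <- any(prop > 0 & prop < 1)
  separated <- !mixed && all(diff(prop >= 0.5) >= 0)

  starts <- list()
  # probit-regression start
  gl <- tryCatch(
    suppressWarnings(stats::glm(cbind(k, n - k) ~ x,
                                family = stats::binomial("probit"))),
    error = function(e) NULL
  )
  if (!is.null(gl) && is.finite(stats::coef(gl)[2]) && stats::coef(gl)[2] > 0) {
    b <- stats::coef(gl)
    starts <- c(starts, list(c(-b[1] / b[2], log(1 / b[2]))))
  }
  # moment start: response-weighted location/spread
  w <- k + 0.5
  mu0 <- sum(x * w) / sum(w)
  s0 <- max(stats::sd(rep(x, n)) / 2, diff(range(x)) / 10, 1e-3)
  starts <- c(starts, list(c(mu0, log(s0))))
  # coarse grid of starts
  for (m in stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE))
    for (s in c(s0 / 2, s0 * 2))
      starts <- c(starts, list(c(m, log(s))))

  obj <- if (method == "ml") .cg_nll else .cg_wls
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, obj, x = x, k = k, n = n, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("psychometric fit failed from all starts", call. = FALSE)
  # polish with a derivative-based pass
  pol <- tryCatch(
    stats::optim(best$par, obj, x = x, k = k, n = n, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-10)),
    error = function(e) NULL
  )
  if (!is.null(pol) && pol$value <= best$value) best <- pol

  mu <- unname(best$par[1])
  sigma <- unname(exp(best$par[2]))
  sigma_min <- 1e-3 * reference
  converged <- !separated && best$convergence == 0 && sigma > sigma_min
  if (sigma <= sigma_min) sigma <- sigma_min

  structure(
    list(
      mu = mu, sigma = sigma,
      log_likelihood = -.cg_nll(c(mu, log(sigma)), x, k, n),
      converged = converged,
      n_trials = sum(n),
      reference = reference,
      pse = mu,
      jnd = stats::qnorm(0.75) * sigma,
      weber_fraction = stats::qnorm(0.75) * sigma / mu,
      bias_percent = 100 * (mu - reference) / reference
    ),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> pse = %.3f, jnd = %.3f, WF = %.4f, bias = %.2f%%%s\n",
    x$pse, x$jnd, x$weber_fraction, x$bias_percent,
    if (x$converged) "" else " [NOT CONVERGED]"
  ))
  invisible(x)
}

#' Derive PSE, JND, Weber fraction and percent bias from a fit
#'
#' PSE is the fitted median `mu`; JND is the numerosity difference taking the
#' psychometric function from 50% to 75%, i.e. `qnorm(0.75) * sigma`; the
#' Weber fraction divides the JND by the perceived numerosity (the PSE by
#' default, switchable to the physical reference); bias is the percent
#' deviation of the PSE from the reference.
#'
#' @param fit A `psychometric_fit`.
#' @param reference Reference numerosity (defaults to the one stored in the
#'   fit).
#' @param wf_denominator `"pse"` (perceived numerosity, default) or
#'   `"reference"`.
#' @param allow_nonconverged Set `TRUE` to derive indices from a
#'   non-converged fit anyway.
#' @return A list with `pse`, `jnd`, `weber_fraction`, `bias_percent`.
#' @export
derive_indices <- function(fit, reference = fit$reference,
                           wf_denominator = c("pse", "reference"),
                           allow_nonconverged = FALSE) {
  stopifnot(inherits(fit, "psychometric_fit"))
  wf_denominator <- match.arg(wf_denominator)
  if (!fit$converged && !allow_nonconverged)
    stop("fit did not converge; pass allow_nonconverged = TRUE to override",
         call. = FALSE)
  jnd <- stats::qnorm(0.75) * fit$sigma
  denom <- if (wf_denominator == "pse") fit$mu else reference
  list(
    pse = fit$mu,
    jnd = jnd,
    weber_fraction = jnd / denom,
    bias_percent = 100 * (fit$mu - reference) / reference
  )
}

#' Fit every cell of a trial log
#'
#' Convenience wrapper: tallies responses with [aggregate_responses()] and
#' fits each observer x task x condition x numerosity cell.
#'
#' @param records Trial tibble (possibly many sessions).
#' @param allow_nonconverged Keep non-converged fits in the output (flagged)
#'   instead of erroring.
#' @param method Fit objective, passed to [fit_cumulative_gaussian()].
#' @return A tibble with one row per cell: identifiers plus `mu`, `sigma`,
#'   `pse`, `jnd`, `weber_fraction`, `bias_percent`, `n_trials`, `converged`.
#' @export
fit_all_cells <- function(records, allow_nonconverged = TRUE,
                          method = c("wls", "ml")) {
  method <- match.arg(method)
  tal <- aggregate_responses(records)
  cells <- tal |>
    dplyr::group_by(.data$observer_id, .data$task, .data$condition,
                    .data$reference_numerosity) |>
    dplyr::group_split()
  rows <- lapply(cells, function(cell) {
    fit <- fit_cumulative_gaussian(cell, method = method)
    if (!fit$converged && !allow_nonconverged)
      stop(sprintf("fit did not converge in cell %s/%s/%s/N%d",
                   cell$observer_id[1], cell$task[1], cell$condition[1],
                   cell$reference_numerosity[1]), call. = FALSE)
    tibble::tibble(
      observer_id = cell$observer_id[1],
      task = cell$task[1],
      condition = cell$condition[1],
      reference_numerosity = cell$reference_numerosity[1],
      mu = fit$mu, sigma = fit$sigma,
      pse = fit$pse, jnd = fit$jnd,
      weber_fraction = fit$weber_fraction,
      bias_percent = fit$bias_percent,
      n_trials = fit$n_trials,
      converged = fit$converged
    )
  })
  dplyr::bind_rows(rows)
}

#' Write fitted cells as CSV
#'
#' @param fits Tibble from [fit_all_cells()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fits_csv <- function(fits, path) {
  utils::write.csv(fits, path, row.names = FALSE)
  invisible(path)
}
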