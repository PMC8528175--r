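#' Summarise biases by cell, numerosity band and AQ group
#'
#' Joins per-cell psychometric fits with the cohort, splits numerosities into
#' a low band (at or below `band_threshold`) and a high band, splits
#' observers at the sample AQ median (observers exactly at the median go to
#' the low-AQ group), and returns per-cell means and SDs.
#'
#' @param fits Tibble from [fit_all_cells()].
#' @param cohort Cohort tibble from [sample_cohort()] (needs `observer_id`
#'   and `aq`).
#' @param band_threshold Upper edge of the low-numerosity band (default 25).
#' @return A tibble with one row per task x condition x band x AQ group:
#'   `mean_bias`, `sd_bias`, `mean_wf`, `n`.
#' @export
summarize_group_biases <- function(fits, cohort, band_threshold = 25) {
  stopifnot(all(c("observer_id", "aq") %in% names(cohort)))
  med <- stats::median(cohort$aq)
  dat <- fits |>
    dplyr::inner_join(cohort[, c("observer_id", "aq")], by = "observer_id") |>
    dplyr::mutate(
      band = ifelse(.data$reference_numerosity <= band_threshold, "low", "high"),
      aq_group = ifelse(.data$aq <= med, "low_aq", "high_aq")
    )
  dropped <- fits |>
    dplyr::anti_join(cohort[, "observer_id", drop = FALSE], by = "observer_id")
  if (nrow(dropped) > 0)
    warning(sprintf("%d fit rows had no matching observer and were omitted",
                    nrow(dropped)), call. = FALSE)
  # observer-level mean within band first, then group summary
  dat |>
    dplyr::group_by(.data$observer_id, .data$task, .data$condition,
                    .data$band, .data$aq_group) |>
    dplyr::summarise(
      bias = mean(.data$bias_percent),
      wf = mean(.data$weber_fraction),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$task, .data$condition, .data$band, .data$aq_group) |>
    dplyr::summarise(
      mean_bias = mean(.data$bias),
      sd_bias = stats::sd(.data$bias),
      mean_wf = mean(.data$wf),
      n = dplyr::n(),
      .groups = "drop"
    )
}

# log integrand of the JZS (Zellner-Siow) correlation Bayes factor
.jzs_log_integrand <- function(g, r2, n) {
  (n - 2) / 2 * log1p(g) - (n - 1) / 2 * log1p((1 - r2) * g) +
    0.5 * log(n / 2) - lgamma(0.5) - 1.5 * log(g) - n / (2 * g)
}

#' Bayes factor for a Pearson correlation coefficient
#'
#' Default-prior Bayes factor `BF10` for a correlation, reported as log10.
#' The default `"jzs"` method places a Zellner-Siow (JZS) prior on the
#' standardised regression slope (inverse-gamma(1/2, n/2) mixing on `g`) and
#' integrates numerically; it reproduces the values printed by classical
#' Bayesian-correlation software (log10 BF = 0.68 at r = 0.59, n = 18; -0.43
#' at r = 0.30, n = 18). The `"stretched_beta"` method implements the exact
#' two-sided analysis with a stretched-beta prior of width `kappa` on the
#' population correlation.
#'
#' @param r Sample Pearson correlation in (-1, 1).
#' @param n Sample size (>= 3).
#' @param method `"jzs"` (default) or `"stretched_beta"`.
#' @param kappa Stretched-beta prior width (default 1, the uniform prior);
#'   ignored for `"jzs"`.
#' @return log10 of BF10. `|r|` numerically at 1 returns the cap `1e6` (with
#'   a warning): the evidence is unbounded.
#' @export
bf_pearson <- function(r, n, method = c("jzs", "stretched_beta"), kappa = 1) {
  method <- match.arg(method)
  stopifnot(n >= 3, abs(r) <= 1)
  if (abs(r) >= 1 - 1e-10) {
    warning("|r| at 1: Bayes factor unbounded, returning capped value",
            call. = FALSE)
    return(1e6)
  }
  if (method == "jzs") {
    r2 <- r^2
    # integrate in two pieces on a log-stable scale
    f <- function(g) exp(.jzs_log_integrand(g, r2, n))
    bf <- stats::integrate(f, 0, 1, rel.tol = 1e-10)$value +
      stats::integrate(f, 1, Inf, rel.tol = 1e-10)$value
    log10(bf)
  } else {
    # Exact two-sided stretched-beta BF (closed form with Gauss 2F1)
    a <- 1 / kappa
    lg <- (1 - 2 / kappa) * log(2) + 0.5 * log(pi) - lbeta(a, a) +
      lgamma((n + 2 / kappa - 1) / 2) - lgamma((n + 2 / kappa) / 2)
    h <- .hyp2f1((n - 1) / 2, (n - 1) / 2, (n + 2 / kappa) / 2, r^2)
    (lg + log(h)) / log(10)
  }
}

# Gauss hypergeometric 2F1 by direct series; adequate for z in [0, 1).
.hyp2f1 <- function(a, b, c, z) {
  stopifnot(z >= 0, z < 1)
  term <- 1
  total <- 1
  for (k in 0:100000) {
    term <- term * (a + k) * (b + k) / ((c + k) * (k + 1)) * z
    total <- total + term
    if (abs(term) < 1e-15 * abs(total)) return(total)
  }
  warning("2F1 series did not fully converge", call. = FALSE)
  total
}

#' Pearson correlation with p-value and default-prior Bayes factor
#'
#' @param x,y Numeric vectors of equal length (n >= 3, no missing values).
#' @param method,kappa Passed to [bf_pearson()].
#' @return An object of class `correlation_bf`: list with `r`, `n`, `p`
#'   (two-sided, from the t transform) and `log10_bf` (BF10).
#' @examples
#' set.seed(1)
#' x <- rnorm(18); y <- 0.6 * x + rnorm(18, sd = 0.8)
#' pearson_with_bf(x, y)
#' @export
pearson_with_bf <- function(x, y, method = c("jzs", "stretched_beta"),
                            kappa = 1) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y", call. = FALSE)
  n <- length(x)
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-10) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), n - 2)
  }
  structure(
    list(r = r, n = n, p = p,
         log10_bf = bf_pearson(r, n, method = method, kappa = kappa)),
    class = "correlation_bf"
  )
}

#' @export
print.correlation_bf <- function(x, ...) {
  cat(sprintf("<correlation_bf> r = %.3f (n = %d), p = %.4g, log10 BF10 = %.3f\n",
              x$r, x$n, x$p, x$log10_bf))
  invisible(x)
}

# Sum of squares of effect `vars` in a balanced crossed design, by
# Moebius inclusion-exclusion over marginal means.
.effect_ss <- function(data, dv, vars) {
  n_total <- nrow(data)
  grand <- mean(data[[dv]])
  if (length(vars) == 0) return(n_total * grand^2)
  cells <- unique(data[, vars, drop = FALSE])
  # marginal mean lookup per subset
  subsets <- unlist(lapply(0:length(vars), function(k)
    utils::combn(vars, k, simplify = FALSE)), recursive = FALSE)
  marg <- lapply(subsets, function(s) {
    if (length(s) == 0) return(grand)
    agg <- stats::aggregate(data[[dv]], by = data[s], FUN = mean)
    agg
  })
  names(marg) <- vapply(subsets, paste, "", collapse = "\r")
  tau2 <- 0
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, , drop = FALSE]
    val <- 0
    for (si in seq_along(subsets)) {
      s <- subsets[[si]]
      sgn <- (-1)^(length(vars) - length(s))
      if (length(s) == 0) {
        m <- grand
      } else {
        agg <- marg[[si]]
        sel <- rep(TRUE, nrow(agg))
        for (v in s) sel <- sel & (agg[[v]] == cell[[v]])
        m <- agg$x[sel]
      }
      val <- val + sgn * m
    }
    tau2 <- tau2 + val^2
  }
  reps <- n_total / nrow(cells)
  reps * tau2
}

#' Repeated-measures ANOVA for balanced within-subject designs
#'
#' Classical sums-of-squares decomposition with the subject as a random
#' blocking factor: every within-subject effect is tested against its own
#' interaction with subject. Reports F, degrees of freedom, p, partial eta
#' squared (`SS_effect / (SS_effect + SS_error)`), and an approximate log10
#' Bayes factor per effect from the BIC difference between maximum-likelihood
#' mixed models (random subject intercept) with and without the effect
#' (higher-order terms containing the effect are removed together with it).
#' The BIC Bayes factors are labelled approximate: they are not a replica of
#' g-prior Bayesian ANOVA software.
#'
#' @param data Long-format data frame: one row per subject x cell.
#' @param dv Name of the response column.
#' @param subject Name of the subject-identifier column.
#' @param factors Character vector of within-subject factor columns.
#' @return An object of class `anova_rm`: tibble with one row per effect
#'   (`effect`, `ss`, `ss_error`, `df1`, `df2`, `F`, `p`, `eta_p2`,
#'   `log10_bf_bic`).
#' @export
rm_anova_within <- function(data, dv, subject, factors) {
  stopifnot(all(c(dv, subject, factors) %in% names(data)),
            length(factors) >= 1)
  data <- as.data.frame(data)
  for (v in c(subject, factors)) data[[v]] <- factor(data[[v]])
  n_subj <- nlevels(data[[subject]])
  if (n_subj < 2) stop("need at least 2 subjects", call. = FALSE)
  lev <- vapply(factors, function(v) nlevels(data[[v]]), integer(1))
  expected <- n_subj * prod(lev)
  counts <- table(data[, c(subject, factors)])
  if (nrow(data) != expected || any(counts != 1))
    stop("unbalanced design: every subject needs exactly one value per cell",
         call. = FALSE)

  effects <- unlist(lapply(1:length(factors), function(k)
    utils::combn(factors, k, simplify = FALSE)), recursive = FALSE)

  rows <- lapply(effects, function(e) {
    ss_e <- .effect_ss(data, dv, e)
    ss_err <- .effect_ss(data, dv, c(e, subject))
    df1 <- prod(lev[e] - 1)
    df2 <- df1 * (n_subj - 1)
    Fval <- (ss_e / df1) / (ss_err / df2)
    tibble::tibble(
      effect = paste(e, collapse = ":"),
      ss = ss_e, ss_error = ss_err,
      df1 = df1, df2 = df2, F = Fval,
      p = stats::pf(Fval, df1, df2, lower.tail = FALSE),
      eta_p2 = ss_e / (ss_e + ss_err)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$log10_bf_bic <- .anova_bic_bf(data, dv, subject, factors, out$effect)
  class(out) <- c("anova_rm", class(out))
  out
}

# BIC-approximate log10 BF10 per effect via ML lmer fits.
.anova_bic_bf <- function(data, dv, subject, factors, effect_labels) {
  full_terms <- paste(factors, collapse = " * ")
  full_form <- stats::as.formula(
    sprintf("%s ~ %s + (1 | %s)", dv, full_terms, subject))
  fit_bic <- function(form) {
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(form, data = data, REML = FALSE)
    ))
    stats::BIC(fit)
  }
  bic_full <- fit_bic(full_form)
  all_terms <- attr(stats::terms(stats::as.formula(
    sprintf("%s ~ %s", dv, full_terms))), "term.labels")
  vapply(effect_labels, function(e) {
    evars <- strsplit(e, ":")[[1]]
    keep <- Filter(function(t) {
      !all(evars %in% strsplit(t, ":")[[1]])
    }, all_terms)
    red_form <- stats::as.formula(sprintf(
      "%s ~ %s + (1 | %s)", dv,
      if (length(keep)) paste(keep, collapse = " + ") else "1", subject))
    bic_red <- fit_bic(red_form)
    (bic_red - bic_full) / (2 * log(10))
  }, numeric(1))
}

#' Jarque-Bera test of composite normality
#'
#' `JB = n/6 * (S^2 + (K - 3)^2 / 4)` with sample skewness `S` and kurtosis
#' `K` (moment estimators), referred to a chi-squared distribution with 2
#' degrees of freedom. The chi-squared reference is asymptotic and
#' anticonservative in small samples.
#'
#' @param x Numeric vector, n >= 8.
#' @return List with `jb`, `p`, `skewness`, `kurtosis`, `n`.
#' @export
jarque_bera <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("need at least 8 observations", call. = FALSE)
  m <- x - mean(x)
  m2 <- mean(m^2)
  if (m2 == 0) stop("zero variance", call. = FALSE)
  S <- mean(m^3) / m2^1.5
  K <- mean(m^4) / m2^2
  jb <- n / 6 * (S^2 + (K - 3)^2 / 4)
  list(jb = jb, p = stats::pchisq(jb, df = 2, lower.tail = FALSE),
       skewness = S, kurtosis = K, n = n)
}
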