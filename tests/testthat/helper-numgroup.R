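# Simulate aggregated 2AFC tallies from a true cumulative Gaussian at
# QUEST-like (log-normally placed, integer) probe levels.
simulate_cg_tallies <- function(mu, sigma, n_trials = 180,
                                placement_sd = 0.155, seed = NULL) {
  draw <- function() {
    x <- pmax(1, round(10^(log10(mu) + stats::rnorm(n_trials, 0, placement_sd))))
    p <- stats::pnorm((x - mu) / sigma)
    k <- stats::rbinom(n_trials, 1, p)
    agg <- stats::aggregate(cbind(k = k, one = rep(1, n_trials)),
                            by = list(probe_numerosity = x), FUN = sum)
    data.frame(probe_numerosity = agg$probe_numerosity,
               n_probe_more = agg$k, n_total = agg$one)
  }
  if (!is.null(seed)) withr::with_seed(seed, draw()) else draw()
}

# A tiny deterministic cohort row for observer-model tests.
test_observer <- function(p_single = 1, p_dual = 0.35, p_high = 0.4,
                          w_single = 0.2, w_dual = 0.3, lapse = 0,
                          distractor_accuracy = 0.85) {
  tibble::tibble(
    observer_id = "obsT", aq = 13L,
    p_group_low_single = p_single, p_group_low_dual = p_dual,
    p_group_high = p_high, w_single = w_single, w_dual = w_dual,
    lapse = lapse, distractor_accuracy = distractor_accuracy
  )
}

# Hand-built dot pattern for validator tests.
manual_pattern <- function(xy, connectors = data.frame(i = integer(), j = integer()),
                           config = stimulus_config(nrow(xy))) {
  structure(
    list(
      dots = data.frame(x = xy[, 1], y = xy[, 2],
                        polarity = rep(c("white", "black"), length.out = nrow(xy))),
      connectors = connectors,
      config = config,
      kind = if (nrow(connectors)) "connected" else "isolated"
    ),
    class = "dot_pattern"
  )
}
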