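test_that("the QUEST prior is a normalised discretised Gaussian", {
  st <- quest_init(quest_config(15))
  expect_equal(sum(st$posterior), 1, tolerance = 1e-12)
  expect_true(all(st$posterior >= 0))
  expect_equal(st$grid[which.max(st$posterior)], log10(15), tolerance = 0.005)
  # a very broad prior is near-uniform over the working range of the grid
  broad <- quest_init(quest_config(15, prior_sd = 50, grid_halfwidth = 100.5))
  central <- broad$posterior[abs(broad$grid - log10(15)) <= 0.6]
  expect_lt(diff(range(central)) / max(central), 1e-3)
  expect_error(quest_config(15, grid_halfwidth = 0.3),
               "grid must cover the prior")
})

test_that("posterior updates equal the brute-force grid Bayes rule", {
  cfg <- quest_config(15, grid_halfwidth = 0.6, grid_step = 0.025)  # coarse toy grid
  st <- quest_init(cfg)
  probes <- c(1.2, 1.1, 1.05, 1.15, 1.0)
  resps <- c("probe_more", "ref_more", "ref_more", "probe_more", "probe_more")
  seq_state <- st
  for (i in seq_along(probes))
    seq_state <- quest_update(seq_state, probes[i], resps[i])
  # oracle: multiply the prior by the full likelihood product in one pass
  lik <- rep(1, length(st$grid))
  for (i in seq_along(probes)) {
    p <- stats::pnorm((probes[i] - st$grid) / cfg$assumed_slope_sd)
    lik <- lik * if (resps[i] == "probe_more") p else 1 - p
  }
  oracle <- st$posterior * lik
  oracle <- oracle / sum(oracle)
  expect_equal(seq_state$posterior, oracle, tolerance = 1e-12)
  expect_identical(seq_state$trial, 5L)
})

test_that("single responses move the posterior the right way", {
  st <- quest_init(quest_config(15))
  m0 <- quest_mean(st)
  up <- quest_update(st, log10(15), "probe_more")
  expect_lt(quest_mean(up), m0)   # probe seen as more: PSE likely below probe
  down <- quest_update(st, log10(15), "ref_more")
  expect_gt(quest_mean(down), m0)
  # two opposite responses at an off-centre probe land between prior and probe
  x <- log10(20)
  both <- quest_update(quest_update(st, x, "probe_more"), x, "ref_more")
  expect_gt(quest_mean(both), m0)
  expect_lt(quest_mean(both), x)
})

test_that("probe recommendations are perturbed integers about the mean", {
  cfg0 <- quest_config(15, perturbation_sd = 0)
  st <- quest_init(cfg0)
  expect_identical(quest_recommend(st, cfg0), 15L)
  cfg <- quest_config(15)
  withr::local_seed(6)
  recs <- replicate(4000, quest_recommend(st, cfg))
  expect_true(all(recs >= 1 & recs == round(recs)))
  expect_lt(abs(stats::sd(log10(recs)) - 0.15), 0.005)
})

test_that("the posterior contracts and converges to a synthetic observer's PSE", {
  # Drive the staircase directly with Bernoulli responses from a symmetric
  # log-Gaussian observer with PSE 12; no stimulus generation involved.
  true_pse <- log10(12)
  slope <- 0.1
  cfg <- quest_config(15, n_trials = 180)
  errs <- c()
  sd_drop <- c()
  withr::local_seed(17)
  for (rep in 1:40) {
    st <- quest_init(cfg)
    sd0 <- sqrt(sum(st$grid^2 * st$posterior) - quest_mean(st)^2)
    for (t in 1:180) {
      pn <- quest_recommend(st, cfg)
      p <- stats::pnorm((log10(pn) - true_pse) / slope)
      resp <- if (stats::runif(1) < p) "probe_more" else "ref_more"
      st <- quest_update(st, log10(pn), resp)
    }
    sd1 <- sqrt(sum(st$grid^2 * st$posterior) - quest_mean(st)^2)
    errs[rep] <- abs(quest_mean(st) - true_pse)
    sd_drop[rep] <- sd1 < sd0
  }
  expect_gte(mean(errs <= 0.02), 0.95)
  expect_true(all(sd_drop))
})

test_that("halving the grid step barely moves the final posterior mean", {
  run_with_step <- function(step) {
    cfg <- quest_config(15, grid_step = step)
    st <- quest_init(cfg)
    withr::with_seed(23, {
      for (t in 1:60) {
        pn <- quest_recommend(st, cfg)
        p <- stats::pnorm((log10(pn) - log10(12)) / 0.1)
        resp <- if (stats::runif(1) < p) "probe_more" else "ref_more"
        st <- quest_update(st, log10(pn), resp)
      }
    })
    quest_mean(st)
  }
  expect_lt(abs(run_with_step(0.005) - run_with_step(0.0025)), 1e-3)
})

test_that("simulated sessions have the full trial budget and are reproducible", {
  obs <- test_observer()
  cfg <- quest_config(15, seed = 314)
  tr1 <- run_session(obs, 15, "connected", "single", cfg)
  expect_identical(nrow(tr1), 180L)
  expect_true(all(tr1$probe_numerosity >= 1))
  expect_true(all(tr1$response %in% c("probe_more", "ref_more")))
  expect_true(all(is.na(tr1$distractor_correct)))
  tr2 <- run_session(obs, 15, "connected", "single", cfg)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
  # dual sessions carry distractor responses
  trd <- run_session(obs, 15, "isolated", "dual",
                     quest_config(15, n_trials = 30, seed = 9))
  expect_true(all(!is.na(trd$distractor_correct)))
})

test_that("an ideal grouping observer drags probes towards the illusory PSE", {
  obs <- test_observer(p_single = 1, w_single = 1e-4)
  tr <- run_session(obs, 15, "connected", "single", quest_config(15, seed = 41))
  late <- tr$probe_numerosity[121:180]
  expect_equal(mean(late), 12, tolerance = 0.6)
  # trial log round-trips through CSV
  f <- withr::local_tempfile(fileext = ".csv")
  write_trials_csv(tr, f)
  back <- read_trials_csv(f)
  expect_equal(back$probe_numerosity, tr$probe_numerosity)
  expect_equal(back$response, tr$response)
})
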