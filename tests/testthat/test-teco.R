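# Carbon model: temperature scalar identities, conservation, the analytic
# one-pool steady state, the likelihood, sampler correctness on a known
# target, and posterior summaries.

test_that("temperature scalar identities", {
  expect_equal(temperature_scalar(2.5, 10, 10), 1)
  expect_equal(temperature_scalar(2, 20, 10), 2)
  expect_equal(temperature_scalar(2, 0, 10), 0.5)
  expect_error(temperature_scalar(-1, 10, 10), "positive")
})

test_that("carbon is conserved and degenerate inputs behave", {
  # zero input, zero initial pools: everything stays zero
  drv <- data.frame(day = 1:50, temp = 16, c_input = 0)
  zero <- setNames(rep(0, 6), names(default_initial_state()))
  traj0 <- simulate_teco(teco_parameters(), drv, initial = zero)
  expect_equal(sum(abs(traj0$pools)), 0)
  expect_equal(sum(abs(traj0$rh)), 0)

  # conservation on seasonal drivers, several parameter sets
  for (q in c(1.6, 2.5, 4.5)) {
    ds <- generate_teco_dataset(teco_dataset_spec(
      true_params = teco_parameters(q10 = q), n_days = 400, seed = 7))
    traj <- simulate_teco(ds$truth, ds$drivers, initial = ds$initial)
    expect_lt(abs(carbon_balance_residual(traj)),
              1e-8 * sum(ds$drivers$c_input))
  }

  # constant temperature at the reference: scalar is 1, so the run matches
  # a q10 = 1.5-vs-any comparison made at temp == tref
  drv_ref <- data.frame(day = 1:100, temp = 10, c_input = 1)
  t_a <- simulate_teco(teco_parameters(q10 = 1.5), drv_ref)
  t_b <- simulate_teco(teco_parameters(q10 = 4), drv_ref)
  expect_equal(t_a$rh, t_b$rh)

  # warming monotonicity: q10 > 1 raises respiration above the reference run
  drv_warm <- data.frame(day = 1:100, temp = 20, c_input = 1)
  expect_true(all(simulate_teco(teco_parameters(q10 = 2), drv_warm)$rh >
                    simulate_teco(teco_parameters(q10 = 2), drv_ref)$rh))

  # instability guard
  drv_hot <- data.frame(day = 1:10, temp = 80, c_input = 1)
  pars <- teco_parameters(q10 = 5, k_litter = 0.027)
  expect_error(simulate_teco(pars, drv_hot), "unstable")
})

test_that("one-pool reduction converges to the analytic steady state u/k", {
  # all input to foliage (unscaled first-order exit): x* = u/k
  k <- 0.02; u <- 1
  n <- ceiling(20 / k)  # 20 turnover times
  drv <- data.frame(day = seq_len(n), temp = 10, c_input = u)
  pars <- teco_parameters(k_foliage = k)
  traj <- simulate_teco(pars, drv,
                        initial = setNames(rep(0, 6),
                                           names(default_initial_state())),
                        alloc = c(foliage = 1, root = 0))
  expect_equal(unname(traj$pools[n, "foliage"]), u / k, tolerance = 1e-3)
})

test_that("log posterior equals an independently summed Gaussian density", {
  ds <- generate_teco_dataset(teco_dataset_spec(n_days = 120, seed = 9))
  sim <- simulate_teco(ds$truth, ds$drivers, initial = ds$initial)
  lp <- log_posterior(ds$truth, ds$drivers, ds$obs, initial = ds$initial)
  hand <- sum(dnorm(ds$obs$rh$value - sim$rh, sd = ds$obs$sd_rh, log = TRUE)) +
    sum(dnorm(ds$obs$agb$value - sim$agb[ds$obs$agb$day],
              sd = ds$obs$sd_agb, log = TRUE))
  expect_equal(lp, hand)

  # outside bounds -> -Inf
  v <- ds$truth$values; v["q10"] <- 6
  expect_identical(log_posterior(v, ds$drivers, ds$obs, initial = ds$initial),
                   -Inf)
  # zero residuals are the likelihood maximum over q10 perturbations
  ds0 <- generate_teco_dataset(teco_dataset_spec(
    n_days = 120, obs_noise_sd_rh = 0, obs_noise_sd_agb = 0, seed = 9))
  lp0 <- log_posterior(ds0$truth, ds0$drivers, ds0$obs, initial = ds0$initial)
  v0 <- ds0$truth$values; v0["q10"] <- v0["q10"] + 0.1
  expect_gt(lp0, log_posterior(v0, ds0$drivers, ds0$obs, initial = ds0$initial))

  expect_error(log_posterior(ds$truth, ds$drivers, list(rh = NULL, agb = NULL)),
               "empty")
})

test_that("the MH kernel samples a standard normal correctly", {
  # detailed-balance smoke test on a 1-parameter N(0, 1) target
  res <- warmclip:::mh_sample(
    function(v) -v^2 / 2, init = 0.5, lower = -50, upper = 50, scales = 2,
    n_steps = 30000, burn_in = 2000, seed = 13, adapt = FALSE)
  x <- res$samples[-(1:2000), 1]
  expect_lt(abs(mean(x)), 0.08)
  expect_lt(abs(var(x) - 1), 0.12)
  expect_true(res$acceptance_rate > 0.2 && res$acceptance_rate < 0.7)
})

test_that("chains are reproducible and recover a known Q10 quickly", {
  ds <- generate_teco_dataset(teco_dataset_spec(
    true_params = teco_parameters(q10 = 3), n_days = 2 * 365, seed = 23))
  cfg <- mh_config(n_steps = 6000, burn_in = 2000, seed = 14)
  ch1 <- run_mh_chain(ds$drivers, ds$obs, config = cfg, initial = ds$initial)
  ch2 <- run_mh_chain(ds$drivers, ds$obs, config = cfg, initial = ds$initial)
  expect_identical(ch1$samples, ch2$samples)
  expect_true(all(ch1$samples[, "q10"] >= 1.5 & ch1$samples[, "q10"] <= 5))
  s <- summarize_posterior(ch1, "q10")
  expect_lt(abs(s$mode - 3), 0.3)
  expect_true(s$ci[1] <= s$mode && s$mode <= s$ci[2] + 1e-9 ||
                s$ci[1] <= s$mean && s$mean <= s$ci[2])
})

test_that("posterior summaries handle degenerate and known chains", {
  fake <- structure(
    list(samples = matrix(2.2, nrow = 600, ncol = 7,
                          dimnames = list(NULL, warmclip:::TECO_PARAM_NAMES)),
         log_posteriors = rep(0, 600), acceptance_rate = 0, burn_in = 100,
         seed = 1L, bounds = default_teco_bounds()),
    class = "teco_mcmc")
  s <- summarize_posterior(fake, "q10")
  expect_equal(s$mode, 2.2)
  expect_equal(s$mean, 2.2)
  expect_equal(s$ci, c(2.2, 2.2))

  # histogram mode lands within one bin width of a known unimodal mode
  set.seed(15)
  draws <- rnorm(20000, mean = 3, sd = 0.2)
  fake$samples <- matrix(draws, ncol = 7, nrow = 20000)
  colnames(fake$samples) <- warmclip:::TECO_PARAM_NAMES
  s2 <- summarize_posterior(fake, "q10", bins = 40)
  binw <- diff(range(draws[-(1:100)])) / 40
  expect_lt(abs(s2$mode - 3), binw + 1e-9)
  expect_true(s2$ci[1] <= s2$mode && s2$mode <= s2$ci[2])

  fake$samples <- fake$samples[1:150, ]
  fake$burn_in <- 100
  expect_error(summarize_posterior(fake, "q10"), "100")
  expect_error(summarize_posterior(fake, "k_nonexistent"), "unknown")
})

test_that("parameter constructors validate bounds", {
  expect_error(teco_parameters(q10 = 1.2), "outside bounds")
  expect_error(teco_parameters(k_litter = -1), "positive")
  expect_error(mh_config(n_steps = 100, burn_in = 100), "burn_in")
})
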