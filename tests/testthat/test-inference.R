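toy_params <- function(r = 3, kappa = 10, dap = 0.4, das = 0.5, dis = 0.3) {
  model_params(r, kappa,
               detection_schedule(stats::qlogis(dap)),
               detection_schedule(stats::qlogis(das)),
               detection_schedule(stats::qlogis(dis)))
}

toy_data <- function(A_P, A_S, I_S) {
  n <- length(A_P)
  colony_data(make_counts(2009 + seq_len(n) - 1,
                          A_P + A_S + I_S, A_P, A_S + I_S, 0, A_P, A_S))
}

test_that("impossible observed counts give -Inf, not an error", {
  d <- toy_data(A_P = 3, A_S = 1, I_S = 0)
  params <- toy_params()
  # latent P below the observed removals
  expect_identical(log_likelihood(params, list(P = 2L, s_init = 5L), d),
                   -Inf)
  # latent successful count below the inactive detections
  d2 <- toy_data(A_P = 0, A_S = 0, I_S = 4)
  expect_identical(log_likelihood(params, list(P = 3L, s_init = 5L), d2),
                   -Inf)
})

test_that("with nothing observed and negligible detection, only the
           Poisson term remains", {
  d <- toy_data(A_P = 0, A_S = 0, I_S = 0)
  params <- toy_params(dap = 1e-12, das = 1e-12, dis = 1e-12)
  ll <- log_likelihood(params, list(P = 4L, s_init = 5L), d)
  mu <- mean_primaries(5, 3, 10)
  expect_equal(ll, dpois(4, mu, log = TRUE), tolerance = 1e-9)
})

test_that("likelihood sums to the exhaustively enumerated probability on a
           two-year toy system", {
  params <- toy_params(r = 1.5, kappa = 8, dap = 0.4, das = 0.5, dis = 0.3)
  obs <- data.frame(A_P = c(1, 2), A_S = c(1, 0), I_S = c(0, 1))
  d <- toy_data(A_P = obs$A_P, A_S = obs$A_S, I_S = obs$I_S)
  s_init <- 3L
  p_oracle <- oracle_enumerate(1.5, 8, rep(0.4, 2), rep(0.5, 2),
                               rep(0.3, 2), s_init, obs, p_max = 60)
  p_lik <- likelihood_sum(params, d, s_init, p_max = 60)
  expect_lt(abs(p_oracle - p_lik), 1e-10)
  expect_gt(p_oracle, 0)
})

test_that("stage-unrecorded years contribute a detected-colonies binomial
           term", {
  counts <- make_counts(2007, 4, 0, 0, 4, 0, 1)
  d <- colony_data(counts)
  params <- toy_params(das = 0.5)
  P <- 10L; s_init <- 4L
  ll <- log_likelihood(params, list(P = P, s_init = s_init), d)
  mu <- mean_primaries(4, 3, 10)
  expect_equal(ll, dpois(P, mu, log = TRUE) + dbinom(4, P, 0.5, log = TRUE),
               tolerance = 1e-12)
  # the known removal lowers the successful count: P below the removal
  # would be impossible
  expect_identical(log_likelihood(params, list(P = 0L, s_init = 4L), d),
                   -Inf)
})

test_that("log-posterior decomposes into likelihood plus prior and
           respects support", {
  d <- toy_data(A_P = c(2, 3), A_S = c(1, 1), I_S = c(0, 2))
  priors <- prior_spec()
  set.seed(5)
  for (i in 1:10) {
    params <- toy_params(r = runif(1, 1, 12), kappa = runif(1, 5, 80),
                         dap = runif(1, .05, .6), das = runif(1, .05, .6),
                         dis = runif(1, .05, .6))
    latents <- list(P = as.integer(sample(5:30, 2)),
                    s_init = sample(1:20, 1))
    lp <- log_posterior(params, latents, d, priors)
    if (!is.finite(lp)) next
    manual <- log_likelihood(params, latents, d) +
      dnorm(log(params$r), priors$r_meanlog, priors$r_sdlog, log = TRUE) +
      dnorm(log(params$kappa), priors$kappa_meanlog, priors$kappa_sdlog,
            log = TRUE) +
      dnorm(params$det_active_primary$logit_intercept, 0,
            priors$intercept_sd, log = TRUE) +
      dnorm(params$det_active_secondary$logit_intercept, 0,
            priors$intercept_sd, log = TRUE) +
      dnorm(params$det_inactive_secondary$logit_intercept, 0,
            priors$intercept_sd, log = TRUE) +
      3 * dnorm(0, 0, priors$slope_sd, log = TRUE) -
      log(priors$s_init_max)
    expect_equal(lp, manual, tolerance = 1e-10)
  }
  # outside the s_init prior support
  params <- toy_params()
  expect_identical(
    log_posterior(params, list(P = c(10L, 10L), s_init = 25L), d, priors),
    -Inf)
})

test_that("identical seed and config give identical chains", {
  d <- andernos_data()
  cfg <- mcmc_config(n_iterations = 600, n_burn_in = 200, thinning = 2,
                     n_chains = 2, seed = 11)
  f1 <- run_mcmc(d, prior_spec(), cfg)
  f2 <- run_mcmc(d, prior_spec(), cfg)
  expect_identical(f1$samples, f2$samples)
  # different seed moves the chain
  f3 <- run_mcmc(d, prior_spec(), mcmc_config(n_iterations = 600,
                                              n_burn_in = 200, thinning = 2,
                                              n_chains = 2, seed = 12))
  expect_false(identical(f1$samples, f3$samples))
})

test_that("posterior summaries behave on degenerate and known chains", {
  # constant chain: estimate equals the constant, zero-width interval
  const <- matrix(5, nrow = 50, ncol = 2,
                  dimnames = list(NULL, c("r", "log_posterior")))
  fake <- structure(list(samples = list(const), acceptance = list(),
                         config = NULL, priors = NULL,
                         data = list(n_years = 1), fixed_schedules = TRUE),
                    class = "colony_fit")
  s <- summarize_posterior(fake, derived = FALSE)
  expect_equal(s$median[s$quantity == "r"], 5)
  expect_equal(s$ci_lower[s$quantity == "r"], 5)
  expect_equal(s$ci_upper[s$quantity == "r"], 5)

  # large iid normal sample recovers the known 95% quantiles
  set.seed(1)
  z <- matrix(rnorm(1e6), ncol = 1, dimnames = list(NULL, "r"))
  fake2 <- fake
  fake2$samples <- list(cbind(z, log_posterior = 0))
  s2 <- summarize_posterior(fake2, derived = FALSE)
  expect_lt(abs(s2$ci_lower[s2$quantity == "r"] + 1.96), 0.01)
  expect_lt(abs(s2$ci_upper[s2$quantity == "r"] - 1.96), 0.01)
  expect_error(summarize_posterior(structure(
    list(samples = list(const[0, , drop = FALSE]), fixed_schedules = TRUE,
         data = list(n_years = 1)), class = "colony_fit")), "empty")
})

test_that("discovery percentages: limits and per-sample ordering", {
  d <- andernos_data()
  cfg <- mcmc_config(n_iterations = 1500, n_burn_in = 500, thinning = 2,
                     n_chains = 2, seed = 3)
  fit <- run_mcmc(d, prior_spec(), cfg)
  der <- velutina:::.derive_samples(fit)
  # discovered-while-active can never exceed ever-discovered
  expect_true(all(der[, "pct_discovered_active_nests"] <=
                    der[, "pct_discovered_nests"] + 1e-12))
  expect_true(all(der[, "pct_discovered_active_colonies"] <=
                    der[, "pct_discovered_colonies"] + 1e-12))
  pcts <- discovery_percentages(fit)
  expect_true(all(pcts$ci_lower <= pcts$median & pcts$median <=
                    pcts$ci_upper))

  # analytic limits at fixed detection levels
  tiny <- detection_schedule(stats::qlogis(1e-12))
  p0 <- model_params(9.6, 25, tiny, tiny, tiny)
  e0 <- expected_discoveries(100, 99, p0, 0)
  expect_equal(sum(e0), 0, tolerance = 1e-8)
  full <- detection_schedule(stats::qlogis(1 - 1e-12))
  p1 <- model_params(9.6, 25, full, full, full)
  eq <- equilibrium_with_control(p1, 0)
  expect_equal(eq$P_star, 0)  # total control eliminates the population
})

test_that("split R-hat and ESS flag disagreement and agreement", {
  set.seed(2)
  agree <- cbind(rnorm(500), rnorm(500))
  expect_lt(split_rhat(agree), 1.05)
  disagree <- cbind(rnorm(500), rnorm(500) + 5)
  expect_gt(split_rhat(disagree), 1.5)
  iid <- matrix(rnorm(2000), ncol = 2)
  expect_gt(ess_basic(iid), 1000)
})
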