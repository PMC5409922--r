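test_that("mean primaries follows the density-dependent growth map", {
  expect_equal(mean_primaries(0, 10, 25), 0)
  expect_equal(mean_primaries(50, 10, 25), 500 / 3)
  # saturation at r * kappa
  expect_lt(abs(mean_primaries(1e9, 10, 25) - 250), 1e-5)
  expect_error(mean_primaries(-1, 10, 25), "S_prev")
  # increasing and concave in S_prev
  s <- seq(0, 200, by = 1)
  m <- mean_primaries(s, 9.6, 25)
  expect_true(all(diff(m) > 0))
  expect_true(all(diff(diff(m)) < 1e-12))
})

test_that("detection schedules stay inside (0,1) and move on the logit
           scale", {
  sch <- detection_schedule(stats::qlogis(0.03), 0.2)
  p <- detection_prob(sch, 0:20)
  expect_true(all(p > 0 & p < 1))
  expect_equal(p[1], 0.03)
  expect_true(all(diff(p) > 0))
})

test_that("cohort step respects the no-observation and total-control
           limits", {
  params0 <- model_params(10, 25,
                          detection_schedule(stats::qlogis(1e-12)),
                          detection_schedule(stats::qlogis(1e-12)),
                          detection_schedule(stats::qlogis(1e-12)))
  set.seed(1)
  st <- step_cohort(50, params0, 0)
  expect_equal(st$A_P + st$A_S + st$I_S, 0)
  expect_equal(st$S, st$P)

  params1 <- model_params(10, 25,
                          detection_schedule(stats::qlogis(1 - 1e-12)),
                          detection_schedule(stats::qlogis(1 - 1e-12)),
                          detection_schedule(stats::qlogis(0.5)))
  set.seed(2)
  st1 <- step_cohort(50, params1, 0)
  expect_equal(st1$S, 0)
  expect_equal(st1$A_P, st1$P)
})

test_that("cohort step matches analytic means over replicates", {
  params <- model_params(10, 25,
                         detection_schedule(stats::qlogis(0.3)),
                         detection_schedule(stats::qlogis(0.3)),
                         detection_schedule(stats::qlogis(0.3)))
  set.seed(99)
  n_rep <- 10000
  P <- S <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    st <- step_cohort(50, params, 0)
    P[i] <- st$P; S[i] <- st$S
    # conservation: every colony destroyed as primary, as secondary, or
    # successful
    expect_identical(st$A_P + st$A_S + st$S, st$P)
  }
  mu <- 500 / 3
  expect_lt(abs(mean(P) - mu), 3 * sd(P) / sqrt(n_rep))
  # thinning identity: E[S] = mu * (1-d_AP)(1-d_AS)
  expect_lt(abs(mean(S) - mu * 0.49), 3 * sd(S) / sqrt(n_rep))
})

test_that("equilibrium without control solves the fixed-point identity", {
  expect_equal(equilibrium_no_control(1, 100), 0)
  expect_equal(equilibrium_no_control(0.5, 100), 0)
  expect_equal(equilibrium_no_control(2, 100), 100)
  # K = kappa (r - 1) satisfies mean_primaries(K) = K
  for (r in c(2, 5, 9.64)) {
    for (kappa in c(10, 25.35, 80)) {
      K <- equilibrium_no_control(r, kappa)
      expect_equal(mean_primaries(K, r, kappa), K, tolerance = 1e-12)
      expect_equal(K, oracle_fixed_point(r, kappa), tolerance = 1e-6)
    }
  }
  # inverting kappa from a target capacity round-trips
  kappa <- 219 / (9.64 - 1)
  expect_equal(equilibrium_no_control(9.64, kappa), 219)
})

test_that("equilibrium with control matches the fixed-point oracle and
           reduces correctly", {
  tiny <- detection_schedule(stats::qlogis(1e-12))
  params_nc <- model_params(9.64, 25.35, tiny, tiny, tiny)
  eq <- equilibrium_with_control(params_nc, 0)
  expect_equal(eq$P_star, equilibrium_no_control(9.64, 25.35),
               tolerance = 1e-6)

  params <- model_params(9.64, 25.35,
                         detection_schedule(stats::qlogis(0.1)),
                         detection_schedule(stats::qlogis(0.28)),
                         detection_schedule(stats::qlogis(0.2)))
  eq2 <- equilibrium_with_control(params, 0)
  q <- (1 - 0.1) * (1 - 0.28)
  S_oracle <- oracle_fixed_point(9.64, 25.35, q = q)
  expect_equal(eq2$S_star, S_oracle, tolerance = 1e-6)
  expect_equal(eq2$P_star, S_oracle / q, tolerance = 1e-6)

  # subcritical: r q <= 1 eliminates the population
  heavy <- model_params(2, 50,
                        detection_schedule(stats::qlogis(0.6)),
                        detection_schedule(stats::qlogis(0.6)),
                        detection_schedule(stats::qlogis(0.2)))
  eq3 <- equilibrium_with_control(heavy, 0)
  expect_equal(eq3$S_star, 0)
  expect_equal(eq3$P_star, 0)
})

test_that("long-run simulated mean matches the controlled equilibrium", {
  params <- model_params(9.6, 25,
                         detection_schedule(stats::qlogis(0.10)),
                         detection_schedule(stats::qlogis(0.28)),
                         detection_schedule(stats::qlogis(0.2)))
  eq <- equilibrium_with_control(params, 0)
  set.seed(123)
  n_years <- 4000
  S <- 10
  Ps <- numeric(n_years)
  for (y in seq_len(n_years)) {
    st <- step_cohort(S, params, 0)
    S <- st$S
    Ps[y] <- st$P
  }
  keep <- Ps[-(1:200)]
  se <- sd(keep) / sqrt(length(keep) / 10)  # conservative for autocorrelation
  expect_lt(abs(mean(keep) - eq$P_star), 4 * se)
})

test_that("expected discoveries are the thinned equilibrium counts", {
  params <- model_params(5, 40,
                         detection_schedule(stats::qlogis(0.1)),
                         detection_schedule(stats::qlogis(0.3)),
                         detection_schedule(stats::qlogis(0.2)))
  e <- expected_discoveries(100, 63, params, 0)
  expect_equal(unname(e), c(10, 27, 12.6))
  tiny <- detection_schedule(stats::qlogis(1e-14))
  p0 <- model_params(5, 40, tiny, tiny, tiny)
  expect_equal(max(expected_discoveries(100, 63, p0, 0)), 0,
               tolerance = 1e-10)
})
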