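# Bayesian inference for the colony-dynamics model: likelihood over the
# latent primary-nest trajectory, weakly informative priors, block-wise
# random-walk Metropolis-Hastings, posterior summaries and derived
# equilibrium predictions.

#' Prior specification
#'
#' The source data carry no information about priors, so defaults are weakly
#' informative: log-normal priors on the growth rate r (median 5) and the
#' density-dependence scale kappa (median 50), normal priors on the logit
#' intercept and slope of each detection schedule, and a discrete-uniform
#' prior on the number of successful secondaries in the year before
#' observation began.
#'
#' @param r_meanlog,r_sdlog log-normal prior on r.
#' @param kappa_meanlog,kappa_sdlog log-normal prior on kappa.
#' @param intercept_sd,slope_sd normal prior sd on logit intercepts/slopes
#'   (mean 0).
#' @param s_init_max upper end of the discrete-uniform prior {1, ...,
#'   s_init_max} on the pre-observation successful secondaries.
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(r_meanlog = log(5), r_sdlog = 1,
                       kappa_meanlog = log(50), kappa_sdlog = 1.5,
                       intercept_sd = 2, slope_sd = 0.5,
                       s_init_max = 20L) {
  stopifnot(r_sdlog > 0, kappa_sdlog > 0, intercept_sd > 0, slope_sd > 0,
            s_init_max >= 1)
  structure(list(r_meanlog = r_meanlog, r_sdlog = r_sdlog,
                 kappa_meanlog = kappa_meanlog, kappa_sdlog = kappa_sdlog,
                 intercept_sd = intercept_sd, slope_sd = slope_sd,
                 s_init_max = as.integer(s_init_max)),
            class = "prior_spec")
}

#' MCMC configuration
#'
#' @param n_iterations iterations per chain (post-adaptation samples are
#'   taken after `n_burn_in`).
#' @param n_burn_in burn-in iterations discarded (proposal scales adapt
#'   during burn-in toward ~25\% acceptance, then freeze).
#' @param thinning keep every `thinning`-th post-burn-in iteration.
#' @param n_chains number of independent chains (seeded `seed + chain - 1`).
#' @param seed integer RNG seed.
#' @param scale_continuous initial random-walk sd for continuous parameters
#'   (log r, log kappa, logit intercepts/slopes).
#' @param scale_latent initial half-width of the uniform integer proposal
#'   for each latent primary count.
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iterations = 50000L, n_burn_in = 10000L,
                        thinning = 10L, n_chains = 4L, seed = 1L,
                        scale_continuous = 0.15, scale_latent = 8) {
  stopifnot(n_burn_in < n_iterations, thinning >= 1, n_chains >= 1,
            scale_continuous > 0, scale_latent >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 n_burn_in = as.integer(n_burn_in),
                 thinning = as.integer(thinning),
                 n_chains = as.integer(n_chains),
                 seed = as.integer(seed),
                 scale_continuous = scale_continuous,
                 scale_latent = scale_latent),
            class = "mcmc_config")
}

#' Assemble observation data for the likelihood
#'
#' Converts a yearly-counts table into the fixed observed quantities the
#' likelihood conditions on. Years with a primary/secondary split contribute
#' active-primary-destroyed, active-secondary-destroyed and
#' inactive-secondary-detected counts; years without a stage split (the
#' first two years of the study data) contribute only their detected-colony
#' total, with their active-destroyed count treated as a known removal.
#' Inactive-primary detections are outside the three-class observation model
#' and are ignored by the likelihood.
#'
#' @param counts a `yearly_counts` table (consecutive years).
#' @param s_min optional named integer vector of per-year lower bounds on
#'   the successful secondaries (names = years), e.g. from nests known to
#'   have released foundresses.
#' @return object of class `colony_data`.
#' @export
colony_data <- function(counts, s_min = NULL) {
  validate_yearly_counts(counts)
  counts <- counts[order(counts$year), , drop = FALSE]
  if (nrow(counts) > 1 && any(diff(counts$year) != 1))
    stop("years must be consecutive", call. = FALSE)
  classified <- counts$n_primary + counts$n_secondary > 0
  smin <- rep(0L, nrow(counts))
  if (!is.null(s_min)) {
    idx <- match(as.integer(names(s_min)), counts$year)
    if (any(is.na(idx))) stop("s_min names a year outside the data",
                              call. = FALSE)
    smin[idx] <- as.integer(s_min)
  }
  d <- list(
    years = counts$year,
    n_years = nrow(counts),
    classified = classified,
    C = ifelse(classified, NA_integer_, counts$n_detected_total),
    D = ifelse(classified, 0L, counts$n_active_secondary_destroyed),
    A_P = ifelse(classified, counts$n_active_primary_destroyed, 0L),
    A_S = ifelse(classified, counts$n_active_secondary_destroyed, 0L),
    I_S = ifelse(classified, counts$n_inactive_secondary_detected,
                 NA_integer_),
    s_min = smin
  )
  # precomputed views used by the likelihood hot path
  d$idx_cl <- which(classified)
  d$idx_un <- which(!classified)
  d$A_removed <- d$A_P + d$A_S + d$D     # known removals before success
  d$A_P_cl <- d$A_P[d$idx_cl]
  d$A_S_cl <- d$A_S[d$idx_cl]
  d$I_S_cl <- d$I_S[d$idx_cl]
  d$C_un <- d$C[d$idx_un]
  structure(d, class = "colony_data")
}

# Fast internal likelihood on unpacked numerics. `P` integer vector of
# latent primaries per year; s_init successful secondaries the year before
# year 1; dap/das/dis detection probabilities per year. Returns -Inf for any
# configuration the observed counts make impossible.
.loglik <- function(r, kappa, dap, das, dis, P, s_init, data) {
  S <- P - data$A_removed
  if (any(P < 0) || s_init < 0 || any(S < data$s_min)) return(-Inf)
  cl <- data$idx_cl
  un <- data$idx_un
  if (any(data$I_S_cl > S[cl])) return(-Inf)
  if (length(un) && any(data$C_un > P[un])) return(-Inf)
  S_prev <- c(s_init, S[-data$n_years])
  mu <- r * S_prev / (1 + S_prev / kappa)
  ll <- sum(stats::dpois(P, mu, log = TRUE)) +
    sum(stats::dbinom(data$A_P_cl, P[cl], dap[cl], log = TRUE)) +
    sum(stats::dbinom(data$A_S_cl, P[cl] - data$A_P_cl, das[cl],
                      log = TRUE)) +
    sum(stats::dbinom(data$I_S_cl, S[cl], dis[cl], log = TRUE)) +
    sum(stats::dbinom(data$C_un, P[un], das[un], log = TRUE))
  if (is.nan(ll)) -Inf else ll
}

.sched_probs <- function(params, year_index) {
  list(dap = detection_prob(params$det_active_primary, year_index),
       das = detection_prob(params$det_active_secondary, year_index),
       dis = detection_prob(params$det_inactive_secondary, year_index))
}

#' Log-likelihood of the observed counts
#'
#' Sums, over years, the Poisson reproduction term for the latent primaries
#' and the binomial detection terms for each observed count (see
#' [colony_data()] for which counts enter). Impossible configurations (an
#' observed count exceeding its latent denominator, or a latent successful
#' count below its known lower bound) give `-Inf`, never an error.
#'
#' @param params a [model_params()].
#' @param latents list with `P` (integer vector of latent primaries, one per
#'   year) and `s_init` (successful secondaries the year before year 1).
#' @param data a [colony_data()].
#' @return log-likelihood (scalar, possibly `-Inf`).
#' @export
log_likelihood <- function(params, latents, data) {
  stopifnot(inherits(data, "colony_data"),
            length(latents$P) == data$n_years)
  yi <- seq_len(data$n_years) - 1
  d <- .sched_probs(params, yi)
  .loglik(params$r, params$kappa, d$dap, d$das, d$dis,
          as.integer(latents$P), as.integer(latents$s_init), data)
}

.log_prior <- function(theta, s_init, priors) {
  # theta: log_r, log_kappa, a_ap, b_ap, a_as, b_as, a_is, b_is
  if (s_init < 1 || s_init > priors$s_init_max) return(-Inf)
  stats::dnorm(theta[1], priors$r_meanlog, priors$r_sdlog, log = TRUE) +
    stats::dnorm(theta[2], priors$kappa_meanlog, priors$kappa_sdlog,
                 log = TRUE) +
    sum(stats::dnorm(theta[c(3, 5, 7)], 0, priors$intercept_sd, log = TRUE)) +
    sum(stats::dnorm(theta[c(4, 6, 8)], 0, priors$slope_sd, log = TRUE)) -
    log(priors$s_init_max)
}

#' Log-posterior density
#'
#' [log_likelihood()] plus the prior log-densities of [prior_spec()];
#' `-Inf` propagates (parameters outside the prior support, impossible
#' latent configurations).
#'
#' @inheritParams log_likelihood
#' @param priors a [prior_spec()].
#' @return log-posterior up to a normalising constant.
#' @export
log_posterior <- function(params, latents, data, priors = prior_spec()) {
  theta <- c(log(params$r), log(params$kappa),
             params$det_active_primary$logit_intercept,
             params$det_active_primary$logit_slope,
             params$det_active_secondary$logit_intercept,
             params$det_active_secondary$logit_slope,
             params$det_inactive_secondary$logit_intercept,
             params$det_inactive_secondary$logit_slope)
  lp <- .log_prior(theta, latents$s_init, priors)
  if (!is.finite(lp)) return(-Inf)
  lp + log_likelihood(params, latents, data)
}

.prob_map <- function(x, scale) {
  if (identical(scale, "linear")) pmin(pmax(x, 1e-9), 1 - 1e-9)
  else stats::plogis(x)
}

.theta_to_probs <- function(theta, yi, scale = "logit") {
  list(dap = .prob_map(theta[3] + theta[4] * yi, scale),
       das = .prob_map(theta[5] + theta[6] * yi, scale),
       dis = .prob_map(theta[7] + theta[8] * yi, scale))
}

.init_state <- function(data, priors, fixed_theta = NULL,
                        scale = "logit") {
  observed <- ifelse(data$classified, data$A_P + data$A_S + data$I_S, data$C)
  P <- pmax(2L * as.integer(observed) + 5L,
            data$A_P + data$A_S + data$D + data$s_min + 1L)
  p0 <- c(0.1, 0.25, 0.2)
  x0 <- if (identical(scale, "linear")) p0 else stats::qlogis(p0)
  theta <- c(log(5), log(50), x0[1], 0, x0[2], 0, x0[3], 0)
  if (!is.null(fixed_theta)) theta[3:8] <- fixed_theta
  list(theta = theta, P = P, s_init = min(5L, priors$s_init_max))
}

#' Fit the colony-dynamics model by Metropolis-Hastings MCMC
#'
#' Block-wise random-walk Metropolis-Hastings over the continuous
#' parameters (log r, log kappa, three logit-linear detection schedules)
#' and the integer latents (primaries per year, pre-observation successful
#' secondaries). Continuous blocks use Gaussian proposals on the log/logit
#' scale; integer blocks use symmetric uniform +-step proposals. Proposal
#' scales adapt toward ~25\% acceptance during burn-in, then freeze so the
#' retained chain is a valid Markov chain. Runs are reproducible: chain `c`
#' is seeded `seed + c - 1`.
#'
#' @param data a [colony_data()].
#' @param priors a [prior_spec()].
#' @param config an [mcmc_config()].
#' @param fix_schedules optional [model_params()] (or list with the three
#'   schedule elements) whose detection schedules are held fixed instead of
#'   sampled — useful for parameter-recovery experiments where detection is
#'   known.
#' @param schedule_scale scale on which detection varies linearly with
#'   year: `"logit"` (default) or `"linear"` (raw probability, clipped;
#'   sensitivity variant).
#' @return object of class `colony_fit`: list with `samples` (one matrix
#'   per chain: r, kappa, schedule parameters, s_init, latent primaries
#'   `P_<year>`, log_posterior), `acceptance`, `config`, `priors`, `data`.
#' @export
run_mcmc <- function(data, priors = prior_spec(), config = mcmc_config(),
                     fix_schedules = NULL,
                     schedule_scale = c("logit", "linear")) {
  stopifnot(inherits(data, "colony_data"))
  schedule_scale <- match.arg(schedule_scale)
  yi <- seq_len(data$n_years) - 1
  fixed_theta <- NULL
  if (!is.null(fix_schedules))
    fixed_theta <- c(fix_schedules$det_active_primary$logit_intercept,
                     fix_schedules$det_active_primary$logit_slope,
                     fix_schedules$det_active_secondary$logit_intercept,
                     fix_schedules$det_active_secondary$logit_slope,
                     fix_schedules$det_inactive_secondary$logit_intercept,
                     fix_schedules$det_inactive_secondary$logit_slope)
  update_theta <- if (is.null(fixed_theta)) 1:8 else 1:2
  par_names <- c("r", "kappa", "ap_intercept", "ap_slope", "as_intercept",
                 "as_slope", "is_intercept", "is_slope", "s_init",
                 paste0("P_", data$years), "log_posterior")

  chains <- vector("list", config$n_chains)
  acc_all <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    st <- .init_state(data, priors, fixed_theta, schedule_scale)
    theta <- st$theta; P <- st$P; s_init <- st$s_init
    d <- .theta_to_probs(theta, yi, schedule_scale)
    lp <- .log_prior(theta, s_init, priors) +
      .loglik(exp(theta[1]), exp(theta[2]), d$dap, d$das, d$dis,
              P, s_init, data)
    if (!is.finite(lp)) {
      # widen the latent state until the likelihood is finite
      for (mult in c(2, 4, 8, 16)) {
        P_try <- P * mult
        lp <- .log_prior(theta, s_init, priors) +
          .loglik(exp(theta[1]), exp(theta[2]), d$dap, d$das, d$dis,
                  P_try, s_init, data)
        if (is.finite(lp)) { P <- P_try; break }
      }
      if (!is.finite(lp))
        stop("could not find a finite starting state; check the data for ",
             "internally impossible counts or widen the priors",
             call. = FALSE)
    }

    n_theta <- length(theta)
    sc_theta <- rep(config$scale_continuous, n_theta)
    sc_P <- rep(config$scale_latent, data$n_years)
    sc_joint <- config$scale_continuous
    sc_det <- config$scale_continuous
    sc_Pall <- config$scale_latent
    n_prop <- n_acc <- numeric(n_theta + data$n_years + 4L)
    n_keep <- (config$n_iterations - config$n_burn_in) %/% config$thinning
    out <- matrix(NA_real_, n_keep, length(par_names),
                  dimnames = list(NULL, par_names))
    kept <- 0L

    for (it in seq_len(config$n_iterations)) {
      for (j in update_theta) {
        prop <- theta
        prop[j] <- prop[j] + stats::rnorm(1, 0, sc_theta[j])
        dp <- .theta_to_probs(prop, yi, schedule_scale)
        lp_prop <- .log_prior(prop, s_init, priors) +
          .loglik(exp(prop[1]), exp(prop[2]), dp$dap, dp$das, dp$dis,
                  P, s_init, data)
        n_prop[j] <- n_prop[j] + 1
        if (lp_prop - lp > log(stats::runif(1))) {
          theta <- prop; lp <- lp_prop; d <- dp
          n_acc[j] <- n_acc[j] + 1
        }
      }
      # joint ridge move along the (log r, log kappa) anti-diagonal: the
      # carrying capacity kappa (r - 1) is much better identified than r
      # and kappa separately, so single-site moves alone crawl along this
      # ridge
      {
        eps <- stats::rnorm(1, 0, sc_joint)
        prop <- theta
        prop[1] <- prop[1] + eps
        prop[2] <- prop[2] - eps
        lp_prop <- .log_prior(prop, s_init, priors) +
          .loglik(exp(prop[1]), exp(prop[2]), d$dap, d$das, d$dis,
                  P, s_init, data)
        jdx <- n_theta + data$n_years + 2L
        n_prop[jdx] <- n_prop[jdx] + 1
        if (lp_prop - lp > log(stats::runif(1))) {
          theta <- prop; lp <- lp_prop
          n_acc[jdx] <- n_acc[jdx] + 1
        }
      }
      # joint detection-level move: shift the three logit intercepts
      # together (overall detectability trades off against total
      # abundance, another poorly identified direction)
      if (is.null(fixed_theta)) {
        eps <- stats::rnorm(1, 0, sc_det)
        prop <- theta
        prop[c(3, 5, 7)] <- prop[c(3, 5, 7)] + eps
        dp <- .theta_to_probs(prop, yi, schedule_scale)
        lp_prop <- .log_prior(prop, s_init, priors) +
          .loglik(exp(prop[1]), exp(prop[2]), dp$dap, dp$das, dp$dis,
                  P, s_init, data)
        jdx <- n_theta + data$n_years + 3L
        n_prop[jdx] <- n_prop[jdx] + 1
        if (lp_prop - lp > log(stats::runif(1))) {
          theta <- prop; lp <- lp_prop; d <- dp
          n_acc[jdx] <- n_acc[jdx] + 1
        }
      }
      # joint abundance-level move: shift every latent primary count by
      # the same signed step
      {
        k <- max(1L, round(sc_Pall))
        step <- sample(c(-k:-1, 1:k), 1)
        P_prop <- P + step
        lp_prop <- .log_prior(theta, s_init, priors) +
          .loglik(exp(theta[1]), exp(theta[2]), d$dap, d$das, d$dis,
                  P_prop, s_init, data)
        jdx <- n_theta + data$n_years + 4L
        n_prop[jdx] <- n_prop[jdx] + 1
        if (lp_prop - lp > log(stats::runif(1))) {
          P <- P_prop; lp <- lp_prop
          n_acc[jdx] <- n_acc[jdx] + 1
        }
      }
      for (y in seq_len(data$n_years)) {
        k <- max(1L, round(sc_P[y]))
        step <- sample(c(-k:-1, 1:k), 1)
        P_prop <- P
        P_prop[y] <- P_prop[y] + step
        lp_prop <- .log_prior(theta, s_init, priors) +
          .loglik(exp(theta[1]), exp(theta[2]), d$dap, d$das, d$dis,
                  P_prop, s_init, data)
        jdx <- n_theta + y
        n_prop[jdx] <- n_prop[jdx] + 1
        if (lp_prop - lp > log(stats::runif(1))) {
          P <- P_prop; lp <- lp_prop
          n_acc[jdx] <- n_acc[jdx] + 1
        }
      }
      s_prop <- s_init + sample(c(-1L, 1L), 1)
      lp_prop <- .log_prior(theta, s_prop, priors)
      if (is.finite(lp_prop))
        lp_prop <- lp_prop +
          .loglik(exp(theta[1]), exp(theta[2]), d$dap, d$das, d$dis,
                  P, s_prop, data)
      jdx <- n_theta + data$n_years + 1L
      n_prop[jdx] <- n_prop[jdx] + 1
      if (lp_prop - lp > log(stats::runif(1))) {
        s_init <- s_prop; lp <- lp_prop
        n_acc[jdx] <- n_acc[jdx] + 1
      }

      if (it <= config$n_burn_in && it %% 100 == 0) {
        rate <- ifelse(n_prop > 0, n_acc / n_prop, 0.25)
        adj <- exp(0.6 * (rate - 0.25))
        sc_theta <- pmin(pmax(sc_theta * adj[seq_len(n_theta)], 1e-3), 5)
        sc_P <- pmin(pmax(sc_P * adj[n_theta + seq_len(data$n_years)], 1), 60)
        sc_joint <- min(max(sc_joint * adj[n_theta + data$n_years + 2L],
                            1e-3), 5)
        sc_det <- min(max(sc_det * adj[n_theta + data$n_years + 3L],
                          1e-3), 5)
        sc_Pall <- min(max(sc_Pall * adj[n_theta + data$n_years + 4L],
                           1), 100)
        n_prop[] <- 0; n_acc[] <- 0
      }
      if (it > config$n_burn_in &&
          (it - config$n_burn_in) %% config$thinning == 0) {
        kept <- kept + 1L
        out[kept, ] <- c(exp(theta[1]), exp(theta[2]), theta[3:8],
                         s_init, P, lp)
      }
    }
    chains[[ch]] <- out[seq_len(kept), , drop = FALSE]
    rate <- ifelse(n_prop > 0, n_acc / n_prop, NA)
    names(rate) <- c(par_names[1:8], paste0("P_", data$years), "s_init",
                     "joint_r_kappa", "joint_detection", "joint_latents")
    acc_all[[ch]] <- rate
  }
  structure(list(samples = chains, acceptance = acc_all, config = config,
                 priors = priors, data = data,
                 fixed_schedules = !is.null(fixed_theta),
                 schedule_scale = schedule_scale),
            class = "colony_fit")
}

#' @export
print.colony_fit <- function(x, ...) {
  cat("Colony-dynamics model fit:", length(x$samples), "chain(s) of",
      nrow(x$samples[[1]]), "retained samples,", x$data$n_years,
      "years of data\n")
  s <- summarize_posterior(x, derived = FALSE)
  print(s[s$quantity %in% c("r", "kappa"), ], row.names = FALSE, digits = 4)
  invisible(x)
}

# Pool retained samples across chains into one matrix.
.pooled <- function(fit) do.call(rbind, fit$samples)

# Per-sample derived quantities at the detection levels of the final
# observed year: equilibria with/without control, expected annual
# discoveries, and discovery percentages under both candidate denominators.
.derive_samples <- function(fit) {
  m <- .pooled(fit)
  yi_max <- fit$data$n_years - 1
  scale <- fit$schedule_scale %||% "logit"
  dap <- .prob_map(m[, "ap_intercept"] + m[, "ap_slope"] * yi_max, scale)
  das <- .prob_map(m[, "as_intercept"] + m[, "as_slope"] * yi_max, scale)
  dis <- .prob_map(m[, "is_intercept"] + m[, "is_slope"] * yi_max, scale)
  r <- m[, "r"]; kappa <- m[, "kappa"]
  q <- (1 - dap) * (1 - das)
  K_no_control <- ifelse(r > 1, kappa * (r - 1), 0)
  S_star <- ifelse(r * q > 1, kappa * (r * q - 1), 0)
  P_star <- ifelse(S_star > 0, S_star / q, 0)
  e_ap <- P_star * dap
  e_as <- P_star * (1 - dap) * das
  e_is <- S_star * dis
  discovered <- e_ap + e_as + e_is
  nests <- P_star * (2 - dap)        # one primary per colony, one secondary
                                     # per colony whose primary survived
  pct_nests <- ifelse(nests > 0, 100 * discovered / nests, 0)
  pct_active_nests <- ifelse(nests > 0, 100 * (e_ap + e_as) / nests, 0)
  pct_colonies <- ifelse(P_star > 0, 100 * discovered / P_star, 0)
  pct_active_colonies <- ifelse(P_star > 0, 100 * (e_ap + e_as) / P_star, 0)
  cbind(K_no_control = K_no_control, K_control = P_star, S_star = S_star,
        expected_active_primary = e_ap, expected_active_secondary = e_as,
        expected_inactive_secondary = e_is,
        pct_discovered_nests = pct_nests,
        pct_discovered_active_nests = pct_active_nests,
        pct_discovered_colonies = pct_colonies,
        pct_discovered_active_colonies = pct_active_colonies,
        d_active_primary_final = dap, d_active_secondary_final = das,
        d_inactive_secondary_final = dis)
}

#' Posterior summaries
#'
#' Equal-tailed credible intervals, posterior median (the reported point
#' estimate) and mean for every model parameter and latent, plus derived
#' quantities (carrying capacities with and without control, expected
#' annual discoveries, discovery percentages) computed sample-by-sample and
#' then summarised — never from plugged-in summary values. Convergence
#' diagnostics (split R-hat, effective sample size) are attached per
#' quantity when at least two chains were run.
#'
#' @param fit a `colony_fit` from [run_mcmc()].
#' @param level credible level (default 0.95).
#' @param derived include derived equilibrium quantities (default TRUE).
#' @return data.frame: quantity, median, mean, ci_lower, ci_upper, rhat,
#'   ess.
#' @export
summarize_posterior <- function(fit, level = 0.95, derived = TRUE) {
  stopifnot(inherits(fit, "colony_fit"), level > 0, level < 1)
  if (!nrow(fit$samples[[1]])) stop("empty chain", call. = FALSE)
  m <- .pooled(fit)
  keep <- setdiff(colnames(m), "log_posterior")
  if (fit$fixed_schedules)
    keep <- setdiff(keep, c("ap_intercept", "ap_slope", "as_intercept",
                            "as_slope", "is_intercept", "is_slope"))
  mat <- m[, keep, drop = FALSE]
  if (derived) mat <- cbind(mat, .derive_samples(fit))
  a <- (1 - level) / 2
  summ <- data.frame(
    quantity = colnames(mat),
    median = apply(mat, 2, stats::median),
    mean = colMeans(mat),
    ci_lower = apply(mat, 2, stats::quantile, probs = a),
    ci_upper = apply(mat, 2, stats::quantile, probs = 1 - a),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (length(fit$samples) >= 2) {
    diag <- vapply(colnames(mat), function(q) {
      draws <- if (q %in% colnames(m))
        sapply(fit$samples, function(s) s[, q])
      else {
        nch <- length(fit$samples)
        per <- nrow(fit$samples[[1]])
        matrix(mat[, q], nrow = per, ncol = nch)
      }
      c(split_rhat(draws), ess_basic(draws))
    }, numeric(2))
    summ$rhat <- diag[1, ]
    summ$ess <- diag[2, ]
  }
  summ
}

#' Split R-hat and effective sample size
#'
#' Standard split-chain potential scale reduction factor and a basic
#' autocorrelation-based effective sample size (initial positive sequence
#' estimator), computed on a matrix of draws with one column per chain.
#'
#' @param draws numeric matrix, iterations x chains.
#' @return scalar diagnostic.
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws) %/% 2L
  if (n < 2) return(NA_real_)
  halves <- cbind(draws[seq_len(n), , drop = FALSE],
                  draws[n + seq_len(n), , drop = FALSE])
  mns <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(mns)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @rdname split_rhat
#' @export
ess_basic <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4) return(NA_real_)
  rho_sum <- 0
  for (ch in seq_len(ncol(draws))) {
    x <- draws[, ch]
    if (stats::var(x) == 0) next
    ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
    pos <- which(ac < 0)
    if (length(pos)) ac <- ac[seq_len(pos[1] - 1)]
    rho_sum <- rho_sum + sum(ac)
  }
  rho_bar <- rho_sum / ncol(draws)
  n * ncol(draws) / (1 + 2 * max(rho_bar, 0))
}

#' Posterior discovery percentages
#'
#' Per posterior sample, the percentage of nests ever discovered and the
#' percentage discovered while active, at the detection levels of the final
#' observed year and the controlled equilibrium. Because the denominator
#' ("nests") is ambiguous, both candidates are reported: physical nests
#' (one primary per colony plus one secondary per colony whose primary
#' survived) and colonies. Summaries are of the per-sample ratios.
#'
#' @param fit a `colony_fit`.
#' @param level credible level.
#' @return data.frame with median, mean and CI for the four percentage
#'   definitions.
#' @export
discovery_percentages <- function(fit, level = 0.95) {
  der <- .derive_samples(fit)
  cols <- c("pct_discovered_nests", "pct_discovered_active_nests",
            "pct_discovered_colonies", "pct_discovered_active_colonies")
  a <- (1 - level) / 2
  data.frame(
    quantity = cols,
    median = apply(der[, cols], 2, stats::median),
    mean = colMeans(der[, cols]),
    ci_lower = apply(der[, cols], 2, stats::quantile, probs = a),
    ci_upper = apply(der[, cols], 2, stats::quantile, probs = 1 - a),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
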