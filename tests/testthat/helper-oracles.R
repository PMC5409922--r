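# Shared helpers: tiny data constructors and independent oracles used by
# several test files.

# Construct a valid yearly_counts row vector quickly.
make_counts <- function(year, total, prim, sec, unc, ap, as_) {
  data.frame(year = year, n_detected_total = total, n_primary = prim,
             n_secondary = sec, n_unclassified = unc,
             n_active_primary_destroyed = ap,
             n_active_secondary_destroyed = as_,
             n_inactive_secondary_detected = sec + unc - as_)
}

# Random record set with valid dates for property tests.
random_records <- function(n, years = 2009:2011) {
  stages <- sample(c("primary", "secondary", "unknown"), n, replace = TRUE)
  year <- sample(years, n, replace = TRUE)
  found <- as.Date(paste0(year, "-01-01")) + sample(90:250, n, replace = TRUE)
  gap <- sample(0:120, n, replace = TRUE)
  destroyed <- found + gap
  destroyed[sample(n, max(0, n %/% 5))] <- NA
  data.frame(year = year, date_found = as.character(found),
             date_destroyed = ifelse(is.na(destroyed), "0",
                                     as.character(destroyed)),
             stage = stages, stringsAsFactors = FALSE)
}

# Brute-force per-record tally: the independent counting oracle for
# tally_yearly.
oracle_tally <- function(records, cutoffs = activity_cutoffs()) {
  act <- classify_activity(records$stage, records$date_destroyed, cutoffs)
  years <- sort(unique(records$year))
  out <- NULL
  for (y in years) {
    tot <- prim <- sec <- unc <- ap <- as_ <- 0
    for (i in seq_len(nrow(records))) {
      if (records$year[i] != y) next
      tot <- tot + 1
      if (records$stage[i] == "primary") {
        prim <- prim + 1
        if (act[i] == "active") ap <- ap + 1
      } else {
        if (records$stage[i] == "secondary") sec <- sec + 1 else unc <- unc + 1
        if (act[i] == "active") as_ <- as_ + 1
      }
    }
    out <- rbind(out, make_counts(y, tot, prim, sec, unc, ap, as_))
  }
  out
}

# Exhaustive enumeration of the generative process for a toy two-class
# system: years with full stage split, Poisson primaries truncated where
# the tail is negligible. Returns the exact probability of the observed
# counts by summing over every latent path, independently of the
# likelihood code (forward enumeration of P, A_P, A_S, I_S draws).
oracle_enumerate <- function(r, kappa, dap, das, dis, s_init, obs,
                             p_max = 60) {
  n <- nrow(obs)
  recurse <- function(y, s_prev) {
    if (y > n) return(1)
    mu <- r * s_prev / (1 + s_prev / kappa)
    total <- 0
    for (P in 0:p_max) {
      pr_P <- stats::dpois(P, mu)
      if (pr_P == 0) next
      # observed A_P, A_S, I_S fix the path given P
      A_P <- obs$A_P[y]; A_S <- obs$A_S[y]; I_S <- obs$I_S[y]
      if (A_P > P || A_S > P - A_P) next
      S <- P - A_P - A_S
      if (I_S > S) next
      pr <- pr_P *
        stats::dbinom(A_P, P, dap[y]) *
        stats::dbinom(A_S, P - A_P, das[y]) *
        stats::dbinom(I_S, S, dis[y])
      if (pr > 0) total <- total + pr * recurse(y + 1, S)
    }
    total
  }
  recurse(1, s_init)
}

# The same probability via the package likelihood, summing
# exp(log_likelihood) over all admissible latent configurations.
likelihood_sum <- function(params, data, s_init, p_max = 60) {
  n <- data$n_years
  grids <- rep(list(0:p_max), n)
  grid <- do.call(expand.grid, grids)
  total <- 0
  for (i in seq_len(nrow(grid))) {
    ll <- log_likelihood(params, list(P = as.integer(grid[i, ]),
                                      s_init = s_init), data)
    if (is.finite(ll)) total <- total + exp(ll)
  }
  total
}

# Fixed-point iteration of the deterministic mean map under thinning:
# independent oracle for the closed-form equilibria.
oracle_fixed_point <- function(r, kappa, q = 1, tol = 1e-9,
                               max_iter = 100000) {
  S <- 1
  for (i in seq_len(max_iter)) {
    S_new <- q * r * S / (1 + S / kappa)
    if (abs(S_new - S) < tol) return(S_new)
    S <- S_new
  }
  S
}
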