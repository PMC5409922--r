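# Density-dependent colony dynamics with layered imperfect detection.
#
# One colony occupies a primary nest, then (if the primary is not destroyed
# while active) a secondary nest. A secondary nest not destroyed while
# active is "successful": it released foundresses that seed next year's
# primaries. The number of primaries each year is Poisson with a
# Beverton-Holt mean in last year's successful secondaries.

#' Year-varying detection probability schedule
#'
#' Detection effort changed over the invasion, so each detection class
#' (active primary, active secondary, inactive secondary) gets a
#' probability that varies linearly on the logit scale with year index
#' (0 = first observed year). The logit parameterisation keeps the
#' probability inside (0, 1) for every year without clipping.
#'
#' A raw-linear variant (`scale = "linear"`, probability
#' `intercept + slope * year` clipped into (0, 1)) is available for
#' sensitivity analysis, since a straight-line trend on the probability
#' scale is an equally literal reading of "varies linearly".
#'
#' @param logit_intercept detection probability at year 0, on the logit
#'   scale (`scale = "logit"`) or probability scale (`scale = "linear"`).
#' @param logit_slope change per year, on the same scale.
#' @param scale `"logit"` (default) or `"linear"`.
#' @return object of class `detection_schedule`.
#' @seealso [detection_prob()]
#' @export
detection_schedule <- function(logit_intercept, logit_slope = 0,
                               scale = c("logit", "linear")) {
  scale <- match.arg(scale)
  stopifnot(is.finite(logit_intercept), is.finite(logit_slope))
  structure(list(logit_intercept = logit_intercept,
                 logit_slope = logit_slope, scale = scale),
            class = "detection_schedule")
}

#' @rdname detection_schedule
#' @param schedule a `detection_schedule`.
#' @param year_index integer year index (0 = first year), vectorised.
#' @return [detection_prob()]: probability in (0, 1).
#' @export
detection_prob <- function(schedule, year_index) {
  x <- schedule$logit_intercept + schedule$logit_slope * year_index
  if (identical(schedule$scale, "linear"))
    pmin(pmax(x, 1e-9), 1 - 1e-9)
  else
    stats::plogis(x)
}

#' Demographic and detection parameters
#'
#' @param r intrinsic between-year growth rate (> 0): expected primaries per
#'   successful secondary at low density.
#' @param kappa density-dependence scale (colonies, > 0). The no-control
#'   equilibrium colony number is `kappa * (r - 1)`.
#' @param det_active_primary,det_active_secondary,det_inactive_secondary
#'   [detection_schedule()] objects for the three detection classes. Active
#'   nests that are detected are destroyed; detected inactive secondaries
#'   have already released foundresses, so their discovery has no
#'   demographic effect.
#' @return object of class `model_params`.
#' @export
model_params <- function(r, kappa,
                         det_active_primary = detection_schedule(stats::qlogis(0.1)),
                         det_active_secondary = detection_schedule(stats::qlogis(0.25)),
                         det_inactive_secondary = detection_schedule(stats::qlogis(0.2))) {
  stopifnot(is.numeric(r), r > 0, is.numeric(kappa), kappa > 0,
            inherits(det_active_primary, "detection_schedule"),
            inherits(det_active_secondary, "detection_schedule"),
            inherits(det_inactive_secondary, "detection_schedule"))
  structure(list(r = r, kappa = kappa,
                 det_active_primary = det_active_primary,
                 det_active_secondary = det_active_secondary,
                 det_inactive_secondary = det_inactive_secondary),
            class = "model_params")
}

#' Expected number of primary nests
#'
#' The Beverton-Holt mean of the yearly Poisson reproduction step:
#' `r * S_prev / (1 + S_prev / kappa)`, where `S_prev` is the number of
#' successful secondary nests the year before. Increasing and concave in
#' `S_prev`, saturating at `r * kappa`.
#'
#' @param S_prev successful secondaries the previous year (>= 0,
#'   vectorised).
#' @param r,kappa demographic parameters (> 0).
#' @return expected primaries (same length as `S_prev`).
#' @export
mean_primaries <- function(S_prev, r, kappa) {
  if (any(S_prev < 0) || any(r <= 0) || any(kappa <= 0))
    stop("mean_primaries requires S_prev >= 0, r > 0, kappa > 0",
         call. = FALSE)
  r * S_prev / (1 + S_prev / kappa)
}

#' Simulate one year of the colony / detection process
#'
#' Draws the latent cohort for one year: primaries `P ~ Poisson(mean)`,
#' active primaries destroyed `A_P ~ Bin(P, d_AP)`, active secondaries
#' destroyed `A_S ~ Bin(P - A_P, d_AS)`, successful secondaries
#' `S = P - A_P - A_S`, and detected inactive secondaries
#' `I_S ~ Bin(S, d_IS)` (detection of an inactive secondary does not reduce
#' `S`). Uses the current R RNG stream; seed with [set.seed()].
#'
#' @param S_prev successful secondaries the previous year (integer >= 0).
#' @param params a [model_params()].
#' @param year_index year index for the detection schedules (0-based).
#' @return list with integers `P`, `A_P`, `A_S`, `S`, `I_S`.
#' @export
step_cohort <- function(S_prev, params, year_index = 0) {
  stopifnot(S_prev >= 0)
  mu <- mean_primaries(S_prev, params$r, params$kappa)
  P <- stats::rpois(1, mu)
  A_P <- stats::rbinom(1, P, detection_prob(params$det_active_primary,
                                            year_index))
  A_S <- stats::rbinom(1, P - A_P, detection_prob(params$det_active_secondary,
                                                  year_index))
  S <- P - A_P - A_S
  I_S <- stats::rbinom(1, S, detection_prob(params$det_inactive_secondary,
                                            year_index))
  list(P = P, A_P = A_P, A_S = A_S, S = S, I_S = I_S)
}

#' Equilibrium colony numbers
#'
#' Without any detection and destruction the deterministic mean map
#' `S -> r S / (1 + S / kappa)` has the non-zero fixed point
#' `K = kappa (r - 1)` whenever `r > 1`: the carrying capacity of colonies.
#' Under control, a colony survives both active-detection filters with
#' probability `q = (1 - d_AP)(1 - d_AS)`, giving equilibrium successful
#' secondaries `S* = kappa (r q - 1)` (when `r q > 1`, else 0) and
#' equilibrium colonies `P* = S* / q`.
#'
#' @param r,kappa demographic parameters (> 0).
#' @return [equilibrium_no_control()]: equilibrium colonies (0 when
#'   `r <= 1`).
#' @export
equilibrium_no_control <- function(r, kappa) {
  stopifnot(all(r > 0), all(kappa > 0))
  ifelse(r > 1, kappa * (r - 1), 0)
}

#' @rdname equilibrium_no_control
#' @param params a [model_params()].
#' @param year_index year index at which detection schedules are evaluated
#'   (typically the final observed year, where detection peaked).
#' @return [equilibrium_with_control()]: list with `P_star` (equilibrium
#'   colonies) and `S_star` (equilibrium successful secondaries).
#' @export
equilibrium_with_control <- function(params, year_index) {
  d_ap <- detection_prob(params$det_active_primary, year_index)
  d_as <- detection_prob(params$det_active_secondary, year_index)
  q <- (1 - d_ap) * (1 - d_as)
  S_star <- if (params$r * q > 1) params$kappa * (params$r * q - 1) else 0
  list(P_star = if (S_star > 0) S_star / q else 0, S_star = S_star)
}

#' Expected annual nest discoveries at equilibrium
#'
#' At the controlled equilibrium (`P_star` colonies, `S_star` successful
#' secondaries) the expected yearly discoveries are `P* d_AP` active
#' primaries, `P* (1 - d_AP) d_AS` active secondaries and `S* d_IS`
#' inactive secondaries.
#'
#' @param P_star,S_star equilibrium colonies and successful secondaries.
#' @param params a [model_params()].
#' @param year_index year index for the detection schedules.
#' @return named numeric vector: `active_primary`, `active_secondary`,
#'   `inactive_secondary`.
#' @export
expected_discoveries <- function(P_star, S_star, params, year_index) {
  stopifnot(P_star >= 0, S_star >= 0)
  d_ap <- detection_prob(params$det_active_primary, year_index)
  d_as <- detection_prob(params$det_active_secondary, year_index)
  d_is <- detection_prob(params$det_inactive_secondary, year_index)
  c(active_primary = P_star * d_ap,
    active_secondary = P_star * (1 - d_ap) * d_as,
    inactive_secondary = S_star * d_is)
}
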