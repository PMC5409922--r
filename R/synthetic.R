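# Synthetic invasions with known parameters: yearly counts via the
# generative model, and record-level nest tables (dates, stages, habitat)
# that tally back to those counts exactly.

#' Default habitat frequencies for synthetic records
#'
#' Structure-class probabilities matching the observed habitat mix:
#' 67.2\% natural (62.7\% on trees, oak dominating at 40.3\% of all
#' structure-recorded nests), 32.8\% man-made dominated by buildings
#' (27.9\%).
#'
#' @return named numeric vector of structure-token probabilities (sums
#'   to 1).
#' @export
default_habitat_frequencies <- function() {
  p <- c(oak = 0.403, pine = 0.100, plane = 0.025, poplar = 0.015,
         alder = 0.010, cedar = 0.010, locust = 0.010, birch = 0.005,
         tulip = 0.005, acacia = 0.005, lime = 0.005, sweetgum = 0.005,
         fir = 0.004, tree = 0.020, `tree stump` = 0.005,
         bush = 0.020, hedge = 0.015, bamboo = 0.005, bank = 0.005,
         building = 0.279, `manhole cover` = 0.015,
         `ventilation grill` = 0.004, `road sign` = 0.004,
         birdhouse = 0.004, `electricity pylon` = 0.004,
         `other man-made` = 0.018)
  p / sum(p)
}

#' Configuration for a synthetic invasion
#'
#' Defaults emulate the study system: an eight-year invasion seeded by a
#' single successful colony, growth rate near 9.6, density-dependence scale
#' near 25 colonies, and detection probabilities rising over the period
#' (active primaries ~3\% to ~10\%, active secondaries ~12\% to ~28\%,
#' inactive secondaries ~8\% to ~20\% on the logit-linear schedules).
#'
#' @param params a [model_params()]; default as above.
#' @param n_years number of simulated years (>= 2).
#' @param s_init successful secondary nests the year before observation.
#' @param start_year first calendar year (cosmetic; default 2007).
#' @param seed integer seed; every draw for the dataset flows from it.
#' @param habitat_frequencies structure-token probabilities for
#'   [generate_records()].
#' @param p_inactive_primary probability an inactive primary nest is
#'   reported (outside the demographic observation model; default 0.5 so
#'   synthetic tables, like the study table, contain inactive-primary
#'   detections).
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(params = NULL, n_years = 8L, s_init = 1L,
                             start_year = 2007L, seed = 1L,
                             habitat_frequencies = default_habitat_frequencies(),
                             p_inactive_primary = 0.5) {
  if (is.null(params))
    params <- model_params(
      r = 9.6, kappa = 25,
      det_active_primary = detection_schedule(
        stats::qlogis(0.03),
        (stats::qlogis(0.10) - stats::qlogis(0.03)) / 7),
      det_active_secondary = detection_schedule(
        stats::qlogis(0.12),
        (stats::qlogis(0.28) - stats::qlogis(0.12)) / 7),
      det_inactive_secondary = detection_schedule(
        stats::qlogis(0.08),
        (stats::qlogis(0.20) - stats::qlogis(0.08)) / 7))
  stopifnot(n_years >= 2, s_init >= 0,
            abs(sum(habitat_frequencies) - 1) < 1e-8,
            p_inactive_primary >= 0, p_inactive_primary <= 1)
  structure(list(params = params, n_years = as.integer(n_years),
                 s_init = as.integer(s_init),
                 start_year = as.integer(start_year),
                 seed = as.integer(seed),
                 habitat_frequencies = habitat_frequencies,
                 p_inactive_primary = p_inactive_primary),
            class = "synthetic_config")
}

#' Simulate a synthetic invasion
#'
#' Iterates the stochastic cohort step ([step_cohort()]) from the seed
#' population, recording both the latent truth and the observed yearly
#' counts in the standard yearly-counts schema. Detected primaries are the
#' active-destroyed ones plus (optionally) reported inactive primaries;
#' detected secondaries are the active-destroyed plus detected inactive
#' secondaries.
#'
#' @param config a [synthetic_config()].
#' @return list with `truth` (data.frame: year, P, A_P, A_S, S, I_S,
#'   s_init attribute, true parameters attached as attribute `params`) and
#'   `counts` (a `yearly_counts` table).
#' @export
generate_invasion <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_years
  P <- A_P <- A_S <- S <- I_S <- I_P <- integer(n)
  S_prev <- config$s_init
  for (y in seq_len(n)) {
    step <- step_cohort(S_prev, config$params, year_index = y - 1)
    P[y] <- step$P; A_P[y] <- step$A_P; A_S[y] <- step$A_S
    S[y] <- step$S; I_S[y] <- step$I_S
    I_P[y] <- stats::rbinom(1, step$P - step$A_P, config$p_inactive_primary)
    S_prev <- step$S
  }
  years <- config$start_year + seq_len(n) - 1L
  truth <- data.frame(year = years, P = P, A_P = A_P, A_S = A_S, S = S,
                      I_S = I_S, I_P_detected = I_P)
  attr(truth, "s_init") <- config$s_init
  attr(truth, "params") <- config$params
  counts <- data.frame(
    year = years,
    n_detected_total = A_P + I_P + A_S + I_S,
    n_primary = A_P + I_P,
    n_secondary = A_S + I_S,
    n_unclassified = 0L,
    n_active_primary_destroyed = A_P,
    n_active_secondary_destroyed = A_S,
    n_inactive_secondary_detected = I_S
  )
  class(counts) <- c("yearly_counts", "data.frame")
  validate_yearly_counts(counts)
  list(truth = truth, counts = counts)
}

# date helpers: uniform integer draw of dates in [from, to] (month-day
# strings applied to `year`)
.rdate <- function(n, year, from, to) {
  a <- as.Date(paste0(year, "-", from))
  b <- as.Date(paste0(year, "-", to))
  a + sample.int(as.integer(b - a) + 1L, n, replace = TRUE) - 1L
}

#' Generate record-level nest data from yearly counts
#'
#' Emits one record per detected nest with a stage, discovery and
#' destruction dates consistent with its activity class under the default
#' cut-offs (active primaries destroyed between April and the end of July,
#' active secondaries by mid-November, inactive nests after their cut-off),
#' and a structure token sampled from the configured habitat frequencies.
#' By construction [tally_yearly()] applied to the output reproduces the
#' input counts exactly.
#'
#' @param counts a `yearly_counts` table.
#' @param config a [synthetic_config()] (habitat frequencies and seed).
#' @return a `nest_records` data.frame.
#' @export
generate_records <- function(counts, config = synthetic_config()) {
  validate_yearly_counts(counts)
  set.seed(config$seed + 1L)
  rows <- list()
  emit <- function(year, stage, n, found_win, destr_win = NULL) {
    if (n <= 0) return()
    found <- .rdate(n, year, found_win[1], found_win[2])
    destroyed <- if (is.null(destr_win)) as.Date(rep(NA, n)) else {
      lo <- as.Date(paste0(year, "-", destr_win[1]))
      hi <- as.Date(paste0(year, "-", destr_win[2]))
      pmax(found, lo) +
        sapply(as.integer(hi - pmax(found, lo)), function(d)
          sample.int(d + 1L, 1L) - 1L)
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      year = year, date_found = found,
      date_destroyed = as.Date(destroyed, origin = "1970-01-01"),
      stage = stage, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(counts))) {
    cc <- counts[i, ]
    y <- cc$year
    # primaries: active destroyed in season, the rest destroyed after the
    # primary cut-off
    emit(y, "primary", cc$n_active_primary_destroyed,
         c("04-01", "07-20"), c("04-01", "07-31"))
    emit(y, "primary", cc$n_primary - cc$n_active_primary_destroyed,
         c("04-01", "07-20"), c("08-01", "10-31"))
    # secondaries / unclassified: active-destroyed get the pre-cut-off
    # window; the inactive remainder is split between the secondary and
    # unclassified stages
    n_act <- cc$n_active_secondary_destroyed
    n_act_sec <- min(n_act, cc$n_secondary)
    emit(y, "secondary", n_act_sec, c("08-01", "11-05"), c("08-01", "11-15"))
    emit(y, "unknown", n_act - n_act_sec, c("08-01", "11-05"),
         c("08-01", "11-15"))
    emit(y, "secondary", cc$n_secondary - n_act_sec,
         c("11-16", "12-10"), c("11-16", "12-28"))
    emit(y, "unknown", cc$n_unclassified - (n_act - n_act_sec),
         c("11-16", "12-10"), c("11-16", "12-28"))
  }
  rec <- do.call(rbind, rows)
  rec$structure <- sample(names(config$habitat_frequencies), nrow(rec),
                          replace = TRUE,
                          prob = config$habitat_frequencies)
  out <- parse_nest_records(rec, stop_on_error = TRUE)
  out[order(out$year, out$date_found), ]
}

#' Write a synthetic dataset bundle
#'
#' Writes the record CSV and counts CSV in the schemas consumed by
#' [parse_nest_records()] / [read_yearly_counts()], plus a truth JSON with
#' the generating parameters and latent trajectory, for recovery tests.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list of written paths.
#' @export
write_synthetic_bundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_invasion(config)
  rec <- generate_records(sim$counts, config)
  paths <- list(records = file.path(dir, "records.csv"),
                counts = file.path(dir, "counts.csv"),
                truth = file.path(dir, "truth.json"))
  rec_out <- as.data.frame(rec)[, c("year", "date_found", "date_destroyed",
                                    "stage", "structure_text")]
  names(rec_out)[5] <- "structure"
  rec_out$date_destroyed <- ifelse(is.na(rec_out$date_destroyed), "0",
                                   as.character(rec_out$date_destroyed))
  utils::write.csv(rec_out, paths$records, row.names = FALSE)
  write_yearly_counts(sim$counts, paths$counts)
  p <- config$params
  jsonlite::write_json(list(
    r = p$r, kappa = p$kappa,
    det_active_primary = unclass(p$det_active_primary),
    det_active_secondary = unclass(p$det_active_secondary),
    det_inactive_secondary = unclass(p$det_inactive_secondary),
    s_init = config$s_init, seed = config$seed,
    truth = sim$truth), paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
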