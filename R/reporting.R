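# End-to-end runners: file-in / file-out wrappers over the analysis
# modules, suitable for scripting. A thin command-line front-end lives in
# inst/cli/velutina.R.

.msg <- function(verbose, ...) if (verbose) message(...)

#' Tally a record-level nest CSV into yearly counts
#'
#' Parses the record CSV, writes the yearly-counts CSV and a plain-text
#' validation report listing any rejected rows.
#'
#' @param records_csv path to a record-level CSV (see
#'   [parse_nest_records()]).
#' @param out_dir output directory (created if needed).
#' @param cutoffs an [activity_cutoffs()].
#' @param verbose log progress to stderr.
#' @return invisibly, list with `counts`, `rejected` and the written paths.
#' @export
run_tally <- function(records_csv, out_dir, cutoffs = activity_cutoffs(),
                      verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- parse_nest_records(records_csv, cutoffs)
  rejected <- attr(rec, "rejected")
  counts <- tally_yearly(rec, cutoffs)
  counts_path <- file.path(out_dir, "yearly_counts.csv")
  write_yearly_counts(counts, counts_path)
  report_path <- file.path(out_dir, "validation_report.txt")
  lines <- c(sprintf("records parsed: %d", nrow(rec)),
             sprintf("records rejected: %d", nrow(rejected)))
  if (nrow(rejected))
    lines <- c(lines, sprintf("  row %d [%s]: %s", rejected$row,
                              rejected$field, rejected$message))
  writeLines(lines, report_path)
  .msg(verbose, "tally: ", nrow(rec), " records -> ", nrow(counts),
       " years (", nrow(rejected), " rejected)")
  if (!nrow(rec)) .msg(verbose, "tally: input contained no records")
  invisible(list(counts = counts, rejected = rejected,
                 counts_path = counts_path, report_path = report_path))
}

#' Densities and destroyed-while-active percentages from yearly counts
#'
#' @param counts_csv path to a yearly-counts CSV.
#' @param out_dir output directory.
#' @param terrain a [terrain_config()].
#' @param verbose log progress to stderr.
#' @return invisibly, list with `densities`, `pct_active` and written
#'   paths.
#' @export
run_describe <- function(counts_csv, out_dir, terrain = terrain_config(),
                         verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- read_yearly_counts(counts_csv)
  dens <- density_table(counts, terrain)
  pct <- pct_destroyed_active(counts)
  dens_path <- file.path(out_dir, "densities.csv")
  pct_path <- file.path(out_dir, "pct_destroyed_active.csv")
  utils::write.csv(dens, dens_path, row.names = FALSE)
  utils::write.csv(pct, pct_path, row.names = FALSE)
  .msg(verbose, "describe: ", nrow(counts), " years; peak density ",
       max(dens$density_commune), " nests/km2 (commune-wide)")
  invisible(list(densities = dens, pct_active = pct,
                 densities_path = dens_path, pct_path = pct_path))
}

#' Fit the colony-dynamics model to a yearly-counts CSV
#'
#' Runs the Metropolis-Hastings sampler and writes the retained samples,
#' a posterior summary table (parameters plus derived carrying capacities,
#' expected discoveries and discovery percentages), and a short markdown
#' report. Priors and MCMC settings can be overridden through a YAML
#' config file whose top-level keys `priors:` and `mcmc:` hold any
#' [prior_spec()] / [mcmc_config()] arguments.
#'
#' @param counts_csv path to a yearly-counts CSV.
#' @param out_dir output directory.
#' @param config_yaml optional YAML file with `priors` and `mcmc` blocks.
#' @param seed overrides the MCMC seed if not NULL.
#' @param s_min optional named vector of per-year lower bounds on
#'   successful secondaries (see [colony_data()]).
#' @param verbose log progress to stderr.
#' @return invisibly, list with the `colony_fit`, the summary data.frame
#'   and written paths.
#' @export
run_fit <- function(counts_csv, out_dir, config_yaml = NULL, seed = NULL,
                    s_min = NULL, verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- read_yearly_counts(counts_csv)
  pr_args <- list(); mc_args <- list()
  if (!is.null(config_yaml)) {
    cfg <- yaml::read_yaml(config_yaml)
    pr_args <- cfg$priors %||% list()
    mc_args <- cfg$mcmc %||% list()
    if (!is.null(cfg$s_min)) s_min <- unlist(cfg$s_min)
  }
  if (!is.null(seed)) mc_args$seed <- as.integer(seed)
  priors <- do.call(prior_spec, pr_args)
  config <- do.call(mcmc_config, mc_args)
  data <- colony_data(counts, s_min = s_min)
  .msg(verbose, "fit: ", config$n_chains, " chain(s) x ",
       config$n_iterations, " iterations on ", data$n_years, " years")
  fit <- run_mcmc(data, priors, config)
  summ <- summarize_posterior(fit)
  samples_path <- file.path(out_dir, "chain_samples.csv")
  summary_path <- file.path(out_dir, "posterior_summary.csv")
  report_path <- file.path(out_dir, "report.md")
  pooled <- do.call(rbind, lapply(seq_along(fit$samples), function(ch)
    cbind(chain = ch, as.data.frame(fit$samples[[ch]]))))
  utils::write.csv(pooled, samples_path, row.names = FALSE)
  utils::write.csv(summ, summary_path, row.names = FALSE)
  writeLines(.fit_report(counts, fit, summ), report_path)
  .msg(verbose, "fit: posterior median r = ",
       round(summ$median[summ$quantity == "r"], 2))
  invisible(list(fit = fit, summary = summ, samples_path = samples_path,
                 summary_path = summary_path, report_path = report_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.md_table <- function(df) {
  fmt <- function(x) if (is.numeric(x)) formatC(x, format = "g", digits = 4)
    else as.character(x)
  body <- apply(vapply(df, fmt, character(nrow(df))), 1, paste,
                collapse = " | ")
  c(paste(names(df), collapse = " | "),
    paste(rep("---", ncol(df)), collapse = " | "),
    body)
}

.fit_report <- function(counts, fit, summ) {
  dens <- density_table(counts)
  pct <- pct_destroyed_active(counts)
  key <- summ[summ$quantity %in%
                c("r", "kappa", "s_init", "K_no_control", "K_control",
                  "expected_active_primary", "expected_active_secondary",
                  "expected_inactive_secondary", "pct_discovered_nests",
                  "pct_discovered_colonies"), ]
  c("# Colony-dynamics fit report", "",
    "## Yearly counts", "", .md_table(as.data.frame(counts)), "",
    "## Detected-colony densities (nests per km2)", "",
    .md_table(dens[, c("year", "colonies", "density_commune",
                       "density_urban")]), "",
    "## Percentage of detections destroyed while active", "",
    .md_table(pct[, c("year", "pct")]), "",
    "## Posterior summary (median, mean, 95% CI)", "",
    .md_table(key))
}

#' Generate and write a synthetic invasion bundle
#'
#' @param out_dir output directory.
#' @param config_yaml optional YAML overriding [synthetic_config()]
#'   arguments (keys `r`, `kappa`, `n_years`, `s_init`, `seed`, plus
#'   `det_*` intercept/slope pairs).
#' @param seed overrides the seed if not NULL.
#' @param verbose log progress to stderr.
#' @return invisibly, the list of written paths.
#' @export
run_simulate <- function(out_dir, config_yaml = NULL, seed = NULL,
                         verbose = TRUE) {
  args <- list()
  if (!is.null(config_yaml)) args <- yaml::read_yaml(config_yaml)
  if (!is.null(seed)) args$seed <- as.integer(seed)
  sched <- function(key, default) {
    v <- args[[key]]
    if (is.null(v)) default else detection_schedule(v$logit_intercept,
                                                    v$logit_slope %||% 0)
  }
  base <- synthetic_config()
  params <- model_params(
    r = args$r %||% base$params$r,
    kappa = args$kappa %||% base$params$kappa,
    det_active_primary = sched("det_active_primary",
                               base$params$det_active_primary),
    det_active_secondary = sched("det_active_secondary",
                                 base$params$det_active_secondary),
    det_inactive_secondary = sched("det_inactive_secondary",
                                   base$params$det_inactive_secondary))
  config <- synthetic_config(params = params,
                             n_years = args$n_years %||% base$n_years,
                             s_init = args$s_init %||% base$s_init,
                             seed = args$seed %||% base$seed)
  paths <- write_synthetic_bundle(config, out_dir)
  .msg(verbose, "simulate: wrote ", paths$records, ", ", paths$counts,
       ", ", paths$truth)
  invisible(paths)
}
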