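# Record-level nest data: parsing, structure vocabulary, yearly tallies and
# the colony-counting rule.

# Structure vocabulary. Tokens the field records use for the structure a nest
# was attached to, mapped to natural vs man-made. Tree genus tokens are kept
# separately so habitat summaries can break trees down by genus.
.tree_genera <- c("oak", "pine", "plane", "poplar", "alder", "cedar",
                  "locust", "birch", "tulip", "acacia", "lime",
                  "sweetgum", "fir")
.natural_other <- c("tree", "tree stump", "bush", "hedge", "bamboo", "bank")
.man_made <- c("building", "manhole cover", "ventilation grill", "road sign",
               "birdhouse", "electricity pylon", "other man-made")

#' Classify a nest-structure description
#'
#' Maps free-text structure tokens onto the natural / man-made dichotomy and
#' extracts the tree genus where one is named. Unmapped descriptions are
#' classed `"unknown"` with a warning, so typos in field data surface rather
#' than silently vanishing from habitat summaries.
#'
#' @param text character vector of structure descriptions (NA allowed).
#' @return data.frame with columns `structure_class`
#'   (natural/man_made/unknown) and `tree_genus` (NA unless a genus token).
#' @export
classify_structure <- function(text) {
  text_norm <- tolower(trimws(as.character(text)))
  text_norm[text_norm %in% c("", "na")] <- NA_character_
  cls <- ifelse(is.na(text_norm), "unknown",
         ifelse(text_norm %in% c(.tree_genera, .natural_other), "natural",
         ifelse(text_norm %in% .man_made, "man_made", "unknown")))
  unmapped <- !is.na(text_norm) & cls == "unknown"
  if (any(unmapped))
    warning("unmapped structure description(s): ",
            paste(unique(text_norm[unmapped]), collapse = ", "),
            call. = FALSE)
  genus <- ifelse(!is.na(text_norm) & text_norm %in% .tree_genera,
                  text_norm, NA_character_)
  data.frame(structure_class = cls, tree_genus = genus,
             stringsAsFactors = FALSE)
}

#' Parse a record-level nest CSV
#'
#' Reads one row per discovered nest. Mandatory columns: `year`,
#' `date_found`, `date_destroyed`, `stage`. Optional: `structure` (free
#' text), `x`, `y` (coordinates; carried through untouched). Dates are
#' ISO-8601; a destruction date of `"0"` or blank means the nest was never
#' destroyed. Rows whose mandatory fields cannot be parsed are rejected, not
#' silently dropped: the returned object carries a row-indexed rejection
#' table and `stop_on_error = TRUE` turns any rejection into an error.
#'
#' @param source path to a CSV file, or a data.frame already in that schema.
#' @param cutoffs [activity_cutoffs()] used to derive each nest's activity at
#'   destruction.
#' @param stop_on_error error out if any row is rejected (default FALSE).
#' @return A data.frame of class `nest_records` with columns `year`,
#'   `date_found`, `date_destroyed`, `stage`, `structure_text`,
#'   `structure_class`, `tree_genus`, `activity_at_destruction`, and an
#'   attribute `rejected` (data.frame: row, field, message).
#' @export
parse_nest_records <- function(source, cutoffs = activity_cutoffs(),
                               stop_on_error = FALSE) {
  raw <- if (is.data.frame(source)) source else
    utils::read.csv(source, stringsAsFactors = FALSE,
                    colClasses = "character")
  raw[] <- lapply(raw, as.character)
  need <- c("year", "date_found", "date_destroyed", "stage")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  n <- nrow(raw)
  rej <- list()
  note <- function(row, field, message)
    rej[[length(rej) + 1L]] <<- data.frame(row = row, field = field,
                                           message = message,
                                           stringsAsFactors = FALSE)

  year <- suppressWarnings(as.integer(raw$year))
  bad <- which(is.na(year))
  for (i in bad) note(i, "year", paste0("unparseable year '", raw$year[i], "'"))

  parse_date_col <- function(col, field, required) {
    x <- trimws(raw[[col]])
    x[x %in% c("", "0", "NA")] <- NA_character_
    d <- suppressWarnings(as.Date(x, format = "%Y-%m-%d"))
    bad <- which(!is.na(x) & is.na(d))
    for (i in bad) note(i, field, paste0("malformed date '", x[i], "'"))
    if (required) {
      miss <- which(is.na(x))
      for (i in miss) note(i, field, "missing discovery date")
    }
    d
  }
  date_found <- parse_date_col("date_found", "date_found", required = TRUE)
  date_destroyed <- parse_date_col("date_destroyed", "date_destroyed",
                                   required = FALSE)

  stage <- tolower(trimws(raw$stage))
  stage[stage == ""] <- "unknown"
  bad <- which(!stage %in% c("primary", "secondary", "unknown"))
  for (i in bad) note(i, "stage", paste0("stage token '", raw$stage[i],
                                         "' outside vocabulary"))
  ood <- which(!is.na(date_found) & !is.na(date_destroyed) &
                 date_destroyed < date_found)
  for (i in ood) note(i, "date_destroyed",
                      "destruction date precedes discovery date")

  rejected <- if (length(rej)) do.call(rbind, rej) else
    data.frame(row = integer(), field = character(), message = character(),
               stringsAsFactors = FALSE)
  keep <- setdiff(seq_len(n), unique(rejected$row))
  if (stop_on_error && nrow(rejected))
    stop(nrow(rejected), " row(s) rejected; first: row ", rejected$row[1],
         " (", rejected$field[1], "): ", rejected$message[1], call. = FALSE)

  structure_text <- if ("structure" %in% names(raw)) {
    s <- trimws(raw$structure); s[s == ""] <- NA_character_; s
  } else rep(NA_character_, n)
  sc <- classify_structure(structure_text[keep])

  rec <- data.frame(
    year = year[keep],
    date_found = date_found[keep],
    date_destroyed = date_destroyed[keep],
    stage = stage[keep],
    structure_text = structure_text[keep],
    structure_class = sc$structure_class,
    tree_genus = sc$tree_genus,
    stringsAsFactors = FALSE
  )
  rec$activity_at_destruction <-
    classify_activity(rec$stage, rec$date_destroyed, cutoffs)
  class(rec) <- c("nest_records", "data.frame")
  attr(rec, "rejected") <- rejected
  attr(rec, "cutoffs") <- cutoffs
  rec
}

#' Aggregate nest records to yearly counts
#'
#' Produces one row per calendar year in the yearly-counts schema: total
#' detections, stage breakdown, and destroyed-while-active counts. Nests of
#' unknown stage are tallied in `n_unclassified`; when destroyed while active
#' they are counted with the secondaries (the conservative all-secondary
#' assumption for stage-unrecorded years). Nests never destroyed contribute
#' to detection counts only.
#'
#' @param records a `nest_records` object (or data.frame with the same
#'   columns).
#' @param cutoffs [activity_cutoffs()]; used to (re)derive activity if the
#'   derived column is absent.
#' @return data.frame of class `yearly_counts`; see [validate_yearly_counts()]
#'   for the column invariants.
#' @export
tally_yearly <- function(records, cutoffs = activity_cutoffs()) {
  if (!nrow(records)) return(.empty_counts())
  if (is.null(records$activity_at_destruction))
    records$activity_at_destruction <-
      classify_activity(records$stage, records$date_destroyed, cutoffs)
  years <- sort(unique(records$year))
  rows <- lapply(years, function(y) {
    r <- records[records$year == y, , drop = FALSE]
    act <- r$activity_at_destruction == "active"
    n_sec <- sum(r$stage == "secondary")
    n_unc <- sum(r$stage == "unknown")
    n_asd <- sum(act & r$stage != "primary")
    data.frame(
      year = y,
      n_detected_total = nrow(r),
      n_primary = sum(r$stage == "primary"),
      n_secondary = n_sec,
      n_unclassified = n_unc,
      n_active_primary_destroyed = sum(act & r$stage == "primary"),
      n_active_secondary_destroyed = n_asd,
      n_inactive_secondary_detected = n_sec + n_unc - n_asd
    )
  })
  counts <- do.call(rbind, rows)
  class(counts) <- c("yearly_counts", "data.frame")
  validate_yearly_counts(counts)
  counts
}

.empty_counts <- function() {
  counts <- data.frame(year = integer(), n_detected_total = integer(),
                       n_primary = integer(), n_secondary = integer(),
                       n_unclassified = integer(),
                       n_active_primary_destroyed = integer(),
                       n_active_secondary_destroyed = integer(),
                       n_inactive_secondary_detected = integer())
  class(counts) <- c("yearly_counts", "data.frame")
  counts
}

#' Validate a yearly-counts table
#'
#' Checks the internal consistency of a yearly-counts table: stage counts
#' sum to the total; active-destroyed counts never exceed the detections
#' they are drawn from (unclassified nests pooling with secondaries); the
#' inactive-secondary column equals secondaries-plus-unclassified minus
#' active-secondary-destroyed.
#'
#' @param counts data.frame in the yearly-counts schema.
#' @return `counts`, invisibly, with class `yearly_counts`; errors on any
#'   violated invariant.
#' @export
validate_yearly_counts <- function(counts) {
  need <- c("year", "n_detected_total", "n_primary", "n_secondary",
            "n_unclassified", "n_active_primary_destroyed",
            "n_active_secondary_destroyed", "n_inactive_secondary_detected")
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols))
    stop("counts table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  with(counts, {
    if (any(n_primary + n_secondary + n_unclassified != n_detected_total))
      stop("stage counts do not sum to n_detected_total", call. = FALSE)
    if (any(n_active_primary_destroyed > n_primary))
      stop("more active primaries destroyed than primaries detected",
           call. = FALSE)
    if (any(n_active_secondary_destroyed > n_secondary + n_unclassified))
      stop("more active secondaries destroyed than secondary/unclassified ",
           "detections", call. = FALSE)
    if (any(n_inactive_secondary_detected !=
              n_secondary + n_unclassified - n_active_secondary_destroyed))
      stop("inactive-secondary column inconsistent", call. = FALSE)
    if (any(counts[need] < 0)) stop("negative count", call. = FALSE)
  })
  if (!inherits(counts, "yearly_counts"))
    class(counts) <- c("yearly_counts", "data.frame")
  invisible(counts)
}

#' Number of detected reproductive colonies in a year
#'
#' A colony occupies one primary then one secondary nest, so counting both
#' nest types double-counts. The colony count for a year is the number of
#' primary nests destroyed while active (those colonies never built a
#' secondary) plus all secondary nests found, active or inactive. For years
#' where stage was not recorded at all, every nest is taken as one detected
#' colony. In a mixed year, unclassified nests are counted with the
#' secondaries (with a warning).
#'
#' @param counts a `yearly_counts` table (one or more rows).
#' @return integer vector of detected colonies, one per row.
#' @export
detected_colonies <- function(counts) {
  validate_yearly_counts(counts)
  classified <- counts$n_primary + counts$n_secondary > 0
  mixed <- classified & counts$n_unclassified > 0
  if (any(mixed))
    warning("year(s) ", paste(counts$year[mixed], collapse = ", "),
            " mix classified and unclassified nests; counting unclassified ",
            "as secondary", call. = FALSE)
  ifelse(!classified & counts$n_unclassified > 0,
         counts$n_detected_total,
         counts$n_active_primary_destroyed + counts$n_secondary +
           counts$n_unclassified)
}

#' Read / write yearly-counts CSV
#'
#' @param path CSV path in the eight-column yearly-counts schema.
#' @return [read_yearly_counts()]: a validated `yearly_counts` data.frame.
#' @export
read_yearly_counts <- function(path) {
  counts <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_yearly_counts(counts)
  counts
}

#' @rdname read_yearly_counts
#' @param counts a `yearly_counts` table.
#' @export
write_yearly_counts <- function(counts, path) {
  validate_yearly_counts(counts)
  utils::write.csv(as.data.frame(counts), path, row.names = FALSE)
  invisible(path)
}
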