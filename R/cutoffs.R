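#' Seasonal activity cut-off dates
#'
#' The hornet life cycle fixes two calendar boundaries: a colony abandons its
#' primary nest for a secondary nest by the end of July, and colonies die off
#' (foundresses dispersing to hibernate) by the middle of November. A primary
#' nest destroyed after the primary cut-off, or a secondary nest destroyed
#' after the secondary cut-off, was therefore already inactive and its
#' destruction removed no colony.
#'
#' Cut-offs are month-day strings so the rule is identical in leap years.
#' A nest destroyed *on* the cut-off day counts as active.
#'
#' @param primary month-day (`"MM-DD"`) after which primary nests are assumed
#'   abandoned. Default `"07-31"` (end of July).
#' @param secondary month-day after which secondary (or stage-unknown) nests
#'   are assumed inactive. Default `"11-15"` (middle of November).
#' @return An object of class `activity_cutoffs`.
#' @examples
#' classify_activity("primary", as.Date("2009-08-10"), activity_cutoffs())
#' @export
activity_cutoffs <- function(primary = "07-31", secondary = "11-15") {
  stopifnot(is.character(primary), length(primary) == 1L,
            is.character(secondary), length(secondary) == 1L)
  if (!grepl("^[01][0-9]-[0-3][0-9]$", primary) ||
      !grepl("^[01][0-9]-[0-3][0-9]$", secondary))
    stop("cut-offs must be 'MM-DD' strings", call. = FALSE)
  if (primary >= secondary)
    stop("primary cut-off must fall before the secondary cut-off", call. = FALSE)
  structure(list(primary = primary, secondary = secondary),
            class = "activity_cutoffs")
}

#' @export
print.activity_cutoffs <- function(x, ...) {
  cat("Activity cut-offs: primary nests active through", x$primary,
      "| secondary nests active through", x$secondary, "\n")
  invisible(x)
}

#' Classify whether a nest was active when destroyed
#'
#' Applies the calendar rules: a primary nest destroyed on or before the
#' primary cut-off was active; destroyed later, it had already been abandoned.
#' Secondary nests (and nests of unknown stage, which get the secondary rule)
#' are active through the secondary cut-off. A missing destruction date means
#' the nest was never destroyed.
#'
#' @param stage character vector with values `"primary"`, `"secondary"` or
#'   `"unknown"`.
#' @param date_destroyed `Date` vector (NA = not destroyed).
#' @param cutoffs an [activity_cutoffs()] object.
#' @return character vector: `"active"`, `"inactive"` or `"not_destroyed"`.
#' @export
classify_activity <- function(stage, date_destroyed,
                              cutoffs = activity_cutoffs()) {
  stopifnot(inherits(cutoffs, "activity_cutoffs"))
  if (!length(stage)) return(character())
  bad <- !stage %in% c("primary", "secondary", "unknown")
  if (any(bad))
    stop("unknown stage token(s): ", paste(unique(stage[bad]), collapse = ", "),
         call. = FALSE)
  n <- max(length(stage), length(date_destroyed))
  stage <- rep_len(stage, n)
  date_destroyed <- rep_len(as.Date(date_destroyed), n)
  cutoff <- ifelse(stage == "primary", cutoffs$primary, cutoffs$secondary)
  monthday <- format(date_destroyed, "%m-%d")
  out <- ifelse(is.na(date_destroyed), "not_destroyed",
                ifelse(monthday <= cutoff, "active", "inactive"))
  out
}
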