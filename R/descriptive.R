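# Descriptive statistics: nest densities over the commune terrain,
# destroyed-while-active percentages, habitat breakdowns.

#' Terrain configuration for the study commune
#'
#' Andernos-les-Bains covers 20.59 km2, of which 47% is urban land.
#' (Corine land-cover rounds the urban share to "approximately 48%"; 0.47 is
#' the value consistent with the published urban densities and is the
#' default, with 0.48 available as an explicit alternative.)
#'
#' @param commune_area_km2 commune area in km2 (> 0).
#' @param urban_fraction proportion of the commune that is urban, in (0, 1].
#' @return object of class `terrain_config`.
#' @export
terrain_config <- function(commune_area_km2 = 20.59, urban_fraction = 0.47) {
  stopifnot(is.numeric(commune_area_km2), commune_area_km2 > 0,
            is.numeric(urban_fraction), urban_fraction > 0,
            urban_fraction <= 1)
  structure(list(commune_area_km2 = commune_area_km2,
                 urban_fraction = urban_fraction),
            class = "terrain_config")
}

#' Nest (colony) density per square kilometre
#'
#' Whole-commune density divides colonies by the commune area; urban-only
#' density assumes every colony sits in the urban fraction of the commune
#' (which is where essentially all nests were reported) and divides by the
#' urban area alone.
#'
#' @param n_colonies number of colonies (vectorised, >= 0).
#' @param terrain a [terrain_config()].
#' @param scope `"whole_commune"` or `"urban_only"`.
#' @return numeric vector of densities (nests per km2), unrounded. Published
#'   tables round to 2 decimal places.
#' @examples
#' round(nest_density(99, terrain_config(), "whole_commune"), 2) # 4.81
#' round(nest_density(99, terrain_config(), "urban_only"), 2)    # 10.23
#' @export
nest_density <- function(n_colonies, terrain = terrain_config(),
                         scope = c("whole_commune", "urban_only")) {
  scope <- match.arg(scope)
  stopifnot(all(n_colonies >= 0))
  area <- terrain$commune_area_km2
  if (scope == "urban_only") area <- area * terrain$urban_fraction
  n_colonies / area
}

#' Yearly density table
#'
#' Convenience wrapper producing one row per year with the detected-colony
#' count and both density scopes, rounded to 2 dp alongside the raw values.
#'
#' @param counts a `yearly_counts` table.
#' @param terrain a [terrain_config()].
#' @return data.frame: year, colonies, density_commune, density_urban (2 dp)
#'   plus `_raw` columns.
#' @export
density_table <- function(counts, terrain = terrain_config()) {
  colonies <- detected_colonies(counts)
  dc <- nest_density(colonies, terrain, "whole_commune")
  du <- nest_density(colonies, terrain, "urban_only")
  data.frame(year = counts$year, colonies = colonies,
             density_commune = round(dc, 2), density_urban = round(du, 2),
             density_commune_raw = dc, density_urban_raw = du)
}

#' Percentage of detected nests destroyed while active
#'
#' Only destruction of an active nest removes a colony; this series tracks
#' how the control effort sharpened over the invasion. The percentage is
#' (active primaries destroyed + active secondaries destroyed) over all
#' detected nests, by year.
#'
#' @param counts a `yearly_counts` table.
#' @return data.frame: year, pct (nearest integer, NA when no detections),
#'   pct_raw.
#' @export
pct_destroyed_active <- function(counts) {
  validate_yearly_counts(counts)
  active <- counts$n_active_primary_destroyed +
    counts$n_active_secondary_destroyed
  raw <- ifelse(counts$n_detected_total > 0,
                100 * active / counts$n_detected_total, NA_real_)
  data.frame(year = counts$year, pct = round(raw), pct_raw = raw)
}

#' Habitat breakdown of nest structures
#'
#' Summarises, over records that include a structure description, how many
#' nests sat on natural versus man-made structures, how many were on trees,
#' and the tree-genus breakdown, overall and per nest stage. Percentages are
#' reported to 1 dp, both against all structure-recorded nests and (for
#' genera) against tree nests. Tree counts include records labelled just
#' "tree" and tree stumps.
#'
#' @param records a `nest_records` table.
#' @return object of class `habitat_summary`: list with counts,
#'   `genus_counts`, `by_stage`, and a `percent` helper table.
#' @export
habitat_summary <- function(records) {
  has <- !is.na(records$structure_text)
  r <- records[has, , drop = FALSE]
  n <- nrow(r)
  is_tree <- r$structure_class == "natural" &
    (!is.na(r$tree_genus) | r$structure_text %in% c("tree", "tree stump"))
  genus_counts <- if (n) table(factor(r$tree_genus[!is.na(r$tree_genus)],
                                      levels = .tree_genera)) else
    table(factor(character(), levels = .tree_genera))
  by_stage <- do.call(rbind, lapply(c("primary", "secondary", "unknown"),
    function(s) {
      rs <- r[r$stage == s, , drop = FALSE]
      data.frame(stage = s, n = nrow(rs),
                 n_natural = sum(rs$structure_class == "natural"),
                 n_man_made = sum(rs$structure_class == "man_made"),
                 n_trees = sum(is_tree[r$stage == s]))
    }))
  out <- list(
    n_records = nrow(records),
    n_with_structure = n,
    n_natural = sum(r$structure_class == "natural"),
    n_man_made = sum(r$structure_class == "man_made"),
    n_trees = sum(is_tree),
    genus_counts = genus_counts,
    by_stage = by_stage
  )
  pct <- function(k, d) if (d > 0) round(100 * k / d, 1) else NA_real_
  out$percent <- data.frame(
    quantity = c("natural", "man_made", "trees",
                 names(genus_counts)),
    n = c(out$n_natural, out$n_man_made, out$n_trees,
          as.integer(genus_counts)),
    pct_of_structure_recorded =
      vapply(c(out$n_natural, out$n_man_made, out$n_trees,
               as.integer(genus_counts)), pct, 0, d = n),
    pct_of_tree_nests =
      c(NA, NA, NA,
        vapply(as.integer(genus_counts), pct, 0, d = out$n_trees))
  )
  class(out) <- "habitat_summary"
  out
}

#' @export
print.habitat_summary <- function(x, ...) {
  cat("Nest habitat summary:", x$n_with_structure, "of", x$n_records,
      "records include a structure\n")
  cat(sprintf("  natural  %3d (%.1f%%)   man-made %3d (%.1f%%)   trees %3d (%.1f%%)\n",
              x$n_natural, 100 * x$n_natural / max(x$n_with_structure, 1),
              x$n_man_made, 100 * x$n_man_made / max(x$n_with_structure, 1),
              x$n_trees, 100 * x$n_trees / max(x$n_with_structure, 1)))
  gp <- x$genus_counts[x$genus_counts > 0]
  if (length(gp))
    cat("  genera:", paste(names(gp), as.integer(gp), collapse = ", "), "\n")
  print(x$by_stage, row.names = FALSE)
  invisible(x)
}
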