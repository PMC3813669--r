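# Unit-year panel: one row per spatial unit (municipality) per survey year,
# with total and child populations and physician / pediatrician headcounts.

.uy_columns <- c("region_id", "unit_id", "year", "population",
                 "child_population", "physicians", "pediatricians")

.uy_count_columns <- c("population", "child_population",
                       "physicians", "pediatricians")

#' Default column mapping for unit-year tables
#'
#' Maps the canonical field names used throughout the package to the column
#' names found in an input file. Override entries to ingest registry exports
#' with different headers, e.g.
#' `unit_year_columns(unit_id = "municipality_code")`.
#'
#' @param ... Named overrides, one per canonical field. Valid names are
#'   `region_id`, `unit_id`, `year`, `population`, `child_population`,
#'   `physicians`, `pediatricians`.
#' @return Named character vector mapping canonical field -> file column.
#' @export
#' @examples
#' unit_year_columns()
#' unit_year_columns(region_id = "prefecture", physicians = "md_count")
unit_year_columns <- function(...) {
  map <- setNames(.uy_columns, .uy_columns)
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), .uy_columns)
    if (length(bad)) {
      abort(paste0("Unknown unit-year field(s): ", toString(bad)))
    }
    map[names(dots)] <- dots
  }
  map
}

new_unit_year_panel <- function(x) {
  x <- tibble::as_tibble(x)[.uy_columns]
  class(x) <- c("unit_year_panel", class(x))
  x
}

#' Construct a unit-year panel from vectors
#'
#' @param region_id,unit_id Identifiers (coerced to character).
#' @param year Integer survey year.
#' @param population,child_population Resident headcounts; the child
#'   population is the population under 15 years, the denominator used for
#'   pediatrician inequality.
#' @param physicians,pediatricians Provider headcounts.
#' @return A `unit_year_panel` tibble.
#' @export
unit_year_panel <- function(region_id, unit_id, year, population,
                            child_population, physicians, pediatricians) {
  x <- tibble::tibble(
    region_id = as.character(region_id),
    unit_id = as.character(unit_id),
    year = as.integer(year),
    population = as.numeric(population),
    child_population = as.numeric(child_population),
    physicians = as.numeric(physicians),
    pediatricians = as.numeric(pediatricians)
  )
  assert_unit_year_panel(x)
  new_unit_year_panel(x)
}

assert_unit_year_panel <- function(x, call = rlang::caller_env()) {
  for (col in .uy_count_columns) {
    if (any(is.na(x[[col]]))) {
      abort(paste0("Column '", col, "' contains missing values."), call = call)
    }
    if (any(x[[col]] < 0)) {
      abort(paste0("Column '", col, "' contains negative values."), call = call)
    }
  }
  if (any(x$child_population > x$population)) {
    abort("child_population exceeds population for some rows.", call = call)
  }
  dup <- duplicated(x[c("unit_id", "year")])
  if (any(dup)) {
    abort(paste0("Duplicate (unit_id, year) keys: ",
                 toString(head(unique(x$unit_id[dup]), 5))), call = call)
  }
  invisible(x)
}

#' Read a unit-year table from delimited text
#'
#' Expects UTF-8 comma-delimited text with a header row. Column names are
#' resolved through `column_map`, so arbitrary registry exports can be
#' ingested; row order is preserved.
#'
#' @param source Path or connection readable by [readr::read_csv()].
#' @param column_map Mapping from canonical fields to file columns, as
#'   produced by [unit_year_columns()].
#' @return A `unit_year_panel` tibble with the canonical columns.
#' @export
read_unit_year_table <- function(source, column_map = unit_year_columns()) {
  raw <- readr::read_csv(source, col_types = readr::cols(.default = "c"),
                         comment = "#", progress = FALSE)
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols)) {
    abort(paste0("Input is missing required column(s): ",
                 toString(missing_cols)))
  }
  out <- tibble::as_tibble(setNames(raw[unname(column_map)],
                                    names(column_map)))
  out$year <- .parse_numeric(out$year, "year")
  for (col in .uy_count_columns) {
    out[[col]] <- .parse_numeric(out[[col]], col)
  }
  out$year <- as.integer(out$year)
  assert_unit_year_panel(out)
  new_unit_year_panel(out)
}

.parse_numeric <- function(x, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    abort(paste0("Non-numeric value in column '", col, "' at data row ",
                 bad[1], ": '", x[bad[1]], "'"))
  }
  out
}

#' Write a unit-year table
#'
#' Emits the canonical CSV dialect (stable column order, LF line endings) so
#' that write-then-read is the identity on panels.
#'
#' @param panel A `unit_year_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_unit_year_table <- function(panel, path) {
  readr::write_csv(panel[.uy_columns], path, eol = "\n", progress = FALSE)
  invisible(path)
}

#' Read a boundary crosswalk
#'
#' A crosswalk maps pre-merger unit identifiers onto the harmonized
#' (many-to-one) post-merger identifiers, so that a fixed set of boundaries
#' can be used for all survey years.
#'
#' @param source CSV path/connection with columns `old_unit_id,new_unit_id`.
#' @return A `crosswalk` tibble.
#' @export
read_crosswalk <- function(source) {
  raw <- readr::read_csv(source, col_types = readr::cols(.default = "c"),
                         comment = "#", progress = FALSE)
  missing_cols <- setdiff(c("old_unit_id", "new_unit_id"), names(raw))
  if (length(missing_cols)) {
    abort(paste0("Crosswalk is missing required column(s): ",
                 toString(missing_cols)))
  }
  crosswalk(raw$old_unit_id, raw$new_unit_id)
}

#' Construct a boundary crosswalk
#'
#' @param old_unit_id,new_unit_id Parallel vectors of identifiers; each old
#'   id must map to exactly one new id.
#' @return A `crosswalk` tibble with columns `old_unit_id`, `new_unit_id`.
#' @export
crosswalk <- function(old_unit_id, new_unit_id) {
  x <- tibble::tibble(old_unit_id = as.character(old_unit_id),
                      new_unit_id = as.character(new_unit_id))
  dup <- duplicated(x$old_unit_id)
  if (any(dup)) {
    conflicted <- unique(x$old_unit_id[dup])
    ok <- vapply(conflicted, function(id) {
      length(unique(x$new_unit_id[x$old_unit_id == id])) == 1L
    }, logical(1))
    if (!all(ok)) {
      abort(paste0("Crosswalk maps old unit(s) to more than one new unit: ",
                   toString(conflicted[!ok])))
    }
    x <- x[!dup, ]
  }
  class(x) <- c("crosswalk", class(x))
  x
}

#' Apply a boundary crosswalk to a panel
#'
#' Rows whose units map to the same harmonized unit within a year are
#' collapsed into a single row whose populations and provider counts are the
#' sums of the merged rows. Merges never cross regions: the mapping must be
#' total over the panel and region-consistent.
#'
#' @param panel A `unit_year_panel`.
#' @param cw A `crosswalk`.
#' @return A `unit_year_panel` on harmonized boundaries.
#' @export
apply_crosswalk <- function(panel, cw) {
  idx <- match(panel$unit_id, cw$old_unit_id)
  if (anyNA(idx)) {
    missing_ids <- unique(panel$unit_id[is.na(idx)])
    abort(paste0("Crosswalk does not cover unit id(s): ",
                 toString(head(missing_ids, 10))))
  }
  mapped <- panel
  mapped$unit_id <- cw$new_unit_id[idx]

  region_check <- dplyr::distinct(mapped, .data$unit_id, .data$region_id)
  crossers <- region_check$unit_id[duplicated(region_check$unit_id)]
  if (length(crossers)) {
    abort(paste0("Crosswalk merges cross region boundaries for new unit(s): ",
                 toString(unique(crossers))))
  }

  out <- mapped |>
    dplyr::group_by(.data$region_id, .data$unit_id, .data$year) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(.uy_count_columns), sum),
                     .groups = "drop") |>
    dplyr::arrange(.data$region_id, .data$unit_id, .data$year)
  new_unit_year_panel(out)
}

#' Per-capita provider rate
#'
#' Providers per `scale` persons. In reporting mode the rate is rounded
#' half-up at one decimal, the convention used for published per-100,000
#' workforce densities.
#'
#' @param count Provider headcount (vectorized).
#' @param population Denominator population; must be positive.
#' @param scale Persons per reporting unit (default 100,000).
#' @param reporting Round half-up to one decimal when `TRUE`.
#' @return Numeric rate(s).
#' @export
#' @examples
#' per_capita_rate(230297, 124.9e6)  # 184.4 physicians per 100,000
per_capita_rate <- function(count, population, scale = 1e5, reporting = TRUE) {
  if (any(population <= 0)) {
    abort("population must be positive.")
  }
  if (any(count < 0) || scale <= 0) {
    abort("count must be non-negative and scale positive.")
  }
  rate <- scale * count / population
  if (reporting) round_half_up(rate, 1L) else rate
}

round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Validate a unit-year panel
#'
#' Reporting operation: enumerates missing region-year cells (against
#' `expected_years`), duplicate `(unit_id, year)` keys, rows with negative
#' values, and zero-population units. A clean balanced panel yields an empty
#' report.
#'
#' @param panel A `unit_year_panel` (or coercible data frame).
#' @param expected_years Years every region is expected to cover; defaults to
#'   the years present in the panel.
#' @return A `panel_validation_report` list with components
#'   `missing_cells`, `duplicates`, `negative_rows`, `zero_population_units`
#'   and logical `clean`.
#' @export
validate_panel <- function(panel, expected_years = sort(unique(panel$year))) {
  panel <- tibble::as_tibble(panel)

  present <- dplyr::distinct(panel, .data$region_id, .data$year)
  grid <- tidyr::expand_grid(region_id = unique(panel$region_id),
                             year = as.integer(expected_years))
  missing_cells <- dplyr::anti_join(grid, present,
                                    by = c("region_id", "year"))

  dup_key <- duplicated(panel[c("unit_id", "year")]) |
    duplicated(panel[c("unit_id", "year")], fromLast = TRUE)
  duplicates <- dplyr::distinct(panel[dup_key, c("unit_id", "year")])

  neg <- rep(FALSE, nrow(panel))
  for (col in .uy_count_columns) neg <- neg | (panel[[col]] < 0)
  negative_rows <- which(neg)

  zero_pop <- dplyr::distinct(
    panel[panel$population <= 0, c("region_id", "unit_id", "year")]
  )

  report <- structure(
    list(missing_cells = missing_cells,
         duplicates = duplicates,
         negative_rows = negative_rows,
         zero_population_units = zero_pop,
         clean = nrow(missing_cells) == 0L && nrow(duplicates) == 0L &&
           length(negative_rows) == 0L && nrow(zero_pop) == 0L),
    class = "panel_validation_report"
  )
  report
}

#' @export
print.panel_validation_report <- function(x, ...) {
  cat("<panel_validation_report>\n")
  if (x$clean) {
    cat("  panel is balanced and clean\n")
  } else {
    cat("  missing region-year cells:", nrow(x$missing_cells), "\n")
    cat("  duplicate (unit, year) keys:", nrow(x$duplicates), "\n")
    cat("  negative-value rows:", length(x$negative_rows), "\n")
    cat("  zero-population units:", nrow(x$zero_population_units), "\n")
  }
  invisible(x)
}
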