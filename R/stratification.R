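# Urban/rural stratification of regions and stratified change-point fits.
#
# Three classification schemes for the 47 Japanese prefectures are built in:
# "oecd" (13 predominantly urban prefectures under the OECD regional
# typology), "metro" (14 prefectures containing central cities of major
# metropolitan areas), and "density" (7 prefectures with population density
# of at least 1000 per square km). Custom schemes are an explicit list of
# urban region ids.

.jp_prefectures <- c(
  "Hokkaido", "Aomori", "Iwate", "Miyagi", "Akita", "Yamagata", "Fukushima",
  "Ibaraki", "Tochigi", "Gunma", "Saitama", "Chiba", "Tokyo", "Kanagawa",
  "Niigata", "Toyama", "Ishikawa", "Fukui", "Yamanashi", "Nagano", "Gifu",
  "Shizuoka", "Aichi", "Mie", "Shiga", "Kyoto", "Osaka", "Hyogo", "Nara",
  "Wakayama", "Tottori", "Shimane", "Okayama", "Hiroshima", "Yamaguchi",
  "Tokushima", "Kagawa", "Ehime", "Kochi", "Fukuoka", "Saga", "Nagasaki",
  "Kumamoto", "Oita", "Miyazaki", "Kagoshima", "Okinawa"
)

.builtin_urban <- list(
  oecd = c("Miyagi", "Saitama", "Chiba", "Tokyo", "Kanagawa", "Shizuoka",
           "Aichi", "Kyoto", "Osaka", "Hyogo", "Nara", "Hiroshima",
           "Fukuoka"),
  metro = c("Hokkaido", "Miyagi", "Saitama", "Chiba", "Tokyo", "Kanagawa",
            "Niigata", "Shizuoka", "Aichi", "Kyoto", "Osaka", "Hyogo",
            "Hiroshima", "Fukuoka"),
  density = c("Saitama", "Chiba", "Tokyo", "Kanagawa", "Aichi", "Osaka",
              "Fukuoka")
)

#' The 47 Japanese prefecture names
#'
#' Romanized names, used as the default region identifiers of the synthetic
#' generator so that the built-in urban/rural schemes apply to synthetic
#' panels unchanged.
#'
#' @return Character vector of length 47.
#' @export
jp_prefectures <- function() .jp_prefectures

#' Define an urban/rural stratification scheme
#'
#' @param name `"oecd"`, `"metro"`, `"density"`, or `"custom"`. Built-ins
#'   carry the fixed prefecture lists described above; `"custom"` requires
#'   `urban_regions`.
#' @param urban_regions For custom schemes, the region ids classified as
#'   urban. Matching is case-insensitive.
#' @return A `strat_scheme` list with `name`, `urban_regions`.
#' @export
#' @examples
#' strat_scheme("oecd")
#' strat_scheme("custom", urban_regions = c("Tokyo", "Osaka"))
strat_scheme <- function(name = c("oecd", "metro", "density", "custom"),
                         urban_regions = NULL) {
  name <- match.arg(name)
  if (name == "custom") {
    if (is.null(urban_regions) || length(urban_regions) == 0L) {
      abort("A custom scheme requires a non-empty urban_regions list.")
    }
    urban_regions <- as.character(urban_regions)
  } else {
    if (!is.null(urban_regions)) {
      abort("urban_regions can only be supplied with name = \"custom\".")
    }
    urban_regions <- .builtin_urban[[name]]
  }
  structure(list(name = name, urban_regions = urban_regions),
            class = "strat_scheme")
}

#' Read a custom scheme from a one-column text file
#'
#' One urban region id per line; blank lines and lines starting with `#`
#' are ignored.
#'
#' @param path File path.
#' @return A custom `strat_scheme`.
#' @export
read_strat_scheme <- function(path) {
  lines <- trimws(readr::read_lines(path, progress = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  strat_scheme("custom", urban_regions = lines)
}

#' @export
print.strat_scheme <- function(x, ...) {
  cat("<strat_scheme> ", x$name, ": ", length(x$urban_regions),
      " urban region(s)\n", sep = "")
  invisible(x)
}

#' Classify regions as urban or other
#'
#' @param region_id Region identifier(s).
#' @param scheme A `strat_scheme` (or a built-in scheme name).
#' @return Character vector of `"urban"` / `"other"`.
#' @export
#' @examples
#' classify("Nara", "oecd")   # urban
#' classify("Nara", "metro")  # other
classify <- function(region_id, scheme) {
  if (is.character(scheme)) {
    scheme <- strat_scheme(scheme)
  }
  ifelse(tolower(region_id) %in% tolower(scheme$urban_regions),
         "urban", "other")
}

#' Stratified change-point fits
#'
#' Splits the Gini panel into urban and other strata (a partition: every
#' region lands in exactly one stratum) and fits the change-point model
#' independently in each with identical options. A stratum whose design is
#' rank deficient is reported as an error condition without aborting the
#' other stratum.
#'
#' @inheritParams fit_changepoint
#' @param scheme A `strat_scheme` or built-in scheme name.
#' @return A `stratified_fits` list with components `urban` and `other`
#'   (each a `changepoint_fit`, or a condition object if the per-stratum fit
#'   failed), plus `scheme` and `sizes` (regions per stratum).
#' @export
stratified_fits <- function(panel, scheme, knot_year,
                            year_coding = c("wave-index", "calendar-offset"),
                            se_type = c("conventional", "cluster")) {
  if (is.character(scheme)) {
    scheme <- strat_scheme(scheme)
  }
  stratum <- classify(panel$region_id, scheme)
  if (!all(c("urban", "other") %in% unique(stratum))) {
    abort("Both strata must be non-empty in the panel.")
  }
  fits <- lapply(c(urban = "urban", other = "other"), function(s) {
    tryCatch(
      fit_changepoint(panel[stratum == s, ], knot_year,
                      year_coding = year_coding, se_type = se_type),
      error = function(e) e
    )
  })
  sizes <- vapply(c(urban = "urban", other = "other"), function(s) {
    length(unique(panel$region_id[stratum == s]))
  }, integer(1))
  structure(list(urban = fits$urban, other = fits$other,
                 scheme = scheme, sizes = sizes),
            class = "stratified_fits")
}

#' @export
print.stratified_fits <- function(x, ...) {
  cat("<stratified_fits> scheme =", x$scheme$name, "\n")
  for (s in c("urban", "other")) {
    cat("--", s, "(", x$sizes[[s]], "regions ) --\n")
    if (inherits(x[[s]], "condition")) {
      cat("  fit failed:", conditionMessage(x[[s]]), "\n")
    } else {
      print(x[[s]])
    }
  }
  invisible(x)
}
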