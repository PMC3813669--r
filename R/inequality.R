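# Population-weighted Lorenz curves and Gini coefficients.
#
# Units are ranked by ascending provider-to-population ratio; the Lorenz
# x-axis is the cumulative share of the denominator population and the
# y-axis the cumulative share of providers. The Gini is twice the area
# between the curve and the diagonal, evaluated by the trapezoid rule
# (exact for a piecewise-linear curve). An algebraically equivalent
# population-weighted pairwise mean-difference form is provided as an
# independent cross-check.

#' Build a Lorenz curve for one region-year
#'
#' Units are sorted ascending by `providers / population` (stable for ties)
#' and cumulative shares are accumulated against the supplied denominator
#' population — total population for physicians, child population for
#' pediatricians.
#'
#' @param population Denominator populations, one per unit; units with zero
#'   population are dropped with a warning.
#' @param providers Provider headcounts, one per unit. Units with zero
#'   providers are kept: they occupy the flat initial segment of the curve.
#' @return A `lorenz_curve`: list with `points` (tibble of `x`, `y`,
#'   starting at (0,0) and ending at (1,1)) and `n_units`.
#' @export
#' @examples
#' build_lorenz(c(1, 1), c(0, 10))
build_lorenz <- function(population, providers) {
  u <- .clean_units(population, providers)
  o <- order(u$providers / u$population)
  p <- u$population[o]
  q <- u$providers[o]
  structure(
    list(points = tibble::tibble(x = c(0, cumsum(p) / sum(p)),
                                 y = c(0, cumsum(q) / sum(q))),
         n_units = length(p)),
    class = "lorenz_curve"
  )
}

.clean_units <- function(population, providers, call = rlang::caller_env()) {
  if (length(population) != length(providers)) {
    abort("population and providers must have equal length.", call = call)
  }
  if (any(population < 0) || any(providers < 0)) {
    abort("populations and provider counts must be non-negative.",
          call = call)
  }
  zero <- population == 0
  if (all(zero)) {
    abort("all units have zero population; Lorenz curve undefined.",
          call = call)
  }
  if (any(zero)) {
    warn(paste0("Excluding ", sum(zero),
                " zero-population unit(s) from the Lorenz curve."))
    population <- population[!zero]
    providers <- providers[!zero]
  }
  if (sum(providers) == 0) {
    abort("total providers is zero; Lorenz curve undefined.", call = call)
  }
  list(population = population, providers = providers)
}

#' @export
print.lorenz_curve <- function(x, ...) {
  cat("<lorenz_curve> ", x$n_units, " units, ",
      nrow(x$points), " points\n", sep = "")
  invisible(x)
}

#' Gini coefficient from a Lorenz curve
#'
#' Trapezoid area rule: `1 - sum((x_k - x_{k-1}) * (y_k + y_{k-1}))`,
#' clamped to `[0, 1)` against floating-point drift.
#'
#' @param curve A `lorenz_curve`.
#' @return Gini coefficient in `[0, 1)`.
#' @export
gini_from_lorenz <- function(curve) {
  pts <- curve$points
  n <- nrow(pts)
  dx <- pts$x[-1] - pts$x[-n]
  sy <- pts$y[-1] + pts$y[-n]
  g <- 1 - sum(dx * sy)
  min(max(g, 0), 1)
}

# Fast path used by gini_panel and the synthetic calibrator: same trapezoid
# rule without constructing the curve object.
gini_weighted <- function(population, providers) {
  o <- order(providers / population)
  p <- population[o]
  q <- providers[o]
  x <- cumsum(p)
  y <- cumsum(q)
  n <- length(p)
  # sum of dx * (y_k + y_{k-1}) on the unnormalized scale
  g <- 1 - sum(p * (y + c(0, y[-n]))) / (x[n] * y[n])
  min(max(g, 0), 1)
}

#' Population-weighted pairwise Gini (independent oracle)
#'
#' Computes the Gini as the population-weighted relative mean absolute
#' difference of provider-to-population ratios:
#' `sum_ij w_i w_j |r_i - r_j| / (2 mu)` with `w` the denominator-population
#' shares and `mu` the overall provider rate. For a piecewise-linear Lorenz
#' curve this is algebraically identical to [gini_from_lorenz()]; it is kept
#' as an always-available cross-check of the trapezoid implementation.
#'
#' @inheritParams build_lorenz
#' @return Gini coefficient in `[0, 1)`.
#' @export
gini_pairwise <- function(population, providers) {
  u <- .clean_units(population, providers)
  w <- u$population / sum(u$population)
  r <- u$providers / u$population
  mu <- sum(u$providers) / sum(u$population)
  g <- sum(outer(w, w) * abs(outer(r, r, "-"))) / (2 * mu)
  min(max(g, 0), 1)
}

#' Small-sample Gini adjustment
#'
#' Multiplies a sample Gini by `n / (n - 1)` (n the number of units) to
#' correct the small-sample downward bias. The adjusted value may exceed the
#' raw one and can reach 1.
#'
#' @param g Raw Gini value(s).
#' @param n Number of units; must be at least 2.
#' @return Adjusted Gini value(s).
#' @export
adjust_small_sample <- function(g, n) {
  if (any(n < 2)) {
    abort("small-sample adjustment requires n >= 2.")
  }
  g * n / (n - 1)
}

#' Region-year Gini panel
#'
#' Computes the population-weighted Gini for every region-year in a
#' unit-year panel, pairing the chosen provider field with its denominator
#' (physicians with total population, pediatricians with the under-15 child
#' population). Zero-population units are excluded with a warning;
#' region-years whose total provider count is zero have an undefined Gini
#' and are emitted as `NA` with a message — never as 0.
#'
#' @param panel A `unit_year_panel`.
#' @param provider `"physicians"` or `"pediatricians"` (or any count column).
#' @param denominator Denominator column; defaults to `"child_population"`
#'   when `provider` is `"pediatricians"`, else `"population"`.
#' @param adjusted Apply the `n/(n-1)` small-sample adjustment.
#' @return A `gini_panel` tibble with columns `region_id`, `year`, `gini`,
#'   `n_units`, `adjusted`.
#' @export
gini_panel <- function(panel, provider = c("physicians", "pediatricians"),
                       denominator = NULL, adjusted = FALSE) {
  provider <- if (length(provider) > 1) match.arg(provider) else provider
  if (is.null(denominator)) {
    denominator <- if (identical(provider, "pediatricians")) {
      "child_population"
    } else {
      "population"
    }
  }
  if (!provider %in% names(panel) || !denominator %in% names(panel)) {
    abort("provider/denominator columns not found in panel.")
  }
  if (nrow(panel) == 0L) {
    abort("panel is empty.")
  }

  pop <- panel[[denominator]]
  prov <- panel[[provider]]
  n_zero_pop <- sum(pop == 0)
  if (n_zero_pop > 0) {
    warn(paste0("Excluding ", n_zero_pop,
                " zero-population unit-year row(s) from Gini computation."))
  }
  keep <- pop > 0
  # "\u001f" (unit separator) cannot occur in well-formed identifiers
  key <- factor(paste(panel$region_id[keep], panel$year[keep],
                      sep = "\u001f"))
  pops <- split(pop[keep], key)
  provs <- split(prov[keep], key)

  g <- vapply(seq_along(pops), function(i) {
    if (sum(provs[[i]]) == 0) NA_real_ else gini_weighted(pops[[i]], provs[[i]])
  }, numeric(1))
  n_units <- lengths(pops)

  lab <- strsplit(levels(key), "\u001f", fixed = TRUE)
  out <- tibble::tibble(
    region_id = vapply(lab, `[`, character(1), 1L),
    year = as.integer(vapply(lab, `[`, character(1), 2L)),
    gini = g,
    n_units = as.integer(n_units),
    adjusted = adjusted
  )
  if (adjusted) {
    out$gini <- adjust_small_sample(out$gini, out$n_units)
  }
  if (anyNA(out$gini)) {
    inform(paste0(sum(is.na(out$gini)),
                  " region-year cell(s) have zero total providers; ",
                  "Gini emitted as missing."))
  }
  out <- dplyr::arrange(out, .data$region_id, .data$year)
  class(out) <- c("gini_panel", class(out))
  out
}

#' National (single-region) Gini series
#'
#' Convenience wrapper reproducing the two national constructions: with
#' `units = "unit"` every municipality contributes as a unit of one
#' nationwide region; with `units = "region"` regions themselves are the
#' units (their totals are aggregated first).
#'
#' @inheritParams gini_panel
#' @param units `"unit"` or `"region"`.
#' @return A `gini_panel` with `region_id = "national"`.
#' @export
national_gini_series <- function(panel,
                                 provider = c("physicians", "pediatricians"),
                                 units = c("unit", "region"),
                                 denominator = NULL, adjusted = FALSE) {
  units <- match.arg(units)
  x <- tibble::as_tibble(panel)
  if (units == "region") {
    x <- x |>
      dplyr::group_by(.data$region_id, .data$year) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(.uy_count_columns), sum),
                       .groups = "drop") |>
      dplyr::rename(unit_id = "region_id")
    x$region_id <- "national"
  } else {
    x$region_id <- "national"
  }
  gini_panel(new_unit_year_panel(x[.uy_columns]), provider = provider,
             denominator = denominator, adjusted = adjusted)
}

#' Export Lorenz curves for plotting
#'
#' @inheritParams gini_panel
#' @return Tibble with columns `region_id`, `year`, `x`, `y`.
#' @export
lorenz_export <- function(panel, provider = c("physicians", "pediatricians"),
                          denominator = NULL) {
  provider <- if (length(provider) > 1) match.arg(provider) else provider
  if (is.null(denominator)) {
    denominator <- if (identical(provider, "pediatricians")) {
      "child_population"
    } else {
      "population"
    }
  }
  keep <- panel[[denominator]] > 0
  x <- panel[keep, ]
  x |>
    dplyr::group_by(.data$region_id, .data$year) |>
    dplyr::group_modify(function(d, key) {
      if (sum(d[[provider]]) == 0) {
        return(tibble::tibble(x = numeric(0), y = numeric(0)))
      }
      crv <- suppressWarnings(build_lorenz(d[[denominator]], d[[provider]]))
      crv$points
    }) |>
    dplyr::ungroup()
}

#' Write a Gini panel as CSV
#'
#' Emits `region_id,year,gini,n_units,adjusted` with LF line endings.
#'
#' @param panel A `gini_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gini_panel <- function(panel, path) {
  readr::write_csv(panel[c("region_id", "year", "gini", "n_units",
                           "adjusted")],
                   path, eol = "\n", progress = FALSE)
  invisible(path)
}

#' Read a Gini panel written by [write_gini_panel()]
#'
#' @param source CSV path/connection.
#' @return A `gini_panel` tibble.
#' @export
read_gini_panel <- function(source) {
  out <- readr::read_csv(
    source,
    col_types = readr::cols(region_id = "c", year = "i", gini = "d",
                            n_units = "i", adjusted = "l"),
    comment = "#", progress = FALSE
  )
  class(out) <- c("gini_panel", class(out))
  out
}
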