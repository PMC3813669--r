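# Fixed-knot linear change-point regression on a region-year Gini panel.
#
# Model: E(Y) = b0 + b1*t + b2*z + b3*z*t, with z = 1 for years at or after
# the knot. b1 is the pre-period slope, b1 + b3 the post-period slope, so b3
# is the pre-vs-post slope difference — the policy-effect estimate.

#' Build the change-point design
#'
#' @param panel A `gini_panel` (or any tibble with `region_id`, `year`,
#'   `gini`).
#' @param knot_year The fixed knot; years at or after it form the
#'   post-period.
#' @param year_coding `"wave-index"`: t is the 0-based rank of the survey
#'   wave (one unit = one survey, the default for biennial data);
#'   `"calendar-offset"`: t is calendar years since the first observed year.
#'   Coefficient magnitudes depend on this choice, so every fit embeds it.
#' @return The panel with columns `t`, `z`, `zt` appended.
#' @export
build_design <- function(panel, knot_year,
                         year_coding = c("wave-index", "calendar-offset")) {
  if (nrow(panel) == 0L) {
    abort("panel is empty.")
  }
  year_coding <- match.arg(year_coding)
  yrs <- sort(unique(panel$year))
  t <- switch(year_coding,
    "wave-index" = match(panel$year, yrs) - 1L,
    "calendar-offset" = panel$year - yrs[1]
  )
  out <- tibble::as_tibble(panel)
  out$t <- as.numeric(t)
  out$z <- as.numeric(panel$year >= knot_year)
  out$zt <- out$z * out$t
  out
}

#' Fit a fixed-knot change-point regression
#'
#' Pooled ordinary least squares over all region-year rows of the Gini
#' panel. Standard errors are conventional OLS by default; cluster-robust by
#' region (CR1, t reference with `n_regions - 1` df) is available for
#' sensitivity to within-region correlation. Region-years with a missing
#' Gini (zero-provider cells) are dropped listwise with a message.
#'
#' @inheritParams build_design
#' @param se_type `"conventional"` or `"cluster"` (cluster-robust by
#'   region).
#' @return A `changepoint_fit`: list with `coefficients` (tibble of `term`,
#'   `estimate`, `se`, `p_value`), `knot_year`, `year_coding`, `se_type`,
#'   `n_obs`, `n_regions`, `sigma`, `r_squared`, and the underlying `lm`
#'   object in `model`.
#' @export
fit_changepoint <- function(panel, knot_year,
                            year_coding = c("wave-index", "calendar-offset"),
                            se_type = c("conventional", "cluster")) {
  year_coding <- match.arg(year_coding)
  se_type <- match.arg(se_type)
  d <- build_design(panel, knot_year, year_coding)
  n_missing <- sum(is.na(d$gini))
  if (n_missing > 0) {
    inform(paste0("Dropping ", n_missing,
                  " region-year row(s) with missing Gini."))
    d <- d[!is.na(d$gini), ]
  }
  if (length(unique(d$z)) < 2L) {
    abort(paste0("All observations fall on one side of the knot (",
                 knot_year, "); the change-point design is rank deficient."))
  }
  if (nrow(unique(d[c("t", "z")])) < 4L || nrow(d) < 5L) {
    abort(paste0("Need at least 4 distinct design rows (and residual ",
                 "df > 0) spanning both sides of the knot."))
  }

  fit <- lm(gini ~ t + z + zt, data = d)
  est <- unname(coef(fit))
  if (anyNA(est)) {
    abort("Change-point design is rank deficient.")
  }

  if (se_type == "conventional") {
    sm <- suppressWarnings(summary(fit))
    se <- unname(sm$coefficients[, "Std. Error"])
    p <- unname(sm$coefficients[, "Pr(>|t|)"])
  } else {
    vc <- sandwich::vcovCL(fit, cluster = d$region_id, type = "HC1")
    g <- length(unique(d$region_id))
    ct <- lmtest::coeftest(fit, vcov. = vc, df = g - 1L)
    se <- unname(ct[, "Std. Error"])
    p <- unname(ct[, "Pr(>|t|)"])
  }

  structure(
    list(
      coefficients = tibble::tibble(
        term = c("beta0", "beta1", "beta2", "beta3"),
        label = c("intercept", "year", "z", "z:year"),
        estimate = est, se = se, p_value = p
      ),
      knot_year = knot_year,
      year_coding = year_coding,
      se_type = se_type,
      n_obs = nrow(d),
      n_regions = length(unique(d$region_id)),
      df_residual = fit$df.residual,
      sigma = sqrt(sum(fit$residuals^2) / fit$df.residual),
      r_squared = suppressWarnings(summary(fit))$r.squared,
      model = fit
    ),
    class = "changepoint_fit"
  )
}

#' @export
print.changepoint_fit <- function(x, digits = 4, ...) {
  cat("<changepoint_fit>  knot =", x$knot_year,
      " coding =", x$year_coding, " SE =", x$se_type, "\n")
  cat("  n_obs =", x$n_obs, " regions =", x$n_regions, "\n")
  print(as.data.frame(x$coefficients), digits = digits, row.names = FALSE)
  s <- slopes(x)
  cat(sprintf("  slope pre = %.*g, post = %.*g (per %s unit)\n",
              digits, s[["pre"]], digits, s[["post"]], x$year_coding))
  invisible(x)
}

#' Pre- and post-knot slopes of a change-point fit
#'
#' @param fit A `changepoint_fit`.
#' @return Named numeric vector `c(pre = beta1, post = beta1 + beta3)`;
#'   `post - pre` equals `beta3` exactly.
#' @export
slopes <- function(fit) {
  b <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  c(pre = unname(b["beta1"]), post = unname(b["beta1"] + b["beta3"]))
}

#' Coefficient table of a change-point fit
#'
#' One row per coefficient with estimate, standard error and two-sided
#' p-value, mirroring the usual published layout.
#'
#' @param fit A `changepoint_fit`.
#' @return A tibble.
#' @export
fit_report <- function(fit) {
  out <- fit$coefficients
  out$knot_year <- fit$knot_year
  out$year_coding <- fit$year_coding
  out$se_type <- fit$se_type
  out
}

#' Per-year mean Gini over a set of regions
#'
#' Unweighted mean of the region Gini values for each year — the descriptive
#' series usually plotted alongside the regression.
#'
#' @param panel A `gini_panel`.
#' @param regions Regions to average over; default all regions present.
#' @return Tibble with `year`, `mean_gini`, `n_regions`.
#' @export
mean_series <- function(panel, regions = NULL) {
  x <- tibble::as_tibble(panel)
  if (!is.null(regions)) {
    x <- x[x$region_id %in% regions, ]
  }
  if (nrow(x) == 0L) {
    abort("No panel rows match the requested regions.")
  }
  x |>
    dplyr::group_by(year = .data$year) |>
    dplyr::summarise(mean_gini = mean(.data$gini, na.rm = TRUE),
                     n_regions = sum(!is.na(.data$gini)),
                     .groups = "drop")
}
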