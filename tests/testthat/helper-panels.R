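# Fixtures built in code: random unit instances, exact piecewise-linear
# Gini panels, and a small hand-written unit-year table.

# random (population, providers) instances for Gini property tests
random_units <- function(n, allow_zero_providers = TRUE) {
  population <- stats::rlnorm(n, 8, 1)
  ratio <- stats::rlnorm(n, -6, 0.8)
  if (allow_zero_providers && n > 2) {
    ratio[sample(n, size = max(1, n %/% 5))] <- 0
  }
  providers <- ratio * population
  if (sum(providers) == 0) providers[1] <- population[1] * 1e-3
  list(population = population, providers = providers)
}

# exact panel Y = b0 + b1 t + b2 z + b3 z t on the wave-index coding
exact_gini_panel <- function(beta, n_regions = 5,
                             years = seq(1996, 2010, 2), knot = 2004) {
  t <- seq_along(years) - 1
  z <- as.numeric(years >= knot)
  y <- beta[1] + beta[2] * t + beta[3] * z + beta[4] * z * t
  out <- tidyr::expand_grid(region_id = sprintf("R%02d", seq_len(n_regions)),
                            year = as.integer(years))
  out$gini <- rep(y, times = n_regions)
  out$n_units <- 10L
  out$adjusted <- FALSE
  out
}

toy_table <- function() {
  unit_year_panel(
    region_id = rep("A", 6),
    unit_id = rep(c("m1", "m2", "m3"), 2),
    year = rep(c(1996L, 1998L), each = 3),
    population = c(100, 300, 600, 100, 300, 600),
    child_population = c(20, 50, 90, 18, 45, 80),
    physicians = c(1, 3, 9, 1, 4, 9),
    pediatricians = c(0, 1, 2, 0, 1, 2)
  )
}

# small multi-region panel covering both oecd strata
small_synth_config <- function(...) {
  synthetic_config(
    n_regions = 8, units_per_region = 10,
    region_ids = c("Tokyo", "Osaka", "Miyagi", "Aomori",
                   "Iwate", "Akita", "Kochi", "Shimane"),
    ...
  )
}
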