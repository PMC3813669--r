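test_that("Lorenz curves satisfy the curve invariants on random instances", {
  # trivial shapes first
  even <- build_lorenz(c(1, 1), c(5, 5))
  expect_equal(even$points$x, c(0, 0.5, 1))
  expect_equal(even$points$y, c(0, 0.5, 1))

  conc <- build_lorenz(c(1, 1), c(0, 10))
  expect_equal(conc$points$y, c(0, 0, 1))

  set.seed(42)
  for (rep in 1:50) {
    u <- random_units(5)
    crv <- build_lorenz(u$population, u$providers)
    pts <- crv$points
    expect_equal(pts$x[1], 0)
    expect_equal(pts$y[1], 0)
    expect_equal(pts$x[nrow(pts)], 1)
    expect_equal(pts$y[nrow(pts)], 1)
    expect_true(all(diff(pts$x) > 0))                  # x strictly increasing
    expect_true(all(diff(pts$y) >= -1e-15))            # y non-decreasing
    slopes <- diff(pts$y) / diff(pts$x)
    expect_true(all(diff(slopes) >= -1e-9))            # convex
    expect_true(all(pts$y <= pts$x + 1e-12))           # below diagonal
  }
})

test_that("degenerate unit sets are rejected or cleaned", {
  expect_error(build_lorenz(c(1, 1), c(0, 0)), "total providers")
  expect_error(build_lorenz(c(0, 0), c(1, 1)), "zero population")
  expect_warning(crv <- build_lorenz(c(0, 1, 1), c(1, 1, 3)),
                 "zero-population")
  expect_equal(crv$n_units, 2L)
})

test_that("trapezoid Gini agrees with the pairwise mean-difference oracle", {
  # analytic extremes
  expect_equal(gini_from_lorenz(build_lorenz(c(2, 2, 2), c(7, 7, 7))), 0)
  expect_equal(gini_from_lorenz(build_lorenz(rep(1, 4), c(0, 0, 0, 9))),
               0.75)
  expect_equal(gini_pairwise(1000, 3), 0)          # single unit
  expect_equal(gini_pairwise(c(1, 1), c(4, 0)), 0.5)

  set.seed(7)
  for (rep in 1:200) {
    u <- random_units(sample(2:50, 1))
    g1 <- gini_from_lorenz(build_lorenz(u$population, u$providers))
    g2 <- gini_pairwise(u$population, u$providers)
    expect_lt(abs(g1 - g2), 1e-12)
  }
})

test_that("Gini is invariant to scaling, tie order, and unit splitting", {
  set.seed(13)
  for (rep in 1:20) {
    u <- random_units(12)
    g <- gini_pairwise(u$population, u$providers)

    # scale invariance in the provider counts
    c_ <- stats::runif(1, 0.01, 100)
    expect_equal(gini_pairwise(u$population, c_ * u$providers), g,
                 tolerance = 1e-12)

    # tie-order invariance: duplicate-ratio units can be permuted freely
    v_pop <- c(u$population, 2 * u$population[3])
    v_prov <- c(u$providers, 2 * u$providers[3])
    perm <- sample(length(v_pop))
    expect_equal(gini_pairwise(v_pop[perm], v_prov[perm]),
                 gini_pairwise(v_pop, v_prov), tolerance = 1e-12)

    # replication invariance: halving a unit into two equal parts
    w_pop <- c(u$population[-1], u$population[1] / 2, u$population[1] / 2)
    w_prov <- c(u$providers[-1], u$providers[1] / 2, u$providers[1] / 2)
    expect_equal(gini_pairwise(w_pop, w_prov), g, tolerance = 1e-12)
  }
})

test_that("merging units never increases the Gini; bound 1 - w_min attained", {
  set.seed(29)
  for (rep in 1:20) {
    u <- random_units(10)
    g <- gini_pairwise(u$population, u$providers)
    # merge a random pair of units
    i <- sample(10, 2)
    m_pop <- c(u$population[-i], sum(u$population[i]))
    m_prov <- c(u$providers[-i], sum(u$providers[i]))
    gm <- gini_pairwise(m_pop, m_prov)
    expect_lte(gm, g + 1e-12)
  }

  # all providers in the smallest unit attains G = 1 - w_min
  pop <- c(10, 20, 30, 40)
  prov <- c(5, 0, 0, 0)
  expect_equal(gini_pairwise(pop, prov), 1 - 10 / 100)
})

test_that("small-sample adjustment is exact multiplication by n/(n-1)", {
  expect_equal(adjust_small_sample(0.3, 2), 0.6)
  expect_equal(adjust_small_sample(0.3, 10), 0.3 * 10 / 9)
  expect_error(adjust_small_sample(0.3, 1), "n >= 2")
  # factor tends to 1
  expect_lt(abs(adjust_small_sample(0.95, 1000) - 0.95), 1e-3)
})

test_that("gini_panel matches direct pairwise computation per region-year", {
  cfg <- small_synth_config(seed = 17, count_mode = "poisson")
  panel <- generate_panel(cfg)
  gp <- suppressMessages(gini_panel(panel, "physicians"))
  expect_s3_class(gp, "gini_panel")
  expect_equal(nrow(gp), 8 * 8)  # balanced: 8 regions x 8 waves

  for (i in sample(nrow(gp), 10)) {
    rows <- panel[panel$region_id == gp$region_id[i] &
                    panel$year == gp$year[i], ]
    expect_equal(gp$gini[i],
                 gini_pairwise(rows$population, rows$physicians),
                 tolerance = 1e-12)
  }

  # pediatricians are paired with the child population
  gped <- suppressMessages(gini_panel(panel, "pediatricians"))
  i <- which(gped$region_id == "Tokyo" & gped$year == 2004)
  rows <- panel[panel$region_id == "Tokyo" & panel$year == 2004, ]
  expect_equal(gped$gini[i],
               gini_pairwise(rows$child_population, rows$pediatricians),
               tolerance = 1e-12)

  # adjusted panel = raw panel scaled by n/(n-1) row-wise
  gadj <- suppressMessages(gini_panel(panel, "physicians", adjusted = TRUE))
  expect_equal(gadj$gini, gp$gini * gp$n_units / (gp$n_units - 1))
})

test_that("equal-ratio panels give zero Gini; zero-provider cells missing", {
  flat <- unit_year_panel(
    region_id = rep("A", 16),
    unit_id = rep(sprintf("m%d", 1:2), 8),
    year = rep(seq(1996L, 2010L, 2L), each = 2),
    population = rep(c(100, 400), 8),
    child_population = rep(c(10, 40), 8),
    physicians = rep(c(2, 8), 8),        # identical ratios
    pediatricians = rep(c(0, 0), 8)      # no pediatricians at all
  )
  gp <- gini_panel(flat, "physicians")
  expect_equal(gp$gini, rep(0, 8))

  expect_message(gped <- gini_panel(flat, "pediatricians"), "missing")
  expect_true(all(is.na(gped$gini)))
})

test_that("national series constructions collapse groupings correctly", {
  cfg <- small_synth_config(seed = 23)
  panel <- generate_panel(cfg)

  by_unit <- national_gini_series(panel, "physicians", units = "unit")
  expect_equal(unique(by_unit$region_id), "national")
  expect_equal(by_unit$n_units, rep(80L, 8))

  by_region <- national_gini_series(panel, "physicians", units = "region")
  expect_equal(by_region$n_units, rep(8L, 8))
  # regions-as-units equals a direct Gini over region totals
  tot <- panel |>
    dplyr::filter(year == 2000) |>
    dplyr::group_by(region_id) |>
    dplyr::summarise(pop = sum(population), prov = sum(physicians))
  expect_equal(by_region$gini[by_region$year == 2000],
               gini_pairwise(tot$pop, tot$prov), tolerance = 1e-12)

  # within-region inequality exceeds none of its parts trivially; instead
  # check the by-unit national Gini is at least the by-region one
  expect_true(all(by_unit$gini >= by_region$gini - 1e-12))
})

test_that("gini panel CSV round-trips through the package readers", {
  cfg <- small_synth_config(seed = 31)
  gp <- suppressMessages(gini_panel(generate_panel(cfg)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_gini_panel(gp, path)
  back <- read_gini_panel(path)
  expect_equal(as.data.frame(back), as.data.frame(gp))
})
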