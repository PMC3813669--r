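test_that("CSV reader maps columns, preserves rows, and reports bad input", {
  csv <- paste(
    "region_id,unit_id,year,population,child_population,physicians,pediatricians",
    "A,m1,1996,100,20,1,0",
    "A,m2,1996,300,50,3,1",
    "B,m3,1996,600,90,9,2",
    sep = "\n"
  )
  panel <- read_unit_year_table(I(csv))
  expect_s3_class(panel, "unit_year_panel")
  expect_equal(nrow(panel), 3L)
  expect_equal(panel$unit_id, c("m1", "m2", "m3"))
  expect_equal(panel$population, c(100, 300, 600))

  # renamed headers resolved through the column map
  csv2 <- gsub("population", "pop", csv, fixed = TRUE)
  csv2 <- gsub("child_pop", "kids", csv2, fixed = TRUE)
  panel2 <- read_unit_year_table(
    I(csv2), unit_year_columns(population = "pop", child_population = "kids"))
  expect_equal(panel2$child_population, panel$child_population)

  # missing column -> schema error naming the column
  csv3 <- paste(
    "region_id,unit_id,year,child_population,physicians,pediatricians",
    "A,m1,1996,20,1,0", sep = "\n")
  expect_error(read_unit_year_table(I(csv3)), "population")

  # non-numeric count -> parse error with the row number
  csv4 <- sub("300", "lots", csv)
  expect_error(read_unit_year_table(I(csv4)), "row 2")
})

test_that("write-then-read is the identity on generated panels", {
  cfg <- small_synth_config(count_mode = "poisson", seed = 11)
  panel <- generate_panel(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_unit_year_table(panel, path)
  back <- read_unit_year_table(path)
  expect_equal(as.data.frame(back), as.data.frame(panel))
})

test_that("panel construction enforces the record invariants", {
  expect_error(
    unit_year_panel("A", "m1", 1996, population = -5, child_population = 0,
                    physicians = 0, pediatricians = 0),
    "negative")
  expect_error(
    unit_year_panel("A", "m1", 1996, population = 10, child_population = 20,
                    physicians = 0, pediatricians = 0),
    "child_population")
  expect_error(
    unit_year_panel(c("A", "A"), c("m1", "m1"), c(1996, 1996),
                    population = c(1, 1), child_population = c(0, 0),
                    physicians = c(0, 0), pediatricians = c(0, 0)),
    "Duplicate")
})

test_that("crosswalk merging is additive and conserves region totals", {
  panel <- toy_table()

  # identity mapping leaves the panel unchanged (up to row order)
  ident <- crosswalk(c("m1", "m2", "m3"), c("m1", "m2", "m3"))
  out <- apply_crosswalk(panel, ident)
  expect_equal(dplyr::arrange(as.data.frame(out), year, unit_id),
               dplyr::arrange(as.data.frame(panel), year, unit_id))

  # A(100,1) + B(300,3) -> C(400,4)
  cw <- crosswalk(c("m1", "m2", "m3"), c("C", "C", "m3"))
  merged <- apply_crosswalk(panel, cw)
  c96 <- merged[merged$unit_id == "C" & merged$year == 1996, ]
  expect_equal(c96$population, 400)
  expect_equal(c96$physicians, 4)
  expect_equal(c96$child_population, 70)

  # conservation oracle on random instances: region-year totals unchanged
  set.seed(202)
  for (rep in 1:10) {
    cfg <- small_synth_config(seed = rep)
    big <- generate_panel(cfg)
    units <- unique(big$unit_id)
    # random many-to-one map collapsing units within their own region
    target <- vapply(strsplit(units, "-"), `[`, character(1), 1L)
    grp <- paste0(target, "-G", sample(3, length(units), replace = TRUE))
    cw <- crosswalk(units, grp)
    merged <- apply_crosswalk(big, cw)
    tot <- function(x) {
      dplyr::summarise(
        dplyr::group_by(tibble::as_tibble(x), region_id, year),
        pop = sum(population), prov = sum(physicians), .groups = "drop")
    }
    expect_equal(tot(merged), tot(big), tolerance = 1e-12)
  }

  # unmapped ids and cross-region merges are errors
  expect_error(apply_crosswalk(panel, crosswalk("m1", "X")), "m2")
  two_regions <- unit_year_panel(
    c("A", "B"), c("m1", "m2"), c(1996L, 1996L),
    population = c(1, 1), child_population = c(0, 0),
    physicians = c(1, 1), pediatricians = c(0, 0))
  expect_error(
    apply_crosswalk(two_regions, crosswalk(c("m1", "m2"), c("C", "C"))),
    "cross region")
})

test_that("per-capita rates reproduce published one-decimal reporting", {
  # national totals with printed populations
  expect_equal(per_capita_rate(230297, 124.9e6), 184.4)
  expect_equal(per_capita_rate(14677, 17.8e6), 82.5)
  expect_equal(per_capita_rate(0, 12345), 0)

  # homogeneity: scaling numerator and denominator together changes nothing
  set.seed(5)
  for (k in stats::runif(5, 0.1, 50)) {
    expect_equal(per_capita_rate(k * 321, k * 6.54e5, reporting = FALSE),
                 per_capita_rate(321, 6.54e5, reporting = FALSE))
  }

  # half-up rounding at one decimal, not banker's rounding
  expect_equal(per_capita_rate(825, 1e6, scale = 1e5), 82.5)
  expect_error(per_capita_rate(1, 0), "positive")
})

test_that("panel validation enumerates every violation and only those", {
  cfg <- small_synth_config(seed = 3)
  clean <- generate_panel(cfg)
  rep0 <- validate_panel(clean)
  expect_true(rep0$clean)
  expect_equal(nrow(rep0$missing_cells), 0L)

  # drop one region-year
  holed <- clean[!(clean$region_id == "Tokyo" & clean$year == 2004), ]
  rep1 <- validate_panel(holed, expected_years = cfg$years)
  expect_false(rep1$clean)
  expect_equal(as.data.frame(rep1$missing_cells),
               data.frame(region_id = "Tokyo", year = 2004L))

  # duplicate a (unit, year) row
  duped <- dplyr::bind_rows(tibble::as_tibble(clean), clean[1, ])
  rep2 <- validate_panel(duped)
  expect_equal(nrow(rep2$duplicates), 1L)
  expect_equal(rep2$duplicates$unit_id, clean$unit_id[1])
})
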