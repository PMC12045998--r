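scenario_table <- function(mg, crop, country, low, med, high) {
  out <- data.frame(major_group = mg, crop = crop, country = country,
                    m_low = low, m_median = med, m_high = high,
                    stringsAsFactors = FALSE)
  class(out) <- c("scenario_mass_table", "data.frame")
  out
}

test_that("correction factors are exact scenario-to-first-guess ratios", {
  mt <- mass_table(c("H", "H"), c("Corn", "Wheat"), c("Italy", "Italy"),
                   c(100, 200))
  sc <- scenario_table(c("H", "H"), c("Corn", "Wheat"), c("Italy", "Italy"),
                       c(100, 100), c(100, 400), c(150, 500))
  K <- correction_factors(sc, mt)
  get <- function(crop, s) K$K[K$crop == crop & K$scenario == s]
  expect_equal(get("Corn", "Median"), 1)    # m_S = m_tilde
  expect_equal(get("Wheat", "Median"), 2)   # m_S = 2 m_tilde
  expect_equal(get("Wheat", "High"), 2.5)
  # full synthetic table: element-wise ratio oracle
  mt2 <- panel_first_guess("H")
  draws <- sample_parameters(load_reference_calibration()$H, 200, 6)
  sc2 <- scenario_quartiles(propagate(draws, mt2))
  K2 <- correction_factors(sc2, mt2)
  i <- match(mass_key_strings(K2), mass_key_strings(mt2))
  col <- c(Low = "m_low", Median = "m_median", High = "m_high")[K2$scenario]
  j <- match(mass_key_strings(K2), mass_key_strings(sc2))
  expect_equal(K2$K, vapply(seq_len(nrow(K2)), function(r)
    sc2[[col[r]]][j[r]], 0) / mt2$mass_kg[i], tolerance = 1e-12)
  expect_true(all(K2$K[K2$scenario == "Low"] <=
                    K2$K[K2$scenario == "High"]))

  bad <- mass_table(c("H", "H"), c("Corn", "Wheat"), c("Italy", "Italy"),
                    c(0, 200))
  expect_error(correction_factors(sc, bad), "zero first-guess")
})

test_that("applying factors rescales pixels by crop, country and group", {
  tax <- load_taxonomy()
  ct <- data.frame(id = 1:2, country = c("Italy", "France"))
  crops <- apr_raster(matrix(pcg_class_codes["Corn"], 4, 4), cellsize = 250)
  countries <- apr_raster(matrix(rep(1:2, each = 8), 4, 4), cellsize = 250)
  apr <- apr_raster(matrix(0.4, 4, 4), cellsize = 250)
  keys <- expand.grid(crop = "Corn", country = c("Italy", "France"),
                      stringsAsFactors = FALSE)

  # K = 1 everywhere: identity on applicable pixels
  sc1 <- scenario_table("H", keys$crop, keys$country, 10, 10, 10)
  mt1 <- mass_table(rep("H", 2), keys$crop, keys$country, c(10, 10))
  K1 <- correction_factors(sc1, mt1)
  out1 <- apply_correction(apr, K1, crops, countries, ct, tax, "Glyphosate")
  expect_equal(out1$values, apr$values)

  # doubling one country's factor doubles exactly those pixels
  sc2 <- scenario_table(rep("H", 2), keys$crop, keys$country,
                        c(20, 10), c(20, 10), c(20, 10))
  K2 <- correction_factors(sc2, mt1)
  out2 <- apply_correction(apr, K2, crops, countries, ct, tax, "Glyphosate")
  it <- countries$values == 1
  expect_true(all(out2$values[it] == 0.8))
  expect_true(all(out2$values[!it] == 0.4))

  # pixels outside the applicable crops and excluded pixels are nodata
  crops3 <- crops
  crops3$values[1, 1] <- NA
  out3 <- apply_correction(apr, K1, crops3, countries, ct, tax, "Glyphosate")
  expect_true(is.na(out3$values[1, 1]))
  out_wheat_only <- apply_correction(apr, K1, crops, countries, ct, tax,
                                     "Pinoxaden")  # wheat-only ai, corn raster
  expect_true(all(is.na(out_wheat_only$values)))

  # missing factor falls back to the region average for the same crop
  K_miss <- K2[K2$country != "France", ]
  expect_warning(
    out4 <- apply_correction(apr, K_miss, crops, countries, ct, tax,
                             "Glyphosate", "Median"),
    "fallback")
  # France (SEU) borrows Italy's (SEU) Corn factor
  expect_true(all(out4$values[!it] == 0.8))
})

test_that("scenario maps conserve mass and order pixel-wise", {
  fx <- pipeline_fixture()
  ct <- utils::read.csv(file.path(fx$out, "correction_factors.csv"))
  sc <- utils::read.csv(file.path(fx$out, "scenario_mass.csv"))
  crops <- read_raster(file.path(fx$out, "crops.asc"))
  countries <- read_raster(file.path(fx$out, "countries.asc"))
  tax <- load_taxonomy()
  s <- fx$scenario
  ctab <- data.frame(id = seq_along(s$countries), country = s$countries)

  for (ai in c("Glyphosate", "Chlorpyrifos")) {
    maps <- lapply(c("Low", "Median", "High"), function(sn)
      read_raster(file.path(fx$out, "maps", paste0(ai, "_", sn, ".asc"))))
    # pixel-wise scenario ordering
    expect_true(all(maps[[1]]$values <= maps[[2]]$values, na.rm = TRUE))
    expect_true(all(maps[[2]]$values <= maps[[3]]$values, na.rm = TRUE))
    # nodata exactly on excluded/non-applicable crop pixels
    row <- tax[tax$ai_name == ai, ]
    cls <- names(pcg_class_codes)[match(crops$values, pcg_class_codes)]
    applicable <- !is.na(cls) & cls %in% row$applicable_crops[[1]]
    expect_true(all(is.na(maps[[2]]$values[!applicable])))
  }

  # mass closure: sum of APR_S x cell area over an mg's ais equals m_mg,S
  area <- cell_area_ha(crops)
  cls <- names(pcg_class_codes)[match(crops$values, pcg_class_codes)]
  ctry <- ctab$country[match(countries$values, ctab$id)]
  for (mg in unique(sc$major_group)) {
    ais <- s$ai_list[tax$major_group[match(s$ai_list, tax$ai_name)] == mg]
    for (sn in c("Low", "Median", "High")) {
      col <- c(Low = "m_low", Median = "m_median", High = "m_high")[[sn]]
      acc <- new.env()
      for (ai in ais) {
        m <- read_raster(file.path(fx$out, "maps", paste0(ai, "_", sn, ".asc")))
        ok <- !is.na(m$values)
        key <- paste(calibration_crop(cls[ok]), ctry[ok], sep = "|")
        sums <- tapply(m$values[ok] * area, key, sum)
        for (k in names(sums))
          assign(k, sums[[k]] + mget(k, acc, ifnotfound = 0)[[1]], acc)
      }
      sub <- sc[sc$major_group == mg, ]
      for (r in seq_len(nrow(sub))) {
        k <- paste(sub$crop[r], sub$country[r], sep = "|")
        got <- mget(k, acc, ifnotfound = NA)[[1]]
        if (!is.na(got) && sub[[col]][r] > 0)
          expect_equal(got, sub[[col]][r], tolerance = 1e-6)
      }
    }
  }
})

test_that("scenario maps round-trip through files with deterministic names", {
  g1 <- apr_raster(matrix(stats::runif(9), 3, 3), cellsize = 250)
  attr(g1, "ai") <- "2,4-d"; attr(g1, "scenario") <- "Low"
  g2 <- apr_raster(matrix(stats::runif(9), 3, 3), cellsize = 250)
  attr(g2, "ai") <- "Glyphosate"; attr(g2, "scenario") <- "High"
  out <- tempfile("maps")
  paths <- write_scenario_maps(list(g1, g2), out)
  expect_length(list.files(out, pattern = "\\.asc$"), 2)
  expect_true(file.exists(file.path(out, "2_4-d_Low.asc")))
  back <- read_raster(file.path(out, "Glyphosate_High.asc"))
  expect_raster_equal(back, g2, tolerance = 1e-9)
})
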