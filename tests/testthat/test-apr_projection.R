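test_that("nearest-neighbour projection matches a brute-force search", {
  # constant coarse field projects to a constant fine field
  coarse <- apr_raster(matrix(3.2, 2, 2), xmin = -5, ymax = 105, cellsize = 60)
  target <- apr_raster(matrix(0, 10, 10), xmin = 0, ymax = 100, cellsize = 10)
  expect_true(all(project_apr(coarse, target)$values == 3.2))

  # identical geometry is the identity
  set.seed(3)
  g <- apr_raster(matrix(stats::runif(100), 10, 10), xmin = 0, ymax = 100,
                  cellsize = 10)
  expect_equal(project_apr(g, g)$values, g$values)

  # brute-force oracle over all (fine, coarse) centre pairs
  brute <- function(coarse, target) {
    xt <- coarse$xmin + (seq_len(ncol(coarse$values)) - 0.5) * coarse$cellsize
    yt <- coarse$ymax - (seq_len(nrow(coarse$values)) - 0.5) * coarse$cellsize
    out <- matrix(NA_real_, nrow(target$values), ncol(target$values))
    for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
      x <- target$xmin + (j - 0.5) * target$cellsize
      y <- target$ymax - (i - 0.5) * target$cellsize
      d <- outer(yt, xt, function(yy, xx) (xx - x)^2 + (yy - y)^2)
      out[i, j] <- coarse$values[which(d == min(d))[1]]
    }
    out
  }
  set.seed(9)
  coarse2 <- apr_raster(matrix(stats::runif(6), 2, 3), xmin = -7.3, ymax = 108.9,
                        cellsize = 55)
  expect_equal(project_apr(coarse2, target)$values, brute(coarse2, target))

  # nodata propagates
  vc <- matrix(stats::runif(4), 2, 2); vc[1, 1] <- NA
  coarse3 <- apr_raster(vc, xmin = 0, ymax = 100, cellsize = 50)
  proj <- project_apr(coarse3, target)
  expect_true(all(is.na(proj$values[1:5, 1:5])))
  expect_false(anyNA(proj$values[6:10, 1:10]))

  # projection onto its own grid is idempotent
  p1 <- project_apr(coarse2, target)
  expect_equal(project_apr(p1, target)$values, p1$values)

  # disjoint extents refused
  far <- apr_raster(matrix(0, 5, 5), xmin = 1e6, ymax = 1e6, cellsize = 10)
  expect_error(project_apr(coarse2, far), "beyond the coarse grid")
  wrong_crs <- apr_raster(matrix(1, 2, 2), xmin = 0, ymax = 100, cellsize = 50,
                          crs = 4326)
  expect_error(project_apr(wrong_crs, target), "CRS")
})

test_that("authorization masking zeroes banned countries exactly", {
  b <- gen_crop_raster(tiny_scenario(n_countries = 2L))
  fine <- apr_raster(matrix(1.5, 100, 100), xmin = 0, ymax = 5000, cellsize = 50)
  ct <- b$country_table

  all_ok <- data.frame(ai_name = "Glyphosate", country = ct$country,
                       approved = TRUE)
  expect_equal(apply_authorization(fine, "Glyphosate", all_ok, b$countries,
                                   ct)$values, fine$values)

  none <- transform(all_ok, approved = FALSE)
  expect_true(all(apply_authorization(fine, "Glyphosate", none, b$countries,
                                      ct)$values == 0))

  one_ban <- all_ok
  one_ban$approved[one_ban$country == ct$country[1]] <- FALSE
  masked <- apply_authorization(fine, "Glyphosate", one_ban, b$countries, ct)
  in_banned <- b$countries$values == ct$id[1]
  expect_true(all(masked$values[in_banned] == 0))
  expect_true(all(masked$values[!in_banned] == 1.5))
  # masking never increases mass
  expect_lte(sum(masked$values), sum(fine$values))

  expect_error(apply_authorization(fine, "Glyphosate", all_ok[-1, ],
                                   b$countries, ct), "no authorization record")
})

test_that("first-guess mass accumulates rate x area over applicable crops", {
  tax <- load_taxonomy()
  ct <- data.frame(id = 1L, country = "Italy")
  crops <- apr_raster(matrix(pcg_class_codes["Corn"], 2, 2), cellsize = 250)
  countries <- apr_raster(matrix(1, 2, 2), cellsize = 250)
  apr <- apr_raster(matrix(0.2, 2, 2), cellsize = 250)

  mt <- first_guess_mass(list(Glyphosate = apr), crops, countries, ct, tax)
  expect_equal(mt$mass_kg, 4 * 0.2 * 6.25)   # 5 kg
  expect_identical(mt$crop, "Corn")
  expect_identical(mt$major_group, "H")

  # zero rates give zero mass
  z <- first_guess_mass(list(Glyphosate = apr_raster(matrix(0, 2, 2),
                                                     cellsize = 250)),
                        crops, countries, ct, tax)
  expect_equal(z$mass_kg, 0)

  # crops outside the applicable set contribute nothing: Pinoxaden is
  # wheat-only, the raster is corn
  expect_error(first_guess_mass(list(Pinoxaden = apr), crops, countries, ct,
                                tax), "no mass accumulated")
})

test_that("first-guess mass matches a per-pixel brute-force accumulation", {
  tax <- load_taxonomy()
  set.seed(21)
  nr <- 20
  cls <- sample(c(pcg_class_codes, NA), nr * nr, replace = TRUE)
  crops <- apr_raster(matrix(cls, nr, nr), cellsize = 250)
  cid <- sample(1:3, nr * nr, replace = TRUE)
  countries <- apr_raster(matrix(cid, nr, nr), cellsize = 250)
  ct <- data.frame(id = 1:3, country = c("Italy", "France", "Poland"))
  rates <- list(
    Glyphosate = apr_raster(matrix(stats::runif(nr * nr), nr, nr), cellsize = 250),
    Azoxystrobin = apr_raster(matrix(stats::runif(nr * nr), nr, nr), cellsize = 250))

  mt <- first_guess_mass(rates, crops, countries, ct, tax)

  # oracle: loop over every pixel and ingredient
  acc <- list()
  for (ai in names(rates)) {
    row <- tax[tax$ai_name == ai, ]
    for (i in seq_len(nr * nr)) {
      cl <- names(pcg_class_codes)[match(cls[i], pcg_class_codes)]
      if (is.na(cl) || !cl %in% row$applicable_crops[[1]]) next
      key <- paste(row$major_group, calibration_crop(cl),
                   ct$country[cid[i]], sep = "|")
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) +
        rates[[ai]]$values[i] * 6.25
    }
  }
  expect_setequal(paste(mt$major_group, mt$crop, mt$country, sep = "|"),
                  names(acc))
  for (k in names(acc))
    expect_equal(mt$mass_kg[paste(mt$major_group, mt$crop, mt$country,
                                  sep = "|") == k], acc[[k]],
                 tolerance = 1e-12)

  # additivity: totals equal the sum over a partition of one country's pixels
  sel <- cid == 1
  cid_split <- cid
  cid_split[sel][seq_len(sum(sel)) %% 2 == 0] <- 4L
  ct4 <- rbind(ct, data.frame(id = 4L, country = "Spain"))
  mt_split <- first_guess_mass(rates, crops,
                               apr_raster(matrix(cid_split, nr, nr),
                                          cellsize = 250), ct4, tax)
  for (mg in unique(mt$major_group)) for (cr in unique(mt$crop)) {
    orig <- mt$mass_kg[mt$major_group == mg & mt$crop == cr &
                         mt$country == "Italy"]
    parts <- mt_split$mass_kg[mt_split$major_group == mg & mt_split$crop == cr &
                                mt_split$country %in% c("Italy", "Spain")]
    if (length(orig)) expect_equal(sum(parts), orig, tolerance = 1e-12)
  }
})
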