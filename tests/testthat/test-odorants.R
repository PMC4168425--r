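test_that("compute_oav forms the concentration/threshold ratio and its log", {
  benzene <- odorant("benzene", threshold = 2.13, molecular_weight = 78.11)

  # threshold-level sample: OAV exactly 1
  at_thr <- compute_oav(concentration(2.13, "mg/m3"), benzene)
  expect_equal(at_thr$oav, 1)
  expect_equal(at_thr$ln_oav, 0)

  # 61.3 g/m3 against a 2.13 mg/m3 threshold: 61300 / 2.13
  high <- compute_oav(concentration(61.3, "g/m3"), benzene)
  expect_equal(high$oav, 61300 / 2.13)
  expect_equal(high$ln_oav, log(61300 / 2.13))
  expect_equal(round(high$ln_oav, 2), 10.27)

  eb <- odorant("ethylbenzene", threshold = 0.25)
  expect_equal(compute_oav(0.25, eb)$ln_oav, 0)

  expect_error(compute_oav(concentration(0, "mg/m3"), benzene),
               class = "odormix_invalid_input")
  # ppm sample without molecular weight cannot be converted
  no_mw <- odorant("mystery", threshold = 1)
  expect_error(compute_oav(concentration(5, "ppm"), no_mw),
               class = "odormix_missing_data")
})

test_that("compute_oav is homogeneous in concentration and threshold", {
  set.seed(11)
  for (i in 1:20) {
    c0 <- runif(1, 0.1, 100)
    thr <- runif(1, 0.01, 10)
    k <- runif(1, 0.1, 1000)
    base <- compute_oav(c0, odorant("x", thr))
    scaled <- compute_oav(c0 * k, odorant("x", thr * k))
    expect_equal(scaled$oav, base$oav)
  }
})

test_that("unit conversion follows the ideal-gas relation and round-trips", {
  # molecular weight equal to the molar volume: mg/m3 and ppm coincide
  self <- odorant("ideal", 1, molecular_weight = 24.45)
  expect_equal(
    convert_concentration(concentration(1000, "mg/m3"), "ppm", self)$value,
    1000)

  eb <- odorant("ethylbenzene", 0.25, molecular_weight = 106.17)
  ppm <- convert_concentration(concentration(0.25, "mg/m3"), "ppm", eb)
  expect_equal(ppm$value, 0.25 * 24.45 / 106.17)
  expect_equal(round(ppm$value, 4), 0.0576)

  expect_equal(convert_concentration(concentration(5.8, "g/m3"), "mg/m3")$value,
               5800)

  # round trip mg/m3 -> ppm -> mg/m3 within 1e-12 relative error
  set.seed(5)
  for (i in 1:10) {
    v <- runif(1, 1e-3, 1e4)
    mw <- runif(1, 20, 300)
    od <- odorant("x", 1, molecular_weight = mw)
    back <- convert_concentration(
      convert_concentration(concentration(v, "mg/m3"), "ppm", od),
      "mg/m3", od)$value
    expect_equal(back, v, tolerance = 1e-12)
  }

  expect_error(
    convert_concentration(concentration(1, "mg/m3"), "ppm", odorant("x", 1)),
    class = "odormix_missing_data")
})

test_that("panel threshold is initial concentration over mean dilution multiple", {
  expect_equal(threshold_from_panel(100, 100)$value, 1)
  expect_equal(threshold_from_panel(100, c(50, 100, 150))$value, 1)
  expect_equal(threshold_from_panel(64, c(32, 32))$value, 2)

  # geometric option for olfactometry-standard averaging
  expect_equal(threshold_from_panel(100, c(50, 200), average = "geometric")$value,
               100 / 100)

  # scale equivariance in the initial concentration
  set.seed(7)
  mult <- runif(5, 2, 500)
  t1 <- threshold_from_panel(10, mult)$value
  t2 <- threshold_from_panel(10 * 13.5, mult)$value
  expect_equal(t2, t1 * 13.5)

  expect_error(threshold_from_panel(100, numeric(0)),
               class = "odormix_invalid_input")
  expect_error(threshold_from_panel(100, c(10, 0.5)),
               class = "odormix_invalid_input")
})

test_that("odorant tables round-trip through CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,cas,molecular_weight,threshold_mg_m3",
               "benzene,71-43-2,78.11,2.13",
               "toluene,,,1.67"), f)
  ods <- read_odorants(f)
  expect_named(ods, c("benzene", "toluene"))
  expect_equal(ods$benzene$threshold, 2.13)
  expect_equal(ods$benzene$molecular_weight, 78.11)
  expect_null(ods$toluene$molecular_weight)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("name,foo\nx,1", bad)
  expect_error(read_odorants(bad), class = "odormix_invalid_input")
})
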