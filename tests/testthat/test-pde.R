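test_that("the transform maps OI and lnOAV pairs into curve space", {
  # benzene+toluene sample at lnOAV 3.36 / 2.24: mixing ratio 0.6
  m <- data.frame(ln_oav_a = 3.36, ln_oav_b = 2.24, oi = 4.8)
  tr <- pde_transform(m, "a")
  expect_equal(tr$x, 0.6)
  expect_equal(tr$oi_m, 4.8 / 5.6)

  tr2 <- pde_transform(data.frame(ln_oav_a = 2, ln_oav_b = 2, oi = 4), "a")
  expect_equal(tr2$x, 0.5)
  expect_equal(tr2$oi_m, 1)

  tr3 <- pde_transform(data.frame(ln_oav_a = 3, ln_oav_b = 1, oi = 2), "a")
  expect_equal(tr3$x, 0.75)
  expect_equal(tr3$oi_m, 0.5)
})

test_that("transform rejects sub-threshold components and reconstructs exactly", {
  expect_error(pde_transform(data.frame(ln_oav_a = -0.5, ln_oav_b = 2, oi = 3), "a"),
               class = "odormix_subthreshold")
  expect_error(pde_transform(data.frame(ln_oav_a = 0, ln_oav_b = 2, oi = 3), "a"),
               class = "odormix_subthreshold")

  df <- random_mixture_df(50, seed = 17)
  tra <- pde_transform(df, "a")
  trb <- pde_transform(df, "b")
  total <- df$ln_oav_a + df$ln_oav_b
  # x_a + x_b = 1 and oi_m * total = oi, exactly
  expect_equal(tra$x + trb$x, rep(1, 50))
  expect_equal(tra$oi_m * total, df$oi)
  # axis can be named by odorant
  expect_equal(pde_transform(df, "beta")$x, trb$x)
  expect_error(pde_transform(df, "gamma"), class = "odormix_invalid_input")
})

test_that("the tangent decomposition reproduces the worked benzene+toluene example", {
  dec <- tangent_decompose(curve_bt(), 0.6)
  expect_equal(round_half_up(dec$y_prime, 2), 0.83)
  expect_equal(round_half_up(dec$slope, 2), 0.23)

  # intercept identities hold exactly
  expect_equal(dec$oi_axis_m, (1 - 0.6) * dec$slope + dec$y_prime)
  expect_equal(dec$oi_other_m, -0.6 * dec$slope + dec$y_prime)
  # tangent-line identity: lnOAV-share-weighted intercepts return y'
  expect_equal(0.6 * dec$oi_axis_m + 0.4 * dec$oi_other_m, dec$y_prime)

  expect_error(tangent_decompose(curve_bt(), 1), class = "odormix_domain_error")
  expect_error(tangent_decompose(curve_bt(), -0.2), class = "odormix_domain_error")
})

test_that("a horizontal tangent gives both components the same partial OI", {
  cv <- interaction_curve(c(2, -2, 1.3))   # vertex at x = 0.5
  dec <- tangent_decompose(cv, 0.5)
  expect_equal(dec$slope, 0)
  expect_equal(dec$oi_axis_m, dec$oi_other_m)
  expect_equal(dec$oi_axis_m, dec$y_prime)
})

test_that("negative partial differential OIs are returned with an advisory flag", {
  dec <- tangent_decompose(curve_te(), 0.97)
  expect_true(dec$oi_other_m < 0)
  expect_true(dec$negative)
  expect_output(print(dec), "negative")
})

test_that("prediction reproduces the published mixture predictions", {
  # toluene+ethylbenzene, ethylbenzene on the axis
  p1 <- predict_oi(curve_te(), 3.36, 3.54)
  expect_equal(round_half_up(p1$predicted_oi, 1), 5.3)
  # ethylbenzene+o-xylene
  p2 <- predict_oi(curve_eox(), 1.34, 3.82)
  expect_equal(round_half_up(p2$predicted_oi, 1), 4.5)
  expect_equal(round_half_up(p2$oi_a_m, 2), 0.05)
  expect_equal(round_half_up(p2$oi_b_m, 2), 1.17)

  # a flat curve has no interaction structure: OI = c * total lnOAV
  flat <- interaction_curve(c(0, 0, 0.8))
  expect_equal(predict_oi(flat, 2.5, 1.5)$predicted_oi, 0.8 * 4)

  expect_error(predict_oi(curve_te(), -1, 2), class = "odormix_subthreshold")
})

test_that("predicted OI equals total lnOAV times the curve value", {
  set.seed(23)
  for (i in 1:30) {
    cv <- interaction_curve(c(runif(1, 0.5, 3), runif(1, -3, -0.5),
                              runif(1, 0.8, 2)))
    la <- runif(1, 0.2, 6); lb <- runif(1, 0.2, 6)
    p <- predict_oi(cv, la, lb)
    expect_equal(p$predicted_oi, (la + lb) * curve_value(cv, p$x),
                 tolerance = 1e-10)
  }
})

test_that("axis orientation is consistent: mirrored curve, swapped axis", {
  # f fitted with component a on the axis vs g(x) = f(1 - x) with b on it
  co <- c(1.7, -2.1, 1.4)
  f <- interaction_curve(co, components = c("p", "q"), axis_component = "p")
  # mirror: g(x) = a2 x^2 - (2 a2 + a1) x + (a2 + a1 + a0)
  g <- interaction_curve(c(co[1], -2 * co[1] - co[2], sum(co)),
                         components = c("p", "q"), axis_component = "q")
  set.seed(4)
  for (i in 1:10) {
    la <- runif(1, 0.3, 5); lb <- runif(1, 0.3, 5)
    pf <- predict_oi(f, la, lb)
    pg <- predict_oi(g, la, lb)
    expect_equal(pf$predicted_oi, pg$predicted_oi, tolerance = 1e-10)
    expect_equal(pf$oi_a_m, pg$oi_a_m, tolerance = 1e-10)
    expect_equal(pf$oi_b_m, pg$oi_b_m, tolerance = 1e-10)
  }
})

test_that("fit_pde runs the whole chain from an observation table", {
  df <- random_mixture_df(22, seed = 31)
  tr <- pde_transform(df, "alpha")
  df$oi <- (df$ln_oav_a + df$ln_oav_b) * quad(c(1.9, -2.1, 1.4), tr$x)
  cv <- fit_pde(df, axis_component = "alpha")
  expect_equal(unname(cv$coefficients), c(1.9, -2.1, 1.4), tolerance = 1e-8)
  expect_equal(cv$axis_component, "alpha")
  expect_equal(cv$label, "alpha+beta")

  auto <- suppressWarnings(fit_pde(df, axis_component = "alpha",
                                   family = "auto"))
  expect_equal(auto$family, "quadratic")

  ext <- fit_pde(df, extended = TRUE)
  expect_true(ext$symmetric)
})
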