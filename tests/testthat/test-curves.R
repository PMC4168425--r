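test_that("noise-free points reproduce their generating curve exactly", {
  x <- c(0.2, 0.5, 0.8)
  cv <- fit_curve(x, quad(c(1.93, -2.09, 1.39), x))
  expect_equal(unname(cv$coefficients), c(1.93, -2.09, 1.39), tolerance = 1e-10)
  expect_equal(cv$r_squared, 1, tolerance = 1e-10)

  flat <- fit_curve(seq(0.1, 0.9, by = 0.2), rep(0.7, 5))
  expect_equal(unname(flat$coefficients), c(0, 0, 0.7), tolerance = 1e-12)
})

test_that("the quadratic fit matches a brute-force normal-equations oracle", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    x <- runif(n, 0.05, 0.95)
    y <- runif(n, 0, 2)
    cv <- fit_curve(x, y)
    expect_equal(unname(cv$coefficients), unname(quad_normal_equations(x, y)),
                 tolerance = 1e-8)
  }
})

test_that("noisy quadratic data recover the true coefficients", {
  # 22-point design, noise sd 0.05: estimates are unbiased and each
  # coefficient's average absolute error stays well inside sampling noise
  truth <- c(2.36, -2.36, 1.36)
  x <- seq(0.08, 0.92, length.out = 22)
  coefs <- t(vapply(1:40, function(i) {
    set.seed(600 + i)
    fit_curve(x, quad(truth, x) + rnorm(22, 0, 0.05))$coefficients
  }, numeric(3)))
  expect_true(all(abs(colMeans(coefs) - truth) < 0.05))
  expect_true(all(colMeans(abs(sweep(coefs, 2, truth))) < 0.15))
})

test_that("degenerate designs are rejected with informative errors", {
  expect_error(fit_curve(rep(0.5, 5), runif(5)),
               class = "odormix_degenerate_design")
  expect_error(fit_curve(c(0.2, 0.8), c(1, 2)),
               class = "odormix_invalid_input") # too few points for 3 coefs
  expect_error(fit_curve(c(-0.1, 0.5, 0.9), c(1, 2, 3), family = "logarithmic"),
               class = "odormix_domain_error")
})

test_that("family comparison ranks by fit quality with parsimony tie-breaks", {
  set.seed(12)
  x <- seq(0.05, 0.95, length.out = 30)

  # data generated from a quadratic: quadratic ranked first
  yq <- quad(c(1.9, -2.1, 1.4), x) + rnorm(30, 0, 0.02)
  fits <- suppressWarnings(compare_families(x, yq))
  expect_equal(fits[[1]]$family, "quadratic")

  # perfectly linear data: quadratic and cubic tie at R^2 = 1 with leading
  # coefficients ~ 0; parsimony puts the quadratic ahead of the cubic
  yl <- 0.5 + 0.3 * x
  fl <- suppressWarnings(compare_families(x, yl,
                                          families = c("quadratic", "cubic")))
  expect_equal(fl[[1]]$family, "quadratic")
  expect_lt(abs(fl[[1]]$coefficients[["a2"]]), 1e-8)
  expect_lt(abs(fl[[2]]$coefficients[["a3"]]), 1e-8)

  # exponential data: the exponential family fits nearly perfectly
  ye <- exp(-x) + rnorm(30, 0, 0.002)
  fe <- suppressWarnings(compare_families(x, ye))
  expect_gt(fe[["exponential"]]$r_squared, 0.99)

  # x <= 0 excludes logarithmic/power with a warning, not an error
  x0 <- c(0, seq(0.1, 0.9, length.out = 9))
  w <- capture_warnings(f0 <- compare_families(x0, quad(c(2, -2, 1.3), x0)))
  expect_true(any(grepl("skipped", w)))
  expect_false(any(c("logarithmic", "power") %in% names(f0)))
})

test_that("closed-form values and slopes agree with numerical differentiation", {
  curves <- list(
    interaction_curve(c(1.9, -2.1, 1.4), family = "quadratic"),
    interaction_curve(c(0.4, 1.2, -0.9, 1.1), family = "cubic"),
    interaction_curve(c(1.1, -0.35), family = "logarithmic"),
    interaction_curve(c(1.4, -0.8), family = "exponential"),
    interaction_curve(c(0.9, 0.6), family = "power"),
    interaction_curve(c(2.0, 4.0, 0.5), family = "logistic")
  )
  h <- 1e-6
  for (cv in curves) {
    for (x in c(0.2, 0.5, 0.8)) {
      num <- (curve_value(cv, x + h) - curve_value(cv, x - h)) / (2 * h)
      expect_equal(curve_slope(cv, x), num, tolerance = 1e-5)
    }
  }
})

test_that("the symmetric fit is invariant under axis mirroring", {
  set.seed(9)
  x <- runif(40, 0.05, 0.95)
  y <- quad(c(2.36, -2.36, 1.36), x) + rnorm(40, 0, 0.05)
  cv <- fit_extended(x, y)
  cv_mir <- fit_extended(1 - x, y)
  expect_equal(cv$coefficients, cv_mir$coefficients, tolerance = 1e-10)
  expect_true(cv$symmetric)
  expect_equal(cv$coefficients[["a1"]], -cv$coefficients[["a2"]])

  # noise-free symmetric points: exact recovery
  xs <- seq(0.1, 0.9, length.out = 9)
  exact <- fit_extended(xs, quad(c(2.36, -2.36, 1.36), xs))
  expect_equal(unname(exact$coefficients), c(2.36, -2.36, 1.36),
               tolerance = 1e-10)
})

test_that("prediction intervals behave like OLS intervals", {
  x <- seq(0.1, 0.9, length.out = 10)

  # exact fit: zero residual variance, zero-width interval
  cv0 <- fit_curve(x, quad(c(2, -2, 1.3), x))
  pi0 <- prediction_interval(cv0, c(0.3, 0.6))
  expect_equal(pi0$upper - pi0$lower, c(0, 0), tolerance = 1e-7)

  set.seed(31)
  cv <- fit_curve(x, quad(c(2, -2, 1.3), x) + rnorm(10, 0, 0.1))
  # leverage widens the interval outside the data's x-range
  pic <- prediction_interval(cv, 0.5)
  pio <- prediction_interval(cv, 1.4)
  expect_gt(pio$upper - pio$lower, pic$upper - pic$lower)

  # cross-check one interval against the textbook formula
  X <- cbind(1, x, x^2)
  beta <- solve(t(X) %*% X, t(X) %*% cv$data$y)
  res <- cv$data$y - X %*% beta
  s2 <- sum(res^2) / (10 - 3)
  x0 <- c(1, 0.4, 0.16)
  half <- qt(0.95, 7) * sqrt(s2 * (1 + t(x0) %*% solve(t(X) %*% X) %*% x0))
  pim <- prediction_interval(cv, 0.4, level = 0.90)
  expect_equal(pim$upper - pim$fit, as.numeric(half), tolerance = 1e-8)

  # three points, three coefficients: no residual dof
  cv3 <- fit_curve(c(0.2, 0.5, 0.8), c(1, 0.8, 1.1))
  expect_error(prediction_interval(cv3, 0.5),
               class = "odormix_interval_undefined")
  # iterative families carry no linear-model design
  xg <- seq(0.1, 0.9, length.out = 15)
  cve <- fit_curve(xg, 1.4 * exp(-0.8 * xg), family = "exponential")
  expect_error(prediction_interval(cve, 0.5), class = "odormix_invalid_input")
})
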