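test_that("relative survival of a series against itself is identically 1", {
  s <- tibble::tibble(time_h = seq(0, 48, 8), count = c(100, 90, 70, 60, 50, 40, 30))
  rs <- relative_survival(s, s)
  expect_true(all(rs$relative == 1))
  expect_equal(rs$relative[1], 1)
})

test_that("halving counts against a constant control gives relative 0.5", {
  s <- tibble::tibble(time_h = c(0, 24, 48), count = c(100, 75, 50))
  ctrl <- tibble::tibble(time_h = c(0, 24, 48), count = c(100, 100, 100))
  rs <- relative_survival(s, ctrl)
  expect_equal(rs$relative, c(1, 0.75, 0.5))
})

test_that("mismatched or degenerate series are rejected", {
  s <- tibble::tibble(time_h = c(0, 24), count = c(10, 5))
  expect_error(relative_survival(s, tibble::tibble(time_h = c(0, 20),
                                                   count = c(10, 5))),
               "timepoints differ")
  expect_error(relative_survival(tibble::tibble(time_h = c(0, 24),
                                                count = c(0, 5)), s),
               "> 0")
})

test_that("AUC matches closed forms and is linear", {
  const <- tibble::tibble(time_h = c(0, 48), relative = c(1, 1))
  expect_equal(survival_auc(const), 48)
  lin <- tibble::tibble(time_h = c(0, 48), relative = c(1, 0.5))
  expect_equal(survival_auc(lin), 36)
  # piecewise-linear quadrature oracle: integrate the interpolant
  withr::with_seed(3, {
    t <- sort(c(0, runif(6, 0, 48), 48))
    y <- runif(8, 0.2, 1.2)
  })
  series <- tibble::tibble(time_h = t, relative = y)
  oracle <- stats::integrate(stats::approxfun(t, y), 0, 48,
                             subdivisions = 1000L)$value
  expect_equal(survival_auc(series), oracle, tolerance = 1e-6)
  scaled <- series; scaled$relative <- 2.5 * scaled$relative
  expect_equal(survival_auc(scaled), 2.5 * survival_auc(series))
  expect_error(survival_auc(series[1, ]), "at least 2")
})

test_that("simulated linear decline to one-half reproduces its AUC", {
  # rates chosen so the mean relative survival is linear from 1 to 0.5:
  # control flat, arm counts set to the linear curve directly
  t <- seq(0, 48, by = 8)
  arm <- tibble::tibble(time_h = t, count = 1000 * (1 - 0.5 * t / 48))
  ctrl <- tibble::tibble(time_h = t, count = rep(1000, length(t)))
  expect_equal(survival_auc(relative_survival(arm, ctrl)), 36)
})

test_that("a noiseless 4PL is recovered to numerical precision", {
  conc <- c(0, 0.1, 0.5, 1, 2, 5, 10, 50)
  lx <- log10(pmax(conc, 0.001))
  y <- 10 + (100 - 10) / (1 + 10^(1 * (lx - log10(5))))
  fit <- fit_dose_response(tibble::tibble(conc = conc, response = y))
  expect_true(fit$converged)
  expect_equal(fit$ic50, 5, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  expect_equal(fit$top, 100, tolerance = 1e-5)
  expect_false(fit$extrapolated)
})

test_that("IC50 is recovered within 20% under 5% noise across seeds", {
  conc <- rep(c(0.1, 0.25, 0.75, 2, 5, 12, 30, 80), each = 3)
  for (s in 1:5) {
    y <- 100 / (1 + 10^(1.2 * (log10(conc) - log10(5)))) +
      withr::with_seed(s, stats::rnorm(length(conc), 0, 5))
    fit <- fit_dose_response(tibble::tibble(conc = conc, response = y))
    expect_true(fit$converged)
    expect_lt(abs(fit$ic50 - 5) / 5, 0.2)
  }
})

test_that("an increasing response flips the hill sign and still converges", {
  conc <- c(0.1, 0.5, 1, 5, 10, 50)
  y <- 100 - 90 / (1 + 10^(1 * (log10(conc) - log10(3))))
  fit <- fit_dose_response(tibble::tibble(conc = conc, response = y))
  expect_true(fit$converged)
  expect_lt(fit$hill, 0)
  expect_equal(fit$ic50, 3, tolerance = 1e-4)
})

test_that("the 4PL fit is invariant to concentration units", {
  conc <- c(0.1, 0.5, 1, 5, 10, 50)
  y <- 100 / (1 + 10^(1.3 * (log10(conc) - log10(5))))
  f_um <- fit_dose_response(tibble::tibble(conc = conc, response = y))
  f_nm <- fit_dose_response(tibble::tibble(conc = conc * 1000, response = y))
  expect_equal(f_nm$ic50, 1000 * f_um$ic50, tolerance = 1e-6)
  expect_equal(f_nm$hill, f_um$hill, tolerance = 1e-6)
})

test_that("fit prerequisites are enforced and tidiers report the fit", {
  expect_error(fit_dose_response(tibble::tibble(conc = c(0, 1, 2, 3),
                                                response = 1:4)),
               "5 distinct")
  conc <- c(0, 0.1, 1, 5, 20, 100)
  y <- 100 / (1 + 10^(log10(pmax(conc, 1e-3)) - log10(5)))
  fit <- fit_dose_response(tibble::tibble(conc = conc, response = y))
  td <- generics::tidy(fit)
  expect_setequal(td$term, c("top", "bottom", "log10_ic50", "ic50", "hill"))
  gl <- generics::glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n, 6)
})
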