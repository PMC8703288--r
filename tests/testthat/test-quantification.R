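test_that("trapezoidal integration matches closed forms", {
  rt <- seq(0, 4, by = 1 / 120)
  # rectangular pulse of height h and width w
  h <- 500
  pulse <- ifelse(rt >= 1 & rt <= 2, h, 0)
  xic <- tibble::tibble(rt_min = rt, intensity = pulse)
  expect_equal(integrate_peak(xic, c(0.5, 2.5), "none"), h * 1,
               tolerance = 0.01)

  # Gaussian peak: area = A * sigma * sqrt(2 pi)
  A <- 1e4; s <- 0.05
  xg <- tibble::tibble(rt_min = rt,
                       intensity = gaussian_trace(rt, 2, s, A))
  expect_equal(integrate_peak(xg, c(1.5, 2.5), "none"),
               A * s * sqrt(2 * pi), tolerance = 0.005)

  # zero signal integrates to zero; empty window errors
  x0 <- tibble::tibble(rt_min = rt, intensity = 0)
  expect_equal(integrate_peak(x0, c(1, 2)), 0)
  expect_error(integrate_peak(xg, c(10, 11)), "empty")

  # linear baseline subtraction removes an offset ramp
  xb <- tibble::tibble(rt_min = rt,
                       intensity = 100 + 50 * rt + gaussian_trace(rt, 2, s, A))
  expect_equal(integrate_peak(xb, c(1.5, 2.5), "linear"),
               A * s * sqrt(2 * pi), tolerance = 0.005)
})

test_that("calibration fits reproduce exact and noisy lines", {
  pts <- tibble::tibble(conc_um = c(1, 2, 5, 10), area = 2 * c(1, 2, 5, 10))
  fit <- fit_calibration(pts)
  expect_equal(fit$slope, 2)
  expect_equal(fit$r, 1)
  expect_equal(fit$lod_um, 0)
  expect_equal(fit$loq_um, 0)

  # noisy series against the normal-equations oracle
  set.seed(31)
  x <- rep(c(2, 5, 10, 25, 50, 100), each = 3)
  y <- 1.27e7 * x * exp(stats::rnorm(length(x), 0, 0.05))
  fitn <- fit_calibration(tibble::tibble(conc_um = x, area = y))
  expect_equal(fitn$slope, oracle_ls_origin(x, y), tolerance = 1e-9)
  expect_equal(fitn$r, oracle_pearson_r(x, y), tolerance = 1e-9)
  expect_true(fitn$lod_um > 0 && fitn$lod_um < fitn$loq_um)
  expect_equal(fitn$loq_um / fitn$lod_um, 10 / 3.3, tolerance = 1e-9)

  expect_error(fit_calibration(pts[1:2, ]), "3 calibration points")
  expect_error(fit_calibration(tibble::tibble(conc_um = c(5, 5, 5),
                                              area = c(1, 2, 3))),
               "identical")
})

test_that("tidy and glance expose the fit in broom style", {
  pts <- tibble::tibble(conc_um = c(1, 2, 5, 10), area = 2 * c(1, 2, 5, 10))
  fit <- fit_calibration(pts, analyte_name = "demo")
  td <- generics::tidy(fit)
  expect_identical(td$term, "slope")
  expect_equal(td$estimate, 2)
  gl <- generics::glance(fit)
  expect_identical(names(gl),
                   c("slope", "r", "residual_sd", "lod_um", "loq_um", "n"))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})

test_that("calibration slope is unbiased under multiplicative noise", {
  x <- rep(c(2, 5, 10, 25, 50, 100), each = 3)
  true_slope <- 1.27e7
  set.seed(77)
  slopes <- replicate(200, {
    y <- true_slope * x * exp(stats::rnorm(length(x), -0.05^2 / 2, 0.05))
    fit_calibration(tibble::tibble(conc_um = x, area = y))$slope
  })
  bias <- mean(slopes) - true_slope
  se <- stats::sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(bias), 2 * se + 1e-9)
})

test_that("concentrations are censored against LOD and LOQ", {
  fit <- structure(list(slope = 1e7, lod_um = 2.17, loq_um = 7.15),
                   class = "calibration_fit")
  got <- concentration_from_area(c(0, 1e7, 5e7, 1e8), fit)
  expect_equal(got$conc_um, c(0, 1, 5, 10))
  expect_identical(got$censoring,
                   c("below_lod", "below_lod", "below_loq", "quantifiable"))
  # identity: area = slope * c returns c
  expect_equal(concentration_from_area(1e7 * 3.7, fit)$conc_um, 3.7)
  expect_error(concentration_from_area(-1, fit), ">= 0")
})

test_that("unit conversions to per-cell and intracellular scales", {
  expect_equal(per_cell_amount(1, cells = 1e7, extract_ml = 1, dilution = 1),
               0.1)
  expect_equal(per_cell_amount(1, cells = 2e7, extract_ml = 1, dilution = 1),
               0.05)
  expect_error(per_cell_amount(1, cells = 0), "> 0")

  expect_equal(intracellular_concentration(1, 1), 1)
  # P. minimum: 50.6 fmol/cell in 0.7116 pL is 71.1 mM
  expect_equal(intracellular_concentration(50.6, 0.7116), 71.1,
               tolerance = 1e-3)
  expect_equal(intracellular_concentration(0, 2), 0)
  expect_error(intracellular_concentration(1, 0), "> 0")

  expect_equal(cell_volume_from_shape("cylinder", d = 10, h = 10), 0.7854,
               tolerance = 1e-4)
  expect_equal(cell_volume_from_shape("sphere", d = 6), 113.10 * 1e-3,
               tolerance = 1e-4)
  expect_equal(cell_volume_from_shape("prolate_spheroid", d = 4, h = 10),
               pi / 6 * 16 * 10 * 1e-3)
  expect_error(cell_volume_from_shape("sphere", d = -1), "> 0")
  expect_error(cell_volume_from_shape("cube", d = 1))
})

test_that("noise-free experiments round-trip configured fmol/cell within 1%", {
  ana <- short_cys()
  sc <- scenario("test species", ana,
                 tibble::tibble(condition = "35 PSU",
                                analyte = ana$name,
                                fmol_per_cell = 22.3),
                 replicates = 2, biological_cv = 0,
                 cell_density_per_ml = 1e5, cell_volume_pl = 2.7875,
                 noise_cv = 0, baseline_rate = 0, run_length = 4)
  exp0 <- simulate_experiment(sc, seed = 1)
  cal <- simulate_calibration(ana, c(5, 10, 25, 50), seed = 2,
                              noise_cv = 0, baseline_rate = 0,
                              run_length = 4)
  fit <- fit_calibration(measure_calibration(cal, ana))
  q <- quantify_samples(exp0, ana, fit)
  expect_equal(q$fmol_per_cell, rep(22.3, 2), tolerance = 0.01)
  expect_equal(q$mm, rep(8.0, 2), tolerance = 0.01)
  expect_identical(unique(q$censoring), "quantifiable")
})
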