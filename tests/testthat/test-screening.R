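test_that("XIC extraction isolates the target window", {
  ana <- short_cys()
  run <- short_run(amounts = 10, noise_cv = 0, baseline_rate = 0)
  xic <- extract_xic(run, ana$mz, tol_ppm = 5)
  expect_equal(xic$rt_min[which.max(xic$intensity)], 2, tolerance = 0.01)

  # a window elsewhere sees nothing
  far <- extract_xic(run, 160.0, tol_ppm = 5)
  expect_true(all(far$intensity == 0))
  expect_error(extract_xic(run, 156, tol_ppm = 0), "tol_ppm")
  expect_error(extract_xic(run[0, ], 156), "empty run")
})

test_that("co-eluting peaks 50 ppm apart resolve into separate XICs", {
  rt <- seq(0, 4, by = 1 / 120)
  mz1 <- 156.03251
  mz2 <- mz1 * (1 + 50e-6)
  run <- manual_run(list(
    list(mz = mz1, intensity = gaussian_trace(rt, 2, 0.05, 1000)),
    list(mz = mz2, intensity = gaussian_trace(rt, 2, 0.05, 500))
  ), rt)
  x1 <- extract_xic(run, mz1, tol_ppm = 5)
  x2 <- extract_xic(run, mz2, tol_ppm = 5)
  expect_equal(max(x1$intensity), 1000, tolerance = 1e-6)
  expect_equal(max(x2$intensity), 500, tolerance = 1e-6)
})

test_that("feature detection finds exactly the planted analytes", {
  panel <- dplyr::bind_rows(short_gbt(1), short_cys(2),
                            analyte("ectoine", "C6H10N2O2", rt_min = 3,
                                    response_factor = 2.96e8))
  run <- simulate_run(panel, c(20, 20, 20), run_length = 4,
                      noise_cv = 0, baseline_rate = 0, seed = 1)
  feats <- attach_isotopologues(detect_features(run), run)
  main <- feats[!feats$isotopologue, ]
  expect_equal(nrow(main), 3L)
  expect_equal(sort(main$mz), sort(panel$mz), tolerance = 1e-6)
  expect_equal(sort(main$rt_min), c(1, 2, 3), tolerance = 0.01)

  # detected area agrees with direct XIC integration
  for (i in seq_len(nrow(main))) {
    xic_area <- integrate_peak(extract_xic(run, main$mz[i]),
                               c(main$rt_min[i] - 0.3, main$rt_min[i] + 0.3),
                               "none")
    expect_equal(main$area[i], xic_area, tolerance = 0.01)
  }
})

test_that("features below the signal-to-noise threshold are dropped", {
  rt <- seq(0, 4, by = 1 / 120)
  # flat noise floor on an off-peak m/z channel establishes mad-based noise
  noise <- rep(c(80, 100, 120, 90, 110), length.out = length(rt))
  weak <- noise + gaussian_trace(rt, 2, 0.05, 25)    # apex S/N ~ 8 < 10
  strong <- noise + gaussian_trace(rt, 2, 0.05, 5000)
  run_weak <- manual_run(list(list(mz = 156.0325, intensity = weak)), rt)
  run_strong <- manual_run(list(list(mz = 156.0325, intensity = strong)), rt)
  expect_equal(nrow(detect_features(run_weak, min_snr = 10)), 0L)
  expect_equal(nrow(detect_features(run_strong, min_snr = 10)), 1L)
  expect_error(detect_features(run_weak, min_scans = 2), "min_scans")
})

test_that("pure-noise runs produce almost no false positives", {
  total <- 0
  for (s in 1:20) {
    run <- simulate_run(short_cys(), 0, run_length = 4, noise_cv = 0.02,
                        baseline_rate = 2, seed = s)
    total <- total + nrow(detect_features(run, min_snr = 3))
  }
  expect_lte(total, 20)  # on average at most one spurious feature per run
})

test_that("isotopologue envelopes separate sulfur from sulfur-free analytes", {
  panel <- dplyr::bind_rows(short_gbt(1), short_cys(2))
  run <- simulate_run(panel, c(30, 30), run_length = 4, noise_cv = 0,
                      baseline_rate = 0, seed = 1)
  feats <- flag_sulfur(attach_isotopologues(detect_features(run), run))
  main <- feats[!feats$isotopologue, ]
  cys <- main[abs(main$mz - 156.0325) < 0.01, ]
  gbt <- main[abs(main$mz - 118.0863) < 0.01, ]
  expect_equal(cys$m2_ratio, 0.0447, tolerance = 0.002)
  expect_equal(cys$m2_shift, 1.99580, tolerance = 2e-4)
  expect_true(cys$sulfur_flag)
  expect_lt(gbt$m2_ratio, 0.01)
  expect_false(gbt$sulfur_flag)

  # the flag is invariant to intensity scaling
  run10 <- run
  run10$intensity <- run10$intensity * 10
  feats10 <- flag_sulfur(attach_isotopologues(detect_features(run10), run10))
  expect_equal(feats10$sulfur_flag, feats$sulfur_flag)
  expect_equal(feats10$m2_ratio, feats$m2_ratio, tolerance = 1e-9)
})

test_that("screening recall is 1 for planted sulfur features at zero noise", {
  s_panel <- dplyr::bind_rows(
    short_cys(1.2),
    analyte("DMSP", "C5H10O2S", rt_min = 2.2, response_factor = 8.28e7),
    analyte("DMSA-like", "C3H8O2S", rt_min = 3.1, response_factor = 5e7)
  )
  run <- simulate_run(s_panel, c(15, 15, 15), run_length = 4, noise_cv = 0,
                      baseline_rate = 0, seed = 1)
  feats <- flag_sulfur(attach_isotopologues(detect_features(run), run))
  main <- feats[!feats$isotopologue, ]
  hit <- vapply(s_panel$mz, function(m) {
    any(abs(main$mz - m) < 1e-3 & main$sulfur_flag)
  }, logical(1))
  expect_true(all(hit))
})

test_that("differential screen selects up-regulated features and skips flat ones", {
  panel <- dplyr::bind_rows(short_gbt(1), short_cys(2))
  sim_cond <- function(amounts, seeds) {
    lapply(seeds, function(s) {
      run <- simulate_run(panel, amounts, run_length = 4, noise_cv = 0.02,
                          baseline_rate = 1, seed = s)
      flag_sulfur(attach_isotopologues(detect_features(run), run))
    })
  }
  low <- sim_cond(c(30, 10), 1:3)
  high <- sim_cond(c(30, 24), 4:6)
  cand <- differential_screen(low, high, fc_min = 1.5, p_max = 0.05)
  expect_gte(nrow(cand), 1L)
  expect_equal(cand$mz[1], short_cys()$mz, tolerance = 1e-5)
  expect_true(cand$sulfur_flag[1])
  # the flat glycine betaine feature is not a candidate
  expect_false(any(abs(cand$mz - short_gbt()$mz) < 0.01))
})

test_that("the packaged mining fixture yields exactly the cysteinolic candidate", {
  sc <- scenario_salinity_screen(seed = 7)
  exp1 <- simulate_experiment(sc, seed = 7)
  feats <- lapply(exp1$run, function(r) {
    flag_sulfur(attach_isotopologues(detect_features(r), r))
  })
  cand <- differential_screen(feats[exp1$condition == "35 PSU"],
                              feats[exp1$condition == "50 PSU"])
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$mz, 156.03251, tolerance = 1e-5 * 156)
  expect_true(cand$sulfur_flag)
  expect_equal(cand$fold_change, 2.4, tolerance = 0.25)
})
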