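test_that("formula parsing, canonical writing and round trips", {
  comp <- parse_formula("C3H10NO4S")
  expect_equal(unclass(comp)[c("C", "H", "N", "O", "S")],
               c(C = 3L, H = 10L, N = 1L, O = 4L, S = 1L))
  expect_equal(unclass(parse_formula("H2O")), c(H = 2L, O = 1L))

  # canonical writer is a left inverse of the parser on Hill-form input
  for (f in c("C3H9NO4S", "H2O", "C5H11NO2", "O3S", "C6H10N2O2", "H3N")) {
    expect_identical(format_formula(parse_formula(f)), f)
  }
  # and idempotent through one canonicalisation for common trivial names
  for (f in c("SO3", "NH3")) {
    canon <- format_formula(parse_formula(f))
    expect_identical(format_formula(parse_formula(canon)), canon)
    expect_equal(monoisotopic_mass(canon), monoisotopic_mass(f))
  }
  # repeated element symbols accumulate
  expect_identical(format_formula(parse_formula("CH3CH3")), "C2H6")
})

test_that("malformed and unknown formulas are rejected", {
  expect_error(parse_formula("C3H10NoXq"), "unknown element")
  expect_error(parse_formula(""), "non-empty")
  expect_error(parse_formula("c3h10"), "malformed")
  expect_error(parse_formula("C3-H10"), "malformed")
})

test_that("monoisotopic masses match element-wise sums", {
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-6)
  # neutral cysteinolic acid
  expect_equal(monoisotopic_mass("C3H9NO4S"), 155.025230, tolerance = 1e-6)
  # empty composition (self-subtraction) has zero mass
  empty <- formula_subtract("H2O", "H2O")
  expect_equal(monoisotopic_mass(empty), 0)

  # additivity over compositions
  set.seed(42)
  els <- c("C", "H", "N", "O", "S")
  for (i in 1:20) {
    a <- stats::setNames(sample(0:6, 5, replace = TRUE), els)
    b <- stats::setNames(sample(0:6, 5, replace = TRUE), els)
    a_str <- paste0(els[a > 0], a[a > 0], collapse = "")
    b_str <- paste0(els[b > 0], b[b > 0], collapse = "")
    if (!nzchar(a_str) || !nzchar(b_str)) next
    expect_equal(monoisotopic_mass(formula_add(a_str, b_str)),
                 monoisotopic_mass(a_str) + monoisotopic_mass(b_str),
                 tolerance = 1e-12)
  }
})

test_that("adduct m/z uses the proton mass and handles bad charge", {
  # printed calculated value for protonated cysteinolic acid
  expect_equal(adduct_mz("C3H9NO4S", "[M+H]+"), 156.03251,
               tolerance = 5e-5 / 156)
  expect_equal(adduct_mz("H2O", "[M+H]+"), 19.01784, tolerance = 1e-5)
  expect_error(
    adduct_mz("H2O", list(name = "bad", mass_shift = 1, charge = 0L)),
    "charge")
  expect_error(adduct("[M+2H]2+"), "unsupported")
})

test_that("ppm error is the standard relative difference", {
  expect_equal(mass_error_ppm(156.03232, 156.03251), -1.2176,
               tolerance = 1e-3)
  expect_equal(mass_error_ppm(500, 500), 0)
  expect_error(mass_error_ppm(100, 0), "> 0")
})

test_that("isotope patterns obey their structural invariants", {
  pat <- isotope_pattern("C3H9NO4S")
  expect_equal(pat$shift[1], 0)
  expect_equal(pat$abundance[1], 1)
  expect_true(all(diff(pat$shift) > 0))
  expect_true(all(pat$abundance > 0 & pat$abundance <= 1))
  expect_error(isotope_pattern("C3H9NO4S", threshold = 0), "threshold")
  expect_error(isotope_pattern("C3H9NO4S", threshold = 1), "threshold")
})

test_that("sulfur-bearing formulas show the M+2 signature at 1.99580", {
  for (f in c("C3H9NO4S", "H2S", "C5H10O2S", "C2H6OS")) {
    pat <- isotope_pattern(f)
    m2 <- pat[abs(pat$shift - 1.99580) < 1e-4, ]
    expect_equal(nrow(m2), 1L)
    # one sulfur: abundance equals the 34S/32S natural ratio
    expect_equal(m2$abundance, 0.0447, tolerance = 0.002)
  }
  # the spacing itself reproduces the printed 1.9958 at 4 decimals
  pat <- isotope_pattern("H2S")
  expect_equal(round(pat$shift[abs(pat$shift - 2) < 0.05], 4), 1.9958)
})

test_that("carbon-only M+1 equals the binomial expectation", {
  pat <- isotope_pattern("C10")
  r13 <- 0.0107 / 0.9893
  m1 <- pat$abundance[abs(pat$shift - 1.00335) < 1e-3]
  expect_equal(m1, 10 * r13, tolerance = 1e-6)
})

test_that("patterns match the exhaustive enumeration oracle", {
  cases <- list(c(C = 3, H = 9, N = 1, O = 4, S = 1),
                c(C = 5, H = 11, N = 1, O = 2),
                c(H = 2, S = 1),
                c(C = 6, H = 10, N = 2, O = 2))
  for (counts in cases) {
    f <- paste0(names(counts), counts, collapse = "")
    got <- isotope_pattern(f, threshold = 1e-4)
    want <- oracle_isotope_pattern(as.list(counts))
    for (i in seq_len(nrow(got))) {
      j <- which.min(abs(want$shift - got$shift[i]))
      expect_lt(abs(want$shift[j] - got$shift[i]), 1e-4)
      expect_lt(abs(want$abundance[j] - got$abundance[i]), 1e-6)
    }
  }
})
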