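we_spec <- function(base = 0, opt = 25, max = 35, r = 1) {
  drc_spec("wang_engel", "tas", params = list(psi_base = base, psi_opt = opt,
                                              psi_max = max, r = r))
}

test_that("wang_engel response: boundary zeros, maximum at optimum, oracle value", {
  spec <- we_spec()
  expect_equal(eval_drc(spec, 25), 1)
  expect_equal(eval_drc(spec, 0), 0)
  expect_equal(eval_drc(spec, 35), 0)
  # independent step-by-step evaluation: alpha first, then the response
  a <- log(2) / log((35 - 0) / (25 - 0))
  x <- 12.5
  manual <- 1 * (2 * (x - 0)^a * (25 - 0)^a - (x - 0)^(2 * a)) / (25 - 0)^(2 * a)
  expect_equal(eval_drc(spec, x), manual, tolerance = 1e-12)
  # continuity: limits from inside approach 0
  expect_lt(eval_drc(spec, 1e-6), 1e-4)
  expect_lt(eval_drc(spec, 35 - 1e-6), 1e-4)
})

test_that("wang_engel_alpha closed forms and constraint", {
  expect_equal(wang_engel_alpha(0, 10, 20), 1)           # ratio 2 -> ln2/ln2
  expect_equal(wang_engel_alpha(0, 5, 20), 0.5)          # ratio 4 -> ln2/ln4
  expect_equal(wang_engel_alpha(0, 25, 35), log(2) / log(35 / 25),
               tolerance = 1e-15)
  expect_error(wang_engel_alpha(0, 30, 20), "psi_base < psi_opt < psi_max")
})

test_that("broken_stick threshold and linear families behave per definition", {
  bs <- drc_spec("broken_stick", "tas", params = list(psi_base = 5, slope = 1))
  expect_equal(eval_drc(bs, 5), 0)
  expect_equal(eval_drc(bs, 6), 1)
  expect_equal(eval_drc(bs, 4), 0)
  lin <- drc_spec("linear", "SPI", params = list(intercept = -1, slope = 2))
  expect_equal(eval_drc(lin, 0), -1)  # negative responses allowed
  expect_equal(eval_drc(lin, 2), 3)
})

test_that("asymptotic family clips at zero and approaches its asymptote", {
  as_ <- drc_spec("asymptotic", "tas", params = list(psi_base = 0, lrc = 0, Asym = 2))
  expect_equal(eval_drc(as_, 1e6), 2, tolerance = 1e-9)
  expect_equal(eval_drc(as_, -5), 0)   # clipped below the base
  expect_equal(eval_drc(as_, 0), 0)
})

test_that("invalid specifications are rejected", {
  expect_error(drc_spec("wang_engel", "tas",
                        params = list(psi_base = 10, psi_opt = 5, psi_max = 35, r = 1)),
               "psi_base < psi_opt < psi_max")
  expect_error(drc_spec("asymptotic", "tas",
                        params = list(psi_base = 0, lrc = 0, Asym = -1)),
               "Asym > 0")
  expect_error(drc_spec("linear", "tas", params = list(intercept = 0, slope = Inf)),
               "finite")
  expect_error(drc_spec("broken_stick", "tas", params = list(psi_base = 1)),
               "slope")
})

test_that("eval_drc is vectorization-safe and non-linear families are >= 0", {
  set.seed(11)
  specs <- list(
    we_spec(),
    drc_spec("broken_stick", "tas", params = list(psi_base = 3, slope = 0.4)),
    drc_spec("asymptotic", "tas", params = list(psi_base = 2, lrc = -1, Asym = 1.5)))
  x <- runif(50, -10, 45)
  for (spec in specs) {
    vec <- eval_drc(spec, x)
    single <- vapply(x, function(xi) eval_drc(spec, xi), 0)
    expect_identical(vec, single)
    expect_true(all(vec >= 0))
  }
  # maximum attained exactly at the optimum
  expect_true(all(eval_drc(we_spec(), x) <= eval_drc(we_spec(), 25)))
})

test_that("accumulate_dose sums daily responses over a half-open window", {
  w <- toy_weather(20, tas = 25)
  spec <- we_spec()
  d <- accumulate_dose(spec, w, w$date[1], w$date[1] + 10)
  expect_equal(nrow(d), 10)
  expect_equal(d$cumulative[10], 10)  # constant optimum, r = 1

  empty <- accumulate_dose(spec, w, w$date[1], w$date[1])
  expect_equal(nrow(empty), 0)

  expect_error(accumulate_dose(spec, w, w$date[1], w$date[20] + 5), "missing")
})

test_that("dose accumulation is additive over contiguous windows", {
  set.seed(21)
  w <- toy_weather(30, tas = runif(30, 0, 35))
  spec <- we_spec()
  a <- w$date[1]; b <- w$date[11]; c_ <- w$date[25]
  d_ab <- accumulate_dose(spec, w, a, b)
  d_bc <- accumulate_dose(spec, w, b, c_)
  d_ac <- accumulate_dose(spec, w, a, c_)
  expect_equal(d_ab$cumulative[nrow(d_ab)] + d_bc$cumulative[nrow(d_bc)],
               d_ac$cumulative[nrow(d_ac)], tolerance = 1e-10)
})

test_that("broken stick with base 0 and slope 1 reproduces growing degree days", {
  set.seed(22)
  tas <- runif(40, -5, 20)
  w <- toy_weather(40, tas = tas)
  gdd <- drc_spec("broken_stick", "tas", params = list(psi_base = 0, slope = 1))
  d <- accumulate_dose(gdd, w, w$date[1], w$date[1] + 40)
  # classical GDD accumulation with base temperature 0, via an explicit loop
  acc <- 0
  for (x in tas) acc <- acc + max(x - 0, 0)
  expect_equal(d$cumulative[40], acc, tolerance = 1e-10)
})

test_that("DRC specs round-trip through JSON bit-exactly", {
  spec <- drc_spec("wang_engel", "tas", "jointing-heading",
                   list(psi_base = 1 / 3, psi_opt = 25.123456789012345,
                        psi_max = 35, r = 0.1))
  path <- withr::local_tempfile(fileext = ".json")
  write_drc_spec(spec, path)
  back <- read_drc_spec(path)
  expect_identical(back$params, spec$params)
  expect_identical(back$family, spec$family)
  expect_identical(back$covariate, spec$covariate)
})
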