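# controls with a given relaxed biceps vector in one F stratum
biceps_controls <- function(vals, age = 50, sex = "F") {
  make_cohort(length(vals), rel_biceps = vals, age = age, sex = sex)
}

one_stratum <- function(sex = "F") {
  data.frame(sex = sex, age_low = 18, age_high = 90, stringsAsFactors = FALSE)
}

test_that("empirical quantile cutoffs follow the type-7 definition", {
  # constant sample: any percentile equals the constant
  ref <- build_reference(biceps_controls(rep(2, 10)), one_stratum())
  expect_equal(lookup_cutoff(ref, "BICEPS", "RELAXED", "F", 50), 2)

  # hand-computed: 20 values 1.0..2.9, position 0.05*(20-1)+1 = 1.95
  # => 1.0 + 0.95 * 0.1 = 1.095
  ref <- build_reference(biceps_controls(seq(1.0, 2.9, by = 0.1)), one_stratum())
  expect_equal(lookup_cutoff(ref, "BICEPS", "RELAXED", "F", 50), 1.095)
})

test_that("Gaussian parametric cutoff is mean - 1.6449 sd at the 5th percentile", {
  set.seed(42)
  vals <- rnorm(400, 2.51, 0.52)
  ref <- build_reference(biceps_controls(vals), one_stratum(),
                         method = "GAUSSIAN_PARAMETRIC")
  cut <- lookup_cutoff(ref, "BICEPS", "RELAXED", "F", 50)
  expect_equal(cut, mean(vals) - 1.6449 * sd(vals), tolerance = 1e-4)
  # at the configured moments this is ~2.51 - 1.6449 * 0.52
  expect_equal(cut, 2.51 - 1.6449 * 0.52, tolerance = 0.08)
})

test_that("reference building rejects bad inputs", {
  mixed <- make_cohort(3, group = c("CONTROL", "CONTROL", "ALS"),
                       rel_biceps = c(2, 2, 1))
  expect_error(build_reference(mixed, one_stratum()), "CONTROL rows only")
  expect_error(build_reference(biceps_controls(rep(2, 10)), one_stratum(),
                               percentile = 0), "strictly between")
  expect_error(build_reference(biceps_controls(rep(2, 10)), one_stratum(),
                               percentile = 100), "strictly between")
  # a configured stratum with <2 controls is named in the error
  strata <- data.frame(sex = c("F", "F"), age_low = c(18, 60),
                       age_high = c(60, 90), stringsAsFactors = FALSE)
  expect_error(build_reference(biceps_controls(rep(2, 10), age = 30), strata),
               "too few controls in stratum F \\[60,90\\)")
  # thin cells under the empirical method fall back to Gaussian with warning
  expect_warning(
    ref <- build_reference(biceps_controls(c(2, 2.2, 2.4, 2.6), age = 30),
                           one_stratum()),
    "fell back to GAUSSIAN_PARAMETRIC")
  expect_identical(ref$cutoffs$cell_method, "GAUSSIAN_PARAMETRIC")
})

test_that("cutoff lookup respects stratum edges and coverage", {
  strata <- data.frame(sex = c("F", "F"), age_low = c(18, 40),
                       age_high = c(40, 90), stringsAsFactors = FALSE)
  co <- make_cohort(20, age = rep(c(30, 50), each = 10),
                    rel_biceps = rep(c(2.0, 3.0), each = 10))
  ref <- build_reference(co, strata)
  # internal edge belongs to the bin where it is the inclusive low edge
  expect_equal(lookup_cutoff(ref, "BICEPS", "RELAXED", "F", 40), 3.0)
  expect_equal(lookup_cutoff(ref, "BICEPS", "RELAXED", "F", 39.9), 2.0)
  expect_error(lookup_cutoff(ref, "BICEPS", "RELAXED", "F", 95),
               "outside configured strata")
  expect_error(lookup_cutoff(ref, "FDI", "CONTRACTED", "F", 30),
               "not assessed in the contracted state")
})

test_that("adding a control below the cutoff never raises it (monotone)", {
  set.seed(11)
  for (i in 1:20) {
    vals <- round(rnorm(30, 2.5, 0.5), 3)
    ref0 <- build_reference(biceps_controls(vals), one_stratum())
    c0 <- lookup_cutoff(ref0, "BICEPS", "RELAXED", "F", 50)
    low <- max(0.01, c0 - runif(1, 0, 1))
    ref1 <- build_reference(biceps_controls(c(vals, low)), one_stratum())
    c1 <- lookup_cutoff(ref1, "BICEPS", "RELAXED", "F", 50)
    expect_lte(c1, c0 + 1e-12)
  }
})

test_that("empirical and Gaussian cutoffs converge on large Gaussian strata", {
  set.seed(5)
  vals <- rnorm(1e5, 2.51, 0.52)
  co <- biceps_controls(vals)
  emp <- lookup_cutoff(build_reference(co, one_stratum()),
                       "BICEPS", "RELAXED", "F", 50)
  gau <- lookup_cutoff(build_reference(co, one_stratum(),
                                       method = "GAUSSIAN_PARAMETRIC"),
                       "BICEPS", "RELAXED", "F", 50)
  expect_lt(abs(emp - gau), 0.01)
})

test_that("about 5% of a fresh same-distribution sample falls below the cutoff", {
  set.seed(9)
  ref <- build_reference(biceps_controls(rnorm(5e4, 2.51, 0.52)), one_stratum())
  cut <- lookup_cutoff(ref, "BICEPS", "RELAXED", "F", 50)
  fresh <- rnorm(2e4, 2.51, 0.52)
  p_hat <- mean(fresh < cut)
  expect_lt(abs(p_hat - 0.05), 0.007)  # ~4.5 binomial SEs plus cutoff noise
})

test_that("JSON serialization round-trips and re-validates", {
  set.seed(2)
  co <- make_cohort(40, age = runif(40, 20, 85), sex = rep(c("F", "M"), 20))
  for (m in muscles()) co[[musono:::thick_col(m, "RELAXED")]] <- runif(40, 1, 3)
  for (m in contracted_muscles()) {
    co[[musono:::thick_col(m, "CONTRACTED")]] <- runif(40, 2, 4)
  }
  co <- suppressWarnings(as_cohort(plain(co)))
  ref <- suppressWarnings(build_reference(co))
  f <- withr::local_tempfile(fileext = ".json")
  save_reference(ref, f)
  back <- load_reference(f)
  expect_equal(back$percentile, ref$percentile)
  expect_equal(back$strata, ref$strata)
  expect_equal(back$cutoffs, ref$cutoffs)

  # tampered files fail validation
  bad <- jsonlite::read_json(f, simplifyVector = TRUE)
  bad$cutoffs$cutoff_cm[1] <- -1
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, f2, auto_unbox = TRUE)
  expect_error(load_reference(f2), "non-positive")
})
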