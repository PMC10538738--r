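test_that("flag_muscle uses a strict below-cutoff comparison", {
  expect_equal(flag_muscle(0.30, 0.35), "ABNORMAL")
  expect_equal(flag_muscle(0.35, 0.35), "NORMAL")  # boundary: equal is NORMAL
  # a mean control subject against a Gaussian-parametric control cutoff
  expect_equal(flag_muscle(2.51, 2.51 - 1.6449 * 0.52), "NORMAL")
  expect_error(flag_muscle(-0.1, 0.5), "negative thickness")
  expect_error(flag_muscle(0.5, 0), "positive")
})

test_that("differential markers compute and propagate missingness", {
  co <- make_cohort(4, group = c("CONTROL", "ALS", "MYO", "SMA"),
                    rel_biceps = c(2.51, 1.81, 0.40, NA),
                    rel_edb = c(0.76, 0.46, 0.60, 0.5),
                    mrc_elbow_flex = c(NA, 4, 4, 3.8),
                    mrc_bigtoe_ext = c(NA, 4, 2.9, NA))
  expect_equal(biceps_minus_edb(co), c(1.75, 1.35, -0.20, NA))
  expect_equal(mrc_differential(co), c(NA, 0, 1.1, NA))
  # PNP group means: elbow flexion 5, big toe 2.9 => 2.1
  pnp <- make_cohort(1, group = "PNP", mrc_elbow_flex = 5, mrc_bigtoe_ext = 2.9)
  expect_equal(mrc_differential(pnp), 2.1)
})

test_that("classify_subject populates flags, verdicts and counts", {
  ref <- fixed_reference(default_cutoff = 1)

  all_normal <- make_cohort(
    1, rel_biceps = 2, rel_fdi = 2, rel_apb = 2, rel_adm = 2, rel_quad = 2,
    rel_ta = 2, rel_ahb = 2, rel_edb = 2,
    fasc_biceps = FALSE, fasc_fdi = FALSE, fasc_apb = FALSE, fasc_adm = FALSE,
    fasc_quad = FALSE, fasc_ta = FALSE, fasc_ahb = FALSE, fasc_edb = FALSE)
  p <- classify_subject(all_normal, ref)
  expect_false(p$relaxed_positive)
  expect_false(p$fasc_positive_all8)
  expect_false(p$fasc_positive_proximal)
  expect_equal(p$n_relaxed_observed, 8L)

  # abnormal in EDB alone drives the >=1 rule
  edb_only <- make_cohort(1, rel_biceps = 2, rel_fdi = 2, rel_apb = 2,
                          rel_adm = 2, rel_quad = 2, rel_ta = 2, rel_ahb = 2,
                          rel_edb = 0.5)
  p <- classify_subject(edb_only, ref)
  expect_true(p$relaxed_positive)
  expect_equal(p$n_relaxed_abnormal, 1L)
  expect_equal(p$flag_rel_edb, "ABNORMAL")

  # fasciculations in exactly {FDI, AHB}: all-8 rule fires, proximal doesn't
  fasc <- make_cohort(1, fasc_biceps = FALSE, fasc_fdi = TRUE, fasc_apb = FALSE,
                      fasc_adm = FALSE, fasc_quad = FALSE, fasc_ta = FALSE,
                      fasc_ahb = TRUE, fasc_edb = FALSE)
  p <- classify_subject(fasc, ref)
  expect_equal(p$fasc_count_all8, 2L)
  expect_equal(p$fasc_count_proximal, 0L)
  expect_true(p$fasc_positive_all8)
  expect_false(p$fasc_positive_proximal)
})

test_that("missing muscles are excluded, never scored", {
  ref <- fixed_reference(default_cutoff = 1)
  empty <- make_cohort(1)  # nothing measured at all
  p <- classify_subject(empty, ref)
  expect_true(is.na(p$relaxed_positive))
  expect_true(is.na(p$contracted_positive))
  expect_true(is.na(p$fasc_count_all8))
  expect_true(is.na(p$fasc_positive_proximal))
  expect_equal(p$n_relaxed_observed, 0L)

  # one observed normal muscle: verdict is a definite negative
  one <- make_cohort(1, rel_adm = 2)
  p <- classify_subject(one, ref)
  expect_false(p$relaxed_positive)
  expect_equal(p$flag_rel_biceps, NA_character_)

  # fasciculation observed only distally: proximal count stays missing
  distal <- make_cohort(1, fasc_edb = TRUE, fasc_fdi = TRUE)
  p <- classify_subject(distal, ref)
  expect_equal(p$fasc_count_all8, 2L)
  expect_true(is.na(p$fasc_count_proximal))
  expect_true(p$fasc_positive_all8)
})

test_that("age outside reference coverage propagates as an error", {
  ref <- fixed_reference()
  old <- make_cohort(1, age = 95, rel_biceps = 2)
  expect_error(classify_cohort(old, ref), "outside reference coverage.*S001")
})

test_that("lowering a thickness can only flip the verdict towards positive", {
  ref <- fixed_reference(default_cutoff = 1.5)
  set.seed(31)
  for (i in 1:25) {
    th <- round(runif(8, 0.5, 2.5), 3)
    args <- stats::setNames(as.list(th), musono:::thick_col(muscles(), "RELAXED"))
    co <- do.call(make_cohort, c(list(n = 1), args))
    before <- classify_subject(co, ref)$relaxed_positive
    m <- sample(muscles(), 1)
    col <- musono:::thick_col(m, "RELAXED")
    co2 <- co
    co2[[col]] <- max(0, co2[[col]] - runif(1, 0, 2))
    after <- classify_subject(co2, ref)$relaxed_positive
    expect_false(before && !after)  # TRUE never becomes FALSE
  }
})

test_that("adding a fasciculating muscle never lowers counts or verdicts", {
  ref <- fixed_reference()
  set.seed(32)
  for (i in 1:25) {
    fl <- sample(c(TRUE, FALSE, NA), 8, replace = TRUE)
    args <- stats::setNames(as.list(fl), musono:::fasc_col(muscles()))
    co <- do.call(make_cohort, c(list(n = 1), args))
    before <- classify_subject(co, ref)
    off <- muscles()[is.na(fl) | !fl]
    if (length(off) == 0) next
    m <- sample(off, 1)
    co2 <- co
    co2[[musono:::fasc_col(m)]] <- TRUE
    after <- classify_subject(co2, ref)
    expect_gte(after$fasc_count_all8, max(before$fasc_count_all8, 0, na.rm = TRUE))
    if (isTRUE(before$fasc_positive_all8)) expect_true(after$fasc_positive_all8)
    if (isTRUE(before$fasc_positive_proximal)) {
      expect_true(after$fasc_positive_proximal)
    }
  }
})

test_that("classification is deterministic and row-order independent", {
  co <- simulate_cohort(default_config(seed = 3))
  ref <- suppressWarnings(build_reference(co[co$group == "CONTROL", ]))
  p1 <- classify_cohort(co, ref)
  p2 <- classify_cohort(co, ref)
  expect_identical(p1, p2)
  idx <- rev(seq_len(nrow(co)))
  shuffled <- suppressWarnings(as_cohort(plain(co)[idx, ], provenance = "shuffled"))
  p3 <- classify_cohort(shuffled, ref)
  expect_equal(plain(p3), plain(plain(p1)[idx, ]))
})

test_that("rule_config validates thresholds and profiles serialize", {
  expect_error(rule_config(min_abnormal_muscles = 0))
  expect_error(rule_config(proximal_set = c("BICEPS", "DELTOID")))
  cfg <- rule_config(fasc_threshold_all8 = 3)
  co <- make_cohort(1, fasc_biceps = TRUE, fasc_quad = TRUE, fasc_edb = FALSE)
  p <- classify_subject(co, fixed_reference(), cfg)
  expect_false(p$fasc_positive_all8)  # 2 < 3
  expect_true(p$fasc_positive_proximal)

  f <- withr::local_tempfile(fileext = ".csv")
  write_profiles(p, f)
  lines <- readLines(f)
  expect_length(lines, 2)
  expect_match(lines[2], "true")
})
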