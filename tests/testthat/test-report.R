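test_that("facility ranking averages, sorts and ranks deterministically", {
  aeci <- data.frame(
    visit_id = as.character(1:8),
    facility_id = c("F2", "F2", "F1", "F1", "F3", "F3", "F3", "F3"),
    aeci = c(1, -1, -0.3, -0.1, 0.3, 0.3, 0.2, 0.4),
    stringsAsFactors = FALSE)
  r <- facility_mean_aeci(aeci)
  expect_equal(r$facility_id, c("F1", "F2", "F3"))
  expect_equal(r$mean_aeci, c(-0.2, 0, 0.3))
  expect_equal(r$rank, 1:3)
  expect_equal(r$n_visits, c(2L, 2L, 4L))

  # invariance to visit order
  r2 <- facility_mean_aeci(aeci[sample(8), ])
  expect_equal(r2, r)
  expect_error(facility_mean_aeci(aeci[0, ]), "empty")
})

test_that("AAECI cells are division-quarter means with honest empties", {
  divs <- census_divisions()
  n <- 36
  aeci <- data.frame(visit_id = as.character(1:n), facility_id = "F",
                     aeci = 0.7, stringsAsFactors = FALSE)
  sm <- aaeci_by_division_quarter(aeci,
                                  rep(divs, 4),
                                  rep(c(1, 4, 7, 10), each = 9))
  expect_true(all(sm$aaeci == 0.7))
  expect_equal(dim(sm$aaeci), c(9, 4))

  # months restricted to Q1: other quarters are absent, not zero
  sm2 <- aaeci_by_division_quarter(aeci, rep(divs, 4),
                                   rep(c(1, 2, 3, 1), each = 9))
  expect_true(all(is.na(sm2$aaeci[, c("Q2", "Q3", "Q4")])))
  expect_true(all(!is.na(sm2$aaeci[, "Q1"])))
  expect_equal(sum(sm2$n), n)

  expect_error(aaeci_by_division_quarter(aeci, rep("Atlantis", n),
                                         rep(1, n)), "division")
  expect_error(aaeci_by_division_quarter(aeci, rep(divs[1], n),
                                         rep(13, n)), "months")
})

test_that("the count-weighted mean of AAECI cells equals the overall mean", {
  set.seed(301)
  n <- 2000
  divs <- sample(census_divisions(), n, replace = TRUE)
  months <- sample(1:12, n, replace = TRUE)
  vals <- rnorm(n)
  vals <- vals - mean(vals)  # centered, as OLS residuals are
  aeci <- data.frame(visit_id = as.character(1:n), facility_id = "F",
                     aeci = vals, stringsAsFactors = FALSE)
  sm <- aaeci_by_division_quarter(aeci, divs, months)
  weighted <- sum(sm$aaeci * sm$n, na.rm = TRUE) / sum(sm$n)
  expect_equal(weighted, 0, tolerance = 1e-12)
  # row-permutation invariance
  perm <- sample(n)
  sm_p <- aaeci_by_division_quarter(aeci[perm, ], divs[perm], months[perm])
  expect_equal(sm_p$aaeci, sm$aaeci, tolerance = 1e-12)
})

test_that("monthly profile computes means and a calibrated F test", {
  # equal month means with positive within-month variance: F = 0, p = 1
  aeci <- data.frame(visit_id = as.character(1:48), facility_id = "F",
                     aeci = rep(c(-1, 1), 24), stringsAsFactors = FALSE)
  months <- rep(1:12, each = 4)
  mp <- monthly_profile(aeci, months)
  expect_equal(mp$f_statistic, 0, tolerance = 1e-12)
  expect_equal(mp$p_value, 1, tolerance = 1e-12)
  expect_equal(mp$profile$mean, rep(0, 12))
  expect_equal(mp$df1, 11)
  expect_equal(mp$df2, 48 - 12)
  # grand weighted mean of month means equals the overall mean
  expect_equal(sum(mp$profile$mean * mp$profile$n) / sum(mp$profile$n),
               mean(aeci$aeci), tolerance = 1e-12)

  expect_error(monthly_profile(aeci, rep(1, 48)), "distinct")
  expect_error(monthly_profile(aeci, rep(0, 48)), "1-12")
})

test_that("a generated August trough appears as the minimum monthly mean", {
  cfg <- claims_config(n_facilities = 10, n_visits = 40000, seed = 33,
                       true_alpha1 = qlogis(0.315), true_alpha2 = log(0.8),
                       seasonal_amplitude = 0.3)
  vis <- generate_visits(cfg, generate_facilities(cfg))
  tr <- attr(vis, "truth")
  eci <- data.frame(visit_id = vis$visit_id, facility_id = vis$facility_id,
                    aeci = vis$y - (1 - tr$pi) * tr$lam,
                    stringsAsFactors = FALSE)
  # truth expectation includes the seasonal term, so strip it back out to
  # expose the raw seasonal signal the way a month-blind model would
  mean_flat <- mean((1 - tr$pi) * tr$lam)
  eci$aeci <- vis$y - mean_flat
  mp <- monthly_profile(eci, vis$admission_month)
  # August sits in the trough: among the lowest months and below both the
  # annual mean and the opposite-phase peak month (February)
  expect_lte(rank(mp$profile$mean)[8], 3)
  expect_lt(mp$profile$mean[8], mean(eci$aeci))
  expect_lt(mp$profile$mean[8], mp$profile$mean[2])
  expect_lt(mp$p_value, 0.01)
})

test_that("the end-to-end pipeline runs, writes artifacts and is reproducible", {
  cfg <- make_default_config(seed = 41, n_facilities = 50, n_visits = 5000)
  cfg$facility_effect_mode <- "rate_shift"
  out1 <- file.path(tempdir(), "pipe1")
  out2 <- file.path(tempdir(), "pipe2")
  res <- run_pipeline(cfg, out_dir = out1)
  expect_s3_class(res$fit, "zip_fit")
  expect_gt(res$rmse$pct_reduction, 0)
  expect_equal(nrow(res$ranking), 50)
  expect_setequal(
    c("facilities.csv", "visits.csv", "truth.json", "eci.csv", "aeci.csv",
      "ranking.csv", "facility_fit.csv", "ratio_table.csv",
      "seasonal_matrix.csv", "monthly_profile.csv", "fit.json",
      "preprocess_report.json", "rmse.json", "run_log.json"),
    list.files(out1))

  run_pipeline(cfg, out_dir = out2)
  for (f in list.files(out1)) {
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))),
                     label = paste("md5 of", f))
  }
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("pipeline failures name the failing stage", {
  cfg <- make_default_config(seed = 42, n_facilities = 5, n_visits = 200)
  # a patient design asking for an unseen variable fails in 'encode'
  bad_spec <- design_spec("not_a_variable", "continuous")
  expect_error(run_pipeline(cfg, pl_spec = bad_spec), "encode")
})

test_that("pipeline accepts CSV inputs", {
  cfg <- make_default_config(seed = 43, n_facilities = 10, n_visits = 800)
  fac <- generate_facilities(cfg)
  vis <- generate_visits(cfg, fac)
  d <- file.path(tempdir(), "csv_in")
  write_claims(cfg, fac, vis, d)
  res <- run_pipeline(list(visits_csv = file.path(d, "visits.csv"),
                           facilities_csv = file.path(d, "facilities.csv")))
  expect_s3_class(res$fit, "zip_fit")
  expect_equal(res$fit$n_obs, 800)
  unlink(d, recursive = TRUE)
})
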