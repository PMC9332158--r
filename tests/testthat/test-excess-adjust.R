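test_that("ECI is the observed count minus the mixture expectation", {
  preds <- data.frame(pi = c(0.3151, 0.3151, 0.5),
                      lam = c(0.46, 0.46, 1.1),
                      mean = c(0.3151, 0.3151, 0.55))
  eci <- compute_eci(c(0L, 2L, 0L), preds,
                     visit_id = c("a", "b", "c"),
                     facility_id = c("F1", "F1", "F2"))
  expect_equal(eci$eci, c(-0.3151, 1.6849, -0.55))
  expect_true(all(eci$eci >= -preds$mean))
  expect_error(compute_eci(c(0L, 1L), preds), "differ")
})

test_that("two-group facility OLS reproduces the closed-form mean difference", {
  set.seed(201)
  n <- 400
  grp <- rep(c("A", "B"), each = n / 2)
  eci_vals <- rnorm(n, ifelse(grp == "A", -0.1, 0.25), 0.5)
  eci <- data.frame(visit_id = sprintf("V%03d", 1:n),
                    facility_id = rep(c("F1", "F2"), each = n / 2),
                    eci = eci_vals, stringsAsFactors = FALSE)
  df <- data.frame(ftype = grp, stringsAsFactors = FALSE)
  dm <- encode_design(df, design_spec("ftype", "categorical", "A"),
                      row_keys = eci$visit_id)
  fit <- fit_facility_ols(eci, dm)
  m <- tapply(eci_vals, grp, mean)
  expect_equal(unname(fit$theta["ftype=B"]), unname(m["B"] - m["A"]),
               tolerance = 1e-12)
  expect_equal(unname(fit$theta["(Intercept)"]), unname(m["A"]),
               tolerance = 1e-12)
})

test_that("facility OLS matches the lm oracle for estimates, SEs and p-values", {
  set.seed(202)
  n <- 300
  df <- data.frame(a = sample(c("x", "y", "z"), n, TRUE),
                   b = sample(c("u", "v"), n, TRUE),
                   stringsAsFactors = FALSE)
  eci_vals <- rnorm(n, (df$a == "y") * 0.3 - (df$b == "v") * 0.2, 1)
  eci <- data.frame(visit_id = as.character(1:n), facility_id = "F",
                    eci = eci_vals, stringsAsFactors = FALSE)
  dm <- encode_design(df, design_spec(c("a", "b"), "categorical", c("x", "u")))
  ours <- fit_facility_ols(eci, dm)
  ref <- summary(stats::lm(eci_vals ~ I(df$a == "y") + I(df$a == "z") +
                             I(df$b == "v")))
  expect_equal(unname(ours$theta), unname(ref$coefficients[, 1]),
               tolerance = 1e-10)
  expect_equal(unname(ours$standard_errors), unname(ref$coefficients[, 2]),
               tolerance = 1e-10)
  expect_equal(unname(ours$p_values), unname(ref$coefficients[, 4]),
               tolerance = 1e-10)
  expect_equal(ours$sigma2, ref$sigma^2, tolerance = 1e-10)
})

test_that("degenerate and rank-deficient designs are handled explicitly", {
  n <- 50
  eci <- data.frame(visit_id = as.character(1:n), facility_id = "F",
                    eci = rep(0, n), stringsAsFactors = FALSE)
  df <- data.frame(a = rep(c("x", "y"), n / 2), stringsAsFactors = FALSE)
  dm <- encode_design(df, design_spec("a", "categorical", "x"))
  fit <- fit_facility_ols(eci, dm)
  expect_equal(unname(fit$theta), c(0, 0))
  expect_equal(fit$sigma2, 0)

  # duplicated indicator column -> error naming the collinear column
  dm2 <- dm
  dm2$x <- cbind(dm$x, `a=y_dup` = dm$x[, "a=y"])
  eci$eci <- rnorm(n)
  expect_error(fit_facility_ols(eci, dm2), "a=y_dup")
})

test_that("AECI is the centered facility-regression residual", {
  set.seed(203)
  cfg <- make_default_config(seed = 22, n_facilities = 30, n_visits = 3000)
  cfg$facility_effect_mode <- "rate_shift"
  fac <- generate_facilities(cfg)
  vis <- generate_visits(cfg, fac)
  tr <- attr(vis, "truth")
  preds <- data.frame(pi = tr$pi, lam = tr$lam, mean = (1 - tr$pi) * tr$lam)
  eci <- compute_eci(vis$y, preds, vis$visit_id, vis$facility_id)
  fl <- fac[match(vis$facility_id, fac$facility_id), ]
  # a compact facility design: 30 facilities cannot support all 33 columns
  fl_spec <- design_spec(c("teaching_status", "academic_status", "urban_rural"),
                         "categorical", c("No", "No", "Urban"))
  dm <- encode_design(fl, fl_spec, row_keys = vis$visit_id)
  fit <- fit_facility_ols(eci, dm)
  aeci <- compute_aeci(eci, fit, dm)

  n <- nrow(aeci)
  expect_lt(abs(sum(aeci$aeci)), 1e-8 * n)
  for (j in seq_len(ncol(dm$x)))
    expect_lt(abs(sum(aeci$aeci * dm$x[, j])), 1e-8 * n)

  # intercept-only adjustment is plain centering
  dm0 <- dm; dm0$x <- dm$x[, 1, drop = FALSE]
  fit0 <- fit_facility_ols(eci, dm0)
  aeci0 <- compute_aeci(eci, fit0, dm0)
  expect_equal(aeci0$aeci, eci$eci - mean(eci$eci), tolerance = 1e-12)

  # shifting ECI by a constant leaves AECI unchanged
  eci_shift <- eci; eci_shift$eci <- eci$eci + 5
  fit_s <- fit_facility_ols(eci_shift, dm)
  aeci_s <- compute_aeci(eci_shift, fit_s, dm)
  expect_equal(aeci_s$aeci, aeci$aeci, tolerance = 1e-8)

  # permutation equivariance
  perm <- sample(n)
  eci_p <- eci[perm, ]
  dm_p <- dm; dm_p$x <- dm$x[perm, , drop = FALSE]
  fit_p <- fit_facility_ols(eci_p, dm_p)
  aeci_p <- compute_aeci(eci_p, fit_p, dm_p)
  expect_equal(aeci_p$aeci, aeci$aeci[perm], tolerance = 1e-10)

  expect_error(compute_aeci(eci, fit, dm0), "match")
})

test_that("ECI is statistically centered when the fitted model is the truth's", {
  cfg <- make_default_config(seed = 23, n_facilities = 20, n_visits = 20000)
  vis <- generate_visits(cfg, generate_facilities(cfg))
  prep <- preprocess_visits(vis)
  dm <- encode_design(prep$visits, patient_design_spec())
  fit <- fit_zip(dm, prep$visits$y)
  eci <- compute_eci(prep$visits$y, predict(fit, dm),
                     prep$visits$visit_id, prep$visits$facility_id)
  n <- nrow(eci)
  expect_lt(abs(mean(eci$eci)), 4 * sd(eci$eci) / sqrt(n))
})

test_that("stratum regression isolates idiosyncratic facility differences", {
  set.seed(204)
  fac <- data.frame(facility_id = sprintf("F%02d", 1:6),
                    teaching_status = c("No", "No", "No", "Yes", "No", "No"),
                    academic_status = "No", stringsAsFactors = FALSE)
  # facilities F01..F03, F05, F06 share the stratum; F02 has a true offset
  n_per <- 40
  ids <- c(rep(c("F01", "F02", "F03", "F05", "F06"), each = n_per), "F04", "F04")
  eci <- data.frame(visit_id = as.character(seq_along(ids)),
                    facility_id = ids,
                    eci = rnorm(length(ids)) + (ids == "F02") * 1.5,
                    stringsAsFactors = FALSE)
  rep_ <- stratum_facility_regression(eci, fac,
                                      list(teaching_status = "No",
                                           academic_status = "No"))
  expect_equal(rep_$n_facilities, 5)
  expect_lt(rep_$p_value, 1e-6)

  # two-facility stratum: coefficient equals the facility mean difference
  eci2 <- eci[eci$facility_id %in% c("F01", "F02"), ]
  rep2 <- stratum_facility_regression(eci2, fac,
                                      list(teaching_status = "No"))
  m <- tapply(eci2$eci, eci2$facility_id, mean)
  expect_equal(rep2$coefficients$estimate[2], unname(m["F02"] - m["F01"]),
               tolerance = 1e-10)

  # a stratum matching a single facility is rejected
  expect_error(stratum_facility_regression(eci, fac,
                                           list(teaching_status = "Yes")),
               "two facilities")
  expect_error(stratum_facility_regression(eci, fac,
                                           list(teaching_status = "None")),
               "no visits")
})

test_that("stratum F test holds its nominal size under the null", {
  set.seed(205)
  fac <- data.frame(facility_id = sprintf("F%02d", 1:4),
                    teaching_status = "No", stringsAsFactors = FALSE)
  rejections <- 0
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    ids <- rep(fac$facility_id, each = 25)
    eci <- data.frame(visit_id = as.character(seq_along(ids)),
                      facility_id = ids, eci = rnorm(length(ids)),
                      stringsAsFactors = FALSE)
    rep_ <- stratum_facility_regression(eci, fac, list(teaching_status = "No"))
    rejections <- rejections + (rep_$p_value < 0.05)
  }
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rejections / n_rep - 0.05), 3 * se)
})

test_that("facility ordering is recoverable from mean ECI under known shifts", {
  cfg <- claims_config(
    n_facilities = 50, n_visits = 50000, seed = 24,
    facility_marginals = list(academic_status = c(No = 0.5, Yes = 0.5)),
    true_alpha1 = qlogis(0.315), true_alpha2 = log(0.8),
    facility_effect_mode = "rate_shift",
    true_theta = c("academic_status=Yes" = log(0.8)),
    facility_idiosyncratic_sd = 0.1)
  fac <- generate_facilities(cfg)
  vis <- generate_visits(cfg, fac)
  tr <- attr(vis, "truth")
  # expectation WITHOUT facility knowledge: patient-level truth only
  mean_pl <- (1 - plogis(qlogis(0.315))) * exp(log(0.8))
  eci <- data.frame(visit_id = vis$visit_id, facility_id = vis$facility_id,
                    eci = vis$y - mean_pl, stringsAsFactors = FALSE)
  per_fac <- tapply(eci$eci, eci$facility_id, mean)
  truth_fac <- attr(fac, "truth")
  rho <- cor(per_fac[truth_fac$facility_id], truth_fac$total_log_shift,
             method = "spearman")
  expect_gt(rho, 0.8)
})
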