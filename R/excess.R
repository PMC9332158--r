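#' Per-visit excess coding intensity (ECI)
#'
#' ECI is the observed count of additional coded procedures minus its
#' expectation under the patient-level zero-inflated Poisson model:
#' negative values indicate coding below the industry expectation for that
#' patient mix, positive values indicate over-coding.
#'
#' @param y Observed counts, aligned with `predictions`.
#' @param predictions Prediction table from [predict.zip_fit()] (or
#'   [predict_zip_params()]), with a `mean` column.
#' @param visit_id,facility_id Optional key vectors carried through.
#' @return Data frame with `visit_id`, `facility_id`, `eci`.
#' @export
compute_eci <- function(y, predictions, visit_id = NULL, facility_id = NULL) {
  if (length(y) != nrow(predictions))
    stop("`y` and `predictions` lengths differ", call. = FALSE)
  n <- length(y)
  data.frame(
    visit_id = if (is.null(visit_id)) sprintf("V%07d", seq_len(n)) else visit_id,
    facility_id = if (is.null(facility_id)) NA_character_ else facility_id,
    eci = as.numeric(y) - predictions$mean,
    stringsAsFactors = FALSE)
}

#' Facility-level linear adjustment of ECI
#'
#' Fits, at visit level, the ordinary-least-squares regression of ECI on
#' the facility-characteristic design (intercept included), modeling ECI
#' as Normal with mean `theta * FL`. Estimation is by QR decomposition;
#' standard errors use the residual variance `RSS / (n - p)` and p-values
#' the t distribution with `n - p` degrees of freedom. Each visit is one
#' row, so standard errors ignore within-facility clustering — a
#' deliberate property of the method, documented as a caveat.
#'
#' @param eci ECI table from [compute_eci()].
#' @param fl_design `"design_matrix"` of facility characteristics joined to
#'   visits (one row per visit, same order as `eci`).
#' @return Object of class `"facility_ols"`: `theta` (named estimates),
#'   `sigma2`, `standard_errors`, `t_stats`, `p_values`, `n_obs`,
#'   `r_squared`, `fitted`, `residuals`, `design_column_names`.
#' @export
fit_facility_ols <- function(eci, fl_design) {
  x <- design_x(fl_design)
  yv <- eci$eci
  n <- length(yv)
  p <- ncol(x)
  if (n != nrow(x))
    stop("`eci` and `fl_design` are not conformable", call. = FALSE)
  if (n <= p)
    stop("need more visits than facility design columns", call. = FALSE)
  qr_x <- qr(x)
  if (qr_x$rank < p) {
    dropped <- colnames(x)[qr_x$pivot[(qr_x$rank + 1L):p]]
    stop("facility design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  theta <- qr.coef(qr_x, yv)
  fitted <- drop(x %*% theta)
  res <- yv - fitted
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * diag(xtx_inv))
  # undo any pivoting in the R factor
  se[qr_x$pivot] <- se
  tstat <- theta / se
  pval <- 2 * stats::pt(abs(tstat), df = n - p, lower.tail = FALSE)
  tss <- sum((yv - mean(yv))^2)
  structure(
    list(theta = stats::setNames(theta, colnames(x)),
         sigma2 = sigma2,
         standard_errors = stats::setNames(se, colnames(x)),
         t_stats = stats::setNames(tstat, colnames(x)),
         p_values = stats::setNames(pval, colnames(x)),
         n_obs = n,
         r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
         fitted = fitted,
         residuals = res,
         design_column_names = colnames(x)),
    class = "facility_ols")
}

#' @export
print.facility_ols <- function(x, ...) {
  cat(sprintf("Facility-level OLS on ECI: n = %d, sigma^2 = %.4f, R^2 = %.4f\n",
              x$n_obs, x$sigma2, x$r_squared))
  print(round(cbind(estimate = x$theta, se = x$standard_errors,
                    p = x$p_values), 4))
  invisible(x)
}

#' @export
coef.facility_ols <- function(object, ...) object$theta

#' Table-style summary of the facility adjustment
#'
#' @param object A `"facility_ols"`.
#' @param ... Unused.
#' @return Data frame with `term`, `estimate`, `std_error`, `t_value`,
#'   `p_value`.
#' @export
summary.facility_ols <- function(object, ...) {
  data.frame(term = object$design_column_names,
             estimate = unname(object$theta),
             std_error = unname(object$standard_errors),
             t_value = unname(object$t_stats),
             p_value = unname(object$p_values),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Adjusted excess coding intensity (AECI)
#'
#' AECI subtracts from each visit's ECI its facility-characteristic
#' expectation `theta * FL` (intercept included), i.e. it is exactly the
#' residual of the facility-level regression. By the OLS normal equations
#' AECI sums to zero and is orthogonal to every facility design column;
#' what remains is the idiosyncratic, facility-unexplained part of excess
#' coding.
#'
#' @param eci ECI table.
#' @param fit The `"facility_ols"` from [fit_facility_ols()].
#' @param fl_design The same design used for the fit.
#' @return Data frame with `visit_id`, `facility_id`, `aeci`.
#' @export
compute_aeci <- function(eci, fit, fl_design) {
  x <- design_x(fl_design)
  if (!identical(colnames(x), fit$design_column_names))
    stop("facility design does not match the fitted adjustment",
         call. = FALSE)
  if (nrow(x) != nrow(eci))
    stop("`eci` and `fl_design` are not conformable", call. = FALSE)
  data.frame(visit_id = eci$visit_id,
             facility_id = eci$facility_id,
             aeci = eci$eci - drop(x %*% fit$theta),
             stringsAsFactors = FALSE)
}

#' Within-stratum regression of ECI on facility identity
#'
#' Restricts to the facilities whose characteristics all equal the given
#' stratum levels and regresses ECI on facility-ID indicators (reference:
#' lexicographically first facility). The joint F test against the
#' intercept-only model asks whether facility identity still explains
#' coding differences after facility characteristics have been held
#' exactly equal — i.e. whether idiosyncratic facility behavior remains.
#'
#' @param eci ECI table (with `facility_id`).
#' @param facilities Facility table.
#' @param stratum Named list/vector: facility variable -> level.
#' @param min_visits Minimum visits a facility needs to enter (default 2).
#' @return Object of class `"stratum_report"`: the stratum definition,
#'   per-facility coefficients with 95% confidence intervals, the joint F
#'   statistic with degrees of freedom and p-value, and the cohort sizes.
#' @export
stratum_facility_regression <- function(eci, facilities, stratum,
                                        min_visits = 2L) {
  stratum <- unlist(stratum)
  keep <- rep(TRUE, nrow(facilities))
  for (v in names(stratum)) {
    if (!v %in% names(facilities))
      stop(sprintf("stratum variable '%s' not in facility table", v),
           call. = FALSE)
    keep <- keep & facilities[[v]] == stratum[[v]]
  }
  fac_ids <- facilities$facility_id[keep]
  rows <- eci[eci$facility_id %in% fac_ids, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("no visits fall in the requested stratum", call. = FALSE)
  counts <- table(rows$facility_id)
  ok_ids <- names(counts)[counts >= min_visits]
  if (length(ok_ids) < 2L)
    stop("stratum must contain at least two facilities with enough visits",
         call. = FALSE)
  rows <- rows[rows$facility_id %in% ok_ids, , drop = FALSE]
  fid <- factor(rows$facility_id, levels = sort(ok_ids))
  fit <- stats::lm(rows$eci ~ fid)
  sm <- summary(fit)
  ci <- stats::confint(fit)
  coefs <- data.frame(term = rownames(sm$coefficients),
                      estimate = sm$coefficients[, 1],
                      std_error = sm$coefficients[, 2],
                      ci_lo = ci[, 1], ci_hi = ci[, 2],
                      row.names = NULL, stringsAsFactors = FALSE)
  fstat <- sm$fstatistic
  p <- stats::pf(fstat[["value"]], fstat[["numdf"]], fstat[["dendf"]],
                 lower.tail = FALSE)
  structure(
    list(stratum = stratum,
         coefficients = coefs,
         f_statistic = unname(fstat[["value"]]),
         df1 = unname(fstat[["numdf"]]),
         df2 = unname(fstat[["dendf"]]),
         p_value = unname(p),
         n_obs = nrow(rows),
         n_facilities = length(ok_ids)),
    class = "stratum_report")
}

#' @export
print.stratum_report <- function(x, ...) {
  cat(sprintf(
    "Stratum regression: %d facilities, %d visits; F(%d, %d) = %.3f, p = %.4g\n",
    x$n_facilities, x$n_obs, x$df1, x$df2, x$f_statistic, x$p_value))
  cat("  stratum:",
      paste(sprintf("%s=%s", names(x$stratum), x$stratum), collapse = ", "),
      "\n")
  invisible(x)
}
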