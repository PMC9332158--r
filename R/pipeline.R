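#' Run the full excess-coding-intensity pipeline
#'
#' Drives every stage end to end: (optional) synthetic generation or CSV
#' loading, preprocessing (log length of stay, complete-case filter,
#' rare-category collapse), patient-level zero-inflated Poisson fit,
#' mixture-mean prediction and RMSE comparison, per-visit ECI, the
#' facility-level adjustment, per-visit AECI, and the reporting surfaces
#' (facility ranking, AAECI by division and quarter, monthly profile).
#' With an output directory all intermediate artifacts are written as CSV
#' and JSON; two runs with the same configuration are identical.
#'
#' @param config Either a [claims_config()] (synthetic input) or a list
#'   with `visits_csv` and `facilities_csv` paths to user-supplied tables.
#' @param out_dir Optional directory for artifacts.
#' @param pl_spec Patient design specification (default
#'   [patient_design_spec()]).
#' @param fl_spec Facility design specification (default
#'   [facility_design_spec()]).
#' @param threshold Rare-category collapse threshold.
#' @param fix_references When `TRUE` (default), a categorical reference
#'   level absent from the data (possible in small synthetic cohorts where
#'   a rare level is never drawn) is replaced by the modal observed level
#'   before encoding, with a message. ECI, AECI, predictions and every
#'   report are invariant to the reference choice; only the coefficient
#'   labeling changes. Set `FALSE` to insist on the frozen references.
#' @return Invisibly, a list with every stage's output: `facilities`,
#'   `visits`, `prep` (report and maps), `fit`, `predictions`, `rmse`,
#'   `ratio_table`, `eci`, `facility_fit`, `aeci`, `ranking`, `seasonal`,
#'   `monthly`.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         pl_spec = patient_design_spec(),
                         fl_spec = facility_design_spec(),
                         threshold = 0.001,
                         fix_references = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  if (inherits(config, "claims_config")) {
    facilities <- stage("simulate", generate_facilities(config))
    visits <- stage("simulate", generate_visits(config, facilities))
  } else {
    facilities <- stage("load", utils::read.csv(config$facilities_csv,
                                                stringsAsFactors = FALSE))
    visits <- stage("load", utils::read.csv(config$visits_csv,
                                            stringsAsFactors = FALSE))
  }

  prep <- stage("prepare", preprocess_visits(visits, threshold = threshold))
  clean <- prep$visits

  if (fix_references) pl_spec <- heal_references(pl_spec, clean)
  pl_design <- stage("encode", encode_design(clean, pl_spec))
  fit <- stage("fit", fit_zip(pl_design, clean$y))
  preds <- stage("predict", predict(fit, pl_design))
  rmse <- stage("predict", rmse_comparison(clean$y, preds$mean))
  ratios <- stage("predict", ratio_table(fit))

  eci <- stage("eci", compute_eci(clean$y, preds,
                                  visit_id = clean$visit_id,
                                  facility_id = clean$facility_id))

  idx <- match(clean$facility_id, facilities$facility_id)
  if (anyNA(idx))
    stop("pipeline stage 'adjust' failed: visit references unknown facility_id",
         call. = FALSE)
  fl_joined <- facilities[idx, , drop = FALSE]
  if (fix_references) fl_spec <- heal_references(fl_spec, fl_joined)
  fl_design <- stage("adjust", encode_design(fl_joined, fl_spec,
                                             row_keys = clean$visit_id))
  fl_design <- stage("adjust", drop_aliased_columns(fl_design))
  facility_fit <- stage("adjust", fit_facility_ols(eci, fl_design))
  aeci <- stage("adjust", compute_aeci(eci, facility_fit, fl_design))

  ranking <- stage("report", facility_mean_aeci(aeci))
  seasonal <- stage("report", aaeci_by_division_quarter(
    aeci, fl_joined$census_division, clean$admission_month))
  monthly <- stage("report", monthly_profile(aeci, clean$admission_month))

  result <- list(facilities = facilities, visits = visits, prep = prep,
                 fit = fit, predictions = preds, rmse = rmse,
                 ratio_table = ratios, eci = eci,
                 facility_fit = facility_fit, aeci = aeci,
                 ranking = ranking, seasonal = seasonal, monthly = monthly)

  if (!is.null(out_dir))
    stage("write", write_pipeline_artifacts(result, config, out_dir))
  invisible(result)
}

# Remove exactly collinear (aliased) design columns, keeping the earliest
# of each aliased set. Small synthetic cohorts can alias facility levels
# (e.g. two rare levels occurring at the same single facility); the strict
# fitters refuse such designs, so the pipeline prunes them with a message.
drop_aliased_columns <- function(dm) {
  qr_x <- qr(dm$x)
  if (qr_x$rank == ncol(dm$x)) return(dm)
  drop <- qr_x$pivot[(qr_x$rank + 1L):ncol(dm$x)]
  message("dropping aliased facility design column(s): ",
          paste(colnames(dm$x)[drop], collapse = ", "))
  dm$x <- dm$x[, -drop, drop = FALSE]
  dm
}

# Swap in the modal observed level wherever a spec's reference level does
# not occur in the data (reference-coded contrasts are undefined for an
# unobserved reference).
heal_references <- function(spec, data) {
  for (i in seq_len(nrow(spec))) {
    if (spec$kind[i] != "categorical") next
    v <- spec$variable[i]
    if (!v %in% names(data)) next
    obs <- table(as.character(data[[v]]))
    if (!spec$reference[i] %in% names(obs)) {
      modal <- names(obs)[which.max(obs)]
      message(sprintf(
        "reference level '%s' of '%s' unobserved; using modal level '%s'",
        spec$reference[i], v, modal))
      spec$reference[i] <- modal
    }
  }
  spec
}

# Serialize every pipeline artifact as CSV/JSON under `out_dir`.
write_pipeline_artifacts <- function(result, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  if (inherits(config, "claims_config"))
    write_claims(config, result$facilities, result$visits, out_dir)
  w(result$eci, "eci.csv")
  w(result$aeci, "aeci.csv")
  w(result$ranking, "ranking.csv")
  w(summary(result$facility_fit), "facility_fit.csv")
  w(as.data.frame(result$ratio_table), "ratio_table.csv")
  w(as.data.frame(result$seasonal), "seasonal_matrix.csv")
  w(result$monthly$profile, "monthly_profile.csv")
  jsonlite::write_json(
    list(parameters = as.list(result$fit$coefficients),
         loglik = result$fit$loglik,
         n_obs = result$fit$n_obs,
         converged = result$fit$converged,
         n_iter = result$fit$n_iter,
         gradient_norm = result$fit$gradient_norm,
         design_column_names = result$fit$design_column_names,
         covariance = result$fit$vcov),
    file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA,
    matrix = "rowmajor")
  jsonlite::write_json(
    list(n_in = result$prep$report$n_in,
         n_out = result$prep$report$n_out,
         n_dropped = result$prep$report$n_dropped,
         fraction_dropped = result$prep$report$fraction_dropped,
         per_variable_missing = as.list(result$prep$report$per_variable_missing),
         category_maps = lapply(result$prep$maps, unclass)),
    file.path(out_dir, "preprocess_report.json"), auto_unbox = TRUE,
    digits = NA)
  jsonlite::write_json(
    list(rmse_model = result$rmse$rmse_model,
         rmse_null = result$rmse$rmse_null,
         pct_reduction = result$rmse$pct_reduction),
    file.path(out_dir, "rmse.json"), auto_unbox = TRUE, digits = NA)
  run_log <- list(
    package_version = as.character(utils::packageVersion("codingintensity")),
    seed = if (inherits(config, "claims_config")) config$seed else NA,
    monthly_p_value = result$monthly$p_value,
    month_association_f = result$monthly$f_statistic)
  jsonlite::write_json(run_log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
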