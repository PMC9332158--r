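#' Complete-case filter
#'
#' Drops every visit with any missing field (`NA`, `NaN`, or an empty /
#' whitespace-only string) and reports what was removed. No imputation is
#' performed anywhere in the package: downstream models see complete rows
#' only.
#'
#' @param visits Visit table (data frame).
#' @return A list with `visits` (the filtered table) and `report`, a
#'   `"filter_report"` containing `n_in`, `n_out`, `n_dropped`,
#'   `fraction_dropped` and per-variable missingness counts.
#' @export
complete_case_filter <- function(visits) {
  stopifnot(is.data.frame(visits))
  n_in <- nrow(visits)
  miss <- vapply(visits, function(col) {
    m <- is.na(col)
    if (is.character(col)) m <- m | !nzchar(trimws(col))
    m
  }, logical(n_in))
  if (n_in == 1L) miss <- matrix(miss, nrow = 1L,
                                 dimnames = list(NULL, names(visits)))
  any_miss <- rowSums(miss) > 0
  out <- visits[!any_miss, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("complete-case filtering removed every row", call. = FALSE)
  report <- structure(
    list(n_in = n_in,
         n_out = nrow(out),
         n_dropped = sum(any_miss),
         fraction_dropped = sum(any_miss) / n_in,
         per_variable_missing = colSums(miss)),
    class = "filter_report")
  list(visits = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Complete-case filter: %d in, %d out, %d dropped (%.2f%%)\n",
              x$n_in, x$n_out, x$n_dropped, 100 * x$fraction_dropped))
  nz <- x$per_variable_missing[x$per_variable_missing > 0]
  if (length(nz))
    cat("  missing by variable:",
        paste(sprintf("%s=%d", names(nz), nz), collapse = ", "), "\n")
  invisible(x)
}

#' Collapse rare categorical levels
#'
#' Relabels, in a single pass per variable, every level whose observed
#' frequency is strictly below `threshold` into an `"Other"` level — the
#' existing `"Other"` level when the variable already has one, otherwise a
#' new `"Other (collapsed)"` level. Frequencies are computed once on the
#' input table (no cascading re-checks after merging). A level sitting
#' exactly at the threshold is retained: the rule is a strict inequality.
#'
#' @param visits Visit table.
#' @param threshold Frequency threshold in (0, 0.5); default 0.001 (0.1%).
#' @param protected Variables never collapsed (default `"sex"`, whose rare
#'   Unknown level is conventionally reported as-is in this cohort).
#' @param id_cols Columns never treated as categorical variables.
#' @return List with `visits` (collapsed table) and `maps`, a list of
#'   `"category_map"` records (variable, collapsed levels, target level,
#'   threshold) — empty when nothing was collapsed.
#' @export
collapse_rare_categories <- function(visits, threshold = 0.001,
                                     protected = "sex",
                                     id_cols = c("visit_id", "facility_id")) {
  stopifnot(is.data.frame(visits), threshold > 0, threshold < 0.5)
  n <- nrow(visits)
  maps <- list()
  vars <- names(visits)[vapply(visits, function(c)
    is.character(c) || is.factor(c), logical(1))]
  vars <- setdiff(vars, c(protected, id_cols))
  for (v in vars) {
    vals <- as.character(visits[[v]])
    freq <- table(vals) / n
    rare <- names(freq)[freq < threshold]
    if (!length(rare)) next
    target <- if ("Other" %in% names(freq)) "Other" else "Other (collapsed)"
    rare <- setdiff(rare, target)
    if (!length(rare)) next
    vals[vals %in% rare] <- target
    visits[[v]] <- vals
    maps[[length(maps) + 1L]] <- structure(
      list(variable = v, collapsed_levels = sort(rare),
           target_level = target, threshold = threshold),
      class = "category_map")
  }
  list(visits = visits, maps = maps)
}

#' Apply recorded category merges to a table
#'
#' Replays the merges recorded by [collapse_rare_categories()] so a second
#' table (or the original) can be brought onto the collapsed level sets.
#'
#' @param visits Visit table.
#' @param maps List of `"category_map"` records.
#' @return The relabeled table.
#' @export
apply_category_maps <- function(visits, maps) {
  for (m in maps) {
    vals <- as.character(visits[[m$variable]])
    vals[vals %in% m$collapsed_levels] <- m$target_level
    visits[[m$variable]] <- vals
  }
  visits
}

#' Add the log length-of-stay covariate
#'
#' Appends `log_los = log(los_days)` (natural log). Non-positive or
#' missing stays produce `NA`, which the complete-case filter then removes
#' when the pipeline is run in order.
#'
#' @param visits Visit table with a `los_days` column.
#' @return The table with a `log_los` column.
#' @export
add_log_los <- function(visits) {
  if (!"los_days" %in% names(visits))
    stop("`visits` has no `los_days` column", call. = FALSE)
  los <- visits$los_days
  ok <- !is.na(los) & los > 0
  log_los <- rep(NA_real_, length(los))
  log_los[ok] <- log(los[ok])
  visits$log_los <- log_los
  visits
}

#' Run the standard preprocessing pipeline
#'
#' Fixed order: log length-of-stay transform (routing invalid stays to
#' missingness), complete-case filter, rare-category collapse. Re-running
#' on its own output is a no-op.
#'
#' @param visits Raw visit table.
#' @param threshold,protected Passed to [collapse_rare_categories()].
#' @return List with `visits`, `report` (filter report) and `maps`
#'   (category maps).
#' @export
preprocess_visits <- function(visits, threshold = 0.001, protected = "sex") {
  staged <- add_log_los(visits)
  filtered <- complete_case_filter(staged)
  collapsed <- collapse_rare_categories(filtered$visits, threshold = threshold,
                                        protected = protected)
  list(visits = collapsed$visits, report = filtered$report,
       maps = collapsed$maps)
}
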