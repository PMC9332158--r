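#' Build a design-matrix specification
#'
#' A design spec fixes, once, which variables enter a model, whether each is
#' categorical or continuous, and the reference level of each categorical.
#' Freezing the spec (rather than deriving it from whatever levels a data
#' set happens to contain) keeps fitted coefficient vectors stable across
#' runs and data subsets.
#'
#' @param variable Character vector of variable names.
#' @param kind `"categorical"` or `"continuous"`, recycled as needed.
#' @param reference Reference level per variable (`NA` for continuous).
#' @return A data frame of class `"design_spec"`.
#' @examples
#' design_spec(c("sex", "log_los"), c("categorical", "continuous"),
#'             c("Female", NA))
#' @export
design_spec <- function(variable, kind, reference = NA_character_) {
  kind <- match.arg(kind, c("categorical", "continuous"), several.ok = TRUE)
  out <- data.frame(variable = as.character(variable),
                    kind = rep_len(kind, length(variable)),
                    reference = rep_len(as.character(reference), length(variable)),
                    stringsAsFactors = FALSE)
  bad <- out$kind == "categorical" & is.na(out$reference)
  if (any(bad))
    stop("categorical variables need a reference level: ",
         paste(out$variable[bad], collapse = ", "), call. = FALSE)
  class(out) <- c("design_spec", "data.frame")
  out
}

#' Default patient-level design specification
#'
#' Sex (reference Female), race (reference White), log length of stay and
#' the AHRQ tract summary index: the compact covariate set that carries the
#' true effects in the default synthetic configuration. With `full = TRUE`
#' the remaining claim fields (age group, payor, point of origin, discharge
#' status, principal diagnosis group, MS-DRG) are added with the reference
#' levels conventional for this cohort (over-84 age, Medicare Traditional,
#' non-healthcare-facility origin, home/self-care discharge, M17, MS-DRG
#' 470).
#'
#' @param full Include the full claim variable set.
#' @return A `"design_spec"` object.
#' @export
patient_design_spec <- function(full = FALSE) {
  base <- design_spec(
    variable = c("sex", "race", "log_los", "ahrq_index"),
    kind = c("categorical", "categorical", "continuous", "continuous"),
    reference = c("Female", "White", NA, NA))
  if (!full) return(base)
  extra <- design_spec(
    variable = c("age_group", "primary_payor", "point_of_origin",
                 "discharge_status", "principal_dx_group", "msdrg"),
    kind = "categorical",
    reference = c(">84", "Medicare Traditional", "Non-Healthcare Facility",
                  "Home or Self-Care", "M17", "470"))
  out <- rbind(base, extra)
  class(out) <- c("design_spec", "data.frame")
  out
}

#' Default facility-level design specification
#'
#' Teaching status, academic status, urban/rural, ownership, bed-count
#' band, Census regional division and case-mix-index band, with the
#' reference levels no / no / urban / voluntary non-profit-private / 1-100
#' beds / South Atlantic / CMI 0.
#'
#' @return A `"design_spec"` object.
#' @export
facility_design_spec <- function() {
  design_spec(
    variable = c("teaching_status", "academic_status", "urban_rural",
                 "ownership", "bed_count_band", "census_division",
                 "cmi_band"),
    kind = "categorical",
    reference = c("No", "No", "Urban", "Voluntary Non-Profit-Private",
                  "1-100", "South Atlantic", "0"))
}

#' Encode a table into a reference-coded design matrix
#'
#' Builds the numeric design matrix for a model: an intercept column of
#' ones, then for each spec variable in order either the continuous column
#' passed through unchanged or one 0/1 indicator per non-reference level
#' (levels in lexicographic order). Column names are `"variable=level"` for
#' indicators. Unseen levels simply produce no indicator; a reference level
#' absent from the data is an error because the implied contrast would be
#' undefined.
#'
#' @param data Data frame holding the spec variables (one row per visit).
#' @param spec A [design_spec()].
#' @param row_keys Optional identifier vector stored with the matrix
#'   (defaults to `data$visit_id` when present).
#' @return An object of class `"design_matrix"`: a list with elements `x`
#'   (numeric matrix), `row_keys`, `reference_levels` and `spec`.
#' @export
encode_design <- function(data, spec, row_keys = NULL) {
  stopifnot(inherits(spec, "design_spec"))
  missing_vars <- setdiff(spec$variable, names(data))
  if (length(missing_vars))
    stop("variables absent from data: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  if (is.null(row_keys) && "visit_id" %in% names(data))
    row_keys <- data$visit_id
  n <- nrow(data)
  cols <- list("(Intercept)" = rep(1, n))
  refs <- character(0)
  for (i in seq_len(nrow(spec))) {
    v <- spec$variable[i]
    if (spec$kind[i] == "continuous") {
      x <- data[[v]]
      if (!is.numeric(x))
        stop(sprintf("continuous variable '%s' is not numeric", v),
             call. = FALSE)
      cols[[v]] <- as.numeric(x)
    } else {
      vals <- as.character(data[[v]])
      levels <- sort(unique(vals))
      ref <- spec$reference[i]
      if (!ref %in% levels)
        stop(sprintf("reference level '%s' of '%s' not observed in data",
                     ref, v), call. = FALSE)
      refs[v] <- ref
      for (lev in setdiff(levels, ref))
        cols[[paste0(v, "=", lev)]] <- as.numeric(vals == lev)
    }
  }
  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  structure(list(x = x, row_keys = row_keys, reference_levels = refs,
                 spec = spec),
            class = "design_matrix")
}

#' @export
as.matrix.design_matrix <- function(x, ...) x$x

#' @export
dim.design_matrix <- function(x) dim(x$x)

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("Design matrix: %d rows x %d columns\n", nrow(x$x), ncol(x$x)))
  cat("  columns:", paste(utils::head(colnames(x$x), 8), collapse = ", "),
      if (ncol(x$x) > 8) "..." else "", "\n")
  if (length(x$reference_levels)) {
    cat("  references:",
        paste(sprintf("%s=%s", names(x$reference_levels), x$reference_levels),
              collapse = ", "), "\n")
  }
  invisible(x)
}

# Align a named coefficient vector to the non-intercept columns of a design
# matrix; unnamed columns get 0, unknown names are an error.
align_coefs <- function(coefs, design_colnames, what = "coefficient") {
  non_int <- setdiff(design_colnames, "(Intercept)")
  full <- stats::setNames(numeric(length(non_int)), non_int)
  if (length(coefs)) {
    unknown <- setdiff(names(coefs), non_int)
    if (length(unknown))
      stop(sprintf("%s names not present in design: %s", what,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    full[names(coefs)] <- coefs
  }
  full
}
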