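#' Per-facility mean AECI ranking
#'
#' Averages AECI across the visits of each facility and ranks facilities
#' ascending (rank 1 = lowest mean AECI, i.e. strongest under-coding
#' relative to expectation; the top ranks are the strongest over-coders).
#' Ties are broken by facility ID, so the ranking is deterministic and
#' invariant to visit order.
#'
#' @param aeci AECI table from [compute_aeci()] (any table with
#'   `facility_id` and `aeci` columns).
#' @return Data frame sorted by rank: `facility_id`, `n_visits`,
#'   `mean_aeci`, `rank`.
#' @export
facility_mean_aeci <- function(aeci) {
  if (nrow(aeci) == 0L) stop("empty AECI table", call. = FALSE)
  agg <- stats::aggregate(aeci$aeci, by = list(facility_id = aeci$facility_id),
                          FUN = mean)
  cnt <- as.data.frame(table(facility_id = aeci$facility_id),
                       stringsAsFactors = FALSE)
  out <- merge(agg, cnt, by = "facility_id")
  names(out) <- c("facility_id", "mean_aeci", "n_visits")
  out <- out[order(out$mean_aeci, out$facility_id), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("facility_id", "n_visits", "mean_aeci", "rank")]
}

#' Aggregate AECI by Census division and calendar quarter
#'
#' Averages AECI (AAECI) within each of the nine Census regional divisions
#' crossed with calendar quarters (Q1 = January-March, ..., Q4 =
#' October-December). Cells with no visits are `NA`, never zero-filled.
#'
#' @param aeci AECI table.
#' @param divisions Per-visit Census division labels (must come from the
#'   nine-division set, see [census_divisions()]).
#' @param months Per-visit admission months, integers 1-12.
#' @return Object of class `"seasonal_matrix"`: a list with `aaeci` (9 x 4
#'   matrix, divisions x quarters) and `n` (cell visit counts).
#' @export
aaeci_by_division_quarter <- function(aeci, divisions, months) {
  if (!all(divisions %in% .census_divisions))
    stop("unknown Census division label(s): ",
         paste(unique(setdiff(divisions, .census_divisions)), collapse = ", "),
         call. = FALSE)
  if (!all(months %in% 1:12))
    stop("months must be integers 1-12", call. = FALSE)
  if (length(divisions) != nrow(aeci) || length(months) != nrow(aeci))
    stop("`divisions`/`months` must align with `aeci`", call. = FALSE)
  quarter <- factor(paste0("Q", (as.integer(months) - 1L) %/% 3L + 1L),
                    levels = paste0("Q", 1:4))
  div <- factor(divisions, levels = .census_divisions)
  sums <- tapply(aeci$aeci, list(div, quarter), sum)
  n <- table(div, quarter)
  aaeci <- sums / ifelse(n > 0, n, NA)
  n_mat <- matrix(as.integer(n), nrow = 9,
                  dimnames = list(.census_divisions, paste0("Q", 1:4)))
  structure(list(aaeci = aaeci, n = n_mat), class = "seasonal_matrix")
}

#' @export
print.seasonal_matrix <- function(x, ...) {
  cat("AAECI by Census division x quarter\n")
  print(round(x$aaeci, 4))
  invisible(x)
}

#' Turn a seasonal matrix into a long data frame
#'
#' @param x A `"seasonal_matrix"`.
#' @param ... Unused.
#' @return Data frame with `census_division`, `quarter`, `aaeci`, `n`
#'   (one row per cell, empty cells with `NA` aaeci).
#' @export
as.data.frame.seasonal_matrix <- function(x, ...) {
  data.frame(census_division = rep(rownames(x$aaeci), times = 4),
             quarter = rep(colnames(x$aaeci), each = 9),
             aaeci = as.vector(x$aaeci),
             n = as.vector(x$n),
             stringsAsFactors = FALSE)
}

#' Monthly AECI profile with an admission-month association test
#'
#' Computes mean AECI per admission month and tests the association of
#' admission month with the residual by a one-way F test: OLS of AECI on
#' month indicators (reference January), F against the intercept-only
#' model with `(k - 1, n - k)` degrees of freedom for `k` observed months.
#'
#' @param aeci AECI table (or, if preferred, an ECI table with the column
#'   renamed; the profile applies to either residual).
#' @param months Per-visit admission months, integers 1-12 with at least
#'   two distinct values.
#' @return Object of class `"monthly_profile"`: data frame `profile`
#'   (`month`, `mean`, `n` for all 12 months, `NA` mean where unobserved),
#'   plus `f_statistic`, `df1`, `df2`, `p_value`, `n_obs`.
#' @export
monthly_profile <- function(aeci, months) {
  if (!all(months %in% 1:12))
    stop("months must be integers 1-12", call. = FALSE)
  if (length(months) != nrow(aeci))
    stop("`months` must align with `aeci`", call. = FALSE)
  if (length(unique(months)) < 2L)
    stop("need at least two distinct admission months", call. = FALSE)
  vals <- aeci[[if ("aeci" %in% names(aeci)) "aeci" else "eci"]]
  m <- factor(as.integer(months), levels = 1:12)
  means <- tapply(vals, m, mean)
  n <- as.integer(table(m))
  fit <- stats::lm(vals ~ droplevels(m))
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- stats::pf(fstat[["value"]], fstat[["numdf"]], fstat[["dendf"]],
                 lower.tail = FALSE)
  structure(
    list(profile = data.frame(month = 1:12, mean = as.vector(means), n = n),
         f_statistic = unname(fstat[["value"]]),
         df1 = unname(fstat[["numdf"]]),
         df2 = unname(fstat[["dendf"]]),
         p_value = unname(p),
         n_obs = length(vals)),
    class = "monthly_profile")
}

#' @export
print.monthly_profile <- function(x, ...) {
  cat(sprintf("Monthly residual profile: F(%d, %d) = %.3f, p = %.4g\n",
              x$df1, x$df2, x$f_statistic, x$p_value))
  print(transform(x$profile, mean = round(mean, 4)))
  invisible(x)
}

#' Dot plot of the facility ranking
#'
#' @param ranking Output of [facility_mean_aeci()].
#' @return A ggplot object (requires ggplot2).
#' @export
plot_facility_ranking <- function(ranking) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  ggplot2::ggplot(ranking,
                  ggplot2::aes(x = .data$rank, y = .data$mean_aeci)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Facility rank", y = "Mean AECI per facility") +
    ggplot2::theme_minimal()
}

#' Heatmap of AAECI by division and quarter
#'
#' @param sm A `"seasonal_matrix"`.
#' @return A ggplot object (requires ggplot2).
#' @export
plot_seasonal_heatmap <- function(sm) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- as.data.frame(sm)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$quarter,
                                   y = .data$census_division,
                                   fill = .data$aaeci)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "Quarter", y = "Census division", fill = "AAECI") +
    ggplot2::theme_minimal()
}
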