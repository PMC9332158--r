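#' Generate a synthetic facility table
#'
#' Draws `n_facilities` facilities with categorical characteristics sampled
#' independently from the configured facility marginals, plus one
#' idiosyncratic Normal log-rate effect per facility (bookkept in a truth
#' table, never exported with the data). The draw uses its own seed
#' substream, so changing `n_visits` leaves the facility table untouched.
#'
#' @param config A [claims_config()].
#' @return A data frame (one row per facility) with `facility_id` and the
#'   configured characteristic columns. The attribute `"truth"` holds a
#'   data frame with the idiosyncratic effect, the structured
#'   `theta * FL` shift and their sum (`total_log_shift`, zero when
#'   `facility_effect_mode = "none"`).
#' @export
generate_facilities <- function(config) {
  validate_claims_config(config)
  n <- config$n_facilities
  with_seed(substream_seed(config$seed, 1L), {
    fac <- data.frame(facility_id = sprintf("F%05d", seq_len(n)),
                      stringsAsFactors = FALSE)
    for (v in names(config$facility_marginals)) {
      p <- config$facility_marginals[[v]]
      fac[[v]] <- sample(names(p), n, replace = TRUE, prob = p)
    }
    idio <- stats::rnorm(n, 0, config$facility_idiosyncratic_sd)
    theta_fl <- facility_theta_shift(fac, config$true_theta)
    active <- config$facility_effect_mode == "rate_shift"
    truth <- data.frame(
      facility_id = fac$facility_id,
      idiosyncratic = idio,
      theta_fl = theta_fl,
      total_log_shift = if (active) theta_fl + idio else 0,
      stringsAsFactors = FALSE)
    attr(fac, "truth") <- truth
    fac
  })
}

# Linear predictor contribution of a named coefficient vector evaluated
# directly on a data frame: "variable=level" names add coef * 1{var == level},
# bare names add coef * the numeric column. Unlike a design-matrix product
# this does not depend on which levels happen to be observed.
linpred_from_named <- function(data, coefs, what = "coefficient") {
  out <- numeric(nrow(data))
  for (nm in names(coefs)) {
    parts <- regmatches(nm, regexpr("=", nm), invert = TRUE)[[1]]
    if (length(parts) == 2L) {
      if (!parts[1] %in% names(data))
        stop(sprintf("%s name '%s' does not match a variable=level", what, nm),
             call. = FALSE)
      out <- out + coefs[[nm]] * (data[[parts[1]]] == parts[2])
    } else {
      if (!nm %in% names(data) || !is.numeric(data[[nm]]))
        stop(sprintf("%s name '%s' is not a numeric variable", what, nm),
             call. = FALSE)
      out <- out + coefs[[nm]] * data[[nm]]
    }
  }
  out
}

# theta * FL for each facility row, from "variable=level"-named shifts.
facility_theta_shift <- function(facilities, true_theta) {
  linpred_from_named(facilities, true_theta, "true_theta")
}

# Seasonal log-rate term: amplitude * -cos peaking away from, and dipping
# at, August (month 8).
seasonal_log_rate <- function(month, amplitude) {
  if (amplitude == 0) return(numeric(length(month)))
  -amplitude * cos(2 * pi * (month - 8) / 12)
}

#' Generate a synthetic visit table
#'
#' Draws patient covariates, admission month, length of stay and the AHRQ
#' index from the configured marginals, assigns each visit a facility
#' uniformly, and draws the outcome count from the configured
#' zero-inflated Poisson truth: `logit(pi) = alpha1 + gamma * PL`,
#' `log(lambda) = alpha2 + beta * PL`, with the facility log-rate shift
#' (structured `theta * FL` plus idiosyncratic) added to `log(lambda)` when
#' `facility_effect_mode = "rate_shift"`, and a seasonal sinusoid (trough
#' in August) added when `seasonal_amplitude > 0`. Then `y = 0` with
#' probability `pi`, else `y ~ Poisson(lambda)`.
#'
#' @param config A [claims_config()].
#' @param facilities A facility table from [generate_facilities()].
#' @return A data frame with one row per visit (`visit_id`, `facility_id`,
#'   outcome `y`, the categorical covariates, `los_days`, `ahrq_index`,
#'   `admission_month`). The per-visit truth (`pi`, `lam`) is attached as
#'   attribute `"truth"` and never part of the exported columns.
#' @export
generate_visits <- function(config, facilities) {
  validate_claims_config(config)
  if (is.null(facilities) || nrow(facilities) == 0L)
    stop("`facilities` must be a nonempty facility table", call. = FALSE)
  if (anyDuplicated(facilities$facility_id))
    stop("facility_id values must be unique", call. = FALSE)
  n <- config$n_visits
  with_seed(substream_seed(config$seed, 2L), {
    visits <- data.frame(visit_id = sprintf("V%07d", seq_len(n)),
                         facility_id = sample(facilities$facility_id, n,
                                              replace = TRUE),
                         stringsAsFactors = FALSE)
    for (v in names(config$patient_marginals)) {
      p <- config$patient_marginals[[v]]
      visits[[v]] <- sample(names(p), n, replace = TRUE, prob = p)
    }
    visits$los_days <- config$los_distribution$shift +
      stats::rlnorm(n, config$los_distribution$meanlog,
                    config$los_distribution$sdlog)
    visits$ahrq_index <- stats::rbeta(n, config$ahrq_distribution$shape1,
                                      config$ahrq_distribution$shape2)
    visits$admission_month <- as.integer(sample(
      names(config$month_marginals), n, replace = TRUE,
      prob = config$month_marginals))

    # Linear predictors of the truth, evaluated directly on the covariates
    # so they never depend on which levels a finite draw happens to contain.
    internal <- visits
    internal$log_los <- log(visits$los_days)
    eta1 <- config$true_alpha1 +
      linpred_from_named(internal, config$true_gamma, "true_gamma")
    eta2 <- config$true_alpha2 +
      linpred_from_named(internal, config$true_beta, "true_beta")
    if (config$facility_effect_mode == "rate_shift") {
      truth_fac <- attr(facilities, "truth")
      if (is.null(truth_fac))
        stop("facility table lacks its truth attribute; regenerate it with generate_facilities()",
             call. = FALSE)
      idx <- match(visits$facility_id, truth_fac$facility_id)
      if (anyNA(idx))
        stop("visit references a facility_id absent from the facility table",
             call. = FALSE)
      eta2 <- eta2 + truth_fac$total_log_shift[idx]
    }
    eta2 <- eta2 + seasonal_log_rate(visits$admission_month,
                                     config$seasonal_amplitude)

    pi <- stats::plogis(eta1)
    lam <- exp(eta2)
    structural_zero <- stats::runif(n) < pi
    y <- integer(n)
    y[!structural_zero] <- stats::rpois(sum(!structural_zero),
                                        lam[!structural_zero])
    visits$y <- y
    visits <- visits[, c("visit_id", "facility_id", "y",
                         setdiff(names(visits),
                                 c("visit_id", "facility_id", "y")))]
    attr(visits, "truth") <- data.frame(visit_id = visits$visit_id,
                                        pi = pi, lam = lam,
                                        stringsAsFactors = FALSE)
    visits
  })
}

#' Write generated claims tables to disk
#'
#' Writes `facilities.csv` and `visits.csv` (RFC-4180, header row, UTF-8)
#' plus `truth.json` holding the true generator parameters and the
#' per-visit `pi` and `lambda`, for test harnesses and reproducibility.
#'
#' @param config The [claims_config()] used for generation.
#' @param facilities,visits The generated tables (with truth attributes).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_claims <- function(config, facilities, visits, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fac_path <- file.path(dir, "facilities.csv")
  vis_path <- file.path(dir, "visits.csv")
  truth_path <- file.path(dir, "truth.json")
  utils::write.csv(as.data.frame(facilities), fac_path, row.names = FALSE)
  utils::write.csv(as.data.frame(visits), vis_path, row.names = FALSE)
  truth <- list(
    true_alpha1 = config$true_alpha1,
    true_alpha2 = config$true_alpha2,
    true_gamma = as.list(config$true_gamma),
    true_beta = as.list(config$true_beta),
    true_theta = as.list(config$true_theta),
    facility_effect_mode = config$facility_effect_mode,
    facility_idiosyncratic_sd = config$facility_idiosyncratic_sd,
    seasonal_amplitude = config$seasonal_amplitude,
    facility_truth = attr(facilities, "truth"),
    visit_truth = attr(visits, "truth"))
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(facilities = fac_path, visits = vis_path, truth = truth_path))
}
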