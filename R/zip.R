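#' Zero-inflated Poisson parameter bundle
#'
#' The model has two linked components sharing one covariate set: a
#' logit-linked probability `pi` of a structural zero (intercept `alpha1`,
#' coefficients `gamma`) and a log-linked Poisson rate `lambda` (intercept
#' `alpha2`, coefficients `beta`). The observed count is zero with
#' probability `pi` and Poisson(`lambda`) otherwise.
#'
#' @param alpha1 Zero-inflation intercept (logit scale).
#' @param gamma Named zero-inflation coefficient vector.
#' @param alpha2 Count intercept (log scale).
#' @param beta Named count coefficient vector (same length/names as
#'   `gamma`).
#' @return An object of class `"zip_params"`.
#' @export
zip_params <- function(alpha1, gamma, alpha2, beta) {
  if (length(gamma) != length(beta))
    stop("`gamma` and `beta` must have the same length", call. = FALSE)
  structure(list(alpha1 = as.numeric(alpha1),
                 gamma = stats::setNames(as.numeric(gamma), names(gamma)),
                 alpha2 = as.numeric(alpha2),
                 beta = stats::setNames(as.numeric(beta), names(beta))),
            class = "zip_params")
}

# Flatten to the joint optimizer vector: (alpha1, gamma..., alpha2, beta...)
zip_flatten <- function(params) {
  c(params$alpha1, params$gamma, params$alpha2, params$beta)
}

zip_unflatten <- function(v, p, names_non_int = NULL) {
  k <- p - 1L
  zip_params(alpha1 = v[1L],
             gamma = stats::setNames(v[seq_len(k) + 1L], names_non_int),
             alpha2 = v[p + 1L],
             beta = stats::setNames(v[p + 1L + seq_len(k)], names_non_int))
}

design_x <- function(X) {
  if (inherits(X, "design_matrix")) X$x else as.matrix(X)
}

zip_linpred <- function(params, x) {
  p <- ncol(x)
  list(eta1 = drop(x %*% c(params$alpha1, params$gamma)),
       eta2 = drop(x %*% c(params$alpha2, params$beta)))
}

#' Zero-inflated Poisson log-likelihood
#'
#' For zero counts the contribution is
#' `log(pi + (1 - pi) * exp(-lambda))`, evaluated through a log-sum-exp
#' identity so extreme linear predictors cannot underflow; for positive
#' counts it is `log(1 - pi) - lambda + y * log(lambda) - log(y!)` with
#' `log(y!)` via `lgamma`.
#'
#' @param params A [zip_params()] object.
#' @param X Design matrix (intercept first column) or `"design_matrix"`.
#' @param y Nonnegative integer counts.
#' @return The scalar log-likelihood.
#' @export
zip_loglik <- function(params, X, y) {
  x <- design_x(X)
  stop_if_not_count(y)
  if (length(y) != nrow(x))
    stop("`y` and `X` are not conformable", call. = FALSE)
  lp <- zip_linpred(params, x)
  eta1 <- lp$eta1
  lam <- exp(lp$eta2)
  ll <- numeric(length(y))
  z <- y == 0
  # log p0 = log(exp(eta1) + exp(-lambda)) - log(1 + exp(eta1))
  ll[z] <- logsumexp2(eta1[z], -lam[z]) - log1pexp(eta1[z])
  ll[!z] <- -log1pexp(eta1[!z]) - lam[!z] + y[!z] * lp$eta2[!z] -
    lgamma(y[!z] + 1)
  sum(ll)
}

#' Analytic score of the zero-inflated Poisson log-likelihood
#'
#' Exact gradient with respect to the joint parameter vector
#' `(alpha1, gamma, alpha2, beta)`. Per observation, with
#' `p0 = pi + (1 - pi) exp(-lambda)`:
#' zeros contribute `pi (1 - pi)(1 - e^-lambda) / p0` to the logit block
#' and `-(1 - pi) e^-lambda lambda / p0` to the log block; positive counts
#' contribute `-pi` and `y - lambda`. The design matrix then maps these
#' per-observation terms onto the coefficients.
#'
#' @inheritParams zip_loglik
#' @return Numeric gradient vector of length `2 * ncol(X)`.
#' @export
zip_score <- function(params, X, y) {
  x <- design_x(X)
  stop_if_not_count(y)
  if (length(y) != nrow(x))
    stop("`y` and `X` are not conformable", call. = FALSE)
  lp <- zip_linpred(params, x)
  pi <- stats::plogis(lp$eta1)
  lam <- exp(lp$eta2)
  z <- y == 0
  d1 <- numeric(length(y))
  d2 <- numeric(length(y))
  if (any(z)) {
    # stable p0 via the log form used by the likelihood
    logp0 <- logsumexp2(lp$eta1[z], -lam[z]) - log1pexp(lp$eta1[z])
    p0 <- pmax(exp(logp0), .Machine$double.xmin)
    em <- exp(-lam[z])
    d1[z] <- pi[z] * (1 - pi[z]) * (1 - em) / p0
    d2[z] <- -(1 - pi[z]) * em * lam[z] / p0
  }
  d1[!z] <- -pi[!z]
  d2[!z] <- y[!z] - lam[!z]
  c(drop(crossprod(x, d1)), drop(crossprod(x, d2)))
}

# Solve info %*% x = g through an eigendecomposition, flooring small or
# negative eigenvalues. Quasi-separated fits have likelihood directions
# that flatten toward a boundary; the floor turns those into large finite
# steps (and, for the covariance, large finite Wald variances) instead of
# a singular solve.
info_pseudo_solve <- function(info, g = NULL, rel_floor = 1e-10) {
  ed <- eigen((info + t(info)) / 2, symmetric = TRUE)
  emax <- max(ed$values)
  if (!is.finite(emax) || emax <= 0) return(NULL)
  inv_vals <- 1 / pmax(ed$values, emax * rel_floor)
  if (is.null(g)) {
    ed$vectors %*% (inv_vals * t(ed$vectors))
  } else {
    drop(ed$vectors %*% (inv_vals * crossprod(ed$vectors, g)))
  }
}

# Observed information at `v`: negative Jacobian of the analytic score by
# central finite differences (column count is small, so 2p score calls).
zip_observed_info <- function(v, x, y, names_non_int, h = 1e-5) {
  p <- ncol(x)
  q <- length(v)
  J <- matrix(NA_real_, q, q)
  for (j in seq_len(q)) {
    hj <- h * max(1, abs(v[j]))
    vp <- v; vp[j] <- vp[j] + hj
    vm <- v; vm[j] <- vm[j] - hj
    sp <- zip_score(zip_unflatten(vp, p, names_non_int), x, y)
    sm <- zip_score(zip_unflatten(vm, p, names_non_int), x, y)
    J[, j] <- (sp - sm) / (2 * hj)
  }
  -(J + t(J)) / 2
}

#' Fit the zero-inflated Poisson model by maximum likelihood
#'
#' Quasi-Newton (BFGS) maximization of [zip_loglik()] with the analytic
#' [zip_score()], followed by Newton polishing steps (with step halving)
#' until the score sup-norm falls below `tol`. Starting values: the
#' zero-component block from a logistic regression of `1{y == 0}` on `X`,
#' the count block from a Poisson regression of `y` on `X` restricted to
#' `y > 0`. The covariance is the inverse of the observed information
#' estimated by finite differences of the analytic score at the optimum;
#' when the information is singular the covariance entries are `NA` and
#' downstream ratio tables flag the affected coefficients.
#'
#' @param X Design matrix (`"design_matrix"` or numeric matrix whose first
#'   column is the intercept).
#' @param y Nonnegative integer counts, with at least one zero and one
#'   positive value.
#' @param tol Convergence tolerance on the score sup-norm.
#' @param max_iter Maximum optimizer iterations.
#' @param start Optional [zip_params()] starting value.
#' @return An object of class `"zip_fit"`: `params`, `coefficients`
#'   (flattened, named `zero_*` / `count_*`), `vcov`, `loglik`, `n_obs`,
#'   `converged`, `n_iter`, `gradient_norm`, `design_column_names`.
#' @export
fit_zip <- function(X, y, tol = 1e-6, max_iter = 500L, start = NULL) {
  x <- design_x(X)
  stop_if_not_count(y)
  n <- length(y)
  p <- ncol(x)
  if (n != nrow(x)) stop("`y` and `X` are not conformable", call. = FALSE)
  if (n <= 2L * p)
    stop("need more observations than parameters (2 * ncol(X))", call. = FALSE)
  if (!any(y == 0) || !any(y > 0))
    stop("`y` must contain at least one zero and one positive count",
         call. = FALSE)
  names_non_int <- colnames(x)[-1L]

  if (is.null(start)) {
    g0 <- tryCatch(
      stats::glm.fit(x, as.numeric(y == 0),
                     family = stats::binomial())$coefficients,
      error = function(e) rep(0, p))
    b0 <- tryCatch(
      stats::glm.fit(x[y > 0, , drop = FALSE], y[y > 0],
                     family = stats::poisson())$coefficients,
      error = function(e) rep(0, p))
    g0[!is.finite(g0)] <- 0
    b0[!is.finite(b0)] <- 0
    v0 <- c(g0, b0)
  } else {
    v0 <- zip_flatten(start)
  }

  negll <- function(v) -zip_loglik(zip_unflatten(v, p, names_non_int), x, y)
  neggr <- function(v) -zip_score(zip_unflatten(v, p, names_non_int), x, y)
  ll_start <- -negll(v0)

  opt <- stats::optim(v0, fn = negll, gr = neggr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-14))
  v <- opt$par
  n_iter <- opt$counts[["gradient"]]

  # Newton polish to drive the score norm below tol; BFGS alone often
  # stops on function-value stagnation with a still-loose gradient.
  ll <- -negll(v)
  for (it in seq_len(30L)) {
    g <- zip_score(zip_unflatten(v, p, names_non_int), x, y)
    if (max(abs(g)) < tol) break
    info <- zip_observed_info(v, x, y, names_non_int)
    step <- info_pseudo_solve(info, g)
    if (is.null(step) || !all(is.finite(step))) break
    improved <- FALSE
    for (half in 0:20) {
      v_new <- v + step / 2^half
      ll_new <- -negll(v_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) {
        v <- v_new; ll <- ll_new; improved <- TRUE
        break
      }
    }
    n_iter <- n_iter + 1L
    if (!improved) break
  }

  g <- zip_score(zip_unflatten(v, p, names_non_int), x, y)
  gradient_norm <- max(abs(g))
  converged <- gradient_norm < tol
  if (!converged)
    warning(sprintf(
      "ZIP fit did not reach the score tolerance (sup-norm %.3g > %.3g)",
      gradient_norm, tol), call. = FALSE)

  info <- zip_observed_info(v, x, y, names_non_int)
  vc <- info_pseudo_solve(info)
  if (is.null(vc)) {
    vc <- matrix(NA_real_, 2L * p, 2L * p)
  } else if (any(!is.finite(vc)) || any(diag(vc) < 0)) {
    bad <- !is.finite(diag(vc)) | diag(vc) < 0
    vc[bad, ] <- NA_real_
    vc[, bad] <- NA_real_
  }
  coef_names <- c(paste0("zero_", colnames(x)),
                  paste0("count_", colnames(x)))
  dimnames(vc) <- list(coef_names, coef_names)

  structure(
    list(params = zip_unflatten(v, p, names_non_int),
         coefficients = stats::setNames(v, coef_names),
         vcov = vc,
         loglik = ll,
         loglik_start = ll_start,
         n_obs = n,
         converged = converged,
         n_iter = as.integer(n_iter),
         gradient_norm = gradient_norm,
         design_column_names = colnames(x)),
    class = "zip_fit")
}

#' @export
print.zip_fit <- function(x, ...) {
  cat(sprintf(
    "Zero-inflated Poisson fit: n = %d, logLik = %.3f, %sconverged (score sup-norm %.2g)\n",
    x$n_obs, x$loglik, if (x$converged) "" else "NOT ", x$gradient_norm))
  est <- x$coefficients
  se <- sqrt(diag(x$vcov))
  print(round(cbind(estimate = est, se = se), 4))
  invisible(x)
}

#' @export
coef.zip_fit <- function(object, ...) object$coefficients

#' @export
vcov.zip_fit <- function(object, ...) object$vcov

#' @export
logLik.zip_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n_obs, class = "logLik")
}

#' Predict zero-inflation probability, rate and mixture mean
#'
#' Returns per-visit `pi` (inverse-logit of the zero-component linear
#' predictor), `lam` (exponentiated count predictor) and
#' `mean = (1 - pi) * lam`, the expected count under the mixture — the
#' expectation subtracted from the observed count to form the excess
#' coding intensity residual.
#'
#' @param object A `"zip_fit"`.
#' @param X Design matrix with exactly the columns the fit was trained on.
#' @param ... Unused.
#' @return Data frame with columns `pi`, `lam`, `mean`.
#' @export
predict.zip_fit <- function(object, X, ...) {
  x <- design_x(X)
  if (!identical(colnames(x), object$design_column_names))
    stop("design columns do not match the fitted model", call. = FALSE)
  predict_zip_params(object$params, x)
}

#' Mixture prediction from explicit parameters
#'
#' Same computation as [predict.zip_fit()] but from a bare
#' [zip_params()], so known-truth expectations can be formed without a
#' fit.
#'
#' @param params A [zip_params()].
#' @param X Design matrix (intercept first).
#' @return Data frame with columns `pi`, `lam`, `mean`.
#' @export
predict_zip_params <- function(params, X) {
  x <- design_x(X)
  lp <- zip_linpred(params, x)
  pi <- stats::plogis(lp$eta1)
  lam <- exp(lp$eta2)
  data.frame(pi = pi, lam = lam, mean = (1 - pi) * lam)
}

#' Incidence-rate-ratio / odds-ratio table with Wald intervals
#'
#' Exponentiates the count-block coefficients into incidence rate ratios
#' and the zero-block coefficients into odds ratios, with Wald confidence
#' intervals formed on the log/logit scale and then exponentiated.
#' Coefficients whose estimate or standard error has diverged (quasi-
#' separation) are flagged and displayed with a capped `0 .. Inf` interval
#' rather than astronomically scaled bounds.
#'
#' @param fit A `"zip_fit"`.
#' @param level Confidence level (default 0.95).
#' @param cap Absolute log-scale estimate (or standard error) beyond which
#'   a coefficient is treated as separated.
#' @return Data frame (class `"ratio_table"`) with one row per design
#'   column: `term`, `irr`, `irr_lo`, `irr_hi`, `or_`, `or_lo`, `or_hi`,
#'   `separation_flag`.
#' @export
ratio_table <- function(fit, level = 0.95, cap = 15) {
  stopifnot(inherits(fit, "zip_fit"))
  z <- stats::qnorm((1 + level) / 2)
  p <- length(fit$design_column_names)
  se <- sqrt(diag(fit$vcov))
  gamma_idx <- seq_len(p)
  beta_idx <- p + seq_len(p)
  mk <- function(est, s) {
    flag <- !is.finite(est) | !is.finite(s) | abs(est) > cap | s > cap
    lo <- exp(est - z * s)
    hi <- exp(est + z * s)
    lo[flag] <- 0
    hi[flag] <- Inf
    ratio <- exp(pmin(pmax(est, -cap * 3), cap * 3))
    data.frame(ratio = ratio, lo = lo, hi = hi, flag = flag)
  }
  irr <- mk(fit$coefficients[beta_idx], se[beta_idx])
  or_ <- mk(fit$coefficients[gamma_idx], se[gamma_idx])
  out <- data.frame(term = fit$design_column_names,
                    irr = irr$ratio, irr_lo = irr$lo, irr_hi = irr$hi,
                    or_ = or_$ratio, or_lo = or_$lo, or_hi = or_$hi,
                    separation_flag = irr$flag | or_$flag,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("ratio_table", "data.frame")
  out
}

#' Root-mean-square-error comparison against the mean-only model
#'
#' Compares the risk-adjusted predictions with the non-informative model
#' that predicts the observed mean for every visit:
#' `pct_reduction = 100 * (1 - rmse_model / rmse_null)`.
#'
#' @param y Observed counts.
#' @param pred_mean Model-predicted mixture means.
#' @return List of class `"rmse_report"` with `rmse_model`, `rmse_null`,
#'   `pct_reduction`.
#' @export
rmse_comparison <- function(y, pred_mean) {
  if (length(y) == 0L) stop("empty input", call. = FALSE)
  if (length(y) != length(pred_mean))
    stop("`y` and `pred_mean` lengths differ", call. = FALSE)
  rmse_model <- sqrt(mean((y - pred_mean)^2))
  rmse_null <- sqrt(mean((y - mean(y))^2))
  structure(list(rmse_model = rmse_model, rmse_null = rmse_null,
                 pct_reduction = 100 * (1 - rmse_model / rmse_null)),
            class = "rmse_report")
}

#' @export
print.rmse_report <- function(x, ...) {
  cat(sprintf("RMSE %.4f (risk-adjusted) vs %.4f (mean-only): %.2f%% reduction\n",
              x$rmse_model, x$rmse_null, x$pct_reduction))
  invisible(x)
}
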