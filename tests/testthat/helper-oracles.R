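# Independent, deliberately unvectorized oracles used to cross-check the
# package's vectorized implementations.

# Per-observation mixture log-likelihood, summed in a plain loop; uses
# dpois() for the count component so it shares no code path with
# zip_loglik().
ref_zip_loglik <- function(alpha1, gamma, alpha2, beta, X, y) {
  total <- 0
  for (i in seq_len(nrow(X))) {
    xi <- X[i, -1]
    pi_i <- 1 / (1 + exp(-(alpha1 + sum(gamma * xi))))
    lam_i <- exp(alpha2 + sum(beta * xi))
    if (y[i] == 0) {
      total <- total + log(pi_i + (1 - pi_i) * exp(-lam_i))
    } else {
      total <- total + log(1 - pi_i) + stats::dpois(y[i], lam_i, log = TRUE)
    }
  }
  total
}

# Central finite-difference gradient of zip_loglik.
fd_zip_score <- function(params, X, y, h = 1e-6) {
  v <- codingintensity:::zip_flatten(params)
  p <- ncol(if (inherits(X, "design_matrix")) X$x else X)
  nn <- names(params$gamma)
  vapply(seq_along(v), function(j) {
    vp <- v; vp[j] <- vp[j] + h
    vm <- v; vm[j] <- vm[j] - h
    (zip_loglik(codingintensity:::zip_unflatten(vp, p, nn), X, y) -
       zip_loglik(codingintensity:::zip_unflatten(vm, p, nn), X, y)) / (2 * h)
  }, numeric(1))
}

# Random small ZIP instance (design + counts drawn from a ZIP truth).
random_zip_instance <- function(n = 50, k = 3) {
  X <- cbind(1, matrix(rnorm(n * k), n, k))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(k)))
  alpha1 <- rnorm(1, -0.5, 0.5)
  gamma <- setNames(rnorm(k, 0, 0.3), paste0("x", seq_len(k)))
  alpha2 <- rnorm(1, -0.5, 0.5)
  beta <- setNames(rnorm(k, 0, 0.3), paste0("x", seq_len(k)))
  pi <- plogis(drop(X %*% c(alpha1, gamma)))
  lam <- exp(drop(X %*% c(alpha2, beta)))
  y <- ifelse(runif(n) < pi, 0L, rpois(n, lam))
  list(X = X, y = y,
       params = zip_params(alpha1, gamma, alpha2, beta))
}

# Minimal intercept-only generator configuration.
intercept_only_config <- function(n_visits, seed, alpha1, alpha2, ...) {
  claims_config(n_facilities = 5L, n_visits = n_visits, seed = seed,
                true_alpha1 = alpha1, true_alpha2 = alpha2, ...)
}

# Small complete visit table for preprocessing tests.
toy_visits <- function(n = 10) {
  data.frame(visit_id = sprintf("V%03d", seq_len(n)),
             facility_id = rep("F1", n),
             y = rep(c(0L, 1L), length.out = n),
             sex = rep(c("Female", "Male"), length.out = n),
             payor = rep("Medicare", n),
             los_days = rep(2, n),
             stringsAsFactors = FALSE)
}
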