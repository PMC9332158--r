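#' @keywords internal
"_PACKAGE"

# The nine U.S. Census Bureau regional divisions.
.census_divisions <- c(
  "East North Central", "East South Central", "Middle Atlantic",
  "Mountain", "New England", "Pacific", "South Atlantic",
  "West North Central", "West South Central"
)

#' U.S. Census regional divisions
#'
#' The nine Census Bureau regional division labels used for facility
#' geography and the division-by-quarter aggregation report.
#'
#' @return Character vector of length 9, in alphabetical order.
#' @export
census_divisions <- function() .census_divisions

# log(1 + exp(x)) without overflow (Maechler's piecewise scheme).
log1pexp <- function(x) {
  out <- x
  i1 <- x <= -37
  i2 <- x > -37 & x <= 18
  i3 <- x > 18 & x <= 33.3
  out[i1] <- exp(x[i1])
  out[i2] <- log1p(exp(x[i2]))
  out[i3] <- x[i3] + exp(-x[i3])
  # x > 33.3: log1p(exp(x)) == x to double precision
  out
}

# Elementwise log(exp(a) + exp(b)); tolerates -Inf entries.
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  d <- -abs(a - b)
  out <- m + log1p(exp(d))
  inf <- is.infinite(m) & m < 0
  out[inf] <- -Inf
  # when one term is -Inf the sum is just the other term
  only <- is.infinite(d)
  out[only] <- m[only]
  out
}

# Run `expr` under a temporary RNG state seeded by `seed`; the caller's
# .Random.seed (if any) is restored afterwards so generator calls do not
# perturb unrelated randomness.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

# Deterministic substream seed derived from a root seed; keeps the result a
# valid 32-bit integer. Distinct k give effectively independent streams.
substream_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647)
  as.integer((s * 48271 + 12345 * k) %% 2147483647)
}

stop_if_not_count <- function(y, what = "y") {
  if (!is.numeric(y) || anyNA(y) || any(y < 0) || any(y != floor(y))) {
    stop(sprintf("`%s` must contain nonnegative integer counts", what),
         call. = FALSE)
  }
  invisible(y)
}
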