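# Weighted moment helpers shared across the package.
#
# All weighted variances/covariances use the "population" convention
# (denominator = sum of weights), which treats weights as frequency or
# inverse-probability masses.  This convention is what makes the index
# identities (regression transform == covariance formula, absolute ==
# 4 * mean * relative) hold to machine precision.

weighted_mean <- function(x, w) {
  sum(w * x) / sum(w)
}

weighted_var <- function(x, w) {
  m <- weighted_mean(x, w)
  sum(w * (x - m)^2) / sum(w)
}

weighted_cov <- function(x, y, w) {
  mx <- weighted_mean(x, w)
  my <- weighted_mean(y, w)
  sum(w * (x - mx) * (y - my)) / sum(w)
}

# Kish effective sample size under unequal weights.
effective_n <- function(w) {
  sum(w)^2 / sum(w^2)
}

check_weights <- function(w, n) {
  if (length(w) != n) {
    stop("weights must have length ", n, ", got ", length(w))
  }
  if (anyNA(w) || any(!is.finite(w))) {
    stop("weights must be finite and non-missing")
  }
  if (any(w < 0)) {
    stop("weights must be non-negative")
  }
  if (sum(w) <= 0) {
    stop("total weight must be positive")
  }
  invisible(w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Resolve a weights argument that may be NULL (uniform), a numeric vector,
# a weight_set, or the name of a column in `data`.
resolve_weights <- function(weights, data) {
  n <- nrow(data)
  if (is.null(weights)) {
    return(rep(1, n))
  }
  if (inherits(weights, "weight_set")) {
    weights <- weights$w
  } else if (is.character(weights) && length(weights) == 1L) {
    if (!weights %in% names(data)) {
      stop("weights column '", weights, "' not found in data")
    }
    weights <- data[[weights]]
  }
  check_weights(as.numeric(weights), n)
}
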