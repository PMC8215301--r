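#' Orient and scale an outcome for concentration-index estimation
#'
#' Recodes an outcome in both the "attainment" orientation (larger value =
#' better health) and the mirror "shortfall" orientation (larger = worse),
#' each scaled to the unit interval so that the concentration index is
#' invariant to the instrument's measurement scale.  Binary outcomes map to
#' \{0, 1\}; ordinal outcomes are scaled over their level codes; continuous
#' outcomes are min-max scaled using theoretical instrument bounds when
#' supplied, otherwise the observed (positively weighted) range.
#'
#' @param values outcome vector: numeric, logical, or an (ordered) factor
#'   for ordinal outcomes.
#' @param kind one of `"continuous"`, `"binary"`, `"ordinal"`; inferred from
#'   the type of `values` when omitted.
#' @param higher_is_better logical; does a larger raw value mean better
#'   health?  (`FALSE` for e.g. a smoking indicator or BMI-type risk score.)
#' @param bounds optional theoretical `(min, max)` of the raw instrument;
#'   all values must lie inside.  Ignored for factors (level range used).
#' @param weights optional observation weights (used only to locate the
#'   observed range and the weighted mean).
#' @return An object of class `outcome_coding`: list with `attainment` and
#'   `shortfall` vectors in \[0, 1\] (element-wise complements), the weighted
#'   attainment mean `mu`, the `bounds` used, their provenance
#'   `bounds_source` (`"theoretical"` or `"observed"`), and `kind`.
#' @export
code_outcome <- function(values, kind = NULL, higher_is_better = TRUE,
                         bounds = NULL, weights = NULL) {
  if (anyNA(values)) {
    stop("outcome contains missing values; impute or subset first")
  }
  n <- length(values)
  if (n == 0L) stop("empty outcome vector")
  w <- if (is.null(weights)) rep(1, n) else check_weights(as.numeric(weights), n)

  if (is.factor(values)) {
    kind <- kind %||% "ordinal"
    bounds <- c(1, nlevels(values))
    bounds_source <- "theoretical"
    v <- as.numeric(values)
  } else {
    v <- as.numeric(values)
    if (is.null(kind)) {
      u <- unique(v)
      kind <- if (length(u) <= 2L && all(u %in% c(0, 1))) "binary" else "continuous"
    }
    if (kind == "binary") {
      if (!all(v %in% c(0, 1))) {
        stop("binary outcome must contain only 0/1 values")
      }
      bounds <- c(0, 1)
      bounds_source <- "theoretical"
    } else if (!is.null(bounds)) {
      if (length(bounds) != 2L || bounds[1] >= bounds[2]) {
        stop("`bounds` must be an increasing (min, max) pair")
      }
      if (any(v < bounds[1]) || any(v > bounds[2])) {
        stop("values outside the supplied theoretical bounds")
      }
      bounds_source <- "theoretical"
    } else {
      bounds <- range(v[w > 0])
      bounds_source <- "observed"
    }
  }
  kind <- match.arg(kind, c("continuous", "binary", "ordinal"))

  if (bounds[1] == bounds[2]) {
    stop("constant outcome: scaling to [0, 1] is undefined")
  }
  scaled <- (v - bounds[1]) / (bounds[2] - bounds[1])
  attainment <- if (higher_is_better) scaled else 1 - scaled
  mu <- weighted_mean(attainment, w)

  structure(
    list(
      attainment = attainment,
      shortfall = 1 - attainment,
      mu = mu,
      bounds = bounds,
      bounds_source = bounds_source,
      kind = kind,
      higher_is_better = higher_is_better,
      n = n
    ),
    class = "outcome_coding"
  )
}

#' @export
print.outcome_coding <- function(x, ...) {
  cat("Outcome coding:", x$kind, "| n =", x$n,
      "| bounds", paste0("[", format(x$bounds[1]), ", ", format(x$bounds[2]), "]"),
      paste0("(", x$bounds_source, ")"), "\n")
  cat("weighted attainment mean mu =", format(x$mu), "\n")
  invisible(x)
}
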