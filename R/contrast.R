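#' Contrast inequality between school systems via an interaction model
#'
#' Fits one weighted regression of the transformed outcome on the fractional
#' rank, a system dummy and their interaction.  The socio-economic rank
#' coding is computed once on the full weighted sample, while the transform's
#' mean and rank variance are computed within each system arm, so that each
#' arm's slope equals its stand-alone concentration index and the interaction
#' coefficient equals the difference in the index between the selective and
#' comprehensive systems.
#'
#' @param data a data frame (e.g. a `cohort_table`).
#' @param outcome name of the outcome column.
#' @param system name of the binary system column; the level
#'   `"comprehensive"` (if present, else the first level) is the reference.
#' @param strat name of the ordered stratifying column (origin class,
#'   destination class, education band, ...).
#' @param weights optional weights: a numeric vector, a `weight_set`, or the
#'   name of a column in `data`.
#' @param variant index variant, as in [concentration_index()].
#' @param higher_is_better,kind,bounds outcome metadata passed to
#'   [code_outcome()]; taken from the table's outcome metadata when the
#'   column was produced by [generate_cohort()] and not supplied.
#' @param se_method `"robust"`, `"bootstrap"`, or `"none"`.  The bootstrap
#'   resamples records and recomputes ranks, transforms and (optionally)
#'   weights.
#' @param boot_reps,conf_level,seed see [concentration_index()].
#' @param weight_refit optional function `f(data)` returning a weight vector,
#'   called on each bootstrap resample so that weight-estimation uncertainty
#'   is propagated.
#' @return An object of class `system_contrast`: list with `arms` (data frame
#'   of per-arm estimates with intervals, means and rank variances) and
#'   `difference` (selective minus comprehensive, with interval).
#' @export
system_contrast <- function(data, outcome, system = "system",
                            strat = "origin_class", weights = NULL,
                            variant = "relative_attainment",
                            higher_is_better = NULL, kind = NULL,
                            bounds = NULL,
                            se_method = c("robust", "bootstrap", "none"),
                            boot_reps = 999, conf_level = 0.95, seed = NULL,
                            weight_refit = NULL) {
  se_method <- match.arg(se_method)
  for (col in c(outcome, system, strat)) {
    if (!col %in% names(data)) stop("column '", col, "' not found in data")
  }
  meta <- outcome_meta(data, outcome)
  higher_is_better <- higher_is_better %||% meta$higher_is_better %||% TRUE
  kind <- kind %||% meta$kind
  bounds <- bounds %||% meta$bounds

  sys <- droplevels(as.factor(data[[system]]))
  if (nlevels(sys) != 2L) {
    stop("system column must have exactly two observed levels, got ",
         nlevels(sys))
  }
  ref <- if ("comprehensive" %in% levels(sys)) "comprehensive" else levels(sys)[1L]
  sys <- stats::relevel(factor(sys, ordered = FALSE), ref = ref)
  sel_level <- levels(sys)[2L]

  w <- resolve_weights(weights, data)
  ranks <- fractional_rank(data[[strat]], w)
  coding <- code_outcome(data[[outcome]], kind = kind,
                         higher_is_better = higher_is_better,
                         bounds = bounds, weights = w)

  variant <- match.arg(variant, c("relative_attainment", "relative_shortfall",
                                  "absolute", "absolute_attainment",
                                  "absolute_shortfall"))
  if (variant == "absolute") variant <- "absolute_attainment"
  relative <- startsWith(variant, "relative")
  y <- oriented_values(coding, variant)
  r <- ranks$rank
  is_sel <- sys == sel_level

  arm_stats <- lapply(list(comp = !is_sel, sel = is_sel), function(i) {
    if (length(unique(r[i & w > 0])) < 2L) {
      stop("a system arm has fewer than 2 distinct rank values")
    }
    list(mu = weighted_mean(y[i], w[i]), vr = weighted_var(r[i], w[i]))
  })
  if (relative && any(vapply(arm_stats, function(s) s$mu <= 0 || s$mu >= 1,
                             logical(1)))) {
    stop("an arm's outcome mean lies outside (0, 1): relative index undefined")
  }

  d <- numeric(length(y))
  d[!is_sel] <- transform_dependent(y[!is_sel], arm_stats$comp$mu,
                                    arm_stats$comp$vr, relative)
  d[is_sel] <- transform_dependent(y[is_sel], arm_stats$sel$mu,
                                   arm_stats$sel$vr, relative)

  fit <- stats::lm(d ~ r * sys, weights = w)
  cf <- stats::coef(fit)
  b_comp <- unname(cf["r"])
  b_int <- unname(cf[paste0("r:sys", sel_level)])
  b_sel <- b_comp + b_int

  est <- data.frame(
    system = c(ref, sel_level),
    estimate = c(b_comp, b_sel),
    se = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
    mu = c(arm_stats$comp$mu, arm_stats$sel$mu),
    var_rank = c(arm_stats$comp$vr, arm_stats$sel$vr),
    n = c(sum(!is_sel), sum(is_sel)),
    n_eff = c(effective_n(w[!is_sel]), effective_n(w[is_sel])),
    stringsAsFactors = FALSE
  )
  diff <- list(estimate = b_int, se = NA_real_,
               conf_low = NA_real_, conf_high = NA_real_)

  if (se_method == "robust") {
    V <- sandwich::vcovHC(fit, type = "HC1")
    se_comp <- sqrt(V["r", "r"])
    int_lab <- paste0("r:sys", sel_level)
    se_int <- sqrt(V[int_lab, int_lab])
    se_sel <- sqrt(V["r", "r"] + V[int_lab, int_lab] + 2 * V["r", int_lab])
    zq <- stats::qnorm(1 - (1 - conf_level) / 2)
    est$se <- c(se_comp, se_sel)
    est$conf_low <- est$estimate - zq * est$se
    est$conf_high <- est$estimate + zq * est$se
    diff$se <- se_int
    diff$conf_low <- b_int - zq * se_int
    diff$conf_high <- b_int + zq * se_int
  } else if (se_method == "bootstrap") {
    if (!is.null(seed)) set.seed(seed)
    n <- length(y)
    cls <- ranks$class_int
    k <- length(ranks$levels)
    raw <- data[[outcome]]
    bs <- matrix(NA_real_, boot_reps, 3L)
    for (b in seq_len(boot_reps)) {
      idx <- sample.int(n, n, replace = TRUE)
      wb <- if (is.null(weight_refit)) w[idx] else {
        check_weights(weight_refit(data[idx, , drop = FALSE]), n)
      }
      sh <- group_shares(cls[idx], wb, k)
      mb <- cumsum(sh) - sh / 2
      rb <- mb[cls[idx]]
      yb <- y[idx]
      sb <- is_sel[idx]
      ci_arm <- function(i) {
        mu <- weighted_mean(yb[i], wb[i])
        cv <- weighted_cov(yb[i], rb[i], wb[i])
        if (relative) 2 * cv / mu else 8 * cv
      }
      c_comp <- ci_arm(!sb)
      c_sel <- ci_arm(sb)
      bs[b, ] <- c(c_comp, c_sel, c_sel - c_comp)
    }
    a <- (1 - conf_level) / 2
    qs <- apply(bs, 2L, stats::quantile, probs = c(a, 1 - a), names = FALSE)
    sds <- apply(bs, 2L, stats::sd)
    est$se <- sds[1:2]
    est$conf_low <- qs[1L, 1:2]
    est$conf_high <- qs[2L, 1:2]
    diff$se <- sds[3L]
    diff$conf_low <- qs[1L, 3L]
    diff$conf_high <- qs[2L, 3L]
  }

  structure(
    list(variant = variant, outcome = outcome, strat = strat,
         arms = est, difference = diff, conf_level = conf_level,
         se_method = se_method, reference = ref, selective = sel_level),
    class = "system_contrast"
  )
}

outcome_meta <- function(data, outcome) {
  meta <- attr(data, "outcome_meta")
  if (is.null(meta) || is.null(meta[[outcome]])) list() else meta[[outcome]]
}

#' @export
print.system_contrast <- function(x, ...) {
  cat("System contrast in ", x$variant, " concentration index for '",
      x$outcome, "' (rank variable: ", x$strat, ")\n", sep = "")
  print(x$arms, row.names = FALSE, digits = 4)
  cat(sprintf("difference (%s - %s): %.4g", x$selective, x$reference,
              x$difference$estimate))
  if (!is.na(x$difference$se)) {
    cat(sprintf("  [%.4g, %.4g]", x$difference$conf_low, x$difference$conf_high))
  }
  cat("\n")
  invisible(x)
}

#' Weighted outcome means by system and/or cognitive-ability bin
#'
#' Computes weighted cell means with normal-approximation intervals, either
#' by system arm, by bins of a continuous score (default width 5, as for an
#' IQ-style ability scale), or both.  Sparse marginal bins are merged inward
#' until each retains at least `merge_n` records.
#'
#' @param data data frame.
#' @param outcome name of a numeric outcome column.
#' @param by optional name of a grouping column (e.g. the system).
#' @param ability optional name of a continuous column to bin.
#' @param bin_width bin width for `ability` (default 5).
#' @param merge_n minimum records per marginal bin before merging (default 50).
#' @param weights optional weights (vector, `weight_set`, or column name).
#' @param conf_level confidence level for the cell intervals.
#' @return data frame with one row per cell: grouping values, weighted
#'   `mean`, `se`, `conf_low`, `conf_high`, `n` and `n_eff`.
#' @export
grouped_means <- function(data, outcome, by = NULL, ability = NULL,
                          bin_width = 5, merge_n = 50, weights = NULL,
                          conf_level = 0.95) {
  if (!outcome %in% names(data)) stop("column '", outcome, "' not found")
  w <- resolve_weights(weights, data)
  y <- as.numeric(data[[outcome]])
  if (anyNA(y)) stop("outcome contains missing values")

  groups <- list()
  if (!is.null(by)) groups[[by]] <- as.factor(data[[by]])
  if (!is.null(ability)) {
    groups[[paste0(ability, "_bin")]] <-
      bin_with_merged_margins(as.numeric(data[[ability]]), bin_width, merge_n)
  }
  if (length(groups) == 0L) groups$all <- factor(rep("all", length(y)))

  idx <- interaction(groups, drop = TRUE, sep = " / ")
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(levels(idx), function(lv) {
    i <- idx == lv
    if (!any(i)) return(NULL)
    wm <- weighted_mean(y[i], w[i])
    ne <- effective_n(w[i])
    se <- sqrt(weighted_var(y[i], w[i]) / ne)
    cell <- as.data.frame(lapply(groups, function(g) g[i][1L]))
    cbind(cell, data.frame(mean = wm, se = se,
                           conf_low = wm - zq * se, conf_high = wm + zq * se,
                           n = sum(i), n_eff = ne))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Fixed-width bins with sparse margins merged inward.
bin_with_merged_margins <- function(x, width, merge_n) {
  lo <- floor(min(x) / width) * width
  hi <- ceiling(max(x) / width) * width
  if (hi <= lo) hi <- lo + width
  breaks <- seq(lo, hi, by = width)
  counts <- table(cut(x, breaks, include.lowest = TRUE))
  # merge from the left margin
  while (length(breaks) > 2L && counts[1L] < merge_n) {
    breaks <- breaks[-2L]
    counts <- table(cut(x, breaks, include.lowest = TRUE))
  }
  # merge from the right margin
  while (length(breaks) > 2L && counts[length(counts)] < merge_n) {
    breaks <- breaks[-(length(breaks) - 1L)]
    counts <- table(cut(x, breaks, include.lowest = TRUE))
  }
  b <- cut(x, breaks, include.lowest = TRUE)
  if (any(table(b) == 0)) stop("empty ability bin after merging")
  b
}
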