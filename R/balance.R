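# Balance diagnostics and balance-criterion weight selection.

# Expand confounders to numeric balance columns: factor levels become 0/1
# indicators (all levels, since Table-1-style reports show every category),
# numeric columns pass through.
balance_columns <- function(data, confounders) {
  cols <- list()
  for (nm in confounders) {
    col <- data[[nm]]
    if (is.null(col)) stop("column '", nm, "' not found")
    if (is.numeric(col)) {
      cols[[nm]] <- stats::setNames(list(col), nm)
    } else {
      col <- as.factor(col)
      lv <- levels(col)
      cols[[nm]] <- stats::setNames(
        lapply(lv, function(l) as.numeric(col == l)),
        paste0(nm, ":", lv)
      )
    }
  }
  cols
}

# Standardized mean difference between the two arms for one numeric column,
# with weighted means and weighted (population) variances:
# (m1 - m0) / sqrt((v1 + v0) / 2).
smd_value <- function(x, sel, w) {
  m1 <- weighted_mean(x[sel], w[sel])
  m0 <- weighted_mean(x[!sel], w[!sel])
  v1 <- weighted_var(x[sel], w[sel])
  v0 <- weighted_var(x[!sel], w[!sel])
  pooled <- (v1 + v0) / 2
  if (pooled == 0) {
    if (m1 == m0) return(0)
    stop("zero pooled variance with unequal arm means: SMD undefined")
  }
  (m1 - m0) / sqrt(pooled)
}

#' Mean absolute standardized mean difference across confounder levels
#'
#' The balance criterion used to select among candidate weight sets: the
#' mean of |SMD| over every confounder level (factors expanded to level
#' indicators) and continuous confounder.
#'
#' @param data data frame.
#' @param weights weights (vector, `weight_set`, or column name).
#' @param confounders confounder column names.
#' @param exposure binary exposure column name.
#' @return A single non-negative number.
#' @export
balance_criterion <- function(data, weights = NULL,
                              confounders = attr(data, "confounders"),
                              exposure = "system") {
  w <- resolve_weights(weights, data)
  ex <- droplevels(as.factor(data[[exposure]]))
  sel_level <- if ("selective" %in% levels(ex)) "selective" else levels(ex)[2L]
  sel <- ex == sel_level
  cols <- unlist(balance_columns(data, confounders), recursive = FALSE)
  mean(vapply(cols, function(x) abs(smd_value(x, sel, w)), numeric(1)))
}

#' Select the best-balancing weight set
#'
#' Returns the candidate with the smallest mean absolute SMD across all
#' confounder levels; ties (within `tie_tol`) are broken by the smaller
#' coefficient of variation of the weights.  The criterion value of every
#' candidate is recorded on the returned set.
#'
#' @param candidates a (preferably named) list of `weight_set` objects.
#' @param data data frame the weights refer to.
#' @param confounders confounder column names.
#' @param exposure binary exposure column name.
#' @param tie_tol criterion difference treated as a tie (default 1e-10).
#' @return The selected `weight_set`, with `$criterion` (its own value) and
#'   `$candidate_criteria` (named vector over all candidates).
#' @export
select_weights <- function(candidates, data,
                           confounders = attr(data, "confounders"),
                           exposure = "system", tie_tol = 1e-10) {
  if (length(candidates) == 0L) stop("empty candidate list")
  if (inherits(candidates, "weight_set")) candidates <- list(candidates)
  if (is.null(names(candidates))) {
    names(candidates) <- vapply(candidates, `[[`, character(1), "method")
  }
  crit <- vapply(candidates, function(ws) {
    balance_criterion(data, ws, confounders, exposure)
  }, numeric(1))
  best <- which(crit <= min(crit) + tie_tol)
  if (length(best) > 1L) {
    cv <- vapply(candidates[best], function(ws) {
      stats::sd(ws$w) / mean(ws$w)
    }, numeric(1))
    best <- best[which.min(cv)]
  } else {
    best <- best[1L]
  }
  out <- candidates[[best]]
  out$criterion <- crit[[best]]
  out$candidate_criteria <- crit
  out$selected <- names(candidates)[best]
  out
}

#' Before/after covariate balance report
#'
#' Builds a Table-1-style report: per confounder level, the unweighted
#' percentage (or mean, for continuous confounders) in the full sample and
#' in each arm, and the weighted percentage in each arm; per level, the
#' standardized mean difference before and after weighting; and the
#' weighted pseudo-population size of each arm.
#'
#' @param data data frame.
#' @param weights weights (vector, `weight_set`, or column name).
#' @param confounders confounder column names.
#' @param exposure binary exposure column name.
#' @return An object of class `balance_report`: list with `table` (long
#'   data frame of level statistics), `smd` (per-level SMD before/after),
#'   and `n` (unweighted and weighted arm sizes).
#' @export
balance_report <- function(data, weights,
                           confounders = attr(data, "confounders"),
                           exposure = "system") {
  w <- resolve_weights(weights, data)
  ex <- droplevels(as.factor(data[[exposure]]))
  sel_level <- if ("selective" %in% levels(ex)) "selective" else levels(ex)[2L]
  sel <- ex == sel_level
  u <- rep(1, nrow(data))

  cols_by_var <- balance_columns(data, confounders)
  rows <- list()
  smd_rows <- list()
  for (nm in names(cols_by_var)) {
    is_cat <- !is.numeric(data[[nm]])
    scale <- if (is_cat) 100 else 1
    for (lab in names(cols_by_var[[nm]])) {
      x <- cols_by_var[[nm]][[lab]]
      level <- if (is_cat) sub(paste0("^", nm, ":"), "", lab) else NA_character_
      rows[[lab]] <- data.frame(
        variable = nm, level = level,
        all_unweighted = scale * weighted_mean(x, u),
        comprehensive_unweighted = scale * weighted_mean(x[!sel], u[!sel]),
        selective_unweighted = scale * weighted_mean(x[sel], u[sel]),
        comprehensive_weighted = scale * weighted_mean(x[!sel], w[!sel]),
        selective_weighted = scale * weighted_mean(x[sel], w[sel]),
        stringsAsFactors = FALSE
      )
      smd_rows[[lab]] <- data.frame(
        variable = nm, level = level,
        smd_before = smd_value(x, sel, u),
        smd_after = smd_value(x, sel, w),
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  smd <- do.call(rbind, smd_rows)
  rownames(tab) <- rownames(smd) <- NULL

  structure(
    list(
      table = tab,
      smd = smd,
      n = c(all = nrow(data),
            comprehensive_unweighted = sum(!sel),
            selective_unweighted = sum(sel),
            comprehensive_weighted = sum(w[!sel]),
            selective_weighted = sum(w[sel])),
      exposure = exposure
    ),
    class = "balance_report"
  )
}

#' @export
print.balance_report <- function(x, ...) {
  cat("Covariate balance report\n")
  cat("N:", paste(names(x$n), round(x$n, 1), sep = " = ", collapse = ", "),
      "\n\n")
  print(x$table, row.names = FALSE, digits = 3)
  cat("\nmean |SMD| before:", format(mean(abs(x$smd$smd_before)), digits = 3),
      "| after:", format(mean(abs(x$smd$smd_after)), digits = 3), "\n")
  invisible(x)
}
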