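#' Fit a school-system propensity model
#'
#' Models the probability of selective-system attendance as a function of
#' baseline confounders.  Three candidates are provided: a main-effects
#' logistic regression, a flexible logistic regression with a natural cubic
#' spline basis (default 4 df) on each continuous confounder, and a
#' ridge-penalized logistic regression with the penalty chosen by
#' cross-validated deviance.
#'
#' @param data data frame with the exposure and confounder columns.
#' @param confounders character vector of confounder column names; must be
#'   complete (missingness is handled upstream).
#' @param exposure name of the binary exposure column.
#' @param method `"logit"`, `"spline"` or `"ridge"`.
#' @param spline_df spline degrees of freedom for `"spline"` (default 4).
#' @param ridge_nfolds CV folds for `"ridge"` (default 5).
#' @param seed seed fixing the CV fold assignment for `"ridge"`.
#' @return An object of class `propensity_model`: list with `method`, the
#'   per-record probability of selective attendance `p`, the fitted object,
#'   the `exposure` column name and the `selective_level`.
#' @export
fit_propensity <- function(data, confounders = attr(data, "confounders"),
                           exposure = "system",
                           method = c("logit", "spline", "ridge"),
                           spline_df = 4, ridge_nfolds = 5, seed = 1L) {
  method <- match.arg(method)
  if (is.null(confounders) || length(confounders) == 0L) {
    stop("no confounder columns supplied")
  }
  missing_cols <- setdiff(c(exposure, confounders), names(data))
  if (length(missing_cols) > 0L) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "))
  }
  X <- data[confounders]
  if (anyNA(X)) {
    stop("missing values among confounders; impose/handle missingness upstream")
  }
  ex <- droplevels(as.factor(data[[exposure]]))
  if (nlevels(ex) != 2L) {
    stop("exposure must have exactly two observed levels, got ", nlevels(ex))
  }
  sel_level <- if ("selective" %in% levels(ex)) "selective" else levels(ex)[2L]
  yy <- as.numeric(ex == sel_level)

  # origin class enters as an unordered factor: we model level effects, not
  # polynomial contrasts
  X[] <- lapply(X, function(col) {
    if (is.ordered(col)) factor(col, ordered = FALSE) else col
  })

  if (method %in% c("logit", "spline")) {
    terms <- vapply(confounders, function(nm) {
      col <- X[[nm]]
      if (method == "spline" && is.numeric(col) &&
          length(unique(col)) > spline_df) {
        sprintf("splines::ns(%s, df = %d)", nm, spline_df)
      } else nm
    }, character(1))
    f <- stats::reformulate(terms, response = ".y")
    d <- cbind(X, .y = yy)
    separated <- FALSE
    fit <- withCallingHandlers(
      stats::glm(f, family = stats::binomial(), data = d),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) {
          separated <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    p <- unname(stats::fitted(fit))
    if (separated || any(p < 1e-10) || any(p > 1 - 1e-10)) {
      stop("(near-)perfect separation in the propensity model: fitted ",
           "probabilities reach 0/1; consider method = 'ridge' (penalized ",
           "likelihood)")
    }
  } else {
    mm <- stats::model.matrix(~ ., data = X)[, -1L, drop = FALSE]
    set.seed(as.integer(seed))
    foldid <- sample(rep_len(seq_len(ridge_nfolds), nrow(mm)))
    fit <- glmnet::cv.glmnet(mm, yy, family = "binomial", alpha = 0,
                             foldid = foldid, type.measure = "deviance")
    p <- as.vector(stats::predict(fit, newx = mm, s = "lambda.min",
                                  type = "response"))
  }

  structure(
    list(method = method, p = p, fit = fit, exposure = exposure,
         selective_level = sel_level, confounders = confounders),
    class = "propensity_model"
  )
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("Propensity model (", x$method, ") for '", x$exposure,
      "' = ", x$selective_level, "\n", sep = "")
  cat("fitted probabilities: ",
      paste(format(range(x$p), digits = 3), collapse = " .. "), "\n")
  invisible(x)
}

#' Inverse probability weights for the whole-population estimand
#'
#' Weights each record by the reciprocal of the probability of the system it
#' actually attended (1/p for selective, 1/(1-p) for comprehensive), so that
#' each weighted arm estimates the counterfactual in which the entire
#' population attended that system; each arm's weight total is then close to
#' the full sample size under positivity.
#'
#' @param model a [fit_propensity()] object (or a numeric probability
#'   vector, in which case `data` and `exposure` identify the arms).
#' @param data the data frame the model was fitted on.
#' @param exposure exposure column name (taken from the model when given).
#' @param truncate_at optional percentile in (0, 1) at which weights are
#'   truncated from above (default `NULL`, no truncation).
#' @return An object of class `weight_set`: list with the weight vector `w`,
#'   `method`, `estimand = "average-population"` and per-arm weight totals.
#' @export
make_ipw <- function(model, data, exposure = NULL, truncate_at = NULL) {
  if (inherits(model, "propensity_model")) {
    p <- model$p
    exposure <- exposure %||% model$exposure
    sel_level <- model$selective_level
    label <- paste0("ipw_", model$method)
  } else {
    p <- as.numeric(model)
    if (is.null(exposure)) stop("`exposure` required with a raw probability vector")
    ex0 <- droplevels(as.factor(data[[exposure]]))
    sel_level <- if ("selective" %in% levels(ex0)) "selective" else levels(ex0)[2L]
    label <- "ipw"
  }
  if (length(p) != nrow(data)) stop("probabilities not aligned to data rows")
  if (any(p <= 0) || any(p >= 1)) {
    stop("propensity of 0 or 1 encountered: positivity violated")
  }
  sel <- data[[exposure]] == sel_level
  w <- ifelse(sel, 1 / p, 1 / (1 - p))
  if (!is.null(truncate_at)) {
    if (truncate_at <= 0 || truncate_at >= 1) stop("truncate_at must be in (0, 1)")
    cap <- stats::quantile(w, truncate_at, names = FALSE)
    w <- pmin(w, cap)
  }
  weight_set(w, method = label,
             arm_totals = c(comprehensive = sum(w[!sel]),
                            selective = sum(w[sel])))
}

weight_set <- function(w, method, arm_totals = NULL, criterion = NA_real_) {
  structure(
    list(w = w, method = method, estimand = "average-population",
         arm_totals = arm_totals, criterion = criterion),
    class = "weight_set"
  )
}

#' @export
print.weight_set <- function(x, ...) {
  cat("Weight set (", x$method, "), estimand: ", x$estimand, "\n", sep = "")
  cat("weights: n =", length(x$w), "| range",
      paste(format(range(x$w), digits = 3), collapse = " .. "),
      "| effective n", round(effective_n(x$w), 1), "\n")
  if (!is.null(x$arm_totals)) {
    cat("weighted arm totals:",
        paste(names(x$arm_totals), round(x$arm_totals, 1), collapse = ", "),
        "\n")
  }
  if (!is.na(x$criterion)) {
    cat("balance criterion (mean |SMD|):", format(x$criterion, digits = 4), "\n")
  }
  invisible(x)
}
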