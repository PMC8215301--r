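#' Inverse-probability-of-response weights for wave attrition
#'
#' First stage of the two-stage MI/IPW strategy: responders (records with at
#' least one observed outcome) are weighted by the reciprocal of their
#' fitted probability of responding, modelled by logistic regression on
#' fully observed baseline confounders.  Non-responders receive weight 0 and
#' are excluded from outcome stages.  The final analysis weight is the
#' product of this response weight and the confounding weight.
#'
#' @param table a `cohort_table` (typically after [impose_missingness()]).
#' @param baseline baseline confounder column names (default: the table's
#'   `confounders` attribute).
#' @return A `weight_set` with method `"response_ipw"`; `$responded` holds
#'   the response indicator.
#' @export
response_weights <- function(table, baseline = attr(table, "confounders")) {
  meta <- attr(table, "outcome_meta")
  if (is.null(meta)) stop("table carries no outcome metadata")
  if (anyNA(table[baseline])) {
    stop("baseline confounders must be fully observed")
  }
  responded <- if ("responded" %in% names(table)) {
    table$responded
  } else {
    rowSums(!is.na(table[names(meta)])) > 0
  }

  if (all(responded)) {
    w <- rep(1, nrow(table))
  } else {
    d <- table[baseline]
    d$.resp <- as.numeric(responded)
    fit <- stats::glm(stats::reformulate(baseline, ".resp"),
                      family = stats::binomial(), data = d)
    p <- stats::fitted(fit)
    if (any(p[responded] < 1e-12)) {
      stop("fitted response probability of 0 for a responder")
    }
    w <- ifelse(responded, 1 / p, 0)
  }
  out <- weight_set(w, method = "response_ipw")
  out$responded <- responded
  out
}

#' Chained-equation multiple imputation of item non-response
#'
#' Fills missing outcome cells by iterated chained equations with proper
#' posterior parameter draws: type-1 predictive mean matching (5 donors) for
#' continuous variables, logistic regression for binaries, and a
#' proportional-odds
#' model for ordered factors, each regressed on the baseline confounders,
#' the other outcomes (current completed values) and, optionally, the
#' analysis weight as a covariate.  Observed cells are identical across the
#' m completed tables; only originally missing cells vary.
#'
#' @param table a `cohort_table` with missing outcome cells.
#' @param m number of completed tables (default 5; at least 2).
#' @param iterations chained-equation sweeps per table (default 10).
#' @param seed integer seed; results are deterministic given the seed.
#' @param predictors predictor column names (default: baseline confounders).
#' @param weights optional analysis weights included as a covariate in every
#'   imputation model.
#' @return An object of class `imputation_set`: list with `tables` (list of
#'   m completed `cohort_table`s), `m`, `iterations`, `seed`, and `models`
#'   (imputation model label per variable).
#' @export
impute_missing <- function(table, m = 5, iterations = 10, seed,
                           predictors = attr(table, "confounders"),
                           weights = NULL) {
  if (m < 2) stop("m must be at least 2")
  meta <- attr(table, "outcome_meta")
  if (is.null(meta)) stop("table carries no outcome metadata")
  set.seed(as.integer(seed))

  vars <- names(meta)[vapply(names(meta), function(v) anyNA(table[[v]]),
                             logical(1))]
  if (length(vars) == 0L) {
    return(structure(list(tables = replicate(m, table, simplify = FALSE),
                          m = m, iterations = 0L, seed = as.integer(seed),
                          models = character(0)),
                     class = "imputation_set"))
  }
  for (v in vars) {
    if (all(is.na(table[[v]]))) {
      stop("variable '", v, "' is 100% missing: nothing to fit an ",
           "imputation model on")
    }
  }

  models <- vapply(vars, function(v) {
    col <- table[[v]]
    if (is.ordered(col)) "polr"
    else if (is.factor(col)) "logreg"
    else if (all(stats::na.omit(col) %in% c(0, 1))) "logreg"
    else "pmm"
  }, character(1))

  w_cov <- if (is.null(weights)) NULL else resolve_weights(weights, table)

  base <- table
  miss_idx <- lapply(vars, function(v) which(is.na(table[[v]])))
  names(miss_idx) <- vars

  completed <- vector("list", m)
  for (im in seq_len(m)) {
    cur <- base
    # initialise by sampling observed values
    for (v in vars) {
      obs <- which(!is.na(base[[v]]))
      cur[[v]][miss_idx[[v]]] <- base[[v]][sample(obs, length(miss_idx[[v]]),
                                                  replace = TRUE)]
    }
    for (it in seq_len(iterations)) {
      for (v in vars) {
        cur[[v]] <- impute_one(cur, v, miss_idx[[v]],
                               obs_rows = which(!is.na(base[[v]])),
                               predictors = c(predictors, setdiff(vars, v)),
                               model = models[[v]], w_cov = w_cov)
      }
    }
    completed[[im]] <- cur
  }

  structure(
    list(tables = completed, m = m, iterations = iterations,
         seed = as.integer(seed), models = models),
    class = "imputation_set"
  )
}

# One chained-equation update for variable v: fit on originally observed
# rows, draw parameters from their approximate posterior, impute the
# originally missing rows.
impute_one <- function(cur, v, na_rows, obs_rows, predictors, model, w_cov) {
  d <- cur[predictors]
  d[] <- lapply(d, function(col) {
    if (is.ordered(col)) factor(col, ordered = FALSE) else col
  })
  if (!is.null(w_cov)) d$.wcov <- w_cov
  rhs <- names(d)
  d$.y <- cur[[v]]
  f <- stats::reformulate(rhs, ".y")

  if (model == "pmm") {
    # type-1 predictive mean matching: observed rows predicted with the ML
    # coefficients, missing rows with a posterior draw; each missing cell
    # takes the observed value of one of its 5 nearest predicted donors.
    # Keeps imputations inside the instrument's support.
    fit <- stats::lm(f, data = d, subset = obs_rows)
    res_df <- fit$df.residual
    sigma2_hat <- sum(stats::residuals(fit)^2) / res_df
    sigma2_star <- sigma2_hat * res_df / stats::rchisq(1L, res_df)
    beta_hat <- stats::coef(fit)
    beta_hat <- beta_hat[!is.na(beta_hat)]
    beta_star <- draw_coefs(fit, scale = sigma2_star / sigma2_hat)
    mm_obs <- imputation_matrix(f, d[obs_rows, , drop = FALSE], names(beta_hat))
    mm_mis <- imputation_matrix(f, d[na_rows, , drop = FALSE], names(beta_star))
    yhat_obs <- as.vector(mm_obs %*% beta_hat)
    yhat_mis <- as.vector(mm_mis %*% beta_star)
    donors <- pmm_donors(yhat_obs, yhat_mis, k = 5L)
    cur[[v]][na_rows] <- cur[[v]][obs_rows][donors]
  } else if (model == "logreg") {
    yfac <- is.factor(d$.y)
    fit <- stats::glm(f, family = stats::binomial(), data = d,
                      subset = obs_rows)
    beta_star <- draw_coefs(fit)
    mm <- imputation_matrix(f, d[na_rows, , drop = FALSE], names(beta_star))
    p <- stats::plogis(as.vector(mm %*% beta_star))
    draw <- stats::rbinom(length(na_rows), 1L, p)
    cur[[v]][na_rows] <- if (yfac) levels(cur[[v]])[draw + 1L] else draw
  } else {  # polr
    fit <- tryCatch(
      MASS::polr(f, data = d, subset = obs_rows, Hess = TRUE),
      error = function(e) {
        stop("proportional-odds imputation model for '", v,
             "' failed to converge: ", conditionMessage(e))
      }
    )
    th_hat <- c(stats::coef(fit), fit$zeta)
    V <- stats::vcov(fit)
    th <- th_hat + as.vector(t(chol(V)) %*% stats::rnorm(length(th_hat)))
    k <- length(stats::coef(fit))
    beta_star <- th[seq_len(k)]
    zeta_star <- sort(th[-seq_len(k)])
    mm <- imputation_matrix(f, d[na_rows, , drop = FALSE],
                            c("(Intercept)", names(stats::coef(fit))))
    eta <- as.vector(mm[, -1L, drop = FALSE] %*% beta_star)
    cum <- vapply(zeta_star, function(z) stats::plogis(z - eta),
                  numeric(length(eta)))
    if (length(eta) == 1L) cum <- matrix(cum, nrow = 1L)
    u <- stats::runif(length(eta))
    lev <- 1L + rowSums(u > cum)
    cur[[v]][na_rows] <- levels(cur[[v]])[lev]
  }
  cur[[v]]
}

# For each predicted missing value, sample one of the k nearest observed
# predictions and return its (observed-row) index.  In a sorted array the k
# nearest neighbours are contiguous and a two-pointer walk visits them in
# increasing distance order, so drawing a target rank first and recording
# the element taken at that step samples uniformly from the k nearest with
# only k vectorised passes.
pmm_donors <- function(yhat_obs, yhat_mis, k = 5L) {
  ord <- order(yhat_obs)
  ys <- yhat_obs[ord]
  n_obs <- length(ys)
  nm <- length(yhat_mis)
  k <- min(k, n_obs)
  lo <- findInterval(yhat_mis, ys)
  hi <- lo + 1L
  target <- sample.int(k, nm, replace = TRUE)
  donor <- integer(nm)
  for (j in seq_len(k)) {
    dl <- ifelse(lo >= 1L, yhat_mis - ys[pmax(lo, 1L)], Inf)
    dr <- ifelse(hi <= n_obs, ys[pmin(hi, n_obs)] - yhat_mis, Inf)
    take_left <- dl <= dr
    pick <- ifelse(take_left, lo, hi)
    sel <- target == j
    donor[sel] <- pick[sel]
    lo <- lo - as.integer(take_left)
    hi <- hi + as.integer(!take_left)
  }
  ord[donor]
}

# Posterior draw of regression coefficients (non-aliased ones only).
draw_coefs <- function(fit, scale = 1) {
  b <- stats::coef(fit)
  ok <- !is.na(b)
  V <- stats::vcov(fit)[ok, ok, drop = FALSE] * scale
  b[ok] <- b[ok] + as.vector(t(chol(V)) %*% stats::rnorm(sum(ok)))
  b[ok]
}

# Model matrix for prediction rows, restricted to the fitted columns.
imputation_matrix <- function(f, newdata, cols) {
  newdata$.y <- NULL
  mm <- stats::model.matrix(stats::delete.response(stats::terms(f)),
                            data = newdata)
  mm[, cols[cols %in% colnames(mm)], drop = FALSE]
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("Imputation set: m =", x$m, "| iterations =", x$iterations,
      "| seed =", x$seed, "\n")
  if (length(x$models)) {
    cat("models:", paste(names(x$models), x$models, sep = " = ",
                         collapse = ", "), "\n")
  } else {
    cat("no missing cells: completed tables are identical copies\n")
  }
  invisible(x)
}

#' Rubin combination of concentration-index estimates across imputations
#'
#' Pools m estimates of the same variant: the point estimate is their mean,
#' the total variance is the within-imputation variance plus
#' (1 + 1/m) times the between-imputation variance, and the interval uses a
#' t reference with the conventional degrees of freedom
#' \eqn{(m-1)\,(1 + W / ((1+1/m)B))^2}.
#'
#' @param estimates list of `ci_estimate` objects (same variant, each with a
#'   standard error from its own SE method).
#' @return A pooled `ci_estimate` with `se_method = "rubin"` and the
#'   components `within_var`, `between_var`, `df`, `m` attached.
#' @export
pool_estimates <- function(estimates) {
  stopifnot(length(estimates) >= 2L,
            all(vapply(estimates, inherits, logical(1), "ci_estimate")))
  variants <- unique(vapply(estimates, `[[`, character(1), "variant"))
  if (length(variants) != 1L) {
    stop("cannot pool mismatched variants: ", paste(variants, collapse = ", "))
  }
  ses <- vapply(estimates, `[[`, numeric(1), "se")
  if (anyNA(ses)) {
    stop("every estimate needs a within-imputation standard error to pool")
  }
  m <- length(estimates)
  q <- vapply(estimates, `[[`, numeric(1), "estimate")
  qbar <- mean(q)
  W <- mean(ses^2)
  B <- stats::var(q)
  total <- W + (1 + 1 / m) * B
  conf_level <- estimates[[1L]]$conf_level

  if (B == 0) {
    df <- Inf
    lo <- qbar - stats::qnorm(1 - (1 - conf_level) / 2) * sqrt(total)
    hi <- qbar + stats::qnorm(1 - (1 - conf_level) / 2) * sqrt(total)
  } else {
    df <- (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
    tq <- stats::qt(1 - (1 - conf_level) / 2, df)
    lo <- qbar - tq * sqrt(total)
    hi <- qbar + tq * sqrt(total)
  }

  structure(
    list(
      variant = variants, estimate = qbar, se = sqrt(total),
      conf_low = lo, conf_high = hi, conf_level = conf_level,
      mu = mean(vapply(estimates, `[[`, numeric(1), "mu")),
      var_rank = mean(vapply(estimates, `[[`, numeric(1), "var_rank")),
      n = estimates[[1L]]$n,
      n_eff = mean(vapply(estimates, `[[`, numeric(1), "n_eff")),
      se_method = "rubin", within_var = W, between_var = B, df = df, m = m
    ),
    class = "ci_estimate"
  )
}
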