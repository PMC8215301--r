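#' Configuration for the end-to-end inequality pipeline
#'
#' Bundles every choice the pipeline makes: cohort source (synthetic
#' generation or a CSV written by [write_cohort()]), confounder set,
#' outcomes and stratifiers to analyse, candidate weighting methods, the
#' uncertainty method, the multiple-imputation size, and the
#' negative-control variable.  All randomness derives from `seed`.
#'
#' @param n cohort size for synthetic generation.
#' @param seed integer master seed.
#' @param allocation class/exposure allocation mode, see [generate_cohort()].
#' @param input_path optional CSV path (from [write_cohort()]); when given,
#'   `n`/`allocation`/`outcome_specs` are ignored.
#' @param outcome_specs optional list of [outcome_spec()] objects for the
#'   generator (default [default_outcome_specs()]).
#' @param confounders confounder column names (default: the table's
#'   metadata).
#' @param outcomes outcome column names to analyse.
#' @param stratifiers ordered stratifier column names (origin class,
#'   destination class, education band ...).
#' @param methods candidate propensity methods among `"logit"`, `"spline"`,
#'   `"ridge"`, `"entropy"`.
#' @param variants index variants to report.
#' @param se_method `"bootstrap"` or `"robust"`.
#' @param boot_reps bootstrap replicates when `se_method = "bootstrap"`.
#' @param m completed tables for multiple imputation (used when the cohort
#'   has item non-response; at least 2).
#' @param iterations chained-equation sweeps.
#' @param truncate_at optional weight-truncation percentile.
#' @param negative_control name of a pre-exposure variable expected to show
#'   no class inequality; must not appear among the confounders or outcomes.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n = 10000, seed = 1L, allocation = "multinomial",
                       input_path = NULL, outcome_specs = NULL,
                       confounders = NULL,
                       outcomes = c("wellbeing", "smoker",
                                    "self_rated_health"),
                       stratifiers = "origin_class",
                       methods = c("logit", "spline", "ridge"),
                       variants = c("relative_attainment",
                                    "relative_shortfall", "absolute"),
                       se_method = "bootstrap", boot_reps = 999,
                       m = 5, iterations = 5, truncate_at = NULL,
                       negative_control = "bmi_baseline") {
  config <- list(
    n = as.integer(n), seed = as.integer(seed), allocation = allocation,
    input_path = input_path, outcome_specs = outcome_specs,
    confounders = confounders, outcomes = outcomes,
    stratifiers = stratifiers, methods = methods, variants = variants,
    se_method = se_method, boot_reps = as.integer(boot_reps),
    m = as.integer(m), iterations = as.integer(iterations),
    truncate_at = truncate_at, negative_control = negative_control
  )
  class(config) <- "run_config"
  validate_run_config(config)
}

validate_run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$input_path) && config$n < 1) stop("n must be positive")
  bad <- setdiff(config$methods, c("logit", "spline", "ridge", "entropy"))
  if (length(bad)) stop("unknown weighting method(s): ", paste(bad, collapse = ", "))
  if (length(config$methods) == 0L) stop("at least one weighting method required")
  if (!config$se_method %in% c("bootstrap", "robust")) {
    stop("se_method must be 'bootstrap' or 'robust'")
  }
  if (!is.null(config$negative_control)) {
    if (!is.null(config$confounders) &&
        config$negative_control %in% config$confounders) {
      stop("configuration contradiction: negative control '",
           config$negative_control, "' is listed among the confounders")
    }
    if (config$negative_control %in% config$outcomes) {
      stop("configuration contradiction: negative control '",
           config$negative_control, "' is listed among the outcomes")
    }
  }
  config
}

#' Write / read a pipeline configuration as JSON
#'
#' Round-trip safe: `read_run_config(write_run_config(cfg, path))` equals
#' `cfg`, including any generator outcome specifications.
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `path` invisibly; `read_run_config()` returns the `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  if (!is.null(out$outcome_specs)) {
    out$outcome_specs <- lapply(out$outcome_specs, unclass)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  specs <- raw$outcome_specs
  raw$outcome_specs <- NULL
  config <- do.call(run_config, raw[!vapply(raw, is.null, logical(1))])
  if (!is.null(specs)) {
    config$outcome_specs <- lapply(specs, function(s) {
      do.call(outcome_spec, s[!vapply(s, is.null, logical(1))])
    })
  }
  validate_run_config(config)
}

#' Run the full inequality pipeline
#'
#' Executes the stages in fixed order: cohort (generate or load), missing
#' data (response weights + chained-equation imputation when needed),
#' confounder balance (candidate propensity weights, balance-criterion
#' selection, before/after report), inequality (per outcome x stratifier x
#' variant system contrasts, Rubin-pooled over imputations), grouped
#' outcome means, and the negative-control check.  Identical configurations
#' and seeds give identical bundles.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, result tables are written
#'   as CSV plus a JSON manifest.
#' @return An object of class `results_bundle`: list with `balance`
#'   (`balance_report`), `weights` (`weight_set`), `results` (long data
#'   frame of estimates), `means` (grouped weighted means),
#'   `negative_control` (check report), and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  validate_run_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- cohort ---------------------------------------------------------
  cohort <- stage("cohort", {
    if (!is.null(config$input_path)) {
      read_cohort(config$input_path)
    } else {
      generate_cohort(
        outcomes = config$outcome_specs %||% default_outcome_specs(),
        n = config$n, seed = config$seed, allocation = config$allocation
      )
    }
  })
  tab <- cohort$table
  confounders <- config$confounders %||% attr(tab, "confounders")
  missing_cols <- setdiff(
    c(confounders, config$outcomes, config$stratifiers,
      config$negative_control),
    names(tab)
  )
  if (length(missing_cols)) {
    stop("pipeline stage 'cohort' failed: config references missing ",
         "column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.null(config$negative_control) &&
      config$negative_control %in% confounders) {
    stop("pipeline stage 'cohort' failed: negative control used in the ",
         "propensity model", call. = FALSE)
  }

  # --- missing data ---------------------------------------------------
  meta <- attr(tab, "outcome_meta")
  any_missing <- anyNA(tab[names(meta)])
  rw <- stage("missingness", {
    if (any_missing) response_weights(tab, confounders) else NULL
  })
  responders <- if (is.null(rw)) rep(TRUE, nrow(tab)) else rw$responded
  analysis_tabs <- stage("missingness", {
    resp_tab <- tab[responders, , drop = FALSE]
    if (anyNA(resp_tab[names(meta)])) {
      impute_missing(resp_tab, m = config$m, iterations = config$iterations,
                     seed = config$seed + 1L, predictors = confounders)$tables
    } else {
      list(resp_tab)
    }
  })

  # --- balance --------------------------------------------------------
  selected <- stage("balance", {
    candidates <- list()
    for (mth in config$methods) {
      candidates[[mth]] <- if (mth == "entropy") {
        entropy_balance(tab, confounders)
      } else {
        make_ipw(fit_propensity(tab, confounders, method = mth,
                                seed = config$seed),
                 tab, truncate_at = config$truncate_at)
      }
    }
    select_weights(candidates, tab, confounders)
  })
  bal <- stage("balance", balance_report(tab, selected, confounders))

  w_final_all <- selected$w * (if (is.null(rw)) 1 else rw$w)
  w_final <- w_final_all[responders]

  # --- inequality -----------------------------------------------------
  set.seed(config$seed + 2L)
  results <- stage("inequality", {
    rows <- list()
    for (oc in config$outcomes) {
      for (st in config$stratifiers) {
        for (vr in config$variants) {
          fits <- lapply(analysis_tabs, function(ti) {
            system_contrast(ti, oc, strat = st, weights = w_final,
                            variant = vr, se_method = config$se_method,
                            boot_reps = config$boot_reps)
          })
          rows[[length(rows) + 1L]] <- pool_contrasts(fits, oc, st)
        }
      }
    }
    do.call(rbind, rows)
  })

  means <- stage("means", {
    rows <- lapply(config$outcomes, function(oc) {
      pooled <- pool_means(lapply(analysis_tabs, function(ti) {
        ti[[oc]] <- as.numeric(ti[[oc]])
        grouped_means(ti, oc, by = "system", weights = w_final)
      }))
      cbind(outcome = oc, pooled)
    })
    do.call(rbind, rows)
  })

  nc <- stage("negative_control", {
    if (is.null(config$negative_control)) NULL else {
      estimate_negative_control(analysis_tabs, config$negative_control,
                                w_final, config)
    }
  })

  manifest <- list(
    package_version = tryCatch(
      as.character(utils::packageVersion("healthineq")),
      error = function(e) NA_character_),
    seed = config$seed,
    config_hash = config_hash(config),
    n_records = nrow(tab),
    n_responders = sum(responders),
    selected_weights = selected$selected %||% selected$method,
    candidate_criteria = as.list(selected$candidate_criteria),
    m_imputations = length(analysis_tabs)
  )

  bundle <- structure(
    list(balance = bal, weights = selected, results = results, means = means,
         negative_control = nc, manifest = manifest, config = config),
    class = "results_bundle"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    utils::write.csv(bal$table, file.path(out_dir, "balance_table.csv"),
                     row.names = FALSE)
    utils::write.csv(bal$smd, file.path(out_dir, "balance_smd.csv"),
                     row.names = FALSE)
    utils::write.csv(means, file.path(out_dir, "grouped_means.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  bundle
}

# Rubin-combine a scalar across imputations (normal reference when the
# between-imputation variance is 0).
pool_scalar <- function(q, se, conf_level = 0.95) {
  m <- length(q)
  qbar <- mean(q)
  if (m == 1L) {
    zq <- stats::qnorm(1 - (1 - conf_level) / 2)
    return(list(estimate = qbar, se = se,
                lo = qbar - zq * se, hi = qbar + zq * se))
  }
  W <- mean(se^2)
  B <- stats::var(q)
  total <- sqrt(W + (1 + 1 / m) * B)
  if (B == 0) {
    tq <- stats::qnorm(1 - (1 - conf_level) / 2)
  } else {
    df <- (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
    tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  }
  list(estimate = qbar, se = total, lo = qbar - tq * total,
       hi = qbar + tq * total)
}

pool_contrasts <- function(fits, outcome, strat) {
  f1 <- fits[[1L]]
  rows <- list()
  for (i in seq_len(nrow(f1$arms))) {
    p <- pool_scalar(vapply(fits, function(f) f$arms$estimate[i], numeric(1)),
                     vapply(fits, function(f) f$arms$se[i], numeric(1)),
                     f1$conf_level)
    rows[[length(rows) + 1L]] <- data.frame(
      outcome = outcome, stratifier = strat, variant = f1$variant,
      group = f1$arms$system[i], estimate = p$estimate, se = p$se,
      conf_low = p$lo, conf_high = p$hi,
      mu = mean(vapply(fits, function(f) f$arms$mu[i], numeric(1))),
      n_eff = f1$arms$n_eff[i], stringsAsFactors = FALSE
    )
  }
  p <- pool_scalar(vapply(fits, function(f) f$difference$estimate, numeric(1)),
                   vapply(fits, function(f) f$difference$se, numeric(1)),
                   f1$conf_level)
  rows[[length(rows) + 1L]] <- data.frame(
    outcome = outcome, stratifier = strat, variant = f1$variant,
    group = "difference", estimate = p$estimate, se = p$se,
    conf_low = p$lo, conf_high = p$hi, mu = NA_real_,
    n_eff = NA_real_, stringsAsFactors = FALSE
  )
  do.call(rbind, rows)
}

pool_means <- function(tabs) {
  t1 <- tabs[[1L]]
  for (i in seq_len(nrow(t1))) {
    p <- pool_scalar(vapply(tabs, function(t) t$mean[i], numeric(1)),
                     vapply(tabs, function(t) t$se[i], numeric(1)))
    t1$mean[i] <- p$estimate
    t1$se[i] <- p$se
    t1$conf_low[i] <- p$lo
    t1$conf_high[i] <- p$hi
  }
  t1
}

estimate_negative_control <- function(analysis_tabs, control, w_final,
                                      config) {
  ests <- lapply(analysis_tabs, function(ti) {
    meta <- outcome_meta(ti, control)
    coding <- code_outcome(ti[[control]], kind = meta$kind,
                           higher_is_better = meta$higher_is_better %||% TRUE,
                           bounds = meta$bounds, weights = w_final)
    concentration_index(coding, fractional_rank(ti$origin_class, w_final),
                        w_final, variant = "relative_attainment",
                        se_method = config$se_method,
                        boot_reps = config$boot_reps)
  })
  est <- if (length(ests) > 1L) pool_estimates(ests) else ests[[1L]]
  flag <- est$conf_low > 0 || est$conf_high < 0
  list(variable = control, estimate = est, flagged = flag)
}

#' Negative-control check on a pipeline bundle
#'
#' A pre-exposure variable generated (or believed) independent of origin
#' class should show a concentration index whose interval covers zero;
#' an interval excluding zero is flagged (not failed) as a sign of residual
#' confounding.  A control listed among the confounders is a configuration
#' contradiction and errors.
#'
#' @param config the [run_config()] used for the run.
#' @param bundle the [run_pipeline()] result.
#' @return list with the control variable name, its `ci_estimate`, and
#'   `flagged`.
#' @export
negative_control <- function(config, bundle) {
  validate_run_config(config)
  stopifnot(inherits(bundle, "results_bundle"))
  if (is.null(bundle$negative_control)) {
    stop("the bundle holds no negative-control estimate")
  }
  bundle$negative_control
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_run_config(config, f)
  unname(tools::md5sum(f))
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("Inequality pipeline results\n")
  cat("  records:", x$manifest$n_records,
      "| responders:", x$manifest$n_responders,
      "| imputations:", x$manifest$m_imputations, "\n")
  cat("  weights:", x$manifest$selected_weights,
      "(mean |SMD|", format(x$weights$criterion, digits = 3), ")\n")
  if (!is.null(x$negative_control)) {
    cat("  negative control '", x$negative_control$variable, "': ",
        format(x$negative_control$estimate$estimate, digits = 3),
        if (x$negative_control$flagged) "  ** FLAGGED **" else "  (covers 0)",
        "\n", sep = "")
  }
  cat("\n")
  print(utils::head(x$results, 12), row.names = FALSE, digits = 3)
  if (nrow(x$results) > 12) cat("... (", nrow(x$results), "rows )\n")
  invisible(x)
}
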