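#' Generate a synthetic two-system cohort with known inequality
#'
#' Draws a person-level cohort table with the statistical structure the
#' downstream analysis assumes: independent categorical confounders, a
#' cognitive-ability score and a four-category ordered origin class sharing
#' a latent advantage factor, a binary school-system exposure that is a
#' logistic function of the confounders, and outcomes whose expected
#' attainment is a known function of the fractional origin-class rank.
#' Outcomes are planted on the *realised* rank coding of the generated
#' table, and the returned `truth` is computed by exact enumeration over the
#' realised class shares, so that a noise-free outcome analysed with
#' [concentration_index()] reproduces the truth to machine precision.
#'
#' @param confounders a [confounder_spec()].
#' @param exposure an [exposure_spec()]; under `allocation = "balanced"` the
#'   exposure model is ignored and arms are interleaved within class.
#' @param outcomes list of [outcome_spec()] objects.
#' @param n number of records (positive integer).
#' @param seed integer seed; identical arguments give byte-identical tables.
#' @param allocation `"multinomial"` draws class and exposure stochastically;
#'   `"balanced"` is a validation mode with exact largest-remainder class
#'   counts and alternating within-class exposure, so realised shares equal
#'   the specified probabilities exactly.
#' @return A list with
#'   \describe{
#'     \item{table}{a `cohort_table` data frame (`id`, confounder columns,
#'       `ability_raw`, `ability_std`, `origin_class` (ordered,
#'       disadvantaged first), `system`, outcome columns) carrying
#'       `confounders` and `outcome_meta` attributes;}
#'     \item{truth}{data frame of per outcome x system true means and
#'       relative/absolute concentration indices (attainment orientation,
#'       with the shortfall mirror);}
#'     \item{specs}{the generating specifications.}
#'   }
#' @export
generate_cohort <- function(confounders = default_confounder_spec(),
                            exposure = default_exposure_spec(),
                            outcomes = default_outcome_specs(),
                            n, seed,
                            allocation = c("multinomial", "balanced")) {
  allocation <- match.arg(allocation)
  stopifnot(inherits(confounders, "confounder_spec"),
            inherits(exposure, "exposure_spec"))
  if (inherits(outcomes, "outcome_spec")) outcomes <- list(outcomes)
  if (length(n) != 1L || is.na(n) || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer")
  }
  n <- as.integer(n)
  set.seed(as.integer(seed))

  # latent advantage factor links origin class and ability
  advantage <- stats::rnorm(n)
  class_levels <- rev(confounders$class_labels)       # disadvantaged first
  probs_disadv <- rev(confounders$class_probs)
  if (allocation == "multinomial") {
    cls_idx <- findInterval(stats::pnorm(advantage),
                            cumsum(probs_disadv), left.open = TRUE) + 1L
  } else {
    counts <- largest_remainder(probs_disadv, n)
    cls_idx <- integer(n)
    cls_idx[order(advantage)] <- rep.int(seq_along(counts), counts)
  }
  origin_class <- factor(class_levels[cls_idx], levels = class_levels,
                         ordered = TRUE)

  rho <- confounders$ability_class_cor
  ability_raw <- confounders$ability_mean_raw + confounders$ability_sd_raw *
    (rho * advantage + sqrt(1 - rho^2) * stats::rnorm(n))
  ability_std <- standardise_ability(ability_raw)

  tab <- data.frame(id = seq_len(n))
  for (nm in names(confounders$categorical)) {
    v <- confounders$categorical[[nm]]
    tab[[nm]] <- factor(sample(v$labels, n, replace = TRUE, prob = v$probs),
                        levels = v$labels)
  }
  tab$ability_raw <- ability_raw
  tab$ability_std <- ability_std
  tab$origin_class <- origin_class

  # exposure
  if (allocation == "balanced") {
    sel <- logical(n)
    for (g in seq_along(class_levels)) {
      i <- which(cls_idx == g)
      sel[i[seq_along(i) %% 2L == 0L]] <- TRUE
    }
  } else {
    lp <- linear_predictor(tab, exposure$intercept, exposure$coefficients)
    p_sel <- stats::plogis(lp)
    if (any(p_sel <= 0) || any(p_sel >= 1)) {
      stop("exposure probabilities must lie strictly in (0, 1)")
    }
    sel <- stats::runif(n) < p_sel
  }
  tab$system <- factor(ifelse(sel, "selective", "comprehensive"),
                       levels = c("comprehensive", "selective"))

  # plant outcomes on the realised pooled rank coding
  rk <- fractional_rank(origin_class)
  r <- rk$rank
  s <- as.numeric(sel)
  meta <- list()
  for (spec in outcomes) {
    gen <- generate_outcome(spec, r, s)
    tab[[spec$name]] <- gen$values
    meta[[spec$name]] <- gen$meta
  }

  truth <- simulation_truth(outcomes, rk$groups$share, rk$groups$midpoint)

  attr(tab, "confounders") <- c(names(confounders$categorical),
                                "ability_std", "origin_class")
  attr(tab, "outcome_meta") <- meta
  class(tab) <- c("cohort_table", "data.frame")

  list(table = tab, truth = truth,
       specs = list(confounders = confounders, exposure = exposure,
                    outcomes = outcomes, n = n, seed = as.integer(seed),
                    allocation = allocation))
}

largest_remainder <- function(p, n) {
  raw <- p * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    take <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[take] <- counts[take] + 1
  }
  as.integer(counts)
}

# One outcome column (raw orientation) plus its coding metadata.
generate_outcome <- function(spec, r, s) {
  a <- spec$alpha + s * spec$system_shift
  b <- spec$beta + s * spec$system_beta_shift
  eta <- a + b * r
  if (spec$kind == "continuous") {
    y_att <- if (spec$noise_sd == 0) eta else rbeta_meansd(eta, spec$noise_sd)
    values <- if (spec$higher_is_better) y_att else 1 - y_att
    meta <- list(kind = "continuous", higher_is_better = spec$higher_is_better,
                 bounds = c(0, 1))
  } else if (spec$kind == "binary") {
    y_att <- stats::rbinom(length(r), 1L, stats::plogis(eta))
    values <- if (spec$higher_is_better) y_att else 1L - y_att
    meta <- list(kind = "binary", higher_is_better = spec$higher_is_better,
                 bounds = c(0, 1))
  } else {
    K <- length(spec$cutpoints) + 1L
    cum <- vapply(spec$cutpoints, function(ck) stats::plogis(ck - eta),
                  numeric(length(r)))
    u <- stats::runif(length(r))
    lev <- 1L + rowSums(u > cum)               # attainment-oriented level
    if (!spec$higher_is_better) lev <- K + 1L - lev
    values <- factor(lev, levels = seq_len(K), ordered = TRUE)
    meta <- list(kind = "ordinal", higher_is_better = spec$higher_is_better,
                 bounds = c(1, K))
  }
  list(values = values, meta = meta)
}

# Beta draw with exact mean m and standard deviation sd (method of moments).
rbeta_meansd <- function(m, sd) {
  v <- sd^2
  if (any(v >= m * (1 - m))) {
    stop("noise_sd too large for Beta noise at the planted mean profile")
  }
  phi <- m * (1 - m) / v - 1
  stats::rbeta(length(m), m * phi, (1 - m) * phi)
}

# Exact enumeration of per-system truth over the realised class shares.
simulation_truth <- function(outcomes, share, mid) {
  rows <- list()
  for (spec in outcomes) {
    for (sys in c("comprehensive", "selective")) {
      s <- as.numeric(sys == "selective")
      a <- spec$alpha + s * spec$system_shift
      b <- spec$beta + s * spec$system_beta_shift
      e <- expected_attainment(spec, a, b, mid)
      mu <- sum(share * e)
      cv <- sum(share * e * mid) - mu * 0.5
      rel <- 2 * cv / mu
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = spec$name, system = sys, mean = mu,
        relative_attainment = rel,
        relative_shortfall = -mu * rel / (1 - mu),
        absolute = 4 * mu * rel,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

expected_attainment <- function(spec, a, b, mid) {
  eta <- a + b * mid
  if (spec$kind == "continuous") {
    eta
  } else if (spec$kind == "binary") {
    stats::plogis(eta)
  } else {
    K <- length(spec$cutpoints) + 1L
    cum <- vapply(spec$cutpoints, function(ck) stats::plogis(ck - eta),
                  numeric(length(mid)))
    cum <- cbind(cum, 1)
    pk <- cum - cbind(0, cum[, -K, drop = FALSE])
    as.vector(pk %*% ((seq_len(K) - 1) / (K - 1)))
  }
}

# Evaluate intercept + named coefficient contributions on table columns.
linear_predictor <- function(data, intercept, coefficients) {
  lp <- rep(intercept, nrow(data))
  for (nm in names(coefficients)) {
    if (!nm %in% names(data)) {
      stop("model references unknown column '", nm, "'")
    }
    cf <- coefficients[[nm]]
    col <- data[[nm]]
    if (is.numeric(col)) {
      lp <- lp + cf * col
    } else {
      lev <- as.character(col)
      if (!all(lev %in% names(cf))) {
        stop("coefficient vector for '", nm, "' misses levels: ",
             paste(setdiff(unique(lev), names(cf)), collapse = ", "))
      }
      lp <- lp + unname(cf[lev])
    }
  }
  lp
}

#' Standardise an ability score to mean 100, SD 15
#'
#' Affine (rank-preserving) transform so the (weighted) mean is 100 and the
#' (weighted, population-denominator) standard deviation is 15, the
#' conventional IQ-style scale for childhood cognitive ability tests.
#'
#' @param scores numeric raw scores with at least two distinct values.
#' @param weights optional non-negative weights.
#' @param target_mean,target_sd target location and scale.
#' @return Numeric vector of standardised scores.
#' @export
standardise_ability <- function(scores, weights = NULL,
                                target_mean = 100, target_sd = 15) {
  if (anyNA(scores)) stop("scores contain missing values")
  n <- length(scores)
  w <- if (is.null(weights)) rep(1, n) else check_weights(as.numeric(weights), n)
  if (length(unique(scores[w > 0])) < 2L) {
    stop("constant score vector: standardisation undefined (zero variance)")
  }
  m <- weighted_mean(scores, w)
  s <- sqrt(weighted_var(scores, w))
  target_mean + target_sd * (scores - m) / s
}

#' Impose wave attrition and item non-response on a cohort table
#'
#' Wave non-response (attrition) blanks every outcome column of the affected
#' records; item non-response blanks single cells.  Both mechanisms are
#' missing-at-random logistic models in fully observed baseline confounders,
#' which are never blanked.  A `responded` indicator and per-variable
#' `miss_*` indicators are appended.
#'
#' @param table a `cohort_table` from [generate_cohort()].
#' @param attrition optional `list(intercept =, coefficients = list(...))`
#'   giving the log-odds of wave *non-response* as a function of baseline
#'   columns.
#' @param item optional named list (one element per outcome column to
#'   affect) of models in the same form, giving log-odds of item
#'   missingness.
#' @param seed integer seed.
#' @return The modified `cohort_table`.
#' @export
impose_missingness <- function(table, attrition = NULL, item = NULL, seed) {
  stopifnot(is.data.frame(table))
  if (is.null(attrition) && is.null(item)) {
    return(table)
  }
  set.seed(as.integer(seed))
  meta <- attr(table, "outcome_meta")
  if (is.null(meta)) stop("table carries no outcome metadata")
  outcome_cols <- names(meta)
  conf_cols <- attr(table, "confounders")

  check_model <- function(model, label) {
    if (!is.finite(model$intercept %||% NA_real_)) {
      stop(label, ": intercept must be finite (degenerate response ",
           "probability rejected)")
    }
    for (nm in names(model$coefficients)) {
      if (any(!is.finite(model$coefficients[[nm]]))) {
        stop(label, ": non-finite coefficient for '", nm, "'")
      }
      if (nm %in% outcome_cols) {
        stop(label, ": model references '", nm, "', a column that may ",
             "itself be missing; missingness models must use fully ",
             "observed baseline confounders")
      }
    }
  }

  responded <- rep(TRUE, nrow(table))
  if (!is.null(attrition)) {
    check_model(attrition, "attrition model")
    p_miss <- stats::plogis(linear_predictor(table, attrition$intercept,
                                             attrition$coefficients))
    responded <- stats::runif(nrow(table)) >= p_miss
    for (oc in outcome_cols) table[[oc]][!responded] <- NA
  }
  table$responded <- responded

  for (vn in names(item)) {
    if (!vn %in% outcome_cols) {
      stop("item model for '", vn, "' does not target an outcome column")
    }
    check_model(item[[vn]], paste0("item model for '", vn, "'"))
    p_miss <- stats::plogis(linear_predictor(table, item[[vn]]$intercept,
                                             item[[vn]]$coefficients))
    hit <- stats::runif(nrow(table)) < p_miss
    table[[vn]][hit] <- NA
    table[[paste0("miss_", vn)]] <- hit | !responded
  }

  attr(table, "confounders") <- conf_cols
  attr(table, "outcome_meta") <- meta
  table
}

#' @export
`[.cohort_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "confounders") <- attr(x, "confounders")
    attr(out, "outcome_meta") <- attr(x, "outcome_meta")
    class(out) <- class(x)
  }
  out
}
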