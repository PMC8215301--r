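#' Specify the baseline confounder distribution of a synthetic cohort
#'
#' Describes the joint distribution of pre-secondary-school confounders:
#' independent categorical variables given by marginal probabilities, a
#' continuous cognitive-ability score, and a four-category ordered origin
#' social class (NS-SEC style).  Ability and origin class share a latent
#' advantage factor with configurable correlation, since real cohort tables
#' report only the marginals.
#'
#' @param categorical named list; each element is a list with `labels`
#'   (category names) and `probs` (marginal probabilities summing to 1).
#' @param ability_mean_raw,ability_sd_raw location and scale of the raw
#'   ability score before standardisation to mean 100, SD 15.
#' @param class_labels exactly four ordered origin-class labels, from most
#'   to least advantaged.
#' @param class_probs probabilities for `class_labels`, summing to 1.
#' @param ability_class_cor correlation between the latent advantage factor
#'   driving class and the ability score (default 0.3).
#' @return An object of class `confounder_spec`.
#' @export
confounder_spec <- function(categorical = list(),
                            ability_mean_raw = 45, ability_sd_raw = 12,
                            class_labels = c("higher_managerial",
                                             "lower_managerial",
                                             "intermediate", "routine"),
                            class_probs = c(0.16, 0.05, 0.21, 0.58),
                            ability_class_cor = 0.3) {
  if (length(class_labels) != 4L) {
    stop("exactly 4 ordered origin-class labels are required")
  }
  check_probs(class_probs, "class_probs", length(class_labels))
  for (nm in names(categorical)) {
    v <- categorical[[nm]]
    if (is.null(v$labels) || is.null(v$probs)) {
      stop("categorical variable '", nm, "' needs `labels` and `probs`")
    }
    check_probs(v$probs, nm, length(v$labels))
  }
  if (ability_sd_raw <= 0) stop("ability_sd_raw must be positive")
  if (abs(ability_class_cor) >= 1) stop("ability_class_cor must be in (-1, 1)")
  structure(
    list(categorical = categorical,
         ability_mean_raw = ability_mean_raw,
         ability_sd_raw = ability_sd_raw,
         class_labels = class_labels,
         class_probs = class_probs,
         ability_class_cor = ability_class_cor),
    class = "confounder_spec"
  )
}

check_probs <- function(p, what, k) {
  if (length(p) != k) stop("'", what, "': need ", k, " probabilities")
  if (any(p < 0) || any(p > 1)) stop("'", what, "': probabilities outside [0, 1]")
  if (abs(sum(p) - 1) > 1e-12) {
    stop("'", what, "': probabilities sum to ", format(sum(p), digits = 15),
         ", not 1 (tolerance 1e-12)")
  }
  invisible(p)
}

#' Default confounder specification for a 1958-style British birth cohort
#'
#' Marginal category frequencies echo the published baseline tables of the
#' 1958 cohort (sex, broad ethnicity, region of residence, parental
#' education/aspirations/interest, state primary school), with the father's
#' four-category NS-SEC margins for origin class.  Marginals are normalised
#' exactly to sum to one.
#'
#' @return A `confounder_spec`.
#' @export
default_confounder_spec <- function() {
  norm <- function(x) x / sum(x)
  confounder_spec(
    categorical = list(
      sex = list(labels = c("female", "male"), probs = norm(c(489, 511))),
      ethnicity = list(labels = c("white", "asian", "black", "other"),
                       probs = norm(c(987, 2, 5, 6))),
      region = list(
        labels = c("ew_riding", "east", "midlands", "north", "north_midlands",
                   "north_west", "scotland", "south", "south_east",
                   "south_west", "wales"),
        probs = norm(c(84, 86, 93, 69, 78, 129, 106, 63, 176, 61, 55))),
      parent_left_edu = list(labels = c("15_or_below", "16_to_18", "19_plus"),
                             probs = norm(c(732, 213, 55))),
      parent_hope_stay = list(labels = c("dont_know", "no", "yes"),
                              probs = norm(c(142, 30, 828))),
      parent_interest = list(labels = c("little", "some", "very"),
                             probs = norm(c(153, 428, 418))),
      state_primary = list(labels = c("no", "yes"), probs = norm(c(59, 941)))
    )
  )
}

#' Specify the school-system exposure model
#'
#' Selective-system attendance follows a logistic model in the confounders,
#' so that (with positive coefficients on advantage and ability) selective
#' pupils are enriched among advantaged, higher-ability children.
#'
#' @param intercept log-odds intercept.
#' @param coefficients named list of log-odds effects: a scalar for a
#'   numeric column (applied to the column as-is, e.g. `ability_std`), or a
#'   named vector over levels for a categorical column.
#' @return An object of class `exposure_spec`.
#' @export
exposure_spec <- function(intercept = 0, coefficients = list()) {
  if (!is.finite(intercept)) stop("exposure intercept must be finite")
  for (nm in names(coefficients)) {
    if (any(!is.finite(coefficients[[nm]]))) {
      stop("non-finite exposure coefficient for '", nm, "'")
    }
  }
  structure(list(intercept = intercept, coefficients = coefficients),
            class = "exposure_spec")
}

#' @rdname exposure_spec
#' @param p marginal probability of selective attendance for the null
#'   (unconfounded) exposure model.
#' @export
null_exposure_spec <- function(p = 0.4) {
  if (p <= 0 || p >= 1) stop("p must be strictly inside (0, 1)")
  exposure_spec(intercept = stats::qlogis(p))
}

#' Default confounded exposure model
#'
#' Selective attendance rises with cognitive ability (about 0.5 log-odds per
#' 15-point SD), with origin-class advantage, and for private primary
#' schooling; calibrated to give roughly 40% selective attendance overall.
#'
#' @export
default_exposure_spec <- function() {
  exposure_spec(
    intercept = -3.9,
    coefficients = list(
      ability_std = 1 / 30,
      origin_class = c(routine = 0, intermediate = 0.4,
                       lower_managerial = 0.7, higher_managerial = 0.9),
      state_primary = c(yes = 0, no = 1.2)
    )
  )
}

#' Specify a synthetic outcome with planted inequality
#'
#' Outcomes are parameterised on the attainment (larger = better health)
#' 0--1 scale through the fractional origin-class rank \eqn{r}: the expected
#' attainment at rank \eqn{r} is `alpha + beta * r` for continuous outcomes
#' (Beta-distributed noise keeps values strictly inside (0, 1) without
#' disturbing the planted mean and covariance), and `alpha + beta * r` on
#' the logit scale for binary and proportional-odds ordinal outcomes.
#' `system_shift` and `system_beta_shift` move the intercept and rank slope
#' under the selective system.  When `higher_is_better = FALSE` the stored
#' raw column is the reversed (ill-health) orientation.
#'
#' @param name column name.
#' @param kind `"continuous"`, `"binary"` or `"ordinal"`.
#' @param higher_is_better direction of the stored raw column.
#' @param alpha outcome level (continuous: attainment scale; binary/ordinal:
#'   logit scale) at rank 0 under the comprehensive system.
#' @param beta linear effect of the fractional rank (the planted inequality).
#' @param system_shift,system_beta_shift additive changes to `alpha`/`beta`
#'   under the selective system.
#' @param noise_sd residual SD for continuous outcomes (Beta noise).
#' @param cutpoints ordered logit cutpoints for ordinal outcomes (K levels
#'   need K - 1 cutpoints).
#' @return An object of class `outcome_spec`.
#' @export
outcome_spec <- function(name, kind = c("continuous", "binary", "ordinal"),
                         higher_is_better = TRUE, alpha = 0.5, beta = 0,
                         system_shift = 0, system_beta_shift = 0,
                         noise_sd = 0.1, cutpoints = NULL) {
  kind <- match.arg(kind)
  if (kind == "continuous") {
    for (s in c(0, 1)) {  # both systems
      a <- alpha + s * system_shift
      b <- beta + s * system_beta_shift
      mm <- c(a, a + b)   # expected attainment at rank 0 and rank 1
      if (any(mm <= 0) || any(mm >= 1)) {
        stop("'", name, "': expected attainment leaves (0, 1); ",
             "the relative index would be undefined")
      }
      if (noise_sd < 0) stop("noise_sd must be non-negative")
      if (noise_sd > 0 && noise_sd^2 >= min(mm * (1 - mm))) {
        stop("'", name, "': noise_sd too large for a (0, 1) outcome with ",
             "this mean profile")
      }
    }
  }
  if (kind == "ordinal") {
    if (is.null(cutpoints) || length(cutpoints) < 1L ||
        is.unsorted(cutpoints, strictly = TRUE)) {
      stop("ordinal outcome needs strictly increasing `cutpoints`")
    }
  }
  structure(
    list(name = name, kind = kind, higher_is_better = higher_is_better,
         alpha = alpha, beta = beta, system_shift = system_shift,
         system_beta_shift = system_beta_shift, noise_sd = noise_sd,
         cutpoints = cutpoints),
    class = "outcome_spec"
  )
}

#' Population variance of the fractional rank implied by class shares
#'
#' @param class_probs class shares ordered from most to least advantaged
#'   (as in [confounder_spec()]).
#' @return The variance of the cumulative-midpoint rank coding.
#' @export
rank_variance <- function(class_probs = c(0.16, 0.05, 0.21, 0.58)) {
  p <- rev(class_probs)  # disadvantaged first
  mid <- cumsum(p) - p / 2
  sum(p * mid^2) - 0.5^2
}

#' Continuous outcome spec with exactly planted concentration indices
#'
#' Solves `alpha` and `beta` (and the selective-system shifts) so that the
#' relative attainment concentration index equals `ci_comprehensive` /
#' `ci_selective` at the given outcome mean under the population class
#' shares: `beta = ci * mean / (2 * var(rank))`, `alpha = mean - beta / 2`.
#'
#' @param name column name.
#' @param mean target weighted mean of the scaled outcome in each arm.
#' @param ci_comprehensive,ci_selective target relative attainment indices.
#' @param noise_sd residual SD (Beta noise).
#' @param class_probs class shares, most advantaged first.
#' @return An `outcome_spec`.
#' @export
planted_ci_outcome <- function(name, mean = 0.5, ci_comprehensive = 0.1,
                               ci_selective = ci_comprehensive,
                               noise_sd = 0.1,
                               class_probs = c(0.16, 0.05, 0.21, 0.58)) {
  v <- rank_variance(class_probs)
  beta_c <- ci_comprehensive * mean / (2 * v)
  beta_s <- ci_selective * mean / (2 * v)
  alpha_c <- mean - beta_c / 2
  alpha_s <- mean - beta_s / 2
  outcome_spec(name, "continuous", alpha = alpha_c, beta = beta_c,
               system_shift = alpha_s - alpha_c,
               system_beta_shift = beta_s - beta_c, noise_sd = noise_sd)
}

#' Default outcome battery for the synthetic cohorts
#'
#' Mirrors the structure of the adult outcomes the analysis targets: a
#' bounded mental-wellbeing score and a life-satisfaction score (continuous,
#' higher better), current smoking (binary, higher worse, roughly a quarter
#' of the cohort smoking), four-level self-rated health and destination
#' social class (ordinal, higher better), age of leaving full-time education
#' in four ordered bands with larger means and steeper social gradients
#' under the selective system, and a baseline BMI-style negative-control
#' score generated independently of origin class.
#'
#' @return Named list of `outcome_spec` objects.
#' @export
default_outcome_specs <- function() {
  specs <- list(
    outcome_spec("wellbeing", "continuous", alpha = 0.55, beta = 0.10,
                 noise_sd = 0.12),
    outcome_spec("life_satisfaction", "continuous", alpha = 0.60,
                 beta = 0.08, noise_sd = 0.15),
    outcome_spec("smoker", "binary", higher_is_better = FALSE,
                 alpha = 0.9, beta = 0.6),
    outcome_spec("self_rated_health", "ordinal", alpha = 0, beta = 0.8,
                 cutpoints = c(-2.5, -1.2, 0.2)),
    outcome_spec("age_left_education", "ordinal", alpha = 0, beta = 1.2,
                 system_shift = 0.35, system_beta_shift = 0.5,
                 cutpoints = c(0, 1.2, 2.2)),
    outcome_spec("destination_class", "ordinal", alpha = 0, beta = 1.5,
                 system_beta_shift = 0.4, cutpoints = c(-0.8, 0.2, 1.8)),
    outcome_spec("bmi_baseline", "continuous", higher_is_better = FALSE,
                 alpha = 0.45, beta = 0, noise_sd = 0.12)
  )
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}
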