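test_that("generation is deterministic given the seed", {
  a <- generate_cohort(n = 500, seed = 42)
  b <- generate_cohort(n = 500, seed = 42)
  expect_identical(a$table, b$table)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(n = 500, seed = 43)
  expect_false(identical(a$table, c$table))
})

test_that("no planted inequality means zero true indices", {
  specs <- list(outcome_spec("flat", "continuous", alpha = 0.4, beta = 0,
                             noise_sd = 0.05),
                outcome_spec("flat_bin", "binary", alpha = 0.2, beta = 0))
  sim <- generate_cohort(outcomes = specs, n = 300, seed = 1)
  expect_equal(sim$truth$relative_attainment, rep(0, 4))
  expect_equal(sim$truth$absolute, rep(0, 4))
})

test_that("four equal classes with y = rank match the enumeration oracle", {
  # ranks 0.125/0.375/0.625/0.875; brute force over the four values:
  # var(r) = mean(r^2) - 0.25 = 0.078125, mu = 0.5 when y = r, so the
  # covariance identity gives CI = 2 * 0.078125 / 0.5 = 0.3125 and the
  # absolute index 4 * 0.5 * 0.3125 = 0.625
  mid <- c(0.125, 0.375, 0.625, 0.875)
  oracle_var <- mean(mid^2) - mean(mid)^2
  oracle_rel <- 2 * oracle_var / 0.5
  spec <- confounder_spec(class_probs = rep(0.25, 4))
  # alpha = 0 would put the rank-0 mean on the boundary; nudge inside
  sim <- generate_cohort(confounders = spec, outcomes = list(
    outcome_spec("y", "continuous", alpha = 1e-9, beta = 1 - 2e-9,
                 noise_sd = 0)),
    exposure = null_exposure_spec(), n = 4000, seed = 2,
    allocation = "balanced")
  tru <- sim$truth[sim$truth$system == "comprehensive", ]
  expect_equal(tru$relative_attainment, oracle_rel, tolerance = 1e-6)
  expect_equal(tru$relative_attainment, 0.3125, tolerance = 1e-6)
  expect_equal(tru$absolute, 0.625, tolerance = 1e-6)
  expect_equal(tru$absolute, 4 * tru$mean * tru$relative_attainment,
               tolerance = 1e-12)
})

test_that("noise-free estimates reproduce the closed-form truth to 1e-10", {
  specs <- list(
    outcome_spec("cont", "continuous", alpha = 0.3, beta = 0.2,
                 noise_sd = 0),
    outcome_spec("bin", "binary", alpha = -0.5, beta = 0.8),
    outcome_spec("ord", "ordinal", beta = 1.1, cutpoints = c(-1, 0, 1))
  )
  sim <- generate_cohort(outcomes = specs, exposure = null_exposure_spec(),
                         n = 3000, seed = 3)
  tab <- sim$table
  rk <- fractional_rank(tab$origin_class)
  tru <- sim$truth[sim$truth$system == "comprehensive", ]
  # the continuous noise-free outcome must match exactly; the stochastic
  # binary/ordinal outcomes match their own realised expectation only in
  # distribution, so only 'cont' is checked at machine precision
  cod <- code_outcome(tab$cont, kind = "continuous", bounds = c(0, 1))
  est <- concentration_index(cod, rk, variant = "relative_attainment",
                             se_method = "none")
  expect_equal(est$estimate,
               tru$relative_attainment[tru$outcome == "cont"],
               tolerance = 1e-10)
  est_abs <- concentration_index(cod, rk, variant = "absolute",
                                 se_method = "none")
  expect_equal(est_abs$estimate, tru$absolute[tru$outcome == "cont"],
               tolerance = 1e-10)
  # truth internal identity for every outcome and system
  expect_equal(sim$truth$absolute,
               4 * sim$truth$mean * sim$truth$relative_attainment,
               tolerance = 1e-12)
})

test_that("binary and ordinal truths match brute-force enumeration", {
  spec_bin <- outcome_spec("b", "binary", alpha = -0.4, beta = 0.9)
  spec_ord <- outcome_spec("o", "ordinal", alpha = 0.2, beta = 1.3,
                           cutpoints = c(-0.9, 0.1, 1.4))
  sim <- generate_cohort(outcomes = list(spec_bin, spec_ord),
                         exposure = null_exposure_spec(),
                         n = 1000, seed = 4)
  rk <- fractional_rank(sim$table$origin_class)
  sh <- rk$groups$share
  mid <- rk$groups$midpoint
  # binary: enumerate P(good | class)
  p <- plogis(-0.4 + 0.9 * mid)
  mu <- sum(sh * p)
  cv <- sum(sh * p * mid) - mu * 0.5
  tru <- sim$truth
  expect_equal(tru$relative_attainment[tru$outcome == "b" &
                                         tru$system == "comprehensive"],
               2 * cv / mu, tolerance = 1e-12)
  # ordinal: enumerate the 4 x 4 class-by-level table
  eta <- 0.2 + 1.3 * mid
  cum <- sapply(c(-0.9, 0.1, 1.4), function(ck) plogis(ck - eta))
  pk <- cbind(cum, 1) - cbind(0, cum)
  ey <- as.vector(pk %*% c(0, 1/3, 2/3, 1))
  mu_o <- sum(sh * ey)
  cv_o <- sum(sh * ey * mid) - mu_o * 0.5
  expect_equal(tru$relative_attainment[tru$outcome == "o" &
                                         tru$system == "comprehensive"],
               2 * cv_o / mu_o, tolerance = 1e-12)
})

test_that("selective pupils are more able and more advantaged", {
  sim <- generate_cohort(n = 20000, seed = 5)
  tab <- sim$table
  sel <- tab$system == "selective"
  # ability difference, assessed against its Monte-Carlo error
  se_gap <- sqrt(var(tab$ability_std[sel]) / sum(sel) +
                   var(tab$ability_std[!sel]) / sum(!sel))
  expect_gt(mean(tab$ability_std[sel]) - mean(tab$ability_std[!sel]),
            3 * se_gap)
  adv <- tab$origin_class %in% c("higher_managerial", "lower_managerial")
  se_adv <- sqrt(mean(adv) * (1 - mean(adv)) *
                   (1 / sum(sel) + 1 / sum(!sel)))
  expect_gt(mean(adv[sel]) - mean(adv[!sel]), 3 * se_adv)
})

test_that("spec constructors validate their invariants", {
  expect_error(confounder_spec(class_probs = c(0.5, 0.5)), "probabilities")
  expect_error(confounder_spec(class_labels = c("high", "low"),
                               class_probs = c(0.5, 0.5)), "4 ordered")
  expect_error(confounder_spec(class_probs = c(0.3, 0.3, 0.3, 0.2)),
               "sum to")
  expect_error(outcome_spec("y", "continuous", alpha = 0.9, beta = 0.5),
               "leaves \\(0, 1\\)")
  expect_error(outcome_spec("y", "continuous", alpha = 0.5, beta = 0,
                            noise_sd = 0.6), "noise_sd")
  expect_error(outcome_spec("y", "ordinal", cutpoints = c(1, 0)),
               "increasing")
  expect_error(generate_cohort(n = 0, seed = 1), "positive")
})

test_that("standardisation hits mean 100 and SD 15 and preserves order", {
  set.seed(6)
  x <- rgamma(1000, 3, 1)
  z <- standardise_ability(x)
  expect_equal(mean(z), 100, tolerance = 1e-8)
  expect_equal(sqrt(mean((z - mean(z))^2)), 15, tolerance = 1e-8)
  expect_identical(order(z), order(x))
  # weighted version standardises in the weighted metric
  w <- runif(1000, 0.5, 2)
  zw <- standardise_ability(x, w)
  expect_equal(weighted.mean(zw, w), 100, tolerance = 1e-8)
  expect_equal(sqrt(sum(w * (zw - 100)^2) / sum(w)), 15, tolerance = 1e-8)
  # idempotence: input already on the target scale comes back unchanged
  expect_equal(standardise_ability(z), z, tolerance = 1e-10)
  expect_error(standardise_ability(rep(7, 10)), "constant")
})

test_that("imposing no missingness returns the table unchanged", {
  sim <- generate_cohort(n = 200, seed = 7)
  expect_identical(impose_missingness(sim$table, NULL, NULL, seed = 1),
                   sim$table)
})

test_that("degenerate attrition models are rejected", {
  sim <- generate_cohort(n = 100, seed = 8)
  expect_error(
    impose_missingness(sim$table,
                       attrition = list(intercept = Inf,
                                        coefficients = list()),
                       seed = 1),
    "finite")
  expect_error(
    impose_missingness(sim$table,
                       item = list(wellbeing = list(
                         intercept = 0,
                         coefficients = list(smoker = 1))),
                       seed = 1),
    "itself be missing")
})

test_that("realized attrition matches the model-implied mean probability", {
  sim <- generate_cohort(n = 10000, seed = 9)
  attr_model <- list(
    intercept = -1.5,
    coefficients = list(origin_class = c(
      routine = 0.8, intermediate = 0.4, lower_managerial = 0.2,
      higher_managerial = 0)))
  tab <- impose_missingness(sim$table, attrition = attr_model, seed = 10)
  lp <- attr_model$intercept +
    attr_model$coefficients$origin_class[as.character(sim$table$origin_class)]
  p_miss <- plogis(unname(lp))
  mc_se <- sqrt(sum(p_miss * (1 - p_miss))) / length(p_miss)
  expect_lt(abs(mean(!tab$responded) - mean(p_miss)), 3 * mc_se)
  # wave non-response blanks every outcome of affected records
  meta_cols <- names(attr(tab, "outcome_meta"))
  nr <- !tab$responded
  expect_true(all(is.na(tab[nr, meta_cols])))
  # baseline confounders never blanked
  expect_false(anyNA(tab[attr(tab, "confounders")]))
})

test_that("cohort tables round-trip through CSV + JSON sidecar", {
  sim <- generate_cohort(n = 300, seed = 11)
  path <- tempfile(fileext = ".csv")
  write_cohort(sim, path)
  back <- read_cohort(path)
  expect_equal(back$table, sim$table)
  expect_equal(back$truth, sim$truth)
})
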