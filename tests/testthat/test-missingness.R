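test_that("no attrition gives unit response weights", {
  sim <- generate_cohort(n = 300, seed = 51)
  rw <- response_weights(sim$table)
  expect_equal(rw$w, rep(1, 300))
  expect_true(all(rw$responded))
})

test_that("MCAR attrition gives reciprocal-rate weights", {
  sim <- generate_cohort(n = 20000, seed = 52)
  tab <- impose_missingness(
    sim$table,
    attrition = list(intercept = qlogis(0.2), coefficients = list()),
    seed = 53)
  rw <- response_weights(tab, baseline = c("sex", "origin_class"))
  resp <- rw$responded
  # responder weights estimate 1/0.8 = 1.25: each cell's fitted response
  # probability within 3 SEs of 0.8, and the average on target
  fitted_p <- 1 / rw$w[resp]
  for (cell in split(fitted_p, tab$origin_class[resp])) {
    se_cell <- sqrt(0.8 * 0.2 / length(cell))
    expect_lt(abs(cell[1] - 0.8), 3 * se_cell * 2)  # sex halves the cell
  }
  se <- sqrt(0.8 * 0.2 / length(resp))
  expect_lt(abs(mean(fitted_p) - 0.8), 3 * se)
  expect_equal(rw$w[!resp], rep(0, sum(!resp)))
})

test_that("response weights restore the baseline class distribution", {
  sim <- generate_cohort(n = 20000, seed = 54)
  attr_model <- list(
    intercept = -1.2,
    coefficients = list(origin_class = c(
      routine = 1.0, intermediate = 0.5, lower_managerial = 0.2,
      higher_managerial = 0)))
  tab <- impose_missingness(sim$table, attrition = attr_model, seed = 55)
  rw <- response_weights(tab)
  resp <- rw$responded
  target <- as.vector(prop.table(table(tab$origin_class)))
  est <- as.vector(tapply(rw$w[resp], tab$origin_class[resp], sum) /
                     sum(rw$w[resp]))
  set.seed(3)
  n <- nrow(tab)
  boot <- replicate(199, {
    i <- sample(which(resp), sum(resp), replace = TRUE)
    as.vector(tapply(rw$w[i], tab$origin_class[i], sum) / sum(rw$w[i]))
  })
  boot_se <- apply(boot, 1, sd)
  expect_true(all(abs(est - target) < 3 * boot_se))
})

test_that("a complete table imputes to m identical copies", {
  sim <- generate_cohort(n = 200, seed = 56)
  imp <- impute_missing(sim$table, m = 3, iterations = 5, seed = 57)
  expect_identical(imp$tables[[1]], sim$table)
  expect_identical(imp$tables[[2]], imp$tables[[3]])
  expect_equal(imp$iterations, 0L)
})

test_that("imputation is deterministic and only fills missing cells", {
  sim <- generate_cohort(n = 2000, seed = 58)
  tab <- impose_missingness(
    sim$table,
    item = list(wellbeing = list(
      intercept = -1.5,
      coefficients = list(origin_class = c(
        routine = 0.5, intermediate = 0, lower_managerial = -0.3,
        higher_managerial = -0.6)))),
    seed = 59)
  na_rows <- is.na(tab$wellbeing)
  expect_gt(sum(na_rows), 0)
  imp1 <- impute_missing(tab, m = 3, iterations = 3, seed = 60)
  imp2 <- impute_missing(tab, m = 3, iterations = 3, seed = 60)
  expect_identical(imp1$tables, imp2$tables)
  for (t_i in imp1$tables) {
    expect_false(anyNA(t_i$wellbeing))
    expect_identical(t_i$wellbeing[!na_rows], tab$wellbeing[!na_rows])
  }
  # the two completed tables differ somewhere among the imputed cells
  expect_false(identical(imp1$tables[[1]]$wellbeing[na_rows],
                         imp1$tables[[2]]$wellbeing[na_rows]))
  expect_error(impute_missing(tab, m = 1, iterations = 3, seed = 1),
               "at least 2")
})

test_that("MCAR 10% missingness: pooled mean within 3 SEs of complete mean", {
  spec <- outcome_spec("y", "continuous", alpha = 0.3, beta = 0.2,
                       noise_sd = 0.1)
  sim <- generate_cohort(outcomes = list(spec),
                         exposure = null_exposure_spec(),
                         n = 10000, seed = 61)
  full_mean <- mean(sim$table$y)
  tab <- impose_missingness(
    sim$table,
    item = list(y = list(intercept = qlogis(0.1), coefficients = list())),
    seed = 62)
  imp <- impute_missing(tab, m = 5, iterations = 5, seed = 63)
  pooled_mean <- mean(vapply(imp$tables, function(t_i) mean(t_i$y),
                             numeric(1)))
  se <- sd(sim$table$y) / sqrt(nrow(tab))
  expect_lt(abs(pooled_mean - full_mean), 3 * se)
})

test_that("ordinal outcomes impute through the proportional-odds model", {
  sim <- generate_cohort(n = 3000, seed = 64)
  tab <- impose_missingness(
    sim$table,
    item = list(self_rated_health = list(
      intercept = -1.5,
      coefficients = list(origin_class = c(
        routine = 0.5, intermediate = 0.2, lower_managerial = 0,
        higher_managerial = -0.3)))),
    seed = 65)
  imp <- impute_missing(tab, m = 2, iterations = 3, seed = 66)
  expect_equal(unname(imp$models["self_rated_health"]), "polr")
  for (t_i in imp$tables) {
    expect_false(anyNA(t_i$self_rated_health))
    expect_s3_class(t_i$self_rated_health, "ordered")
  }
})

test_that("Rubin pooling follows the combination rules", {
  mk <- function(est, se) {
    structure(list(variant = "relative_attainment", estimate = est,
                   se = se, conf_low = NA, conf_high = NA,
                   conf_level = 0.95, mu = 0.5, var_rank = 0.066,
                   n = 100, n_eff = 100, se_method = "robust"),
              class = "ci_estimate")
  }
  # identical estimates pool to themselves with zero between-variance
  same <- pool_estimates(list(mk(0.1, 0.02), mk(0.1, 0.02), mk(0.1, 0.02)))
  expect_equal(same$estimate, 0.1)
  expect_equal(same$between_var, 0)
  expect_equal(same$se, 0.02)
  # {0.10, 0.12, 0.14} pools to the arithmetic mean
  trio <- pool_estimates(list(mk(0.10, 0.02), mk(0.12, 0.02),
                              mk(0.14, 0.02)))
  expect_equal(trio$estimate, 0.12)
  expect_equal(trio$between_var, var(c(0.10, 0.12, 0.14)))
  # dominant between-variance widens the interval beyond the components
  pair <- pool_estimates(list(mk(0.0, 0.01), mk(0.3, 0.01)))
  comp_width <- 2 * qnorm(0.975) * 0.01
  expect_gt(pair$conf_high - pair$conf_low, comp_width)
  expect_error(pool_estimates(list(mk(0.1, 0.02))), "length")
  bad <- mk(0.1, 0.02); bad$variant <- "absolute_attainment"
  expect_error(pool_estimates(list(mk(0.1, 0.02), bad)), "mismatch")
})

test_that("pooled MI estimate beats the complete-case estimate under MAR", {
  spec <- outcome_spec("y", "continuous", alpha = 0.3, beta = 0.2,
                       noise_sd = 0.1)
  reps <- 30
  wins <- logical(reps)
  for (i in seq_len(reps)) {
    sim <- generate_cohort(outcomes = list(spec),
                           exposure = null_exposure_spec(),
                           n = 10000, seed = 700 + i)
    truth <- sim$truth$relative_attainment[
      sim$truth$system == "comprehensive"][1]
    tab <- impose_missingness(sim$table, item = class_mar_item(),
                              seed = 800 + i)
    cc <- tab[!is.na(tab$y), ]
    est_cc <- concentration_index(
      code_outcome(cc$y, bounds = c(0, 1)),
      fractional_rank(cc$origin_class),
      variant = "relative_attainment", se_method = "none")$estimate
    imp <- impute_missing(tab, m = 5, iterations = 5, seed = 900 + i)
    est_mi <- mean(vapply(imp$tables, function(t_i) {
      concentration_index(code_outcome(t_i$y, bounds = c(0, 1)),
                          fractional_rank(t_i$origin_class),
                          variant = "relative_attainment",
                          se_method = "none")$estimate
    }, numeric(1)))
    wins[i] <- abs(est_mi - truth) < abs(est_cc - truth)
  }
  expect_gte(mean(wins), 0.8)
})
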