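test_that("null exposure model yields near-zero propensity coefficients", {
  sim <- generate_cohort(exposure = null_exposure_spec(0.4),
                         n = 20000, seed = 31)
  pm <- fit_propensity(sim$table, method = "logit")
  sm <- summary(pm$fit)$coefficients
  slopes <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  expect_true(all(abs(slopes[, "Estimate"]) < 3 * slopes[, "Std. Error"]))
})

test_that("main-effects logistic recovers the generating coefficients", {
  sim <- generate_cohort(n = 50000, seed = 32)
  pm <- fit_propensity(sim$table,
                       confounders = c("ability_std", "origin_class",
                                       "state_primary"),
                       method = "logit")
  sm <- summary(pm$fit)$coefficients
  # generating values (default_exposure_spec): ability 1/30 per point,
  # class effects relative to routine (the first ordered level),
  # state_primary 'yes' = -1.2 relative to 'no'
  truth <- c("(Intercept)" = -3.9 + 1.2,
             ability_std = 1 / 30,
             origin_classintermediate = 0.4,
             origin_classlower_managerial = 0.7,
             origin_classhigher_managerial = 0.9,
             state_primaryyes = -1.2)
  for (nm in names(truth)) {
    expect_lt(abs(sm[nm, "Estimate"] - truth[[nm]]),
              3 * sm[nm, "Std. Error"])
  }
})

test_that("degenerate exposures are rejected", {
  sim <- generate_cohort(n = 100, seed = 33)
  tab <- sim$table
  tab$system <- factor(rep("selective", 100),
                       levels = c("comprehensive", "selective"))
  expect_error(fit_propensity(tab), "two observed levels")
  # perfect separation is reported with advice
  tab2 <- sim$table
  tab2$sep <- as.numeric(tab2$system == "selective")
  expect_error(fit_propensity(tab2, confounders = "sep", method = "logit"),
               "separation")
})

test_that("IPW weights are the reciprocal of the attended-arm probability", {
  d <- data.frame(system = factor(c("comprehensive", "selective"),
                                  levels = c("comprehensive", "selective")))
  ws <- make_ipw(c(0.5, 0.5), d, exposure = "system")
  expect_equal(ws$w, c(2, 2))
  ws2 <- make_ipw(c(0.2, 0.8), d, exposure = "system")
  expect_equal(ws2$w, c(1.25, 1.25))
  expect_error(make_ipw(c(0, 0.5), d, exposure = "system"), "positivity")
})

test_that("IPW arm totals and weighted arm means hit the population target", {
  sim <- generate_cohort(n = 20000, seed = 34)
  tab <- sim$table
  ws <- make_ipw(fit_propensity(tab, method = "logit"), tab)
  n <- nrow(tab)
  expect_lt(abs(ws$arm_totals[["comprehensive"]] - n) / n, 0.05)
  expect_lt(abs(ws$arm_totals[["selective"]] - n) / n, 0.05)
  # weighted selective-arm mean ability vs full-sample mean, bootstrap SE
  sel <- tab$system == "selective"
  target <- mean(tab$ability_std)
  est <- weighted.mean(tab$ability_std[sel], ws$w[sel])
  set.seed(1)
  boot <- replicate(199, {
    i <- sample.int(n, n, replace = TRUE)
    si <- sel[i]
    weighted.mean(tab$ability_std[i][si], ws$w[i][si])
  })
  expect_lt(abs(est - target), 3 * sd(boot))
})

test_that("IPW matches brute-force reweighting on a tiny enumerable table", {
  d <- tiny_cohort()
  p <- c(0.3, 0.5, 0.6, 0.4, 0.7, 0.5, 0.2, 0.8, 0.5, 0.6, 0.3, 0.4)
  ws <- make_ipw(p, d, exposure = "system")
  sel <- d$system == "selective"
  manual <- ifelse(sel, 1 / p, 1 / (1 - p))
  expect_equal(ws$w, manual)
  expect_equal(weighted.mean(d$y[sel], ws$w[sel]),
               sum(d$y[sel] / p[sel]) / sum(1 / p[sel]))
})

test_that("weight truncation caps the upper tail", {
  sim <- generate_cohort(n = 5000, seed = 35)
  pm <- fit_propensity(sim$table, method = "logit")
  raw <- make_ipw(pm, sim$table)
  trunc <- make_ipw(pm, sim$table, truncate_at = 0.99)
  expect_lte(max(trunc$w), max(raw$w))
  expect_equal(max(trunc$w), unname(quantile(raw$w, 0.99)))
})

test_that("entropy balancing solves the single-binary-constraint closed form", {
  d <- data.frame(
    g = factor(c(rep("A", 40), rep("B", 60), rep("A", 50), rep("B", 50))),
    system = factor(rep(c("comprehensive", "selective"), each = 100),
                    levels = c("comprehensive", "selective")))
  # target share of A = 0.5 in both arms
  eb <- entropy_balance(d, "g", target = c(gB = 0.5))
  comp <- d$system == "comprehensive"
  # comprehensive arm is 40% A: per-record weights 0.5/0.4 and 0.5/0.6
  # relative to uniform
  uniform <- 200 / 100
  expect_equal(eb$w[comp & d$g == "A"][1] / uniform, 1.25, tolerance = 1e-8)
  expect_equal(eb$w[comp & d$g == "B"][1] / uniform, 0.5 / 0.6,
               tolerance = 1e-8)
  # selective arm already at target: uniform weights
  expect_equal(unique(round(eb$w[!comp], 10)), uniform)
})

test_that("entropy balancing achieves exact moments; infeasible targets error", {
  sim <- generate_cohort(n = 5000, seed = 36)
  eb <- entropy_balance(sim$table)
  expect_lt(eb$moment_error, 1e-8)
  br <- balance_report(sim$table, eb)
  expect_true(all(abs(br$smd$smd_after) < 1e-6))
  # a target above the arm maximum cannot be met
  tgt <- colMeans(model.matrix(
    ~ ., data = data.frame(ability_std = sim$table$ability_std)))[-1]
  expect_error(
    entropy_balance(sim$table, "ability_std",
                    target = c(ability_std = max(sim$table$ability_std) + 1)),
    "infeasible")
})

test_that("weight selection is the argmin of the balance criterion", {
  sim <- generate_cohort(n = 10000, seed = 37)
  tab <- sim$table
  cands <- list(
    logit = make_ipw(fit_propensity(tab, method = "logit"), tab),
    spline = make_ipw(fit_propensity(tab, method = "spline"), tab),
    ridge = make_ipw(fit_propensity(tab, method = "ridge", seed = 1), tab)
  )
  sel <- select_weights(cands, tab)
  expect_equal(sel$criterion, min(sel$candidate_criteria))
  brute <- vapply(cands, function(ws) balance_criterion(tab, ws),
                  numeric(1))
  expect_equal(sel$candidate_criteria, brute)
  # singleton candidate comes straight back
  single <- select_weights(cands["logit"], tab)
  expect_equal(single$selected, "logit")
  # dominance: an exactly balanced candidate beats any unbalanced one
  eb <- entropy_balance(tab)
  sel2 <- select_weights(c(cands, list(entropy = eb)), tab)
  expect_equal(sel2$selected, "entropy")
  expect_error(select_weights(list(), tab), "empty")
})

test_that("selected weights improve on unweighted balance", {
  sim <- generate_cohort(n = 10000, seed = 38)
  tab <- sim$table
  sel <- select_weights(list(
    logit = make_ipw(fit_propensity(tab, method = "logit"), tab)), tab)
  expect_lt(sel$criterion, balance_criterion(tab, NULL))
})

test_that("SMD formula matches the hand-computed binary example", {
  # arm means 0.6/0.4 with arm variances 0.24/0.24 -> 0.2/sqrt(0.24)
  x <- c(rep(1, 60), rep(0, 40), rep(1, 40), rep(0, 60))
  d <- data.frame(
    v = x,
    system = factor(rep(c("selective", "comprehensive"), each = 100),
                    levels = c("comprehensive", "selective")))
  br <- balance_report(d, NULL, confounders = "v")
  expect_equal(br$smd$smd_before, 0.2 / sqrt(0.24), tolerance = 1e-12)
})

test_that("identical arms give zero SMDs; constant-unequal errors", {
  d <- data.frame(
    v = rep(c(0, 1), 50),
    system = factor(rep(c("comprehensive", "selective"), each = 50),
                    levels = c("comprehensive", "selective")))
  br <- balance_report(d, NULL, confounders = "v")
  expect_equal(br$smd$smd_after, 0)
  d2 <- data.frame(
    v = rep(c(0, 1), each = 50),
    system = factor(rep(c("comprehensive", "selective"), each = 50),
                    levels = c("comprehensive", "selective")))
  expect_error(balance_report(d2, NULL, confounders = "v"),
               "zero pooled variance")
})

test_that("balance report percentages sum to 100 and arms match the population", {
  sim <- generate_cohort(n = 20000, seed = 39)
  tab <- sim$table
  ws <- make_ipw(fit_propensity(tab, method = "logit"), tab)
  br <- balance_report(tab, ws)
  for (v in unique(br$table$variable)) {
    rows <- br$table[br$table$variable == v, ]
    if (all(!is.na(rows$level))) {
      for (col in c("all_unweighted", "comprehensive_weighted",
                    "selective_weighted")) {
        expect_equal(sum(rows[[col]]), 100, tolerance = 0.01)
      }
    }
  }
  # counterfactual-population property: each weighted arm tracks the full
  # sample on every confounder level within 3 bootstrap SEs
  set.seed(2)
  n <- nrow(tab)
  adv <- as.numeric(tab$origin_class == "higher_managerial")
  sel <- tab$system == "selective"
  target <- mean(adv)
  for (arm in list(sel, !sel)) {
    est <- weighted.mean(adv[arm], ws$w[arm])
    boot <- replicate(199, {
      i <- sample.int(n, n, replace = TRUE)
      ai <- arm[i]
      weighted.mean(adv[i][ai], ws$w[i][ai])
    })
    expect_lt(abs(est - target), 3 * sd(boot))
  }
})
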