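# Shared fixture builders: everything is generated in code at test time.

# Ordered class factor with given per-group counts (disadvantaged first).
make_classes <- function(counts, labels = paste0("g", seq_along(counts))) {
  factor(rep(labels, counts), levels = labels, ordered = TRUE)
}

# A tiny two-arm table with an ordered class, a system and a continuous
# outcome; used by the oracle-equivalence checks.
tiny_cohort <- function(seed = 1) {
  set.seed(seed)
  n <- 12L
  data.frame(
    origin_class = make_classes(c(5, 4, 3)),
    system = factor(rep(c("comprehensive", "selective"), 6),
                    levels = c("comprehensive", "selective")),
    y = round(runif(n), 3)
  )
}

# Random small table for property-style checks over many draws.
random_ci_case <- function(seed) {
  set.seed(seed)
  n <- sample(20:200, 1)
  k <- sample(2:6, 1)
  cls <- factor(sample(seq_len(k), n, replace = TRUE,
                       prob = as.vector(stats::rmultinom(1, 50, rep(1, k)) + 1)),
                levels = seq_len(k), ordered = TRUE)
  list(
    cls = cls,
    y = runif(n),
    w = runif(n, 0.2, 3)
  )
}

# Wellbeing-style outcome with planted per-system relative CIs 0.10 / 0.20.
planted_contrast_spec <- function(noise_sd = 0.1) {
  planted_ci_outcome("y", mean = 0.5, ci_comprehensive = 0.10,
                     ci_selective = 0.20, noise_sd = noise_sd)
}

# Item-nonresponse model used in the missing-data recovery checks:
# outcome missingness rises steeply with social disadvantage.
class_mar_item <- function() {
  list(y = list(
    intercept = 0,
    coefficients = list(origin_class = c(
      routine = 0, intermediate = -1, lower_managerial = -1.6,
      higher_managerial = -2.2))
  ))
}
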