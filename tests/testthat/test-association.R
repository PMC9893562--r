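test_that("percent change from baseline is exact and handles edge cases", {
  p <- data.frame(unit_id = rep("L1", 2), timepoint_months = c(2, 5),
                  measure = "talus_mm3", value = c(2, 1),
                  stringsAsFactors = FALSE)
  out <- percent_change_from_baseline(p)
  expect_equal(out$value, c(0, -50))

  # multiplicative decline 0.8/month from a 2-month baseline: closed form
  tp <- c(2, 3, 4, 5)
  p2 <- data.frame(unit_id = "a", timepoint_months = tp,
                   measure = "talus_mm3", value = 3 * 0.8^(tp - 2),
                   stringsAsFactors = FALSE)
  expect_equal(percent_change_from_baseline(p2)$value,
               100 * (0.8^(tp - 2) - 1))

  # unit without a baseline is dropped with a warning
  p3 <- rbind(p, data.frame(unit_id = "L2", timepoint_months = 5,
                            measure = "talus_mm3", value = 4))
  expect_warning(out3 <- percent_change_from_baseline(p3), "baseline")
  expect_false("L2" %in% out3$unit_id)

  p4 <- data.frame(unit_id = "L3", timepoint_months = c(2, 5),
                   measure = "talus_mm3", value = c(0, 1))
  expect_error(percent_change_from_baseline(p4), "baseline value of 0")
})

test_that("running metrics transform as log10(x + 1)", {
  expect_equal(log_transform_metric(c(0, 9, 999)), c(0, 1, 3))
  expect_error(log_transform_metric(-0.1), "negative")
  set.seed(51)
  x <- sort(rexp(50, 1 / 1000))
  expect_false(is.unsorted(log_transform_metric(x)))  # order-preserving
})

test_that("change-since-first is an elementwise delta within unit", {
  expect_equal(change_since_first(c(5, 7, 4)), c(0, 2, -1))
  expect_equal(change_since_first(3), 0)
  set.seed(52)
  x <- rnorm(30)
  unit <- rep(1:6, each = 5)
  time <- rep(1:5, 6)
  got <- change_since_first(x, time = time, unit = unit)
  for (u in 1:6) {
    idx <- unit == u
    expect_equal(got[idx], x[idx] - x[idx][1])   # oracle subtraction
  }
  # respects time order, not row order
  expect_equal(change_since_first(c(7, 5), time = c(2, 1)), c(2, 0))
})

test_that("factorial mixed model recovers known effect structure", {
  sim_factorial <- function(seed, geno_delta = 0, interaction = 0) {
    set.seed(seed)
    d <- expand.grid(unit = 1:40, time = factor(1:3))
    d$genotype <- ifelse(d$unit <= 20, "WT", "TG")
    d$activity <- ifelse(d$unit %% 2 == 0, "run", "sed")
    d$y <- geno_delta * (d$genotype == "TG") +
      interaction * (d$genotype == "TG") * (as.integer(d$time) - 1) +
      rep(rnorm(40, 0, 1), 3) + rnorm(nrow(d), 0, 1)
    d
  }
  pval <- function(fit, term) fit$table$p_value[fit$table$term == term]

  # pure genotype main effect, 5 SD: detected, across seeds
  for (s in 1:3) {
    fit <- factorial_mixed_effects(sim_factorial(s, geno_delta = 5),
                                   "y", c("genotype", "activity", "time"),
                                   "unit")
    expect_lt(pval(fit, "genotype"), 0.001)
    expect_equal(fit$type, "mixed")
  }

  # genotype x time interaction only
  fit_i <- factorial_mixed_effects(sim_factorial(7, interaction = 2),
                                   "y", c("genotype", "time"), "unit")
  expect_lt(pval(fit_i, "genotype:time"), 0.001)

  # identical groups: terms non-significant at roughly the nominal rate
  set.seed(60)
  rejections <- replicate(60, {
    d <- sim_factorial(sample.int(1e6, 1))
    f <- factorial_mixed_effects(d, "y", c("genotype", "activity"), "unit")
    f$table$p_value < 0.05
  })
  expect_lt(mean(rejections), 0.15)

  # single timepoint degrades to a fixed-effects ANOVA
  d1 <- sim_factorial(9)
  d1 <- d1[d1$time == 1, ]
  fit1 <- factorial_mixed_effects(d1, "y", c("genotype", "activity"), "unit")
  expect_equal(fit1$type, "fixed")
})

sim_pc <- function(seed, rho, n_units = 50, n_time = 4, sd_u = 1) {
  set.seed(seed)
  unit <- rep(seq_len(n_units), each = n_time)
  time <- rep(seq_len(n_time), n_units)
  n <- n_units * n_time
  ex <- rnorm(n)
  ey <- rho * ex + sqrt(1 - rho^2) * rnorm(n)
  x <- 2 * time + rep(rnorm(n_units, 0, sd_u), each = n_time) + ex
  y <- -1 * time + rep(rnorm(n_units, 0, sd_u), each = n_time) + ey
  data.frame(x = x, y = y, time = time, unit = unit)
}

test_that("partial correlation is exact on identities and bounded", {
  d <- sim_pc(71, 0.5)
  same <- partial_correlation_longitudinal(d$x, d$x, d$time, d$unit)
  expect_equal(same$rho, 1)
  expect_equal(same$p_value, 0)
  opp <- partial_correlation_longitudinal(d$x, -d$x, d$time, d$unit)
  expect_equal(opp$rho, -1)
  pc <- partial_correlation_longitudinal(d$x, d$y, d$time, d$unit)
  expect_lte(abs(pc$rho), 1)
  expect_equal(pc$df, nrow(d) - 2 - 3)
  expect_gte(pc$n_obs, pc$n_units)

  expect_error(partial_correlation_longitudinal(1:2, 1:2, 1:2, 1:2),
               "at least 3")
  cst <- rep(1, nrow(d))
  expect_error(partial_correlation_longitudinal(cst, d$y, d$time, d$unit),
               "zero residual variance")
})

test_that("detrending removes time- and unit-level shifts", {
  d <- sim_pc(72, -0.4)
  base <- partial_correlation_longitudinal(d$x, d$y, d$time, d$unit)$rho
  # any per-time constant added to y leaves rho unchanged
  y_t <- d$y + c(100, -50, 3, 7)[d$time]
  expect_equal(partial_correlation_longitudinal(d$x, y_t, d$time, d$unit)$rho,
               base, tolerance = 1e-8)
  # unit-specific constants are absorbed by the random intercept
  d2 <- sim_pc(73, -0.4, n_units = 60)
  b2 <- partial_correlation_longitudinal(d2$x, d2$y, d2$time, d2$unit)$rho
  y_u <- d2$y + 5 * d2$unit
  shifted <- partial_correlation_longitudinal(d2$x, y_u, d2$time, d2$unit)$rho
  expect_lt(abs(shifted - b2), 0.01)
})

test_that("partial correlation recovers truth across the rho grid", {
  for (rho in c(-0.9, -0.6, 0, 0.4, 0.7)) {
    est <- vapply(1:12, function(s) {
      d <- sim_pc(1000 * s + round(100 * rho), rho, n_units = 100)
      partial_correlation_longitudinal(d$x, d$y, d$time, d$unit)$rho
    }, 0)
    expect_lt(abs(mean(est) - rho), 0.05)
  }
})

test_that("repeated-measures correlation method agrees on sign and size", {
  d <- sim_pc(74, -0.6, n_units = 80)
  r1 <- partial_correlation_longitudinal(d$x, d$y, d$time, d$unit)
  r2 <- partial_correlation_longitudinal(d$x, d$y, d$time, d$unit,
                                         method = "rmcorr")
  expect_equal(r2$method, "rmcorr")
  expect_lt(abs(r1$rho - r2$rho), 0.1)
  expect_equal(partial_correlation_longitudinal(d$x, d$x, d$time, d$unit,
                                                method = "rmcorr")$rho, 1)
  expect_equal(r2$df, r1$n_obs - r1$n_units - 1 - 3)
})
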