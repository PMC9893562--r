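test_that("trajectory interpolates linearly with hard zero after cessation", {
  flat <- tiny_preset(distance = 8000, distance_sd = 0)
  tr <- trajectory(flat, c(60, 65, 100, 135, 140))
  expect_equal(tr$distance_median, rep(8000, 5))

  p <- tiny_preset(distance = 2660, distance_sd = 100)
  p$distance_end <- 0
  p$cessation_age_days <- 113
  # preset anchors interpolate at 65/135; cessation forces zero from 113 on
  tr2 <- trajectory(p, c(65, 100, 113, 120, 135))
  expect_equal(tr2$distance_median[1], 2660)
  expect_equal(tr2$distance_median[2], 2660 * (1 - 35 / 70))
  expect_equal(tr2$distance_median[3:5], c(0, 0, 0))

  # midpoint is the arithmetic mean of the endpoint values
  q <- tiny_preset()
  q$distance_start <- 1000; q$distance_end <- 500
  expect_equal(trajectory(q, 100)$distance_median, 750)

  expect_error(trajectory(q, 59), "60")
  expect_error(trajectory(q, 141), "140")
})

test_that("simulated nights honor stream and bout invariants", {
  pr <- tiny_preset(distance = 80, rate = 0.8, n_runs = 6)
  par <- trajectory(pr, 65)
  set.seed(81)
  for (i in 1:30) {
    ts <- simulate_night(par)
    s <- event_stream("a", "2024-03-01", as.numeric(ts))  # validates
    if (!length(ts)) next
    expect_lt(max(ts), 43200)                 # night-locked
    expect_gte(min(ts), 0)
    b <- segment_bouts(as.numeric(ts))
    # re-analysis recovers the generated truth exactly
    expect_equal(nrow(b), attr(ts, "n_bouts"))
    expect_equal(sum(b$revolutions), attr(ts, "revolutions"))
    expect_equal(length(ts), attr(ts, "revolutions"))
  }
  # zero-distance parameters give an empty day
  z <- trajectory(tiny_preset(distance = 0, distance_sd = 0), 65)
  expect_length(simulate_night(z), 0L)
})

test_that("a preset whose median demand exceeds the night errors by name", {
  pr <- tiny_preset(distance = 20000, distance_sd = 0, rate = 0.3, n_runs = 5)
  expect_error(simulate_night(trajectory(pr, 65), label = "overfull"),
               "infeasible packing for overfull")
})

test_that("daily distance draws honor the configured median", {
  set.seed(82)
  # truncated-normal regime
  d1 <- replicate(400, {
    ts <- simulate_night(trajectory(tiny_preset(distance = 100,
                                                distance_sd = 30), 65))
    length(ts) * pi * 0.115
  })
  expect_lt(abs(median(d1) - 100) / 100, 0.05)
  # heavy-censoring regime (SD > median) switches to zero-inflated draws
  # whose marginal median still equals the configured median
  set.seed(83)
  d2 <- draw_daily_distance(4000, median = 50, sd = 120)
  expect_gt(mean(d2 == 0), 0.3)
  expect_lt(abs(median(d2) - 50) / 50, 0.10)
})

test_that("cohorts are reproducible and respect mortality censoring", {
  pr <- tiny_preset(n_animals = 2L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  make_cohort(pr, seed = 5, out_dir = d1, ages = 60:62)
  make_cohort(pr, seed = 5, out_dir = d2, ages = 60:62)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # layout round-trips through the readers
  m <- read_manifest(file.path(d1, "manifest.csv"))
  expect_equal(nrow(m), 2L)
  streams <- read_cohort_days(m, d1)
  expect_length(streams, 6L)

  # a different seed changes the data
  d3 <- withr::local_tempdir()
  make_cohort(pr, seed = 6, out_dir = d3, ages = 60:62)
  same <- mapply(function(f) identical(readLines(file.path(d1, f)),
                                       readLines(file.path(d3, f))),
                 setdiff(f1, c("manifest.csv", "gaps.csv")))
  expect_false(all(same))

  # duplicate strata are rejected
  expect_error(make_cohort(rbind(pr, pr), seed = 1,
                           out_dir = withr::local_tempdir()),
               "duplicate preset strata")

  # streams end at death
  prm <- tiny_preset(n_animals = 3L, mortality = c(62L))
  sim <- simulate_stratum(prm, seed = 9, ages = 60:65)
  ages_by <- tapply(vapply(sim$streams, function(s) s$age_days, 0L),
                    vapply(sim$streams, function(s) s$animal_id, ""), max)
  expect_equal(unname(ages_by[["WTM03"]]), 61L)   # death at 62 censors onward
  expect_equal(unname(ages_by[["WTM01"]]), 65L)
})

test_that("the default presets encode the study's running arm", {
  gp <- group_presets()
  expect_equal(sum(gp$n_animals), 44L)
  expect_equal(gp$n_animals, c(9L, 9L, 12L, 14L))
  expect_setequal(paste(gp$genotype, gp$sex),
                  c("WT M", "WT F", "TNF-Tg M", "TNF-Tg F"))
  # transgenic strata decline; cessation only where it precedes endpoint
  expect_true(all(gp$distance_end <= gp$distance_start))
  tnf_f <- preset_for("TNF-Tg", "F", gp)
  expect_equal(tnf_f$distance_end, 0)          # ceases within the window
  expect_equal(tnf_f$cessation_age_days, 113)
  expect_equal(preset_for("TNF-Tg", "M", gp)$cessation_age_days, 140)
})

test_that("pipeline recovers configured group medians from tiny cohorts", {
  pr <- tiny_preset(distance = 60, distance_sd = 10, rate = 0.8, n_runs = 6,
                    n_animals = 4L)
  est <- vapply(1:6, function(s) {
    sim <- simulate_stratum(pr, seed = s, ages = 60:69)
    daily <- daily_metrics_table(sim$streams)
    bins <- bin_cohort(daily, sim$manifest, metrics = "distance")
    mean(bins$value[bins$bin_center == 65])
  }, 0)
  expect_lt(abs(mean(est) - 60) / 60, 0.10)
})

test_that("configured cessation age is recovered by detection", {
  pr <- tiny_preset(distance = 700, distance_sd = 150, n_animals = 8L)
  pr$distance_end <- 0
  pr$cessation_age_days <- 110
  hits <- vapply(1:15, function(s) {
    sim <- simulate_stratum_daily(pr, seed = s, ages = 60:140)
    bins <- bin_cohort(sim$daily, sim$manifest, metrics = "distance")
    detect_cessation(bins)$cessation_bin_center
  }, 0)
  expect_true(all(hits == 115))   # first bin wholly past 110 d
})

test_that("biomarker links reproduce degenerate and null couplings", {
  links <- link_presets()
  expect_true(all(abs(links$rho) <= 1))
  expect_equal(nrow(links), 16L)
  expect_setequal(unique(links$unit_kind), c("animal", "limb"))

  # null link: estimated rho near zero
  l0 <- link_for("talus_mm3", "distance", "TNF-Tg", "F")
  l0$rho <- 0
  d0 <- simulate_biomarkers(l0, seed = 91)
  pc0 <- partial_correlation_longitudinal(
    d0$running_change, d0$biomarker_value, d0$timepoint_months, d0$unit_id)
  expect_lt(abs(pc0$rho), 0.1)

  # perfect link with no free residual noise: rho recovered at 1
  l1 <- link_for("talus_mm3", "distance", "TNF-Tg", "F")
  l1$rho <- 1
  l1$y_sd_unit <- 0
  d1 <- simulate_biomarkers(l1, seed = 92)
  pc1 <- partial_correlation_longitudinal(
    d1$running_change, d1$biomarker_value, d1$timepoint_months, d1$unit_id)
  expect_gt(pc1$rho, 0.99)

  l2 <- l1; l2$rho <- 1.5
  expect_error(simulate_biomarkers(l2, seed = 1), "<= 1")
})
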