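#' Per-day generator parameters along a preset trajectory
#'
#' Linearly interpolates each behavioral parameter between its age-65 and
#' age-135 preset values (extrapolating on the same line within the 60-140 d
#' simulation range, floored at zero), and applies a hard zero to distance
#' after the preset's cessation age.
#'
#' @param preset One row of [group_presets()].
#' @param age_days Age(s) in days, each within `[60, 140]`.
#' @return Data frame with one row per age: `age_days`, `distance_median`,
#'   `distance_sd`, `rate`, `n_runs`, `run_length`.
#' @export
trajectory <- function(preset, age_days) {
  if (any(age_days < 60 | age_days > 140)) {
    stop("age_days must lie in [60, 140]", call. = FALSE)
  }
  lerp <- function(v65, v135) {
    pmax(0, v65 + (v135 - v65) * (age_days - 65) / 70)
  }
  out <- data.frame(
    age_days = age_days,
    distance_median = lerp(preset$distance_start, preset$distance_end),
    distance_sd = lerp(preset$distance_start_sd, preset$distance_end_sd),
    rate = lerp(preset$rate_start, preset$rate_end),
    n_runs = lerp(preset$n_runs_start, preset$n_runs_end),
    run_length = lerp(preset$run_length_start, preset$run_length_end)
  )
  ces <- preset$cessation_age_days
  if (!is.na(ces)) {
    gone <- age_days >= ces
    out$distance_median[gone] <- 0
    out$distance_sd[gone] <- 0
  }
  out
}

# Draw a daily distance target. Truncated normal (truncation-free median =
# `median`) in the usual regime; when the configured SD exceeds the median
# (terminal disease: mostly-zero days with rare bursts) a zero-inflated
# exponential calibrated to the same marginal median is used instead.
draw_daily_distance <- function(n, median, sd) {
  if (median <= 0) return(rep(0, n))
  if (sd <= 0) return(rep(median, n))
  if (sd > median) {
    p0 <- 0.4
    # marginal median m: p0 + (1 - p0) * F_exp(m) = 0.5
    lambda <- -log(1 - (0.5 - p0) / (1 - p0)) / median
    zero <- stats::runif(n) < p0
    ifelse(zero, 0, stats::rexp(n, rate = lambda))
  } else {
    lo <- stats::pnorm(0, mean = median, sd = sd)
    stats::qnorm(stats::runif(n, lo, 1), mean = median, sd = sd)
  }
}

#' Simulate one night of switch closures
#'
#' Generates a single animal-day timestamp stream with the bout structure
#' the micro-analysis assumes: a daily distance target drawn around the
#' configured median, converted to revolutions by the wheel geometry;
#' a Poisson number of bouts; revolutions spread over bouts by a symmetric
#' multinomial (at least one per bout; the bout count is reduced when fewer
#' revolutions than bouts are available — distance wins on conflict);
#' within-bout inter-closure intervals of `1/rate` with uniform +/-20%
#' jitter (capped at 7 s so jittered intervals stay under the 9-s bout
#' criterion); and bout start times placed in the 00:00-12:00 dark window
#' with all inter-bout gaps forced above 9 s. All closures fall in the dark
#' window.
#'
#' @param params One row of [trajectory()] output (fields `distance_median`,
#'   `distance_sd`, `rate`, `n_runs`).
#' @param geometry A [wheel_geometry()].
#' @param label Preset label used in error messages.
#' @return Numeric vector of closure times (seconds since midnight, 10-ms
#'   resolution), possibly empty, with attributes `n_bouts` and
#'   `revolutions` recording the generated truth for round-trip checks.
#' @export
simulate_night <- function(params, geometry = wheel_geometry(),
                           label = "preset") {
  dark_s <- 43200
  dist <- draw_daily_distance(1L, params$distance_median, params$distance_sd)
  rev <- round(dist / geometry$circumference_m)
  if (rev < 1) return(numeric())
  n <- stats::rpois(1L, max(params$n_runs, 1e-9))
  n <- max(1L, min(n, rev))
  isi_base <- min(1 / max(params$rate, 1e-9), 7)
  # physical capacity of the dark window: running time plus inter-bout gaps
  # cannot exceed 12 h. Upper-tail distance draws are truncated at capacity
  # (a wheel cannot be run longer than the night); a preset whose *median*
  # demand already exceeds capacity is a configuration error.
  budget <- 43200 - 9.6 * (n - 1L)
  cap <- n + floor(0.98 * budget / isi_base)
  median_rev <- params$distance_median / geometry$circumference_m
  if (budget <= 0 || median_rev > cap) {
    stop(sprintf(
      "infeasible packing for %s: median %.0f revolutions at %.2f rev/s do not fit the dark window",
      label, median_rev, params$rate), call. = FALSE)
  }
  rev <- min(rev, cap)
  extra <- if (rev > n) {
    as.integer(stats::rmultinom(1L, rev - n, rep(1 / n, n)))
  } else integer(n)
  rev_per_bout <- 1L + extra
  isi <- lapply(rev_per_bout, function(r) {
    if (r <= 1L) numeric() else isi_base * stats::runif(r - 1L, 0.8, 1.2)
  })
  durations <- vapply(isi, sum, 0)
  total_run <- sum(durations)
  min_gap <- 9.02
  pref_gap <- 9.5
  slack <- dark_s - total_run
  gap_floor <- if (slack >= pref_gap * (n - 1L)) pref_gap else min_gap
  free <- slack - gap_floor * (n - 1L)
  # jitter can overshoot the conservative capacity cap by a sliver; shed
  # single revolutions from the longest bouts until the night fits
  while (free < 0) {
    i <- which.max(rev_per_bout)
    if (rev_per_bout[i] <= 1L) {
      stop(sprintf(
        "infeasible packing for %s: %.0f revolutions at %.2f rev/s do not fit the dark window",
        label, rev, params$rate), call. = FALSE)
    }
    free <- free + isi[[i]][length(isi[[i]])]
    isi[[i]] <- isi[[i]][-length(isi[[i]])]
    rev_per_bout[i] <- rev_per_bout[i] - 1L
    durations[i] <- sum(isi[[i]])
  }
  w <- stats::rexp(n + 1L)
  shares <- free * w / sum(w)
  gaps <- if (n > 1L) gap_floor + shares[2:n] else numeric()
  start <- numeric(n)
  start[1L] <- shares[1L]
  if (n > 1L) {
    for (i in 2:n) start[i] <- start[i - 1L] + durations[i - 1L] + gaps[i - 1L]
  }
  ts <- unlist(lapply(seq_len(n), function(i) {
    start[i] + c(0, cumsum(isi[[i]]))
  }), use.names = FALSE)
  structure(round(ts, 2), n_bouts = n,
            revolutions = as.integer(sum(rev_per_bout)))
}

child_seed <- function(root_seed, index) {
  # deterministic per-animal split of the root seed, kept inside 32-bit range
  as.integer((as.numeric(root_seed) * 1000003 + index * 7919) %% 2147483647)
}

#' Simulate event streams for one preset stratum
#'
#' Draws one animal's days from `ages[1]` to the earlier of the last
#' requested age and the animal's death age, using a per-animal child seed
#' derived from the root seed (`(seed * 1000003 + index * 7919) mod 2^31-1`)
#' so cohorts are reproducible animal-by-animal.
#'
#' @param preset One row of [group_presets()].
#' @param seed Root integer seed.
#' @param ages Integer ages (days) to simulate. Default `60:140`.
#' @param n_animals Number of animals; default the preset's `n_animals`.
#' @param date_of_birth Shared date of birth for the simulated animals.
#' @param geometry A [wheel_geometry()].
#' @param id_prefix Prefix for generated animal ids.
#' @return List with `manifest` (a `wheel_manifest`) and `streams`
#'   (list of [event_stream()]).
#' @export
simulate_stratum <- function(preset, seed, ages = 60:140,
                             n_animals = preset$n_animals,
                             date_of_birth = as.Date("2024-01-01"),
                             geometry = wheel_geometry(),
                             id_prefix = NULL) {
  if (is.null(id_prefix)) {
    id_prefix <- paste0(ifelse(preset$genotype == "WT", "WT", "TG"),
                        preset$sex)
  }
  deaths <- preset$mortality[[1L]]
  label <- paste(preset$genotype, preset$sex)
  ids <- sprintf("%s%02d", id_prefix, seq_len(n_animals))
  death_age <- rep(NA_integer_, n_animals)
  if (length(deaths)) {
    k <- min(length(deaths), n_animals)
    death_age[(n_animals - k + 1L):n_animals] <- sort(deaths)[seq_len(k)]
  }
  manifest <- data.frame(
    animal_id = ids, date_of_birth = date_of_birth,
    genotype = factor(preset$genotype, genotype_levels()),
    sex = factor(preset$sex, sex_levels()),
    group = factor("running", group_levels()),
    death_age_days = death_age, stringsAsFactors = FALSE
  )
  class(manifest) <- c("wheel_manifest", "data.frame")
  streams <- list()
  for (a in seq_len(n_animals)) {
    set.seed(child_seed(seed, a))
    last <- if (is.na(death_age[a])) max(ages) else
      min(max(ages), death_age[a] - 1L)
    for (age in ages[ages <= last]) {
      par <- trajectory(preset, age)
      ts <- simulate_night(par, geometry = geometry, label = label)
      streams[[length(streams) + 1L]] <- event_stream(
        ids[a], date_of_birth + age, ts, age_days = age)
    }
  }
  list(manifest = manifest, streams = streams)
}

#' Simulate and write a full cohort to disk
#'
#' Generates all preset strata with [simulate_stratum()] and writes the
#' on-disk layout the readers expect: `manifest.csv`, one
#' `<animal_id>/<ISO-date>.rev` log per observed animal-day, and an empty
#' `gaps.csv`. Output is byte-identical for a given seed.
#'
#' @param presets Preset table, default [group_presets()] (44 running
#'   animals across the four strata).
#' @param seed Root integer seed.
#' @param out_dir Output directory (created if needed).
#' @param ages Ages (days) to simulate per animal.
#' @param geometry A [wheel_geometry()].
#' @return `out_dir`, invisibly.
#' @export
make_cohort <- function(presets = group_presets(), seed, out_dir,
                        ages = 60:140, geometry = wheel_geometry()) {
  strata_key <- paste(presets$genotype, presets$sex)
  if (anyDuplicated(strata_key)) {
    stop("duplicate preset strata: ",
         strata_key[duplicated(strata_key)][1L], call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifests <- list()
  for (i in seq_len(nrow(presets))) {
    sim <- simulate_stratum(presets[i, , drop = FALSE],
                            seed = child_seed(seed, 10000L + i),
                            ages = ages, geometry = geometry)
    manifests[[i]] <- sim$manifest
    for (s in sim$streams) {
      adir <- file.path(out_dir, s$animal_id)
      dir.create(adir, showWarnings = FALSE)
      write_event_day(s, file.path(adir, paste0(format(s$day_date), ".rev")))
    }
  }
  manifest <- do.call(rbind, manifests)
  class(manifest) <- c("wheel_manifest", "data.frame")
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  writeLines("animal_id,date,reason", file.path(out_dir, "gaps.csv"))
  invisible(out_dir)
}

#' Simulate daily distance values without event streams
#'
#' Lightweight generator path for statistical tests that operate downstream
#' of the micro-analysis: draws the daily distance targets directly (the
#' same distributions [simulate_night()] packs into timestamps) and returns
#' a daily-metrics-shaped table with the distance column populated.
#'
#' @inheritParams simulate_stratum
#' @return List with `manifest` and `daily` (columns `animal_id`,
#'   `age_days`, `total_distance_m`).
#' @export
simulate_stratum_daily <- function(preset, seed, ages = 60:140,
                                   n_animals = preset$n_animals,
                                   date_of_birth = as.Date("2024-01-01"),
                                   id_prefix = NULL) {
  if (is.null(id_prefix)) {
    id_prefix <- paste0(ifelse(preset$genotype == "WT", "WT", "TG"),
                        preset$sex)
  }
  ids <- sprintf("%s%02d", id_prefix, seq_len(n_animals))
  deaths <- preset$mortality[[1L]]
  death_age <- rep(NA_integer_, n_animals)
  if (length(deaths)) {
    k <- min(length(deaths), n_animals)
    death_age[(n_animals - k + 1L):n_animals] <- sort(deaths)[seq_len(k)]
  }
  manifest <- data.frame(
    animal_id = ids, date_of_birth = date_of_birth,
    genotype = factor(preset$genotype, genotype_levels()),
    sex = factor(preset$sex, sex_levels()),
    group = factor("running", group_levels()),
    death_age_days = death_age, stringsAsFactors = FALSE
  )
  class(manifest) <- c("wheel_manifest", "data.frame")
  rows <- list()
  for (a in seq_len(n_animals)) {
    set.seed(child_seed(seed, a))
    last <- if (is.na(death_age[a])) max(ages) else
      min(max(ages), death_age[a] - 1L)
    use <- ages[ages <= last]
    if (!length(use)) next
    par <- trajectory(preset, use)
    dist <- vapply(seq_along(use), function(i) {
      draw_daily_distance(1L, par$distance_median[i], par$distance_sd[i])
    }, 0)
    rows[[a]] <- data.frame(animal_id = ids[a], age_days = use,
                            total_distance_m = dist,
                            stringsAsFactors = FALSE)
  }
  list(manifest = manifest,
       daily = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Simulate a linked running/biomarker longitudinal panel
#'
#' Generates, for one [link_presets()] row, a running-metric series and a
#' biomarker series over `n_units` units and the preset's timepoints, such
#' that the biomarker's residual (about its time trend and unit intercept)
#' is constructed jointly with the running metric's analysis-scale residual
#' (log-transformed, change-since-first, mixed-model detrended) to have the
#' configured partial correlation: the biomarker is
#' `trend(t) + b_u + sd_resid * (rho * r_x_std + sqrt(1 - rho^2) * z)`.
#'
#' @param link One row of [link_presets()].
#' @param seed Integer seed.
#' @param n_units Number of experimental units (animals or limbs); default
#'   the preset's `n_units`.
#' @return Data frame with one row per unit-timepoint: `unit_id`,
#'   `timepoint_months`, `running_value` (raw metric scale),
#'   `running_change` (analysis scale) and `biomarker_value`, plus the
#'   stratum descriptors.
#' @export
simulate_biomarkers <- function(link, seed, n_units = link$n_units) {
  rho <- link$rho
  if (abs(rho) > 1) stop("|target rho| must be <= 1", call. = FALSE)
  set.seed(seed)
  tp <- link$timepoints[[1L]]
  x_trend <- link$x_trend[[1L]]
  y_trend <- link$y_trend[[1L]]
  stopifnot(length(x_trend) == length(tp), length(y_trend) == length(tp))
  n_t <- length(tp)
  unit_id <- rep(sprintf("U%03d", seq_len(n_units)), each = n_t)
  time <- rep(tp, times = n_units)
  # raw running metric: lognormal noise around the stratum trajectory
  x_raw <- rep(x_trend, times = n_units) *
    exp(stats::rnorm(n_units * n_t, 0, link$x_sd_log))
  x_change <- running_change_scale(x_raw, time = time, unit = unit_id)
  r_x <- mixed_time_detrend(x_change, time, unit_id)
  sd_rx <- stats::sd(r_x)
  r_x_std <- if (sd_rx > 0) (r_x - mean(r_x)) / sd_rx else r_x
  b_u <- rep(stats::rnorm(n_units, 0, link$y_sd_unit), each = n_t)
  z <- stats::rnorm(n_units * n_t)
  y <- rep(y_trend, times = n_units) + b_u +
    link$y_sd_resid * (rho * r_x_std + sqrt(1 - rho^2) * z)
  data.frame(
    unit_id = unit_id,
    genotype = link$genotype, sex = link$sex,
    activity_group = "running",
    timepoint_months = time,
    metric = link$metric, measure = link$measure,
    running_value = x_raw, running_change = x_change,
    biomarker_value = y,
    stringsAsFactors = FALSE
  )
}
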