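#' Metric names used by the longitudinal layer
#'
#' Maps the short behavioral metric names to the columns of the daily-metrics
#' table. `distance` is followed to 135 days of age; the derived metrics
#' (`rate`, `run_length`, `n_runs`, `distance_per_run`) stop at 125 days,
#' after which running is absent in the most affected animals.
#'
#' @return Named character vector: metric name -> daily-metrics column.
#' @export
metric_columns <- function() {
  c(distance = "total_distance_m",
    rate = "rate_rev_per_s",
    run_length = "run_length_rev",
    n_runs = "n_runs",
    distance_per_run = "distance_per_run_m")
}

last_bin_center <- function(metric) {
  if (metric == "distance") 135 else 125
}

#' Bin one animal's daily metrics into 10-day medians
#'
#' Daily values are collapsed to per-animal medians over 10-day age windows
#' synchronized to the date of birth: half-open windows `[60,70), [70,80),
#' ...` labeled by their centers 65, 75, ... Days before age 60 are excluded
#' (variable initiation of running), bins beyond the metric's last center are
#' dropped, and bins centered after the animal's death age are censored.
#' Observed zero-activity days participate in the medians; wheel-unavailable
#' days are simply absent from `daily`.
#'
#' @param daily Daily-metrics rows for a single animal (see
#'   [daily_metrics_table()]); must carry `age_days`.
#' @param metrics Character vector of metric names (see [metric_columns()]).
#' @param death_age_days Optional censoring age in days.
#'
#' @return Long data frame: `animal_id`, `metric`, `bin_center`, `value`
#'   (the 10-day median), `n_days` (observed days in the window). A bin is
#'   present only if at least one day was observed in it.
#' @export
bin_10day <- function(daily, metrics = names(metric_columns()),
                      death_age_days = NA_integer_) {
  metrics <- match.arg(metrics, names(metric_columns()), several.ok = TRUE)
  if (nrow(daily) == 0L) {
    return(data.frame(animal_id = character(), metric = character(),
                      bin_center = numeric(), value = numeric(),
                      n_days = integer(), stringsAsFactors = FALSE))
  }
  if (length(unique(daily$animal_id)) != 1L) {
    stop("`daily` must contain a single animal; see bin_cohort()",
         call. = FALSE)
  }
  if (any(is.na(daily$age_days))) {
    stop("age_days is required for binning", call. = FALSE)
  }
  centers_all <- floor(daily$age_days / 10) * 10 + 5
  out <- list()
  for (metric in metrics) {
    col <- metric_columns()[[metric]]
    keep <- centers_all >= 65 & centers_all <= last_bin_center(metric)
    if (!is.na(death_age_days)) keep <- keep & centers_all <= death_age_days
    if (!any(keep)) next
    vals <- tapply(daily[[col]][keep], centers_all[keep], stats::median)
    n_days <- tapply(daily[[col]][keep], centers_all[keep], length)
    out[[metric]] <- data.frame(
      animal_id = daily$animal_id[1L],
      metric = metric,
      bin_center = as.numeric(names(vals)),
      value = as.numeric(vals),
      n_days = as.integer(n_days),
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(animal_id = character(), metric = character(),
                      bin_center = numeric(), value = numeric(),
                      n_days = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, c(unname(out), list(make.row.names = FALSE)))
  res[order(res$metric, res$bin_center), , drop = FALSE]
}

#' Bin a whole cohort's daily metrics
#'
#' Applies [bin_10day()] per animal, attaching genotype/sex/group and the
#' censoring age from the manifest.
#'
#' @param daily Daily-metrics table for many animals.
#' @param manifest A [read_manifest()] result.
#' @param metrics Metric names to bin.
#' @return Long data frame with `animal_id`, `genotype`, `sex`, `group`,
#'   `metric`, `bin_center`, `value`, `n_days`.
#' @export
bin_cohort <- function(daily, manifest, metrics = names(metric_columns())) {
  pieces <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- as.character(manifest$animal_id[i])
    sub <- daily[daily$animal_id == id, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    b <- bin_10day(sub, metrics = metrics,
                   death_age_days = manifest$death_age_days[i])
    if (nrow(b) == 0L) return(NULL)
    b$genotype <- as.character(manifest$genotype[i])
    b$sex <- as.character(manifest$sex[i])
    b$group <- as.character(manifest$group[i])
    b
  })
  pieces <- Filter(Negate(is.null), pieces)
  if (!length(pieces)) {
    return(data.frame(animal_id = character(), metric = character(),
                      bin_center = numeric(), value = numeric(),
                      n_days = integer(), genotype = character(),
                      sex = character(), group = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(pieces, list(make.row.names = FALSE)))
}

#' Group-level summary of binned series
#'
#' Per (genotype, sex, metric, bin): mean and sample SD (n - 1) across the
#' per-animal 10-day medians, plus the number of contributing animals. SD is
#' `NA` when a single animal contributes.
#'
#' @param bins Output of [bin_cohort()] (or [bin_10day()] rows augmented with
#'   `genotype`/`sex`).
#' @return Data frame: `genotype`, `sex`, `metric`, `bin_center`, `mean`,
#'   `sd`, `n`.
#' @export
group_summary <- function(bins) {
  if (nrow(bins) == 0L) {
    return(data.frame(genotype = character(), sex = character(),
                      metric = character(), bin_center = numeric(),
                      mean = numeric(), sd = numeric(), n = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- interaction(bins$genotype, bins$sex, bins$metric, bins$bin_center,
                     drop = TRUE, sep = "\r")
  agg <- lapply(split(bins, key), function(d) {
    data.frame(genotype = d$genotype[1L], sex = d$sex[1L],
               metric = d$metric[1L], bin_center = d$bin_center[1L],
               mean = mean(d$value),
               sd = if (nrow(d) > 1L) stats::sd(d$value) else NA_real_,
               n = nrow(d), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(unname(agg), list(make.row.names = FALSE)))
  res[order(res$genotype, res$sex, res$metric, res$bin_center), ,
      drop = FALSE]
}

#' Detect cessation of running for one group
#'
#' At each 10-day bin in ascending age the per-animal bin medians of total
#' daily distance are tested against zero with a two-sided one-sample t-test;
#' cessation is the first bin whose test is not significant at `alpha`. Bins
#' in which every animal's median is exactly zero are declared non-significant
#' without a test (the degenerate SD = 0 case), and bins with identical
#' positive values are declared significant. Bins with fewer than two animals
#' cannot be tested and are skipped (reported with `tested = FALSE`). All
#' bins, including those after cessation, are reported for audit.
#'
#' @param bins Binned rows for one group with `metric == "distance"`
#'   (columns `animal_id`, `bin_center`, `value`).
#' @param alpha Significance level. Default 0.05.
#' @return A list of class `cessation_result`: `cessation_bin_center` (`NA`
#'   if the group never ceases), and `table` with per-bin `n`, `mean`,
#'   `statistic`, `p_value`, `tested`, `significant`.
#' @export
detect_cessation <- function(bins, alpha = 0.05) {
  bins <- bins[bins$metric == "distance", , drop = FALSE]
  if (nrow(bins) == 0L) stop("no distance bins supplied", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  centers <- sort(unique(bins$bin_center))
  rows <- lapply(centers, function(ctr) {
    v <- bins$value[bins$bin_center == ctr]
    n <- length(v)
    if (n < 2L) {
      return(data.frame(bin_center = ctr, n = n, mean = mean(v),
                        statistic = NA_real_, p_value = NA_real_,
                        tested = FALSE, significant = NA))
    }
    if (all(v == 0)) {
      data.frame(bin_center = ctr, n = n, mean = 0, statistic = NA_real_,
                 p_value = 1, tested = TRUE, significant = FALSE)
    } else if (stats::sd(v) == 0) {
      data.frame(bin_center = ctr, n = n, mean = mean(v),
                 statistic = Inf, p_value = 0, tested = TRUE,
                 significant = TRUE)
    } else {
      tt <- stats::t.test(v, mu = 0)
      data.frame(bin_center = ctr, n = n, mean = mean(v),
                 statistic = unname(tt$statistic), p_value = tt$p.value,
                 tested = TRUE, significant = tt$p.value < alpha)
    }
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!any(tab$tested)) {
    warning("fewer than 2 animals in every bin; cessation cannot be assessed")
    res <- list(cessation_bin_center = NA_real_, alpha = alpha, table = tab)
    class(res) <- "cessation_result"
    return(res)
  }
  nonsig <- tab$tested & !tab$significant
  ces <- if (any(nonsig)) tab$bin_center[which(nonsig)[1L]] else NA_real_
  res <- list(cessation_bin_center = ces, alpha = alpha, table = tab)
  class(res) <- "cessation_result"
  res
}

#' @export
print.cessation_result <- function(x, ...) {
  cat("<cessation_result> alpha =", x$alpha, "\n")
  if (is.na(x$cessation_bin_center)) {
    cat("no cessation detected within the observed bins\n")
  } else {
    cat("cessation at bin center", x$cessation_bin_center, "days\n")
  }
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Day-resolution cessation estimate by linear interpolation
#'
#' The binned test localizes cessation only to a 10-day window. As a
#' complementary day-resolution estimate, the group mean distance trajectory
#' is linearly interpolated to its zero crossing: the first pair of adjacent
#' bins whose means bracket zero (positive then non-positive) yields the
#' crossing day.
#'
#' @param summary [group_summary()] rows for one group's distance metric.
#' @return Estimated crossing age in days, or `NA` if the trajectory never
#'   reaches zero.
#' @export
interpolate_cessation_day <- function(summary) {
  s <- summary[summary$metric == "distance", , drop = FALSE]
  s <- s[order(s$bin_center), , drop = FALSE]
  if (nrow(s) < 2L) return(NA_real_)
  for (i in seq_len(nrow(s) - 1L)) {
    m1 <- s$mean[i]; m2 <- s$mean[i + 1L]
    if (m1 > 0 && m2 <= 0) {
      c1 <- s$bin_center[i]; c2 <- s$bin_center[i + 1L]
      return(c1 + (c2 - c1) * m1 / (m1 - m2))
    }
  }
  NA_real_
}
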