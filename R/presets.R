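#' Default group presets for the cage simulator
#'
#' One row per genotype-by-sex stratum of the running arm, parameterized by
#' the published start (age 65 d) and end (age 135 d) group values of the
#' four behavioral metrics: daily distance (10-day median of m/day, with
#' between/within-day SD), pooled running rate (rev/s), run length
#' (rev/bout) and number of runs (bouts/day). Transgenic strata carry a
#' running-cessation age; the TNF-Tg female preset declines to zero at its
#' cessation age (113 d), the TNF-Tg male cessation (140 d) lies beyond the
#' observation window. `mortality` lists per-animal death ages (days) for
#' animals lost before scheduled endpoint, emulating the study's censoring
#' pattern.
#'
#' @return Data frame of class `group_presets`, one row per stratum, with a
#'   `mortality` list column.
#' @export
group_presets <- function() {
  p <- data.frame(
    genotype = c("WT", "WT", "TNF-Tg", "TNF-Tg"),
    sex = c("M", "F", "M", "F"),
    n_animals = c(9L, 9L, 12L, 14L),
    distance_start = c(4604.7, 8703.3, 2380.4, 2660.1),
    distance_start_sd = c(2428.9, 1541.4, 1687.7, 2284.7),
    distance_end = c(3007.4, 7472.8, 17.1, 0),
    distance_end_sd = c(2216.6, 1559.2, 35.4, 31.1),
    rate_start = c(0.6, 0.9, 0.5, 0.5),
    rate_end = c(0.9, 0.9, 0.3, 0.1),
    run_length_start = c(120.8, 158.5, 79.2, 88.1),
    run_length_end = c(124.0, 117.6, 28.0, 5.4),
    n_runs_start = c(96.8, 83.2, 67.2, 52.0),
    n_runs_end = c(87.9, 81.5, 38.5, 11.4),
    cessation_age_days = c(NA, NA, 140, 113),
    stringsAsFactors = FALSE
  )
  p$mortality <- list(integer(), 100L, integer(),
                      c(118L, 124L, 129L, 133L, 136L))
  class(p) <- c("group_presets", "data.frame")
  p
}

#' Look up one preset stratum
#'
#' @param genotype `"WT"` or `"TNF-Tg"`.
#' @param sex `"M"` or `"F"`.
#' @param presets Preset table, default [group_presets()].
#' @return A single preset row.
#' @export
preset_for <- function(genotype, sex, presets = group_presets()) {
  row <- presets[presets$genotype == genotype & presets$sex == sex, ,
                 drop = FALSE]
  if (nrow(row) != 1L) {
    stop("no unique preset for ", genotype, " ", sex, call. = FALSE)
  }
  row
}

#' Biomarker-link presets
#'
#' Configuration of the simulated coupling between a running metric and a
#' micro-CT biomarker within one genotype-by-sex stratum: the target partial
#' correlation of the time-detrended residuals, the biomarker's time trend
#' and variance components, and the running metric's typical trajectory at
#' the imaging timepoints. Targets cover aerated lung volume (animal as
#' unit) and talus bone volume (limb as unit) against distance and rate,
#' with the published partial-correlation values as configured truth.
#'
#' @return Data frame of class `link_presets`, one row per
#'   (measure, metric, genotype, sex), with list columns `y_trend` and
#'   `x_trend` aligned to `timepoints` (months).
#' @export
link_presets <- function() {
  strata <- data.frame(
    genotype = rep(c("WT", "TNF-Tg", "WT", "TNF-Tg"), each = 1L),
    sex = c("F", "F", "M", "M"),
    stringsAsFactors = FALSE
  )
  rho_tab <- rbind(
    data.frame(measure = "aerated_lung_mm3", metric = "distance", strata,
               rho = c(0.705, 0.380, 0.412, 0.677)),
    data.frame(measure = "aerated_lung_mm3", metric = "rate", strata,
               rho = c(0.693, 0.403, 0.379, 0.647)),
    data.frame(measure = "talus_mm3", metric = "distance", strata,
               rho = c(0.268, -0.614, 0.302, -0.903)),
    data.frame(measure = "talus_mm3", metric = "rate", strata,
               rho = c(0.263, -0.594, 0.316, -0.865))
  )
  rho_tab$unit_kind <- ifelse(rho_tab$measure == "talus_mm3", "limb", "animal")
  tp <- c(2, 3, 4, 5)
  rho_tab$timepoints <- rep(list(tp), nrow(rho_tab))
  # biomarker time trends: aerated lung roughly stable/improving in runners,
  # talus volume eroding in TNF-Tg; absolute levels in mm^3
  y_trend_for <- function(measure, genotype) {
    if (measure == "aerated_lung_mm3") {
      if (genotype == "WT") c(230, 240, 250, 259) else c(180, 210, 250, 291)
    } else {
      if (genotype == "WT") c(1.25, 1.27, 1.28, 1.30) else
        c(1.20, 1.05, 0.85, 0.72)
    }
  }
  rho_tab$y_trend <- mapply(y_trend_for, rho_tab$measure, rho_tab$genotype,
                            SIMPLIFY = FALSE)
  rho_tab$y_sd_unit <- ifelse(rho_tab$measure == "aerated_lung_mm3", 15, 0.10)
  rho_tab$y_sd_resid <- ifelse(rho_tab$measure == "aerated_lung_mm3", 10, 0.08)
  # running-metric trend at the imaging months, from the behavioral presets
  gp <- group_presets()
  x_trend_for <- function(metric, genotype, sex) {
    pr <- preset_for(genotype, sex, gp)
    ages <- pmin(pmax(round(tp * 30.44), 60), 140)
    tr <- trajectory(pr, ages)
    if (metric == "distance") tr$distance_median else tr$rate
  }
  rho_tab$x_trend <- mapply(x_trend_for, rho_tab$metric, rho_tab$genotype,
                            rho_tab$sex, SIMPLIFY = FALSE)
  rho_tab$x_sd_log <- ifelse(rho_tab$metric == "distance", 0.35, 0.15)
  rho_tab$n_units <- 100L
  rownames(rho_tab) <- NULL
  class(rho_tab) <- c("link_presets", "data.frame")
  rho_tab
}

#' Look up one biomarker-link preset
#'
#' @param measure Biomarker measure name (e.g. `"talus_mm3"`).
#' @param metric Running metric (`"distance"` or `"rate"`).
#' @param genotype,sex Stratum.
#' @param links Link table, default [link_presets()].
#' @return A single link row.
#' @export
link_for <- function(measure, metric, genotype, sex, links = link_presets()) {
  row <- links[links$measure == measure & links$metric == metric &
               links$genotype == genotype & links$sex == sex, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("no unique link preset for ", measure, "/", metric, " in ",
         genotype, " ", sex, call. = FALSE)
  }
  row
}
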