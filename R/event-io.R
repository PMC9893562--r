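#' Read an animal manifest
#'
#' The manifest is a CSV with one row per animal and columns `animal_id`,
#' `date_of_birth` (ISO date), `genotype` (`WT` or `TNF-Tg`), `sex` (`M` or
#' `F`), `group` (`running` or `sedentary`) and optionally `death_age_days`
#' (age at death in days, blank when the animal reached scheduled endpoint).
#'
#' @param path Path to the manifest CSV.
#' @return A data frame of class `wheel_manifest` with parsed columns;
#'   `genotype`, `sex` and `group` are factors with the levels above.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("animal_id", "date_of_birth", "genotype", "sex", "group")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("manifest is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"death_age_days" %in% names(raw)) raw$death_age_days <- NA_character_
  death <- suppressWarnings(as.integer(raw$death_age_days))
  death[!nzchar(trimws(ifelse(is.na(raw$death_age_days), "",
                              raw$death_age_days)))] <- NA_integer_
  m <- data.frame(
    animal_id = raw$animal_id,
    date_of_birth = as.Date(raw$date_of_birth),
    genotype = raw$genotype,
    sex = raw$sex,
    group = raw$group,
    death_age_days = death,
    stringsAsFactors = FALSE
  )
  validate_manifest(m)
  m$genotype <- factor(m$genotype, levels = genotype_levels())
  m$sex <- factor(m$sex, levels = sex_levels())
  m$group <- factor(m$group, levels = group_levels())
  class(m) <- c("wheel_manifest", "data.frame")
  m
}

genotype_levels <- function() c("WT", "TNF-Tg")
sex_levels <- function() c("M", "F")
group_levels <- function() c("running", "sedentary")

validate_manifest <- function(m) {
  if (nrow(m) == 0L) return(invisible(m))
  dup <- duplicated(m$animal_id)
  if (any(dup)) {
    stop("duplicate animal_id in manifest: ",
         paste(unique(m$animal_id[dup]), collapse = ", "), call. = FALSE)
  }
  check_enum <- function(values, levels, field) {
    bad <- which(!(as.character(values) %in% levels))
    if (length(bad)) {
      stop(sprintf("manifest row %d: unknown %s value '%s' (expected one of %s)",
                   bad[1L], field, as.character(values)[bad[1L]],
                   paste(levels, collapse = ", ")), call. = FALSE)
    }
  }
  check_enum(m$genotype, genotype_levels(), "genotype")
  check_enum(m$sex, sex_levels(), "sex")
  check_enum(m$group, group_levels(), "group")
  if (any(is.na(m$date_of_birth))) {
    stop("manifest row ", which(is.na(m$date_of_birth))[1L],
         ": unparseable date_of_birth", call. = FALSE)
  }
  bad_death <- which(!is.na(m$death_age_days) & m$death_age_days <= 0L)
  if (length(bad_death)) {
    stop("manifest row ", bad_death[1L], ": death_age_days must be > 0",
         call. = FALSE)
  }
  invisible(m)
}

#' Write an animal manifest
#'
#' @param manifest A `wheel_manifest` (or compatible data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  out <- data.frame(
    animal_id = as.character(manifest$animal_id),
    date_of_birth = format(manifest$date_of_birth, "%Y-%m-%d"),
    genotype = as.character(manifest$genotype),
    sex = as.character(manifest$sex),
    group = as.character(manifest$group),
    death_age_days = ifelse(is.na(manifest$death_age_days), "",
                            as.character(manifest$death_age_days)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a validated event stream
#'
#' One animal-day of switch-closure timestamps. Timestamps are seconds since
#' midnight at 10-ms resolution; acquisition is sequential so they must be
#' non-decreasing. A day on which the wheel was accessible but unused is an
#' `available` stream with zero closures; a day without wheel access (e.g.
#' imaging under anesthesia) is `available = FALSE` and carries no timestamps.
#'
#' @param animal_id Animal identifier.
#' @param day_date Calendar date of the recording day (`Date` or ISO string).
#' @param timestamps Numeric vector of seconds since midnight, non-decreasing,
#'   each in `[0, 86400)` and a multiple of 0.01 s.
#' @param age_days Age in days on `day_date` (`day_date - date_of_birth`);
#'   `NA` when unknown.
#' @param available Whether the wheel was accessible that day.
#' @return An object of class `event_stream`.
#' @export
event_stream <- function(animal_id, day_date, timestamps = numeric(),
                         age_days = NA_integer_, available = TRUE) {
  day_date <- as.Date(day_date)
  timestamps <- as.numeric(timestamps)
  s <- structure(
    list(animal_id = as.character(animal_id), day_date = day_date,
         age_days = as.integer(age_days),
         timestamps = round(timestamps, 2), available = isTRUE(available)),
    class = "event_stream"
  )
  validate_event_stream(s, raw_timestamps = timestamps)
  s
}

validate_event_stream <- function(s, raw_timestamps = s$timestamps) {
  t <- raw_timestamps
  if (!s$available && length(t) > 0L) {
    stop("unavailable day must carry no timestamps", call. = FALSE)
  }
  if (length(t)) {
    if (any(!is.finite(t))) stop("non-finite timestamp", call. = FALSE)
    bad_range <- which(t < 0 | t >= 86400)
    if (length(bad_range)) {
      stop(sprintf("timestamp out of [0, 86400) at line %d: %s",
                   bad_range[1L], format(t[bad_range[1L]])), call. = FALSE)
    }
    dec <- which(diff(t) < 0)
    if (length(dec)) {
      stop(sprintf("timestamps decrease at line %d (%.2f after %.2f)",
                   dec[1L] + 1L, t[dec[1L] + 1L], t[dec[1L]]), call. = FALSE)
    }
    off_grid <- which(abs(t * 100 - round(t * 100)) > 1e-5)
    if (length(off_grid)) {
      stop(sprintf("timestamp at line %d is not a multiple of 0.01 s: %s",
                   off_grid[1L], format(t[off_grid[1L]], digits = 15)),
           call. = FALSE)
    }
  }
  invisible(s)
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("<event_stream> %s %s (age %s d): %d closure(s)%s\n",
              x$animal_id, format(x$day_date), format(x$age_days),
              length(x$timestamps),
              if (x$available) "" else " [wheel unavailable]"))
  invisible(x)
}

#' Read one animal-day revolution log
#'
#' Logs hold one timestamp (seconds since midnight, two decimals) per line.
#' The input is validated, not repaired: out-of-order timestamps are an error
#' because acquisition is strictly sequential.
#'
#' @param path Path to a `.rev` log file.
#' @param animal_id,day_date Identity of the animal-day the file records.
#' @param date_of_birth Optional `Date`; when given, `age_days` is derived.
#' @return An [event_stream()].
#' @export
read_event_day <- function(path, animal_id, day_date, date_of_birth = NULL) {
  if (!file.exists(path)) stop("event log not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  t <- if (length(lines)) {
    parsed <- suppressWarnings(as.numeric(lines))
    if (any(is.na(parsed))) {
      stop(sprintf("%s: unparseable timestamp at line %d: '%s'",
                   path, which(is.na(parsed))[1L], lines[which(is.na(parsed))[1L]]),
           call. = FALSE)
    }
    parsed
  } else numeric()
  age <- if (is.null(date_of_birth)) NA_integer_ else
    as.integer(as.Date(day_date) - as.Date(date_of_birth))
  event_stream(animal_id, day_date, t, age_days = age, available = TRUE)
}

#' Write one animal-day revolution log
#'
#' Inverse of [read_event_day()]: writes one timestamp per line with two
#' decimal places, so `read_event_day(write_event_day(s, p), ...)`
#' reproduces `s` exactly. A zero-closure day yields an empty file.
#'
#' @param stream An [event_stream()] with `available = TRUE`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_day <- function(stream, path) {
  stopifnot(inherits(stream, "event_stream"))
  if (!stream$available) {
    stop("unavailable days are represented by file absence, not a log file",
         call. = FALSE)
  }
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write ", path, call. = FALSE))
  on.exit(close(con))
  if (length(stream$timestamps)) {
    writeLines(sprintf("%.2f", stream$timestamps), con)
  }
  invisible(path)
}

#' Read the wheel-unavailability table
#'
#' `gaps.csv` lists animal-days on which the wheel was inaccessible
#' (imaging, anesthesia recovery); those days are excluded from aggregation
#' rather than counted as zero-activity days.
#'
#' @param path Path to `gaps.csv` (columns `animal_id,date,reason`). A
#'   missing file is an empty table.
#' @return Data frame with columns `animal_id`, `date` (`Date`), `reason`.
#' @export
read_gaps <- function(path) {
  if (!file.exists(path)) {
    return(data.frame(animal_id = character(), date = as.Date(character()),
                      reason = character(), stringsAsFactors = FALSE))
  }
  g <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  data.frame(animal_id = g$animal_id, date = as.Date(g$date),
             reason = g$reason, stringsAsFactors = FALSE)
}

#' Read every logged day for the animals of a manifest
#'
#' Walks a data directory laid out as `<animal_id>/<ISO-date>.rev`, one file
#' per observed animal-day, and returns validated event streams. Dates listed
#' in `gaps.csv` at the directory root are wheel-unavailable days; by default
#' they are simply absent from the result (`gap_policy = "missing"`), or they
#' can be materialized as zero-activity days (`gap_policy = "zero"`) when an
#' analysis wants the anesthesia-day convention in which lost days count as
#' observed zeros.
#'
#' @param manifest A [read_manifest()] result (running animals are read;
#'   sedentary animals have no logs).
#' @param data_dir Root of the per-animal log directories.
#' @param gap_policy `"missing"` (default) or `"zero"`.
#' @return A list of [event_stream()] objects.
#' @export
read_cohort_days <- function(manifest, data_dir,
                             gap_policy = c("missing", "zero")) {
  gap_policy <- match.arg(gap_policy)
  gaps <- read_gaps(file.path(data_dir, "gaps.csv"))
  streams <- list()
  for (i in seq_len(nrow(manifest))) {
    id <- as.character(manifest$animal_id[i])
    dob <- manifest$date_of_birth[i]
    dir <- file.path(data_dir, id)
    if (!dir.exists(dir)) next
    files <- sort(list.files(dir, pattern = "\\.rev$", full.names = TRUE))
    for (f in files) {
      day <- as.Date(sub("\\.rev$", "", basename(f)))
      streams[[length(streams) + 1L]] <-
        read_event_day(f, id, day, date_of_birth = dob)
    }
    if (gap_policy == "zero") {
      gd <- gaps$date[gaps$animal_id == id]
      for (day in as.list(gd)) {
        streams[[length(streams) + 1L]] <- event_stream(
          id, day, numeric(), age_days = as.integer(day - dob),
          available = TRUE)
      }
    }
  }
  streams
}
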