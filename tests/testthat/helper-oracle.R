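# Independent brute-force bout partitioner: walks the stream closure by
# closure and opens a new bout at every gap exceeding the pause, returning
# per-bout revolution counts and spans. Deliberately loop-based and separate
# from the vectorized implementation under test.
oracle_bouts <- function(timestamps, pause_s = 9) {
  if (!length(timestamps)) {
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      revolutions = integer()))
  }
  starts <- ends <- revs <- c()
  bout_start <- timestamps[1]
  count <- 1L
  if (length(timestamps) > 1) {
    for (i in 2:length(timestamps)) {
      if (timestamps[i] - timestamps[i - 1] > pause_s) {
        starts <- c(starts, bout_start)
        ends <- c(ends, timestamps[i - 1])
        revs <- c(revs, count)
        bout_start <- timestamps[i]
        count <- 1L
      } else {
        count <- count + 1L
      }
    }
  }
  starts <- c(starts, bout_start)
  ends <- c(ends, timestamps[length(timestamps)])
  revs <- c(revs, count)
  data.frame(start_s = starts, end_s = ends, revolutions = as.integer(revs))
}

# Random small stream on the 10-ms grid, clustered so both intra- and
# inter-bout gaps occur.
random_stream <- function(n = NULL, span_s = 600) {
  if (is.null(n)) n <- sample(0:60, 1)
  if (n == 0) return(numeric())
  gaps <- sample(c(stats::runif(n, 0, 6), stats::runif(n, 6, 30)), n)
  round(cumsum(gaps), 2)
}

# A miniature preset with small distances so event-stream fixtures stay tiny.
tiny_preset <- function(genotype = "WT", sex = "M", n_animals = 2L,
                        distance = 30, distance_sd = 5, rate = 0.5,
                        n_runs = 4, cessation = NA, mortality = integer()) {
  p <- data.frame(
    genotype = genotype, sex = sex, n_animals = n_animals,
    distance_start = distance, distance_start_sd = distance_sd,
    distance_end = distance, distance_end_sd = distance_sd,
    rate_start = rate, rate_end = rate,
    run_length_start = 20, run_length_end = 20,
    n_runs_start = n_runs, n_runs_end = n_runs,
    cessation_age_days = cessation,
    stringsAsFactors = FALSE
  )
  p$mortality <- list(mortality)
  p
}

write_manifest_csv <- function(path, rows) {
  header <- "animal_id,date_of_birth,genotype,sex,group,death_age_days"
  writeLines(c(header, rows), path)
}
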