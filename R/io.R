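#' Write a simulation record to a directory of plain-text files
#'
#' Arrays are stored as CSV (rates, per-day patterns, epsilon, weight
#' snapshots, mask, read-out traces) and the configuration, seed and
#' shapes as JSON, so a record round-trips without loss through text
#' formats.
#'
#' @param record A `simulation_record`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [read_record()]
#' @export
write_record <- function(record, dir) {
  stopifnot(inherits(record, "simulation_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name)
    utils::write.csv(as.data.frame(x),
                     file.path(dir, paste0(name, ".csv")), row.names = FALSE)
  if (!is.null(record$rates)) wcsv(record$rates, "rates")
  if (is.list(record$patterns)) {
    wcsv(record$patterns$A, "patterns_A")
    wcsv(record$patterns$B, "patterns_B")
  } else wcsv(record$patterns, "patterns")
  if (!is.null(record$baseline)) {
    if (is.list(record$baseline$patterns)) {
      wcsv(record$baseline$patterns$A, "baseline_patterns_A")
      wcsv(record$baseline$patterns$B, "baseline_patterns_B")
    } else wcsv(record$baseline$patterns, "baseline_patterns")
  }
  wcsv(record$epsilon, "epsilon")
  wcsv(record$mask, "mask")
  for (d in seq_along(record$W_snapshots))
    wcsv(record$W_snapshots[[d]], sprintf("W_day%d", d))
  if (!is.null(record$readout)) {
    wcsv(record$readout$y_trace, "readout_y")
    wcsv(record$readout$W_out, "readout_W_final")
  }
  meta <- list(params = unclass(record$params), seed = record$seed,
               n_days = nrow(record$epsilon),
               two_context = isTRUE(record$schedule$two_context),
               active = record$active,
               has_rates = !is.null(record$rates),
               has_baseline = !is.null(record$baseline),
               has_readout = !is.null(record$readout))
  jsonlite::write_json(meta, file.path(dir, "record.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read back a record directory
#'
#' Restores the arrays written by [write_record()]. The full schedule is
#' not reconstructed (re-create it from config + seed); the returned list
#' carries the numeric content and metadata.
#'
#' @param dir Directory written by [write_record()].
#' @return List with the stored matrices and the metadata under `$meta`.
#' @export
read_record <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "record.json"),
                              simplifyVector = TRUE)
  rcsv <- function(name) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) return(NULL)
    as.matrix(utils::read.csv(path))
  }
  W <- list()
  for (d in seq_len(meta$n_days)) W[[d]] <- unname(rcsv(sprintf("W_day%d", d)))
  pats <- if (isTRUE(meta$two_context)) {
    list(A = unname(rcsv("patterns_A")), B = unname(rcsv("patterns_B")))
  } else unname(rcsv("patterns"))
  list(rates = unname(rcsv("rates")), patterns = pats,
       baseline_patterns = if (isTRUE(meta$two_context)) {
         list(A = unname(rcsv("baseline_patterns_A")),
              B = unname(rcsv("baseline_patterns_B")))
       } else unname(rcsv("baseline_patterns")),
       epsilon = unname(rcsv("epsilon")), mask = unname(rcsv("mask")),
       W_snapshots = W,
       readout_y = unname(rcsv("readout_y")),
       meta = meta)
}

#' Serialize a stimulation schedule to JSON
#'
#' @param schedule A `stim_schedule`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "stim_schedule"))
  x <- unclass(schedule)
  x$epsilon_by_day <- as.data.frame(x$epsilon_by_day)
  x$epsilon_baseline <- as.data.frame(x$epsilon_baseline)
  x$day_windows <- as.data.frame(x$day_windows)
  x$pattern_steps <- as.data.frame(x$pattern_steps)
  if (!is.null(x$beta)) x$beta <- as.data.frame(x$beta)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a schedule back from JSON
#'
#' @param path File written by [write_schedule()].
#' @return A `stim_schedule` equal to the one written.
#' @export
read_schedule <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$epsilon_by_day <- unname(as.matrix(x$epsilon_by_day))
  x$epsilon_baseline <- unname(as.matrix(x$epsilon_baseline))
  dw <- as.matrix(x$day_windows)
  dimnames(dw) <- list(NULL, c("start", "end"))
  storage.mode(dw) <- "integer"
  x$day_windows <- dw
  ps <- as.matrix(x$pattern_steps)
  storage.mode(ps) <- "integer"
  dimnames(ps) <- if (isTRUE(x$two_context)) list(NULL, c("A", "B")) else NULL
  x$pattern_steps <- ps
  if (!is.null(x$beta)) x$beta <- unname(as.matrix(x$beta))
  x$n_steps <- as.integer(x$n_steps)
  x$target <- as.integer(x$target)
  x$day_of_step <- as.integer(x$day_of_step)
  if (!is.null(x$context)) x$context <- as.integer(x$context)
  class(x) <- "stim_schedule"
  x
}
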