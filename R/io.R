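# Delimited-text readers and writers.  Events and censuses travel as UTF-8
# CSV with a header; matrices as TSV with roster ids on both margins.

#' Read an agonistic event log from CSV
#'
#' Expects header columns `day,winner,loser,behavior,vivarium,zone`.  Parse
#' and validation errors name the offending file line (the header is line 1).
#'
#' @param path path to a CSV file.
#' @param roster optional character vector fixing the roster and its order;
#'   inferred (sorted) from the file when `NULL`.
#' @return an [event_log()].
#' @export
read_event_log <- function(path, roster = NULL) {
  events <- read_delim_checked(path, EVENT_COLUMNS,
                               required = c("day", "winner", "loser", "vivarium"))
  events$winner <- as.character(events$winner)
  events$loser <- as.character(events$loser)
  if (is.null(roster)) roster <- sort(unique(c(events$winner, events$loser)))
  validate_events(events, roster, line_offset = 1L)
  event_log(events, roster = roster)
}

#' Write an event log to CSV
#' @param log an [event_log()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "event_log"))
  utils::write.csv(log$events, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a census log from CSV
#'
#' Expects header columns `day,timepoint,vivarium,id`.  Duplicate
#' (day, timepoint, id) records are collapsed with a warning.
#'
#' @inheritParams read_event_log
#' @return a [census_log()].
#' @export
read_census_log <- function(path, roster = NULL) {
  sightings <- read_delim_checked(path, CENSUS_COLUMNS, required = CENSUS_COLUMNS)
  census_log(sightings, roster = roster)
}

#' Write a census log to CSV
#' @param log a [census_log()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_census_log <- function(log, path) {
  stopifnot(inherits(log, "census_log"))
  utils::write.csv(log$sightings, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

read_delim_checked <- function(path, columns, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                    fileEncoding = "UTF-8"),
    error = function(e) stop("cannot parse '", path, "': ", conditionMessage(e),
                             call. = FALSE)
  )
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("'%s' lacks header column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in setdiff(columns, names(df))) df[[col]] <- NA_character_
  df[, columns, drop = FALSE]
}

#' Write a roster-labelled matrix as TSV
#'
#' @param m square matrix with roster ids as dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  check_sociomatrix(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a roster-labelled TSV matrix
#' @param path path written by [write_matrix_tsv()].
#' @return matrix with roster dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  check_sociomatrix(m)
  m
}
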