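# Core data containers: event logs of agonistic interactions and census logs
# of spatial sightings.  Both are plain lists of a roster plus a data frame,
# so downstream matrix builders can rely on a fixed, explicit individual
# ordering.

EVENT_COLUMNS <- c("day", "winner", "loser", "behavior", "vivarium", "zone")
CENSUS_COLUMNS <- c("day", "timepoint", "vivarium", "id")

#' Construct an agonistic event log
#'
#' An event log couples a roster of individual ids with an ordered table of
#' winner/loser interaction records, each carrying the observation day, a
#' behavior label from the ethogram, and a two-level location (vivarium
#' index plus free-text zone).  All sociomatrices are built from this
#' container, and the roster order attached here is carried on every matrix
#' so that permutations never silently change meaning.
#'
#' @param events data frame with columns `day`, `winner`, `loser`,
#'   `behavior`, `vivarium`, `zone` (`behavior` and `zone` may be omitted).
#' @param roster character vector of individual ids.  When `NULL` the roster
#'   is inferred as the lexicographically sorted union of winners and losers.
#' @return an object of class `event_log`: a list with elements `roster`
#'   (character) and `events` (data frame).
#' @export
event_log <- function(events, roster = NULL) {
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  if (!"behavior" %in% names(events)) {
    events$behavior <- rep("agonistic", nrow(events))
  }
  if (!"zone" %in% names(events)) events$zone <- rep(NA_character_, nrow(events))
  missing_cols <- setdiff(c("day", "winner", "loser", "vivarium"), names(events))
  if (length(missing_cols)) {
    stop("event table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  events <- events[, EVENT_COLUMNS]
  events$winner <- as.character(events$winner)
  events$loser <- as.character(events$loser)
  events$zone <- as.character(events$zone)
  events$behavior <- as.character(events$behavior)
  supplied <- !is.null(roster)
  if (!supplied) roster <- sort(unique(c(events$winner, events$loser)))
  roster <- as.character(roster)
  if (anyDuplicated(roster)) stop("roster ids must be unique", call. = FALSE)
  validate_events(events, roster)
  if (length(roster) < 2) stop("a roster needs at least 2 individuals", call. = FALSE)
  structure(list(roster = roster, events = events), class = "event_log")
}

validate_events <- function(events, roster, line_offset = 0L) {
  where <- function(i) {
    if (line_offset > 0) sprintf("line %d", i + line_offset) else sprintf("row %d", i)
  }
  n <- nrow(events)
  if (n) {
    day <- suppressWarnings(as.numeric(events$day))
    bad <- which(is.na(day) | day < 1 | day != floor(day))
    if (length(bad)) {
      stop(sprintf("%s: 'day' must be a positive integer (got '%s')",
                   where(bad[1]), events$day[bad[1]]), call. = FALSE)
    }
    viv <- suppressWarnings(as.integer(events$vivarium))
    bad <- which(is.na(viv) | viv < 1)
    if (length(bad)) {
      stop(sprintf("%s: 'vivarium' must be a positive integer index (got '%s')",
                   where(bad[1]), events$vivarium[bad[1]]), call. = FALSE)
    }
    self <- which(events$winner == events$loser)
    if (length(self)) {
      stop(sprintf("%s: winner and loser are the same individual ('%s')",
                   where(self[1]), events$winner[self[1]]), call. = FALSE)
    }
    unknown <- which(!(events$winner %in% roster) | !(events$loser %in% roster))
    if (length(unknown)) {
      i <- unknown[1]
      off <- setdiff(c(events$winner[i], events$loser[i]), roster)[1]
      stop(sprintf("%s: id '%s' is not in the roster", where(i), off),
           call. = FALSE)
    }
  }
  invisible(events)
}

#' Construct a census log of spatial sightings
#'
#' One row per sighting of an individual in a vivarium at a census time
#' point.  An individual may appear at most once per census period
#' (day x timepoint); duplicates are collapsed with a warning.
#'
#' @param sightings data frame with columns `day`, `timepoint`, `vivarium`,
#'   `id`.
#' @param roster character vector of individual ids; inferred (sorted) from
#'   the sightings when `NULL`.
#' @return an object of class `census_log`: list with `roster`, `sightings`,
#'   and `periods` (the ordered unique day x timepoint labels).
#' @export
census_log <- function(sightings, roster = NULL) {
  sightings <- as.data.frame(sightings, stringsAsFactors = FALSE)
  missing_cols <- setdiff(CENSUS_COLUMNS, names(sightings))
  if (length(missing_cols)) {
    stop("census table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  sightings <- sightings[, CENSUS_COLUMNS]
  sightings$id <- as.character(sightings$id)
  sightings$timepoint <- as.character(sightings$timepoint)
  if (is.null(roster)) roster <- sort(unique(sightings$id))
  roster <- as.character(roster)
  if (anyDuplicated(roster)) stop("roster ids must be unique", call. = FALSE)
  unknown <- setdiff(sightings$id, roster)
  if (length(unknown)) {
    stop("census ids not in roster: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(sightings$day, sightings$timepoint, sightings$id, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sprintf("collapsed %d duplicate (day, timepoint, id) sighting(s)",
                    sum(duplicated(key))), call. = FALSE)
    sightings <- sightings[!duplicated(key), , drop = FALSE]
  }
  period <- paste(sightings$day, sightings$timepoint, sep = ":")
  periods <- unique(period[order(as.numeric(sightings$day), sightings$timepoint)])
  structure(list(roster = roster, sightings = sightings, periods = periods),
            class = "census_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> %d individuals, %d agonistic events over %s day(s)\n",
              length(x$roster), nrow(x$events),
              if (nrow(x$events)) max(x$events$day) else 0))
  invisible(x)
}

#' @export
print.census_log <- function(x, ...) {
  cat(sprintf("<census_log> %d individuals, %d sightings across %d census periods\n",
              length(x$roster), nrow(x$sightings), length(x$periods)))
  invisible(x)
}
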