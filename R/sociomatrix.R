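# Sociomatrix builders: the frequency win/loss matrix, its Appleby-rule
# binarization, and the symmetrized total-interaction matrix.

#' Build the frequency win/loss sociomatrix
#'
#' `M[i, j]` counts the events in which `i` defeated `j`; winners in rows,
#' losers in columns.  The diagonal is structurally zero (individuals cannot
#' interact agonistically with themselves) and the entries sum to the number
#' of events used.
#'
#' @param log an [event_log()].
#' @param behaviors optional character vector restricting which ethogram
#'   labels enter the matrix; default uses every recorded winner/loser event.
#' @return integer matrix with roster ids as dimnames.
#' @export
frequency_matrix <- function(log, behaviors = NULL) {
  stopifnot(inherits(log, "event_log"))
  roster <- log$roster
  if (!length(roster)) stop("empty roster", call. = FALSE)
  ev <- log$events
  if (!is.null(behaviors)) ev <- ev[ev$behavior %in% behaviors, , drop = FALSE]
  m <- table(factor(ev$winner, levels = roster),
             factor(ev$loser, levels = roster))
  m <- matrix(as.integer(m), nrow = length(roster),
              dimnames = list(roster, roster))
  diag(m) <- 0L
  m
}

#' Binarize a frequency sociomatrix (Appleby tie rule)
#'
#' `B[i, j] = 1` and `B[j, i] = 0` exactly when `i` won more contests
#' against `j` than the reverse.  Tied dyads — including dyads that never
#' interacted — receive 0 in both directions, so for every dyad
#' `B[i, j] + B[j, i]` is 0 or 1.
#'
#' @param freq frequency sociomatrix from [frequency_matrix()].
#' @return 0/1 integer matrix with the same roster.
#' @export
binarize <- function(freq) {
  check_sociomatrix(freq)
  b <- (freq > t(freq)) * 1L
  diag(b) <- 0L
  dimnames(b) <- dimnames(freq)
  b
}

#' Symmetrize a frequency sociomatrix
#'
#' Total interactions per dyad: the frequency matrix plus its transpose.
#' Substrate of the community-detection stage.
#'
#' @inheritParams binarize
#' @return symmetric matrix with the same roster.
#' @export
symmetrize <- function(freq) {
  check_sociomatrix(freq)
  s <- freq + t(freq)
  diag(s) <- if (is.integer(s)) 0L else 0
  s
}

#' Classify every dyad of a frequency sociomatrix
#'
#' Returns per-dyad interaction totals together with counts of decided,
#' tied, and unknown (never-interacted) relationships.  The distinction
#' matters for de Vries' h': tied and unknown dyads are both undecided, but
#' are reported separately.
#'
#' @inheritParams binarize
#' @return list with `dyads` (data frame: i, j, wins_ij, wins_ji),
#'   `n_decided`, `n_tied`, `n_unknown`.
#' @export
dyad_summary <- function(freq) {
  check_sociomatrix(freq)
  idx <- dyad_index(nrow(freq))
  w1 <- freq[idx]
  w2 <- t(freq)[upper.tri(freq)]
  roster <- rownames(freq)
  list(
    dyads = data.frame(i = roster[idx[, 1]], j = roster[idx[, 2]],
                       wins_ij = w1, wins_ji = w2,
                       stringsAsFactors = FALSE),
    n_decided = sum(w1 != w2),
    n_tied = sum(w1 == w2 & w1 + w2 > 0),
    n_unknown = sum(w1 + w2 == 0)
  )
}
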