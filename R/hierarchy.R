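# Dominance-hierarchy statistics on sociomatrices, each with its
# Monte-Carlo randomization significance test, plus the I&SI ranking.
#
# p-value convention throughout: add-one correction
# (1 + #{null >= observed}) / (1 + n_rand), so a finite randomization never
# yields p = 0.

# Per-dyad win counts of the upper triangle: W1 = wins of the lower-index
# individual, W2 = wins of the higher-index individual.
dyad_counts <- function(freq) {
  idx <- upper.tri(freq)
  list(w1 = freq[idx], w2 = t(freq)[idx])
}

#' Directional consistency of a frequency sociomatrix
#'
#' `DC = sum(H - L) / sum(H + L)` over dyads with at least one interaction,
#' where `H` and `L` are the larger and smaller directed counts within each
#' dyad.  DC is 1 when every dyad is one-directional and 0 when every dyad
#' is split evenly.  Significance: each event's direction is re-flipped
#' fair-coin independently (equivalently, each dyad's wins are redrawn
#' Binomial(n, 1/2)), and p is the add-one proportion of randomizations with
#' DC at least as large as observed.
#'
#' @param freq frequency sociomatrix.
#' @param n_rand number of randomizations.
#' @param seed integer seed (or `NULL` to use the current RNG stream).
#' @return list with `dc`, `p`, `n_rand`.
#' @export
directional_consistency <- function(freq, n_rand = 10000, seed = NULL) {
  check_sociomatrix(freq)
  dc_ <- dyad_counts(freq)
  n <- dc_$w1 + dc_$w2
  keep <- n > 0
  if (!any(keep)) stop("no interactions: directional consistency undefined",
                       call. = FALSE)
  n <- n[keep]
  total <- sum(n)
  dc <- sum(abs(dc_$w1[keep] - dc_$w2[keep])) / total
  dc_rand <- with_seed(seed, {
    k <- matrix(stats::rbinom(length(n) * n_rand, n, 0.5), nrow = length(n))
    colSums(abs(2 * k - n)) / total
  })
  list(dc = dc, p = mc_pvalue(sum(dc_rand >= dc), n_rand), n_rand = n_rand)
}

landau_h_of_v <- function(v, n) {
  12 / (n^3 - n) * sum((v - (n - 1) / 2)^2)
}

#' de Vries' modified h' linearity index with randomization test
#'
#' Landau's `h = 12/(N^3 - N) * sum_i (V_i - (N-1)/2)^2`, where `V_i` is the
#' number of individuals dominated by `i`.  The modified `h'` treats tied
#' and never-interacted (unknown) dyads as undecided and equals the exact
#' expectation of `h` when every undecided dyad is imputed to one side or
#' the other fair-coin — computed in closed form as `h` with undecided dyads
#' split 0.5/0.5 plus `12/(N^3 - N) * sum_i(u_i)/4`, `u_i` being the number
#' of undecided dyads involving `i`.
#'
#' Significance uses the package's common direction-flip null: each
#' randomized matrix keeps the observed dyad structure (which relationships
#' are decided, tied, or unknown) but re-orients every decided relationship
#' fair-coin, and its `h'` is computed with the identical
#' undecided-imputation expectation.  p is the add-one proportion of
#' randomized matrices with `h'` at least the observed value.  Keeping the
#' undecided structure fixed makes the null exchangeable with the observed
#' statistic, so the test is calibrated; re-randomizing the observed side
#' per trial (an alternative reading of the two-step procedure) shrinks the
#' per-trial observed value toward its expectation and is markedly
#' conservative.
#'
#' @inheritParams directional_consistency
#' @return list with `h_prime`, `p`, `n_rand`, `n_unknown`, `n_tied`.
#' @export
landau_h_prime <- function(freq, n_rand = 10000, seed = NULL) {
  check_sociomatrix(freq)
  n <- nrow(freq)
  if (n < 3) stop("h' needs at least 3 individuals", call. = FALSE)
  dc_ <- dyad_counts(freq)
  idx <- dyad_index(n)
  decided_1 <- dc_$w1 > dc_$w2   # lower-index individual dominates
  decided_2 <- dc_$w2 > dc_$w1
  undecided <- !(decided_1 | decided_2)
  n_unknown <- sum(dc_$w1 + dc_$w2 == 0)
  n_tied <- sum(undecided) - n_unknown

  v_base <- tabulate(c(idx[decided_1, 1], idx[decided_2, 2]), nbins = n)
  u_i <- tabulate(c(idx[undecided, 1], idx[undecided, 2]), nbins = n)
  unknown_corr <- 12 / (n^3 - n) * sum(u_i) / 4
  h_prime <- landau_h_of_v(v_base + u_i / 2, n) + unknown_corr

  da <- idx[!undecided, 1]
  db <- idx[!undecided, 2]
  n_dec <- sum(!undecided)
  p <- with_seed(seed, {
    extreme <- 0L
    for (t in seq_len(n_rand)) {
      r <- stats::runif(n_dec) < 0.5
      v_rand <- tabulate(c(da[r], db[!r]), nbins = n) + u_i / 2
      if (landau_h_of_v(v_rand, n) + unknown_corr >= h_prime) {
        extreme <- extreme + 1L
      }
    }
    mc_pvalue(extreme, n_rand)
  })
  list(h_prime = h_prime, p = p, n_rand = n_rand,
       n_unknown = n_unknown, n_tied = n_tied)
}

#' David's scores from a frequency sociomatrix
#'
#' Dyadic win proportions `P[i,j] = wins_ij / (wins_ij + wins_ji)` (zero
#' contribution for never-interacting dyads), or the chance-corrected
#' variant `Dij = Pij - (Pij - 0.5)/(n_ij + 1)` when `dyadic = "Dij"`.
#' `DS = w + w2 - l - l2` with `w = rowSums(P)`, `w2 = P %*% w`,
#' `l = colSums(P)`, `l2 = t(P) %*% l`; `NormDS = (DS + N(N-1)/2) / N`.
#' David's scores always sum to zero.
#'
#' @inheritParams directional_consistency
#' @param dyadic `"Pij"` (raw proportions, default) or `"Dij"`
#'   (chance-corrected).
#' @return data frame with per-individual `w`, `w2`, `l`, `l2`, `DS`,
#'   `NormDS`, plus the dyadic proportion matrix as attribute `"P"`.
#' @export
david_scores <- function(freq, dyadic = c("Pij", "Dij")) {
  check_sociomatrix(freq)
  dyadic <- match.arg(dyadic)
  n_mat <- freq + t(freq)
  p <- freq / n_mat
  p[n_mat == 0] <- 0
  if (dyadic == "Dij") {
    p <- p - (p - 0.5) / (n_mat + 1)
    p[n_mat == 0] <- 0
  }
  diag(p) <- 0
  n <- nrow(freq)
  w <- unname(rowSums(p))
  l <- unname(colSums(p))
  w2 <- as.vector(p %*% w)
  l2 <- as.vector(t(p) %*% l)
  ds <- w + w2 - l - l2
  out <- data.frame(id = rownames(freq), w = w, w2 = w2, l = l, l2 = l2,
                    DS = ds, NormDS = (ds + n * (n - 1) / 2) / n,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "P") <- p
  out
}

steepness_stat <- function(freq, dyadic) {
  nds <- sort(david_scores(freq, dyadic = dyadic)$NormDS, decreasing = TRUE)
  ranks <- seq_along(nds)
  abs(stats::cov(ranks, nds) / stats::var(ranks))
}

#' Hierarchy steepness with randomization test
#'
#' Absolute slope of the ordinary least-squares fit of normalized David's
#' scores against their descending rank (1..N); 1 for a perfectly despotic
#' linear hierarchy, 0 when all scores are equal.  The null redraws each
#' dyad's wins Binomial(n, 1/2) (event-direction flipping), and p is the
#' add-one proportion of randomized matrices at least as steep.
#'
#' @inheritParams david_scores
#' @param n_rand number of randomizations.
#' @param seed integer seed.
#' @return list with `steepness`, `p`, `n_rand`, `dyadic`.
#' @export
steepness <- function(freq, n_rand = 10000, seed = NULL,
                      dyadic = c("Pij", "Dij")) {
  check_sociomatrix(freq)
  dyadic <- match.arg(dyadic)
  n <- nrow(freq)
  if (n < 3) stop("steepness needs at least 3 individuals", call. = FALSE)
  obs <- steepness_stat(freq, dyadic)
  dc_ <- dyad_counts(freq)
  tot <- dc_$w1 + dc_$w2
  idx <- dyad_index(n)
  stp_rand <- with_seed(seed, {
    vapply(seq_len(n_rand), function(t) {
      k <- stats::rbinom(length(tot), tot, 0.5)
      m <- matrix(0, n, n, dimnames = dimnames(freq))
      m[idx] <- k
      m[idx[, c(2, 1), drop = FALSE]] <- tot - k
      steepness_stat(m, dyadic)
    }, numeric(1))
  })
  list(steepness = obs, p = mc_pvalue(sum(stp_rand >= obs), n_rand),
       n_rand = n_rand, dyadic = dyadic)
}

# Transitive / cyclic / complete triad counts of a binary dominance matrix.
triad_census <- function(b) {
  b2 <- b %*% b
  trans <- sum(b2 * b)
  cyclic <- sum(diag(b2 %*% b)) / 3
  list(complete = trans + cyclic, transitive = trans, cyclic = cyclic)
}

#' Rescale a proportion of transitive triads to t.tri
#'
#' Linear rescaling `t.tri = 4 * (Pt - 0.75)` that maps the random
#' expectation Pt = 0.75 to 0 and complete transitivity Pt = 1 to 1.
#'
#' @param pt proportion of complete triads that are transitive, in `[0, 1]`.
#' @return the scaled triangle-transitivity statistic.
#' @export
#' @examples
#' ttri_scale(0.94)
ttri_scale <- function(pt) {
  stopifnot(is.numeric(pt), all(pt >= 0 & pt <= 1))
  4 * (pt - 0.75)
}

#' Triangle transitivity with Monte-Carlo null
#'
#' A triad is complete when all three of its dyads carry a directed
#' relation; it is transitive when those relations are acyclic.  `Pt` is the
#' transitive share of complete triads and `t.tri = 4 (Pt - 0.75)` its
#' rescaling.  The null generates random dominance graphs with the same
#' number of individuals and of directed relations: the related dyads are
#' resampled uniformly and each is oriented fair-coin (mutual edges are
#' impossible in a binarized win/loss matrix, so the null respects that
#' structural antisymmetry).
#'
#' @param binary binarized sociomatrix from [binarize()].
#' @param n_rand number of random graphs.
#' @param seed integer seed.
#' @return list with `pt`, `t_tri`, `p`, `n_random`, `n_complete_triads`.
#' @export
triangle_transitivity <- function(binary, n_rand = 1000, seed = NULL) {
  check_sociomatrix(binary)
  n <- nrow(binary)
  tc <- triad_census(binary)
  if (tc$complete == 0) {
    stop("no complete triads: triangle transitivity undefined", call. = FALSE)
  }
  pt <- tc$transitive / tc$complete
  t_tri <- ttri_scale(pt)
  m <- sum(binary)
  pairs <- dyad_index(n)
  t_rand <- with_seed(seed, {
    vapply(seq_len(n_rand), function(t) {
      k <- sample.int(nrow(pairs), m)
      flip <- stats::runif(m) < 0.5
      b <- matrix(0, n, n)
      b[pairs[k, , drop = FALSE][flip, c(2, 1), drop = FALSE]] <- 1
      b[pairs[k, , drop = FALSE][!flip, , drop = FALSE]] <- 1
      r <- triad_census(b)
      if (r$complete == 0) -Inf else ttri_scale(r$transitive / r$complete)
    }, numeric(1))
  })
  list(pt = pt, t_tri = t_tri,
       p = mc_pvalue(sum(t_rand >= t_tri), n_rand),
       n_random = n_rand, n_complete_triads = tc$complete)
}

# (I, SI) of an ordering: I counts dyads where the lower-ranked individual
# dominates the higher-ranked one; SI sums their rank distances.
isi_cost <- function(b, ord) {
  bo <- b[ord, ord]
  lower <- which(lower.tri(bo) & bo == 1, arr.ind = TRUE)
  c(I = nrow(lower), SI = if (nrow(lower)) sum(lower[, 1] - lower[, 2]) else 0L)
}

lex_less <- function(a, b) a[1] < b[1] || (a[1] == b[1] && a[2] < b[2])

# One local-search pass: every pairwise swap of two rank positions, then
# every single-individual insertion (remove from one position, re-insert at
# another, shifting the block between them).  Insertions escape the local
# minima that swaps alone leave behind.
isi_sweep <- function(b, ord, max_sweeps) {
  n <- length(ord)
  cost <- isi_cost(b, ord)
  sweeps <- 0L
  converged <- FALSE
  while (sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    improved <- FALSE
    for (a in seq_len(n - 1)) {
      for (bb in seq(a + 1, n)) {
        cand <- ord
        cand[c(a, bb)] <- ord[c(bb, a)]
        cand_cost <- isi_cost(b, cand)
        if (lex_less(cand_cost, cost)) {
          ord <- cand
          cost <- cand_cost
          improved <- TRUE
        }
      }
    }
    for (a in seq_len(n)) {
      for (bb in seq_len(n)) {
        if (a == bb) next
        cand <- append(ord[-a], ord[a], after = bb - 1L)
        cand_cost <- isi_cost(b, cand)
        if (lex_less(cand_cost, cost)) {
          ord <- cand
          cost <- cand_cost
          improved <- TRUE
        }
      }
    }
    if (!improved) {
      converged <- TRUE
      break
    }
  }
  list(ord = ord, cost = cost, converged = converged, sweeps = sweeps)
}

#' I&SI dominance ranking
#'
#' Finds an ordering of individuals minimizing, lexicographically, the
#' number of inconsistencies I (dyads in which the lower-ranked individual
#' dominates the higher-ranked one) and their strength SI (summed rank
#' distances of inconsistent dyads).  The search starts from the descending
#' David's-score order and sweeps over all pairwise swaps and all
#' single-individual insertions, accepting any move that reduces (I, SI)
#' lexicographically; random-restart orderings guard against local minima,
#' and the best result over all restarts is returned.
#'
#' @param binary binarized sociomatrix.
#' @param n_restarts random restarts beyond the David's-score start.
#' @param max_sweeps cap on full swap sweeps per restart.
#' @param seed integer seed for the restarts.
#' @return list of class `isi_ranking`: `ordering` (ids, best first),
#'   `ranks` (named integer vector), `I`, `SI`, `converged`, `restarts`,
#'   and `note` (set when the matrix has no relations at all).
#' @export
isi_rank <- function(binary, n_restarts = 20, max_sweeps = 1000, seed = NULL) {
  check_sociomatrix(binary)
  n <- nrow(binary)
  roster <- rownames(binary)
  note <- NULL
  if (sum(binary) == 0) {
    note <- "no relations: any ordering is consistent"
    res <- list(ord = seq_len(n), cost = c(I = 0L, SI = 0L), converged = TRUE)
  } else {
    ds_order <- order(david_scores(binary)$DS, decreasing = TRUE)
    res <- with_seed(seed, {
      starts <- c(list(ds_order),
                  replicate(max(0, n_restarts), sample.int(n), simplify = FALSE))
      best <- NULL
      for (s in starts) {
        cand <- isi_sweep(binary, s, max_sweeps)
        if (is.null(best) || lex_less(cand$cost, best$cost)) best <- cand
      }
      best
    })
  }
  ranks <- integer(n)
  ranks[res$ord] <- seq_len(n)
  names(ranks) <- roster
  structure(list(ordering = roster[res$ord], ranks = ranks,
                 I = unname(res$cost[1]), SI = unname(res$cost[2]),
                 converged = res$converged, restarts = n_restarts,
                 note = note),
            class = "isi_ranking")
}

#' Full hierarchy summary of an event log
#'
#' Convenience wrapper running directional consistency, h', steepness,
#' triangle transitivity, and the I&SI ranking on the sociomatrices of one
#' event log, with per-statistic sub-seeds derived from a single seed.
#'
#' @param log an [event_log()].
#' @param n_rand randomizations for DC, h', and steepness.
#' @param n_rand_ttri random graphs for triangle transitivity.
#' @param seed integer seed.
#' @param n_restarts restarts for [isi_rank()].
#' @return list with components `dc`, `h_prime`, `steepness`,
#'   `transitivity`, `ranking`, and the matrices used.
#' @export
hierarchy_summary <- function(log, n_rand = 10000, n_rand_ttri = 1000,
                              seed = NULL, n_restarts = 20) {
  freq <- frequency_matrix(log)
  bin <- binarize(freq)
  list(
    dc = directional_consistency(freq, n_rand, seed = derive_seed(seed, 1)),
    h_prime = landau_h_prime(freq, n_rand, seed = derive_seed(seed, 2)),
    steepness = steepness(freq, n_rand, seed = derive_seed(seed, 3)),
    transitivity = triangle_transitivity(bin, n_rand_ttri,
                                         seed = derive_seed(seed, 4)),
    ranking = isi_rank(bin, n_restarts = n_restarts,
                       seed = derive_seed(seed, 5)),
    frequency = freq, binary = bin
  )
}
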