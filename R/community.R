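# Girvan-Newman community detection on the symmetrized interaction network,
# modularity maximization over the edge-removal sequence, and bootstrap
# comembership consensus.

# Direct evaluation of weighted modularity
# Q = (1/2m) * sum_ij [A_ij - k_i k_j / 2m] delta(c_i, c_j).
modularity_direct <- function(s, membership) {
  m2 <- sum(s)
  if (m2 == 0) return(NA_real_)
  k <- rowSums(s)
  same <- outer(membership, membership, "==")
  sum((s - outer(k, k) / m2) * same) / m2
}

#' Girvan-Newman community detection
#'
#' Iteratively removes the edge with the highest edge betweenness
#' (recomputed after every removal), evaluating the weighted modularity `Q`
#' of the component partition of the original graph at every step of the
#' removal sequence, and returns the partition maximizing `Q`.  Modularity
#' always uses the raw interaction weights.
#'
#' For the betweenness step, interaction weights are treated as edge
#' lengths (`betweenness = "distance"`, the default).  Shortest paths then
#' concentrate on weak ties, which in a dense sociomatrix are exactly the
#' between-community ties, so the removal sequence cuts along them; this is
#' also how the classic igraph edge-betweenness clustering treats weights.
#' The inverse convention (`"inverse"`, lengths `1/weight`) and unweighted
#' betweenness (`"unweighted"`) are available; on dense weighted
#' interaction networks both disperse shortest paths over strong ties and
#' routinely fail to visit modular partitions at all, which is why they are
#' not the default.  The result is invariant under uniform rescaling of all
#' weights in every mode.
#'
#' @param s symmetric interaction matrix from [symmetrize()], or any
#'   symmetric non-negative weight matrix with roster dimnames.
#' @param betweenness edge-length convention for the betweenness step:
#'   `"distance"`, `"inverse"`, or `"unweighted"`.
#' @return list of class `community_result`: `membership` (named character,
#'   labels "A", "B", ... by decreasing community size), `Q_max`, `sizes`,
#'   `n_communities`, and `removals` (the ordered edge-removal record; the
#'   slower non-default modes also record each removal's betweenness and
#'   the modularity after it).
#' @export
girvan_newman <- function(s, betweenness = c("distance", "inverse",
                                             "unweighted")) {
  betweenness <- match.arg(betweenness)
  check_sociomatrix(s)
  if (any(s < 0)) stop("weights must be non-negative", call. = FALSE)
  if (max(abs(s - t(s))) > 1e-8) stop("matrix must be symmetric", call. = FALSE)
  if (sum(s) == 0) stop("empty graph: no positive interaction weights",
                        call. = FALSE)
  roster <- rownames(s)
  diag(s) <- 0
  g0 <- igraph::graph_from_adjacency_matrix(s, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  w0 <- igraph::E(g0)$weight
  if (betweenness == "distance") {
    # the C implementation uses weights as distances for betweenness and as
    # strengths for the modularity sequence: exactly this convention
    res <- suppressWarnings(
      igraph::cluster_edge_betweenness(g0, weights = w0, directed = FALSE,
                                       modularity = TRUE, membership = TRUE)
    )
    best_memb <- igraph::membership(res)
    best_q <- max(res$modularity)
    ends0 <- igraph::ends(g0, igraph::E(g0), names = FALSE)
    rem <- res$removed.edges
    removals <- data.frame(step = seq_along(rem),
                           from = roster[pmin(ends0[rem, 1], ends0[rem, 2])],
                           to = roster[pmax(ends0[rem, 1], ends0[rem, 2])],
                           stringsAsFactors = FALSE)
  } else {
    g <- g0
    best_memb <- igraph::components(g0)$membership
    best_q <- igraph::modularity(g0, best_memb, weights = w0)
    removal_list <- list()
    step <- 0L
    while (igraph::ecount(g) > 0) {
      step <- step + 1L
      ew <- igraph::E(g)$weight
      eb <- igraph::edge_betweenness(
        g, directed = FALSE,
        weights = if (betweenness == "inverse") 1 / ew else NULL
      )
      ends <- igraph::ends(g, igraph::E(g), names = FALSE)
      lo <- pmin(ends[, 1], ends[, 2])
      hi <- pmax(ends[, 1], ends[, 2])
      sel <- order(-eb, lo, hi)[1]
      removed <- c(lo[sel], hi[sel])
      g <- igraph::delete_edges(g, sel)
      memb <- igraph::components(g)$membership
      q <- igraph::modularity(g0, memb, weights = w0)
      removal_list[[step]] <- data.frame(step = step,
                                         from = roster[removed[1]],
                                         to = roster[removed[2]],
                                         betweenness = eb[sel], Q_after = q,
                                         stringsAsFactors = FALSE)
      if (q > best_q) {
        best_q <- q
        best_memb <- memb
      }
    }
    removals <- do.call(rbind, removal_list)
  }
  membership <- relabel_by_size(best_memb, roster)
  structure(list(membership = membership, Q_max = best_q,
                 sizes = sort(table(membership), decreasing = TRUE),
                 n_communities = length(unique(membership)),
                 removals = removals),
            class = "community_result")
}

# Relabel integer community codes as "A", "B", ... by decreasing size
# (ties: community containing the earliest roster index first).
relabel_by_size <- function(memb, roster) {
  first_idx <- tapply(seq_along(memb), memb, min)
  tab <- table(memb)
  ord <- order(-as.integer(tab), as.integer(first_idx))
  codes <- names(tab)[ord]
  labels <- make.unique(c(LETTERS, paste0("C", seq_len(max(0, length(codes) - 26)))))
  out <- labels[match(as.character(memb), codes)]
  names(out) <- roster
  out
}

#' Bootstrap comembership matrix
#'
#' Resamples the agonistic events with replacement (each replicate has the
#' original number of observations), rebuilds the symmetrized interaction
#' matrix, reruns Girvan-Newman detection, and records how often each pair
#' of individuals lands in the same community.  Individuals isolated in a
#' replicate (no sampled interactions) form singleton components and are
#' therefore co-assigned with no one.
#'
#' @param log an [event_log()].
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @param betweenness passed to [girvan_newman()].
#' @return symmetric matrix of comembership proportions in `[0, 1]` with
#'   unit diagonal; attribute `"n_boot"` records the replicate count.
#' @export
bootstrap_comembership <- function(log, n_boot = 1000, seed = NULL,
                                   betweenness = "distance") {
  stopifnot(inherits(log, "event_log"))
  ev <- log$events
  if (!nrow(ev)) stop("event log is empty", call. = FALSE)
  roster <- log$roster
  n <- length(roster)
  counts <- matrix(0, n, n, dimnames = list(roster, roster))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(ev), replace = TRUE)
      boot_log <- event_log(ev[idx, , drop = FALSE], roster = roster)
      s <- symmetrize(frequency_matrix(boot_log))
      memb <- girvan_newman(s, betweenness = betweenness)$membership
      counts <- counts + outer(memb, memb, "==")
    }
  })
  cm <- counts / n_boot
  diag(cm) <- 1
  attr(cm, "n_boot") <- n_boot
  cm
}

#' Consensus communities from a comembership matrix
#'
#' Runs Girvan-Newman detection on the comembership proportions treated as
#' a weighted graph, then labels as `"unassigned"` every individual whose
#' mean comembership with the members of each detected community falls
#' below `assign_threshold`.
#'
#' @param comembership matrix from [bootstrap_comembership()].
#' @param assign_threshold minimum mean comembership with some community's
#'   members required for assignment.
#' @param betweenness passed to [girvan_newman()].
#' @return `community_result` whose `membership` may contain
#'   `"unassigned"`; `sizes` covers the assigned communities only, and
#'   `unassigned` lists the unplaced ids.
#' @export
consensus_communities <- function(comembership, assign_threshold = 0.5,
                                  betweenness = "distance") {
  check_sociomatrix(comembership)
  roster <- rownames(comembership)
  cm <- comembership
  diag(cm) <- 0
  res <- girvan_newman(cm, betweenness = betweenness)
  memb <- res$membership
  for (i in seq_along(roster)) {
    groups <- unique(memb[memb != "unassigned"])
    support <- vapply(groups, function(grp) {
      members <- setdiff(roster[memb == grp], roster[i])
      if (!length(members)) return(NA_real_)
      mean(comembership[roster[i], members])
    }, numeric(1))
    if (all(is.na(support)) || max(support, na.rm = TRUE) < assign_threshold) {
      memb[i] <- "unassigned"
    }
  }
  assigned <- memb[memb != "unassigned"]
  sizes <- sort(table(assigned), decreasing = TRUE)
  # relabel assigned communities by size after unassignment
  relabeled <- memb
  if (length(sizes)) {
    new_names <- LETTERS[seq_along(sizes)]
    for (k in seq_along(sizes)) {
      relabeled[memb == names(sizes)[k]] <- new_names[k]
    }
    names(sizes) <- new_names
  }
  structure(list(membership = relabeled, Q_max = res$Q_max,
                 sizes = sizes,
                 n_communities = length(sizes),
                 unassigned = roster[relabeled == "unassigned"],
                 assign_threshold = assign_threshold,
                 removals = res$removals),
            class = "community_result")
}

#' @export
print.community_result <- function(x, ...) {
  cat(sprintf("<community_result> %d communities (Q_max = %.3f)\n",
              x$n_communities, x$Q_max))
  print(x$sizes)
  if (!is.null(x$unassigned) && length(x$unassigned)) {
    cat("unassigned:", paste(x$unassigned, collapse = ", "), "\n")
  }
  invisible(x)
}
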