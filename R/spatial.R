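# Spatial distribution of agonistic behavior: per-individual location-usage
# counts, Shannon's evenness with a multinomial unevenness test, and nMDS
# ordination of space usage.

#' Location-usage counts per individual
#'
#' `given[i, v]` counts wins by individual `i` in vivarium `v`;
#' `received[i, v]` counts losses.  Row sums match the frequency-matrix
#' marginals exactly.
#'
#' @param log an [event_log()].
#' @param n_vivaria number of vivaria (columns); defaults to the largest
#'   index present, with a floor of 4.
#' @param missing how to treat events with a missing vivarium: `"drop"`
#'   (with a warning) or `"error"`.
#' @return list of class `location_usage` with matrices `given`,
#'   `received`, and `total` (given + received).
#' @export
location_usage <- function(log, n_vivaria = NULL,
                           missing = c("drop", "error")) {
  stopifnot(inherits(log, "event_log"))
  missing <- match.arg(missing)
  ev <- log$events
  viv <- suppressWarnings(as.integer(ev$vivarium))
  if (anyNA(viv) && nrow(ev)) {
    if (missing == "error") stop("event(s) with missing vivarium", call. = FALSE)
    warning(sprintf("dropping %d event(s) with missing vivarium", sum(is.na(viv))),
            call. = FALSE)
    ev <- ev[!is.na(viv), , drop = FALSE]
    viv <- viv[!is.na(viv)]
  }
  if (is.null(n_vivaria)) n_vivaria <- max(4L, viv, na.rm = TRUE)
  roster <- log$roster
  lev <- seq_len(n_vivaria)
  tab <- function(ids) {
    m <- table(factor(ids, levels = roster), factor(viv, levels = lev))
    matrix(as.integer(m), nrow = length(roster),
           dimnames = list(roster, paste0("V", lev)))
  }
  given <- tab(ev$winner)
  received <- tab(ev$loser)
  structure(list(given = given, received = received,
                 total = given + received),
            class = "location_usage")
}

#' Shannon's evenness of a count vector
#'
#' `J = H / ln K` with `H = -sum p_k ln p_k` over the `K` locations
#' (zero counts contribute nothing).  `J` is 1 for perfectly uniform usage
#' and 0 when all counts fall in a single location.  A zero total returns
#' `NA` (undefined).
#'
#' @param counts non-negative counts over locations (K >= 2).
#' @return evenness in `[0, 1]`, or `NA` for a zero total.
#' @export
shannon_evenness <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  k <- length(counts)
  if (k < 2) stop("need at least 2 locations", call. = FALSE)
  total <- sum(counts)
  if (total == 0) return(NA_real_)
  p <- counts[counts > 0] / total
  -sum(p * log(p)) / log(k)
}

#' Unevenness significance by a uniform-multinomial null
#'
#' The per-individual test of spatial unevenness: the null redistributes
#' the same total count over the locations as a uniform multinomial, and p
#' is the add-one proportion of null draws whose evenness is at most the
#' observed one (one-sided towards unevenness).  A single event yields
#' p = 1: one observation cannot be uneven beyond chance.
#'
#' @inheritParams shannon_evenness
#' @param n_rand number of multinomial draws.
#' @param seed integer seed.
#' @return list with `J`, `p`, `n_rand`, `total`.
#' @export
evenness_significance <- function(counts, n_rand = 10000, seed = NULL) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  k <- length(counts)
  total <- sum(counts)
  if (total < 1) stop("total count must be >= 1", call. = FALSE)
  j_obs <- shannon_evenness(counts)
  j_null <- with_seed(seed, {
    draws <- stats::rmultinom(n_rand, total, rep(1 / k, k))
    apply(draws, 2, shannon_evenness)
  })
  list(J = j_obs, p = mc_pvalue(sum(j_null <= j_obs), n_rand),
       n_rand = n_rand, total = total)
}

#' Distance matrix between individuals' space-usage profiles
#'
#' Pairwise distances between the per-vivarium total interaction counts
#' (given + received) of each individual.  Bray-Curtis is the default for
#' count compositions; Euclidean is available.  Individuals with all-zero
#' profiles are excluded with a warning.
#'
#' @param usage a [location_usage()] result.
#' @param metric `"bray-curtis"` or `"euclidean"`.
#' @return symmetric distance matrix over the retained individuals;
#'   attribute `"excluded"` lists dropped ids.
#' @export
usage_distance <- function(usage, metric = c("bray-curtis", "euclidean")) {
  stopifnot(inherits(usage, "location_usage"))
  metric <- match.arg(metric)
  total <- usage$total
  zero <- rowSums(total) == 0
  if (any(zero)) {
    warning("excluding individual(s) with no located interactions: ",
            paste(rownames(total)[zero], collapse = ", "), call. = FALSE)
    total <- total[!zero, , drop = FALSE]
  }
  if (nrow(total) < 2) stop("need at least 2 individuals with usage",
                            call. = FALSE)
  d <- as.matrix(vegan::vegdist(total, method = if (metric == "bray-curtis")
    "bray" else "euclidean"))
  attr(d, "excluded") <- rownames(usage$total)[zero]
  d
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Minimizes Kruskal's stress-1 (monotone regression of configuration
#' distances on dissimilarity ranks) by iterative majorization, starting
#' from the classical metric-scaling configuration plus random restarts,
#' and returns the centered best configuration.
#'
#' @param d symmetric distance matrix (zero diagonal, >= 3 items).
#' @param k embedding dimension.
#' @param n_starts total starts (first is metric scaling, rest random).
#' @param max_iter iteration cap per start.
#' @param seed integer seed for the random starts.
#' @return list of class `ordination`: `points` (centered N x k), `stress`
#'   (Kruskal stress-1), `iters`, `converged`.
#' @export
nmds <- function(d, k = 2, n_starts = 20, max_iter = 500, seed = NULL) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be a square matrix",
                                                call. = FALSE)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 items", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8) stop("d must be symmetric", call. = FALSE)
  dd <- stats::as.dist(d)
  with_seed(seed, {
    init <- stats::cmdscale(dd, k = k)
    if (ncol(init) < k) {
      init <- cbind(init, matrix(0, n, k - ncol(init)))
    }
    starts <- c(list(init),
                replicate(max(0, n_starts - 1),
                          matrix(stats::rnorm(n * k), n, k), simplify = FALSE))
    best <- NULL
    for (y0 in starts) {
      fit <- vegan::monoMDS(dd, y = y0, k = k, model = "global",
                            maxit = max_iter)
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
    pts <- scale(best$points, center = TRUE, scale = FALSE)
    attr(pts, "scaled:center") <- NULL
    rownames(pts) <- rownames(d)
    colnames(pts) <- paste0("MDS", seq_len(k))
    structure(list(points = pts, stress = best$stress,
                   iters = best$iters,
                   converged = best$iters < max_iter),
              class = "ordination")
  })
}

#' Spatial summary of an event log
#'
#' Location-usage counts, per-individual evenness of giving and receiving
#' aggression with unevenness p-values, and the nMDS ordination of usage
#' profiles.
#'
#' @param log an [event_log()].
#' @param n_rand multinomial draws per evenness test.
#' @param n_starts nMDS starts.
#' @param metric distance metric for [usage_distance()].
#' @param seed integer seed.
#' @return list with `usage`, `evenness` (data frame), `ordination`.
#' @export
spatial_summary <- function(log, n_rand = 10000, n_starts = 20,
                            metric = "bray-curtis", seed = NULL) {
  usage <- location_usage(log)
  even_row <- function(counts, off) {
    if (sum(counts) == 0) return(c(J = NA_real_, p = NA_real_))
    r <- evenness_significance(counts, n_rand = n_rand,
                               seed = derive_seed(seed, off))
    c(J = r$J, p = r$p)
  }
  n <- nrow(usage$given)
  ev <- data.frame(
    id = rownames(usage$given),
    t(vapply(seq_len(n), function(i) {
      c(even_row(usage$given[i, ], 100 + i),
        even_row(usage$received[i, ], 200 + i))
    }, numeric(4))),
    row.names = NULL, stringsAsFactors = FALSE
  )
  names(ev) <- c("id", "J_given", "p_given", "J_received", "p_received")
  ord <- tryCatch({
    d <- usage_distance(usage, metric = metric)
    nmds(d, n_starts = n_starts, seed = derive_seed(seed, 300))
  }, error = function(e) NULL, warning = function(w) {
    suppressWarnings({
      d <- usage_distance(usage, metric = metric)
      nmds(d, n_starts = n_starts, seed = derive_seed(seed, 300))
    })
  })
  list(usage = usage, evenness = ev, ordination = ord)
}
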