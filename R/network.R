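# Directed-network structure metrics on the binarized dominance network,
# their randomization nulls, and per-individual position metrics.
#
# Two distinct unreachable-pair conventions are used deliberately:
# closeness assigns unreachable targets a distance of N (the convention of
# the classic sna toolchain), while average path length substitutes the
# maximum finite geodesic (the network diameter).  Both are documented with
# the functions.

binary_graph <- function(binary) {
  igraph::graph_from_adjacency_matrix(binary, mode = "directed")
}

#' Density of a directed dominance network
#'
#' Proportion of the `N (N - 1)` possible directed ties that exist.
#'
#' @param binary binarized sociomatrix from [binarize()].
#' @return density in `[0, 1]`.
#' @export
network_density <- function(binary) {
  check_sociomatrix(binary)
  n <- nrow(binary)
  if (n < 2) stop("density needs at least 2 individuals", call. = FALSE)
  sum(binary) / (n * (n - 1))
}

#' Average directed path length
#'
#' Mean directed geodesic over all ordered pairs, substituting the maximum
#' finite geodesic (the diameter) for unreachable pairs.
#'
#' @inheritParams network_density
#' @return mean path length (>= 1).
#' @export
average_path_length <- function(binary) {
  check_sociomatrix(binary)
  if (sum(binary) == 0) stop("no edges: path length undefined", call. = FALSE)
  d <- igraph::distances(binary_graph(binary), mode = "out")
  off <- d[row(d) != col(d)]
  finite <- off[is.finite(off)]
  if (!length(finite)) stop("no finite directed path", call. = FALSE)
  off[!is.finite(off)] <- max(finite)
  mean(off)
}

#' Freeman degree centralization
#'
#' `sum_i (c_max - c_i) / (N - 1)^2`: the skew of the out- (or in-) degree
#' distribution relative to the directed star, which attains 1.
#'
#' @inheritParams network_density
#' @param mode `"out"` or `"in"`.
#' @return centralization in `[0, 1]`.
#' @export
degree_centralization <- function(binary, mode = c("out", "in")) {
  check_sociomatrix(binary)
  mode <- match.arg(mode)
  n <- nrow(binary)
  if (n < 3) stop("centralization needs at least 3 individuals", call. = FALSE)
  deg <- if (mode == "out") rowSums(binary) else colSums(binary)
  sum(max(deg) - deg) / (n - 1)^2
}

# Closeness with unreachable targets assigned distance N.  d[i, j] is the
# directed geodesic i -> j; out-closeness of i sums over row i, in-closeness
# of i over column i.
closeness_values <- function(binary, mode) {
  n <- nrow(binary)
  d <- igraph::distances(binary_graph(binary), mode = "out")
  d[!is.finite(d)] <- n
  diag(d) <- 0
  unname(if (mode == "out") (n - 1) / rowSums(d) else (n - 1) / colSums(d))
}

#' Freeman closeness centralization
#'
#' Centralization of out- (or in-) closeness, normalized by the
#' centralization that a same-size directed star attains under the identical
#' unreachable-handling convention (unreachable distance := N), so the
#' directed out-star scores exactly 1.
#'
#' @inheritParams degree_centralization
#' @return centralization in `[0, 1]`.
#' @export
closeness_centralization <- function(binary, mode = c("out", "in")) {
  check_sociomatrix(binary)
  mode <- match.arg(mode)
  n <- nrow(binary)
  if (n < 3) stop("centralization needs at least 3 individuals", call. = FALSE)
  clo <- closeness_values(binary, mode)
  star <- matrix(0L, n, n, dimnames = dimnames(binary))
  if (mode == "out") star[1, -1] <- 1L else star[-1, 1] <- 1L
  clo_star <- closeness_values(star, mode)
  sum(max(clo) - clo) / sum(max(clo_star) - clo_star)
}

# Kleinberg hub scores by power iteration on A %*% t(A), scaled to max 1.
hub_scores <- function(binary, tol = 1e-12, max_iter = 10000) {
  n <- nrow(binary)
  if (sum(binary) == 0) return(rep(0, n))
  m <- binary %*% t(binary)
  x <- rep(1, n)
  for (iter in seq_len(max_iter)) {
    x_new <- as.vector(m %*% x)
    nrm <- sqrt(sum(x_new^2))
    if (nrm == 0) return(rep(0, n))
    x_new <- x_new / nrm
    if (max(abs(x_new - x)) < tol) {
      return(x_new / max(x_new))
    }
    x <- x_new
  }
  stop(sprintf("hub-score power iteration did not converge in %d iterations",
               max_iter), call. = FALSE)
}

#' Per-individual network position metrics
#'
#' Out- and in-degree (row and column sums of the binary matrix), out- and
#' in-closeness (`(N-1) / sum of directed distances`, unreachable targets
#' at distance N), and Kleinberg's hub score (principal eigenvector of
#' `A %*% t(A)` via power iteration, scaled so the maximum is 1).  An I&SI
#' ranking can be attached for downstream correlation tables.
#'
#' @inheritParams network_density
#' @param ranking optional [isi_rank()] result; adds an `isi_rank` column.
#' @return data frame, one row per individual.
#' @export
node_metrics <- function(binary, ranking = NULL) {
  check_sociomatrix(binary)
  out <- data.frame(
    id = rownames(binary),
    out_degree = as.integer(rowSums(binary)),
    in_degree = as.integer(colSums(binary)),
    out_closeness = closeness_values(binary, "out"),
    in_closeness = closeness_values(binary, "in"),
    hub_score = hub_scores(binary),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (!is.null(ranking)) out$isi_rank <- unname(ranking$ranks[out$id])
  out
}

assortativity_stat <- function(binary, deg) {
  e <- which(binary == 1, arr.ind = TRUE)
  x <- deg[e[, 1]]
  y <- deg[e[, 2]]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Degree assortativity with a rewiring null
#'
#' Pearson correlation, across directed edges, between the chosen degree
#' (out or in) of the edge's source and target.  Positive values indicate a
#' core-periphery tendency.  Null graphs keep the number of individuals and
#' of dominance relations, resampling which dyads are related and orienting
#' each fair-coin (`null = "rewire"`); a degree-label permutation null is
#' available as `null = "label"`.  p is the add-one proportion of null
#' assortativities at least as large as observed.
#'
#' @inheritParams degree_centralization
#' @param n_rand number of null graphs.
#' @param seed integer seed.
#' @param null `"rewire"` or `"label"`.
#' @return list with `r`, `p`, `n_rand`, `mode`, and `degenerate` (`TRUE`,
#'   with `r = NA` and no p, when the endpoint degrees have zero variance).
#' @export
degree_assortativity <- function(binary, mode = c("out", "in"),
                                 n_rand = 10000, seed = NULL,
                                 null = c("rewire", "label")) {
  check_sociomatrix(binary)
  mode <- match.arg(mode)
  null <- match.arg(null)
  n <- nrow(binary)
  degree_of <- function(b) if (mode == "out") rowSums(b) else colSums(b)
  r <- assortativity_stat(binary, degree_of(binary))
  if (is.na(r)) {
    return(list(r = NA_real_, p = NA_real_, n_rand = 0L, mode = mode,
                degenerate = TRUE))
  }
  m <- sum(binary)
  pairs <- dyad_index(n)
  r_rand <- with_seed(seed, vapply(seq_len(n_rand), function(t) {
    if (null == "rewire") {
      k <- sample.int(nrow(pairs), m)
      flip <- stats::runif(m) < 0.5
      b <- matrix(0L, n, n)
      b[pairs[k, , drop = FALSE][flip, c(2, 1), drop = FALSE]] <- 1L
      b[pairs[k, , drop = FALSE][!flip, , drop = FALSE]] <- 1L
      assortativity_stat(b, degree_of(b))
    } else {
      assortativity_stat(binary, degree_of(binary)[sample.int(n)])
    }
  }, numeric(1)))
  list(r = r, p = mc_pvalue(sum(r_rand >= r, na.rm = TRUE), n_rand),
       n_rand = n_rand, mode = mode, degenerate = FALSE)
}

#' Extreme-degree test against a Bernoulli graph null
#'
#' Compares the observed maximum out-degree and minimum in-degree against
#' random directed Bernoulli graphs with the same number of individuals and
#' density.  In such graphs the N out-degrees (and, separately, the N
#' in-degrees) are independent Binomial(N-1, density) draws, which is how
#' the null is sampled.  Each replicate draws `n_random` graphs;
#' `p_max` is the add-one proportion with maximum out-degree at least the
#' observed one, `p_min` the proportion with minimum in-degree at most the
#' observed one.  The mean and SD over replicates are reported.
#'
#' @inheritParams network_density
#' @param n_random Bernoulli graphs per replicate.
#' @param replicates number of replicates.
#' @param seed integer seed.
#' @return list with `p_max_mean`, `p_max_sd`, `p_min_mean`, `p_min_sd`,
#'   the observed extremes, `n_random`, `replicates`.
#' @export
extreme_degree_test <- function(binary, n_random = 5000, replicates = 20,
                                seed = NULL) {
  check_sociomatrix(binary)
  n <- nrow(binary)
  if (n < 3) stop("extreme-degree test needs at least 3 individuals",
                  call. = FALSE)
  dens <- sum(binary) / (n * (n - 1))
  obs_max_out <- max(rowSums(binary))
  obs_min_in <- min(colSums(binary))
  res <- with_seed(seed, {
    p_max <- p_min <- numeric(replicates)
    for (rep_i in seq_len(replicates)) {
      outdeg <- matrix(stats::rbinom(n_random * n, n - 1, dens), nrow = n_random)
      indeg <- matrix(stats::rbinom(n_random * n, n - 1, dens), nrow = n_random)
      max_out <- apply(outdeg, 1, max)
      min_in <- apply(indeg, 1, min)
      p_max[rep_i] <- mc_pvalue(sum(max_out >= obs_max_out), n_random)
      p_min[rep_i] <- mc_pvalue(sum(min_in <= obs_min_in), n_random)
    }
    list(p_max = p_max, p_min = p_min)
  })
  list(p_max_mean = mean(res$p_max), p_max_sd = stats::sd(res$p_max),
       p_min_mean = mean(res$p_min), p_min_sd = stats::sd(res$p_min),
       max_out_degree = obs_max_out, min_in_degree = obs_min_in,
       n_random = n_random, replicates = replicates)
}

#' Spearman correlations among node measures with Holm adjustment
#'
#' All pairwise Spearman rank correlations among the numeric node metrics
#' and any supplied per-individual covariates (body mass, relative gene
#' expression, ...), with Holm-adjusted p-values.  Constant columns are
#' flagged and excluded.
#'
#' @param metrics data frame from [node_metrics()] (must contain `id`).
#' @param covariates optional data frame with an `id` column and numeric
#'   covariates, matched to `metrics` by id.
#' @return list with matrices `rho`, `p`, `p_holm`, the vector `excluded`,
#'   and `n` (individuals used).
#' @export
correlate_node_measures <- function(metrics, covariates = NULL) {
  stopifnot(is.data.frame(metrics), "id" %in% names(metrics))
  df <- metrics
  if (!is.null(covariates)) {
    stopifnot(is.data.frame(covariates), "id" %in% names(covariates))
    df <- merge(df, covariates, by = "id", sort = FALSE)
  }
  if (nrow(df) < 4) stop("need at least 4 individuals", call. = FALSE)
  num <- df[vapply(df, is.numeric, logical(1))]
  constant <- vapply(num, function(x) stats::sd(x, na.rm = TRUE) == 0, logical(1))
  excluded <- names(num)[constant]
  if (length(excluded)) {
    warning("excluding constant column(s): ", paste(excluded, collapse = ", "),
            call. = FALSE)
    num <- num[!constant]
  }
  k <- ncol(num)
  if (k < 2) stop("fewer than 2 usable measures", call. = FALSE)
  vars <- names(num)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(rho) <- 1
  for (a in seq_len(k - 1)) {
    for (b in seq(a + 1, k)) {
      ct <- suppressWarnings(
        stats::cor.test(num[[a]], num[[b]], method = "spearman", exact = FALSE)
      )
      rho[a, b] <- rho[b, a] <- unname(ct$estimate)
      p[a, b] <- p[b, a] <- ct$p.value
    }
  }
  raw <- p[upper.tri(p)]
  adj <- holm_adjust(raw)
  p_holm <- p
  p_holm[upper.tri(p_holm)] <- adj
  p_holm[lower.tri(p_holm)] <- t(p_holm)[lower.tri(p_holm)]
  list(rho = rho, p = p, p_holm = p_holm, excluded = excluded, n = nrow(df))
}

#' Network-level summary of a binarized dominance network
#'
#' Density, average path length, out-degree and out-closeness
#' centralization, out- and in-degree assortativity with rewiring p-values,
#' and the Bernoulli-graph extreme-degree test.
#'
#' @inheritParams network_density
#' @param n_rand randomizations for the assortativity tests.
#' @param n_random,replicates Bernoulli-graph draws for
#'   [extreme_degree_test()].
#' @param seed integer seed.
#' @return list of the component results.
#' @export
network_summary <- function(binary, n_rand = 10000, n_random = 5000,
                            replicates = 20, seed = NULL) {
  check_sociomatrix(binary)
  list(
    density = network_density(binary),
    average_path_length = average_path_length(binary),
    out_degree_centralization = degree_centralization(binary, "out"),
    out_closeness_centralization = closeness_centralization(binary, "out"),
    assortativity_out = degree_assortativity(binary, "out", n_rand,
                                             seed = derive_seed(seed, 11)),
    assortativity_in = degree_assortativity(binary, "in", n_rand,
                                            seed = derive_seed(seed, 12)),
    extreme_degree = extreme_degree_test(binary, n_random, replicates,
                                         seed = derive_seed(seed, 13))
  )
}
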