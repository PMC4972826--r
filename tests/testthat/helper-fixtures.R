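# Shared fixtures and independent oracles, all built in code.

ids_of <- function(n) sprintf("M%02d", seq_len(n))

named_matrix <- function(x, n) {
  m <- matrix(x, n, n, dimnames = list(ids_of(n), ids_of(n)))
  diag(m) <- if (is.integer(m)) 0L else 0
  m
}

# Perfectly linear dominance: i beats j for all i < j (k wins each).
linear_tournament <- function(n, wins = 1L) {
  m <- named_matrix(0L, n)
  m[upper.tri(m)] <- wins
  m
}

census_from <- function(rows, roster = NULL) {
  df <- as.data.frame(do.call(rbind, lapply(rows, as.list)),
                      stringsAsFactors = FALSE)
  names(df) <- c("day", "timepoint", "vivarium", "id")
  df$day <- as.integer(df$day)
  df$vivarium <- as.integer(df$vivarium)
  census_log(df, roster = roster)
}

tiny_event_log <- function(rows) {
  df <- as.data.frame(do.call(rbind, lapply(rows, as.list)),
                      stringsAsFactors = FALSE)
  names(df) <- c("day", "winner", "loser", "vivarium")
  df$day <- as.integer(df$day)
  df$vivarium <- as.integer(df$vivarium)
  event_log(df)
}

# Random binarized dominance matrix: each dyad related with prob p_rel,
# orientation fair-coin.
random_binary <- function(n, p_rel = 0.7) {
  b <- named_matrix(0L, n)
  idx <- which(upper.tri(b), arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    if (runif(1) < p_rel) {
      if (runif(1) < 0.5) {
        b[idx[k, 1], idx[k, 2]] <- 1L
      } else {
        b[idx[k, 2], idx[k, 1]] <- 1L
      }
    }
  }
  b
}

# --- independent oracles -------------------------------------------------

# Exhaustive I&SI minimum over all orderings (n <= 7).
brute_isi <- function(b) {
  n <- nrow(b)
  perms <- permutations_of(n)
  best <- c(Inf, Inf)
  for (i in seq_len(nrow(perms))) {
    ord <- perms[i, ]
    bo <- b[ord, ord]
    low <- which(lower.tri(bo) & bo == 1, arr.ind = TRUE)
    cost <- c(nrow(low), if (nrow(low)) sum(low[, 1] - low[, 2]) else 0)
    if (cost[1] < best[1] || (cost[1] == best[1] && cost[2] < best[2])) {
      best <- cost
    }
  }
  best
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

# All set partitions of n items as restricted-growth strings.
set_partitions <- function(n) {
  out <- list()
  recur <- function(prefix, maxv) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxv + 1L)) {
      recur(c(prefix, v), max(maxv, v))
    }
  }
  recur(1L, 1L)
  do.call(rbind, out)
}

# Direct weighted-modularity evaluation (the formula, nothing shared with
# the implementation path).
q_oracle <- function(s, membership) {
  m2 <- sum(s)
  k <- rowSums(s)
  tot <- 0
  for (i in seq_len(nrow(s))) {
    for (j in seq_len(ncol(s))) {
      if (membership[i] == membership[j]) {
        tot <- tot + s[i, j] - k[i] * k[j] / m2
      }
    }
  }
  unname(tot / m2)
}

# Kruskal stress-1 of a configuration against a dissimilarity matrix,
# with the monotone fit via isotonic regression on the dissimilarity order.
stress1_oracle <- function(coords, d) {
  lowd <- d[lower.tri(d)]
  conf <- as.matrix(dist(coords))[lower.tri(d)]
  ord <- order(lowd)
  fit <- numeric(length(conf))
  fit[ord] <- isoreg(conf[ord])$yf
  sqrt(sum((conf - fit)^2) / sum(conf^2))
}

# Adjusted Rand index between two label vectors (mclust's definition).
ari_oracle <- function(a, b) mclust::adjustedRandIndex(a, b)

expect_valid_p <- function(p) {
  expect_true(is.numeric(p) && p > 0 && p <= 1)
}
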