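# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so library functions never
#' perturb user-level randomness.  A `NULL` seed leaves the RNG stream alone.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a reproducible sub-seed from a base seed; keeps results stable when
# stages are added because each stage owns a fixed offset.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 31L + offset * 7919) %% 2147483647)
}

#' Monte-Carlo p-value with add-one correction
#'
#' `(1 + n_extreme) / (1 + n_rand)`, so a finite randomization never returns
#' an exact zero.
#' @noRd
mc_pvalue <- function(n_extreme, n_rand) (1 + n_extreme) / (1 + n_rand)

# Indices of the unordered dyads (upper triangle, column-major) of an N x N
# matrix, as a two-column matrix of (i, j) with i < j.
dyad_index <- function(n) {
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}

# Validate a square matrix carrying a roster in its dimnames.
check_sociomatrix <- function(m, name = deparse(substitute(m))) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(sprintf("'%s' must be a square matrix", name), call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop(sprintf("'%s' must carry roster ids as dimnames", name), call. = FALSE)
  }
  if (!identical(rownames(m), colnames(m))) {
    stop(sprintf("row and column roster of '%s' differ", name), call. = FALSE)
  }
  invisible(m)
}

#' Holm step-down adjustment of p-values
#'
#' Sort ascending, multiply the k-th smallest by `m - k + 1`, enforce
#' monotonicity, cap at 1.  Equivalent to `stats::p.adjust(method = "holm")`;
#' kept explicit because several reported tables depend on it.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the original order.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.02, 0.04))
holm_adjust <- function(p) {
  stopifnot(is.numeric(p), all(is.na(p) | (p >= 0 & p <= 1)))
  m <- sum(!is.na(p))
  ord <- order(p, na.last = TRUE)
  adj <- rep(NA_real_, length(p))
  running <- 0
  for (k in seq_len(m)) {
    val <- (m - k + 1) * p[ord[k]]
    running <- max(running, val)
    adj[ord[k]] <- min(1, running)
  }
  adj
}
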