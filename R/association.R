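# Half-weight association indices from census data, and the two
# matrix-level tests linking association to community structure.

#' Half-weight association index matrix
#'
#' For each unordered dyad (A, B), over all census periods:
#' `x` = periods where both were identified in the same vivarium,
#' `yAB` = periods where both were identified but in different vivaria,
#' `yA` / `yB` = periods where only one of the two was identified.  Then
#' `HWI = x / (x + yAB + 0.5 * (yA + yB))`, in `[0, 1]`.  Individuals not
#' sighted in a period contribute to none of the counts for that period —
#' the half-weight denominator is the standard correction for such partial
#' observability.  Dyads with a zero denominator (neither ever identified)
#' are `NA` and flagged via the `"undefined"` attribute.
#'
#' @param census a [census_log()].
#' @return symmetric matrix of association indices with `NA` diagonal;
#'   attributes `"x"`, `"yAB"`, `"y_only"` carry the count matrices and
#'   `"undefined"` the flagged dyad indicator.
#' @export
hwi_matrix <- function(census) {
  stopifnot(inherits(census, "census_log"))
  roster <- census$roster
  n <- length(roster)
  if (!length(census$periods)) stop("census has no periods", call. = FALSE)
  x <- yab <- y_only <- matrix(0, n, n, dimnames = list(roster, roster))
  sg <- census$sightings
  period <- paste(sg$day, sg$timepoint, sep = ":")
  for (per in unique(period)) {
    rows <- sg[period == per, , drop = FALSE]
    seen <- as.numeric(roster %in% rows$id)
    viv <- rep(NA_integer_, n)
    viv[match(rows$id, roster)] <- as.integer(rows$vivarium)
    both <- outer(seen, seen)
    same_viv <- outer(viv, viv, "==")
    same_viv[is.na(same_viv)] <- FALSE
    x <- x + both * same_viv
    yab <- yab + both * !same_viv
    y_only <- y_only + outer(seen, 1 - seen) + outer(1 - seen, seen)
  }
  denom <- x + yab + 0.5 * y_only
  hwi <- x / denom
  undefined <- denom == 0
  hwi[undefined] <- NA_real_
  diag(hwi) <- NA_real_
  diag(undefined) <- FALSE
  attr(hwi, "x") <- x
  attr(hwi, "yAB") <- yab
  attr(hwi, "y_only") <- y_only
  attr(hwi, "undefined") <- undefined
  hwi
}

# Upper-triangle vector of a symmetric matrix, dropping the diagonal.
ut_vector <- function(m) m[upper.tri(m)]

#' Mantel test between two symmetric matrices
#'
#' Correlation of the off-diagonal upper triangles, with significance from
#' jointly permuting rows and columns of the second matrix.  The p-value is
#' two-sided on the correlation magnitude with the add-one correction:
#' `(1 + #{|r_perm| >= |r_obs|}) / (1 + n_perm)`.
#'
#' @param m1,m2 symmetric matrices over the same roster.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `r`, `p`, `n_perm`, `method`.
#' @export
mantel_test <- function(m1, m2, n_perm = 1000, seed = NULL,
                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  check_sociomatrix(m1)
  check_sociomatrix(m2)
  if (!identical(dim(m1), dim(m2))) stop("matrix shapes differ", call. = FALSE)
  if (!identical(rownames(m1), rownames(m2))) {
    stop("matrices must share a roster order", call. = FALSE)
  }
  v1 <- ut_vector(m1)
  v2 <- ut_vector(m2)
  ok <- stats::complete.cases(v1, v2)
  if (stats::sd(v1[ok]) == 0 || stats::sd(v2[ok]) == 0) {
    stop("constant matrix: Mantel correlation undefined", call. = FALSE)
  }
  r <- stats::cor(v1[ok], v2[ok], method = method)
  n <- nrow(m1)
  r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(t) {
    p <- sample.int(n)
    vp <- ut_vector(m2[p, p])
    okp <- stats::complete.cases(v1, vp)
    if (stats::sd(vp[okp]) == 0) return(NA_real_)
    stats::cor(v1[okp], vp[okp], method = method)
  }, numeric(1)))
  list(r = r, p = mc_pvalue(sum(abs(r_perm) >= abs(r), na.rm = TRUE), n_perm),
       n_perm = n_perm, method = method)
}

#' Within- versus between-community association test
#'
#' Observed statistic: median of within-community association indices minus
#' the median of between-community indices.  The null permutes community
#' labels over individuals; p is the add-one proportion of permuted
#' statistics at least as large as observed.  Per-community within medians
#' are reported alongside.
#'
#' @param hwi association matrix from [hwi_matrix()].
#' @param communities a `community_result` (or named membership vector);
#'   individuals labelled `"unassigned"` are ignored.
#' @param n_rand number of label permutations.
#' @param seed integer seed.
#' @return list with `median_within` (named, per community),
#'   `median_within_all`, `median_between`, `statistic`, `p`, `n_rand`.
#' @export
within_between_test <- function(hwi, communities, n_rand = 10000, seed = NULL) {
  check_sociomatrix(hwi)
  memb <- if (inherits(communities, "community_result")) {
    communities$membership
  } else {
    communities
  }
  memb <- memb[rownames(hwi)]
  keep <- !is.na(memb) & memb != "unassigned"
  labels <- memb[keep]
  if (length(unique(labels)) < 2 || any(table(labels) < 2)) {
    stop("need at least 2 communities with at least 2 members each",
         call. = FALSE)
  }
  sub <- hwi[keep, keep, drop = FALSE]
  stat_of <- function(lab) {
    same <- outer(lab, lab, "==")
    w <- sub[upper.tri(sub) & same]
    b <- sub[upper.tri(sub) & !same]
    stats::median(w, na.rm = TRUE) - stats::median(b, na.rm = TRUE)
  }
  observed <- stat_of(labels)
  med_within <- vapply(sort(unique(labels)), function(grp) {
    block <- sub[labels == grp, labels == grp, drop = FALSE]
    stats::median(block[upper.tri(block)], na.rm = TRUE)
  }, numeric(1))
  same <- outer(labels, labels, "==")
  med_within_all <- stats::median(sub[upper.tri(sub) & same], na.rm = TRUE)
  med_between <- stats::median(sub[upper.tri(sub) & !same], na.rm = TRUE)
  stat_rand <- with_seed(seed, vapply(seq_len(n_rand), function(t) {
    stat_of(sample(labels))
  }, numeric(1)))
  list(median_within = med_within, median_within_all = med_within_all,
       median_between = med_between, statistic = observed,
       p = mc_pvalue(sum(stat_rand >= observed, na.rm = TRUE), n_rand),
       n_rand = n_rand)
}
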