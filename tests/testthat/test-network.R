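test_that("density and average path length match hand enumeration", {
  expect_equal(network_density(named_matrix(0L, 4)), 0)
  expect_equal(network_density(binarize(linear_tournament(4))), 0.5)

  complete <- named_matrix(1L, 3)
  expect_equal(average_path_length(complete), 1)

  path <- named_matrix(0L, 3)
  path["M01", "M02"] <- 1L; path["M02", "M03"] <- 1L
  # finite: 1, 2, 1; unreachable pairs take the diameter 2
  expect_equal(average_path_length(path), 5 / 3)

  # strongly connected: substitution never triggers, equals plain mean
  cyc <- named_matrix(0L, 4)
  cyc["M01", "M02"] <- cyc["M02", "M03"] <- cyc["M03", "M04"] <-
    cyc["M04", "M01"] <- 1L
  d <- igraph::distances(igraph::graph_from_adjacency_matrix(cyc), mode = "out")
  expect_equal(average_path_length(cyc), mean(d[row(d) != col(d)]))
})

test_that("degree centralization is 1 for the out-star and 0 when regular", {
  star <- named_matrix(0L, 5)
  star["M01", -1] <- 1L
  expect_equal(degree_centralization(star, "out"), 1)

  cyc3 <- named_matrix(0L, 3)
  cyc3["M01", "M02"] <- cyc3["M02", "M03"] <- cyc3["M03", "M01"] <- 1L
  expect_equal(degree_centralization(cyc3, "out"), 0)

  set.seed(23)
  b <- random_binary(4)
  deg <- rowSums(b)
  expect_equal(degree_centralization(b, "out"),
               sum(max(deg) - deg) / (4 - 1)^2)
})

test_that("closeness centralization is normalized to the directed star", {
  star <- named_matrix(0L, 6)
  star["M01", -1] <- 1L
  expect_equal(closeness_centralization(star, "out"), 1)

  cyc3 <- named_matrix(0L, 3)
  cyc3["M01", "M02"] <- cyc3["M02", "M03"] <- cyc3["M03", "M01"] <- 1L
  expect_equal(closeness_centralization(cyc3, "out"), 0)

  set.seed(29)
  b <- random_binary(5)
  n <- 5
  d <- igraph::distances(igraph::graph_from_adjacency_matrix(b), mode = "out")
  d[!is.finite(d)] <- n
  diag(d) <- 0
  clo <- (n - 1) / rowSums(d)
  star_clo <- c(1, rep(1 / n, n - 1))
  expect_equal(closeness_centralization(b, "out"),
               sum(max(clo) - clo) / sum(max(star_clo) - star_clo))
})

test_that("node metrics follow their closed-form conventions", {
  src <- named_matrix(0L, 5)
  src["M01", -1] <- 1L
  nm <- node_metrics(src)
  expect_equal(nm$hub_score, c(1, 0, 0, 0, 0))
  expect_identical(nm$out_degree, c(4L, 0L, 0L, 0L, 0L))
  expect_equal(nm$out_closeness[1], 1)
  expect_equal(nm$in_closeness[1], 4 / (4 * 5))

  tour <- binarize(linear_tournament(6))
  r <- isi_rank(tour, n_restarts = 2, seed = 1)
  nm2 <- node_metrics(tour, ranking = r)
  expect_true(all(diff(nm2$out_degree[order(nm2$isi_rank)]) < 0))
})

test_that("hub scores match a full eigendecomposition to 1e-8", {
  set.seed(41)
  for (rep in 1:10) {
    b <- random_binary(5, p_rel = 0.8)
    if (sum(b) == 0) next
    hub <- node_metrics(b)$hub_score
    ev <- eigen(b %*% t(b), symmetric = TRUE)$vectors[, 1]
    ev <- abs(ev) / max(abs(ev))
    expect_equal(hub, ev, tolerance = 1e-8)
  }
})

test_that("node metrics are equivariant under roster permutation", {
  set.seed(47)
  b <- random_binary(6)
  perm <- sample.int(6)
  bp <- b[perm, perm]
  nm <- node_metrics(b)
  nmp <- node_metrics(bp)
  reord <- match(nm$id[perm], nmp$id)
  expect_equal(nmp$out_closeness[reord], nm$out_closeness[perm])
  expect_equal(nmp$hub_score[reord], nm$hub_score[perm])
  expect_identical(nmp$in_degree[reord], nm$in_degree[perm])
})

test_that("assortativity matches the direct edge correlation and flags
           degenerate degree distributions", {
  cyc3 <- named_matrix(0L, 3)
  cyc3["M01", "M02"] <- cyc3["M02", "M03"] <- cyc3["M03", "M01"] <- 1L
  res <- degree_assortativity(cyc3, "out", n_rand = 20, seed = 1)
  expect_true(res$degenerate)
  expect_true(is.na(res$r))

  # two high-out-degree nodes tied to each other, low-degree chain apart
  b <- named_matrix(0L, 6)
  b["M01", c("M02", "M03", "M04")] <- 1L
  b["M02", c("M01", "M05", "M06")] <- 0L
  b["M02", "M01"] <- 0L
  b["M02", c("M05", "M06")] <- 1L
  b["M01", "M02"] <- 1L
  b["M05", "M06"] <- 1L
  e <- which(b == 1, arr.ind = TRUE)
  deg <- rowSums(b)
  oracle <- cor(deg[e[, 1]], deg[e[, 2]])
  got <- degree_assortativity(b, "out", n_rand = 50, seed = 2)
  expect_equal(got$r, oracle)
  expect_valid_p(got$p)
})

test_that("the extreme-degree test agrees with the exact Bernoulli tail", {
  set.seed(53)
  b <- random_binary(4, p_rel = 0.9)
  dens <- sum(b) / 12
  res <- extreme_degree_test(b, n_random = 4000, replicates = 2, seed = 3)
  # exact: out-degrees are iid Binomial(3, dens)
  p_max_exact <- 1 - pbinom(max(rowSums(b)) - 1, 3, dens)^4
  p_exact <- 1 - (1 - p_max_exact)  # tail prob that max >= observed
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(res$p_max_mean - p_exact), 3 * se + 1 / 4000)

  p_min_exact <- 1 - (1 - pbinom(min(colSums(b)), 3, dens))^4
  se_min <- sqrt(p_min_exact * (1 - p_min_exact) / 4000)
  expect_lt(abs(res$p_min_mean - p_min_exact), 3 * se_min + 1 / 4000)
})

test_that("a maximal out-degree in a sparse network is highly significant", {
  b <- named_matrix(0L, 10)
  b["M01", -1] <- 1L
  res <- extreme_degree_test(b, n_random = 2000, replicates = 2, seed = 5)
  expect_lt(res$p_max_mean, 0.01)
})

test_that("Spearman tables carry Holm-adjusted p-values and drop constants", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  set.seed(59)
  p <- runif(12)
  expect_equal(holm_adjust(p), p.adjust(p, method = "holm"))

  b <- binarize(linear_tournament(6))
  nm <- node_metrics(b)
  res <- correlate_node_measures(nm)
  expect_equal(res$rho["out_degree", "in_degree"], -1)
  expect_equal(unname(diag(res$rho)), rep(1, nrow(res$rho)))

  nm$flat <- 1
  expect_warning(res2 <- correlate_node_measures(nm), "constant")
  expect_identical(res2$excluded, "flat")

  cov <- data.frame(id = nm$id, expr = seq_len(6))
  res3 <- correlate_node_measures(nm[, c("id", "out_degree", "in_degree")],
                                  covariates = cov)
  expect_true("expr" %in% rownames(res3$rho))
  expect_equal(res3$rho["expr", "out_degree"], -1)
})
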