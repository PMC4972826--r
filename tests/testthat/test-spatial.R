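test_that("location usage counts wins and losses where they happened", {
  log <- tiny_event_log(list(c(1, "A", "B", 2)))
  u <- location_usage(log)
  expect_identical(u$given["A", "V2"], 1L)
  expect_identical(u$received["B", "V2"], 1L)
  expect_identical(sum(u$given), 1L)

  col <- simulate_colony(sim_config(seed = 13))
  u2 <- location_usage(col$events)
  f <- frequency_matrix(col$events)
  expect_identical(unname(rowSums(u2$given)), unname(rowSums(f)))
  expect_identical(unname(rowSums(u2$received)), unname(colSums(f)))
})

test_that("with perfect fidelity a community never acts outside its
           territory", {
  col <- simulate_colony(sim_config(N = 12, community_sizes = c(7, 5),
                                    phi = 1, n_events = 400, seed = 17))
  u <- location_usage(col$events)
  a_ids <- names(col$truth$community)[col$truth$community == "A"]
  expect_identical(sum(u$given[a_ids, c("V3", "V4")]), 0L)
  expect_identical(sum(u$received[a_ids, c("V3", "V4")]), 0L)
})

test_that("events with missing locations are dropped with a warning or
           rejected", {
  ev <- data.frame(day = c(1, 2), winner = c("A", "B"), loser = c("B", "A"),
                   vivarium = c(1, NA))
  log <- event_log(ev[1, ], roster = c("A", "B"))
  log$events <- rbind(log$events, data.frame(day = 2, winner = "B",
                                             loser = "A", behavior = "x",
                                             vivarium = NA, zone = NA))
  expect_warning(u <- location_usage(log), "missing vivarium")
  expect_identical(sum(u$given), 1L)
  expect_error(location_usage(log, missing = "error"), "missing vivarium")
})

test_that("Shannon evenness matches hand-evaluated entropies", {
  expect_equal(shannon_evenness(c(5, 5, 5, 5)), 1)
  expect_equal(shannon_evenness(c(0, 9, 0)), 0)
  expect_equal(shannon_evenness(c(2, 2, 4)), 0.9464, tolerance = 1e-4)
  expect_true(is.na(shannon_evenness(c(0, 0))))
  # invariant under permutation of locations
  expect_equal(shannon_evenness(c(1, 7, 2, 5)), shannon_evenness(c(7, 5, 1, 2)))
})

test_that("the unevenness test flags concentration and degrades gracefully", {
  res <- evenness_significance(c(40, 0, 0, 0), n_rand = 3000, seed = 3)
  expect_lt(res$p, 0.001)
  expect_equal(res$J, 0)

  single <- evenness_significance(c(1, 0, 0, 0), n_rand = 200, seed = 4)
  expect_equal(single$p, 1)
})

test_that("usage distances behave like count-composition distances", {
  given <- matrix(c(2, 0, 2, 0,
                    0, 3, 2, 0), 4, 2,
                  dimnames = list(ids_of(4), c("V1", "V2")))
  u <- structure(list(given = given,
                      received = matrix(0L, 4, 2,
                                        dimnames = dimnames(given)),
                      total = given), class = "location_usage")
  # profiles: M01 = (2,0), M02 = (0,3), M03 = (2,2), M04 = (0,0)
  expect_warning(d <- usage_distance(u), "no located interactions")
  expect_identical(attr(d, "excluded"), "M04")
  expect_equal(unname(d["M01", "M02"]), 1)          # disjoint support
  expect_equal(unname(d["M01", "M03"]), 1 / 3)      # (0 + 2) / 6
  de <- usage_distance(structure(list(given = given[1:3, ],
                                      received = 0L * given[1:3, ],
                                      total = given[1:3, ]),
                                 class = "location_usage"),
                       metric = "euclidean")
  expect_equal(unname(de["M01", "M02"]), sqrt(13))
})

test_that("nMDS recovers a planar configuration and matches a brute-force
           stress optimizer", {
  set.seed(79)
  pts <- matrix(rnorm(16), 8, 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(ids_of(8), ids_of(8))
  ord <- nmds(d, n_starts = 5, seed = 5)
  expect_lt(ord$stress, 1e-4)
  expect_equal(unname(colMeans(ord$points)), c(0, 0), tolerance = 1e-8)
  proc <- vegan::procrustes(pts, ord$points, symmetric = TRUE)
  expect_lt(proc$ss, 1e-3)

  # 4-point fixture against a multi-start Nelder-Mead oracle
  set.seed(83)
  d4 <- as.matrix(dist(matrix(runif(8), 4, 2)))
  d4 <- d4 + as.matrix(dist(matrix(runif(8), 4, 2)))  # non-Euclidean mix
  dimnames(d4) <- list(ids_of(4), ids_of(4))
  fit <- nmds(d4, n_starts = 10, seed = 6)
  objective <- function(par) stress1_oracle(matrix(par, 4, 2), d4)
  best <- Inf
  for (tries in 1:30) {
    res <- optim(rnorm(8), objective, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, res$value)
  }
  expect_lt(abs(fit$stress - best), 1e-3)

  # final stress never exceeds the metric-scaling initialization's stress
  init <- cmdscale(as.dist(d4), k = 2)
  expect_lte(fit$stress, stress1_oracle(init, d4) + 1e-10)
})

test_that("the spatial summary ties usage, evenness, and ordination
           together", {
  col <- simulate_colony(sim_config(N = 12, community_sizes = c(7, 5),
                                    n_events = 300, seed = 19))
  sp <- spatial_summary(col$events, n_rand = 100, n_starts = 3, seed = 7)
  expect_identical(nrow(sp$evenness), 12L)
  expect_true(all(sp$evenness$J_given >= 0 & sp$evenness$J_given <= 1,
                  na.rm = TRUE))
  expect_false(is.null(sp$ordination))
  expect_identical(ncol(sp$ordination$points), 2L)
})
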