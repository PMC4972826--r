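test_that("directional consistency matches hand-evaluated fixtures", {
  # dyads (3,1) and (5,0): DC = (2 + 5) / (4 + 5) = 7/9
  f <- named_matrix(0L, 3)
  f["M01", "M02"] <- 3L; f["M02", "M01"] <- 1L
  f["M01", "M03"] <- 5L
  dc <- directional_consistency(f, n_rand = 200, seed = 1)
  expect_equal(dc$dc, 7 / 9)
  expect_valid_p(dc$p)

  one_way <- linear_tournament(4, wins = 3L)
  expect_equal(directional_consistency(one_way, n_rand = 50, seed = 1)$dc, 1)

  split <- named_matrix(2L, 3)  # every dyad split 2-2
  expect_equal(directional_consistency(split, n_rand = 50, seed = 1)$dc, 0)

  expect_error(directional_consistency(named_matrix(0L, 3), n_rand = 10),
               "no interactions")
})

test_that("David's scores reproduce the linear fixture and conserve to zero", {
  m <- linear_tournament(3)
  ds <- david_scores(m)
  expect_equal(ds$DS, c(3, 0, -3))
  expect_equal(ds$NormDS, c(2, 1, 0))

  even <- named_matrix(2L, 4)  # all dyads 50/50
  expect_equal(david_scores(even)$DS, rep(0, 4))

  set.seed(31)
  for (rep in 1:10) {
    f <- named_matrix(rpois(49, 2), 7)
    expect_equal(sum(david_scores(f)$DS), 0, tolerance = 1e-10)
    expect_equal(sum(david_scores(f, dyadic = "Dij")$DS), 0, tolerance = 1e-10)
  }
})

test_that("steepness is 1 for a despotic linear hierarchy and 0 for ties", {
  st <- steepness(linear_tournament(3), n_rand = 100, seed = 2)
  expect_equal(st$steepness, 1)
  expect_valid_p(st$p)
  expect_equal(steepness(named_matrix(2L, 4), n_rand = 50, seed = 1)$steepness, 0)
})

test_that("h' is 1 for a known linear order and matches the imputation
           oracle with one unknown dyad", {
  lin <- linear_tournament(4)
  h <- landau_h_prime(lin, n_rand = 100, seed = 3)
  expect_equal(h$h_prime, 1)
  expect_identical(h$n_unknown, 0L)
  expect_valid_p(h$p)

  # remove the M02-M03 relation: exact h' = mean of h over both imputations
  unk <- lin
  unk["M02", "M03"] <- 0L
  h_of <- function(v) 12 / (4^3 - 4) * sum((v - 3 / 2)^2)
  # imputation 1: M02 beats M03 -> V = (3,2,1,0); imputation 2 -> V = (3,1,2,0)
  oracle <- mean(c(h_of(c(3, 2, 1, 0)), h_of(c(3, 1, 2, 0))))
  got <- landau_h_prime(unk, n_rand = 100, seed = 3)
  expect_equal(got$h_prime, oracle)
  expect_identical(got$n_unknown, 1L)
})

test_that("h' treats tied dyads as undecided and flags them separately", {
  f <- linear_tournament(4, wins = 2L)
  f["M02", "M03"] <- 2L; f["M03", "M02"] <- 2L
  h <- landau_h_prime(f, n_rand = 50, seed = 1)
  expect_identical(h$n_tied, 1L)
  expect_identical(h$n_unknown, 0L)
  # same undecided structure as the unknown-dyad case: identical h'
  unk <- linear_tournament(4)
  unk["M02", "M03"] <- 0L
  expect_equal(h$h_prime, landau_h_prime(unk, n_rand = 50, seed = 1)$h_prime)
})

test_that("triangle transitivity handles tournaments, cycles, and scaling", {
  tour <- binarize(linear_tournament(5))
  tt <- triangle_transitivity(tour, n_rand = 100, seed = 4)
  expect_equal(tt$pt, 1)
  expect_equal(tt$t_tri, 1)
  expect_identical(tt$n_complete_triads, choose(5, 3))

  cyc <- named_matrix(0L, 3)
  cyc["M01", "M02"] <- 1L; cyc["M02", "M03"] <- 1L; cyc["M03", "M01"] <- 1L
  tc <- triangle_transitivity(cyc, n_rand = 100, seed = 4)
  expect_equal(tc$pt, 0)
  expect_equal(tc$t_tri, -3)

  expect_equal(ttri_scale(1), 1)
  expect_equal(ttri_scale(0.75), 0)
  expect_error(triangle_transitivity(named_matrix(0L, 4), n_rand = 10),
               "no complete triads")
})

test_that("the I&SI ranking solves small cases exactly", {
  tour <- binarize(linear_tournament(5))
  shuffled <- tour[c(3, 1, 5, 2, 4), c(3, 1, 5, 2, 4)]
  r <- isi_rank(shuffled, n_restarts = 3, seed = 5)
  expect_identical(r$I, 0L)
  expect_identical(r$SI, 0L)
  expect_identical(r$ordering, ids_of(5))

  # planted single reversal: exhaustive oracle over all 120 orderings
  rev1 <- binarize(linear_tournament(5))
  rev1["M01", "M04"] <- 0L
  rev1["M04", "M01"] <- 1L
  opt <- brute_isi(rev1)
  got <- isi_rank(rev1, n_restarts = 5, seed = 6)
  expect_identical(c(got$I, got$SI), as.integer(opt))

  zero <- named_matrix(0L, 4)
  z <- isi_rank(zero, n_restarts = 2, seed = 1)
  expect_identical(z$I, 0L)
  expect_match(z$note, "no relations")
})

test_that("the I&SI heuristic never does worse than its David's-score start", {
  set.seed(17)
  for (rep in 1:15) {
    b <- random_binary(7, p_rel = 0.8)
    ds_ord <- order(david_scores(b)$DS, decreasing = TRUE)
    start_cost <- colonynet:::isi_cost(b, ds_ord)
    r <- isi_rank(b, n_restarts = 3, seed = rep)
    expect_true(r$I < start_cost[1] ||
                  (r$I == start_cost[1] && r$SI <= start_cost[2]))
  }
})

test_that("randomization p-values are never zero and at most one", {
  col <- null_colony(N = 8, n_events = 120, seed = 13)
  f <- frequency_matrix(col$events)
  expect_valid_p(directional_consistency(f, n_rand = 30, seed = 1)$p)
  expect_valid_p(landau_h_prime(f, n_rand = 30, seed = 1)$p)
  expect_valid_p(steepness(f, n_rand = 30, seed = 1)$p)
  expect_valid_p(triangle_transitivity(binarize(f), n_rand = 30, seed = 1)$p)
})
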