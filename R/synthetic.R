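# Synthetic colony generator.  Plants the statistical structure the
# downstream analyses assume — a steep near-linear dominance hierarchy, two
# spatially segregated communities of unequal size plus a small set of
# "floater" individuals, and census sightings correlated with community
# membership — so every pipeline stage is testable without external data.
#
# Agonistic interactions require co-location, so a dyad's interaction
# opportunity is the product of the social within-community bias `w` and
# the probability that the two animals share a territory, which follows
# from the location fidelity `phi`: same community phi^2 + (1-phi)^2,
# different communities 2 phi (1-phi), and 1/2 whenever a floater is
# involved (floaters split their time evenly across both territories).

#' Configuration for the synthetic colony generator
#'
#' Defaults emulate a 30-male colony observed over 19 days: 1230 agonistic
#' events, communities of 19 and 8 individuals with 3 floaters, three census
#' time points per day.  Winners are drawn from a Bradley-Terry-style
#' logistic contest model on evenly spaced latent dominance scores.
#'
#' @param N group size.
#' @param community_sizes sizes of 2 territorial communities, optionally
#'   followed by a third count of floaters; must sum to `N`.
#' @param sigma_d total spread of the evenly spaced latent dominance scores
#'   (logit units); larger values steepen the hierarchy.
#' @param beta contest steepness: individual `i` beats `j` with probability
#'   `plogis(beta * (d_i - d_j))`.
#' @param w within-community social bias (>= 1): over and above co-location,
#'   same-community pairs are `w` times as likely to interact as other pairs.
#' @param phi location fidelity in `[0.5, 1]`: probability that a community
#'   member is found in its home vivarium pair (community A: vivaria 1-2;
#'   community B: vivaria 3-4).  Floaters split their time evenly across
#'   both territories.  `phi` also sets each dyad's co-location probability
#'   and hence its interaction opportunity.
#' @param p_sight probability an individual is identified in a census period.
#' @param n_events total number of agonistic events.
#' @param n_days observation days.
#' @param censuses_per_day census time points per day.
#' @param behaviors ethogram labels sampled for events.
#' @param seed integer seed; generation is deterministic given the config.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(N = 30, community_sizes = c(19, 8, 3), sigma_d = 2,
                       beta = 3, w = 5, phi = 0.9, p_sight = 0.8,
                       n_events = 1230, n_days = 19, censuses_per_day = 3,
                       behaviors = c("fighting", "chasing", "mounting"),
                       seed = 1) {
  cfg <- list(N = as.integer(N), community_sizes = as.integer(community_sizes),
              sigma_d = sigma_d, beta = beta, w = w, phi = phi,
              p_sight = p_sight, n_events = as.integer(n_events),
              n_days = as.integer(n_days),
              censuses_per_day = as.integer(censuses_per_day),
              behaviors = behaviors, seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (N < 2) stop("N must be at least 2", call. = FALSE)
    if (!length(community_sizes) %in% c(2L, 3L)) {
      stop("community_sizes must give 2 communities plus an optional floater count",
           call. = FALSE)
    }
    if (sum(community_sizes) != N) {
      stop("community sizes must sum to N", call. = FALSE)
    }
    if (any(community_sizes[1:2] < 1)) {
      stop("both territorial communities need at least one member", call. = FALSE)
    }
    if (beta < 0) stop("beta must be >= 0", call. = FALSE)
    if (w < 1) stop("w must be >= 1", call. = FALSE)
    if (phi < 0.5 || phi > 1) stop("phi must lie in [0.5, 1]", call. = FALSE)
    if (p_sight <= 0 || p_sight > 1) stop("p_sight must lie in (0, 1]", call. = FALSE)
    if (n_events < 1) stop("n_events must be positive", call. = FALSE)
    if (n_days < 1 || censuses_per_day < 1) {
      stop("n_days and censuses_per_day must be positive", call. = FALSE)
    }
  })
  invisible(cfg)
}

home_pair <- function(community) {
  switch(community, A = c(1L, 2L), B = c(3L, 4L), c(NA_integer_, NA_integer_))
}

#' Simulate a structured colony
#'
#' Events are generated by repeated draws: an unordered dyad is chosen with
#' probability proportional to its social bias (`w` when both members share
#' a territorial community, 1 otherwise) times its co-location probability
#' under the fidelity `phi` (see the model note below); the winner follows
#' the logistic contest model; the event's vivarium is drawn from the
#' conditional territory distribution given that the pair is co-located
#' (same-community pairs fight in their home territory with probability
#' `phi^2 / (phi^2 + (1-phi)^2)`, mixed community pairs fair-coin,
#' community-floater pairs in the community's home with probability `phi`).
#' Censuses identify each individual with probability `p_sight` and place
#' it in its home territory with probability `phi`; floaters coin-flip a
#' territory per sighting.
#'
#' @param config a [sim_config()].
#' @return list of class `synthetic_colony` with elements `events`
#'   ([event_log()]), `census` ([census_log()]), and `truth` (planted
#'   community labels, dominance order, and latent scores).
#' @export
simulate_colony <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(config$seed, simulate_colony_impl(config))
}

# Probability two individuals share a territory, given their communities
# and the location fidelity phi.  Floaters split time evenly, so any dyad
# involving a floater co-locates with probability 1/2.
colocation_prob <- function(ci, cj, phi) {
  ifelse(ci == "floater" | cj == "floater", 0.5,
         ifelse(ci == cj, phi^2 + (1 - phi)^2, 2 * phi * (1 - phi)))
}

simulate_colony_impl <- function(cfg) {
  N <- cfg$N
  ids <- sprintf("M%02d", seq_len(N))
  sizes <- cfg$community_sizes
  groups <- c("A", "B", "floater")[seq_along(sizes)]
  community <- sample(rep(groups, sizes))
  names(community) <- ids
  d <- seq(cfg$sigma_d / 2, -cfg$sigma_d / 2, length.out = N)[sample.int(N)]
  names(d) <- ids

  pairs <- dyad_index(N)
  ci <- community[pairs[, 1]]
  cj <- community[pairs[, 2]]
  same_comm <- ci == cj & ci != "floater"
  dyad_w <- ifelse(same_comm, cfg$w, 1) * colocation_prob(ci, cj, cfg$phi)

  k <- sample.int(nrow(pairs), cfg$n_events, replace = TRUE, prob = dyad_w)
  a <- pairs[k, 1]
  b <- pairs[k, 2]
  p_a_wins <- stats::plogis(cfg$beta * (d[a] - d[b]))
  a_wins <- stats::rbinom(cfg$n_events, 1L, p_a_wins) == 1L
  winner <- ifelse(a_wins, a, b)
  loser <- ifelse(a_wins, b, a)

  # event territory given co-location
  comm_a <- community[a]
  comm_b <- community[b]
  phi <- cfg$phi
  p_home_same <- phi^2 / (phi^2 + (1 - phi)^2)
  u <- stats::runif(cfg$n_events)
  both_float <- comm_a == "floater" & comm_b == "floater"
  one_float <- xor(comm_a == "floater", comm_b == "floater")
  anchor <- ifelse(comm_a == "floater", comm_b, comm_a)
  in_anchor_home <- ifelse(
    both_float, u < 0.5,
    ifelse(one_float, u < phi,
           ifelse(comm_a == comm_b, u < p_home_same, u < 0.5))
  )
  # both_float rows coin-flip a territory; anchor is "floater" there, so
  # resolve them to community A's territory on heads
  territory <- ifelse(in_anchor_home & anchor != "floater", anchor,
                      ifelse(!in_anchor_home & anchor != "floater",
                             ifelse(anchor == "A", "B", "A"),
                             ifelse(in_anchor_home, "A", "B")))
  vivarium <- ifelse(territory == "A", sample(c(1L, 2L), cfg$n_events, TRUE),
                     sample(c(3L, 4L), cfg$n_events, TRUE))

  events <- data.frame(
    day = sort(sample.int(cfg$n_days, cfg$n_events, replace = TRUE)),
    winner = ids[winner], loser = ids[loser],
    behavior = sample(cfg$behaviors, cfg$n_events, replace = TRUE),
    vivarium = vivarium,
    zone = sample(c("top", "shelf", "nestbox"), cfg$n_events, replace = TRUE),
    stringsAsFactors = FALSE
  )

  census <- simulate_census(ids, community, cfg)

  structure(list(
    events = event_log(events, roster = ids),
    census = census,
    truth = list(community = community,
                 order = ids[order(d, decreasing = TRUE)],
                 scores = d)
  ), class = "synthetic_colony")
}

# Vectorized vivarium draw: community members stay in their home pair with
# probability phi; floaters coin-flip a territory each time.
draw_vivarium <- function(comm, phi) {
  n <- length(comm)
  in_a_territory <- ifelse(
    comm == "A", stats::runif(n) < phi,
    ifelse(comm == "B", stats::runif(n) >= phi, stats::runif(n) < 0.5)
  )
  ifelse(in_a_territory, sample(c(1L, 2L), n, replace = TRUE),
         sample(c(3L, 4L), n, replace = TRUE))
}

simulate_census <- function(ids, community, cfg) {
  timepoints <- paste0("T", seq_len(cfg$censuses_per_day))
  grid <- expand.grid(day = seq_len(cfg$n_days), timepoint = timepoints,
                      id = ids, stringsAsFactors = FALSE)
  seen <- stats::runif(nrow(grid)) < cfg$p_sight
  grid <- grid[seen, , drop = FALSE]
  grid$vivarium <- draw_vivarium(community[grid$id], cfg$phi)
  grid <- grid[order(grid$day, grid$timepoint, grid$id), CENSUS_COLUMNS]
  rownames(grid) <- NULL
  census_log(grid, roster = ids)
}

#' Simulate an unstructured (null) colony
#'
#' Dyads uniform, winners fair-coin, event and census locations uniform over
#' the four vivaria: no hierarchy, no communities, no territoriality.  Used
#' to calibrate every randomization test.
#'
#' @param N group size (>= 3).
#' @param n_events number of agonistic events.
#' @param seed integer seed.
#' @param n_days,censuses_per_day,p_sight census design, as in [sim_config()].
#' @return a `synthetic_colony` whose `truth` carries no structure.
#' @export
null_colony <- function(N = 30, n_events = 1230, seed = 1, n_days = 19,
                        censuses_per_day = 3, p_sight = 0.8) {
  if (N < 3) stop("N must be at least 3", call. = FALSE)
  with_seed(seed, {
    ids <- sprintf("M%02d", seq_len(N))
    pairs <- dyad_index(N)
    k <- sample.int(nrow(pairs), n_events, replace = TRUE)
    a_wins <- stats::runif(n_events) < 0.5
    winner <- ifelse(a_wins, pairs[k, 1], pairs[k, 2])
    loser <- ifelse(a_wins, pairs[k, 2], pairs[k, 1])
    events <- data.frame(
      day = sort(sample.int(n_days, n_events, replace = TRUE)),
      winner = ids[winner], loser = ids[loser],
      behavior = "fighting",
      vivarium = sample.int(4L, n_events, replace = TRUE),
      zone = NA_character_,
      stringsAsFactors = FALSE
    )
    timepoints <- paste0("T", seq_len(censuses_per_day))
    grid <- expand.grid(day = seq_len(n_days), timepoint = timepoints,
                        id = ids, stringsAsFactors = FALSE)
    grid <- grid[stats::runif(nrow(grid)) < p_sight, , drop = FALSE]
    grid$vivarium <- sample.int(4L, nrow(grid), replace = TRUE)
    grid <- grid[order(grid$day, grid$timepoint, grid$id), CENSUS_COLUMNS]
    rownames(grid) <- NULL
    structure(list(
      events = event_log(events, roster = ids),
      census = census_log(grid, roster = ids),
      truth = list(community = NULL, order = NULL, scores = NULL)
    ), class = "synthetic_colony")
  })
}
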