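#' @title Elo-rating dominance attributes
#' @description
#' Sequential (classical) Elo ratings over the time-ordered agonistic
#' record give each adult an expected probability of beating every
#' groupmate. From these: the summed winning probability (SWP) of the
#' subject male normalized by group size, the hierarchy steepness (slope of
#' ordered normalized SWP against normalized rank), and the group
#' aggression rate per observation hour per individual. The sequential Elo
#' is a deterministic stand-in for Bayesian steepness estimators built on
#' the same expected-winning-probability quantity; it shares their scale
#' conventions but carries no posterior uncertainty.
#' @name dominance
NULL

#' Sequential Elo ratings
#'
#' Events are processed in time order. With ratings `R_w`, `R_l` before an
#' event, the winner's expected score is
#' `E = 1 / (1 + 10^((R_l - R_w)/scale))`; the winner gains `k * (1 - E)`
#' and the loser loses the same amount, so total rating is conserved.
#' Displacements count as wins like any other agonistic outcome.
#'
#' @param agonistic Event table (`winner_id, loser_id, timestamp, kind`).
#' @param adults Character vector of all adult IDs (unbeaten individuals
#'   keep the start rating).
#' @param start Start rating, default 1000.
#' @param k Update step, default 100.
#' @param scale Logistic scale, default 400.
#' @return Named numeric vector of final ratings.
#' @export
elo_ratings <- function(agonistic, adults, start = 1000, k = 100,
                        scale = 400) {
  r <- stats::setNames(rep(start, length(adults)), adults)
  if (!nrow(agonistic)) return(r)
  unknown <- setdiff(c(agonistic$winner_id, agonistic$loser_id), adults)
  if (length(unknown))
    stop("agonistic events involve unknown individuals: ",
         paste(unique(unknown), collapse = ", "))
  ord <- order(agonistic$timestamp)
  w <- agonistic$winner_id[ord]
  l <- agonistic$loser_id[ord]
  for (i in seq_along(w)) {
    e <- 1 / (1 + 10^((r[l[i]] - r[w[i]]) / scale))
    delta <- k * (1 - e)
    r[w[i]] <- r[w[i]] + delta
    r[l[i]] <- r[l[i]] - delta
  }
  r
}

#' Pairwise expected winning probabilities
#'
#' @param ratings Named rating vector.
#' @param scale Logistic scale matching [elo_ratings()].
#' @return Matrix `p[i, j] = P(i beats j)`; `p[i, j] + p[j, i] = 1`.
#' @export
winning_prob_matrix <- function(ratings, scale = 400) {
  p <- 1 / (1 + 10^(outer(ratings, ratings, function(a, b) b - a) / scale))
  diag(p) <- NA_real_
  p
}

#' Summed winning probability, normalized by group size
#'
#' `SWP_i` is the sum over groupmates of the expected probability that `i`
#' wins a single agonistic interaction — the likelihood of beating a random
#' partner. It is returned both raw (in `[0, n-1]`, summing to
#' `n(n-1)/2` across the group) and divided by group size.
#'
#' @inheritParams winning_prob_matrix
#' @return Data.frame with columns `id`, `swp`, `swp_normalized`.
#' @export
winning_probability <- function(ratings, scale = 400) {
  p <- winning_prob_matrix(ratings, scale)
  swp <- rowSums(p, na.rm = TRUE)
  data.frame(id = names(ratings), swp = unname(swp),
             swp_normalized = unname(swp) / length(ratings),
             stringsAsFactors = FALSE)
}

#' Hierarchy steepness
#'
#' SWP values are scaled to `[0, 1]` (divided by `n - 1`), sorted
#' descending, and regressed on normalized rank `(rank - 1)/(n - 1)` by
#' ordinary least squares; steepness is the absolute slope. 1 means a
#' strictly despotic linear hierarchy, 0 a flat one.
#'
#' @param swp Raw summed winning probabilities (length n >= 3).
#' @return Steepness in `[0, 1]`.
#' @export
steepness <- function(swp) {
  n <- length(swp)
  if (n < 3) stop("steepness needs at least 3 individuals")
  y <- sort(swp, decreasing = TRUE) / (n - 1)
  x <- (seq_len(n) - 1) / (n - 1)
  unname(abs(stats::coef(stats::lm.fit(cbind(1, x), y))[2]))
}

#' Group aggression rate
#'
#' Number of agonistic interactions divided by observation time (hours),
#' normalized by group size.
#'
#' @param n_events Number of agonistic events observed in the group.
#' @param observation_hours Observation effort in hours.
#' @param n_adults Group size (adults).
#' @return Events per hour per individual.
#' @export
aggression_rate <- function(n_events, observation_hours, n_adults) {
  if (observation_hours <= 0) stop("observation time must be positive")
  n_events / observation_hours / n_adults
}

#' All dominance attributes of one group
#'
#' @param agonistic Agonistic event table for the group.
#' @param adults Adult IDs.
#' @param male_id Subject male ID.
#' @param observation_hours Group observation effort (hours).
#' @param config A [run_config()] supplying Elo parameters.
#' @return List: `ratings`, `swp` table, male `winning_probability`
#'   (normalized SWP), group `steepness` and `aggression`.
#' @export
dominance_summary <- function(agonistic, adults, male_id,
                              observation_hours, config = run_config()) {
  r <- elo_ratings(agonistic, adults, config$elo_start, config$elo_k,
                   config$elo_scale)
  swp <- winning_probability(r, config$elo_scale)
  list(
    ratings = r,
    swp = swp,
    winning_probability = swp$swp_normalized[swp$id == male_id],
    steepness = steepness(swp$swp),
    aggression = aggression_rate(nrow(agonistic), observation_hours,
                                 length(adults))
  )
}
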