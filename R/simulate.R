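#' @title Synthetic study generator
#' @description
#' Generates complete observation datasets with the statistical structure
#' the analysis assumes: single-male groups of 6-9 adults, ~3.4 h of
#' 10-min focal follows per individual with grooming bouts, ~100 proximity
#' scans per individual at 2-min intervals inside a 3.5 x 8 m room (plus a
#' second room at the 6 m maximum inter-individual distance), ad libitum
#' agonistic sequences, and ~2 h of raw video per male carrying ~87 min of
#' true (in-sight) observation and ~1130 coded action units over the 17-AU
#' vocabulary, with out-of-sight (`AUX`) and feeding (`AD50a`) intervals
#' and occasional `AU43`.
#'
#' Each male carries two latents: an emission-rate latent (events/s) and a
#' diversity latent `z` driving the symmetric Dirichlet concentration of
#' his AU usage. The coupling `beta` propagates `z` into the social layer:
#' groups of high-`z` males are spatially tighter (smaller dispersion
#' around the shared attractor), their male grooms more, sits closer to
#' the group centre, and affiliation is spread more evenly. At `beta = 0`
#' expressivity and sociality are independent, which is the null used for
#' calibration.
#' @name synthetic-data
NULL

.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  x / rowSums(x)
}

#' Simulation parameters
#'
#' Defaults reproduce the study conditions: nine single-male groups
#' totalling 66 adults (mean 7.33, range 6-9), ~20 focal follows of up to
#' 600 s per individual (~3.4 h) with five 2-min scans per full follow
#' (~100 scans), 120 min of raw footage per male with ~27% out of sight
#' (~87 min true observation) and an emission rate averaging 0.2155
#' events/s (~1130 AU events per male).
#'
#' @param n_groups Number of groups.
#' @param group_sizes Adults per group; `NULL` uses the study composition
#'   `c(9, 8, 8, 7, 7, 7, 7, 7, 6)` when `n_groups == 9`, otherwise sizes
#'   are drawn uniformly from 6-9.
#' @param contexts Behavioural context labels.
#' @param follows_mean,follows_sd,follows_min Focal follows per individual
#'   (normal draw, rounded, floored).
#' @param follow_duration Full follow length (s); a follow ends early
#'   (uniform 120-600 s) with probability `p_early`.
#' @param p_early Probability a follow is terminated early.
#' @param scan_interval Scan spacing within a follow (s).
#' @param bout_rate Expected grooming bouts per full follow.
#' @param bout_mean Mean grooming bout duration (s).
#' @param affinity_shape Gamma shape of latent dyadic grooming affinities;
#'   larger values spread grooming more evenly.
#' @param sigma0 Baseline spatial dispersion around the group attractor
#'   (m).
#' @param p_separate Probability an individual is in the second room
#'   during a scan.
#' @param footage_mean,footage_sd Raw video footage per male (minutes).
#' @param video_max Maximum video length (s).
#' @param context_bout_mean Mean length of a context bout (s).
#' @param context_conc Dirichlet concentration of per-male context
#'   exposure shares (small values = strong imbalance across contexts).
#' @param aux_fraction,aux_bout_mean Target fraction of footage out of
#'   sight and mean out-of-sight bout length (s).
#' @param feed_fraction,feed_bout_mean Same for feeding intervals.
#' @param lambda0,sdlog_lambda Mean AU emission rate (events/s of visible
#'   time) and its log-normal spread across males (mean-preserving).
#' @param alpha0,sdlog_alpha Centre and log-scale of the symmetric
#'   Dirichlet concentration governing AU-usage evenness; the standardized
#'   log-concentration is the male's diversity latent `z`.
#' @param au_duration_mean Mean AU duration (s, exponential).
#' @param au43_rate Emission rate of `AU43` (events/s; always excluded by
#'   the analysis).
#' @param agonism_rate Agonistic events per group observation hour.
#' @param despotism Logistic scale on latent rank differences; 0 makes
#'   every contest a coin flip.
#' @param beta Coupling of the standardized diversity latent into group
#'   cohesion, male spatial centrality, male grooming rate and network
#'   evenness (0 = none).
#' @return List of class `maqsoc_sim_params`.
#' @export
sim_params <- function(n_groups = 9, group_sizes = NULL,
                       contexts = default_contexts(),
                       follows_mean = 22, follows_sd = 8, follows_min = 6,
                       follow_duration = 600, p_early = 0.2,
                       scan_interval = 120,
                       bout_rate = 0.8, bout_mean = 90,
                       affinity_shape = 1.5,
                       sigma0 = 1.5, p_separate = 0.1,
                       footage_mean = 120, footage_sd = 15,
                       video_max = 600,
                       context_bout_mean = 60, context_conc = 2,
                       aux_fraction = 0.27, aux_bout_mean = 20,
                       feed_fraction = 0.12, feed_bout_mean = 30,
                       lambda0 = 0.2155, sdlog_lambda = 0.3,
                       alpha0 = 1, sdlog_alpha = 0.6,
                       au_duration_mean = 1.5, au43_rate = 0.005,
                       agonism_rate = 4, despotism = 2,
                       beta = 0.5) {
  p <- as.list(environment())
  stopifnot(p$n_groups >= 1, length(p$contexts) >= 1,
            p$lambda0 >= 0, p$alpha0 > 0, p$sigma0 > 0,
            p$follows_mean > 0, p$footage_mean > 0,
            p$aux_fraction >= 0, p$aux_fraction < 1,
            p$feed_fraction >= 0, p$feed_fraction < 1,
            p$agonism_rate >= 0, p$despotism >= 0)
  if (is.null(p$group_sizes)) {
    p$group_sizes <- if (n_groups == 9) c(9, 8, 8, 7, 7, 7, 7, 7, 6)
                     else NA  # drawn at simulation time
  } else if (length(p$group_sizes) != n_groups)
    stop("group_sizes must have length n_groups")
  structure(p, class = "maqsoc_sim_params")
}

# --- AU stream ------------------------------------------------------------

#' Simulate one male's AU event stream
#'
#' Footage is tiled with context bouts, out-of-sight (`AUX`) and feeding
#' (`AD50a`) intervals are overlaid, and AU events are emitted as a
#' Poisson process over the visible time of each context with identities
#' drawn from the male's AU-usage distribution and exponential durations
#' truncated at visibility boundaries (no event is emitted out of sight).
#'
#' @param subject_id Male ID (used in the output tables).
#' @param lambda Emission rate (events per visible second).
#' @param au_probs Probability vector over the 17-AU vocabulary.
#' @param context_exposures Named vector: raw footage seconds per context.
#' @param params A [sim_params()] (bout lengths, AUX/feeding fractions,
#'   durations, `au43_rate`, `video_max`).
#' @param seed Optional seed.
#' @return List: `au_events`, `context_timeline` (video-relative times).
#' @export
simulate_au_stream <- function(subject_id, lambda, au_probs,
                               context_exposures, params = sim_params(),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(context_exposures > 0), lambda >= 0,
            abs(sum(au_probs) - 1) < 1e-8)
  vocab <- maqfacs_vocabulary()$code
  contexts <- names(context_exposures)
  # context bouts on the global footage axis, in shuffled order
  bouts <- list()
  for (ctx in contexts) {
    remaining <- context_exposures[[ctx]]
    lens <- numeric(0)
    while (remaining > 1e-9) {
      l <- min(stats::rexp(1, 1 / params$context_bout_mean) + 1, remaining)
      lens <- c(lens, l)
      remaining <- remaining - l
    }
    bouts[[ctx]] <- lens
  }
  bout_ctx <- rep(contexts, lengths(bouts))
  bout_len <- unlist(bouts, use.names = FALSE)
  ord <- sample(length(bout_len))
  bout_ctx <- bout_ctx[ord]; bout_len <- bout_len[ord]
  ends <- cumsum(bout_len)
  starts <- c(0, utils::head(ends, -1))
  total <- ends[length(ends)]
  # split bouts at video boundaries so every row lives in one video
  cuts <- sort(unique(c(starts, ends,
                        seq(0, total, by = params$video_max), total)))
  cuts <- cuts[cuts <= total + 1e-9]
  seg_on <- utils::head(cuts, -1); seg_off <- cuts[-1]
  keep <- seg_off - seg_on > 1e-9
  seg_on <- seg_on[keep]; seg_off <- seg_off[keep]
  mid <- (seg_on + seg_off) / 2
  seg_ctx <- bout_ctx[findInterval(mid, c(0, ends), rightmost.closed = TRUE)]
  seg_vid <- floor(mid / params$video_max)
  # overlay intervals: Poisson coverage with intensity chosen so the
  # expected covered fraction matches the target
  draw_cover <- function(fraction, mean_len) {
    if (fraction <= 0) return(cbind(on = numeric(0), off = numeric(0)))
    n <- stats::rpois(1, -log(1 - fraction) * total / mean_len)
    if (!n) return(cbind(on = numeric(0), off = numeric(0)))
    on <- stats::runif(n, 0, total)
    off <- pmin(on + stats::rexp(n, 1 / mean_len), total)
    .merge_intervals(on, off)
  }
  aux <- draw_cover(params$aux_fraction, params$aux_bout_mean)
  feed <- draw_cover(params$feed_fraction, params$feed_bout_mean)
  # visible pieces per segment: intersect segments with the complement of
  # the out-of-sight cover (both interval sets are sorted and disjoint)
  comp_on <- c(0, aux[, 2]); comp_off <- c(aux[, 1], total)
  ckeep <- comp_off - comp_on > 1e-9
  comp_on <- comp_on[ckeep]; comp_off <- comp_off[ckeep]
  n_c <- length(comp_on); n_s <- length(seg_on)
  pon <- pmax(rep(seg_on, each = n_c), rep.int(comp_on, n_s))
  poff <- pmin(rep(seg_off, each = n_c), rep.int(comp_off, n_s))
  pkeep <- poff - pon > 1e-9
  vis_on <- pon[pkeep]; vis_off <- poff[pkeep]
  vis_seg <- rep(seq_len(n_s), each = n_c)[pkeep]
  vis_len <- vis_off - vis_on
  emit <- function(rate, codes) {
    n <- stats::rpois(1, rate * sum(vis_len))
    if (!n) return(NULL)
    piece <- sample(length(vis_len), n, replace = TRUE,
                    prob = vis_len / sum(vis_len))
    onset <- vis_on[piece] + stats::runif(n) * vis_len[piece]
    dur <- stats::rexp(n, 1 / params$au_duration_mean)
    offset <- pmin(onset + dur, vis_off[piece] - 1e-9)
    offset <- pmax(offset, onset + 1e-6)
    .df(seg = vis_seg[piece], onset = onset, offset = offset,
        au_code = sample(codes, n, replace = TRUE,
                         prob = if (length(codes) > 1) au_probs else NULL))
  }
  ev <- emit(lambda, vocab)
  ev43 <- emit(params$au43_rate, "AU43")
  ev <- rbind(ev, ev43)
  rows <- list()
  if (!is.null(ev) && nrow(ev)) {
    rows$au <- .df(
      subject_id = subject_id,
      video_id = paste0(subject_id, "_V", seg_vid[ev$seg] + 1),
      au_code = ev$au_code,
      onset = ev$onset - seg_vid[ev$seg] * params$video_max,
      offset = ev$offset - seg_vid[ev$seg] * params$video_max,
      context = seg_ctx[ev$seg])
  }
  # AUX / AD50a rows, split at video boundaries, context taken at onset
  special_rows <- function(iv, code) {
    if (!nrow(iv)) return(NULL)
    vm <- params$video_max
    crosses <- floor(iv[, 1] / vm) != floor((iv[, 2] - 1e-12) / vm)
    pieces_on <- iv[!crosses, 1]; pieces_off <- iv[!crosses, 2]
    for (i in which(crosses)) {
      brk <- unique(c(iv[i, 1],
                      seq(ceiling(iv[i, 1] / vm) * vm, iv[i, 2], by = vm),
                      iv[i, 2]))
      pieces_on <- c(pieces_on, utils::head(brk, -1))
      pieces_off <- c(pieces_off, brk[-1])
    }
    keep <- pieces_off - pieces_on > 1e-9
    pieces_on <- pieces_on[keep]; pieces_off <- pieces_off[keep]
    if (!length(pieces_on)) return(NULL)
    vid <- floor((pieces_on + pieces_off) / 2 / params$video_max)
    seg_of <- findInterval((pieces_on + pieces_off) / 2, c(0, ends),
                           rightmost.closed = TRUE)
    .df(
      subject_id = subject_id,
      video_id = paste0(subject_id, "_V", vid + 1),
      au_code = code,
      onset = pieces_on - vid * params$video_max,
      offset = pieces_off - vid * params$video_max,
      context = bout_ctx[pmin(seg_of, length(bout_ctx))])
  }
  rows$aux <- special_rows(aux, "AUX")
  rows$feed <- special_rows(feed, "AD50a")
  au_events <- .rbind_df(rows)
  au_events <- au_events[order(au_events$video_id, au_events$onset,
                               au_events$au_code), ]
  rownames(au_events) <- NULL
  timeline <- .df(
    subject_id = subject_id,
    video_id = paste0(subject_id, "_V", seg_vid + 1),
    context = seg_ctx,
    onset = seg_on - seg_vid * params$video_max,
    offset = seg_off - seg_vid * params$video_max)
  list(au_events = au_events, context_timeline = timeline)
}

# --- proximity ------------------------------------------------------------

#' Simulate proximity scans for one group
#'
#' A two-dimensional attraction model: at each scan every individual is
#' placed around a shared attractor in the main room with normal
#' dispersion `sigma` (truncated to the room), except that with
#' probability `p_separate` an individual is in the second room. Smaller
#' `sigma` means a more cohesive group; `sigma_male` lets the male sit
#' tighter to the attractor than the rest.
#'
#' @param group_id Group label.
#' @param adults Adult IDs.
#' @param male_id Subject male ID.
#' @param follows Follow table for the group (scans happen at
#'   `scan_interval` steps inside each follow).
#' @param sigma Group dispersion (m).
#' @param sigma_male Male dispersion (m); defaults to `sigma`.
#' @param p_separate Second-room probability per individual per scan.
#' @param scan_interval Seconds between scans within a follow.
#' @param seed Optional seed.
#' @return Long-format scan table.
#' @export
simulate_proximity <- function(group_id, adults, male_id, follows,
                               sigma, sigma_male = sigma,
                               p_separate = 0.1, scan_interval = 120,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(adults) >= 2, sigma > 0)
  n_scan_per <- floor(follows$duration / scan_interval)
  f_idx <- rep(seq_len(nrow(follows)), n_scan_per)
  k_idx <- sequence(n_scan_per)
  n_scans <- length(f_idx)
  if (!n_scans) stop("no follow long enough to contain a scan")
  scan_id <- paste0(group_id, "_S", seq_len(n_scans))
  ax <- stats::runif(n_scans, 0.8, 2.7)
  ay <- stats::runif(n_scans, 1.0, 7.0)
  n_ind <- length(adults)
  sig <- rep(ifelse(adults == male_id, sigma_male, sigma), each = n_scans)
  n_tot <- n_scans * n_ind
  in_annex <- stats::runif(n_tot) < p_separate
  x <- pmin(pmax(stats::rnorm(n_tot, ax, sig), 0), 3.5)
  y <- pmin(pmax(stats::rnorm(n_tot, ay, sig), 0), 8)
  x[in_annex] <- stats::runif(sum(in_annex), 0, 1.5)
  y[in_annex] <- stats::runif(sum(in_annex), 0, 6)
  out <- .df(
    scan_id = rep.int(scan_id, n_ind), group_id = group_id,
    focal_id = rep.int(follows$focal_id[f_idx], n_ind),
    timestamp = rep.int(follows$start[f_idx] + k_idx * scan_interval,
                        n_ind),
    individual_id = rep(adults, each = n_scans), x = x, y = y,
    room = ifelse(in_annex, "annex", "main"))
  out
}

# --- agonism --------------------------------------------------------------

#' Simulate agonistic events for one group
#'
#' Dyads are drawn uniformly; the winner of each event is decided by a
#' logistic rule on the latent-strength difference scaled by `despotism`
#' (0 makes every contest a coin flip, large values a fixed outcome).
#'
#' @param group_id Group label.
#' @param adults Adult IDs.
#' @param strengths Named latent strength per adult (any real scale).
#' @param n_events Number of events.
#' @param despotism Logistic scale.
#' @param period Study period (s) over which timestamps are spread.
#' @param seed Optional seed.
#' @return Agonistic event table, time-ordered.
#' @export
simulate_agonism <- function(group_id, adults, strengths, n_events,
                             despotism = 2, period = 86400, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(adults) >= 2, despotism >= 0)
  if (!n_events)
    return(data.frame(group_id = character(0), winner_id = character(0),
                      loser_id = character(0), timestamp = numeric(0),
                      kind = character(0), stringsAsFactors = FALSE))
  i <- sample(length(adults), n_events, replace = TRUE)
  j <- (i + sample(length(adults) - 1, n_events, replace = TRUE) - 1) %%
    length(adults) + 1
  p_i <- stats::plogis(despotism * (strengths[adults[i]] -
                                    strengths[adults[j]]))
  i_wins <- stats::runif(n_events) < p_i
  .df(
    group_id = group_id,
    winner_id = ifelse(i_wins, adults[i], adults[j]),
    loser_id = ifelse(i_wins, adults[j], adults[i]),
    timestamp = sort(stats::runif(n_events, 0, period)),
    kind = sample(c("contact", "non-contact", "displacement"), n_events,
                  replace = TRUE, prob = c(0.2, 0.5, 0.3)))
}

# --- full study -----------------------------------------------------------

#' Simulate a complete study
#'
#' Generates every record kind for every group under one seed:
#' individuals, focal follows with grooming bouts, proximity scans,
#' agonistic events and the male AU streams with their context timelines.
#' The per-male truth (latents) is attached for parameter-recovery checks.
#'
#' @param params A [sim_params()].
#' @param seed Integer seed; the dataset is a deterministic function of
#'   `(params, seed)`.
#' @param validate Re-check all record invariants on the generated tables
#'   (default `TRUE`; can be disabled inside tight simulation loops, the
#'   generator constructs valid records by design).
#' @return List with the elements of [read_observations()] plus `truth`
#'   (data.frame of per-male latents and derived group parameters).
#' @export
simulate_study <- function(params = sim_params(), seed = 1,
                           validate = TRUE) {
  stopifnot(inherits(params, "maqsoc_sim_params"))
  set.seed(seed)
  n_g <- params$n_groups
  sizes <- params$group_sizes
  if (length(sizes) == 1 && is.na(sizes))
    sizes <- sample(6:9, n_g, replace = TRUE)
  group_ids <- sprintf("G%02d", seq_len(n_g))
  vocab <- maqfacs_vocabulary()$code
  all <- list(individuals = list(), follows = list(),
              grooming_bouts = list(), scans = list(), agonistic = list(),
              au_events = list(), context_timeline = list())
  truth <- list()
  stage_seed <- matrix(sample.int(.Machine$integer.max - 1, n_g * 5),
                       nrow = n_g)
  for (g in seq_len(n_g)) {
    gid <- group_ids[g]
    n <- sizes[g]
    ids <- sprintf("%s_I%02d", gid, seq_len(n))
    male <- ids[1]
    all$individuals[[g]] <- .df(
      id = ids, group_id = gid,
      sex = c("male", rep("female", n - 1)),
      age_class = "adult",
      is_subject_male = c(TRUE, rep(FALSE, n - 1)))
    # male latents
    z <- stats::rnorm(1)                      # diversity latent
    u <- stats::rnorm(1)                      # rate latent
    alpha_m <- params$alpha0 * exp(params$sdlog_alpha * z)
    lambda_m <- params$lambda0 *
      exp(params$sdlog_lambda * u - params$sdlog_lambda^2 / 2)
    b <- params$beta
    sigma_g <- max(0.3, min(3, params$sigma0 * exp(-0.4 * b * z)))
    sigma_m <- max(0.15, sigma_g * exp(-0.8 * b * z))
    groom_mult <- exp(b * z)
    even_shape <- params$affinity_shape * exp(0.5 * b * z)
    # follows
    n_follows <- pmax(params$follows_min,
                      round(stats::rnorm(n, params$follows_mean,
                                         params$follows_sd)))
    n_f <- sum(n_follows)
    focal <- rep(ids, n_follows)
    early <- stats::runif(n_f) < params$p_early
    dur <- ifelse(early, stats::runif(n_f, 120, params$follow_duration),
                  params$follow_duration)
    follows <- .df(
      follow_id = sprintf("%s_F%03d", focal, sequence(n_follows)),
      group_id = gid, focal_id = focal,
      start = cumsum(c(0, utils::head(dur + 60, -1))),
      duration = dur)
    period <- sum(follows$duration)
    # latent grooming affinities (dyadic, symmetric)
    set.seed(stage_seed[g, 1])
    aff <- matrix(0, n, n, dimnames = list(ids, ids))
    w <- stats::rgamma(n * (n - 1) / 2, shape = even_shape, rate = 1)
    aff[upper.tri(aff)] <- w
    aff <- aff + t(aff)
    aff[male, ] <- aff[male, ] * groom_mult
    aff[, male] <- aff[, male] * groom_mult
    # grooming bouts within follows
    n_b <- stats::rpois(nrow(follows),
                        params$bout_rate * follows$duration /
                          params$follow_duration)
    gb <- NULL
    has <- which(n_b > 0)
    if (length(has)) {
      f_id <- rep(follows$follow_id[has], n_b[has])
      f_focal <- rep(follows$focal_id[has], n_b[has])
      f_dur <- rep(follows$duration[has], n_b[has])
      # partner ~ categorical(affinity row of the focal), via inverse CDF
      pa <- aff
      diag(pa) <- 0
      zero <- rowSums(pa) == 0
      pa[zero, ] <- 1; diag(pa) <- 0
      cs <- pa / rowSums(pa)
      cs <- t(apply(cs, 1, cumsum))
      cs[, ncol(cs)] <- 1  # guard against rounding in the last bin
      u_b <- stats::runif(length(f_id))
      partner <- ids[max.col(cs[f_focal, , drop = FALSE] >= u_b,
                             ties.method = "first")]
      b_dur <- pmin(stats::rexp(length(f_id), 1 / params$bout_mean),
                    f_dur - 1)
      b_start <- stats::runif(length(f_id)) * (f_dur - b_dur)
      gb <- .df(follow_id = f_id, partner_id = partner,
                start = b_start, duration = b_dur)
    } else {
      gb <- data.frame(follow_id = character(0), partner_id = character(0),
                       start = numeric(0), duration = numeric(0),
                       stringsAsFactors = FALSE)
    }
    all$follows[[g]] <- follows
    all$grooming_bouts[[g]] <- gb
    # scans
    all$scans[[g]] <- simulate_proximity(
      gid, ids, male, follows, sigma = sigma_g, sigma_male = sigma_m,
      p_separate = params$p_separate, scan_interval = params$scan_interval,
      seed = stage_seed[g, 2])
    # agonism: latent strengths, male advantaged on average
    set.seed(stage_seed[g, 3])
    strengths <- stats::setNames(stats::rnorm(n), ids)
    strengths[male] <- strengths[male] + 1
    hours <- period / 3600
    n_events <- stats::rpois(1, params$agonism_rate * hours)
    all$agonistic[[g]] <- simulate_agonism(
      gid, ids, strengths, n_events, params$despotism, period,
      seed = stage_seed[g, 5])
    # male AU stream
    footage <- max(5, stats::rnorm(1, params$footage_mean,
                                   params$footage_sd)) * 60
    shares <- drop(.rdirichlet(1, rep(params$context_conc,
                                      length(params$contexts))))
    exposures <- stats::setNames(pmax(shares * footage, 30),
                                 params$contexts)
    au_probs <- drop(.rdirichlet(1, rep(alpha_m, length(vocab))))
    stream <- simulate_au_stream(male, lambda_m, au_probs, exposures,
                                 params, seed = stage_seed[g, 4])
    all$au_events[[g]] <- stream$au_events
    all$context_timeline[[g]] <- stream$context_timeline
    truth[[g]] <- data.frame(
      group_id = gid, male_id = male, n_adults = n,
      z = z, u = u, alpha = alpha_m, lambda = lambda_m,
      sigma = sigma_g, sigma_male = sigma_m, groom_mult = groom_mult,
      focal_hours = hours, footage_min = footage / 60,
      true_diversity = 1 / sum(au_probs^2),  # Simpson effective number
      shannon_diversity = exp(-sum(au_probs[au_probs > 0] *
                                   log(au_probs[au_probs > 0]))),
      stringsAsFactors = FALSE)
  }
  out <- lapply(all, .rbind_df)
  out$truth <- do.call(rbind, truth)
  rownames(out$truth) <- NULL
  if (validate) validate_observations(out[names(out) != "truth"])
  out
}
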