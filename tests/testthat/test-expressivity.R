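# one-video fixture builders ------------------------------------------------

tl1 <- function(contexts, bounds, subject = "M1", video = "V1") {
  data.frame(subject_id = subject, video_id = video, context = contexts,
             onset = head(bounds, -1), offset = bounds[-1],
             stringsAsFactors = FALSE)
}

ev1 <- function(code, onset, offset, context, subject = "M1",
                video = "V1") {
  data.frame(subject_id = subject, video_id = video, au_code = code,
             onset = onset, offset = offset, context = context,
             stringsAsFactors = FALSE)
}

test_that("true observation time is footage minus out-of-sight time", {
  tl <- tl1("low_vigilance", c(0, 600))
  ev <- ev1("AUX", 100, 220, "low_vigilance")
  led <- build_ledger(ev, tl)
  expect_equal(led$context$t[led$context$context == "low_vigilance"], 480)
  expect_equal(sum(led$context$t), 480)
})

test_that("feeding mask drops mastication codes only; AU43 never counts", {
  tl <- tl1("low_vigilance", c(0, 600))
  ev <- rbind(
    ev1("AD50a", 100, 200, "low_vigilance"),
    ev1("AU25", 120, 130, "low_vigilance"),   # inside feeding: dropped
    ev1("EAU1", 125, 135, "low_vigilance"),   # co-occurring: retained
    ev1("AU25", 300, 310, "low_vigilance"),   # outside feeding: retained
    ev1("AU43", 400, 405, "low_vigilance"))   # always excluded
  led <- build_ledger(ev, tl)
  row <- led$context[led$context$context == "low_vigilance", ]
  expect_equal(row$f, 2)
  expect_setequal(led$au_counts$au_code, c("EAU1", "AU25"))
  expect_false("AU43" %in% led$au_counts$au_code)
  prof <- aggregate_profile(led)
  expect_false(any(prof$proportions[, "AU25"] > 0.5 + 1e-9))
})

test_that("events are truncated at out-of-sight boundaries or dropped", {
  tl <- tl1("high_vigilance", c(0, 500))
  ev <- rbind(
    ev1("AUX", 100, 200, "high_vigilance"),
    ev1("AU12", 90, 150, "high_vigilance"),    # truncated to 10 s
    ev1("AU12", 120, 180, "high_vigilance"),   # fully out of sight
    ev1("AU6", 300, 320, "high_vigilance"))
  led <- build_ledger(ev, tl)
  row <- led$context[led$context$context == "high_vigilance", ]
  expect_equal(row$f, 2)
  expect_equal(row$d, 10 + 20)
  expect_equal(row$t, 400)
})

test_that("ledger totals equal a brute-force sweep on random streams", {
  set.seed(17)
  cfg <- run_config()
  for (rep in 1:5) {
    total <- 400
    n_ctx <- 3
    bounds <- c(0, sort(runif(n_ctx - 1, 50, total - 50)), total)
    contexts <- sample(default_contexts(), n_ctx)
    tl <- tl1(contexts, bounds)
    n_ev <- 25
    on <- runif(n_ev, 0, total - 5)
    ev <- ev1(sample(maqfacs_vocabulary()$code, n_ev, replace = TRUE),
              on, on + runif(n_ev, 0.5, 5),
              contexts[findInterval(on, bounds, rightmost.closed = TRUE)])
    aux_on <- sort(runif(2, 0, total - 40))
    special <- rbind(
      ev1("AUX", aux_on, aux_on + c(25, 30),
          contexts[findInterval(aux_on, bounds,
                                rightmost.closed = TRUE)]),
      ev1("AD50a", 10, 60,
          contexts[findInterval(10, bounds, rightmost.closed = TRUE)]))
    all_ev <- rbind(ev, special)
    led <- build_ledger(all_ev, tl, cfg)
    sweep <- oracle_ledger_sweep(tl, all_ev, cfg$mastication_mask,
                                 dt = 0.005)
    lc <- led$context[match(names(sweep$t), led$context$context), ]
    expect_equal(lc$t, as.numeric(sweep$t), tolerance = 0.05)
    got_f <- led$context$f[match(names(sweep$f), led$context$context)]
    expect_equal(got_f, as.numeric(sweep$f))
    got_d <- led$context$d[match(names(sweep$d), led$context$context)]
    expect_equal(got_d, as.numeric(sweep$d), tolerance = 0.2)
  }
})

test_that("rate and duration are per-context ratios; overlap can exceed 100%", {
  tl <- tl1("low_vigilance", c(0, 100))
  on <- seq(0, 90, by = 10)[1:10]
  ev <- ev1("AU12", on, on + 0.5, "low_vigilance")
  led <- build_ledger(ev, tl)
  rd <- rate_duration_per_context(led)
  expect_equal(rd$rate, 10 / 100)
  # two overlapping 50 s AUs in 80 s of footage -> 125% duration
  tl2 <- tl1("low_vigilance", c(0, 80))
  ev2 <- ev1(c("AU12", "AU6"), c(0, 20), c(50, 70), "low_vigilance")
  rd2 <- rate_duration_per_context(build_ledger(ev2, tl2))
  expect_equal(rd2$duration_pct, 125)
  # the union variant is bounded by 100%
  rd2u <- rate_duration_per_context(
    build_ledger(ev2, tl2, union_durations = TRUE), "union")
  expect_equal(rd2u$duration_pct, 100 * 70 / 80)
  # empty context with positive time: rate 0, duration 0
  led3 <- build_ledger(ev1("AU12", 1, 2, "low_vigilance"),
                       tl1(c("low_vigilance", "high_vigilance"),
                           c(0, 50, 100)))
  rd3 <- rate_duration_per_context(led3)
  expect_equal(rd3$rate[rd3$context == "high_vigilance"], 0)
})

test_that("diversity is the exponentiated Shannon entropy", {
  tl <- tl1("low_vigilance", c(0, 100))
  single <- build_ledger(ev1("AU12", 1:5, 1:5 + 0.5, "low_vigilance"), tl)
  expect_equal(diversity_per_context(single)$diversity, 1)
  two <- build_ledger(ev1(c("AU12", "AU12", "AU6", "AU6"),
                          c(1, 3, 5, 7), c(2, 4, 6, 8), "low_vigilance"),
                      tl)
  expect_equal(diversity_per_context(two)$diversity, 2)
  counts <- c(4, 3, 2, 1)
  codes <- rep(c("AU12", "AU6", "AU25", "EAU1"), counts)
  on <- seq_along(codes)
  mixed <- build_ledger(ev1(codes, on, on + 0.5, "low_vigilance"), tl)
  p <- counts / sum(counts)
  expect_equal(diversity_per_context(mixed)$diversity,
               exp(-sum(p * log(p))))
})

test_that("profiles average per-context scores with equal weight", {
  tl <- tl1(c("low_vigilance", "high_vigilance"), c(0, 100, 200))
  # context 1: two AUs evenly (D = 2); context 2: a single AU (D = 1)
  ev <- rbind(ev1(c("AU12", "AU6"), c(1, 3), c(2, 4), "low_vigilance"),
              ev1("AU12", 150, 151, "high_vigilance"))
  prof <- aggregate_profile(build_ledger(ev, tl))
  expect_equal(prof$profile$au_diversity, 1.5)
  expect_equal(prof$profile$au_rate, mean(c(2 / 100, 1 / 100)))
  expect_equal(sum(prof$proportions), 1)
  expect_equal(unname(prof$proportions[1, "AU12"]), 2 / 3)
  # a single context: the profile equals that context's measures
  one <- aggregate_profile(build_ledger(
    ev1(c("AU12", "AU6"), c(1, 3), c(2, 4), "low_vigilance"),
    tl1("low_vigilance", c(0, 100))))
  expect_equal(one$profile$au_diversity, 2)
  expect_equal(one$profile$au_rate, 2 / 100)
})

test_that("measures are invariant to splitting a context across videos", {
  ev_a <- rbind(ev1(c("AU12", "AU6"), c(1, 3), c(2, 4), "low_vigilance"),
                ev1("AU25", 50, 52, "low_vigilance"))
  tl_a <- tl1("low_vigilance", c(0, 100))
  ev_b <- ev_a; ev_b$video_id <- c("V1", "V1", "V2")
  ev_b$onset[3] <- 10; ev_b$offset[3] <- 12
  tl_b <- rbind(tl1("low_vigilance", c(0, 60)),
                tl1("low_vigilance", c(0, 40), video = "V2"))
  pa <- aggregate_profile(build_ledger(ev_a, tl_a))
  pb <- aggregate_profile(build_ledger(ev_b, tl_b))
  expect_equal(pa$profile$au_rate, pb$profile$au_rate)
  expect_equal(pa$profile$au_diversity, pb$profile$au_diversity)
  expect_equal(pa$proportions, pb$proportions)
})

test_that("scale relations: doubling t halves rate/duration, D unchanged", {
  tl <- tl1(c("low_vigilance", "high_vigilance"), c(0, 100, 250))
  set.seed(3)
  on <- runif(20, 0, 240)
  ev <- ev1(sample(maqfacs_vocabulary()$code, 20, replace = TRUE),
            on, on + runif(20, 0.2, 3),
            ifelse(on < 100, "low_vigilance", "high_vigilance"))
  led <- build_ledger(ev, tl)
  led2 <- led
  led2$context$t <- led2$context$t * 2
  p1 <- aggregate_profile(led); p2 <- aggregate_profile(led2)
  expect_equal(p2$profile$au_rate, p1$profile$au_rate / 2)
  expect_equal(p2$profile$au_duration, p1$profile$au_duration / 2)
  expect_equal(p2$profile$au_diversity, p1$profile$au_diversity)
})

test_that("robustness filter reports correlations and flags lost subjects", {
  params <- sim_params(n_groups = 6, group_sizes = rep(6:8, 2),
                       follows_mean = 4, follows_sd = 1, follows_min = 3,
                       footage_mean = 45, footage_sd = 5)
  d <- simulate_study(params, seed = 5)
  led <- build_ledger(d$au_events, d$context_timeline)
  # min_seconds = 0 changes nothing
  rep0 <- robustness_filter(led, 0)
  expect_equal(rep0$original$profile, rep0$filtered$profile)
  rep60 <- robustness_filter(led, 60)
  expect_true(all(rep60$correlations > 0.5, na.rm = TRUE))
  # correlations match the direct Pearson formula
  o <- rep0$original$profile
  f <- rep60$filtered$profile
  common <- intersect(o$subject_id, f$subject_id)
  r_direct <- cor(o$au_rate[match(common, o$subject_id)],
                  f$au_rate[match(common, f$subject_id)])
  expect_equal(unname(rep60$correlations["au_rate"]), r_direct)
  # a threshold beyond every context flags all subjects
  expect_warning(expect_error(robustness_filter(led, 1e6)))
})
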