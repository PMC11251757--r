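# Independent oracles used by the tests. Each is a deliberately naive
# reimplementation (brute force, enumeration, closed form) kept separate
# from the package's code paths.

# all simple paths between s and t in an undirected weighted graph,
# returned as list of vertex index vectors
.all_simple_paths <- function(adj, s, t) {
  n <- nrow(adj)
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) { paths[[length(paths) + 1]] <<- path; return() }
    for (w in seq_len(n))
      if (adj[v, w] > 0 && !(w %in% path)) walk(c(path, w))
  }
  walk(s)
  paths
}

# weighted betweenness by exhaustive path enumeration: length of a path is
# the sum of reciprocal weights; shortest paths split counts fractionally
oracle_betweenness <- function(m) {
  n <- nrow(m)
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- .all_simple_paths(m, s, t)
    if (!length(paths)) next
    lens <- vapply(paths, function(p) {
      sum(1 / m[cbind(p[-length(p)], p[-1])])
    }, numeric(1))
    best <- min(lens)
    on_best <- paths[lens <= best + 1e-12 * max(1, best)]
    for (p in on_best) {
      inner <- p[-c(1, length(p))]
      b[inner] <- b[inner] + 1 / length(on_best)
    }
  }
  names(b) <- rownames(m)
  b
}

# eigenvector centrality via dense symmetric eigendecomposition
oracle_eigen <- function(m) {
  v <- abs(eigen(m, symmetric = TRUE)$vectors[, 1])
  stats::setNames(v / max(v), rownames(m))
}

# weighted Newman modularity by the direct double sum
oracle_modularity <- function(m, membership) {
  W <- sum(m) / 2
  s <- rowSums(m)
  q <- 0
  n <- nrow(m)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (membership[i] == membership[j])
      q <- q + m[i, j] / (2 * W) - s[i] * s[j] / (2 * W)^2
  unname(q)
}

# exhaustive search over all set partitions for the max-modularity
# partition (feasible to ~10 nodes)
oracle_best_partition <- function(m) {
  n <- nrow(m)
  best_q <- -Inf; best <- NULL
  assign_next <- function(memb, k) {
    i <- length(memb) + 1
    if (i > n) {
      q <- oracle_modularity(m, memb)
      if (q > best_q) { best_q <<- q; best <<- memb }
      return()
    }
    for (c in seq_len(k + 1)) assign_next(c(memb, c), max(k, c))
  }
  assign_next(integer(0), 0)
  list(membership = best, q = best_q)
}

# classical Elo by plain sequential recomputation
oracle_elo <- function(winners, losers, adults, start, k, scale) {
  r <- stats::setNames(rep(start, length(adults)), adults)
  for (i in seq_along(winners)) {
    ew <- 1 / (1 + 10^((r[losers[i]] - r[winners[i]]) / scale))
    r[winners[i]] <- r[winners[i]] + k * (1 - ew)
    r[losers[i]] <- r[losers[i]] - k * (1 - ew)
  }
  r
}

# Gaussian log-likelihood LRT computed from first principles
oracle_lrt <- function(x, y) {
  n <- length(y)
  fit <- stats::lm(y ~ x)
  rss1 <- sum(stats::residuals(fit)^2)
  rss0 <- sum((y - mean(y))^2)
  ll <- function(rss) -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  chisq <- 2 * (ll(rss1) - ll(rss0))
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE),
       r2 = 1 - rss1 / rss0, rss_full = rss1, rss_null = rss0)
}

# expressivity ledger by fine-grained time sweep (dt-resolution grid);
# events/intervals all on one video of one subject
oracle_ledger_sweep <- function(timeline, events, mask = c("AU25", "AU26"),
                                dt = 0.01) {
  vocab <- maqsoc::maqfacs_vocabulary()$code
  total <- max(timeline$offset)
  grid <- seq(dt / 2, total - dt / 2, by = dt)
  ctx_at <- function(x) {
    i <- findInterval(x, timeline$onset)
    timeline$context[pmax(i, 1)]
  }
  in_iv <- function(x, iv) {
    if (!nrow(iv)) return(rep(FALSE, length(x)))
    res <- rep(FALSE, length(x))
    for (r in seq_len(nrow(iv)))
      res <- res | (x >= iv$onset[r] & x < iv$offset[r])
    res
  }
  aux <- events[events$au_code == "AUX", c("onset", "offset")]
  feed <- events[events$au_code == "AD50a", c("onset", "offset")]
  visible <- !in_iv(grid, aux)
  t_by_ctx <- tapply(rep(dt, sum(visible)), ctx_at(grid[visible]), sum)
  au <- events[events$au_code %in% vocab, ]
  drop <- au$au_code %in% mask & in_iv(au$onset, feed)
  au <- au[!drop, ]
  f <- d <- stats::setNames(numeric(0), character(0))
  keep <- logical(nrow(au))
  dsum <- stats::setNames(rep(0, length(unique(timeline$context))),
                          unique(timeline$context))
  fcnt <- dsum
  for (i in seq_len(nrow(au))) {
    pts <- grid[grid >= au$onset[i] & grid < au$offset[i]]
    vis_len <- sum(!in_iv(pts, aux)) * dt
    if (vis_len <= dt / 2) next   # (approximately) fully out of sight
    ctx <- au$context[i]
    dsum[ctx] <- dsum[ctx] + vis_len
    fcnt[ctx] <- fcnt[ctx] + 1
  }
  list(t = t_by_ctx, f = fcnt, d = dsum)
}

# tiny fixture: hand-built observation set with three adults
make_three_adults <- function() {
  individuals <- data.frame(
    id = c("A", "B", "C"), group_id = "G1",
    sex = c("male", "female", "female"), age_class = "adult",
    is_subject_male = c(TRUE, FALSE, FALSE), stringsAsFactors = FALSE)
  follows <- data.frame(
    follow_id = c("FA", "FB", "FC"), group_id = "G1",
    focal_id = c("A", "B", "C"), start = c(0, 700, 1400),
    duration = c(600, 600, 600), stringsAsFactors = FALSE)
  list(individuals = individuals, follows = follows)
}

# scan rows for one scan: focal plus partners at given coords/rooms
scan_rows <- function(scan_id, focal, ids, x, y, room,
                      group_id = "G1", timestamp = 0) {
  data.frame(scan_id = scan_id, group_id = group_id, focal_id = focal,
             timestamp = timestamp, individual_id = ids, x = x, y = y,
             room = room, stringsAsFactors = FALSE)
}

# random connected weighted graph on n nodes
random_weighted_graph <- function(n, p_edge = 0.7) {
  repeat {
    m <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (stats::runif(1) < p_edge)
        m[i, j] <- m[j, i] <- stats::runif(1, 0.2, 3)
    g <- igraph::graph_from_adjacency_matrix(m, "undirected",
                                             weighted = TRUE)
    if (igraph::components(g)$no == 1 && sum(m) > 0) break
  }
  dimnames(m) <- list(paste0("n", 1:n), paste0("n", 1:n))
  m
}
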