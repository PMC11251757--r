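#' @title Weighted social network metrics
#' @description
#' Individual and group-level attributes of the weighted affiliation
#' network: eigenvector and betweenness centrality, nodal and network
#' strength, walktrap community structure with Newman modularity, and a
#' centralization score normalized by the value the most centralized
#' topology of the same size (the star) would attain. Edge weights are
#' affinities (larger = stronger); betweenness converts them to path
#' lengths by taking reciprocals.
#' @name network-metrics
NULL

.as_graph <- function(m) {
  stopifnot(is.matrix(m), max(abs(m - t(m))) < 1e-12, all(m >= 0))
  igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Eigenvector centrality of a weighted network
#'
#' Leading eigenvector of the non-negative weight matrix, rescaled so the
#' maximum score is 1. Interpretable as social capital: high scores mean
#' strong connections to individuals who are themselves well connected.
#' On disconnected graphs, scores are computed per component and
#' max-normalized globally, with a warning.
#'
#' @param m Symmetric non-negative weight matrix with ID dimnames.
#' @return Named numeric vector in `[0, 1]` with maximum 1.
#' @export
eigenvector_centrality <- function(m) {
  if (all(m == 0)) stop("eigenvector centrality undefined on a zero matrix")
  g <- .as_graph(m)
  comps <- igraph::components(g)
  if (comps$no > 1) {
    warning("graph disconnected: eigenvector centrality per component, ",
            "max-normalized globally")
    sc <- numeric(nrow(m))
    names(sc) <- rownames(m)
    for (k in seq_len(comps$no)) {
      vs <- which(comps$membership == k)
      if (length(vs) == 1) { sc[vs] <- 0; next }
      sub <- m[vs, vs, drop = FALSE]
      if (all(sub == 0)) { sc[vs] <- 0; next }
      ev <- eigen(sub, symmetric = TRUE)$vectors[, 1]
      sc[vs] <- abs(ev)
    }
    return(sc / max(sc))
  }
  sc <- igraph::eigen_centrality(g, weights = igraph::E(g)$weight)$vector
  sc <- sc / max(sc)
  sc[rownames(m)]
}

#' Weighted betweenness centrality
#'
#' Number of shortest paths between all other dyads passing through each
#' node, with ties over equal-length paths split fractionally. Affinity
#' weights are converted to distances as `1/weight`, so strong ties are
#' short paths.
#'
#' @inheritParams eigenvector_centrality
#' @return Named numeric vector of unnormalized path counts.
#' @export
betweenness_centrality <- function(m) {
  if (all(m == 0)) stop("betweenness undefined on a zero matrix")
  g <- .as_graph(m)
  w <- igraph::E(g)$weight
  sc <- igraph::betweenness(g, weights = 1 / w, directed = FALSE)
  sc[rownames(m)]
}

#' Nodal and network strength
#'
#' Nodal strength is the sum of the weighted connections incident to each
#' individual; network strength is the sum of all ties across the group
#' (each unordered dyad counted once). Strength is computed from
#' non-standardized matrices so it is comparable across groups; when the
#' input is proximity, pass the reversed matrix so larger means stronger.
#'
#' @inheritParams eigenvector_centrality
#' @param scope `"node"` for per-individual strengths, `"network"` for the
#'   group total.
#' @return Named vector (node) or single number (network).
#' @export
strength <- function(m, scope = c("node", "network")) {
  scope <- match.arg(scope)
  stopifnot(all(m >= 0))
  if (scope == "node") rowSums(m) else sum(m[upper.tri(m)])
}

#' Walktrap community detection
#'
#' Agglomerative merging of nodes with similar short-random-walk
#' distributions (Pons-Latapy), cut at the maximum-modularity point of the
#' merge sequence. Deterministic given the input.
#'
#' @inheritParams eigenvector_centrality
#' @param steps Random-walk length, default 4.
#' @return Named integer membership vector.
#' @export
walktrap_communities <- function(m, steps = 4) {
  if (nrow(m) < 2)
    return(stats::setNames(rep(1L, nrow(m)), rownames(m)))
  g <- .as_graph(m)
  wt <- igraph::cluster_walktrap(g, weights = igraph::E(g)$weight,
                                 steps = steps)
  stats::setNames(as.integer(igraph::membership(wt)), rownames(m))
}

#' Weighted Newman modularity
#'
#' \deqn{Q = \sum_c \left[ w_c/W - (s_c/2W)^2 \right]} where `W` is the
#' total edge weight, `w_c` the weight inside community `c` and `s_c` the
#' summed strength of its members. Q is 0 for the single-community
#' partition and approaches 1 for strong community structure.
#'
#' @inheritParams eigenvector_centrality
#' @param membership Community assignment covering all nodes (integer or
#'   factor vector in node order).
#' @return Modularity Q.
#' @export
modularity_q <- function(m, membership) {
  stopifnot(length(membership) == nrow(m))
  g <- .as_graph(m)
  igraph::modularity(g, as.integer(as.factor(membership)),
                     weights = igraph::E(g)$weight)
}

#' Eigenvector centralization, star-normalized
#'
#' \deqn{C = \sum_i (c_{max} - c_i) / T(n)} where the `c_i` are
#' max-normalized eigenvector centralities and `T(n)` is the same sum
#' evaluated on the n-node star — the most centralized topology — so that
#' groups of different sizes are comparable. The star scores 1 and the
#' complete graph 0.
#'
#' @inheritParams eigenvector_centrality
#' @return Centralization in `[0, 1]`.
#' @export
centralization <- function(m) {
  n <- nrow(m)
  if (n < 3) stop("centralization needs at least 3 individuals")
  if (igraph::components(.as_graph(m))$no > 1)
    stop("centralization undefined on a disconnected graph")
  sc <- eigenvector_centrality(m)
  raw <- sum(max(sc) - sc)
  raw / .star_tmax(n)
}

# Sum of (c_max - c_i) over the n-node star with max-normalized eigen
# scores: centre 1, leaves 1/sqrt(n-1).
.star_tmax <- function(n) {
  (n - 1) * (1 - 1 / sqrt(n - 1))
}

#' All network attributes of one group
#'
#' Convenience bundle: individual metrics for the subject male (from the
#' DSI network) plus group-level metrics. Strength measures are computed
#' from the raw (non-standardized) grooming and reversed-proximity
#' matrices.
#'
#' @param dsi_m DSI matrix from [dsi()].
#' @param grooming Raw grooming matrix.
#' @param proximity Raw proximity matrix (metres).
#' @param male_id ID of the subject male.
#' @param config A [run_config()].
#' @return Named list of scalars plus the community membership.
#' @export
network_summary <- function(dsi_m, grooming, proximity, male_id,
                            config = run_config()) {
  rev_prox <- reverse_proximity(proximity, config$max_distance)
  # one igraph build shared by all DSI-based metrics
  g <- .as_graph(dsi_m)
  w <- igraph::E(g)$weight
  if (igraph::components(g)$no > 1)
    stop("DSI network disconnected for group ",
         attr(dsi_m, "group_id") %||% "")
  ec <- igraph::eigen_centrality(g, weights = w)$vector
  ec <- ec / max(ec)
  ec <- ec[rownames(dsi_m)]
  bc <- igraph::betweenness(g, weights = 1 / w,
                            directed = FALSE)[rownames(dsi_m)]
  wt <- igraph::cluster_walktrap(g, weights = w,
                                 steps = config$walktrap_steps)
  memb <- stats::setNames(as.integer(igraph::membership(wt)),
                          rownames(dsi_m))
  list(
    eigenvector = unname(ec[male_id]),
    betweenness = unname(bc[male_id]),
    strength_nodal_grooming = unname(strength(grooming)[male_id]),
    strength_nodal_proximity = unname(strength(rev_prox)[male_id]),
    centralization = sum(max(ec) - ec) / .star_tmax(nrow(dsi_m)),
    strength_network_grooming = strength(grooming, "network"),
    strength_network_proximity = strength(rev_prox, "network"),
    modularity = igraph::modularity(g, memb, weights = w),
    membership = memb
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
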