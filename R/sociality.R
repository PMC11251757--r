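#' @title Dyadic sociality: proximity, grooming and the composite index
#' @description
#' Scan-sampling records become a mean-distance matrix, focal follows a
#' grooming-rate matrix, and the two combine into the Dyadic Sociality
#' Index (DSI): each measure is divided by its across-dyad mean and the
#' measures are averaged, so the DSI of an average dyad is 1 by
#' construction.
#' @name sociality
NULL

.empty_dyad_matrix <- function(ids, measure, group_id) {
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  structure(m, measure = measure, group_id = group_id)
}

#' Unordered adult dyads of a matrix
#' @param m Symmetric dyadic matrix with dimnames.
#' @return Data.frame with columns `a`, `b`, `value`.
#' @export
dyad_values <- function(m) {
  ids <- rownames(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  data.frame(a = ids[idx[, 1]], b = ids[idx[, 2]],
             value = m[idx], stringsAsFactors = FALSE)
}

#' Mean dyadic proximity matrix (metres)
#'
#' Entry (A, B) is the total summed distance observed between A and B over
#' every scan conducted on A or B, divided by the number of scans conducted
#' on A plus the number conducted on B. Within a scan, individuals in
#' different rooms contribute the maximum inter-individual distance; same
#' room distances are Euclidean, capped at that maximum (the cap is the
#' greatest distance at which animals can be seen apart, so it is global).
#'
#' @param scans Long-format scan table (see [read_observations()]).
#' @param adults Character vector of adult IDs defining the dyad universe.
#' @param max_distance Cap and cross-room distance in metres (default 6).
#' @param allow_missing If `TRUE`, dyads with no scan in which both members
#'   are positioned are `NA`; otherwise they raise an error.
#' @return Symmetric matrix over `adults`, attribute `measure =
#'   "proximity_m"`. Lower values mean closer average proximity.
#' @export
proximity_matrix <- function(scans, adults, max_distance = 6,
                             allow_missing = FALSE) {
  stopifnot(length(adults) >= 2)
  n <- length(adults)
  # scans conducted on each adult (focal-based denominator); every scan
  # positions its own focal, so focal rows count scans once each
  focal_rows <- scans$focal_id == scans$individual_id
  n_scans <- table(factor(scans$focal_id[focal_rows], levels = adults))
  sc <- scans[scans$individual_id %in% adults & scans$focal_id %in% adults, ]
  # a scan conducted on focal F contributes the F-partner distance of every
  # dyad containing F; distances between two non-focal individuals in that
  # scan do not enter (the denominator counts scans conducted on A or B)
  fr <- sc[sc$individual_id == sc$focal_id, ]
  fi <- match(sc$scan_id, fr$scan_id)
  partner <- sc$individual_id != sc$focal_id & !is.na(fi)
  dx <- sc$x - fr$x[fi]
  dy <- sc$y - fr$y[fi]
  d <- ifelse(sc$room == fr$room[fi],
              pmin(sqrt(dx^2 + dy^2), max_distance), max_distance)
  ia <- factor(sc$focal_id[partner], levels = adults)
  ib <- factor(sc$individual_id[partner], levels = adults)
  sum_half <- matrix(0, n, n, dimnames = list(adults, adults))
  acc <- tapply(d[partner], list(ia, ib), sum)
  acc[is.na(acc)] <- 0
  sum_half[] <- acc
  sum_d <- sum_half + t(sum_half)
  denom <- outer(as.numeric(n_scans), as.numeric(n_scans), "+")
  dimnames(denom) <- list(adults, adults)
  m <- sum_d / denom
  m[denom == 0] <- NA_real_
  diag(m) <- 0
  if (anyNA(m[upper.tri(m)]) && !allow_missing) {
    miss <- dyad_values(m)
    miss <- miss[is.na(miss$value), ]
    stop("dyads with zero joint scan denominator: ",
         paste(paste(miss$a, miss$b, sep = "-"), collapse = ", "))
  }
  structure(m, measure = "proximity_m",
            group_id = scans$group_id[1])
}

#' Dyadic grooming-rate matrix
#'
#' Entry (A, B) is the total summed time A and B were observed grooming
#' (bouts from both individuals' follows, direction pooled) divided by the
#' total focal seconds of A plus B.
#'
#' @param follows Follow table; `grooming_bouts` bout table keyed by
#'   `follow_id`.
#' @param grooming_bouts Bout table (`follow_id, partner_id, start,
#'   duration`).
#' @param adults Character vector of adult IDs.
#' @return Symmetric non-negative matrix, attribute `measure = "grooming"`.
#' @export
grooming_matrix <- function(follows, grooming_bouts, adults) {
  stopifnot(length(adults) >= 2)
  focal_sec <- tapply(follows$duration,
                      factor(follows$focal_id, levels = adults), sum)
  focal_sec[is.na(focal_sec)] <- 0
  if (any(focal_sec == 0))
    stop("adults with zero focal time: ",
         paste(adults[focal_sec == 0], collapse = ", "))
  n <- length(adults)
  g <- matrix(0, n, n, dimnames = list(adults, adults))
  if (nrow(grooming_bouts)) {
    focal_of <- stats::setNames(follows$focal_id, follows$follow_id)
    a <- unname(focal_of[grooming_bouts$follow_id])
    b <- grooming_bouts$partner_id
    ok <- a %in% adults & b %in% adults
    acc <- tapply(grooming_bouts$duration[ok],
                  list(factor(a[ok], levels = adults),
                       factor(b[ok], levels = adults)), sum)
    acc[is.na(acc)] <- 0
    g[] <- acc
    g <- g + t(g)
  }
  denom <- outer(as.numeric(focal_sec), as.numeric(focal_sec), "+")
  m <- g / denom
  diag(m) <- 0
  structure(m, measure = "grooming", group_id = follows$group_id[1])
}

#' Dyadic Sociality Index
#'
#' Proximity is first reversed (`max_distance - mean distance`) so higher
#' values mean stronger association, then each measure is divided by its
#' mean across all dyads and the measures are averaged:
#' \deqn{DSI_{ab} = \frac{1}{d}\sum_{i=1}^{d} f_{i,ab} / \bar f_i}
#' with d = 2 measures. The across-dyad mean of the DSI is exactly 1. A
#' measure that is identically zero across dyads cannot be mean-normalized;
#' it is dropped with a warning and d reduced.
#'
#' @param grooming Grooming matrix from [grooming_matrix()].
#' @param proximity Proximity matrix in metres from [proximity_matrix()].
#' @param max_distance Reversal constant (metres), default 6.
#' @return Symmetric DSI matrix (attribute `measure = "dsi"`), non-negative,
#'   with mean over unordered dyads equal to 1.
#' @export
dsi <- function(grooming, proximity, max_distance = 6) {
  stopifnot(identical(rownames(grooming), rownames(proximity)))
  if (any(proximity[upper.tri(proximity)] > max_distance + 1e-9))
    stop("proximity entries exceed max_distance")
  rev_prox <- max_distance - proximity
  diag(rev_prox) <- 0
  measures <- list(grooming = grooming, proximity = rev_prox)
  ut <- upper.tri(grooming)
  means <- vapply(measures, function(m) mean(m[ut]), numeric(1))
  keep <- means > 0
  if (!all(keep)) {
    warning("measure(s) identically zero across dyads dropped from DSI: ",
            paste(names(measures)[!keep], collapse = ", "))
    measures <- measures[keep]
    means <- means[keep]
  }
  if (!length(measures)) stop("no usable sociality measure for DSI")
  acc <- 0
  for (i in seq_along(measures)) acc <- acc + measures[[i]] / means[i]
  m <- acc / length(measures)
  diag(m) <- 0
  structure(m, measure = "dsi", group_id = attr(grooming, "group_id"),
            reversed_proximity = rev_prox)
}

#' Reversed proximity matrix
#'
#' Convenience accessor: `max_distance - proximity`, the form in which
#' proximity enters the DSI and the strength measures (higher = stronger).
#'
#' @param proximity Matrix from [proximity_matrix()].
#' @param max_distance Reversal constant, default 6.
#' @return Symmetric matrix, attribute `measure = "reversed_proximity"`.
#' @export
reverse_proximity <- function(proximity, max_distance = 6) {
  m <- max_distance - proximity
  diag(m) <- 0
  structure(m, measure = "reversed_proximity",
            group_id = attr(proximity, "group_id"))
}
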