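#' @title Single-predictor Gaussian GLMs, LRT grid and AU clustering
#' @description
#' Every model has one predictor and a Gaussian error structure, and is
#' compared against the intercept-only null by a likelihood-ratio test
#' (chi-squared, 1 df). With maximum-likelihood variance the statistic has
#' the closed form `chi2 = n * ln(RSS_null / RSS_full) = -n * ln(1 - R2)`.
#' Models within a family are ranked by small-sample AICc with k = 3
#' parameters (intercept, slope, variance). No multiple-testing adjustment
#' is applied — the analysis is exploratory and adjustments there risk
#' type-II errors — so individual significant results warrant caution.
#' @name inference
NULL

#' Gaussian GLM with likelihood-ratio test against the intercept-only null
#'
#' Ordinary least squares for the full (`y ~ x`) and null (`y ~ 1`) models;
#' the LRT uses the Gaussian log-likelihood with maximum-likelihood
#' variance, so `chi2 = 2 * (ll_full - ll_null) = n * ln(RSS0/RSS1)` with
#' p from a chi-squared(1). A perfect fit (RSS = 0) is reported as
#' `chi2 = Inf`, `p = 0`, with a flag.
#'
#' @param x Predictor (numeric, length n >= 3).
#' @param y Outcome.
#' @param predictor,outcome Labels carried into the result.
#' @return One-row data.frame: `predictor, outcome, n, slope, intercept,
#'   rss_full, rss_null, chisq, p, r2, aicc, perfect_fit`.
#' @export
fit_glm_lrt <- function(x, y, predictor = "x", outcome = "y") {
  stopifnot(length(x) == length(y), length(x) >= 3)
  n <- length(x)
  rss_null <- sum((y - mean(y))^2)
  if (stats::sd(x) == 0) {
    warning("constant predictor: chi-squared = 0")
    coefs <- c(mean(y), 0)
    rss_full <- rss_null
  } else {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, x = x), y)
    coefs <- fit$coefficients
    rss_full <- sum(fit$residuals^2)
  }
  perfect <- rss_full < .Machine$double.eps * max(1, rss_null)
  if (perfect) {
    warning("perfect fit: likelihood ratio unbounded")
    chisq <- Inf; p <- 0; r2 <- 1; aicc <- -Inf
  } else {
    ll_full <- -n / 2 * (log(2 * pi) + log(rss_full / n) + 1)
    chisq <- if (rss_null == 0) 0 else n * log(rss_null / rss_full)
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
    r2 <- if (rss_null == 0) 0 else 1 - rss_full / rss_null
    k <- 3  # intercept, slope, ML variance
    aicc <- -2 * ll_full + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  }
  .df(predictor = predictor, outcome = outcome, n = n,
      slope = unname(coefs[2]), intercept = unname(coefs[1]),
      rss_full = rss_full, rss_null = rss_null,
      chisq = chisq, p = p, r2 = r2, aicc = aicc,
      perfect_fit = perfect)
}

#' The 3 x 11 expressivity-by-social-attribute model grid
#'
#' One Gaussian GLM per combination of expressivity predictor (AU rate, AU
#' duration, AU diversity) and social outcome (5 individual-level:
#' eigenvector, betweenness, nodal strength from grooming and proximity,
#' winning probability; 6 group-level: centralization, network strength
#' from grooming and proximity, modularity, group aggression, steepness),
#' each tested against its null by LRT.
#'
#' @param data Data.frame with one row per subject male containing the
#'   three predictor columns and eleven outcome columns (names below).
#' @return Data.frame of 33 [fit_glm_lrt()] rows.
#' @export
run_model_grid <- function(data) {
  predictors <- c("au_rate", "au_duration", "au_diversity")
  outcomes <- c("eigenvector", "betweenness", "strength_nodal_grooming",
                "strength_nodal_proximity", "winning_probability",
                "centralization", "strength_network_grooming",
                "strength_network_proximity", "modularity",
                "group_aggression", "steepness")
  missing <- setdiff(c(predictors, outcomes), names(data))
  if (length(missing))
    stop("model grid input lacks column(s): ",
         paste(missing, collapse = ", "))
  bad <- !stats::complete.cases(data[c(predictors, outcomes)])
  if (any(bad))
    stop("missing cell(s) for subject(s): ",
         paste(which(bad), collapse = ", "))
  res <- list()
  for (o in outcomes)
    for (p in predictors)
      res[[paste(p, o)]] <- fit_glm_lrt(data[[p]], data[[o]], p, o)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-AU exploratory models of eigenvector centrality
#'
#' One model per action unit: the predictor is the AU's proportion of the
#' male's overall facial movement, the outcome his eigenvector centrality.
#' Models are ranked by AICc (best = 0 on the `delta_aicc` column); R2
#' orders identically for a fixed outcome.
#'
#' @param proportions Subjects x AU proportion matrix (17 columns).
#' @param eigenvector Eigenvector centrality per subject (same row order).
#' @return Data.frame of ranked [fit_glm_lrt()] rows with `delta_aicc` and
#'   the AU face `region`.
#' @export
per_au_models <- function(proportions, eigenvector) {
  vocab <- maqfacs_vocabulary()
  stopifnot(all(vocab$code %in% colnames(proportions)),
            nrow(proportions) == length(eigenvector))
  res <- lapply(vocab$code, function(au) {
    if (all(proportions[, au] == proportions[1, au])) {
      warning("AU with constant proportion across males: ", au)
    }
    fit_glm_lrt(proportions[, au], eigenvector, au, "eigenvector")
  })
  out <- do.call(rbind, res)
  out$region <- vocab$region[match(out$predictor, vocab$code)]
  out <- out[order(out$aicc), ]
  out$delta_aicc <- out$aicc - out$aicc[1]
  rownames(out) <- NULL
  out
}

# mean silhouette width of a k-means partition; singleton clusters get 0
.mean_silhouette <- function(points, membership) {
  sil <- cluster::silhouette(membership, stats::dist(points))
  if (length(sil) == 1 && is.na(sil)) return(NA_real_)
  mean(sil[, "sil_width"])
}

#' Cluster action units by their proportion profiles
#'
#' Each AU is a point in male-space (its proportion in every male's
#' repertoire); Euclidean k-means with multi-restart is run for k = 2 up
#' to the number of AUs, the mean silhouette width is computed for each k,
#' and the k with the highest silhouette is chosen (ties go to the
#' smallest k). Member AUs are aggregated by summing their proportions
#' within each male, so mass is conserved.
#'
#' @param proportions Subjects x AU proportion matrix.
#' @param k_range Candidate numbers of clusters, default 2 to n AUs.
#' @param restarts k-means restarts (default 50).
#' @param seed Seed fixed for the scan (default 42).
#' @return List of class `maqsoc_clusters`: `k` (chosen), `silhouette`
#'   (data.frame `k, mean_silhouette`), `membership` (named by AU),
#'   `cluster_proportions` (subjects x k matrix), `members` (list).
#' @export
cluster_aus <- function(proportions, k_range = NULL, restarts = 50,
                        seed = 42) {
  pts <- t(proportions)           # AUs as points in male-space
  n_pts <- nrow(pts)
  stopifnot(n_pts >= 2, ncol(pts) >= 2)
  n_distinct <- nrow(unique(pts))
  if (n_distinct == 1)
    stop("all AU profiles identical: clustering degenerate")
  if (is.null(k_range)) k_range <- 2:n_pts
  sil <- rep(NA_real_, length(k_range))
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    if (k > n_distinct) {
      warning("k = ", k, " exceeds the number of distinct AU profiles; ",
              "skipped")
      next
    }
    if (k == n_pts) {
      # every AU its own cluster: silhouette width is 0 by convention
      fits[[i]] <- list(cluster = stats::setNames(seq_len(n_pts),
                                                  rownames(pts)))
      sil[i] <- 0
      next
    }
    set.seed(seed + k)
    km <- stats::kmeans(pts, centers = k, nstart = restarts,
                        iter.max = 100)
    fits[[i]] <- km
    sil[i] <- .mean_silhouette(pts, km$cluster)
  }
  best <- which(sil == max(sil, na.rm = TRUE))[1]   # ties -> smallest k
  km <- fits[[best]]
  agg <- sapply(seq_len(k_range[best]), function(cl)
    rowSums(proportions[, names(km$cluster)[km$cluster == cl],
                        drop = FALSE]))
  colnames(agg) <- paste0("cluster", seq_len(k_range[best]))
  members <- split(names(km$cluster), km$cluster)
  names(members) <- colnames(agg)
  structure(list(k = k_range[best],
                 silhouette = data.frame(k = k_range,
                                         mean_silhouette = sil),
                 membership = km$cluster,
                 cluster_proportions = agg,
                 members = members),
            class = "maqsoc_clusters")
}

#' Cluster-level models of eigenvector centrality
#'
#' One model per AU cluster: the predictor is the summed proportion of the
#' cluster's member AUs in each male's repertoire, the outcome his
#' eigenvector centrality; AICc-ranked like [per_au_models()].
#'
#' @param clusters A [cluster_aus()] result.
#' @param eigenvector Eigenvector centrality per subject (row order of the
#'   proportion matrix).
#' @return Ranked data.frame with a `members` column listing each
#'   cluster's AUs.
#' @export
cluster_models <- function(clusters, eigenvector) {
  agg <- clusters$cluster_proportions
  stopifnot(nrow(agg) == length(eigenvector))
  res <- lapply(colnames(agg), function(cl)
    fit_glm_lrt(agg[, cl], eigenvector, cl, "eigenvector"))
  out <- do.call(rbind, res)
  out$members <- vapply(out$predictor, function(cl)
    paste(clusters$members[[cl]], collapse = "+"), character(1))
  out <- out[order(out$aicc), ]
  out$delta_aicc <- out$aicc - out$aicc[1]
  rownames(out) <- NULL
  out
}
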