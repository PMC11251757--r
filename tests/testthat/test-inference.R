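test_that("the worked GLM/LRT example is reproduced exactly", {
  fit <- fit_glm_lrt(c(1, 2, 3), c(1, 2, 2))
  expect_equal(fit$slope, 0.5)
  expect_equal(fit$rss_full, 1 / 6)
  expect_equal(fit$rss_null, 2 / 3)
  expect_equal(fit$r2, 0.75)
  expect_equal(fit$chisq, 3 * log(4))
  orc <- oracle_lrt(c(1, 2, 3), c(1, 2, 2))
  expect_equal(fit$chisq, orc$chisq, tolerance = 1e-12)
  expect_equal(fit$p, orc$p, tolerance = 1e-12)
})

test_that("chi-squared equals the glm/lrtest route and the RSS identity", {
  skip_if_not_installed("lmtest")
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    x <- rnorm(n); y <- 0.4 * x + rnorm(n)
    fit <- fit_glm_lrt(x, y)
    full <- stats::glm(y ~ x, family = gaussian())
    null <- stats::glm(y ~ 1, family = gaussian())
    lr <- lmtest::lrtest(null, full)
    expect_equal(fit$chisq, lr$Chisq[2], tolerance = 1e-9)
    expect_equal(fit$p, lr$`Pr(>Chisq)`[2], tolerance = 1e-9)
    expect_equal(fit$chisq, -n * log(1 - fit$r2), tolerance = 1e-9)
    expect_equal(fit$aicc,
                 -2 * as.numeric(stats::logLik(full)) + 6 + 24 / (n - 4),
                 tolerance = 1e-9)
  }
})

test_that("LRT is invariant to affine rescaling of x and y", {
  set.seed(13)
  x <- rnorm(12); y <- 0.7 * x + rnorm(12)
  base <- fit_glm_lrt(x, y)
  resc <- fit_glm_lrt(3 * x - 5, -2 * y + 11)
  expect_equal(resc$chisq, base$chisq, tolerance = 1e-9)
  expect_equal(resc$r2, base$r2, tolerance = 1e-9)
})

test_that("degenerate fits are flagged rather than mis-reported", {
  expect_warning(fit <- fit_glm_lrt(rep(2, 5), rnorm(5)), "constant")
  expect_equal(fit$chisq, 0)
  expect_equal(fit$r2, 0)
  x <- 1:6
  expect_warning(fit2 <- fit_glm_lrt(x, 2 * x + 1), "perfect")
  expect_true(fit2$perfect_fit)
  expect_equal(fit2$chisq, Inf)
  expect_equal(fit2$p, 0)
})

test_that("the model grid covers 3 x 11 cells and is deterministic", {
  set.seed(14)
  outcomes <- c("eigenvector", "betweenness", "strength_nodal_grooming",
                "strength_nodal_proximity", "winning_probability",
                "centralization", "strength_network_grooming",
                "strength_network_proximity", "modularity",
                "group_aggression", "steepness")
  df <- as.data.frame(setNames(
    lapply(c("au_rate", "au_duration", "au_diversity", outcomes),
           function(i) rnorm(9)),
    c("au_rate", "au_duration", "au_diversity", outcomes)))
  grid <- run_model_grid(df)
  expect_equal(nrow(grid), 33)
  expect_equal(sort(unique(grid$predictor)),
               sort(c("au_rate", "au_duration", "au_diversity")))
  # a duplicated outcome column yields identical test rows
  df2 <- df; df2$betweenness <- df2$eigenvector
  g2 <- run_model_grid(df2)
  expect_equal(g2$chisq[g2$outcome == "betweenness"],
               g2$chisq[g2$outcome == "eigenvector"])
  df3 <- df; df3$modularity <- NULL
  expect_error(run_model_grid(df3), "modularity")
})

test_that("per-AU table is ranked by AICc and composes fit_glm_lrt", {
  set.seed(15)
  vocab <- maqfacs_vocabulary()$code
  props <- matrix(rexp(9 * 17), 9, dimnames = list(paste0("M", 1:9),
                                                   vocab))
  props <- props / rowSums(props)
  ec <- rnorm(9)
  tab <- per_au_models(props, ec)
  expect_equal(nrow(tab), 17)
  expect_equal(tab$delta_aicc[1], 0)
  expect_true(!is.unsorted(tab$delta_aicc))
  for (i in c(1, 9, 17)) {
    au <- tab$predictor[i]
    direct <- fit_glm_lrt(props[, au], ec)
    expect_equal(tab$chisq[i], direct$chisq)
    expect_equal(tab$r2[i], direct$r2)
  }
  # ranking invariant to the order of input rows
  perm <- sample(9)
  tab2 <- per_au_models(props[perm, ], ec[perm])
  expect_equal(tab2$predictor, tab$predictor)
  expect_equal(tab2$chisq, tab$chisq, tolerance = 1e-12)
  # face regions follow the vocabulary
  expect_equal(tab$region[tab$predictor == "EAU2"], "ears")
})

test_that("k-means clustering recovers planted AU groups and conserves mass", {
  set.seed(16)
  males <- 6
  centre_a <- rep(0.1, males); centre_b <- rep(0.9, males)
  pts <- rbind(
    t(replicate(4, centre_a + rnorm(males, 0, 0.01))),
    t(replicate(4, centre_b + rnorm(males, 0, 0.01))))
  vocab8 <- maqfacs_vocabulary()$code[1:8]
  rownames(pts) <- vocab8
  props <- t(pts)   # males x AUs
  cl <- cluster_aus(props, k_range = 2:7)
  expect_equal(cl$k, 2)
  expect_equal(length(unique(cl$membership[vocab8[1:4]])), 1)
  expect_equal(length(unique(cl$membership[vocab8[5:8]])), 1)
  # aggregated proportions conserve each male's total
  expect_equal(unname(rowSums(cl$cluster_proportions)),
               unname(rowSums(props)), tolerance = 1e-12)
  # identical AU profiles are degenerate
  same <- matrix(0.25, 4, 4,
                 dimnames = list(paste0("M", 1:4), vocab8[1:4]))
  expect_error(cluster_aus(same), "degenerate")
})

test_that("silhouette-based k selection picks the planted k", {
  set.seed(18)
  males <- 9
  centres <- matrix(runif(3 * males), 3)
  pts <- centres[rep(1:3, times = c(6, 6, 5)), ] +
    matrix(rnorm(17 * males, 0, 0.02), 17)
  rownames(pts) <- maqfacs_vocabulary()$code
  props <- t(pts)
  cl <- cluster_aus(props)
  expect_equal(cl$k, 3)
  expect_equal(cl$silhouette$k, 2:17)
  expect_true(all(cl$silhouette$mean_silhouette >= -1 &
                  cl$silhouette$mean_silhouette <= 1, na.rm = TRUE))
  tab <- cluster_models(cl, rnorm(males))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$delta_aicc[1], 0)
})

test_that("cluster-level models compose fit_glm_lrt", {
  set.seed(19)
  vocab <- maqfacs_vocabulary()$code
  props <- matrix(rexp(8 * 17), 8, dimnames = list(paste0("M", 1:8),
                                                   vocab))
  props <- props / rowSums(props)
  ec <- rnorm(8)
  cl <- cluster_aus(props)
  tab <- cluster_models(cl, ec)
  expect_equal(nrow(tab), cl$k)
  for (i in seq_len(nrow(tab))) {
    direct <- fit_glm_lrt(cl$cluster_proportions[, tab$predictor[i]], ec)
    expect_equal(tab$chisq[i], direct$chisq)
  }
  expect_true(all(diff(tab$aicc) >= 0))
})
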