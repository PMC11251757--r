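#!/usr/bin/env Rscript

# Stage 5: the statistical surface.
#
# (i) 3 x 11 grid of single-predictor Gaussian GLMs (AU rate, duration,
# diversity against the individual and group social attributes), each
# compared with its intercept-only null by likelihood-ratio test; (ii) one
# exploratory model per action unit against eigenvector centrality, AICc
# ranked; (iii) k-means clustering of AU proportions with silhouette-based
# k selection and cluster-level models. P-values are unadjusted: this is
# an exploratory analysis, and single significant cells deserve caution.

library(maqsoc)

data <- read_observations("results/observations")
config <- run_config()
a <- analyze_study(data, config)

grid <- run_model_grid(a$grid_data)
write.csv(grid, "results/model_grid.csv", row.names = FALSE)

male_order <- match(a$grid_data$male_id, rownames(a$profiles$proportions))
props <- a$profiles$proportions[male_order, , drop = FALSE]

per_au <- per_au_models(props, a$grid_data$eigenvector)
write.csv(per_au, "results/per_au_models.csv", row.names = FALSE)

cl <- cluster_aus(props, restarts = config$kmeans_restarts,
                  seed = config$kmeans_seed)
write.csv(cl$silhouette, "results/silhouette_scan.csv", row.names = FALSE)
cl_tab <- cluster_models(cl, a$grid_data$eigenvector)
write.csv(cl_tab, "results/cluster_models.csv", row.names = FALSE)

sig <- grid[grid$p < 0.05, c("predictor", "outcome", "chisq", "p")]
cat(sprintf("model grid: %d tests, %d with p < 0.05 (no adjustment)\n",
            nrow(grid), nrow(sig)))
if (nrow(sig)) print(sig, row.names = FALSE, digits = 3)
cat(sprintf("best per-AU predictor of centrality: %s (chi2 = %.2f)\n",
            per_au$predictor[1], per_au$chisq[1]))
cat(sprintf("silhouette-optimal k = %d; best cluster: %s (chi2 = %.2f)\n",
            cl$k, cl_tab$members[1], cl_tab$chisq[1]))
cat("tables in results/model_grid.csv, per_au_models.csv, cluster_models.csv\n")
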