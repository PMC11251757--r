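#!/usr/bin/env Rscript

# Stage 3: dominance attributes from the agonistic record.
#
# Sequential Elo ratings per group give expected pairwise winning
# probabilities; from these the males' normalized summed winning
# probability, the group hierarchy steepness, and the aggression rate per
# observation hour per individual. Writes results/dominance_summary.csv.

library(maqsoc)

data <- read_observations("results/observations")
config <- run_config()

ind <- data$individuals[data$individuals$age_class == "adult", ]
rows <- lapply(unique(ind$group_id), function(gid) {
  ad <- ind[ind$group_id == gid, ]
  ag <- data$agonistic[data$agonistic$group_id == gid, ]
  fo <- data$follows[data$follows$group_id == gid, ]
  dom <- dominance_summary(ag, ad$id, ad$id[ad$is_subject_male],
                           sum(fo$duration) / 3600, config)
  data.frame(group_id = gid, n_adults = nrow(ad), n_events = nrow(ag),
             male_winning_probability = dom$winning_probability,
             steepness = dom$steepness, aggression = dom$aggression)
})
out <- do.call(rbind, rows)
write.csv(out, "results/dominance_summary.csv", row.names = FALSE)

cat(sprintf("steepness: %.2f-%.2f | male normalized SWP: %.2f-%.2f\n",
            min(out$steepness), max(out$steepness),
            min(out$male_winning_probability),
            max(out$male_winning_probability)))
cat("summary in results/dominance_summary.csv\n")
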