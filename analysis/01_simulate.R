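#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study.
#
# Nine single-male rhesus groups (66 adults, sizes 6-9) observed as in the
# study design: ~3.4 h of focal follows per individual with 2-min scans,
# ad libitum agonistic records, and ~2 h of raw close-up footage per male
# carrying MaqFACS-coded action units with out-of-sight and feeding
# intervals. Writes the observation CSVs under results/observations/.

library(maqsoc)

seed <- 42
out <- "results/observations"

d <- simulate_study(sim_params(), seed = seed)
write_observations(d[names(d) != "truth"], out)
write.csv(d$truth, file.path(out, "truth.csv"), row.names = FALSE)

vocab <- maqfacs_vocabulary()$code
au <- d$au_events[d$au_events$au_code %in% vocab, ]
cat(sprintf("groups: %d | adults: %d (mean %.2f/group)\n",
            length(unique(d$individuals$group_id)),
            nrow(d$individuals),
            nrow(d$individuals) / length(unique(d$individuals$group_id))))
cat(sprintf("focal hours/individual: %.2f | AU events/male: %.0f\n",
            sum(d$follows$duration) / 3600 / nrow(d$individuals),
            nrow(au) / 9))
cat("observation tables written to", out, "\n")
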