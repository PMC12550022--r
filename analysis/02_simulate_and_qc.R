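#!/usr/bin/env Rscript
# Step 2 — simulate crowdsourced collections and apply quality control.
#
# Two simulated datasets: a clean recovery-study collection (compliant
# workers only) and a contaminated one with planted speeders and
# position-biased workers. The QC stage must pass the former untouched and
# strip exactly the contaminants from the latter. Also estimates the
# chance-level choice consistency of uniform responders.

library(sposer)
dir.create("results", showWarnings = FALSE)

## Recovery-study collection --------------------------------------------------
sim <- simulate_recovery_dataset(seed = 101)
print(sim)
qc <- qc_report(sim$choices)
print(qc)
write_choices_tsv(qc$retained, "results/choices_retained.tsv")
write_embedding_tsv(sim$truth, "results/ground_truth_embedding.tsv")

## Contaminated collection ----------------------------------------------------
simc <- simulate_contaminated_dataset(seed = 202)
qcc <- qc_report(simc$choices)
print(qcc)
planted <- attr(simc, "contaminants")
cat(sprintf("Planted contaminants: %d; excluded: %d; false exclusions: %d\n",
            length(planted),
            sum(qcc$excluded_workers$worker_id %in% planted),
            sum(!qcc$excluded_workers$worker_id %in% planted)))
write.table(qcc$excluded_workers, "results/qc_excluded_workers.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

## Chance-level consistency ---------------------------------------------------
zero <- matrix(0, 24, 1, dimnames = list(sprintf("i%02d", 1:24), NULL))
des <- suppressWarnings(build_design(rownames(zero), repeat_n_triplets = 1000,
                                     repeat_count = 10, pair_coverage = 0,
                                     set_size = 32, seed = 303))
uni <- simulate_dataset(zero, des,
                        lapply(1:5, function(i)
                          worker_profile(paste0("u", i), lapse_rate = 1)),
                        seed = 304)
cat(sprintf("Uniform-responder consistency: %.2f%% (chance = 33.3%%)\n",
            100 * choice_consistency(uni$choices)))

qc_df <- data.frame(
  quantity = c("clean_retained_percent", "clean_consistency_percent",
               "contaminated_retained_percent", "contaminants_excluded",
               "false_exclusions", "uniform_consistency_percent"),
  value = c(100 * qc$retained_fraction, 100 * qc$consistency,
            100 * qcc$retained_fraction,
            sum(qcc$excluded_workers$worker_id %in% planted),
            sum(!qcc$excluded_workers$worker_id %in% planted),
            100 * choice_consistency(uni$choices)))
write.table(qc_df, "results/qc_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
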