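#!/usr/bin/env Rscript
# Step 1 — experiment design arithmetic and a materialized reduced design.
#
# Reproduces the sampling plan of the full-scale collection (768 stimuli;
# two exhaustive passes over a 48-item subset, 1,000 triplets repeated 40
# times, and 4 triplets per stimulus pair) and materializes a reduced
# design at simulation scale for the later steps.

library(sposer)
dir.create("results", showWarnings = FALSE)

plan <- design_plan(768, subset_size = 48, subset_passes = 2,
                    repeat_n_triplets = 1000, repeat_count = 40,
                    pair_coverage = 4, set_size = 32)
cat(sprintf("Full-scale plan: %s trials (%s exhaustive + %s repeat + %s main) in %s sets of 32\n",
            format(plan$n_total, big.mark = ","),
            format(plan$n_exhaustive, big.mark = ","),
            format(plan$n_repeat, big.mark = ","),
            format(plan$n_main, big.mark = ","),
            format(plan$n_sets, big.mark = ",")))
cat(sprintf("Possible triplets: %s (%.1f million); pilot subset coverage %.1f%%\n",
            format(count_triplets(768), big.mark = ","),
            count_triplets(768) / 1e6, unique_percent(6720, 48)))

plan_df <- data.frame(quantity = c("n_exhaustive", "n_repeat", "n_main",
                                   "n_total", "n_sets"),
                      value = c(plan$n_exhaustive, plan$n_repeat, plan$n_main,
                                plan$n_total, plan$n_sets))
write.table(plan_df, "results/design_plan_full_scale.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# Reduced design used by the simulation study: 60 items, 17 triplets per
# pair, plus a repeat block for consistency estimation.
items <- sprintf("item_%03d", 1:60)
design <- suppressWarnings(
  build_design(items, repeat_n_triplets = 500, repeat_count = 10,
               pair_coverage = 17, set_size = 32, seed = 101))
print(design)
write_design_tsv(design, "results/design_reduced.tsv")
cat("Reduced design written to results/design_reduced.tsv\n")
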