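#!/usr/bin/env Rscript
# Step 5 — stimulus-database curation on synthetic classifier outputs:
# best-frame selection, category representatives, cosine dissimilarities,
# hierarchical clustering into meta-clusters, and the naming-accuracy
# exclusion rule.

library(sposer)
dir.create("results", showWarnings = FALSE)

## Synthetic per-frame class probabilities: 12 categories x 3 videos x 10
## frames over 12 classes, with block structure (triplets of related
## categories share probability mass).
classes <- sprintf("act_%02d", 1:12)
frames <- withr::with_seed(71, {
  rows <- list()
  for (ci in seq_along(classes)) {
    for (v in 1:3) {
      block <- (ci - 1) %/% 3            # 4 blocks of 3 related categories
      base <- rep(0.02, 12)
      base[(block * 3 + 1):(block * 3 + 3)] <- 0.15
      base[ci] <- 0.5
      for (f in 1:10) {
        p <- base + runif(12, 0, 0.08)
        p <- p / sum(p)
        rows[[length(rows) + 1]] <- data.frame(
          video = sprintf("%s_v%d", classes[ci], v),
          category = classes[ci], frame = f,
          t(setNames(p, classes)))
      }
    }
  }
  do.call(rbind, rows)
})

reps <- category_representatives(frames)
D <- cosine_dissimilarity_matrix(reps)
hc <- hierarchical_clusters(D, linkage = "average", k = 4)
cat("Cluster assignments:\n")
print(hc$assignments)
cat(sprintf("Mean categories per meta-cluster: %.2f\n", hc$mean_cluster_size))

write.table(data.frame(category = names(hc$assignments),
                       cluster = hc$assignments),
            "results/curation_clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(hc$merges, "results/curation_dendrogram_merges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## Naming-accuracy exclusion on synthetic validation accuracies ----------------
acc <- withr::with_seed(72, data.frame(
  category = rep(classes, each = 3),
  exemplar = rep(1:3, length(classes)),
  accuracy = pmin(1, pmax(0, rep(c(0.9, 0.88, 0.6, 0.55), each = 9) +
                               rnorm(36, 0, 0.05)))))
flt <- naming_accuracy_filter(acc, threshold = 0.7)
cat(sprintf("Categories excluded for poor naming accuracy: %d of %d\n",
            sum(flt$excluded), nrow(flt)))
write.table(flt, "results/naming_accuracy_filter.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
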