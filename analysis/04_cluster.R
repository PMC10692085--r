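#!/usr/bin/env Rscript
# Unsupervised stage: outlier screen, elbow-selected k-means on the
# movement embeddings, 2-D visualization coordinates, and the
# cluster-vs-expert-score cross-tabulation.

library(caninecoping)

emb <- read.csv("results/embeddings.csv", check.names = FALSE)
Z <- as.matrix(emb[, -1])
rownames(Z) <- emb$trial_id

clus <- cluster_trials(Z, k_max = 8, seed = 9)
write.csv(clus$inertia_curve, "results/inertia_curve.csv", row.names = FALSE)
write.csv(data.frame(trial_id = names(clus$assignments),
                     cluster = clus$assignments),
          "results/clusters.csv", row.names = FALSE)

cat(sprintf("outliers excluded: %d (%s)\n", length(clus$excluded_outliers),
            paste(clus$excluded_outliers, collapse = ", ")))
cat(sprintf("elbow-selected k = %d; cluster sizes: %s\n", clus$k_selected,
            paste(table(clus$assignments), collapse = " / ")))

# 2-D map for plotting, normalized to the unit square
Y <- project_2d(Z[names(clus$assignments), ], seed = 9)
write.csv(data.frame(trial_id = rownames(Y), Y,
                     cluster = clus$assignments[rownames(Y)]),
          "results/tsne_coordinates.csv", row.names = FALSE)

# cross-tabulate clusters against the majority expert label
ratings <- read.csv("results/cohort/ratings.csv",
                    colClasses = "character")
votes <- collapse_and_vote(ratings)
labels <- setNames(votes$majority, votes$trial_id)
xt <- crosstab(clus$assignments, labels[names(clus$assignments)])
print(xt)
write.csv(as.data.frame.matrix(xt), "results/crosstab.csv")
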