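#!/usr/bin/env Rscript
# Validation statistics: inter-rater agreement of the expert panel and the
# Mann-Whitney comparison of each C-BARQ category between the two clusters.

library(caninecoping)

## agreement on the full 53-dog panel: the 50 simulated trials plus the
## three negative-scored dogs (rating-only rows, rated unanimously)
ratings <- read.csv("results/cohort/ratings.csv",
                    colClasses = "character")
negatives <- generate_ratings(rep("away", 3), seed = 53, unanimous = rep(TRUE, 3),
                              trial_ids = sprintf("neg_%d", 1:3))
panel <- rbind(ratings[, c("rater1", "rater2", "rater3")],
               negatives[, c("rater1", "rater2", "rater3")])
agr <- agreement_report(panel)
cat(sprintf("agreement: n = %d, Po = %.3f (%.0f%%), free-marginal kappa = %.2f\n",
            agr$n_subjects, agr$percent_agreement,
            100 * agr$percent_agreement, agr$kappa))
write.csv(data.frame(n_subjects = agr$n_subjects,
                     percent_agreement = agr$percent_agreement,
                     kappa = agr$kappa),
          "results/agreement.csv", row.names = FALSE)

## C-BARQ category differences between the two clusters
clusters <- read.csv("results/clusters.csv")
cbarq <- read.csv("results/cohort/cbarq.csv")
assign <- setNames(clusters$cluster, clusters$trial_id)
cmp <- compare_clusters_cbarq(cbarq, assign)
print(cmp, digits = 3)
write.csv(cmp, "results/cbarq_comparison.csv", row.names = FALSE)
sig <- cmp$category[cmp$p < 0.05]
cat(sprintf("categories with p < 0.05: %s\n",
            if (length(sig)) paste(sig, collapse = ", ") else "none"))
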