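#!/usr/bin/env Rscript
# Supervised stage: budgeted pipeline search for the expert-score
# classifier and one regressor per C-BARQ category, on the movement
# embeddings of the clustered trials.

library(caninecoping)

emb <- read.csv("results/embeddings.csv", check.names = FALSE)
Z <- as.matrix(emb[, -1]); rownames(Z) <- emb$trial_id
clusters <- read.csv("results/clusters.csv")
ratings <- read.csv("results/cohort/ratings.csv", colClasses = "character")
cbarq <- read.csv("results/cohort/cbarq.csv")

votes <- collapse_and_vote(ratings)
labels <- setNames(votes$majority, votes$trial_id)
ids <- clusters$trial_id[!is.na(labels[clusters$trial_id]) &
                           labels[clusters$trial_id] != "-"]
X <- Z[ids, , drop = FALSE]

cls <- pipeline_search(X, labels[ids],
                       search_config("classification", budget = 200,
                                     seed = 7))
cat(sprintf("classifier (n = %d, budget 200): accuracy %.3f, precision %.3f, recall %.3f, F1 %.3f\n",
            length(ids), cls$report$accuracy, cls$report$precision,
            cls$report$recall, cls$report$f1))
write.csv(data.frame(metric = names(cls$report),
                     value = unlist(cls$report)),
          "results/classifier_metrics.csv", row.names = FALSE)

reg <- do.call(rbind, lapply(cbarq_categories(), function(cat) {
  y <- cbarq[[cat]][match(ids, cbarq$trial_id)]
  r <- pipeline_search(X, y, search_config("regression", budget = 100,
                                           seed = 7))$report
  data.frame(category = cat, mae = r$mae, mse = r$mse, r2 = r$r2)
}))
print(reg, digits = 3)
write.csv(reg, "results/regression_metrics.csv", row.names = FALSE)
cat(sprintf("best MSE: %s (%.3f); best R2: %s (%.3f)\n",
            reg$category[which.min(reg$mse)], min(reg$mse),
            reg$category[which.max(reg$r2)], max(reg$r2)))
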