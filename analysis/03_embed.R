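#!/usr/bin/env Rscript
# Train the 1-D convolutional autoencoder on the trajectory dataset and
# embed every trial into the movement space used for clustering.

library(caninecoping)

dataset <- readRDS("results/dataset.rds")

trained <- train_autoencoder(dataset, seed = 7)
Z <- encode(trained$model, dataset)

write.csv(trained$grid_results, "results/embedding_grid.csv",
          row.names = FALSE)
write.csv(trained$log, "results/embedding_log.csv", row.names = FALSE)
write.csv(data.frame(trial_id = rownames(Z), Z, check.names = FALSE),
          "results/embeddings.csv", row.names = FALSE)

sel <- trained$selected
cat(sprintf("selected grid point: %d filters, lr %g (val MAE %.3f m)\n",
            sel$n_filters, sel$learning_rate, sel$val_mae))
cat(sprintf("movement space: %d trials x %d dimensions\n",
            nrow(Z), ncol(Z)))
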