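#!/usr/bin/env Rscript
# Stage 4 — the cross-platform rank-pair classifier.
#
# Builds the 780 binary gene-pair features, trains the random forest on
# the discovery assignment, reports OOB error / AUC and the importance
# ranking, then subtypes the platform-shifted validation cohort by NMF
# and measures how well the transferred classifier reproduces it.

suppressPackageStartupMessages(library(pyropattern))
SEED <- 1
dat <- "results/data"
out <- "results/classifier"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

expr <- read_matrix_tsv(file.path(dat, "discovery_expr.tsv"))
vexpr <- read_matrix_tsv(file.path(dat, "validation_expr.tsv"))
asg <- utils::read.delim("results/subtyping/assignment.tsv")
panel <- pyroptosis_panel()

F <- pair_features(expr, panel)
message(nrow(F), " rank-pair features over the ", length(panel),
        "-gene panel")
model <- train_classifier(F, asg, n_trees = 500,
                          seed = derive_seed(SEED, "forest"))
oob_auc <- pair_auc(model$oob_votes[, "C2"],
                    asg$subtype[match(rownames(model$oob_votes),
                                      asg$sample_id)])
message(sprintf("training cohort: OOB error %.3f, OOB AUC %.3f",
                model$oob_error, oob_auc))
top <- model$importance[order(-model$importance$mean_decrease_accuracy), ]
message("top pairs by mean decrease accuracy: ",
        paste(utils::head(top$pair, 5), collapse = ", "))

vnmf <- nmf_factorize(vexpr[panel, ], k = 2, n_restarts = 30,
                      seed = derive_seed(SEED, "nmf_validation"))
vpred <- predict(model, pair_features(vexpr, panel))
v_auc <- pair_auc(vpred$score, vnmf$assignment$subtype)
message(sprintf(
  "validation cohort (noisy monotone platform): transfer AUC %.3f, %d/%d labels agree",
  v_auc, sum(vpred$subtype == vnmf$assignment$subtype), nrow(vpred)))

write_table_tsv(top, file.path(out, "pair_importance.tsv"))
write_table_tsv(vpred, file.path(out, "validation_predictions.tsv"))
write_table_tsv(data.frame(metric = c("oob_error", "oob_auc",
                                      "validation_auc"),
                           value = c(model$oob_error, oob_auc, v_auc)),
                file.path(out, "classifier_metrics.tsv"))
message("tables under ", out)
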