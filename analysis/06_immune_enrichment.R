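#!/usr/bin/env Rscript
# Stage 6 — immune gene-set enrichment and prognostic set selection.
#
# Scores the gene-set collection per sample (ssGSEA-form running sum),
# contrasts enrichment between the two patterns in the discovery and the
# platform-shifted validation cohort with moderated t, intersects the
# C2-enriched sets across cohorts, selects prognostic sets by LASSO-Cox,
# and annotates their gene content by hypergeometric ORA.

suppressPackageStartupMessages(library(pyropattern))
SEED <- 1
dat <- "results/data"
out <- "results/enrichment"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

expr <- read_matrix_tsv(file.path(dat, "discovery_expr.tsv"))
vexpr <- read_matrix_tsv(file.path(dat, "validation_expr.tsv"))
surv <- read_table(file.path(dat, "discovery_surv.tsv"), "surv")
asg <- utils::read.delim("results/subtyping/assignment.tsv")
sets <- read_gmt(file.path(dat, "immune_sets.gmt"))
truth_sets <- readLines(file.path(dat, "enriched_truth.txt"))

esA <- es_score(expr, sets, alpha = 0.25, min_overlap = 5)
diffA <- moderated_t_diff(esA, asg)

vnmf <- nmf_factorize(vexpr[pyroptosis_panel(), ], k = 2, n_restarts = 30,
                      seed = derive_seed(SEED, "nmf_validation"))
esB <- es_score(vexpr, sets, alpha = 0.25, min_overlap = 5)
diffB <- moderated_t_diff(esB, vnmf$assignment)

nA <- sum(diffA$q < 0.05 & diffA$direction == "up_C2")
nB <- sum(diffB$q < 0.05 & diffB$direction == "up_C2")
inter <- enriched_intersection(diffA, diffB, "up_C2", 0.05)
message(sprintf(
  "sets enriched in ELANE-low: %d (discovery), %d (validation), %d shared; recall of implanted truth %d/%d",
  nA, nB, length(inter), sum(truth_sets %in% inter), length(truth_sets)))

lasso <- lasso_cox_select(esA[inter, , drop = FALSE], surv,
                          n_folds = 10, seed = derive_seed(SEED, "lasso"))
message("LASSO-Cox selects ", length(lasso$selected),
        " prognostic set(s): ", paste(lasso$selected, collapse = ", "))
sel_cox <- do.call(rbind, lapply(lasso$selected, function(s) {
  d <- cbind(surv, es = esA[s, surv$sample_id])
  cbind(set = s, cox_fit(d, "es"))
}))
if (!is.null(sel_cox))
  message("univariate Cox on the selected sets: HR ",
          paste(sprintf("%.2f", sel_cox$hr), collapse = ", "))

query <- unique(unlist(sets[lasso$selected]))
if (length(query) > 0) {
  ora <- ora_hypergeometric(query, sets, rownames(expr))
  message("ORA: ", sum(ora$q < 0.05), " annotation term(s) at q < 0.05")
} else {
  ora <- NULL
  message("no sets selected; ORA skipped")
}

write_table_tsv(diffA, file.path(out, "diff_es_discovery.tsv"))
write_table_tsv(diffB, file.path(out, "diff_es_validation.tsv"))
writeLines(inter, file.path(out, "intersection.txt"))
write_table_tsv(data.frame(set = lasso$selected,
                           coefficient = if (length(lasso$selected))
                             lasso$coefficients else numeric(0)),
                file.path(out, "lasso_selection.tsv"))
if (!is.null(sel_cox)) write_table_tsv(sel_cox,
                                       file.path(out, "selected_cox.tsv"))
if (!is.null(ora)) write_table_tsv(ora, file.path(out, "ora.tsv"))
message("tables under ", out)
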