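#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs.
#
# Builds the synthetic counterpart of the study design: a discovery
# cohort (77 + 55 samples over the 40-gene pyroptosis panel plus 200
# background genes, 19-gene subtype signature, subtype-linked survival),
# an independent validation cohort pushed through a noisy monotone
# platform distortion (microarray-vs-RNA-seq surrogate), a 16-sample
# single-cell dataset, and a 50-set gene-set collection with 10 sets
# enriched for the C2-up signature. Everything is written as TSV/GMT
# under results/data/.

suppressPackageStartupMessages(library(pyropattern))
SEED <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cp <- cohort_params(n_background = 200)
disc <- generate_cohort(cp, seed = derive_seed(SEED, "discovery"))
valid <- generate_cohort(cp, seed = derive_seed(SEED, "validation"))
shift <- platform_spec("monotone-nonlinear", gain = 1.5, curvature = 1.3,
                       pernoise_sd = 0.3)
valid_shifted <- platform_shift(valid$expr, shift,
                                seed = derive_seed(SEED, "shift"))

sc_cohort <- generate_cohort(cohort_params(n_c1 = 8, n_c2 = 8),
                             seed = derive_seed(SEED, "sc_bulk"))
sc <- generate_single_cell(sc_cohort$expr, sc_cohort$truth, sc_params(),
                           seed = derive_seed(SEED, "sc"))

sig <- subtype_signature()
gs <- generate_gene_sets(rownames(disc$expr), n_sets = 50,
                         n_enriched = 10, enrich_genes = sig$up_c2,
                         seed = derive_seed(SEED, "gene_sets"))

write_matrix_tsv(disc$expr, file.path(out, "discovery_expr.tsv"))
write_table_tsv(disc$surv, file.path(out, "discovery_surv.tsv"))
write_table_tsv(disc$truth, file.path(out, "discovery_truth.tsv"))
write_matrix_tsv(valid_shifted, file.path(out, "validation_expr.tsv"))
write_table_tsv(valid$surv, file.path(out, "validation_surv.tsv"))
write_table_tsv(valid$truth, file.path(out, "validation_truth.tsv"))
write_matrix_tsv(sc$counts, file.path(out, "sc_counts.tsv"))
write_table_tsv(sc$annotation, file.path(out, "sc_annotation.tsv"))
write_table_tsv(sc_cohort$truth, file.path(out, "sc_truth.tsv"))
write_gmt(gs$sets, file.path(out, "immune_sets.gmt"))
writeLines(gs$truth, file.path(out, "enriched_truth.txt"))

message("discovery: ", nrow(disc$expr), " genes x ", ncol(disc$expr),
        " samples (", sum(disc$truth$subtype == "C1"), " C1 / ",
        sum(disc$truth$subtype == "C2"), " C2)")
message("validation: ", ncol(valid_shifted),
        " samples after monotone platform shift")
message("single cell: ", ncol(sc$counts), " cells from ",
        length(unique(sc$annotation$sample_id)), " samples")
message("gene sets: ", length(gs$sets), " (", length(gs$truth),
        " enriched); inputs under ", out)
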