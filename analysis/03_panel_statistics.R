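#!/usr/bin/env Rscript
# Stage 3 — classical statistics on the panel.
#
# Mann-Whitney differential expression between the two patterns (the
# 19-gene signature), the panel correlation structure, per-gene Cox
# regression (univariate and age/sex-adjusted), and parallel-analysis
# factor extraction linking the pattern to clinical covariates.

suppressPackageStartupMessages(library(pyropattern))
SEED <- 1
dat <- "results/data"
out <- "results/prognostics"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

expr <- read_matrix_tsv(file.path(dat, "discovery_expr.tsv"))
surv <- read_table(file.path(dat, "discovery_surv.tsv"), "surv")
asg <- utils::read.delim("results/subtyping/assignment.tsv")
panel <- pyroptosis_panel()

de <- mannwhitney_de(expr[panel, ], asg)
called <- de$gene[de$q < 0.05]
message(length(called), " panel genes DE at q < 0.05 (",
        sum(de$direction[de$q < 0.05] == "up_C2", na.rm = TRUE),
        " up in C2): ", paste(sort(called), collapse = ", "))

corr <- pearson_matrix(expr[panel, ])
message(sprintf("strongest panel correlation: %s-%s r = %.2f",
  rownames(corr$r)[which(corr$r == max(corr$r[upper.tri(corr$r)]),
                         arr.ind = TRUE)[1, 1]],
  colnames(corr$r)[which(corr$r == max(corr$r[upper.tri(corr$r)]),
                         arr.ind = TRUE)[1, 2]],
  max(corr$r[upper.tri(corr$r)])))

dat_cox <- cbind(surv, as.data.frame(t(expr[panel, surv$sample_id])))
uni <- cox_batch(dat_cox, panel)
adj <- cox_batch(dat_cox, panel, adjusters = c("age", "sex"))
sig_uni <- uni$covariate[uni$q < 0.05]
message(length(sig_uni), " genes prognostic at FDR < 0.05 (univariate); ",
        sum(adj$covariate %in% sig_uni & adj$p < 0.05),
        " of them survive age/sex adjustment")

# factor analysis over pattern membership and encoded clinical covariates
enc <- rbind(
  pattern_c2 = as.numeric(asg$subtype == "C2"),
  age = surv$age[match(asg$sample_id, surv$sample_id)],
  sex_m = as.numeric(surv$sex[match(asg$sample_id,
                                    surv$sample_id)] == "M"),
  karyo_fav = as.numeric(surv$karyotype_risk[
    match(asg$sample_id, surv$sample_id)] == "favorable"),
  karyo_poor = as.numeric(surv$karyotype_risk[
    match(asg$sample_id, surv$sample_id)] == "poor"),
  elane = expr["ELANE", asg$sample_id],
  casp1 = expr["CASP1", asg$sample_id],
  zbp1 = expr["ZBP1", asg$sample_id])
fa <- parallel_factors(enc, n_sim = 100, seed = derive_seed(SEED, "fa"))
message("parallel analysis retains ", fa$n_factors, " factor(s)")

write_table_tsv(de, file.path(out, "differential_expression.tsv"))
write_matrix_tsv(round(corr$r, 6), file.path(out, "pearson_r.tsv"))
write_table_tsv(uni, file.path(out, "cox_univariate.tsv"))
write_table_tsv(adj, file.path(out, "cox_adjusted.tsv"))
if (!is.null(fa$loadings))
  write_matrix_tsv(round(fa$loadings, 6), file.path(out,
                                                    "factor_loadings.tsv"))
message("tables under ", out)
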