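# End-to-end orchestration: simulate (or load) -> subtype discovery ->
# rank-pair classifier -> platform-shifted validation -> pseudobulk ->
# differential expression / correlation / Cox / KM -> enrichment ->
# LASSO gene-set selection -> ORA -> hub genes. Every stochastic stage is
# seeded through derive_seed(seed, stage), so one config reproduces all
# numeric outputs bit for bit.

pipeline_defaults <- function() {
  list(preset = "simulate", seed = 1, out_dir = NULL,
       n_c1 = 77, n_c2 = 55, effect_size = 1.5, noise_sd = 1,
       hr_c2_vs_c1 = 2, censor_rate = 0.3, n_background = 200,
       k_range = 2:6, n_restarts = 30, n_trees = 500,
       validation_gain = 1.5, validation_curvature = 1.3,
       validation_pernoise = 0.3,
       n_sc_per_subtype = 8, cells_per_sample = 100,
       malignant_fraction = 0.7, library_size_mean = 5000, min_cells = 50,
       n_sets = 50, n_enriched = 10, set_size = c(10, 50),
       alpha = 0.25, min_overlap = 5, q_threshold = 0.05,
       lasso_folds = 10,
       expr_path = NULL, surv_path = NULL, gmt_path = NULL, panel = NULL)
}

#' Validate a pipeline configuration
#'
#' Merges user settings over the defaults; unknown keys are rejected
#' before any computation.
#'
#' @param config named list of overrides, or a path to a YAML file.
#' @return Validated config list of class `pipeline_config`.
#' @export
load_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  defs <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defs, config)
  if (!cfg$preset %in% c("simulate", "load"))
    stop("preset must be 'simulate' or 'load'")
  if (cfg$preset == "load") {
    for (f in c("expr_path", "surv_path")) {
      if (is.null(cfg[[f]])) stop("preset 'load' requires ", f)
      if (!file.exists(cfg[[f]])) stop("missing input file: ", cfg[[f]])
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full pyroptosis-pattern analysis
#'
#' Executes the whole workflow on a simulated preset (or loaded inputs)
#' and, when `out_dir` is set, writes every table as TSV plus a
#' machine-readable `summary.json` of headline numbers (selected k,
#' silhouette, AUCs, DE count, selected sets, hubs).
#'
#' @param config list / YAML path accepted by [load_config()].
#' @return Invisible list with all stage results and a `summary` list.
#' @export
run_full <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else load_config(config)
  seed <- cfg$seed
  panel <- cfg$panel %||% pyroptosis_panel()
  sig <- subtype_signature()

  # --- stage: cohorts ---------------------------------------------------
  if (cfg$preset == "simulate") {
    cp <- cohort_params(n_c1 = cfg$n_c1, n_c2 = cfg$n_c2,
                        effect_size = cfg$effect_size,
                        noise_sd = cfg$noise_sd,
                        hr_c2_vs_c1 = cfg$hr_c2_vs_c1,
                        censor_rate = cfg$censor_rate,
                        n_background = cfg$n_background)
    disc <- generate_cohort(cp, seed = derive_seed(seed, "discovery"))
    valid <- generate_cohort(cp, seed = derive_seed(seed, "validation"))
    shift <- platform_spec("monotone-nonlinear", gain = cfg$validation_gain,
                           curvature = cfg$validation_curvature,
                           pernoise_sd = cfg$validation_pernoise)
    valid_shifted <- platform_shift(valid$expr, shift,
                                    seed = derive_seed(seed, "shift"))
  } else {
    expr <- read_matrix_tsv(cfg$expr_path)
    surv <- read_table(cfg$surv_path, "surv")
    disc <- list(expr = expr, surv = surv, truth = NULL)
    valid <- NULL; valid_shifted <- NULL
  }

  # --- stage: subtype discovery ----------------------------------------
  sel <- select_k(disc$expr[panel, , drop = FALSE], k_range = cfg$k_range,
                  n_restarts = cfg$n_restarts,
                  seed = derive_seed(seed, "select_k"))
  nmf <- nmf_factorize(disc$expr[panel, , drop = FALSE], k = sel$k,
                       n_restarts = cfg$n_restarts,
                       seed = derive_seed(seed, "nmf"))
  groups <- nmf$assignment

  # --- stage: panel statistics -----------------------------------------
  de <- mannwhitney_de(disc$expr[panel, , drop = FALSE], groups)
  corr <- pearson_matrix(disc$expr[panel, , drop = FALSE])
  survdat <- disc$surv
  gene_cox <- local({
    dat <- cbind(survdat,
                 as.data.frame(t(disc$expr[panel, survdat$sample_id])))
    list(univariate = cox_batch(dat, panel),
         adjusted = cox_batch(dat, panel, adjusters = c("age", "sex")))
  })
  km_all <- km_logrank(survdat, groups)
  km_strata <- lapply(stats::setNames(nm = unique(survdat$karyotype_risk)),
                      function(s) {
    res <- tryCatch(km_logrank(survdat, groups, stratum = s),
                    error = function(e) NULL)
    if (is.null(res)) NULL else list(chisq = res$chisq, p = res$p,
                                     n = res$n)
  })

  # --- stage: rank-pair classifier -------------------------------------
  Ftr <- pair_features(disc$expr, panel)
  model <- train_classifier(Ftr, groups, n_trees = cfg$n_trees,
                            seed = derive_seed(seed, "forest"))
  oob_auc <- pair_auc(model$oob_votes[, model$classes[2]],
                      groups$subtype[match(rownames(model$oob_votes),
                                           groups$sample_id)])
  if (!is.null(valid)) {
    vnmf <- nmf_factorize(valid$expr[panel, , drop = FALSE], k = 2,
                          n_restarts = cfg$n_restarts,
                          seed = derive_seed(seed, "nmf_validation"))
    vpred <- predict(model, pair_features(valid_shifted, panel))
    valid_auc <- pair_auc(vpred$score, vnmf$assignment$subtype)
  } else {
    vnmf <- NULL; vpred <- NULL; valid_auc <- NA_real_
  }

  # --- stage: single-cell / pseudobulk ---------------------------------
  pb_assign <- NULL; ct_tests <- NULL
  if (cfg$preset == "simulate") {
    scp <- cohort_params(n_c1 = cfg$n_sc_per_subtype,
                         n_c2 = cfg$n_sc_per_subtype,
                         effect_size = cfg$effect_size,
                         noise_sd = cfg$noise_sd,
                         hr_c2_vs_c1 = cfg$hr_c2_vs_c1,
                         censor_rate = cfg$censor_rate)
    sc_bulk <- generate_cohort(scp, seed = derive_seed(seed, "sc_bulk"))
    sc <- generate_single_cell(sc_bulk$expr, sc_bulk$truth,
                               sc_params(cfg$cells_per_sample,
                                         cfg$malignant_fraction,
                                         cfg$library_size_mean),
                               seed = derive_seed(seed, "sc"))
    pb <- aggregate_pseudobulk(sc$counts, sc$annotation,
                               min_cells = cfg$min_cells)
    pb_assign <- classify_pseudobulk(model, pb, panel)
    ct <- tryCatch(celltype_proportions(
      sc$annotation[sc$annotation$sample_id %in% pb_assign$sample_id, ],
      pb_assign), error = function(e) NULL)
    ct_tests <- if (is.null(ct)) NULL else ct$tests
  }

  # --- stage: enrichment + LASSO + ORA ---------------------------------
  universe <- rownames(disc$expr)
  enrich_genes <- c(sig$up_c2, sig$up_c1)
  gs <- generate_gene_sets(universe, n_sets = cfg$n_sets,
                           set_size = cfg$set_size,
                           n_enriched = cfg$n_enriched,
                           enrich_genes = enrich_genes,
                           seed = derive_seed(seed, "gene_sets"))
  esA <- es_score(disc$expr, gs$sets, alpha = cfg$alpha,
                  min_overlap = cfg$min_overlap)
  diffA <- moderated_t_diff(esA, groups)
  if (!is.null(valid)) {
    esB <- es_score(valid_shifted, gs$sets, alpha = cfg$alpha,
                    min_overlap = cfg$min_overlap)
    diffB <- moderated_t_diff(esB, vnmf$assignment)
    inter <- enriched_intersection(diffA, diffB, direction = "up_C2",
                                   q_threshold = cfg$q_threshold)
  } else {
    diffB <- NULL
    inter <- diffA$set[diffA$q < cfg$q_threshold &
                         diffA$direction == "up_C2"]
  }
  lasso <- if (length(inter) >= 2)
    lasso_cox_select(esA[inter, , drop = FALSE], survdat,
                     n_folds = cfg$lasso_folds,
                     seed = derive_seed(seed, "lasso"))
  else NULL
  sel_sets <- if (is.null(lasso)) character(0) else lasso$selected
  query <- unique(unlist(gs$sets[sel_sets]))
  ora <- if (length(query) > 0)
    ora_hypergeometric(query, gs$sets, universe) else NULL

  # --- stage: hub genes -------------------------------------------------
  hub <- NULL
  if (length(query) >= 9) {
    set.seed(derive_seed(seed, "ppi"))
    cl_genes <- split(query, rep_len(1:3, length(query)))
    edges <- do.call(rbind, lapply(1:3, function(k) {
      g <- cl_genes[[k]]
      if (length(g) < 2) return(NULL)
      cmb <- utils::combn(g, 2)
      keep <- stats::runif(ncol(cmb)) < 0.4
      data.frame(gene_a = cmb[1, keep], gene_b = cmb[2, keep],
                 stringsAsFactors = FALSE)
    }))
    clusters <- stats::setNames(rep(paste0("cluster", 1:3),
                                    lengths(cl_genes)),
                                unlist(cl_genes))
    hub <- suppressWarnings(hub_genes(edges, clusters, top_n = 3))
  }

  summary <- list(
    seed = seed,
    selected_k = sel$k,
    mean_silhouette = nmf$mean_silhouette,
    subtype_sizes = as.list(table(groups$subtype)),
    de_genes_q05 = sum(de$q < 0.05),
    oob_auc = oob_auc,
    validation_auc = valid_auc,
    km_logrank_p = km_all$p,
    n_enriched_up_c2 = sum(diffA$q < cfg$q_threshold &
                             diffA$direction == "up_C2"),
    n_intersection = length(inter),
    lasso_selected = sel_sets,
    pseudobulk_groups = if (!is.null(pb_assign))
      as.list(table(pb_assign$subtype)) else NULL,
    hubs = if (!is.null(hub)) hub$hubs else NULL)

  result <- list(config = cfg, summary = summary, select_k = sel,
                 nmf = nmf, de = de, correlation = corr,
                 gene_cox = gene_cox, km = km_all, km_strata = km_strata,
                 model = model, validation = list(nmf = vnmf,
                                                  predictions = vpred),
                 pseudobulk = list(assignment = pb_assign,
                                   celltype_tests = ct_tests),
                 enrichment = list(diff_discovery = diffA,
                                   diff_validation = diffB,
                                   intersection = inter,
                                   truth_sets = gs$truth),
                 lasso = lasso, ora = ora, hubs = hub)

  if (!is.null(cfg$out_dir)) write_report(result, cfg$out_dir)
  invisible(result)
}

# Write the report bundle: TSV tables plus summary.json.
write_report <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    write_table_tsv(df, file.path(out_dir, paste0(name, ".tsv")))
  w(result$nmf$assignment, "subtype_assignment")
  write_matrix_tsv(result$nmf$consensus, file.path(out_dir,
                                                   "consensus.tsv"))
  w(result$select_k$criterion, "k_selection")
  w(result$de, "differential_expression")
  w(result$gene_cox$univariate, "cox_univariate")
  w(result$gene_cox$adjusted, "cox_adjusted")
  w(result$model$importance, "pair_importance")
  w(result$enrichment$diff_discovery, "diff_es_discovery")
  if (!is.null(result$enrichment$diff_validation))
    w(result$enrichment$diff_validation, "diff_es_validation")
  if (!is.null(result$pseudobulk$assignment))
    w(result$pseudobulk$assignment, "pseudobulk_assignment")
  if (!is.null(result$pseudobulk$celltype_tests))
    w(result$pseudobulk$celltype_tests, "celltype_tests")
  if (!is.null(result$ora)) w(result$ora, "ora")
  if (!is.null(result$hubs)) w(result$hubs$degrees, "hub_degrees")
  jsonlite::write_json(result$summary,
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
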