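# Pseudobulk aggregation of single-cell counts into bulk-like CPM
# profiles, classification of the aggregated samples with the rank-pair
# model, and cell-type composition contrasts between the two patterns.

#' Aggregate single-cell counts into per-sample pseudobulk log2 CPM
#'
#' Counts are summed per sample over the retained cells (malignant cells
#' only when `malignant_only = TRUE`), normalized to counts per million
#' (each linear CPM column sums to 1e6 exactly), and returned as
#' `log2(CPM + 1)`. Samples with fewer than `min_cells` retained cells are
#' excluded and reported.
#'
#' @param counts gene x cell nonnegative integer matrix.
#' @param ann cell annotation data.frame (cell_id, sample_id, cell_type,
#'   malignant); every count column must be annotated.
#' @param malignant_only aggregate malignant cells only (default TRUE).
#' @param min_cells minimum retained cells per sample (default 50).
#' @return Gene x sample matrix of log2(CPM + 1); excluded samples are in
#'   the `"excluded"` attribute, retained-cell counts in `"n_cells"`.
#' @export
aggregate_pseudobulk <- function(counts, ann, malignant_only = TRUE,
                                 min_cells = 50) {
  if (min_cells < 1) stop("min_cells must be >= 1")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (!all(colnames(counts) %in% ann$cell_id))
    stop("unannotated cells: ",
         paste(utils::head(setdiff(colnames(counts), ann$cell_id), 5),
               collapse = ", "))
  ann <- ann[match(colnames(counts), ann$cell_id), ]
  keep <- if (malignant_only) ann$malignant == 1 else rep(TRUE, nrow(ann))
  n_cells <- table(factor(ann$sample_id[keep],
                          levels = unique(ann$sample_id)))
  retained <- names(n_cells)[n_cells >= min_cells]
  excluded <- setdiff(unique(ann$sample_id), retained)
  if (length(retained) == 0) stop("all samples excluded by min_cells")

  totals <- vapply(retained, function(s)
    rowSums(counts[, keep & ann$sample_id == s, drop = FALSE]),
    numeric(nrow(counts)))
  cpm <- sweep(totals, 2, colSums(totals), "/") * 1e6
  out <- log2(cpm + 1)
  dimnames(out) <- list(rownames(counts), retained)
  attr(out, "excluded") <- excluded
  attr(out, "n_cells") <- as.integer(n_cells[retained])
  attr(out, "scale") <- "log2"
  out
}

#' Classify pseudobulk samples into pyroptosis patterns
#'
#' Composition of [pair_features()] and [predict.pair_model()]: because
#' the features are rank-based, log2 and linear CPM inputs give identical
#' labels.
#'
#' @param model a trained `pair_model`.
#' @param pb pseudobulk gene x sample matrix (log2 or linear CPM).
#' @param panel the gene panel used at training time.
#' @return data.frame with sample_id, score (C2 vote fraction), subtype.
#' @export
classify_pseudobulk <- function(model, pb, panel) {
  predict(model, pair_features(pb, panel))
}

#' Cell-type composition contrasts between patterns
#'
#' Per-sample cell-type fractions (summing to 1), with a two-sided
#' Mann-Whitney test per cell type between the two groups and BH
#' adjustment across types.
#'
#' @param ann cell annotation data.frame.
#' @param groups subtype assignment for every annotated sample (named
#'   vector or data.frame with sample_id/subtype); each group needs >= 2
#'   samples.
#' @return List with `fractions` (sample x cell-type matrix) and `tests`
#'   (data.frame: cell_type, p, q, direction).
#' @export
celltype_proportions <- function(ann, groups) {
  grp <- as_group_vector(groups)
  samples <- unique(ann$sample_id)
  miss <- setdiff(samples, names(grp))
  if (length(miss) > 0)
    stop("samples without a group label: ", paste(miss, collapse = ", "))
  grp <- grp[samples]
  lv <- sort(unique(grp))
  if (length(lv) != 2) stop("exactly two groups are required")
  if (any(table(grp) < 2)) stop("each group needs >= 2 samples")

  tab <- table(factor(ann$sample_id, levels = samples), ann$cell_type)
  fractions <- sweep(unclass(tab), 1, rowSums(tab), "/")
  p <- vapply(colnames(fractions), function(ct) {
    x <- fractions[grp == lv[1], ct]
    y <- fractions[grp == lv[2], ct]
    if (length(unique(c(x, y))) == 1) return(1)
    suppressWarnings(stats::wilcox.test(x, y)$p.value)
  }, numeric(1))
  diff <- vapply(colnames(fractions), function(ct)
    mean(fractions[grp == lv[2], ct]) - mean(fractions[grp == lv[1], ct]),
    numeric(1))
  tests <- data.frame(cell_type = colnames(fractions), p = unname(p),
                      q = bh_adjust(unname(p)),
                      direction = ifelse(diff >= 0,
                                         paste0("up_", lv[2]),
                                         paste0("up_", lv[1])),
                      stringsAsFactors = FALSE)
  list(fractions = fractions, tests = tests)
}
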