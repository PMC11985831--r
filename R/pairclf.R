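# Rank-pair (gene i > gene j) featurization and the random-forest subtype
# classifier built on it. Because features depend on expression only
# through within-sample gene rankings, a model trained on one platform
# transfers to any monotone distortion of another.

#' Binary rank-pair features over a gene panel
#'
#' Feature (i, j), for panel positions i < j, equals 1 for a sample iff
#' gene i's expression strictly exceeds gene j's in that sample (ties give
#' 0). A p-gene panel yields p(p-1)/2 features; pair order follows the
#' panel order lexicographically and is deterministic.
#'
#' @param expr gene x sample expression matrix (any scale; features are
#'   invariant to strictly increasing per-sample transforms).
#' @param panel ordered gene vector, all present in `expr`, no duplicates.
#' @return Binary pairs x samples matrix of class `pair_features` with
#'   rownames `"geneA>geneB"`; the pair table is attached as attribute
#'   `"pairs"`.
#' @export
pair_features <- function(expr, panel) {
  check_expr(expr)
  if (length(panel) < 2) stop("panel needs at least 2 genes")
  if (anyDuplicated(panel))
    stop("duplicate panel genes: ",
         paste(unique(panel[duplicated(panel)]), collapse = ", "))
  missing <- setdiff(panel, rownames(expr))
  if (length(missing) > 0)
    stop("panel genes missing from expression matrix: ",
         paste(missing, collapse = ", "))
  X <- expr[panel, , drop = FALSE]
  cmb <- utils::combn(length(panel), 2)
  F <- (X[cmb[1, ], , drop = FALSE] > X[cmb[2, ], , drop = FALSE]) + 0L
  rownames(F) <- paste(panel[cmb[1, ]], panel[cmb[2, ]], sep = ">")
  colnames(F) <- colnames(expr)
  attr(F, "pairs") <- data.frame(gene_i = panel[cmb[1, ]],
                                 gene_j = panel[cmb[2, ]],
                                 stringsAsFactors = FALSE)
  class(F) <- c("pair_features", class(F))
  F
}

#' Train the rank-pair random-forest subtype classifier
#'
#' Fits a bagged decision-tree ensemble (via \pkg{randomForest}) on binary
#' pair features with out-of-bag (OOB) error and both permutation (mean
#' decrease accuracy) and impurity (mean decrease Gini) importances.
#'
#' @param F pairs x samples binary feature matrix from [pair_features()].
#' @param labels subtype labels: named vector, factor, or a data.frame
#'   with sample_id/subtype. Two classes, each with >= 2 samples.
#' @param n_trees ensemble size (default 500).
#' @param seed RNG seed; the fit is deterministic given it.
#' @param mtry features tried per split (default floor(sqrt(n_features))).
#' @return List of class `pair_model`: the fitted forest, pair ids,
#'   `oob_error`, `importance` table, and the class vocabulary.
#' @export
train_classifier <- function(F, labels, n_trees = 500, seed = 1,
                             mtry = NULL) {
  lab <- as_group_vector(labels)
  if (!is.null(names(lab)) && all(colnames(F) %in% names(lab)))
    lab <- lab[colnames(F)]
  if (length(lab) != ncol(F))
    stop("labels do not match the feature matrix samples")
  y <- factor(lab)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (any(table(y) < 2)) stop("each class needs >= 2 samples")
  mtry <- mtry %||% max(1, floor(sqrt(nrow(F))))
  set.seed(seed)
  rf <- randomForest::randomForest(x = t(unclass(F)), y = y,
                                   ntree = n_trees, mtry = mtry,
                                   importance = TRUE)
  imp <- randomForest::importance(rf)
  importance <- data.frame(
    pair = rownames(imp),
    mean_decrease_accuracy = imp[, "MeanDecreaseAccuracy"],
    mean_decrease_gini = imp[, "MeanDecreaseGini"],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(forest = rf, pair_ids = rownames(F),
                 classes = levels(y),
                 oob_error = unname(rf$err.rate[n_trees, "OOB"]),
                 oob_votes = rf$votes,
                 importance = importance, n_trees = n_trees,
                 seed = seed),
            class = "pair_model")
}

#' Predict pyroptosis patterns from pair features
#'
#' @param object a fitted `pair_model`.
#' @param F pair-feature matrix whose pairs match the training pairs
#'   exactly (identity and order); a mismatch is an error listing the
#'   missing/extra pairs.
#' @param ... unused.
#' @return data.frame with sample_id, `score` (fraction of trees voting
#'   for the second class, C2) and `subtype` (ties at 0.5 go to C1).
#' @export
predict.pair_model <- function(object, F, ...) {
  if (!identical(rownames(F), object$pair_ids)) {
    missing <- setdiff(object$pair_ids, rownames(F))
    extra <- setdiff(rownames(F), object$pair_ids)
    stop("pair set mismatch with the trained model",
         if (length(missing)) paste0("; missing: ",
           paste(utils::head(missing, 5), collapse = ", ")) else "",
         if (length(extra)) paste0("; extra: ",
           paste(utils::head(extra, 5), collapse = ", ")) else "",
         if (length(missing) == 0 && length(extra) == 0)
           "; pairs are reordered" else "")
  }
  votes <- stats::predict(object$forest, t(unclass(F)), type = "vote")
  pos <- object$classes[2]
  score <- votes[, pos]
  data.frame(sample_id = colnames(F), score = unname(score),
             subtype = ifelse(score > 0.5, pos, object$classes[1]),
             stringsAsFactors = FALSE)
}

#' Area under the ROC curve via the Mann-Whitney U statistic
#'
#' `AUC = U / (n1 * n0)` computed from midranks, so tied scores contribute
#' 1/2.
#'
#' @param scores numeric classification scores (larger = more positive).
#' @param labels binary labels; the positive class is `positive` if given,
#'   else the last factor level / the value "C2" when present.
#' @param positive optional positive-class value.
#' @return AUC in [0, 1].
#' @export
pair_auc <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("both classes must be present")
  pos <- positive %||% if ("C2" %in% classes) "C2" else classes[2]
  if (!pos %in% classes) stop("positive class absent")
  y <- labels == pos
  r <- rank(scores)
  n1 <- sum(y); n0 <- sum(!y)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
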