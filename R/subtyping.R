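# Consensus NMF subtyping on the pyroptosis panel. The factorization uses
# Lee-Seung multiplicative updates for the Frobenius objective; consensus
# over random restarts defines a co-clustering similarity whose
# average-linkage cut gives the final assignment, scored by silhouette
# width against the consensus distance.

#' Consensus non-negative matrix factorization
#'
#' Runs `n_restarts` multiplicative-update NMF fits from random
#' initializations, records per-restart cluster labels (argmax row of H per
#' sample), and averages co-membership into a consensus matrix. Final
#' labels cut an average-linkage hierarchical tree on `1 - consensus` into
#' `k` groups. When ELANE is among the genes, cluster names are anchored so
#' that C1 is the cluster with the higher mean ELANE expression (the
#' ELANE-high pattern); otherwise clusters are named by decreasing size.
#'
#' @param expr gene x sample matrix, log2 scale by default.
#' @param k number of clusters (>= 1).
#' @param n_restarts random restarts for the consensus (default 30).
#' @param max_iter maximum multiplicative updates per restart (default 500).
#' @param tol relative Frobenius-objective improvement below which a
#'   restart stops (default 1e-6).
#' @param seed RNG seed; restart r uses a seed derived from it.
#' @param input_scale `"log2"` (default: values are used on the log2
#'   scale, where the subtype structure is additive and genes contribute
#'   comparably to the Frobenius loss; log2 expression is nonnegative in
#'   practice and stray negative values are clamped to 0) or `"linear"`
#'   (values used as given; negatives are an error).
#' @return List of class `pyro_nmf`: `W`, `H` (best restart),
#'   `objective_trace`, `consensus`, and `assignment` (data.frame with
#'   sample_id, subtype, confidence, silhouette) plus `mean_silhouette`.
#' @export
nmf_factorize <- function(expr, k, n_restarts = 30, max_iter = 500,
                          tol = 1e-6, seed = 1,
                          input_scale = c("log2", "linear")) {
  check_expr(expr)
  input_scale <- match.arg(input_scale)
  if (k < 1) stop("k must be >= 1")
  if (k > ncol(expr)) stop("k exceeds the number of samples")
  if (n_restarts < 1) stop("n_restarts must be >= 1")
  if (input_scale == "log2") {
    V <- pmax(expr, 0)
  } else {
    if (any(expr < 0)) stop("NMF input must be nonnegative")
    V <- expr
  }
  n <- ncol(V)

  best <- NULL
  consensus <- matrix(0, n, n)
  for (r in seq_len(n_restarts)) {
    fit <- nmf_single(V, k, max_iter, tol,
                      derive_seed(seed, paste0("nmf_restart_", r)))
    # compensate the W/H scale ambiguity before reading off labels
    Hn <- fit$H * sqrt(colSums(fit$W^2))
    labels_r <- max.col(t(Hn), ties.method = "first")
    consensus <- consensus + outer(labels_r, labels_r, "==")
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  consensus <- consensus / n_restarts
  dimnames(consensus) <- list(colnames(V), colnames(V))

  if (k == 1) {
    labels <- rep(1L, n)
  } else {
    hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
    labels <- stats::cutree(hc, k = k)
  }
  labels <- order_cluster_labels(labels, expr, k)
  lab_chr <- paste0("C", labels)

  sil <- if (k >= 2)
    silhouette_width(labels, 1 - consensus)
  else list(widths = rep(0, n), mean = 0)
  confidence <- vapply(seq_len(n), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1) 1 else mean(consensus[i, setdiff(own, i)])
  }, numeric(1))

  assignment <- data.frame(sample_id = colnames(V), subtype = lab_chr,
                           confidence = confidence,
                           silhouette = sil$widths,
                           stringsAsFactors = FALSE)
  structure(list(W = best$W, H = best$H,
                 objective_trace = best$trace, consensus = consensus,
                 assignment = assignment, mean_silhouette = sil$mean,
                 k = k),
            class = "pyro_nmf")
}

# One multiplicative-update run from a random uniform initialization.
nmf_single <- function(V, k, max_iter, tol, seed) {
  set.seed(seed)
  g <- nrow(V); n <- ncol(V)
  scale0 <- sqrt(mean(V) / k)
  W <- matrix(stats::runif(g * k, 0, scale0), g, k)
  H <- matrix(stats::runif(k * n, 0, scale0), k, n)
  eps <- .Machine$double.eps
  trace <- numeric(0)
  obj_prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V) / (crossprod(W) %*% H + eps))
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    obj <- sum((V - W %*% H)^2)
    trace <- c(trace, obj)
    if (is.finite(obj_prev) &&
        (obj_prev - obj) < tol * max(obj_prev, eps)) break
    obj_prev <- obj
  }
  list(W = W, H = H, objective = obj, trace = trace)
}

# Rename integer cluster labels so C1 is the ELANE-high cluster (the
# paper's designation); without ELANE, order by decreasing cluster size.
order_cluster_labels <- function(labels, expr, k) {
  if (k == 1) return(labels)
  if ("ELANE" %in% rownames(expr)) {
    key <- vapply(seq_len(k), function(cl)
      mean(expr["ELANE", labels == cl]), numeric(1))
    ord <- order(key, decreasing = TRUE)
  } else {
    ord <- order(tabulate(labels, k), decreasing = TRUE)
  }
  match(labels, ord)
}

#' Select the number of clusters by consensus silhouette
#'
#' For each k, consensus NMF is run and the mean silhouette width of the
#' consensus-derived labels against the distance `1 - consensus` is
#' computed; the k maximizing the mean silhouette is returned together with
#' the full criterion table.
#'
#' @inheritParams nmf_factorize
#' @param k_range candidate cluster counts, a subset of 2..(n-1).
#' @return List with `k` (selected) and `criterion` (data.frame of k and
#'   mean silhouette).
#' @export
select_k <- function(expr, k_range = 2:6, n_restarts = 30, seed = 1,
                     max_iter = 500, tol = 1e-6) {
  if (length(k_range) == 0) stop("empty k_range")
  if (any(k_range < 2 | k_range > ncol(expr) - 1))
    stop("k_range must lie in [2, n_samples - 1]")
  crit <- vapply(k_range, function(k) {
    fit <- nmf_factorize(expr, k, n_restarts = n_restarts,
                         max_iter = max_iter, tol = tol,
                         seed = derive_seed(seed, paste0("select_k_", k)))
    fit$mean_silhouette
  }, numeric(1))
  list(k = k_range[which.max(crit)],
       criterion = data.frame(k = k_range, mean_silhouette = crit))
}

#' Silhouette widths for a clustering against a distance matrix
#'
#' Standard silhouette: `s(i) = (b - a) / max(a, b)` with `a` the mean
#' distance to the own cluster and `b` the smallest mean distance to any
#' other cluster. Members of singleton clusters get width 0, as do points
#' with `a = b = 0`.
#'
#' @param labels integer or character cluster labels (>= 2 clusters, each
#'   non-empty).
#' @param dmat symmetric distance matrix with zero diagonal.
#' @return List with per-sample `widths` and their `mean`.
#' @export
silhouette_width <- function(labels, dmat) {
  labels <- as.character(labels)
  n <- length(labels)
  if (!is.matrix(dmat) || nrow(dmat) != n || ncol(dmat) != n)
    stop("dmat must be an n x n matrix matching labels")
  if (max(abs(dmat - t(dmat))) > 1e-8 || any(abs(diag(dmat)) > 1e-12))
    stop("dmat must be symmetric with zero diagonal")
  cl <- unique(labels)
  if (length(cl) < 2) stop("need at least 2 clusters")
  widths <- vapply(seq_len(n), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1) return(0)
    a <- mean(dmat[i, setdiff(own, i)])
    b <- min(vapply(setdiff(cl, labels[i]), function(g)
      mean(dmat[i, labels == g]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  list(widths = widths, mean = mean(widths))
}
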