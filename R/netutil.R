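#' Degree-based hub genes within precomputed PPI clusters
#'
#' Degrees count edges whose two endpoints lie in the same cluster; within
#' each cluster, genes are ranked by decreasing degree with alphabetical
#' tie-breaking and the top `top_n` reported (fewer if the cluster is
#' smaller). Cluster members absent from the edge list keep degree 0 and
#' are retained with a warning.
#'
#' @param edges data.frame of undirected edges (columns gene_a, gene_b, or
#'   the first two columns), self-loops and duplicates already collapsed
#'   by [read_table()] or equivalent.
#' @param clusters named character/integer vector mapping gene -> cluster,
#'   or a data.frame (gene, cluster).
#' @param top_n hubs reported per cluster (default 3).
#' @return List of class `hub_report`: `hubs` (named list per cluster) and
#'   `degrees` (data.frame: gene, cluster, degree, rank).
#' @export
hub_genes <- function(edges, clusters, top_n = 3) {
  if (top_n < 1) stop("top_n must be >= 1")
  if (is.data.frame(clusters)) {
    cl <- stats::setNames(as.character(clusters[[2]]),
                          as.character(clusters[[1]]))
  } else {
    cl <- stats::setNames(as.character(clusters), names(clusters))
  }
  if (length(cl) == 0) stop("empty cluster map")
  a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
  isolated <- setdiff(names(cl), c(a, b))
  if (length(isolated) > 0)
    warning("cluster member(s) absent from the edge list (degree 0): ",
            paste(isolated, collapse = ", "))

  within <- !is.na(cl[a]) & !is.na(cl[b]) & cl[a] == cl[b]
  deg_tab <- lapply(sort(unique(cl)), function(k) {
    members <- sort(names(cl)[cl == k])
    ev <- within & cl[a] == k
    ends <- c(a[which(ev)], b[which(ev)])
    deg <- vapply(members, function(g) sum(ends == g), integer(1))
    ord <- order(-deg, members)
    data.frame(gene = members[ord], cluster = k, degree = deg[ord],
               rank = seq_along(members), stringsAsFactors = FALSE)
  })
  degrees <- do.call(rbind, deg_tab)
  rownames(degrees) <- NULL
  hubs <- lapply(split(degrees, degrees$cluster), function(d)
    utils::head(d$gene, top_n))
  structure(list(hubs = hubs, degrees = degrees), class = "hub_report")
}
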