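# Single-sample gene-set enrichment (ssGSEA-form running sum), moderated-t
# differential enrichment between patterns, cross-cohort intersection of
# enriched sets, and hypergeometric over-representation.

#' Single-sample enrichment scores (ssGSEA-form running sum)
#'
#' Per sample, genes are ranked by descending expression. Walking down the
#' ranking, in-set genes advance the running sum by their rank statistic
#' (descending rank, largest at the top) raised to `alpha` and normalized
#' to the in-set total; out-of-set genes advance a uniform complement. The
#' score is the sum of the running-sum deviations divided by
#' `n_genes - n_set`. With `alpha = 0` the score depends on the data only
#' through within-sample ranks.
#'
#' @param expr gene x sample matrix (>= 2 genes).
#' @param sets named list of member-gene vectors.
#' @param alpha rank-weight exponent (default 0.25).
#' @param min_overlap minimum set genes present in the expression universe
#'   (default 5); smaller sets are dropped and reported.
#' @return Set x sample score matrix; dropped set names in attribute
#'   `"dropped"`, the method tag in `"method"`.
#' @export
es_score <- function(expr, sets, alpha = 0.25, min_overlap = 5) {
  check_expr(expr)
  if (nrow(expr) < 2) stop("need >= 2 genes")
  if (alpha < 0) stop("alpha must be >= 0")
  universe <- rownames(expr)
  overlap <- lapply(sets, function(s) intersect(s, universe))
  keep <- lengths(overlap) >= min_overlap & lengths(overlap) < length(universe)
  dropped <- names(sets)[!keep]
  if (!any(keep)) stop("no gene set passes min_overlap against the universe")
  sets_idx <- lapply(overlap[keep], function(s) match(s, universe))

  N <- length(universe)
  es <- matrix(NA_real_, sum(keep), ncol(expr),
               dimnames = list(names(sets)[keep], colnames(expr)))
  for (s in seq_len(ncol(expr))) {
    ord <- order(expr[, s], decreasing = TRUE)
    pos <- integer(N); pos[ord] <- seq_len(N)  # gene -> rank position
    rstat <- as.numeric(N - seq_len(N) + 1)    # rank statistic by position
    w <- rstat^alpha
    for (k in seq_along(sets_idx)) {
      m <- length(sets_idx[[k]])
      inset <- logical(N)
      inset[pos[sets_idx[[k]]]] <- TRUE
      step_in <- ifelse(inset, w, 0)
      step_in <- step_in / sum(step_in)
      step_out <- ifelse(inset, 0, 1 / (N - m))
      dev <- cumsum(step_in) - cumsum(step_out)
      es[k, s] <- sum(dev) / (N - m)
    }
  }
  attr(es, "dropped") <- dropped
  attr(es, "method") <- list(name = "ssgsea_running_sum", alpha = alpha,
                             min_overlap = min_overlap)
  es
}

#' Moderated-t differential enrichment between two patterns
#'
#' Per set, a two-group t statistic with empirical-Bayes variance
#' shrinkage: the posterior variance is `(d0*s0^2 + d*s^2) / (d0 + d)`
#' where the prior degrees of freedom `d0` and variance `s0^2` are
#' estimated across sets by method of moments from the pooled sample
#' variances; p-values use `d0 + d` degrees of freedom and are BH-adjusted
#' across all sets. `prior_df = 0` disables shrinkage and reproduces the
#' ordinary pooled-variance t.
#'
#' @param es set x sample score matrix.
#' @param groups two-group assignment over the samples (named vector or
#'   data.frame with sample_id/subtype); each group >= 2 samples.
#' @param prior_df optional fixed prior degrees of freedom (overrides the
#'   method-of-moments estimate; 0 = no shrinkage, Inf = full shrinkage to
#'   the prior variance).
#' @return data.frame per set: set, diff (mean ES of the second group
#'   minus the first, i.e. C2 - C1), t, p, q, direction.
#' @export
moderated_t_diff <- function(es, groups, prior_df = NULL) {
  grp <- as_group_vector(groups)
  if (!is.null(names(grp)) && all(colnames(es) %in% names(grp)))
    grp <- grp[colnames(es)]
  if (length(grp) != ncol(es)) stop("groups do not match es samples")
  lv <- sort(unique(grp))
  if (length(lv) != 2) stop("exactly two groups are required")
  n1 <- sum(grp == lv[1]); n2 <- sum(grp == lv[2])
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 samples")

  x1 <- es[, grp == lv[1], drop = FALSE]
  x2 <- es[, grp == lv[2], drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1, stats::var); v2 <- apply(x2, 1, stats::var)
  d <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d

  if (is.null(prior_df)) {
    mom <- moments_prior(s2, d)
    d0 <- mom$d0; s0 <- mom$s0
  } else {
    d0 <- prior_df
    s0 <- mean(s2)
  }
  post <- if (is.infinite(d0)) rep(s0, length(s2))
          else if (d0 == 0) s2
          else (d0 * s0 + d * s2) / (d0 + d)
  diff <- m2 - m1
  tt <- diff / sqrt(post * (1 / n1 + 1 / n2))
  df <- d0 + d
  p <- if (is.infinite(df)) 2 * stats::pnorm(-abs(tt))
       else 2 * stats::pt(-abs(tt), df = df)
  data.frame(set = rownames(es), diff = unname(diff), t = unname(tt),
             p = unname(p), q = bh_adjust(unname(p)),
             direction = ifelse(diff >= 0, paste0("up_", lv[2]),
                                paste0("up_", lv[1])),
             stringsAsFactors = FALSE)
}

# Method-of-moments fit of the scaled inverse-chi-square variance prior:
# marginally s^2 ~ s0^2 * F(d, d0), matching the first two moments of the
# observed pooled variances.
moments_prior <- function(s2, d) {
  m <- mean(s2); v <- stats::var(s2)
  if (!is.finite(v) || v <= 0 || m <= 0)
    return(list(d0 = Inf, s0 = m))
  r <- v / m^2
  denom <- r * d - 2
  if (denom <= 0) return(list(d0 = Inf, s0 = m))
  d0 <- (2 * d - 4 + 4 * r * d) / denom
  if (!is.finite(d0) || d0 <= 4) d0 <- max(d0, 4.01)
  s0 <- m * (d0 - 2) / d0
  list(d0 = d0, s0 = s0)
}

#' Intersect enriched gene sets across two cohorts
#'
#' Names significant (q below threshold) with the stated direction in BOTH
#' differential tables, on the shared name universe.
#'
#' @param diffA,diffB data.frames from [moderated_t_diff()].
#' @param direction direction label to require (e.g. `"up_C2"`).
#' @param q_threshold FDR threshold (default 0.05).
#' @return Character vector of set names.
#' @export
enriched_intersection <- function(diffA, diffB, direction = "up_C2",
                                  q_threshold = 0.05) {
  shared <- intersect(diffA$set, diffB$set)
  if (length(shared) == 0) stop("empty shared set universe")
  sigA <- diffA$set[diffA$q < q_threshold & diffA$direction == direction]
  sigB <- diffB$set[diffB$q < q_threshold & diffB$direction == direction]
  intersect(intersect(sigA, sigB), shared)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p for the overlap of a query gene list with
#' each annotation term, BH-adjusted across terms. Terms with no overlap
#' with the universe are dropped with a warning.
#'
#' @param query gene list (subset of `universe`, non-empty).
#' @param annotation named list of term member vectors.
#' @param universe background gene list.
#' @return data.frame: term, overlap, term_size, p, q.
#' @export
ora_hypergeometric <- function(query, annotation, universe) {
  if (length(query) == 0) stop("empty query")
  if (!all(query %in% universe))
    stop("query genes outside the universe: ",
         paste(utils::head(setdiff(query, universe), 5), collapse = ", "))
  term_in_universe <- lapply(annotation, function(s) intersect(s, universe))
  empty <- lengths(term_in_universe) == 0
  if (any(empty)) {
    warning("term(s) with zero universe overlap dropped: ",
            paste(names(annotation)[empty], collapse = ", "))
    term_in_universe <- term_in_universe[!empty]
  }
  if (length(term_in_universe) == 0) stop("no usable annotation terms")
  N <- length(universe); n <- length(query)
  res <- lapply(names(term_in_universe), function(nm) {
    K <- length(term_in_universe[[nm]])
    ov <- length(intersect(query, term_in_universe[[nm]]))
    p <- stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = nm, overlap = ov, term_size = K, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out
}
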