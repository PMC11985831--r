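# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed from a parent seed and a stage tag
#'
#' All stochastic stages draw their seeds through this function so that one
#' top-level seed reproduces the whole pipeline while stages stay
#' independently re-runnable.
#'
#' @param seed integer parent seed.
#' @param tag character stage tag.
#' @return An integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  v <- utf8ToInt(tag)
  h <- sum(v * seq_along(v)) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% (.Machine$integer.max - 1))
}

# Assert an expression matrix shape: numeric, finite, unique dimnames.
check_expr <- function(expr, what = "expression matrix") {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop(what, " must have gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(expr)))
    stop(what, ": duplicated gene ids: ",
         paste(unique(rownames(expr)[duplicated(rownames(expr))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(expr)))
    stop(what, ": duplicated sample ids: ",
         paste(unique(colnames(expr)[duplicated(colnames(expr))]),
               collapse = ", "), call. = FALSE)
  if (any(!is.finite(expr)))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(expr)
}

# Coerce a grouping argument (named vector, factor, or data.frame with
# sample_id/subtype columns) to a named character vector.
as_group_vector <- function(groups) {
  if (is.data.frame(groups)) {
    if (!all(c("sample_id", "subtype") %in% names(groups)))
      stop("group data.frame needs columns 'sample_id' and 'subtype'",
           call. = FALSE)
    out <- as.character(groups$subtype)
    names(out) <- as.character(groups$sample_id)
    return(out)
  }
  out <- as.character(groups)
  names(out) <- names(groups)
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over [stats::p.adjust()] used by every module that reports
#' FDR, so a single implementation backs all q-values.
#'
#' @param p numeric vector of p-values.
#' @return Vector of BH-adjusted q-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
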