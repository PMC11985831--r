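# Readers and writers for the plain-text formats the pipeline touches:
# TSV matrices and tables, and GMT gene-set collections. All readers are
# strict validators: malformed input raises an error naming the offending
# row/column rather than silently coercing.

#' Read a gene x sample expression matrix from TSV
#'
#' Expects a header row of sample ids, a first column of gene ids, TAB
#' separation, no quoting, and a complete numeric body.
#'
#' @param path file path.
#' @param scale_flag `"log2"` (default) or `"linear"`; recorded as the
#'   `"scale"` attribute of the returned matrix.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path, scale_flag = c("log2", "linear")) {
  scale_flag <- match.arg(scale_flag)
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1)
    stop("ragged TSV: line(s) ",
         paste(which(nf != nf[1]), collapse = ", "),
         " have a different field count")
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character")
  genes <- tab[[1]]
  if (anyDuplicated(genes))
    stop("duplicated gene ids: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  samples <- colnames(tab)[-1]
  if (anyDuplicated(samples))
    stop("duplicated sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  body <- as.matrix(tab[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-numeric or missing cell at gene ", genes[bad[1, 1]],
         ", sample ", samples[bad[1, 2]], " ('", body[bad[1, , drop = FALSE]],
         "')")
  dimnames(vals) <- list(genes, samples)
  check_expr(vals)
  attr(vals, "scale") <- scale_flag
  vals
}

#' Write an expression (or count) matrix as TSV
#'
#' @param expr numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @export
write_matrix_tsv <- function(expr, path) {
  check_expr(expr)
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' MSigDB dialect: one set per line, `name TAB description TAB member...`.
#' Duplicate members within a set are dropped with a warning; duplicate set
#' names are an error.
#'
#' @param path file path.
#' @return Named list of member-gene character vectors; descriptions kept
#'   as the `"description"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short) > 0)
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(short, collapse = ", "))
  nm <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nm))
    stop("duplicate set names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- vapply(parts, `[[`, character(1), 2)
  sets <- lapply(seq_along(parts), function(i) {
    members <- parts[[i]][-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("set ", nm[i], ": duplicate members deduplicated")
      members <- unique(members)
    }
    members
  })
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(desc, nm)
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of member-gene vectors.
#' @param path output path.
#' @param description optional named descriptions (defaults to "na").
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names")
  desc <- description %||% attr(sets, "description") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]] %||% "na", sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a typed, validated table (clinical, cell annotation, or edge list)
#'
#' @param path file path to a TSV with a header row.
#' @param schema one of `"surv"` (requires sample_id, os_time, os_event;
#'   optional age, sex, karyotype_risk), `"cells"` (cell_id, sample_id,
#'   cell_type, malignant), or `"edges"` (two gene columns; self-loops
#'   dropped with a warning, duplicate/mirrored edges collapsed).
#' @return A validated data.frame.
#' @export
read_table <- function(path, schema = c("surv", "cells", "edges")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  switch(schema,
         surv = validate_surv(df),
         cells = validate_cells(df),
         edges = validate_edges(df))
}

validate_surv <- function(df) {
  need <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample ids in clinical table")
  df$os_time <- as.numeric(df$os_time)
  if (any(is.na(df$os_time) | df$os_time <= 0))
    stop("os_time must be positive; offending sample(s): ",
         paste(df$sample_id[is.na(df$os_time) | df$os_time <= 0],
               collapse = ", "))
  df$os_event <- as.numeric(df$os_event)
  if (!all(df$os_event %in% c(0, 1)))
    stop("os_event must be 0/1; offending sample(s): ",
         paste(df$sample_id[!df$os_event %in% c(0, 1)], collapse = ", "))
  if ("karyotype_risk" %in% names(df)) {
    ok <- c("favorable", "intermediate/normal", "poor")
    bad <- setdiff(unique(df$karyotype_risk), ok)
    if (length(bad) > 0)
      stop("unknown karyotype_risk categories: ",
           paste(bad, collapse = ", "))
  }
  df
}

validate_cells <- function(df) {
  need <- c("cell_id", "sample_id", "cell_type", "malignant")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("cell annotation missing column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$cell_id)) stop("duplicated cell ids")
  if (any(!nzchar(df$sample_id))) stop("empty sample id in annotation")
  df$malignant <- as.integer(df$malignant)
  if (!all(df$malignant %in% c(0L, 1L)))
    stop("malignant flag must be 0/1")
  df
}

validate_edges <- function(df) {
  if (ncol(df) < 2) stop("edge list needs two gene columns")
  a <- as.character(df[[1]]); b <- as.character(df[[2]])
  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-loop(s) dropped: ",
            paste(unique(a[self]), collapse = ", "))
    a <- a[!self]; b <- b[!self]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(paste(lo, hi, sep = "\r"))
  data.frame(gene_a = lo[keep], gene_b = hi[keep],
             stringsAsFactors = FALSE)
}

#' Write a data.frame as a TSV table
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
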