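#' Parameters for the synthetic two-subtype AML cohort generator
#'
#' Defines the study conditions emulated by [generate_cohort()]: two latent
#' pyroptosis patterns (C1, ELANE-high; C2, ELANE-low) over a fixed gene
#' panel, a 19-gene differential signature (16 genes up in C2, 3 up in C1),
#' and subtype-linked exponential survival in which C2 carries the higher
#' hazard.
#'
#' @param n_c1,n_c2 samples per subtype (defaults 77 and 55).
#' @param panel ordered gene-symbol vector (default the bundled 40-gene
#'   pyroptosis panel).
#' @param de_up_c2,de_up_c1 genes up-regulated in C2 / C1; disjoint subsets
#'   of `panel`.
#' @param effect_size mean log2 shift between subtypes in units of the
#'   within-group SD (default 1.5).
#' @param noise_sd residual within-group log2 SD (default 1).
#' @param baseline_hazard C1 event hazard, events per day (default 1/600).
#' @param hr_c2_vs_c1 subtype hazard ratio, C2 versus C1 (default 2).
#' @param censor_rate expected fraction of administratively censored
#'   samples (default 0.3).
#' @param n_background count of additional null (subtype-uninformative)
#'   genes appended below the panel so enrichment universes can exceed the
#'   panel (default 0).
#' @return A validated list of class `cohort_params`.
#' @export
cohort_params <- function(n_c1 = 77, n_c2 = 55,
                          panel = pyroptosis_panel(),
                          de_up_c2 = subtype_signature()$up_c2,
                          de_up_c1 = subtype_signature()$up_c1,
                          effect_size = 1.5, noise_sd = 1,
                          baseline_hazard = 1 / 600, hr_c2_vs_c1 = 2,
                          censor_rate = 0.3, n_background = 0) {
  if (n_c1 < 2 || n_c2 < 2) stop("need at least 2 samples per subtype")
  if (anyDuplicated(panel)) stop("panel contains duplicated genes")
  if (length(intersect(de_up_c1, de_up_c2)) > 0)
    stop("de_up_c1 and de_up_c2 overlap: ",
         paste(intersect(de_up_c1, de_up_c2), collapse = ", "))
  missing <- setdiff(c(de_up_c1, de_up_c2), panel)
  if (length(missing) > 0)
    stop("DE genes absent from panel: ", paste(missing, collapse = ", "))
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (hr_c2_vs_c1 <= 0) stop("hr_c2_vs_c1 must be > 0")
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)")
  if (n_background < 0) stop("n_background must be >= 0")
  structure(list(n_c1 = n_c1, n_c2 = n_c2, panel = panel,
                 de_up_c2 = de_up_c2, de_up_c1 = de_up_c1,
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline_hazard = baseline_hazard,
                 hr_c2_vs_c1 = hr_c2_vs_c1, censor_rate = censor_rate,
                 n_background = n_background),
            class = "cohort_params")
}

# Per-gene log2 baseline expression, a fixed property of the gene symbol
# (hashed), shared by every generated cohort: cohorts differ in noise,
# subtype composition and platform, not in the genes' reference levels.
gene_baseline <- function(genes) {
  vapply(genes, function(g) {
    set.seed(derive_seed(20260925, paste0("baseline_", g)))
    stats::runif(1, 3, 10)
  }, numeric(1))
}

# Uniform(0, tau) administrative censoring horizon achieving the target
# expected censoring fraction under the cohort's mixture of exponential
# hazards: P(censored | rate) = (1 - exp(-rate*tau)) / (rate*tau).
censor_horizon <- function(rates, target) {
  f <- function(tau) mean((1 - exp(-rates * tau)) / (rates * tau)) - target
  stats::uniroot(f, lower = 1e-6, upper = 1e9, tol = 1e-8)$root
}

#' Generate a synthetic two-subtype cohort
#'
#' Per-gene log2 values are Normal(baseline_g + subtype shift, noise_sd).
#' Baselines are drawn once per gene from Uniform(3, 10) as a fixed
#' function of the gene symbol, so all cohorts share the same reference
#' expression levels (cohorts differ in sampling noise, composition, and
#' platform, not in gene biology); genes in
#' `de_up_c2` are shifted by +effect_size * noise_sd in C2 (and `de_up_c1`
#' genes by the negative), all other genes share means. Survival times are
#' exponential with the C2 hazard multiplied by `hr_c2_vs_c1`, censored by
#' independent Uniform(0, tau) administrative censoring calibrated to
#' `censor_rate`. Clinical covariates (age, sex, karyotype risk) are drawn
#' with subtype-linked karyotype and age distributions.
#'
#' The expression, survival, and clinical draws use separate RNG streams
#' derived from `seed`, so e.g. changing `n_background` leaves the
#' survival realization untouched.
#'
#' @param params a [cohort_params()] object.
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @return List with `expr` (log2 gene x sample matrix), `surv`
#'   (data.frame: sample_id, os_time, os_event, age, sex, karyotype_risk)
#'   and `truth` (data.frame: sample_id, subtype).
#' @export
generate_cohort <- function(params = cohort_params(), seed = 1) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  n <- p$n_c1 + p$n_c2
  subtype <- rep(c("C1", "C2"), c(p$n_c1, p$n_c2))
  sample_id <- sprintf("S%03d", seq_len(n))
  genes <- p$panel
  if (p$n_background > 0)
    genes <- c(genes, sprintf("BG%04d", seq_len(p$n_background)))
  g <- length(genes)

  baseline <- gene_baseline(genes)
  set.seed(derive_seed(seed, "expr"))
  delta <- numeric(g)
  names(delta) <- genes
  delta[p$de_up_c2] <- p$effect_size * p$noise_sd
  delta[p$de_up_c1] <- -p$effect_size * p$noise_sd
  mu <- baseline + outer(delta, as.numeric(subtype == "C2"))
  expr <- mu + matrix(stats::rnorm(g * n, sd = p$noise_sd), g, n)
  dimnames(expr) <- list(genes, sample_id)

  set.seed(derive_seed(seed, "survival"))
  rate <- p$baseline_hazard * ifelse(subtype == "C2", p$hr_c2_vs_c1, 1)
  t_event <- stats::rexp(n, rate)
  if (p$censor_rate > 0) {
    tau <- censor_horizon(unique(rate), p$censor_rate)
    t_cens <- stats::runif(n, 0, tau)
  } else {
    t_cens <- rep(Inf, n)
  }
  os_time <- pmax(pmin(t_event, t_cens), 1e-3)
  os_event <- as.integer(t_event <= t_cens)

  set.seed(derive_seed(seed, "clinical"))
  karyo_p <- list(C1 = c(favorable = 0.40, `intermediate/normal` = 0.50,
                         poor = 0.10),
                  C2 = c(favorable = 0.10, `intermediate/normal` = 0.50,
                         poor = 0.40))
  karyotype_risk <- vapply(subtype, function(s)
    sample(names(karyo_p[[s]]), 1, prob = karyo_p[[s]]), character(1))
  age <- round(pmin(pmax(stats::rnorm(n, ifelse(subtype == "C2", 58, 50),
                                      12), 18), 88))
  sex <- sample(c("F", "M"), n, replace = TRUE)

  surv <- data.frame(sample_id = sample_id, os_time = os_time,
                     os_event = os_event, age = age, sex = sex,
                     karyotype_risk = karyotype_risk,
                     stringsAsFactors = FALSE, row.names = NULL)
  truth <- data.frame(sample_id = sample_id, subtype = subtype,
                      stringsAsFactors = FALSE)
  out <- list(expr = expr, surv = surv, truth = truth)
  attr(out, "seed") <- seed
  out
}

#' Specification of a cross-platform distortion
#'
#' Stands in for the systematic difference between expression platforms
#' (e.g. microarray versus RNA-seq): an identity, affine, or strictly
#' monotone nonlinear map of log2 values plus per-measurement noise.
#'
#' @param kind one of `"identity"`, `"affine"`, `"monotone-nonlinear"`.
#' @param gain multiplicative slope (> 0).
#' @param offset additive log2 shift.
#' @param curvature exponent of the monotone map (> 0).
#' @param pernoise_sd per-measurement additive Gaussian noise SD.
#' @return A validated list of class `platform_spec`.
#' @export
platform_spec <- function(kind = c("identity", "affine",
                                   "monotone-nonlinear"),
                          gain = 1, offset = 0, curvature = 1,
                          pernoise_sd = 0) {
  kind <- match.arg(kind)
  if (gain <= 0) stop("gain must be > 0")
  if (curvature <= 0) stop("curvature must be > 0")
  if (pernoise_sd < 0) stop("pernoise_sd must be >= 0")
  structure(list(kind = kind, gain = gain, offset = offset,
                 curvature = curvature, pernoise_sd = pernoise_sd),
            class = "platform_spec")
}

#' Apply a platform distortion to an expression matrix
#'
#' The monotone-nonlinear map is `gain * (x - min(x) + 1)^curvature +
#' offset`, strictly increasing on the observed range, so with
#' `pernoise_sd = 0` within-sample gene rankings (and hence rank-pair
#' features) are preserved exactly.
#'
#' @param expr log2 gene x sample matrix.
#' @param spec a [platform_spec()].
#' @param seed RNG seed for the per-measurement noise.
#' @return Distorted matrix of the same shape and dimnames; the generated
#'   noise matrix is attached as attribute `"noise"` so downstream checks
#'   can reconstruct the transform.
#' @export
platform_shift <- function(expr, spec, seed = 1) {
  check_expr(expr)
  stopifnot(inherits(spec, "platform_spec"))
  base <- switch(spec$kind,
    identity = expr,
    affine = spec$gain * expr + spec$offset,
    `monotone-nonlinear` =
      spec$gain * (expr - min(expr) + 1)^spec$curvature + spec$offset)
  if (spec$pernoise_sd > 0) {
    set.seed(seed)
    noise <- matrix(stats::rnorm(length(expr), sd = spec$pernoise_sd),
                    nrow(expr), ncol(expr))
  } else {
    noise <- matrix(0, nrow(expr), ncol(expr))
  }
  out <- base + noise
  dimnames(out) <- dimnames(expr)
  attr(out, "noise") <- noise
  out
}

#' Parameters for the synthetic single-cell generator
#'
#' @param cells_per_sample cells generated per bulk sample (>= 1).
#' @param malignant_fraction fraction of malignant cells in (0, 1].
#' @param library_size_mean expected total counts per cell (> 0).
#' @param celltype_labels vocabulary for non-malignant cell-type labels.
#' @return A validated list of class `sc_params`.
#' @export
sc_params <- function(cells_per_sample = 100, malignant_fraction = 0.7,
                      library_size_mean = 5000,
                      celltype_labels = c("Tcell", "Bcell", "NK",
                                          "Monocyte")) {
  if (cells_per_sample < 1) stop("cells_per_sample must be >= 1")
  if (malignant_fraction <= 0 || malignant_fraction > 1)
    stop("malignant_fraction must be in (0, 1]")
  if (library_size_mean <= 0) stop("library_size_mean must be > 0")
  if (length(celltype_labels) < 1) stop("need at least one cell-type label")
  structure(list(cells_per_sample = cells_per_sample,
                 malignant_fraction = malignant_fraction,
                 library_size_mean = library_size_mean,
                 celltype_labels = celltype_labels),
            class = "sc_params")
}

#' Generate synthetic single-cell counts from a bulk cohort
#'
#' Each malignant cell's counts are multinomial with gene probabilities
#' proportional to its sample's linear-scale bulk profile; non-malignant
#' cells draw from a shared background profile (the geometric mean of the
#' linear bulk profiles), keeping them subtype-uninformative. Library sizes
#' are Poisson around `library_size_mean`.
#'
#' @param bulk log2 gene x sample expression matrix.
#' @param truth data.frame with sample_id and subtype (carried into the
#'   annotation for downstream evaluation).
#' @param params an [sc_params()] object.
#' @param seed RNG seed.
#' @return List with `counts` (gene x cell integer matrix) and `annotation`
#'   (data.frame: cell_id, sample_id, cell_type, malignant).
#' @export
generate_single_cell <- function(bulk, truth, params = sc_params(),
                                 seed = 1) {
  check_expr(bulk, "bulk matrix")
  stopifnot(inherits(params, "sc_params"))
  if (ncol(bulk) < 1) stop("empty bulk matrix")
  set.seed(seed)
  lin <- 2^bulk
  background <- exp(rowMeans(log(lin)))
  n_cells <- params$cells_per_sample
  n_mal <- max(1L, round(params$malignant_fraction * n_cells))
  if (params$malignant_fraction == 1) n_mal <- n_cells

  counts <- NULL
  ann <- vector("list", ncol(bulk))
  for (s in seq_len(ncol(bulk))) {
    sid <- colnames(bulk)[s]
    malignant <- c(rep(1L, n_mal), rep(0L, n_cells - n_mal))
    libsize <- stats::rpois(n_cells, params$library_size_mean)
    libsize[libsize == 0] <- 1L
    mat <- matrix(0L, nrow(bulk), n_cells)
    p_mal <- lin[, s] / sum(lin[, s])
    p_bg <- background / sum(background)
    for (ci in seq_len(n_cells)) {
      pr <- if (malignant[ci] == 1L) p_mal else p_bg
      mat[, ci] <- stats::rmultinom(1, libsize[ci], pr)[, 1]
    }
    ctype <- ifelse(malignant == 1L, "Malignant",
                    sample(params$celltype_labels, n_cells, replace = TRUE))
    cell_id <- sprintf("%s_c%04d", sid, seq_len(n_cells))
    colnames(mat) <- cell_id
    counts <- cbind(counts, mat)
    ann[[s]] <- data.frame(cell_id = cell_id, sample_id = sid,
                           cell_type = ctype, malignant = malignant,
                           stringsAsFactors = FALSE)
  }
  rownames(counts) <- rownames(bulk)
  annotation <- do.call(rbind, ann)
  rownames(annotation) <- NULL
  list(counts = counts, annotation = annotation)
}

#' Generate a synthetic gene-set collection with known enriched sets
#'
#' `n_enriched` sets draw at least 75% of their members from
#' `enrich_genes` (the genes differential between subtypes); the remaining
#' sets are sampled uniformly from the universe. Enriched set sizes are
#' capped at `floor(|enrich_genes| / 0.75)` so the 75% membership floor is
#' always attainable.
#'
#' @param universe gene symbols to sample from.
#' @param n_sets number of sets.
#' @param set_size integer range `c(min, max)` of set sizes.
#' @param n_enriched how many sets to enrich (<= n_sets).
#' @param enrich_genes genes the enriched sets concentrate on.
#' @param seed RNG seed.
#' @param names optional set names (must be unique, length n_sets).
#' @return List with `sets` (a named list of member vectors, GMT-writable)
#'   and `truth` (character vector of enriched set names).
#' @export
generate_gene_sets <- function(universe, n_sets = 50,
                               set_size = c(10, 50), n_enriched = 10,
                               enrich_genes = character(), seed = 1,
                               names = NULL) {
  if (length(universe) == 0) stop("empty universe")
  if (anyDuplicated(universe)) stop("universe contains duplicates")
  if (set_size[1] < 2) stop("set sizes must be >= 2")
  if (set_size[2] > length(universe))
    stop("set_size exceeds universe size")
  if (n_enriched > n_sets) stop("n_enriched must be <= n_sets")
  if (n_enriched > 0 && length(enrich_genes) == 0)
    stop("n_enriched > 0 requires enrich_genes")
  if (!all(enrich_genes %in% universe))
    stop("enrich_genes must be contained in universe")
  if (is.null(names)) {
    names <- sprintf("SET_%03d", seq_len(n_sets))
  } else {
    if (length(names) != n_sets) stop("names must have length n_sets")
    if (anyDuplicated(names))
      stop("duplicate set names requested: ",
           paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  set.seed(seed)
  sizes <- sample(seq(set_size[1], set_size[2]), n_sets, replace = TRUE)
  sets <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    if (i <= n_enriched) {
      size_i <- max(set_size[1],
                    min(sizes[i], floor(length(enrich_genes) / 0.75)))
      k <- min(ceiling(0.75 * size_i), length(enrich_genes))
      core <- sample(enrich_genes, k)
      rest <- sample(setdiff(universe, core), size_i - k)
      sets[[i]] <- sample(c(core, rest))
    } else {
      sets[[i]] <- sample(universe, sizes[i])
    }
  }
  names(sets) <- names
  list(sets = sets, truth = names[seq_len(n_enriched)])
}
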