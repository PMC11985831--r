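# Survival and classical statistics: panel-gene differential expression,
# correlation matrices, Cox regression (univariate and adjusted, Breslow
# ties), Kaplan-Meier/log-rank (optionally within karyotype strata),
# LASSO-Cox gene-set selection, Fisher exact clinical contrasts, and
# parallel-analysis factor extraction.

#' Mann-Whitney differential expression between two groups
#'
#' Per gene, a two-sided Mann-Whitney U test: exact by enumeration of all
#' group assignments when the combined sample size is <= 20 (ties handled
#' through midranks; the two-sided p is the probability of a U at least as
#' far from its null mean as observed), normal approximation with tie
#' correction otherwise; BH adjustment across genes. Genes constant
#' across all samples get p = 1 and are flagged.
#'
#' @param expr gene x sample matrix.
#' @param groups two-group assignment (named vector or data.frame with
#'   sample_id/subtype); each group >= 2 samples.
#' @return data.frame: gene, U, p, q, direction (`up_<group>` by mean
#'   difference), constant flag.
#' @export
mannwhitney_de <- function(expr, groups) {
  check_expr(expr)
  grp <- as_group_vector(groups)
  if (!is.null(names(grp)) && all(colnames(expr) %in% names(grp)))
    grp <- grp[colnames(expr)]
  if (length(grp) != ncol(expr)) stop("groups do not match samples")
  lv <- sort(unique(grp))
  if (length(lv) != 2) stop("exactly two groups are required")
  if (any(table(grp) < 2)) stop("each group needs >= 2 samples")

  res <- lapply(rownames(expr), function(g) {
    x <- expr[g, grp == lv[1]]
    y <- expr[g, grp == lv[2]]
    if (length(unique(c(x, y))) == 1)
      return(data.frame(gene = g, U = length(x) * length(y) / 2, p = 1,
                        direction = NA_character_, constant = TRUE,
                        stringsAsFactors = FALSE))
    n <- length(x) + length(y)
    if (n <= 20) {
      res <- mw_exact_enum(x, y)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
      res <- list(U = unname(wt$statistic), p = wt$p.value)
    }
    data.frame(gene = g, U = res$U, p = res$p,
               direction = if (mean(y) >= mean(x)) paste0("up_", lv[2])
                           else paste0("up_", lv[1]),
               constant = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out[, c("gene", "U", "p", "q", "direction", "constant")]
}

# Exact two-sided Mann-Whitney by full enumeration: U for every
# assignment of the pooled midranks to group 1; p is the probability of a
# U at least as far from n1*n2/2 as the observed one.
mw_exact_enum <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(r), n1)
  u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  center <- n1 * length(y) / 2
  list(U = u_obs,
       p = mean(abs(u_all - center) >= abs(u_obs - center) - 1e-9))
}

#' Pairwise Pearson correlation matrix with p-values
#'
#' p-values from the t transform `t = r * sqrt((n-2) / (1-r^2))` with
#' `n - 2` degrees of freedom. Zero-variance genes give NA with a warning.
#'
#' @param expr gene x sample matrix with >= 3 samples.
#' @return List with `r` (symmetric, unit diagonal) and `p` matrices.
#' @export
pearson_matrix <- function(expr) {
  check_expr(expr)
  n <- ncol(expr)
  if (n < 3) stop("need >= 3 samples")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0))
    warning("zero-variance gene(s), correlations undefined: ",
            paste(rownames(expr)[sds == 0], collapse = ", "))
  r <- suppressWarnings(stats::cor(t(expr)))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  diag(r) <- 1; diag(p) <- 0
  list(r = r, p = p)
}

#' Cox proportional-hazards fit for one covariate (optionally adjusted)
#'
#' Partial-likelihood fit (Breslow tie handling) via \pkg{survival}, Wald
#' test, HR with 95% CI.
#'
#' @param surv data.frame with os_time, os_event and the covariate (and
#'   adjuster) columns.
#' @param covariate name of the covariate of interest.
#' @param adjusters character vector of adjustment covariates (e.g. age,
#'   sex).
#' @return One-row data.frame: covariate, hr, ci_low, ci_high, p,
#'   adjusters, converged.
#' @export
cox_fit <- function(surv, covariate, adjusters = character()) {
  if (sum(surv$os_event) < 1) stop("no events")
  v <- surv[[covariate]]
  if (is.null(v)) stop("covariate not found: ", covariate)
  if (length(unique(v)) == 1) stop("covariate is constant: ", covariate)
  dat <- surv
  if ("sex" %in% adjusters && !is.numeric(dat$sex))
    dat$sex <- as.numeric(factor(dat$sex)) - 1
  fml <- stats::reformulate(c(sprintf("`%s`", covariate),
                              sprintf("`%s`", adjusters)),
                            response = "survival::Surv(os_time, os_event)")
  fit <- tryCatch(survival::coxph(fml, data = dat, ties = "breslow"),
                  warning = function(w) {
                    f <- suppressWarnings(
                      survival::coxph(fml, data = dat, ties = "breslow"))
                    attr(f, "flagged") <- conditionMessage(w)
                    f
                  })
  sm <- summary(fit)
  row <- grep(covariate, rownames(sm$coefficients), fixed = TRUE)[1]
  beta <- sm$coefficients[row, "coef"]
  se <- sm$coefficients[row, "se(coef)"]
  data.frame(covariate = covariate, hr = exp(beta),
             ci_low = exp(beta - 1.96 * se),
             ci_high = exp(beta + 1.96 * se),
             p = sm$coefficients[row, "Pr(>|z|)"],
             adjusters = paste(adjusters, collapse = "+"),
             converged = is.null(attr(fit, "flagged")),
             stringsAsFactors = FALSE)
}

#' Batch Cox regression over many covariates with BH adjustment
#'
#' @inheritParams cox_fit
#' @param covariates covariate names fitted one at a time.
#' @return data.frame of [cox_fit()] rows plus a BH `q` column.
#' @export
cox_batch <- function(surv, covariates, adjusters = character()) {
  out <- do.call(rbind, lapply(covariates, function(cv)
    cox_fit(surv, cv, adjusters)))
  out$q <- bh_adjust(out$p)
  out
}

#' Kaplan-Meier curves and log-rank test between groups
#'
#' Product-limit estimates per group with the log-rank chi-square from
#' observed-minus-expected over the risk sets. With `stratum` given, the
#' analysis runs within that karyotype (or other stratum column) subset.
#'
#' @param surv data.frame with os_time, os_event, sample_id.
#' @param groups group assignment (named vector or data.frame).
#' @param stratum optional value of `stratum_col` to subset to before the
#'   analysis.
#' @param stratum_col column used for subsetting (default
#'   "karyotype_risk").
#' @return List with `fit` (a `survfit` object), `chisq`, `p`, and `n`.
#' @export
km_logrank <- function(surv, groups, stratum = NULL,
                       stratum_col = "karyotype_risk") {
  grp <- as_group_vector(groups)
  dat <- surv
  dat$group <- grp[match(dat$sample_id, names(grp))]
  if (any(is.na(dat$group))) stop("samples without a group label")
  if (!is.null(stratum)) {
    dat <- dat[dat[[stratum_col]] == stratum, , drop = FALSE]
    if (nrow(dat) == 0) stop("empty stratum: ", stratum)
  }
  if (any(table(dat$group) == 0) || length(unique(dat$group)) < 2)
    stop("each group needs at least one subject")
  fit <- survival::survfit(survival::Surv(os_time, os_event) ~ group,
                           data = dat)
  sd <- survival::survdiff(survival::Surv(os_time, os_event) ~ group,
                           data = dat)
  df <- length(unique(dat$group)) - 1
  list(fit = fit, chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE),
       n = nrow(dat))
}

#' LASSO-Cox selection of prognostic gene sets
#'
#' L1-penalized Cox regression over a log-spaced lambda path with
#' cross-validated partial-likelihood deviance; the chosen lambda is the
#' CV minimizer and the selection is the sets with nonzero coefficients
#' there. Fold assignment is deterministic given the seed; folds without
#' events are reshuffled with a warning.
#'
#' @param es set x sample enrichment-score matrix (>= 2 candidate sets).
#' @param surv data.frame with sample_id, os_time, os_event covering the
#'   es samples; events must be >= n_folds.
#' @param n_folds CV folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @return List of class `lasso_selection`: selected, coefficients,
#'   lambda, lambda_path, cv_deviance, n_folds.
#' @export
lasso_cox_select <- function(es, surv, n_folds = 10, seed = 1) {
  if (nrow(es) < 2) stop("need >= 2 candidate sets")
  idx <- match(colnames(es), surv$sample_id)
  if (any(is.na(idx))) stop("es samples missing from the survival table")
  sv <- surv[idx, ]
  if (sum(sv$os_event) < n_folds)
    stop("events must be >= n_folds")
  x <- t(es)
  y <- survival::Surv(sv$os_time, sv$os_event)
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(n_folds), nrow(x)))
  for (tries in 1:20) {
    ev_per_fold <- tapply(sv$os_event, foldid, sum)
    if (all(ev_per_fold >= 1)) break
    warning("fold without events; reshuffling folds")
    foldid <- sample(rep_len(seq_len(n_folds), nrow(x)))
  }
  cv <- glmnet::cv.glmnet(x, y, family = "cox", alpha = 1,
                          foldid = foldid)
  cf <- as.matrix(stats::coef(cv, s = "lambda.min"))
  nz <- cf[, 1] != 0
  structure(list(selected = rownames(cf)[nz],
                 coefficients = stats::setNames(cf[nz, 1],
                                                rownames(cf)[nz]),
                 lambda = cv$lambda.min, lambda_path = cv$lambda,
                 cv_deviance = cv$cvm, n_folds = n_folds),
            class = "lasso_selection")
}

#' Fisher's exact test for a 2 x K contingency table
#'
#' 2 x 2 tables use the exact two-sided hypergeometric test (sum of table
#' probabilities <= the observed one). Larger tables use exact network
#' enumeration when small and a seeded Monte Carlo approximation (flagged)
#' otherwise.
#'
#' @param tab contingency matrix of nonnegative integers with positive
#'   margins.
#' @param seed RNG seed for the Monte Carlo branch.
#' @param mc_draws Monte Carlo replicates (default 1e5).
#' @param mc_threshold total count above which 2 x K tables switch to
#'   Monte Carlo (default 500).
#' @return List with `p` and `monte_carlo` flag.
#' @export
fisher_exact <- function(tab, seed = 1, mc_draws = 1e5,
                         mc_threshold = 500) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table must contain nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin")
  small <- ncol(tab) <= 2 || sum(tab) <= mc_threshold
  if (small) {
    list(p = stats::fisher.test(tab)$p.value, monte_carlo = FALSE)
  } else {
    set.seed(seed)
    list(p = stats::fisher.test(tab, simulate.p.value = TRUE,
                                B = mc_draws)$p.value,
         monte_carlo = TRUE)
  }
}

#' Parallel-analysis factor retention with principal-axis loadings
#'
#' Retention walks down the observed correlation-matrix eigenvalues and
#' keeps factors until one fails to exceed the criterion computed from
#' `n_sim` same-shape standard-normal datasets: the `quantile` (default
#' 0.95, which keeps spurious retention on pure noise near 5%) or, with
#' `quantile = NULL`, the mean of the simulated eigenvalues at that
#' position. Loadings come from
#' iterated principal-axis factoring on the retained factors, varimax
#' rotated when more than one factor is kept. Variables creating a
#' singular correlation matrix are dropped with a warning.
#'
#' @param data variable x sample numeric matrix (categoricals pre-encoded
#'   as 0/1 dummies); >= 3 variables.
#' @param n_sim simulated null datasets (default 100).
#' @param seed RNG seed for the simulation.
#' @param quantile simulated-eigenvalue quantile used as the retention
#'   criterion (default 0.95); `NULL` uses the simulated mean.
#' @return List of class `factor_report`: n_factors, loadings,
#'   eigen_observed, eigen_simulated, dropped.
#' @export
parallel_factors <- function(data, n_sim = 100, seed = 1,
                             quantile = 0.95) {
  if (!is.matrix(data)) data <- as.matrix(data)
  if (nrow(data) < 3) stop("need >= 3 variables")
  X <- t(data)  # samples x variables
  dropped <- character(0)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    dropped <- colnames(X)[sds == 0]
    warning("constant variable(s) dropped: ",
            paste(dropped, collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  R <- stats::cor(X)
  # collapse perfectly collinear pairs (singular correlation matrix)
  up <- which(abs(R) > 1 - 1e-10 & upper.tri(R), arr.ind = TRUE)
  if (nrow(up) > 0) {
    drop_idx <- unique(up[, 2])
    dropped <- c(dropped, colnames(R)[drop_idx])
    warning("collinear variable(s) dropped: ",
            paste(colnames(R)[drop_idx], collapse = ", "))
    X <- X[, -drop_idx, drop = FALSE]
    R <- stats::cor(X)
  }
  n <- nrow(X); p <- ncol(X)
  eig_obs <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  set.seed(seed)
  sim <- matrix(0, n_sim, p)
  for (i in seq_len(n_sim)) {
    Z <- matrix(stats::rnorm(n * p), n, p)
    sim[i, ] <- eigen(stats::cor(Z), symmetric = TRUE,
                      only.values = TRUE)$values
  }
  eig_sim <- if (is.null(quantile)) colMeans(sim)
             else apply(sim, 2, stats::quantile, probs = quantile)
  # sequential retention: stop at the first eigenvalue that fails the
  # criterion (later chance exceedances do not count)
  fail <- which(eig_obs <= eig_sim)
  n_factors <- if (length(fail) == 0) p else fail[1] - 1L
  loadings <- NULL
  if (n_factors >= 1) {
    loadings <- principal_axis(R, n_factors)
    if (n_factors >= 2)
      loadings <- stats::varimax(loadings)$loadings[, , drop = FALSE]
    rownames(loadings) <- colnames(X)
    colnames(loadings) <- paste0("Factor", seq_len(n_factors))
  }
  structure(list(n_factors = n_factors, loadings = loadings,
                 eigen_observed = eig_obs, eigen_simulated = eig_sim,
                 dropped = dropped),
            class = "factor_report")
}

# Iterated principal-axis factoring: communalities start at squared
# multiple correlations and are refined until stable.
principal_axis <- function(R, k, max_iter = 100, tol = 1e-6) {
  p <- ncol(R)
  Rinv <- tryCatch(solve(R), error = function(e) pinv_svd(R))
  h2 <- pmin(pmax(1 - 1 / diag(Rinv), 0.05), 0.995)
  for (it in seq_len(max_iter)) {
    Rh <- R
    diag(Rh) <- h2
    e <- eigen(Rh, symmetric = TRUE)
    ev <- pmax(e$values[seq_len(k)], 0)
    L <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev), k, k)
    h2_new <- pmin(rowSums(L^2), 0.995)
    if (max(abs(h2_new - h2)) < tol) {
      h2 <- h2_new
      break
    }
    h2 <- h2_new
  }
  L
}

# Moore-Penrose pseudo-inverse via SVD (fallback for singular R).
pinv_svd <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}
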