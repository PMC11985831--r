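test_that("Mann-Whitney exact p equals enumeration for small samples", {
  set.seed(1)
  for (rep in 1:10) {
    x <- sample(40, 3); y <- sample(40, 3)
    expr <- matrix(c(x, y), 1, 6,
                   dimnames = list("g", paste0("s", 1:6)))
    grp <- stats::setNames(rep(c("A", "B"), each = 3), colnames(expr))
    de <- mannwhitney_de(expr, grp)
    expect_equal(de$p, mw_exact_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney null rejection rate stays near nominal", {
  fracs <- vapply(1:30, function(s) {
    set.seed(s)
    expr <- matrix(rnorm(40 * 20), 40, 20,
                   dimnames = list(paste0("g", 1:40), paste0("s", 1:20)))
    grp <- stats::setNames(rep(c("A", "B"), each = 10), colnames(expr))
    mean(mannwhitney_de(expr, grp)$q < 0.05)
  }, numeric(1))
  expect_lte(mean(fracs), 0.05)
})

test_that("the 19 implanted genes are recovered on the default preset", {
  co <- default_cohort(seed = 1)
  de <- mannwhitney_de(co$expr, co$truth)
  called <- de$gene[de$q < 0.05]
  sig <- subtype_signature()
  expect_true(all(c(sig$up_c2, sig$up_c1) %in% called))
  expect_lte(length(called), 22)
  up2 <- de$direction[match(sig$up_c2, de$gene)]
  expect_true(all(up2 == "up_C2"))
})

test_that("constant genes are flagged with p = 1", {
  expr <- matrix(c(rep(1, 6), rnorm(6)), 2, 6, byrow = TRUE,
                 dimnames = list(c("flat", "ok"), paste0("s", 1:6)))
  grp <- stats::setNames(rep(c("A", "B"), 3), colnames(expr))
  de <- mannwhitney_de(expr, grp)
  expect_equal(de$p[de$gene == "flat"], 1)
  expect_true(de$constant[de$gene == "flat"])
})

test_that("Pearson matrix matches the direct covariance formula", {
  expr <- matrix(c(1, 2, 3, 4, 5,
                   2, 1, 4, 3, 6,
                   -1, -2, -3, -4, -5), 3, 5, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), paste0("s", 1:5)))
  pm <- pearson_matrix(expr)
  manual <- function(x, y)
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pm$r["a", "b"], manual(expr["a", ], expr["b", ]),
               tolerance = 1e-12)
  expect_equal(pm$r["a", "a"], 1)
  expect_equal(pm$r["a", "c"], -1)
  expect_equal(pm$p["a", "c"], 0)
  # p matches cor.test
  ct <- stats::cor.test(expr["a", ], expr["b", ])
  expect_equal(pm$p["a", "b"], ct$p.value, tolerance = 1e-9)

  expr2 <- rbind(expr, flat = rep(1, 5))
  expect_warning(pm2 <- pearson_matrix(expr2), "zero-variance")
  expect_true(is.na(pm2$r["flat", "a"]))
})

test_that("Cox fit matches a grid-searched partial likelihood", {
  surv <- data.frame(sample_id = paste0("s", 1:6),
                     os_time = c(2, 5, 7, 11, 13, 17),
                     os_event = 1, x = c(1, 0, 1, 0, 1, 0))
  fit <- cox_fit(surv, "x")
  # brute-force partial likelihood over a fine beta grid (Breslow, but
  # all times distinct so ties never arise)
  pl <- function(beta) {
    ll <- 0
    for (i in which(surv$os_event == 1)) {
      risk <- surv$os_time >= surv$os_time[i]
      ll <- ll + beta * surv$x[i] - log(sum(exp(beta * surv$x[risk])))
    }
    ll
  }
  grid <- seq(-3, 3, by = 1e-4)
  beta_hat <- grid[which.max(vapply(grid, pl, numeric(1)))]
  expect_equal(log(fit$hr), beta_hat, tolerance = 1e-3)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)
})

test_that("Cox recovers a known hazard ratio at n = 500", {
  set.seed(11)
  n <- 500
  x <- rep(0:1, each = n / 2)
  time <- stats::rexp(n, 0.01 * 2^x)
  surv <- data.frame(sample_id = paste0("s", 1:n), os_time = time,
                     os_event = 1, x = x)
  fit <- cox_fit(surv, "x")
  expect_gte(fit$hr, 1.8)
  expect_lte(fit$hr, 2.2)
})

test_that("Cox null calibration: unit HR and nominal type-I error", {
  set.seed(12)
  res <- t(vapply(1:200, function(i) {
    n <- 100
    x <- stats::rnorm(n)
    surv <- data.frame(sample_id = seq_len(n),
                       os_time = stats::rexp(n, 0.01),
                       os_event = 1, x = x)
    fit <- cox_fit(surv, "x")
    c(hr = fit$hr, sig = fit$p < 0.05)
  }, numeric(2)))
  expect_gte(mean(res[, "hr"]), 0.9)
  expect_lte(mean(res[, "hr"]), 1.1)
  expect_lte(mean(res[, "sig"]), 0.105)  # binomial error around 0.05
})

test_that("batch Cox applies BH across covariates and supports adjusters", {
  co <- default_cohort(seed = 21)
  genes <- pyroptosis_panel()[1:5]
  dat <- cbind(co$surv, as.data.frame(t(co$expr[genes, co$surv$sample_id])))
  out <- cox_batch(dat, genes)
  expect_equal(out$q, bh_stepup_oracle(out$p), tolerance = 1e-12)
  adj <- cox_batch(dat, genes, adjusters = c("age", "sex"))
  expect_equal(adj$adjusters, rep("age+sex", 5))
  expect_true(all(adj$hr > 0))
  expect_error(cox_fit(transform(dat, os_event = 0), genes[1]), "no events")
})

test_that("log-rank equals the hand-computed risk-set statistic", {
  time <- c(3, 5, 7, 9, 11, 13)
  event <- c(1, 1, 1, 1, 0, 1)
  group <- rep(c("A", "B"), 3)
  surv <- data.frame(sample_id = paste0("s", 1:6), os_time = time,
                     os_event = event)
  km <- km_logrank(surv, stats::setNames(group, surv$sample_id))
  expect_equal(km$chisq, logrank_oracle(time, event, group),
               tolerance = 1e-9)

  # identical groups: statistic 0, p = 1
  surv2 <- rbind(surv, transform(surv, sample_id = paste0("t", 1:6)))
  grp2 <- stats::setNames(rep(c("A", "B"), each = 6), surv2$sample_id)
  # same survival data duplicated into both groups
  surv2$os_time <- rep(time, 2); surv2$os_event <- rep(event, 2)
  km2 <- km_logrank(surv2, grp2)
  expect_lt(km2$chisq, 1e-9)
  expect_equal(km2$p, 1, tolerance = 1e-6)
})

test_that("KM curves stay flat beyond the last event under censoring", {
  surv <- data.frame(sample_id = paste0("s", 1:6),
                     os_time = c(2, 4, 6, 8, 10, 20),
                     os_event = c(1, 1, 0, 1, 0, 0))
  grp <- stats::setNames(rep(c("A", "B"), 3), surv$sample_id)
  km <- km_logrank(surv, grp)
  sf <- summary(km$fit)
  last <- utils::tail(sf$surv, 1)
  expect_gt(last, 0)  # censored tail: no drop to zero
})

test_that("stratified KM runs within the requested karyotype subset", {
  co <- default_cohort(seed = 30)
  km <- km_logrank(co$surv, co$truth, stratum = "intermediate/normal")
  expect_equal(km$n,
               sum(co$surv$karyotype_risk == "intermediate/normal"))
  expect_error(km_logrank(co$surv, co$truth, stratum = "nonexistent"),
               "empty stratum")
})

test_that("Cox and log-rank agree on direction at large n", {
  co <- default_cohort(seed = 33, n_c1 = 300, n_c2 = 300)
  dat <- cbind(co$surv, g = as.numeric(co$truth$subtype == "C2"))
  fit <- cox_fit(dat, "g")
  expect_gt(fit$hr, 1)  # C2 carries the implanted excess hazard
  km <- km_logrank(co$surv, co$truth)
  expect_lt(km$p, 0.01)
  sf <- survival::survfit(survival::Surv(os_time, os_event) ~ subtype,
                          data = cbind(co$surv, subtype = co$truth$subtype))
  s_at <- summary(sf, times = stats::median(co$surv$os_time))
  expect_gt(s_at$surv[1], s_at$surv[2])  # C1 curve above C2
})

test_that("full shrinkage at the top of the lambda path empties the model", {
  set.seed(41)
  es <- matrix(rnorm(10 * 60), 10, 60,
               dimnames = list(paste0("S", 1:10), paste0("s", 1:60)))
  surv <- data.frame(sample_id = colnames(es),
                     os_time = stats::rexp(60, 0.01), os_event = 1)
  sel <- lasso_cox_select(es, surv, n_folds = 5, seed = 1)
  fit_max <- glmnet::glmnet(t(es), survival::Surv(surv$os_time,
                                                  surv$os_event),
                            family = "cox", lambda = max(sel$lambda_path))
  expect_equal(sum(as.matrix(stats::coef(fit_max)) != 0), 0)
  expect_true(all(sel$selected %in% rownames(es)))
})

test_that("LASSO-Cox recovers risky sets among null candidates", {
  hits <- t(vapply(1:12, function(s) {
    set.seed(s)
    n <- 200
    es <- matrix(rnorm(52 * n), 52, n,
                 dimnames = list(paste0("S", 1:52), paste0("s", 1:n)))
    risk <- exp(1.0 * (es[1, ] + es[2, ]))
    surv <- data.frame(sample_id = colnames(es),
                       os_time = stats::rexp(n, 0.01 * risk),
                       os_event = 1)
    sel <- lasso_cox_select(es, surv, n_folds = 10, seed = s)
    c(truth = all(c("S1", "S2") %in% sel$selected),
      false = length(setdiff(sel$selected, c("S1", "S2"))))
  }, numeric(2)))
  expect_gte(mean(hits[, "truth"]), 0.8)
})

test_that("fold assignment is deterministic and checked for events", {
  set.seed(42)
  es <- matrix(rnorm(5 * 40), 5, 40,
               dimnames = list(paste0("S", 1:5), paste0("s", 1:40)))
  surv <- data.frame(sample_id = colnames(es),
                     os_time = stats::rexp(40, 0.02), os_event = 1)
  s1 <- lasso_cox_select(es, surv, n_folds = 5, seed = 7)
  s2 <- lasso_cox_select(es, surv, n_folds = 5, seed = 7)
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$lambda, s2$lambda)
  surv0 <- transform(surv, os_event = rep(c(1, 0), c(3, 37)))
  expect_error(lasso_cox_select(es, surv0, n_folds = 10), "n_folds")
})

test_that("Fisher 2x2 equals the closed-form hypergeometric", {
  tab <- matrix(c(10, 0, 0, 10), 2, 2)
  f <- fisher_exact(tab)
  expect_equal(f$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_false(f$monte_carlo)

  tab2 <- matrix(c(5, 5, 5, 5), 2, 2)
  expect_equal(fisher_exact(tab2)$p, 1)
  expect_error(fisher_exact(matrix(c(0, 0, 1, 2), 2, 2)), "empty margin")
})

test_that("2xK enumeration and Monte Carlo agree within simulation error", {
  tab <- matrix(c(8, 2, 4, 6, 3, 7), 2, 3)
  exact <- fisher_exact(tab)
  mc <- fisher_exact(tab, seed = 5, mc_draws = 2e4, mc_threshold = 0)
  expect_false(exact$monte_carlo)
  expect_true(mc$monte_carlo)
  expect_lt(abs(exact$p - mc$p), 0.02)
})

test_that("parallel analysis retains nothing spurious on pure noise", {
  nf <- vapply(1:30, function(s) {
    set.seed(s)
    parallel_factors(matrix(stats::rnorm(2000), 20, 100),
                     n_sim = 30, seed = s + 500)$n_factors
  }, numeric(1))
  expect_gte(mean(nf <= 1), 0.9)
})

test_that("two correlated blocks give two factors with clean loadings", {
  set.seed(9)
  n <- 100
  f1 <- stats::rnorm(n); f2 <- stats::rnorm(n)
  X <- rbind(t(sapply(1:5, function(i) sqrt(0.8) * f1 +
                        sqrt(0.2) * stats::rnorm(n))),
             t(sapply(1:5, function(i) sqrt(0.8) * f2 +
                        sqrt(0.2) * stats::rnorm(n))))
  rownames(X) <- paste0("v", 1:10)
  pf <- parallel_factors(X, n_sim = 50, seed = 1)
  expect_equal(pf$n_factors, 2L)
  block1 <- apply(abs(pf$loadings[1:5, ]), 1, max)
  block2 <- apply(abs(pf$loadings[6:10, ]), 1, max)
  expect_true(all(c(block1, block2) >= 0.6))
})

test_that("varimax rotation preserves communalities", {
  set.seed(10)
  L <- matrix(stats::rnorm(20), 10, 2)
  rot <- stats::varimax(L)$loadings[, ]
  expect_equal(rowSums(L^2), rowSums(rot^2), tolerance = 1e-9)
})

test_that("constant variables are dropped with a warning", {
  set.seed(11)
  X <- rbind(matrix(stats::rnorm(300), 3, 100), flat = rep(1, 100))
  rownames(X)[1:3] <- paste0("v", 1:3)
  expect_warning(pf <- parallel_factors(X, n_sim = 20, seed = 1),
                 "constant")
  expect_true("flat" %in% pf$dropped)
})

test_that("shared BH helper equals the step-up oracle on random vectors", {
  set.seed(99)
  for (rep in 1:1000) {
    p <- stats::runif(sample(3:60, 1))
    expect_equal(bh_adjust(p), bh_stepup_oracle(p), tolerance = 1e-12)
  }
})
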