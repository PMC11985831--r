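toy_expr <- function(g = 20, n = 10, seed = 1) {
  set.seed(seed)
  matrix(rnorm(g * n, 7, 2), g, n,
         dimnames = list(paste0("g", seq_len(g)), paste0("s", seq_len(n))))
}

test_that("top-ranked sets score positive and bottom-ranked negative", {
  expr <- toy_expr()
  s1 <- colnames(expr)[1]
  ord <- order(expr[, s1], decreasing = TRUE)
  sets <- list(top = rownames(expr)[ord[1:5]],
               bottom = rownames(expr)[ord[16:20]])
  es <- es_score(expr, sets, alpha = 0.25, min_overlap = 2)
  expect_gt(es["top", s1], 0)
  expect_lt(es["bottom", s1], 0)
})

test_that("the running sum matches the brute-force walk oracle", {
  # 5-gene universe, 2-gene set, alpha = 0: hand-walk every step
  expr <- matrix(c(3, 9, 1, 7, 5), 5, 1,
                 dimnames = list(paste0("g", 1:5), "s1"))
  sets <- list(S = c("g2", "g4"))
  es <- es_score(expr, sets, alpha = 0, min_overlap = 2)
  # ranking: g2(9) g4(7) g5(5) g1(3) g3(1); set occupies the top 2 ranks
  # deviations: 1/2-0, 1-0, 1-1/3, 1-2/3, 0 -> sum = 5/2 - 1 = 1.5... walk:
  expect_equal(unname(es["S", "s1"]),
               es_walk_oracle(expr[, 1], c(2, 4), alpha = 0))

  set.seed(9)
  for (rep in 1:8) {
    vals <- sample(100, 7)
    names(vals) <- paste0("g", 1:7)
    idx <- sample(7, 3)
    expr_r <- matrix(vals, 7, 1, dimnames = list(names(vals), "s"))
    for (a in c(0, 0.25, 1)) {
      es_r <- es_score(expr_r, list(S = names(vals)[idx]),
                       alpha = a, min_overlap = 2)
      expect_equal(unname(es_r["S", "s"]),
                   es_walk_oracle(vals, idx, alpha = a),
                   tolerance = 1e-12)
    }
  }
})

test_that("duplicate sets score identically and small sets are dropped", {
  expr <- toy_expr()
  sets <- list(A = rownames(expr)[1:6], B = rownames(expr)[1:6],
               tiny = rownames(expr)[1:2])
  es <- es_score(expr, sets, min_overlap = 5)
  expect_equal(es["A", ], es["B", ])
  expect_identical(attr(es, "dropped"), "tiny")
  expect_error(es_score(expr, list(tiny = rownames(expr)[1:2]),
                        min_overlap = 5), "min_overlap")
})

test_that("alpha = 0 scores depend only on within-sample ranks", {
  expr <- toy_expr()
  sets <- list(A = rownames(expr)[3:9])
  es1 <- es_score(expr, sets, alpha = 0)
  es2 <- es_score(2^(expr / 3), sets, alpha = 0)
  expect_equal(es1[, ], es2[, ], tolerance = 1e-12)
})

test_that("moderated t reduces to the pooled t when shrinkage is off", {
  set.seed(3)
  es <- matrix(rnorm(50 * 12), 50, 12,
               dimnames = list(paste0("S", 1:50), paste0("s", 1:12)))
  grp <- stats::setNames(rep(c("C1", "C2"), each = 6), colnames(es))
  d <- moderated_t_diff(es, grp, prior_df = 0)
  for (i in c(1, 25, 50)) {
    tt <- stats::t.test(es[i, 7:12], es[i, 1:6], var.equal = TRUE)
    expect_equal(d$t[i], unname(tt$statistic), tolerance = 1e-9)
    expect_equal(d$p[i], tt$p.value, tolerance = 1e-9)
  }
})

test_that("moderated t tracks limma's on shared data", {
  skip_if_not_installed("limma")
  set.seed(4)
  es <- matrix(rnorm(200 * 16), 200, 16,
               dimnames = list(paste0("S", 1:200), paste0("s", 1:16)))
  es[1:20, 9:16] <- es[1:20, 9:16] + 1
  grp <- stats::setNames(rep(c("C1", "C2"), each = 8), colnames(es))
  d <- moderated_t_diff(es, grp)
  design <- cbind(1, as.numeric(grp == "C2"))
  fit <- limma::eBayes(limma::lmFit(es, design))
  expect_gt(stats::cor(d$t, fit$t[, 2]), 0.98)
})

test_that("null enrichment keeps the moderated-t FDR near nominal", {
  fracs <- vapply(1:20, function(s) {
    set.seed(s)
    es <- matrix(rnorm(500 * 20), 500, 20,
                 dimnames = list(paste0("S", 1:500), paste0("s", 1:20)))
    grp <- stats::setNames(rep(c("C1", "C2"), each = 10), colnames(es))
    mean(moderated_t_diff(es, grp)$q < 0.05)
  }, numeric(1))
  expect_lte(mean(fracs), 0.05)
})

test_that("BH q-values equal the textbook step-up on small tables", {
  es <- matrix(c(0.5, 0.6, 0.4, 0.45, 5, 5.5, 0.2, 0.25, 0.9, 0.8, 0.7,
                 0.75), 3, 4, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), paste0("s", 1:4)))
  grp <- stats::setNames(c("C1", "C1", "C2", "C2"), colnames(es))
  d <- moderated_t_diff(es, grp, prior_df = 0)
  expect_equal(d$q, bh_stepup_oracle(d$p), tolerance = 1e-12)
})

test_that("intersection is idempotent, respects direction, and finds truth", {
  set.seed(6)
  dA <- data.frame(set = paste0("S", 1:20),
                   q = runif(20), direction = sample(c("up_C1", "up_C2"),
                                                     20, replace = TRUE))
  expect_identical(enriched_intersection(dA, dA, "up_C2", 0.5),
                   dA$set[dA$q < 0.5 & dA$direction == "up_C2"])
  dB <- dA
  dB$q <- ifelse(dA$q < 0.5 & dA$direction == "up_C2", 0.9, dB$q)
  expect_length(enriched_intersection(dA, dB, "up_C2", 0.5), 0L)
})

test_that("two independent cohorts recover the enriched truth", {
  sig <- subtype_signature()
  enrich <- sig$up_c2
  run_cohort <- function(seed) {
    co <- default_cohort(seed = seed, n_background = 100)
    gs <- generate_gene_sets(rownames(co$expr), n_sets = 40,
                             n_enriched = 8, enrich_genes = enrich,
                             seed = 99)  # same collection both cohorts
    list(diff = moderated_t_diff(es_score(co$expr, gs$sets), co$truth),
         truth = gs$truth)
  }
  a <- run_cohort(201); b <- run_cohort(202)
  inter <- enriched_intersection(a$diff, b$diff, "up_C2", 0.05)
  recall <- mean(a$truth %in% inter)
  expect_gte(recall, 0.8)
})

test_that("hypergeometric ORA matches the exact tail sum", {
  universe <- paste0("g", 1:100)
  term <- universe[1:20]
  query <- c(universe[1:3], universe[51:57])  # overlap 3, query 10
  res <- ora_hypergeometric(query, list(T1 = term), universe)
  expect_equal(res$p, sum(stats::dhyper(3:10, 20, 80, 10)),
               tolerance = 1e-12)
  expect_equal(res$overlap, 3L)

  # a term made of the query itself is the most significant
  ann <- list(self = query, other = universe[30:49])
  res2 <- ora_hypergeometric(query, ann, universe)
  expect_equal(res2$term[which.min(res2$p)], "self")

  expect_warning(
    res3 <- ora_hypergeometric(query, list(x = "absent", self = query),
                               universe),
    "zero universe overlap")
  expect_identical(res3$term, "self")
  expect_error(ora_hypergeometric(character(), ann, universe), "empty query")
})
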