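# Independent brute-force oracles used to freeze expected values. These
# deliberately share no code with the package implementations they check.

# Textbook BH step-up: sort p, q_(i) = min_{j >= i} p_(j) * m / j.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(cummin(rev(p[ord] * m / seq_len(m))), 1)
  q <- numeric(m)
  q[ord] <- rev(q_sorted)
  q
}

# Exhaustive silhouette: means computed with explicit loops.
silhouette_oracle <- function(labels, d) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- sum(d[i, own]) / length(own)
    bs <- sapply(setdiff(unique(labels), labels[i]), function(g) {
      idx <- which(labels == g)
      sum(d[i, idx]) / length(idx)
    })
    b <- min(bs)
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

# Exact two-sided Mann-Whitney p by looping over all group assignments:
# the probability of a U at least as far from its null center as the
# observed one (midranks handle ties).
mw_exact_oracle <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x)
  n <- length(vals)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  center <- n1 * length(y) / 2
  hits <- 0; total <- 0
  for (idx in utils::combn(n, n1, simplify = FALSE)) {
    u <- sum(r[idx]) - n1 * (n1 + 1) / 2
    hits <- hits + (abs(u - center) >= abs(u_obs - center) - 1e-9)
    total <- total + 1
  }
  hits / total
}

# Two-group log-rank chi-square from explicit risk-set sums.
logrank_oracle <- function(time, event, group) {
  g1 <- unique(group)[1]
  o <- 0; e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}

# ssGSEA-form running sum walked step by step (alpha-weighted in-set
# increments, uniform out-of-set increments, summed deviation / (N - m)).
es_walk_oracle <- function(values, set_idx, alpha = 0) {
  N <- length(values)
  ord <- order(values, decreasing = TRUE)
  inset <- ord %in% set_idx
  rstat <- N - seq_len(N) + 1
  w_in <- ifelse(inset, rstat^alpha, 0)
  w_in <- w_in / sum(w_in)
  w_out <- ifelse(inset, 0, 1 / (N - length(set_idx)))
  run <- 0; dev_sum <- 0
  for (i in seq_len(N)) {
    run <- run + w_in[i] - w_out[i]
    dev_sum <- dev_sum + run
  }
  dev_sum / (N - length(set_idx))
}

# AUC by exhaustive pairwise comparison (ties count 1/2).
auc_pairwise_oracle <- function(scores, labels, positive) {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  total <- 0
  for (i in pos) for (j in neg) {
    total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  total / (length(pos) * length(neg))
}

# Small default cohort reused across tests.
default_cohort <- function(seed = 1, ...) {
  generate_cohort(cohort_params(...), seed = seed)
}
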