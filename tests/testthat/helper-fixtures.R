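# Shared fixtures and independent oracles used across the suite.

# A deterministic 34-region profile around 2.5 mm.
make_profile <- function(seed = 1, mean = 2.5, sd = 0.25) {
  set.seed(seed)
  stats::setNames(pmax(rnorm(34, mean, sd), 1), cortasym::dk_regions)
}

# Independent brute-force Jensen-Shannon distance oracle: plain loops over
# the entropy definition, no shared code with the implementation.
oracle_jsd <- function(p, q) {
  ent <- function(v) {
    s <- 0
    for (vi in v) if (vi > 0) s <- s - vi * log(vi, base = 2)
    s
  }
  m <- (p + q) / 2
  d2 <- ent(m) - (ent(p) + ent(q)) / 2
  sqrt(max(d2, 0))
}

# Hand step-up BH oracle.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# Brute-force AUC: concordant-pair counting with half-credit ties.
oracle_auc <- function(score, pos) {
  s_pos <- score[pos]
  s_neg <- score[!pos]
  tot <- 0
  for (a in s_pos) for (b in s_neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(s_pos) * length(s_neg))
}

# Textbook one-way ANOVA F from explicit sums of squares.
oracle_anova_f <- function(y, g) {
  g <- as.factor(g)
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(g) - 1
  df2 <- length(y) - nlevels(g)
  (ssb / df1) / (ssw / df2)
}

# Two-sided Fisher p for a 2x2 table by hypergeometric enumeration.
oracle_fisher_2x2 <- function(tab) {
  rs <- rowSums(tab)
  cs <- colSums(tab)
  n <- sum(tab)
  prob_a <- function(a) {
    choose(rs[1], a) * choose(rs[2], cs[1] - a) / choose(n, cs[1])
  }
  amin <- max(0, cs[1] - rs[2])
  amax <- min(rs[1], cs[1])
  probs <- sapply(amin:amax, prob_a)
  p_obs <- prob_a(tab[1, 1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Spearman rho by explicit average-rank-then-Pearson computation.
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Small cohort config for fast unit tests.
small_synth <- function(seed = 1, ...) {
  synthetic_config(
    "dian_like",
    n_per_group = c(CTR = 15L, AMC = 15L, SMC_MCI = 8L, SMC_AD = 7L),
    n_visits = 3L,
    seed = seed,
    ...
  )
}
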