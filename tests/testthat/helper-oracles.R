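# Independent oracles: every statistic the package computes is re-derived
# here by direct term-by-term evaluation (explicit loops, textbook
# formulas, or exhaustive enumeration), sharing no code with the package
# internals.

# Weir-Cockerham theta-hat, summing each defining term explicitly.
# p: observed frequencies; n: sample sizes in alleles.
oracle_fst <- function(p, n) {
  p <- unname(p); n <- unname(n)
  s <- length(p)
  ntot <- 0; for (i in 1:s) ntot <- ntot + n[i]
  pbar <- 0; for (i in 1:s) pbar <- pbar + n[i] * p[i] / ntot
  msp <- 0; for (i in 1:s) msp <- msp + n[i] * (p[i] - pbar)^2
  msp <- msp / (s - 1)
  den <- 0; for (i in 1:s) den <- den + (n[i] - 1)
  msg <- 0; for (i in 1:s) msg <- msg + n[i] * p[i] * (1 - p[i])
  msg <- msg / den
  sq <- 0; for (i in 1:s) sq <- sq + n[i]^2
  nc <- (ntot - sq / ntot) / (s - 1)
  list(msp = msp, msg = msg, nc = nc, pbar = pbar,
       theta = (msp - msg) / (msp + (nc - 1) * msg))
}

# Pearson X^2 with hand-summed (O - E)^2 / E over row/column-margin
# expecteds.  tab: matrix of counts.
oracle_chisq <- function(tab) {
  total <- sum(tab)
  x2 <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / total
    x2 <- x2 + (tab[i, j] - e)^2 / e
  }
  x2
}

# Textbook one-way ANOVA from a list of per-group value vectors.
oracle_anova <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- 0; ssw <- 0
  for (g in groups) {
    ssb <- ssb + length(g) * (mean(g) - grand)^2
    for (v in g) ssw <- ssw + (v - mean(g))^2
  }
  df1 <- length(groups) - 1
  df2 <- length(all_v) - length(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Step-by-step NSCM: panel is a list of SNPs, each a list of per-population
# individual frequency vectors (dosage / 2).
oracle_nscm <- function(panel) {
  sk <- vapply(panel, function(snp) {
    ssw <- 0; n <- 0
    for (g in snp) { ssw <- ssw + sum((g - mean(g))^2); n <- n + length(g) }
    sqrt(ssw / (n - length(snp)))
  }, numeric(1))
  s0 <- stats::median(sk)
  lapply(seq_along(panel), function(k) {
    snp <- panel[[k]]
    n <- sum(lengths(snp))
    ak <- mean(unlist(snp))
    d <- vapply(seq_along(snp), function(i) {
      mi <- sqrt(1 / length(snp[[i]]) + 1 / n)
      (mean(snp[[i]]) - ak) / (mi * (s0 + sk[k]))
    }, numeric(1))
    list(ss_d = sum(d^2), s0 = s0, sk = sk[k], d = d)
  })
}

# Exact hypergeometric upper tail P(X >= k) by enumerating every one of the
# choose(N, n) draws of n genes from a universe with K successes (N <= 12).
oracle_hypergeom <- function(N, K, n, k) {
  universe <- c(rep(1, K), rep(0, N - K))
  draws <- utils::combn(N, n)
  hits <- 0
  for (j in seq_len(ncol(draws)))
    if (sum(universe[draws[, j]]) >= k) hits <- hits + 1
  hits / ncol(draws)
}

# Classic BH step-up by explicit loop.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    q_sorted[i] <- running
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Counter-based seed stream for multi-fixture runs (kept below 2^31).
.derive_seed_acc <- function(seed, i)
  as.integer((as.double(seed) + 7919 * i) %% 2147483629)

# Random genotype-count dataset with s populations.
rand_snp_dataset <- function(s = 3L, n_range = c(20L, 120L),
                             snp_id = "rand") {
  counts <- t(vapply(seq_len(s), function(i) {
    n <- sample(seq(n_range[1], n_range[2]), 1L)
    p <- stats::runif(1, 0.05, 0.95)
    drop(stats::rmultinom(1, n, c(p^2, 2 * p * (1 - p), (1 - p)^2)))
  }, numeric(3)))
  snp_dataset(snp_id, counts)
}

# Per-individual frequency values (dosage / 2) of one population's counts.
dosage_freqs <- function(counts)
  rep(c(1, 0.5, 0), times = counts)
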