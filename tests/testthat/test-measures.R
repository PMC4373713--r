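test_that("fst_weir honours its fixed points", {
  # complete fixation between two populations forces theta = 1
  fix <- snp_dataset("fix", rbind(c(0, 0, 50), c(50, 0, 0)))
  expect_equal(fst_weir(fix)$theta_hat, 1)

  # identical frequencies with equal n: MSP = 0, theta = -1/(n_c - 1),
  # with n_c = 100 alleles here
  eq <- snp_dataset("eq", rbind(c(0, 50, 0), c(0, 50, 0), c(0, 50, 0)))
  f <- fst_weir(eq)
  expect_equal(f$n_c, 100)
  expect_equal(f$msp, 0)
  expect_equal(f$theta_hat, -1 / 99)

  # monomorphic in every population: 0/0, no information
  mono <- snp_dataset("mono", rbind(c(0, 0, 50), c(0, 0, 50)))
  expect_true(is.nan(fst_weir(mono)$theta_hat))
})

test_that("fst_weir reproduces the term-by-term evaluation oracle", {
  # the equally-spaced configuration p = (0.1, 0.2, 0.3), 200 alleles/pop
  o <- oracle_fst(c(0.1, 0.2, 0.3), c(200, 200, 200))
  counts <- rbind(c(0, 20, 80), c(0, 40, 60), c(0, 60, 40))  # p = .1,.2,.3
  f <- fst_weir(snp_dataset("t2", counts))
  expect_equal(f$theta_hat, o$theta, tolerance = 1e-12)
  expect_equal(f$msp, o$msp, tolerance = 1e-12)
  expect_equal(f$msg, o$msg, tolerance = 1e-12)
  expect_equal(f$n_c, o$nc, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:25) {
    d <- rand_snp_dataset(sample(2:5, 1))
    f <- fst_weir(d)
    o <- oracle_fst(allele_frequency(d), 2 * d$n_individuals)
    expect_equal(f$theta_hat, o$theta, tolerance = 1e-9)
  }
})

test_that("fst_weir is invariant to allele relabeling and collapses n_c", {
  set.seed(12)
  for (i in 1:20) {
    d <- rand_snp_dataset(3)
    flipped <- snp_dataset(d$snp_id, d$counts[, 3:1])  # swap AA <-> aa
    expect_equal(fst_weir(d)$theta_hat, fst_weir(flipped)$theta_hat,
                 tolerance = 1e-12)
  }
  # equal sample sizes: n_c equals the common per-population allele count
  d <- snp_dataset("bal", rbind(c(10, 20, 30), c(5, 30, 25), c(20, 20, 20)))
  expect_equal(fst_weir(d)$n_c, 120)
})

test_that("for two large equal populations theta converges to the classical form", {
  # n -> infinity limit of the estimator for fixed (p1, p2):
  # (p1 - p2)^2 / (p1 + p2 - 2 p1 p2), the classical two-population Fst
  n <- 1e4  # individuals per population
  for (p in list(c(0.2, 0.4), c(0.1, 0.7), c(0.45, 0.55))) {
    counts <- t(vapply(p, function(pi) {
      nAA <- round(n * pi^2); nAa <- round(2 * n * pi) - 2 * nAA
      c(nAA, nAa, n - nAA - nAa)
    }, numeric(3)))
    th <- fst_weir(snp_dataset("lim", counts))$theta_hat
    classical <- (p[1] - p[2])^2 / (p[1] + p[2] - 2 * p[1] * p[2])
    expect_lt(abs(th - classical), 2 / n)
  }
})

test_that("fst_weir rejects degenerate inputs", {
  expect_error(snp_dataset("one", rbind(c(1, 2, 3))), "at least 2")
  zero <- snp_dataset("z", rbind(c(0, 0, 0), c(10, 10, 10)))
  expect_error(fst_weir(zero), "no sampled individuals")
})

test_that("chisq_homogeneity is zero on homogeneous tables and matches oracles", {
  # identical frequencies (possibly different n) carry no signal
  hom <- snp_dataset("hom", rbind(c(5, 15, 30), c(10, 30, 60)))
  r <- chisq_homogeneity(hom)
  expect_equal(r$value, 0)
  expect_equal(r$p_value, 1)

  # hand-summable 2x3 allele table [[30,70],[50,50],[70,30]]:
  # genotype counts chosen to give allele counts 30/100, 50/100, 70/100
  d <- snp_dataset("tbl", rbind(c(10, 10, 30), c(15, 20, 15), c(30, 10, 10)))
  expect_equal(unname(2 * d$counts[, 1] + d$counts[, 2]), c(30, 50, 70))
  r <- chisq_homogeneity(d)
  tab <- cbind(c(30, 50, 70), c(70, 50, 30))
  expect_equal(r$value, oracle_chisq(tab), tolerance = 1e-12)
  expect_equal(r$df, 2)

  # independent generic implementation on random tables
  set.seed(13)
  for (i in 1:25) {
    d <- rand_snp_dataset(sample(2:4, 1))
    r <- chisq_homogeneity(d)
    x <- 2 * d$counts[, 1] + d$counts[, 2]
    tab <- cbind(x, 2 * d$n_individuals - x)
    if (all(colSums(tab) > 0)) {
      ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      expect_equal(r$value, unname(ref$statistic), tolerance = 1e-9)
      expect_equal(r$p_value, ref$p.value, tolerance = 1e-9)
    }
  }
})

test_that("chisq_homogeneity handles a globally absent allele and genotype tables", {
  mono <- snp_dataset("mono", rbind(c(0, 0, 40), c(0, 0, 60)))
  r <- chisq_homogeneity(mono)
  expect_equal(r$value, 0)
  expect_equal(r$p_value, 1)

  d <- snp_dataset("g", rbind(c(10, 20, 10), c(5, 10, 25)))
  rg <- chisq_homogeneity(d, table = "genotype")
  ref <- suppressWarnings(stats::chisq.test(t(d$counts), correct = FALSE))
  expect_equal(rg$value, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(rg$df, 2)
})

test_that("anova_f matches the sums-of-squares oracle and its fixed points", {
  # equal genotype composition in every population: zero between-group SS
  same <- snp_dataset("same", rbind(c(25, 50, 25), c(25, 50, 25), c(25, 50, 25)))
  a <- anova_f(same)
  expect_equal(a$f_stat, 0)
  expect_equal(a$p_value, 1)

  # two internally constant, different populations: infinite F
  degen <- snp_dataset("deg", rbind(c(10, 0, 0), c(0, 0, 10)))
  a <- anova_f(degen)
  expect_identical(a$f_stat, Inf)
  expect_equal(a$p_value, 0)

  # dosages pop1: 0,1,2,1; pop2: 2,2,1,1; pop3: 0,0,1,1
  toy <- snp_dataset("toy", rbind(c(1, 2, 1), c(2, 2, 0), c(0, 2, 2)))
  a <- anova_f(toy)
  o <- oracle_anova(list(c(2, 1, 1, 0), c(2, 2, 1, 1), c(1, 1, 0, 0)))
  expect_equal(a$f_stat, o$f, tolerance = 1e-12)
  expect_equal(a$p_value, o$p, tolerance = 1e-12)

  # the weighted effect-sum constraint
  set.seed(14)
  for (i in 1:10) {
    d <- rand_snp_dataset(3)
    a <- anova_f(d)
    expect_equal(sum(d$n_individuals * a$group_effects), 0, tolerance = 1e-9)
  }
})

test_that("anova_f equals lm's one-way ANOVA and the two-group t^2 identity", {
  set.seed(15)
  for (i in 1:10) {
    d <- rand_snp_dataset(3)
    dos <- unlist(lapply(seq_len(3), function(j)
      rep(c(2, 1, 0), times = d$counts[j, ])))
    grp <- factor(rep(seq_len(3), d$n_individuals))
    ref <- stats::anova(stats::lm(dos ~ grp))
    a <- anova_f(d)
    expect_equal(a$f_stat, ref[["F value"]][1], tolerance = 1e-9)
    expect_equal(a$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-9)
  }
  for (i in 1:10) {
    d <- rand_snp_dataset(2)
    dos <- lapply(1:2, function(j) rep(c(2, 1, 0), times = d$counts[j, ]))
    tt <- stats::t.test(dos[[1]], dos[[2]], var.equal = TRUE)
    expect_equal(anova_f(d)$f_stat, unname(tt$statistic)^2, tolerance = 1e-9)
  }
})

test_that("anova_f requires more individuals than groups", {
  tiny <- snp_dataset("tiny", rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_error(anova_f(tiny), "n > s")
})

test_that("nscm_ssd follows the step-by-step oracle on a toy panel", {
  set.seed(16)
  panel <- list(
    snp_dataset("k1", rbind(c(3, 4, 3), c(1, 2, 7), c(5, 3, 2))),
    snp_dataset("k2", rbind(c(0, 5, 5), c(2, 6, 2), c(4, 4, 2)))
  )
  res <- nscm_ssd(panel)
  oracle_panel <- lapply(panel, function(d)
    lapply(seq_len(nrow(d$counts)), function(i) dosage_freqs(d$counts[i, ])))
  o <- oracle_nscm(oracle_panel)
  for (k in 1:2) {
    expect_equal(res[[k]]$ss_d, o[[k]]$ss_d, tolerance = 1e-12)
    expect_equal(res[[k]]$s0, o[[k]]$s0, tolerance = 1e-12)
    expect_equal(res[[k]]$pooled_sd, o[[k]]$sk, tolerance = 1e-12)
  }
})

test_that("nscm_ssd fixed points: zero distances, median s0, order invariance", {
  # identical composition in all populations: every a_ik equals a_k
  flat <- snp_dataset("flat", rbind(c(2, 6, 2), c(2, 6, 2), c(2, 6, 2)))
  set.seed(17)
  other <- replicate(2, rand_snp_dataset(3), simplify = FALSE)
  res <- nscm_ssd(c(list(flat), other))
  expect_equal(res[[1]]$ss_d, 0)

  # s0 is the middle s_k of a 3-SNP panel
  sk <- vapply(res, `[[`, numeric(1), "pooled_sd")
  expect_equal(attr(res, "s0"), sort(sk)[2])

  # SNP order does not change SS_d (s0 depends only on the multiset of s_k)
  perm <- nscm_ssd(c(other, list(flat)))
  expect_equal(perm[[3]]$ss_d, res[[1]]$ss_d)
  expect_equal(attr(perm, "s0"), attr(res, "s0"))
})

test_that("nscm_ssd validates its panel", {
  expect_error(nscm_ssd(list()), "empty")
  set.seed(18)
  one <- rand_snp_dataset(3)
  expect_warning(nscm_ssd(list(one)), "size 1")
  bad <- snp_dataset("bad", rbind(pA = c(1, 2, 3), pB = c(3, 2, 1)))
  expect_error(nscm_ssd(list(one, bad)), "population structure")
})

test_that("allele_frequency follows the counting identity", {
  expect_equal(allele_frequency(c(25, 50, 25)), 0.5)
  expect_equal(allele_frequency(c(100, 0, 0)), 1)
  expect_equal(allele_frequency(c(10, 20, 70)), 0.2)
  expect_error(allele_frequency(c(0, 0, 0)), "0 individuals")
})
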