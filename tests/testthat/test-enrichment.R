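toy_sets <- function() list(
  gene_set("T1", "first", "BP", c("g1", "g2", "g3", "g4", "g5")),
  gene_set("T2", "second", "MF", c("g4", "g5", "g6", "g7")),
  gene_set("T3", "third", "PATHWAY", c("g8", "g9"))
)

test_that("drawing the whole background gives fold 1 and p 1 everywhere", {
  bg <- paste0("g", 1:10)
  res <- hypergeom_enrich(bg, bg, toy_sets())
  expect_equal(res$fold_enrichment, rep(1, 3))
  expect_equal(res$p_value, rep(1, 3))
  expect_equal(res$k / res$n, res$K / res$N)
})

test_that("hypergeometric p and fold follow the enumeration oracle", {
  # N = 20, K = 5, n = 10, k = 4
  bg <- paste0("g", 1:20)
  sets <- list(gene_set("T", "term", "BP", paste0("g", 1:5)),
               gene_set("ALL", "universe", "BP", bg))  # keeps N = 20
  input <- paste0("g", c(1:4, 10:15))                  # k = 4 of the term
  res <- hypergeom_enrich(input, bg, sets)
  row <- res[res$term_id == "T", ]
  expect_equal(row$fold_enrichment, (4 / 10) / (5 / 20))
  exact <- sum(choose(5, 4:5) * choose(15, 10 - (4:5))) / choose(20, 10)
  expect_equal(row$p_value, exact, tolerance = 1e-12)

  # small random instances against exhaustive enumeration
  set.seed(61)
  for (i in 1:20) {
    N <- sample(6:12, 1)
    K <- sample(2:(N - 1), 1)
    n <- sample(2:(N - 1), 1)
    bg <- paste0("x", seq_len(N))
    sets <- list(gene_set("T", "t", "CC", bg[seq_len(K)]),
                 gene_set("U", "u", "CC", bg))
    input <- sample(bg, n)
    row <- hypergeom_enrich(input, bg, sets)
    row <- row[row$term_id == "T", ]
    expect_equal(row$p_value,
                 oracle_hypergeom(N, K, n, row$k), tolerance = 1e-9)
  }
})

test_that("terms missed by the input are reported with fold 0 and p 1", {
  bg <- paste0("g", 1:10)
  res <- hypergeom_enrich(c("g1", "g2"), bg, toy_sets())
  miss <- res[res$term_id == "T3", ]
  expect_equal(miss$k, 0)
  expect_equal(miss$fold_enrichment, 0)
  expect_equal(miss$p_value, 1)
})

test_that("boundary case k = K matches the oracle", {
  bg <- paste0("g", 1:12)
  sets <- list(gene_set("T", "t", "BP", c("g1", "g2", "g3")),
               gene_set("U", "u", "BP", bg))
  input <- c("g1", "g2", "g3", "g4", "g5")
  row <- hypergeom_enrich(input, bg, sets)
  row <- row[row$term_id == "T", ]
  expect_equal(row$k, 3)
  expect_equal(row$p_value, oracle_hypergeom(12, 3, 5, 3), tolerance = 1e-12)
})

test_that("untestable and unannotated genes are filtered as documented", {
  bg <- paste0("g", 1:10)
  sets <- c(toy_sets(), list(gene_set("tiny", "singleton", "BP", "g10")))
  expect_message(res <- hypergeom_enrich(c("g1", "g4"), bg, sets), "dropped")
  expect_false("tiny" %in% res$term_id)
  # genes without any annotation do not count towards n or N
  expect_equal(unique(res$N), 9)  # g10's only term was dropped
  expect_error(hypergeom_enrich("g1", character(), toy_sets()), "background")
  expect_warning(hypergeom_enrich(c("g1", "zzz"), bg, toy_sets()),
                 "outside the background")
})

test_that("bh_adjust reproduces the classic step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(62)
  for (i in 1:30) {
    p <- stats::runif(sample(3:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    # q-values are non-decreasing in sorted-p order and bounded by 1
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    expect_true(all(q >= 0 & q <= 1))
    # the q <= alpha set equals the classic step-up rejection set
    alpha <- 0.1
    m <- length(p)
    ps <- sort(p)
    cutoff <- max(c(0, which(ps <= alpha * seq_len(m) / m)))
    rejected <- p <= (if (cutoff == 0) -1 else ps[cutoff])
    expect_equal(q <= alpha, rejected)
  }
})

test_that("fold enrichment exceeds 1 exactly when the input rate does", {
  set.seed(63)
  bg <- paste0("g", 1:30)
  sets <- list(gene_set("T", "t", "BP", bg[1:8]),
               gene_set("U", "u", "BP", bg))
  for (i in 1:20) {
    input <- sample(bg, sample(5:20, 1))
    row <- hypergeom_enrich(input, bg, sets)
    row <- row[row$term_id == "T", ]
    expect_equal(row$fold_enrichment > 1, row$k / row$n > row$K / row$N)
  }
})

test_that("enriching a list against itself finds nothing significant", {
  set.seed(64)
  for (i in 1:5) {
    bg <- paste0("g", 1:25)
    sets <- lapply(1:6, function(t)
      gene_set(paste0("T", t), "t", "BP", sample(bg, 8)))
    res <- hypergeom_enrich(bg, bg, sets)
    expect_equal(sum(res$significant), 0)
  }
})

test_that("compare_backgrounds joins the three runs per term", {
  bg_all <- paste0("g", 1:20)
  bg_dr <- paste0("g", 1:10)
  sets <- list(gene_set("T", "t", "BP", paste0("g", c(1:4, 11:14))),
               gene_set("U", "u", "BP", bg_all))
  # input identical to the intermediate background: the input-vs-dr columns
  # must be exactly null
  res <- compare_backgrounds(bg_dr, bg_dr, bg_all, sets)
  expect_equal(res$fold_input_vs_dr, rep(1, 2))
  expect_equal(res$fold_input_vs_all, res$fold_dr_vs_all)
  expect_error(compare_backgrounds(c("g1", "g99"), bg_dr, bg_all, sets),
               "subset")
  expect_error(compare_backgrounds("g1", c(bg_dr, "g99"), bg_all, sets),
               "subset")
})

test_that("a term enriched in the intermediate background but not beyond it", {
  # the term's rate inside bg_dr is elevated over bg_all, while the input
  # matches bg_dr's rate: significant vs. all, null vs. dr
  bg_all <- paste0("g", 1:40)
  bg_dr <- paste0("g", 1:20)
  term <- paste0("g", 1:10)          # 50% of dr, 25% of all
  sets <- list(gene_set("T", "t", "BP", term),
               gene_set("U", "u", "BP", bg_all))
  input <- paste0("g", c(1:5, 11:15))  # 50% in term, like bg_dr
  res <- compare_backgrounds(input, bg_dr, bg_all, sets)
  row <- res[res$term_id == "T", ]
  expect_gt(row$fold_input_vs_all, 1)
  expect_gt(row$fold_dr_vs_all, 1)
  expect_equal(row$fold_input_vs_dr, 1)
  expect_equal(row$q_input_vs_dr, 1)
})

test_that("the EASE variant is more conservative than the plain tail", {
  bg <- paste0("g", 1:20)
  sets <- list(gene_set("T", "t", "BP", bg[1:5]),
               gene_set("U", "u", "BP", bg))
  input <- bg[1:8]
  plain <- hypergeom_enrich(input, bg, sets)
  ease <- hypergeom_enrich(input, bg, sets, ease = TRUE)
  expect_gte(ease$p_value[ease$term_id == "T"],
             plain$p_value[plain$term_id == "T"])
})
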