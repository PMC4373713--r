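## Synthetic annotation fixtures ----------------------------------------------
##
## Emulates the real-data inputs of the classification + enrichment stages:
## a per-SNP per-population allele-frequency table, a SNP-to-gene map, and
## GMT-style gene sets, with known planted truth.  Differentiation is
## controlled generatively through the frequency spacing d (large d for
## high-differentiation genes, d = 0 for low), not by inverting the Fst
## formula.

#' Generate a synthetic frequency / gene-map / gene-set fixture
#'
#' Genes are split into a high-differentiation (HD) fraction and a
#' low-differentiation (LD) remainder.  Each SNP of an HD gene draws its
#' three population frequencies with spacing `d_hd` (and `p1` uniform on
#' `[0, min(0.05, 1 - 2 d_hd)]`, keeping the locus strongly differentiated);
#' LD SNPs use `d = 0` with `p1` uniform on `[0.1, 0.5]` (common variants,
#' so the locus is informative but undifferentiated).  Genotypes are then
#' sampled under Hardy-Weinberg equilibrium at `n_alleles / 2` individuals
#' per population and summarized as observed frequencies.
#'
#' Gene sets are built so that each planted term achieves a prescribed fold
#' enrichment when the recovered HD genes are tested against all annotated
#' genes: the planted term contains `hd_in_planted` HD genes out of
#' `term_size`, and the number of annotated HD genes is set to
#' `hd_in_planted * n_annotated / (planted_fold * term_size)` so that
#' `(k/n) / (K/N) = planted_fold` under perfect label recovery.  Remaining
#' terms are drawn from the annotated pool without planted-term HD genes.
#'
#' @param n_genes number of genes.
#' @param n_snps number of SNPs (assigned to genes round-robin; default one
#'   per gene).
#' @param frac_hd fraction of genes planted as HD.
#' @param n_terms number of gene sets.
#' @param planted_terms how many terms are planted as enriched.
#' @param term_size genes per term.
#' @param planted_fold target fold enrichment of each planted term.
#' @param hd_in_planted HD genes inside each planted term.
#' @param n_annotated size of the annotated gene universe.
#' @param n_alleles alleles sampled per population per SNP.
#' @param d_hd frequency spacing of HD SNPs.
#' @param seed integer seed (same seed, identical fixture).
#' @return Object of class `annotation_fixture`: list with
#'   `frequency_table`, `snp_gene_map`, `gene_sets` and `planted_truth`
#'   (generating labels per gene and SNP, planted term ids, and the
#'   expected contingency numbers under perfect recovery).
#' @export
make_annotation_fixture <- function(n_genes = 400L, n_snps = n_genes,
                                    frac_hd = 0.25, n_terms = 50L,
                                    planted_terms = 1L, term_size = 20L,
                                    planted_fold = 5, hd_in_planted = 15L,
                                    n_annotated = 200L, n_alleles = 1000L,
                                    d_hd = 0.45, seed = 1L) {
  if (frac_hd < 0 || frac_hd > 1) stop("'frac_hd' must lie in [0, 1]",
                                       call. = FALSE)
  if (planted_terms > n_terms)
    stop("'planted_terms' cannot exceed 'n_terms'", call. = FALSE)
  set.seed(seed)

  genes <- sprintf("G%04d", seq_len(n_genes))
  n_hd <- round(frac_hd * n_genes)
  hd_genes <- sort(sample(genes, n_hd))
  gene_label <- ifelse(genes %in% hd_genes, "HD", "LD")

  ## SNPs and map
  snps <- sprintf("s%05d", seq_len(n_snps))
  snp_gene <- genes[(seq_len(n_snps) - 1L) %% n_genes + 1L]
  snp_label <- ifelse(snp_gene %in% hd_genes, "HD", "LD")
  map <- data.frame(snp_id = snps, gene_id = snp_gene,
                    stringsAsFactors = FALSE)

  ## frequency table
  n_ind <- ceiling(n_alleles / 2)
  d_vec <- ifelse(snp_label == "HD", d_hd, 0)
  p1 <- ifelse(snp_label == "HD",
               stats::runif(n_snps, 0, min(0.05, 1 - 2 * d_hd)),
               stats::runif(n_snps, 0.1, 0.5))
  pmat <- cbind(p1, p1 + d_vec, p1 + 2 * d_vec)
  g <- .draw_genotype_matrix(rep(n_ind, 3L), pmat)
  phat <- (2 * g$nAA + g$nAa) / (2 * g$n)
  freq <- data.frame(
    snp_id = rep(snps, 3L),
    population = rep(paste0("pop", 1:3), each = n_snps),
    allele_freq = as.numeric(phat),
    n_alleles = 2L * n_ind,
    stringsAsFactors = FALSE
  )
  freq <- freq[order(freq$snp_id, freq$population), ]
  rownames(freq) <- NULL

  ## annotated universe sized for the target fold enrichment
  k_planted <- min(hd_in_planted, n_hd %/% max(planted_terms, 1L))
  n_hd_annot <- if (k_planted > 0)
    max(round(k_planted * n_annotated / (planted_fold * term_size)),
        planted_terms * k_planted) else 0L
  n_hd_annot <- min(n_hd_annot, n_hd)
  planted_hd <- if (k_planted > 0)
    matrix(sample(hd_genes, planted_terms * k_planted),
           nrow = planted_terms) else matrix(character(), nrow = 0L)
  extra_hd <- sample(setdiff(hd_genes, as.vector(planted_hd)),
                     n_hd_annot - planted_terms * k_planted)
  ld_genes <- setdiff(genes, hd_genes)
  n_ld_annot <- min(n_annotated - n_hd_annot, length(ld_genes))
  ld_annot <- sort(sample(ld_genes, n_ld_annot))
  pool <- c(as.vector(planted_hd), extra_hd, ld_annot)

  cats <- c("BP", "MF", "CC", "PATHWAY")
  term_ids <- sprintf("T%04d", seq_len(n_terms))
  term_cat <- sample(cats, n_terms, replace = TRUE)
  fill_pool <- c(extra_hd, ld_annot)          # planted-term HD genes excluded
  sets <- vector("list", n_terms)
  for (t in seq_len(n_terms)) {
    members <- if (t <= planted_terms && k_planted > 0) {
      c(planted_hd[t, ], sample(ld_annot, term_size - k_planted))
    } else {
      sample(fill_pool, min(term_size, length(fill_pool)))
    }
    sets[[t]] <- members
  }
  ## every annotated gene must carry at least one annotation
  uncovered <- setdiff(pool, unique(unlist(sets)))
  if (length(uncovered) && n_terms > planted_terms) {
    host <- sample(seq(planted_terms + 1L, n_terms), length(uncovered),
                   replace = TRUE)
    for (j in seq_along(uncovered))
      sets[[host[j]]] <- c(sets[[host[j]]], uncovered[j])
  }
  gene_sets <- lapply(seq_len(n_terms), function(t)
    gene_set(term_ids[t], paste("synthetic term", term_ids[t]),
             term_cat[t], sets[[t]]))

  planted_ids <- if (planted_terms > 0 && k_planted > 0)
    term_ids[seq_len(planted_terms)] else character()
  expected <- if (length(planted_ids)) data.frame(
    term_id = planted_ids, k = k_planted, n = length(pool) - n_ld_annot,
    K = term_size, N = length(pool),
    fold_enrichment = (k_planted / (length(pool) - n_ld_annot)) /
      (term_size / length(pool)),
    stringsAsFactors = FALSE
  ) else data.frame()

  structure(
    list(frequency_table = freq,
         snp_gene_map = map,
         gene_sets = gene_sets,
         planted_truth = list(
           genes = data.frame(gene_id = genes, label = gene_label,
                              stringsAsFactors = FALSE),
           snps = data.frame(snp_id = snps, gene_id = snp_gene,
                             label = snp_label, d = d_vec, p1 = p1,
                             stringsAsFactors = FALSE),
           planted_term_ids = planted_ids,
           annotated_genes = sort(pool),
           expected = expected,
           params = list(n_genes = n_genes, n_snps = n_snps,
                         frac_hd = frac_hd, n_terms = n_terms,
                         planted_terms = planted_terms,
                         term_size = term_size, planted_fold = planted_fold,
                         hd_in_planted = k_planted,
                         n_annotated = n_annotated, n_alleles = n_alleles,
                         d_hd = d_hd, seed = seed))),
    class = "annotation_fixture"
  )
}

#' @export
print.annotation_fixture <- function(x, ...) {
  p <- x$planted_truth$params
  cat(sprintf(paste0("Synthetic annotation fixture: %d genes (%d HD), ",
                     "%d SNPs, %d terms (%d planted), seed %d\n"),
              p$n_genes, sum(x$planted_truth$genes$label == "HD"),
              p$n_snps, p$n_terms, length(x$planted_truth$planted_term_ids),
              p$seed))
  invisible(x)
}

#' Write a fixture to the interchange formats the readers accept
#'
#' Emits `frequency.tsv`, `snp_gene_map.tsv`, `gene_sets.gmt` and
#' `planted_genes.tsv` into `dir`, in exactly the dialects read by
#' [read_frequency_table()], [read_snp_gene_map()] and [read_gene_sets()].
#'
#' @param fixture an [make_annotation_fixture()] result.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_annotation_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "annotation_fixture"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    frequency = file.path(dir, "frequency.tsv"),
    map = file.path(dir, "snp_gene_map.tsv"),
    gmt = file.path(dir, "gene_sets.gmt"),
    truth = file.path(dir, "planted_genes.tsv")
  )
  write_frequency_table(fixture$frequency_table, paths["frequency"])
  write_snp_gene_map(fixture$snp_gene_map, paths["map"])
  write_gene_sets(fixture$gene_sets, paths["gmt"])
  .write_tsv(fixture$planted_truth$genes, paths["truth"])
  invisible(paths)
}
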