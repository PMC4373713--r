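## Fst-based classification of SNPs and genes ---------------------------------

#' Per-SNP Fst from an allele-frequency table
#'
#' Applies the Weir-Cockerham estimator (see [fst_weir()]) to
#' frequency-only input: one row per (SNP, population) with the observed
#' allele frequency and the number of alleles sampled.  SNPs observed in
#' fewer than `min_pops` populations are dropped (a message reports how
#' many), mirroring the reduction of a real multi-panel dataset to its
#' compatible SNPs.
#'
#' @param freq data frame with columns `snp_id`, `population`,
#'   `allele_freq`, `n_alleles` (as read by [read_frequency_table()]).
#' @param min_pops minimum populations per SNP; defaults to the number of
#'   distinct populations present in the table.
#' @return A data frame, one row per retained SNP: `snp_id`, `n_pops`,
#'   `msp`, `msg`, `n_c`, `p_bar`, `theta_hat`.
#' @export
fst_from_frequencies <- function(freq, min_pops = NULL) {
  need <- c("snp_id", "population", "allele_freq", "n_alleles")
  if (!is.data.frame(freq) || !all(need %in% names(freq)))
    stop("'freq' needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (any(freq$n_alleles < 1))
    stop("'n_alleles' must be at least 1 in every row", call. = FALSE)
  if (is.null(min_pops)) min_pops <- length(unique(freq$population))
  if (min_pops < 2L) stop("'min_pops' must be at least 2", call. = FALSE)

  idx <- split(seq_len(nrow(freq)), freq$snp_id)
  keep <- vapply(idx, length, integer(1)) >= min_pops
  if (any(!keep))
    message(sum(!keep), " SNP(s) dropped: fewer than ", min_pops,
            " populations")
  idx <- idx[keep]
  if (length(idx) == 0L)
    return(data.frame(snp_id = character(), n_pops = integer(),
                      msp = numeric(), msg = numeric(), n_c = numeric(),
                      p_bar = numeric(), theta_hat = numeric()))

  rows <- lapply(names(idx), function(id) {
    i <- idx[[id]]
    eng <- .fst_engine(matrix(freq$allele_freq[i], nrow = 1L),
                       matrix(freq$n_alleles[i], nrow = 1L))
    data.frame(snp_id = id, n_pops = length(i), msp = eng$msp,
               msg = eng$msg, n_c = eng$n_c, p_bar = eng$p_bar,
               theta_hat = eng$theta_hat, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Merge populations of a frequency table
#'
#' Pre-processing transform for pooling closely related panels (e.g.
#' merging the two East-Asian panels into one): the merged frequency is the
#' allele-count-weighted average and the merged size is the sum of alleles.
#'
#' @param freq frequency table (see [fst_from_frequencies()]).
#' @param from character vector of population labels to merge.
#' @param to label of the merged population.
#' @return The transformed frequency table.
#' @export
merge_populations <- function(freq, from, to) {
  sel <- freq$population %in% from
  if (!any(sel)) return(freq)
  sub <- freq[sel, , drop = FALSE]
  agg_n <- tapply(sub$n_alleles, sub$snp_id, sum)
  agg_x <- tapply(sub$allele_freq * sub$n_alleles, sub$snp_id, sum)
  merged <- data.frame(snp_id = names(agg_n), population = to,
                       allele_freq = as.numeric(agg_x / agg_n),
                       n_alleles = as.numeric(agg_n),
                       stringsAsFactors = FALSE)
  out <- rbind(freq[!sel, need_cols <- c("snp_id", "population",
                                         "allele_freq", "n_alleles")],
               merged[, need_cols])
  out[order(out$snp_id, out$population), , drop = FALSE]
}

#' Split SNPs into high- and low-differentiation groups
#'
#' Wright's categories with strict inequalities: HD is `theta_hat > 0.25`
#' (very high divergence), LD is `theta_hat < 0.05` (low divergence);
#' values on a boundary and `NaN` estimates fall in neither group.
#'
#' @param fst_table output of [fst_from_frequencies()] (columns `snp_id`,
#'   `theta_hat`).
#' @param hd_threshold,ld_threshold the two cutoffs, `0 < ld < hd`.
#' @return List with character vectors `hd`, `ld`, `remainder` and
#'   `excluded_nan`.
#' @export
group_snps <- function(fst_table, hd_threshold = 0.25, ld_threshold = 0.05) {
  if (!all(c("snp_id", "theta_hat") %in% names(fst_table)))
    stop("'fst_table' needs columns snp_id and theta_hat", call. = FALSE)
  if (!(0 < ld_threshold && ld_threshold < hd_threshold))
    stop("need 0 < ld_threshold < hd_threshold", call. = FALSE)
  th <- fst_table$theta_hat
  nan <- is.na(th)
  list(
    hd = fst_table$snp_id[!nan & th > hd_threshold],
    ld = fst_table$snp_id[!nan & th < ld_threshold],
    remainder = fst_table$snp_id[!nan & th >= ld_threshold & th <= hd_threshold],
    excluded_nan = fst_table$snp_id[nan]
  )
}

#' Assign genes to differentiation groups through their SNPs
#'
#' A gene is HD when at least one of its mapped SNPs has
#' `theta_hat > hd_threshold`; it is LD when all of its scored SNPs have
#' `theta_hat < ld_threshold` (the conservative reading under which no gene
#' can satisfy both definitions; `ld_rule = "any"` relaxes this to
#' at-least-one-SNP-below).  Everything else is intermediate.  SNPs absent
#' from the map are dropped with a message; `NaN` estimates do not count.
#'
#' @param fst_table output of [fst_from_frequencies()].
#' @param map data frame with columns `snp_id`, `gene_id` (a SNP may map to
#'   several genes and contributes its estimate to each).
#' @param hd_threshold,ld_threshold Wright's cutoffs (see [group_snps()]).
#' @param ld_rule `"all"` (default) or `"any"`.
#' @return A data frame, one row per gene: `gene_id`, `group` (`"HD"`,
#'   `"LD"` or `"intermediate"`), `max_fst`, `n_snps`.
#' @export
group_genes <- function(fst_table, map, hd_threshold = 0.25,
                        ld_threshold = 0.05, ld_rule = c("all", "any")) {
  ld_rule <- match.arg(ld_rule)
  if (!all(c("snp_id", "gene_id") %in% names(map)))
    stop("'map' needs columns snp_id and gene_id", call. = FALSE)
  scored <- fst_table[!is.na(fst_table$theta_hat), , drop = FALSE]
  unmapped <- setdiff(scored$snp_id, map$snp_id)
  if (length(unmapped))
    message(length(unmapped), " scored SNP(s) absent from the gene map; dropped")
  m <- merge(map, scored[, c("snp_id", "theta_hat")], by = "snp_id")
  if (nrow(m) == 0L)
    return(data.frame(gene_id = character(), group = character(),
                      max_fst = numeric(), n_snps = integer()))
  mx <- tapply(m$theta_hat, m$gene_id, max)
  mn <- tapply(m$theta_hat, m$gene_id, min)
  ns <- tapply(m$theta_hat, m$gene_id, length)
  hd <- mx > hd_threshold
  ld <- if (ld_rule == "all") !hd & mx < ld_threshold else !hd & mn < ld_threshold
  data.frame(
    gene_id = names(mx),
    group = ifelse(hd, "HD", ifelse(ld, "LD", "intermediate")),
    max_fst = as.numeric(mx),
    n_snps = as.integer(ns),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' SNPs with individually reportable differentiation
#'
#' Returns the SNPs whose Fst estimate strictly exceeds the highlight
#' threshold (0.5 by default), sorted by decreasing estimate with ties
#' broken lexicographically by SNP id.
#'
#' @param fst_table output of [fst_from_frequencies()].
#' @param threshold highlight cutoff.
#' @return Data frame `snp_id`, `theta_hat`, sorted.
#' @export
highlight_snps <- function(fst_table, threshold = 0.5) {
  th <- fst_table$theta_hat
  sel <- !is.na(th) & th > threshold
  out <- fst_table[sel, c("snp_id", "theta_hat"), drop = FALSE]
  out <- out[order(-out$theta_hat, out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group summary table (count / mean / median of Fst)
#'
#' One row per group (HD, LD) plus a Total row over all scored SNPs,
#' computed over non-`NaN` estimates only.
#'
#' @param fst_table output of [fst_from_frequencies()].
#' @param groups output of [group_snps()] on the same table.
#' @return Data frame `group`, `snp_count`, `mean_fst`, `median_fst`.
#' @export
summarize_groups <- function(fst_table, groups) {
  th <- stats::setNames(fst_table$theta_hat, fst_table$snp_id)
  th <- th[!is.na(th)]
  one <- function(label, ids) {
    v <- th[names(th) %in% ids]
    data.frame(group = label, snp_count = length(v),
               mean_fst = if (length(v)) mean(v) else NaN,
               median_fst = if (length(v)) stats::median(v) else NaN,
               stringsAsFactors = FALSE)
  }
  rbind(one("HD", groups$hd), one("LD", groups$ld),
        one("Total", names(th)))
}
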