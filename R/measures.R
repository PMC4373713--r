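## Vectorized engines -------------------------------------------------------
##
## Every measure is implemented once, on D x s matrices (D datasets/SNPs in
## rows, s populations in columns), so that the simulation benchmark can
## score thousands of simulated SNPs without looping.  The exported per-SNP
## operations wrap these engines with one-row matrices.

## Weir & Cockerham theta-hat from allele frequencies and allele counts.
## `n` is in ALLELES here (2x individuals for diploids): the estimator's
## underlying ANOVA is over per-allele indicator variables.
.fst_engine <- function(phat, n) {
  s <- ncol(phat)
  if (s < 2L) stop("Fst needs at least 2 populations", call. = FALSE)
  if (any(n < 1)) stop("every population needs at least 1 allele sampled",
                       call. = FALSE)
  ntot  <- rowSums(n)
  pbar  <- rowSums(n * phat) / ntot
  msp   <- rowSums(n * (phat - pbar)^2) / (s - 1)
  msg   <- rowSums(n * phat * (1 - phat)) / rowSums(n - 1)
  nc    <- (ntot - rowSums(n^2) / ntot) / (s - 1)
  denom <- msp + (nc - 1) * msg
  theta <- (msp - msg) / denom
  theta[denom == 0] <- NaN   # monomorphic everywhere: 0/0 carries no signal
  list(msp = msp, msg = msg, n_c = nc, p_bar = pbar, theta_hat = theta)
}

## Pearson X^2 of homogeneity on the 2 x s allele-count table.
## `x` = counted-allele counts, `n2` = total alleles, both D x s.
.chisq_engine <- function(x, n2) {
  s    <- ncol(x)
  phat <- x / n2
  pbar <- rowSums(x) / rowSums(n2)
  x2   <- rowSums(n2 * (phat - pbar)^2) / (pbar * (1 - pbar))
  x2[pbar <= 0 | pbar >= 1] <- 0   # one allele absent overall: no signal
  p <- stats::pchisq(x2, df = s - 1, lower.tail = FALSE)
  list(statistic = x2, p_value = p, df = s - 1)
}

## One-way fixed-effects ANOVA on allele dosages (0/1/2 per individual),
## computed from genotype counts.  `n` is in INDIVIDUALS, D x s.
.anova_engine <- function(nAA, nAa, n) {
  s     <- ncol(n)
  ntot  <- rowSums(n)
  x     <- 2 * nAA + nAa               # dosage sums per population
  gmean <- rowSums(x) / ntot
  means <- x / n
  ssb   <- rowSums(n * (means - gmean)^2)
  # within-group SS: sum of squared dosages minus n * mean^2
  ssw   <- rowSums(4 * nAA + nAa - n * means^2)
  msb   <- ssb / (s - 1)
  msw   <- ssw / (ntot - s)
  f     <- msb / msw
  f[msw == 0 & msb > 0] <- Inf
  f[msw == 0 & msb == 0] <- NaN
  p <- stats::pf(f, s - 1, ntot - s, lower.tail = FALSE)
  p[is.infinite(f)] <- 0
  list(grand_mean = gmean, group_means = means, ms_between = msb,
       ms_within = msw, f_stat = f, df1 = s - 1, df2 = ntot - s, p_value = p)
}

## Nearest-shrunken-centroid standardized distances on the allele-frequency
## scale (per-individual dosage / 2).  `n` in INDIVIDUALS, D x s.  s0 is the
## panel median of the pooled SDs s_k unless supplied.
.nscm_engine <- function(nAA, nAa, n, s0 = NULL, m_form = c("sqrt", "literal")) {
  m_form <- match.arg(m_form)
  ntot <- rowSums(n)
  s    <- ncol(n)
  a    <- (2 * nAA + nAa) / (2 * n)          # a_ik, per-population mean
  ak   <- rowSums(2 * nAA + nAa) / (2 * ntot) # overall (weighted) mean
  # pooled within-population SS on the frequency scale:
  # per individual the value is dosage/2, so sum of squares is
  # (4 nAA + nAa)/4 and the centered SS is that minus n * a^2
  wss  <- rowSums(nAA + nAa / 4 - n * a^2)
  sk   <- sqrt(wss / (ntot - s))
  if (is.null(s0)) s0 <- stats::median(sk)
  mi   <- if (m_form == "sqrt") sqrt(1 / n + 1 / ntot) else 1 / n + 1 / ntot
  num  <- a - ak
  d    <- num / (mi * (s0 + sk))
  d[num == 0] <- 0                           # zero numerator wins over 0/0
  list(pop_means = a, overall_mean = ak, pooled_sd = sk, s0 = s0,
       m = mi, d_matrix = d, ss_d = rowSums(d^2))
}

## Public per-SNP operations -------------------------------------------------

#' Weir and Cockerham's Fst estimator for one SNP
#'
#' Computes the method-of-moments estimator
#' `theta_hat = (MSP - MSG) / (MSP + (n_c - 1) MSG)` from the observed mean
#' squares between (`MSP`) and within (`MSG`) populations, where `n_c` is
#' the imbalance-corrected average sample size.  Sample sizes enter in
#' allele units (2 x individuals for diploids), since the estimator's
#' underlying analysis of variance is over per-allele indicators.
#'
#' The estimate is reported as-is: it is legitimately slightly negative
#' near zero differentiation and is never clamped.  A locus monomorphic in
#' every population gives `MSP = MSG = 0` and `theta_hat = NaN`.
#'
#' @param dataset a [snp_dataset()].
#' @return An object of class `fst_components`: list with `snp_id`, `msp`,
#'   `msg`, `n_c`, `p_bar` and `theta_hat`.
#' @examples
#' d <- snp_dataset("rs1", rbind(c(0, 0, 100), c(100, 0, 0)))
#' fst_weir(d)$theta_hat  # 1: complete fixation
#' @export
fst_weir <- function(dataset) {
  stopifnot(inherits(dataset, "snp_dataset"))
  if (any(dataset$n_individuals == 0))
    stop("population with no sampled individuals in SNP ", dataset$snp_id,
         call. = FALSE)
  n_alleles <- matrix(2 * dataset$n_individuals, nrow = 1L)
  phat <- matrix(allele_frequency(dataset), nrow = 1L)
  eng <- .fst_engine(phat, n_alleles)
  structure(
    list(snp_id = dataset$snp_id, msp = eng$msp, msg = eng$msg,
         n_c = eng$n_c, p_bar = eng$p_bar, theta_hat = eng$theta_hat),
    class = "fst_components"
  )
}

#' @export
print.fst_components <- function(x, ...) {
  cat("Weir-Cockerham Fst for", x$snp_id, "\n")
  cat(sprintf("  MSP = %.6g, MSG = %.6g, n_c = %.6g, p_bar = %.4f\n",
              x$msp, x$msg, x$n_c, x$p_bar))
  cat(sprintf("  theta_hat = %.6g\n", x$theta_hat))
  invisible(x)
}

#' Chi-square test of allele-frequency homogeneity
#'
#' Pearson's X^2 on the `2 x s` table of allele counts
#' (`2 n_i p_i`, `2 n_i (1 - p_i)`), testing `p_1 = ... = p_s`, with
#' `df = s - 1` and no continuity correction.  If one allele is absent in
#' every population the statistic is 0 and p = 1.  A `3 x s` genotype-count
#' variant (df adjusted for genotype categories absent overall) is available
#' via `table = "genotype"`.
#'
#' @param dataset a [snp_dataset()].
#' @param table `"allele"` (default) or `"genotype"`.
#' @return An object of class `measure_result`: list with `snp_id`,
#'   `measure`, `value` (the X^2 statistic), `df` and `p_value`.
#' @export
chisq_homogeneity <- function(dataset, table = c("allele", "genotype")) {
  stopifnot(inherits(dataset, "snp_dataset"))
  table <- match.arg(table)
  if (any(dataset$n_individuals == 0))
    stop("population with no sampled individuals in SNP ", dataset$snp_id,
         call. = FALSE)
  if (table == "allele") {
    x  <- matrix(.allele_counts(dataset), nrow = 1L)
    n2 <- matrix(2 * dataset$n_individuals, nrow = 1L)
    eng <- .chisq_engine(x, n2)
    value <- eng$statistic; df <- eng$df; p <- eng$p_value
  } else {
    tab <- t(dataset$counts)                       # genotypes x populations
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]   # drop absent genotypes
    if (nrow(tab) < 2L) {
      value <- 0; df <- (3 - 1) * (ncol(tab) - 1); p <- 1
    } else {
      exp_ <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      value <- sum((tab - exp_)^2 / exp_)
      df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
      p <- stats::pchisq(value, df, lower.tail = FALSE)
    }
  }
  structure(
    list(snp_id = dataset$snp_id, measure = "chisq",
         value = as.numeric(value), df = df, p_value = as.numeric(p)),
    class = "measure_result"
  )
}

#' @export
print.measure_result <- function(x, ...) {
  cat(sprintf("%s [%s]: value = %.6g", x$snp_id, x$measure, x$value))
  if (!is.null(x$p_value) && !is.na(x$p_value))
    cat(sprintf(", p = %.4g", x$p_value))
  cat("\n")
  invisible(x)
}

#' One-way ANOVA F-test on allele dosages
#'
#' Fits the fixed-effects model `a_ij = mu + tau_i + e_ij` (with the
#' weighted constraint `sum n_i tau_i = 0`) to per-individual allele
#' dosages (0, 1 or 2 copies of the counted allele, reconstructed from the
#' genotype counts) and tests `tau_i = 0` for all populations with
#' `F = MS_between / MS_within` on `(s - 1, n - s)` degrees of freedom.
#'
#' Degenerate draws never abort: when `MS_within = 0` with distinct group
#' means the statistic is `+Inf` with p = 0; when both mean squares are 0 it
#' is `NaN`.
#'
#' @param dataset a [snp_dataset()].
#' @return An object of class `anova_decomposition`: list with
#'   `grand_mean`, `group_effects` (named `tau_i` estimates), `ms_between`,
#'   `ms_within`, `f_stat`, `df` and `p_value`.
#' @export
anova_f <- function(dataset) {
  stopifnot(inherits(dataset, "snp_dataset"))
  s <- length(dataset$populations)
  n <- sum(dataset$n_individuals)
  if (n <= s)
    stop("ANOVA needs more individuals than populations (n > s)", call. = FALSE)
  eng <- .anova_engine(matrix(dataset$counts[, 1L], nrow = 1L),
                       matrix(dataset$counts[, 2L], nrow = 1L),
                       matrix(dataset$n_individuals, nrow = 1L))
  effects <- drop(eng$group_means) - eng$grand_mean
  names(effects) <- dataset$populations
  structure(
    list(snp_id = dataset$snp_id,
         grand_mean = eng$grand_mean,
         group_effects = effects,
         ms_between = eng$ms_between,
         ms_within = eng$ms_within,
         f_stat = eng$f_stat,
         df = c(eng$df1, eng$df2),
         p_value = eng$p_value),
    class = "anova_decomposition"
  )
}

#' @export
print.anova_decomposition <- function(x, ...) {
  cat("Dosage ANOVA for", x$snp_id, "\n")
  cat(sprintf("  F(%d, %d) = %.6g, p = %.4g\n", x$df[1], x$df[2],
              x$f_stat, x$p_value))
  invisible(x)
}

#' Nearest-shrunken-centroid standardized distances (SS_d) for a SNP panel
#'
#' For each SNP `k` of a panel sharing one population structure, computes
#' the standardized distance of each population's mean allele frequency
#' `a_ik` from the overall mean `a_k`,
#' `d_ik = (a_ik - a_k) / (m_i (s_0 + s_k))`, and summarizes the SNP as
#' `SS_d = sum_i d_ik^2`.  Here `s_k` is the pooled within-population
#' standard deviation of the per-individual frequencies (dosage / 2,
#' denominator `n - s`), `m_i = sqrt(1/n_i + 1/n)` makes `m_i s_k` the
#' standard error of the numerator, and the fudge constant `s_0` is the
#' median of `s_k` over the panel (guarding against inflation of `d_ik`
#' at SNPs with tiny within-population variance).
#'
#' @param panel a list of [snp_dataset()] objects (or a single one, which
#'   is accepted with a warning since `s_0` then degenerates to that SNP's
#'   own `s_k`).
#' @param s0 optional fudge constant; defaults to the panel median of `s_k`.
#' @param m_form `"sqrt"` (default; `m_i = sqrt(1/n_i + 1/n)`, the form
#'   under which `m_i s_k` is a standard error) or `"literal"`
#'   (`m_i = 1/n_i + 1/n`).
#' @return A list of `nscm_components` objects (one per SNP; fields
#'   `snp_id`, `pop_means`, `overall_mean`, `pooled_sd`, `s0`, `m`,
#'   `d_matrix`, `ss_d`), with the shared `s0` attached as an attribute.
#' @export
nscm_ssd <- function(panel, s0 = NULL, m_form = c("sqrt", "literal")) {
  m_form <- match.arg(m_form)
  if (inherits(panel, "snp_dataset")) panel <- list(panel)
  if (length(panel) == 0L) stop("empty SNP panel", call. = FALSE)
  if (!all(vapply(panel, inherits, logical(1), "snp_dataset")))
    stop("'panel' must be a list of snp_dataset objects", call. = FALSE)
  pops <- panel[[1L]]$populations
  same <- vapply(panel, function(d) identical(d$populations, pops), logical(1))
  if (!all(same))
    stop("all SNPs in a panel must share the same population structure",
         call. = FALSE)
  if (length(panel) == 1L && is.null(s0))
    warning("panel of size 1: s0 equals this SNP's own s_k", call. = FALSE)
  nAA <- do.call(rbind, lapply(panel, function(d) d$counts[, 1L]))
  nAa <- do.call(rbind, lapply(panel, function(d) d$counts[, 2L]))
  n   <- do.call(rbind, lapply(panel, function(d) d$n_individuals))
  eng <- .nscm_engine(nAA, nAa, n, s0 = s0, m_form = m_form)
  out <- lapply(seq_along(panel), function(k) {
    structure(
      list(snp_id = panel[[k]]$snp_id,
           pop_means = stats::setNames(eng$pop_means[k, ], pops),
           overall_mean = eng$overall_mean[k],
           pooled_sd = eng$pooled_sd[k],
           s0 = eng$s0,
           m = stats::setNames(eng$m[k, ], pops),
           d_matrix = stats::setNames(eng$d_matrix[k, ], pops),
           ss_d = eng$ss_d[k]),
      class = "nscm_components"
    )
  })
  attr(out, "s0") <- eng$s0
  out
}

#' @export
print.nscm_components <- function(x, ...) {
  cat(sprintf("NSCM components for %s: SS_d = %.6g (s_k = %.4g, s_0 = %.4g)\n",
              x$snp_id, x$ss_d, x$pooled_sd, x$s0))
  invisible(x)
}
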