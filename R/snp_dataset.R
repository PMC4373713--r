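#' Genotype counts for one population at one SNP
#'
#' A `population_sample` holds the observed genotype counts of a biallelic
#' SNP in one subpopulation: the number of individuals homozygous for the
#' counted allele (`n_AA`), heterozygous (`n_Aa`), and homozygous for the
#' other allele (`n_aa`).
#'
#' @param population_id single character label, e.g. `"YRI"`.
#' @param genotype_counts integer vector of length 3, `(n_AA, n_Aa, n_aa)`.
#'
#' @return An object of class `population_sample`: a list with elements
#'   `population_id`, `n_individuals` and `genotype_counts` (named vector).
#' @examples
#' population_sample("CEU", c(25, 50, 25))
#' @export
population_sample <- function(population_id, genotype_counts) {
  if (length(population_id) != 1L || is.na(population_id))
    stop("'population_id' must be a single non-missing label", call. = FALSE)
  gc <- as.numeric(genotype_counts)
  if (length(gc) != 3L || anyNA(gc) || any(gc < 0) || any(gc != round(gc)))
    stop("'genotype_counts' must be 3 non-negative integer counts (n_AA, n_Aa, n_aa)",
         call. = FALSE)
  names(gc) <- c("n_AA", "n_Aa", "n_aa")
  structure(
    list(population_id = as.character(population_id),
         n_individuals = sum(gc),
         genotype_counts = gc),
    class = "population_sample"
  )
}

#' Per-SNP genotype counts across populations
#'
#' Bundles the genotype counts of one SNP across `s >= 2` populations; the
#' unit every measure of population differentiation in this package
#' operates on.
#'
#' @param snp_id single character label.
#' @param samples list of [population_sample()] objects (length >= 2), or
#'   alternatively an `s x 3` count matrix whose rownames are population ids
#'   and whose columns are `(n_AA, n_Aa, n_aa)`.
#'
#' @return An object of class `snp_dataset`: a list with elements `snp_id`,
#'   `populations` (character), `counts` (`s x 3` matrix) and `n_individuals`
#'   (per-population totals).
#' @examples
#' snp_dataset("rs1", list(
#'   population_sample("YRI", c(10, 40, 50)),
#'   population_sample("CEU", c(30, 40, 30))
#' ))
#' @export
snp_dataset <- function(snp_id, samples) {
  if (length(snp_id) != 1L || is.na(snp_id))
    stop("'snp_id' must be a single non-missing label", call. = FALSE)
  if (is.matrix(samples)) {
    if (ncol(samples) != 3L)
      stop("count matrix must have 3 columns (n_AA, n_Aa, n_aa)", call. = FALSE)
    ids <- rownames(samples)
    if (is.null(ids)) ids <- paste0("pop", seq_len(nrow(samples)))
    samples <- lapply(seq_len(nrow(samples)),
                      function(i) population_sample(ids[i], samples[i, ]))
  }
  if (!is.list(samples) ||
      !all(vapply(samples, inherits, logical(1), "population_sample")))
    stop("'samples' must be a list of population_sample objects", call. = FALSE)
  if (length(samples) < 2L)
    stop("a snp_dataset needs at least 2 populations", call. = FALSE)
  ids <- vapply(samples, `[[`, character(1), "population_id")
  if (anyDuplicated(ids))
    stop("population ids must be unique within a SNP", call. = FALSE)
  counts <- do.call(rbind, lapply(samples, `[[`, "genotype_counts"))
  dimnames(counts) <- list(ids, c("n_AA", "n_Aa", "n_aa"))
  structure(
    list(snp_id = as.character(snp_id),
         populations = ids,
         counts = counts,
         n_individuals = rowSums(counts)),
    class = "snp_dataset"
  )
}

#' Observed allele frequency of a population sample
#'
#' The frequency of the counted allele, `(2 n_AA + n_Aa) / (2 n)`.
#'
#' @param x a [population_sample()], a [snp_dataset()] (one frequency per
#'   population), or a bare length-3 count vector `(n_AA, n_Aa, n_aa)`.
#' @return Numeric frequency in `[0, 1]` (vector for a `snp_dataset`).
#' @examples
#' allele_frequency(c(25, 50, 25)) # 0.5
#' @export
allele_frequency <- function(x) {
  if (inherits(x, "snp_dataset")) {
    f <- (2 * x$counts[, 1L] + x$counts[, 2L]) / (2 * x$n_individuals)
    names(f) <- x$populations
    return(f)
  }
  if (inherits(x, "population_sample")) x <- x$genotype_counts
  x <- as.numeric(x)
  if (length(x) != 3L || anyNA(x) || any(x < 0))
    stop("expected 3 non-negative genotype counts", call. = FALSE)
  n <- sum(x)
  if (n == 0) stop("cannot compute an allele frequency from 0 individuals",
                   call. = FALSE)
  (2 * x[1L] + x[2L]) / (2 * n)
}

#' @export
print.snp_dataset <- function(x, ...) {
  cat("SNP", x$snp_id, "-", length(x$populations), "populations\n")
  tab <- cbind(x$counts, n = x$n_individuals,
               p_hat = round(allele_frequency(x), 4))
  print(tab)
  invisible(x)
}

#' @export
print.population_sample <- function(x, ...) {
  cat("Population", x$population_id, "- n =", x$n_individuals,
      "(AA/Aa/aa =", paste(x$genotype_counts, collapse = "/"),
      "), p_hat =", round(allele_frequency(x), 4), "\n")
  invisible(x)
}

## allele counts of a snp_dataset (counted allele, per population)
.allele_counts <- function(dataset) {
  2 * dataset$counts[, 1L] + dataset$counts[, 2L]
}
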