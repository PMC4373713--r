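## Hardy-Weinberg simulation of three-population SNP datasets -----------------

## Deterministic counter-based sub-seed derivation: every scenario (and every
## repetition within a scenario) gets its own 32-bit seed from the master
## seed, so blocks are independently reproducible.  Arithmetic is kept below
## 2^53 so the modular products are exact in doubles.
.derive_seed <- function(seed, index) {
  s <- as.double(seed %% 94906249L)
  as.integer((s * 22695477 + as.double(index) * 1000003 + 12345) %% 2147483629)
}

#' Draw the allele-frequency vector (p1, p2, p3) for one simulated SNP
#'
#' Allele frequencies of the three populations are equally spaced with gap
#' `d`: `p2 = p1 + d`, `p3 = p1 + 2d`, with
#' `p1 ~ Uniform[0, min(0.5, 1 - 2d)]`.  The upper bound 0.5 (rather
#' than 1) exploits the symmetry of every measure under allele relabeling
#' `p -> 1 - p`; the bound `1 - 2d` keeps `p3 <= 1`.  `d = 0` is the null
#' configuration (no differentiation).
#'
#' @param d allele-frequency spacing in `[0, 0.5]`.
#' @param n number of vectors to draw.
#' @return A numeric vector `(p1, p2, p3)` when `n = 1`, otherwise an
#'   `n x 3` matrix.  Uses the current RNG state.
#' @examples
#' set.seed(1)
#' make_p_vector(0.3)
#' @export
make_p_vector <- function(d, n = 1L) {
  if (length(d) != 1L || is.na(d) || d < 0 || d > 0.5)
    stop("'d' must be a single value in [0, 0.5]", call. = FALSE)
  p1 <- stats::runif(n, 0, min(0.5, 1 - 2 * d))
  p <- cbind(p1 = p1, p2 = p1 + d, p3 = p1 + 2 * d)
  if (n == 1L) drop(p) else p
}

## Vectorized multinomial HWE genotype draws: for each row of `p` (D draws)
## and each population i, counts ~ Multinomial(n_i; p^2, 2pq, q^2), realized
## through the exact conditional-binomial factorization
##   n_AA ~ Bin(n, p^2),  n_Aa | n_AA ~ Bin(n - n_AA, 2pq / (1 - p^2)).
.draw_genotype_matrix <- function(sample_sizes, p) {
  p <- rbind(p)
  D <- nrow(p); s <- length(sample_sizes)
  nAA <- nAa <- naa <- matrix(0L, D, s)
  for (i in seq_len(s)) {
    pi <- p[, i]
    nAA[, i] <- stats::rbinom(D, sample_sizes[i], pi^2)
    rem <- sample_sizes[i] - nAA[, i]
    cond <- ifelse(pi < 1, 2 * pi * (1 - pi) / (1 - pi^2), 0)
    nAa[, i] <- stats::rbinom(D, rem, pmin(cond, 1))
    naa[, i] <- rem - nAa[, i]
  }
  list(nAA = nAA, nAa = nAa, naa = naa,
       n = matrix(sample_sizes, D, s, byrow = TRUE))
}

#' Simulate one SNP dataset under Hardy-Weinberg equilibrium
#'
#' Genotype counts of population `i` are drawn from a single multinomial
#' with `n_i` trials and cell probabilities `(p_i^2, 2 p_i q_i, q_i^2)`, so
#' the three counts always sum to `n_i` and each marginal is the binomial
#' with the stated HWE proportion.
#'
#' @param sample_sizes integer vector of per-population sizes (individuals).
#' @param p allele-frequency vector, same length as `sample_sizes`.
#' @param snp_id label for the simulated SNP.
#' @return A [snp_dataset()].  Uses the current RNG state.
#' @examples
#' set.seed(1)
#' draw_snp_dataset(c(100, 100, 100), make_p_vector(0.2))
#' @export
draw_snp_dataset <- function(sample_sizes, p, snp_id = "sim") {
  if (length(p) != length(sample_sizes))
    stop("'p' and 'sample_sizes' must have the same length", call. = FALSE)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  if (any(sample_sizes < 1))
    stop("sample sizes must be at least 1", call. = FALSE)
  counts <- vapply(seq_along(p), function(i) {
    drop(stats::rmultinom(1, sample_sizes[i],
                          c(p[i]^2, 2 * p[i] * (1 - p[i]), (1 - p[i])^2)))
  }, numeric(3))
  snp_dataset(snp_id, t(counts))
}

#' The simulation scenario grids of the benchmarking studies
#'
#' Two designs over the same six sample-size triples
#' (balanced: (100,100,100), (200,200,200), (400,400,400); unbalanced:
#' (200,100,100), (100,200,100), (100,100,200)):
#' \describe{
#'   \item{`distribution_study`}{crossed with `d` in \{0.1, 0.2, 0.3\},
#'     200 datasets per condition, single repetition — the per-measure
#'     value distributions behind box-plot comparisons.}
#'   \item{`sensitivity_specificity`}{crossed with `d` in
#'     \{0, 0.05, ..., 0.3\} (`d = 0` is the null), 100 datasets per
#'     condition, 100 repetitions — the specificity/sensitivity study.}
#' }
#'
#' @param kind `"distribution_study"` or `"sensitivity_specificity"`.
#' @param seed master seed; each scenario row receives a distinct
#'   deterministic sub-seed derived from it.
#' @return A data frame with columns `scenario` ("I" balanced / "II"
#'   unbalanced), `n1`, `n2`, `n3`, `d`, `n_datasets`, `n_repetitions`,
#'   `seed`.
#' @export
scenario_grid <- function(kind = c("distribution_study",
                                   "sensitivity_specificity"),
                          seed = 1L) {
  kind <- match.arg(kind)
  sizes <- rbind(
    c(100, 100, 100), c(200, 200, 200), c(400, 400, 400),  # Scenario I
    c(200, 100, 100), c(100, 200, 100), c(100, 100, 200)   # Scenario II
  )
  scen <- rep(c("I", "II"), each = 3)
  if (kind == "distribution_study") {
    dgrid <- c(0.1, 0.2, 0.3); n_datasets <- 200L; n_rep <- 1L
  } else {
    dgrid <- seq(0, 0.3, by = 0.05); n_datasets <- 100L; n_rep <- 100L
  }
  grid <- expand.grid(size_row = seq_len(nrow(sizes)), d = dgrid,
                      KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(
    kind = kind,
    scenario = scen[grid$size_row],
    n1 = sizes[grid$size_row, 1], n2 = sizes[grid$size_row, 2],
    n3 = sizes[grid$size_row, 3],
    d = grid$d,
    n_datasets = n_datasets,
    n_repetitions = n_rep,
    stringsAsFactors = FALSE
  )
  out$seed <- vapply(seq_len(nrow(out)), function(i) .derive_seed(seed, i),
                     integer(1))
  out
}
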