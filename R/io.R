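## Readers and writers for the interchange formats ----------------------------
##
## Floats are serialized with 6 significant digits; NaN/NA as the literal
## "NA".  All writers and readers round-trip.

.write_tsv <- function(x, path) {
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(v)
    ifelse(is.na(v), NA, signif(v, 6)))
  utils::write.table(x, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-SNP per-population allele-frequency table
#'
#' Tab-separated with a header row and columns `snp_id`, `population`,
#' `allele_freq`, `n_alleles`.  Rows violating the invariants
#' (`allele_freq` outside `[0, 1]`, `n_alleles < 1`, a frequency
#' inconsistent with an integer allele count) and duplicate
#' (SNP, population) pairs raise an error naming the offending row.
#'
#' @param path file path.
#' @return Data frame of validated records.
#' @export
read_frequency_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "population", "allele_freq", "n_alleles")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad_num <- which(is.na(x$allele_freq) | is.na(x$n_alleles))
  if (length(bad_num))
    stop("non-numeric allele_freq/n_alleles at data row ", bad_num[1L],
         " of ", path, call. = FALSE)
  bad <- which(x$allele_freq < 0 | x$allele_freq > 1)
  if (length(bad))
    stop("allele_freq outside [0, 1] at data row ", bad[1L], " of ", path,
         call. = FALSE)
  bad <- which(x$n_alleles < 1 | x$n_alleles != round(x$n_alleles))
  if (length(bad))
    stop("invalid n_alleles at data row ", bad[1L], " of ", path,
         call. = FALSE)
  cnt <- x$allele_freq * x$n_alleles
  bad <- which(abs(cnt - round(cnt)) > 1e-4 * x$n_alleles + 1e-8)
  if (length(bad))
    stop("allele_freq * n_alleles is not an integer allele count at data row ",
         bad[1L], " of ", path, call. = FALSE)
  dup <- duplicated(x[, c("snp_id", "population")])
  if (any(dup))
    stop("duplicate (snp_id, population) pair at data row ", which(dup)[1L],
         " of ", path, call. = FALSE)
  x[, need]
}

#' Write an allele-frequency table
#' @param x data frame with columns `snp_id`, `population`, `allele_freq`,
#'   `n_alleles`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_frequency_table <- function(x, path) {
  need <- c("snp_id", "population", "allele_freq", "n_alleles")
  stopifnot(all(need %in% names(x)))
  .write_tsv(x[, need], path)
}

#' Read a SNP-to-gene map
#'
#' Tab-separated with header columns `snp_id`, `gene_id`, one pair per
#' row; a SNP may map to several genes.  Duplicated pairs are collapsed.
#'
#' @param path file path.
#' @return Data frame `snp_id`, `gene_id`.
#' @export
read_snp_gene_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "gene_id")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!nzchar(x$snp_id) | !nzchar(x$gene_id) |
                 is.na(x$snp_id) | is.na(x$gene_id))
  if (length(bad))
    stop("empty snp_id/gene_id at data row ", bad[1L], " of ", path,
         call. = FALSE)
  unique(x[, need])
}

#' Write a SNP-to-gene map
#' @param x data frame with columns `snp_id`, `gene_id`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_snp_gene_map <- function(x, path) {
  stopifnot(all(c("snp_id", "gene_id") %in% names(x)))
  .write_tsv(x[, c("snp_id", "gene_id")], path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one term per line, tab-separated fields
#' `term`, `description`, then the member genes.  Gene ids are uppercased
#' and deduplicated; terms empty after deduplication are dropped with a
#' warning; lines with fewer than three fields are an error.  The term
#' category is parsed from a `BP:`/`MF:`/`CC:`/`KEGG:`/`PATHWAY:` prefix on
#' the term field (as written by [write_gene_sets()]); unprefixed terms are
#' treated as pathways.
#'
#' @param path file path.
#' @return List of [gene_set()] objects.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, " of ", path, " has fewer than 3 fields",
           call. = FALSE)
    term <- f[1L]
    cat_ <- "PATHWAY"
    m <- regmatches(term, regexec("^(BP|MF|CC|KEGG|PATHWAY):(.+)$", term))[[1L]]
    if (length(m) == 3L) {
      cat_ <- if (m[2L] == "KEGG") "PATHWAY" else m[2L]
      term <- m[3L]
    }
    genes <- unique(toupper(f[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      warning("GMT line ", i, ": term ", term, " has no genes; dropped",
              call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <- gene_set(term, f[2L], cat_, genes)
  }
  out
}

#' Write gene sets to a GMT file
#'
#' Writes the standard three-plus fields per line, with the category
#' encoded as a `BP:`/`MF:`/`CC:`/`PATHWAY:` prefix on the term field so
#' that [read_gene_sets()] round-trips it.
#'
#' @param gene_sets list of [gene_set()] objects.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(gene_sets, path) {
  stopifnot(all(vapply(gene_sets, inherits, logical(1), "gene_set")))
  lines <- vapply(gene_sets, function(gs)
    paste(c(paste0(gs$category, ":", gs$term_id), gs$term_name, gs$genes),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

## Plain-text run configuration (DCF) -----------------------------------------

.config_keys <- c("seed", "scenario_kind", "alpha", "fst_threshold",
                  "nscm_threshold", "hd_threshold", "ld_threshold",
                  "highlight_threshold", "background_mode")
.config_numeric <- c("seed", "alpha", "fst_threshold", "nscm_threshold",
                     "hd_threshold", "ld_threshold", "highlight_threshold")

#' Read a run configuration file
#'
#' Debian-control-style `key: value` plain text.  Recognized keys: `seed`,
#' `scenario_kind`, `alpha`, `fst_threshold`, `nscm_threshold`,
#' `hd_threshold`, `ld_threshold`, `highlight_threshold`,
#' `background_mode`; anything else is rejected.
#'
#' @param path file path.
#' @return Named list of settings (numbers parsed).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dcf <- read.dcf(path)
  keys <- colnames(dcf)
  unknown <- setdiff(keys, .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- as.list(dcf[1L, ])
  for (k in intersect(keys, .config_numeric)) cfg[[k]] <- as.numeric(cfg[[k]])
  cfg
}

#' Write a run configuration file
#' @param config named list of settings (recognized keys only).
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  unknown <- setdiff(names(config), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  write.dcf(as.data.frame(config, stringsAsFactors = FALSE), path)
  invisible(path)
}
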