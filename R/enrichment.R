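## Hypergeometric over-representation analysis with BH correction -------------

#' A named gene set (GO term or pathway)
#'
#' @param term_id unique term label (e.g. `"GO:0007154"`).
#' @param term_name human-readable description.
#' @param category one of `"BP"`, `"MF"`, `"CC"`, `"PATHWAY"`.
#' @param genes character vector of member gene ids (non-empty; uppercased
#'   and deduplicated).
#' @return Object of class `gene_set`.
#' @export
gene_set <- function(term_id, term_name = term_id,
                     category = c("BP", "MF", "CC", "PATHWAY"), genes) {
  category <- match.arg(category)
  genes <- unique(toupper(as.character(genes)))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) stop("a gene set cannot be empty", call. = FALSE)
  structure(list(term_id = as.character(term_id),
                 term_name = as.character(term_name),
                 category = category, genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("[%s] %s (%s): %d genes\n", x$category, x$term_id,
              x$term_name, length(x$genes)))
  invisible(x)
}

#' Hypergeometric term enrichment of a gene list
#'
#' For each term, tests whether the input list contains more term genes
#' than expected from drawing `n` genes without replacement from the `N`
#' annotated background genes, of which `K` belong to the term:
#' `p = P(X >= k)` for hypergeometric `X`.  Following the usual
#' over-representation convention, only genes carrying at least one
#' annotation in the tested categories count towards `n` and `N`.  Fold
#' enrichment is `(k/n) / (K/N)` (0 when `k = 0`, in which case the term is
#' still reported with p = 1).  Benjamini-Hochberg q-values are computed
#' over all tested terms jointly (or per category), and `significant`
#' flags `q <= 0.05`.
#'
#' @param input_genes character vector of input gene ids; genes outside the
#'   background are dropped with a warning.
#' @param background_genes character vector defining the background
#'   universe.
#' @param gene_sets list of [gene_set()] objects.
#' @param min_term_size terms with fewer than this many background genes
#'   are untestable and dropped (a message reports how many).
#' @param ease if `TRUE`, applies the conservative EASE variant that
#'   removes one input success from the tail (`P(X >= k)` computed at
#'   `k - 1`).
#' @param adjust `"joint"` (BH across all categories together, default) or
#'   `"per_category"`.
#' @param alpha significance level on the q-value.
#' @return A data frame, one row per tested term: `term_id`, `term_name`,
#'   `category`, `k`, `n`, `K`, `N`, `fold_enrichment`, `p_value`,
#'   `q_value`, `significant`.
#' @export
hypergeom_enrich <- function(input_genes, background_genes, gene_sets,
                             min_term_size = 2L, ease = FALSE,
                             adjust = c("joint", "per_category"),
                             alpha = 0.05) {
  adjust <- match.arg(adjust)
  if (!all(vapply(gene_sets, inherits, logical(1), "gene_set")))
    stop("'gene_sets' must be a list of gene_set objects", call. = FALSE)
  bg <- unique(toupper(background_genes))
  input <- unique(toupper(input_genes))
  if (length(bg) == 0L) stop("empty background", call. = FALSE)
  outside <- setdiff(input, bg)
  if (length(outside)) {
    warning(length(outside), " input gene(s) outside the background; ",
            "intersected away", call. = FALSE)
    input <- intersect(input, bg)
  }
  term_bg <- lapply(gene_sets, function(gs) intersect(gs$genes, bg))
  small <- lengths(term_bg) < min_term_size
  if (any(small))
    message(sum(small), " term(s) dropped: fewer than ", min_term_size,
            " background genes")
  gene_sets <- gene_sets[!small]
  term_bg <- term_bg[!small]
  if (length(gene_sets) == 0L) stop("no testable terms", call. = FALSE)

  # the annotation universe: genes carrying >= 1 annotation among the
  # testable terms
  annotated <- unique(unlist(term_bg))
  N <- length(annotated)
  input_ann <- intersect(input, annotated)
  n <- length(input_ann)
  if (n == 0L) stop("no annotated input genes after filtering", call. = FALSE)

  res <- do.call(rbind, lapply(seq_along(gene_sets), function(i) {
    gs <- gene_sets[[i]]
    data.frame(term_id = gs$term_id, term_name = gs$term_name,
               category = gs$category,
               k = length(intersect(term_bg[[i]], input_ann)),
               n = n, K = length(term_bg[[i]]), N = N,
               stringsAsFactors = FALSE)
  }))

  ktail <- if (ease) pmax(res$k - 1L, 0L) else res$k
  res$p_value <- stats::phyper(ktail - 1L, res$K, res$N - res$K, res$n,
                               lower.tail = FALSE)
  res$fold_enrichment <- ifelse(res$k == 0, 0,
                                (res$k / res$n) / (res$K / res$N))
  res$q_value <- if (adjust == "joint") bh_adjust(res$p_value) else
    stats::ave(res$p_value, res$category, FUN = bh_adjust)
  res$significant <- res$q_value <= alpha
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min_{j >= i} ( m p_(j) / j )` over the sorted p-values, capped
#' at 1 — the classic FDR-controlling step-up adjustment.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Enrichment under two nested backgrounds, joined per term
#'
#' Runs three enrichment analyses — input vs. the full background, the
#' intermediate gene list vs. the full background, and input vs. the
#' intermediate list — and joins fold enrichments and q-values per term.
#' The canonical use is comparing a high-differentiation gene group against
#' all annotated genes and against the drug-related genes it was drawn
#' from.
#'
#' @param input_genes the gene group of interest.
#' @param bg_dr the intermediate background (e.g. all drug-related genes);
#'   must contain `input_genes`.
#' @param bg_all the full background; must contain `bg_dr`.
#' @param gene_sets list of [gene_set()] objects.
#' @param ... passed on to [hypergeom_enrich()].
#' @return A data frame keyed by term with columns
#'   `fold_input_vs_all`, `q_input_vs_all`, `fold_dr_vs_all`,
#'   `q_dr_vs_all`, `fold_input_vs_dr`, `q_input_vs_dr`.
#' @export
compare_backgrounds <- function(input_genes, bg_dr, bg_all, gene_sets, ...) {
  input <- unique(toupper(input_genes))
  dr <- unique(toupper(bg_dr))
  all_ <- unique(toupper(bg_all))
  if (length(setdiff(input, dr)))
    stop("'input_genes' must be a subset of 'bg_dr'", call. = FALSE)
  if (length(setdiff(dr, all_)))
    stop("'bg_dr' must be a subset of 'bg_all'", call. = FALSE)
  a <- hypergeom_enrich(input, all_, gene_sets, ...)
  b <- hypergeom_enrich(dr, all_, gene_sets, ...)
  c_ <- hypergeom_enrich(input, dr, gene_sets, ...)
  key <- c("term_id", "term_name", "category")
  take <- function(x, suffix) {
    x <- x[, c(key, "fold_enrichment", "q_value")]
    names(x)[4:5] <- paste0(c("fold_", "q_"), suffix)
    x
  }
  out <- merge(merge(take(a, "input_vs_all"), take(b, "dr_vs_all"), by = key),
               take(c_, "input_vs_dr"), by = key)
  out[order(out$q_input_vs_all), ]
}
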