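## Benchmarking the four measures over the simulation grid --------------------

#' Rejection rule for one measure
#'
#' The chi-square and ANOVA tests reject on their p-value; Fst and NSCM
#' have no p-value and reject when the statistic exceeds a value threshold.
#'
#' @param measure one of `"fst"`, `"chisq"`, `"anova_f"`, `"nscm_ssd"`.
#' @param kind `"p_value_threshold"` (reject when p < threshold) or
#'   `"value_threshold"` (reject when the statistic exceeds the threshold).
#' @param threshold the cutoff; a p-value threshold must lie in (0, 1).
#' @return An object of class `decision_rule`.
#' @export
decision_rule <- function(measure = c("fst", "chisq", "anova_f", "nscm_ssd"),
                          kind = c("p_value_threshold", "value_threshold"),
                          threshold) {
  measure <- match.arg(measure)
  kind <- match.arg(kind)
  if (length(threshold) != 1L || is.na(threshold))
    stop("'threshold' must be a single number", call. = FALSE)
  if (kind == "p_value_threshold" && (threshold <= 0 || threshold >= 1))
    stop("a p-value threshold must lie in (0, 1)", call. = FALSE)
  structure(list(measure = measure, kind = kind, threshold = threshold),
            class = "decision_rule")
}

#' Calibrate the NSCM rejection threshold on null simulations
#'
#' Simulates null panels (`d = 0`) at a reference sample-size configuration
#' and returns an upper quantile of the pooled per-SNP `SS_d` values.  The
#' threshold is calibrated once and then held fixed across all scenarios,
#' so its specificity is exactly `prob` at the reference configuration and
#' may drift elsewhere.
#'
#' @param sample_sizes reference configuration (individuals per population).
#' @param prob quantile of the null `SS_d` distribution to use.
#' @param n_panels,panel_size number and size of the simulated null panels
#'   (the fudge constant `s_0` is the within-panel median of `s_k`, as in a
#'   real analysis).
#' @param seed integer seed for the calibration draws.
#' @return The scalar threshold.
#' @export
calibrate_nscm_threshold <- function(sample_sizes = c(100, 100, 100),
                                     prob = 0.99, n_panels = 100L,
                                     panel_size = 100L, seed = 1L) {
  ssd <- unlist(lapply(seq_len(n_panels), function(b) {
    set.seed(.derive_seed(seed, b))
    p <- make_p_vector(0, panel_size)
    g <- .draw_genotype_matrix(sample_sizes, p)
    .nscm_engine(g$nAA, g$nAa, g$n)$ss_d
  }))
  stats::quantile(ssd, prob, names = FALSE)
}

#' Default rejection rules for the four measures
#'
#' Chi-square and ANOVA reject at `p < alpha`.  Fst rejects when
#' `theta_hat` exceeds Wright's low-divergence boundary (0.05 by default).
#' NSCM rejects when `SS_d` exceeds a null quantile calibrated once at the
#' (100,100,100) reference configuration (see
#' [calibrate_nscm_threshold()]) and held fixed across scenarios.
#'
#' @param alpha significance level of the p-value rules.
#' @param fst_threshold value threshold on `theta_hat`.
#' @param nscm_threshold value threshold on `SS_d`; if `NULL`, calibrated
#'   with `calibration_seed`.
#' @param calibration_seed seed of the NSCM calibration draws.
#' @return Named list of four [decision_rule()] objects.
#' @export
default_decision_rules <- function(alpha = 0.05, fst_threshold = 0.05,
                                   nscm_threshold = NULL,
                                   calibration_seed = 1L) {
  if (is.null(nscm_threshold))
    nscm_threshold <- calibrate_nscm_threshold(seed = calibration_seed)
  list(
    chisq    = decision_rule("chisq", "p_value_threshold", alpha),
    anova_f  = decision_rule("anova_f", "p_value_threshold", alpha),
    fst      = decision_rule("fst", "value_threshold", fst_threshold),
    nscm_ssd = decision_rule("nscm_ssd", "value_threshold", nscm_threshold)
  )
}

## Score one block of simulated datasets with all four measures.
## Returns per-dataset columns; s0 for NSCM is the block-panel median.
.score_block <- function(g) {
  x  <- 2 * g$nAA + g$nAa
  n2 <- 2 * g$n
  fst   <- .fst_engine(x / n2, n2)
  chisq <- .chisq_engine(x, n2)
  anova <- .anova_engine(g$nAA, g$nAa, g$n)
  nscm  <- .nscm_engine(g$nAA, g$nAa, g$n)
  data.frame(
    fst = fst$theta_hat,
    chisq = chisq$statistic, chisq_p = chisq$p_value,
    anova_f = anova$f_stat, anova_f_p = anova$p_value,
    nscm_ssd = nscm$ss_d
  )
}

## TRUE where the rule rejects; NaN statistics never reject (monomorphic
## draws carry no evidence against the null).
.apply_rule <- function(rule, scores) {
  v <- switch(rule$measure,
              chisq = if (rule$kind == "p_value_threshold") scores$chisq_p else scores$chisq,
              anova_f = if (rule$kind == "p_value_threshold") scores$anova_f_p else scores$anova_f,
              fst = scores$fst,
              nscm_ssd = scores$nscm_ssd)
  rej <- if (rule$kind == "p_value_threshold") v < rule$threshold else v > rule$threshold
  rej[is.na(rej)] <- FALSE
  rej
}

#' Distribution study: per-dataset measure values over a scenario grid
#'
#' For every scenario row, simulates `n_datasets` SNPs and scores each with
#' all four measures.  For the p-value measures (chi-square, ANOVA) the
#' display value is `-log10(p)`; for Fst and NSCM it is the raw statistic —
#' the tidy table behind box-plot comparisons of the measures.
#'
#' @param scenarios a data frame from
#'   [scenario_grid()]`("distribution_study")` (or any subset / custom grid
#'   with the same columns).
#' @return A long data frame: `scenario`, `n1`..`n3`, `d`, `dataset`,
#'   `measure`, `value` (raw statistic), `p_value` (NA for Fst/NSCM) and
#'   `display`.
#' @export
run_distribution_study <- function(scenarios = scenario_grid("distribution_study")) {
  .check_scenarios(scenarios)
  out <- lapply(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, ]
    set.seed(sc$seed)
    p <- make_p_vector(sc$d, sc$n_datasets)
    g <- .draw_genotype_matrix(c(sc$n1, sc$n2, sc$n3), p)
    sco <- .score_block(g)
    D <- sc$n_datasets
    data.frame(
      scenario = sc$scenario, n1 = sc$n1, n2 = sc$n2, n3 = sc$n3, d = sc$d,
      dataset = rep(seq_len(D), 4L),
      measure = rep(c("chisq", "anova_f", "fst", "nscm_ssd"), each = D),
      value = c(sco$chisq, sco$anova_f, sco$fst, sco$nscm_ssd),
      p_value = c(sco$chisq_p, sco$anova_f_p, rep(NA_real_, 2L * D)),
      display = c(-log10(sco$chisq_p), -log10(sco$anova_f_p),
                  sco$fst, sco$nscm_ssd),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

.check_scenarios <- function(scenarios) {
  need <- c("scenario", "n1", "n2", "n3", "d", "n_datasets",
            "n_repetitions", "seed")
  if (!is.data.frame(scenarios) || !all(need %in% names(scenarios)))
    stop("'scenarios' must be a scenario grid data frame (see scenario_grid)",
         call. = FALSE)
  invisible(scenarios)
}

#' Sensitivity/specificity study over a scenario grid
#'
#' For every scenario row and every repetition, simulates `n_datasets` SNPs
#' and applies each measure's rejection rule.  With `d = 0` the reported
#' metric is the specificity (fraction of null datasets not rejected); with
#' `d > 0` it is the sensitivity (fraction rejected).  Estimates are means
#' over repetitions with their Monte-Carlo standard errors.  Datasets whose
#' statistic is `NaN` (monomorphic draws) count as non-rejections; their
#' frequency is reported in `nan_rate`.
#'
#' @param scenarios a data frame from
#'   [scenario_grid()]`("sensitivity_specificity")` (or a subset).
#' @param rules named list of [decision_rule()]s covering all four measures
#'   (see [default_decision_rules()]).
#' @return A data frame: `scenario`, `n1`..`n3`, `d`, `measure`, `metric`,
#'   `estimate`, `mc_stderr`, `nan_rate`, `n_repetitions`, `n_datasets`.
#' @export
evaluate_sensitivity_specificity <- function(scenarios, rules) {
  .check_scenarios(scenarios)
  measures <- c("chisq", "anova_f", "fst", "nscm_ssd")
  missing_rules <- setdiff(measures, names(rules))
  if (length(missing_rules))
    stop("missing decision rule for measure(s): ",
         paste(missing_rules, collapse = ", "), call. = FALSE)
  if (!all(vapply(rules[measures], inherits, logical(1), "decision_rule")))
    stop("'rules' must contain decision_rule objects", call. = FALSE)
  out <- lapply(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, ]
    sizes <- c(sc$n1, sc$n2, sc$n3)
    rej <- matrix(NA_real_, sc$n_repetitions, length(measures),
                  dimnames = list(NULL, measures))
    nan <- numeric(sc$n_repetitions)
    for (r in seq_len(sc$n_repetitions)) {
      set.seed(.derive_seed(sc$seed, r))
      p <- make_p_vector(sc$d, sc$n_datasets)
      g <- .draw_genotype_matrix(sizes, p)
      sco <- .score_block(g)
      for (m in measures) rej[r, m] <- mean(.apply_rule(rules[[m]], sco))
      nan[r] <- mean(is.na(sco$fst))
    }
    frac <- if (sc$d == 0) 1 - rej else rej
    data.frame(
      scenario = sc$scenario, n1 = sc$n1, n2 = sc$n2, n3 = sc$n3, d = sc$d,
      measure = measures,
      metric = if (sc$d == 0) "specificity" else "sensitivity",
      estimate = colMeans(frac),
      mc_stderr = apply(frac, 2, stats::sd) / sqrt(sc$n_repetitions),
      nan_rate = mean(nan),
      n_repetitions = sc$n_repetitions, n_datasets = sc$n_datasets,
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  do.call(rbind, out)
}

#' Rank the measures by sensitivity and flag the headline orderings
#'
#' Orders the measures by estimated sensitivity within each
#' (sample sizes, d) cell and evaluates three headline claims within
#' Monte-Carlo error (two combined standard errors): (i) Fst has the
#' highest sensitivity at the small balanced configuration (100,100,100)
#' for small `d` (0.05, 0.1); (ii) NSCM has the lowest sensitivity in every
#' cell; (iii) the two edge-unbalanced designs (200,100,100) and
#' (100,100,200) have equal sensitivities.
#'
#' @param results output of [evaluate_sensitivity_specificity()] covering
#'   all four measures on a common grid.
#' @return A list of class `measure_ranking` with elements `rankings`
#'   (long data frame with per-cell ranks) and `headlines` (data frame
#'   `claim`, `pass`).
#' @export
rank_measures <- function(results) {
  sens <- results[results$metric == "sensitivity", , drop = FALSE]
  if (nrow(sens) == 0L)
    stop("no sensitivity rows in 'results'", call. = FALSE)
  cell <- interaction(sens$n1, sens$n2, sens$n3, sens$d, drop = TRUE)
  if (any(tapply(sens$measure, cell, function(m) length(unique(m))) != 4L))
    stop("incomplete grid: every (sizes, d) cell needs all four measures",
         call. = FALSE)
  sens$rank <- stats::ave(-sens$estimate, cell, FUN = rank)

  ge_within <- function(a, b)  # a >= b within 2 combined MC standard errors
    a$estimate >= b$estimate - 2 * sqrt(a$mc_stderr^2 + b$mc_stderr^2)
  pick <- function(n1, n2, n3, d, m)
    sens[sens$n1 == n1 & sens$n2 == n2 & sens$n3 == n3 &
         sens$d == d & sens$measure == m, ]

  cells <- unique(sens[, c("n1", "n2", "n3", "d")])
  others <- c("chisq", "anova_f", "nscm_ssd")

  fst_top <- TRUE
  has_small <- FALSE
  for (d in intersect(c(0.05, 0.1), cells$d)) {
    if (nrow(pick(100, 100, 100, d, "fst")) == 0L) next
    has_small <- TRUE
    a <- pick(100, 100, 100, d, "fst")
    for (m in others)
      fst_top <- fst_top && ge_within(a, pick(100, 100, 100, d, m))
  }
  if (!has_small) fst_top <- NA

  nscm_low <- TRUE
  for (i in seq_len(nrow(cells))) {
    b <- pick(cells$n1[i], cells$n2[i], cells$n3[i], cells$d[i], "nscm_ssd")
    for (m in c("chisq", "anova_f", "fst"))
      nscm_low <- nscm_low &&
        ge_within(pick(cells$n1[i], cells$n2[i], cells$n3[i], cells$d[i], m), b)
  }

  sym <- NA
  sym_d <- unique(cells$d[cells$n1 == 200 & cells$n3 == 100])
  sym_d <- intersect(sym_d, cells$d[cells$n1 == 100 & cells$n3 == 200])
  if (length(sym_d)) {
    sym <- TRUE
    for (d in sym_d) for (m in c(others, "fst")) {
      a <- pick(200, 100, 100, d, m); b <- pick(100, 100, 200, d, m)
      sym <- sym && ge_within(a, b) && ge_within(b, a)
    }
  }

  structure(
    list(rankings = sens[order(sens$n1, sens$n2, sens$n3, sens$d, sens$rank), ],
         headlines = data.frame(
           claim = c("fst_highest_sensitivity_small_n_small_d",
                     "nscm_lowest_sensitivity_everywhere",
                     "edge_unbalanced_designs_equivalent"),
           pass = c(fst_top, nscm_low, sym))),
    class = "measure_ranking"
  )
}

#' @export
print.measure_ranking <- function(x, ...) {
  cat("Measure ranking over", nrow(unique(x$rankings[, c("n1","n2","n3","d")])),
      "grid cells\n")
  print(x$headlines, row.names = FALSE)
  invisible(x)
}
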