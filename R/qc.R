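# RNA-quality analyses: correlation of degradation covariates (DV200, RIN,
# block age, RNA yield) with sequencing/mapping metrics, and DV200-
# stratified summaries of the mapping metrics.

#' Correlation table of QC covariates and mapping metrics
#'
#' Spearman rho and two-sided p for every (covariate, metric) pair and for
#' every covariate-covariate pair (DV200 vs RIN, DV200 vs block age, ...),
#' using pairwise-complete observations. Delegates to [spearman_cor()].
#' Pairs with fewer than `min_n` complete observations, or an all-missing
#' column, are skipped with a note row.
#'
#' @param sample_sheet Sample sheet carrying the columns.
#' @param covariates Quality covariate columns (default DV200, RIN, block
#'   age, RNA yield).
#' @param metrics Mapping metric columns (default input reads,
#'   uniquely-mapped %, multimapped %).
#' @param min_n Minimum complete pairs (default 3).
#' @return A tibble with columns `var_1`, `var_2`, `rho`, `p`, `n`, `note`.
#' @export
qc_correlation_table <- function(sample_sheet,
                                 covariates = c("dv200", "rin",
                                                "block_age_years",
                                                "rna_yield_ng"),
                                 metrics = c("input_reads",
                                             "uniquely_mapped_pct",
                                             "multimapped_pct"),
                                 min_n = 3) {
  covariates <- intersect(covariates, names(sample_sheet))
  metrics <- intersect(metrics, names(sample_sheet))
  if (length(covariates) == 0) abort("No covariate columns present.")
  pairs <- c(
    if (length(covariates) > 1) utils::combn(covariates, 2, simplify = FALSE),
    unlist(lapply(covariates, function(cv) lapply(metrics, function(mt)
      c(cv, mt))), recursive = FALSE))
  purrr::map_dfr(pairs, function(pr) {
    x <- sample_sheet[[pr[1]]]; y <- sample_sheet[[pr[2]]]
    n_complete <- sum(stats::complete.cases(x, y))
    if (n_complete < min_n) {
      return(tibble(var_1 = pr[1], var_2 = pr[2], rho = NA_real_,
                    p = NA_real_, n = n_complete,
                    note = "fewer complete pairs than minimum"))
    }
    r <- spearman_cor(x, y)
    tibble(var_1 = pr[1], var_2 = pr[2], rho = r$rho, p = r$p, n = r$n,
           note = r$note)
  })
}

#' DV200-stratified summary of mapping metrics
#'
#' Bins FFPE samples by DV200 at the given cutpoints (default a single cut
#' at 30, the level below which extra PCR cycles are commonly added),
#' reports per-stratum n, median and IQR of each metric, and a
#' rank-sum comparison (two-sided Wilcoxon) between adjacent strata.
#'
#' @param sample_sheet Sample sheet with `dv200` and the metric columns.
#' @param dv200_bins Interior cutpoints (default `c(30)`).
#' @param metrics Metric columns to summarise.
#' @return A list with `summary` (per-stratum tibble) and `tests`
#'   (adjacent-strata Wilcoxon results).
#' @export
stratified_qc_summary <- function(sample_sheet, dv200_bins = c(30),
                                  metrics = c("input_reads",
                                              "uniquely_mapped_pct",
                                              "multimapped_pct")) {
  if (!"dv200" %in% names(sample_sheet)) abort("Sheet lacks a `dv200` column.")
  metrics <- intersect(metrics, names(sample_sheet))
  sheet <- sample_sheet[!is.na(sample_sheet$dv200), ]
  breaks <- c(-Inf, sort(dv200_bins), Inf)
  sheet$stratum <- cut(sheet$dv200, breaks = breaks)
  strata <- levels(sheet$stratum)
  summary <- purrr::map_dfr(strata, function(st) {
    d <- sheet[sheet$stratum == st, ]
    purrr::map_dfr(metrics, function(met) {
      v <- d[[met]][!is.na(d[[met]])]
      tibble(stratum = st, metric = met, n = length(v),
             median = if (length(v)) median(v) else NA_real_,
             q1 = if (length(v)) unname(quantile(v, 0.25, type = 7)) else NA_real_,
             q3 = if (length(v)) unname(quantile(v, 0.75, type = 7)) else NA_real_)
    })
  })
  tests <- purrr::map_dfr(seq_len(length(strata) - 1), function(i) {
    purrr::map_dfr(metrics, function(met) {
      x <- sheet[[met]][sheet$stratum == strata[i]]
      y <- sheet[[met]][sheet$stratum == strata[i + 1]]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < 2 || length(y) < 2) {
        return(tibble(stratum_1 = strata[i], stratum_2 = strata[i + 1],
                      metric = met, statistic = NA_real_, p = NA_real_,
                      note = "empty or near-empty stratum"))
      }
      w <- suppressWarnings(wilcox.test(x, y))
      tibble(stratum_1 = strata[i], stratum_2 = strata[i + 1], metric = met,
             statistic = unname(w$statistic), p = w$p.value,
             note = NA_character_)
    })
  })
  list(summary = summary, tests = tests)
}
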