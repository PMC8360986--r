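# Cohort-referenced expression-outlier calling.
#
# A gene is an outlier in a sample when, relative to a large reference
# cohort, all three of the following hold:
#   (1) z-score (FPKM - cohort mean) / cohort SD  >= z_min   (default 2),
#   (2) FPKM >= fpkm_min                                     (default 20),
#   (3) FPKM above the upper Tukey fence q3 + iqr_mult * IQR (default 1.5).
# The criteria are conjunctive, and the fence is one-sided (overexpression
# is the clinically relevant direction). z-scores are computed on raw FPKM.

#' Per-gene cohort statistics for outlier scoring
#'
#' Computes mean, SD and quartiles of each panel gene across a reference
#' cohort. Quartiles use the inclusive linear-interpolation convention
#' (R's `quantile(type = 7)`). Genes with zero cohort SD are flagged
#' `degenerate` and are never called as outliers. Panel genes absent from
#' the cohort are reported with a warning and excluded.
#'
#' @param ref Reference cohort expression tibble (`gene_id` + samples).
#' @param panel Optional character vector of genes to retain (e.g. a
#'   druggable-cancer panel); `NULL` keeps every gene.
#' @return A tibble with columns `gene`, `mean`, `sd`, `q1`, `q3`, `iqr`,
#'   `n`, `degenerate`.
#' @export
compute_cohort_stats <- function(ref, panel = NULL) {
  check_expression_tbl(ref, "ref")
  m <- expr_to_matrix(ref)
  if (ncol(m) < 2) abort("Reference cohort must contain at least 2 samples.")
  if (!is.null(panel)) {
    missing <- setdiff(panel, rownames(m))
    if (length(missing)) {
      warn(sprintf("%d panel gene(s) absent from the cohort and excluded: %s",
                   length(missing),
                   paste(head(missing, 5), collapse = ", ")))
    }
    m <- m[intersect(panel, rownames(m)), , drop = FALSE]
    if (nrow(m) == 0) abort("No panel genes present in the reference cohort.")
  }
  q <- t(apply(m, 1, quantile, probs = c(0.25, 0.75), type = 7, names = FALSE))
  sdv <- apply(m, 1, sd)
  tibble(
    gene = rownames(m),
    mean = unname(rowMeans(m)),
    sd = unname(sdv),
    q1 = unname(q[, 1]),
    q3 = unname(q[, 2]),
    iqr = unname(q[, 2] - q[, 1]),
    n = ncol(m),
    degenerate = unname(sdv == 0)
  )
}

#' Call cohort-referenced expression outliers
#'
#' Scores every (gene, sample) of `matrix` whose gene has cohort statistics
#' and returns one call record per pair with the three criterion flags and
#' their conjunction. Genes present in the matrix but absent from `stats`
#' are skipped with a warning; degenerate (zero-SD) genes get `z = NaN` and
#' are never outliers.
#'
#' @param matrix Expression tibble to score.
#' @param stats Output of [compute_cohort_stats()].
#' @param z_min Minimum z-score (default 2).
#' @param fpkm_min Minimum FPKM (default 20).
#' @param iqr_mult Tukey fence multiplier (default 1.5).
#' @param platform Optional platform label carried into the calls.
#' @return A tibble with columns `gene`, `sample`, `platform`, `fpkm`, `z`,
#'   `passes_z`, `passes_fpkm`, `passes_iqr`, `is_outlier`.
#' @export
call_outliers <- function(matrix, stats, z_min = 2, fpkm_min = 20,
                          iqr_mult = 1.5, platform = NA_character_) {
  check_expression_tbl(matrix)
  check_scalar(z_min, "z_min")
  check_scalar(fpkm_min, "fpkm_min")
  check_scalar(iqr_mult, "iqr_mult", 0)
  m <- expr_to_matrix(matrix)
  shared <- intersect(stats$gene, rownames(m))
  if (length(shared) == 0) abort("No gene of `matrix` has cohort statistics.")
  only_matrix <- setdiff(rownames(m), stats$gene)
  if (length(only_matrix)) {
    warn(sprintf("%d gene(s) without cohort statistics skipped (e.g. %s).",
                 length(only_matrix), head(only_matrix, 1)))
  }
  st <- stats[match(shared, stats$gene), ]
  mm <- m[shared, , drop = FALSE]
  long <- tibble(
    gene = rep(shared, times = ncol(mm)),
    sample = rep(colnames(mm), each = length(shared)),
    platform = platform,
    fpkm = as.vector(mm))
  idx <- match(long$gene, st$gene)
  mean_ <- st$mean[idx]; sd_ <- st$sd[idx]
  fence <- st$q3[idx] + iqr_mult * st$iqr[idx]
  degen <- st$degenerate[idx]
  z <- ifelse(degen, NaN, (long$fpkm - mean_) / sd_)
  long$z <- z
  long$passes_z <- !degen & z >= z_min
  long$passes_fpkm <- long$fpkm >= fpkm_min
  long$passes_iqr <- long$fpkm > fence
  long$is_outlier <- long$passes_z & long$passes_fpkm & long$passes_iqr
  long
}

#' Cross-platform concordance of outlier calls
#'
#' For each non-reference platform, the percentage of reference-positive
#' (gene, patient) pairs that are also positive on that platform, together
#' with the symmetric Jaccard index of the positive sets. Pairs whose
#' patient lacks a sample on either platform are excluded from the
#' denominator. A reference with zero positives yields an empty result
#' with a note attribute.
#'
#' @param calls A tibble of outlier calls from [call_outliers()] for all
#'   platforms (rows carry a `platform` column), or a named list of per-
#'   platform call tibbles.
#' @param sample_sheet Sample sheet mapping `sample_id` to `patient` and
#'   `platform`.
#' @param reference Name of the reference platform.
#' @return A tibble with columns `platform`, `n_reference_positive`,
#'   `n_concordant`, `concordance_pct`, `jaccard`.
#' @export
outlier_concordance <- function(calls, sample_sheet, reference) {
  if (is.list(calls) && !is.data.frame(calls)) {
    calls <- bind_rows(purrr::imap(calls, function(x, pf) {
      x$platform <- pf
      x
    }))
  }
  if (!reference %in% calls$platform) {
    abort(sprintf("Reference platform '%s' has no calls.", reference))
  }
  calls <- left_join(calls,
                     sample_sheet[, c("sample_id", "patient")],
                     by = c(sample = "sample_id"))
  if (anyNA(calls$patient)) {
    abort("Some call samples are absent from the sample sheet.")
  }
  pos <- calls[calls$is_outlier, c("platform", "gene", "patient")]
  ref_pos <- pos[pos$platform == reference, c("gene", "patient")]
  platforms <- setdiff(unique(calls$platform), reference)
  present <- unique(sample_sheet[, c("patient", "platform")])
  if (nrow(ref_pos) == 0) {
    out <- tibble(platform = character(), n_reference_positive = integer(),
                  n_concordant = integer(), concordance_pct = numeric(),
                  jaccard = numeric())
    attr(out, "note") <- "Reference platform has no positive calls; concordance undefined."
    return(out)
  }
  res <- purrr::map_dfr(platforms, function(pf) {
    pf_patients <- present$patient[present$platform == pf]
    eligible <- ref_pos[ref_pos$patient %in% pf_patients, ]
    pf_pos <- pos[pos$platform == pf, c("gene", "patient")]
    key <- function(d) paste(d$gene, d$patient)
    hit <- key(eligible) %in% key(pf_pos)
    ref_patients <- present$patient[present$platform == reference]
    pf_pos_eligible <- pf_pos[pf_pos$patient %in% ref_patients, ]
    uni <- union(key(eligible), key(pf_pos_eligible))
    tibble(platform = pf,
           n_reference_positive = nrow(eligible),
           n_concordant = sum(hit),
           concordance_pct = if (nrow(eligible)) 100 * mean(hit) else NA_real_,
           jaccard = if (length(uni)) {
             length(intersect(key(eligible), key(pf_pos_eligible))) / length(uni)
           } else NA_real_)
  })
  res
}
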