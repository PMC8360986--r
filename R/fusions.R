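# Fusion-detection concordance: evidence filtering, cross-platform
# detection matrices against a reference fusion set, and the correlation
# between junction-read support and fusion-transcript expression.

#' Filter fusion candidates by read support
#'
#' Keeps rows with `junction_reads >= min_junction` and
#' `spanning_pairs >= min_spanning` (both inclusive, defaults 1 and 1),
#' preserving row order. Filtering is idempotent and monotone: raising a
#' threshold never adds rows.
#'
#' @param table A fusion-call tibble (see [read_fusion_table()]).
#' @param min_junction Minimum junction reads (default 1).
#' @param min_spanning Minimum spanning pairs (default 1).
#' @return The filtered tibble.
#' @export
filter_fusion_calls <- function(table, min_junction = 1, min_spanning = 1) {
  if (min_junction < 0 || min_spanning < 0) {
    abort("Fusion filter thresholds must be non-negative.")
  }
  validate_fusion_table(table)
  table[table$junction_reads >= min_junction &
          table$spanning_pairs >= min_spanning, ]
}

#' Cross-platform fusion detection matrix
#'
#' For every fusion of the reference set (identified by patient and the
#' ordered 5'->3' gene pair) and every platform, reports `detected` when a
#' filtered call with the same identity exists on that platform,
#' `no_sample` when the sample sheet has no sample for that (patient,
#' platform), and `not_detected` otherwise. Per-platform sensitivity is
#' `detected / (fusions - no_sample)`.
#'
#' @param tables Fusion calls for all platforms (single tibble with a
#'   `platform` column, or a named list). These should already be
#'   support-filtered (see [filter_fusion_calls()]).
#' @param reference_set Tibble of reference fusions with columns `patient`,
#'   `gene5`, `gene3` — typically the filtered reference-platform table or
#'   a curated truth list.
#' @param sample_sheet Sample sheet declaring which (patient, platform)
#'   samples exist.
#' @param platforms Platforms to report (default: those in the sheet).
#' @return A list with `matrix` (tibble: `patient`, `fusion`, `platform`,
#'   `status`) and `sensitivity` (tibble: `platform`, `n_detected`,
#'   `n_evaluable`, `sensitivity_pct`).
#' @export
build_detection_matrix <- function(tables, reference_set, sample_sheet,
                                   platforms = NULL) {
  if (is.list(tables) && !is.data.frame(tables)) {
    tables <- bind_rows(purrr::imap(tables, function(x, pf) {
      x$platform <- pf
      x
    }))
  }
  if (nrow(reference_set) == 0) abort("Reference fusion set is empty.")
  ref <- distinct(as_tibble(reference_set)[, c("patient", "gene5", "gene3")])
  ref$fusion <- paste0(ref$gene5, "::", ref$gene3)
  if (is.null(platforms)) platforms <- unique(sample_sheet$platform)
  present <- unique(paste(sample_sheet$patient, sample_sheet$platform))
  call_key <- paste(tables$patient, tables$platform,
                    tables$gene5, tables$gene3)
  grid <- tidyr::crossing(ref, platform = platforms)
  grid$status <- dplyr::case_when(
    !paste(grid$patient, grid$platform) %in% present ~ "no_sample",
    paste(grid$patient, grid$platform, grid$gene5, grid$gene3) %in%
      call_key ~ "detected",
    TRUE ~ "not_detected")
  mat <- grid[, c("patient", "fusion", "platform", "status")] |>
    arrange(.data$patient, .data$fusion, .data$platform)
  sens <- mat |>
    group_by(.data$platform) |>
    summarise(
      n_detected = sum(.data$status == "detected"),
      n_evaluable = sum(.data$status != "no_sample"),
      sensitivity_pct = ifelse(.data$n_evaluable > 0,
                               100 * .data$n_detected / .data$n_evaluable,
                               NA_real_),
      .groups = "drop")
  list(matrix = mat, sensitivity = sens)
}

#' Correlation of junction-read support with fusion expression
#'
#' Spearman correlation between `junction_reads` and `fusion_fpkm`,
#' within each platform and pooled over all rows. Groups with fewer than
#' 3 fusions are reported as undefined with a note. Delegates to
#' [spearman_cor()] (one source of truth for rank correlations).
#'
#' @param table A fusion-call tibble.
#' @param group_by_platform Also report per-platform correlations
#'   (default `TRUE`).
#' @return A tibble with columns `platform` (`"pooled"` for the pooled
#'   row), `rho`, `p`, `n`, `note`.
#' @export
junction_expression_correlation <- function(table, group_by_platform = TRUE) {
  validate_fusion_table(table)
  one <- function(d, label) {
    r <- spearman_cor(d$junction_reads, d$fusion_fpkm)
    tibble(platform = label, rho = r$rho, p = r$p, n = r$n,
           note = if ("note" %in% names(r)) r$note else NA_character_)
  }
  out <- one(table, "pooled")
  if (group_by_platform) {
    per <- purrr::map_dfr(unique(table$platform), function(pf) {
      one(table[table$platform == pf, ], pf)
    })
    out <- bind_rows(per, out)
  }
  out
}
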