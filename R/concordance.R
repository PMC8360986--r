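# Expression concordance between platforms: Spearman correlation (global,
# per patient, and panel-restricted), gene-detection overlap, density-peak
# characterization of the FPKM distribution, and rank-based comparison of
# mapping statistics.

#' Log-transform an expression matrix
#'
#' Entrywise `log2(FPKM + pseudocount)`. The transform is strictly
#' monotone, so every rank statistic downstream (Spearman, Wilcoxon,
#' Kruskal-Wallis) is unchanged by it; it matters only for densities,
#' summaries and display.
#'
#' @param matrix Expression tibble.
#' @param pseudocount Positive offset added before the log (default 1, so
#'   0 FPKM maps to 0).
#' @return An expression tibble on the log2 scale.
#' @export
log_transform <- function(matrix, pseudocount = 1) {
  check_expression_tbl(matrix)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0) {
    abort("`pseudocount` must be a single positive number.")
  }
  mutate(matrix, across(-"gene_id", ~ log2(.x + pseudocount)))
}

#' Spearman rank correlation with paired-observation handling
#'
#' Midrank tie handling; pairs with a missing value in either vector are
#' dropped. Two-sided p-values come from the exact permutation null for
#' n <= 10 (when there are no ties) and from the t-approximation
#' otherwise. With fewer than 3 complete pairs the result is undefined
#' (`NA` with a note).
#'
#' @param x,y Paired numeric vectors.
#' @return A one-row tibble with columns `rho`, `p`, `n` (and a `note`
#'   column when the result is undefined).
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) {
    return(tibble(rho = NA_real_, p = NA_real_, n = n,
                  note = "fewer than 3 complete pairs"))
  }
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(rho = NA_real_, p = NA_real_, n = n,
                  note = "constant input"))
  }
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = n <= 10, continuity = FALSE))
  # estimate via Pearson on midranks (tie-corrected); cor.test's S-based
  # estimate can drift by machine epsilon
  rho <- cor(x, y, method = "spearman")
  tibble(rho = max(-1, min(1, rho)), p = ct$p.value, n = n,
         note = NA_character_)
}

# Matched sample pairs for one patient across two platforms.
matched_pairs <- function(sample_sheet, platform_a, platform_b) {
  a <- sample_sheet[sample_sheet$platform == platform_a,
                    c("patient", "sample_id")]
  b <- sample_sheet[sample_sheet$platform == platform_b,
                    c("patient", "sample_id")]
  inner_join(a, b, by = "patient", suffix = c("_1", "_2"))
}

#' Within-patient cross-platform correlation matrix
#'
#' For every patient and every (ordered) platform pair, the Spearman
#' correlation of the two samples' expression over the shared gene set —
#' the within-patient analogue of a platform-concordance heatmap. Patients
#' lacking a sample on a platform simply yield no row for that pair
#' (absent, never zero).
#'
#' @param matrices Named list of expression tibbles, one per platform.
#' @param sample_sheet Sample sheet with `sample_id`, `patient`, `platform`.
#' @param log_first Log-transform before correlating (rank statistics are
#'   unaffected; kept for interface symmetry). Default `FALSE`.
#' @param min_fpkm Optional detection filter: genes with FPKM below this in
#'   both samples of a pair are dropped. Default 0 keeps all shared genes.
#' @return A tibble with columns `patient`, `platform_1`, `platform_2`,
#'   `sample_1`, `sample_2`, `rho`, `p`, `n`.
#' @export
platform_correlation_matrix <- function(matrices, sample_sheet,
                                        log_first = FALSE, min_fpkm = 0) {
  stopifnot(is.list(matrices), !is.null(names(matrices)))
  if (log_first) matrices <- lapply(matrices, log_transform)
  mats <- lapply(matrices, expr_to_matrix)
  platforms <- names(mats)
  combos <- utils::combn(platforms, 2, simplify = FALSE)
  purrr::map_dfr(combos, function(pr) {
    shared <- intersect(rownames(mats[[pr[1]]]), rownames(mats[[pr[2]]]))
    pairs <- matched_pairs(sample_sheet, pr[1], pr[2])
    purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
      v1 <- mats[[pr[1]]][shared, pairs$sample_id_1[i]]
      v2 <- mats[[pr[2]]][shared, pairs$sample_id_2[i]]
      if (min_fpkm > 0) {
        keep <- v1 >= min_fpkm | v2 >= min_fpkm
        v1 <- v1[keep]; v2 <- v2[keep]
      }
      r <- spearman_cor(v1, v2)
      tibble(patient = pairs$patient[i],
             platform_1 = pr[1], platform_2 = pr[2],
             sample_1 = pairs$sample_id_1[i], sample_2 = pairs$sample_id_2[i],
             rho = r$rho, p = r$p, n = r$n)
    })
  })
}

#' Panel-restricted concordance with the reference platform
#'
#' Two modes. `by = "gene"`: for each panel gene, the Spearman correlation
#' across matched patients between its reference-platform expression and
#' its expression on each capture platform (the per-gene immune-panel
#' analysis). `by = "sample"`: for each matched sample pair, the
#' correlation across panel genes. Genes/pairs with fewer than 3 complete
#' observations are skipped with a note row (`rho = NA`).
#'
#' @param matrices Named list of expression tibbles.
#' @param sample_sheet Sample sheet.
#' @param panel Character vector of panel genes.
#' @param reference Reference platform name.
#' @param by `"gene"` or `"sample"`.
#' @return A tibble of correlations; see
#'   [panel_correlation_summary()] for the per-platform median-rho ranking.
#' @export
panel_correlation <- function(matrices, sample_sheet, panel, reference,
                              by = c("gene", "sample")) {
  by <- match.arg(by)
  stopifnot(reference %in% names(matrices))
  mats <- lapply(matrices, expr_to_matrix)
  platforms <- setdiff(names(mats), reference)
  purrr::map_dfr(platforms, function(pf) {
    shared_genes <- intersect(intersect(panel, rownames(mats[[reference]])),
                              rownames(mats[[pf]]))
    pairs <- matched_pairs(sample_sheet, reference, pf)
    if (by == "gene") {
      purrr::map_dfr(shared_genes, function(g) {
        v1 <- mats[[reference]][g, pairs$sample_id_1]
        v2 <- mats[[pf]][g, pairs$sample_id_2]
        r <- spearman_cor(v1, v2)
        tibble(platform = pf, gene = g, rho = r$rho, p = r$p, n = r$n,
               note = r$note)
      })
    } else {
      purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
        v1 <- mats[[reference]][shared_genes, pairs$sample_id_1[i]]
        v2 <- mats[[pf]][shared_genes, pairs$sample_id_2[i]]
        r <- spearman_cor(v1, v2)
        tibble(platform = pf, patient = pairs$patient[i],
               rho = r$rho, p = r$p, n = r$n, note = r$note)
      })
    }
  })
}

#' @param correlations Output of [panel_correlation()].
#' @rdname panel_correlation
#' @export
panel_correlation_summary <- function(correlations) {
  correlations |>
    group_by(.data$platform) |>
    summarise(median_rho = median(.data$rho, na.rm = TRUE),
              n = sum(!is.na(.data$rho)), .groups = "drop") |>
    arrange(dplyr::desc(.data$median_rho))
}

#' Gene-detection overlap across platforms
#'
#' A gene counts as detected on a platform when its FPKM exceeds
#' `detect_min_fpkm` in at least `detect_min_samples` samples. Returns the
#' number of genes detected on all platforms, the platform-exclusive
#' counts, and the union, plus the full per-gene detection pattern.
#'
#' @param matrices Named list of expression tibbles (>= 2).
#' @param detect_min_fpkm Detection threshold (strict; default 0).
#' @param detect_min_samples Minimum number of samples above threshold.
#' @return A list with `summary` (tibble: `category`, `n`) and `patterns`
#'   (per-gene logical detection tibble); thresholds kept as attributes.
#' @export
gene_detection_overlap <- function(matrices, detect_min_fpkm = 0,
                                   detect_min_samples = 1) {
  stopifnot(is.list(matrices), length(matrices) >= 2)
  detected <- lapply(matrices, function(x) {
    m <- expr_to_matrix(x)
    rownames(m)[rowSums(m > detect_min_fpkm) >= detect_min_samples]
  })
  all_genes <- sort(unique(unlist(detected)))
  pat <- tibble(gene = all_genes)
  for (pf in names(detected)) pat[[pf]] <- all_genes %in% detected[[pf]]
  pmat <- as.matrix(pat[names(detected)])
  shared <- sum(rowSums(pmat) == length(detected))
  uniq <- vapply(seq_along(detected), function(i) {
    sum(pmat[, i] & rowSums(pmat) == 1)
  }, numeric(1))
  summary <- tibble(
    category = c("shared_all", paste0("unique_", names(detected)), "union"),
    n = c(shared, uniq, length(all_genes)))
  structure(list(summary = summary, patterns = pat),
            detect_min_fpkm = detect_min_fpkm,
            detect_min_samples = detect_min_samples,
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("<overlap_summary> detection: FPKM >", attr(x, "detect_min_fpkm"),
      "in >=", attr(x, "detect_min_samples"), "sample(s)\n")
  print(x$summary)
  invisible(x)
}

#' Density peaks of the pooled expression distribution
#'
#' Pools all matrix entries, log-transforms them (`log2(FPKM + 1)`), fits a
#' Gaussian kernel density (Silverman's rule-of-thumb bandwidth unless
#' given) and reports strict local maxima whose density exceeds 5% of the
#' global maximum — a check that a matrix shows the bimodal
#' zero-peak/expressed-peak structure typical of FPKM distributions.
#'
#' @param matrix Expression tibble with at least 100 values.
#' @param bandwidth Optional kernel bandwidth on the log2 scale.
#' @param n_grid Density grid size (default 512).
#' @param min_rel_height Minimum peak height relative to the global
#'   maximum (default 0.05).
#' @return A tibble with columns `peak_log2`, `peak_fpkm`, `density`,
#'   sorted by location.
#' @export
expression_peaks <- function(matrix, bandwidth = NULL, n_grid = 512,
                             min_rel_height = 0.05) {
  check_expression_tbl(matrix)
  v <- as.vector(expr_to_matrix(matrix))
  if (length(v) < 100) abort("Need at least 100 values for a density estimate.")
  lv <- log2(v + 1)
  if (length(unique(lv)) == 1) {
    return(tibble(peak_log2 = lv[1], peak_fpkm = 2^lv[1] - 1, density = Inf))
  }
  d <- if (is.null(bandwidth)) {
    density(lv, bw = "nrd0", n = n_grid)
  } else {
    density(lv, bw = bandwidth, n = n_grid)
  }
  y <- d$y
  k <- length(y)
  is_peak <- c(FALSE, y[2:(k - 1)] > y[1:(k - 2)] & y[2:(k - 1)] > y[3:k],
               FALSE)
  # the zero spike sits at the grid edge; treat a boundary maximum as a peak
  is_peak[1] <- y[1] > y[2]
  is_peak[k] <- y[k] > y[k - 1]
  is_peak <- is_peak & y > min_rel_height * max(y)
  tibble(peak_log2 = d$x[is_peak], peak_fpkm = 2^d$x[is_peak] - 1,
         density = y[is_peak]) |>
    arrange(.data$peak_log2)
}

#' Rank-based comparison of mapping statistics between platforms
#'
#' For a given metric column of the sample sheet, runs the Kruskal-Wallis
#' omnibus test across platforms and pairwise Wilcoxon signed-rank tests
#' (paired within patient) for every platform pair. All tests are
#' two-sided; p-values are reported raw (no multiple-testing correction)
#' with an optional Benjamini-Hochberg column.
#'
#' @param sample_sheet Sample sheet containing the metric column.
#' @param metrics Character vector of metric column names (default the
#'   mapping trio: input reads, uniquely-mapped %, multimapped %).
#' @param group Grouping column (default `"platform"`).
#' @param paired Use the signed-rank test on within-patient pairs (default
#'   `TRUE`); unpairable samples raise an error listing them.
#' @param adjust Add a BH-adjusted p column across the pairwise tests.
#' @return A tibble with columns `metric`, `test`, `group_1`, `group_2`,
#'   `statistic`, `p` (and `p_adj` when `adjust = TRUE`).
#' @export
compare_mapping_stats <- function(sample_sheet,
                                  metrics = c("input_reads",
                                              "uniquely_mapped_pct",
                                              "multimapped_pct"),
                                  group = "platform", paired = TRUE,
                                  adjust = FALSE) {
  miss <- setdiff(c(metrics, group), names(sample_sheet))
  if (length(miss)) {
    abort(paste("Sample sheet lacks column(s):", paste(miss, collapse = ", ")))
  }
  groups <- unique(sample_sheet[[group]])
  if (length(groups) < 2) abort("Need at least two groups to compare.")
  out <- purrr::map_dfr(metrics, function(met) {
    vals <- sample_sheet[[met]]
    kw <- kruskal.test(vals ~ factor(sample_sheet[[group]]))
    omni <- tibble(metric = met, test = "kruskal-wallis",
                   group_1 = NA_character_, group_2 = NA_character_,
                   statistic = unname(kw$statistic), p = kw$p.value)
    combos <- utils::combn(as.character(groups), 2, simplify = FALSE)
    pw <- purrr::map_dfr(combos, function(pr) {
      if (paired) {
        pairs <- matched_pairs(sample_sheet[, c("patient", "sample_id",
                                                group)] |>
                                 rename(platform = dplyr::all_of(group)),
                               pr[1], pr[2])
        x <- vals[match(pairs$sample_id_1, sample_sheet$sample_id)]
        y <- vals[match(pairs$sample_id_2, sample_sheet$sample_id)]
        keep <- stats::complete.cases(x, y)
        x <- x[keep]; y <- y[keep]
        if (length(x) < 3) {
          return(tibble(metric = met, test = "wilcoxon-signed-rank",
                        group_1 = pr[1], group_2 = pr[2],
                        statistic = NA_real_, p = NA_real_))
        }
        if (all(x == y)) {
          # no signed ranks favouring either platform: no evidence at all
          w <- list(statistic = 0, p.value = 1)
        } else {
          w <- suppressWarnings(wilcox.test(x, y, paired = TRUE))
        }
      } else {
        g <- sample_sheet[[group]]
        x <- vals[g == pr[1]]; y <- vals[g == pr[2]]
        if (all(x[!is.na(x)] %in% y[!is.na(y)]) && identical(sort(x), sort(y))) {
          w <- list(statistic = NA_real_, p.value = 1)
        } else {
          w <- suppressWarnings(wilcox.test(x, y))
        }
      }
      tibble(metric = met, test = "wilcoxon-signed-rank",
             group_1 = pr[1], group_2 = pr[2],
             statistic = unname(w$statistic), p = w$p.value)
    })
    bind_rows(omni, pw)
  })
  if (adjust) {
    is_pw <- out$test != "kruskal-wallis"
    out$p_adj <- NA_real_
    out$p_adj[is_pw] <- stats::p.adjust(out$p[is_pw], method = "BH")
  }
  out
}
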