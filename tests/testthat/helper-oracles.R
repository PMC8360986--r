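# Independent oracles and small fixture builders used across tests.

# Brute-force outlier caller: naive loops, no shared code with the
# implementation. Quartiles via the same stated convention (inclusive
# linear interpolation, quantile type 7).
brute_force_outliers <- function(cohort_mat, obs_mat, z_min, fpkm_min,
                                 iqr_mult) {
  out <- list()
  for (g in rownames(obs_mat)) {
    ref <- cohort_mat[g, ]
    mu <- sum(ref) / length(ref)
    sdv <- sqrt(sum((ref - mu)^2) / (length(ref) - 1))
    q1 <- unname(quantile(ref, 0.25, type = 7))
    q3 <- unname(quantile(ref, 0.75, type = 7))
    fence <- q3 + iqr_mult * (q3 - q1)
    for (s in colnames(obs_mat)) {
      v <- obs_mat[g, s]
      if (sdv == 0) {
        flag <- FALSE
      } else {
        flag <- ((v - mu) / sdv >= z_min) && (v >= fpkm_min) && (v > fence)
      }
      out[[length(out) + 1]] <- data.frame(gene = g, sample = s,
                                           is_outlier = flag)
    }
  }
  do.call(rbind, out)
}

# Spearman rho by the definitional route: Pearson correlation of midranks.
brute_force_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Closed-form kappa from a confusion matrix.
kappa_from_table <- function(tab) {
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}

# A tibble expression matrix from a plain matrix.
expr_tbl <- function(m) {
  tibble::as_tibble(as.data.frame(m), rownames = "gene_id")
}

# A small matched-study design used where speed matters more than scale.
small_design <- function(n_genes = 800, seed = 1, cohort_n = 80, ...) {
  study_design(n_genes = n_genes, cohort_n = cohort_n, seed = seed, ...)
}
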