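test_that("log transform maps known values and preserves ranks", {
  m <- expr_tbl(matrix(c(0, 1023, 7), nrow = 1,
                       dimnames = list("g", c("a", "b", "c"))))
  lt <- log_transform(m)
  expect_equal(unlist(lt[1, -1], use.names = FALSE), c(0, 10, 3))
  expect_error(log_transform(m, pseudocount = 0), "positive")

  set.seed(2)
  x <- rexp(200); y <- rexp(200) * (x + 1)
  before <- spearman_cor(x, y)$rho
  after <- spearman_cor(log2(x + 1), y)$rho
  expect_equal(before, after)
})

test_that("spearman_cor matches the midrank formula and handles edge cases", {
  x <- c(1, 2, 3, 4, 5); y <- c(5, 6, 7, 8, 7)
  r <- spearman_cor(x, y)
  expect_equal(r$rho, brute_force_spearman(x, y))
  expect_equal(spearman_cor(x, 2 * x + 1)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  expect_equal(spearman_cor(c(1, 2), c(3, 4))$n, 2)
  expect_true(is.na(spearman_cor(c(1, 2), c(3, 4))$rho))
  # missing pairs are dropped before anything else
  r2 <- spearman_cor(c(x, NA), c(y, 1))
  expect_equal(r2$n, 5)
  expect_equal(r2$rho, r$rho)
  # invariance under strictly monotone transforms (property)
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(30); b <- rnorm(30)
    base <- spearman_cor(a, b)$rho
    expect_equal(spearman_cor(exp(a), b)$rho, base)
    expect_equal(spearman_cor(a, b^3)$rho, base)
  }
})

test_that("exact and approximate p-values are used at the documented sizes", {
  set.seed(8)
  x <- rnorm(8); y <- rnorm(8)
  r_small <- spearman_cor(x, y)
  ct <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(r_small$p, ct$p.value)
  x2 <- rnorm(40); y2 <- x2 + rnorm(40)
  r_big <- spearman_cor(x2, y2)
  ct2 <- cor.test(x2, y2, method = "spearman", exact = FALSE,
                  continuity = FALSE)
  expect_equal(r_big$p, ct2$p.value)
})

test_that("platform correlation matrix respects pairing and missingness", {
  b <- simulate_matched_study(small_design(seed = 4))
  dup <- list(X = b$matrices[[1]], Y = b$matrices[[1]])
  sheet <- dplyr::bind_rows(
    tibble::tibble(sample_id = names(dup$X)[-1], patient = sub("\\..*", "", names(dup$X)[-1]),
                   platform = "X", preservation = "FF"),
    tibble::tibble(sample_id = names(dup$Y)[-1], patient = sub("\\..*", "", names(dup$Y)[-1]),
                   platform = "Y", preservation = "FFPE"))
  sheet$sample_id <- paste(sheet$sample_id, sheet$platform, sep = "_")
  names(dup$X)[-1] <- paste(names(dup$X)[-1], "X", sep = "_")
  names(dup$Y)[-1] <- paste(names(dup$Y)[-1], "Y", sep = "_")
  r <- platform_correlation_matrix(dup, sheet)
  expect_equal(r$rho, rep(1, nrow(r)))

  # missing sample -> absent cell, never zero
  r_full <- platform_correlation_matrix(b$matrices, b$sample_sheet)
  tw <- r_full[r_full$platform_1 == "TWIST" | r_full$platform_2 == "TWIST", ]
  expect_false("P07" %in% tw$patient)
  expect_true("P07" %in% r_full$patient)
})

test_that("panel correlation ranks the least-noisy platform first", {
  plat <- tibble::tibble(
    platform = c("REF", "low", "mid", "high"),
    reference = c(TRUE, FALSE, FALSE, FALSE),
    rho_target = NA_real_, noise_scale = c(0, 0.3, 1, 2.5),
    platform_bias = 0)
  wins <- vapply(1:10, function(seed) {
    d <- study_design(n_patients = 11, n_genes = 400, platforms = plat,
                      missing_assignments = tibble::tibble(
                        patient = character(), platform = character()),
                      cohort_n = 2, seed = seed)
    b <- simulate_matched_study(d)
    pc <- panel_correlation(b$matrices, b$sample_sheet,
                            panel = sprintf("G%05d", 1:73),
                            reference = "REF", by = "gene")
    s <- panel_correlation_summary(pc)
    s$platform[1] == "low"
  }, logical(1))
  expect_gte(mean(wins), 0.9)

  # per-sample mode: identical platform -> rho 1 for every matched pair
  b <- simulate_matched_study(small_design(seed = 2))
  twin <- list(`FF-TruSeq` = b$matrices[["FF-TruSeq"]],
               copy = b$matrices[["FF-TruSeq"]])
  names(twin$copy)[-1] <- sub("FF-TruSeq", "copy", names(twin$copy)[-1])
  sheet <- b$sample_sheet[b$sample_sheet$platform == "FF-TruSeq", ]
  sheet2 <- sheet
  sheet2$platform <- "copy"
  sheet2$sample_id <- sub("FF-TruSeq", "copy", sheet2$sample_id)
  pc <- panel_correlation(twin, dplyr::bind_rows(sheet, sheet2),
                          panel = sprintf("G%05d", 1:20),
                          reference = "FF-TruSeq", by = "sample")
  expect_equal(pc$rho, rep(1, nrow(pc)))
})

test_that("gene detection overlap equals brute-force set algebra", {
  set.seed(3)
  genes <- sprintf("g%03d", 1:200)
  mats <- lapply(c(A = 1, B = 2, C = 3), function(i) {
    keep <- sample(c(TRUE, FALSE), 200, replace = TRUE, prob = c(0.8, 0.2))
    m <- matrix(rexp(sum(keep) * 4), ncol = 4,
                dimnames = list(genes[keep], paste0("s", 1:4)))
    expr_tbl(m)
  })
  ov <- gene_detection_overlap(mats)
  sets <- lapply(mats, function(x) {
    m <- as.matrix(x[-1]); rownames(m) <- x$gene_id
    rownames(m)[apply(m > 0, 1, sum) >= 1]
  })
  expect_equal(ov$summary$n[ov$summary$category == "shared_all"],
               length(Reduce(intersect, sets)))
  for (nm in names(sets)) {
    expect_equal(
      ov$summary$n[ov$summary$category == paste0("unique_", nm)],
      length(setdiff(sets[[nm]], unlist(sets[names(sets) != nm]))))
  }
  expect_equal(ov$summary$n[ov$summary$category == "union"],
               length(unique(unlist(sets))))

  # identical matrices -> no exclusive genes
  same <- list(A = mats$A, B = mats$A)
  ov2 <- gene_detection_overlap(same)
  expect_true(all(ov2$summary$n[grepl("unique", ov2$summary$category)] == 0))
})

test_that("expression peaks find the zero and expressed modes", {
  m <- simulate_reference_cohort(2000, 20, seed = 10)
  pk <- expression_peaks(m)
  expect_gte(nrow(pk), 2)
  # first peak at the zero spike
  expect_lt(abs(pk$peak_log2[1]), 0.5)
  # expressed mode near 100 FPKM (within half a decade)
  main <- pk[which.max(pk$peak_fpkm), ]
  expect_lt(abs(log10(main$peak_fpkm) - 2), 0.5)

  # a capture-biased matrix peaks near 1000 FPKM
  shifted <- m
  shifted[-1] <- shifted[-1] * 10
  pk2 <- expression_peaks(shifted)
  main2 <- pk2[which.max(pk2$peak_fpkm), ]
  expect_lt(abs(log10(main2$peak_fpkm) - 3), 0.5)

  # all-equal input degenerates to a single peak
  flat <- expr_tbl(matrix(0, nrow = 20, ncol = 10,
                          dimnames = list(sprintf("g%d", 1:20),
                                          sprintf("s%d", 1:10))))
  expect_equal(nrow(expression_peaks(flat)), 1)
})

test_that("mapping-statistic tests behave at the null and under shift", {
  b <- simulate_matched_study(small_design(seed = 8))
  b <- simulate_qc_metrics(b, seed = 8)
  res <- compare_mapping_stats(b$sample_sheet)
  expect_true(all(c("kruskal-wallis", "wilcoxon-signed-rank") %in% res$test))
  expect_true(all(res$p >= 0 & res$p <= 1, na.rm = TRUE))

  # identical paired vectors -> p exactly 1
  sheet <- b$sample_sheet
  base <- sheet$input_reads[sheet$platform == "Agilent"]
  sheet$input_reads[sheet$platform == "IDT"] <-
    base[match(sheet$patient[sheet$platform == "IDT"],
               sheet$patient[sheet$platform == "Agilent"])]
  res2 <- compare_mapping_stats(sheet, metrics = "input_reads")
  row <- res2[res2$group_1 == "Agilent" & res2$group_2 == "IDT" &
                !is.na(res2$group_1), ]
  expect_equal(row$p, 1)

  # a large location shift is detected by the omnibus test
  hits <- vapply(1:10, function(s) {
    bb <- simulate_qc_metrics(b, seed = s)
    sh <- bb$sample_sheet
    sh$uniquely_mapped_pct[sh$platform == "TWIST"] <-
      sh$uniquely_mapped_pct[sh$platform == "TWIST"] - 30
    r <- compare_mapping_stats(sh, metrics = "uniquely_mapped_pct")
    r$p[r$test == "kruskal-wallis"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
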