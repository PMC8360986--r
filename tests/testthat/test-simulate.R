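test_that("reference cohort has the requested shape and zero structure", {
  m <- simulate_reference_cohort(50, 650, seed = 1)
  expect_equal(ncol(m) - 1, 650)
  expect_equal(nrow(m), 50)
  expect_true(all(as.matrix(m[-1]) >= 0))

  # no unexpressed component -> no exact zeros
  m0 <- simulate_reference_cohort(40, 30,
                                  mixture_params(weight_unexpressed = 0),
                                  seed = 2)
  expect_true(all(as.matrix(m0[-1]) > 0))

  expect_error(simulate_reference_cohort(0, 10), "n_genes")
  expect_error(simulate_reference_cohort(10, 1), "n_samples")
})

test_that("per-gene zero fractions are binomial around weight_unexpressed", {
  w <- 0.3
  m <- simulate_reference_cohort(1000, 650,
                                 mixture_params(weight_unexpressed = w),
                                 seed = 1)
  zf <- rowMeans(as.matrix(m[-1]) == 0)
  se <- sqrt(w * (1 - w) / 650)
  inside <- mean(abs(zf - w) <= 3 * se)
  expect_gt(inside, 0.97)
  expect_lt(abs(mean(zf) - w), 3 * se)
})

test_that("matched study is deterministic and respects the design", {
  d <- small_design(seed = 42)
  b1 <- simulate_matched_study(d)
  b2 <- simulate_matched_study(d)
  expect_identical(serialize(b1, NULL), serialize(b2, NULL))
  expect_named(b1$matrices, d$platforms$platform)
  # one sample per (patient, platform) except declared missing
  expect_equal(nrow(b1$sample_sheet), 11 * 4 - 1)
  expect_false("P07.TWIST" %in% b1$sample_sheet$sample_id)
  # all matrices share the gene index
  ids <- lapply(b1$matrices, `[[`, "gene_id")
  expect_true(all(vapply(ids, identical, logical(1), ids[[1]])))
})

test_that("zero-noise platform reproduces reference ranks exactly", {
  plat <- tibble::tibble(
    platform = c("REF", "DUP"), reference = c(TRUE, FALSE),
    rho_target = c(NA, NA), noise_scale = c(0, 0),
    platform_bias = c(0, 1))
  d <- study_design(n_patients = 4, n_genes = 500, platforms = plat,
                    missing_assignments = tibble::tibble(
                      patient = character(), platform = character()),
                    cohort_n = 10, seed = 5)
  b <- simulate_matched_study(d)
  r <- platform_correlation_matrix(b$matrices, b$sample_sheet)
  expect_equal(r$rho, rep(1, nrow(r)))
})

test_that("empirical Spearman approaches rho_target and decreases with noise", {
  plat <- tibble::tibble(
    platform = c("REF", "A"), reference = c(TRUE, FALSE),
    rho_target = c(NA, 0.85), noise_scale = c(0, NA), platform_bias = c(0, 0))
  d <- study_design(n_patients = 5, n_genes = 15000, platforms = plat,
                    missing_assignments = tibble::tibble(
                      patient = character(), platform = character()),
                    cohort_n = 2, seed = 9)
  b <- simulate_matched_study(d)
  r <- platform_correlation_matrix(b$matrices, b$sample_sheet)
  expect_true(all(abs(r$rho - 0.85) <= 0.05))

  # monotonicity: larger noise scale, lower expected correlation
  mean_rho <- vapply(c(0.3, 1, 3), function(s) {
    rs <- vapply(1:3, function(seed) {
      plat2 <- tibble::tibble(
        platform = c("REF", "A"), reference = c(TRUE, FALSE),
        rho_target = c(NA, NA), noise_scale = c(0, s), platform_bias = c(0, 0))
      d2 <- study_design(n_patients = 3, n_genes = 3000, platforms = plat2,
                         missing_assignments = tibble::tibble(
                           patient = character(), platform = character()),
                         cohort_n = 2, seed = seed)
      b2 <- simulate_matched_study(d2)
      mean(platform_correlation_matrix(b2$matrices, b2$sample_sheet)$rho)
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_true(all(diff(mean_rho) < 0))
})

test_that("spiking changes only the targeted entries and guarantees recovery", {
  b <- simulate_matched_study(small_design(seed = 3))
  targets <- tibble::tibble(gene = c("G00010", "G00020"),
                            patient = c("P02", "P07"))
  b2 <- spike_outliers(b, targets, z_target = 6, min_fpkm = 200)

  cm <- as.matrix(b$cohort[-1])
  rownames(cm) <- b$cohort$gene_id
  for (pf in names(b$matrices)) {
    m_old <- as.matrix(b$matrices[[pf]][-1])
    m_new <- as.matrix(b2$matrices[[pf]][-1])
    rownames(m_old) <- rownames(m_new) <- b$matrices[[pf]]$gene_id
    diff_idx <- which(m_old != m_new, arr.ind = TRUE)
    sheet <- b$sample_sheet[b$sample_sheet$platform == pf, ]
    expected <- sum(targets$patient %in% sheet$patient)
    expect_equal(nrow(diff_idx), expected)
    for (k in seq_len(nrow(targets))) {
      sid <- sheet$sample_id[sheet$patient == targets$patient[k]]
      if (length(sid) == 1) {
        v <- m_new[targets$gene[k], sid]
        ref <- cm[targets$gene[k], ]
        expect_gte((v - mean(ref)) / sd(ref), 6)
        expect_gte(v, 200)
      }
    }
  }
  # patient P07 has no TWIST sample, so TWIST carries one spike fewer
  expect_error(spike_outliers(b, tibble::tibble(gene = "NOPE", patient = "P01")),
               "Unknown gene")
  expect_identical(spike_outliers(b, targets[0, ]), b)
})

test_that("fusion simulation ties read support to fusion expression", {
  b <- simulate_matched_study(small_design(seed = 7))
  b <- simulate_fusions(b, n_fusions = 8, lambda_per_fpkm = 50, seed = 7)
  ft <- b$fusion_tables
  expect_equal(nrow(b$truth$fusions), 8)
  expect_true(all(ft$junction_reads >= 0))
  # high rate: junction reads track fusion FPKM within every platform
  for (pf in unique(ft$platform)) {
    d <- ft[ft$platform == pf, ]
    expect_gte(brute_force_spearman(d$junction_reads, d$fusion_fpkm), 0.85)
  }
  # a zero-FPKM fusion yields zero junction reads everywhere
  b0 <- b
  b0$truth$fusions$fusion_fpkm <- 0
  tb <- simulate_fusions(b0, n_fusions = 2, lambda_per_fpkm = 0, seed = 1)
  expect_true(all(tb$fusion_tables$junction_reads == 0))
})

test_that("QC metrics follow the degradation model", {
  b <- simulate_matched_study(small_design(seed = 1))
  b <- simulate_qc_metrics(b, age_slope = 9.5, seed = 1)
  sheet <- b$sample_sheet
  ffpe <- sheet[sheet$preservation == "FFPE", ]
  expect_true(all(ffpe$dv200 >= 0 & ffpe$dv200 <= 100))
  expect_true(all(sheet$rin >= 1 & sheet$rin <= 10))
  expect_true(all(sheet$rin[sheet$preservation == "FF"] >= 6))
  # block age inversely correlated with DV200 (sign check over seeds)
  signs <- vapply(1:20, function(s) {
    bb <- simulate_qc_metrics(b, age_slope = 9.5, seed = s)
    f <- bb$sample_sheet[bb$sample_sheet$preservation == "FFPE", ]
    cor(f$block_age_years, f$dv200, method = "spearman")
  }, numeric(1))
  expect_true(mean(signs < 0) >= 0.95)
  # with no age effect the correlation is centred on zero
  null_rho <- vapply(1:20, function(s) {
    bb <- simulate_qc_metrics(b, age_slope = 0, seed = s)
    f <- bb$sample_sheet[bb$sample_sheet$preservation == "FFPE", ]
    cor(f$block_age_years, f$dv200, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(null_rho)), 0.2)
  # DV200 spans roughly the degraded-FFPE range (about 22-87, median ~45)
  expect_gt(min(ffpe$dv200), 0)
  expect_lt(min(ffpe$dv200), 45)
  expect_gt(max(ffpe$dv200), 55)
  expect_true(abs(median(ffpe$dv200) - 45) < 15)
})

test_that("subtype labels flip at the requested rate", {
  b <- simulate_matched_study(small_design(seed = 2))
  agree <- vapply(1:20, function(s) {
    bb <- simulate_subtype_labels(b, flip_prob = 0.2, seed = s)
    sheet <- bb$sample_sheet
    truth <- setNames(bb$truth$subtypes$subtype, bb$truth$subtypes$patient)
    cap <- sheet[sheet$platform != "FF-TruSeq", ]
    mean(cap$subtype == truth[cap$patient])
  }, numeric(1))
  expect_lt(abs(mean(agree) - 0.8), 0.05)
})
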