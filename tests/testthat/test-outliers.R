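test_that("cohort statistics use the inclusive quartile convention", {
  m <- expr_tbl(matrix(c(1, 2, 3, 4, 5), nrow = 1,
                       dimnames = list("g1", paste0("s", 1:5))))
  st <- compute_cohort_stats(m)
  expect_equal(st$mean, 3)
  expect_equal(st$q1, 2)
  expect_equal(st$q3, 4)
  expect_equal(st$iqr, 2)
  expect_equal(st$n, 5)
  expect_false(st$degenerate)
})

test_that("constant genes are flagged degenerate and never called", {
  m <- expr_tbl(matrix(5, nrow = 1, ncol = 6,
                       dimnames = list("flat", paste0("s", 1:6))))
  st <- compute_cohort_stats(m)
  expect_true(st$degenerate)
  obs <- expr_tbl(matrix(1e6, nrow = 1, ncol = 1,
                         dimnames = list("flat", "x1")))
  calls <- call_outliers(obs, st)
  expect_true(is.nan(calls$z))
  expect_false(calls$is_outlier)
})

test_that("panel restriction and missing genes behave as declared", {
  ref <- simulate_reference_cohort(20, 10, seed = 1)
  expect_warning(st <- compute_cohort_stats(ref, panel = c("G00001", "G00002",
                                                           "ABSENT")),
                 "absent from the cohort")
  expect_setequal(st$gene, c("G00001", "G00002"))
  expect_error(compute_cohort_stats(expr_tbl(matrix(1, 1, 1,
    dimnames = list("g", "s"))), NULL), "at least 2 samples")
})

test_that("the three outlier criteria are conjunctive", {
  st <- tibble::tibble(gene = c("gA", "gB"), mean = c(10, 10), sd = c(5, 5),
                       q1 = c(7, 7), q3 = c(15, 15), iqr = c(8, 8),
                       n = 650, degenerate = FALSE)
  # gA: fpkm 40 -> z = 6, fence 27, passes everything
  # gB: fpkm 19.9 -> z = 1.98 fails z and the FPKM floor
  obs <- expr_tbl(matrix(c(40, 19.9), nrow = 2,
                         dimnames = list(c("gA", "gB"), "s1")))
  calls <- call_outliers(obs, st, z_min = 2, fpkm_min = 20, iqr_mult = 1.5)
  a <- calls[calls$gene == "gA", ]
  expect_equal(a$z, 6)
  expect_true(a$passes_z && a$passes_fpkm && a$passes_iqr && a$is_outlier)
  b <- calls[calls$gene == "gB", ]
  expect_false(b$is_outlier)

  # an entry passing z and IQR but below the FPKM floor is not an outlier
  st2 <- tibble::tibble(gene = "gC", mean = 1, sd = 0.5, q1 = 0.8, q3 = 1.4,
                        iqr = 0.6, n = 650, degenerate = FALSE)
  obs2 <- expr_tbl(matrix(19.9, 1, 1, dimnames = list("gC", "s1")))
  c2 <- call_outliers(obs2, st2)
  expect_true(c2$passes_z && c2$passes_iqr)
  expect_false(c2$passes_fpkm)
  expect_false(c2$is_outlier)
  expect_identical(c2$is_outlier, c2$passes_z & c2$passes_fpkm & c2$passes_iqr)
})

test_that("call_outliers matches the brute-force oracle on random draws", {
  set.seed(99)
  for (i in 1:50) {
    cohort <- matrix(rexp(30 * 15, rate = 1 / 30), 30, 15,
                     dimnames = list(sprintf("g%02d", 1:30),
                                     sprintf("c%02d", 1:15)))
    obs <- matrix(rexp(30 * 5, rate = 1 / 50), 30, 5,
                  dimnames = list(rownames(cohort), sprintf("s%d", 1:5)))
    z_min <- runif(1, 0.5, 4); fpkm_min <- runif(1, 0, 60)
    iqr_mult <- runif(1, 0.5, 3)
    st <- compute_cohort_stats(expr_tbl(cohort))
    got <- call_outliers(expr_tbl(obs), st, z_min, fpkm_min, iqr_mult)
    want <- brute_force_outliers(cohort, obs, z_min, fpkm_min, iqr_mult)
    key <- paste(got$gene, got$sample)
    expect_identical(got$is_outlier[order(key)],
                     want$is_outlier[order(paste(want$gene, want$sample))])
  }
})

test_that("raising any threshold never enlarges the outlier set", {
  set.seed(7)
  cohort <- expr_tbl(matrix(rexp(40 * 20, 1 / 25), 40, 20,
                            dimnames = list(sprintf("g%02d", 1:40),
                                            sprintf("c%02d", 1:20))))
  obs <- expr_tbl(matrix(rexp(40 * 8, 1 / 60), 40, 8,
                         dimnames = list(sprintf("g%02d", 1:40),
                                         sprintf("s%d", 1:8))))
  st <- compute_cohort_stats(cohort)
  base <- call_outliers(obs, st, 1.5, 10, 1)
  base_set <- paste(base$gene, base$sample)[base$is_outlier]
  for (bump in list(c(2.5, 10, 1), c(1.5, 30, 1), c(1.5, 10, 2))) {
    harder <- call_outliers(obs, st, bump[1], bump[2], bump[3])
    harder_set <- paste(harder$gene, harder$sample)[harder$is_outlier]
    expect_true(all(harder_set %in% base_set))
  }
})

test_that("outlier concordance handles identity, disjoint and missing cases", {
  sheet <- tibble::tibble(
    sample_id = c("p1.R", "p2.R", "p1.A", "p2.A", "p1.B"),
    patient = c("p1", "p2", "p1", "p2", "p1"),
    platform = c("R", "R", "A", "A", "B"),
    preservation = c("FF", "FF", "FFPE", "FFPE", "FFPE"))
  mk <- function(platform, positives) {
    tibble::tibble(gene = c("g1", "g2"),
                   sample = paste0(c("p1", "p2"), ".", platform),
                   platform = platform, fpkm = 100, z = 5,
                   passes_z = TRUE, passes_fpkm = TRUE, passes_iqr = TRUE,
                   is_outlier = positives)
  }
  # identical call sets -> 100%
  calls <- dplyr::bind_rows(mk("R", c(TRUE, TRUE)), mk("A", c(TRUE, TRUE)),
                            mk("B", c(TRUE, FALSE))[1, ])
  oc <- outlier_concordance(calls, sheet, "R")
  expect_equal(oc$concordance_pct[oc$platform == "A"], 100)
  # platform B has no sample for p2: that pair must leave the denominator
  expect_equal(oc$n_reference_positive[oc$platform == "B"], 1)
  expect_equal(oc$concordance_pct[oc$platform == "B"], 100)

  # disjoint sets -> 0%
  calls2 <- dplyr::bind_rows(mk("R", c(TRUE, FALSE)), mk("A", c(FALSE, TRUE)))
  oc2 <- outlier_concordance(calls2, sheet, "R")
  expect_equal(oc2$concordance_pct[oc2$platform == "A"], 0)

  # reference without positives -> empty result with a note
  calls3 <- dplyr::bind_rows(mk("R", c(FALSE, FALSE)), mk("A", c(TRUE, TRUE)))
  oc3 <- outlier_concordance(calls3, sheet, "R")
  expect_equal(nrow(oc3), 0)
  expect_match(attr(oc3, "note"), "no positive calls")
})

test_that("dominating spikes give 100% concordance on every platform", {
  for (seed in c(11, 12, 13)) {
    b <- simulate_matched_study(study_design(n_genes = 600, cohort_n = 650,
                                             seed = seed))
    targets <- tibble::tibble(gene = sprintf("G%05d", 1:5),
                              patient = sprintf("P%02d", 1:5))
    b <- spike_outliers(b, targets, z_target = 6, min_fpkm = 200)
    st <- compute_cohort_stats(b$cohort)
    calls <- dplyr::bind_rows(lapply(names(b$matrices), function(pf)
      call_outliers(b$matrices[[pf]], st, platform = pf)))
    oc <- outlier_concordance(calls, b$sample_sheet, "FF-TruSeq")
    expect_equal(nrow(oc), 3)
    expect_true(all(oc$concordance_pct == 100))
  }
})
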