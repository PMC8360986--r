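# Readers and writers for every tabular artifact the pipeline touches.
# All files are UTF-8 TSV with a header row (plain text for gene panels,
# YAML for configuration). Readers validate strictly and name the offending
# row/column; they never silently coerce.

#' Read and write gene-by-sample FPKM expression matrices
#'
#' The on-disk format is a TSV whose first column holds gene identifiers
#' and whose remaining columns are one numeric FPKM vector per sample.
#' Negative values, duplicate gene or sample IDs, missing entries and
#' ragged rows are rejected with an error naming the offending cell.
#'
#' @param path File path.
#' @return `read_expression_matrix()` returns an expression tibble
#'   (`gene_id` + one column per sample).
#' @export
read_expression_matrix <- function(path) {
  hdr <- strsplit(readr::read_lines(path, n_max = 1), "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 2) abort(sprintf("%s: expected gene ID + sample columns.", path))
  if (anyDuplicated(hdr[-1])) {
    abort(sprintf("%s: duplicate sample ID '%s' in header.", path,
                  hdr[-1][duplicated(hdr[-1])][1]))
  }
  ct <- do.call(readr::cols,
                c(setNames(list(readr::col_character()), hdr[1]),
                  list(.default = readr::col_double())))
  x <- suppressWarnings(readr::read_tsv(path, col_types = ct,
                                        progress = FALSE,
                                        show_col_types = FALSE))
  names(x)[1] <- "gene_id"
  x$gene_id <- as.character(x$gene_id)
  prob <- readr::problems(x)
  if (nrow(prob) > 0) {
    abort(sprintf("Malformed expression matrix %s: row %d, column %d (%s).",
                  path, prob$row[1], prob$col[1], prob$expected[1]))
  }
  check_expression_tbl(x, path)
  as_tibble(x)
}

#' @param matrix An expression tibble.
#' @rdname read_expression_matrix
#' @export
write_expression_matrix <- function(matrix, path) {
  check_expression_tbl(matrix)
  readr::write_tsv(matrix, path)
  invisible(path)
}

#' Read and write fusion-call tables
#'
#' Expected columns: `patient`, `platform`, `gene5` (5' partner), `gene3`
#' (3' partner), `junction_reads`, `spanning_pairs`, `fusion_fpkm`.
#' Read counts must be non-negative integers; the two partners must
#' differ. A canonical `fusion` column (`gene5::gene3`) is added on read.
#'
#' @param path File path.
#' @return A tibble of validated fusion calls.
#' @export
read_fusion_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    patient = readr::col_character(), platform = readr::col_character(),
    gene5 = readr::col_character(), gene3 = readr::col_character(),
    junction_reads = readr::col_double(),
    spanning_pairs = readr::col_double(),
    fusion_fpkm = readr::col_double()), progress = FALSE,
    show_col_types = FALSE)
  validate_fusion_table(x, path)
  x$junction_reads <- as.integer(x$junction_reads)
  x$spanning_pairs <- as.integer(x$spanning_pairs)
  x$fusion <- paste0(x$gene5, "::", x$gene3)
  as_tibble(x)
}

validate_fusion_table <- function(x, where = "fusion table") {
  need <- c("patient", "platform", "gene5", "gene3",
            "junction_reads", "spanning_pairs", "fusion_fpkm")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(sprintf("%s: missing column(s) %s.", where,
                  paste(miss, collapse = ", ")))
  }
  for (col in c("junction_reads", "spanning_pairs")) {
    v <- x[[col]]
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      abort(sprintf("%s: `%s` must be a non-negative integer (row %d is %s).",
                    where, col, bad[1], v[bad[1]]))
    }
  }
  if (any(is.na(x$fusion_fpkm) | x$fusion_fpkm < 0)) {
    bad <- which(is.na(x$fusion_fpkm) | x$fusion_fpkm < 0)[1]
    abort(sprintf("%s: `fusion_fpkm` must be non-negative (row %d).",
                  where, bad))
  }
  same <- which(x$gene5 == x$gene3)
  if (length(same)) {
    abort(sprintf("%s: gene5 == gene3 ('%s') at row %d.",
                  where, x$gene5[same[1]], same[1]))
  }
  invisible(x)
}

#' @param table A fusion-call tibble.
#' @rdname read_fusion_table
#' @export
write_fusion_table <- function(table, path) {
  validate_fusion_table(table)
  readr::write_tsv(table[setdiff(names(table), "fusion")], path)
  invisible(path)
}

#' Split a hyphenated fusion name into its 5'/3' partners
#'
#' `"TPM3-NTRK1"` becomes `c("TPM3", "NTRK1")`. The split is on the first
#' separator, so gene symbols that themselves contain hyphens must use the
#' unambiguous `"::"` form (`"NKX2-1::ALK"`), which is tried first.
#'
#' @param x Character vector of fusion names.
#' @return A tibble with columns `gene5`, `gene3`.
#' @export
parse_fusion_name <- function(x) {
  parts <- lapply(x, function(nm) {
    if (grepl("::", nm, fixed = TRUE)) {
      strsplit(nm, "::", fixed = TRUE)[[1]]
    } else {
      sub <- regexpr("-", nm, fixed = TRUE)
      if (sub < 0) abort(sprintf("'%s' is not a recognisable fusion name.", nm))
      c(substr(nm, 1, sub - 1), substr(nm, sub + 1, nchar(nm)))
    }
  })
  bad <- which(vapply(parts, length, integer(1)) != 2 |
                 vapply(parts, function(p) any(!nzchar(p)), logical(1)))
  if (length(bad)) {
    abort(sprintf("'%s' is not a recognisable fusion name.", x[bad[1]]))
  }
  tibble(gene5 = vapply(parts, `[`, character(1), 1),
         gene3 = vapply(parts, `[`, character(1), 2))
}

#' Read and write gene panels
#'
#' A panel file lists one gene per line; blank lines and `#` comments are
#' ignored. Duplicate entries are dropped with a warning. An empty panel is
#' an error.
#'
#' @param path File path.
#' @return A character vector of unique gene identifiers with attribute
#'   `panel_name` (the file stem).
#' @export
read_gene_panel <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  genes <- lines[nzchar(lines)]
  if (length(genes) == 0) abort(sprintf("Gene panel %s is empty.", path))
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warn(sprintf("Panel %s contains duplicate gene(s): %s; deduplicated.",
                 path, paste(head(dup, 5), collapse = ", ")))
    genes <- unique(genes)
  }
  structure(genes, panel_name = sub("\\.[^.]*$", "", basename(path)))
}

#' @param panel Character vector of genes.
#' @rdname read_gene_panel
#' @export
write_gene_panel <- function(panel, path) {
  readr::write_lines(unique(as.character(panel)), path)
  invisible(path)
}

#' Read and write sample sheets
#'
#' Required columns: `sample_id`, `patient`, `platform`, `preservation`
#' (`FF` or `FFPE`). Optional columns: `subtype` plus the QC/mapping fields
#' (`dv200`, `rin`, `block_age_years`, `rna_yield_ng`, `input_reads`,
#' `uniquely_mapped_pct`, `multimapped_pct`). Missing optional values
#' propagate as `NA`, never imputed. `(patient, platform)` pairs must be
#' unique; DV200 must lie in \[0, 100\] and RIN in \[1, 10\] where present.
#'
#' @param path File path.
#' @return A sample-sheet tibble.
#' @export
read_sample_sheet <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_sheet(x, path)
}

validate_sample_sheet <- function(x, where = "sample sheet") {
  need <- c("sample_id", "patient", "platform", "preservation")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(sprintf("%s: missing column(s) %s.", where,
                  paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(x$sample_id)) abort(sprintf("%s: duplicate sample_id.", where))
  key <- paste(x$patient, x$platform)
  if (anyDuplicated(key)) {
    abort(sprintf("%s: duplicate (patient, platform) pair '%s'.", where,
                  key[duplicated(key)][1]))
  }
  bad <- setdiff(unique(x$preservation), c("FF", "FFPE"))
  if (length(bad)) {
    abort(sprintf("%s: preservation must be FF or FFPE (found '%s').",
                  where, bad[1]))
  }
  if ("dv200" %in% names(x) &&
      any(!is.na(x$dv200) & (x$dv200 < 0 | x$dv200 > 100))) {
    abort(sprintf("%s: dv200 outside [0, 100].", where))
  }
  if ("rin" %in% names(x) && any(!is.na(x$rin) & (x$rin < 1 | x$rin > 10))) {
    abort(sprintf("%s: rin outside [1, 10].", where))
  }
  as_tibble(x)
}

#' @param sheet A sample-sheet tibble.
#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  readr::write_tsv(sheet, path)
  invisible(path)
}

#' Write a simulated study bundle to a directory
#'
#' Emits one expression-matrix TSV per platform
#' (`expression_<platform>.tsv`), the sample sheet, the fusion tables and
#' truth tables (when present), the reference cohort matrix, and the
#' generative configuration echoed as YAML.
#'
#' @param bundle A `study_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  safe <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)
  for (pf in names(bundle$matrices)) {
    write_expression_matrix(bundle$matrices[[pf]],
                            file.path(dir, sprintf("expression_%s.tsv", safe(pf))))
  }
  write_sample_sheet(bundle$sample_sheet, file.path(dir, "sample_sheet.tsv"))
  write_expression_matrix(bundle$cohort, file.path(dir, "reference_cohort.tsv"))
  if (!is.null(bundle$fusion_tables)) {
    write_fusion_table(bundle$fusion_tables, file.path(dir, "fusion_calls.tsv"))
  }
  if (!is.null(bundle$truth$fusions)) {
    readr::write_tsv(bundle$truth$fusions, file.path(dir, "truth_fusions.tsv"))
  }
  if (nrow(bundle$truth$outliers) > 0) {
    readr::write_tsv(bundle$truth$outliers, file.path(dir, "truth_outliers.tsv"))
  }
  d <- bundle$design
  yaml::write_yaml(list(
    n_patients = d$n_patients, n_genes = d$n_genes, cohort_n = d$cohort_n,
    seed = d$seed, params = unclass(d$params),
    platforms = lapply(seq_len(nrow(d$platforms)), function(i)
      as.list(d$platforms[i, ])),
    missing_assignments = if (nrow(d$missing_assignments)) {
      lapply(seq_len(nrow(d$missing_assignments)), function(i)
        as.list(d$missing_assignments[i, ]))
    }
  ), file.path(dir, "design.yaml"))
  invisible(dir)
}
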