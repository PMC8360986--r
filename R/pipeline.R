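# Pipeline orchestration: validated YAML configuration, stage execution
# (simulate -> outliers -> concordance -> subtypes -> fusions -> qc), TSV
# stage outputs, a YAML run manifest and a JSON headline summary that is
# byte-identical for identical config + seed.

default_config <- function() {
  list(
    seed = 1L,
    reference = "FF-TruSeq",
    alpha = 0.05,
    out_dir = NULL,
    inputs = NULL,
    simulate = list(
      n_patients = 11L, n_genes = 15000L, cohort_n = 650L,
      spike_n = 5L, spike_z_target = 6, spike_min_fpkm = 200,
      n_fusions = 8L, lambda_per_fpkm = 0.5,
      flip_prob = 0.2, age_slope = 9.5),
    thresholds = list(
      z_min = 2, fpkm_min = 20, iqr_mult = 1.5,
      min_junction = 1L, min_spanning = 1L,
      detect_min_fpkm = 0, detect_min_samples = 1L),
    panels = list(
      druggable_size = 138L, immune_size = 73L,
      druggable_path = NULL, immune_path = NULL)
  )
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), checks every key against the known
#' schema — unknown keys are rejected with a "did you mean" suggestion —
#' fills defaults, and type-checks thresholds. All problems are reported
#' at once. Default thresholds are the standard calling rules: z >= 2,
#' FPKM >= 20, 1.5 x IQR, junction reads >= 1, spanning pairs >= 1.
#'
#' @param config Path to a YAML file, a list, or `NULL` for the full
#'   default configuration.
#' @return A validated, fully defaulted configuration (class `run_config`).
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  if (!is.list(config)) abort("Configuration must be a YAML mapping.")
  defaults <- default_config()
  problems <- character()
  check_keys <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    for (key in unknown) {
      hit <- agrep(key, allowed, max.distance = 2, value = TRUE)
      problems <<- c(problems, sprintf(
        "unknown key '%s'%s%s", key,
        if (nzchar(where)) paste0(" in ", where) else "",
        if (length(hit)) sprintf(" — did you mean '%s'?", hit[1]) else ""))
    }
  }
  check_keys(config, names(defaults), "")
  for (section in c("simulate", "thresholds", "panels")) {
    if (!is.null(config[[section]])) {
      if (!is.list(config[[section]])) {
        problems <- c(problems, sprintf("'%s' must be a mapping.", section))
        config[[section]] <- list()
      }
      check_keys(config[[section]], names(defaults[[section]]), section)
    }
  }
  merged <- defaults
  for (nm in intersect(names(config), names(defaults))) {
    if (is.list(defaults[[nm]]) && !is.null(config[[nm]])) {
      merged[[nm]] <- modifyList(defaults[[nm]],
                                 config[[nm]][intersect(names(config[[nm]]),
                                                        names(defaults[[nm]]))])
    } else if (!is.null(config[[nm]])) {
      merged[[nm]] <- config[[nm]]
    }
  }
  th <- merged$thresholds
  for (nm in names(th)) {
    if (!is.numeric(th[[nm]]) || length(th[[nm]]) != 1 || is.na(th[[nm]]) ||
        th[[nm]] < 0) {
      problems <- c(problems, sprintf("threshold '%s' must be a non-negative number.", nm))
    }
  }
  if (!is.numeric(merged$alpha) || merged$alpha <= 0 || merged$alpha >= 1) {
    problems <- c(problems, "'alpha' must lie in (0, 1).")
  }
  if (!is.character(merged$reference) || length(merged$reference) != 1) {
    problems <- c(problems, "'reference' must be a single platform name.")
  }
  if (is.null(merged$inputs) &&
      !merged$reference %in% default_platforms()$platform) {
    problems <- c(problems, sprintf(
      "'reference' platform '%s' is not in the simulated platform set (%s).",
      merged$reference, paste(default_platforms()$platform, collapse = ", ")))
  }
  if (length(problems)) {
    abort(paste0("Invalid configuration:\n", paste("-", problems, collapse = "\n")))
  }
  merged$seed <- as.integer(merged$seed)
  structure(merged, class = "run_config")
}

# Panels for simulated gene indices: deterministic slices of the gene set
# standing in for the druggable-cancer and immune panels.
simulated_panels <- function(gene_ids, cfg) {
  n_drug <- min(cfg$panels$druggable_size, length(gene_ids))
  n_imm <- min(cfg$panels$immune_size, max(length(gene_ids) - n_drug, 0))
  list(druggable = gene_ids[seq_len(n_drug)],
       immune = gene_ids[n_drug + seq_len(n_imm)])
}

subset_expression <- function(matrix, genes) {
  matrix[matrix$gene_id %in% genes, , drop = FALSE]
}

#' Run the full concordance pipeline
#'
#' Simulates (or loads) a matched multi-platform study, then runs every
#' analysis stage: cohort-referenced outlier calling and cross-platform
#' concordance, global and immune-panel correlation, gene-detection
#' overlap, expression density peaks, mapping-statistic tests, subtype
#' agreement, fusion filtering/detection/correlation, and QC correlations.
#' Optional stages that lack inputs (e.g. no subtype labels) are skipped
#' and recorded in the manifest without aborting. All stage tables are
#' written as TSV to `out_dir` together with `manifest.yaml` and
#' `summary.json`; the summary is byte-identical for identical
#' config + seed.
#'
#' @param config A [validate_config()] result, a config list, a YAML path,
#'   or `NULL` for defaults.
#' @param out_dir Output directory; overrides `config$out_dir`. `NULL`
#'   skips writing and returns tables only.
#' @return A list of class `report_bundle` with elements `tables` (per-
#'   stage tibbles), `summary` (headline list), `manifest`, `bundle`.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  skipped <- character()

  if (!is.null(cfg$inputs)) {
    bundle <- read_study_bundle(cfg$inputs$bundle_dir)
  } else {
    s <- cfg$simulate
    design <- study_design(n_patients = s$n_patients, n_genes = s$n_genes,
                           cohort_n = s$cohort_n, seed = cfg$seed)
    bundle <- simulate_matched_study(design)
    panels <- simulated_panels(bundle$matrices[[1]]$gene_id, cfg)
    if (s$spike_n > 0) {
      patients <- patient_names(s$n_patients)
      targets <- tibble(
        gene = panels$druggable[seq_len(min(s$spike_n, length(panels$druggable)))],
        patient = patients[1 + (seq_len(min(s$spike_n, length(panels$druggable))) - 1)
                           %% length(patients)])
      bundle <- spike_outliers(bundle, targets,
                               z_target = s$spike_z_target,
                               min_fpkm = s$spike_min_fpkm)
    }
    bundle <- simulate_fusions(bundle, n_fusions = s$n_fusions,
                               lambda_per_fpkm = s$lambda_per_fpkm,
                               seed = cfg$seed)
    bundle <- simulate_qc_metrics(bundle, age_slope = s$age_slope,
                                  seed = cfg$seed)
    bundle <- simulate_subtype_labels(bundle, flip_prob = s$flip_prob,
                                      seed = cfg$seed)
  }
  if (!is.null(cfg$inputs)) {
    panels <- list(
      druggable = if (!is.null(cfg$panels$druggable_path)) {
        read_gene_panel(cfg$panels$druggable_path)
      } else simulated_panels(bundle$matrices[[1]]$gene_id, cfg)$druggable,
      immune = if (!is.null(cfg$panels$immune_path)) {
        read_gene_panel(cfg$panels$immune_path)
      } else simulated_panels(bundle$matrices[[1]]$gene_id, cfg)$immune)
  }
  reference <- cfg$reference
  if (!reference %in% names(bundle$matrices)) {
    abort(sprintf("Reference platform '%s' absent from the bundle.", reference))
  }
  th <- cfg$thresholds
  tables <- list()

  # outliers
  stats <- compute_cohort_stats(bundle$cohort, panel = panels$druggable)
  calls <- bind_rows(lapply(names(bundle$matrices), function(pf) {
    call_outliers(subset_expression(bundle$matrices[[pf]], stats$gene),
                  stats, z_min = th$z_min, fpkm_min = th$fpkm_min,
                  iqr_mult = th$iqr_mult, platform = pf)
  }))
  tables$outlier_calls <- calls
  tables$outlier_concordance <-
    outlier_concordance(calls, bundle$sample_sheet, reference)

  # concordance
  tables$correlation_matrix <-
    platform_correlation_matrix(bundle$matrices, bundle$sample_sheet)
  tables$panel_correlation <-
    panel_correlation(bundle$matrices, bundle$sample_sheet,
                      panels$immune, reference, by = "gene")
  tables$panel_correlation_summary <-
    panel_correlation_summary(tables$panel_correlation)
  overlap <- gene_detection_overlap(bundle$matrices,
                                    detect_min_fpkm = th$detect_min_fpkm,
                                    detect_min_samples = th$detect_min_samples)
  tables$detection_overlap <- overlap$summary
  tables$expression_peaks <- bind_rows(lapply(names(bundle$matrices),
                                              function(pf) {
    pk <- expression_peaks(bundle$matrices[[pf]])
    pk$platform <- pf
    pk
  }))
  if (all(c("input_reads", "uniquely_mapped_pct") %in%
          names(bundle$sample_sheet)) &&
      any(!is.na(bundle$sample_sheet$input_reads))) {
    tables$mapping_tests <- compare_mapping_stats(bundle$sample_sheet)
  } else {
    skipped <- c(skipped, "mapping_tests: no mapping metrics in sample sheet")
  }

  # subtypes
  if ("subtype" %in% names(bundle$sample_sheet) &&
      any(!is.na(bundle$sample_sheet$subtype))) {
    tables$subtype_agreement <-
      agreement_summary(bundle$sample_sheet, reference)
  } else {
    skipped <- c(skipped, "subtypes: no subtype labels in sample sheet")
  }

  # fusions
  if (!is.null(bundle$fusion_tables) && nrow(bundle$fusion_tables) > 0) {
    filtered <- filter_fusion_calls(bundle$fusion_tables,
                                    min_junction = th$min_junction,
                                    min_spanning = th$min_spanning)
    tables$fusion_calls_filtered <- filtered
    ref_set <- filtered[filtered$platform == reference, ]
    if (nrow(ref_set) > 0) {
      det <- build_detection_matrix(filtered, ref_set, bundle$sample_sheet,
                                    platforms = names(bundle$matrices))
      tables$fusion_detection <- det$matrix
      tables$fusion_sensitivity <- det$sensitivity
    } else {
      skipped <- c(skipped, "fusion detection: no reference fusions survive filtering")
    }
    tables$fusion_correlation <-
      junction_expression_correlation(bundle$fusion_tables)
  } else {
    skipped <- c(skipped, "fusions: no fusion tables")
  }

  # qc
  if ("dv200" %in% names(bundle$sample_sheet) &&
      any(!is.na(bundle$sample_sheet$dv200))) {
    tables$qc_correlations <- qc_correlation_table(bundle$sample_sheet)
    strat <- stratified_qc_summary(bundle$sample_sheet)
    tables$qc_stratified <- strat$summary
    tables$qc_stratified_tests <- strat$tests
  } else {
    skipped <- c(skipped, "qc: no DV200 values")
  }

  # headline summary — every number re-derivable from a stage table
  ffpe_ref <- tables$correlation_matrix |>
    filter(.data$platform_1 == reference | .data$platform_2 == reference)
  summary <- list(
    reference = reference,
    n_patients = length(unique(bundle$sample_sheet$patient)),
    n_platforms = length(bundle$matrices),
    rho_vs_reference = list(min = min(ffpe_ref$rho), max = max(ffpe_ref$rho)),
    outlier_concordance_pct = if (nrow(tables$outlier_concordance)) {
      setNames(as.list(tables$outlier_concordance$concordance_pct),
               tables$outlier_concordance$platform)
    },
    immune_panel_median_rho = setNames(
      as.list(tables$panel_correlation_summary$median_rho),
      tables$panel_correlation_summary$platform),
    subtype_overall_kappa = if (!is.null(tables$subtype_agreement)) {
      overall <- filter(tables$subtype_agreement, .data$scope == "overall")
      setNames(as.list(overall$kappa), overall$platform)
    },
    fusion_sensitivity_pct = if (!is.null(tables$fusion_sensitivity)) {
      setNames(as.list(tables$fusion_sensitivity$sensitivity_pct),
               tables$fusion_sensitivity$platform)
    },
    shared_detected_genes =
      tables$detection_overlap$n[tables$detection_overlap$category == "shared_all"]
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("ffpeconcord")),
    seed = cfg$seed,
    timestamp = format(Sys.time(), tz = "UTC"),
    skipped_stages = if (length(skipped)) skipped else "none",
    config = unclass(cfg))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables)) {
      readr::write_tsv(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  structure(list(tables = tables, summary = summary, manifest = manifest,
                 bundle = bundle),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> stages:", paste(names(x$tables), collapse = ", "), "\n")
  cat(sprintf("  rho vs reference: %.3f-%.3f; shared detected genes: %d\n",
              x$summary$rho_vs_reference$min, x$summary$rho_vs_reference$max,
              x$summary$shared_detected_genes))
  invisible(x)
}

#' Read a study bundle written by [write_study_bundle()]
#'
#' @param dir Directory containing `expression_<platform>.tsv` files, a
#'   `sample_sheet.tsv`, a `reference_cohort.tsv` and optionally
#'   `fusion_calls.tsv` and truth tables.
#' @return A `study_bundle` (truth tables empty when absent).
#' @export
read_study_bundle <- function(dir) {
  sheet <- read_sample_sheet(file.path(dir, "sample_sheet.tsv"))
  files <- list.files(dir, pattern = "^expression_.*\\.tsv$", full.names = TRUE)
  if (length(files) == 0) abort(sprintf("No expression matrices in %s.", dir))
  matrices <- lapply(files, read_expression_matrix)
  names(matrices) <- sub("^expression_(.*)\\.tsv$", "\\1", basename(files))
  # platform file names are sanitised on write; map back through the sheet
  plat <- unique(sheet$platform)
  safe <- gsub("[^A-Za-z0-9._-]", "_", plat)
  hit <- match(names(matrices), safe)
  names(matrices)[!is.na(hit)] <- plat[hit[!is.na(hit)]]
  cohort_path <- file.path(dir, "reference_cohort.tsv")
  cohort <- if (file.exists(cohort_path)) read_expression_matrix(cohort_path)
  fus_path <- file.path(dir, "fusion_calls.tsv")
  fus <- if (file.exists(fus_path)) read_fusion_table(fus_path)
  ref_guess <- unique(sheet$platform[sheet$preservation == "FF"])
  platforms <- tibble(platform = plat,
                      reference = plat %in% ref_guess[1],
                      rho_target = NA_real_,
                      noise_scale = NA_real_, platform_bias = 0)
  n_pat <- length(unique(sheet$patient))
  design <- structure(list(
    n_patients = n_pat, n_genes = nrow(matrices[[1]]),
    platforms = platforms,
    missing_assignments = tibble(patient = character(), platform = character()),
    cohort_n = if (!is.null(cohort)) ncol(cohort) - 1 else NA_integer_,
    params = mixture_params(), seed = NA_integer_), class = "study_design")
  structure(list(matrices = matrices, sample_sheet = sheet, cohort = cohort,
                 fusion_tables = fus,
                 truth = list(outliers = tibble(gene = character(),
                                                patient = character()),
                              fusions = NULL, subtypes = NULL),
                 design = design),
            class = "study_bundle")
}
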