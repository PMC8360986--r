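# Molecular-subtype agreement between platforms: overall observed
# agreement, multiclass and one-vs-rest Cohen's kappa, and the
# Landis-Koch qualitative interpretation.

#' Cohen's kappa between two categorical labelings
#'
#' Observed agreement `po` is the fraction of identical labels; chance
#' agreement `pe` is the sum over classes of the product of the two
#' marginal proportions; `kappa = (po - pe) / (1 - pe)`. Kappa is 0 when
#' agreement is at chance level and 1 at perfect agreement. When both
#' labelings are constant and identical (`pe = 1`), kappa is defined as 1
#' with a note. Named vectors are matched on their intersection of names
#' (mismatched keys are dropped with a warning); unnamed vectors are
#' matched by position.
#'
#' @param a,b Character/factor label vectors.
#' @return An object of class `kappa_result`; use [tidy()] / [glance()]
#'   for tibble output. Fields: `kappa`, `po`, `pe`, `n`, `category`
#'   (Landis-Koch), `note`.
#' @export
cohens_kappa <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b)) &&
      !anyDuplicated(names(a)) && !anyDuplicated(names(b))) {
    keys <- intersect(names(a), names(b))
    if (length(keys) == 0) abort("No shared keys between the two labelings.")
    if (length(keys) < length(a) || length(keys) < length(b)) {
      warn(sprintf("%d unmatched key(s) dropped.",
                   length(a) + length(b) - 2 * length(keys)))
    }
    a <- a[keys]; b <- b[keys]
  }
  if (length(a) != length(b)) abort("Labelings differ in length.")
  keep <- !is.na(a) & !is.na(b)
  a <- as.character(a)[keep]; b <- as.character(b)[keep]
  n <- length(a)
  if (n < 1) abort("No complete label pairs.")
  po <- mean(a == b)
  classes <- union(a, b)
  pe <- sum(vapply(classes, function(cl) mean(a == cl) * mean(b == cl),
                   numeric(1)))
  note <- NA_character_
  if (pe >= 1) {
    kappa <- 1
    note <- "both labelings constant and identical; kappa defined as 1"
  } else {
    kappa <- (po - pe) / (1 - pe)
  }
  structure(list(kappa = kappa, po = po, pe = pe, n = n,
                 category = interpret_kappa(kappa), note = note),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (%s); po = %.3f, pe = %.3f, n = %d\n",
              x$kappa, x$category, x$po, x$pe, x$n))
  if (!is.na(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' @rdname cohens_kappa
#' @param x A `kappa_result`.
#' @param ... Unused.
#' @method tidy kappa_result
#' @export
tidy.kappa_result <- function(x, ...) {
  tibble(kappa = x$kappa, po = x$po, pe = x$pe, n = x$n,
         category = x$category, note = x$note)
}

#' @rdname cohens_kappa
#' @method glance kappa_result
#' @export
glance.kappa_result <- function(x, ...) tidy.kappa_result(x)

#' One-vs-rest kappa for a single class
#'
#' Binarizes both labelings as `class` vs everything else, then applies
#' [cohens_kappa()]. A class absent from both labelings has no agreement
#' signal: the result is `NA` with a note.
#'
#' @param a,b Label vectors.
#' @param class The class to isolate.
#' @param classes Optional declared class set; an unknown `class` is an
#'   error when supplied.
#' @return A `kappa_result` (possibly with `kappa = NA`).
#' @export
per_class_kappa <- function(a, b, class, classes = NULL) {
  if (!is.null(classes) && !class %in% classes) {
    abort(sprintf("Class '%s' is not in the declared class set.", class))
  }
  if (!is.null(names(a)) && !is.null(names(b))) {
    keys <- intersect(names(a), names(b))
    a <- a[keys]; b <- b[keys]
  }
  if (!class %in% c(a, b)) {
    return(structure(list(kappa = NA_real_, po = NA_real_, pe = NA_real_,
                          n = length(a), category = NA_character_,
                          note = sprintf("class '%s' absent from both labelings",
                                         class)),
                     class = "kappa_result"))
  }
  cohens_kappa(ifelse(as.character(a) == class, class, ".rest"),
               ifelse(as.character(b) == class, class, ".rest"))
}

#' Landis-Koch interpretation of a kappa value
#'
#' Qualitative bands: below 0 "Poor", 0.00-0.20 "Slight", 0.21-0.40
#' "Fair", 0.41-0.60 "Moderate", 0.61-0.80 "Substantial", 0.81-1.00
#' "Almost perfect". Bands are half-open with the printed upper bound
#' inclusive: (0.20, 0.40] is "Fair", and so on. Values above 1 are an
#' error.
#'
#' @param kappa Numeric vector of kappa values (each <= 1).
#' @return Character vector of category labels.
#' @export
interpret_kappa <- function(kappa) {
  if (any(!is.na(kappa) & kappa > 1)) abort("kappa cannot exceed 1.")
  cut_pts <- c(-Inf, 0, 0.20, 0.40, 0.60, 0.80, 1)
  labels <- c("Poor", "Slight", "Fair", "Moderate", "Substantial",
              "Almost perfect")
  # "Below 0.0" is Poor, so 0 itself opens the Slight band
  out <- as.character(cut(kappa, breaks = cut_pts, labels = labels,
                          right = TRUE, include.lowest = FALSE))
  out[!is.na(kappa) & kappa == 0] <- "Slight"
  out[!is.na(kappa) & kappa < 0] <- "Poor"
  out
}

#' Per-platform subtype agreement against a reference
#'
#' For each non-reference platform: overall percent agreement with the
#' reference over patients present on both, the overall multiclass kappa,
#' and one-vs-rest kappas per class (mirroring per-class reporting such as
#' LumP/LumU/Ba-Sq agreement). Missing samples and missing labels are
#' excluded pairwise; classes absent from both labelings yield `NA`
#' per-class rows with a note.
#'
#' @param sample_sheet Sample sheet with `patient`, `platform`, `subtype`.
#' @param reference Reference platform name.
#' @param classes Declared class set (default: the classes observed).
#' @return A tibble with columns `platform`, `scope` (`"overall"` or the
#'   class name), `agreement_pct`, `kappa`, `po`, `pe`, `n`, `category`,
#'   `note`.
#' @export
agreement_summary <- function(sample_sheet, reference, classes = NULL) {
  need <- c("patient", "platform", "subtype")
  miss <- setdiff(need, names(sample_sheet))
  if (length(miss)) {
    abort(paste("Sample sheet lacks column(s):", paste(miss, collapse = ", ")))
  }
  sheet <- sample_sheet[!is.na(sample_sheet$subtype), ]
  ref_lab <- setNames(sheet$subtype[sheet$platform == reference],
                      sheet$patient[sheet$platform == reference])
  if (length(ref_lab) == 0) {
    abort(sprintf("Reference platform '%s' has no labelled samples.", reference))
  }
  if (is.null(classes)) classes <- sort(unique(sheet$subtype))
  platforms <- setdiff(unique(sheet$platform), reference)
  purrr::map_dfr(platforms, function(pf) {
    pf_lab <- setNames(sheet$subtype[sheet$platform == pf],
                       sheet$patient[sheet$platform == pf])
    keys <- intersect(names(ref_lab), names(pf_lab))
    if (length(keys) == 0) {
      return(tibble(platform = pf, scope = "overall",
                    agreement_pct = NA_real_, kappa = NA_real_,
                    po = NA_real_, pe = NA_real_, n = 0L,
                    category = NA_character_,
                    note = "no matched labelled pairs"))
    }
    a <- ref_lab[keys]; b <- pf_lab[keys]
    overall <- cohens_kappa(unname(a), unname(b))
    rows <- tibble(platform = pf, scope = "overall",
                   agreement_pct = 100 * overall$po,
                   kappa = overall$kappa, po = overall$po, pe = overall$pe,
                   n = overall$n, category = overall$category,
                   note = overall$note)
    per_class <- purrr::map_dfr(classes, function(cl) {
      k <- per_class_kappa(unname(a), unname(b), cl)
      tibble(platform = pf, scope = cl,
             agreement_pct = if (is.na(k$po)) NA_real_ else 100 * k$po,
             kappa = k$kappa, po = k$po, pe = k$pe, n = k$n,
             category = k$category, note = k$note)
    })
    bind_rows(rows, per_class)
  })
}
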