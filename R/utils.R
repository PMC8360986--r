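# Internal helpers shared across modules.

# Deterministic sub-seed derivation: one master seed, independent streams per
# labelled sub-generator, so adding a platform never perturbs the others.
# Kept below 2^31 - 1 (R integers are 32-bit).
split_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483647L)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# An expression matrix travels as a tibble: first column `gene_id`, one
# numeric column per sample. These helpers validate and convert.
check_expression_tbl <- function(x, arg = "matrix") {
  if (!is.data.frame(x) || !"gene_id" %in% names(x)) {
    abort(sprintf("`%s` must be a data frame with a `gene_id` first column.", arg))
  }
  if (anyDuplicated(x$gene_id)) {
    dup <- unique(x$gene_id[duplicated(x$gene_id)])
    abort(sprintf("Duplicate gene IDs in `%s`: %s", arg,
                  paste(head(dup, 5), collapse = ", ")))
  }
  vals <- x[setdiff(names(x), "gene_id")]
  if (anyDuplicated(names(vals))) {
    abort(sprintf("Duplicate sample IDs in `%s`.", arg))
  }
  bad_col <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(bad_col)) {
    abort(sprintf("Non-numeric expression column(s) in `%s`: %s", arg,
                  paste(head(bad_col, 5), collapse = ", ")))
  }
  m <- as.matrix(vals)
  if (anyNA(m)) abort(sprintf("Missing values in `%s` are not allowed.", arg))
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("Negative FPKM in `%s` at gene %s, sample %s.", arg,
                  x$gene_id[idx[1]], colnames(m)[idx[2]]))
  }
  invisible(x)
}

expr_to_matrix <- function(x) {
  m <- as.matrix(x[setdiff(names(x), "gene_id")])
  rownames(m) <- x$gene_id
  m
}

matrix_to_expr <- function(m) {
  tibble::as_tibble(as.data.frame(m), rownames = "gene_id")
}

sample_ids_of <- function(x) setdiff(names(x), "gene_id")

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be an integer >= %s.", name, min))
  }
  as.integer(x)
}

check_scalar <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a number in [%s, %s].", name, min, max))
  }
  as.numeric(x)
}
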