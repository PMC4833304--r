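#' Expression tables
#'
#' All user-facing functions in pairqc exchange expression data as a tidy
#' "expression table": a data frame whose first column (`gene_id`) holds
#' unique gene identifiers and whose remaining columns are one numeric,
#' nonnegative expression vector per sample (FPKM, TPM, CPM, ranks, ...).
#' A numeric matrix with gene rownames and sample colnames is accepted
#' everywhere an expression table is, and is converted on the way in.
#'
#' Invariants enforced by [validate_expression()]:
#' * gene identifiers and sample names are unique,
#' * every value is finite and `>= 0` (missing values are a hard error:
#'   the perturbation and scoring model has no missing-data pathway),
#' * at least 2 samples (co-variation needs multiple samples).
#'
#' @name expression_table
NULL

# ---- internal canonical form: numeric matrix, genes x samples -------------

as_expr_matrix <- function(x, arg = "x") {
  if (is.matrix(x)) {
    m <- x
    if (is.null(rownames(m))) {
      abort(sprintf("`%s` must have gene identifiers as rownames.", arg))
    }
  } else if (is.data.frame(x)) {
    if (ncol(x) < 2L) {
      abort(sprintf("`%s` must have a gene-id column plus sample columns.", arg))
    }
    ids <- as.character(x[[1L]])
    m <- as.matrix(x[, -1L, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(!vapply(x[-1L], is.numeric, logical(1)))[1L]
      abort(sprintf(
        "`%s`: sample column '%s' is not numeric.",
        arg, names(x)[-1L][bad]
      ))
    }
    rownames(m) <- ids
  } else {
    abort(sprintf("`%s` must be a data frame or a numeric matrix.", arg))
  }
  m
}

expr_as_tibble <- function(m) {
  tibble::as_tibble(
    cbind(tibble::tibble(gene_id = rownames(m)), tibble::as_tibble(m))
  )
}

# Validate the canonical matrix form; returns it invisibly.
check_expr_matrix <- function(m, arg = "x") {
  ids <- rownames(m)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    abort(sprintf("`%s` has a duplicated gene identifier: '%s'.", arg, dup))
  }
  smp <- colnames(m)
  if (!is.null(smp) && anyDuplicated(smp)) {
    abort(sprintf(
      "`%s` has a duplicated sample name: '%s'.",
      arg, smp[duplicated(smp)][1L]
    ))
  }
  if (ncol(m) < 2L) {
    abort(sprintf("`%s` must have at least 2 samples, got %d.", arg, ncol(m)))
  }
  bad <- which(!is.finite(m) | m < 0)
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(m))
    abort(sprintf(
      "`%s` has a non-finite, missing or negative value at gene '%s', sample '%s'.",
      arg, rownames(m)[i[1L]],
      if (is.null(smp)) as.character(i[2L]) else smp[i[2L]]
    ))
  }
  invisible(m)
}

#' Validate an expression table
#'
#' Checks the invariants documented in [expression_table] and returns the
#' input invisibly, so it can be dropped into a pipe.
#'
#' @param x An expression table (data frame with `gene_id` first column) or
#'   a numeric matrix with gene rownames.
#' @return `x`, invisibly. Errors describe the first offending cell.
#' @export
validate_expression <- function(x) {
  check_expr_matrix(as_expr_matrix(x))
  invisible(x)
}

#' Read a gene-by-sample expression matrix
#'
#' Reads a delimited text file whose header row holds sample names, first
#' column gene identifiers, and body nonnegative numeric expression, and
#' returns it as a validated expression table. Row and column order are
#' preserved from the file.
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter; tab by default, use `","` for CSV.
#' @return A tibble: `gene_id` plus one numeric column per sample.
#' @examples
#' f <- system.file("extdata", "synthetic_expression.tsv", package = "pairqc")
#' expr <- read_expression_matrix(f)
#' @export
read_expression_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  tbl <- readr::read_delim(
    path,
    delim = delimiter, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      readr::col_character(), .default = readr::col_double()
    )
  )
  if (ncol(tbl) < 2L) {
    abort(sprintf("'%s' must have a gene-id column plus >= 2 sample columns.", path))
  }
  names(tbl)[1L] <- "gene_id"
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0L) {
    abort(sprintf(
      "'%s' has a non-numeric cell at row %d, column %d.",
      path, prob$row[1L], prob$col[1L]
    ))
  }
  validate_expression(tbl)
  tbl
}

#' Write an expression table to tab-separated text
#'
#' Inverse of [read_expression_matrix()]: sample names in the header row,
#' gene identifiers in the first column.
#'
#' @param x Expression table or matrix.
#' @param path Output path.
#' @param delimiter Field delimiter (default tab).
#' @return `x` invisibly.
#' @export
write_expression_matrix <- function(x, path, delimiter = "\t") {
  m <- check_expr_matrix(as_expr_matrix(x))
  readr::write_delim(expr_as_tibble(m), path, delim = delimiter)
  invisible(x)
}

#' Rank-transform each gene across samples
#'
#' Replaces every gene's expression profile by its ranks across samples
#' (1..n), with ties receiving the average (mid) rank. Rank transformation
#' is the only normalisation the perturbation/scoring model needs; the
#' detection step is rank-based and therefore invariant to any monotone
#' per-gene normalisation.
#'
#' @param x Expression table or matrix.
#' @return An expression table of per-gene ranks, same shape and order.
#' @examples
#' m <- matrix(c(2, 8, 4), 1, dimnames = list("g1", c("a", "b", "c")))
#' rank_transform(m) # ranks 1, 3, 2
#' @export
rank_transform <- function(x) {
  m <- check_expr_matrix(as_expr_matrix(x))
  expr_as_tibble(row_midranks(m))
}
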