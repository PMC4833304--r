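#' Gene-pair tables
#'
#' A pair table is a tibble with character columns `gene_a`, `gene_b` and a
#' `kind` column (`"housekeeping"`, `"random"` or `"self_replicate"`).
#' Pairs are unordered: (A,B) and (B,A) are the same pair, no gene is
#' paired with itself (except across replicate experiments, where the two
#' members are distinct suffixed profiles of the same gene), and no pair
#' appears twice.
#'
#' @name pair_table
NULL

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

new_pair_table <- function(gene_a, gene_b, kind) {
  tibble::tibble(
    gene_a = as.character(gene_a),
    gene_b = as.character(gene_b),
    kind = kind
  )
}

#' Load a two-column gene-pair file
#'
#' Reads a tab-separated file of gene identifier pairs (lines starting with
#' `#` are skipped), drops duplicated unordered pairs keeping first
#' occurrence, and errors on self-pairs.
#'
#' @param path Path to a two-column TSV.
#' @param kind Provenance tag for the loaded set, default `"housekeeping"`.
#' @return A [pair_table].
#' @examples
#' f <- system.file("extdata", "synthetic_pairs.tsv", package = "pairqc")
#' pairs <- load_pairs(f)
#' @export
load_pairs <- function(path, kind = "housekeeping") {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  tbl <- readr::read_tsv(
    path,
    comment = "#", col_names = FALSE, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (ncol(tbl) < 2L || nrow(tbl) < 1L) {
    abort(sprintf("'%s' must contain at least one two-column pair row.", path))
  }
  a <- tbl[[1L]]
  b <- tbl[[2L]]
  if (any(a == b)) {
    abort(sprintf(
      "'%s' pairs a gene with itself ('%s', row %d).",
      path, a[a == b][1L], which(a == b)[1L]
    ))
  }
  keep <- !duplicated(pair_key(a, b))
  new_pair_table(a[keep], b[keep], kind)
}

#' Filter pairs against an expression table
#'
#' Keeps only pairs where both genes are measured in `x` and both vary
#' across samples (a constant profile has no defined regression). Warns if
#' fewer than `min_pairs` survive: aggregate detection needs roughly 500 or
#' more pairs to be stable.
#'
#' @param pairs A [pair_table].
#' @param x Expression table or matrix.
#' @param min_pairs Threshold below which a warning is emitted (default 500).
#' @return The filtered pair table, in the original order.
#' @export
filter_pairs <- function(pairs, x, min_pairs = 500L) {
  m <- check_expr_matrix(as_expr_matrix(x))
  v <- variable_genes(m)
  keep <- pairs$gene_a %in% v & pairs$gene_b %in% v
  out <- pairs[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    abort("No pairs survive filtering: no pair has both genes measured and variable.")
  }
  if (nrow(out) < min_pairs) {
    warn(sprintf(
      "Only %d pairs survive filtering; aggregate detection is unstable below ~%d pairs.",
      nrow(out), min_pairs
    ))
  }
  out
}

# Genes with nonzero variance across samples.
variable_genes <- function(m) {
  rn <- rowRanges_minmax(m)
  rownames(m)[rn[, 1L] < rn[, 2L]]
}

rowRanges_minmax <- function(m) {
  cbind(do.call(pmin, as.data.frame(m)), do.call(pmax, as.data.frame(m)))
}

#' Draw a random-pair null set
#'
#' Samples `n_pairs` distinct unordered gene pairs uniformly from the
#' variance-filtered genes of `x`, excluding any pair present in `exclude`
#' (genes may still be shared with excluded pairs). Strong detection
#' performance on such a null set indicates systematic technical
#' co-variation rather than biology.
#'
#' @param x Expression table or matrix.
#' @param n_pairs Number of pairs to draw.
#' @param exclude Optional [pair_table] of pairs that must not be drawn
#'   (typically the housekeeping set).
#' @param seed Optional integer seed; the draw is a pure function of
#'   `(x, n_pairs, exclude, seed)`.
#' @return A [pair_table] with `kind = "random"`.
#' @export
sample_random_pairs <- function(x, n_pairs, exclude = NULL, seed = NULL) {
  m <- check_expr_matrix(as_expr_matrix(x))
  check_scalar_number(n_pairs, "n_pairs", lower = 1)
  genes <- variable_genes(m)
  g <- length(genes)
  if (g < 2L) abort("Need at least 2 variable genes to sample pairs.")
  excl <- if (is.null(exclude)) character(0) else pair_key(exclude$gene_a, exclude$gene_b)
  total <- choose(g, 2) - length(unique(pair_key_all_present(excl, genes)))
  if (n_pairs > total) {
    abort(sprintf(
      "Requested %d random pairs but only %.0f distinct pairs are available.",
      n_pairs, total
    ))
  }
  with_seed_if(seed, {
    picked <- character(0)
    out_a <- character(0)
    out_b <- character(0)
    guard <- 0L
    while (length(out_a) < n_pairs) {
      need <- n_pairs - length(out_a)
      i <- sample.int(g, 2L * need, replace = TRUE)
      j <- sample.int(g, 2L * need, replace = TRUE)
      ok <- i != j
      a <- genes[i[ok]]
      b <- genes[j[ok]]
      key <- pair_key(a, b)
      ok2 <- !duplicated(key) & !(key %in% picked) & !(key %in% excl)
      a <- a[ok2]
      b <- b[ok2]
      key <- key[ok2]
      take <- seq_len(min(length(a), need))
      out_a <- c(out_a, a[take])
      out_b <- c(out_b, b[take])
      picked <- c(picked, key[take])
      guard <- guard + 1L
      if (guard > 10000L) abort("Random pair sampling failed to converge.")
    }
    new_pair_table(out_a, out_b, "random")
  })
}

# keys in `excl` whose two genes are both in `genes` (others can't be drawn
# anyway, so they don't reduce the available pool)
pair_key_all_present <- function(excl, genes) {
  if (!length(excl)) return(character(0))
  parts <- strsplit(excl, "\r", fixed = TRUE)
  ok <- vapply(parts, function(p) all(p %in% genes), logical(1))
  excl[ok]
}

#' Pair each gene with its replicate profile
#'
#' Stacks two replicate experiments (same samples, overlapping genes) into
#' one expression table in which every shared gene appears twice — once per
#' experiment, with suffixed identifiers — and returns the self pairs
#' linking the two profiles of each gene. The perturb/score engine then
#' runs unchanged with true replicates in place of co-expressed pairs.
#'
#' @param x,y Aligned replicate expression tables (identical sample names,
#'   overlapping gene identifiers).
#' @param suffixes Length-2 character suffixes for the two experiments.
#' @return A list with `expr` (stacked expression table) and `pairs`
#'   (a [pair_table] with `kind = "self_replicate"`).
#' @export
replicate_self_pairs <- function(x, y, suffixes = c(".x", ".y")) {
  mx <- check_expr_matrix(as_expr_matrix(x, "x"), "x")
  my <- check_expr_matrix(as_expr_matrix(y, "y"), "y")
  if (!identical(colnames(mx), colnames(my))) {
    abort("`x` and `y` must have identical sample names in the same order.")
  }
  shared <- intersect(rownames(mx), rownames(my))
  if (length(shared) == 0L) abort("`x` and `y` share no gene identifiers.")
  a <- paste0(shared, suffixes[1L])
  b <- paste0(shared, suffixes[2L])
  stacked <- rbind(mx[shared, , drop = FALSE], my[shared, , drop = FALSE])
  rownames(stacked) <- c(a, b)
  list(
    expr = expr_as_tibble(stacked),
    pairs = new_pair_table(a, b, "self_replicate")
  )
}
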