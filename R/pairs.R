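#' Intersect a gene panel with the genes measured in every cohort
#'
#' Restricts a panel to the genes present in all supplied cohorts, keeping
#' the panel's canonical order. Signatures are only portable across cohorts
#' and platforms for genes measured everywhere.
#'
#' @param cohorts List of `brgpi_cohort` objects, expression matrices, or
#'   plain character vectors of gene ids.
#' @param panel Character vector of panel gene ids in canonical order.
#' @return The shared panel genes, in panel order.
#' @export
intersect_panel <- function(cohorts, panel) {
  if (!length(cohorts)) stop("at least one cohort is required", call. = FALSE)
  gene_sets <- lapply(cohorts, function(co) {
    if (inherits(co, "brgpi_cohort")) co$gene_ids
    else if (is.matrix(co)) rownames(co)
    else as.character(co)
  })
  shared <- panel
  for (gs in gene_sets) shared <- shared[shared %in% gs]
  if (!length(shared)) {
    miss <- vapply(seq_along(gene_sets), function(i) {
      sprintf("cohort %d missing: %s", i,
              paste(utils::head(setdiff(panel, gene_sets[[i]]), 10), collapse = ", "))
    }, "")
    stop("no panel gene is shared by all cohorts\n",
         paste(miss, collapse = "\n"), call. = FALSE)
  }
  shared
}

#' Build all candidate gene pairs from a panel
#'
#' Enumerates every unordered pair of panel genes in canonical orientation:
#' `gene_a` is the gene that appears first in the supplied panel order, and
#' the pair's indicator reads "gene_a expressed above gene_b". For `n` genes
#' this yields `n (n - 1) / 2` pairs.
#'
#' @param genes Character vector of at least two gene ids, in canonical order.
#' @return Data frame with columns `gene_a`, `gene_b`, `pair_id`
#'   (`"GENEA|GENEB"`).
#' @export
#' @examples
#' build_pairs(c("CCL2", "CXCL9", "VEGFA"))
build_pairs <- function(genes) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate gene ids in panel", call. = FALSE)
  if (length(genes) < 2) stop("at least two genes are required", call. = FALSE)
  idx <- utils::combn(length(genes), 2)
  ga <- genes[idx[1, ]]
  gb <- genes[idx[2, ]]
  data.frame(gene_a = ga, gene_b = gb,
             pair_id = paste(ga, gb, sep = "|"),
             stringsAsFactors = FALSE)
}

#' Encode samples by within-sample relative-expression indicators
#'
#' For each pair and sample, scores 1 if `gene_a` is expressed strictly above
#' `gene_b` within that sample and 0 otherwise (ties score 0). The encoding
#' depends only on the sign of within-sample expression differences, so it is
#' identical before and after any strictly increasing per-sample transform —
#' this is what makes pair signatures normalization-free.
#'
#' @param expression Gene-by-sample matrix with gene ids as rownames, or a
#'   `brgpi_cohort`.
#' @param pairs Data frame from [build_pairs()] (columns `gene_a`, `gene_b`,
#'   `pair_id`).
#' @return An object of class `brgpi_pairs`: list with `pairs`, `sample_ids`
#'   and `values` (pair-by-sample 0/1 integer matrix, rownames = pair ids).
#' @export
encode_pairs <- function(expression, pairs) {
  if (inherits(expression, "brgpi_cohort")) expression <- expression$expression
  expression <- as.matrix(expression)
  need <- unique(c(pairs$gene_a, pairs$gene_b))
  miss <- setdiff(need, rownames(expression))
  if (length(miss))
    stop("pair gene(s) absent from expression matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  v <- (expression[pairs$gene_a, , drop = FALSE] >
          expression[pairs$gene_b, , drop = FALSE]) + 0L
  storage.mode(v) <- "integer"
  rownames(v) <- pairs$pair_id
  structure(list(pairs = pairs,
                 sample_ids = colnames(expression),
                 values = v),
            class = "brgpi_pairs")
}

#' @export
print.brgpi_pairs <- function(x, ...) {
  cat(sprintf("Pair indicator matrix: %d pairs x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Drop near-constant pair indicators
#'
#' Retains only pairs whose indicator mean across samples lies in
#' `[min_frac, 1 - min_frac]`. Pairs that are (almost) always 0 or always 1
#' carry no contrast for survival screening and only inflate the number of
#' tests; a constancy filter of this kind is standard in relative-ordering
#' signature construction.
#'
#' @param indicators A `brgpi_pairs` object.
#' @param min_frac Minimum minority fraction, in `(0, 0.5]` (default 0.2).
#' @return A filtered `brgpi_pairs` object (possibly with zero pairs).
#' @export
filter_pairs <- function(indicators, min_frac = 0.2) {
  stopifnot(inherits(indicators, "brgpi_pairs"))
  if (!is.numeric(min_frac) || min_frac <= 0 || min_frac > 0.5)
    stop("min_frac must lie in (0, 0.5]", call. = FALSE)
  m <- rowMeans(indicators$values)
  keep <- m >= min_frac & m <= 1 - min_frac
  structure(list(pairs = indicators$pairs[keep, , drop = FALSE],
                 sample_ids = indicators$sample_ids,
                 values = indicators$values[keep, , drop = FALSE]),
            class = "brgpi_pairs")
}

#' Write / read a pair indicator matrix as TSV
#'
#' The dialect matches the expression TSV: first column `pair_id`
#' (`"GENEA|GENEB"`), one 0/1 column per sample.
#'
#' @param indicators A `brgpi_pairs` object.
#' @param path Output file.
#' @return `write_indicators` invisibly returns `path`; `read_indicators`
#'   returns a `brgpi_pairs` object.
#' @export
write_indicators <- function(indicators, path) {
  stopifnot(inherits(indicators, "brgpi_pairs"))
  df <- data.frame(pair_id = rownames(indicators$values),
                   indicators$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_indicators
#' @export
read_indicators <- function(path) {
  m <- read_expression(path)
  if (!all(m %in% c(0L, 1L)))
    stop("indicator file contains values other than 0/1", call. = FALSE)
  parts <- strsplit(rownames(m), "|", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad))
    stop("malformed pair id(s): ",
         paste(utils::head(rownames(m)[bad], 5), collapse = ", "), call. = FALSE)
  pairs <- data.frame(gene_a = vapply(parts, `[`, "", 1),
                      gene_b = vapply(parts, `[`, "", 2),
                      pair_id = rownames(m), stringsAsFactors = FALSE)
  v <- m
  storage.mode(v) <- "integer"
  structure(list(pairs = pairs, sample_ids = colnames(m), values = v),
            class = "brgpi_pairs")
}
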