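# Expression matrices (genes x samples raw counts) and median-of-ratios
# normalization.

#' Create an expression matrix
#'
#' @param counts Numeric matrix, genes in rows (rownames = gene IDs),
#'   samples in columns (colnames = sample/tissue names); non-negative.
#' @param normalized Whether values are already size-factor normalized.
#' @return An \code{expr_matrix} object.
#' @export
expr_matrix <- function(counts, normalized = FALSE) {
  stopifnot(is.matrix(counts), is.numeric(counts))
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts))) stop("duplicate sample IDs")
  if (any(is.na(counts))) stop("counts contain missing values")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(counts = counts, normalized = isTRUE(normalized)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$normalized) "normalized" else "raw counts"))
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample IDs and a first column of gene IDs.
#'
#' @param path TSV file.
#' @return A raw-count [expr_matrix] (\code{normalized = FALSE}).
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("expression TSV needs gene IDs plus >= 1 sample")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate gene ID in expression file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (any(is.na(vals))) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("missing/non-numeric cell at gene ", ids[bad[1L]],
         ", sample ", colnames(vals)[bad[2L]])
  }
  rownames(vals) <- ids
  expr_matrix(vals, normalized = FALSE)
}

#' Write an expression matrix as TSV
#' @param m An [expr_matrix].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m$counts), m$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed as the median, over genes with
#' all-positive counts, of the ratio of the gene's count in that sample to
#' the gene's geometric mean across samples.
#'
#' @param m An [expr_matrix] of raw counts.
#' @return Named positive numeric vector, one factor per sample.
#' @export
#' @examples
#' m <- expr_matrix(matrix(c(10, 30, 20, 60), 2,
#'                         dimnames = list(c("g1", "g2"), c("s1", "s2"))))
#' size_factors(m) # 0.7071, 1.4142
size_factors <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  counts <- m$counts
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stop("no gene has all-positive counts; add pseudocounts before ",
         "normalization")
  loggeo <- rowMeans(log(counts[ref, , drop = FALSE]))
  sf <- apply(counts[ref, , drop = FALSE], 2L, function(col)
    exp(median(log(col) - loggeo)))
  setNames(sf, colnames(counts))
}

#' Normalize an expression matrix by its size factors
#' @param m A raw-count [expr_matrix].
#' @return A normalized [expr_matrix] (each sample divided by its factor).
#' @export
normalize_expression <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$normalized) return(m)
  sf <- size_factors(m)
  expr_matrix(sweep(m$counts, 2L, sf, "/"), normalized = TRUE)
}
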