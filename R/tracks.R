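# Annotation sets (classed intervals: repeats, SNPs, somatic mutations,
# cancer-protein loci) and sparse signal tracks (conservation, histone
# marks). Both carry per-chromosome IRanges indexes built once at
# construction so feature extraction stays fast.

#' Create an annotation set
#'
#' A named collection of classed genomic intervals, e.g. repeat elements
#' with class labels LINE/SINE/LTR/Satellite, GWAS SNPs, or somatic
#' mutations.
#'
#' @param name Set name.
#' @param records data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open) and \code{class}.
#' @param vocabulary Allowed class labels; defaults to the labels present.
#' @return An \code{annotation_set}.
#' @export
annotation_set <- function(name, records, vocabulary = NULL) {
  stopifnot(is.character(name), is.data.frame(records))
  need <- c("chrom", "start", "end", "class")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  records$start <- as.integer(records$start)
  records$end <- as.integer(records$end)
  records$class <- as.character(records$class)
  if (nrow(records) > 0L && any(records$start < 0L | records$start >= records$end))
    stop("all records need 0 <= start < end")
  if (is.null(vocabulary)) vocabulary <- sort(unique(records$class))
  bad <- setdiff(records$class, vocabulary)
  if (length(bad))
    stop("record classes outside vocabulary: ", paste(unique(bad), collapse = ", "))
  index <- lapply(split(records, records$chrom), function(d)
    list(ir = .as_iranges(d$start, d$end), class = d$class))
  structure(list(name = name, records = records, vocabulary = vocabulary,
                 index = index),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set '%s': %d records, classes: %s\n",
              x$name, nrow(x$records), paste(x$vocabulary, collapse = ", ")))
  invisible(x)
}

#' Create a signal track
#'
#' A sparse per-base signal (bedGraph semantics): sorted non-overlapping
#' intervals with finite float values; uncovered bases have implicit
#' value 0.
#'
#' @param name Track name, e.g. \code{"H1hescH3k4me1"} or
#'   \code{"phastCons"}.
#' @param data data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open) and \code{value}.
#' @return A \code{signal_track}.
#' @export
signal_track <- function(name, data) {
  stopifnot(is.character(name), is.data.frame(data))
  need <- c("chrom", "start", "end", "value")
  if (!all(need %in% names(data)))
    stop("data must have columns: ", paste(need, collapse = ", "))
  data$start <- as.integer(data$start)
  data$end <- as.integer(data$end)
  data$value <- as.numeric(data$value)
  if (nrow(data) > 0L) {
    if (any(!is.finite(data$value))) stop("track values must be finite")
    if (any(data$start < 0L | data$start >= data$end))
      stop("all intervals need 0 <= start < end")
  }
  data <- data[order(data$chrom, data$start), , drop = FALSE]
  rownames(data) <- NULL
  index <- lapply(split(data, data$chrom), function(d) {
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)]))
      stop("track '", name, "' has overlapping intervals on ", d$chrom[1L])
    list(ir = .as_iranges(d$start, d$end), value = d$value)
  })
  structure(list(name = name, data = data, index = index),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track '%s': %d intervals on %d chromosome(s)\n",
              x$name, nrow(x$data), length(x$index)))
  invisible(x)
}

#' Read a BED annotation file (class label in column 4)
#'
#' @param path BED4+ file; column 4 holds the record class (repeat class,
#'   SNP/mutation tag, gene symbol for loci sets).
#' @param name Set name; defaults to the file name.
#' @param vocabulary Optional fixed class vocabulary.
#' @return An [annotation_set].
#' @export
read_annotation_bed <- function(path, name = basename(path), vocabulary = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  records <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    class = if (!is.null(gr$name)) as.character(gr$name) else "record",
    stringsAsFactors = FALSE)
  annotation_set(name, records, vocabulary)
}

#' Write an annotation set as BED4
#' @param annot An [annotation_set].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_annotation_bed <- function(annot, path) {
  df <- annot$records
  utils::write.table(df[, c("chrom", "start", "end", "class")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#' @param path bedGraph file (4 columns, 0-based half-open).
#' @param name Track name; defaults to the file name without extension.
#' @return A [signal_track].
#' @export
read_bedgraph <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  signal_track(name, data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = as.numeric(gr$score),
    stringsAsFactors = FALSE))
}

#' Write a signal track as bedGraph
#' @param track A [signal_track].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  utils::write.table(track$data[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a one-ID-per-line gene list
#' @param path Plain-text file, one identifier per line; blank lines and
#'   lines starting with '#' are skipped.
#' @return Character vector of IDs.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write a one-ID-per-line gene list
#' @param ids Character vector.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}
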