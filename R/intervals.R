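# Genome-interval primitives. All coordinates are 0-based, half-open
# [start, end); format readers/writers localize dialect conversions.

#' Create a genomic interval
#'
#' Intervals are 0-based, half-open \code{[start, end)}, the BED-native
#' convention used throughout the package.
#'
#' @param chrom Chromosome name (non-empty string).
#' @param start 0-based inclusive start, \code{0 <= start < end}.
#' @param end Exclusive end.
#' @param strand One of \code{"+"}, \code{"-"}, \code{"."}.
#' @return An object of class \code{genomic_interval}.
#' @export
#' @examples
#' genomic_interval("chr1", 100, 200, "+")
genomic_interval <- function(chrom, start, end, strand = ".") {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end, ")")
  if (!strand %in% c("+", "-", "."))
    stop("strand must be one of '+', '-', '.'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s:%d-%d(%s)>\n", x$chrom, x$start, x$end, x$strand))
  invisible(x)
}

interval_width <- function(x) x$end - x$start

# internal: convert 0-based half-open columns to an IRanges (1-based closed)
.as_iranges <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

#' Merged TSS flank window
#'
#' Returns the single window \code{[tss - w, tss + w)} around a gene's
#' transcription start site, with the upstream and downstream halves merged
#' and the left edge clipped at zero. The TSS is the strand-aware 5' end of
#' the gene body.
#'
#' @param gene A single-row [gene_set] subset, or a list with fields
#'   \code{chrom}, \code{start}, \code{end}, \code{strand}.
#' @param w Flank half-width in bp, \code{> 0}.
#' @return A [genomic_interval].
#' @export
tss_flank <- function(gene, w) {
  w <- as.integer(w)
  if (is.na(w) || w <= 0L) stop("w must be a positive integer")
  tss <- if (gene$strand == "-") gene$end - 1L else gene$start
  genomic_interval(gene$chrom, max(0L, tss - w), tss + w, gene$strand)
}

#' Count annotation records overlapping a region
#'
#' @param region A [genomic_interval].
#' @param annot An [annotation_set].
#' @param class_label Record class to count (e.g. \code{"SINE"}); must be in
#'   the set's vocabulary.
#' @return Integer count of records of that class intersecting the region by
#'   at least one base.
#' @export
count_overlaps <- function(region, annot, class_label) {
  stopifnot(inherits(region, "genomic_interval"), inherits(annot, "annotation_set"))
  if (!class_label %in% annot$vocabulary)
    stop("unknown class label '", class_label, "'; known: ",
         paste(annot$vocabulary, collapse = ", "))
  df <- data.frame(chrom = region$chrom, start = region$start, end = region$end)
  as.integer(count_overlaps_many(annot, df, class_label))
}

# Vectorized overlap counting: one count per row of `regions`
# (data.frame chrom/start/end). Used by the feature extractors.
count_overlaps_many <- function(annot, regions, class_label) {
  stopifnot(inherits(annot, "annotation_set"))
  out <- integer(nrow(regions))
  if (nrow(regions) == 0L) return(out)
  for (ch in unique(regions$chrom)) {
    sel <- which(regions$chrom == ch)
    idx <- annot$index[[ch]]
    if (is.null(idx)) next
    keep <- idx$class == class_label
    if (!any(keep)) next
    q <- .as_iranges(regions$start[sel], regions$end[sel])
    out[sel] <- IRanges::countOverlaps(q, idx$ir[keep])
  }
  out
}

#' Base-weighted mean signal over a region
#'
#' Averages a sparse signal track over every base of \code{region};
#' bases not covered by the track contribute 0, matching bedGraph sparse
#' semantics.
#'
#' @param track A [signal_track].
#' @param region A [genomic_interval]; zero-length regions are an error.
#' @return Mean signal (float, 0 if entirely uncovered).
#' @export
mean_signal <- function(track, region) {
  stopifnot(inherits(track, "signal_track"), inherits(region, "genomic_interval"))
  if (interval_width(region) <= 0L) stop("zero-length region")
  df <- data.frame(chrom = region$chrom, start = region$start, end = region$end,
                   group = 1L)
  unname(mean_signal_regions(track, df))[1L]
}

# Vectorized grouped signal mean: `regions` has chrom/start/end/group; the
# return value is one base-weighted mean per group (union of that group's
# intervals), uncovered bases counting as 0. Groups with zero total width
# yield NA.
mean_signal_regions <- function(track, regions) {
  stopifnot(inherits(track, "signal_track"))
  groups <- unique(regions$group)
  sums <- setNames(numeric(length(groups)), as.character(groups))
  widths <- setNames(numeric(length(groups)), as.character(groups))
  w <- pmax(regions$end - regions$start, 0L)
  wt <- tapply(w, regions$group, sum)
  widths[names(wt)] <- wt
  for (ch in unique(regions$chrom)) {
    sel <- which(regions$chrom == ch)
    idx <- track$index[[ch]]
    if (is.null(idx)) next
    q <- .as_iranges(regions$start[sel], regions$end[sel])
    hits <- IRanges::findOverlaps(q, idx$ir)
    if (length(hits) == 0L) next
    ov <- IRanges::width(IRanges::pintersect(q[S4Vectors::queryHits(hits)],
                                             idx$ir[S4Vectors::subjectHits(hits)]))
    contrib <- ov * idx$value[S4Vectors::subjectHits(hits)]
    byg <- tapply(contrib, regions$group[sel][S4Vectors::queryHits(hits)], sum)
    sums[names(byg)] <- sums[names(byg)] + byg
  }
  res <- ifelse(widths > 0, sums / widths, NA_real_)
  setNames(res, names(widths))[as.character(groups)]
}
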