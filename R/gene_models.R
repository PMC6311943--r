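# Gene models: one record per gene with strand, body, exon structure and
# biotype. Collections are stored as a data.frame ("gene_set") with a
# list-column of exon matrices, the lightest container that keeps
# per-gene exon structure first-class.

GENE_BIOTYPES <- c("lncRNA-antisense", "lncRNA-intergenic",
                   "lncRNA-overlapping", "protein_coding", "miRNA")

#' Create a gene set
#'
#' @param df data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open body), \code{strand}
#'   (\code{+}/\code{-}), \code{biotype}, and a list-column \code{exons} of
#'   two-column integer matrices (\code{start}, \code{end}), sorted and
#'   non-overlapping, all within the gene body. A missing \code{exons}
#'   column defaults to single-exon genes spanning the body.
#' @return A \code{gene_set} (data.frame subclass).
#' @export
gene_set <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("gene_id", "chrom", "start", "end", "strand", "biotype")
  if (!all(need %in% names(df)))
    stop("gene set needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$start < 0L | df$start >= df$end))
    stop("gene bodies need 0 <= start < end")
  if (!all(df$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  bad <- setdiff(df$biotype, GENE_BIOTYPES)
  if (length(bad))
    stop("unknown biotype(s): ", paste(unique(bad), collapse = ", "),
         "; known: ", paste(GENE_BIOTYPES, collapse = ", "))
  if (is.null(df$exons))
    df$exons <- lapply(seq_len(nrow(df)), function(i)
      cbind(start = df$start[i], end = df$end[i]))
  for (i in seq_len(nrow(df))) {
    ex <- df$exons[[i]]
    if (!is.matrix(ex) || ncol(ex) != 2L || nrow(ex) < 1L)
      stop("gene ", df$gene_id[i], ": exons must be a 2-column matrix")
    storage.mode(ex) <- "integer"
    colnames(ex) <- c("start", "end")
    if (any(ex[, 1L] >= ex[, 2L]))
      stop("gene ", df$gene_id[i], ": empty exon")
    if (is.unsorted(ex[, 1L], strictly = TRUE) ||
        (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L])))
      stop("gene ", df$gene_id[i], ": exons must be sorted and non-overlapping")
    if (ex[1L, 1L] < df$start[i] || ex[nrow(ex), 2L] > df$end[i])
      stop("gene ", df$gene_id[i], ": exon outside gene span")
    df$exons[[i]] <- ex
  }
  rownames(df) <- NULL
  class(df) <- c("gene_set", "data.frame")
  df
}

#' Strand-aware transcription start sites
#' @param genes A [gene_set].
#' @return Integer vector of TSS positions (0-based), one per gene.
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "-", genes$end - 1L, genes$start)
}

#' Introns of one gene
#' @param exons Two-column exon matrix of a gene.
#' @return Two-column matrix of intron intervals (gaps between consecutive
#'   exons); zero rows for intronless genes.
#' @export
gene_introns <- function(exons) {
  if (nrow(exons) < 2L)
    return(cbind(start = integer(0), end = integer(0)))
  cbind(start = exons[-nrow(exons), 2L], end = exons[-1L, 1L])
}

# single-row accessor used by scalar operations
gene_row <- function(genes, i) {
  if (is.character(i)) i <- match(i, genes$gene_id)
  list(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
       start = genes$start[i], end = genes$end[i],
       strand = genes$strand[i], biotype = genes$biotype[i],
       exons = genes$exons[[i]])
}

#' Read gene models from GTF or BED12
#'
#' GTF files must carry \code{gene} and \code{exon} rows with a
#' \code{gene_id} attribute (and optionally \code{gene_biotype}); 1-based
#' closed GTF coordinates are converted to the package's 0-based half-open
#' convention. BED12 blocks are expanded to exons; BED carries no biotype,
#' so \code{default_biotype} is assigned.
#'
#' @param path Input file.
#' @param format \code{"gtf"} or \code{"bed12"}.
#' @param default_biotype Biotype for formats that do not encode one.
#' @return A [gene_set].
#' @export
read_gene_models <- function(path, format = c("gtf", "bed12"),
                             default_biotype = "lncRNA-intergenic") {
  format <- match.arg(format)
  if (format == "gtf") {
    nf <- utils::count.fields(path, sep = "\t", comment.char = "#",
                              quote = "")
    if (length(nf) && any(nf < 9L))
      stop("malformed GTF line ", which(nf < 9L)[1L], ": fewer than 9 fields")
    gr <- rtracklayer::import(path, format = "gtf")
    md <- S4Vectors::mcols(gr)
    if (is.null(md$gene_id)) stop("GTF lacks gene_id attributes")
    is_gene <- md$type == "gene"
    is_exon <- md$type == "exon"
    if (!any(is_gene)) stop("GTF has no 'gene' rows")
    g <- gr[is_gene]
    biotype <- if (!is.null(md$gene_biotype)) md$gene_biotype[as.vector(is_gene)]
               else rep(default_biotype, sum(is_gene))
    df <- data.frame(
      gene_id = md$gene_id[as.vector(is_gene)],
      chrom = as.character(GenomicRanges::seqnames(g)),
      start = GenomicRanges::start(g) - 1L,
      end = GenomicRanges::end(g),
      strand = as.character(GenomicRanges::strand(g)),
      biotype = as.character(biotype),
      stringsAsFactors = FALSE)
    ex <- gr[is_exon]
    exl <- split(data.frame(start = GenomicRanges::start(ex) - 1L,
                            end = GenomicRanges::end(ex)),
                 md$gene_id[as.vector(is_exon)])
    df$exons <- lapply(df$gene_id, function(id) {
      d <- exl[[id]]
      if (is.null(d)) {
        i <- match(id, df$gene_id)
        return(cbind(start = df$start[i], end = df$end[i]))
      }
      d <- d[order(d$start), , drop = FALSE]
      cbind(start = as.integer(d$start), end = as.integer(d$end))
    })
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    df <- data.frame(
      gene_id = as.character(gr$name),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      biotype = default_biotype,
      stringsAsFactors = FALSE)
    df$strand[!df$strand %in% c("+", "-")] <- "+"
    blocks <- gr$blocks
    df$exons <- lapply(seq_along(gr), function(i) {
      if (is.null(blocks) || length(blocks[[i]]) == 0L)
        return(cbind(start = df$start[i], end = df$end[i]))
      b <- blocks[[i]]
      cbind(start = df$start[i] + IRanges::start(b) - 1L,
            end = df$start[i] + IRanges::end(b))
    })
  }
  gene_set(df)
}

#' Write gene models
#'
#' @param genes A [gene_set].
#' @param path Output file.
#' @param format \code{"gtf"} (gene + exon rows, \code{gene_id} and
#'   \code{gene_biotype} attributes) or \code{"bed12"}.
#' @return The path, invisibly.
#' @export
write_gene_models <- function(genes, path, format = c("gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "gtf") {
    lines <- character(0)
    for (i in seq_len(nrow(genes))) {
      attrs <- sprintf('gene_id "%s"; gene_biotype "%s";',
                       genes$gene_id[i], genes$biotype[i])
      lines <- c(lines, paste(genes$chrom[i], "lncScout", "gene",
                              genes$start[i] + 1L, genes$end[i], ".",
                              genes$strand[i], ".", attrs, sep = "\t"))
      ex <- genes$exons[[i]]
      lines <- c(lines, paste(genes$chrom[i], "lncScout", "exon",
                              ex[, 1L] + 1L, ex[, 2L], ".",
                              genes$strand[i], ".", attrs, sep = "\t"))
    }
    writeLines(lines, path)
  } else {
    rows <- vapply(seq_len(nrow(genes)), function(i) {
      ex <- genes$exons[[i]]
      paste(genes$chrom[i], genes$start[i], genes$end[i], genes$gene_id[i],
            0L, genes$strand[i], genes$start[i], genes$end[i], "0",
            nrow(ex),
            paste0(paste(ex[, 2L] - ex[, 1L], collapse = ","), ","),
            paste0(paste(ex[, 1L] - genes$start[i], collapse = ","), ","),
            sep = "\t")
    }, character(1))
    writeLines(rows, path)
  }
  invisible(path)
}
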