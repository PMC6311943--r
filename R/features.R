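# Feature extraction: genomic (18), expression (16), epigenetic (27)
# blocks, the feature manifest, and assembly of the full gene x feature
# table with an explicit missing-value mask.

#' Default driver-gene panel for network features
#'
#' Mutational-hotspot cancer driver genes whose Spearman correlation with
#' each lncRNA is used as a network feature. Overridable everywhere a
#' driver list is accepted.
#' @export
DRIVER_GENES <- c("BRAF", "CDKN2A", "CTNNB1", "EGFR", "ERBB2", "FBXW7",
                  "GNAS", "H3F3A", "HRAS", "IDH1", "KRAS", "NRAS",
                  "PIK3CA", "PTEN", "RAC1", "SF3B1", "TP53", "U2AF1")

#' The 16 default tissue names for expression features
#' @export
TISSUES_16 <- c("adipose", "adrenal_gland", "brain", "breast", "colon",
                "heart", "kidney", "leukocyte", "liver", "lung",
                "lymph_node", "ovary", "prostate_gland", "skeletal_muscle",
                "testis", "thyroid_gland")

#' The 9 default histone-signal track names
#'
#' Three marks (H3k4me1, H3k4me3, H3k27ac) in three cell lines (Gm12878,
#' K562, H1hesc).
#' @export
TRACK_NAMES <- as.vector(outer(c("Gm12878", "K562", "H1hesc"),
                               c("H3k4me1", "H3k4me3", "H3k27ac"),
                               paste0))

REPEAT_CLASSES <- c("LINE", "LTR", "Satellite", "SINE")

GENOMIC_FEATURES <- c("gc_flank1k", "gc_flank5k", "gc_genebody", "gc_exon",
                      "gc_intron", "cons_exon", "cons_intron",
                      "cons_flank1k",
                      as.vector(t(outer(REPEAT_CLASSES,
                                        c("genebody", "flank1k"),
                                        paste, sep = "_"))),
                      "mirna_host_count", "micropeptide_length")

#' Build the default feature manifest
#'
#' Orders and names every feature column with its category tag: 18 genomic,
#' 16 expression, 27 epigenetic, and 4 + |drivers| network features (22
#' with the default 18-gene driver panel; 83 total). Counts follow the
#' manifest, never a hard-coded constant.
#'
#' @param drivers Driver gene names (one Spearman-correlation feature each).
#' @param tissues Tissue names (one expression feature each).
#' @param tracks Histone track names (three region features each).
#' @return data.frame with columns \code{feature}, \code{category}.
#' @export
feature_manifest <- function(drivers = DRIVER_GENES, tissues = TISSUES_16,
                             tracks = TRACK_NAMES) {
  epi <- as.vector(t(outer(tracks, c("genebody", "flank1k", "flank5k"),
                           paste, sep = "_")))
  net <- c(paste0("scc_", drivers), "cancer_protein_neighbors", "degree",
           "cancer_mirna_interactions", "mirna_interactions")
  df <- data.frame(
    feature = c(GENOMIC_FEATURES, paste0("expr_", tissues), epi, net),
    category = c(rep("genomic", length(GENOMIC_FEATURES)),
                 rep("expression", length(tissues)),
                 rep("epigenetic", length(epi)),
                 rep("network", length(net))),
    stringsAsFactors = FALSE)
  if (anyDuplicated(df$feature)) stop("manifest feature names must be unique")
  df
}

#' GC content of a nucleotide sequence
#'
#' @param seq Character string over A/C/G/T/N (case-insensitive).
#' @return (G+C)/(A+C+G+T); N bases are excluded from the denominator.
#'   All-N or empty sequences give NA (missing).
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- Biostrings::DNAString(toupper(seq))
  f <- Biostrings::letterFrequency(s, letters = c("A", "C", "G", "T"))
  tot <- sum(f)
  if (tot == 0L) return(NA_real_)
  unname((f[["C"]] + f[["G"]]) / tot)
}

#' Longest ORF length in amino acids
#'
#' Scans the three forward reading frames for the longest open reading
#' frame that starts with ATG and ends at a stop codon; returns its length
#' in codons excluding the stop, or 0 if no such ORF exists.
#'
#' @param seq Nucleotide string (length >= 3).
#' @return Integer peptide length.
#' @export
longest_orf_peptide_length <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  if (nchar(s) < 3L) return(0L)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    n_codons <- (nchar(s) - frame) %/% 3L
    if (n_codons < 2L) next
    starts <- frame + 3L * (seq_len(n_codons) - 1L) + 1L
    codons <- substring(s, starts, starts + 2L)
    open_at <- NA_integer_
    for (j in seq_along(codons)) {
      if (codons[j] %in% stops) {
        if (!is.na(open_at)) {
          best <- max(best, j - open_at)
          open_at <- NA_integer_
        }
      } else if (is.na(open_at) && codons[j] == "ATG") {
        open_at <- j
      }
    }
  }
  as.integer(best)
}

# ---- vectorized extraction helpers ------------------------------------

# GC over grouped regions; regions: chrom/start/end/group. Regions are
# clipped to the chromosome; groups with no unambiguous base give NA.
gc_of_regions <- function(seqs, regions) {
  groups <- unique(regions$group)
  acgt <- matrix(0, nrow = length(groups), ncol = 4L,
                 dimnames = list(as.character(groups), c("A", "C", "G", "T")))
  for (ch in unique(regions$chrom)) {
    if (!ch %in% names(seqs)) stop("chromosome absent from FASTA: ", ch)
    len <- Biostrings::width(seqs)[match(ch, names(seqs))]
    sel <- which(regions$chrom == ch)
    s <- pmax(regions$start[sel], 0L) + 1L
    e <- pmin(regions$end[sel], len)
    ok <- s <= e
    if (!any(ok)) next
    v <- Biostrings::Views(seqs[[ch]], start = s[ok], end = e[ok])
    f <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
    byg <- rowsum(f, group = as.character(regions$group[sel][ok]))
    acgt[rownames(byg), ] <- acgt[rownames(byg), , drop = FALSE] + byg
  }
  tot <- rowSums(acgt)
  res <- ifelse(tot > 0, (acgt[, "C"] + acgt[, "G"]) / tot, NA_real_)
  setNames(res, rownames(acgt))[as.character(groups)]
}

# spliced transcript sequence of one gene (exons joined, minus strand
# reverse-complemented)
spliced_sequence <- function(gene, seqs) {
  if (!gene$chrom %in% names(seqs))
    stop("chromosome absent from FASTA: ", gene$chrom)
  ex <- gene$exons
  parts <- Biostrings::Views(seqs[[gene$chrom]],
                             start = ex[, 1L] + 1L, end = ex[, 2L])
  s <- paste(as.character(parts), collapse = "")
  if (gene$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

# regions data.frame builders; group = gene_id
.body_regions <- function(genes)
  data.frame(chrom = genes$chrom, start = genes$start, end = genes$end,
             group = genes$gene_id, stringsAsFactors = FALSE)

.flank_regions <- function(genes, w) {
  tss <- gene_tss(genes)
  data.frame(chrom = genes$chrom, start = pmax(0L, tss - as.integer(w)),
             end = tss + as.integer(w), group = genes$gene_id,
             stringsAsFactors = FALSE)
}

.exon_regions <- function(genes) {
  n <- vapply(genes$exons, nrow, integer(1))
  data.frame(chrom = rep(genes$chrom, n),
             start = unlist(lapply(genes$exons, function(e) e[, 1L])),
             end = unlist(lapply(genes$exons, function(e) e[, 2L])),
             group = rep(genes$gene_id, n), stringsAsFactors = FALSE)
}

.intron_regions <- function(genes) {
  introns <- lapply(genes$exons, gene_introns)
  n <- vapply(introns, nrow, integer(1))
  data.frame(chrom = rep(genes$chrom, n),
             start = unlist(lapply(introns, function(e) e[, 1L])),
             end = unlist(lapply(introns, function(e) e[, 2L])),
             group = rep(genes$gene_id, n), stringsAsFactors = FALSE)
}

# reindex a per-group named vector onto the full gene_id vector (absent
# groups, e.g. intronless genes, become NA)
.by_gene <- function(x, gene_ids) {
  out <- setNames(rep(NA_real_, length(gene_ids)), gene_ids)
  x <- x[!is.na(names(x))]
  out[names(x)[names(x) %in% gene_ids]] <- x[names(x) %in% gene_ids]
  out
}

# ---- feature blocks ----------------------------------------------------

# Genomic block for a whole gene_set. Returns genes x 18 matrix.
genomic_block <- function(genes, seqs, repeats, conservation, mirnas,
                          peptide_table = NULL) {
  ids <- genes$gene_id
  body <- .body_regions(genes)
  fl1 <- .flank_regions(genes, 1000L)
  fl5 <- .flank_regions(genes, 5000L)
  exr <- .exon_regions(genes)
  inr <- .intron_regions(genes)

  out <- matrix(NA_real_, nrow = length(ids), ncol = length(GENOMIC_FEATURES),
                dimnames = list(ids, GENOMIC_FEATURES))
  out[, "gc_flank1k"] <- .by_gene(gc_of_regions(seqs, fl1), ids)
  out[, "gc_flank5k"] <- .by_gene(gc_of_regions(seqs, fl5), ids)
  out[, "gc_genebody"] <- .by_gene(gc_of_regions(seqs, body), ids)
  out[, "gc_exon"] <- .by_gene(gc_of_regions(seqs, exr), ids)
  if (nrow(inr) > 0L)
    out[, "gc_intron"] <- .by_gene(gc_of_regions(seqs, inr), ids)
  out[, "cons_exon"] <- .by_gene(mean_signal_regions(conservation, exr), ids)
  if (nrow(inr) > 0L)
    out[, "cons_intron"] <- .by_gene(mean_signal_regions(conservation, inr), ids)
  out[, "cons_flank1k"] <- .by_gene(mean_signal_regions(conservation, fl1), ids)
  for (cl in REPEAT_CLASSES) {
    out[, paste0(cl, "_genebody")] <- count_overlaps_many(repeats, body, cl)
    out[, paste0(cl, "_flank1k")] <- count_overlaps_many(repeats, fl1, cl)
  }
  mirna_bodies <- annotation_set("mirna_bodies", data.frame(
    chrom = mirnas$chrom, start = mirnas$start, end = mirnas$end,
    class = rep("miRNA", nrow(mirnas)), stringsAsFactors = FALSE),
    vocabulary = "miRNA")
  out[, "mirna_host_count"] <- count_overlaps_many(mirna_bodies, body, "miRNA")
  if (!is.null(peptide_table)) {
    out[, "micropeptide_length"] <-
      peptide_table$peptide_length[match(ids, peptide_table$gene_id)]
  } else {
    out[, "micropeptide_length"] <- vapply(seq_len(nrow(genes)), function(i)
      as.numeric(longest_orf_peptide_length(
        spliced_sequence(gene_row(genes, i), seqs))), numeric(1))
  }
  out
}

#' Genomic features of one gene
#'
#' The 18 default genomic features: GC content of the merged 1 kb and 5 kb
#' TSS flanks, gene body, exon union and intron union; mean conservation of
#' exon union, intron union and 1 kb flank; LINE/LTR/Satellite/SINE counts
#' in gene body and 1 kb flank; hosted miRNA count; micropeptide (longest
#' ORF) length. Intron features of intronless genes are missing (NA).
#'
#' @param gene A single-row [gene_set].
#' @param seqs A \code{DNAStringSet} keyed by chromosome.
#' @param repeats Repeat [annotation_set] (classes LINE/LTR/Satellite/SINE).
#' @param conservation Conservation [signal_track] (e.g. phastCons).
#' @param mirnas [gene_set] of miRNA genes.
#' @param peptide_table Optional data.frame (\code{gene_id},
#'   \code{peptide_length}); takes precedence over the ORF scan.
#' @return Named numeric vector of length 18.
#' @export
genomic_features <- function(gene, seqs, repeats, conservation, mirnas,
                             peptide_table = NULL) {
  stopifnot(inherits(gene, "gene_set"), nrow(gene) == 1L)
  genomic_block(gene, seqs, repeats, conservation, mirnas, peptide_table)[1L, ]
}

#' Epigenetic features of one gene
#'
#' Mean signal of each histone track over the gene body and the merged 1 kb
#' and 5 kb TSS flanks (27 features with the default 9 tracks).
#'
#' @param gene A single-row [gene_set].
#' @param tracks Named list of [signal_track]s.
#' @return Named numeric vector, \code{<track>_<region>} per value.
#' @export
epigenetic_features <- function(gene, tracks) {
  stopifnot(inherits(gene, "gene_set"), nrow(gene) == 1L)
  epigenetic_block(gene, tracks)[1L, ]
}

epigenetic_block <- function(genes, tracks) {
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    stop("tracks must be a named list")
  ids <- genes$gene_id
  regions <- list(genebody = .body_regions(genes),
                  flank1k = .flank_regions(genes, 1000L),
                  flank5k = .flank_regions(genes, 5000L))
  cols <- as.vector(t(outer(names(tracks), names(regions), paste, sep = "_")))
  out <- matrix(NA_real_, nrow = length(ids), ncol = length(cols),
                dimnames = list(ids, cols))
  for (tn in names(tracks)) {
    tr <- tracks[[tn]]
    if (!inherits(tr, "signal_track")) stop("missing or invalid track: ", tn)
    for (rn in names(regions))
      out[, paste(tn, rn, sep = "_")] <-
        .by_gene(mean_signal_regions(tr, regions[[rn]]), ids)
  }
  out
}

#' Expression features of one gene
#'
#' The gene's normalized expression value in each tissue, one feature per
#' tissue in matrix column order.
#'
#' @param gene_id Gene identifier.
#' @param m A normalized [expr_matrix].
#' @return Named numeric vector (\code{expr_<tissue>}); all-NA if the gene
#'   is absent.
#' @export
expression_features <- function(gene_id, m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!m$normalized) stop("expression matrix must be normalized first")
  cols <- paste0("expr_", colnames(m$counts))
  if (!gene_id %in% rownames(m$counts))
    return(setNames(rep(NA_real_, ncol(m$counts)), cols))
  setNames(as.numeric(m$counts[gene_id, ]), cols)
}

expression_block <- function(gene_ids, m) {
  if (!m$normalized) stop("expression matrix must be normalized first")
  out <- matrix(NA_real_, nrow = length(gene_ids), ncol = ncol(m$counts),
                dimnames = list(gene_ids, paste0("expr_", colnames(m$counts))))
  present <- gene_ids[gene_ids %in% rownames(m$counts)]
  out[present, ] <- m$counts[present, , drop = FALSE]
  out
}

#' Assemble the full feature table
#'
#' Computes all four feature blocks for each gene and binds them in
#' manifest order, keeping an explicit missing-value mask. Missing values
#' (intron features of intronless genes, genes absent from the expression
#' matrix, etc.) are imputed per column on the assembled population, or
#' left as NA with \code{imputation = "none"}.
#'
#' @param genes [gene_set] of the genes to featurize (lncRNAs).
#' @param resources Named list with \code{sequences} (DNAStringSet),
#'   \code{repeats}, \code{conservation}, \code{tracks} (named list of 9),
#'   \code{mirnas} ([gene_set]), \code{expression} (normalized
#'   [expr_matrix]), and for the network block either a precomputed
#'   \code{network} ([build_network()] result) plus \code{drivers},
#'   \code{cancer_proteins}, \code{mirna_interactions},
#'   \code{cancer_mirnas}; optional \code{peptide_table}.
#' @param manifest Feature manifest ([feature_manifest()]); defaults to one
#'   derived from the resources.
#' @param imputation \code{"median"}, \code{"zero"} or \code{"none"}.
#' @param network_block Optional precomputed genes x network-features
#'   matrix; computed from the resources when NULL.
#' @return A \code{feature_table}: list with \code{gene_ids},
#'   \code{values} (matrix), \code{mask} (TRUE where the raw value was
#'   missing), \code{categories}, \code{manifest}, \code{imputation}.
#' @export
assemble_feature_table <- function(genes, resources, manifest = NULL,
                                   imputation = c("median", "zero", "none"),
                                   network_block = NULL) {
  imputation <- match.arg(imputation)
  stopifnot(inherits(genes, "gene_set"))
  m <- resources$expression
  if (!inherits(m, "expr_matrix")) stop("resources$expression required")
  if (!m$normalized) m <- normalize_expression(m)
  drivers <- resources$drivers %||% DRIVER_GENES
  if (is.null(manifest))
    manifest <- feature_manifest(drivers = drivers,
                                 tissues = colnames(m$counts),
                                 tracks = names(resources$tracks))
  ids <- genes$gene_id
  gb <- genomic_block(genes, resources$sequences, resources$repeats,
                      resources$conservation, resources$mirnas,
                      resources$peptide_table)
  eb <- expression_block(ids, m)
  pb <- epigenetic_block(genes, resources$tracks)
  if (is.null(network_block))
    network_block <- network_block_all(ids, resources$network, m, drivers,
                                       resources$cancer_proteins,
                                       resources$mirna_interactions,
                                       resources$cancer_mirnas)
  values <- cbind(gb, eb, pb, network_block)
  if (!all(manifest$feature %in% colnames(values)))
    stop("manifest features not computed: ",
         paste(setdiff(manifest$feature, colnames(values)), collapse = ", "))
  values <- values[, manifest$feature, drop = FALSE]
  mask <- is.na(values)
  if (imputation == "median") {
    med <- apply(values, 2L, median, na.rm = TRUE)
    med[is.na(med)] <- 0
    for (j in which(colSums(mask) > 0L))
      values[mask[, j], j] <- med[j]
  } else if (imputation == "zero") {
    values[mask] <- 0
  }
  structure(list(gene_ids = ids, values = values, mask = mask,
                 categories = setNames(manifest$category, manifest$feature),
                 manifest = manifest, imputation = imputation),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  tab <- table(x$categories)
  cat(sprintf("feature_table: %d genes x %d features (%s); imputation=%s\n",
              length(x$gene_ids), ncol(x$values),
              paste(names(tab), tab, sep = ":", collapse = ", "),
              x$imputation))
  invisible(x)
}

#' Write a feature table as TSV
#' @param ft A \code{feature_table}.
#' @param path Output path (gene_id column + named feature columns).
#' @return The path, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  df <- data.frame(gene_id = ft$gene_ids, ft$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
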