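# Writing a simulated bundle to disk in standard formats and reading it
# back; the on-disk layout is the interface the pipeline stages consume.

.bundle_files <- c(
  genes = "genes.gtf", genome = "genome.fa", repeats = "repeats.bed",
  snps = "snps.bed", mutations = "mutations.bed",
  conservation = "conservation.bedGraph", expression = "expression.tsv",
  tumor = "tumor.tsv", normal = "normal.tsv",
  mirna_interactions = "mirna_interactions.tsv",
  drivers = "drivers.txt", cancer_proteins = "cancer_proteins.txt",
  cancer_mirnas = "cancer_mirnas.txt", positives = "positives.txt",
  unknowns = "unknowns.txt",
  negative_candidates = "negative_candidates.txt",
  go_map = "go_map.tsv", truth = "truth.tsv")

#' Write a simulated bundle to a directory
#'
#' Emits every resource as a plain-text standard format (GTF, FASTA, BED,
#' bedGraph, TSV, ID lists) plus a MANIFEST.json with per-file checksums,
#' the configuration and the seed.
#'
#' @param bundle A [simulate_bundle()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_gene_models(bundle$genes, p("genes.gtf"), format = "gtf")
  Biostrings::writeXStringSet(bundle$sequences, p("genome.fa"))
  write_annotation_bed(bundle$repeats, p("repeats.bed"))
  write_annotation_bed(bundle$snps, p("snps.bed"))
  write_annotation_bed(bundle$mutations, p("mutations.bed"))
  write_bedgraph(bundle$conservation, p("conservation.bedGraph"))
  for (tn in names(bundle$tracks))
    write_bedgraph(bundle$tracks[[tn]],
                   file.path(dir, "tracks", paste0(tn, ".bedGraph")))
  write_expression_matrix(bundle$expression, p("expression.tsv"))
  for (nm in c("tumor", "normal")) {
    df <- data.frame(gene_id = rownames(bundle[[nm]]), bundle[[nm]],
                     check.names = FALSE)
    utils::write.table(df, p(paste0(nm, ".tsv")), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  utils::write.table(bundle$mirna_interactions, p("mirna_interactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_list(bundle$drivers, p("drivers.txt"))
  write_gene_list(bundle$cancer_proteins, p("cancer_proteins.txt"))
  write_gene_list(bundle$cancer_mirnas, p("cancer_mirnas.txt"))
  write_gene_list(bundle$positives, p("positives.txt"))
  tr <- bundle$truth
  write_gene_list(tr$gene_id[tr$role == "unknown"], p("unknowns.txt"))
  write_gene_list(tr$gene_id[tr$role %in% c("pool", "decoy")],
                  p("negative_candidates.txt"))
  utils::write.table(bundle$go_map, p("go_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(tr, p("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(.bundle_files, file.path("tracks",
                                      paste0(names(bundle$tracks),
                                             ".bedGraph")))
  manifest <- list(
    seed = bundle$seed,
    config = unclass(bundle$config),
    chrom_lengths = as.list(bundle$chrom_lengths),
    checksums = as.list(tools::md5sum(file.path(dir, unname(files)))))
  names(manifest$checksums) <- unname(files)
  jsonlite::write_json(manifest, p("MANIFEST.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a bundle directory back into memory
#'
#' @param dir Directory written by [write_bundle()] (or assembled by hand
#'   in the same layout).
#' @return A \code{sim_bundle}-shaped list of parsed resources.
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  need <- p(c("genes.gtf", "genome.fa", "expression.tsv"))
  miss <- need[!file.exists(need)]
  if (length(miss))
    stop("bundle incomplete, missing: ", paste(basename(miss), collapse = ", "))
  manifest <- if (file.exists(p("MANIFEST.json")))
    jsonlite::read_json(p("MANIFEST.json"), simplifyVector = TRUE) else NULL
  track_files <- list.files(p("tracks"), pattern = "\\.bedGraph$",
                            full.names = TRUE)
  tracks <- setNames(lapply(track_files, read_bedgraph),
                     sub("\\.bedGraph$", "", basename(track_files)))
  truth <- if (file.exists(p("truth.tsv")))
    utils::read.delim(p("truth.tsv"), stringsAsFactors = FALSE) else NULL
  structure(list(
    config = manifest$config, seed = manifest$seed,
    genes = read_gene_models(p("genes.gtf"), format = "gtf"),
    sequences = Biostrings::readDNAStringSet(p("genome.fa")),
    repeats = read_annotation_bed(p("repeats.bed"), "repeats",
                                  vocabulary = REPEAT_CLASSES),
    snps = read_annotation_bed(p("snps.bed"), "gwas_snps"),
    mutations = read_annotation_bed(p("mutations.bed"), "somatic_mutations"),
    conservation = read_bedgraph(p("conservation.bedGraph"), "phastCons"),
    tracks = tracks,
    expression = read_expression_matrix(p("expression.tsv")),
    tumor = .read_named_matrix(p("tumor.tsv")),
    normal = .read_named_matrix(p("normal.tsv")),
    mirna_interactions = utils::read.delim(p("mirna_interactions.tsv"),
                                           stringsAsFactors = FALSE),
    drivers = read_gene_list(p("drivers.txt")),
    cancer_proteins = read_gene_list(p("cancer_proteins.txt")),
    cancer_mirnas = read_gene_list(p("cancer_mirnas.txt")),
    positives = read_gene_list(p("positives.txt")),
    unknowns = read_gene_list(p("unknowns.txt")),
    negative_candidates = read_gene_list(p("negative_candidates.txt")),
    go_map = read_go_map(p("go_map.tsv")),
    truth = truth,
    chrom_lengths = unlist(manifest$chrom_lengths)),
    class = "sim_bundle")
}

.read_named_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}
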