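# Shared fixtures and independent brute-force oracles. Oracles are written
# from first principles (per-base expansion, pair enumeration) and never
# call the code paths they check.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small hand-built gene set: three genes on two chromosomes
toy_genes <- function() {
  gene_set(data.frame(
    gene_id = c("g1", "g2", "g3"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(100L, 5000L, 200L),
    end = c(1100L, 6200L, 800L),
    strand = c("+", "-", "+"),
    biotype = c("lncRNA-intergenic", "lncRNA-intergenic", "protein_coding"),
    exons = I(list(cbind(start = c(100L, 700L), end = c(400L, 1100L)),
                   cbind(start = c(5000L, 5600L), end = c(5300L, 6200L)),
                   cbind(start = 200L, end = 800L))),
    stringsAsFactors = FALSE))
}

# feature table + resources for a bundle (the standard downstream prep)
bundle_features <- function(b) {
  m <- normalize_expression(b$expression)
  net <- build_network(m)
  lnc <- b$genes[grepl("^lncRNA", b$genes$biotype), ]
  res <- list(sequences = b$sequences, repeats = b$repeats,
              conservation = b$conservation, tracks = b$tracks,
              mirnas = b$genes[b$genes$biotype == "miRNA", ],
              expression = m, network = net, drivers = b$drivers,
              cancer_proteins = b$cancer_proteins,
              mirna_interactions = b$mirna_interactions,
              cancer_mirnas = b$cancer_mirnas)
  assemble_feature_table(lnc, res)
}

small_bundle_cfg <- function(...) {
  sim_config(n_positive = 40L, n_negative_pool = 90L, n_decoy = 10L,
             n_unknown = 20L, n_coding = 30L, n_mirna = 12L, ...)
}

# ---- independent oracles ----------------------------------------------

# per-base brute force: count of class records overlapping [start, end)
bf_count_overlaps <- function(records, chrom, start, end, cl) {
  n <- 0L
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$chrom == chrom && r$class == cl &&
        max(r$start, start) < min(r$end, end)) n <- n + 1L
  }
  n
}

# per-base expansion oracle for mean signal over [start, end)
bf_mean_signal <- function(track_df, chrom, start, end) {
  vals <- numeric(end - start)
  bases <- seq.int(start, end - 1L)
  for (i in seq_len(nrow(track_df))) {
    r <- track_df[i, ]
    if (r$chrom != chrom) next
    hit <- bases >= r$start & bases < r$end
    vals[hit] <- r$value
  }
  mean(vals)
}

# concordant-pair (Mann-Whitney) AUC oracle with half-credit ties
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# ECDF sup-gap oracle
bf_ks_d <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}

# longest ORF oracle: scan every ATG position, walk codons to a stop
bf_orf <- function(seq) {
  s <- toupper(seq)
  best <- 0L
  for (i in seq_len(max(0L, nchar(s) - 2L))) {
    if (substr(s, i, i + 2L) != "ATG") next
    j <- i
    while (j + 5L <= nchar(s)) {
      codon <- substr(s, j + 3L, j + 5L)
      if (codon %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, (j + 3L - i) %/% 3L)
        break
      }
      j <- j + 3L
    }
  }
  best
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
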