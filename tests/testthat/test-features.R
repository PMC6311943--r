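test_that("gc_content handles standard and ambiguous bases", {
  expect_equal(gc_content("GCGC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("ACGTN"), 0.5)
  expect_true(is.na(gc_content("NNNN")))
})

test_that("longest ORF scan agrees with the ATG-walk oracle", {
  expect_equal(longest_orf_peptide_length("ATGAAATAA"), 2L)
  expect_equal(longest_orf_peptide_length("CCCCCC"), 0L)
  set.seed(5)
  for (i in 1:30) {
    s <- random_dna(sample(50:300, 1))
    expect_equal(longest_orf_peptide_length(s), bf_orf(s), info = s)
  }
})

test_that("size factors reproduce median-of-ratios by hand and by DESeq2", {
  m <- expr_matrix(matrix(c(10, 30, 20, 60), 2,
                          dimnames = list(c("g1", "g2"), c("s1", "s2"))))
  sf <- size_factors(m)
  # hand: geometric means sqrt(200), sqrt(1800); ratios give sqrt(1/2), sqrt(2)
  expect_equal(unname(sf), c(sqrt(1 / 2), sqrt(2)), tolerance = 1e-4)

  same <- expr_matrix(matrix(c(5, 9, 5, 9), 2,
                             dimnames = list(c("a", "b"), c("s1", "s2"))))
  expect_equal(unname(size_factors(same)), c(1, 1))

  set.seed(2)
  counts <- matrix(rpois(60, 40) + 1, 10,
                   dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  sf1 <- size_factors(expr_matrix(counts))
  # scale equivariance holds on factor ratios (the global geometric-mean
  # renormalization of median-of-ratios cancels)
  scaled <- counts; scaled[, 3] <- scaled[, 3] * 4
  sf2 <- size_factors(expr_matrix(scaled))
  expect_equal(unname(sf2[3] / sf2[1]), unname(4 * sf1[3] / sf1[1]),
               tolerance = 1e-12)
  # independent oracle
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(sf1), unname(ref), tolerance = 1e-8)

  allzero <- expr_matrix(matrix(c(0, 1, 2, 0), 2,
                                dimnames = list(c("a", "b"),
                                                c("s1", "s2"))))
  expect_error(size_factors(allzero), "pseudocount")
})

test_that("normalization cancels per-sample depth scaling", {
  set.seed(3)
  counts <- matrix(rpois(80, 30) + 1, 10,
                   dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
  scaled <- sweep(counts, 2, c(2, 1, 0.5, 4, 0.25, 1, 1, 1), "*")
  n1 <- normalize_expression(expr_matrix(counts))
  n2 <- normalize_expression(expr_matrix(scaled))
  expect_equal(n1$counts, n2$counts, tolerance = 1e-12)
  expect_equal(expression_features("g3", n1),
               expression_features("g3", n2), tolerance = 1e-12)
})

test_that("genomic features of a toy gene match per-feature oracles", {
  set.seed(17)
  chrom_seq <- random_dna(12000, gc = 0.45)
  seqs <- Biostrings::DNAStringSet(c(c1 = chrom_seq))
  gene <- gene_set(data.frame(
    gene_id = "gX", chrom = "c1", start = 2000L, end = 3000L, strand = "+",
    biotype = "lncRNA-intergenic",
    exons = I(list(cbind(start = c(2000L, 2600L), end = c(2300L, 3000L)))),
    stringsAsFactors = FALSE))
  rep_rec <- data.frame(
    chrom = "c1",
    start = c(2050L, 2950L, 5000L, 1200L, 2400L, 900L, 2500L),
    end = c(2080L, 2990L, 5030L, 1230L, 2460L, 960L, 2540L),
    class = c("SINE", "SINE", "SINE", "SINE", "LINE", "LTR", "Satellite"))
  repeats <- annotation_set("rep", rep_rec,
                            vocabulary = c("LINE", "LTR", "Satellite",
                                           "SINE"))
  cons_df <- data.frame(chrom = "c1",
                        start = c(1500L, 2000L, 2250L, 2450L, 2700L),
                        end = c(1900L, 2200L, 2400L, 2620L, 2900L),
                        value = c(0.3, 0.9, 0.5, 0.2, 0.7))
  conservation <- signal_track("cons", cons_df)
  mirnas <- gene_set(data.frame(gene_id = "mir1", chrom = "c1",
                                start = 2100L, end = 2170L, strand = "+",
                                biotype = "miRNA"))
  fv <- genomic_features(gene, seqs, repeats, conservation, mirnas)
  expect_length(fv, 18L)

  gc_of <- function(s, e) {  # substring-count oracle on the raw string
    sub <- strsplit(substr(chrom_seq, s + 1, e), "")[[1]]
    sum(sub %in% c("G", "C")) / sum(sub %in% c("A", "C", "G", "T"))
  }
  expect_equal(unname(fv["gc_genebody"]), gc_of(2000, 3000))
  expect_equal(unname(fv["gc_flank1k"]), gc_of(1000, 3000))
  expect_equal(unname(fv["gc_flank5k"]), gc_of(0, 7000))
  gc_exon <- {
    sub <- c(strsplit(substr(chrom_seq, 2001, 2300), "")[[1]],
             strsplit(substr(chrom_seq, 2601, 3000), "")[[1]])
    sum(sub %in% c("G", "C")) / length(sub)
  }
  expect_equal(unname(fv["gc_exon"]), gc_exon)
  expect_equal(unname(fv["gc_intron"]), gc_of(2300, 2600))

  cons_exon <- (bf_mean_signal(cons_df, "c1", 2000, 2300) * 300 +
                bf_mean_signal(cons_df, "c1", 2600, 3000) * 400) / 700
  expect_equal(unname(fv["cons_exon"]), cons_exon, tolerance = 1e-12)
  expect_equal(unname(fv["cons_intron"]),
               bf_mean_signal(cons_df, "c1", 2300, 2600), tolerance = 1e-12)
  expect_equal(unname(fv["cons_flank1k"]),
               bf_mean_signal(cons_df, "c1", 1000, 3000), tolerance = 1e-12)

  for (cl in c("SINE", "LINE", "LTR", "Satellite")) {
    expect_equal(unname(fv[paste0(cl, "_genebody")]),
                 bf_count_overlaps(rep_rec, "c1", 2000, 3000, cl), info = cl)
    expect_equal(unname(fv[paste0(cl, "_flank1k")]),
                 bf_count_overlaps(rep_rec, "c1", 1000, 3000, cl), info = cl)
  }
  expect_equal(unname(fv["mirna_host_count"]), 1)
  spliced <- paste0(substr(chrom_seq, 2001, 2300),
                    substr(chrom_seq, 2601, 3000))
  expect_equal(unname(fv["micropeptide_length"]), bf_orf(spliced))
})

test_that("intronless genes get missing intron features", {
  seqs <- Biostrings::DNAStringSet(c(c1 = random_dna(5000)))
  gene <- gene_set(data.frame(gene_id = "g0", chrom = "c1", start = 1000L,
                              end = 1600L, strand = "+",
                              biotype = "lncRNA-intergenic"))
  empty_ann <- annotation_set("rep", data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    class = character(0)), vocabulary = c("LINE", "LTR", "Satellite",
                                          "SINE"))
  cons <- signal_track("c", data.frame(chrom = "c1", start = 0L,
                                       end = 5000L, value = 0.5))
  fv <- genomic_features(gene, seqs, empty_ann, cons, mirnas = gene[0, ])
  expect_true(is.na(fv["gc_intron"]))
  expect_true(is.na(fv["cons_intron"]))
  expect_false(is.na(fv["gc_exon"]))
})

test_that("epigenetic features average tracks over the three regions", {
  gene <- gene_set(data.frame(gene_id = "g", chrom = "c1", start = 6000L,
                              end = 8000L, strand = "+",
                              biotype = "lncRNA-intergenic"))
  zero <- signal_track("z", data.frame(chrom = character(0),
                                       start = integer(0),
                                       end = integer(0),
                                       value = numeric(0)))
  const <- signal_track("k", data.frame(chrom = "c1", start = 0L,
                                        end = 20000L, value = 1.75))
  step_df <- data.frame(chrom = "c1", start = c(5500L, 6500L, 7200L),
                        end = c(6400L, 7000L, 9000L),
                        value = c(2, 5, 1))
  step <- signal_track("s", step_df)
  tracks <- list(z = zero, k = const, s = step)
  fv <- epigenetic_features(gene, tracks)
  expect_length(fv, 9L)
  expect_equal(unname(fv[c("z_genebody", "z_flank1k", "z_flank5k")]),
               c(0, 0, 0))
  expect_equal(unname(fv[c("k_genebody", "k_flank1k", "k_flank5k")]),
               rep(1.75, 3))
  expect_equal(unname(fv["s_genebody"]),
               bf_mean_signal(step_df, "c1", 6000, 8000), tolerance = 1e-12)
  expect_equal(unname(fv["s_flank1k"]),
               bf_mean_signal(step_df, "c1", 5000, 7000), tolerance = 1e-12)
  expect_equal(unname(fv["s_flank5k"]),
               bf_mean_signal(step_df, "c1", 1000, 11000), tolerance = 1e-12)
  expect_error(epigenetic_features(gene, list(zero)), "named")
})

test_that("assembled table has manifest shape, bounds and honest mask", {
  b <- cached("small_bundle", simulate_bundle(small_bundle_cfg(), seed = 31))
  ft <- cached("small_ft", bundle_features(b))
  expect_equal(ncol(ft$values), 18 + 16 + 27 + 22)
  expect_equal(as.integer(table(ft$categories)[c("genomic", "expression",
                                                 "epigenetic", "network")]),
               c(18L, 16L, 27L, 22L))
  gc_cols <- grep("^gc_", colnames(ft$values))
  vals <- ft$values[, gc_cols][!ft$mask[, gc_cols]]
  expect_true(all(vals >= 0 & vals <= 1))
  cons_cols <- grep("^cons_", colnames(ft$values))
  expect_true(all(ft$values[, cons_cols] >= 0 & ft$values[, cons_cols] <= 1))
  cnt_cols <- grep("_genebody$|_flank1k$", colnames(ft$values))
  cnt_cols <- intersect(cnt_cols, grep("SINE|LINE|LTR|Satellite",
                                       colnames(ft$values)))
  expect_true(all(ft$values[, cnt_cols] >= 0))
  expect_true(all(ft$values[, cnt_cols] == floor(ft$values[, cnt_cols])))
  epi_cols <- names(ft$categories)[ft$categories == "epigenetic"]
  expect_true(all(ft$values[, epi_cols] >= 0))
  expect_false(any(is.na(ft$values)))
})

test_that("imputation policies fill exactly the masked cells", {
  b <- cached("small_bundle", simulate_bundle(small_bundle_cfg(), seed = 31))
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
  ft_none <- assemble_feature_table(lnc, res, imputation = "none")
  ft_med <- assemble_feature_table(lnc, res, imputation = "median")
  ft_zero <- assemble_feature_table(lnc, res, imputation = "zero")
  expect_identical(is.na(ft_none$values), ft_none$mask)
  expect_true(any(ft_none$mask))  # intronless decoys exist
  expect_false(any(is.na(ft_med$values)))
  expect_identical(ft_med$values[!ft_none$mask],
                   ft_none$values[!ft_none$mask])
  j <- which(colSums(ft_none$mask) > 0)[1]
  med <- median(ft_none$values[, j], na.rm = TRUE)
  expect_true(all(ft_med$values[ft_none$mask[, j], j] == med))
  expect_true(all(ft_zero$values[ft_none$mask[, j], j] == 0))
})

test_that("feature extraction is deterministic and order-independent", {
  b <- cached("small_bundle", simulate_bundle(small_bundle_cfg(), seed = 31))
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
  sub <- lnc[c(5, 1, 9), ]
  ft1 <- assemble_feature_table(sub, res, imputation = "none")
  ft2 <- assemble_feature_table(sub[c(2, 1, 3), ], res, imputation = "none")
  expect_equal(ft1$values["LNCP0001", ], ft2$values["LNCP0001", ])
  ft3 <- assemble_feature_table(sub, res, imputation = "none")
  expect_identical(ft1$values, ft3$values)
})
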