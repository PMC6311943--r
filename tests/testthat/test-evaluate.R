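test_that("KS statistic matches ECDF enumeration and stays invariant", {
  r <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$d, 0)
  r <- ks_two_sample(c(1, 2, 3), c(1.5, 2.5, 3.5))
  expect_equal(r$d, 1 / 3, tolerance = 1e-12)
  r <- ks_two_sample(c(1, 2), c(5, 6, 7))
  expect_equal(r$d, 1)
  expect_equal(r$n1, 2L); expect_equal(r$n2, 3L)
  expect_error(ks_two_sample(numeric(0), 1:3), "empty")
  set.seed(13)
  for (i in 1:30) {
    a <- rnorm(sample(5:40, 1)); b <- rnorm(sample(5:40, 1), sd = 2)
    r <- ks_two_sample(a, b)
    expect_equal(r$d, bf_ks_d(a, b), tolerance = 1e-12)
    # symmetry
    expect_equal(r$d, ks_two_sample(b, a)$d, tolerance = 1e-12)
    expect_equal(r$p, ks_two_sample(b, a)$p, tolerance = 1e-12)
    # invariance under a common strictly monotone transform
    r2 <- ks_two_sample(exp(a), exp(b))
    expect_equal(r2$d, r$d, tolerance = 1e-12)
  }
})

test_that("DE fraction counts |log2FC| above the cutoff", {
  expect_equal(de_fraction(c(2.0, 0.5, -1.5)), 2 / 3)
  expect_equal(de_fraction(rep(0, 5)), 0)
  expect_equal(de_fraction(c(0, 0.3, -0.1, 0), cutoff = 0), 0.5)
  expect_message(v <- de_fraction(c(2, NA, 0)), "excluded")
  expect_equal(v, 0.5)
  expect_error(de_fraction(c(NA_real_, NA_real_)), "NA")
  lfc <- log2_fold_change(
    matrix(c(30, 10), 2, 3, dimnames = list(c("a", "b"), NULL)),
    matrix(c(10, 10), 2, 3, dimnames = list(c("a", "b"), NULL)), eps = 1)
  expect_equal(unname(lfc), c(log2(31 / 11), 0))
})

test_that("closest distances match examples and brute force", {
  anch <- annotation_set("cp", data.frame(
    chrom = "chr1", start = c(150L, 500L), end = c(160L, 600L),
    class = "protein"))
  g_over <- gene_set(data.frame(gene_id = "o", chrom = "chr1", start = 100L,
                                end = 200L, strand = "+",
                                biotype = "lncRNA-intergenic"))
  expect_equal(unname(closest_distances(g_over, anch, 5, seed = 1)$query), 0)
  anch2 <- annotation_set("cp", data.frame(chrom = "chr1", start = 500L,
                                           end = 600L, class = "protein"))
  expect_equal(unname(closest_distances(g_over, anch2, 5, seed = 1)$query),
               300)
  expect_error(closest_distances(g_over, annotation_set("e", data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    class = character(0))), 5), "anchors")

  set.seed(14)
  starts <- sample(0:50000, 50)
  g <- gene_set(data.frame(gene_id = sprintf("q%02d", 1:50),
                           chrom = sample(c("chr1", "chr2"), 50, TRUE),
                           start = starts, end = starts + 500L,
                           strand = "+", biotype = "lncRNA-intergenic"))
  arec <- data.frame(chrom = sample(c("chr1", "chr2"), 30, TRUE),
                     start = sample(0:50000, 30), class = "p")
  arec$end <- arec$start + 200L
  cd <- closest_distances(g, annotation_set("a", arec), 10, seed = 2)
  for (i in 1:50) {
    same <- arec[arec$chrom == g$chrom[i], ]
    oracle <- min(pmax(0, pmax(same$start - g$end[i],
                               g$start[i] - same$end)))
    expect_equal(unname(cd$query[g$gene_id[i]]), oracle, info = i)
  }
  expect_length(cd$background, 10L)
  # reproducible background
  cd2 <- closest_distances(g, annotation_set("a", arec), 10, seed = 2)
  expect_identical(cd$background, cd2$background)
})

test_that("mutation burden counts body overlaps", {
  g <- toy_genes()
  expect_equal(unname(mutation_burden(g, annotation_set("m", data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    class = character(0))))), c(0L, 0L, 0L))
  mrec <- data.frame(chrom = "chr1",
                     start = c(150L, 500L, 1050L, 2000L, 5500L),
                     class = "somatic")
  mrec$end <- mrec$start + 1L
  mb <- mutation_burden(g, annotation_set("m", mrec))
  expect_equal(unname(mb["g1"]), 3L)  # 150, 500, 1050 inside [100,1100)
  expect_equal(unname(mb["g2"]), 1L)
  expect_equal(unname(mb["g3"]), 0L)
  set.seed(15)
  rrec <- data.frame(chrom = sample(c("chr1", "chr2"), 60, TRUE),
                     start = sample(0:7000, 60), class = "somatic")
  rrec$end <- rrec$start + 1L
  mb2 <- mutation_burden(g, annotation_set("m", rrec))
  for (i in 1:3)
    expect_equal(unname(mb2[i]),
                 bf_count_overlaps(rrec, g$chrom[i], g$start[i], g$end[i],
                                   "somatic"))
})

test_that("hypergeometric enrichment equals exhaustive enumeration", {
  expect_equal(hypergeometric_enrichment(2, 2, 2, 4), 1 / 6,
               tolerance = 1e-12)
  expect_equal(hypergeometric_enrichment(0, 0, 3, 10), 1)
  expect_error(hypergeometric_enrichment(3, 2, 5, 10), "margins")
  # draw-all-subsets oracle for small N
  for (N in c(4, 6, 9, 11)) {
    for (K in c(0, 2, N %/% 2, N)) {
      for (n in c(1, N %/% 2, N)) {
        subsets <- combn(N, n)
        succ <- seq_len(K)
        counts <- apply(subsets, 2, function(s) sum(s %in% succ))
        for (k in 0:min(K, n)) {
          expect_equal(hypergeometric_enrichment(k, K, n, N),
                       mean(counts >= k), tolerance = 1e-12,
                       info = paste(k, K, n, N))
        }
      }
    }
  }
})

# shared fixture network: one hub lncRNA connected to annotated coding genes
go_fixture <- function(n_coding = 40, n_hub_nb = 12, seed = 1) {
  set.seed(seed)
  coding <- sprintf("C%02d", seq_len(n_coding))
  edges <- data.frame(a = "LNC1", b = coding[seq_len(n_hub_nb)],
                      rs = 0.9, p = 1e-6, p_adj = 1e-4,
                      stringsAsFactors = FALSE)
  nodes <- data.frame(gene_id = c("LNC1", "LNC2", coding),
                      biotype = NA, constant = FALSE)
  net <- structure(list(nodes = nodes, edges = edges, rs_cutoff = 0.6,
                        p_adj_cutoff = 0.01, n_samples = 16),
                   class = "coexpression_network")
  go <- do.call(rbind, lapply(coding, function(g)
    data.frame(gene_id = g,
               term = sample(sprintf("T%02d", 1:12), 4),
               stringsAsFactors = FALSE)))
  list(net = net, go = go, coding = coding)
}

test_that("GO transfer ranks a neighbor-exclusive term first", {
  fx <- go_fixture(seed = 3)
  go <- fx$go
  nb <- fx$net$edges$b
  go <- go[!(go$term == "T01"), ]  # strip T01, then make it neighbor-only
  go <- rbind(go, data.frame(gene_id = nb, term = "T01"))
  res <- go_transfer(fx$net, go, "LNC1")
  expect_equal(res$term[1], "T01")
  expect_true(res$significant[1])
  # p-values equal direct hypergeometric calls
  background <- unique(go$gene_id)
  for (i in seq_len(nrow(res))) {
    with_term <- unique(go$gene_id[go$term == res$term[i]])
    expect_equal(res$p[i],
                 hypergeometric_enrichment(sum(nb %in% with_term),
                                           length(with_term), length(nb),
                                           length(background)),
                 tolerance = 1e-12)
  }
  # isolated gene -> empty result with flag
  res2 <- go_transfer(fx$net, go, "LNC2")
  expect_equal(nrow(res2), 0L)
  expect_true(isTRUE(attr(res2, "isolated")))
  expect_error(go_transfer(fx$net, go, "NOPE"), "not in network")
})

test_that("GO transfer is calibrated under a shuffled-label null", {
  frac_sig <- vapply(1:6, function(s) {
    fx <- go_fixture(n_coding = 60, n_hub_nb = 15, seed = 20 + s)
    res <- go_transfer(fx$net, fx$go, "LNC1", alpha = 0.05)
    mean(res$significant)
  }, numeric(1))
  # one-sided test at alpha: super-uniform p-values keep the rate low
  expect_lt(mean(frac_sig), 0.10)
})
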