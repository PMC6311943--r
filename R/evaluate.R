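# Evaluation of feature distributions and predicted candidates: KS tests,
# differential-expression fraction, closest-distance analysis, mutation
# burden, and guilt-by-association GO transfer.

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum gap between the two empirical CDFs; the p-value uses
#' the asymptotic Kolmogorov distribution with effective sample size
#' \code{n1 * n2 / (n1 + n2)}.
#'
#' @param a,b Numeric samples (non-empty).
#' @return List with \code{d}, \code{p}, \code{n1}, \code{n2}.
#' @export
ks_two_sample <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(d = unname(kt$statistic), p = unname(kt$p.value),
       n1 = length(a), n2 = length(b))
}

#' Fraction of differentially expressed genes
#'
#' @param log2fc Vector of log2 fold changes; NAs are excluded (count
#'   reported via a message), all-NA input is an error.
#' @param cutoff Absolute log2 fold-change cutoff (default 1).
#' @return Fraction with \code{|log2fc| > cutoff}.
#' @export
de_fraction <- function(log2fc, cutoff = 1.0) {
  n_na <- sum(is.na(log2fc))
  x <- log2fc[!is.na(log2fc)]
  if (length(x) == 0L) stop("all fold changes are NA")
  if (n_na > 0L) message(n_na, " NA fold change(s) excluded")
  mean(abs(x) > cutoff)
}

#' Log2 fold changes between tumor and normal expression
#'
#' \code{log2((mean tumor + eps) / (mean normal + eps))} per gene, with a
#' pseudocount of one normalized count.
#'
#' @param tumor,normal Matrices (genes x replicates) on a common gene set.
#' @param eps Pseudocount.
#' @return Named vector of log2 fold changes.
#' @export
log2_fold_change <- function(tumor, normal, eps = 1) {
  stopifnot(identical(rownames(tumor), rownames(normal)))
  log2((rowMeans(tumor) + eps) / (rowMeans(normal) + eps))
}

#' Distance of genes to their closest anchor loci
#'
#' Per query gene, the minimum gap (0 if overlapping) to any anchor on the
#' same chromosome, plus the same statistic for uniformly sampled random
#' positions as background. Queries on anchor-free chromosomes are dropped
#' with a warning.
#'
#' @param query A [gene_set].
#' @param anchors An [annotation_set] (e.g. cancer-protein loci).
#' @param random_background Number of random background positions; default
#'   10x the query size.
#' @param seed RNG seed for the background.
#' @param chrom_lengths Named vector of chromosome lengths used to place
#'   background positions; defaults to the anchor/query extent per
#'   chromosome.
#' @return List with \code{query} (named distances) and \code{background}.
#' @export
closest_distances <- function(query, anchors, random_background = NULL,
                              seed = 1L, chrom_lengths = NULL) {
  stopifnot(inherits(query, "gene_set"), inherits(anchors, "annotation_set"))
  if (nrow(anchors$records) == 0L) stop("no anchors supplied")
  if (is.null(random_background)) random_background <- 10L * nrow(query)
  anch <- split(anchors$records, anchors$records$chrom)
  min_gap <- function(chrom, start, end) {
    d <- anch[[chrom]]
    if (is.null(d)) return(NA_real_)
    min(pmax(0L, pmax(d$start - end, start - d$end)))
  }
  qd <- vapply(seq_len(nrow(query)), function(i)
    min_gap(query$chrom[i], query$start[i], query$end[i]), numeric(1))
  names(qd) <- query$gene_id
  if (any(is.na(qd))) {
    warning(sum(is.na(qd)), " quer(ies) on anchor-free chromosomes excluded")
    qd <- qd[!is.na(qd)]
  }
  if (is.null(chrom_lengths)) {
    ext <- c(split(pmax(query$end, 0), query$chrom),
             split(anchors$records$end, anchors$records$chrom))
    chrom_lengths <- vapply(split(unlist(ext),
                                  rep(names(ext), lengths(ext))),
                            max, numeric(1))
  }
  chroms <- intersect(names(chrom_lengths), names(anch))
  bg <- with_seed(seed, {
    ch <- sample(chroms, random_background, replace = TRUE,
                 prob = chrom_lengths[chroms] / sum(chrom_lengths[chroms]))
    pos <- floor(runif(random_background) * chrom_lengths[ch])
    vapply(seq_len(random_background), function(i)
      min_gap(ch[i], pos[i], pos[i] + 1), numeric(1))
  })
  list(query = qd, background = bg)
}

#' Somatic mutation burden per gene
#'
#' @param genes A [gene_set].
#' @param mutations An [annotation_set] of mutation records (any class).
#' @return Named integer vector: mutation records overlapping each gene
#'   body.
#' @export
mutation_burden <- function(genes, mutations) {
  stopifnot(inherits(genes, "gene_set"), inherits(mutations, "annotation_set"))
  body <- .body_regions(genes)
  counts <- integer(nrow(genes))
  for (cl in mutations$vocabulary)
    counts <- counts + count_overlaps_many(mutations, body, cl)
  setNames(counts, genes$gene_id)
}

#' One-sided hypergeometric enrichment probability
#'
#' Fisher's exact upper tail: the probability of drawing at least \code{k}
#' annotated items when \code{n} items are drawn from a background of
#' \code{N} containing \code{K} annotated ones.
#'
#' @param k Observed successes in the sample.
#' @param K Successes in the background.
#' @param n Sample size.
#' @param N Background size.
#' @return P(X >= k).
#' @export
hypergeometric_enrichment <- function(k, K, n, N) {
  k <- as.integer(k); K <- as.integer(K); n <- as.integer(n); N <- as.integer(N)
  if (n > N || K > N || k > min(K, n) || any(c(k, K, n, N) < 0L))
    stop("inconsistent margins: need k <= min(K, n), n <= N, K <= N")
  phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Guilt-by-association GO transfer
#'
#' Assigns GO terms to a network gene from the annotations enriched among
#' its immediate co-expression neighbors. For each term annotating at
#' least one neighbor, a one-sided hypergeometric test compares the
#' annotated neighbors against all GO-annotated coding nodes as
#' background; terms with \code{p < alpha} are transferred, ranked by p.
#'
#' @param net A [build_network()] result.
#' @param go data.frame (\code{gene_id}, \code{term}) of biological-process
#'   annotations covering the protein-coding nodes.
#' @param gene Gene identifier (in the network).
#' @param alpha Transfer p-value cutoff (default 0.05).
#' @return data.frame (term, k, n, K, N, p, significant) sorted by p;
#'   zero rows with attribute \code{isolated = TRUE} for isolated genes.
#' @export
go_transfer <- function(net, go, gene, alpha = 0.05) {
  stopifnot(is.data.frame(go), all(c("gene_id", "term") %in% names(go)))
  if (!gene %in% net$nodes$gene_id) stop("gene not in network: ", gene)
  empty <- data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      significant = logical(0))
  background <- unique(go$gene_id[go$gene_id %in% net$nodes$gene_id])
  if (length(background) == 0L) stop("no annotated genes in the network")
  nb <- intersect(unique(network_neighbors(net, gene)), background)
  if (length(nb) == 0L) {
    attr(empty, "isolated") <- TRUE
    return(empty)
  }
  N <- length(background); n <- length(nb)
  terms <- unique(go$term[go$gene_id %in% nb])
  res <- do.call(rbind, lapply(terms, function(tm) {
    with_term <- unique(go$gene_id[go$term == tm])
    k <- sum(nb %in% with_term)
    K <- sum(background %in% with_term)
    data.frame(term = tm, k = k, n = n, K = K, N = N,
               p = hypergeometric_enrichment(k, K, n, N),
               stringsAsFactors = FALSE)
  }))
  res$significant <- res$p < alpha
  res <- res[order(res$p, res$term), ]
  rownames(res) <- NULL
  res
}

#' Read a gene-to-GO-term map
#' @param path Two-column TSV (gene_id, term), no header required; a
#'   header line starting with "gene_id" is skipped.
#' @return data.frame (gene_id, term).
#' @export
read_go_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("gene_id", "term"))
  df[df$gene_id != "gene_id", , drop = FALSE]
}
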