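# Label construction: GWAS-proximity negative pool and balanced negative
# resampling.

#' Build the presumed-negative lncRNA pool
#'
#' A lncRNA enters the pool when no cancer-trait SNP lies within
#' \code{window_bp} of its gene body, i.e. when
#' \code{[start - window_bp, end + window_bp)} contains no SNP record.
#' Known positives are always removed. The SNP set is expected to be
#' pre-filtered to cancer-associated traits by the caller (see
#' [filter_snps_by_trait()]).
#'
#' @param lncRNAs A [gene_set]; by default only intergenic lncRNAs
#'   (\code{biotype == "lncRNA-intergenic"}) are eligible.
#' @param snps An [annotation_set] of SNP positions, or NULL for no filter.
#' @param window_bp Exclusion window in bp on each side of the gene body.
#' @param positives Character vector of known positive gene IDs.
#' @param intergenic_only Restrict the pool to intergenic lncRNAs.
#' @return Character vector of pool gene IDs (input order).
#' @export
build_negative_pool <- function(lncRNAs, snps, window_bp = 10000L,
                                positives = character(0),
                                intergenic_only = TRUE) {
  stopifnot(inherits(lncRNAs, "gene_set"))
  if (nrow(lncRNAs) == 0L) stop("empty lncRNA collection")
  window_bp <- as.integer(window_bp)
  g <- lncRNAs
  if (intergenic_only) g <- g[g$biotype == "lncRNA-intergenic", , drop = FALSE]
  keep <- rep(TRUE, nrow(g))
  if (!is.null(snps) && nrow(snps$records) > 0L) {
    regions <- data.frame(chrom = g$chrom,
                          start = pmax(0L, g$start - window_bp),
                          end = g$end + window_bp)
    hits <- integer(nrow(g))
    for (cl in snps$vocabulary)
      hits <- hits + count_overlaps_many(snps, regions, cl)
    keep <- hits == 0L
  }
  setdiff(g$gene_id[keep], positives)
}

#' Filter a SNP catalog to cancer-associated traits
#'
#' Keeps SNP records whose trait/class string matches any of the keywords
#' (case-insensitive substring match).
#'
#' @param snps An [annotation_set] whose record classes are trait strings.
#' @param keywords Trait keywords.
#' @return A filtered [annotation_set].
#' @export
filter_snps_by_trait <- function(snps,
                                 keywords = c("cancer", "carcinoma", "tumor",
                                              "leukemia", "lymphoma",
                                              "melanoma", "glioma")) {
  stopifnot(inherits(snps, "annotation_set"))
  pat <- paste(tolower(keywords), collapse = "|")
  keep <- grepl(pat, tolower(snps$records$class))
  annotation_set(snps$name, snps$records[keep, , drop = FALSE])
}

#' Sample balanced negative sets
#'
#' Draws \code{n_sets} independent samples of \code{size} distinct IDs,
#' uniformly without replacement within each set, reproducibly from
#' \code{seed}. The same lncRNA may appear in several sets.
#'
#' @param pool Character vector of pool IDs.
#' @param n_sets Number of sets.
#' @param size Set size.
#' @param seed Integer RNG seed.
#' @return List of character vectors (the negative sets, in order).
#' @export
sample_negative_sets <- function(pool, n_sets = 100L, size = 150L, seed = 1L) {
  pool <- as.character(pool)
  if (size > length(pool))
    stop("requested set size ", size, " exceeds pool size ", length(pool))
  with_seed(seed, lapply(seq_len(n_sets), function(i)
    sample(pool, size, replace = FALSE)))
}

#' Bundle labels for training
#'
#' @param positives Positive gene IDs.
#' @param negative_pool Pool IDs (disjoint from positives).
#' @param negative_sets List of sampled negative sets.
#' @param seed Seed the sets were drawn with.
#' @param window_bp SNP exclusion window used for the pool.
#' @return A \code{label_bundle}.
#' @export
label_bundle <- function(positives, negative_pool, negative_sets,
                         seed = NA_integer_, window_bp = 10000L) {
  positives <- as.character(positives)
  negative_pool <- as.character(negative_pool)
  if (length(intersect(positives, negative_pool)))
    stop("positives and negative pool overlap")
  for (s in negative_sets) {
    if (anyDuplicated(s)) stop("negative set contains duplicates")
    if (!all(s %in% negative_pool))
      stop("negative set contains IDs outside the pool")
  }
  structure(list(positives = positives, negative_pool = negative_pool,
                 negative_sets = negative_sets, seed = seed,
                 window_bp = as.integer(window_bp)),
            class = "label_bundle")
}

#' @export
print.label_bundle <- function(x, ...) {
  cat(sprintf("label_bundle: %d positives, pool %d, %d negative sets of %s\n",
              length(x$positives), length(x$negative_pool),
              length(x$negative_sets),
              if (length(x$negative_sets))
                length(x$negative_sets[[1L]]) else 0L))
  invisible(x)
}

#' Write a label bundle as JSON
#' @param bundle A [label_bundle].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_label_bundle <- function(bundle, path) {
  jsonlite::write_json(unclass(bundle), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a label bundle from JSON
#' @param path JSON produced by [write_label_bundle()].
#' @return A [label_bundle].
#' @export
read_label_bundle <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sets <- x$negative_sets
  if (is.matrix(sets)) sets <- lapply(seq_len(nrow(sets)), function(i) sets[i, ])
  if (!is.list(sets)) sets <- as.list(sets)
  label_bundle(x$positives, x$negative_pool, sets,
               seed = x$seed, window_bp = x$window_bp)
}
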