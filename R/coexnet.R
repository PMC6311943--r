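# Coding-lncRNA co-expression network: Spearman correlation of normalized
# expression profiles with a Fisher z-transform significance test, plus
# the network feature block.

#' Spearman's rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive average
#' ranks).
#'
#' @param x,y Numeric vectors of equal length \code{n >= 4}.
#' @return Rs in \code{[-1, 1]}; NA if either vector is constant (callers
#'   map this to "no edge").
#' @export
#' @examples
#' spearman_rs(c(1, 2, 3, 4), c(1, 3, 2, 4)) # 0.8
spearman_rs <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4L) stop("need n >= 4 observations")
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(rank(x), rank(y), method = "pearson")
}

#' Significance of a Spearman correlation via the Fisher z-transform
#'
#' Uses the variance-stabilized statistic
#' \code{z = sqrt((n - 3) / 1.06) * atanh(rs)}, which is approximately
#' standard normal under independence; p is the two-sided normal tail.
#'
#' @param rs Spearman correlation.
#' @param n Sample size (>= 4).
#' @return List with \code{f} (Fisher transform), \code{z}, \code{p}.
#'   \code{|rs| = 1} yields infinite z and p = 0.
#' @export
#' @examples
#' edge_significance(0.8, 20) # f = 1.0986, z = 4.3991
edge_significance <- function(rs, n) {
  stopifnot(is.numeric(rs), length(rs) == 1L, n >= 4L)
  if (is.na(rs) || abs(rs) > 1) stop("rs must be in [-1, 1]")
  f <- atanh(rs)
  z <- sqrt((n - 3) / 1.06) * f
  p <- if (is.infinite(z)) 0 else 2 * pnorm(-abs(z))
  list(f = f, z = z, p = p)
}

#' Build the co-expression network
#'
#' Tests every unordered pair of non-constant genes, adjusts p-values
#' (Benjamini-Hochberg across all tested pairs), and retains an edge iff
#' \code{rs >= rs_cutoff} and \code{p_adj <= p_adj_cutoff}.
#'
#' @param m Normalized [expr_matrix] (>= 4 samples).
#' @param rs_cutoff Signed Spearman cutoff (default 0.6).
#' @param p_adj_cutoff Adjusted p-value cutoff (default 0.01).
#' @param biotypes Optional named character vector (gene_id -> biotype)
#'   stored on the nodes.
#' @return A \code{coexpression_network}: list with \code{nodes}
#'   (data.frame gene_id, biotype, constant), \code{edges} (data.frame
#'   a, b, rs, p, p_adj), and the cutoffs.
#' @export
build_network <- function(m, rs_cutoff = 0.6, p_adj_cutoff = 0.01,
                          biotypes = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!m$normalized) stop("expression matrix must be normalized first")
  n <- ncol(m$counts)
  if (n < 4L) stop("need >= 4 samples to build the network")
  sds <- apply(m$counts, 1L, sd)
  const <- sds == 0
  if (any(const))
    message(sum(const), " constant gene(s) excluded from the network")
  ids <- rownames(m$counts)[!const]
  R <- cor(t(m$counts[!const, , drop = FALSE]), method = "spearman")
  iu <- which(upper.tri(R), arr.ind = TRUE)
  rs <- R[iu]
  rs <- pmin(1, pmax(-1, rs))
  z <- sqrt((n - 3) / 1.06) * atanh(rs)
  p <- ifelse(is.infinite(z), 0, 2 * pnorm(-abs(z)))
  p_adj <- p.adjust(p, method = "BH")
  keep <- rs >= rs_cutoff & p_adj <= p_adj_cutoff
  edges <- data.frame(a = ids[iu[keep, 1L]], b = ids[iu[keep, 2L]],
                      rs = rs[keep], p = p[keep], p_adj = p_adj[keep],
                      stringsAsFactors = FALSE)
  nodes <- data.frame(gene_id = rownames(m$counts),
                      biotype = if (!is.null(biotypes))
                        unname(biotypes[rownames(m$counts)])
                      else NA_character_,
                      constant = const, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, rs_cutoff = rs_cutoff,
                 p_adj_cutoff = p_adj_cutoff, n_samples = n),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d nodes, %d edges (rs >= %g, p_adj <= %g)\n",
              nrow(x$nodes), nrow(x$edges), x$rs_cutoff, x$p_adj_cutoff))
  invisible(x)
}

#' Network neighbors of a gene
#' @param net A \code{coexpression_network}.
#' @param gene_id Gene identifier.
#' @return Character vector of neighboring gene IDs.
#' @export
network_neighbors <- function(net, gene_id) {
  e <- net$edges
  c(e$b[e$a == gene_id], e$a[e$b == gene_id])
}

#' Network feature block for one lncRNA
#'
#' Per driver gene, the raw signed Spearman correlation with that driver
#' (no edge cutoff applied); the number of co-expression neighbors that
#' are cancer-related proteins; the total network degree; and the counts
#' of interacting cancer-related miRNAs and of all interacting miRNAs.
#'
#' @param gene_id lncRNA identifier.
#' @param net [build_network()] result.
#' @param m Normalized [expr_matrix].
#' @param drivers Ordered driver gene names.
#' @param cancer_proteins Character vector of cancer-protein gene IDs.
#' @param mirna_interactions data.frame (\code{mirna_id}, \code{lncRNA_id}).
#' @param cancer_mirnas Character vector of cancer-related miRNA IDs.
#' @return Named numeric vector (length \code{|drivers| + 4}).
#' @export
network_features <- function(gene_id, net, m, drivers = DRIVER_GENES,
                             cancer_proteins = character(0),
                             mirna_interactions = NULL,
                             cancer_mirnas = character(0)) {
  network_block_all(gene_id, net, m, drivers, cancer_proteins,
                    mirna_interactions, cancer_mirnas)[1L, ]
}

network_block_all <- function(gene_ids, net, m, drivers, cancer_proteins,
                              mirna_interactions, cancer_mirnas) {
  cols <- c(paste0("scc_", drivers), "cancer_protein_neighbors", "degree",
            "cancer_mirna_interactions", "mirna_interactions")
  out <- matrix(NA_real_, nrow = length(gene_ids), ncol = length(cols),
                dimnames = list(gene_ids, cols))
  counts <- m$counts
  present <- gene_ids[gene_ids %in% rownames(counts)]
  # driver correlations: raw Spearman, missing for drivers absent from the
  # matrix or constant profiles
  sds <- apply(counts, 1L, sd)
  for (d in drivers) {
    col <- paste0("scc_", d)
    if (!d %in% rownames(counts) || sds[d] == 0) next
    ok <- present[sds[present] > 0]
    if (length(ok))
      out[ok, col] <- suppressWarnings(
        cor(t(counts[ok, , drop = FALSE])[, seq_along(ok), drop = FALSE],
            counts[d, ], method = "spearman"))[, 1L]
  }
  # degree / cancer-protein neighbor counts (constant genes: 0 by design)
  deg <- setNames(numeric(length(gene_ids)), gene_ids)
  cp <- deg
  e <- net$edges
  both <- c(e$a, e$b)
  other <- c(e$b, e$a)
  sel <- both %in% gene_ids
  if (any(sel)) {
    dt <- table(both[sel])
    deg[names(dt)] <- as.numeric(dt)
    cpt <- table(both[sel & other %in% cancer_proteins])
    cp[names(cpt)] <- as.numeric(cpt)
  }
  out[, "degree"] <- deg
  out[, "cancer_protein_neighbors"] <- cp
  # miRNA interaction counts
  mi <- setNames(numeric(length(gene_ids)), gene_ids)
  cmi <- mi
  if (!is.null(mirna_interactions) && nrow(mirna_interactions) > 0L) {
    it <- mirna_interactions[mirna_interactions$lncRNA_id %in% gene_ids, ,
                             drop = FALSE]
    if (nrow(it)) {
      t1 <- table(it$lncRNA_id)
      mi[names(t1)] <- as.numeric(t1)
      itc <- it[it$mirna_id %in% cancer_mirnas, , drop = FALSE]
      if (nrow(itc)) {
        t2 <- table(itc$lncRNA_id)
        cmi[names(t2)] <- as.numeric(t2)
      }
    }
  }
  out[, "mirna_interactions"] <- mi
  out[, "cancer_mirna_interactions"] <- cmi
  out
}

#' Write network edges as TSV
#' @param net A \code{coexpression_network}.
#' @param path Output path (columns gene_a, gene_b, rs, p, p_adj).
#' @return The path, invisibly.
#' @export
write_network <- function(net, path) {
  e <- net$edges
  names(e)[1:2] <- c("gene_a", "gene_b")
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
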