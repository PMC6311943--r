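# Synthetic resource bundle with planted positive-vs-negative class
# differences. The generator emulates, at toy scale, every external
# resource the pipeline consumes (gene models, sequences, repeat/SNP/
# mutation annotations, conservation and histone tracks, a 16-tissue
# expression matrix, miRNA interactions, GO annotations, tumor/normal
# expression) so every stage and the end-to-end run are testable without
# downloads.

PLANTED_TRACKS <- c("H1hescH3k4me1", "H1hescH3k4me3")

#' Simulation configuration
#'
#' Defaults define the reference study conditions: 150 positives, a
#' 600-gene negative pool, 200 unknowns with 50/50 hidden truth, 16
#' tissues, and planted class differences mirroring the features that
#' dominate importance rankings (gene-body SINE/LINE counts, H1hesc
#' H3k4me1/H3k4me3 gene-body signal, driver-gene Spearman correlation,
#' intron GC, exon conservation, cancer-protein connectivity).
#' \code{effect_scale} multiplies every planted difference; 0 gives a null
#' bundle in which both classes share one generative distribution.
#'
#' @param n_positive,n_negative_pool,n_decoy,n_unknown,n_coding,n_mirna
#'   Gene counts; decoys are lncRNAs given nearby GWAS SNPs so the
#'   negative-pool filter has work to do.
#' @param n_chrom Chromosomes the genes are spread over.
#' @param slot_bp Per-gene genomic slot width; keeps SNP exclusion windows
#'   of neighboring genes disjoint.
#' @param tissues Tissue (sample) names.
#' @param base_gc,exon_gc Background and exon GC fractions.
#' @param intron_gc_neg,intron_gc_delta Negative-class intron GC and the
#'   planted positive shift.
#' @param cons_mean,cons_sd,exon_cons_delta Conservation level, spread and
#'   planted exon shift.
#' @param signal_mean,signal_sd,flank_signal_mean Histone body/flank
#'   signal levels; \code{k4me1_delta}, \code{k4me3_delta} are the planted
#'   positive shifts of the two H1hesc tracks.
#' @param k4me1_delta,k4me3_delta Planted histone shifts.
#' @param sine_rate_neg,sine_rate_delta,line_rate_neg,line_rate_delta,
#'   ltr_rate,satellite_rate Per-gene-body repeat Poisson rates.
#' @param driver_rho Latent-factor loading giving positives their Spearman
#'   correlation with the three hot driver genes and the cancer proteins.
#' @param expr_log2_shift Positive-class expression level shift (log2).
#' @param mirna_rate Mean miRNA interactions per lncRNA (unplanted).
#' @param de_prob_neg,de_prob_delta,de_effect,tumor_reps,normal_reps
#'   Tumor/normal differential-expression generator.
#' @param mutation_rate_neg,mutation_rate_delta Somatic mutation rates per
#'   gene body.
#' @param effect_scale Global multiplier on all planted differences.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_positive = 150L, n_negative_pool = 600L,
                       n_decoy = 60L, n_unknown = 200L, n_coding = 60L,
                       n_mirna = 40L, n_chrom = 4L, slot_bp = 12500L,
                       tissues = TISSUES_16,
                       base_gc = 0.42, exon_gc = 0.46,
                       intron_gc_neg = 0.44, intron_gc_delta = 0.025,
                       cons_mean = 0.35, cons_sd = 0.10,
                       exon_cons_delta = 0.075,
                       signal_mean = 2, signal_sd = 0.8,
                       flank_signal_mean = 0.8,
                       k4me1_delta = 0.6, k4me3_delta = 0.6,
                       sine_rate_neg = 3, sine_rate_delta = 2,
                       line_rate_neg = 2.5, line_rate_delta = 2.2,
                       ltr_rate = 1.5, satellite_rate = 0.8,
                       driver_rho = 0.6, expr_log2_shift = 0.3,
                       mirna_rate = 4, cancer_mirna_frac_neg = 0.2,
                       cancer_mirna_frac_delta = 0.55,
                       de_prob_neg = 0.2, de_prob_delta = 0.2,
                       de_effect = 2, tumor_reps = 8L, normal_reps = 8L,
                       mutation_rate_neg = 2, mutation_rate_delta = 3,
                       effect_scale = 1) {
  cfg <- as.list(environment())
  rates <- c(cfg$sine_rate_neg, cfg$line_rate_neg, cfg$ltr_rate,
             cfg$satellite_rate, cfg$mirna_rate, cfg$mutation_rate_neg)
  if (any(rates < 0)) stop("rates must be >= 0")
  if (cfg$driver_rho < 0 || cfg$driver_rho >= 1)
    stop("driver_rho must be in [0, 1)")
  if (cfg$effect_scale < 0) stop("effect_scale must be >= 0")
  if (cfg$slot_bp < 12000L)
    stop("slot_bp too small: SNP windows of neighboring genes would touch")
  class(cfg) <- "sim_config"
  cfg
}

#' Canonical names of the planted informative features
#' @return Character vector of the 10 feature names whose generative
#'   distributions differ between classes in the default bundle.
#' @export
planted_features <- function() {
  c("SINE_genebody", "H1hescH3k4me1_genebody", "scc_ERBB2", "gc_intron",
    "scc_CTNNB1", "H1hescH3k4me3_genebody", "cons_exon", "LINE_genebody",
    "scc_CDKN2A", "cancer_mirna_interactions")
}

.clamp01 <- function(x) pmin(1, pmax(0, x))

.rand_bases <- function(n, gc) {
  strong <- runif(n) < gc
  out <- character(n)
  out[strong] <- sample(c("C", "G"), sum(strong), replace = TRUE)
  out[!strong] <- sample(c("A", "T"), sum(!strong), replace = TRUE)
  out
}

# random exon structure starting at `start`; returns 2-col matrix
.rand_exons <- function(start, n_exons) {
  pos <- start
  ex <- matrix(0L, nrow = n_exons, ncol = 2L,
               dimnames = list(NULL, c("start", "end")))
  for (j in seq_len(n_exons)) {
    w <- sample(150:300, 1L)
    ex[j, ] <- c(pos, pos + w)
    pos <- pos + w + if (j < n_exons) sample(250:500, 1L) else 0L
  }
  ex
}

#' Simulate a complete toy resource bundle
#'
#' Generates gene models, chromosome sequences, repeat/SNP/mutation
#' annotations, a conservation track, nine histone tracks, a 16-tissue
#' raw-count expression matrix, miRNA interactions, GO annotations,
#' tumor/normal expression and the hidden truth table, with class
#' differences planted per the configuration. Identical seeds give
#' identical bundles.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; all bundle randomness derives from it.
#' @param dir Optional directory; when given the bundle is also written to
#'   disk via [write_bundle()].
#' @return A \code{sim_bundle} list (see package vignette for fields).
#' @export
simulate_bundle <- function(cfg = sim_config(), seed = 1L, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  bundle <- with_seed(seed, .simulate_bundle_impl(cfg, seed))
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

.simulate_bundle_impl <- function(cfg, seed) {
  sc <- cfg$effect_scale
  ids <- list(
    positive = sprintf("LNCP%04d", seq_len(cfg$n_positive)),
    pool = sprintf("LNCN%04d", seq_len(cfg$n_negative_pool)),
    decoy = sprintf("LNCD%04d", seq_len(cfg$n_decoy)),
    unknown = sprintf("LNCU%04d", seq_len(cfg$n_unknown)))
  n_cp <- max(0L, min(20L, cfg$n_coding - length(DRIVER_GENES)))
  n_other <- cfg$n_coding - length(DRIVER_GENES) - n_cp
  if (n_other < 0L) stop("n_coding must be >= ", length(DRIVER_GENES))
  coding_ids <- c(DRIVER_GENES,
                  if (n_cp) sprintf("CP%02d", seq_len(n_cp)),
                  if (n_other) sprintf("PCG%02d", seq_len(n_other)))
  cancer_proteins <- c("ERBB2", "CTNNB1", "CDKN2A",
                       if (n_cp) sprintf("CP%02d", seq_len(n_cp)))
  hot_drivers <- c("ERBB2", "CTNNB1", "CDKN2A")

  # truth classes: unknowns are hidden 50/50
  unk_class <- rep(c("pos", "neg"), length.out = cfg$n_unknown)
  roles <- data.frame(
    gene_id = c(ids$positive, ids$pool, ids$decoy, ids$unknown),
    role = rep(c("positive", "pool", "decoy", "unknown"),
               c(cfg$n_positive, cfg$n_negative_pool, cfg$n_decoy,
                 cfg$n_unknown)),
    class = c(rep("pos", cfg$n_positive),
              rep("neg", cfg$n_negative_pool + cfg$n_decoy), unk_class),
    stringsAsFactors = FALSE)

  # ---- layout: one gene per slot, shuffled across n_chrom chromosomes
  lnc_ids <- roles$gene_id
  all_ids <- c(lnc_ids, coding_ids)
  ord <- sample(length(all_ids))
  slots_per_chrom <- ceiling(length(all_ids) / cfg$n_chrom)
  chrom_len <- slots_per_chrom * cfg$slot_bp + 2000L
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  slot <- (seq_along(all_ids) - 1L) %% slots_per_chrom
  chrom_of <- chroms[(seq_along(all_ids) - 1L) %/% slots_per_chrom + 1L]
  gene_start <- slot * cfg$slot_bp + 5200L
  if (max(gene_start) + 2400L > chrom_len) stop("infeasible layout")

  layout <- data.frame(gene_id = all_ids[ord], chrom = chrom_of,
                       start0 = as.integer(gene_start),
                       stringsAsFactors = FALSE)
  layout <- layout[order(match(layout$gene_id, all_ids)), ]

  is_lnc <- layout$gene_id %in% lnc_ids
  n_exons <- ifelse(is_lnc, sample(2:3, nrow(layout), replace = TRUE), 3L)
  # a few intronless decoys exercise the missing-intron-feature path
  intronless <- layout$gene_id %in% utils::head(ids$decoy, 3L)
  n_exons[intronless] <- 1L

  exons <- lapply(seq_len(nrow(layout)), function(i)
    .rand_exons(layout$start0[i], n_exons[i]))
  biotype <- ifelse(is_lnc, "lncRNA-intergenic", "protein_coding")
  # unknowns carry a biotype mix; only intergenic lncRNAs enter pools
  unk_idx <- which(layout$gene_id %in% ids$unknown)
  bt_mix <- sample(c("lncRNA-antisense", "lncRNA-intergenic",
                     "lncRNA-overlapping"), length(unk_idx), replace = TRUE,
                   prob = c(0.25, 0.65, 0.10))
  biotype[unk_idx] <- bt_mix
  genes_df <- data.frame(
    gene_id = layout$gene_id, chrom = layout$chrom,
    start = vapply(exons, function(e) e[1L, 1L], integer(1)),
    end = vapply(exons, function(e) e[nrow(e), 2L], integer(1)),
    strand = sample(c("+", "-"), nrow(layout), replace = TRUE),
    biotype = biotype, stringsAsFactors = FALSE)
  genes_df$exons <- exons

  # miRNA genes: some hosted inside lncRNA bodies, the rest intergenic
  n_host <- min(cfg$n_mirna %/% 2L, length(lnc_ids))
  hosts <- sample(lnc_ids, n_host)
  mir_rows <- lapply(seq_len(cfg$n_mirna), function(i) {
    id <- sprintf("MIR%03d", i)
    if (i <= n_host) {
      h <- genes_df[genes_df$gene_id == hosts[i], ]
      s <- h$start + 50L
      data.frame(gene_id = id, chrom = h$chrom, start = s, end = s + 70L,
                 strand = h$strand, biotype = "miRNA",
                 stringsAsFactors = FALSE)
    } else {
      ch <- sample(chroms, 1L)
      s <- (sample(slots_per_chrom, 1L) - 1L) * cfg$slot_bp + 1000L + i
      data.frame(gene_id = id, chrom = ch, start = s, end = s + 70L,
                 strand = sample(c("+", "-"), 1L), biotype = "miRNA",
                 stringsAsFactors = FALSE)
    }
  })
  mir_df <- do.call(rbind, mir_rows)
  mir_df$exons <- lapply(seq_len(nrow(mir_df)), function(i)
    cbind(start = mir_df$start[i], end = mir_df$end[i]))
  genes <- gene_set(rbind(genes_df, mir_df))

  cls_of <- setNames(roles$class, roles$gene_id)
  is_pos_gene <- function(id) !is.na(cls_of[id]) & cls_of[id] == "pos"

  # ---- sequences: background GC, exon GC, class-shifted intron GC
  seq_list <- lapply(chroms, function(ch) {
    bases <- .rand_bases(chrom_len, cfg$base_gc)
    rows <- which(genes$chrom == ch & genes$biotype != "miRNA")
    for (i in rows) {
      ex <- genes$exons[[i]]
      for (j in seq_len(nrow(ex)))
        bases[(ex[j, 1L] + 1L):ex[j, 2L]] <-
          .rand_bases(ex[j, 2L] - ex[j, 1L], cfg$exon_gc)
      introns <- gene_introns(ex)
      if (nrow(introns)) {
        gc <- cfg$intron_gc_neg +
          if (isTRUE(is_pos_gene(genes$gene_id[i])))
            cfg$intron_gc_delta * sc else 0
        for (j in seq_len(nrow(introns)))
          bases[(introns[j, 1L] + 1L):introns[j, 2L]] <-
            .rand_bases(introns[j, 2L] - introns[j, 1L], gc)
      }
    }
    paste(bases, collapse = "")
  })
  sequences <- Biostrings::DNAStringSet(setNames(unlist(seq_list), chroms))

  # ---- repeats: planted gene-body SINE/LINE rates, background elsewhere
  lnc_rows <- which(genes$gene_id %in% lnc_ids)
  rep_list <- list()
  place_in_body <- function(i, k, w, cl) {
    if (k == 0L) return(NULL)
    s <- genes$start[i] +
      sample.int(max(1L, genes$end[i] - genes$start[i] - w), k, replace = TRUE)
    data.frame(chrom = genes$chrom[i], start = s, end = s + w, class = cl,
               stringsAsFactors = FALSE)
  }
  for (i in lnc_rows) {
    pos <- isTRUE(is_pos_gene(genes$gene_id[i]))
    rep_list[[length(rep_list) + 1L]] <- rbind(
      place_in_body(i, rpois(1L, cfg$sine_rate_neg +
                               if (pos) cfg$sine_rate_delta * sc else 0),
                    30L, "SINE"),
      place_in_body(i, rpois(1L, cfg$line_rate_neg +
                               if (pos) cfg$line_rate_delta * sc else 0),
                    60L, "LINE"),
      place_in_body(i, rpois(1L, cfg$ltr_rate), 80L, "LTR"),
      place_in_body(i, rpois(1L, cfg$satellite_rate), 40L, "Satellite"))
  }
  # background repeats scattered across each chromosome
  for (ch in chroms) {
    k <- max(1L, chrom_len %/% 20000L)
    s <- sort(sample.int(chrom_len - 100L, 4L * k))
    rep_list[[length(rep_list) + 1L]] <- data.frame(
      chrom = ch, start = s, end = s + rep(c(30L, 60L, 80L, 40L), k),
      class = rep(c("SINE", "LINE", "LTR", "Satellite"), k),
      stringsAsFactors = FALSE)
  }
  repeats <- annotation_set("repeats", do.call(rbind, rep_list),
                            vocabulary = REPEAT_CLASSES)

  # ---- conservation: exon values carry the planted shift
  feat_rows <- which(genes$biotype != "miRNA")
  cons_list <- lapply(feat_rows, function(i) {
    pos <- isTRUE(is_pos_gene(genes$gene_id[i]))
    ex <- genes$exons[[i]]
    introns <- gene_introns(ex)
    exon_mu <- cfg$cons_mean + if (pos) cfg$exon_cons_delta * sc else 0
    rows <- data.frame(
      chrom = genes$chrom[i],
      start = c(ex[, 1L], introns[, 1L], genes$start[i] - 1200L),
      end = c(ex[, 2L], introns[, 2L], genes$start[i]),
      value = .clamp01(c(rnorm(nrow(ex), exon_mu, cfg$cons_sd),
                         rnorm(nrow(introns), cfg$cons_mean * 0.6,
                               cfg$cons_sd),
                         rnorm(1L, cfg$cons_mean * 0.7, cfg$cons_sd))),
      stringsAsFactors = FALSE)
    rows[rows$start >= 0L, , drop = FALSE]
  })
  conservation <- signal_track("phastCons", do.call(rbind, cons_list))

  # ---- histone tracks: contiguous flank/body/flank segments per gene
  tracks <- setNames(lapply(TRACK_NAMES, function(tn) {
    planted_delta <- if (tn == "H1hescH3k4me1") cfg$k4me1_delta * sc
                     else if (tn == "H1hescH3k4me3") cfg$k4me3_delta * sc
                     else 0
    seg <- lapply(feat_rows, function(i) {
      pos <- isTRUE(is_pos_gene(genes$gene_id[i]))
      mu <- cfg$signal_mean + if (pos) planted_delta else 0
      s <- genes$start[i]; e <- genes$end[i]
      mid <- s + (e - s) %/% 2L
      data.frame(
        chrom = genes$chrom[i],
        start = c(max(0L, s - 5000L), s, mid, e),
        end = c(s, mid, e, e + 5000L),
        value = pmax(0, c(rnorm(1L, cfg$flank_signal_mean, cfg$signal_sd / 2),
                          rnorm(2L, mu, cfg$signal_sd),
                          rnorm(1L, cfg$flank_signal_mean,
                                cfg$signal_sd / 2))),
        stringsAsFactors = FALSE)
    })
    signal_track(tn, do.call(rbind, seg))
  }), TRACK_NAMES)

  # ---- SNPs: cancer-trait SNPs inside decoy bodies, non-cancer traits
  # sprinkled into pool bodies (removed by the trait filter)
  traits <- c("breast carcinoma", "melanoma", "chronic lymphocytic leukemia",
              "glioma", "colorectal cancer")
  benign <- c("height", "body mass index", "hair color")
  snp_list <- list()
  for (id in ids$decoy) {
    i <- match(id, genes$gene_id)
    k <- 1L + rpois(1L, 1)
    s <- genes$start[i] +
      sample.int(genes$end[i] - genes$start[i] - 1L, k, replace = TRUE)
    snp_list[[length(snp_list) + 1L]] <- data.frame(
      chrom = genes$chrom[i], start = s, end = s + 1L,
      class = sample(traits, k, replace = TRUE), stringsAsFactors = FALSE)
  }
  for (id in sample(ids$pool, min(20L, length(ids$pool)))) {
    i <- match(id, genes$gene_id)
    s <- genes$start[i] + sample.int(genes$end[i] - genes$start[i] - 1L, 1L)
    snp_list[[length(snp_list) + 1L]] <- data.frame(
      chrom = genes$chrom[i], start = s, end = s + 1L,
      class = sample(benign, 1L), stringsAsFactors = FALSE)
  }
  snps <- annotation_set("gwas_snps", do.call(rbind, snp_list))

  # ---- expression: every lncRNA loads a small dictionary of shared
  # tissue programs (so negatives have structured, not iid, profiles);
  # program 1 is the cancer program carried by the hot drivers and cancer
  # proteins, and positives receive a boosted loading on it. Random-sign
  # loadings cancel across genes, keeping the median-of-ratios reference
  # clean.
  n_t <- length(cfg$tissues)
  n_prog <- 4L
  programs <- matrix(rnorm(n_prog * n_t), nrow = n_prog)
  boost <- 2 * cfg$driver_rho * sc
  expr_ids <- c(lnc_ids, coding_ids)
  logq <- matrix(0, nrow = length(expr_ids), ncol = n_t,
                 dimnames = list(expr_ids, cfg$tissues))
  other_prog <- setNames(sample(2:n_prog,
                                length(coding_ids), replace = TRUE),
                         coding_ids)
  for (id in expr_ids) {
    eps <- rnorm(n_t)
    logq[id, ] <- if (id %in% hot_drivers) {
      log(80) + 0.8 * (0.97 * programs[1L, ] + 0.24 * eps)
    } else if (id %in% cancer_proteins) {
      log(80) + 0.8 * (0.97 * programs[1L, ] + 0.24 * eps)
    } else if (id %in% coding_ids) {
      log(80) + 0.8 * (0.90 * programs[other_prog[id], ] + 0.44 * eps)
    } else {
      v <- rnorm(n_prog)
      # positives co-express with the cancer program in either direction
      # (activating or suppressing), so the planted signal lives in the
      # correlation structure rather than in marginal tissue levels
      if (isTRUE(is_pos_gene(id)))
        v[1L] <- v[1L] + sample(c(-1, 1), 1L) * boost * sqrt(sum(v^2))
      w <- v / sqrt(sum(v^2))
      log(30) + (if (isTRUE(is_pos_gene(id)))
                   cfg$expr_log2_shift * sc * log(2) else 0) +
        0.6 * (0.95 * drop(w %*% programs) + 0.31 * eps)
    }
  }
  true_sf <- exp(rnorm(n_t, 0, 0.15))
  counts <- round(sweep(exp(logq), 2L, true_sf, "*"))
  expression <- expr_matrix(counts, normalized = FALSE)

  # ---- miRNA interactions: total interaction count is class-identical;
  # the fraction involving cancer-related miRNAs carries the planted
  # difference
  mirna_ids <- mir_df$gene_id
  cancer_mirnas <- sample(mirna_ids, max(1L, length(mirna_ids) %/% 3L))
  other_mirnas <- setdiff(mirna_ids, cancer_mirnas)
  inter_list <- lapply(lnc_ids, function(id) {
    k <- rpois(1L, cfg$mirna_rate)
    if (k == 0L) return(NULL)
    frac <- cfg$cancer_mirna_frac_neg +
      if (isTRUE(is_pos_gene(id))) cfg$cancer_mirna_frac_delta * sc else 0
    kc <- min(rbinom(1L, k, frac), length(cancer_mirnas))
    ko <- min(k - kc, length(other_mirnas))
    partners <- c(sample(cancer_mirnas, kc), sample(other_mirnas, ko))
    if (length(partners) == 0L) return(NULL)
    data.frame(mirna_id = partners, lncRNA_id = id,
               stringsAsFactors = FALSE)
  })
  mirna_interactions <- do.call(rbind, inter_list)
  if (is.null(mirna_interactions))
    mirna_interactions <- data.frame(mirna_id = character(0),
                                     lncRNA_id = character(0))

  # ---- GO map over coding genes; one cancer-flavored term concentrated
  # on the latent-factor genes
  go_terms <- sprintf("GO:%07d", 10:39)
  cancer_term <- "GO:0000001"
  go_list <- lapply(coding_ids, function(id) {
    terms <- sample(go_terms, sample(3:6, 1L))
    p_cancer <- if (id %in% c(hot_drivers, cancer_proteins)) 0.9 else 0.05
    if (runif(1L) < p_cancer) terms <- c(cancer_term, terms)
    data.frame(gene_id = id, term = terms, stringsAsFactors = FALSE)
  })
  go_map <- do.call(rbind, go_list)

  # ---- tumor/normal expression of lncRNAs for the DE evaluation
  de_prob <- ifelse(cls_of[lnc_ids] == "pos",
                    cfg$de_prob_neg + cfg$de_prob_delta * sc,
                    cfg$de_prob_neg)
  de_flag <- rbinom(length(lnc_ids), 1L, de_prob)
  lfc_true <- de_flag * sample(c(-1, 1), length(lnc_ids), replace = TRUE) *
    cfg$de_effect
  base <- 30
  tumor <- t(vapply(seq_along(lnc_ids), function(i)
    base * 2^lfc_true[i] * exp(rnorm(cfg$tumor_reps, 0, 0.3)),
    numeric(cfg$tumor_reps)))
  normal <- t(vapply(seq_along(lnc_ids), function(i)
    base * exp(rnorm(cfg$normal_reps, 0, 0.3)), numeric(cfg$normal_reps)))
  rownames(tumor) <- rownames(normal) <- lnc_ids
  colnames(tumor) <- paste0("tumor_", seq_len(cfg$tumor_reps))
  colnames(normal) <- paste0("normal_", seq_len(cfg$normal_reps))

  # ---- somatic mutations: planted burden on positives; heavy on cancer
  # proteins (positive control)
  mut_list <- list()
  add_muts <- function(i, rate) {
    k <- rpois(1L, rate)
    if (k == 0L) return(NULL)
    s <- genes$start[i] +
      sample.int(genes$end[i] - genes$start[i] - 1L, k, replace = TRUE)
    data.frame(chrom = genes$chrom[i], start = s, end = s + 1L,
               class = "somatic", stringsAsFactors = FALSE)
  }
  for (id in lnc_ids) {
    i <- match(id, genes$gene_id)
    rate <- cfg$mutation_rate_neg +
      if (isTRUE(is_pos_gene(id))) cfg$mutation_rate_delta * sc else 0
    mut_list[[length(mut_list) + 1L]] <- add_muts(i, rate)
  }
  for (id in cancer_proteins) {
    i <- match(id, genes$gene_id)
    mut_list[[length(mut_list) + 1L]] <-
      add_muts(i, 3 * (cfg$mutation_rate_neg + cfg$mutation_rate_delta))
  }
  mutations <- annotation_set("somatic_mutations",
                              do.call(rbind, mut_list))

  truth <- roles
  truth$de_lfc_true <- lfc_true[match(truth$gene_id, lnc_ids)]

  structure(list(
    config = cfg, seed = as.integer(seed),
    genes = genes, sequences = sequences, repeats = repeats,
    conservation = conservation, tracks = tracks, snps = snps,
    mutations = mutations, expression = expression,
    tumor = tumor, normal = normal,
    mirna_interactions = mirna_interactions,
    drivers = DRIVER_GENES, cancer_proteins = cancer_proteins,
    cancer_mirnas = cancer_mirnas, go_map = go_map,
    positives = ids$positive, truth = truth,
    chrom_lengths = setNames(rep(chrom_len, length(chroms)), chroms)),
    class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf(paste0("sim_bundle (seed %d): %d genes on %d chromosomes, ",
                     "%d positives, effect_scale=%g\n"),
              x$seed, nrow(x$genes), length(x$chrom_lengths),
              length(x$positives), x$config$effect_scale))
  invisible(x)
}

#' Analytic single-feature AUC bounds for the planted Gaussian features
#'
#' For a Gaussian planted feature with positive-class mean shift delta and
#' within-class feature standard deviation sigma, the Bayes-optimal
#' univariate AUC is \code{pnorm(delta / (sigma * sqrt(2)))}. Features
#' whose generators are not Gaussian (Poisson counts, binomial GC,
#' correlation-derived) are flagged not applicable (NA).
#'
#' @param cfg A [sim_config()].
#' @return data.frame (feature, auc_bound, applicable).
#' @export
truth_auc_bound <- function(cfg = sim_config()) {
  sc <- cfg$effect_scale
  # body signal features average two chunks; exon conservation averages
  # ~n_exon values, use the 2-exon case as the conservative reference
  gauss <- data.frame(
    feature = c("H1hescH3k4me1_genebody", "H1hescH3k4me3_genebody",
                "cons_exon"),
    delta = c(cfg$k4me1_delta * sc, cfg$k4me3_delta * sc,
              cfg$exon_cons_delta * sc),
    sigma = c(cfg$signal_sd / sqrt(2), cfg$signal_sd / sqrt(2),
              cfg$cons_sd / sqrt(2)),
    stringsAsFactors = FALSE)
  gauss$auc_bound <- pnorm(gauss$delta / (gauss$sigma * sqrt(2)))
  gauss$applicable <- TRUE
  rest <- data.frame(feature = setdiff(planted_features(), gauss$feature),
                     delta = NA_real_, sigma = NA_real_,
                     auc_bound = NA_real_, applicable = FALSE,
                     stringsAsFactors = FALSE)
  rbind(gauss[, c("feature", "auc_bound", "applicable")],
        rest[, c("feature", "auc_bound", "applicable")])
}
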