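# End-to-end pipeline: wires the stages (simulate, labels, network,
# features, train, importance, predict, evaluate) over a shared run
# configuration with per-stage derived seeds and file artifacts.

#' Pipeline run configuration
#'
#' Aggregates every threshold the pipeline uses, the simulation
#' configuration, the seed and the output directory. The configuration is
#' serialized (with a hash) into each stage's summary for provenance.
#'
#' @param out_dir Output directory.
#' @param seed Root seed; stage seeds are derived from it.
#' @param sim A [sim_config()] for the simulate stage.
#' @param window_bp SNP exclusion window (bp).
#' @param n_sets,set_size Negative resampling design.
#' @param rs_cutoff,p_adj_cutoff Network edge cutoffs.
#' @param k Cross-validation folds.
#' @param algorithms Algorithms for the train stage.
#' @param threshold Candidate probability cutoff.
#' @param alpha GO transfer p-value cutoff.
#' @param log2fc_cutoff Differential-expression |log2FC| cutoff.
#' @param classifier [classifier_config()].
#' @return A \code{run_config} list.
#' @export
run_config <- function(out_dir, seed = 1L, sim = sim_config(),
                       window_bp = 10000L, n_sets = 100L, set_size = 150L,
                       rs_cutoff = 0.6, p_adj_cutoff = 0.01, k = 10L,
                       algorithms = ALGORITHMS, threshold = 0.5,
                       alpha = 0.05, log2fc_cutoff = 1,
                       classifier = classifier_config()) {
  stopifnot(window_bp > 0, n_sets > 0, set_size > 0, k > 1,
            threshold >= 0, alpha > 0, log2fc_cutoff >= 0)
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
              window_bp = as.integer(window_bp),
              n_sets = as.integer(n_sets), set_size = as.integer(set_size),
              rs_cutoff = rs_cutoff, p_adj_cutoff = p_adj_cutoff,
              k = as.integer(k), algorithms = algorithms,
              threshold = threshold, alpha = alpha,
              log2fc_cutoff = log2fc_cutoff, classifier = classifier)
  cfg$hash <- .config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

.config_hash <- function(cfg) {
  cfg$hash <- NULL
  x <- jsonlite::toJSON(lapply(cfg, function(v)
    if (inherits(v, "sim_config")) unclass(v) else v),
    auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(x), tmp)
  substr(unname(tools::md5sum(tmp)), 1L, 12L)
}

PIPELINE_STAGES <- c("simulate", "labels", "network", "features", "train",
                     "importance", "predict", "evaluate")

.stage_outputs <- list(
  simulate = "bundle/MANIFEST.json", labels = "labels.json",
  network = "network_edges.tsv", features = "features.tsv",
  train = "cv_report.json", importance = "importance.tsv",
  predict = "candidates.tsv", evaluate = "evaluation.json")

.stage_deps <- list(
  simulate = character(0), labels = "simulate", network = "simulate",
  features = c("simulate", "network"), train = c("features", "labels"),
  importance = c("features", "labels"),
  predict = c("features", "labels"), evaluate = c("simulate", "predict"))

# rebuild a network object from the edge TSV + expression matrix
.network_from_edges <- function(edges, m, rs_cutoff, p_adj_cutoff) {
  names(edges)[1:2] <- c("a", "b")
  structure(list(nodes = data.frame(gene_id = rownames(m$counts),
                                    biotype = NA_character_,
                                    constant = FALSE,
                                    stringsAsFactors = FALSE),
                 edges = edges, rs_cutoff = rs_cutoff,
                 p_adj_cutoff = p_adj_cutoff, n_samples = ncol(m$counts)),
            class = "coexpression_network")
}

.read_feature_table <- function(path, manifest_path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1L, drop = FALSE])
  rownames(values) <- df[[1L]]
  storage.mode(values) <- "double"
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  structure(list(gene_ids = df[[1L]], values = values,
                 mask = is.na(values),
                 categories = setNames(man$category, man$feature),
                 manifest = man, imputation = "median"),
            class = "feature_table")
}

#' Run the pipeline
#'
#' Executes the requested stages in order inside \code{cfg$out_dir},
#' writing one artifact set per stage plus a JSON summary with the config
#' hash. Re-running with an identical configuration reproduces identical
#' outputs. A stage whose upstream artifact is missing raises a
#' dependency error naming the producing stage.
#'
#' @param cfg A [run_config()].
#' @param stages Ordered subset of
#'   simulate, labels, network, features, train, importance, predict,
#'   evaluate.
#' @return Named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(cfg, stages = PIPELINE_STAGES) {
  stopifnot(inherits(cfg, "run_config"))
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out, f)
  artifacts <- list()
  log <- function(...) message("[lncScout] ", sprintf(...))
  check_deps <- function(stage) {
    for (dep in .stage_deps[[stage]]) {
      if (dep %in% stages) next  # will run earlier in this invocation
      if (!file.exists(p(.stage_outputs[[dep]])))
        stop("stage '", stage, "' needs output of stage '", dep,
             "' (missing ", .stage_outputs[[dep]], "); run it first",
             call. = FALSE)
    }
  }
  summary_of <- function(stage, extra = list()) {
    jsonlite::write_json(
      c(list(stage = stage, config_hash = cfg$hash, seed = cfg$seed,
             timestamped = FALSE), extra),
      p(paste0(stage, "_summary.json")), auto_unbox = TRUE, digits = NA)
  }

  for (stage in stages) {
    check_deps(stage)
    log("stage %s", stage)
    if (stage == "simulate") {
      simulate_bundle(cfg$sim, seed = derive_seed(cfg$seed, 1L),
                      dir = p("bundle"))
      summary_of(stage)
    } else if (stage == "labels") {
      b <- p("bundle")
      genes <- read_gene_models(file.path(b, "genes.gtf"))
      snps <- filter_snps_by_trait(
        read_annotation_bed(file.path(b, "snps.bed")))
      positives <- read_gene_list(file.path(b, "positives.txt"))
      cand <- read_gene_list(file.path(b, "negative_candidates.txt"))
      pool <- build_negative_pool(
        genes[genes$gene_id %in% cand, ], snps,
        window_bp = cfg$window_bp, positives = positives)
      sets <- sample_negative_sets(pool, n_sets = cfg$n_sets,
                                   size = min(cfg$set_size, length(pool)),
                                   seed = derive_seed(cfg$seed, 2L))
      lb <- label_bundle(positives, pool, sets,
                         seed = derive_seed(cfg$seed, 2L),
                         window_bp = cfg$window_bp)
      write_label_bundle(lb, p("labels.json"))
      summary_of(stage, list(n_pool = length(pool),
                             n_sets = length(sets)))
    } else if (stage == "network") {
      m <- normalize_expression(
        read_expression_matrix(p("bundle/expression.tsv")))
      net <- build_network(m, rs_cutoff = cfg$rs_cutoff,
                           p_adj_cutoff = cfg$p_adj_cutoff)
      write_network(net, p("network_edges.tsv"))
      summary_of(stage, list(n_edges = nrow(net$edges)))
    } else if (stage == "features") {
      bundle <- read_bundle(p("bundle"))
      m <- normalize_expression(bundle$expression)
      edges <- utils::read.delim(p("network_edges.tsv"),
                                 stringsAsFactors = FALSE)
      net <- .network_from_edges(edges, m, cfg$rs_cutoff, cfg$p_adj_cutoff)
      lnc <- bundle$genes[grepl("^lncRNA", bundle$genes$biotype), ]
      res <- list(sequences = bundle$sequences, repeats = bundle$repeats,
                  conservation = bundle$conservation,
                  tracks = bundle$tracks,
                  mirnas = bundle$genes[bundle$genes$biotype == "miRNA", ],
                  expression = m, network = net,
                  drivers = bundle$drivers,
                  cancer_proteins = bundle$cancer_proteins,
                  mirna_interactions = bundle$mirna_interactions,
                  cancer_mirnas = bundle$cancer_mirnas)
      ft <- assemble_feature_table(lnc, res)
      write_feature_table(ft, p("features.tsv"))
      jsonlite::write_json(ft$manifest, p("feature_manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      summary_of(stage, list(n_genes = length(ft$gene_ids),
                             n_features = ncol(ft$values)))
    } else if (stage == "train") {
      ft <- .read_feature_table(p("features.tsv"),
                                p("feature_manifest.json"))
      lb <- read_label_bundle(p("labels.json"))
      reports <- evaluate_algorithms(ft, lb$positives, lb$negative_sets,
                                     algorithms = cfg$algorithms,
                                     k = cfg$k,
                                     seed = derive_seed(cfg$seed, 3L),
                                     config = cfg$classifier)
      jsonlite::write_json(
        lapply(reports, function(r) unclass(r)[c("algorithm", "mean_auc",
                                                 "sd_auc", "per_set_auc")]),
        p("cv_report.json"), auto_unbox = TRUE, digits = NA)
      summary_of(stage, list(mean_auc = lapply(reports, `[[`, "mean_auc")))
    } else if (stage == "importance") {
      ft <- .read_feature_table(p("features.tsv"),
                                p("feature_manifest.json"))
      lb <- read_label_bundle(p("labels.json"))
      imp <- feature_importance(ft, lb$positives, lb$negative_sets,
                                num_trees = cfg$classifier$et_num_trees,
                                seed = derive_seed(cfg$seed, 4L))
      utils::write.table(imp, p("importance.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      summary_of(stage)
    } else if (stage == "predict") {
      ft <- .read_feature_table(p("features.tsv"),
                                p("feature_manifest.json"))
      lb <- read_label_bundle(p("labels.json"))
      unknowns <- read_gene_list(p("bundle/unknowns.txt"))
      pred <- predict_candidates(ft, lb$positives, lb$negative_sets,
                                 unknowns, threshold = cfg$threshold,
                                 seed = derive_seed(cfg$seed, 5L),
                                 config = cfg$classifier)
      utils::write.table(pred, p("candidates.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      summary_of(stage, list(n_candidates = sum(pred$is_candidate)))
    } else if (stage == "evaluate") {
      bundle <- read_bundle(p("bundle"))
      ft <- .read_feature_table(p("features.tsv"),
                                p("feature_manifest.json"))
      lb <- read_label_bundle(p("labels.json"))
      pred <- utils::read.delim(p("candidates.tsv"),
                                stringsAsFactors = FALSE)
      cand <- pred$gene_id[pred$is_candidate]
      neg_ref <- lb$negative_sets[[1L]]
      # per-feature KS between positives and one negative sample
      ks <- do.call(rbind, lapply(colnames(ft$values), function(fn) {
        r <- ks_two_sample(
          ft$values[match(lb$positives, ft$gene_ids), fn],
          ft$values[match(neg_ref, ft$gene_ids), fn])
        data.frame(feature = fn, d = r$d, p = r$p)
      }))
      utils::write.table(ks, p("ks_features.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      lfc <- log2_fold_change(bundle$tumor, bundle$normal)
      burden <- mutation_burden(
        bundle$genes[grepl("^lncRNA", bundle$genes$biotype), ],
        bundle$mutations)
      ev <- list(
        de_fraction_positive = de_fraction(lfc[lb$positives],
                                           cfg$log2fc_cutoff),
        de_fraction_negative = de_fraction(lfc[neg_ref],
                                           cfg$log2fc_cutoff),
        de_fraction_candidates = if (length(cand))
          de_fraction(lfc[cand], cfg$log2fc_cutoff) else NA,
        burden_ks_p = ks_two_sample(burden[lb$positives],
                                    burden[neg_ref])$p,
        n_candidates = length(cand))
      jsonlite::write_json(ev, p("evaluation.json"), auto_unbox = TRUE,
                           digits = NA)
      summary_of(stage, ev)
    }
    artifacts[[stage]] <- p(.stage_outputs[[stage]])
  }
  invisible(artifacts)
}
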