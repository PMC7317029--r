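# End-to-end orchestration from a single flat config file, with a manifest
# of every artifact (stage, input hashes, seed) so a rerun with the same
# config is verifiably identical for deterministic stages.

PIPELINE_STAGES <- c("aggregate", "qc", "hits", "cluster", "network",
                     "tracks", "de")

#' Read a pipeline configuration
#'
#' The config is a flat DCF text file (`key: value` per line). Recognized
#' keys: input paths (`scores`, `lethal_file`, `edges`, `annotation`,
#' `tracks`, `expr`, `samples`), `out_dir`, `seed`, `stages` (comma list),
#' `scale_min`/`scale_max`, `hit_categories` (comma list), `quantile_type`,
#' `k_min`, `k_max`, `n_resamples`, `subsample_frac`, `linkage`, `vwp`,
#' `min_complex_size`, `alpha`, `n_perm`, `p_thresh`, `fc_thresh`,
#' `kd_label`.
#'
#' @param path DCF file.
#' @return named list of class `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config not found: %s", path)
  m <- read.dcf(path)
  cfg <- as.list(m[1L, ])
  numeric_keys <- c("seed", "scale_min", "scale_max", "quantile_type",
                    "k_min", "k_max", "n_resamples", "subsample_frac",
                    "vwp", "min_complex_size", "alpha", "n_perm", "p_thresh",
                    "fc_thresh")
  for (k in intersect(names(cfg), numeric_keys)) {
    cfg[[k]] <- as.numeric(cfg[[k]])
  }
  for (k in intersect(names(cfg), c("stages", "hit_categories"))) {
    cfg[[k]] <- trimws(strsplit(cfg[[k]], ",", fixed = TRUE)[[1L]])
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

pipeline_defaults <- function() {
  list(seed = 1, scale_min = -2, scale_max = 2, quantile_type = 7,
       k_min = 2, k_max = 10, n_resamples = 250, subsample_frac = 0.8,
       linkage = "average", vwp = 0.2, min_complex_size = 3, alpha = 0.05,
       n_perm = 1000, p_thresh = 0.01, fc_thresh = 1.5, kd_label = NULL,
       hit_categories = c("invasion", "multilayering", "cell body rounding"),
       stages = PIPELINE_STAGES)
}

stage_seed <- function(master, stage) {
  # deterministic per-stage seeds, independent of which stages are enabled
  (as.integer(master) + 1000L * match(stage, PIPELINE_STAGES)) %% .Machine$integer.max
}

#' Run the screen analysis pipeline
#'
#' Runs the enabled stages in dependency order -- aggregate, qc, hits,
#' cluster, network (with MCODE and, if an annotation table is given,
#' enrichment of the combined hit set), tracks, de -- writing every output
#' as TSV under `out_dir` and returning a manifest with stage, file, md5
#' hash and the per-stage seed. Any stage error aborts with the stage name
#' and offending input.
#'
#' @param config a `pipeline_config`, a path to one, or a named list (merged
#'   over the defaults).
#' @return the manifest (list), invisibly; also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(pipeline_defaults(), as.list(config))
  if (is.null(cfg$out_dir)) stop("config needs `out_dir`", call. = FALSE)
  if (is.null(cfg$scores)) stop("stage `aggregate`: missing input `scores`",
                                call. = FALSE)
  stages <- intersect(PIPELINE_STAGES, cfg$stages)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  scale <- c(cfg$scale_min, cfg$scale_max)

  inputs <- list(scores = cfg$scores, edges = cfg$edges,
                 annotation = cfg$annotation, tracks = cfg$tracks,
                 expr = cfg$expr, samples = cfg$samples)
  need <- list(network = "edges", tracks = "tracks", de = "expr")
  for (st in names(need)) {
    if (st %in% stages && is.null(inputs[[need[[st]]]])) {
      stopf("stage `%s`: missing input `%s`", st, need[[st]])
    }
  }
  for (nm in names(inputs)) {
    if (!is.null(inputs[[nm]]) && !file.exists(inputs[[nm]])) {
      stopf("input `%s` does not exist: %s", nm, inputs[[nm]])
    }
  }

  manifest <- list()
  emit <- function(stage, path, seed = NA) {
    manifest[[length(manifest) + 1L]] <<- list(
      stage = stage, file = basename(path),
      md5 = unname(tools::md5sum(path)), seed = seed)
  }
  out <- function(name) file.path(cfg$out_dir, name)

  table <- read_scores(cfg$scores, scale = scale,
                       lethal_file = cfg$lethal_file)
  matrix <- suppressWarnings(aggregate_scores(table))
  if ("aggregate" %in% stages) {
    write_matrix_tsv(matrix, out("matrix.tsv"), id_col = "line_id")
    emit("aggregate", out("matrix.tsv"))
  }

  if ("qc" %in% stages) {
    seed <- stage_seed(cfg$seed, "qc")
    agree <- scorer_agreement(table)
    write_tsv(agree, out("scorer_agreement.tsv"))
    emit("qc", out("scorer_agreement.tsv"), seed)
    conc <- try(rnai_pair_concordance(matrix, n_perm = cfg$n_perm,
                                      alpha = cfg$alpha, seed = seed),
                silent = TRUE)
    if (!inherits(conc, "try-error")) {
      write_tsv(as.data.frame(conc), out("concordance.tsv"))
      emit("qc", out("concordance.tsv"), seed)
    }
  }

  hits <- NULL
  if ("hits" %in% stages || "network" %in% stages) {
    hits <- call_hits(matrix, quantile_type = cfg$quantile_type)
    if ("hits" %in% stages) {
      write_tsv(as.data.frame(hits), out("hits.tsv"))
      write_tsv(attr(hits, "summary"), out("hit_summary.tsv"))
      emit("hits", out("hits.tsv"))
      emit("hits", out("hit_summary.tsv"))
    }
  }

  if ("cluster" %in% stages) {
    seed <- stage_seed(cfg$seed, "cluster")
    sel <- select_k(row_scale(matrix), k_min = cfg$k_min, k_max = cfg$k_max,
                    seed = seed)
    hc <- cluster_hierarchical(matrix, K = sel$K, linkage = cfg$linkage,
                               scale_rows = TRUE)
    write_heatmap_tsv(hc, out("line_clusters.tsv"))
    emit("cluster", out("line_clusters.tsv"), seed)
    cons <- consensus_cluster(t(matrix), k_min = cfg$k_min,
                              k_max = min(cfg$k_max, ncol(matrix) - 1),
                              n_resamples = cfg$n_resamples,
                              subsample_frac = cfg$subsample_frac,
                              linkage = cfg$linkage, seed = seed)
    labs <- data.frame(category = names(cons$labels),
                       subgroup = unname(cons$labels))
    write_tsv(labs, out("category_subgroups.tsv"))
    emit("cluster", out("category_subgroups.tsv"), seed)
    write_matrix_tsv(cons$consensus[[as.character(cons$K)]],
                     out("consensus_matrix.tsv"), id_col = "category")
    emit("cluster", out("consensus_matrix.tsv"), seed)
  }

  if ("network" %in% stages) {
    gl <- gene_level(matrix, rule = "best-line")
    cats <- intersect(cfg$hit_categories, colnames(matrix))
    if (!length(cats)) stopf("stage `network`: no hit category present")
    gh <- call_hits(line_score_matrix(gl), quantile_type = cfg$quantile_type)
    set <- combine_hits(gh, cats, "enhancer")
    lethal <- attr(table, "lethal_lines")
    lethal_genes <- unique(table$gene_id[table$line_id %in% lethal])
    edges <- read_edges(cfg$edges)
    net <- build_network(set, lethal_genes = lethal_genes, edges = edges)
    write_network_tsv(net, out("network_edges.tsv"), out("network_nodes.tsv"))
    emit("network", out("network_edges.tsv"))
    emit("network", out("network_nodes.tsv"))
    cx <- mcode_complexes(net, vwp = cfg$vwp,
                          min_size = cfg$min_complex_size)
    cx_df <- do.call(rbind, lapply(seq_along(cx), function(i)
      data.frame(complex = i, seed = cx[[i]]$seed, size = cx[[i]]$size,
                 density = cx[[i]]$density, score = cx[[i]]$score,
                 members = paste(cx[[i]]$members, collapse = ","))))
    if (is.null(cx_df)) cx_df <- data.frame()
    write_tsv(cx_df, out("mcode_complexes.tsv"))
    emit("network", out("mcode_complexes.tsv"))
    if (!is.null(cfg$annotation)) {
      ann <- read_annotation(cfg$annotation)
      universe <- unique(unname(line_genes(matrix)))
      er <- enrich(intersect(set$gene_id, universe), universe, ann)
      write_tsv(as.data.frame(er), out("enrichment.tsv"))
      emit("network", out("enrichment.tsv"))
    }
  }

  if ("tracks" %in% stages) {
    tr <- read_tracks(cfg$tracks)
    st <- track_stats(tr)
    write_tsv(st, out("track_stats.tsv"))
    emit("tracks", out("track_stats.tsv"))
  }

  if ("de" %in% stages) {
    expr <- read_expression(cfg$expr)
    samples <- if (!is.null(cfg$samples)) read_sample_sheet(cfg$samples)
               else stop("stage `de`: missing input `samples`", call. = FALSE)
    res <- de_test(expr, samples, kd_label = cfg$kd_label)
    hits_de <- de_filter(res, p_thresh = cfg$p_thresh,
                         fc_thresh = cfg$fc_thresh)
    write_tsv(as.data.frame(res), out("de_results.tsv"))
    write_tsv(as.data.frame(hits_de), out("de_genes.tsv"))
    emit("de", out("de_results.tsv"))
    emit("de", out("de_genes.tsv"))
  }

  man <- list(config = cfg[order(names(cfg))], stages = stages,
              outputs = manifest)
  jsonlite::write_json(man, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(man)
}
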