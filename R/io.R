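detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
}

#' Read an expression study from matrix + metadata files
#'
#' The matrix file is genes x samples, first column gene ids; the
#' metadata file has columns `sample_id`, `group`, `platform`. Tab- and
#' comma-delimited files are detected automatically and parse
#' identically.
#'
#' @param path_matrix Expression matrix TSV/CSV.
#' @param path_metadata Sample metadata TSV/CSV.
#' @return An [expression_study()].
#' @export
read_expression <- function(path_matrix, path_metadata) {
  raw <- read.delim(path_matrix, sep = detect_sep(path_matrix),
                    check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(raw[[1]])
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids in ", path_matrix, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  values <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(values)) {
    stop("non-numeric expression cells in ", path_matrix, call. = FALSE)
  }
  rownames(values) <- gene_ids

  meta <- read.delim(path_metadata, sep = detect_sep(path_metadata),
                     stringsAsFactors = FALSE)
  req <- c("sample_id", "group", "platform")
  if (!all(req %in% names(meta))) {
    stop("metadata must have columns sample_id, group, platform",
         call. = FALSE)
  }
  missing <- setdiff(colnames(values), meta$sample_id)
  if (length(missing)) {
    stop("samples in matrix but not metadata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  meta <- meta[match(colnames(values), meta$sample_id), ]
  expression_study(values, group = meta$group, platform = meta$platform)
}

#' Write an expression study as matrix + metadata TSVs
#'
#' @param study An [expression_study()].
#' @param path_matrix,path_metadata Output paths.
#' @export
write_expression_study <- function(study, path_matrix, path_metadata) {
  stopifnot(inherits(study, "expression_study"))
  df <- data.frame(gene_id = study$gene_ids, study$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path_matrix, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = study$sample_ids, group = study$group,
                     platform = study$platform, stringsAsFactors = FALSE)
  write.table(meta, path_metadata, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(path_matrix, path_metadata))
}

#' Run the full analysis pipeline on simulated multi-platform data
#'
#' End-to-end driver in the study's order: simulate multi-platform
#' case/control studies, per-platform differential expression,
#' cross-platform intersection with direction consistency, co-expression
#' modules on the first platform restricted to consensus genes, hub
#' selection in the most trait-correlated module, differential
#' co-expression rewiring with the hub genes as anchors, and an ensemble
#' net trained on the anchor genes' expression. All stage outputs plus a
#' JSON run summary are written under `out_dir`; stage seeds derive from
#' the master seed.
#'
#' @param config A [sim_config()]; its `seed` is the master seed.
#' @param out_dir Output directory.
#' @param thresholds A [de_thresholds()].
#' @param rule A [rewiring_rule()].
#' @param wgcna_args List of overrides passed to [wgcna_modules()].
#' @param net_config An [ensemble_net_config()] (its seed is re-derived
#'   from the master seed).
#' @param max_anchors Cap on rewiring anchors (default 34).
#' @return The run summary (list of class `run_summary`), invisibly
#'   written as `run_summary.json`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("hkgrun"),
                         thresholds = de_thresholds(),
                         rule = rewiring_rule(),
                         wgcna_args = list(),
                         net_config = NULL,
                         max_anchors = 34L) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_seen <- character(0)
  note <- function(...) {
    warnings_seen <<- c(warnings_seen, sprintf(...))
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  sim <- stage("simulate", simulate_multi_platform(config))
  for (p in names(sim$studies)) {
    write_expression_study(sim$studies[[p]],
                           file.path(out_dir, paste0("expression_", p, ".tsv")),
                           file.path(out_dir, paste0("samples_", p, ".tsv")))
  }

  de_tables <- stage("de", lapply(sim$studies, differential_expression,
                                  thresholds = thresholds))
  for (p in names(de_tables)) {
    write_de_table(de_tables[[p]], file.path(out_dir, paste0("de_", p, ".tsv")))
  }
  note("differential expression uses a per-gene Welch t-test (not a moderated t)")

  consensus <- stage("intersect", intersect_platforms(de_tables))
  write_de_table(consensus, file.path(out_dir, "de_consensus.tsv"))

  study1 <- sim$studies[[1]]
  keep <- union(consensus$consensus$gene,
                names(sim$truth$module_of_gene)[sim$truth$module_of_gene != "unassigned"])
  keep <- intersect(study1$gene_ids, keep)
  if (length(keep) < 20L) keep <- study1$gene_ids
  sub <- expression_study(study1$values[keep, , drop = FALSE],
                          group = study1$group, platform = study1$platform)
  mods <- stage("wgcna", do.call(wgcna_modules, c(list(study = sub), wgcna_args)))
  write.table(
    data.frame(gene = names(mods$module_of_gene),
               module = unname(mods$module_of_gene)),
    file.path(out_dir, "modules.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write.table(mods$mm_gs, file.path(out_dir, "mm_gs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  anchors <- utils::head(mods$hub_genes, max_anchors)
  rewiring <- NULL
  if (length(anchors) >= 1L) {
    pairs <- stage("rewire", pairwise_group_correlations(study1, anchors))
    tm <- transition_matrix(pairs)
    write_transition_table(tm, file.path(out_dir, "transitions.tsv"))
    rewiring <- select_rewired(pairs, rule)
    write.table(rewiring$pairs, file.path(out_dir, "rewired_pairs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    note("no hub genes passed the MM/GS thresholds; rewiring stage skipped")
  }

  # diagnostic stage: anchor-gene features, stratified 80/20 split
  feat_genes <- if (length(anchors) >= 2L) anchors else
    utils::head(consensus$consensus$gene, 10L)
  metrics <- NULL
  if (length(feat_genes) >= 2L) {
    feats <- t(study1$values[feat_genes, , drop = FALSE])
    labels <- study_trait(study1)
    split <- stratified_split(labels, seed = derive_seed(config$seed, 900L))
    if (is.null(net_config)) {
      net_config <- ensemble_net_config(seed = derive_seed(config$seed, 901L))
    }
    model <- stage("train", train_ensemble_net(feats[split$train, , drop = FALSE],
                                               labels[split$train], net_config))
    scores <- predict_scores(model, feats[split$test, , drop = FALSE])
    metrics <- evaluate_scores(labels[split$test], scores)
    write.table(data.frame(sample_id = rownames(feats)[split$test],
                           label = labels[split$test], score = scores),
                file.path(out_dir, "diagnostic_scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    note("fewer than 2 feature genes available; diagnostic stage skipped")
  }

  summary <- structure(
    list(
      seed = config$seed,
      package_version = as.character(utils::packageVersion("hkgrewire")),
      n_platforms = length(sim$studies),
      n_genes = config$n_genes,
      n_samples_per_platform = ncol(study1$values),
      de_per_platform = vapply(de_tables, function(t) sum(t$direction != "ns"),
                               integer(1)),
      consensus_genes = nrow(consensus$consensus),
      consensus_up = consensus$n_up,
      consensus_down = consensus$n_down,
      n_modules = ncol(mods$eigengenes),
      top_module = mods$top_module,
      top_module_trait_correlation =
        mods$module_trait$correlation[mods$module_trait$module == mods$top_module],
      selected_power = mods$scan$selected_power,
      n_hub_genes = length(mods$hub_genes),
      n_anchors = length(anchors),
      rewired_selected = if (is.null(rewiring)) NA_integer_ else rewiring$total,
      diagnostic = if (is.null(metrics)) NULL else
        list(accuracy = metrics$accuracy, auc = metrics$auc,
             f1 = metrics$f1, precision = metrics$precision,
             recall = metrics$recall),
      warnings = warnings_seen
    ),
    class = "run_summary"
  )
  jsonlite::write_json(unclass(summary),
                       file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(summary)
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf(
    "run_summary (seed %d): %d consensus DE genes (%d up / %d down), %d modules, top %s (r = %.3f), %d hubs, %s rewired pairs\n",
    x$seed, x$consensus_genes, x$consensus_up, x$consensus_down,
    x$n_modules, x$top_module, x$top_module_trait_correlation,
    x$n_hub_genes,
    ifelse(is.na(x$rewired_selected), "no", x$rewired_selected)))
  invisible(x)
}
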