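#' Simulation configuration
#'
#' Defines the generating conditions of a two-group (case/control)
#' expression study with planted structure: trait-linked co-expression
#' modules, differentially expressed genes, rewired gene pairs whose
#' correlation differs between groups, and multi-platform replicates with
#' additive batch offsets. Defaults mirror the scale of a large
#' psoriasis skin cohort (about 90 cases vs 80 controls) while staying
#' fully configurable.
#'
#' @param n_cases,n_controls Samples per group.
#' @param n_genes Total genes.
#' @param n_modules,module_size Number and size of planted co-expression
#'   modules; module genes occupy the first `n_modules * module_size`
#'   gene slots.
#' @param module_trait_effect Target correlation (0..1) between each
#'   module's latent factor and the 0/1 disease trait.
#' @param de_fraction Fraction of genes given a group mean shift, drawn
#'   from genes outside modules and rewired pairs.
#' @param de_shift Mean shift in log2 units applied to cases (sign per
#'   gene is randomized).
#' @param beta_range Range of the per-gene module loadings, drawn
#'   uniformly; heterogeneous loadings give modules the connectivity
#'   spread seen in real co-expression networks (hub genes load high,
#'   peripheral genes low). Set both ends to 1 for homogeneous modules.
#' @param rewired_pairs Data frame (or list of 4-element vectors) with
#'   columns `anchor`, `partner`, `rho_control`, `rho_case`: gene pairs
#'   whose within-group Pearson correlation is planted per group.
#'   Anchors/partners may be gene ids (`"G0007"`) or integer indices.
#' @param noise_sd Residual SD of log2 expression (> 0).
#' @param n_platforms Number of platform replicates for
#'   [simulate_multi_platform()].
#' @param batch_offset_sd SD of the additive per-(platform, gene) offset.
#' @param seed Integer master seed; all randomness derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 90, n_controls = 80, n_genes = 2000,
                       n_modules = 5, module_size = 50,
                       module_trait_effect = 0.8,
                       de_fraction = 0.1, de_shift = 2,
                       beta_range = c(0.5, 1.5),
                       rewired_pairs = NULL,
                       noise_sd = 1, n_platforms = 3,
                       batch_offset_sd = 0.5, seed = 1L) {
  n_cases <- stop_if_not_count(n_cases, "n_cases")
  n_controls <- stop_if_not_count(n_controls, "n_controls")
  n_genes <- stop_if_not_count(n_genes, "n_genes")
  n_modules <- stop_if_not_count(n_modules, "n_modules", min = 0L)
  module_size <- stop_if_not_count(module_size, "module_size", min = 0L)
  n_platforms <- stop_if_not_count(n_platforms, "n_platforms")
  stop_if_not_scalar_number(module_trait_effect, "module_trait_effect", 0, 1)
  stop_if_not_scalar_number(de_fraction, "de_fraction", 0, 1)
  stop_if_not_scalar_number(de_shift, "de_shift")
  if (!is.numeric(beta_range) || length(beta_range) != 2L ||
      any(beta_range <= 0) || beta_range[1] > beta_range[2]) {
    stop("'beta_range' must be two positive ascending numbers", call. = FALSE)
  }
  stop_if_not_scalar_number(noise_sd, "noise_sd", 0, strict_lower = TRUE)
  stop_if_not_scalar_number(batch_offset_sd, "batch_offset_sd", 0)
  seed <- stop_if_not_count(seed, "seed", min = 0L)
  if (n_modules * module_size > n_genes) {
    stop("n_modules * module_size must not exceed n_genes", call. = FALSE)
  }
  if (!is.null(rewired_pairs)) {
    if (is.list(rewired_pairs) && !is.data.frame(rewired_pairs)) {
      rewired_pairs <- as.data.frame(do.call(rbind, lapply(rewired_pairs, function(p) {
        stats::setNames(as.list(p),
                        c("anchor", "partner", "rho_control", "rho_case"))
      })))
    }
    req <- c("anchor", "partner", "rho_control", "rho_case")
    if (!all(req %in% names(rewired_pairs))) {
      stop("rewired_pairs needs columns anchor, partner, rho_control, rho_case",
           call. = FALSE)
    }
    rewired_pairs$rho_control <- as.numeric(rewired_pairs$rho_control)
    rewired_pairs$rho_case <- as.numeric(rewired_pairs$rho_case)
    if (any(abs(rewired_pairs$rho_control) > 1) ||
        any(abs(rewired_pairs$rho_case) > 1)) {
      stop("rewired correlations must lie in [-1, 1]", call. = FALSE)
    }
  }
  structure(
    list(n_cases = n_cases, n_controls = n_controls, n_genes = n_genes,
         n_modules = n_modules, module_size = module_size,
         module_trait_effect = module_trait_effect,
         de_fraction = de_fraction, de_shift = de_shift,
         beta_range = beta_range,
         rewired_pairs = rewired_pairs, noise_sd = noise_sd,
         n_platforms = n_platforms, batch_offset_sd = batch_offset_sd,
         seed = seed),
    class = "sim_config"
  )
}

gene_id_format <- function(n) paste0("G", formatC(seq_len(n), width = max(4, nchar(n)), flag = "0"))

resolve_gene_ref <- function(ref, gene_ids) {
  if (is.numeric(ref)) {
    idx <- as.integer(ref)
    if (any(idx < 1L | idx > length(gene_ids))) {
      stop("gene index out of range in rewired_pairs", call. = FALSE)
    }
    return(gene_ids[idx])
  }
  ref <- as.character(ref)
  missing <- setdiff(ref, gene_ids)
  if (length(missing)) {
    stop("unknown gene id(s) in rewired_pairs: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ref
}

# Fix the identity of every planted element (module membership, DE genes
# and signs, rewired pairs, per-gene baseline means) from the config seed.
# Shared across platforms so multi-platform studies re-use one ground truth.
derive_truth <- function(config) {
  gene_ids <- gene_id_format(config$n_genes)
  module_of_gene <- stats::setNames(rep("unassigned", config$n_genes), gene_ids)
  if (config$n_modules > 0 && config$module_size > 0) {
    for (m in seq_len(config$n_modules)) {
      idx <- ((m - 1) * config$module_size + 1):(m * config$module_size)
      module_of_gene[idx] <- paste0("M", m)
    }
  }
  module_genes <- names(module_of_gene)[module_of_gene != "unassigned"]

  rw <- config$rewired_pairs
  if (!is.null(rw)) {
    rw$anchor <- resolve_gene_ref(rw$anchor, gene_ids)
    rw$partner <- resolve_gene_ref(rw$partner, gene_ids)
    if (any(rw$anchor == rw$partner)) {
      stop("a rewired pair may not pair a gene with itself", call. = FALSE)
    }
    clash <- intersect(c(rw$anchor, rw$partner), module_genes)
    if (length(clash)) {
      stop("rewired pair references module gene(s): ",
           paste(clash, collapse = ", "),
           " (would confound the planted ground truth)", call. = FALSE)
    }
    if (anyDuplicated(rw$partner)) {
      stop("a partner gene may appear in only one rewired pair", call. = FALSE)
    }
    if (length(intersect(rw$anchor, rw$partner))) {
      stop("a gene may not be both anchor and partner", call. = FALSE)
    }
  } else {
    rw <- data.frame(anchor = character(0), partner = character(0),
                     rho_control = numeric(0), rho_case = numeric(0))
  }
  rewired_genes <- unique(c(rw$anchor, rw$partner))

  withr::with_seed(derive_seed(config$seed, 11L), {
    baseline <- stats::setNames(rnorm(config$n_genes, mean = 8, sd = 1.5),
                                gene_ids)
    beta <- stats::setNames(rep(0, config$n_genes), gene_ids)
    beta[module_genes] <- runif(length(module_genes),
                                config$beta_range[1], config$beta_range[2])
    eligible <- setdiff(gene_ids, c(module_genes, rewired_genes))
    n_de <- round(config$de_fraction * config$n_genes)
    if (n_de > length(eligible)) {
      stop("de_fraction too large for the number of free genes", call. = FALSE)
    }
    de_genes <- sort(sample(eligible, n_de))
    de_sign <- stats::setNames(sample(c(1L, -1L), n_de, replace = TRUE), de_genes)
  })

  structure(
    list(de_genes = data.frame(gene = de_genes,
                               sign = ifelse(de_sign > 0, "+", "-"),
                               row.names = NULL,
                               stringsAsFactors = FALSE),
         module_of_gene = module_of_gene,
         rewired_pairs = rw,
         hkg_genes = character(0),
         baseline = baseline,
         beta = beta,
         de_sign = de_sign),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "ground_truth: %d DE genes, %d module genes (%d modules), %d rewired pairs, %d HKGs\n",
    nrow(x$de_genes), sum(x$module_of_gene != "unassigned"),
    length(setdiff(unique(x$module_of_gene), "unassigned")),
    nrow(x$rewired_pairs), length(x$hkg_genes)))
  invisible(x)
}

# One draw of the study given fixed ground truth. `offset` is an optional
# per-gene additive platform/batch effect.
simulate_from_truth <- function(config, truth, seed, platform = "P1",
                                offset = NULL) {
  n <- config$n_cases + config$n_controls
  gene_ids <- names(truth$baseline)
  trait <- c(rep(0L, config$n_controls), rep(1L, config$n_cases))
  group <- ifelse(trait == 1L, "case", "control")
  sample_ids <- paste0(platform, "_S",
                       formatC(seq_len(n), width = nchar(n) + 1, flag = "0"))

  p <- mean(trait)
  rho <- config$module_trait_effect
  # alpha chosen so the population correlation between f = alpha*t + eta
  # (eta ~ N(0,1)) and the 0/1 trait equals module_trait_effect
  sd_t <- sqrt(p * (1 - p))
  alpha <- if (rho >= 1) Inf else rho / (sd_t * sqrt(1 - rho^2))

  withr::with_seed(seed, {
    x <- matrix(rnorm(config$n_genes * n, sd = config$noise_sd),
                nrow = config$n_genes, ncol = n,
                dimnames = list(gene_ids, sample_ids))
    x <- x + truth$baseline

    mods <- setdiff(unique(truth$module_of_gene), "unassigned")
    for (m in mods) {
      f <- alpha * trait + rnorm(n)
      members <- names(truth$module_of_gene)[truth$module_of_gene == m]
      x[members, ] <- x[members, , drop = FALSE] +
        outer(truth$beta[members], f)
    }

    if (nrow(truth$de_genes)) {
      shift <- truth$de_sign[truth$de_genes$gene] * config$de_shift
      x[truth$de_genes$gene, ] <- x[truth$de_genes$gene, , drop = FALSE] +
        outer(shift, trait)
    }

    rw <- truth$rewired_pairs
    if (nrow(rw)) {
      # partner = rho * z_anchor + sqrt(1-rho^2) * z_new per group: exact
      # target correlation structure, and anchors may be shared by pairs
      z_anchor <- (x[rw$anchor, , drop = FALSE] -
                     truth$baseline[rw$anchor]) / config$noise_sd
      for (k in seq_len(nrow(rw))) {
        z_new <- rnorm(n)
        rho_k <- ifelse(trait == 1L, rw$rho_case[k], rw$rho_control[k])
        z_p <- rho_k * z_anchor[k, ] + sqrt(1 - rho_k^2) * z_new
        x[rw$partner[k], ] <- truth$baseline[rw$partner[k]] +
          config$noise_sd * z_p
      }
    }
  })

  if (!is.null(offset)) x <- x + offset
  expression_study(x, group = group, platform = platform)
}

#' Simulate a two-group expression study with planted ground truth
#'
#' Generates a log2-scale gene x sample matrix for a case/control design.
#' Module genes follow `x_g = baseline_g + f_m + noise` where the module
#' factor `f_m` correlates with the 0/1 trait at `module_trait_effect`;
#' DE genes get a `de_shift` mean offset in cases; rewired pairs are drawn
#' with group-specific Pearson correlations; all remaining genes are
#' independent noise around their baseline.
#'
#' @param config A [sim_config()].
#' @return List with elements `study` (an [expression_study()]) and
#'   `truth` (a `ground_truth` object: `de_genes` with signs,
#'   `module_of_gene`, `rewired_pairs`, `hkg_genes`).
#' @examples
#' sim <- simulate_two_group_study(sim_config(n_genes = 100, seed = 7))
#' sim$study
#' @export
simulate_two_group_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  truth <- derive_truth(config)
  study <- simulate_from_truth(config, truth,
                               seed = derive_seed(config$seed, 1L))
  list(study = study, truth = truth)
}

#' Simulate multi-platform replicates of one study design
#'
#' Each platform is an independent re-simulation from the same planted
#' ground truth, plus an additive per-(platform, gene) batch offset with
#' SD `batch_offset_sd`. Mirrors a multi-cohort design where the same
#' biology is assayed on several array/sequencing platforms.
#'
#' @param config A [sim_config()] with `n_platforms >= 2`.
#' @return List with `studies` (list of [expression_study()], platforms
#'   labelled `P1`, `P2`, ...) and the shared `truth`.
#' @export
simulate_multi_platform <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_platforms < 2L) {
    stop("n_platforms must be >= 2 for a multi-platform simulation",
         call. = FALSE)
  }
  truth <- derive_truth(config)
  studies <- lapply(seq_len(config$n_platforms), function(p) {
    offset <- withr::with_seed(derive_seed(config$seed, 100L + p), {
      rnorm(config$n_genes, sd = config$batch_offset_sd)
    })
    simulate_from_truth(config, truth,
                        seed = derive_seed(config$seed, 200L + p),
                        platform = paste0("P", p), offset = offset)
  })
  names(studies) <- paste0("P", seq_len(config$n_platforms))
  list(studies = studies, truth = truth)
}

#' Simulate a tissue x exon RPKM matrix with planted stable genes
#'
#' Builds an exon-level RPKM matrix across tissues in which a planted
#' fraction of genes satisfies all three housekeeping stability criteria
#' by construction (every tissue detected, SD of log2 RPKM well below 1,
#' no tissue beyond 4-fold from the gene mean), while the remaining genes
#' violate at least one criterion (a zero-expression tissue, a
#' high-variance profile, or a >= 16-fold-low outlier tissue).
#'
#' @param n_genes,exons_per_gene,n_tissues Matrix dimensions
#'   (`n_tissues >= 2`).
#' @param stable_fraction Fraction of genes planted as stable (0..1).
#' @param seed Integer seed.
#' @return List with `matrix` (a [tissue_exon_matrix()]) and `truth`
#'   (`ground_truth` whose `hkg_genes` is the planted stable set).
#' @export
simulate_tissue_exon_matrix <- function(n_genes = 100, exons_per_gene = 4,
                                        n_tissues = 12,
                                        stable_fraction = 0.5, seed = 1L) {
  n_genes <- stop_if_not_count(n_genes, "n_genes")
  exons_per_gene <- stop_if_not_count(exons_per_gene, "exons_per_gene")
  n_tissues <- stop_if_not_count(n_tissues, "n_tissues", min = 2L)
  stop_if_not_scalar_number(stable_fraction, "stable_fraction", 0, 1)
  seed <- stop_if_not_count(seed, "seed", min = 0L)

  gene_ids <- gene_id_format(n_genes)
  tissue_ids <- paste0("tissue", formatC(seq_len(n_tissues), width = 2, flag = "0"))

  withr::with_seed(seed, {
    n_stable <- round(stable_fraction * n_genes)
    stable <- sort(sample(gene_ids, n_stable))
    exon_rows <- list()
    exon_ids <- character(0)
    exon_tx <- character(0)
    for (g in gene_ids) {
      tx <- sub("^G", "T", g)
      is_stable <- g %in% stable
      mode <- if (is_stable) "stable" else sample(c("zero", "highsd", "fold"), 1L)
      # base abundance; fold-outlier mode needs base/16 >= 1 for detection
      b <- if (mode == "fold") 2^runif(1, 4.5, 6) else 2^runif(1, 2, 6)
      for (e in seq_len(exons_per_gene)) {
        be <- b * 2^runif(1, -0.4, 0.4)
        vals <- switch(
          mode,
          stable = be * 2^pmin(pmax(rnorm(n_tissues, 0, 0.2), -0.6), 0.6),
          zero = {
            v <- be * 2^pmin(pmax(rnorm(n_tissues, 0, 0.2), -0.6), 0.6)
            v[sample(n_tissues, 1L)] <- 0
            v
          },
          highsd = {
            # alternate +-1.6 on log2 scale: sample SD > 1, fold < 4
            s <- rep(c(1.6, -1.6), length.out = n_tissues)
            be * 2^(sample(s) + rnorm(n_tissues, 0, 0.05))
          },
          fold = {
            # one tissue 16-fold low: ratio to mean < 1/4 for any n >= 2
            v <- rep(be, n_tissues) * 2^rnorm(n_tissues, 0, 0.05)
            v[sample(n_tissues, 1L)] <- be / 16
            v
          })
        exon_id <- sprintf("%s_E%02d", g, e)
        exon_rows[[exon_id]] <- vals
        exon_ids <- c(exon_ids, exon_id)
        exon_tx <- c(exon_tx, tx)
      }
    }
  })

  rpkm <- do.call(rbind, exon_rows)
  dimnames(rpkm) <- list(exon_ids, tissue_ids)
  tem <- tissue_exon_matrix(
    rpkm,
    exon_to_transcript = stats::setNames(exon_tx, exon_ids),
    transcript_to_gene = stats::setNames(gene_ids, sub("^G", "T", gene_ids))
  )
  truth <- structure(
    list(de_genes = data.frame(gene = character(0), sign = character(0)),
         module_of_gene = stats::setNames(rep("unassigned", n_genes), gene_ids),
         rewired_pairs = data.frame(anchor = character(0),
                                    partner = character(0),
                                    rho_control = numeric(0),
                                    rho_case = numeric(0)),
         hkg_genes = stable,
         baseline = NULL, de_sign = NULL),
    class = "ground_truth"
  )
  list(matrix = tem, truth = truth)
}

#' Write a simulated study and its ground truth to disk
#'
#' The expression matrix is written as TSV (first column `gene_id`), the
#' sample metadata as a TSV with `sample_id`, `group`, `platform`, and the
#' ground truth as JSON.
#'
#' @param sim Result of [simulate_two_group_study()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_simulation <- function(sim, dir, prefix = "study") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mat <- file.path(dir, paste0(prefix, "_expression.tsv"))
  meta <- file.path(dir, paste0(prefix, "_samples.tsv"))
  truthp <- file.path(dir, paste0(prefix, "_truth.json"))
  write_expression_study(sim$study, mat, meta)
  tr <- sim$truth
  jsonlite::write_json(
    list(de_genes = tr$de_genes,
         module_of_gene = as.list(tr$module_of_gene),
         rewired_pairs = tr$rewired_pairs,
         hkg_genes = tr$hkg_genes),
    truthp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(matrix = mat, metadata = meta, truth = truthp))
}
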