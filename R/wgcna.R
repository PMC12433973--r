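#' Pearson similarity matrix of a study
#'
#' Gene-gene co-expression similarity: `S_ij = |cor(x_i, x_j)|` for the
#' unsigned network (the default), or `(1 + r_ij)/2` for the signed
#' variant. Entries are clamped to \[0, 1\] and the diagonal set to 1.
#'
#' @param study An [expression_study()] or a numeric genes x samples
#'   matrix.
#' @param signed Use the signed transformation. Default `FALSE`.
#' @return Symmetric similarity matrix with gene dimnames.
#' @export
similarity_matrix <- function(study, signed = FALSE) {
  x <- if (inherits(study, "expression_study")) study$values else study
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expected an expression_study or numeric matrix", call. = FALSE)
  }
  if (ncol(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  v <- apply(x, 1, var)
  if (any(v == 0)) {
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(x)[v == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  r <- cor(t(x))
  s <- if (signed) (1 + r) / 2 else abs(r)
  s[s > 1] <- 1; s[s < 0] <- 0
  diag(s) <- 1
  (s + t(s)) / 2
}

#' Scan soft-thresholding powers for scale-free fit
#'
#' For each candidate power the similarity matrix is raised elementwise
#' to that power, node connectivities `k_i = sum_j a_ij` are binned into
#' at most 10 equal-width bins, and the scale-free fit index is the
#' squared Pearson correlation between `log10(mean k per bin)` and
#' `log10(bin frequency)`, negated when the fitted slope is positive
#' (signed-R2 convention). The selected power is the smallest one whose
#' fit reaches `r2_target`, falling back to the best-fitting power with a
#' message when none does.
#'
#' @param study Study or genes x samples matrix (passed to
#'   [similarity_matrix()]), or a precomputed similarity matrix via
#'   `similarity = `.
#' @param powers Ascending positive integer powers to scan.
#' @param r2_target Fit threshold for selection (default 0.8).
#' @param signed Signed similarity (see [similarity_matrix()]).
#' @param similarity Optional precomputed similarity matrix.
#' @return Object of class `soft_threshold_scan`: data frame `scan`
#'   (`power`, `fit_r2`, `mean_connectivity`) plus `selected_power`.
#' @export
pick_soft_threshold <- function(study, powers = 1:20, r2_target = 0.8,
                                signed = FALSE, similarity = NULL) {
  if (!length(powers) || any(powers <= 0) || is.unsorted(powers, strictly = TRUE)) {
    stop("'powers' must be a non-empty ascending vector of positive values",
         call. = FALSE)
  }
  stop_if_not_scalar_number(r2_target, "r2_target", 0, 1)
  s <- if (is.null(similarity)) similarity_matrix(study, signed = signed) else similarity
  check_symmetric(s, "similarity")
  diag(s) <- 0

  fit_r2 <- mean_k <- rep(NA_real_, length(powers))
  for (i in seq_along(powers)) {
    a <- s^powers[i]
    k <- colSums(a)
    mean_k[i] <- mean(k)
    fit_r2[i] <- scale_free_fit(k)
  }
  sel <- which(!is.na(fit_r2) & fit_r2 >= r2_target)
  if (length(sel)) {
    selected <- powers[sel[1L]]
  } else {
    if (all(is.na(fit_r2))) {
      stop("scale-free fit undefined at every power", call. = FALSE)
    }
    selected <- powers[which.max(fit_r2)]
    message(sprintf(
      "no power reached fit R^2 >= %.2f; using the best-fitting power %d (R^2 = %.3f)",
      r2_target, selected, max(fit_r2, na.rm = TRUE)))
  }
  structure(
    list(scan = data.frame(power = powers, fit_r2 = fit_r2,
                           mean_connectivity = mean_k),
         selected_power = selected, r2_target = r2_target),
    class = "soft_threshold_scan"
  )
}

# Signed scale-free fit index from a connectivity vector: <= 10 equal-width
# bins of the k histogram; NA when fewer than 3 non-empty bins survive.
scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(k) < 3L || diff(range(k)) == 0) return(NA_real_)
  bin <- cut(k, breaks = n_bins, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = nlevels(bin))
  keep <- freq > 0
  if (sum(keep) < 3L) return(NA_real_)
  mk <- tapply(k, bin, mean)[keep]
  lx <- log10(mk); ly <- log10(freq[keep] / sum(freq))
  if (sd(lx) == 0 || sd(ly) == 0) return(NA_real_)
  r <- cor(lx, ly)
  slope <- r * sd(ly) / sd(lx)
  if (slope > 0) -r^2 else r^2
}

#' @export
print.soft_threshold_scan <- function(x, ...) {
  cat(sprintf("soft_threshold_scan over powers %s; selected beta = %d\n",
              paste(range(x$scan$power), collapse = ".."), x$selected_power))
  invisible(x)
}

#' Topological overlap similarity
#'
#' For an adjacency matrix `A` with entries in \[0, 1\], the topological
#' overlap between distinct nodes i and j is
#' `(l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over third nodes u and `k_i = sum_u a_iu`;
#' the diagonal is 1. High overlap means the two genes share most of
#' their network neighbourhood.
#'
#' @param adjacency Symmetric numeric matrix, entries in \[0, 1\]. The
#'   diagonal is ignored (treated as 0 in all sums).
#' @return Symmetric TOM matrix with unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  check_symmetric(adjacency, "adjacency")
  a <- adjacency
  if (any(a < -1e-12) || any(a > 1 + 1e-12)) {
    stop("adjacency entries must lie in [0, 1]", call. = FALSE)
  }
  diag(a) <- 0
  l <- a %*% a             # l_ij = sum_u a_iu a_uj (u != i, j since diag 0)
  k <- colSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  (tom + t(tom)) / 2
}

#' Detect co-expression modules by hierarchical clustering
#'
#' Average-linkage clustering of the TOM dissimilarity, cut at a fixed
#' height; clusters below `min_module_size` are left unassigned.
#' Surviving modules are labelled `M1`, `M2`, ... in decreasing size
#' order (ties by smallest member gene id).
#'
#' @param dissimilarity Symmetric matrix in \[0, 1\] (typically
#'   `1 - tom`).
#' @param min_module_size Smallest retained module (default 30).
#' @param cut_height Dendrogram cut height in (0, 1\] (default 0.99).
#' @return Named character vector gene -> module label or
#'   `"unassigned"`.
#' @export
detect_modules <- function(dissimilarity, min_module_size = 30,
                           cut_height = 0.99) {
  check_symmetric(dissimilarity, "dissimilarity")
  if (cut_height <= 0 || cut_height > 1) {
    stop("cut_height must lie in (0, 1]", call. = FALSE)
  }
  min_module_size <- stop_if_not_count(min_module_size, "min_module_size")
  genes <- rownames(dissimilarity)
  if (is.null(genes)) genes <- paste0("G", seq_len(nrow(dissimilarity)))
  hc <- hclust(as.dist(dissimilarity), method = "average")
  raw <- cutree(hc, h = cut_height)
  names(raw) <- genes
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  out <- stats::setNames(rep("unassigned", length(genes)), genes)
  if (length(keep)) {
    first_member <- vapply(keep, function(cl) min(genes[raw == cl]), character(1))
    ord <- keep[order(-as.integer(sizes[keep]), first_member)]
    for (i in seq_along(ord)) {
      out[raw == ord[i]] <- paste0("M", i)
    }
  }
  out
}

#' Module eigengene
#'
#' First principal component over samples of the gene-standardized module
#' submatrix: the module's representative expression profile. Unit norm,
#' sign-oriented so the mean correlation with member genes is positive.
#'
#' @param x Genes x samples matrix restricted to one module (at least 2
#'   genes) or an [expression_study()] plus `genes`.
#' @param genes Optional member gene ids when `x` is a study.
#' @return Numeric vector of length `n_samples`, unit norm.
#' @export
module_eigengene <- function(x, genes = NULL) {
  if (inherits(x, "expression_study")) {
    stopifnot(!is.null(genes))
    x <- x$values[genes, , drop = FALSE]
  }
  if (nrow(x) < 2L) stop("a module needs at least 2 genes", call. = FALSE)
  xs <- t(scale(t(x)))
  if (anyNA(xs)) stop("zero-variance gene in module", call. = FALSE)
  sv <- svd(xs, nu = 0, nv = 1)
  if (sv$d[1] < 1e-12) stop("rank-0 module submatrix", call. = FALSE)
  e <- sv$v[, 1]
  if (mean(cor(t(x), e)) < 0) e <- -e
  e / sqrt(sum(e^2))
}

#' Correlate module eigengenes with a 0/1 trait
#'
#' Pearson correlation of each eigengene with the trait, with the usual
#' t-distribution p-value on n - 2 degrees of freedom.
#'
#' @param eigengenes Samples x modules numeric matrix (or a single
#'   vector), columns named by module.
#' @param trait 0/1 vector with both levels present.
#' @return Data frame `module`, `correlation`, `p`.
#' @export
module_trait_correlation <- function(eigengenes, trait) {
  if (is.vector(eigengenes)) eigengenes <- matrix(eigengenes, ncol = 1,
                                                  dimnames = list(NULL, "M1"))
  trait <- as.numeric(trait)
  if (length(unique(trait)) < 2L) {
    stop("trait must have both levels", call. = FALSE)
  }
  n <- nrow(eigengenes)
  if (any(apply(eigengenes, 2, sd) == 0)) {
    stop("constant eigengene", call. = FALSE)
  }
  r <- as.numeric(cor(eigengenes, trait))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  data.frame(module = colnames(eigengenes), correlation = r, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Module membership and gene significance
#'
#' Module membership `MM(g)` is the signed Pearson correlation between a
#' gene's expression and its own module's eigengene (NA for unassigned
#' genes). Gene significance `GS(g)` is the correlation between the gene
#' and the 0/1 trait, reported as an absolute value by default.
#'
#' @param study An [expression_study()].
#' @param module_of_gene Named gene -> module vector as returned by
#'   [detect_modules()].
#' @param eigengenes Samples x modules matrix of module eigengenes.
#' @param trait 0/1 trait vector; defaults to the study's case labels.
#' @param signed_gs Report signed instead of absolute gene significance.
#' @return Data frame `gene`, `module`, `mm`, `gs`.
#' @export
membership_and_significance <- function(study, module_of_gene, eigengenes,
                                        trait = study_trait(study),
                                        signed_gs = FALSE) {
  stopifnot(inherits(study, "expression_study"))
  genes <- study$gene_ids
  gs <- as.numeric(cor(t(study$values), as.numeric(trait)))
  if (!signed_gs) gs <- abs(gs)
  mm <- rep(NA_real_, length(genes))
  for (m in colnames(eigengenes)) {
    members <- genes[module_of_gene[genes] == m]
    if (length(members)) {
      mm[match(members, genes)] <-
        as.numeric(cor(t(study$values[members, , drop = FALSE]),
                       eigengenes[, m]))
    }
  }
  data.frame(gene = genes, module = unname(module_of_gene[genes]),
             mm = mm, gs = gs, row.names = NULL, stringsAsFactors = FALSE)
}

#' Hub-gene selection criteria
#'
#' @param mm_min,gs_min Strict lower bounds on module membership and gene
#'   significance (defaults 0.8 / 0.8).
#' @return An object of class `hub_criteria`.
#' @export
hub_criteria <- function(mm_min = 0.8, gs_min = 0.8) {
  stop_if_not_scalar_number(mm_min, "mm_min", 0, 1, strict_lower = TRUE)
  stop_if_not_scalar_number(gs_min, "gs_min", 0, 1, strict_lower = TRUE)
  structure(list(mm_min = mm_min, gs_min = gs_min), class = "hub_criteria")
}

#' Select hub genes of a module
#'
#' Genes of the named module with `mm > mm_min` and `gs > gs_min` (strict
#' inequalities).
#'
#' @param mm_gs Data frame from [membership_and_significance()].
#' @param module Module label to restrict to.
#' @param criteria A [hub_criteria()].
#' @return Character vector of hub gene ids.
#' @export
select_hub_genes <- function(mm_gs, module, criteria = hub_criteria()) {
  stopifnot(is.data.frame(mm_gs),
            all(c("gene", "module", "mm", "gs") %in% names(mm_gs)))
  if (!module %in% mm_gs$module) {
    stop(sprintf("unknown module label '%s'", module), call. = FALSE)
  }
  keep <- mm_gs$module == module &
    !is.na(mm_gs$mm) & mm_gs$mm > criteria$mm_min &
    mm_gs$gs > criteria$gs_min
  mm_gs$gene[keep]
}

#' Run the full co-expression module pipeline on one study
#'
#' Convenience wrapper: similarity, soft-threshold scan, adjacency, TOM,
#' module detection, eigengenes, module-trait correlations, MM/GS, and
#' hub genes of the most trait-correlated module.
#'
#' @param study An [expression_study()].
#' @param powers,r2_target Soft-threshold scan settings.
#' @param power Optional explicit soft-thresholding power; skips the scan
#'   (useful when the connectivity distribution is too degenerate to fit,
#'   e.g. a single clean module against pure noise).
#' @param min_module_size,cut_height Module detection settings.
#' @param hub A [hub_criteria()].
#' @param signed Signed network. Default unsigned.
#' @return List of class `module_set` with `module_of_gene`,
#'   `eigengenes`, `module_trait`, `mm_gs`, `hub_genes`, `top_module`,
#'   `scan`.
#' @export
wgcna_modules <- function(study, powers = 1:20, r2_target = 0.8,
                          min_module_size = 30, cut_height = 0.99,
                          hub = hub_criteria(), signed = FALSE,
                          power = NULL) {
  stopifnot(inherits(study, "expression_study"))
  s <- similarity_matrix(study, signed = signed)
  if (is.null(power)) {
    scan <- pick_soft_threshold(study, powers = powers, r2_target = r2_target,
                                similarity = s)
  } else {
    power <- stop_if_not_count(power, "power")
    scan <- structure(
      list(scan = data.frame(power = power, fit_r2 = NA_real_,
                             mean_connectivity = NA_real_),
           selected_power = power, r2_target = r2_target),
      class = "soft_threshold_scan")
  }
  a <- s^scan$selected_power
  diag(a) <- 1
  tom <- tom_similarity(a)
  module_of_gene <- detect_modules(1 - tom, min_module_size = min_module_size,
                                   cut_height = cut_height)
  mods <- setdiff(sort(unique(module_of_gene)), "unassigned")
  if (!length(mods)) {
    stop("no module survived the size filter", call. = FALSE)
  }
  eig <- vapply(mods, function(m) {
    module_eigengene(study$values[names(module_of_gene)[module_of_gene == m], ,
                                  drop = FALSE])
  }, numeric(ncol(study$values)))
  eig <- matrix(eig, ncol = length(mods), dimnames = list(NULL, mods))
  trait <- study_trait(study)
  mt <- module_trait_correlation(eig, trait)
  mm_gs <- membership_and_significance(study, module_of_gene, eig, trait)
  top <- mt$module[which.max(abs(mt$correlation))]
  hubs <- select_hub_genes(mm_gs, top, hub)
  structure(
    list(module_of_gene = module_of_gene, eigengenes = eig,
         module_trait = mt, mm_gs = mm_gs, hub_genes = hubs,
         top_module = top, scan = scan),
    class = "module_set"
  )
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf(
    "module_set: %d modules (beta = %d); top trait module %s (r = %.3f), %d hub genes\n",
    ncol(x$eigengenes), x$scan$selected_power, x$top_module,
    x$module_trait$correlation[x$module_trait$module == x$top_module],
    length(x$hub_genes)))
  invisible(x)
}
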