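#' Differential-expression thresholds
#'
#' A gene is called up (down) when its BH-adjusted p-value is below
#' `p_max` and its log2 fold change exceeds `fc_min` (falls below
#' `-fc_min`), both strict.
#'
#' @param p_max Adjusted-p cutoff (default 0.05).
#' @param fc_min Absolute log2 fold-change cutoff (default 0.5).
#' @return An object of class `de_thresholds`.
#' @export
de_thresholds <- function(p_max = 0.05, fc_min = 0.5) {
  stop_if_not_scalar_number(p_max, "p_max", 0, 1, strict_lower = TRUE)
  stop_if_not_scalar_number(fc_min, "fc_min", 0, strict_lower = TRUE)
  structure(list(p_max = p_max, fc_min = fc_min), class = "de_thresholds")
}

#' Center out additive batch effects
#'
#' Per gene and batch, subtracts the batch mean and adds back the global
#' gene mean, so group contrasts computed afterwards share a common
#' baseline across batches. This is the additive-offset model of
#' limma-style batch removal, without covariate protection.
#'
#' @param study An [expression_study()].
#' @param batch Per-sample batch labels; defaults to the study's platform
#'   labels.
#' @return A batch-centered [expression_study()].
#' @export
batch_center <- function(study, batch = study$platform) {
  stopifnot(inherits(study, "expression_study"))
  batch <- as.character(batch)
  if (length(batch) != ncol(study$values)) {
    stop("'batch' must have one label per sample", call. = FALSE)
  }
  x <- study$values
  global <- rowMeans(x)
  for (b in unique(batch)) {
    idx <- which(batch == b)
    if (length(idx) == 1L) {
      warning(sprintf("batch '%s' has a single sample; centering removes its deviations entirely", b),
              call. = FALSE)
    }
    x[, idx] <- x[, idx, drop = FALSE] - rowMeans(x[, idx, drop = FALSE]) + global
  }
  out <- study
  out$values <- x
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: sort ascending, take the running minimum of
#' `m * p_(j) / j` from the top, cap at 1, return in input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues)) {
    stop("p-values must be numeric and non-missing", call. = FALSE)
  }
  if (any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "BH")
}

#' Two-group differential expression (per-gene Welch t)
#'
#' Per gene: `logFC = mean(case) - mean(control)` on the log2 scale, a
#' two-sided Welch t-test (optionally pooled-variance Student t), BH
#' adjustment across all genes, and a direction call against the
#' thresholds. Degenerate genes with zero variance in both groups get
#' p = 1 when the group means agree and the smallest representable
#' positive p (with a warning) when they differ.
#'
#' @param study An [expression_study()].
#' @param thresholds A [de_thresholds()].
#' @param pooled_variance Use the pooled-variance Student t instead of
#'   Welch. Default `FALSE`.
#' @return Data frame of class `de_table` with columns `gene`, `logFC`,
#'   `p`, `adj_p`, `direction` (`"up"`, `"down"`, `"ns"`) and `platform`.
#' @export
differential_expression <- function(study, thresholds = de_thresholds(),
                                    pooled_variance = FALSE) {
  stopifnot(inherits(study, "expression_study"),
            inherits(thresholds, "de_thresholds"))
  case <- study$values[, study$group == "case", drop = FALSE]
  ctrl <- study$values[, study$group == "control", drop = FALSE]
  n1 <- ncol(case); n0 <- ncol(ctrl)
  if (n1 < 2L || n0 < 2L) stop("need >= 2 samples per group", call. = FALSE)

  m1 <- rowMeans(case); m0 <- rowMeans(ctrl)
  v1 <- apply(case, 1, var); v0 <- apply(ctrl, 1, var)
  logFC <- m1 - m0

  if (pooled_variance) {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }

  p <- rep(NA_real_, length(logFC))
  ok <- se > 0
  p[ok] <- 2 * pt(-abs(logFC[ok] / se[ok]), df = df[ok])
  if (any(!ok)) {
    degenerate_equal <- !ok & logFC == 0
    degenerate_diff <- !ok & logFC != 0
    p[degenerate_equal] <- 1
    if (any(degenerate_diff)) {
      warning(sprintf(
        "%d gene(s) with zero variance in both groups but unequal means; p set to the smallest positive double",
        sum(degenerate_diff)), call. = FALSE)
      p[degenerate_diff] <- .Machine$double.xmin
    }
  }

  adj_p <- bh_adjust(p)
  direction <- rep("ns", length(p))
  direction[adj_p < thresholds$p_max & logFC > thresholds$fc_min] <- "up"
  direction[adj_p < thresholds$p_max & logFC < -thresholds$fc_min] <- "down"

  out <- data.frame(gene = study$gene_ids, logFC = logFC, p = p,
                    adj_p = adj_p, direction = direction,
                    platform = study$platform[1], row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Intersect differential-expression calls across platforms
#'
#' A gene enters the consensus when it is significant (non-`ns`) on every
#' platform and, with `require_consistent_direction` (the default), its
#' direction agrees everywhere. Genes absent from any platform are
#' excluded (intersection semantics).
#'
#' @param tables List of at least two `de_table`s.
#' @param require_consistent_direction Demand an identical direction
#'   across platforms. Default `TRUE`.
#' @return List of class `de_consensus`: `consensus` (data frame `gene`,
#'   `direction`), `n_up`, `n_down`, `n_platforms`.
#' @export
intersect_platforms <- function(tables, require_consistent_direction = TRUE) {
  if (!is.list(tables) || length(tables) < 2L) {
    stop("need at least two DE tables", call. = FALSE)
  }
  genes <- Reduce(intersect, lapply(tables, function(t) t$gene))
  if (!length(genes)) {
    warning("no genes shared by all platforms; consensus is empty",
            call. = FALSE)
    cons <- data.frame(gene = character(0), direction = character(0))
  } else {
    dirs <- vapply(tables, function(t) {
      stats::setNames(t$direction, t$gene)[genes]
    }, character(length(genes)))
    dirs <- matrix(dirs, nrow = length(genes))
    sig <- apply(dirs, 1, function(d) all(d != "ns"))
    if (require_consistent_direction) {
      sig <- sig & apply(dirs, 1, function(d) length(unique(d)) == 1L)
    }
    cons <- data.frame(gene = genes[sig],
                       direction = ifelse(
                         apply(dirs[sig, , drop = FALSE], 1,
                               function(d) sum(d == "up") >= sum(d == "down")),
                         "up", "down"),
                       stringsAsFactors = FALSE)
    # without direction consistency a mixed gene is reported by majority
    # direction; with it the per-platform directions are identical anyway
    cons <- cons[order(cons$gene), , drop = FALSE]
    rownames(cons) <- NULL
  }
  structure(
    list(consensus = cons,
         n_up = sum(cons$direction == "up"),
         n_down = sum(cons$direction == "down"),
         n_platforms = length(tables)),
    class = "de_consensus"
  )
}

#' @export
print.de_consensus <- function(x, ...) {
  cat(sprintf("de_consensus over %d platforms: %d genes (%d up, %d down)\n",
              x$n_platforms, nrow(x$consensus), x$n_up, x$n_down))
  invisible(x)
}

#' Write a DE table or consensus as TSV
#'
#' @param x A `de_table` or `de_consensus`.
#' @param path Output TSV path.
#' @export
write_de_table <- function(x, path) {
  if (inherits(x, "de_consensus")) x <- x$consensus
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
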