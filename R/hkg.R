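#' Tissue-exon RPKM matrix
#'
#' Container for exon-level RPKM values across tissues, plus the
#' exon -> transcript -> gene hierarchy the housekeeping filter evaluates.
#' An exon may belong to several transcripts (supply a two-column data
#' frame mapping); each transcript belongs to exactly one gene.
#'
#' @param rpkm Non-negative numeric matrix, rows = exons, columns = tissues.
#' @param exon_to_transcript Either a named character vector
#'   (exon -> transcript, one transcript per exon) or a data frame with
#'   columns `exon`, `transcript` allowing multi-transcript exons.
#' @param transcript_to_gene Named character vector, transcript -> gene.
#' @return An object of class `tissue_exon_matrix`.
#' @export
tissue_exon_matrix <- function(rpkm, exon_to_transcript, transcript_to_gene) {
  if (!is.matrix(rpkm) || !is.numeric(rpkm)) {
    stop("'rpkm' must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(rpkm) || any(rpkm < 0)) {
    stop("RPKM values must be non-negative and non-missing", call. = FALSE)
  }
  if (is.null(rownames(rpkm))) {
    rownames(rpkm) <- paste0("E", seq_len(nrow(rpkm)))
  }
  if (is.null(colnames(rpkm))) {
    colnames(rpkm) <- paste0("tissue", seq_len(ncol(rpkm)))
  }
  if (is.data.frame(exon_to_transcript)) {
    stopifnot(all(c("exon", "transcript") %in% names(exon_to_transcript)))
    map <- exon_to_transcript[, c("exon", "transcript")]
  } else {
    map <- data.frame(exon = names(exon_to_transcript),
                      transcript = unname(as.character(exon_to_transcript)),
                      stringsAsFactors = FALSE)
  }
  unmapped <- setdiff(rownames(rpkm), map$exon)
  if (length(unmapped)) {
    stop("every exon must map to at least one transcript; unmapped: ",
         paste(utils::head(unmapped, 5), collapse = ", "), call. = FALSE)
  }
  if (is.null(names(transcript_to_gene))) {
    stop("'transcript_to_gene' must be a named character vector", call. = FALSE)
  }
  missing_tx <- setdiff(unique(map$transcript), names(transcript_to_gene))
  if (length(missing_tx)) {
    stop("transcripts without a gene: ",
         paste(utils::head(missing_tx, 5), collapse = ", "), call. = FALSE)
  }
  structure(
    list(rpkm = rpkm, exon_ids = rownames(rpkm), tissue_ids = colnames(rpkm),
         exon_to_transcript = map,
         transcript_to_gene = transcript_to_gene),
    class = "tissue_exon_matrix"
  )
}

#' @export
print.tissue_exon_matrix <- function(x, ...) {
  cat(sprintf("tissue_exon_matrix: %d exons x %d tissues, %d transcripts, %d genes\n",
              nrow(x$rpkm), ncol(x$rpkm),
              length(unique(x$exon_to_transcript$transcript)),
              length(unique(x$transcript_to_gene))))
  invisible(x)
}

#' Housekeeping stability criteria
#'
#' Thresholds of the three exon-level stability criteria: ubiquitous
#' detection (RPKM at or above `detection_min_rpkm` in every tissue), low
#' inter-tissue variability (SD of log2 RPKM below `sd_max_log2`), and no
#' extreme outlier tissue (every tissue/mean ratio strictly inside
#' `(1/fold_max, fold_max)`). A gene is called a housekeeping gene when at
#' least `exon_fraction_min` of the exons of some transcript pass all
#' three.
#'
#' @param detection_min_rpkm Detection floor, linear RPKM (default 1).
#' @param sd_max_log2 Upper bound (exclusive) on the SD of log2 RPKM.
#' @param fold_max Fold-deviation bound; a tissue at exactly `fold_max`
#'   times the mean (or `1/fold_max`) fails.
#' @param exon_fraction_min Minimum passing-exon fraction per transcript,
#'   in (0, 1].
#' @param log2_pseudocount Added before the log2 in the SD criterion;
#'   default 0 since detection already excludes zeros.
#' @param population_sd Use the population (n) instead of the sample
#'   (n - 1) SD. Default `FALSE`.
#' @return An object of class `hkg_criteria`.
#' @export
hkg_criteria <- function(detection_min_rpkm = 1, sd_max_log2 = 1,
                         fold_max = 4, exon_fraction_min = 0.5,
                         log2_pseudocount = 0, population_sd = FALSE) {
  stop_if_not_scalar_number(detection_min_rpkm, "detection_min_rpkm", 0)
  stop_if_not_scalar_number(sd_max_log2, "sd_max_log2", 0, strict_lower = TRUE)
  stop_if_not_scalar_number(fold_max, "fold_max", 1, strict_lower = TRUE)
  stop_if_not_scalar_number(exon_fraction_min, "exon_fraction_min", 0, 1,
                            strict_lower = TRUE)
  stop_if_not_scalar_number(log2_pseudocount, "log2_pseudocount", 0)
  structure(
    list(detection_min_rpkm = detection_min_rpkm, sd_max_log2 = sd_max_log2,
         fold_max = fold_max, exon_fraction_min = exon_fraction_min,
         log2_pseudocount = log2_pseudocount,
         population_sd = isTRUE(population_sd)),
    class = "hkg_criteria"
  )
}

#' Does one exon satisfy all three stability criteria?
#'
#' @param exon_rpkm Numeric vector of RPKM values over tissues (length
#'   at least 2).
#' @param criteria An [hkg_criteria()].
#' @return Logical flag.
#' @examples
#' exon_passes_stability(c(10, 10, 10, 10))           # TRUE
#' exon_passes_stability(c(10, 10, 10, 50))           # FALSE: log2 SD >= 1
#' @export
exon_passes_stability <- function(exon_rpkm, criteria = hkg_criteria()) {
  if (length(exon_rpkm) == 0L) stop("empty RPKM vector", call. = FALSE)
  if (length(exon_rpkm) < 2L) {
    stop("need RPKM in at least 2 tissues", call. = FALSE)
  }
  if (anyNA(exon_rpkm) || any(exon_rpkm < 0)) {
    stop("RPKM values must be non-negative and non-missing", call. = FALSE)
  }
  if (any(exon_rpkm < criteria$detection_min_rpkm)) return(FALSE)
  lg <- log2(exon_rpkm + criteria$log2_pseudocount)
  s <- sd(lg)
  if (criteria$population_sd) {
    n <- length(lg)
    s <- s * sqrt((n - 1) / n)
  }
  if (!is.finite(s) || s >= criteria$sd_max_log2) return(FALSE)
  ratio <- exon_rpkm / mean(exon_rpkm)
  all(ratio > 1 / criteria$fold_max & ratio < criteria$fold_max)
}

#' Call housekeeping genes from a tissue-exon matrix
#'
#' Evaluates every exon against the stability criteria, computes the
#' passing-exon fraction per transcript, and calls a gene a housekeeping
#' gene when any of its transcripts reaches `exon_fraction_min`. The
#' reported `best_transcript` maximizes the passing fraction (ties broken
#' by lexicographically smallest transcript id). Genes with no mapped
#' exons are dropped with a warning.
#'
#' @param tem A [tissue_exon_matrix()].
#' @param criteria An [hkg_criteria()].
#' @return Data frame of class `hkg_call_set` with columns `gene`,
#'   `is_hkg`, `best_transcript`, `passing_exon_fraction`, one row per
#'   gene, ordered by gene id.
#' @export
call_housekeeping_genes <- function(tem, criteria = hkg_criteria()) {
  stopifnot(inherits(tem, "tissue_exon_matrix"))
  pass <- vapply(tem$exon_ids, function(e) {
    exon_passes_stability(tem$rpkm[e, ], criteria)
  }, logical(1))

  map <- tem$exon_to_transcript
  map$pass <- pass[map$exon]
  tx_stats <- stats::aggregate(pass ~ transcript, data = map,
                               FUN = function(z) c(frac = mean(z)))
  tx_frac <- stats::setNames(as.numeric(tx_stats$pass), tx_stats$transcript)

  all_genes <- sort(unique(unname(tem$transcript_to_gene)))
  gene_of_tx <- tem$transcript_to_gene
  rows <- lapply(all_genes, function(g) {
    txs <- names(gene_of_tx)[gene_of_tx == g]
    txs <- intersect(txs, names(tx_frac))
    if (!length(txs)) return(NULL)
    fr <- tx_frac[txs]
    best <- sort(names(fr)[fr == max(fr)])[1L]
    data.frame(gene = g, is_hkg = unname(fr[best]) >= criteria$exon_fraction_min,
               best_transcript = best,
               passing_exon_fraction = unname(fr[best]),
               stringsAsFactors = FALSE)
  })
  dropped <- all_genes[vapply(rows, is.null, logical(1))]
  if (length(dropped)) {
    warning("genes with zero mapped exons excluded from output: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  class(out) <- c("hkg_call_set", "data.frame")
  out
}

#' Read / write housekeeping-filter inputs and outputs
#'
#' `read_tissue_exon_matrix()` assembles a [tissue_exon_matrix()] from an
#' exon RPKM TSV (first column = exon id) and two two-column mapping TSVs.
#' `write_hkg_calls()` writes an `hkg_call_set` as TSV.
#'
#' @param path_rpkm,path_exon_tx,path_tx_gene Input TSV paths.
#' @return A [tissue_exon_matrix()].
#' @export
read_tissue_exon_matrix <- function(path_rpkm, path_exon_tx, path_tx_gene) {
  raw <- read.delim(path_rpkm, check.names = FALSE, stringsAsFactors = FALSE)
  rpkm <- as.matrix(raw[, -1, drop = FALSE])
  rownames(rpkm) <- as.character(raw[[1]])
  etx <- read.delim(path_exon_tx, stringsAsFactors = FALSE)
  names(etx)[1:2] <- c("exon", "transcript")
  txg <- read.delim(path_tx_gene, stringsAsFactors = FALSE)
  tissue_exon_matrix(rpkm, exon_to_transcript = etx,
                     transcript_to_gene = stats::setNames(
                       as.character(txg[[2]]), as.character(txg[[1]])))
}

#' @rdname read_tissue_exon_matrix
#' @param calls An `hkg_call_set`.
#' @param path Output TSV path.
#' @export
write_hkg_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
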