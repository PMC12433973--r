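#' Construct an expression study
#'
#' Bundles a gene x sample matrix of log2-scale expression values with
#' per-sample group (case/control) and platform labels. This is the
#' universal input object of the pipeline: differential expression, the
#' co-expression network core, rewiring and the diagnostic stage all
#' consume it.
#'
#' @param values Numeric matrix, rows = genes, columns = samples, log2
#'   scale. Row and column names are used as gene and sample ids when
#'   `gene_ids` / `sample_ids` are not given.
#' @param group Character vector, one of `"case"` / `"control"` per sample.
#' @param platform Character vector of per-sample platform/batch labels
#'   (a single label is recycled).
#' @param gene_ids,sample_ids Optional explicit labels.
#' @return An object of class `expression_study`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `group`, `platform`.
#' @export
expression_study <- function(values, group, platform = "P1",
                             gene_ids = rownames(values),
                             sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression values must be finite with no missing entries",
         call. = FALSE)
  }
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("length(gene_ids) must equal nrow(values)", call. = FALSE)
  }
  if (length(sample_ids) != ncol(values)) {
    stop("length(sample_ids) must equal ncol(values)", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  group <- as.character(group)
  if (length(group) != ncol(values)) {
    stop("'group' must have one label per sample", call. = FALSE)
  }
  if (!all(group %in% c("case", "control"))) {
    stop("group labels must be 'case' or 'control'", call. = FALSE)
  }
  if (length(unique(group)) < 2L || min(table(group)) < 2L) {
    stop("both groups must be present with at least 2 samples each",
         call. = FALSE)
  }
  platform <- as.character(platform)
  if (length(platform) == 1L) platform <- rep(platform, ncol(values))
  if (length(platform) != ncol(values)) {
    stop("'platform' must be length 1 or one label per sample", call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         group = group, platform = platform),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf(
    "expression_study: %d genes x %d samples (%d case / %d control; platforms: %s)\n",
    nrow(x$values), ncol(x$values),
    sum(x$group == "case"), sum(x$group == "control"),
    paste(unique(x$platform), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$values)

#' Case/control 0-1 trait vector of a study
#'
#' @param study An [expression_study()].
#' @return Integer vector, 1 for case samples, 0 for controls.
#' @export
study_trait <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  as.integer(study$group == "case")
}
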