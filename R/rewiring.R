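#' The eight fixed correlation intervals
#'
#' The differential co-expression statistic bins Pearson correlations
#' into eight fixed intervals spanning \[-1, 1\]. With the default
#' boundary convention the first interval is closed, all others are
#' left-open: `[-1,-0.75], (-0.75,-0.5], ..., (0.75,1]`; hence r = 0
#' falls in "weakest negative". The alternative `"right_open"` convention
#' closes intervals on the left instead.
#'
#' @return Data frame with columns `bin` (1..8), `lower`, `upper`,
#'   `label` (interval string) and `name` (canonical description).
#' @export
correlation_bins <- function() {
  lower <- seq(-1, 0.75, by = 0.25)
  upper <- lower + 0.25
  data.frame(
    bin = 1:8, lower = lower, upper = upper,
    label = c("[-1,-0.75]", "(-0.75,-0.5]", "(-0.5,-0.25]", "(-0.25,0]",
              "(0,0.25]", "(0.25,0.5]", "(0.5,0.75]", "(0.75,1]"),
    name = c("strongest negative", "strong negative", "weak negative",
             "weakest negative", "weakest positive", "weak positive",
             "strong positive", "strongest positive"),
    stringsAsFactors = FALSE
  )
}

#' Map correlation values to their interval
#'
#' Vectorized; values outside \[-1, 1\] by more than 1e-9 are an error,
#' values within that tolerance are clamped.
#'
#' @param r Numeric vector of correlations.
#' @param convention `"left_open"` (default: intervals `(a, b]`, first
#'   closed) or `"right_open"` (intervals `[a, b)`, last closed).
#' @return Integer bin indices in 1..8.
#' @examples
#' bin_correlation(c(-1, -0.75, -0.7499, 0, 0.6, 1))  # 1 1 2 4 7 8
#' @export
bin_correlation <- function(r, convention = c("left_open", "right_open")) {
  convention <- match.arg(convention)
  if (!is.numeric(r) || any(!is.finite(r))) {
    stop("correlations must be finite numbers", call. = FALSE)
  }
  if (any(abs(r) > 1 + 1e-9)) {
    stop("correlation outside [-1, 1]: ",
         paste(utils::head(r[abs(r) > 1 + 1e-9], 3), collapse = ", "),
         call. = FALSE)
  }
  r <- pmin(pmax(r, -1), 1)
  idx <- if (convention == "left_open") {
    ceiling((r + 1) / 0.25)
  } else {
    floor((r + 1) / 0.25) + 1
  }
  as.integer(pmin(pmax(idx, 1L), 8L))
}

#' Per-group correlations between anchor genes and all other genes
#'
#' For each (anchor, partner) pair with partner != anchor, computes the
#' Pearson correlation separately within controls and within cases and
#' bins both. Pairs where either gene has zero variance within a group
#' are excluded; the exclusion count is attached as attribute
#' `n_excluded`.
#'
#' @param study An [expression_study()] with at least 3 samples per group.
#' @param anchors Character vector of anchor gene ids present in the
#'   study.
#' @return Data frame of class `pair_correlations`: `anchor`, `partner`,
#'   `r_control`, `r_case`, `bin_control`, `bin_case`.
#' @export
pairwise_group_correlations <- function(study, anchors) {
  stopifnot(inherits(study, "expression_study"))
  anchors <- as.character(anchors)
  missing <- setdiff(anchors, study$gene_ids)
  if (length(missing)) {
    stop("anchor gene(s) absent from study: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  groups <- list(control = study$group == "control",
                 case = study$group == "case")
  if (any(vapply(groups, sum, integer(1)) < 3L)) {
    stop("need at least 3 samples per group", call. = FALSE)
  }

  rmat <- lapply(groups, function(idx) {
    x <- study$values[, idx, drop = FALSE]
    v <- apply(x, 1, var)
    r <- suppressWarnings(cor(t(x[anchors, , drop = FALSE]), t(x)))
    r[, v == 0] <- NA   # zero variance within this group
    r[anchors[apply(x[anchors, , drop = FALSE], 1, var) == 0], ] <- NA
    r
  })

  pairs <- expand.grid(anchor = anchors, partner = study$gene_ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$anchor != pairs$partner, , drop = FALSE]
  i <- cbind(match(pairs$anchor, anchors), match(pairs$partner, study$gene_ids))
  pairs$r_control <- rmat$control[i]
  pairs$r_case <- rmat$case[i]
  ok <- !is.na(pairs$r_control) & !is.na(pairs$r_case)
  n_excluded <- sum(!ok)
  pairs <- pairs[ok, , drop = FALSE]
  pairs$bin_control <- bin_correlation(pairs$r_control)
  pairs$bin_case <- bin_correlation(pairs$r_case)
  rownames(pairs) <- NULL
  class(pairs) <- c("pair_correlations", "data.frame")
  attr(pairs, "n_excluded") <- n_excluded
  pairs
}

#' Tally pairs into the 8x8 control -> case transition matrix
#'
#' Rows index the control-group bin, columns the case-group bin; cell
#' (i, j) counts the gene pairs whose correlation sat in bin i among
#' controls and bin j among cases.
#'
#' @param pairs A `pair_correlations` data frame (needs `bin_control`,
#'   `bin_case`).
#' @return 8x8 integer matrix of class `transition_matrix` with interval
#'   labels as dimnames and attribute `n_pairs`.
#' @export
transition_matrix <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("bin_control", "bin_case") %in% names(pairs)))
  if (!nrow(pairs)) stop("no pairs to tally", call. = FALSE)
  labels <- correlation_bins()$label
  counts <- table(factor(pairs$bin_control, levels = 1:8),
                  factor(pairs$bin_case, levels = 1:8))
  m <- matrix(as.integer(counts), 8, 8, dimnames = list(labels, labels))
  structure(m, class = c("transition_matrix", class(m)),
            n_pairs = nrow(pairs))
}

#' Rewiring selection rule
#'
#' A control-bin -> case-bin transition (i, j) is selected when the shift
#' spans at least `min_shift` intervals in the allowed direction
#' (`positive`: j - i >= min_shift; `negative`: i - j >= min_shift;
#' `both`: either), or when (i, j) is listed explicitly in
#' `extra_transitions`. The default reproduces the published rule:
#' positive shifts of at least 4 intervals plus the weakest-positive to
#' strongest-positive cell (5, 8).
#'
#' @param min_shift Minimum interval shift, 1..7 (default 4).
#' @param direction One of `"positive"`, `"negative"`, `"both"`.
#' @param extra_transitions List of `c(from, to)` bin pairs always
#'   selected (default `list(c(5, 8))`).
#' @return An object of class `rewiring_rule`.
#' @export
rewiring_rule <- function(min_shift = 4,
                          direction = c("positive", "negative", "both"),
                          extra_transitions = list(c(5L, 8L))) {
  direction <- match.arg(direction)
  min_shift <- stop_if_not_count(min_shift, "min_shift")
  if (min_shift > 7L) stop("min_shift must be in 1..7", call. = FALSE)
  if (!is.null(extra_transitions)) {
    for (tr in extra_transitions) {
      if (length(tr) != 2L || any(!tr %in% 1:8)) {
        stop("extra transitions must be pairs of bins in 1..8", call. = FALSE)
      }
    }
  }
  structure(list(min_shift = min_shift, direction = direction,
                 extra_transitions = extra_transitions),
            class = "rewiring_rule")
}

rule_cells <- function(rule) {
  grid <- expand.grid(from = 1:8, to = 1:8)
  shift <- grid$to - grid$from
  keep <- switch(rule$direction,
                 positive = shift >= rule$min_shift,
                 negative = -shift >= rule$min_shift,
                 both = abs(shift) >= rule$min_shift)
  for (tr in rule$extra_transitions) {
    keep <- keep | (grid$from == tr[1] & grid$to == tr[2])
  }
  grid[keep, , drop = FALSE]
}

#' Select rewired transitions (and pairs)
#'
#' Applies a [rewiring_rule()] to either a [transition_matrix()] or a
#' `pair_correlations` data frame. With a matrix, returns the selected
#' cells and their total count; with pairs, additionally returns the
#' selected pairs with their transition labels.
#'
#' @param x A `transition_matrix` or `pair_correlations` object.
#' @param rule A [rewiring_rule()].
#' @return List of class `rewiring_selection`: `cells` (data frame
#'   `from`, `to`, `count`, restricted to selected cells with nonzero
#'   definitions), `total`, and `pairs` when pair-level input was given.
#' @examples
#' tm <- read_transition_table(
#'   system.file("extdata", "table2.tsv", package = "hkgrewire"))
#' select_rewired(tm)$total   # 139
#' @export
select_rewired <- function(x, rule = rewiring_rule()) {
  stopifnot(inherits(rule, "rewiring_rule"))
  cells <- rule_cells(rule)
  if (inherits(x, "transition_matrix")) {
    cells$count <- x[cbind(cells$from, cells$to)]
    sel_pairs <- NULL
  } else if (inherits(x, "pair_correlations") ||
             (is.data.frame(x) && all(c("bin_control", "bin_case") %in% names(x)))) {
    key <- paste(x$bin_control, x$bin_case)
    sel_key <- paste(cells$from, cells$to)
    sel_pairs <- x[key %in% sel_key, , drop = FALSE]
    rownames(sel_pairs) <- NULL
    cells$count <- vapply(seq_len(nrow(cells)), function(i) {
      sum(x$bin_control == cells$from[i] & x$bin_case == cells$to[i])
    }, numeric(1))
  } else {
    stop("expected a transition_matrix or pair_correlations object",
         call. = FALSE)
  }
  cells <- cells[order(cells$from, cells$to), , drop = FALSE]
  rownames(cells) <- NULL
  structure(list(cells = cells, total = sum(cells$count),
                 rule = rule, pairs = sel_pairs),
            class = "rewiring_selection")
}

#' @export
print.rewiring_selection <- function(x, ...) {
  nz <- x$cells[x$cells$count > 0, , drop = FALSE]
  cat(sprintf("rewiring_selection: %d pairs over %d cells (%d nonzero)\n",
              x$total, nrow(x$cells), nrow(nz)))
  if (nrow(nz)) {
    lab <- correlation_bins()$name
    for (i in seq_len(nrow(nz))) {
      cat(sprintf("  %s -> %s: %d\n", lab[nz$from[i]], lab[nz$to[i]],
                  nz$count[i]))
    }
  }
  invisible(x)
}

#' Read / write a transition matrix TSV
#'
#' The on-disk format is an 8x8 integer table, first column and header
#' row holding the canonical interval labels (rows = control bin,
#' columns = case bin). Label prefixes before the bracketed interval
#' (e.g. a cohort name) are tolerated and stripped.
#'
#' @param path TSV path.
#' @return A [transition_matrix()].
#' @export
read_transition_table <- function(path) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) != 9L || nrow(raw) != 8L) {
    stop(sprintf("expected an 8x8 table with a label column, got %dx%d",
                 nrow(raw), ncol(raw) - 1L), call. = FALSE)
  }
  canon <- correlation_bins()$label
  strip <- function(z) {
    z <- sub("^[^[(]*", "", trimws(z))   # drop any prefix before [ or (
    gsub("\\s+", "", z)
  }
  row_labels <- strip(as.character(raw[[1]]))
  col_labels <- strip(names(raw)[-1])
  if (!identical(row_labels, canon) || !identical(col_labels, canon)) {
    stop("interval labels do not match the eight canonical bins",
         call. = FALSE)
  }
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m) || anyNA(m) || any(m < 0) || any(m != round(m))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  m <- matrix(as.integer(m), 8, 8, dimnames = list(canon, canon))
  structure(m, class = c("transition_matrix", class(m)), n_pairs = sum(m))
}

#' @rdname read_transition_table
#' @param tm A `transition_matrix`.
#' @export
write_transition_table <- function(tm, path) {
  stopifnot(inherits(tm, "transition_matrix"))
  df <- data.frame(control_bin = rownames(tm), unclass(tm)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
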