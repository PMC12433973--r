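#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor sd rnorm runif pt p.adjust quantile cutree hclust
#'   as.dist predict var
#' @importFrom utils read.delim write.table
NULL

# Derive a reproducible sub-seed from a master seed. Kept below 2^31 - 1 so
# the result is always a valid R integer seed.
derive_seed <- function(master, offset) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  as.integer((abs(master) + 7919 * abs(offset)) %% 2147483629 + 1)
}

stop_if_not_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                      strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  if (!lo_ok || x > upper) {
    stop(sprintf("'%s' = %g is outside its allowed range", name, x),
         call. = FALSE)
  }
  invisible(x)
}

stop_if_not_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

check_symmetric <- function(m, name = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(sprintf("'%s' must be a square matrix", name), call. = FALSE)
  }
  if (max(abs(m - t(m))) > tol) {
    stop(sprintf("'%s' must be symmetric", name), call. = FALSE)
  }
  invisible(m)
}
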