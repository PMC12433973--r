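# Independent brute-force oracles used to check the package implementations.

# Step-up BH adjustment, written directly from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * p[ord[i]] / i)
    adj_sorted[i] <- min(running, 1)
  }
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# Topological overlap by explicit triple loop.
oracle_tom <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  k <- colSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# Piecewise bin definition written out interval by interval.
oracle_bin <- function(r) {
  vapply(r, function(v) {
    if (v >= -1 && v <= -0.75) 1L
    else if (v <= -0.5) 2L
    else if (v <= -0.25) 3L
    else if (v <= 0) 4L
    else if (v <= 0.25) 5L
    else if (v <= 0.5) 6L
    else if (v <= 0.75) 7L
    else 8L
  }, integer(1))
}

# AUC as the probability a random positive outscores a random negative,
# ties counted one half, by explicit pair enumeration.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Direct per-exon evaluation of the three housekeeping criteria plus the
# any-transcript gene rule, independent of the package's vectorized path.
oracle_hkg_calls <- function(tem, criteria = hkg_criteria()) {
  exon_pass <- function(v) {
    if (any(v < criteria$detection_min_rpkm)) return(FALSE)
    s <- stats::sd(log2(v + criteria$log2_pseudocount))
    if (!is.finite(s) || s >= criteria$sd_max_log2) return(FALSE)
    ratio <- v / mean(v)
    all(ratio > 1 / criteria$fold_max) && all(ratio < criteria$fold_max)
  }
  map <- tem$exon_to_transcript
  genes <- sort(unique(unname(tem$transcript_to_gene)))
  hkg <- character(0)
  for (g in genes) {
    txs <- names(tem$transcript_to_gene)[tem$transcript_to_gene == g]
    for (tx in txs) {
      exons <- map$exon[map$transcript == tx]
      if (!length(exons)) next
      frac <- mean(vapply(exons, function(e) exon_pass(tem$rpkm[e, ]),
                          logical(1)))
      if (frac >= criteria$exon_fraction_min) {
        hkg <- c(hkg, g)
        break
      }
    }
  }
  hkg
}

# Adjusted Rand index between two label vectors (used when mclust is not
# available; agrees with mclust::adjustedRandIndex).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Small random symmetric adjacency in [0,1] with zero diagonal.
random_adjacency <- function(n, seed) {
  withr::with_seed(seed, {
    a <- matrix(runif(n * n), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    a
  })
}

# Two-Gaussian separable classification problem: class means +-delta/2 on
# every feature.
make_gaussian_problem <- function(n = 200, p = 34, delta = 6, seed = 1) {
  withr::with_seed(seed, {
    labels <- rep(c(0L, 1L), each = n / 2)
    x <- matrix(rnorm(n * p), n, p) + outer(ifelse(labels == 1, delta / 2,
                                                   -delta / 2), rep(1, p))
    colnames(x) <- paste0("f", seq_len(p))
    list(features = x, labels = labels)
  })
}
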