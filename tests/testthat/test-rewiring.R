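test_that("bin boundaries follow the left-open convention", {
  expect_equal(bin_correlation(0.6), 7L)       # strong positive
  expect_equal(bin_correlation(-1), 1L)        # closed lower boundary
  expect_equal(bin_correlation(-0.75), 1L)
  expect_equal(bin_correlation(-0.7499), 2L)
  expect_equal(bin_correlation(0), 4L)         # weakest negative
  expect_equal(bin_correlation(1), 8L)
  expect_equal(bin_correlation(c(0.25, 0.250001)), c(5L, 6L))

  # the alternative convention closes on the left instead
  expect_equal(bin_correlation(0, convention = "right_open"), 5L)
  expect_equal(bin_correlation(1, convention = "right_open"), 8L)

  expect_error(bin_correlation(1.1), "outside")
  expect_error(bin_correlation(NaN), "finite")
  # within-tolerance values are clamped
  expect_equal(bin_correlation(1 + 1e-10), 8L)
})

test_that("binning partitions [-1, 1] exactly on a fine grid", {
  grid <- seq(-1, 1, by = 1e-4)
  bins <- bin_correlation(grid)
  expect_true(all(bins %in% 1:8))
  expect_identical(bins, oracle_bin(grid))
  expect_identical(sort(unique(bins)), 1:8)
})

test_that("pairwise group correlations obey the counting contract", {
  withr::with_seed(4, {
    x <- matrix(rnorm(10 * 24), 10, 24)
  })
  rownames(x) <- paste0("g", sprintf("%02d", 1:10))
  x["g02", ] <- x["g01", ]   # duplicated row
  st <- expression_study(x, group = rep(c("case", "control"), each = 12))
  pairs <- pairwise_group_correlations(st, anchors = c("g01", "g03"))
  expect_equal(nrow(pairs), 2 * (10 - 1))
  dup <- pairs[pairs$anchor == "g01" & pairs$partner == "g02", ]
  expect_equal(dup$r_control, 1)
  expect_equal(dup$r_case, 1)
  expect_equal(dup$bin_control, 8L)
  expect_equal(dup$bin_case, 8L)

  expect_error(pairwise_group_correlations(st, "nope"), "absent")

  # zero-variance partner in one group is excluded and counted
  x2 <- rbind(x, flat = c(rep(3, 12), rnorm(12)))
  st2 <- expression_study(x2, group = rep(c("case", "control"), each = 12))
  p2 <- pairwise_group_correlations(st2, anchors = "g01")
  expect_false("flat" %in% p2$partner)
  expect_equal(attr(p2, "n_excluded"), 1)
})

test_that("planted rewired pairs land in the expected bins", {
  cfg <- sim_config(n_cases = 2000, n_controls = 2000, n_genes = 30,
                    n_modules = 0, module_size = 0, de_fraction = 0,
                    rewired_pairs = data.frame(anchor = "G0001",
                                               partner = "G0002",
                                               rho_control = -0.6,
                                               rho_case = 0.9),
                    seed = 6)
  sim <- simulate_two_group_study(cfg)
  pairs <- pairwise_group_correlations(sim$study, "G0001")
  pl <- pairs[pairs$partner == "G0002", ]
  expect_equal(pl$bin_control, 2L)   # (-0.75,-0.5]
  expect_equal(pl$bin_case, 8L)      # (0.75,1]
})

test_that("the transition matrix equals a brute-force tally and is order-invariant", {
  withr::with_seed(10, {
    pairs <- data.frame(bin_control = sample(1:8, 200, replace = TRUE),
                        bin_case = sample(1:8, 200, replace = TRUE))
  })
  tm <- transition_matrix(pairs)
  expect_s3_class(tm, "transition_matrix")
  expect_equal(attr(tm, "n_pairs"), 200)
  expect_equal(sum(tm), 200)
  for (i in 1:8) for (j in 1:8) {
    expect_equal(tm[i, j],
                 sum(pairs$bin_control == i & pairs$bin_case == j))
  }
  perm <- transition_matrix(pairs[sample(200), ])
  expect_equal(unclass(perm), unclass(tm), ignore_attr = TRUE)
})

test_that("swapping group labels transposes the transition matrix", {
  cfg <- sim_config(n_cases = 40, n_controls = 40, n_genes = 40,
                    n_modules = 0, module_size = 0, de_fraction = 0, seed = 12)
  sim <- simulate_two_group_study(cfg)
  st <- sim$study
  swapped <- expression_study(st$values,
                              group = ifelse(st$group == "case", "control",
                                             "case"),
                              platform = st$platform)
  tm <- transition_matrix(pairwise_group_correlations(st, "G0001"))
  tm_sw <- transition_matrix(pairwise_group_correlations(swapped, "G0001"))
  expect_equal(unclass(tm_sw), t(unclass(tm)), ignore_attr = TRUE)
})

test_that("the default rule selects exactly the qualifying cells", {
  rule <- rewiring_rule()
  cells <- select_rewired(
    transition_matrix(data.frame(bin_control = 1, bin_case = 5)), rule)$cells
  got <- cells[, c("from", "to")]
  # j - i >= 4 gives (1,5..8), (2,6..8), (3,7..8), (4,8); (5,8) is the
  # explicit extra transition
  want <- rbind(
    expand.grid(from = 1, to = 5:8), expand.grid(from = 2, to = 6:8),
    expand.grid(from = 3, to = 7:8), expand.grid(from = 4, to = 8),
    expand.grid(from = 5, to = 8))
  want <- want[order(want$from, want$to), ]
  expect_equal(nrow(got), 11)
  expect_equal(as.matrix(got), as.matrix(want), ignore_attr = TRUE)
})

test_that("selection totals match a brute-force cell sum for random rules", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      m <- matrix(rpois(64, 10), 8, 8)
      shift <- sample(1:7, 1)
      dir <- sample(c("positive", "negative", "both"), 1)
      extra <- if (runif(1) < 0.5) list(c(sample(8, 1), sample(8, 1))) else NULL
    })
    labels <- correlation_bins()$label
    dimnames(m) <- list(labels, labels)
    tm <- structure(m, class = c("transition_matrix", class(m)),
                    n_pairs = sum(m))
    rule <- rewiring_rule(min_shift = shift, direction = dir,
                          extra_transitions = extra)
    # independent enumeration of qualifying cells
    total <- 0
    for (i in 1:8) for (j in 1:8) {
      base <- switch(dir, positive = j - i >= shift,
                     negative = i - j >= shift,
                     both = abs(j - i) >= shift)
      in_extra <- !is.null(extra) && i == extra[[1]][1] && j == extra[[1]][2]
      if (base || in_extra) total <- total + m[i, j]
    }
    expect_equal(select_rewired(tm, rule)$total, total)
  }
})

test_that("pair-level selection returns the selected pairs themselves", {
  pairs <- data.frame(
    anchor = "a", partner = paste0("p", 1:4),
    r_control = c(-0.6, -0.1, 0.1, 0.6),
    r_case = c(0.6, 0.9, 0.2, 0.7))
  pairs$bin_control <- bin_correlation(pairs$r_control)
  pairs$bin_case <- bin_correlation(pairs$r_case)
  class(pairs) <- c("pair_correlations", "data.frame")
  sel <- select_rewired(pairs)
  # (3,7) shift 4 selected; (4,8) selected; (5,5) not; (7,7) not
  expect_equal(sel$total, 2)
  expect_identical(sort(sel$pairs$partner), c("p1", "p2"))
})

test_that("an all-zero matrix selects nothing", {
  labels <- correlation_bins()$label
  m <- matrix(0L, 8, 8, dimnames = list(labels, labels))
  tm <- structure(m, class = c("transition_matrix", class(m)), n_pairs = 0L)
  expect_equal(select_rewired(tm)$total, 0)
})

test_that("the packaged worked-example table parses and round-trips", {
  path <- system.file("extdata", "table2.tsv", package = "hkgrewire")
  tm <- read_transition_table(path)
  expect_equal(attr(tm, "n_pairs"), sum(tm))
  expect_equal(tm["(-0.25,0]", "(0,0.25]"], 66512L)

  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_transition_table(tm, tmp)
  back <- read_transition_table(tmp)
  expect_equal(unclass(back), unclass(tm), ignore_attr = TRUE)
  expect_equal(attr(back, "n_pairs"), attr(tm, "n_pairs"))

  # wrong shape errors
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(readLines(path)[1:7], bad)
  expect_error(read_transition_table(bad), "8x8")
  # bad labels error
  bad2 <- withr::local_tempfile(fileext = ".tsv")
  lines <- readLines(path)
  lines[2] <- sub("\\[-1,-0.75\\]", "[-1,-0.5]", lines[2])
  writeLines(lines, bad2)
  expect_error(read_transition_table(bad2), "labels")
})

test_that("planted rewiring is recovered end to end with few false selections", {
  hits <- 0; planted_n <- 0; false_sel <- 0; null_n <- 0
  for (seed in 1:3) {
    rw <- data.frame(anchor = rep(c("G0001", "G0002"), each = 2),
                     partner = paste0("G000", 3:6),
                     rho_control = c(-0.6, -0.5, -0.7, -0.55),
                     rho_case = c(0.8, 0.9, 0.85, 0.9))
    cfg <- sim_config(n_cases = 500, n_controls = 500, n_genes = 200,
                      n_modules = 0, module_size = 0, de_fraction = 0,
                      rewired_pairs = rw, seed = seed)
    sim <- simulate_two_group_study(cfg)
    pairs <- pairwise_group_correlations(sim$study, c("G0001", "G0002"))
    sel <- select_rewired(pairs)
    key <- paste(sel$pairs$anchor, sel$pairs$partner)
    planted_key <- paste(rw$anchor, rw$partner)
    hits <- hits + sum(planted_key %in% key)
    planted_n <- planted_n + length(planted_key)
    false_sel <- false_sel + sum(!key %in% planted_key)
    null_n <- null_n + nrow(pairs) - length(planted_key)
  }
  expect_gte(hits / planted_n, 0.95)
  expect_lt(false_sel / null_n, 0.01)
})
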