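#' Ensemble network configuration
#'
#' Settings of the averaged neural-network classifier: several
#' single-hidden-layer networks (logistic activations, L2 weight decay)
#' are trained from independent seeded initializations on the same data
#' and their class-1 probabilities averaged.
#'
#' @param n_members Ensemble size (default 5).
#' @param hidden_units Hidden-layer width (default 5).
#' @param weight_decay L2 penalty (default 0.01).
#' @param max_iterations Optimizer iteration cap (default 500).
#' @param seed Master seed; member seeds are derived from it.
#' @return An object of class `ensemble_net_config`.
#' @export
ensemble_net_config <- function(n_members = 5, hidden_units = 5,
                                weight_decay = 0.01, max_iterations = 500,
                                seed = 1L) {
  n_members <- stop_if_not_count(n_members, "n_members")
  hidden_units <- stop_if_not_count(hidden_units, "hidden_units")
  stop_if_not_scalar_number(weight_decay, "weight_decay", 0)
  max_iterations <- stop_if_not_count(max_iterations, "max_iterations")
  seed <- stop_if_not_count(seed, "seed", min = 0L)
  structure(
    list(n_members = n_members, hidden_units = hidden_units,
         weight_decay = weight_decay, max_iterations = max_iterations,
         seed = seed,
         member_seeds = vapply(seq_len(n_members), function(i) {
           derive_seed(seed, 500L + i)
         }, integer(1))),
    class = "ensemble_net_config"
  )
}

#' Stratified train/test split
#'
#' Per class, `round(train_fraction * class size)` samples are drawn into
#' the training set; the rest form the test set. Disjoint, exhaustive,
#' seeded.
#'
#' @param labels 0/1 (or two-level) vector of sample labels.
#' @param train_fraction Training share in (0, 1), default 0.8.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.8, seed = 1L) {
  stop_if_not_scalar_number(train_fraction, "train_fraction", 0, 1,
                            strict_lower = TRUE)
  if (train_fraction >= 1) stop("train_fraction must be below 1", call. = FALSE)
  classes <- unique(labels)
  if (length(classes) < 2L) stop("both classes must be present", call. = FALSE)
  if (any(table(labels) < 2L)) {
    stop("each class needs at least 2 samples", call. = FALSE)
  }
  train <- integer(0)
  withr::with_seed(seed, {
    for (cl in classes) {
      idx <- which(labels == cl)
      n_tr <- round(train_fraction * length(idx))
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)  # keep both sets non-empty
      train <- c(train, sample(idx, n_tr))
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Train an averaged neural-network classifier
#'
#' Features are standardized with training-set means and SDs (stored in
#' the model); each ensemble member is a single-hidden-layer network fit
#' with cross-entropy loss and L2 weight decay from its own seeded random
#' initialization; the model's score for a sample is the arithmetic mean
#' of member class-1 probabilities.
#'
#' @param features Samples x features numeric matrix (column names
#'   required; they are checked at prediction time).
#' @param labels 0/1 vector.
#' @param config An [ensemble_net_config()].
#' @return An object of class `ensemble_net`.
#' @export
train_ensemble_net <- function(features, labels,
                               config = ensemble_net_config()) {
  stopifnot(inherits(config, "ensemble_net_config"))
  features <- as.matrix(features)
  if (any(!is.finite(features))) {
    stop("features must be finite", call. = FALSE)
  }
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)) || length(labels) != nrow(features)) {
    stop("labels must be one 0/1 value per sample", call. = FALSE)
  }
  if (min(table(labels)) < 2L) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  center <- colMeans(features)
  scale_ <- apply(features, 2, sd)
  scale_[scale_ == 0] <- 1
  xs <- sweep(sweep(features, 2, center), 2, scale_, "/")

  members <- lapply(config$member_seeds, function(s) {
    withr::with_seed(s, {
      nnet::nnet(x = xs, y = labels, size = config$hidden_units,
                 decay = config$weight_decay, maxit = config$max_iterations,
                 entropy = TRUE, trace = FALSE)
    })
  })
  structure(
    list(members = members, center = center, scale = scale_,
         features = colnames(features), config = config),
    class = "ensemble_net"
  )
}

#' @export
print.ensemble_net <- function(x, ...) {
  cat(sprintf(
    "ensemble_net: %d members, %d hidden units, decay %g, %d features\n",
    x$config$n_members, x$config$hidden_units, x$config$weight_decay,
    length(x$features)))
  invisible(x)
}

#' Ensemble scores for new samples
#'
#' Mean member class-1 probability after applying the stored
#' standardization. Deterministic given a trained model.
#'
#' @param model An [train_ensemble_net()] model.
#' @param features Samples x features matrix with the training columns.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
predict_scores <- function(model, features) {
  stopifnot(inherits(model, "ensemble_net"))
  features <- as.matrix(features)
  if (is.null(colnames(features))) {
    if (ncol(features) == length(model$features)) {
      colnames(features) <- model$features
    } else {
      stop("feature columns must be named to match the training features",
           call. = FALSE)
    }
  }
  missing <- setdiff(model$features, colnames(features))
  extra <- setdiff(colnames(features), model$features)
  if (length(missing) || length(extra)) {
    stop(sprintf("feature mismatch; missing: %s; extra: %s",
                 paste(missing, collapse = ", "),
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  features <- features[, model$features, drop = FALSE]
  xs <- sweep(sweep(features, 2, model$center), 2, model$scale, "/")
  scores <- rowMeans(vapply(model$members, function(m) {
    as.numeric(predict(m, xs, type = "raw"))
  }, numeric(nrow(xs))))
  pmin(pmax(unname(scores), 0), 1)
}

#' Classification metrics at a score threshold
#'
#' Confusion matrix at `score >= threshold`, accuracy, precision, recall,
#' F1, and the AUC computed as the Mann-Whitney rank statistic (ties
#' count one half). Undefined ratios (empty denominators) are returned
#' as NA with a warning; AUC is NA when only one class is present.
#'
#' @param labels 0/1 vector.
#' @param scores Scores in \[0, 1\].
#' @param threshold Decision threshold (default 0.5).
#' @return List of class `eval_metrics` with `accuracy`, `precision`,
#'   `recall`, `f1`, `auc`, and `confusion` (`tp`, `fp`, `fn`, `tn`).
#' @export
evaluate_scores <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  if (length(scores) != length(labels)) {
    stop("labels and scores must have equal length", call. = FALSE)
  }
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  accuracy <- (tp + tn) / length(labels)
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    warning("no positive predictions; precision undefined", call. = FALSE)
    NA_real_
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("no positive labels; recall undefined", call. = FALSE)
    NA_real_
  }
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_

  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  auc <- if (n1 == 0L || n0 == 0L) {
    warning("single-class labels; AUC undefined", call. = FALSE)
    NA_real_
  } else {
    rk <- rank(scores)   # midranks: ties count one half
    (sum(rk[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  structure(
    list(accuracy = accuracy, precision = precision, recall = recall,
         f1 = f1, auc = auc,
         confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
         threshold = threshold),
    class = "eval_metrics"
  )
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(
    "eval_metrics @ %.2f: accuracy %.3f, precision %s, recall %s, F1 %s, AUC %s\n",
    x$threshold, x$accuracy,
    formatC(x$precision, digits = 3, format = "f"),
    formatC(x$recall, digits = 3, format = "f"),
    formatC(x$f1, digits = 3, format = "f"),
    formatC(x$auc, digits = 3, format = "f")))
  cat(sprintf("  confusion: tp %d, fp %d, fn %d, tn %d\n",
              x$confusion["tp"], x$confusion["fp"], x$confusion["fn"],
              x$confusion["tn"]))
  invisible(x)
}
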