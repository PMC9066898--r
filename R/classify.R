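#' Stratified train/test split
#'
#' Deterministic (for a fixed seed) stratified split: the total training
#' size is `round(n * train_fraction)`, allocated across the two classes by
#' largest remainder, so class proportions in the training set are within
#' one sample of the overall proportions. A 63-sample cohort (32 case / 31
#' control) at the default 2/3 fraction yields 42 training and 21 test
#' samples.
#'
#' @param sample_ids character vector of sample IDs.
#' @param labels binary labels aligned with `sample_ids`.
#' @param train_fraction proportion of samples used for training, in (0, 1).
#' @param seed integer seed controlling the within-class draw.
#' @return list with elements `train` and `test` (character vectors of IDs).
#' @export
split_cohort <- function(sample_ids, labels, train_fraction = 2 / 3, seed = 1L) {
  stopifnot(length(sample_ids) == length(labels),
            train_fraction > 0, train_fraction < 1)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop_("labels must have exactly two classes")
  n_by <- table(labels)[classes]
  if (any(n_by < 2)) stop_("each class needs at least 2 samples to split")
  n_train <- round(length(sample_ids) * train_fraction)
  quota <- as.numeric(n_by) * train_fraction
  base <- floor(quota)
  rem <- quota - base
  extra <- n_train - sum(base)
  if (extra > 0) {
    give <- order(-rem, classes)[seq_len(extra)]
    base[give] <- base[give] + 1
  }
  train <- character(0)
  with_seed(seed, {
    for (i in seq_along(classes)) {
      ids <- sample_ids[labels == classes[i]]
      train <- c(train, sample(ids, base[i]))
    }
  })
  train <- sample_ids[sample_ids %in% train]
  list(train = train, test = setdiff(sample_ids, train))
}

#' Train the module SVM classifier
#'
#' Restricts the profile to the module features, z-scores each feature
#' using training-set statistics only, and fits a linear-kernel
#' soft-margin SVM (cost 1). The returned state records the
#' standardisation parameters so evaluation applies the same transform.
#'
#' @param profile an [expression_profile()] holding the cohort.
#' @param module_features character vector of feature IDs (the module genes).
#' @param train_ids sample IDs used for training.
#' @param seed integer seed (recorded; the linear SVM fit is deterministic).
#' @return list of class `module_classifier` with the fitted model,
#'   `center`, `scale`, `features`, and `train_ids`.
#' @export
train_module_classifier <- function(profile, module_features, train_ids, seed = 1L) {
  stopifnot(inherits(profile, "expression_profile"))
  missing <- setdiff(module_features, rownames(profile$values))
  if (length(missing) > 0) {
    stop_("module feature(s) missing from profile: %s", paste(missing, collapse = ", "))
  }
  if (length(module_features) < 2) stop_("need at least 2 module features")
  bad <- setdiff(train_ids, colnames(profile$values))
  if (length(bad) > 0) stop_("unknown sample id(s): %s", paste(bad, collapse = ", "))
  x <- t(profile$values[module_features, train_ids, drop = FALSE])
  y <- factor(profile$groups[train_ids], levels = c("control", "case"))
  if (length(unique(y)) < 2) stop_("training set must contain both classes")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  model <- with_seed(seed, e1071::svm(xs, y, kernel = "linear", cost = 1,
                                      scale = FALSE))
  structure(list(model = model, center = ctr, scale = scl,
                 features = module_features, train_ids = train_ids, seed = seed),
            class = "module_classifier")
}

#' Evaluate the module classifier on a set of samples
#'
#' Applies the training standardisation, predicts, and reports per-sample
#' predictions, confusion counts, and accuracy (percent, half-up rounded
#' to 2 decimals).
#'
#' @param classifier a `module_classifier`.
#' @param profile the cohort [expression_profile()].
#' @param eval_ids sample IDs to evaluate.
#' @param split label for the result (`"train"` or `"test"`).
#' @return list of class `classifier_result` with `split`, `n`, `correct`,
#'   `accuracy`, and a `predictions` data.frame (`sample`, `true`,
#'   `predicted`).
#' @export
evaluate <- function(classifier, profile, eval_ids, split = "test") {
  stopifnot(inherits(classifier, "module_classifier"),
            inherits(profile, "expression_profile"))
  bad <- setdiff(eval_ids, colnames(profile$values))
  if (length(bad) > 0) stop_("unknown sample id(s): %s", paste(bad, collapse = ", "))
  x <- t(profile$values[classifier$features, eval_ids, drop = FALSE])
  xs <- scale(x, center = classifier$center, scale = classifier$scale)
  pred <- as.character(predict(classifier$model, xs))
  truth <- unname(profile$groups[eval_ids])
  n_correct <- sum(pred == truth)
  structure(list(split = split, n = length(eval_ids), correct = n_correct,
                 accuracy = accuracy_from_counts(n_correct, length(eval_ids)),
                 predictions = data.frame(sample = eval_ids, true = truth,
                                          predicted = pred)),
            class = "classifier_result")
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf("%s set: %d of %d samples correctly classified (accuracy %.2f%%)\n",
              x$split, x$correct, x$n, x$accuracy))
  invisible(x)
}

#' Classification accuracy from counts
#'
#' `100 * n_correct / n_total`, rounded half-up to 2 decimals — the
#' convention behind printed accuracies such as 76.19% for 32 of 42.
#'
#' @param n_correct,n_total non-negative counts, `n_correct <= n_total`,
#'   `n_total > 0`.
#' @return Accuracy in percent.
#' @examples
#' accuracy_from_counts(32, 42)  # 76.19
#' accuracy_from_counts(15, 21)  # 71.43
#' @export
accuracy_from_counts <- function(n_correct, n_total) {
  if (n_total <= 0) stop_("n_total must be positive")
  if (n_correct < 0 || n_correct > n_total) stop_("need 0 <= n_correct <= n_total")
  round_half_up(100 * n_correct / n_total, 2L)
}
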