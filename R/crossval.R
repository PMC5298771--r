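# Run an expression with a temporary RNG seed, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Class-stratified k-fold assignment
#'
#' Partitions trials into k disjoint folds preserving the fall/ADL
#' proportion: within each class, trials are shuffled (deterministically
#' for a given seed) and dealt round-robin, so per-fold class counts
#' differ from the perfect proportion by at most one.
#'
#' @param labels Character vector of \code{"fall"}/\code{"adl"} (or any
#'   two or more class labels).
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling the shuffle.
#' @return Integer vector of fold ids in \code{1..k}, one per trial.
#' @export
stratified_kfold <- function(labels, k = 10, seed = 1) {
  stopifnot(k >= 2, k == round(k))
  n <- length(labels)
  counts <- table(labels)
  if (any(counts < k)) {
    stop("every class needs at least k = ", k, " members; got ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  folds <- integer(n)
  with_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

new_evaluation_result <- function(folds_df, policy, feature = NA_character_,
                                  config = list()) {
  summ <- vapply(c("se", "sp", "ac"), function(m) {
    c(mean = mean(folds_df[[m]]), sd = stats::sd(folds_df[[m]]))
  }, numeric(2))
  if (nrow(folds_df) == 1L) summ["sd", ] <- 0
  structure(list(folds = folds_df, mean = summ["mean", ],
                 sd = summ["sd", ], policy = policy, feature = feature,
                 config = config),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> %s%s, %d fold(s)\n", x$policy,
              if (is.na(x$feature)) "" else paste0(" on ", x$feature),
              nrow(x$folds)))
  for (m in c("se", "sp", "ac")) {
    cat(sprintf("  %s = %.4f +/- %.4f\n", toupper(m), x$mean[[m]],
                x$sd[[m]]))
  }
  invisible(x)
}

eval_fold <- function(fit, test_scores, test_labels, fold_id) {
  cc <- confusion_counts(classify(test_scores, fit), test_labels)
  cm <- classifier_metrics(cc)
  data.frame(fold = fold_id, tp = cc[["tp"]], tn = cc[["tn"]],
             fp = cc[["fp"]], fn = cc[["fn"]], se = cm[["se"]],
             sp = cm[["sp"]], ac = cm[["ac"]],
             threshold = fit$threshold, stringsAsFactors = FALSE)
}

#' Stratified k-fold cross-validation of a threshold policy
#'
#' For each fold, fits the threshold (T1 or T2) on the remaining k-1
#' folds and evaluates sensitivity, specificity and accuracy on the
#' held-out fold.
#'
#' @param scores Score data frame (columns \code{score}, \code{label},
#'   optionally \code{feature}) or numeric vector.
#' @param labels Labels when \code{scores} is a vector.
#' @param policy \code{"T1"} or \code{"T2"}.
#' @param k Number of folds (default 10).
#' @param seed Seed for the stratified fold assignment.
#' @param folds Optional precomputed fold ids (overrides \code{k}/
#'   \code{seed}).
#' @return An \code{evaluation_result}: per-fold confusion counts,
#'   SE/SP/AC and thresholds, plus mean and sd across folds.
#' @export
cross_validate <- function(scores, labels = NULL, policy = c("T1", "T2"),
                           k = 10, seed = 1, folds = NULL) {
  policy <- match.arg(policy)
  feature <- NA_character_
  if (is.data.frame(scores)) {
    labels <- scores$label
    if (any(!is.na(scores$feature))) {
      feature <- scores$feature[!is.na(scores$feature)][1]
    }
    scores <- scores$score
  }
  stopifnot(length(scores) == length(labels))
  if (is.null(folds)) folds <- stratified_kfold(labels, k = k, seed = seed)
  fit_fun <- if (policy == "T1") fit_t1 else fit_t2
  rows <- lapply(sort(unique(folds)), function(f) {
    train <- folds != f
    fit <- fit_fun(scores[train], labels[train], feature = feature)
    eval_fold(fit, scores[!train], labels[!train], f)
  })
  new_evaluation_result(do.call(rbind, rows), policy, feature = feature,
                        config = list(k = length(unique(folds)),
                                      seed = seed))
}

#' Train on one set, evaluate on another
#'
#' Single fit of the threshold policy on the training scores, single
#' evaluation on the test scores — the young-trained vs elderly-tested
#' transfer setting.
#'
#' @param train,test Score data frames (columns \code{score},
#'   \code{label}).
#' @param policy \code{"T1"} or \code{"T2"}.
#' @return An \code{evaluation_result} with a single "fold" plus the
#'   fitted model in \code{$model}.
#' @export
transfer_evaluate <- function(train, test, policy = c("T1", "T2")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(train), is.data.frame(test))
  if (nrow(test) == 0L) stop("empty test set")
  feature <- NA_character_
  if (any(!is.na(train$feature))) {
    feature <- train$feature[!is.na(train$feature)][1]
  }
  fit_fun <- if (policy == "T1") fit_t1 else fit_t2
  fit <- fit_fun(train$score, train$label, feature = feature)
  res <- new_evaluation_result(
    eval_fold(fit, test$score, test$label, 1L), policy,
    feature = feature, config = list(transfer = TRUE))
  res$model <- fit
  res
}
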