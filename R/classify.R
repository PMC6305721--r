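#' Balance two groups by down-sampling the larger one
#'
#' For a pairwise comparison the larger group is subsampled without
#' replacement to the size of the smaller, so the classifier never sees an
#' uneven class design.
#'
#' @param labels named factor of group memberships.
#' @param comparison character vector of the two group names.
#' @param seed integer seed (selection is deterministic given it).
#' @param min_size smallest admissible group; below it an 80/20 split with
#'   10-fold cross-validation is not meaningful.
#' @return character vector of selected sample ids.
#' @export
balance_groups <- function(labels, comparison, seed = 1L, min_size = 10L) {
  stopifnot(length(comparison) == 2)
  a <- names(labels)[labels == comparison[1]]
  b <- names(labels)[labels == comparison[2]]
  if (length(a) < min_size || length(b) < min_size)
    stop("both groups need at least ", min_size, " samples")
  m <- min(length(a), length(b))
  local_seed(seed, {
    c(sample(a, m), sample(b, m))
  })
}

#' Area under the ROC curve by the rank (Mann-Whitney) formulation
#'
#' `AUC = P(score+ > score-) + 0.5 P(tie)`, computed from midranks.
#'
#' @param scores numeric classifier scores, higher meaning more positive.
#' @param positive logical (or 0/1) vector marking the positive class.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_score(c(0.9, 0.8, 0.7, 0.85), c(TRUE, TRUE, FALSE, FALSE))  # 0.75
#' @export
auc_score <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)                             # midranks handle ties
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated random-forest evaluation of group separability
#'
#' Per repeat: a stratified 80/20 train/test split; the forest's `mtry` is
#' tuned by k-fold cross-validation on the training samples; a final forest
#' (500 trees by default) is fitted on the full training set and scored on
#' the held-out test samples. The accuracy distribution over all repeats is
#' returned together with the AUC of a representative repeat (the one whose
#' accuracy attains the median, lowest repeat index on ties) computed from
#' its held-out class probabilities.
#'
#' @param features samples x features numeric matrix.
#' @param labels named factor with exactly two levels over the rows of
#'   `features` (use [balance_groups()] first).
#' @param n_repeats number of independent split/train/test repeats.
#' @param split training fraction.
#' @param cv_folds folds for `mtry` tuning.
#' @param num_trees trees per forest.
#' @param seed master seed; the whole evaluation is reproducible given it.
#' @return list of class `classifier_report`: `comparison`, `accuracies`,
#'   `mean_accuracy`, `accuracy_range`, `auc`, `mtry_chosen`, `seed`.
#' @export
rf_evaluate <- function(features, labels, n_repeats = 50, split = 0.8,
                        cv_folds = 10, num_trees = 500, seed = 1L) {
  features <- as.matrix(features)
  g <- droplevels(factor(labels[rownames(features)]))
  if (anyNA(g)) stop("labels missing for some samples")
  if (nlevels(g) != 2) stop("labels must have exactly two levels")
  if (ncol(features) < 2) stop("need at least 2 features")
  p <- ncol(features)
  mtry_grid <- sort(unique(pmax(1L, pmin(p, floor(c(0.5, 1, 2) * sqrt(p))))))
  pos <- levels(g)[2]
  local_seed(seed, {
    acc <- numeric(n_repeats)
    mtry_used <- integer(n_repeats)
    probs <- vector("list", n_repeats)
    truth <- vector("list", n_repeats)
    for (r in seq_len(n_repeats)) {
      tr <- unlist(lapply(levels(g), function(cl) {
        i <- which(g == cl)
        sample(i, max(1L, round(split * length(i))))
      }))
      te <- setdiff(seq_along(g), tr)
      if (length(unique(g[tr])) < 2 || length(te) == 0)
        stop("degenerate train/test split")
      mtry <- tune_mtry(features[tr, , drop = FALSE], g[tr], mtry_grid,
                        cv_folds, num_trees)
      fit <- ranger::ranger(x = features[tr, , drop = FALSE], y = g[tr],
                            num.trees = num_trees, mtry = mtry,
                            probability = TRUE,
                            seed = sample.int(.Machine$integer.max, 1),
                            num.threads = 1)
      pr <- stats::predict(fit, data = features[te, , drop = FALSE],
                           num.threads = 1)$predictions[, pos]
      pred <- ifelse(pr >= 0.5, pos, levels(g)[1])
      acc[r] <- mean(pred == g[te])
      mtry_used[r] <- mtry
      probs[[r]] <- pr
      truth[[r]] <- g[te] == pos
    }
    rep_i <- which(acc == stats::median(acc))[1]
    if (is.na(rep_i))                            # even n: closest to median
      rep_i <- which.min(abs(acc - stats::median(acc)))
    auc <- auc_score(probs[[rep_i]], truth[[rep_i]])
    structure(list(comparison = levels(g),
                   accuracies = acc,
                   mean_accuracy = mean(acc),
                   accuracy_range = range(acc),
                   auc = auc,
                   mtry_chosen = mtry_used,
                   seed = seed),
              class = "classifier_report")
  })
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("random-forest report %s vs %s: mean accuracy %.3f (range %.3f-%.3f over %d repeats), AUC %.3f\n",
              x$comparison[1], x$comparison[2], x$mean_accuracy,
              x$accuracy_range[1], x$accuracy_range[2],
              length(x$accuracies), x$auc))
  invisible(x)
}

# k-fold CV accuracy per candidate mtry; first best wins
tune_mtry <- function(x, y, grid, folds, num_trees) {
  if (length(grid) == 1) return(grid)
  n <- nrow(x)
  fold <- rep_len(seq_len(folds), n)[sample.int(n)]
  cv <- vapply(grid, function(m) {
    hits <- 0
    for (f in unique(fold)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2) stop("single-class training fold")
      fit <- ranger::ranger(x = x[tr, , drop = FALSE], y = y[tr],
                            num.trees = num_trees, mtry = m,
                            seed = sample.int(.Machine$integer.max, 1),
                            num.threads = 1)
      pred <- stats::predict(fit, data = x[!tr, , drop = FALSE],
                             num.threads = 1)$predictions
      hits <- hits + sum(pred == y[!tr])
    }
    hits / n
  }, 0)
  grid[which.max(cv)]
}
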