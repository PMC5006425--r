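#' Dichotomize survival months at the cohort median
#'
#' Cases with survival strictly above the median, or exactly at it, are
#' labelled long (1); the rest short (0). With an even number of distinct
#' values this yields an exact half/half split.
#'
#' @param values survival months, one per case (n >= 4).
#' @param endpoint label for the endpoint, `"pfs"` or `"os"`.
#' @return An `outcome_labels` list: `labels` (1 = long), `threshold` (the
#'   median), `endpoint`.
#' @export
dichotomize <- function(values, endpoint = c("pfs", "os")) {
  endpoint <- match.arg(endpoint)
  if (length(values) < 4L) stop("need at least 4 cases to dichotomize")
  if (length(unique(values)) == 1L) {
    stop("all survival values are identical; median split is degenerate")
  }
  med <- stats::median(values)
  structure(list(labels = as.integer(values >= med), threshold = med,
                 endpoint = endpoint),
            class = "outcome_labels")
}

# column-wise z-scoring with training-set parameters; constant columns are
# mapped to 0 so they degrade to intercept-only behaviour
.zscore_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

.zscore_apply <- function(x, zs) {
  sweep(sweep(x, 2L, zs$center, "-"), 2L, zs$scale, "/")
}

#' Fit a logistic regression scorer
#'
#' Standardizes the feature columns (z-score with training parameters), fits
#' a binomial GLM, and returns a scoring function mapping new feature rows to
#' probabilities of the positive (long survival) class. Aliased coefficients
#' are treated as zero; separation warnings are suppressed (scores saturate
#' at 0/1, which is the intended behaviour for a scorer).
#'
#' @param features numeric matrix, n cases x k features.
#' @param labels binary vector (1 = long); both classes must be present.
#' @return A function `f(newx) -> probabilities`; the fitted coefficients
#'   and standardization parameters are attached as attributes
#'   `coefficients`, `center`, `scale`.
#' @export
fit_logistic <- function(features, labels) {
  features <- as.matrix(features)
  if (length(unique(labels)) < 2L) {
    stop("both outcome classes must be present to fit the classifier")
  }
  if (nrow(features) != length(labels)) stop("features/labels length mismatch")
  zs <- .zscore_fit(features)
  xz <- .zscore_apply(features, zs)
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, xz), labels, family = stats::binomial()))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  scorer <- function(newx) {
    newx <- matrix(as.numeric(newx), ncol = length(zs$center))
    eta <- cbind(1, .zscore_apply(newx, zs)) %*% beta
    as.numeric(stats::plogis(eta))
  }
  attr(scorer, "coefficients") <- beta
  attr(scorer, "center") <- zs$center
  attr(scorer, "scale") <- zs$scale
  scorer
}

# criterion used by SFFS: resubstitution AUC of the logistic scorer on the
# training data
.resub_auc <- function(features, labels, subset) {
  scorer <- fit_logistic(features[, subset, drop = FALSE], labels)
  scores <- scorer(features[, subset, drop = FALSE])
  empirical_auc(scores, labels, conf = FALSE)$auc
}

#' Sequential floating forward feature selection (SFFS)
#'
#' Greedy forward selection with conditional backward steps: at each round
#' the feature whose addition maximizes the criterion joins the subset, then
#' features are removed as long as removal improves on the best criterion
#' value recorded for the smaller subset size. Search stops at `max_subset`;
#' the best subset encountered (highest criterion, ties to the smaller and
#' earlier subset) is returned. Criterion ties between features are broken
#' by the lower feature index, making the procedure deterministic.
#'
#' @param features numeric matrix, n x k.
#' @param labels binary outcome vector (1 = long).
#' @param max_subset maximum subset size to explore (<= k).
#' @param criterion function `(features, labels, subset) -> numeric` to
#'   maximize; default is the resubstitution AUC of [fit_logistic()] on the
#'   training data.
#' @return Integer vector of selected feature indices (sorted).
#' @export
sffs_select <- function(features, labels, max_subset = 4L, criterion = .resub_auc) {
  features <- as.matrix(features)
  k <- ncol(features)
  stopifnot(k >= 1L)
  max_subset <- min(as.integer(max_subset), k)
  eps <- 1e-10

  best_by_size <- vector("list", max_subset)   # best subset seen per size
  best_J <- rep(-Inf, max_subset)
  subset <- integer(0)
  J_cur <- -Inf
  record <- function(s, J) {
    sz <- length(s)
    if (sz >= 1L && sz <= max_subset && J > best_J[sz] + eps) {
      best_J[sz] <<- J
      best_by_size[[sz]] <<- s
    }
  }
  while (length(subset) < max_subset) {
    cand <- setdiff(seq_len(k), subset)
    Js <- vapply(cand, function(j) criterion(features, labels, c(subset, j)), 0)
    j_add <- cand[which.max(Js)]   # which.max takes the first (lowest index) tie
    subset <- sort(c(subset, j_add))
    J_cur <- criterion(features, labels, subset)
    record(subset, J_cur)
    # floating backward: drop features while that beats the best smaller subset
    while (length(subset) > 2L) {
      Js_rm <- vapply(subset, function(j) {
        criterion(features, labels, setdiff(subset, j))
      }, 0)
      best_rm <- which.max(Js_rm)
      if (Js_rm[best_rm] > best_J[length(subset) - 1L] + eps) {
        subset <- setdiff(subset, subset[best_rm])
        J_cur <- Js_rm[best_rm]
        record(subset, J_cur)
      } else {
        break
      }
    }
  }
  sizes_ok <- which(is.finite(best_J))
  best_size <- sizes_ok[which.max(best_J[sizes_ok])]
  sort(best_by_size[[best_size]])
}

#' Empirical ROC AUC with bootstrap confidence interval
#'
#' The AUC is the Mann-Whitney concordance statistic (ties count one half),
#' computed from midranks. The 95% CI comes from a class-stratified
#' case-level percentile bootstrap.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (1 = positive); both classes required.
#' @param conf compute the bootstrap CI.
#' @param n_boot bootstrap resamples.
#' @param seed optional RNG seed for the bootstrap.
#' @return List with `auc` and (when `conf`) `ci`, the percentile 95% CI.
#' @export
empirical_auc <- function(scores, labels, conf = TRUE, n_boot = 2000L,
                          seed = NULL) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present to compute AUC")
  mw_auc <- function(s, l) {
    r <- rank(s, ties.method = "average")
    n1 <- sum(l == 1L); n0 <- sum(l == 0L)
    (sum(r[l == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  auc <- mw_auc(scores, labels)
  if (!conf) return(list(auc = auc))
  if (!is.null(seed)) set.seed(seed)
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  boot <- vapply(seq_len(n_boot), function(i) {
    idx <- c(sample(pos, n1, replace = TRUE), sample(neg, n0, replace = TRUE))
    mw_auc(scores[idx], labels[idx])
  }, 0)
  list(auc = auc,
       ci = unname(stats::quantile(boot, c(0.025, 0.975), type = 7)))
}

#' Exact binomial-null tail probability of a classification accuracy
#'
#' Probability of observing at least `n_correct` correct predictions out of
#' `n_total` under a Binomial(`n_total`, `chance`) null (random guessing),
#' by exact summation of the binomial mass over the upper tail.
#'
#' @param n_correct observed number of correct predictions.
#' @param n_total number of predictions.
#' @param chance null accuracy, in (0, 1); 0.5 for a balanced two-class task.
#' @return One-sided upper-tail probability P(X >= n_correct).
#' @export
binomial_null_pvalue <- function(n_correct, n_total, chance = 0.5) {
  if (chance <= 0 || chance >= 1) stop("`chance` must lie in (0, 1)")
  if (n_correct < 0 || n_correct > n_total) {
    stop("`n_correct` must lie in 0..n_total")
  }
  if (n_correct == 0) return(1)
  sum(stats::dbinom(seq.int(n_correct, n_total), n_total, chance))
}

#' Build a 2x2 confusion matrix (long = positive class)
#'
#' @param long_long,long_short true-long cases predicted long/short.
#' @param short_long,short_short true-short cases predicted long/short.
#' @return A 2x2 integer matrix, rows = truth (long, short), columns =
#'   prediction (long, short).
#' @export
confusion_matrix <- function(long_long, long_short, short_long, short_short) {
  counts <- c(long_long, long_short, short_long, short_short)
  if (any(counts < 0)) stop("confusion counts must be >= 0")
  matrix(as.integer(counts), 2L, 2L, byrow = TRUE,
         dimnames = list(truth = c("long", "short"),
                         predicted = c("long", "short")))
}

#' Accuracy and predictive values of a confusion matrix
#'
#' Long survival is the positive class: PPV = TP/(TP+FP) over cases
#' predicted long, NPV = TN/(TN+FN) over cases predicted short. A predictive
#' value whose predicted class is empty is returned as `NA`.
#'
#' @param confusion 2x2 matrix from [confusion_matrix()] (rows truth,
#'   columns prediction, long first).
#' @return List with `accuracy`, `ppv`, `npv` (fractions).
#' @export
confusion_metrics <- function(confusion) {
  stopifnot(is.matrix(confusion), all(dim(confusion) == 2L))
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix")
  tp <- confusion[1L, 1L]; fn <- confusion[1L, 2L]
  fp <- confusion[2L, 1L]; tn <- confusion[2L, 2L]
  list(accuracy = (tp + tn) / total,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Relative improvement of one accuracy over a reference
#'
#' @param acc_new,acc_ref accuracies as fractions; `acc_ref > 0`.
#' @return Percent change `100 * (acc_new - acc_ref) / acc_ref`.
#' @export
relative_improvement <- function(acc_new, acc_ref) {
  if (acc_ref <= 0) stop("reference accuracy must be > 0")
  100 * (acc_new - acc_ref) / acc_ref
}

#' Pearson correlation between automated and manual measurements
#'
#' @param auto,manual numeric vectors of equal length (n >= 3), neither
#'   constant.
#' @return Pearson product-moment correlation coefficient.
#' @export
pearson_correlation <- function(auto, manual) {
  if (length(auto) != length(manual)) stop("vectors must have equal length")
  if (length(auto) < 3L) stop("need at least 3 paired measurements")
  if (stats::sd(auto) == 0 || stats::sd(manual) == 0) {
    stop("correlation undefined for a constant vector")
  }
  stats::cor(auto, manual)
}

#' Leave-one-case-out evaluation of the SFFS + logistic pipeline
#'
#' For each of the n folds, one case is held out; SFFS feature selection,
#' feature standardization and the logistic fit all see only the n-1
#' training cases, and the held-out case is scored by the trained model.
#' Held-out scores are thresholded at 0.5 (long = positive) to form the
#' confusion matrix; the empirical AUC with bootstrap CI and the exact
#' binomial-null p-value of the accuracy are computed from the same scores.
#'
#' @param features numeric matrix or data.frame, n cases x k features.
#' @param labels binary outcome vector (1 = long), or an `outcome_labels`.
#' @param max_subset maximum SFFS subset size.
#' @param seed RNG seed for the bootstrap CI.
#' @param n_boot bootstrap resamples for the AUC CI; 0 skips the CI.
#' @return A `cv_result`: per-case `scores`, `fold_subsets`,
#'   `selection_frequency` (times each feature was selected over the n
#'   folds), `confusion`, `accuracy`, `ppv`, `npv`, `auc`, `auc_ci`,
#'   `p_null`.
#' @export
loco_evaluate <- function(features, labels, max_subset = 4L, seed = 7L,
                          n_boot = 2000L) {
  if (inherits(labels, "outcome_labels")) labels <- labels$labels
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 4L) stop("need at least 4 cases for leave-one-case-out evaluation")
  if (length(labels) != n) stop("features/labels length mismatch")
  k <- ncol(features)
  scores <- numeric(n)
  fold_subsets <- vector("list", n)
  for (i in seq_len(n)) {
    tr_x <- features[-i, , drop = FALSE]
    tr_y <- labels[-i]
    if (length(unique(tr_y)) < 2L) {
      stop("fold ", i, ": training labels contain a single class")
    }
    sel <- sffs_select(tr_x, tr_y, max_subset = max_subset)
    scorer <- fit_logistic(tr_x[, sel, drop = FALSE], tr_y)
    scores[i] <- scorer(features[i, sel, drop = FALSE])
    fold_subsets[[i]] <- sel
  }
  sel_freq <- tabulate(unlist(fold_subsets), nbins = k)
  names(sel_freq) <- colnames(features) %||% paste0("f", seq_len(k))
  pred <- as.integer(scores >= 0.5)
  cm <- confusion_matrix(sum(labels == 1L & pred == 1L),
                         sum(labels == 1L & pred == 0L),
                         sum(labels == 0L & pred == 1L),
                         sum(labels == 0L & pred == 0L))
  metrics <- confusion_metrics(cm)
  roc <- empirical_auc(scores, labels, conf = n_boot > 0, n_boot = n_boot,
                       seed = seed)
  if (n_boot <= 0) roc$ci <- c(NA_real_, NA_real_)
  n_correct <- sum(pred == labels)
  structure(
    list(scores = scores, labels = as.integer(labels),
         fold_subsets = fold_subsets, selection_frequency = sel_freq,
         confusion = cm, accuracy = metrics$accuracy, ppv = metrics$ppv,
         npv = metrics$npv, auc = roc$auc, auc_ci = roc$ci,
         p_null = binomial_null_pvalue(n_correct, n, 0.5)),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  n <- length(x$scores)
  cat("<cv_result> leave-one-case-out over ", n, " cases\n", sep = "")
  cat(sprintf("  accuracy %.3f (p vs chance %.3g), AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$accuracy, x$p_null, x$auc, x$auc_ci[1L], x$auc_ci[2L]))
  cat(sprintf("  PPV %.3f, NPV %.3f\n", x$ppv, x$npv))
  top <- sort(x$selection_frequency, decreasing = TRUE)
  top <- top[top > 0]
  if (length(top) > 0) {
    cat("  selection frequency: ",
        paste(names(top), top, sep = "=", collapse = ", "), "/", n, " folds\n",
        sep = "")
  }
  invisible(x)
}
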