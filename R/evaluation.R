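# Metrics and statistical comparison machinery: rank-based AUC, confusion
# metrics and average precision, DeLong's test for correlated ROC curves
# (structural components), Mann-Whitney strategy comparison, and the
# repeated train/validation re-partitioning evaluation loop.

as_labels01 <- function(labels) {
  if (is.character(labels)) labels <- labels == "methylated"
  y <- as.integer(as.logical(labels))
  if (any(is.na(y))) stopf("labels must be 0/1, logical, or methylated/unmethylated")
  y
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator: the probability that a random
#' positive scores above a random negative, ties counted one half.
#'
#' @param scores Numeric vector.
#' @param labels 0/1, logical, or methylated/unmethylated.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  y <- as_labels01(labels)
  m <- sum(y == 1L)
  n <- sum(y == 0L)
  if (m == 0 || n == 0) stopf("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[y == 1L]) - m * (m + 1) / 2) / (m * n)
}

#' Threshold metrics and average precision
#'
#' Accuracy, precision and recall from the 2x2 confusion matrix at the given
#' threshold (calls are \code{score >= threshold}; precision at zero
#' predicted positives is 0 with a warning). AUPR is the step-wise average
#' precision over all score thresholds.
#'
#' @param scores Numeric vector.
#' @param labels 0/1, logical, or methylated/unmethylated.
#' @param threshold Decision threshold.
#' @return List: acc, precision, recall, aupr.
#' @export
pr_metrics <- function(scores, labels, threshold = 0.5) {
  y <- as_labels01(labels)
  if (!length(y)) stopf("empty input")
  call <- scores >= threshold
  tp <- sum(call & y == 1L); fp <- sum(call & y == 0L)
  fn <- sum(!call & y == 1L); tn <- sum(!call & y == 0L)
  acc <- (tp + tn) / length(y)
  if (tp + fp == 0) {
    warnf("no predicted positives at threshold %.4f; precision set to 0", threshold)
    precision <- 0
  } else {
    precision <- tp / (tp + fp)
  }
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  aupr <- if (sum(y == 1L) > 0 && sum(y == 0L) > 0) {
    average_precision(scores, y)
  } else NA_real_
  list(acc = acc, precision = precision, recall = recall, aupr = aupr)
}

# step-interpolated average precision: sum over descending distinct score
# thresholds of precision * recall increment
average_precision <- function(scores, y) {
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]
  ss <- scores[o]
  tp <- cumsum(ys)
  fp <- cumsum(1 - ys)
  # evaluate only at the last index of each tied score block
  last <- c(ss[-1] != ss[-length(ss)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / sum(y)
  drec <- diff(c(0, rec))
  sum(prec * drec)
}

#' Full evaluation report
#'
#' @param scores,labels Test scores and labels.
#' @param threshold Calibrated decision threshold.
#' @return One-row data.frame: auc, acc, precision, recall, aupr, threshold,
#'   n_pos, n_neg.
#' @export
eval_report <- function(scores, labels, threshold = 0.5) {
  y <- as_labels01(labels)
  pm <- pr_metrics(scores, y, threshold)
  data.frame(auc = roc_auc(scores, y), acc = pm$acc,
             precision = pm$precision, recall = pm$recall, aupr = pm$aupr,
             threshold = threshold, n_pos = sum(y == 1L), n_neg = sum(y == 0L))
}

# midrank-based structural components; X = positive scores, Y = negatives
delong_components <- function(scores, y) {
  pos <- scores[y == 1L]
  neg <- scores[y == 0L]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg))
  r_pos <- rank(pos)
  r_neg <- rank(neg)
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' DeLong's test for two correlated ROC curves
#'
#' Compares the AUCs of two score vectors computed on the same samples using
#' the structural-components estimator of the covariance of paired AUCs;
#' returns the two-sided normal p-value. Identical score vectors (zero
#' variance of the difference) return p = 1 with \code{degenerate = TRUE}.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Shared labels.
#' @return List: auc_a, auc_b, delta, z, p, degenerate.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- as_labels01(labels)
  if (length(scores_a) != length(y) || length(scores_b) != length(y)) {
    stopf("scores and labels must have equal length")
  }
  if (sum(y == 1L) < 2 || sum(y == 0L) < 2) {
    stopf("need at least two samples per class")
  }
  ca <- delong_components(scores_a, y)
  cb <- delong_components(scores_b, y)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / ca$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / ca$n
  delta <- ca$auc - cb$auc
  if (var_delta <= .Machine$double.eps) {
    return(list(auc_a = ca$auc, auc_b = cb$auc, delta = delta,
                z = 0, p = 1, degenerate = TRUE))
  }
  z <- delta / sqrt(var_delta)
  list(auc_a = ca$auc, auc_b = cb$auc, delta = delta, z = z,
       p = 2 * pnorm(-abs(z)), degenerate = FALSE)
}

#' Mann-Whitney comparison of per-round performance between two strategies
#'
#' Two-sided Wilcoxon rank-sum test on per-round AUCs (or any paired groups
#' of performance values): exact for small samples (total n <= 20 without
#' ties), normal approximation with continuity and tie correction otherwise.
#'
#' @param auc_a,auc_b Numeric vectors of per-round values.
#' @return List: U (of group a over b), p.
#' @export
compare_strategies <- function(auc_a, auc_b) {
  if (!length(auc_a) || !length(auc_b)) stopf("both groups must be non-empty")
  exact <- (length(auc_a) + length(auc_b)) <= 20 &&
    !anyDuplicated(c(auc_a, auc_b))
  wt <- suppressWarnings(wilcox.test(auc_a, auc_b, exact = exact,
                                     alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Plan for repeated train/validation re-partitioning
#'
#' @param n_rounds Number of rounds.
#' @param val_fraction Fraction of the pool held out for validation in each
#'   round.
#' @param seed Base seed; round r uses seed + r.
#' @return Object of class \code{bootstrap_plan}.
#' @export
bootstrap_plan <- function(n_rounds = 10L, val_fraction = 0.2, seed = 1L) {
  if (n_rounds < 1) stopf("n_rounds must be >= 1")
  if (val_fraction <= 0 || val_fraction >= 1) stopf("val_fraction must be in (0,1)")
  structure(list(n_rounds = as.integer(n_rounds), val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "bootstrap_plan")
}

#' Repeated re-partitioned training and evaluation
#'
#' Each round re-partitions the training pool into train/validation subsets
#' (seeded shuffle), refits via \code{train_fn} and evaluates on the fixed
#' test set at the round's calibrated threshold. Failing rounds are logged
#' and reported as partial results.
#'
#' @param pool Training-pool \code{sample_windows}.
#' @param test Fixed test \code{sample_windows}.
#' @param plan A \code{\link{bootstrap_plan}}.
#' @param train_fn \code{function(train, val, seed)} returning a fitted
#'   classifier (any object accepted by \code{score_fn}).
#' @param score_fn \code{function(fit, windows)} returning scores; defaults
#'   to \code{predict(fit, windows, ...)$score} with the baseline passed
#'   through \code{...}.
#' @param ... Passed to \code{score_fn}.
#' @return List: \code{rounds} (one eval_report row per successful round),
#'   \code{mean} (column means), \code{failures} (character log).
#' @export
bootstrap_evaluate <- function(pool, test, plan, train_fn,
                               score_fn = function(fit, w, ...) {
                                 predict(fit, w, ...)$score
                               }, ...) {
  stopifnot(inherits(plan, "bootstrap_plan"))
  y_test <- test$meta$label == "methylated"
  rounds <- vector("list", plan$n_rounds)
  failures <- character(0)
  for (r in seq_len(plan$n_rounds)) {
    res <- tryCatch({
      set.seed(plan$seed + r)
      n <- length(pool)
      ord <- sample.int(n)
      n_val <- max(1L, round(plan$val_fraction * n))
      val_idx <- ord[seq_len(n_val)]
      tr_idx <- ord[(n_val + 1L):n]
      fit <- train_fn(pool[tr_idx], pool[val_idx], plan$seed + r)
      scores <- score_fn(fit, test, ...)
      th <- if (!is.null(fit$threshold)) fit$threshold else 0.5
      rep <- eval_report(scores, y_test, th)
      rep$round <- r
      rep
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("round %d: %s", r, conditionMessage(res)))
    } else {
      rounds[[r]] <- res
    }
  }
  rounds <- do.call(rbind, rounds[!vapply(rounds, is.null, logical(1))])
  if (is.null(rounds) || nrow(rounds) == 0) {
    stopf("all rounds failed:\n%s", paste(failures, collapse = "\n"))
  }
  mean_row <- as.data.frame(as.list(colMeans(rounds[, setdiff(names(rounds), "round")])))
  list(rounds = rounds, mean = mean_row, failures = failures)
}
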