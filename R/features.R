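# The nine feature-integration strategies: per-position channel matrices
# combining raw kinetics, baseline-referenced kinetics (difference, ratio,
# raw concatenation of predictions) and one-hot sequence.

STRATEGY_TABLE <- data.frame(
  id = 1:9,
  uses_difference = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
  uses_ratio = c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
  uses_sequence = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
  uses_raw = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
  uses_predicted = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
)

#' Describe a feature-integration strategy
#'
#' Strategies 1-6 combine baseline-referenced kinetics (difference = raw -
#' predicted; ratio = raw / predicted) with or without one-hot sequence.
#' Strategy 7 is the ablation without the baseline model (raw kinetics +
#' sequence); strategies 8 and 9 concatenate raw and predicted kinetics
#' directly, without subtraction or division.
#'
#' @param id Integer 1-9.
#' @return List: id, the feature flags, \code{needs_baseline}, \code{channels}
#'   (ordered channel names) and \code{n_channels}.
#' @export
strategy_info <- function(id) {
  if (!id %in% 1:9) stopf("strategy id must be in 1..9, got %s", id)
  row <- STRATEGY_TABLE[STRATEGY_TABLE$id == id, ]
  channels <- c(
    if (row$uses_difference) c("diff_ipd", "diff_pw"),
    if (row$uses_ratio) c("ratio_ipd", "ratio_pw"),
    if (row$uses_raw) c("raw_ipd", "raw_pw"),
    if (row$uses_predicted) c("pred_ipd", "pred_pw"),
    if (row$uses_sequence) c("A", "C", "G", "T")
  )
  list(id = id,
       uses_difference = row$uses_difference, uses_ratio = row$uses_ratio,
       uses_sequence = row$uses_sequence, uses_raw = row$uses_raw,
       uses_predicted = row$uses_predicted,
       needs_baseline = row$uses_difference || row$uses_ratio || row$uses_predicted,
       channels = channels, n_channels = length(channels))
}

#' Kinetics difference feature
#'
#' Element-wise raw minus predicted kinetics; zero at a perfectly explained
#' unmethylated site.
#'
#' @param raw,predicted Numeric vectors of equal length.
#' @return Numeric vector.
#' @export
kinetics_difference <- function(raw, predicted) {
  if (length(raw) != length(predicted)) stopf("length mismatch")
  if (!all(is.finite(raw)) || !all(is.finite(predicted))) {
    stopf("inputs must be finite")
  }
  raw - predicted
}

#' Kinetics ratio feature
#'
#' Element-wise raw divided by predicted kinetics, with the denominator
#' clamped at \code{eps}. Under mean-scale normalization predictions hover
#' near 1, so the clamp only guards pathological values.
#'
#' @param raw,predicted Numeric vectors of equal length.
#' @param eps Lower clamp for the denominator.
#' @return Numeric vector.
#' @export
kinetics_ratio <- function(raw, predicted, eps = 1e-3) {
  if (length(raw) != length(predicted)) stopf("length mismatch")
  out <- raw / pmax(predicted, eps)
  if (!all(is.finite(out))) stopf("non-finite ratio feature")
  out
}

#' Build the per-position feature block of one window
#'
#' @param window A \code{sample_windows} object of length 1 (or a list with
#'   \code{seq41}, \code{kin_ipd}, \code{kin_pw}).
#' @param baseline_pred List with \code{ipd}, \code{pw} length-21 predicted
#'   baselines for this window, or NULL for strategies that need none.
#' @param strategy Strategy id (1-9) or a \code{\link{strategy_info}} result.
#' @param eps Ratio clamp.
#' @return A \code{21 x C} matrix; column names give the channel layout.
#' @export
build_features <- function(window, baseline_pred = NULL, strategy = 6L,
                           eps = 1e-3) {
  info <- if (is.list(strategy)) strategy else strategy_info(strategy)
  seq41 <- if (inherits(window, "sample_windows")) window$seq41[1] else window$seq41
  raw_ipd <- as.numeric(if (is.matrix(window$kin_ipd)) window$kin_ipd[1, ] else window$kin_ipd)
  raw_pw <- as.numeric(if (is.matrix(window$kin_pw)) window$kin_pw[1, ] else window$kin_pw)
  k <- length(raw_ipd)
  if (info$needs_baseline && is.null(baseline_pred)) {
    stopf("strategy %d requires baseline predictions", info$id)
  }
  pr_ipd <- pr_pw <- NULL
  if (info$needs_baseline) {
    pr_ipd <- as.numeric(if (is.matrix(baseline_pred$ipd)) baseline_pred$ipd[1, ] else baseline_pred$ipd)
    pr_pw <- as.numeric(if (is.matrix(baseline_pred$pw)) baseline_pred$pw[1, ] else baseline_pred$pw)
    if (length(pr_ipd) != k || length(pr_pw) != k) {
      stopf("baseline predictions must have length %d", k)
    }
  }
  cols <- list()
  if (info$uses_difference) {
    cols$diff_ipd <- kinetics_difference(raw_ipd, pr_ipd)
    cols$diff_pw <- kinetics_difference(raw_pw, pr_pw)
  }
  if (info$uses_ratio) {
    cols$ratio_ipd <- kinetics_ratio(raw_ipd, pr_ipd, eps)
    cols$ratio_pw <- kinetics_ratio(raw_pw, pr_pw, eps)
  }
  if (info$uses_raw) {
    cols$raw_ipd <- raw_ipd
    cols$raw_pw <- raw_pw
  }
  if (info$uses_predicted) {
    cols$pred_ipd <- pr_ipd
    cols$pred_pw <- pr_pw
  }
  if (info$uses_sequence) {
    flank <- (nchar(seq41) - k) %/% 2L
    central <- substr(seq41, flank + 1L, flank + k)
    oh <- encode_onehot(central)
    cols$A <- oh[, 1]; cols$C <- oh[, 2]; cols$G <- oh[, 3]; cols$T <- oh[, 4]
  }
  m <- do.call(cbind, cols)
  colnames(m) <- info$channels
  m
}

# batch feature construction: windows (sample_windows), baseline predictions
# (list of n x 21 matrices or NULL) -> [n, 21, C]
build_feature_array <- function(windows, baseline_pred, strategy, eps = 1e-3) {
  info <- if (is.list(strategy)) strategy else strategy_info(strategy)
  n <- length(windows)
  k <- ncol(windows$kin_ipd)
  if (info$needs_baseline && is.null(baseline_pred)) {
    stopf("strategy %d requires baseline predictions", info$id)
  }
  X <- array(0, c(n, k, info$n_channels))
  ci <- 0L
  put <- function(mat) {
    ci <<- ci + 1L
    X[, , ci] <<- mat
  }
  if (info$uses_difference) {
    put(windows$kin_ipd - baseline_pred$ipd)
    put(windows$kin_pw - baseline_pred$pw)
  }
  if (info$uses_ratio) {
    put(windows$kin_ipd / pmax(baseline_pred$ipd, eps))
    put(windows$kin_pw / pmax(baseline_pred$pw, eps))
  }
  if (info$uses_raw) {
    put(windows$kin_ipd)
    put(windows$kin_pw)
  }
  if (info$uses_predicted) {
    put(baseline_pred$ipd)
    put(baseline_pred$pw)
  }
  if (info$uses_sequence) {
    flank <- (nchar(windows$seq41[1]) - k) %/% 2L
    central <- substr(windows$seq41, flank + 1L, flank + k)
    oh <- encode_onehot_batch(central)  # [n, k, 4]
    for (c4 in 1:4) put(oh[, , c4])
  }
  if (!all(is.finite(X))) stopf("non-finite feature values")
  dimnames(X) <- list(NULL, NULL, info$channels)
  X
}

# channel grouping used by the late-fusion classifier: each kinetic feature
# pair is one modality branch, the one-hot sequence another
strategy_branches <- function(info) {
  groups <- list()
  if (info$uses_difference) groups$diff <- c("diff_ipd", "diff_pw")
  if (info$uses_ratio) groups$ratio <- c("ratio_ipd", "ratio_pw")
  if (info$uses_raw) groups$raw <- c("raw_ipd", "raw_pw")
  if (info$uses_predicted) groups$pred <- c("pred_ipd", "pred_pw")
  if (info$uses_sequence) groups$seq <- c("A", "C", "G", "T")
  lapply(groups, function(ch) match(ch, info$channels))
}
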