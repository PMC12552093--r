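# Binary methylation classifier: a BiGRU over the per-position feature block
# with a 2-logit softmax head (early concatenation), or a multi-branch late
# fusion variant with one BiGRU per feature modality merged before the head.
# Trained with focal loss over label-smoothed targets, Adam and a StepLR
# schedule; the decision threshold is calibrated to maximize F1 on a
# validation set.

#' Configuration of the methylation classifier
#'
#' @param architecture \code{"early_concat"} (one BiGRU over the concatenated
#'   feature block; the default, suited to subread-level data) or
#'   \code{"late_fusion"} (one BiGRU per feature modality, final hidden states
#'   concatenated before the head; preferable when predicted signals are
#'   noisy, as on CCS data).
#' @param gru_hidden,gru_layers,dropout BiGRU capacity and regularization.
#' @param lr Adam learning rate.
#' @param step_size,gamma_lr StepLR schedule: the learning rate is multiplied
#'   by \code{gamma_lr} every \code{step_size} epochs.
#' @param focal_gamma Focal-loss focusing parameter.
#' @param label_smoothing Label smoothing factor in \[0, 0.5).
#' @param epochs,batch Training schedule.
#' @param seed Seed for initialization, shuffling and dropout.
#' @return Object of class \code{classifier_config}.
#' @export
classifier_config <- function(architecture = c("early_concat", "late_fusion"),
                              gru_hidden = 32L, gru_layers = 1L, dropout = 0.2,
                              lr = 1e-3, step_size = 10L, gamma_lr = 0.5,
                              focal_gamma = 2, label_smoothing = 0.1,
                              epochs = 30L, batch = 64L, seed = 1L) {
  architecture <- match.arg(architecture)
  if (focal_gamma < 0) stopf("focal_gamma must be >= 0")
  if (label_smoothing < 0 || label_smoothing >= 0.5) {
    stopf("label_smoothing must be in [0, 0.5)")
  }
  if (gamma_lr <= 0 || gamma_lr > 1) stopf("gamma_lr must be in (0, 1]")
  if (lr <= 0) stopf("lr must be > 0")
  if (epochs < 1 || step_size < 1) stopf("epochs and step_size must be >= 1")
  if (dropout < 0 || dropout >= 1) stopf("dropout must be in [0,1)")
  structure(list(architecture = architecture,
                 gru_hidden = as.integer(gru_hidden),
                 gru_layers = as.integer(gru_layers), dropout = dropout,
                 lr = lr, step_size = as.integer(step_size),
                 gamma_lr = gamma_lr, focal_gamma = focal_gamma,
                 label_smoothing = label_smoothing,
                 epochs = as.integer(epochs), batch = as.integer(batch),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Focal loss
#'
#' \code{FL(p_t) = -(1 - p_t)^gamma * log(p_t)} where \code{p_t} is the
#' predicted probability of the true class; the modulating factor
#' down-weights well-classified examples so training focuses on hard ones.
#' \code{gamma = 0} recovers the cross-entropy. Probabilities are clamped at
#' 1e-7 before the log.
#'
#' @param p Numeric vector of true-class probabilities in \[0, 1\].
#' @param gamma Focusing parameter (>= 0).
#' @return Mean focal loss over the batch (scalar >= 0).
#' @export
focal_loss <- function(p, gamma = 2) {
  if (any(p < 0 | p > 1)) stopf("probabilities must lie in [0, 1]")
  if (gamma < 0) stopf("gamma must be >= 0")
  pc <- pmax(p, 1e-7)
  mean(-(1 - pc)^gamma * log(pc))
}

#' Smooth hard labels into two-class soft targets
#'
#' Uniform label smoothing: the true class receives \code{1 - factor +
#' factor/2}, the other \code{factor/2}; rows always sum to 1.
#'
#' @param labels Integer/logical vector (1 or TRUE = methylated).
#' @param factor Smoothing factor in \[0, 0.5).
#' @return \code{n x 2} matrix with columns unmethylated, methylated.
#' @export
smooth_labels <- function(labels, factor = 0.1) {
  if (factor < 0 || factor >= 0.5) stopf("factor must be in [0, 0.5)")
  y <- as.integer(as.logical(labels))
  if (any(is.na(y))) stopf("labels must be 0/1 or logical")
  lo <- factor / 2
  hi <- 1 - factor + factor / 2
  cbind(unmethylated = ifelse(y == 1L, lo, hi),
        methylated = ifelse(y == 1L, hi, lo))
}

#' StepLR learning-rate schedule
#'
#' \code{lr(epoch) = lr0 * gamma^floor(epoch / step_size)} with 0-based
#' epochs: the rate is multiplied by \code{gamma} every \code{step_size}
#' epochs.
#'
#' @param lr0 Initial learning rate.
#' @param epoch 0-based epoch index (vectorized).
#' @param step_size Epochs per decay step.
#' @param gamma Decay factor.
#' @return Learning rate(s).
#' @export
step_lr <- function(lr0, epoch, step_size = 10L, gamma = 0.5) {
  lr0 * gamma^(epoch %/% step_size)
}

# softmax over 2 logits, rows
softmax2 <- function(z) {
  m <- pmax(z[, 1], z[, 2])
  e1 <- exp(z[, 1] - m)
  e2 <- exp(z[, 2] - m)
  s <- e1 + e2
  cbind(e1 / s, e2 / s)
}

# focal loss over smoothed two-class targets: mean_i sum_c T_ic (1-p_ic)^g
# (-log p_ic); returns loss and gradient w.r.t. the logits
focal_smooth_loss <- function(logits, targets, gamma) {
  p <- softmax2(logits)
  pc <- pmax(p, 1e-7)
  per <- -targets * (1 - pc)^gamma * log(pc)
  loss <- sum(per) / nrow(logits)
  # dL/dp_c, then through the softmax Jacobian
  g <- targets * (gamma * (1 - pc)^(gamma - 1) * log(pc) - (1 - pc)^gamma / pc)
  g <- g / nrow(logits)
  gp_sum <- rowSums(g * p)
  dz <- p * (g - gp_sum)
  list(loss = loss, dlogits = dz, p = p)
}

# standardize kinetic channels to zero mean / unit sd (training statistics);
# sequence channels are already on the unit scale
fit_channel_scaler <- function(X, info) {
  kin <- !info$channels %in% c("A", "C", "G", "T")
  center <- numeric(length(info$channels))
  scale <- rep(1, length(info$channels))
  for (c in which(kin)) {
    v <- X[, , c]
    center[c] <- mean(v)
    s <- stats::sd(as.vector(v))
    scale[c] <- if (is.finite(s) && s > 1e-8) s else 1
  }
  list(center = center, scale = scale)
}

apply_channel_scaler <- function(X, scaler) {
  for (c in seq_along(scaler$center)) {
    if (scaler$center[c] != 0 || scaler$scale[c] != 1) {
      X[, , c] <- (X[, , c] - scaler$center[c]) / scaler$scale[c]
    }
  }
  X
}

clf_init <- function(info, cfg) {
  if (cfg$architecture == "early_concat") {
    list(net = nn_bigru_init(info$n_channels, cfg$gru_hidden, cfg$gru_layers),
         head = nn_linear_init(2L * cfg$gru_hidden, 2L))
  } else {
    branches <- strategy_branches(info)
    nets <- lapply(branches, function(ch) {
      nn_bigru_init(length(ch), cfg$gru_hidden, cfg$gru_layers)
    })
    list(nets = nets, branches = branches,
         head = nn_linear_init(2L * cfg$gru_hidden * length(nets), 2L))
  }
}

clf_forward <- function(model, cfg, X, training = FALSE) {
  if (cfg$architecture == "early_concat") {
    fw <- nn_bigru_forward(model$net, X, dropout = cfg$dropout,
                           training = training)
    read <- fw$read
    mask <- NULL
    if (training && cfg$dropout > 0) {
      mask <- matrix(rbinom(length(read), 1L, 1 - cfg$dropout) / (1 - cfg$dropout),
                     nrow(read), ncol(read))
      read <- read * mask
    }
    logits <- nn_linear_forward(model$head, read)
    list(logits = logits, fw = fw, read = read, mask = mask)
  } else {
    fws <- vector("list", length(model$nets))
    reads <- vector("list", length(model$nets))
    for (i in seq_along(model$nets)) {
      Xi <- X[, , model$branches[[i]], drop = FALSE]
      fws[[i]] <- nn_bigru_forward(model$nets[[i]], Xi, dropout = cfg$dropout,
                                   training = training)
      reads[[i]] <- fws[[i]]$read
    }
    read <- do.call(cbind, reads)
    mask <- NULL
    if (training && cfg$dropout > 0) {
      mask <- matrix(rbinom(length(read), 1L, 1 - cfg$dropout) / (1 - cfg$dropout),
                     nrow(read), ncol(read))
      read <- read * mask
    }
    logits <- nn_linear_forward(model$head, read)
    list(logits = logits, fws = fws, read = read, mask = mask)
  }
}

clf_backward <- function(model, cfg, fwd, dlogits, X) {
  hb <- nn_linear_backward(model$head, fwd$read, dlogits)
  dread <- hb$dx
  if (!is.null(fwd$mask)) dread <- dread * fwd$mask
  if (cfg$architecture == "early_concat") {
    gb <- nn_bigru_backward(model$net, fwd$fw, dread)
    list(grads = list(net = gb$layers, head = hb$grads))
  } else {
    H2 <- 2L * cfg$gru_hidden
    gnets <- vector("list", length(model$nets))
    for (i in seq_along(model$nets)) {
      cols <- (i - 1L) * H2 + seq_len(H2)
      gb <- nn_bigru_backward(model$nets[[i]], fwd$fws[[i]],
                              dread[, cols, drop = FALSE])
      gnets[[i]] <- gb$layers
    }
    names(gnets) <- names(model$nets)
    list(grads = list(nets = gnets, head = hb$grads))
  }
}

# score windows with a trained model (probability of methylation)
clf_score <- function(model, cfg, X, chunk = 512L) {
  n <- dim(X)[1]
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    rows <- i:min(i + chunk - 1L, n)
    fwd <- clf_forward(model, cfg, X[rows, , , drop = FALSE])
    out[rows] <- softmax2(fwd$logits)[, 2]
    i <- i + chunk
  }
  out
}

#' Calibrate the decision threshold by maximizing F1
#'
#' Scans candidate thresholds (midpoints of sorted unique scores plus the 0
#' and 1 boundaries; calls are \code{score >= threshold}) and returns the one
#' maximizing F1, breaking ties toward the lowest threshold. Degenerate
#' all-equal scores return threshold 0.5 with a warning.
#'
#' @param scores Numeric vector in \[0, 1\].
#' @param labels 0/1 or logical (1 = methylated).
#' @return List with \code{threshold} and \code{f1}.
#' @export
calibrate_threshold <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  if (length(scores) != length(y) || !length(y)) stopf("bad scores/labels")
  u <- sort(unique(scores))
  if (length(u) == 1L) {
    warnf("degenerate validation scores (all equal); threshold set to 0.5")
    calls <- rep(TRUE, length(y))
    tp <- sum(y)
    f1 <- if (tp == 0) 0 else 2 * tp / (2 * tp + sum(1 - y))
    return(list(threshold = 0.5, f1 = f1))
  }
  cand <- unique(c(0, (u[-1] + u[-length(u)]) / 2, 1))
  f1s <- vapply(cand, function(th) {
    call <- scores >= th
    tp <- sum(call & y == 1L)
    fp <- sum(call & y == 0L)
    fn <- sum(!call & y == 1L)
    if (tp == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  best <- which.max(f1s)  # first maximum = lowest threshold
  list(threshold = cand[best], f1 = f1s[best])
}

#' Fit the methylation classifier
#'
#' Builds the per-window feature block of the chosen integration strategy,
#' trains the BiGRU classifier with focal loss over label-smoothed targets
#' (Adam, StepLR decay) and calibrates the decision threshold on the
#' validation windows.
#'
#' @param train,val \code{sample_windows} with labels methylated /
#'   unmethylated; both classes must be present in each.
#' @param strategy Feature-integration strategy id (1-9).
#' @param baseline A frozen \code{\link{baseline_regressor}} model; required
#'   by every strategy except 7.
#' @param config A \code{\link{classifier_config}}.
#' @param verbose Print per-epoch loss.
#' @return Object of class \code{methyl_classifier}.
#' @export
methylation_classifier <- function(train, val, strategy = 6L, baseline = NULL,
                                   config = classifier_config(),
                                   verbose = FALSE) {
  stopifnot(inherits(config, "classifier_config"))
  info <- strategy_info(strategy)
  if (info$needs_baseline && is.null(baseline)) {
    stopf("strategy %d requires a baseline model (only strategy 7 runs without one)",
          info$id)
  }
  lab_tr <- train$meta$label == "methylated"
  lab_va <- val$meta$label == "methylated"
  if (!any(lab_tr) || all(lab_tr)) stopf("training windows must contain both classes")
  if (!any(lab_va) || all(lab_va)) stopf("validation windows must contain both classes")

  bp_tr <- if (info$needs_baseline) predict(baseline, train$seq41) else NULL
  bp_va <- if (info$needs_baseline) predict(baseline, val$seq41) else NULL
  Xtr <- build_feature_array(train, bp_tr, info)
  Xva <- build_feature_array(val, bp_va, info)
  # per-channel affine standardization of the kinetic channels, fitted on the
  # training windows (one-hot channels are left untouched); puts the small
  # baseline-relative variations on the scale the optimizer expects
  scaler <- fit_channel_scaler(Xtr, info)
  Xtr <- apply_channel_scaler(Xtr, scaler)
  Xva <- apply_channel_scaler(Xva, scaler)
  Ttr <- smooth_labels(lab_tr, config$label_smoothing)

  set.seed(config$seed)
  model <- clf_init(info, config)
  clf_params <- function(m) {
    if (config$architecture == "early_concat") {
      list(net = m$net$layers, head = m$head)
    } else {
      list(nets = lapply(m$nets, `[[`, "layers"), head = m$head)
    }
  }
  clf_set_params <- function(m, p) {
    if (config$architecture == "early_concat") {
      m$net$layers <- p$net
    } else {
      for (i in seq_along(m$nets)) m$nets[[i]]$layers <- p$nets[[i]]
    }
    m$head <- p$head
    m
  }
  st <- nn_adam_init(clf_params(model))
  n <- length(train)
  nb <- ceiling(n / config$batch)
  loss_trace <- numeric(config$epochs)
  lr_trace <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    lr_e <- step_lr(config$lr, epoch - 1L, config$step_size, config$gamma_lr)
    lr_trace[epoch] <- lr_e
    ord <- sample.int(n)
    ep_loss <- 0
    for (b in seq_len(nb)) {
      rows <- ord[((b - 1L) * config$batch + 1L):min(b * config$batch, n)]
      fwd <- clf_forward(model, config, Xtr[rows, , , drop = FALSE],
                         training = TRUE)
      fl <- focal_smooth_loss(fwd$logits, Ttr[rows, , drop = FALSE],
                              config$focal_gamma)
      if (!is.finite(fl$loss)) {
        stopf("classifier training diverged (non-finite loss) at epoch %d", epoch)
      }
      ep_loss <- ep_loss + fl$loss * length(rows)
      bk <- clf_backward(model, config, fwd, fl$dlogits, NULL)
      up <- nn_adam_step(clf_params(model), bk$grads, st, lr_e)
      st <- up$state
      model <- clf_set_params(model, up$params)
    }
    loss_trace[epoch] <- ep_loss / n
    if (verbose) message(sprintf("epoch %d/%d  lr %.2e  focal loss %.5f",
                                 epoch, config$epochs, lr_e, loss_trace[epoch]))
  }
  val_scores <- clf_score(model, config, Xva)
  cal <- calibrate_threshold(val_scores, lab_va)
  structure(list(model = model, config = config, strategy = info,
                 scaler = scaler,
                 threshold = cal$threshold, val_f1 = cal$f1,
                 loss_trace = loss_trace, lr_trace = lr_trace,
                 baseline_fingerprint = if (is.null(baseline)) NA_character_ else
                   model_fingerprint(baseline)),
            class = "methyl_classifier")
}

# cheap structural fingerprint used to tie a classifier to its baseline
model_fingerprint <- function(model) {
  v <- nn_param_vec(list(model$net$layers, model$head_ipd, model$head_pw))
  sprintf("%d:%.10e:%.10e", length(v), sum(v), sum(v^2))
}

#' @export
print.methyl_classifier <- function(x, ...) {
  cat(sprintf("Methylation classifier: strategy %d (%s), %s BiGRU %dx%d\n",
              x$strategy$id, paste(x$strategy$channels, collapse = ","),
              x$config$architecture, x$config$gru_hidden, x$config$gru_layers))
  cat(sprintf("  calibrated threshold %.4f (validation F1 %.4f)\n",
              x$threshold, x$val_f1))
  invisible(x)
}

#' @export
summary.methyl_classifier <- function(object, ...) {
  out <- list(strategy = object$strategy$id,
              architecture = object$config$architecture,
              channels = object$strategy$channels,
              threshold = object$threshold, val_f1 = object$val_f1,
              final_loss = tail(object$loss_trace, 1),
              epochs = object$config$epochs)
  class(out) <- "summary.methyl_classifier"
  out
}

#' @export
print.summary.methyl_classifier <- function(x, ...) {
  cat(sprintf("Strategy %d (%s), %d epochs, final focal loss %.5f\n",
              x$strategy, x$architecture, x$epochs, x$final_loss))
  cat(sprintf("  channels: %s\n", paste(x$channels, collapse = ", ")))
  cat(sprintf("  threshold %.4f, validation F1 %.4f\n", x$threshold, x$val_f1))
  invisible(x)
}

#' Score and call methylation on sample windows
#'
#' @param object A trained \code{methyl_classifier}.
#' @param windows A \code{sample_windows} object.
#' @param baseline The frozen baseline model (required unless strategy 7).
#' @param ... Unused.
#' @return Data.frame: contig, pos, strand, score, call (score >= calibrated
#'   threshold), threshold. Deterministic for fixed inputs.
#' @export
predict.methyl_classifier <- function(object, windows, baseline = NULL, ...) {
  info <- object$strategy
  if (info$needs_baseline && is.null(baseline)) {
    stopf("strategy %d requires the baseline model at prediction time", info$id)
  }
  if (info$needs_baseline &&
      !identical(model_fingerprint(baseline), object$baseline_fingerprint)) {
    warnf("baseline model fingerprint differs from the one used in training")
  }
  keep <- rowSums(is.na(windows$kin_ipd)) == 0 &
    rowSums(is.na(windows$kin_pw)) == 0
  if (any(!keep)) {
    message(sprintf("skipping %d window(s) with missing kinetics", sum(!keep)))
    windows <- windows[keep]
  }
  bp <- if (info$needs_baseline) predict(baseline, windows$seq41) else NULL
  X <- build_feature_array(windows, bp, info)
  X <- apply_channel_scaler(X, object$scaler)
  scores <- clf_score(object$model, object$config, X)
  data.frame(windows$meta[, c("contig", "pos", "strand")],
             score = scores, call = scores >= object$threshold,
             threshold = object$threshold,
             stringsAsFactors = FALSE)
}
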