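# Unmethylated-signal model: a BiGRU encoder over a 21-bp one-hot window with
# two independent linear heads predicting the center base's normalized IPD
# and PW. Trained with MSE on WGA (methylation-free) samples, then frozen and
# used as the kinetic baseline inside the classifier. Interpreted with
# integrated gradients.

#' One-hot encode a DNA sequence
#'
#' A, C, G, T map to unit vectors in that fixed column order; N maps to an
#' all-zeros row. Any other character is an error.
#'
#' @param seq A single DNA string.
#' @return An \code{nchar(seq) x 4} matrix with columns A, C, G, T.
#' @export
encode_onehot <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(chars), c(DNA_BASES, "N"))
  if (length(bad)) stopf("invalid base(s) in sequence: %s", paste(bad, collapse = ", "))
  m <- matrix(0, length(chars), 4, dimnames = list(NULL, DNA_BASES))
  hit <- match(chars, DNA_BASES)
  ok <- !is.na(hit)
  m[cbind(which(ok), hit[ok])] <- 1
  m
}

# batch encoder: character vector of equal-width sequences -> [B, T, 4]
encode_onehot_batch <- function(seqs) {
  Tn <- nchar(seqs[1])
  if (any(nchar(seqs) != Tn)) stopf("sequences must have equal width")
  B <- length(seqs)
  chars <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE), nrow = B, byrow = TRUE)
  bad <- setdiff(unique(as.vector(chars)), c(DNA_BASES, "N"))
  if (length(bad)) stopf("invalid base(s) in sequence: %s", paste(bad, collapse = ", "))
  X <- array(0, c(B, Tn, 4))
  hit <- match(chars, DNA_BASES)  # vector over B*T, column-major (b fastest)
  ok <- which(!is.na(hit))
  # linear index into [B, T, 4]: b + (t-1)*B + (c-1)*B*T; chars index = b + (t-1)*B
  X[ok + (hit[ok] - 1L) * B * Tn] <- 1
  X
}

#' Configuration of the baseline kinetic regressor
#'
#' @param window Sequence window width (odd; the model predicts the kinetics
#'   of the central base).
#' @param gru_hidden Hidden units per GRU direction.
#' @param gru_layers Stacked BiGRU layers.
#' @param dropout Dropout fraction (between stacked layers and on the
#'   readout) during training.
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param batch Minibatch size.
#' @param weight_decay Decoupled (AdamW-style) weight decay on the weight
#'   matrices; shrinks weights on uninformative input positions, which keeps
#'   attribution analyses clean.
#' @param min_samples Minimum number of WGA training samples required.
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @return Object of class \code{regressor_config}.
#' @export
regressor_config <- function(window = 21L, gru_hidden = 64L, gru_layers = 2L,
                             dropout = 0.2, epochs = 50L, lr = 1e-3,
                             batch = 64L, weight_decay = 1e-3,
                             min_samples = 200L, seed = 1L) {
  if (window %% 2 != 1 || window < 3) stopf("window must be odd and >= 3")
  if (lr <= 0) stopf("lr must be > 0")
  if (epochs < 1) stopf("epochs must be >= 1")
  if (dropout < 0 || dropout >= 1) stopf("dropout must be in [0,1)")
  if (gru_hidden < 1 || gru_layers < 1) stopf("gru_hidden and gru_layers must be >= 1")
  if (weight_decay < 0) stopf("weight_decay must be >= 0")
  structure(list(window = as.integer(window), onehot_dim = 4L,
                 gru_hidden = as.integer(gru_hidden),
                 gru_layers = as.integer(gru_layers),
                 dropout = dropout, epochs = as.integer(epochs), lr = lr,
                 batch = as.integer(batch), weight_decay = weight_decay,
                 min_samples = as.integer(min_samples),
                 seed = as.integer(seed)),
            class = "regressor_config")
}

# forward through net + both heads; returns list(pred [B,2], fw)
baseline_forward <- function(net, head_ipd, head_pw, X, dropout = 0,
                             training = FALSE) {
  fw <- nn_bigru_forward(net, X, dropout = dropout, training = training)
  read <- fw$read
  mask <- NULL
  if (training && dropout > 0) {
    mask <- matrix(rbinom(length(read), 1L, 1 - dropout) / (1 - dropout),
                   nrow(read), ncol(read))
    read <- read * mask
  }
  pred <- cbind(nn_linear_forward(head_ipd, read),
                nn_linear_forward(head_pw, read))
  list(pred = pred, fw = fw, read = read, mask = mask)
}

#' Fit the unmethylated kinetic baseline regressor
#'
#' Trains a bidirectional GRU encoder with two independent linear heads (IPD
#' and PW) on WGA-derived windows, minimizing mean squared error with Adam.
#' The returned model is frozen: predictions are deterministic and the
#' classifier never updates it.
#'
#' @param seq Character vector of window-width sequences (one per sample).
#' @param ipd,pw Numeric targets: normalized, subread-averaged center-base
#'   kinetics.
#' @param config A \code{\link{regressor_config}}.
#' @param verbose Print per-epoch loss.
#' @return Object of class \code{baseline_model}.
#' @export
baseline_regressor <- function(seq, ipd, pw, config = regressor_config(),
                               verbose = FALSE) {
  stopifnot(inherits(config, "regressor_config"))
  n <- length(seq)
  if (length(ipd) != n || length(pw) != n) {
    stopf("seq, ipd and pw must have equal length")
  }
  if (n < config$min_samples) {
    stopf("need at least %d WGA samples to fit the baseline, got %d",
          config$min_samples, n)
  }
  if (any(nchar(seq) != config$window)) {
    stopf("all sequences must have width %d", config$window)
  }
  set.seed(config$seed)
  X <- encode_onehot_batch(seq)
  Y <- cbind(ipd, pw)
  net <- nn_bigru_init(4L, config$gru_hidden, config$gru_layers)
  head_ipd <- nn_linear_init(2L * config$gru_hidden, 1L)
  head_pw <- nn_linear_init(2L * config$gru_hidden, 1L)
  params <- list(net = net$layers, hi = head_ipd, hp = head_pw)
  st <- nn_adam_init(params)
  loss_trace <- numeric(config$epochs)
  nb <- ceiling(n / config$batch)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (b in seq_len(nb)) {
      rows <- ord[((b - 1L) * config$batch + 1L):min(b * config$batch, n)]
      Xb <- X[rows, , , drop = FALSE]
      Yb <- Y[rows, , drop = FALSE]
      fwd <- baseline_forward(net, head_ipd, head_pw, Xb,
                              dropout = config$dropout, training = TRUE)
      err <- fwd$pred - Yb
      loss <- mean(err^2)
      if (!is.finite(loss)) {
        stopf("training diverged (non-finite MSE) at epoch %d, batch %d; lower lr or check targets",
              epoch, b)
      }
      ep_loss <- ep_loss + loss * length(rows)
      dpred <- 2 * err / length(err)
      gi <- nn_linear_backward(head_ipd, fwd$read, dpred[, 1, drop = FALSE])
      gp <- nn_linear_backward(head_pw, fwd$read, dpred[, 2, drop = FALSE])
      dread <- gi$dx + gp$dx
      if (!is.null(fwd$mask)) dread <- dread * fwd$mask
      gb <- nn_bigru_backward(net, fwd$fw, dread)
      up <- nn_adam_step(params,
                         list(net = gb$layers, hi = gi$grads, hp = gp$grads),
                         st, config$lr, weight_decay = config$weight_decay)
      st <- up$state
      params <- up$params
      net$layers <- params$net
      head_ipd <- params$hi
      head_pw <- params$hp
    }
    loss_trace[epoch] <- ep_loss / n
    if (verbose) message(sprintf("epoch %d/%d  mse %.5f", epoch, config$epochs,
                                 loss_trace[epoch]))
  }
  structure(list(net = net, head_ipd = head_ipd, head_pw = head_pw,
                 config = config, loss_trace = loss_trace,
                 n_train = n, frozen = TRUE),
            class = "baseline_model")
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("Baseline kinetic regressor (frozen): BiGRU %d x %d over %d-bp windows\n",
              x$config$gru_hidden, x$config$gru_layers, x$config$window))
  cat(sprintf("  trained on %d WGA samples, %d epochs, final MSE %.5f\n",
              x$n_train, x$config$epochs, tail(x$loss_trace, 1)))
  invisible(x)
}

#' @export
summary.baseline_model <- function(object, ...) {
  npar <- length(nn_param_vec(list(object$net$layers, object$head_ipd,
                                   object$head_pw)))
  out <- list(config = object$config, n_train = object$n_train,
              n_parameters = npar,
              initial_mse = object$loss_trace[1],
              final_mse = tail(object$loss_trace, 1),
              loss_trace = object$loss_trace)
  class(out) <- "summary.baseline_model"
  out
}

#' @export
print.summary.baseline_model <- function(x, ...) {
  cat(sprintf("Baseline regressor: %d parameters, %d training samples\n",
              x$n_parameters, x$n_train))
  cat(sprintf("  MSE %.5f -> %.5f over %d epochs\n", x$initial_mse,
              x$final_mse, length(x$loss_trace)))
  invisible(x)
}

#' @export
coef.baseline_model <- function(object, ...) {
  list(head_ipd = object$head_ipd, head_pw = object$head_pw)
}

# chunked center-base prediction for window-width sequences; returns [n, 2]
baseline_predict_center <- function(model, seqs, chunk = 2048L) {
  n <- length(seqs)
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("ipd", "pw")))
  has_n <- grepl("N", seqs, fixed = TRUE)
  todo <- which(!has_n)
  i <- 1L
  while (i <= length(todo)) {
    rows <- todo[i:min(i + chunk - 1L, length(todo))]
    X <- encode_onehot_batch(seqs[rows])
    fwd <- baseline_forward(model$net, model$head_ipd, model$head_pw, X)
    out[rows, ] <- fwd$pred
    i <- i + chunk
  }
  out
}

#' Predict baseline kinetics
#'
#' For window-width (21-bp) input the center-base (IPD, PW) prediction is
#' returned. For 41-bp input the model slides over the 21 sub-windows so the
#' output aligns with the central 21 bases (the classifier's kinetic span).
#' Sub-windows containing N yield NA.
#'
#' @param object A \code{baseline_model}.
#' @param newdata Character vector of 21-bp or 41-bp sequences.
#' @param ... Unused.
#' @return For 21-bp input an \code{n x 2} matrix (ipd, pw); for 41-bp input
#'   a list with \code{ipd} and \code{pw}, each \code{n x 21}.
#' @export
predict.baseline_model <- function(object, newdata, ...) {
  w <- object$config$window
  widths <- unique(nchar(newdata))
  if (length(widths) != 1) stopf("all sequences must have equal width")
  if (widths == w) {
    return(baseline_predict_center(object, newdata))
  }
  if (widths != 2L * w - 1L) {
    stopf("sequences must have width %d or %d, got %d", w, 2L * w - 1L, widths)
  }
  n <- length(newdata)
  flank <- (w - 1L) %/% 2L
  subs <- character(n * w)
  for (i in seq_len(w)) {
    subs[(i - 1L) * n + seq_len(n)] <- substring(newdata, i, i + w - 1L)
  }
  pred <- baseline_predict_center(object, subs)
  list(ipd = matrix(pred[, 1], n, w), pw = matrix(pred[, 2], n, w))
}

#' Predict the 21-position kinetic baseline of 41-bp windows
#'
#' Convenience wrapper around \code{\link{predict.baseline_model}} for the
#' classifier's input convention.
#'
#' @param model A \code{baseline_model}.
#' @param seq41 Character vector of 41-bp sequences.
#' @return List with \code{ipd} and \code{pw} matrices (\code{n x 21}).
#' @export
predict_baseline <- function(model, seq41) {
  predict(model, seq41)
}

#' Integrated gradients attribution for the baseline regressor
#'
#' Attributes a predicted center-base kinetic value to the input nucleotide
#' positions, integrating gradients along the straight path from a reference
#' input to the sample (midpoint Riemann approximation). By the completeness
#' axiom the attributions sum to \code{f(x) - f(reference)} up to
#' discretization error.
#'
#' The default reference is the uniform base composition (0.25 per channel):
#' it keeps every point of the integration path on the per-position
#' probability simplex, so attributions track the model's genuine base
#' sensitivity. The all-zeros reference (the N encoding) is also available
#' but scales the total input mass along the path, which smears attribution
#' onto positions the model is provably insensitive to.
#'
#' @param model A frozen \code{baseline_model}.
#' @param seq21 One window-width sequence.
#' @param target \code{"ipd"} or \code{"pw"}.
#' @param n_steps Riemann steps (>= 2).
#' @param baseline_input \code{"uniform"} or \code{"zeros"}.
#' @return Object of class \code{attribution_profile}: signed per-base
#'   attribution matrix (window x 4), per-position scores (summed channel
#'   magnitudes), signed per-position attributions, the prediction, the
#'   reference prediction and the completeness gap.
#' @export
integrated_gradients <- function(model, seq21, target = c("ipd", "pw"),
                                 n_steps = 64L,
                                 baseline_input = c("uniform", "zeros")) {
  target <- match.arg(target)
  baseline_input <- match.arg(baseline_input)
  if (n_steps < 2) stopf("n_steps must be >= 2")
  w <- model$config$window
  if (nchar(seq21) != w) stopf("sequence must have width %d", w)
  head <- if (target == "ipd") model$head_ipd else model$head_pw
  x <- encode_onehot(seq21)
  x0 <- if (baseline_input == "uniform") matrix(0.25, w, 4) else matrix(0, w, 4)
  alphas <- (seq_len(n_steps) - 0.5) / n_steps
  B <- n_steps
  X <- array(0, c(B, w, 4))
  for (b in seq_len(B)) X[b, , ] <- x0 + alphas[b] * (x - x0)
  fw <- nn_bigru_forward(model$net, X)
  dread <- matrix(rep(head$W, each = B), B, ncol(fw$read))
  gb <- nn_bigru_backward(model$net, fw, dread)
  avg_grad <- apply(gb$dX, c(2, 3), mean)
  attribution <- (x - x0) * avg_grad
  col <- if (target == "ipd") 1L else 2L
  f_x <- baseline_forward(model$net, model$head_ipd, model$head_pw,
                          array(x, c(1, w, 4)))$pred[1, col]
  f_0 <- baseline_forward(model$net, model$head_ipd, model$head_pw,
                          array(x0, c(1, w, 4)))$pred[1, col]
  structure(list(
    attribution = attribution,
    position_score = rowSums(abs(attribution)),
    position_signed = rowSums(attribution),
    prediction = f_x, baseline_prediction = f_0,
    completeness_gap = abs(sum(attribution) - (f_x - f_0)),
    n_steps = as.integer(n_steps), target = target,
    baseline_input = baseline_input, seq = seq21
  ), class = "attribution_profile")
}

#' Mean attribution profile over a set of sequences
#'
#' Averages the signed per-position attributions of
#' \code{\link{integrated_gradients}} over many input sequences, the way
#' attribution maps are usually reported: positions the model does not use
#' average toward zero while consistently informative positions persist.
#'
#' @param model A frozen \code{baseline_model}.
#' @param seqs Character vector of window-width sequences.
#' @param target \code{"ipd"} or \code{"pw"}.
#' @param n_steps Riemann steps per sequence.
#' @param baseline_input Reference input, as in
#'   \code{\link{integrated_gradients}}.
#' @return Data.frame with \code{offset} (position relative to center),
#'   \code{mean_signed} and \code{mean_abs} attribution.
#' @export
mean_attribution_profile <- function(model, seqs, target = c("ipd", "pw"),
                                     n_steps = 32L,
                                     baseline_input = c("uniform", "zeros")) {
  target <- match.arg(target)
  baseline_input <- match.arg(baseline_input)
  w <- model$config$window
  signed <- matrix(0, length(seqs), w)
  absd <- matrix(0, length(seqs), w)
  for (i in seq_along(seqs)) {
    ig <- integrated_gradients(model, seqs[i], target, n_steps, baseline_input)
    signed[i, ] <- ig$position_signed
    absd[i, ] <- ig$position_score
  }
  data.frame(offset = seq_len(w) - (w + 1L) %/% 2L,
             mean_signed = colMeans(signed),
             mean_abs = colMeans(absd))
}

#' @export
as.data.frame.attribution_profile <- function(x, ...) {
  w <- length(x$position_score)
  data.frame(offset = seq_len(w) - (w + 1L) %/% 2L,
             score = x$position_score,
             signed = x$position_signed)
}

#' @export
print.attribution_profile <- function(x, ...) {
  w <- length(x$position_score)
  cat(sprintf("Integrated-gradients profile (%s, %d steps): f(x)=%.4f, completeness gap %.2e\n",
              x$target, x$n_steps, x$prediction, x$completeness_gap))
  off <- seq_len(w) - (w + 1) / 2
  top <- order(x$position_score, decreasing = TRUE)[1:3]
  cat(sprintf("  top positions (offset from center): %s\n",
              paste(off[top], collapse = ", ")))
  invisible(x)
}

#' Build a regression frame from a WGA kinetics track
#'
#' One row per covered interior position and strand: the 21-bp read-oriented
#' sequence context and its averaged kinetics, i.e. the training data of the
#' baseline regressor. Noiseless simulator values are carried through when
#' present (oracle checks).
#'
#' @param genome Genome character string.
#' @param track Kinetics data.frame.
#' @param window Context width (odd).
#' @return Data.frame with seq, ipd, pw (+ ipd_true/pw_true if available),
#'   contig, pos, strand.
#' @export
regression_frame <- function(genome, track, window = 21L) {
  flank <- (window - 1L) %/% 2L
  L <- nchar(genome)
  keep <- track$pos >= flank & track$pos <= L - 1L - flank
  t2 <- track[keep, , drop = FALSE]
  seqs <- substring(genome, t2$pos - flank + 1L, t2$pos + flank + 1L)
  minus <- t2$strand == "-"
  if (any(minus)) {
    seqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))
  }
  out <- data.frame(seq = seqs, ipd = t2$ipd, pw = t2$pw,
                    contig = t2$contig, pos = t2$pos, strand = t2$strand,
                    stringsAsFactors = FALSE)
  if ("ipd_true" %in% names(t2)) out$ipd_true <- t2$ipd_true
  if ("pw_true" %in% names(t2)) out$pw_true <- t2$pw_true
  out
}
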