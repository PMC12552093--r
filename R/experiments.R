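# One-call simulation experiment: simulate a genome with motif-placed
# modifications, fit the WGA baseline, build train/test windows, train one
# classifier per feature strategy and evaluate on held-out sites with random
# motif-free negatives. This is the package's reproduction harness for the
# weak (5mC-like) and strong (6mA/4mC-like) signal regimes.

#' Run a seeded strategy-comparison experiment on simulated kinetics
#'
#' Simulates native and WGA kinetics for one genome, fits the unmethylated
#' baseline regressor on the WGA track, splits motif sites into train and
#' test pools (test negatives are random motif-free positions), trains one
#' methylation classifier per requested feature strategy on identical data,
#' and reports test AUC and threshold metrics per strategy.
#'
#' The default network/training sizes are scaled for desk-size simulated
#' cohorts (a few hundred windows); see the methods vignette.
#'
#' @param strategies Feature strategies to compare (ids 1-9).
#' @param shift_preset \code{"weak"} (5mC-like) or \code{"strong"}
#'   (6mA/4mC-like), or a list with \code{ipd_shift}/\code{pw_shift}.
#' @param motif,mod_offset Motif specification.
#' @param genome_length,context_k,subread_noise_sigma,coverage_mean,gc_content
#'   Simulation parameters (see \code{\link{sim_config}}).
#' @param seed Master seed; all stage seeds derive from it.
#' @param baseline_samples WGA positions used to fit the baseline.
#' @param regressor A \code{\link{regressor_config}} (NULL for the scaled
#'   default).
#' @param classifier A \code{\link{classifier_config}} (NULL for the scaled
#'   default).
#' @param test_fraction Fraction of motif sites held out for testing.
#' @param val_fraction Fraction of training windows used for threshold
#'   calibration.
#' @param eval_baseline Also report the baseline regressor's held-out
#'   Pearson r against the noiseless simulator truth.
#' @return Object of class \code{strategy_experiment}: per-strategy
#'   \code{reports} (AUC/ACC/precision/recall/AUPR), \code{scores},
#'   test \code{labels}, fitted models, and baseline quality.
#' @export
strategy_experiment <- function(strategies = c(6L, 7L),
                                shift_preset = "weak",
                                motif = "CCWGG", mod_offset = 1L,
                                genome_length = 40000L, context_k = 7L,
                                subread_noise_sigma = 0.2, coverage_mean = 10,
                                gc_content = 0.5, seed = 1L,
                                baseline_samples = 8000L,
                                regressor = NULL, classifier = NULL,
                                test_fraction = 0.4, val_fraction = 0.2,
                                eval_baseline = TRUE) {
  preset <- if (is.character(shift_preset)) kinetic_shift_preset(shift_preset)
            else shift_preset
  cfg <- sim_config(genome_length = genome_length, gc_content = gc_content,
                    motif = motif, mod_offset = mod_offset,
                    methyl_fraction = 1, context_k = context_k,
                    ipd_shift = preset$ipd_shift, pw_shift = preset$pw_shift,
                    subread_noise_sigma = subread_noise_sigma,
                    coverage_mean = coverage_mean, seed = seed)
  sim <- simulate_dataset(cfg)

  infos <- lapply(strategies, strategy_info)
  needs_bm <- any(vapply(infos, `[[`, logical(1), "needs_baseline")) ||
    eval_baseline
  bm <- NULL
  baseline_r <- c(ipd = NA_real_, pw = NA_real_)
  if (needs_bm) {
    fr <- regression_frame(sim$genome, sim$wga)
    set.seed(seed + 91L)
    idx <- sample.int(nrow(fr), min(baseline_samples, nrow(fr)))
    if (is.null(regressor)) {
      regressor <- regressor_config(gru_hidden = 32L, gru_layers = 1L,
                                    dropout = 0, epochs = 12L, lr = 3e-3,
                                    seed = seed + 92L)
    }
    bm <- baseline_regressor(fr$seq[idx], fr$ipd[idx], fr$pw[idx], regressor)
    if (eval_baseline) {
      hold <- setdiff(seq_len(nrow(fr)), idx)
      hold <- hold[seq_len(min(3000L, length(hold)))]
      pr <- predict(bm, fr$seq[hold])
      baseline_r <- c(ipd = cor(pr[, 1], fr$ipd_true[hold]),
                      pw = cor(pr[, 2], fr$pw_true[hold]))
    }
  }

  sites <- find_motif_sites(sim$genome, motif, mod_offset, sim$contig)
  set.seed(seed + 93L)
  te <- sort(sample.int(nrow(sites), round(test_fraction * nrow(sites))))
  train_w <- build_training_set(sim$genome, sim$native, sim$wga, motif,
                                mod_offset, sampling_plan("train"),
                                sites = sites[-te, , drop = FALSE],
                                contig = sim$contig)
  test_w <- build_test_set(sim$genome, sim$native, motif, mod_offset,
                           sampling_plan("test", seed = seed + 94L),
                           sites = sites[te, , drop = FALSE],
                           known_sites = sites, contig = sim$contig)
  set.seed(seed + 95L)
  n <- length(train_w)
  ord <- sample.int(n)
  n_val <- max(2L, round(val_fraction * n))
  val_w <- train_w[ord[seq_len(n_val)]]
  tr_w <- train_w[ord[(n_val + 1L):n]]

  if (is.null(classifier)) {
    classifier <- classifier_config(gru_hidden = 16L, gru_layers = 1L,
                                    dropout = 0.3, lr = 2e-3, step_size = 40L,
                                    epochs = 60L, batch = 16L,
                                    seed = seed + 96L)
  }
  labels <- test_w$meta$label
  reports <- vector("list", length(strategies))
  scores <- matrix(NA_real_, length(test_w), length(strategies),
                   dimnames = list(NULL, paste0("strategy_", strategies)))
  fits <- vector("list", length(strategies))
  for (i in seq_along(strategies)) {
    info <- infos[[i]]
    bmi <- if (info$needs_baseline) bm else NULL
    fit <- methylation_classifier(tr_w, val_w, strategies[i], bmi, classifier)
    pred <- predict(fit, test_w, bmi)
    rep_i <- eval_report(pred$score, labels, fit$threshold)
    rep_i$strategy <- strategies[i]
    reports[[i]] <- rep_i
    scores[, i] <- pred$score
    fits[[i]] <- fit
  }
  reports <- do.call(rbind, reports)
  structure(list(reports = reports, scores = scores, labels = labels,
                 baseline_r = baseline_r, baseline = bm, classifiers = fits,
                 test_windows = test_w, train_windows = train_w,
                 sim_config = cfg, n_sites = nrow(sites)),
            class = "strategy_experiment")
}

#' @export
print.strategy_experiment <- function(x, ...) {
  cat(sprintf("Strategy experiment: motif %s, %d motif sites, %d test windows\n",
              x$sim_config$motif, x$n_sites, length(x$labels)))
  if (!is.na(x$baseline_r["ipd"])) {
    cat(sprintf("  baseline regressor held-out r: IPD %.3f, PW %.3f\n",
                x$baseline_r["ipd"], x$baseline_r["pw"]))
  }
  df <- x$reports[, c("strategy", "auc", "acc", "precision", "recall", "aupr")]
  print(format(df, digits = 4), row.names = FALSE)
  invisible(x)
}
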