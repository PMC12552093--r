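# Configuration-driven pipeline: simulate -> train-baseline -> build-samples
# -> train-classifier -> predict -> evaluate, every stage exchanging plain
# files under one output directory so runs are resumable and reproducible.

PIPELINE_STAGES <- c("simulate", "train-baseline", "build-samples",
                     "train-classifier", "predict", "evaluate")

#' Default pipeline configuration
#'
#' @return Nested list with every recognized key and its default; see the
#'   methods vignette for the meaning and units of each parameter.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "smrtmet_run",
    stages = PIPELINE_STAGES,
    sim = list(genome_length = 60000L, gc_content = 0.5, motif = "CCWGG",
               mod_offset = 1L, methyl_fraction = 1.0, context_k = 7L,
               shift_preset = "weak", subread_noise_sigma = 0.2,
               coverage_mean = 10, mod_label = "mod"),
    normalization = list(method = "mean_scale", scope = "per_read",
                         epsilon = 1e-6),
    sampling = list(test_fraction = 0.3, exclusion_radius = 20L,
                    balance = TRUE),
    regressor = list(gru_hidden = 32L, gru_layers = 1L, dropout = 0.0,
                     epochs = 10L, lr = 1e-3, batch = 64L,
                     max_samples = 20000L, min_samples = 200L),
    classifier = list(strategy = 6L, architecture = "early_concat",
                      gru_hidden = 16L, gru_layers = 1L, dropout = 0.1,
                      epochs = 20L, lr = 1e-3, step_size = 10L,
                      gamma_lr = 0.5, focal_gamma = 2, label_smoothing = 0.1,
                      batch = 32L, val_fraction = 0.2),
    bootstrap = list(n_rounds = 10L, val_fraction = 0.2)
  )
}

merge_config <- function(defaults, user, path = "", errors = NULL) {
  env <- new.env()
  env$errors <- errors
  rec <- function(d, u, p) {
    for (k in names(u)) {
      full <- if (nzchar(p)) paste0(p, ".", k) else k
      if (!k %in% names(d)) {
        env$errors <- c(env$errors, sprintf("unknown config key '%s'", full))
      } else if (is.list(d[[k]]) && !is.null(names(d[[k]]))) {
        if (!is.list(u[[k]])) {
          env$errors <- c(env$errors, sprintf("config key '%s' must be a mapping", full))
        } else {
          d[[k]] <- rec(d[[k]], u[[k]], full)
        }
      } else {
        d[[k]] <- u[[k]]
      }
    }
    d
  }
  merged <- rec(defaults, user, path)
  list(config = merged, errors = env$errors)
}

#' Validate a pipeline configuration
#'
#' Schema-checks a YAML config (or config list) against the recognized keys,
#' verifies field invariants and cross-field constraints (e.g. a strategy
#' that needs the baseline requires the train-baseline stage or an existing
#' checkpoint), and reports every violation at once. No side effects.
#'
#' @param config Path to a YAML file, or a config list.
#' @return Object of class \code{config_report}: \code{ok}, \code{errors},
#'   and the merged \code{config} (usable when ok).
#' @export
validate_config <- function(config) {
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(user)) user <- list()
  m <- merge_config(default_config(), user)
  cfg <- m$config
  errors <- m$errors
  chk <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)

  chk(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed), "seed must be an integer")
  chk(all(cfg$stages %in% PIPELINE_STAGES),
      sprintf("unknown stage(s): %s; valid stages are %s",
              paste(setdiff(cfg$stages, PIPELINE_STAGES), collapse = ", "),
              paste(PIPELINE_STAGES, collapse = ", ")))
  s <- cfg$sim
  chk(s$genome_length >= 1, "sim.genome_length must be positive")
  chk(s$gc_content >= 0 && s$gc_content <= 1, "sim.gc_content must be in [0,1]")
  chk(is_iupac(s$motif), sprintf("sim.motif '%s' is not a valid IUPAC string", s$motif))
  chk(s$mod_offset >= 0 && s$mod_offset < nchar(s$motif),
      "sim.mod_offset must satisfy 0 <= mod_offset < nchar(motif)")
  chk(s$methyl_fraction >= 0 && s$methyl_fraction <= 1,
      "sim.methyl_fraction must be in [0,1]")
  chk(s$context_k %% 2 == 1 && s$context_k >= 3, "sim.context_k must be odd and >= 3")
  chk(s$coverage_mean >= 1, "sim.coverage_mean must be >= 1")
  chk(s$subread_noise_sigma >= 0, "sim.subread_noise_sigma must be >= 0")
  chk(s$shift_preset %in% c("weak", "strong"),
      "sim.shift_preset must be 'weak' or 'strong'")
  chk(cfg$normalization$method %in% c("mean_scale", "zscore"),
      "normalization.method must be mean_scale or zscore")
  chk(cfg$normalization$epsilon > 0, "normalization.epsilon must be > 0")
  chk(cfg$sampling$test_fraction > 0 && cfg$sampling$test_fraction < 1,
      "sampling.test_fraction must be in (0,1)")
  chk(cfg$sampling$exclusion_radius >= 0, "sampling.exclusion_radius must be >= 0")
  r <- cfg$regressor
  chk(r$epochs >= 1, "regressor.epochs must be >= 1")
  chk(r$lr > 0, "regressor.lr must be > 0")
  chk(r$dropout >= 0 && r$dropout < 1, "regressor.dropout must be in [0,1)")
  cl <- cfg$classifier
  chk(cl$strategy %in% 1:9, "classifier.strategy must be in 1..9")
  chk(cl$architecture %in% c("early_concat", "late_fusion"),
      "classifier.architecture must be early_concat or late_fusion")
  chk(cl$focal_gamma >= 0, "classifier.focal_gamma must be >= 0")
  chk(cl$label_smoothing >= 0 && cl$label_smoothing < 0.5,
      "classifier.label_smoothing must be in [0, 0.5)")
  chk(cl$gamma_lr > 0 && cl$gamma_lr <= 1, "classifier.gamma_lr must be in (0,1]")
  chk(cl$val_fraction > 0 && cl$val_fraction < 1,
      "classifier.val_fraction must be in (0,1)")
  chk(cfg$bootstrap$n_rounds >= 1, "bootstrap.n_rounds must be >= 1")
  # cross-field: a strategy needing the baseline must have a way to get one
  if (cl$strategy %in% 1:9 && cl$strategy != 7 &&
      "train-classifier" %in% cfg$stages &&
      !"train-baseline" %in% cfg$stages &&
      !file.exists(file.path(cfg$out_dir, "baseline_model.rds"))) {
    errors <- c(errors, sprintf(
      "classifier.strategy %d requires the baseline model: include the 'train-baseline' stage (or provide %s)",
      cl$strategy, file.path(cfg$out_dir, "baseline_model.rds")))
  }
  structure(list(ok = length(errors) == 0, errors = errors, config = cfg),
            class = "config_report")
}

#' @export
print.config_report <- function(x, ...) {
  if (x$ok) {
    cat("configuration OK\n")
  } else {
    cat(sprintf("configuration has %d problem(s):\n", length(x$errors)))
    for (e in x$errors) cat("  - ", e, "\n", sep = "")
  }
  invisible(x)
}

need_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    stopf("missing artifact '%s'; run the '%s' stage first", path, stage)
  }
  path
}

#' Run the pipeline
#'
#' Executes the requested stages in order, exchanging artifacts through
#' files under \code{out_dir}. Every run writes the resolved configuration
#' and a package-version fingerprint alongside the outputs; re-running with
#' the same config reproduces all results.
#'
#' @param config Path to a YAML config, or a config list (see
#'   \code{\link{default_config}}).
#' @param stages Stage subset to run (default: the config's stages).
#' @return Invisibly, a list of the artifacts produced (paths, plus the final
#'   evaluation report when the evaluate stage runs).
#' @export
run_pipeline <- function(config, stages = NULL) {
  rep <- validate_config(config)
  if (!rep$ok) {
    stopf("invalid configuration:\n%s", paste(paste0("  - ", rep$errors), collapse = "\n"))
  }
  cfg <- rep$config
  if (!is.null(stages)) cfg$stages <- stages
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(out, "resolved_config.yaml"))
  writeLines(sprintf("smrtmet %s", as.character(utils::packageVersion("smrtmet"))),
             file.path(out, "fingerprint.txt"))
  artifacts <- list(resolved_config = file.path(out, "resolved_config.yaml"))

  preset <- kinetic_shift_preset(cfg$sim$shift_preset)
  sim_cfg <- sim_config(
    genome_length = cfg$sim$genome_length, gc_content = cfg$sim$gc_content,
    motif = cfg$sim$motif, mod_offset = cfg$sim$mod_offset,
    methyl_fraction = cfg$sim$methyl_fraction, context_k = cfg$sim$context_k,
    ipd_shift = preset$ipd_shift, pw_shift = preset$pw_shift,
    subread_noise_sigma = cfg$sim$subread_noise_sigma,
    coverage_mean = cfg$sim$coverage_mean, mod_label = cfg$sim$mod_label,
    seed = cfg$seed
  )

  p_genome <- file.path(out, "genome.fasta")
  p_native <- file.path(out, "kinetics_native.tsv")
  p_wga <- file.path(out, "kinetics_wga.tsv")
  p_truth <- file.path(out, "truth.bed")
  p_baseline <- file.path(out, "baseline_model.rds")
  p_train_w <- file.path(out, "train_windows.tsv")
  p_test_w <- file.path(out, "test_windows.tsv")
  p_clf <- file.path(out, "classifier.rds")
  p_pred <- file.path(out, "predictions.tsv")
  p_eval <- file.path(out, "eval_report.tsv")

  for (stage in cfg$stages) {
    message(sprintf("[smrtmet] stage: %s", stage))
    if (stage == "simulate") {
      sim <- simulate_dataset(sim_cfg)
      write_sim_fixture(sim, out)
      artifacts$simulate <- c(p_genome, p_native, p_wga, p_truth)
    } else if (stage == "train-baseline") {
      need_artifact(p_genome, "simulate")
      need_artifact(p_wga, "simulate")
      genome <- read_genome_fasta(p_genome)[[1]]
      wga <- read_kinetics(p_wga)
      frame <- regression_frame(genome, wga)
      set.seed(cfg$seed + 11L)
      if (nrow(frame) > cfg$regressor$max_samples) {
        frame <- frame[sample.int(nrow(frame), cfg$regressor$max_samples), ]
      }
      rcfg <- regressor_config(
        gru_hidden = cfg$regressor$gru_hidden,
        gru_layers = cfg$regressor$gru_layers,
        dropout = cfg$regressor$dropout, epochs = cfg$regressor$epochs,
        lr = cfg$regressor$lr, batch = cfg$regressor$batch,
        min_samples = cfg$regressor$min_samples, seed = cfg$seed + 12L
      )
      baseline <- baseline_regressor(frame$seq, frame$ipd, frame$pw, rcfg)
      saveRDS(baseline, p_baseline)
      artifacts$baseline <- p_baseline
    } else if (stage == "build-samples") {
      need_artifact(p_genome, "simulate")
      need_artifact(p_native, "simulate")
      need_artifact(p_wga, "simulate")
      genome <- read_genome_fasta(p_genome)[[1]]
      native <- read_kinetics(p_native)
      wga <- read_kinetics(p_wga)
      sites <- find_motif_sites(genome, cfg$sim$motif, cfg$sim$mod_offset,
                                contig = native$contig[1])
      set.seed(cfg$seed + 21L)
      n_test <- round(cfg$sampling$test_fraction * nrow(sites))
      test_rows <- sort(sample.int(nrow(sites), n_test))
      sites_test <- sites[test_rows, , drop = FALSE]
      sites_train <- sites[-test_rows, , drop = FALSE]
      train_w <- build_training_set(genome, native, wga, cfg$sim$motif,
                                    cfg$sim$mod_offset,
                                    sampling_plan("train", seed = cfg$seed + 22L),
                                    sites = sites_train,
                                    contig = native$contig[1])
      test_w <- build_test_set(genome, native, cfg$sim$motif, cfg$sim$mod_offset,
                               sampling_plan("test",
                                             balance = cfg$sampling$balance,
                                             exclusion_radius = cfg$sampling$exclusion_radius,
                                             seed = cfg$seed + 23L),
                               sites = sites_test, known_sites = sites,
                               contig = native$contig[1])
      leak <- intersect(window_keys(train_w), window_keys(test_w))
      if (length(leak)) stopf("train/test leakage at %d site(s)", length(leak))
      write_windows(train_w, p_train_w)
      write_windows(test_w, p_test_w)
      artifacts$samples <- c(p_train_w, p_test_w)
    } else if (stage == "train-classifier") {
      need_artifact(p_train_w, "build-samples")
      strategy <- cfg$classifier$strategy
      baseline <- NULL
      if (strategy_info(strategy)$needs_baseline) {
        need_artifact(p_baseline, "train-baseline")
        baseline <- readRDS(p_baseline)
      }
      pool <- read_windows(p_train_w)
      set.seed(cfg$seed + 31L)
      n <- length(pool)
      ord <- sample.int(n)
      n_val <- max(1L, round(cfg$classifier$val_fraction * n))
      val_w <- pool[ord[seq_len(n_val)]]
      tr_w <- pool[ord[(n_val + 1L):n]]
      ccfg <- classifier_config(
        architecture = cfg$classifier$architecture,
        gru_hidden = cfg$classifier$gru_hidden,
        gru_layers = cfg$classifier$gru_layers,
        dropout = cfg$classifier$dropout, lr = cfg$classifier$lr,
        step_size = cfg$classifier$step_size, gamma_lr = cfg$classifier$gamma_lr,
        focal_gamma = cfg$classifier$focal_gamma,
        label_smoothing = cfg$classifier$label_smoothing,
        epochs = cfg$classifier$epochs, batch = cfg$classifier$batch,
        seed = cfg$seed + 32L
      )
      clf <- methylation_classifier(tr_w, val_w, strategy, baseline, ccfg)
      saveRDS(clf, p_clf)
      log <- data.frame(epoch = seq_along(clf$loss_trace),
                        lr = clf$lr_trace, loss = clf$loss_trace)
      write.table(log, file.path(out, "training_log.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      artifacts$classifier <- p_clf
    } else if (stage == "predict") {
      need_artifact(p_clf, "train-classifier")
      need_artifact(p_test_w, "build-samples")
      clf <- readRDS(p_clf)
      baseline <- if (clf$strategy$needs_baseline) {
        readRDS(need_artifact(p_baseline, "train-baseline"))
      } else NULL
      test_w <- read_windows(p_test_w)
      pred <- predict(clf, test_w, baseline)
      pred$label <- test_w$meta$label
      write.table(pred, p_pred, sep = "\t", quote = FALSE, row.names = FALSE)
      artifacts$predictions <- p_pred
    } else if (stage == "evaluate") {
      need_artifact(p_pred, "predict")
      pred <- read.table(p_pred, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
      rep_df <- eval_report(pred$score, pred$label, pred$threshold[1])
      write.table(rep_df, p_eval, sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(as.list(rep_df), file.path(out, "eval_report.json"),
                           auto_unbox = TRUE, digits = NA)
      artifacts$evaluation <- rep_df
    }
  }
  invisible(artifacts)
}

#' Compare two prediction files with DeLong's test
#'
#' Joins the prediction TSVs of two runs on (contig, pos, strand), requires
#' identical sample sets and labels, and compares their AUCs.
#'
#' @param path_a,path_b Prediction files written by the predict stage.
#' @return The \code{\link{delong_test}} result plus the sample count.
#' @export
compare_predictions <- function(path_a, path_b) {
  a <- read.table(path_a, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  b <- read.table(path_b, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  key_a <- paste(a$contig, a$pos, a$strand)
  key_b <- paste(b$contig, b$pos, b$strand)
  if (!setequal(key_a, key_b)) {
    stopf("prediction files cover different sample sets")
  }
  b <- b[match(key_a, key_b), , drop = FALSE]
  if (!identical(a$label, b$label)) stopf("labels disagree between files")
  res <- delong_test(a$score, b$score, a$label == "methylated")
  res$n <- nrow(a)
  res
}
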