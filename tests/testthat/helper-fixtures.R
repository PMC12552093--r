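# Shared simulated fixtures, memoized so expensive objects are built once per
# test run. Everything is generated in code under fixed seeds.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(name, expr) {
  if (!exists(name, envir = .fx, inherits = FALSE)) {
    assign(name, expr, envir = .fx)
  }
  get(name, envir = .fx)
}

# small noisy dataset for IO / window tests (partial methylation)
fx_small_sim <- function() fx_memo("small_sim", {
  simulate_dataset(sim_config(genome_length = 4000L, motif = "GATC",
                              mod_offset = 1L, methyl_fraction = 0.8,
                              context_k = 5L, subread_noise_sigma = 0.15,
                              coverage_mean = 5, mod_label = "6mA",
                              seed = 42L))
})

# noise-free, narrow-context dataset: every observed value equals the
# ground-truth table entry, so it backs the oracle checks
fx_nf_sim <- function() fx_memo("nf_sim", {
  simulate_dataset(sim_config(genome_length = 3000L, motif = "GATC",
                              mod_offset = 1L, methyl_fraction = 0,
                              context_k = 3L, subread_noise_sigma = 0,
                              coverage_mean = 1, seed = 9L))
})

# throwaway regressor for interface/contract tests (accuracy irrelevant)
fx_tiny_regressor <- function() fx_memo("tiny_regressor", {
  sim <- fx_nf_sim()
  fr <- regression_frame(sim$genome, sim$wga)
  baseline_regressor(fr$seq[1:600], fr$ipd[1:600], fr$pw[1:600],
                     regressor_config(gru_hidden = 8L, gru_layers = 1L,
                                      dropout = 0, epochs = 2L, lr = 3e-3,
                                      min_samples = 100L, seed = 3L))
})

# well-trained narrow-context regressor: with k = 3 and abundant flank
# diversity the mapping is fully learnable, so held-out correlation with the
# noiseless truth approaches 1. Returns list(sim, frame, model).
fx_k3 <- function() fx_memo("k3", {
  sim <- simulate_dataset(sim_config(genome_length = 6000L, motif = "GATC",
                                     mod_offset = 1L, methyl_fraction = 0,
                                     context_k = 3L, subread_noise_sigma = 0,
                                     coverage_mean = 1, seed = 5L))
  fr <- regression_frame(sim$genome, sim$wga)
  model <- baseline_regressor(fr$seq, fr$ipd, fr$pw,
                              regressor_config(gru_hidden = 32L,
                                               gru_layers = 1L, dropout = 0,
                                               epochs = 24L, lr = 3e-3,
                                               seed = 7L))
  list(sim = sim, frame = fr, model = model)
})

# small strong-signal dataset + window sets for classifier unit tests
fx_clf_data <- function() fx_memo("clf_data", {
  pre <- kinetic_shift_preset("strong")
  cfg <- sim_config(genome_length = 12000L, motif = "GATC", mod_offset = 1L,
                    methyl_fraction = 1, context_k = 5L,
                    ipd_shift = pre$ipd_shift, pw_shift = pre$pw_shift,
                    subread_noise_sigma = 0.2, coverage_mean = 5,
                    mod_label = "6mA", seed = 21L)
  sim <- simulate_dataset(cfg)
  sites <- find_motif_sites(sim$genome, cfg$motif, cfg$mod_offset, sim$contig)
  set.seed(22)
  te <- sort(sample.int(nrow(sites), round(0.4 * nrow(sites))))
  train_w <- build_training_set(sim$genome, sim$native, sim$wga, cfg$motif,
                                cfg$mod_offset, sampling_plan("train"),
                                sites = sites[-te, , drop = FALSE],
                                contig = sim$contig)
  test_w <- build_test_set(sim$genome, sim$native, cfg$motif, cfg$mod_offset,
                           sampling_plan("test", seed = 23L),
                           sites = sites[te, , drop = FALSE],
                           known_sites = sites, contig = sim$contig)
  set.seed(24)
  n <- length(train_w)
  ord <- sample.int(n)
  nv <- max(2L, round(0.2 * n))
  list(sim = sim, sites = sites,
       train = train_w[ord[(nv + 1L):n]], val = train_w[ord[seq_len(nv)]],
       test = test_w)
})

fx_fast_clf_config <- function(seed = 31L, epochs = 30L) {
  classifier_config(gru_hidden = 12L, gru_layers = 1L, dropout = 0.2,
                    lr = 2e-3, step_size = 40L, epochs = epochs, batch = 16L,
                    seed = seed)
}

# tiny pipeline configuration used by pipeline and determinism tests
fx_pipeline_config <- function(out_dir, seed = 5L) {
  list(seed = seed, out_dir = out_dir,
       sim = list(genome_length = 12000L, motif = "GATC", mod_offset = 1L,
                  shift_preset = "strong", coverage_mean = 5,
                  context_k = 5L, mod_label = "6mA"),
       regressor = list(gru_hidden = 16L, gru_layers = 1L, dropout = 0,
                        epochs = 6L, lr = 3e-3, max_samples = 4000L,
                        min_samples = 100L),
       classifier = list(strategy = 6L, gru_hidden = 12L, epochs = 12L,
                         batch = 16L, step_size = 40L, lr = 2e-3,
                         dropout = 0.1))
}
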