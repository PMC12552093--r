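test_that("one-hot encoding follows the A,C,G,T convention with N as zeros", {
  m <- encode_onehot("ACGTN")
  expect_equal(m[1, ], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(unname(rowSums(m)), c(1, 1, 1, 1, 0))
  expect_equal(unname(m[5, ]), rep(0, 4))
  expect_error(encode_onehot("ACXG"), "invalid base")
  # encode/argmax round trip over random sequences
  set.seed(1)
  for (i in 1:20) {
    s <- paste0(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
                collapse = "")
    dec <- paste0(c("A", "C", "G", "T")[apply(encode_onehot(s), 1, which.max)],
                  collapse = "")
    expect_identical(dec, s)
  }
})

test_that("regressor config guards its invariants", {
  expect_error(regressor_config(window = 20L), "odd")
  expect_error(regressor_config(lr = 0), "lr")
  expect_error(regressor_config(epochs = 0L), "epochs")
  expect_error(regressor_config(dropout = 1), "dropout")
  expect_s3_class(regressor_config(), "regressor_config")
  expect_equal(regressor_config()$epochs, 50L)
  expect_equal(regressor_config()$lr, 1e-3)
  expect_equal(regressor_config()$batch, 64L)
})

test_that("noise-free kinetics are learnable to near-perfect correlation", {
  k3 <- fx_k3()
  fr <- k3$frame
  hold <- seq(1, nrow(fr), by = 3)
  pred <- predict(k3$model, fr$seq[hold])
  expect_gt(cor(pred[, "ipd"], fr$ipd_true[hold]), 0.99)
  expect_gt(cor(pred[, "pw"], fr$pw_true[hold]), 0.99)
  # loss trace fell substantially
  expect_lt(tail(k3$model$loss_trace, 1), k3$model$loss_trace[1] / 20)
  # and predictions agree with the generating k-mer table
  ctx <- substring(fr$seq[hold[1:200]], 10L, 12L)
  expect_gt(cor(pred[1:200, "ipd"], kmer_value(k3$sim$gt, ctx, "ipd")), 0.99)
})

test_that("shuffled targets destroy the sequence-kinetics association", {
  k3 <- fx_k3()
  fr <- k3$frame
  set.seed(2)
  sh <- sample.int(nrow(fr))
  m <- baseline_regressor(fr$seq, fr$ipd[sh], fr$pw[sh],
                          regressor_config(gru_hidden = 16L, gru_layers = 1L,
                                           dropout = 0, epochs = 4L, lr = 3e-3,
                                           seed = 8L))
  pred <- predict(m, fr$seq)
  expect_lt(abs(cor(pred[, "ipd"], fr$ipd_true)), 0.2)
})

test_that("training is reproducible under a fixed seed", {
  k3 <- fx_k3()
  fr <- k3$frame
  cfg <- regressor_config(gru_hidden = 8L, gru_layers = 1L, dropout = 0.2,
                          epochs = 2L, lr = 1e-3, min_samples = 100L,
                          seed = 17L)
  m1 <- baseline_regressor(fr$seq[1:500], fr$ipd[1:500], fr$pw[1:500], cfg)
  m2 <- baseline_regressor(fr$seq[1:500], fr$ipd[1:500], fr$pw[1:500], cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(predict(m1, fr$seq[1:20]), predict(m2, fr$seq[1:20]))
})

test_that("too-few samples and mismatched widths are refused", {
  fr <- fx_k3()$frame
  expect_error(baseline_regressor(fr$seq[1:10], fr$ipd[1:10], fr$pw[1:10],
                                  regressor_config(min_samples = 200L)),
               "at least 200")
  expect_error(baseline_regressor(substr(fr$seq[1:300], 1, 10),
                                  fr$ipd[1:300], fr$pw[1:300],
                                  regressor_config(min_samples = 100L)),
               "width 21")
})

test_that("41-bp prediction decomposes into sliding 21-bp center predictions", {
  m <- fx_tiny_regressor()
  set.seed(3)
  s41 <- paste0(sample(c("A", "C", "G", "T"), 41, replace = TRUE),
                collapse = "")
  p <- predict(m, s41)
  expect_equal(dim(p$ipd), c(1L, 21L))
  for (i in c(1L, 10L, 21L)) {
    sub <- substr(s41, i, i + 20L)
    expect_equal(p$ipd[1, i], unname(predict(m, sub)[1, "ipd"]))
    expect_equal(p$pw[1, i], unname(predict(m, sub)[1, "pw"]))
  }
  # homopolymer: every sub-window identical, so all 21 predictions equal
  hp <- predict(m, strrep("A", 41L))
  expect_equal(max(hp$ipd) - min(hp$ipd), 0)
  # N in a sub-window flags that position as missing
  sN <- s41
  substr(sN, 1L, 1L) <- "N"
  pN <- predict(m, sN)
  expect_true(is.na(pN$ipd[1, 1]))
  expect_false(anyNA(pN$ipd[1, 2:21]))
  expect_identical(predict_baseline(m, s41), p)
})

test_that("frozen predictions are unchanged by downstream classifier training", {
  m <- fx_tiny_regressor()
  d <- fx_clf_data()
  before <- predict(m, d$test$seq41[1:5])
  fit <- methylation_classifier(d$train, d$val, 9L, m,
                                fx_fast_clf_config(seed = 41L, epochs = 2L))
  after <- predict(m, d$test$seq41[1:5])
  expect_identical(before, after)
  expect_true(m$frozen)
})

test_that("integrated gradients satisfy completeness; degenerate cases handled", {
  k3 <- fx_k3()
  s <- k3$frame$seq[5]
  ig <- integrated_gradients(k3$model, s, "ipd", n_steps = 128L)
  delta <- ig$prediction - ig$baseline_prediction
  expect_lt(ig$completeness_gap, 0.01 * max(abs(delta), 0.05))
  expect_length(ig$position_score, 21L)
  expect_error(integrated_gradients(k3$model, s, "ipd", n_steps = 1L),
               "n_steps")
  df <- as.data.frame(ig)
  expect_equal(df$offset, -10:10)
  # zero-weight head: all attributions vanish
  m0 <- k3$model
  m0$head_ipd$W[] <- 0
  m0$head_ipd$b <- 0
  ig0 <- integrated_gradients(m0, s, "ipd", n_steps = 16L)
  expect_equal(max(abs(ig0$attribution)), 0)
})

test_that("regression frames carry read-oriented contexts and truth columns", {
  sim <- fx_nf_sim()
  fr <- regression_frame(sim$genome, sim$wga)
  expect_true(all(c("seq", "ipd", "pw", "ipd_true", "pw_true") %in% names(fr)))
  expect_true(all(nchar(fr$seq) == 21L))
  i <- which(fr$strand == "-")[1]
  expect_equal(fr$seq[i],
               reverse_complement(substring(sim$genome, fr$pos[i] - 9L,
                                            fr$pos[i] + 11L)))
})
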