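test_that("plus-strand window extraction uses 0-based half-open arithmetic", {
  sim <- fx_small_sim()
  w <- extract_window(sim$genome, sim$native, pos = 100L, strand = "+")
  expect_equal(length(w), 1L)
  # 0-based site 100 with flank 20: genome[80:121) -> 1-based 81..121
  expect_equal(w$seq41[1], substr(sim$genome, 81L, 121L))
  expect_equal(nchar(w$seq41[1]), 41L)
  # kinetic span is the central 21 bases
  expect_equal(ncol(w$kin_ipd), 21L)
  expect_equal(nchar(substr(w$seq41[1], 11L, 31L)), 21L)
  plus <- sim$native[sim$native$strand == "+", ]
  expect_equal(w$kin_ipd[1, ], plus$ipd[match(90:110, plus$pos)])
  expect_equal(w$kin_ipd[1, 11L], plus$ipd[match(100L, plus$pos)])
})

test_that("minus-strand windows are reverse-complemented with matching kinetics", {
  sim <- fx_small_sim()
  wp <- extract_window(sim$genome, sim$native, pos = 200L, strand = "+")
  wm <- extract_window(sim$genome, sim$native, pos = 200L, strand = "-")
  expect_equal(wm$seq41[1], reverse_complement(wp$seq41[1]))
  expect_equal(reverse_complement(wm$seq41[1]), wp$seq41[1])  # involution
  minus <- sim$native[sim$native$strand == "-", ]
  # kin21[i] (1-based) aligns with genome position pos + 10 - (i - 1)
  expect_equal(wm$kin_ipd[1, ], minus$ipd[match(210:190, minus$pos)])
  expect_equal(wm$kin_pw[1, 1L], minus$pw[match(210L, minus$pos)])
})

test_that("edge sites and sites with missing kinetics are dropped", {
  sim <- fx_small_sim()
  expect_equal(length(extract_window(sim$genome, sim$native, 5L, "+")), 0L)
  expect_equal(length(extract_window(sim$genome, sim$native,
                                     nchar(sim$genome) - 3L, "+")), 0L)
  # remove one central kinetic record -> window dropped
  broken <- sim$native[!(sim$native$pos == 305L & sim$native$strand == "+"), ]
  expect_equal(length(extract_window(sim$genome, broken, 300L, "+")), 0L)
  expect_equal(length(extract_window(sim$genome, broken, 330L, "+")), 1L)
})

test_that("training sets pair native positives with WGA negatives at the same motif", {
  sim <- fx_small_sim()
  cfg <- sim$cfg
  sites <- find_motif_sites(sim$genome, cfg$motif, cfg$mod_offset, sim$contig)
  tw <- build_training_set(sim$genome, sim$native, sim$wga, cfg$motif,
                           cfg$mod_offset, sampling_plan("train"),
                           contig = sim$contig)
  lab <- table(tw$meta$label)
  in_range <- sites$pos >= 20L & sites$pos <= nchar(sim$genome) - 21L
  expect_equal(unname(lab["unmethylated"]), sum(in_range))
  expect_equal(unname(lab["methylated"]), sum(in_range))
  expect_setequal(unique(tw$meta$origin), c("native", "wga"))
  # an edge motif site is absent
  expect_false(any(tw$meta$pos < 20L))
  # full methylation: positives equal all in-range motif sites
  pos_keys <- with(tw$meta[tw$meta$label == "methylated", ],
                   paste(pos, strand))
  expect_setequal(pos_keys, paste(sites$pos[in_range], sites$strand[in_range]))
})

test_that("test negatives are balanced, motif-free, candidate-base-matched and seeded", {
  sim <- fx_small_sim()
  cfg <- sim$cfg
  sites <- find_motif_sites(sim$genome, cfg$motif, cfg$mod_offset, sim$contig)
  plan <- sampling_plan("test", exclusion_radius = 20L, seed = 99L)
  te <- build_test_set(sim$genome, sim$native, cfg$motif, cfg$mod_offset,
                       plan, contig = sim$contig)
  lab <- table(te$meta$label)
  expect_equal(unname(lab["methylated"]), unname(lab["unmethylated"]))
  negs <- te$meta[te$meta$label == "unmethylated", ]
  # brute-force overlap scan: no negative within the exclusion radius of any
  # motif-modified base
  for (i in seq_len(nrow(negs))) {
    expect_true(all(abs(negs$pos[i] - sites$pos) > 20L))
  }
  # central base matches the modified base letter in read orientation
  center <- substr(te$seq41, 21L, 21L)
  expect_true(all(center == substr(cfg$motif, cfg$mod_offset + 1L,
                                   cfg$mod_offset + 1L)))
  # same seed -> same negatives; different seed -> different
  te2 <- build_test_set(sim$genome, sim$native, cfg$motif, cfg$mod_offset,
                        plan, contig = sim$contig)
  expect_identical(window_keys(te), window_keys(te2))
  te3 <- build_test_set(sim$genome, sim$native, cfg$motif, cfg$mod_offset,
                        sampling_plan("test", seed = 100L), contig = sim$contig)
  expect_false(identical(window_keys(te), window_keys(te3)))
})

test_that("an over-wide exclusion radius reports the negative shortfall", {
  sim <- fx_small_sim()
  cfg <- sim$cfg
  expect_error(
    build_test_set(sim$genome, sim$native, cfg$motif, cfg$mod_offset,
                   sampling_plan("test", exclusion_radius = 10000L),
                   contig = sim$contig),
    "insufficient eligible negative")
})

test_that("site-split training and test sets share no keys", {
  sim <- fx_small_sim()
  cfg <- sim$cfg
  sites <- find_motif_sites(sim$genome, cfg$motif, cfg$mod_offset, sim$contig)
  set.seed(7)
  te_rows <- sort(sample.int(nrow(sites), round(0.4 * nrow(sites))))
  tw <- build_training_set(sim$genome, sim$native, sim$wga, cfg$motif,
                           cfg$mod_offset, sampling_plan("train"),
                           sites = sites[-te_rows, ], contig = sim$contig)
  te <- build_test_set(sim$genome, sim$native, cfg$motif, cfg$mod_offset,
                       sampling_plan("test", seed = 8L),
                       sites = sites[te_rows, ], known_sites = sites,
                       contig = sim$contig)
  expect_length(intersect(window_keys(tw), window_keys(te)), 0L)
})

test_that("window sets serialize losslessly with label counts conserved", {
  sim <- fx_small_sim()
  cfg <- sim$cfg
  tw <- build_training_set(sim$genome, sim$native, sim$wga, cfg$motif,
                           cfg$mod_offset, sampling_plan("train"),
                           contig = sim$contig)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_windows(tw, path)
  back <- read_windows(path)
  expect_equal(table(back$meta$label), table(tw$meta$label))
  expect_identical(back$seq41, tw$seq41)
  expect_equal(back$kin_ipd, tw$kin_ipd, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$meta$pos, tw$meta$pos)
})

test_that("sampling plans enforce their mode contract", {
  expect_equal(sampling_plan("train")$negative_source, "wga_same_motif")
  expect_equal(sampling_plan("test")$negative_source, "random_non_motif")
  expect_error(sampling_plan("test", exclusion_radius = -1), "exclusion_radius")
  sim <- fx_small_sim()
  expect_error(
    build_training_set(sim$genome, sim$native, sim$wga, sim$cfg$motif,
                       sim$cfg$mod_offset, sampling_plan("test"),
                       contig = sim$contig),
    "mode")
})
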