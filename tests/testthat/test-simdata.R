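test_that("sim_config enforces its invariants", {
  expect_error(sim_config(motif = "CXWGG"), "IUPAC")
  expect_error(sim_config(mod_offset = 5, motif = "GATC"), "mod_offset")
  expect_error(sim_config(context_k = 4), "odd")
  expect_error(sim_config(coverage_mean = 0.5), "coverage_mean")
  expect_error(sim_config(methyl_fraction = 1.2), "methyl_fraction")
  expect_error(sim_config(subread_noise_sigma = -1), "subread_noise_sigma")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("generated methylation truth sits on motif-matching bases", {
  cfg <- sim_config(genome_length = 3000L, motif = "GATC", mod_offset = 1L,
                    methyl_fraction = 1, seed = 11L)
  gg <- generate_genome(cfg)
  expect_equal(nchar(gg$genome), 3000L)
  plus <- gg$truth[gg$truth$strand == "+", ]
  # modified base is the A of GATC (0-based pos p): motif spans 1-based p..p+3
  for (p in plus$pos) {
    expect_equal(substr(gg$genome, p, p + 3L), "GATC")
  }
  minus <- gg$truth[gg$truth$strand == "-", ]
  for (p in minus$pos) {
    # read-orientation GATC on the minus strand: genome shows its complement
    expect_equal(substr(gg$genome, p - 1L, p + 2L), "GATC")
    expect_equal(substr(gg$genome, p + 1L, p + 1L), "T")
  }
  # positions unique per strand
  expect_false(any(duplicated(paste(gg$truth$pos, gg$truth$strand))))
})

test_that("methyl_fraction scales the truth set; degenerate cases handled", {
  cfg0 <- sim_config(genome_length = 2000L, motif = "GATC", mod_offset = 1L,
                     methyl_fraction = 0, seed = 12L)
  expect_equal(nrow(generate_genome(cfg0)$truth), 0L)

  cfg_half <- sim_config(genome_length = 2000L, motif = "GATC", mod_offset = 1L,
                         methyl_fraction = 0.5, seed = 12L)
  gg <- generate_genome(cfg_half)
  all_sites <- find_motif_sites(gg$genome, "GATC", 1L, gg$contig)
  expect_equal(nrow(gg$truth), round(0.5 * nrow(all_sites)))

  expect_error(generate_genome(sim_config(genome_length = 3L, motif = "GATC",
                                          mod_offset = 1L)), "longer")
  # GC-only genome cannot contain an A-rich motif
  cfg_gc <- sim_config(genome_length = 500L, gc_content = 1, motif = "AATT",
                       mod_offset = 1L, seed = 13L)
  expect_warning(gg2 <- generate_genome(cfg_gc), "no occurrence")
  expect_equal(nrow(gg2$truth), 0L)
})

test_that("IUPAC motif matching agrees with a brute-force regex scan", {
  cfg <- sim_config(genome_length = 5000L, motif = "CCWGG", mod_offset = 1L,
                    seed = 14L)
  gg <- generate_genome(cfg)
  got <- find_motif_sites(gg$genome, "CCWGG", 1L)
  want <- oracle_motif_scan(gg$genome, "CCWGG", 1L)
  expect_equal(sort(got$pos[got$strand == "+"]), want$plus)
  expect_equal(sort(got$pos[got$strand == "-"]), want$minus)
  # and for a non-palindromic ambiguous motif
  got2 <- find_motif_sites(gg$genome, "GCNGC", 1L)
  want2 <- oracle_motif_scan(gg$genome, "GCNGC", 1L)
  expect_equal(sort(got2$pos[got2$strand == "+"]), want2$plus)
  expect_equal(sort(got2$pos[got2$strand == "-"]), want2$minus)
})

test_that("noise-free WGA simulation reproduces the k-mer table exactly", {
  sim <- fx_nf_sim()
  expect_equal(sim$wga$ipd, sim$wga$ipd_true)
  expect_equal(sim$wga$pw, sim$wga$pw_true)
  # plus-strand context lookup matches the table
  plus <- sim$wga[sim$wga$strand == "+", ][1:50, ]
  ctx <- substring(sim$genome, plus$pos, plus$pos + 2L)  # 0-based center +-1
  expect_equal(kmer_value(sim$gt, ctx, "ipd"), plus$ipd_true)
  # minus-strand context is the reverse complement
  minus <- sim$wga[sim$wga$strand == "-", ][1:50, ]
  ctx_m <- reverse_complement(substring(sim$genome, minus$pos, minus$pos + 2L))
  expect_equal(kmer_value(sim$gt, ctx_m, "ipd"), minus$ipd_true)
})

test_that("kinetic shifts are multiplicative, strand-local and offset-local", {
  cfg <- sim_config(genome_length = 3000L, motif = "GATC", mod_offset = 1L,
                    methyl_fraction = 1, context_k = 3L,
                    ipd_shift = c("0" = 2.0, "1" = 1.5),
                    pw_shift = c("0" = 1.8),
                    subread_noise_sigma = 0, coverage_mean = 1, seed = 15L)
  gt <- ground_truth_kinetics(cfg)
  gg <- generate_genome(cfg)
  native <- simulate_kinetics(gg$genome, gg$truth, cfg, gt, contig = gg$contig)
  wga <- simulate_kinetics(gg$genome, gg$truth[0, ], cfg, gt, contig = gg$contig)
  key <- function(df) paste(df$pos, df$strand)
  expect_equal(key(native), key(wga))
  ratio <- native$ipd_true / wga$ipd_true
  # expected shift profile per strand from the truth
  expected <- rep(1, nrow(native))
  for (i in seq_len(nrow(gg$truth))) {
    s <- gg$truth[i, ]
    for (off in c(0L, 1L)) {
      p <- if (s$strand == "+") s$pos + off else s$pos - off
      hit <- which(native$pos == p & native$strand == s$strand)
      expected[hit] <- expected[hit] * c(2.0, 1.5)[off + 1L]
    }
  }
  expect_equal(ratio, expected)
  # pw shifted only at offset 0
  pw_ratio <- native$pw_true / wga$pw_true
  shifted <- which(abs(pw_ratio - 1) > 1e-12)
  expect_true(all(native$pos[shifted] %in% gg$truth$pos))
})

test_that("subread averages converge to the configured shift (Monte Carlo)", {
  cfg <- sim_config(genome_length = 1500L, motif = "GATC", mod_offset = 1L,
                    methyl_fraction = 1, context_k = 3L,
                    ipd_shift = c("0" = 2.0), pw_shift = c("0" = 2.0),
                    subread_noise_sigma = 0.2, coverage_mean = 5000,
                    seed = 16L)
  gt <- ground_truth_kinetics(cfg)
  gg <- generate_genome(cfg)
  native <- simulate_kinetics(gg$genome, gg$truth, cfg, gt, contig = gg$contig)
  # matched pair: a methylated site and an unmethylated position sharing the
  # same read-orientation 3-mer context on the plus strand
  plus <- native[native$strand == "+", ]
  ctx <- substring(gg$genome, plus$pos, plus$pos + 2L)
  tpos <- gg$truth$pos[gg$truth$strand == "+"]
  near <- unlist(lapply(-1:1, function(o) gg$truth$pos + o))
  meth_i <- match(tpos[1], plus$pos)
  mate_i <- which(ctx == ctx[meth_i] & !(plus$pos %in% near))[1]
  expect_false(is.na(mate_i))
  ratio <- plus$ipd[meth_i] / plus$ipd[mate_i]
  # each site mean has relative s.e. ~ sigma/sqrt(n); allow 3 s.e. on the ratio
  se <- 3 * sqrt(2) * 2 * cfg$subread_noise_sigma / sqrt(5000)
  expect_lt(abs(ratio - 2.0), se)
})

test_that("same-context draws from native and WGA genomes are exchangeable", {
  # distributional equality at fixed context: unmethylated native positions
  # vs WGA positions, same k-mer, should pass a two-sample KS test
  cfg <- sim_config(genome_length = 4000L, motif = "GATC", mod_offset = 1L,
                    methyl_fraction = 1, context_k = 3L,
                    subread_noise_sigma = 0.3, coverage_mean = 1, seed = 17L)
  gt <- ground_truth_kinetics(cfg)
  gg <- generate_genome(cfg)
  native <- simulate_kinetics(gg$genome, gg$truth, cfg, gt, contig = gg$contig)
  wga <- simulate_kinetics(gg$genome, gg$truth[0, ], cfg, gt, contig = gg$contig)
  plus_n <- native[native$strand == "+", ]
  plus_w <- wga[wga$strand == "+", ]
  ctx <- substring(gg$genome, plus_n$pos, plus_n$pos + 2L)
  near <- unlist(lapply(-1:1, function(o) gg$truth$pos + o))
  # normalize out the per-context mean so draws pool across contexts
  clean <- !(plus_n$pos %in% near)
  x <- (plus_n$ipd / plus_n$ipd_true)[clean]
  y <- plus_w$ipd / plus_w$ipd_true
  ks <- suppressWarnings(stats::ks.test(x, y))
  expect_gt(ks$p.value, 0.001)
})

test_that("simulation is deterministic and fixtures are byte-identical", {
  cfg <- sim_config(genome_length = 2000L, motif = "GATC", mod_offset = 1L,
                    methyl_fraction = 0.7, coverage_mean = 4,
                    subread_noise_sigma = 0.2, seed = 18L)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$native, s2$native)
  expect_identical(s1$truth, s2$truth)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_sim_fixture(s1, d1)
  write_sim_fixture(s2, d2)
  for (f in c("genome.fasta", "kinetics_native.tsv", "kinetics_wga.tsv",
              "truth.bed")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("fixtures round-trip through the readers", {
  sim <- fx_small_sim()
  dir <- withr::local_tempdir()
  paths <- write_sim_fixture(sim, dir)
  genome <- read_genome_fasta(paths$genome)
  expect_identical(unname(genome[1]), sim$genome)
  kin <- read_kinetics(paths$native)
  expect_equal(kin$pos, sim$native$pos)
  expect_equal(kin$strand, sim$native$strand)
  expect_equal(kin$ipd, sim$native$ipd, tolerance = 1e-6)
  expect_equal(kin$pw, sim$native$pw, tolerance = 1e-6)
  truth <- read_truth_bed(paths$truth)
  expect_equal(nrow(truth), nrow(sim$truth))
  expect_equal(truth$pos, sim$truth$pos)
  # BED intervals are 0-based half-open width 1
  raw <- read.table(paths$truth, sep = "\t")
  expect_true(all(raw$V3 - raw$V2 == 1L))
  expect_equal(raw$V2, sim$truth$pos)
  cfg2 <- read_sim_config(paths$config)
  expect_equal(unclass(cfg2), unclass(sim$cfg))
})
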