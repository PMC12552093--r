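# Synthetic SMRT kinetics: seeded genomes, motif-placed methylation truth and
# per-site IPD/PW signals with a known sequence-context ground truth. This is
# the test bed for the whole pipeline: a WGA mode (no modifications) trains
# the baseline regressor, and motif-localized multiplicative kinetic shifts of
# tunable magnitude emulate weak (5mC-like) and strong (6mA/4mC-like) regimes.

#' Preset kinetic-shift profiles
#'
#' Multiplicative IPD/PW effects of a modification on the modified base
#' (offset 0, read orientation) and its downstream neighbour (+1). The
#' \code{"weak"} preset emulates the subtle 5mC signature, \code{"strong"} the
#' pronounced 6mA/4mC one. Values are stand-ins with the right order of
#' magnitude, not chemistry estimates.
#'
#' @param name \code{"weak"} or \code{"strong"}.
#' @return List with named numeric vectors \code{ipd_shift} and
#'   \code{pw_shift}; names are relative offsets.
#' @export
kinetic_shift_preset <- function(name = c("weak", "strong")) {
  name <- match.arg(name)
  if (name == "weak") {
    list(ipd_shift = c("0" = 1.15, "1" = 1.075),
         pw_shift  = c("0" = 1.10, "1" = 1.05))
  } else {
    list(ipd_shift = c("0" = 2.5, "1" = 1.75),
         pw_shift  = c("0" = 2.0, "1" = 1.5))
  }
}

#' Simulation configuration
#'
#' @param genome_length Genome length in bp.
#' @param gc_content GC fraction in \[0, 1\].
#' @param motif IUPAC motif recognized by the emulated methyltransferase.
#' @param mod_offset 0-based offset of the modified base within the motif.
#' @param methyl_fraction Fraction of motif sites that are methylated.
#' @param context_k Odd k-mer width of the ground-truth kinetic function.
#' @param ipd_shift,pw_shift Named numeric vectors of multiplicative kinetic
#'   effects; names are read-orientation offsets relative to the modified base.
#' @param subread_noise_sigma Log-sd of per-subread multiplicative noise.
#' @param coverage_mean Mean subreads per site (shifted Poisson, minimum 1).
#' @param mod_label Label recorded in the methylation truth (e.g. "5mC").
#' @param seed Integer seed; identical configs give identical simulations.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(genome_length = 10000L, gc_content = 0.5,
                       motif = "CCWGG", mod_offset = 1L,
                       methyl_fraction = 1,
                       context_k = 7L,
                       ipd_shift = kinetic_shift_preset("weak")$ipd_shift,
                       pw_shift = kinetic_shift_preset("weak")$pw_shift,
                       subread_noise_sigma = 0.2,
                       coverage_mean = 10,
                       mod_label = "mod",
                       seed = 1L) {
  if (genome_length < 1) stopf("genome_length must be positive")
  if (gc_content < 0 || gc_content > 1) stopf("gc_content must be in [0,1]")
  if (!nzchar(motif) || !is_iupac(motif)) {
    stopf("motif must be a non-empty IUPAC string, got '%s'", motif)
  }
  if (mod_offset < 0 || mod_offset >= nchar(motif)) {
    stopf("mod_offset must satisfy 0 <= mod_offset < nchar(motif)")
  }
  if (context_k %% 2 != 1 || context_k < 3) stopf("context_k must be odd and >= 3")
  if (context_k > 10) stopf("context_k > 10 is not supported")
  if (methyl_fraction < 0 || methyl_fraction > 1) {
    stopf("methyl_fraction must be in [0,1]")
  }
  if (coverage_mean < 1) stopf("coverage_mean must be >= 1")
  if (subread_noise_sigma < 0) stopf("subread_noise_sigma must be >= 0")
  chk_shift <- function(s, what) {
    if (length(s) && (is.null(names(s)) || anyNA(suppressWarnings(as.integer(names(s)))))) {
      stopf("%s must be a named vector with integer offsets as names", what)
    }
    if (any(s <= 0)) stopf("%s factors must be positive", what)
  }
  chk_shift(ipd_shift, "ipd_shift"); chk_shift(pw_shift, "pw_shift")
  structure(list(
    genome_length = as.integer(genome_length), gc_content = gc_content,
    motif = motif, mod_offset = as.integer(mod_offset),
    methyl_fraction = methyl_fraction, context_k = as.integer(context_k),
    ipd_shift = ipd_shift, pw_shift = pw_shift,
    subread_noise_sigma = subread_noise_sigma, coverage_mean = coverage_mean,
    mod_label = mod_label, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Kinetics simulation config: %d bp genome (GC %.2f), motif %s (mod offset %d)\n",
              x$genome_length, x$gc_content, x$motif, x$mod_offset))
  cat(sprintf("  methyl_fraction %.2f, context_k %d, coverage %g, subread log-sd %g, seed %d\n",
              x$methyl_fraction, x$context_k, x$coverage_mean,
              x$subread_noise_sigma, x$seed))
  invisible(x)
}

#' Ground-truth sequence-context kinetic function
#'
#' Draws, once per seed, the mapping from every \code{context_k}-mer to its
#' noiseless unmethylated (IPD, PW) value. Log-values are a sum of
#' center-weighted per-position base effects plus a small k-mer-specific
#' residual, scaled so the marginal distribution over k-mers is log-normal
#' with median 1.0 and log-sd 0.35 per channel. The positional structure makes
#' the context dependence learnable by a sequence model, which is the property
#' the downstream regressor is meant to capture.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return Object of class \code{ground_truth_kinetics} with full lookup
#'   tables (\code{table_ipd}, \code{table_pw}, length \code{4^context_k}).
#' @export
ground_truth_kinetics <- function(cfg) {
  k <- cfg$context_k
  nk <- 4^k
  total_log_sd <- 0.35
  residual_share <- 0.10
  set.seed(cfg$seed)
  draw_channel <- function() {
    w <- exp(-abs(seq_len(k) - (k + 1) / 2) / 1.5)
    var_pos <- (1 - residual_share) * total_log_sd^2 * w / sum(w)
    eff <- matrix(rnorm(k * 4), k, 4)
    eff <- eff - rowMeans(eff)
    pop_sd <- sqrt(rowMeans(eff^2))
    eff <- eff * sqrt(var_pos) / pop_sd
    eta <- rnorm(nk)
    eta <- (eta - mean(eta)) / sd(eta) * sqrt(residual_share) * total_log_sd
    idx <- seq_len(nk) - 1
    logv <- eta
    for (j in seq_len(k) - 1L) {
      digit <- (idx %/% 4^(k - 1L - j)) %% 4
      logv <- logv + eff[j + 1L, digit + 1L]
    }
    exp(logv)
  }
  structure(list(
    k = k,
    table_ipd = draw_channel(),
    table_pw = draw_channel(),
    seed = cfg$seed
  ), class = "ground_truth_kinetics")
}

#' Look up ground-truth kinetics for k-mer strings
#'
#' @param gt A \code{\link{ground_truth_kinetics}} object.
#' @param kmer Character vector of k-mers (read orientation).
#' @param channel \code{"ipd"} or \code{"pw"}.
#' @return Numeric vector of noiseless values.
#' @export
kmer_value <- function(gt, kmer, channel = c("ipd", "pw")) {
  channel <- match.arg(channel)
  if (any(nchar(kmer) != gt$k)) stopf("k-mers must have width %d", gt$k)
  idx <- kmer_string_to_index(kmer)
  tab <- if (channel == "ipd") gt$table_ipd else gt$table_pw
  tab[idx + 1]
}

#' Generate a random genome with motif-placed methylation truth
#'
#' Samples a genome of the requested length and GC content, locates all motif
#' occurrences on both strands (IUPAC-aware) and marks a seeded subset of
#' \code{round(methyl_fraction * n_sites)} of them as methylated.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return List with \code{genome} (character string), \code{contig} name and
#'   \code{truth}, a data.frame (contig, pos, strand, mod_type) of methylated
#'   sites; positions are 0-based modified-base coordinates.
#' @export
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nchar(cfg$motif) > cfg$genome_length) {
    stopf("motif ('%s') is longer than the genome (%d bp)",
          cfg$motif, cfg$genome_length)
  }
  set.seed(cfg$seed + 1L)
  p_gc <- cfg$gc_content / 2
  p_at <- (1 - cfg$gc_content) / 2
  bases <- sample(DNA_BASES, cfg$genome_length, replace = TRUE,
                  prob = c(p_at, p_gc, p_gc, p_at))
  genome <- paste0(bases, collapse = "")
  contig <- "sim1"
  sites <- find_motif_sites(genome, cfg$motif, cfg$mod_offset, contig = contig)
  if (nrow(sites) == 0) {
    warnf("no occurrence of motif '%s' in the simulated genome", cfg$motif)
    truth <- data.frame(contig = character(), pos = integer(),
                        strand = character(), mod_type = character(),
                        stringsAsFactors = FALSE)
    return(list(genome = genome, contig = contig, truth = truth))
  }
  n_mod <- round(cfg$methyl_fraction * nrow(sites))
  pick <- sort(sample(nrow(sites), n_mod))
  truth <- sites[pick, , drop = FALSE]
  truth$mod_type <- rep(cfg$mod_label, nrow(truth))
  rownames(truth) <- NULL
  list(genome = genome, contig = contig, truth = truth)
}

# multiplicative shift profile over the genome for one strand and one channel
shift_profile <- function(L, truth, strand, shift) {
  sh <- rep(1, L)
  st <- truth[truth$strand == strand, , drop = FALSE]
  if (nrow(st) == 0 || length(shift) == 0) return(sh)
  offs <- as.integer(names(shift))
  for (i in seq_along(offs)) {
    # read-orientation offset maps to +off on the plus strand, -off on minus
    p <- if (strand == "+") st$pos + offs[i] else st$pos - offs[i]
    p <- p[p >= 0 & p < L]
    sh[p + 1] <- sh[p + 1] * shift[[i]]
  }
  sh
}

#' Simulate per-site kinetic signals
#'
#' For every interior position p and strand, the noiseless value is
#' \code{kmer_table[context(p)] * shift(p)} where \code{shift(p)} multiplies in
#' the configured IPD/PW effects when p sits at a covered offset from a
#' methylated site on the same strand (1 otherwise). Each site receives
#' \code{1 + Poisson(coverage_mean - 1)} subreads whose values carry
#' independent log-normal noise \code{exp(N(0, subread_noise_sigma))}; the
#' emitted signal is the subread mean. Positions within \code{context_k \%/\% 2}
#' of the contig ends have no defined context and are excluded.
#'
#' @param genome Genome character string.
#' @param truth Methylation truth data.frame (as from
#'   \code{\link{generate_genome}}); zero rows give WGA (no-modification) mode.
#' @param cfg A \code{\link{sim_config}}.
#' @param gt Optional precomputed \code{\link{ground_truth_kinetics}} (so that
#'   several genomes can share one kinetic function).
#' @param seed_offset Offset added to \code{cfg$seed} for the noise stream, so
#'   native and WGA tracks of one dataset use independent draws.
#' @param contig Contig name.
#' @return A data.frame of class \code{sim_kinetics} with columns contig, pos,
#'   strand, ipd, pw, n_subreads and the noiseless means ipd_true, pw_true.
#' @export
simulate_kinetics <- function(genome, truth, cfg, gt = NULL,
                              seed_offset = 2L, contig = "sim1") {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(gt)) gt <- ground_truth_kinetics(cfg)
  set.seed(cfg$seed + seed_offset)
  L <- nchar(genome)
  codes <- seq_codes(genome)
  if (anyNA(codes)) stopf("genome contains non-ACGT characters")
  out <- vector("list", 2)
  for (si in 1:2) {
    strand <- c("+", "-")[si]
    ki <- kmer_indices(codes, gt$k, strand)
    ipd_true <- gt$table_ipd[ki$idx + 1] *
      shift_profile(L, truth, strand, cfg$ipd_shift)[ki$pos + 1]
    pw_true <- gt$table_pw[ki$idx + 1] *
      shift_profile(L, truth, strand, cfg$pw_shift)[ki$pos + 1]
    npos <- length(ki$pos)
    n_sub <- 1L + rpois(npos, cfg$coverage_mean - 1)
    if (cfg$subread_noise_sigma > 0) {
      g <- rep.int(seq_len(npos), n_sub)
      fac_ipd <- as.vector(rowsum(exp(rnorm(length(g), 0, cfg$subread_noise_sigma)), g)) / n_sub
      fac_pw <- as.vector(rowsum(exp(rnorm(length(g), 0, cfg$subread_noise_sigma)), g)) / n_sub
    } else {
      fac_ipd <- fac_pw <- rep(1, npos)
    }
    out[[si]] <- data.frame(
      contig = contig, pos = ki$pos, strand = strand,
      ipd = ipd_true * fac_ipd, pw = pw_true * fac_pw,
      n_subreads = n_sub,
      ipd_true = ipd_true, pw_true = pw_true,
      stringsAsFactors = FALSE
    )
  }
  res <- rbind(out[[1]], out[[2]])
  class(res) <- c("sim_kinetics", "data.frame")
  res
}

#' Simulate a complete dataset: genome, truth, native and WGA kinetics
#'
#' The WGA track is the same genome re-sequenced with all modifications
#' removed (independent noise draws), mirroring whole-genome amplification of
#' the same organism.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param gt Optional shared \code{\link{ground_truth_kinetics}}.
#' @return List of class \code{sim_dataset}: genome, contig, truth, native,
#'   wga, gt, cfg.
#' @export
simulate_dataset <- function(cfg, gt = NULL) {
  if (is.null(gt)) gt <- ground_truth_kinetics(cfg)
  gg <- generate_genome(cfg)
  no_truth <- gg$truth[0, , drop = FALSE]
  native <- simulate_kinetics(gg$genome, gg$truth, cfg, gt, seed_offset = 2L,
                              contig = gg$contig)
  wga <- simulate_kinetics(gg$genome, no_truth, cfg, gt, seed_offset = 3L,
                           contig = gg$contig)
  structure(list(genome = gg$genome, contig = gg$contig, truth = gg$truth,
                 native = native, wga = wga, gt = gt, cfg = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Simulated SMRT dataset: %d bp, motif %s, %d methylated sites, %d kinetic records/track\n",
              nchar(x$genome), x$cfg$motif, nrow(x$truth), nrow(x$native)))
  invisible(x)
}

#' Write a simulated dataset to disk as plain-text fixtures
#'
#' Emits the genome as FASTA, native and WGA kinetics as the package's TSV
#' dialect, the methylation truth as BED6 (0-based half-open single-base
#' intervals) and the configuration as YAML. Files round-trip through the
#' package readers to six decimals.
#'
#' @param sim A \code{\link{simulate_dataset}} result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named list of the file paths written.
#' @export
write_sim_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stopf("cannot create directory '%s'", dir)
  paths <- list(
    genome = file.path(dir, "genome.fasta"),
    native = file.path(dir, "kinetics_native.tsv"),
    wga = file.path(dir, "kinetics_wga.tsv"),
    truth = file.path(dir, "truth.bed"),
    config = file.path(dir, "sim_config.yaml")
  )
  gen <- stats::setNames(sim$genome, sim$contig)
  write_genome_fasta(gen, paths$genome)
  write_kinetics(sim$native, paths$native)
  write_kinetics(sim$wga, paths$wga)
  write_truth_bed(sim$truth, paths$truth)
  cfg <- sim$cfg
  cfg_list <- unclass(cfg)
  cfg_list$ipd_shift <- as.list(cfg_list$ipd_shift)
  cfg_list$pw_shift <- as.list(cfg_list$pw_shift)
  yaml::write_yaml(cfg_list, paths$config)
  invisible(paths)
}

#' Read back a simulation configuration written by \code{write_sim_fixture}
#'
#' @param path YAML file path.
#' @return A \code{\link{sim_config}}.
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim_config(
    genome_length = x$genome_length, gc_content = x$gc_content,
    motif = x$motif, mod_offset = x$mod_offset,
    methyl_fraction = x$methyl_fraction, context_k = x$context_k,
    ipd_shift = unlist(x$ipd_shift), pw_shift = unlist(x$pw_shift),
    subread_noise_sigma = x$subread_noise_sigma,
    coverage_mean = x$coverage_mean, mod_label = x$mod_label, seed = x$seed
  )
}
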