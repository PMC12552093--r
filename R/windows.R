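# Labeled 41-bp sample windows with aligned 21-bp kinetic vectors, and the
# positive/negative sampling rules: training negatives are the same motif's
# instances in WGA data, test negatives are random motif-free positions whose
# central base matches the modified base letter (so composition alone cannot
# separate the classes).

#' Locate IUPAC motif occurrences on both strands
#'
#' Returns the 0-based genomic position of the modified base of every motif
#' occurrence. Minus-strand hits are occurrences of the reverse-complemented
#' motif; their modified-base coordinate is reported on the forward axis with
#' strand "-".
#'
#' @param genome Genome character string (one contig).
#' @param motif IUPAC motif.
#' @param mod_offset 0-based offset of the modified base within the motif.
#' @param contig Contig name for the output.
#' @return Data.frame with contig, pos, strand, sorted by (strand, pos).
#' @export
find_motif_sites <- function(genome, motif, mod_offset, contig = "sim1") {
  if (!is_iupac(motif)) stopf("'%s' is not a valid IUPAC motif", motif)
  if (mod_offset < 0 || mod_offset >= nchar(motif)) {
    stopf("mod_offset out of range for motif '%s'", motif)
  }
  if (nchar(motif) > nchar(genome)) {
    stopf("motif ('%s') is longer than the genome", motif)
  }
  subj <- Biostrings::DNAString(genome)
  mp <- Biostrings::matchPattern(motif, subj, fixed = FALSE)
  pos_plus <- Biostrings::start(mp) - 1L + mod_offset
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  mm <- Biostrings::matchPattern(rc, subj, fixed = FALSE)
  pos_minus <- Biostrings::start(mm) - 1L + (nchar(motif) - 1L - mod_offset)
  out <- data.frame(
    contig = rep(contig, length(pos_plus) + length(pos_minus)),
    pos = c(pos_plus, pos_minus),
    strand = rep(c("+", "-"), c(length(pos_plus), length(pos_minus))),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$strand, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# dense per-strand lookup of a kinetics track (NA where no record)
kinetics_index <- function(track, genome_length) {
  mk <- function(strand) {
    t2 <- track[track$strand == strand, , drop = FALSE]
    ipd <- rep(NA_real_, genome_length)
    pw <- rep(NA_real_, genome_length)
    ipd[t2$pos + 1L] <- t2$ipd
    pw[t2$pos + 1L] <- t2$pw
    list(ipd = ipd, pw = pw)
  }
  list(`+` = mk("+"), `-` = mk("-"))
}

new_sample_windows <- function(seq41, kin_ipd, kin_pw, meta) {
  structure(list(seq41 = seq41, kin_ipd = kin_ipd, kin_pw = kin_pw,
                 meta = meta),
            class = "sample_windows")
}

#' @export
print.sample_windows <- function(x, ...) {
  tab <- table(x$meta$label)
  cat(sprintf("sample_windows: %d windows (%s)\n", length(x$seq41),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
length.sample_windows <- function(x) length(x$seq41)

#' @export
`[.sample_windows` <- function(x, i) {
  new_sample_windows(x$seq41[i],
                     x$kin_ipd[i, , drop = FALSE],
                     x$kin_pw[i, , drop = FALSE],
                     x$meta[i, , drop = FALSE])
}

#' Concatenate sample window sets
#'
#' @param ... \code{sample_windows} objects.
#' @return A single \code{sample_windows} object.
#' @export
bind_windows <- function(...) {
  xs <- list(...)
  new_sample_windows(
    unlist(lapply(xs, `[[`, "seq41")),
    do.call(rbind, lapply(xs, `[[`, "kin_ipd")),
    do.call(rbind, lapply(xs, `[[`, "kin_pw")),
    do.call(rbind, lapply(xs, `[[`, "meta"))
  )
}

#' Unique site keys of a window set
#'
#' @param w A \code{sample_windows} object.
#' @return Character vector "contig:pos:strand", used to assert train/test
#'   disjointness.
#' @export
window_keys <- function(w) {
  paste(w$meta$contig, w$meta$pos, w$meta$strand, sep = ":")
}

# vectorized window construction over a set of candidate sites; sites at
# contig edges or with missing central kinetics are dropped (count reported
# via message when requested)
build_windows <- function(genome, kin_idx, sites, label, origin,
                          flank = 20L, kin_flank = 10L, quiet = TRUE) {
  L <- nchar(genome)
  keep <- sites$pos >= flank & sites$pos <= L - 1L - flank
  n_edge <- sum(!keep)
  sites <- sites[keep, , drop = FALSE]
  n <- nrow(sites)
  if (n == 0) {
    return(new_sample_windows(character(0),
                              matrix(numeric(0), 0, 2 * kin_flank + 1),
                              matrix(numeric(0), 0, 2 * kin_flank + 1),
                              data.frame(contig = character(), pos = integer(),
                                         strand = character(), label = character(),
                                         origin = character(), stringsAsFactors = FALSE)))
  }
  seq41 <- substring(genome, sites$pos - flank + 1L, sites$pos + flank + 1L)
  minus <- sites$strand == "-"
  if (any(minus)) {
    seq41[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seq41[minus])))
  }
  offs <- -kin_flank:kin_flank
  kin_ipd <- matrix(NA_real_, n, length(offs))
  kin_pw <- matrix(NA_real_, n, length(offs))
  for (strand in c("+", "-")) {
    rows <- which(sites$strand == strand)
    if (!length(rows)) next
    # kin21[i] aligns with seq41[i + 10]: genomic pos + off on the plus
    # strand, pos - off on the minus strand (read orientation)
    gpos <- if (strand == "+") outer(sites$pos[rows], offs, `+`)
            else outer(sites$pos[rows], offs, `-`)
    kin_ipd[rows, ] <- kin_idx[[strand]]$ipd[gpos + 1L]
    kin_pw[rows, ] <- kin_idx[[strand]]$pw[gpos + 1L]
  }
  complete <- rowSums(is.na(kin_ipd)) == 0 & rowSums(is.na(kin_pw)) == 0
  n_missing <- sum(!complete)
  if (!quiet && (n_edge || n_missing)) {
    message(sprintf("dropped %d edge site(s) and %d site(s) with missing kinetics",
                    n_edge, n_missing))
  }
  meta <- data.frame(contig = sites$contig, pos = sites$pos,
                     strand = sites$strand,
                     label = label, origin = origin, stringsAsFactors = FALSE)
  w <- new_sample_windows(seq41, kin_ipd, kin_pw, meta)
  w[complete]
}

#' Extract one labeled sample window
#'
#' The 41-bp sequence is centered on the candidate base (0-based index 20);
#' the 21 kinetic values align with the central 21 bases (\code{kin21[i]}
#' belongs to \code{seq41[i + 10]}, 0-based). For minus-strand sites the
#' sequence is the reverse complement and kinetics are taken from the
#' minus-strand track in matching (read) orientation.
#'
#' @param genome Genome character string.
#' @param track Kinetics data.frame (contig, pos, strand, ipd, pw, ...).
#' @param pos 0-based candidate position.
#' @param strand "+" or "-".
#' @param label,origin Window annotation.
#' @param flank Sequence flank (20 gives 41-bp windows).
#' @return A \code{sample_windows} object of length 1, or length 0 if the site
#'   is at a contig edge or lacks kinetics at any central position.
#' @export
extract_window <- function(genome, track, pos, strand,
                           label = "unknown", origin = "native", flank = 20L) {
  kin_idx <- kinetics_index(track, nchar(genome))
  sites <- data.frame(contig = track$contig[1] %||% "sim1", pos = pos,
                      strand = strand, stringsAsFactors = FALSE)
  build_windows(genome, kin_idx, sites, label, origin, flank = flank)
}

#' Sampling plan for positive/negative window construction
#'
#' Training negatives come from the same motif instances in WGA data; test
#' negatives are random genomic positions whose surrounding window contains no
#' known motif-modified base.
#'
#' @param mode \code{"train"} or \code{"test"}.
#' @param balance Force equal negative and positive counts (test mode).
#' @param exclusion_radius Bp radius around known modified bases that random
#'   negatives must avoid; 20 keeps the whole 41-bp context motif-free.
#' @param seed Seed for the negative draw.
#' @return Object of class \code{sampling_plan}.
#' @export
sampling_plan <- function(mode = c("train", "test"), balance = TRUE,
                          exclusion_radius = 20L, seed = 1L) {
  mode <- match.arg(mode)
  if (exclusion_radius < 0) stopf("exclusion_radius must be >= 0")
  structure(list(
    mode = mode,
    negative_source = if (mode == "train") "wga_same_motif" else "random_non_motif",
    balance = isTRUE(balance),
    exclusion_radius = as.integer(exclusion_radius),
    seed = as.integer(seed)
  ), class = "sampling_plan")
}

#' Build the training set: native motif positives vs WGA motif negatives
#'
#' Positives are motif-matching modified-base sites carrying native kinetics
#' (labeled methylated); negatives are the same motif instances carrying WGA
#' kinetics (labeled unmethylated). Because both classes share the motif,
#' sequence composition is uninformative during training and the classifier
#' must learn kinetic evidence.
#'
#' @param genome Genome character string.
#' @param native_track,wga_track Kinetics data.frames.
#' @param motif,mod_offset Motif specification.
#' @param plan A \code{\link{sampling_plan}} with mode "train".
#' @param sites Optional subset of motif sites to use (defaults to all);
#'   pass a split to keep train and test site-disjoint.
#' @param contig Contig name.
#' @param flank Sequence flank.
#' @return A \code{sample_windows} object.
#' @export
build_training_set <- function(genome, native_track, wga_track, motif,
                               mod_offset, plan = sampling_plan("train"),
                               sites = NULL, contig = "sim1", flank = 20L) {
  stopifnot(inherits(plan, "sampling_plan"))
  if (plan$mode != "train") stopf("plan mode must be 'train'")
  if (is.null(sites)) sites <- find_motif_sites(genome, motif, mod_offset, contig)
  kin_nat <- kinetics_index(native_track, nchar(genome))
  kin_wga <- kinetics_index(wga_track, nchar(genome))
  pos_w <- build_windows(genome, kin_nat, sites, "methylated", "native", flank)
  neg_w <- build_windows(genome, kin_wga, sites, "unmethylated", "wga", flank)
  if (length(pos_w) == 0) stopf("no positive training windows could be built")
  if (length(neg_w) == 0) stopf("no negative training windows could be built")
  bind_windows(pos_w, neg_w)
}

#' Build the test set: motif positives vs random motif-free negatives
#'
#' Negatives are drawn uniformly (seeded) from positions whose central base,
#' in read orientation, equals the motif's modified-base letter and whose
#' \code{exclusion_radius} neighbourhood contains no known motif-modified
#' base, on either strand. With \code{balance}, exactly as many negatives as
#' positives are drawn.
#'
#' @param genome Genome character string.
#' @param track Native kinetics data.frame.
#' @param motif,mod_offset Motif specification.
#' @param plan A \code{\link{sampling_plan}} with mode "test".
#' @param sites Optional positive site subset (defaults to all motif sites).
#' @param known_sites All known motif sites used for the exclusion scan
#'   (defaults to all motif occurrences in the genome).
#' @param contig Contig name.
#' @param flank Sequence flank.
#' @return A \code{sample_windows} object.
#' @export
build_test_set <- function(genome, track, motif, mod_offset,
                           plan = sampling_plan("test"), sites = NULL,
                           known_sites = NULL, contig = "sim1", flank = 20L) {
  stopifnot(inherits(plan, "sampling_plan"))
  if (plan$mode != "test") stopf("plan mode must be 'test'")
  all_sites <- find_motif_sites(genome, motif, mod_offset, contig)
  if (is.null(sites)) sites <- all_sites
  if (is.null(known_sites)) known_sites <- all_sites
  kin_idx <- kinetics_index(track, nchar(genome))
  pos_w <- build_windows(genome, kin_idx, sites, "methylated", "native", flank)
  if (length(pos_w) == 0) stopf("no positive test windows could be built")

  L <- nchar(genome)
  # positions blocked by proximity to any known modified base
  blocked <- rep(FALSE, L)
  if (nrow(known_sites)) {
    r <- plan$exclusion_radius
    lo <- pmax(known_sites$pos - r, 0L)
    hi <- pmin(known_sites$pos + r, L - 1L)
    for (i in seq_along(lo)) blocked[(lo[i] + 1L):(hi[i] + 1L)] <- TRUE
  }
  # candidate central base must equal the modified base letter (read
  # orientation): genome base = letter on +, complement(letter) on -
  letter <- substr(motif, mod_offset + 1L, mod_offset + 1L)
  letter_set <- IUPAC_MAP[[letter]]
  comp_set <- chartr("ACGT", "TGCA", letter_set)
  bases <- strsplit(genome, "")[[1]]
  interior <- seq.int(flank, L - 1L - flank)  # 0-based
  elig_plus <- interior[bases[interior + 1L] %in% letter_set &
                          !blocked[interior + 1L]]
  elig_minus <- interior[bases[interior + 1L] %in% comp_set &
                           !blocked[interior + 1L]]
  cand <- data.frame(
    contig = rep(contig, length(elig_plus) + length(elig_minus)),
    pos = c(elig_plus, elig_minus),
    strand = rep(c("+", "-"), c(length(elig_plus), length(elig_minus))),
    stringsAsFactors = FALSE
  )
  n_neg <- if (plan$balance) length(pos_w) else nrow(cand)
  if (nrow(cand) < n_neg) {
    stopf("insufficient eligible negative positions: need %d, found %d (short by %d)",
          n_neg, nrow(cand), n_neg - nrow(cand))
  }
  set.seed(plan$seed)
  # draw extra candidates to absorb drops from missing kinetics, then trim
  draw <- cand[sample(nrow(cand), min(nrow(cand), n_neg + ceiling(0.2 * n_neg) + 50L)), ,
               drop = FALSE]
  neg_w <- build_windows(genome, kin_idx, draw, "unmethylated",
                         "random_negative", flank)
  if (length(neg_w) < n_neg) {
    stopf("insufficient eligible negatives after kinetic filtering: need %d, got %d (short by %d)",
          n_neg, length(neg_w), n_neg - length(neg_w))
  }
  neg_w <- neg_w[seq_len(n_neg)]
  bind_windows(pos_w, neg_w)
}

#' Write sample windows as TSV
#'
#' Columns: contig, pos, strand, label, origin, seq41, ipd_1..ipd_21,
#' pw_1..pw_21.
#'
#' @param w A \code{sample_windows} object.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
write_windows <- function(w, path) {
  k <- ncol(w$kin_ipd)
  df <- data.frame(w$meta, seq41 = w$seq41, stringsAsFactors = FALSE)
  ipd <- as.data.frame(w$kin_ipd)
  names(ipd) <- paste0("ipd_", seq_len(k))
  pw <- as.data.frame(w$kin_pw)
  names(pw) <- paste0("pw_", seq_len(k))
  out <- cbind(df, ipd, pw)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample windows from TSV
#'
#' @param path File written by \code{\link{write_windows}}.
#' @return A \code{sample_windows} object.
#' @export
read_windows <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  ipd_cols <- grep("^ipd_", names(df))
  pw_cols <- grep("^pw_", names(df))
  new_sample_windows(
    df$seq41,
    as.matrix(df[, ipd_cols, drop = FALSE]),
    as.matrix(df[, pw_cols, drop = FALSE]),
    df[, c("contig", "pos", "strand", "label", "origin"), drop = FALSE]
  )
}
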