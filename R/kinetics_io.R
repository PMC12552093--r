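# IO for genomes, kinetics tables and methylation truth, plus the signal
# normalization and subread averaging applied before any modelling.

KINETICS_HEADER <- c("contig", "pos0", "strand", "ipd_mean", "pw_mean", "n_subreads")

#' Write a kinetics table
#'
#' Tab-separated dialect with a '#'-prefixed header line:
#' \code{#contig pos0 strand ipd_mean pw_mean n_subreads}. Positions are
#' 0-based; kinetic values are printed with six decimals.
#'
#' @param track Data.frame with columns contig, pos, strand, ipd, pw,
#'   n_subreads (extra columns are ignored).
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
write_kinetics <- function(track, path) {
  need <- c("contig", "pos", "strand", "ipd", "pw", "n_subreads")
  if (!all(need %in% names(track))) {
    stopf("track must have columns %s", paste(need, collapse = ", "))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(KINETICS_HEADER, collapse = "\t")), con)
  lines <- sprintf("%s\t%d\t%s\t%.6f\t%.6f\t%d",
                   track$contig, as.integer(track$pos), track$strand,
                   track$ipd, track$pw, as.integer(track$n_subreads))
  writeLines(lines, con)
  invisible(path)
}

#' Read a kinetics table
#'
#' Validates the dialect strictly: header must match, every row must have six
#' fields, strands must be + or -, kinetic values must be finite and
#' non-negative, subread counts at least 1, and (contig, pos, strand) keys
#' must be unique. Violations raise errors naming the offending line.
#'
#' @param path File written by \code{\link{write_kinetics}} (or equivalent).
#' @return Data.frame with columns contig, pos, strand, ipd, pw, n_subreads.
#' @export
read_kinetics <- function(path) {
  if (!file.exists(path)) stopf("kinetics file '%s' does not exist", path)
  hdr <- readLines(path, n = 1L)
  expected <- paste0("#", paste(KINETICS_HEADER, collapse = "\t"))
  if (!identical(hdr, expected)) {
    stopf("unexpected kinetics header in '%s': got '%s'", path, hdr)
  }
  nf <- count.fields(path, sep = "\t", comment.char = "")
  bad <- which(nf != 6L)
  bad <- bad[bad > 1L]
  if (length(bad)) {
    stopf("malformed row in '%s' at line %d: expected 6 tab-separated fields, found %d",
          path, bad[1], nf[bad[1]])
  }
  df <- read.table(path, sep = "\t", skip = 1L, comment.char = "",
                   col.names = KINETICS_HEADER,
                   colClasses = c("character", "integer", "character",
                                  "numeric", "numeric", "integer"))
  names(df) <- c("contig", "pos", "strand", "ipd", "pw", "n_subreads")
  line_of <- function(i) i + 1L  # header offset
  bad_strand <- which(!df$strand %in% c("+", "-"))
  if (length(bad_strand)) {
    stopf("invalid strand '%s' in '%s' at line %d (must be + or -)",
          df$strand[bad_strand[1]], path, line_of(bad_strand[1]))
  }
  bad_val <- which(!is.finite(df$ipd) | !is.finite(df$pw) |
                     df$ipd < 0 | df$pw < 0)
  if (length(bad_val)) {
    stopf("negative or non-finite kinetic value in '%s' at line %d",
          path, line_of(bad_val[1]))
  }
  bad_cov <- which(df$n_subreads < 1L)
  if (length(bad_cov)) {
    stopf("n_subreads < 1 in '%s' at line %d", path, line_of(bad_cov[1]))
  }
  key <- paste(df$contig, df$pos, df$strand)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stopf("duplicated record (%s, pos %d, strand %s) in '%s' at line %d",
          df$contig[dup[1]], df$pos[dup[1]], df$strand[dup[1]],
          path, line_of(dup[1]))
  }
  df
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return Named character vector, one element per contig.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a genome FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
write_genome_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write methylation truth as BED6
#'
#' One record per modified base as a 0-based half-open interval of width 1.
#'
#' @param truth Data.frame with contig, pos, strand, mod_type.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
write_truth_bed <- function(truth, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   truth$contig, as.integer(truth$pos),
                   as.integer(truth$pos) + 1L,
                   truth$mod_type, truth$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read methylation truth from BED6
#'
#' @param path BED file written by \code{\link{write_truth_bed}}.
#' @return Data.frame with contig, pos, strand, mod_type.
#' @export
read_truth_bed <- function(path) {
  if (!file.exists(path)) stopf("BED file '%s' does not exist", path)
  if (length(readLines(path, n = 1L)) == 0L) {
    return(data.frame(contig = character(), pos = integer(),
                      strand = character(), mod_type = character(),
                      stringsAsFactors = FALSE))
  }
  df <- read.table(path, sep = "\t",
                   col.names = c("contig", "start", "end", "name", "score", "strand"),
                   colClasses = c("character", "integer", "integer",
                                  "character", "numeric", "character"))
  if (any(df$end - df$start != 1L)) {
    stopf("truth BED intervals must have width 1 (0-based half-open)")
  }
  data.frame(contig = df$contig, pos = df$start, strand = df$strand,
             mod_type = df$name, stringsAsFactors = FALSE)
}

#' Normalization specification for kinetic signals
#'
#' @param method \code{"mean_scale"} (divide by the group mean; keeps values
#'   positive so ratio features stay well-defined) or \code{"zscore"}.
#' @param scope Grouping the statistics are computed over: \code{"per_read"}
#'   or \code{"global"}.
#' @param epsilon Small positive guard against division by ~0.
#' @return Object of class \code{normalization_spec}.
#' @export
normalization_spec <- function(method = c("mean_scale", "zscore"),
                               scope = c("per_read", "global"),
                               epsilon = 1e-6) {
  method <- match.arg(method)
  scope <- match.arg(scope)
  if (epsilon <= 0) stopf("epsilon must be > 0")
  structure(list(method = method, scope = scope, epsilon = epsilon),
            class = "normalization_spec")
}

#' Normalize raw kinetic values within groups
#'
#' Group statistics are computed over all bases of each group (a read under
#' \code{scope = "per_read"}). \code{mean_scale} divides by the group mean;
#' \code{zscore} centers and scales. A group of identical values yields all
#' zeros under zscore rather than an error.
#'
#' @param values Numeric vector of raw kinetic values.
#' @param groups Grouping vector (e.g. read ids) of the same length, or NULL
#'   to treat all values as one group.
#' @param spec A \code{\link{normalization_spec}}.
#' @return Numeric vector of normalized values.
#' @export
normalize_signals <- function(values, groups = NULL, spec = normalization_spec()) {
  stopifnot(inherits(spec, "normalization_spec"))
  if (!length(values)) return(numeric(0))
  if (is.null(groups)) groups <- rep(1L, length(values))
  if (length(groups) != length(values)) {
    stopf("groups must have the same length as values")
  }
  if (spec$method == "mean_scale") {
    m <- ave(values, groups, FUN = mean)
    values / pmax(m, spec$epsilon)
  } else {
    m <- ave(values, groups, FUN = mean)
    s <- ave(values, groups, FUN = stats::sd)
    s[is.na(s)] <- 0
    (values - m) / (s + spec$epsilon)
  }
}

#' Average subread measurements per site
#'
#' @param values Numeric vector of (normalized) per-subread values.
#' @param sites Site key vector of the same length.
#' @param min_coverage Sites with fewer subreads are flagged (not dropped).
#' @return Data.frame with site, mean, n, low_coverage.
#' @export
average_subreads <- function(values, sites, min_coverage = 3L) {
  if (!length(values)) {
    return(data.frame(site = character(), mean = numeric(), n = integer(),
                      low_coverage = logical(), stringsAsFactors = FALSE))
  }
  if (length(sites) != length(values)) {
    stopf("sites must have the same length as values")
  }
  f <- factor(sites, levels = unique(sites))
  n <- as.integer(table(f))
  m <- as.vector(rowsum(values, f, reorder = FALSE)) / n
  data.frame(site = levels(f), mean = m, n = n,
             low_coverage = n < min_coverage, stringsAsFactors = FALSE)
}
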