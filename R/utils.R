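#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rpois rbinom sd cor pnorm wilcox.test predict coef ave
#' @importFrom utils head tail read.table write.table count.fields
NULL

DNA_BASES <- c("A", "C", "G", "T")

IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

is_iupac <- function(motif) {
  all(strsplit(motif, "")[[1]] %in% names(IUPAC_MAP))
}

#' Expand an IUPAC motif into a plain regular expression
#'
#' Each ambiguity code becomes a character class, e.g. \code{CCWGG} becomes
#' \code{CC[AT]GG}. Used for brute-force motif scans.
#'
#' @param motif IUPAC motif string.
#' @return A regular expression string.
#' @export
iupac_regex <- function(motif) {
  chars <- strsplit(motif, "")[[1]]
  paste0(vapply(chars, function(ch) {
    b <- IUPAC_MAP[[ch]]
    if (length(b) == 1) b else paste0("[", paste0(b, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N and IUPAC codes).
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# integer base codes A=0 C=1 G=2 T=3 (NA for anything else)
seq_codes <- function(seq) {
  match(strsplit(seq, "")[[1]], DNA_BASES) - 1L
}

# k-mer index (0-based, base-4, first position most significant) at each
# genomic position of the context centered there; NA near contig ends.
# strand "-" gives the read-orientation (reverse-complement) context index.
kmer_indices <- function(codes, k, strand = "+") {
  L <- length(codes)
  k2 <- k %/% 2L
  pos <- seq.int(k2, L - 1L - k2)  # 0-based centers
  idx <- numeric(length(pos))
  if (strand == "+") {
    for (j in seq_len(k) - 1L) {
      idx <- idx + codes[pos - k2 + j + 1L] * 4^(k - 1L - j)
    }
  } else {
    comp <- 3L - codes
    for (j in seq_len(k) - 1L) {
      idx <- idx + comp[pos + k2 - j + 1L] * 4^(k - 1L - j)
    }
  }
  list(pos = pos, idx = idx)
}

kmer_string_to_index <- function(kmer) {
  vapply(kmer, function(s) {
    cds <- seq_codes(s)
    if (anyNA(cds)) return(NA_real_)
    sum(cds * 4^(rev(seq_along(cds)) - 1L))
  }, numeric(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
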