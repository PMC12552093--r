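# Independent brute-force oracles used to pin expected values. These stay
# deliberately naive (explicit loops, O(n^2) or full enumeration) and share
# no code with the implementation they check.

# AUC by counting all positive/negative pairs, ties worth one half
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# average precision by walking every distinct threshold and recomputing the
# confusion table from scratch
oracle_ap <- function(scores, y) {
  ths <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  prev_rec <- 0
  for (th in ths) {
    call <- scores >= th
    tp <- sum(call & y == 1)
    fp <- sum(call & y == 0)
    prec <- tp / (tp + fp)
    rec <- tp / sum(y == 1)
    ap <- ap + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  ap
}

# best F1 over an exhaustive threshold grid
oracle_best_f1 <- function(scores, y) {
  u <- sort(unique(scores))
  cand <- c(0, u, (u[-1] + u[-length(u)]) / 2, 1, u - 1e-9, u + 1e-9)
  best <- 0
  for (th in cand) {
    call <- scores >= th
    tp <- sum(call & y == 1)
    fp <- sum(call & y == 0)
    fn <- sum(!call & y == 1)
    f1 <- if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    if (f1 > best) best <- f1
  }
  best
}

# exact two-sided Mann-Whitney p by enumerating all group assignments of the
# pooled (tie-free) values; mirrors 2 * min(P(U <= u), P(U >= u)) capped at 1
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a)
  u_of <- function(x, y) {
    u <- 0
    for (xi in x) for (yi in y) u <- u + (xi > yi)
    u
  }
  u_obs <- u_of(a, b)
  combs <- utils::combn(length(pooled), m)
  us <- apply(combs, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# IUPAC motif scan via regex over both strands (overlap-aware)
oracle_motif_scan <- function(genome, motif, mod_offset) {
  scan_one <- function(seq, pat) {
    hits <- gregexpr(paste0("(?=", pat, ")"), seq, perl = TRUE)[[1]]
    if (hits[1] == -1) integer(0) else as.integer(hits) - 1L
  }
  pat <- iupac_regex(motif)
  plus <- scan_one(genome, pat) + mod_offset
  rc_pat <- iupac_regex(reverse_complement(motif))
  minus <- scan_one(genome, rc_pat) + (nchar(motif) - 1L - mod_offset)
  list(plus = sort(plus), minus = sort(minus))
}
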