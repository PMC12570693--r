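# Independent oracles used across the suite.  These deliberately share no
# code with the package internals: plain R, straightforward formulations.

# full O(nm) affine-gap DP, semi-global (global in the read, free end gaps
# in the reference); returns the optimal score only.  Row-vectorised Gotoh:
# D within a row is a prefix-max recurrence.
oracle_semiglobal_score <- function(read, ref, match = 1, mismatch = -4,
                                    gap_open = -6, gap_extend = -1) {
  r <- strsplit(read, "")[[1]]
  s <- strsplit(ref, "")[[1]]
  m <- length(r); n <- length(s)
  open1 <- gap_open + gap_extend
  NEG <- -1e15
  M <- rep(NEG, n + 1); I <- rep(NEG, n + 1); D <- rep(NEG, n + 1)
  for (i in seq_len(m)) {
    sub <- ifelse(s == r[i] & r[i] != "N", match, mismatch)
    if (i == 1) {
      Mn <- c(NEG, sub)          # start state score 0 at any (0, j-1)
      In <- rep(open1, n + 1)    # open from start
    } else {
      prev <- pmax(M, I, D)
      Mn <- c(NEG, prev[seq_len(n)] + sub)
      In <- pmax(M + open1, I + gap_extend)
    }
    # D[j] = max(Mn[j-1] + open1, D[j-1] + ext)  ==  prefix-max over Mn
    j <- 0:n
    c_ <- Mn + open1 - gap_extend * (j + 1)
    Dn <- c(NEG, gap_extend * (j[-1]) + cummax(c_)[seq_len(n)])
    M <- Mn; I <- In; D <- Dn
  }
  max(M, I, D)
}

# 3' quality trimming by exhaustive enumeration of all cut points: remove
# the suffix maximising sum(threshold - q) when positive; ties -> the
# longer removal (smallest cut).
oracle_qual_cut <- function(scores, threshold = 18) {
  L <- length(scores)
  if (L == 0) return(0L)
  pen <- threshold - scores
  best <- 0; cut <- L
  for (c in (L - 1):0) {
    ssum <- sum(pen[(c + 1):L])
    if (ssum > 0 && ssum >= best) { best <- ssum; cut <- c }
  }
  as.integer(cut)
}

# exhaustive 3' adapter scan with the stated rule
oracle_adapter_cut <- function(seq, adapter, rate = 0.1, min_overlap = 3L) {
  s <- strsplit(seq, "")[[1]]
  a <- strsplit(adapter, "")[[1]]
  L <- length(s); A <- length(a)
  best_score <- -1L; best_p <- L
  for (p in 0:(L - 1)) {
    matched <- min(A, L - p)
    if (matched < A && matched < min_overlap) next
    mm <- sum(s[(p + 1):(p + matched)] != a[seq_len(matched)])
    if (mm <= floor(rate * matched)) {
      score <- matched - mm
      if (score > best_score) { best_score <- score; best_p <- p }
    }
  }
  as.integer(best_p)
}

# column-walk over a CIGAR: per reference column of [a, b) (0-based,
# half-open) emit the read base (M) or "-" (D); insertion bases attach to
# the next reference column (their anchor) and belong to the segment when
# a <= anchor < b
oracle_extract <- function(cigar, ref_start, read, a, b) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDS]", cigar))[[1]]
  lens <- as.integer(sub("[MIDS]", "", ops))
  kinds <- sub("[0-9]+", "", ops)
  r <- strsplit(read, "")[[1]]
  p <- ref_start; q <- 0
  cols <- rep(".", b - a)
  ins <- rep("", b - a)
  for (k in seq_along(ops)) {
    if (kinds[k] == "M") {
      for (x in seq_len(lens[k])) {
        if (p >= a && p < b) cols[p - a + 1] <- r[q + 1]
        p <- p + 1; q <- q + 1
      }
    } else if (kinds[k] == "D") {
      for (x in seq_len(lens[k])) {
        if (p >= a && p < b) cols[p - a + 1] <- "-"
        p <- p + 1
      }
    } else {
      if (kinds[k] == "I" && p >= a && p < b) {
        ins[p - a + 1] <- paste0(ins[p - a + 1],
                                 paste(r[(q + 1):(q + lens[k])], collapse = ""))
      }
      q <- q + lens[k]
    }
  }
  covered <- ref_start <= a && p >= b
  gapped <- paste0(paste0(ins, cols), collapse = "")
  list(columns = paste(cols, collapse = ""), gapped = gapped,
       ungapped = gsub("-", "", gapped), covered = covered)
}

# greedy clustering with the same join rule, written independently:
# all-pairs identity by explicit substring sliding
oracle_identity <- function(x, y) {
  if (nchar(x) > nchar(y)) { t <- x; x <- y; y <- t }
  lx <- nchar(x); ly <- nchar(y)
  xs <- strsplit(x, "")[[1]]
  best <- 0
  for (off in 0:(ly - lx)) {
    ys <- strsplit(substr(y, off + 1, off + lx), "")[[1]]
    best <- max(best, sum(xs == ys & xs != "N"))
  }
  best / lx
}

oracle_greedy_cluster <- function(seqs, threshold) {
  ord <- order(-nchar(seqs), seqs, method = "radix")
  s <- seqs[ord]
  rep_of <- integer(length(s))
  reps <- integer(0)
  for (i in seq_along(s)) {
    hit <- 0
    for (k in reps) {
      if (oracle_identity(s[i], s[k]) >= threshold) { hit <- k; break }
    }
    if (hit == 0) { reps <- c(reps, i); rep_of[i] <- i }
    else rep_of[i] <- hit
  }
  # return representative sequence per input sequence, in input order
  out <- character(length(seqs))
  out[ord] <- s[rep_of]
  out
}

# two-sided Fisher p by full hypergeometric enumeration
oracle_fisher_two_sided <- function(k1, n1, k2, n2) {
  K <- k1 + k2
  kk <- max(0, K - n2):min(n1, K)
  probs <- dhyper(kk, n1, n2, K)
  p_obs <- dhyper(k1, n1, n2, K)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random DNA helpers
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

mutate_seq <- function(seq, n_sub = 0, n_indel = 0) {
  s <- strsplit(seq, "")[[1]]
  if (n_sub > 0) {
    pos <- sample(seq_along(s), n_sub)
    for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  }
  if (n_indel > 0) {
    for (x in seq_len(n_indel)) {
      p <- sample(seq_along(s), 1)
      if (runif(1) < 0.5) s <- s[-p]
      else s <- append(s, sample(c("A", "C", "G", "T"), 1), after = p)
    }
  }
  paste(s, collapse = "")
}

# reads data.frame with uniform qualities
make_reads <- function(seqs, q = 37L, ids = NULL) {
  ids <- ids %||% sprintf("r%03d", seq_along(seqs))
  sequenced_reads(ids, seqs, vapply(nchar(seqs), function(L)
    amplistr::int_to_phred(rep(q, L)), character(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
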