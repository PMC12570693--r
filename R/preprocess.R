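#' 3' adapter removal
#'
#' Finds the best-scoring occurrence of the adapter as a full internal match
#' or a partial 3' suffix overlap of at least `min_overlap` bases, allowing
#' at most `floor(max_error_rate * matched_length)` mismatches; the adapter
#' and everything 3' of it are removed, qualities in lockstep. Score ties are
#' resolved to the leftmost placement (longest removal). Reads without an
#' acceptable occurrence are returned unchanged.
#'
#' @param reads a reads `data.frame`.
#' @param adapter adapter sequence (non-empty).
#' @param max_error_rate allowed mismatch fraction, in `[0, 0.5)`.
#' @param min_overlap minimum 3' overlap for a partial match.
#' @return the trimmed reads.
#' @export
trim_adapter <- function(reads, adapter, max_error_rate = 0.1,
                         min_overlap = 3L) {
  stopifnot(nchar(adapter) > 0, max_error_rate >= 0, max_error_rate < 0.5)
  if (nrow(reads) == 0) return(reads)
  keep <- cpp_adapter_cut(reads$seq, toupper(adapter), max_error_rate,
                          as.integer(min_overlap))
  reads$seq <- substr(reads$seq, 1L, keep)
  reads$qual <- substr(reads$qual, 1L, keep)
  reads
}

#' 3' quality trimming (running-sum rule)
#'
#' Scanning from the 3' end, accumulate `threshold - q_i`; the read is cut at
#' the position where the partial sum is maximal and positive (ties resolved
#' to the longer removal), and all bases 3' of the cut are removed. This is
#' the running-sum end-trimming used by standard read trimmers for a `-q`
#' cutoff -- not per-base masking, which would corrupt alignment.
#'
#' @param reads a reads `data.frame`.
#' @param threshold Phred threshold (default 18).
#' @return the trimmed reads.
#' @export
trim_quality <- function(reads, threshold = 18) {
  stopifnot(threshold >= 0)
  if (nrow(reads) == 0) return(reads)
  keep <- cpp_qual_cut(reads$qual, threshold)
  reads$seq <- substr(reads$seq, 1L, keep)
  reads$qual <- substr(reads$qual, 1L, keep)
  reads
}

#' Minimum-length filter
#'
#' Keeps reads of length at least `min_length` (a 60-base read is kept; a
#' 59-base read is discarded at the default threshold).
#'
#' @param reads a reads `data.frame`.
#' @param min_length minimum kept length (default 60).
#' @return `list(reads = kept reads, stats = list(input, kept, discarded))`.
#' @export
filter_length <- function(reads, min_length = 60L) {
  stopifnot(min_length >= 0)
  ok <- nchar(reads$seq) >= min_length
  list(reads = reads[ok, , drop = FALSE],
       stats = list(input = nrow(reads), kept = sum(ok),
                    discarded = sum(!ok)))
}

#' Full read-cleaning stage
#'
#' Adapter removal (if an adapter is given), 3' quality trimming at the
#' given threshold, then length filtering.
#'
#' @param reads a reads `data.frame`.
#' @param adapter optional adapter sequence.
#' @param quality_threshold Phred threshold for 3' trimming.
#' @param min_length minimum kept read length.
#' @param max_error_rate,min_overlap adapter-matching parameters,
#'   see [trim_adapter()].
#' @return `list(reads, stats)` as in [filter_length()].
#' @export
preprocess_reads <- function(reads, adapter = NULL, quality_threshold = 18,
                             min_length = 60L, max_error_rate = 0.1,
                             min_overlap = 3L) {
  if (!is.null(adapter)) {
    reads <- trim_adapter(reads, adapter, max_error_rate, min_overlap)
  }
  reads <- trim_quality(reads, quality_threshold)
  filter_length(reads, min_length)
}
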