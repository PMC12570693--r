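#' Default alignment scoring
#'
#' Match +1, mismatch -4, gap open -6, gap extend -1 (a gap of length k
#' costs `gap_open + k * gap_extend`), mirroring the scoring of the standard
#' short-read mapper for which this aligner substitutes.
#'
#' @return a named list of scoring parameters.
#' @export
alignment_scoring <- function(match = 1, mismatch = -4, gap_open = -6,
                              gap_extend = -1) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend)
}

#' Align reads to a reference amplicon
#'
#' Semi-global alignment: global in the read, free end gaps in the
#' reference, affine gap costs. Both orientations are scored and the better
#' kept (ties toward `+`); traceback ties prefer M over D over I. Large
#' problems are solved in a band of half-width `band` around the modal
#' diagonal of exact `seed_k`-mer matches; small problems (up to
#' `full_dp_cells` DP cells) run the full unbanded DP. Reads sharing no
#' exact seed with the amplicon, or whose best score falls below
#' `min_score_fraction * read_length`, are reported unmapped; reads longer
#' than the amplicon plus `max_expansion` are rejected as unalignable.
#'
#' @param reads a reads `data.frame`.
#' @param amplicon a [reference_amplicon()] (or a plain reference string).
#' @param scoring see [alignment_scoring()].
#' @param band band half-width for large problems.
#' @param seed_k seed k-mer length.
#' @param min_score_fraction mapping threshold as a fraction of read length.
#' @param max_expansion maximum read overhang beyond the amplicon length.
#' @param full_dp_cells problem-size cutoff below which the full DP is used.
#' @return a `data.frame` with one row per read: `read_id`, `strand`,
#'   `ref_start` (0-based local), `cigar`, `score`, `status`
#'   (`aligned`/`unmapped`/`no_seed`/`too_long`), `mapped`, and `seq`/`qual`
#'   in reference orientation.
#' @export
align_reads <- function(reads, amplicon, scoring = alignment_scoring(),
                        band = 30L, seed_k = 15L, min_score_fraction = 0.5,
                        max_expansion = 50L, full_dp_cells = 40000L) {
  ref <- if (inherits(amplicon, "reference_amplicon")) amplicon$sequence
         else toupper(amplicon)
  # align unique sequences once, then fan results back out
  uniq <- unique(reads$seq)
  res <- cpp_align_many(uniq, ref, scoring$match, scoring$mismatch,
                        scoring$gap_open, scoring$gap_extend,
                        as.integer(band), as.integer(seed_k),
                        as.integer(max_expansion), as.integer(full_dp_cells))
  i <- match(reads$seq, uniq)
  strand <- res$strand[i]
  aln <- data.frame(read_id = reads$id,
                    strand = strand,
                    ref_start = res$ref_start[i],
                    cigar = res$cigar[i],
                    score = res$score[i],
                    status = res$status[i],
                    stringsAsFactors = FALSE)
  aln$mapped <- aln$status == "aligned" &
    aln$score >= min_score_fraction * nchar(reads$seq)
  aln$status[aln$status == "aligned" & !aln$mapped] <- "unmapped"
  # store sequence and quality in reference orientation
  minus <- !is.na(strand) & strand == "-" & aln$mapped
  aln$seq <- reads$seq
  aln$qual <- reads$qual
  aln$seq[minus] <- as.character(reverse_complement(reads$seq[minus]))
  aln$qual[minus] <- vapply(reads$qual[minus], function(q)
    intToUtf8(rev(utf8ToInt(q))), character(1), USE.NAMES = FALSE)
  aln
}

#' Align one sequence (convenience wrapper)
#'
#' @param seq a single read sequence.
#' @param amplicon reference amplicon or string.
#' @inheritParams align_reads
#' @return a one-row alignment `data.frame`, see [align_reads()].
#' @export
semiglobal_align <- function(seq, amplicon, scoring = alignment_scoring(),
                             band = 30L, seed_k = 15L,
                             min_score_fraction = 0.5, max_expansion = 50L,
                             full_dp_cells = 40000L) {
  if (length(seq) != 1 || nchar(seq) == 0) stop("seq must be one non-empty string")
  reads <- data.frame(id = "read", seq = toupper(seq),
                      qual = strrep("I", nchar(seq)),
                      stringsAsFactors = FALSE)
  align_reads(reads, amplicon, scoring, band, seed_k, min_score_fraction,
              max_expansion, full_dp_cells)
}

#' Left-normalise indels
#'
#' Shifts every insertion/deletion run to its leftmost equivalent placement
#' (the shifted-out and shifted-in bases are equal), which makes indel
#' placement inside repeat tracts canonical. The alignment score is
#' unchanged and the operation is idempotent.
#'
#' @param alignments an alignment `data.frame` from [align_reads()].
#' @param amplicon the amplicon the alignments refer to.
#' @return the alignments with normalised CIGARs.
#' @export
left_align_indels <- function(alignments, amplicon) {
  ref <- if (inherits(amplicon, "reference_amplicon")) amplicon$sequence
         else toupper(amplicon)
  sel <- which(alignments$mapped)
  if (length(sel)) {
    out <- cpp_left_align(alignments$cigar[sel], alignments$ref_start[sel],
                          alignments$seq[sel], ref)
    alignments$cigar[sel] <- out$cigar
  }
  alignments
}

#' Does an alignment cover a reference interval?
#'
#' TRUE iff every reference column of the half-open local interval
#' `[interval[1], interval[2])` lies within the alignment's reference span
#' (deletions count as covering -- a segment may be all-gap).
#'
#' @param alignments alignment `data.frame`.
#' @param interval 0-based half-open local interval `c(a, b)`.
#' @return logical vector.
#' @export
covers_interval <- function(alignments, interval) {
  a <- interval[1]; b <- interval[2]
  end <- cpp_ref_span(alignments$cigar, alignments$ref_start)
  ok <- alignments$mapped & !is.na(end) &
    alignments$ref_start <= a & end >= b
  ok & !is.na(ok)
}

#' Extract a repeat region (with flanks) from aligned reads
#'
#' Walks each CIGAR over the reference columns of the region extended by
#' `flank5`/`flank3` bases: M emits the read base, D emits `-`; read bases
#' from insertions anchored inside the interval are included (an insertion
#' anchored exactly at the interval start belongs to the segment, one at the
#' end column does not). Reads that do not cover the full interval are
#' dropped and counted. Minus-strand reads were already stored in reference
#' orientation by [align_reads()].
#'
#' @param alignments alignment `data.frame` (ideally left-normalised).
#' @param amplicon the reference amplicon.
#' @param region a region name or [repeat_region()].
#' @param flank5,flank3 flank lengths in reference bp (defaults: the
#'   region's annotated extraction flanks).
#' @return a `data.frame` with columns `read_id`, `columns` (one char per
#'   reference column), `gapped` (columns plus inserted bases), `ungapped`
#'   (gapped without `-`), carrying attributes `reference_cut` (the
#'   reference sequence over the same interval), `interval_locus`,
#'   `region`, `flank5`, `flank3`, `n_input` and `n_covered`.
#' @export
extract_segments <- function(alignments, amplicon, region,
                             flank5 = NULL, flank3 = NULL) {
  rg <- if (is.character(region)) get_region(amplicon, region) else region
  flank5 <- flank5 %||% rg$flank5_len
  flank3 <- flank3 %||% rg$flank3_len
  iv <- region_interval(amplicon, rg, flank5, flank3)
  mapped <- alignments[alignments$mapped, , drop = FALSE]
  ex <- cpp_extract(mapped$cigar, mapped$ref_start, mapped$seq,
                    iv[1], iv[2])
  keep <- ex$covered
  seg <- data.frame(read_id = mapped$read_id[keep],
                    columns = ex$columns[keep],
                    gapped = ex$gapped[keep],
                    ungapped = ex$ungapped[keep],
                    stringsAsFactors = FALSE)
  attr(seg, "reference_cut") <- substr(amplicon$sequence, iv[1] + 1L, iv[2])
  attr(seg, "interval_locus") <- local_to_locus(amplicon, iv)
  attr(seg, "region") <- rg$name
  attr(seg, "flank5") <- flank5
  attr(seg, "flank3") <- flank3
  attr(seg, "n_input") <- nrow(alignments)
  attr(seg, "n_covered") <- sum(keep)
  seg
}
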