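#' Greedy incremental clustering (CD-HIT style)
#'
#' Sequences are processed sorted by length (descending) and then
#' lexicographically; each sequence joins the first existing cluster whose
#' representative it matches at identity at least `identity_threshold`
#' (identity = matches / shorter length, under ungapped sliding of the
#' shorter sequence within the longer), otherwise it seeds a new cluster.
#' Fully deterministic. Note that ungapped identity is deliberately
#' indel-sensitive: reads differing by a repeat-unit indel do not merge at
#' the default threshold, while point-error reads do.
#'
#' @param sequences character vector; names (or `id`) are used as sequence
#'   ids, defaulting to `seq1..seqN` in input order.
#' @param identity_threshold in `(0.5, 1]`, default 0.9.
#' @return `list(assignments = data.frame(id, seq, representative),
#'   clusters = data.frame(representative, seq, size))`, clusters in
#'   creation (processing) order.
#' @export
greedy_cluster <- function(sequences, identity_threshold = 0.9) {
  stopifnot(identity_threshold > 0.5, identity_threshold <= 1)
  ids <- names(sequences) %||% sprintf("seq%d", seq_along(sequences))
  if (length(sequences) == 0) {
    return(list(assignments = data.frame(id = character(0), seq = character(0),
                                         representative = character(0)),
                clusters = data.frame(representative = character(0),
                                      seq = character(0),
                                      size = integer(0))))
  }
  ord <- order(-nchar(sequences), sequences, method = "radix")
  s <- unname(sequences[ord])
  assign_idx <- cpp_greedy_cluster(s, identity_threshold)  # index into s
  rep_ids <- ids[ord][assign_idx]
  assignments <- data.frame(id = ids[ord], seq = s,
                            representative = rep_ids,
                            stringsAsFactors = FALSE)
  reps <- unique(assign_idx)
  clusters <- data.frame(representative = ids[ord][reps],
                         seq = s[reps],
                         size = as.integer(table(assign_idx)[as.character(reps)]),
                         stringsAsFactors = FALSE)
  list(assignments = assignments, clusters = clusters)
}

#' Exact-sequence clustering of extracted segments
#'
#' Groups segments by exact ungapped string equality; clusters are sorted by
#' count (descending), ties by string; fractions are computed over all input
#' segments. Each cluster carries the reference sequence cut at the same
#' interval, mirroring the pipeline's cluster report.
#'
#' @param segments a segments `data.frame` from [extract_segments()], or a
#'   character vector of ungapped segment strings.
#' @param reference_cut reference segment over the same interval (defaults
#'   to the `reference_cut` attribute of `segments`).
#' @return a `data.frame(representative, count, fraction, reference_cut)`.
#' @export
exact_group <- function(segments, reference_cut = NULL) {
  seqs <- if (is.data.frame(segments)) segments$ungapped else segments
  reference_cut <- reference_cut %||% attr(segments, "reference_cut") %||%
    NA_character_
  if (length(seqs) == 0) {
    return(data.frame(representative = character(0), count = integer(0),
                      fraction = numeric(0), reference_cut = character(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(seqs)
  out <- data.frame(representative = names(tab),
                    count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$representative, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out$fraction <- out$count / sum(out$count)
  out$reference_cut <- reference_cut
  out
}

# find `anchor` in `seg` with <= max_mm mismatches, at the position closest
# to `expected` (0-based; ties toward the smaller position); -1 if absent
find_anchor <- function(seg, anchor, expected, max_mm = 1L) {
  la <- nchar(anchor); ls <- nchar(seg)
  if (la == 0 || ls < la) return(-1L)
  starts <- 0:(ls - la)
  starts <- starts[order(abs(starts - expected), starts)]
  a <- utf8ToInt(anchor)
  sv <- utf8ToInt(seg)
  for (p in starts) {
    if (sum(sv[(p + 1):(p + la)] != a) <= max_mm) return(as.integer(p))
  }
  -1L
}

#' Call the repeat number of extracted segments
#'
#' For each segment the tract is located between flank anchors: the last
#' `min(5, flank5)` bases of the 5' flank and the first `min(5, flank3)`
#' bases of the 3' flank, each matched with at most one mismatch (so a flank
#' SNV does not destroy the call). `n_observed` is the maximal run of exact
#' unit copies in the tract; `delta_len` is the tract length minus the
#' reference tract length; the class follows `delta_len`: 0 = `reference`,
#' otherwise `deletion`/`insertion` when divisible by the unit length, else
#' `complex`. Segments whose anchors cannot be found are flagged
#' `anchored = FALSE` and classed `complex`.
#'
#' @param segments segments `data.frame` from [extract_segments()] (5'/3'
#'   flank lengths are read from its attributes).
#' @param amplicon,region the reference amplicon and region (name or
#'   object) the segments were extracted from.
#' @return a `data.frame(read_id, region, n_observed, delta_len, klass,
#'   flank_matches_reference, anchored)`.
#' @export
count_repeat_units <- function(segments, amplicon, region) {
  rg <- if (is.character(region)) get_region(amplicon, region) else region
  flank5 <- attr(segments, "flank5") %||% rg$flank5_len
  flank3 <- attr(segments, "flank3") %||% rg$flank3_len
  u <- nchar(rg$unit)
  a5len <- min(5L, flank5)
  a3len <- min(5L, flank3)
  tstart <- locus_to_local(amplicon, rg$start)
  ref5 <- substr(amplicon$sequence, tstart - a5len + 1L, tstart)
  tend <- locus_to_local(amplicon, rg$end)
  ref3 <- substr(amplicon$sequence, tend + 1L, tend + a3len)
  ref_flank5 <- substr(amplicon$sequence, tstart - flank5 + 1L, tstart)
  ref_flank3 <- substr(amplicon$sequence, tend + 1L, tend + flank3)
  ref_tract_len <- rg$end - rg$start

  # segments are heavily duplicated: call unique strings once
  seqs <- segments$ungapped
  uniq <- unique(seqs)
  n_obs <- integer(length(uniq)); delta <- integer(length(uniq))
  anch <- logical(length(uniq)); flank_ok <- logical(length(uniq))
  tracts <- rep(NA_character_, length(uniq))
  for (k in seq_along(uniq)) {
    s <- uniq[k]
    p5 <- find_anchor(s, ref5, flank5 - a5len)
    p3 <- find_anchor(s, ref3, nchar(s) - flank3)
    t0 <- if (p5 >= 0) p5 + a5len else -1L
    if (p5 < 0 || p3 < 0 || p3 < t0) {
      anch[k] <- FALSE
      n_obs[k] <- 0L
      delta[k] <- NA_integer_
      flank_ok[k] <- FALSE
      next
    }
    anch[k] <- TRUE
    tracts[k] <- substr(s, t0 + 1L, p3)
    delta[k] <- nchar(tracts[k]) - ref_tract_len
    flank_ok[k] <- identical(substr(s, 1L, t0), ref_flank5) &&
      identical(substr(s, p3 + 1L, nchar(s)), ref_flank3)
  }
  n_obs <- as.integer(cpp_unit_run(tracts, rg$unit))
  n_obs[!anch] <- NA_integer_
  klass <- ifelse(!anch, "complex",
           ifelse(delta == 0L, "reference",
           ifelse(delta %% u != 0L, "complex",
           ifelse(delta < 0L, "deletion", "insertion"))))
  i <- match(seqs, uniq)
  data.frame(read_id = segments$read_id,
             region = rg$name,
             n_observed = n_obs[i],
             delta_len = delta[i],
             klass = klass[i],
             flank_matches_reference = flank_ok[i],
             anchored = anch[i],
             stringsAsFactors = FALSE)
}

#' Frequency table of repeat classes
#'
#' Tabulates calls into `reference`, `indels` (deletions + insertions +
#' complex), `deletions`, `insertions` and `complex` fractions over all
#' calls. When `reference_n` is given, classes are recomputed against that
#' repeat count instead of the amplicon reference (the "Ref#" re-referencing
#' against the modal count): the effective tract-length delta becomes
#' `delta_len + (n_ref - reference_n) * unit length`. Rows below
#' `min_fraction` are suppressed in the reported rows but retained in the
#' full table.
#'
#' @param calls a calls `data.frame` from [count_repeat_units()].
#' @param label table label, e.g. `"Q1 DNA"`.
#' @param min_fraction reporting threshold (default 0.02).
#' @param reference_n optional re-reference repeat count (see
#'   [select_mode_reference()]).
#' @param n_ref,unit_len needed with `reference_n`; defaulted from the calls
#'   when omitted is not possible, so pass the region's values.
#' @return a `freq_table`: `list(label, rows, reported, coverage,
#'   min_fraction)`.
#' @export
classify_table <- function(calls, label, min_fraction = 0.02,
                           reference_n = NULL, n_ref = NULL, unit_len = 4L) {
  stopifnot(nrow(calls) > 0)
  delta <- calls$delta_len
  anch <- calls$anchored
  if (!is.null(reference_n)) {
    stopifnot(!is.null(n_ref))
    delta <- delta + (n_ref - reference_n) * unit_len
  }
  klass <- ifelse(!anch, "complex",
           ifelse(delta == 0L, "reference",
           ifelse(delta %% unit_len != 0L, "complex",
           ifelse(delta < 0L, "deletion", "insertion"))))
  n <- length(klass)
  fr <- function(x) sum(x) / n
  rows <- c(reference = fr(klass == "reference"),
            indels = fr(klass != "reference"),
            deletions = fr(klass == "deletion"),
            insertions = fr(klass == "insertion"),
            complex = fr(klass == "complex"))
  freq_table(label, rows, coverage = n, min_fraction = min_fraction)
}

# FrequencyTable container
freq_table <- function(label, rows, coverage, min_fraction = 0.02) {
  structure(list(label = label, rows = rows,
                 reported = rows[rows >= min_fraction],
                 coverage = as.integer(coverage),
                 min_fraction = min_fraction),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(x$label, " (coverage ", x$coverage, ")\n", sep = "")
  for (nm in names(x$reported)) {
    cat(sprintf("  %-12s %.2f\n", nm, x$reported[[nm]]))
  }
  invisible(x)
}

#' Modal repeat count ("Ref#")
#'
#' The most frequent `n_observed` over anchored calls, each read one vote;
#' ties broken toward the smaller count. Used as a substitute reference when
#' (as in the Q2 tract) no read matches the nominal reference count.
#'
#' @param calls a calls `data.frame` from [count_repeat_units()].
#' @return the modal repeat count (integer).
#' @export
select_mode_reference <- function(calls) {
  n <- calls$n_observed[calls$anchored]
  if (length(n) == 0) stop("no anchored repeat calls")
  tab <- table(n)
  best <- max(tab)
  as.integer(min(as.integer(names(tab)[tab == best])))
}

#' Flanking-sequence profile
#'
#' Compares the flank columns of each segment (extracted with profiling
#' flanks, default 10 nt upstream / 6 nt downstream) to the reference cut.
#' Gapped columns are ignored: they do not make a segment a flank variant
#' and are excluded from that column's denominator. Returns the
#' Reference/Variants frequency table and per-position counts of each
#' non-reference base.
#'
#' @param segments segments from [extract_segments()] with the profiling
#'   flank lengths.
#' @param amplicon,region reference amplicon and region.
#' @param label table label.
#' @param min_fraction reporting threshold.
#' @return `list(table = freq_table, per_position = data.frame(position,
#'   ref_base, base, count, denominator))`.
#' @export
profile_flanks <- function(segments, amplicon, region, label = NULL,
                           min_fraction = 0.02) {
  rg <- if (is.character(region)) get_region(amplicon, region) else region
  flank5 <- attr(segments, "flank5")
  flank3 <- attr(segments, "flank3")
  refcut <- attr(segments, "reference_cut")
  iv_locus <- attr(segments, "interval_locus")
  width <- nchar(refcut)
  flank_cols <- c(seq_len(flank5), (width - flank3 + 1L):width)
  ref_bases <- strsplit(refcut, "")[[1]]

  n <- nrow(segments)
  if (n == 0) stop("no segments to profile")
  mat <- matrix(unlist(strsplit(segments$columns, "")), nrow = n,
                byrow = TRUE)
  is_variant <- rep(FALSE, n)
  per_pos <- list()
  for (cix in flank_cols) {
    colv <- mat[, cix]
    informative <- colv != "-" & colv != "."
    mism <- informative & colv != ref_bases[cix]
    is_variant <- is_variant | mism
    if (any(mism)) {
      tb <- table(colv[mism])
      per_pos[[length(per_pos) + 1L]] <- data.frame(
        position = iv_locus[1] + cix - 1L,
        ref_base = ref_bases[cix],
        base = names(tb), count = as.integer(tb),
        denominator = sum(informative),
        stringsAsFactors = FALSE)
    }
  }
  per_position <- if (length(per_pos)) do.call(rbind, per_pos) else
    data.frame(position = integer(0), ref_base = character(0),
               base = character(0), count = integer(0),
               denominator = integer(0))
  rows <- c(Reference = sum(!is_variant) / n, Variants = sum(is_variant) / n)
  list(table = freq_table(label %||% paste(rg$name, "flanks"), rows,
                          coverage = n, min_fraction = min_fraction),
       per_position = per_position)
}

#' Targeted SNV allele frequency
#'
#' Reads the base carried at one locus position by every alignment whose
#' M-operations cover that column; reads with a deletion or an `N` at the
#' site are excluded from coverage. Frequency = alt reads / coverage;
#' when nothing covers the site the frequency is `NA` (missing, not 0).
#'
#' @param alignments alignment `data.frame` from [align_reads()].
#' @param amplicon the reference amplicon.
#' @param position 1-based locus coordinate.
#' @param ref_allele,alt_allele the two alleles (single bases).
#' @return an `snv_call`: `list(position, ref_allele, alt, variant,
#'   frequency, coverage, counts)`.
#' @export
snv_frequency <- function(alignments, amplicon, position, ref_allele,
                          alt_allele) {
  col <- locus_to_local(amplicon, position)
  if (col < 0 || col >= nchar(amplicon$sequence)) {
    stop("position ", position, " outside amplicon '", amplicon$name, "'")
  }
  mapped <- alignments[alignments$mapped, , drop = FALSE]
  base <- cpp_base_at(mapped$cigar, mapped$ref_start, mapped$seq, col)
  informative <- base %in% c("A", "C", "G", "T")
  coverage <- sum(informative)
  counts <- table(factor(base[informative], levels = c("A", "C", "G", "T")))
  structure(list(position = as.integer(position),
                 ref_allele = ref_allele,
                 alt = alt_allele,
                 variant = paste(ref_allele, ">", alt_allele),
                 frequency = if (coverage > 0)
                   unname(counts[alt_allele]) / coverage else NA_real_,
                 coverage = as.integer(coverage),
                 counts = counts),
            class = "snv_call")
}
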