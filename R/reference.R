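#' Annotated repeat region
#'
#' Describes one short-tandem-repeat tract on the locus: the repeat `unit`
#' (default `CCCT`), 1-based half-open locus interval `[start, end)`, the
#' reference repeat count `n_ref` (so `end - start == n_ref * nchar(unit)`),
#' and the default flank lengths used when extracting the region from
#' aligned reads. `flank5_seq`/`flank3_seq` optionally pin the expected
#' flanking sequence (used by the reference builder and validated against
#' the amplicon).
#'
#' @param name region name, e.g. `"Q1"`.
#' @param start 1-based locus coordinate of the first repeat base.
#' @param n_ref reference repeat count.
#' @param unit repeat unit motif.
#' @param flank5_len,flank3_len default extraction flank lengths (bp).
#' @param flank5_seq,flank3_seq optional expected flanking sequences
#'   immediately up-/downstream of the tract.
#' @return an object of class `repeat_region`.
#' @export
repeat_region <- function(name, start, n_ref, unit = "CCCT",
                          flank5_len = 5L, flank3_len = 5L,
                          flank5_seq = NULL, flank3_seq = NULL) {
  stopifnot(n_ref >= 0, nchar(unit) >= 1)
  u <- nchar(unit)
  if (!is.null(flank3_seq) && nchar(flank3_seq) >= u &&
      substr(flank3_seq, 1L, u) == unit) {
    stop("layout error: 3' flank of '", name,
         "' begins with the repeat unit; tract boundary would be ambiguous")
  }
  if (!is.null(flank5_seq) && nchar(flank5_seq) >= u &&
      substr(flank5_seq, nchar(flank5_seq) - u + 1L, nchar(flank5_seq)) == unit) {
    stop("layout error: 5' flank of '", name, "' ends with the repeat unit")
  }
  structure(list(name = name, unit = unit,
                 start = as.integer(start),
                 end = as.integer(start + n_ref * u),
                 n_ref = as.integer(n_ref),
                 flank5_len = as.integer(flank5_len),
                 flank3_len = as.integer(flank3_len),
                 flank5_seq = flank5_seq, flank3_seq = flank3_seq),
            class = "repeat_region")
}

#' Reference amplicon anchored to locus coordinates
#'
#' @param name amplicon name.
#' @param sequence amplicon sequence (A/C/G/T).
#' @param origin 1-based locus coordinate of the first base; a locus
#'   position `pos` maps to 0-based local index `pos - origin`.
#' @param regions list of [repeat_region()] annotations on the amplicon.
#' @return an object of class `reference_amplicon`.
#' @export
reference_amplicon <- function(name, sequence, origin, regions = list()) {
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  for (rg in regions) {
    if (rg$start < origin || rg$end > origin + len) {
      stop("layout error: region '", rg$name, "' outside amplicon '",
           name, "'")
    }
    tract <- substr(sequence, rg$start - origin + 1L, rg$end - origin)
    if (tract != strrep(rg$unit, rg$n_ref)) {
      stop("layout error: reference over region '", rg$name,
           "' is not ", rg$n_ref, " copies of ", rg$unit)
    }
    for (side in c("5", "3")) {
      fs <- rg[[paste0("flank", side, "_seq")]]
      if (is.null(fs)) next
      at <- if (side == "5") rg$start - nchar(fs) else rg$end
      got <- substr(sequence, at - origin + 1L, at - origin + nchar(fs))
      if (got != fs) {
        stop("layout error: ", side, "' flank of '", rg$name,
             "' does not match the reference (", got, " vs ", fs, ")")
      }
    }
  }
  structure(list(name = name, sequence = sequence,
                 origin = as.integer(origin), regions = regions),
            class = "reference_amplicon")
}

#' Locus / local coordinate conversion
#'
#' Locus positions are 1-based; local indices are 0-based; all intervals are
#' half-open `[start, end)`.
#'
#' @param amplicon a [reference_amplicon()].
#' @param pos locus position(s) (1-based).
#' @return `locus_to_local()`: 0-based local indices; `local_to_locus()`:
#'   1-based locus positions.
#' @export
locus_to_local <- function(amplicon, pos) {
  as.integer(pos) - amplicon$origin
}

#' @param idx 0-based local indices.
#' @rdname locus_to_local
#' @export
local_to_locus <- function(amplicon, idx) {
  as.integer(idx) + amplicon$origin
}

# local half-open interval [a, b) of region +/- flanks
region_interval <- function(amplicon, region, flank5 = region$flank5_len,
                            flank3 = region$flank3_len) {
  a <- locus_to_local(amplicon, region$start - flank5)
  b <- locus_to_local(amplicon, region$end + flank3)
  if (a < 0 || b > nchar(amplicon$sequence)) {
    stop("region '", region$name, "' +/- flanks exceeds amplicon '",
         amplicon$name, "'")
  }
  c(a, b)
}

# fetch a region by name from an amplicon
get_region <- function(amplicon, name) {
  for (rg in amplicon$regions) if (rg$name == name) return(rg)
  stop("no region named '", name, "' on amplicon '", amplicon$name, "'")
}

#' Default locus layout
#'
#' Describes a synthetic stand-in for the pRNA-gene segment of the human
#' rDNA reference U13369.1 spanned by the two PCR products: amplicon Q1 over
#' locus positions 41,469-41,790 (321 bp) and amplicon Q2 over
#' 41,748-42,033 (285 bp), each containing one (CCCT)n tract. Only the
#' printed anchors of the design are fixed -- the PCR primer sequences at the
#' product ends, the tract flank contexts `TTTTCTTCCT (CCCT)n GCTCCC` (Q1)
#' and `TGTTCTTTCT (CCCT)n GCTTCC` (Q2), and the `CCC` context of the
#' biallelic C/T site at 41,574 -- the remaining sequence is a seeded random
#' spacer, so coordinates are realistic while no copyrighted reference
#' sequence ships with the package. The true U13369.1 tract coordinates are
#' not printed in the source tables; the fixture places the Q1 tract at
#' \[41,653, 41,685) with `n_ref = 8` (containing the indel positions 41,663
#' and 41,665) and the Q2 tract at \[41,840, 41,876) with `n_ref = 9` (so the
#' flank-variant hotspot 41,878 falls in the 3' flank).
#'
#' @param spacer_seed seed for the random spacer fill.
#' @return a layout list consumed by [build_reference()].
#' @export
default_layout <- function(spacer_seed = 20210413L) {
  list(
    locus_origin = 41469L,
    locus_end = 42033L,
    spacer_seed = as.integer(spacer_seed),
    amplicons = list(
      Q1 = list(start = 41469L, end = 41790L,
                primer_fwd = "CGTTCCCTGTGTTTCCTTCT",
                primer_rev = "GCAGAATCGGTAGGCTCTTC"),
      Q2 = list(start = 41748L, end = 42033L,
                primer_fwd = "GTCTGTCTCTGCGTGGATTC",
                primer_rev = "CGAAACCGTGAGTCGAGAAG")
    ),
    regions = list(
      Q1 = repeat_region("Q1", start = 41653L, n_ref = 8L,
                         flank5_seq = "TTTTCTTCCT", flank3_seq = "GCTCCC"),
      Q2 = repeat_region("Q2", start = 41840L, n_ref = 9L,
                         flank5_seq = "TGTTCTTTCT", flank3_seq = "GCTTCC")
    ),
    # fixed motifs dropped into the spacer (locus position of first base)
    motifs = list(list(at = 41572L, seq = "CCC")),
    snv = list(position = 41574L, ref = "C", alt = "T")
  )
}

#' Build reference amplicons from a layout
#'
#' Fills the locus span with a seeded random spacer, then stamps in the
#' primer sequences at the amplicon ends, each repeat tract with its printed
#' flanking context, and any fixed motifs; finally cuts out and annotates
#' the amplicons. Deterministic for a given layout.
#'
#' @param layout a layout list, see [default_layout()].
#' @return a named list of [reference_amplicon()] objects, with the full
#'   locus sequence in attribute `locus_seq`.
#' @export
build_reference <- function(layout = default_layout()) {
  org <- layout$locus_origin
  len <- layout$locus_end - org
  locus <- with_seed(layout$spacer_seed,
                     paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                           collapse = ""))
  stamp <- function(locus, at, what) {
    i <- at - org  # 0-based
    stopifnot(i >= 0, i + nchar(what) <= len)
    paste0(substr(locus, 1L, i), what, substr(locus, i + nchar(what) + 1L, len))
  }
  # tracts + printed flanks; check region overlap first
  iv <- lapply(layout$regions, function(rg)
    c(rg$start - nchar(rg$flank5_seq %||% ""), rg$end + nchar(rg$flank3_seq %||% "")))
  iv <- iv[order(vapply(iv, `[`, numeric(1), 1L))]
  if (length(iv) > 1) {
    for (k in seq_len(length(iv) - 1L)) {
      if (iv[[k]][2] > iv[[k + 1]][1]) stop("layout error: overlapping regions")
    }
  }
  for (rg in layout$regions) {
    block <- paste0(rg$flank5_seq %||% "", strrep(rg$unit, rg$n_ref),
                    rg$flank3_seq %||% "")
    locus <- stamp(locus, rg$start - nchar(rg$flank5_seq %||% ""), block)
  }
  for (mt in layout$motifs) locus <- stamp(locus, mt$at, mt$seq)
  for (ap in layout$amplicons) {
    locus <- stamp(locus, ap$start, ap$primer_fwd)
    locus <- stamp(locus, ap$end - nchar(ap$primer_rev),
                   as.character(reverse_complement(ap$primer_rev)))
  }
  out <- list()
  for (nm in names(layout$amplicons)) {
    ap <- layout$amplicons[[nm]]
    seqc <- substr(locus, ap$start - org + 1L, ap$end - org)
    regs <- Filter(function(rg) rg$start >= ap$start && rg$end <= ap$end,
                   layout$regions)
    out[[nm]] <- reference_amplicon(nm, seqc, ap$start, unname(regs))
  }
  attr(out, "locus_seq") <- locus
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
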