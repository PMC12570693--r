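#' Simulation configuration
#'
#' Defaults emulate the study's sequencing conditions at desk scale:
#' 250 bp reads from either end of each amplicon molecule, substitution
#' error 1e-3/base (the upper end of the run's reported error rates),
#' rare 1 bp indel errors (2e-5/base; Illumina indel errors are roughly two
#' orders of magnitude below substitutions), PCR stutter adding or removing
#' one repeat unit in 0.2% of molecules, equal strand mix, and a two-state
#' quality model: Phred 37 body with, in 5% of reads, a low-quality
#' (Phred 12) 3' tail of geometric length (mean 20) -- just enough structure
#' to exercise the Q18 trimming rule.
#'
#' @param n_reads number of reads to generate.
#' @param substitution_rate,indel_rate per-base error probabilities.
#' @param stutter_prob per-molecule probability of a +/-1 unit stutter.
#' @param read_length read length in bp, or `"full"` for whole-molecule reads.
#' @param strand_fraction_minus probability a read is emitted as the
#'   reverse complement.
#' @param quality_high,quality_low body / tail Phred scores.
#' @param p_low probability a read carries a low-quality 3' tail.
#' @param low_tail_mean mean tail length (geometric).
#' @param adapter optional adapter sequence appended to every read
#'   (synthetic read-through, to exercise adapter trimming).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_reads = 20000L,
                              substitution_rate = 0.001,
                              indel_rate = 2e-5,
                              stutter_prob = 0.002,
                              read_length = 250L,
                              strand_fraction_minus = 0.5,
                              quality_high = 37L, quality_low = 12L,
                              p_low = 0.05, low_tail_mean = 20,
                              adapter = NULL) {
  probs <- c(substitution_rate, indel_rate, stutter_prob,
             strand_fraction_minus, p_low)
  if (any(probs < 0 | probs > 1)) stop("config error: probability outside [0,1]")
  if (n_reads < 0) stop("config error: n_reads < 0")
  if (!identical(read_length, "full") && read_length < 1) {
    stop("config error: read_length < 1")
  }
  structure(list(n_reads = n_reads, substitution_rate = substitution_rate,
                 indel_rate = indel_rate, stutter_prob = stutter_prob,
                 read_length = read_length,
                 strand_fraction_minus = strand_fraction_minus,
                 quality_high = quality_high, quality_low = quality_low,
                 p_low = p_low, low_tail_mean = low_tail_mean,
                 adapter = adapter),
            class = "simulation_config")
}

#' Default molecule template mixes
#'
#' One row per molecule template: the amplicon it comes from, its repeat
#' count `n` for that amplicon's tract, an optional extra non-tetrameric
#' deletion inside the tract (`xdel_len` bases at tract offset `xdel_off`,
#' producing a "complex" tract length), the allele carried at the biallelic
#' site 41,574 (Q1 amplicon only), an optional flank variant, and the
#' sampling `weight`. Weights within an amplicon sum to 1; the two amplicons
#' are sampled in equal proportion.
#'
#' The default mixes transcribe the structure of the published HT1080
#' frequency tables: the 41,574 T allele at 0.68 (DNA) vs 0.95 (cDNA);
#' Q1 repeat classes at reference 0.20 / deletions 0.65 / insertions 0.08 /
#' complex 0.07 in DNA vs 0.95 / 0.02 / 0.02 / 0.01 in cDNA; Q2 dominated by
#' a modal count of 6 (reference count 9 absent), with 7% one-unit-shorter
#' molecules in DNA vs ~0% in cDNA; 3' flank variants in 15% (Q1 DNA),
#' 2% (Q1 cDNA), 2% (Q2 DNA, at locus 41,878) and 0% (Q2 cDNA).
#'
#' @param sample `"dna"` or `"cdna"`.
#' @param layout the locus layout, see [default_layout()].
#' @return a `data.frame` of templates.
#' @export
default_template_spec <- function(sample = c("dna", "cdna"),
                                  layout = default_layout()) {
  sample <- match.arg(sample)
  if (sample == "dna") {
    q1_rep <- data.frame(n = c(8L, 7L, 6L, 9L, 8L),
                         xdel_len = c(0L, 0L, 0L, 0L, 7L),
                         xdel_off = c(0L, 0L, 0L, 0L, 12L),
                         w = c(0.20, 0.40, 0.25, 0.08, 0.07))
    q2_rep <- data.frame(n = c(6L, 5L, 7L, 6L),
                         xdel_len = c(0L, 0L, 0L, 2L),
                         xdel_off = c(0L, 0L, 0L, 8L),
                         w = c(0.91, 0.07, 0.01, 0.01))
    snv_t <- 0.68; fv_q1 <- 0.15; fv_q2 <- 0.02
  } else {
    q1_rep <- data.frame(n = c(8L, 7L, 9L, 8L),
                         xdel_len = c(0L, 0L, 0L, 7L),
                         xdel_off = c(0L, 0L, 0L, 12L),
                         w = c(0.95, 0.02, 0.02, 0.01))
    q2_rep <- data.frame(n = c(6L, 5L, 7L, 6L),
                         xdel_len = c(0L, 0L, 0L, 2L),
                         xdel_off = c(0L, 0L, 0L, 8L),
                         w = c(0.975, 0.005, 0.015, 0.005))
    snv_t <- 0.95; fv_q1 <- 0.02; fv_q2 <- 0.0
  }
  snv <- layout$snv
  # flank variants: Q1 at 41,688 (3' flank, C>T); Q2 at 41,878 (3' flank, T>C)
  fv <- list(Q1 = list(position = 41688L, alt = "T", p = fv_q1),
             Q2 = list(position = 41878L, alt = "C", p = fv_q2))
  rows <- list()
  for (amp in c("Q1", "Q2")) {
    rep_tab <- if (amp == "Q1") q1_rep else q2_rep
    alleles <- if (amp == "Q1") {
      data.frame(allele = c(snv$alt, snv$ref), w = c(snv_t, 1 - snv_t))
    } else data.frame(allele = NA_character_, w = 1)
    fvp <- fv[[amp]]
    fvs <- if (fvp$p > 0) {
      data.frame(fv = c(TRUE, FALSE), w = c(fvp$p, 1 - fvp$p))
    } else data.frame(fv = FALSE, w = 1)
    for (i in seq_len(nrow(rep_tab))) for (j in seq_len(nrow(alleles)))
      for (k in seq_len(nrow(fvs))) {
        rows[[length(rows) + 1L]] <- data.frame(
          amplicon = amp, n = rep_tab$n[i],
          xdel_len = rep_tab$xdel_len[i], xdel_off = rep_tab$xdel_off[i],
          snv_allele = alleles$allele[j],
          flank_variant = fvs$fv[k],
          fv_position = if (fvs$fv[k]) fvp$position else NA_integer_,
          fv_alt = if (fvs$fv[k]) fvp$alt else NA_character_,
          weight = 0.5 * rep_tab$w[i] * alleles$w[j] * fvs$w[k],
          stringsAsFactors = FALSE)
      }
  }
  spec <- do.call(rbind, rows)
  spec$template_id <- sprintf(
    "%s_n%d%s_%s%s", spec$amplicon, spec$n,
    ifelse(spec$xdel_len > 0, sprintf("x%d", spec$xdel_len), ""),
    ifelse(is.na(spec$snv_allele), "", spec$snv_allele),
    ifelse(spec$flank_variant, "_fv", ""))
  stopifnot(abs(sum(spec$weight) - 1) < 1e-9)
  spec[, c("template_id", "amplicon", "n", "xdel_len", "xdel_off",
           "snv_allele", "flank_variant", "fv_position", "fv_alt", "weight")]
}

#' Multinomial draw of molecules over templates
#'
#' @param template_spec a template `data.frame` with a `weight` column.
#' @param n number of molecules.
#' @param seed optional seed (the caller's RNG state is restored).
#' @return the spec with an added integer `count` column summing to `n`.
#' @export
sample_templates <- function(template_spec, n, seed = NULL) {
  if (is.null(template_spec) || nrow(template_spec) == 0) {
    stop("empty template spec")
  }
  w <- template_spec$weight
  if (abs(sum(w) - 1) > 1e-9) stop("template weights must sum to 1")
  template_spec$count <- with_seed(seed,
                                   as.integer(rmultinom(1, n, w)))
  template_spec
}

# realize the full molecule sequence of one template
realize_template <- function(tpl, amplicons, layout, stutter_delta = 0L) {
  amp <- amplicons[[tpl$amplicon]]
  seqc <- amp$sequence
  rg <- get_region(amp, tpl$amplicon)
  sub_at <- function(seqc, locus_pos, base) {
    i <- locus_to_local(amp, locus_pos) + 1L
    substr(seqc, i, i) <- base
    seqc
  }
  if (!is.na(tpl$snv_allele)) seqc <- sub_at(seqc, layout$snv$position,
                                             tpl$snv_allele)
  if (isTRUE(tpl$flank_variant)) seqc <- sub_at(seqc, tpl$fv_position,
                                                tpl$fv_alt)
  n_realized <- tpl$n + stutter_delta
  if (n_realized < 0L) n_realized <- 0L
  tract <- strrep(rg$unit, n_realized)
  if (tpl$xdel_len > 0 && tpl$xdel_off + tpl$xdel_len <= nchar(tract)) {
    tract <- paste0(substr(tract, 1L, tpl$xdel_off),
                    substr(tract, tpl$xdel_off + tpl$xdel_len + 1L,
                           nchar(tract)))
  }
  a <- locus_to_local(amp, rg$start)
  b <- locus_to_local(amp, rg$end)
  list(seq = paste0(substr(seqc, 1L, a), tract,
                    substr(seqc, b + 1L, nchar(seqc))),
       n_realized = n_realized,
       tract_len = nchar(tract))
}

#' Generate reads from sampled molecule templates
#'
#' Per molecule: the template sequence is realized from its amplicon (SNV
#' allele substituted, tract set to `n` units, optional complex deletion and
#' flank variant applied); with probability `stutter_prob` one repeat unit is
#' added or removed (recorded in the truth table as stutter, not as template
#' identity); the read is the first `read_length` bases from a uniformly
#' chosen molecule end (`"full"` = the whole molecule); per-base substitution
#' and 1 bp indel errors are applied; with probability
#' `strand_fraction_minus` the read is emitted as the reverse complement;
#' qualities come from the two-state model.
#'
#' @param templates a template `data.frame` with `count` column, from
#'   [sample_templates()].
#' @param amplicons reference amplicons, from [build_reference()].
#' @param config a [simulation_config()].
#' @param layout the locus layout the templates refer to.
#' @param seed optional seed (caller's RNG state restored).
#' @param id_prefix prefix for read identifiers.
#' @return `list(reads = <reads data.frame>, truth = <truth data.frame>)`;
#'   truth columns: `read_id`, `template_id`, `amplicon`, `n_true`
#'   (realized repeat count, including stutter), `tract_len_true`,
#'   `allele_41574`, `flank_variant`, `stutter`, `strand`, `from_end`.
#' @export
sequence_reads <- function(templates, amplicons, config = simulation_config(),
                           layout = default_layout(), seed = NULL,
                           id_prefix = "read") {
  with_seed(seed, {
    total <- sum(templates$count)
    if (total == 0) {
      return(list(reads = sequenced_reads(character(0), character(0),
                                          character(0)),
                  truth = data.frame()))
    }
    # molecule-level assignments
    tpl_idx <- rep(seq_len(nrow(templates)), templates$count)
    nmol <- length(tpl_idx)
    stutter <- runif(nmol) < config$stutter_prob
    sdelta <- integer(nmol)
    sdelta[stutter] <- sample(c(-1L, 1L), sum(stutter), replace = TRUE)
    # realize per (template, stutter delta) group
    seqs <- character(nmol)
    n_true <- integer(nmol)
    tract_len <- integer(nmol)
    grp <- paste(tpl_idx, sdelta)
    for (g in unique(grp)) {
      sel <- grp == g
      i <- tpl_idx[which(sel)[1]]
      r <- realize_template(templates[i, ], amplicons, layout,
                            sdelta[which(sel)[1]])
      seqs[sel] <- r$seq
      n_true[sel] <- r$n_realized
      tract_len[sel] <- r$tract_len
    }
    # read window: first read_length bases from a uniformly chosen end
    from_end <- sample(c("left", "right"), nmol, replace = TRUE)
    if (!identical(config$read_length, "full")) {
      L <- pmin(config$read_length, nchar(seqs))
      left <- from_end == "left"
      reads <- character(nmol)
      reads[left] <- substr(seqs[left], 1L, L[left])
      reads[!left] <- substr(seqs[!left], nchar(seqs[!left]) - L[!left] + 1L,
                             nchar(seqs[!left]))
    } else {
      reads <- seqs
    }
    # substitution errors
    n_err <- rbinom(nmol, nchar(reads), config$substitution_rate)
    for (i in which(n_err > 0)) {
      pos <- sample.int(nchar(reads[i]), n_err[i])
      for (p in pos) {
        old <- substr(reads[i], p, p)
        substr(reads[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      }
    }
    # 1 bp indel errors
    n_ind <- rbinom(nmol, nchar(reads), config$indel_rate)
    for (i in which(n_ind > 0)) {
      for (k in seq_len(n_ind[i])) {
        p <- sample.int(nchar(reads[i]), 1)
        if (runif(1) < 0.5) {  # deletion
          reads[i] <- paste0(substr(reads[i], 1L, p - 1L),
                             substr(reads[i], p + 1L, nchar(reads[i])))
        } else {               # insertion
          reads[i] <- paste0(substr(reads[i], 1L, p - 1L),
                             sample(c("A", "C", "G", "T"), 1),
                             substr(reads[i], p, nchar(reads[i])))
        }
      }
    }
    # strand
    minus <- runif(nmol) < config$strand_fraction_minus
    reads[minus] <- as.character(reverse_complement(reads[minus]))
    # optional adapter read-through
    if (!is.null(config$adapter)) reads <- paste0(reads, config$adapter)
    # two-state qualities
    len <- nchar(reads)
    hi <- intToUtf8(config$quality_high + 33L)
    lo <- intToUtf8(config$quality_low + 33L)
    qual <- strrep(hi, len)
    tail_read <- runif(nmol) < config$p_low
    tl <- pmin(rgeom(nmol, 1 / config$low_tail_mean) + 1L, len)
    for (i in which(tail_read)) {
      qual[i] <- paste0(strrep(hi, len[i] - tl[i]), strrep(lo, tl[i]))
    }
    ids <- sprintf("%s_%06d", id_prefix, seq_len(nmol))
    truth <- data.frame(
      read_id = ids,
      template_id = templates$template_id[tpl_idx],
      amplicon = templates$amplicon[tpl_idx],
      n_true = n_true,
      tract_len_true = tract_len,
      allele_41574 = templates$snv_allele[tpl_idx],
      flank_variant = templates$flank_variant[tpl_idx],
      stutter = stutter,
      strand = ifelse(minus, "-", "+"),
      from_end = from_end,
      stringsAsFactors = FALSE)
    list(reads = sequenced_reads(ids, reads, qual), truth = truth)
  })
}

#' One-call synthetic sample
#'
#' @param sample `"dna"` or `"cdna"` (selects the default template mix).
#' @param config a [simulation_config()].
#' @param layout locus layout.
#' @param amplicons reference amplicons (built from `layout` if missing).
#' @param seed seed controlling the whole draw.
#' @return as [sequence_reads()], plus the sampled `templates`.
#' @export
simulate_sample <- function(sample = c("dna", "cdna"),
                            config = simulation_config(),
                            layout = default_layout(),
                            amplicons = build_reference(layout),
                            seed = NULL) {
  sample <- match.arg(sample)
  with_seed(seed, {
    spec <- default_template_spec(sample, layout)
    tpl <- sample_templates(spec, config$n_reads)
    out <- sequence_reads(tpl, amplicons, config, layout,
                          id_prefix = paste0(sample, "_read"))
    out$templates <- tpl
    out
  })
}
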