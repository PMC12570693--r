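test_that("greedy clustering reproduces simple cases", {
  same <- rep("ACGTACGTACGTACGTACGT", 5)
  cl <- greedy_cluster(same, 0.9)
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$size, 5L)
  # two sequences differing at half their positions split
  a <- "ACGTACGTACGTACGTACGT"
  b <- "TGCATGCAACGTACGTACGT"
  expect_equal(nrow(greedy_cluster(c(a, b), 0.9)$clusters), 2L)
  empty <- greedy_cluster(character(0), 0.9)
  expect_equal(nrow(empty$clusters), 0L)
})

test_that("greedy clustering equals the all-pairs brute-force oracle", {
  set.seed(61)
  for (rep in 1:10) {
    pool <- c(random_dna(20), random_dna(20), random_dna(22))
    seqs <- vapply(sample(pool, 30, replace = TRUE), function(s)
      mutate_seq(s, sample(0:2, 1)), character(1), USE.NAMES = FALSE)
    got <- greedy_cluster(seqs, 0.9)
    want <- oracle_greedy_cluster(seqs, 0.9)
    # compare representative sequence assigned to each input sequence
    got_rep <- with(got$assignments,
                    stats::setNames(seq[match(representative, id)], id))
    ids <- sprintf("seq%d", seq_along(seqs))
    expect_identical(unname(got_rep[ids]), want)
  }
})

test_that("exact grouping counts, sorts and conserves", {
  segs <- c(rep("AAAA", 7), rep("CCCC", 3))
  out <- exact_group(segs, reference_cut = "AAAA")
  expect_equal(out$representative, c("AAAA", "CCCC"))
  expect_equal(out$count, c(7L, 3L))
  expect_equal(out$fraction, c(0.7, 0.3))
  expect_equal(sum(out$count), 10L)
  expect_equal(sum(out$fraction), 1)
  one <- exact_group(rep("ACGT", 10), "ACGT")
  expect_equal(one$count, 10L)
  expect_equal(one$fraction, 1)
  # count-ties order lexicographically
  tie <- exact_group(c("TTTT", "AAAA"), "x")
  expect_equal(tie$representative, c("AAAA", "TTTT"))
})

test_that("repeat-number calling counts exact unit runs between anchors", {
  amps <- build_reference()
  amp <- amps$Q1
  rg <- amp$regions[[1]]
  refcut <- paste0("TTCCT", strrep("CCCT", 8), "GCTCC")
  mk <- function(seq) {
    s <- data.frame(read_id = "r", columns = seq, gapped = seq,
                    ungapped = seq, stringsAsFactors = FALSE)
    attr(s, "flank5") <- 5L; attr(s, "flank3") <- 5L
    s
  }
  ref_call <- count_repeat_units(mk(refcut), amp, "Q1")
  expect_equal(ref_call$n_observed, 8L)
  expect_equal(ref_call$delta_len, 0L)
  expect_equal(ref_call$klass, "reference")
  expect_true(ref_call$flank_matches_reference)
  # direct count of a 3-unit tract
  expect_equal(as.integer(amplistr:::cpp_unit_run("CCCTCCCTCCCT", "CCCT")), 3L)
  # one unit deleted
  del1 <- mk(paste0("TTCCT", strrep("CCCT", 7), "GCTCC"))
  call <- count_repeat_units(del1, amp, "Q1")
  expect_equal(call$klass, "deletion")
  expect_equal(call$delta_len, -4L)
  expect_equal(call$n_observed, 7L)
  # the 7 bp deletion written delTCCCTCC: tract length change not
  # divisible by 4 -> complex
  tract <- strrep("CCCT", 8)
  tract7 <- paste0(substr(tract, 1, 12), substr(tract, 20, 32))
  cx <- count_repeat_units(mk(paste0("TTCCT", tract7, "GCTCC")), amp, "Q1")
  expect_equal(cx$delta_len, -7L)
  expect_equal(cx$klass, "complex")
  # a flank SNV does not destroy the call (anchors tolerate 1 mismatch)
  fv <- mk(paste0("TTCCT", strrep("CCCT", 8), "GCTAC"))
  fvc <- count_repeat_units(fv, amp, "Q1")
  expect_equal(fvc$klass, "reference")
  expect_false(fvc$flank_matches_reference)
  expect_true(fvc$anchored)
  # unrecognisable flanks -> unanchored complex
  un <- count_repeat_units(mk(strrep("GGGA", 10)), amp, "Q1")
  expect_false(un$anchored)
  expect_equal(un$klass, "complex")
})

test_that("repeat counts are invariant to indel placement within the tract", {
  amps <- build_reference()
  amp <- amps$Q1
  t0 <- locus_to_local(amp, 41653L)
  full <- amp$sequence
  # the same one-unit-deleted molecule aligned with the deletion at
  # different equivalent placements must give identical calls
  read <- paste0(substr(full, 1, t0), strrep("CCCT", 7),
                 substr(full, t0 + 33, nchar(full)))
  placements <- c(t0, t0 + 4L, t0 + 12L, t0 + 28L)
  calls <- lapply(placements, function(p) {
    aln <- data.frame(read_id = "r", strand = "+", ref_start = 0L,
                      cigar = sprintf("%dM4D%dM", p, nchar(full) - p - 4L),
                      score = 0, status = "aligned", mapped = TRUE,
                      seq = read, qual = strrep("F", nchar(read)))
    aln <- left_align_indels(aln, amp)
    seg <- extract_segments(aln, amp, "Q1")
    count_repeat_units(seg, amp, "Q1")
  })
  ns <- vapply(calls, function(x) x$n_observed, integer(1))
  ks <- vapply(calls, function(x) x$klass, character(1))
  expect_equal(unique(ns), 7L)
  expect_equal(unique(ks), "deletion")
})

test_that("classification tables and the 2% reporting rule behave", {
  calls <- data.frame(
    read_id = sprintf("r%d", 1:200),
    region = "Q1",
    n_observed = c(rep(8L, 40), rep(7L, 130), rep(9L, 16), rep(6L, 12),
                   rep(5L, 2)),
    delta_len = c(rep(0L, 40), rep(-4L, 130), rep(4L, 16), rep(-8L, 12),
                  rep(-12L, 2)),
    klass = c(rep("reference", 40), rep("deletion", 130),
              rep("insertion", 16), rep("deletion", 12), rep("deletion", 2)),
    flank_matches_reference = TRUE, anchored = TRUE,
    stringsAsFactors = FALSE)
  tab <- classify_table(calls, "Q1 test", min_fraction = 0.02)
  expect_equal(unname(tab$rows["reference"]), 0.20)
  expect_equal(unname(tab$rows["deletions"]), 0.72)
  expect_equal(unname(tab$rows["insertions"]), 0.08)
  expect_equal(unname(tab$rows["indels"]), 0.80)
  # classes sum to 1 before thresholding
  expect_equal(unname(tab$rows["reference"] + tab$rows["deletions"] +
                      tab$rows["insertions"] + tab$rows["complex"]), 1)
  # a 1% row is suppressed from the report but retained internally
  expect_false("complex" %in% names(tab$reported))
  calls$klass[1:2] <- "complex"; calls$delta_len[1:2] <- 3L
  tab2 <- classify_table(calls, "x", min_fraction = 0.02)
  expect_equal(unname(tab2$rows["complex"]), 0.01)
  expect_false("complex" %in% names(tab2$reported))
  expect_true("complex" %in% names(tab2$rows))
  # all-reference input
  allref <- calls[1:5, ]
  allref$klass <- "reference"; allref$delta_len <- 0L
  expect_equal(unname(classify_table(allref, "x")$rows["reference"]), 1)
})

test_that("the modal repeat count re-references classification", {
  calls <- data.frame(n_observed = rep(c(5L, 6L, 7L), c(10L, 50L, 5L)),
                      delta_len = rep(c(-16L, -12L, -8L), c(10L, 50L, 5L)),
                      anchored = TRUE, stringsAsFactors = FALSE)
  expect_equal(select_mode_reference(calls), 6L)
  # stated tie rule: toward the smaller count
  tie <- data.frame(n_observed = rep(c(5L, 6L), c(50L, 50L)),
                    delta_len = 0L, anchored = TRUE)
  expect_equal(select_mode_reference(tie), 5L)
  expect_error(select_mode_reference(
    data.frame(n_observed = 1L, delta_len = 0L, anchored = FALSE)),
    "no anchored")
  # against Ref# = 6 (amplicon n_ref = 9), the n = 6 molecules become the
  # reference class and n = 5 one-unit deletions
  tab <- classify_table(calls, "Q2 vs mode", reference_n = 6L, n_ref = 9L)
  expect_equal(unname(tab$rows["reference"]), 50 / 65)
  expect_equal(unname(tab$rows["deletions"]), 10 / 65)
  expect_equal(unname(tab$rows["insertions"]), 5 / 65)
})

test_that("zero-noise pipeline recovers template frequencies exactly", {
  layout <- default_layout()
  amps <- build_reference(layout)
  cfg <- simulation_config(n_reads = 2000, substitution_rate = 0,
                           indel_rate = 0, stutter_prob = 0,
                           strand_fraction_minus = 0, p_low = 0,
                           read_length = "full")
  sim <- simulate_sample("dna", cfg, seed = 67)
  amp <- amps$Q1
  aln <- left_align_indels(align_reads(sim$reads, amp), amp)
  seg <- extract_segments(aln, amp, "Q1")
  truth <- sim$truth[match(seg$read_id, sim$truth$read_id), ]
  # every Q1 read is recovered
  expect_equal(sort(seg$read_id),
               sort(sim$truth$read_id[sim$truth$amplicon == "Q1"]))
  calls <- count_repeat_units(seg, amp, "Q1")
  # class fractions equal the sampled template mix exactly
  truth_class <- ifelse(truth$tract_len_true == 32L, "reference",
                 ifelse((truth$tract_len_true - 32L) %% 4L != 0L, "complex",
                 ifelse(truth$tract_len_true < 32L, "deletion", "insertion")))
  expect_equal(c(table(calls$klass)), c(table(truth_class)))
  # cluster fractions equal the realized molecule-class frequencies exactly
  # (templates differing only at the 41,574 site share a segment, so group
  # truth by what is visible inside the extracted interval)
  cl <- exact_group(seg)
  expect_equal(sum(cl$count), nrow(seg))
  visible <- paste(truth$tract_len_true, truth$flank_variant)
  expect_equal(sort(cl$count), sort(as.integer(table(visible))))
  expect_equal(cl$fraction, cl$count / nrow(seg))
})

test_that("flank profiling finds a planted 3' flank variant", {
  layout <- default_layout()
  amps <- build_reference(layout)
  sim <- simulate_sample("dna",
                         simulation_config(n_reads = 6000,
                                           substitution_rate = 0.001),
                         seed = 71)
  amp <- amps$Q2
  aln <- left_align_indels(align_reads(sim$reads, amp), amp)
  segp <- extract_segments(aln, amp, "Q2", flank5 = 10L, flank3 = 6L)
  fl <- profile_flanks(segp, amp, "Q2")
  # the planted Q2 flank variant sits at 41,878 at 2% of molecules
  pp <- fl$per_position
  hot <- pp[which.max(pp$count), ]
  expect_equal(hot$position, 41878L)
  f <- hot$count / hot$denominator
  expect_lt(abs(f - 0.02), 3 * sqrt(0.02 * 0.98 / hot$denominator) + 0.002)
  # all-reference flanks give Variants 0
  clean <- simulate_sample("cdna",
                           simulation_config(n_reads = 500,
                                             substitution_rate = 0,
                                             indel_rate = 0,
                                             stutter_prob = 0, p_low = 0),
                           seed = 73)
  alnc <- left_align_indels(align_reads(clean$reads, amp), amp)
  segc <- extract_segments(alnc, amp, "Q2", flank5 = 10L, flank3 = 6L)
  flc <- profile_flanks(segc, amp, "Q2")
  expect_equal(unname(flc$table$rows["Variants"]), 0)
})

test_that("gap-spanning flank columns are excluded from denominators", {
  amps <- build_reference()
  amp <- amps$Q1
  rg <- amp$regions[[1]]
  iv <- amplistr:::region_interval(amp, rg, 10L, 6L)
  refcut <- substr(amp$sequence, iv[1] + 1, iv[2])
  gapped <- paste0(strrep("-", 10), substr(refcut, 11, nchar(refcut)))
  segs <- data.frame(read_id = c("a", "b"),
                     columns = c(refcut, gapped),
                     gapped = c(refcut, gapped),
                     ungapped = c(refcut, gsub("-", "", gapped)),
                     stringsAsFactors = FALSE)
  attr(segs, "flank5") <- 10L; attr(segs, "flank3") <- 6L
  attr(segs, "reference_cut") <- refcut
  attr(segs, "interval_locus") <- local_to_locus(amp, iv)
  fl <- profile_flanks(segs, amp, "Q1")
  # the all-gap 5' flank is not a variant and not in any 5' denominator
  expect_equal(unname(fl$table$rows["Variants"]), 0)
  expect_equal(nrow(fl$per_position), 0L)
})

test_that("targeted SNV frequencies count covering, non-gap bases", {
  amps <- build_reference()
  amp <- amps$Q1
  pos <- 41574L
  col <- locus_to_local(amp, pos)
  # all reads carry T at the site
  withT <- amp$sequence
  substr(withT, col + 1, col + 1) <- "T"
  aln <- align_reads(make_reads(rep(substr(withT, 1, 200), 4)), amp)
  call <- snv_frequency(aln, amp, pos, "C", "T")
  expect_equal(call$frequency, 1)
  expect_equal(call$coverage, 4L)
  # a deletion spanning the site is excluded from coverage
  delread <- paste0(substr(amp$sequence, 1, col - 10),
                    substr(amp$sequence, col + 11, 200))
  mix <- align_reads(make_reads(c(substr(withT, 1, 200), delread)), amp)
  mix <- left_align_indels(mix, amp)
  call2 <- snv_frequency(mix, amp, pos, "C", "T")
  expect_equal(call2$coverage, 1L)
  expect_equal(call2$frequency, 1)
  # nothing covering -> missing, not zero
  off <- align_reads(make_reads(substr(amp$sequence, 250, 321)), amp)
  call3 <- snv_frequency(off, amp, pos, "C", "T")
  expect_equal(call3$coverage, 0L)
  expect_true(is.na(call3$frequency))
})

test_that("simulated SNV allele fractions are recovered within 3 sigma", {
  amps <- build_reference()
  sim <- simulate_sample("dna", simulation_config(n_reads = 8000), seed = 79)
  amp <- amps$Q1
  aln <- align_reads(sim$reads, amp)
  call <- snv_frequency(aln, amp, 41574L, "C", "T")
  truth <- sim$truth[sim$truth$amplicon == "Q1", ]
  p0 <- mean(truth$allele_41574 == "T")
  expect_gt(call$coverage, 3000)
  expect_lt(abs(call$frequency - p0),
            3 * sqrt(p0 * (1 - p0) / call$coverage) + 0.002)
})
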