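test_that("perfect substring reads align full-match with the right offset", {
  set.seed(37)
  ref <- random_dna(200)
  for (i in 1:20) {
    a <- sample(1:100, 1); L <- sample(30:100, 1)
    r <- substr(ref, a, a + L - 1)
    al <- semiglobal_align(r, ref, full_dp_cells = 1e6)
    expect_equal(al$cigar, paste0(L, "M"))
    expect_equal(al$ref_start, a - 1L)
    expect_equal(al$score, L)
    expect_equal(al$strand, "+")
    # reverse complement: identical CIGAR, strand "-"
    al2 <- semiglobal_align(as.character(reverse_complement(r)), ref,
                            full_dp_cells = 1e6)
    expect_equal(al2$cigar, al$cigar)
    expect_equal(al2$ref_start, al$ref_start)
    expect_equal(al2$strand, "-")
  }
})

test_that("a repeat-unit deletion yields a single 4D", {
  amps <- build_reference()
  amp <- amps$Q1
  t0 <- locus_to_local(amp, 41653L)
  full <- amp$sequence
  delread <- paste0(substr(full, 1, t0), strrep("CCCT", 7),
                    substr(full, t0 + 33, nchar(full)))
  al <- semiglobal_align(delread, amp, full_dp_cells = 1e7)
  expect_match(al$cigar, "^[0-9]+M4D[0-9]+M$")
  expect_equal(al$score, nchar(delread) - 6 - 4)  # all match minus gap cost
})

test_that("scores equal the brute-force affine DP oracle on random pairs", {
  set.seed(41)
  n_cases <- 520
  for (i in seq_len(n_cases)) {
    nref <- sample(10:60, 1)
    nread <- sample(5:nref, 1)
    ref <- random_dna(nref)
    read <- if (i %% 3 == 0) {
      random_dna(nread)                         # unrelated
    } else {
      a <- sample(1:(nref - nread + 1), 1)      # mutated substring
      mutate_seq(substr(ref, a, a + nread - 1), sample(0:3, 1),
                 sample(0:1, 1))
    }
    got <- semiglobal_align(read, ref, min_score_fraction = -10,
                            full_dp_cells = 1e7)
    # the aligner keeps the better of the two orientations
    want <- max(oracle_semiglobal_score(read, ref),
                oracle_semiglobal_score(
                  as.character(reverse_complement(read)), ref))
    expect_equal(got$score, want,
                 label = sprintf("case %d (%s / %s)", i, read, ref))
  }
})

test_that("the banded seeded path matches the oracle on realistic reads", {
  set.seed(43)
  ref <- random_dna(300)
  for (i in 1:30) {
    L <- sample(80:250, 1)
    a <- sample(1:(300 - L + 1), 1)
    read <- mutate_seq(substr(ref, a, a + L - 1), n_sub = sample(0:5, 1),
                       n_indel = sample(0:1, 1))
    got <- semiglobal_align(read, ref, band = 30, full_dp_cells = 1L)
    want <- max(oracle_semiglobal_score(read, ref),
                oracle_semiglobal_score(
                  as.character(reverse_complement(read)), ref))
    expect_equal(got$score, want)
  }
})

test_that("unalignable and oversized reads are flagged, not aligned", {
  ref <- random_dna(100)
  too_long <- semiglobal_align(random_dna(170), ref, max_expansion = 50)
  expect_equal(too_long$status, "too_long")
  expect_false(too_long$mapped)
  junk <- semiglobal_align(random_dna(90), ref, full_dp_cells = 1e6)
  expect_false(junk$mapped)
})

test_that("indel left-normalisation shifts repeat indels to the left edge", {
  ref <- paste0("GATTACAGGA", strrep("CCCT", 3), "GTACGATCAG")
  # deletion of the last CCCT unit: equivalent placements slide left
  read <- paste0("GATTACAGGA", strrep("CCCT", 2), "GTACGATCAG")
  aln <- data.frame(read_id = "r", strand = "+", ref_start = 0L,
                    cigar = "18M4D10M", score = 0, status = "aligned",
                    mapped = TRUE, seq = read,
                    qual = strrep("F", nchar(read)))
  out <- left_align_indels(aln, ref)
  expect_equal(out$cigar, "10M4D18M")
  # insertion of one unit
  read2 <- paste0("GATTACAGGA", strrep("CCCT", 4), "GTACGATCAG")
  aln2 <- aln
  aln2$seq <- read2
  aln2$cigar <- "22M4I10M"
  expect_equal(left_align_indels(aln2, ref)$cigar, "10M4I22M")
  # no indels -> unchanged; idempotence
  aln3 <- aln
  aln3$seq <- ref
  aln3$cigar <- "32M"
  expect_equal(left_align_indels(aln3, ref)$cigar, "32M")
  once <- left_align_indels(aln, ref)
  expect_identical(left_align_indels(once, ref)$cigar, once$cigar)
})

test_that("left-normalisation picks the leftmost among all equivalent placements", {
  set.seed(47)
  for (i in 1:50) {
    ref <- paste0(random_dna(8), strrep("CCCT", 4), random_dna(8))
    # construct a deletion at every possible placement within the tract and
    # confirm they all normalise to one canonical leftmost CIGAR
    dels <- lapply(8 + 0:12, function(p) {
      read <- paste0(substr(ref, 1, p), substr(ref, p + 5, nchar(ref)))
      list(cigar = sprintf("%dM4D%dM", p, nchar(ref) - p - 4), read = read)
    })
    # keep placements that reproduce the same read string (equivalent ones)
    reads <- vapply(dels, `[[`, "", "read")
    canon <- reads == reads[1]
    cigars <- vapply(which(canon), function(k) {
      aln <- data.frame(read_id = "r", strand = "+", ref_start = 0L,
                        cigar = dels[[k]]$cigar, score = 0,
                        status = "aligned", mapped = TRUE,
                        seq = dels[[k]]$read,
                        qual = strrep("F", nchar(dels[[k]]$read)))
      left_align_indels(aln, ref)$cigar
    }, character(1))
    expect_length(unique(cigars), 1)
  }
})

test_that("coverage of an interval requires the full span", {
  ref <- random_dna(120)
  aln <- align_reads(make_reads(substr(ref, 21, 80)), ref,
                     full_dp_cells = 1e6)
  expect_true(covers_interval(aln, c(30L, 60L)))
  expect_true(covers_interval(aln, c(20L, 80L)))   # exact span
  expect_false(covers_interval(aln, c(19L, 60L)))  # starts one column early
  expect_false(covers_interval(aln, c(30L, 81L)))  # ends one column late
  # a deletion spanning the whole interval still covers it (all-gap segment)
  read <- paste0(substr(ref, 21, 40), substr(ref, 61, 80))
  aln2 <- data.frame(read_id = "r", strand = "+", ref_start = 20L,
                     cigar = "20M20D20M", score = 0, status = "aligned",
                     mapped = TRUE, seq = read,
                     qual = strrep("F", nchar(read)))
  expect_true(covers_interval(aln2, c(45L, 55L)))
})

test_that("segment extraction matches the column-walk oracle", {
  set.seed(53)
  ref <- random_dna(80)
  cases <- list(
    list(cigar = "80M", read = ref, ref_start = 0L),
    list(cigar = "30M4D46M",
         read = paste0(substr(ref, 1, 30), substr(ref, 35, 80)),
         ref_start = 0L),
    list(cigar = "30M4I50M",
         read = paste0(substr(ref, 1, 30), "CCCT", substr(ref, 31, 80)),
         ref_start = 0L),
    list(cigar = "10M2D8M3I40M",
         read = paste0(substr(ref, 11, 20), substr(ref, 23, 30), "GGG",
                       substr(ref, 31, 70)),
         ref_start = 10L))
  for (cs in cases) {
    for (iv in list(c(20L, 40L), c(10L, 35L), c(28L, 33L))) {
      aln <- data.frame(read_id = "r", strand = "+",
                        ref_start = cs$ref_start, cigar = cs$cigar,
                        score = 0, status = "aligned", mapped = TRUE,
                        seq = cs$read, qual = strrep("F", nchar(cs$read)))
      amp <- reference_amplicon("amp", ref, 1L)
      rg <- list(name = "R", start = iv[1] + 1L, end = iv[2] + 1L,
                 n_ref = 0L, unit = "CCCT", flank5_len = 0L, flank3_len = 0L)
      class(rg) <- "repeat_region"
      ora <- oracle_extract(cs$cigar, cs$ref_start, cs$read, iv[1], iv[2])
      got <- amplistr:::cpp_extract(cs$cigar, cs$ref_start, cs$read,
                                    iv[1], iv[2])
      expect_equal(got$columns[1], ora$columns)
      expect_equal(got$gapped[1], ora$gapped)
      expect_equal(got$ungapped[1], ora$ungapped)
      expect_equal(got$covered[1], ora$covered)
    }
  }
})

test_that("insertions at interval boundaries follow the half-open rule", {
  ref <- random_dna(60)
  # insertion anchored exactly at the interval start column: included
  read_in <- paste0(substr(ref, 1, 20), "AAAA", substr(ref, 21, 60))
  got <- amplistr:::cpp_extract("20M4I40M", 0L, read_in, 20L, 40L)
  expect_equal(got$ungapped[1], paste0("AAAA", substr(ref, 21, 40)))
  # insertion anchored at the end column: excluded
  got2 <- amplistr:::cpp_extract("20M4I40M", 0L, read_in, 0L, 20L)
  expect_equal(got2$ungapped[1], substr(ref, 1, 20))
})

test_that("extraction is invariant to the strand of the input reads", {
  amps <- build_reference()
  sim <- simulate_sample("dna", simulation_config(n_reads = 300), seed = 59)
  flip <- sim$reads
  flip$seq <- as.character(reverse_complement(flip$seq))
  flip$qual <- vapply(flip$qual, function(q) intToUtf8(rev(utf8ToInt(q))),
                      character(1), USE.NAMES = FALSE)
  for (amp_name in c("Q1", "Q2")) {
    amp <- amps[[amp_name]]
    a1 <- left_align_indels(align_reads(sim$reads, amp), amp)
    a2 <- left_align_indels(align_reads(flip, amp), amp)
    s1 <- extract_segments(a1, amp, amp_name)
    s2 <- extract_segments(a2, amp, amp_name)
    expect_identical(s1$gapped, s2$gapped)
    expect_identical(s1$read_id, s2$read_id)
  }
})
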