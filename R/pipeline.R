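#' Pipeline configuration
#'
#' Collects every threshold of the two-sample amplicon comparison. All
#' defaults are the analysis' canonical values: quality threshold 18,
#' minimum read length 60, reporting threshold 2%, extraction flanks 5/5,
#' profiling flanks 10/6. The two samples are labelled generically
#' (`sample_a`/`sample_b`, default aliases DNA/cDNA), so the pipeline serves
#' any two-condition amplicon comparison.
#'
#' @param sample_a,sample_b reads `data.frame`s or FASTQ paths.
#' @param labels display labels for the two samples.
#' @param reference amplicons from [build_reference()].
#' @param layout the locus layout (supplies the SNV target by default).
#' @param adapter optional adapter to trim.
#' @param quality_threshold,min_length read-cleaning thresholds.
#' @param first_pass_identity optional identity threshold for a first-pass
#'   greedy clustering of whole reads before alignment (each read is then
#'   represented by its cluster representative). `NULL` (default) skips the
#'   pass: collapsing reads onto 90%-identity representatives erases
#'   sub-threshold point variation -- precisely the SNV and flank-variant
#'   frequencies under study -- so it is opt-in, for denoising use only.
#' @param min_fraction reporting threshold for frequency tables.
#' @param extract_flank5,extract_flank3 extraction flank lengths (bp).
#' @param profile_flank5,profile_flank3 flank-profiling lengths (bp).
#' @param snv_targets list of targeted SNVs, each
#'   `list(amplicon, position, ref, alt)`.
#' @param scoring,band,min_score_fraction aligner settings, see
#'   [align_reads()].
#' @param out_dir optional directory for report artifacts.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sample_a, sample_b,
                            labels = c("DNA", "cDNA"),
                            reference = build_reference(layout),
                            layout = default_layout(),
                            adapter = NULL,
                            quality_threshold = 18, min_length = 60L,
                            first_pass_identity = NULL,
                            min_fraction = 0.02,
                            extract_flank5 = 5L, extract_flank3 = 5L,
                            profile_flank5 = 10L, profile_flank3 = 6L,
                            snv_targets = NULL,
                            scoring = alignment_scoring(), band = 30L,
                            min_score_fraction = 0.5,
                            out_dir = NULL) {
  if (missing(sample_a) || missing(sample_b)) {
    stop("config error: missing required key(s): ",
         paste(c("sample_a", "sample_b")[c(missing(sample_a),
                                           missing(sample_b))],
               collapse = ", "))
  }
  if (is.null(snv_targets)) {
    snv_targets <- list(list(amplicon = "Q1",
                             position = layout$snv$position,
                             ref = layout$snv$ref, alt = layout$snv$alt))
  }
  structure(list(sample_a = sample_a, sample_b = sample_b, labels = labels,
                 reference = reference, layout = layout, adapter = adapter,
                 quality_threshold = quality_threshold,
                 min_length = min_length,
                 first_pass_identity = first_pass_identity,
                 min_fraction = min_fraction,
                 extract_flank5 = extract_flank5,
                 extract_flank3 = extract_flank3,
                 profile_flank5 = profile_flank5,
                 profile_flank3 = profile_flank3,
                 snv_targets = snv_targets, scoring = scoring, band = band,
                 min_score_fraction = min_score_fraction,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full two-sample comparison
#'
#' Stages, per sample and per repeat region: read cleaning; (optional
#' first-pass greedy clustering); semi-global alignment to the region's
#' amplicon with indel left-normalisation; coverage filtering and extraction
#' of the region with 5 bp flanks; exact clustering; repeat-number calling
#' and classification against the amplicon reference and against the modal
#' repeat count of sample A ("Ref#"); flank profiling with 10/6 nt flanks;
#' targeted SNV frequencies. Finally, sample A and sample B tables are
#' compared row-wise with two-proportion tests. A manifest records every
#' threshold and per-stage read counts. Fully deterministic for fixed
#' inputs.
#'
#' @param config a [pipeline_config()].
#' @return an `amplistr_report` list: `manifest`, `regions` (per region:
#'   `mode_reference_n`, per-sample tables/clusters/calls, comparison
#'   data frames) and `snv` (per target: per-sample calls and the test).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  labels <- config$labels
  amps <- config$reference

  load_reads <- function(x) if (is.character(x)) read_fastq(x) else x
  samples <- list(load_reads(config$sample_a), load_reads(config$sample_b))
  names(samples) <- labels

  manifest <- list(
    thresholds = list(quality_threshold = config$quality_threshold,
                      min_length = config$min_length,
                      first_pass_identity = config$first_pass_identity,
                      min_fraction = config$min_fraction,
                      extract_flanks = c(config$extract_flank5,
                                         config$extract_flank3),
                      profile_flanks = c(config$profile_flank5,
                                         config$profile_flank3),
                      scoring = config$scoring, band = config$band,
                      min_score_fraction = config$min_score_fraction),
    stages = list())

  clean <- list()
  for (s in labels) {
    pp <- preprocess_reads(samples[[s]], adapter = config$adapter,
                           quality_threshold = config$quality_threshold,
                           min_length = config$min_length)
    stopifnot(pp$stats$kept + pp$stats$discarded == pp$stats$input)
    reads <- pp$reads
    if (!is.null(config$first_pass_identity)) {
      cl <- greedy_cluster(stats::setNames(reads$seq, reads$id),
                           config$first_pass_identity)
      rep_of <- stats::setNames(cl$assignments$representative,
                                cl$assignments$id)
      rep_seq <- stats::setNames(cl$clusters$seq, cl$clusters$representative)
      reads$seq <- unname(rep_seq[rep_of[reads$id]])
      reads$qual <- strrep("I", nchar(reads$seq))
      manifest$stages[[s]]$first_pass_clusters <- nrow(cl$clusters)
    }
    clean[[s]] <- reads
    manifest$stages[[s]]$preprocess <- pp$stats
  }

  regions <- list()
  alignments <- list()  # per region x sample, reused for SNV targets
  for (amp_name in names(amps)) {
    amp <- amps[[amp_name]]
    for (rg in amp$regions) {
      per_sample <- list()
      for (s in labels) {
        aln <- align_reads(clean[[s]], amp, scoring = config$scoring,
                           band = config$band,
                           min_score_fraction = config$min_score_fraction)
        aln <- left_align_indels(aln, amp)
        alignments[[paste(amp_name, s)]] <- aln
        seg <- extract_segments(aln, amp, rg,
                                flank5 = config$extract_flank5,
                                flank3 = config$extract_flank3)
        calls <- count_repeat_units(seg, amp, rg)
        lab <- paste(rg$name, s)
        tab <- classify_table(calls, lab, config$min_fraction)
        segp <- extract_segments(aln, amp, rg,
                                 flank5 = config$profile_flank5,
                                 flank3 = config$profile_flank3)
        fl <- profile_flanks(segp, amp, rg, label = paste(lab, "flanks"),
                             min_fraction = config$min_fraction)
        per_sample[[s]] <- list(calls = calls, repeat_table = tab,
                                clusters = exact_group(seg),
                                flank_table = fl$table,
                                flank_positions = fl$per_position)
        manifest$stages[[s]][[rg$name]] <- list(
          aligned = sum(aln$mapped),
          covering = attr(seg, "n_covered"),
          covering_profile = attr(segp, "n_covered"))
      }
      n_mode <- select_mode_reference(per_sample[[labels[1]]]$calls)
      for (s in labels) {
        per_sample[[s]]$mode_table <- classify_table(
          per_sample[[s]]$calls, paste(rg$name, s, "vs Ref#"),
          config$min_fraction, reference_n = n_mode, n_ref = rg$n_ref,
          unit_len = nchar(rg$unit))
      }
      comparisons <- list(
        repeat_classes = compare_frequency_tables(
          per_sample[[labels[1]]]$repeat_table,
          per_sample[[labels[2]]]$repeat_table),
        mode_classes = compare_frequency_tables(
          per_sample[[labels[1]]]$mode_table,
          per_sample[[labels[2]]]$mode_table),
        flanks = compare_frequency_tables(
          per_sample[[labels[1]]]$flank_table,
          per_sample[[labels[2]]]$flank_table))
      regions[[rg$name]] <- list(amplicon = amp_name,
                                 mode_reference_n = n_mode,
                                 samples = per_sample,
                                 comparisons = comparisons)
    }
  }

  snv <- list()
  for (tg in config$snv_targets) {
    amp <- amps[[tg$amplicon]]
    calls <- lapply(labels, function(s)
      snv_frequency(alignments[[paste(tg$amplicon, s)]], amp,
                    tg$position, tg$ref, tg$alt))
    names(calls) <- labels
    a <- calls[[1]]; b <- calls[[2]]
    tst <- two_proportion_test(
      counts_from_frequency(a$frequency, a$coverage), a$coverage,
      counts_from_frequency(b$frequency, b$coverage), b$coverage,
      label = sprintf("%d %s", tg$position, a$variant))
    snv[[as.character(tg$position)]] <- list(samples = calls, test = tst)
  }

  report <- structure(list(manifest = manifest, regions = regions,
                           snv = snv, labels = labels),
                      class = "amplistr_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# serialize a freq_table for JSON output
freq_table_list <- function(tb) {
  list(label = tb$label, rows = as.list(tb$rows),
       reported = as.list(tb$reported), coverage = tb$coverage,
       min_fraction = tb$min_fraction)
}

#' Write report artifacts
#'
#' Per region and sample: the cluster report text file; per region: the
#' frequency tables (JSON) and comparison tables (TSV); plus the run
#' manifest (JSON).
#'
#' @param report an `amplistr_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (rg in names(report$regions)) {
    reg <- report$regions[[rg]]
    tabs <- list(mode_reference_n = reg$mode_reference_n)
    for (s in names(reg$samples)) {
      slug <- gsub("[^A-Za-z0-9]+", "_", paste(rg, s))
      render_cluster_report(reg$samples[[s]]$clusters,
                            file.path(out_dir, paste0(slug, "_clusters.txt")))
      tabs[[s]] <- list(
        repeat_table = freq_table_list(reg$samples[[s]]$repeat_table),
        mode_table = freq_table_list(reg$samples[[s]]$mode_table),
        flank_table = freq_table_list(reg$samples[[s]]$flank_table))
    }
    jsonlite::write_json(tabs, file.path(out_dir, paste0(rg, "_tables.json")),
                         auto_unbox = TRUE, digits = NA)
    for (cmp in names(reg$comparisons)) {
      write.table(reg$comparisons[[cmp]],
                  file.path(out_dir, sprintf("%s_%s_compare.tsv", rg, cmp)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (length(report$snv)) {
    calls <- do.call(rbind, lapply(names(report$snv), function(p) {
      x <- report$snv[[p]]
      do.call(rbind, lapply(names(x$samples), function(s)
        data.frame(sample = s, position = x$samples[[s]]$position,
                   variant = x$samples[[s]]$variant,
                   frequency = x$samples[[s]]$frequency,
                   coverage = x$samples[[s]]$coverage,
                   p_value = x$test$p_value, method = x$test$method,
                   stringsAsFactors = FALSE)))
    }))
    write.table(calls, file.path(out_dir, "snv_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
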