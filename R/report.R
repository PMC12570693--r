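#' Render the cluster report text file
#'
#' One line per cluster: representative sequence, occurrence count, and
#' percentage (two decimals), ordered by count; the header line carries the
#' reference sequence cut at the same interval as the segments.
#'
#' @param clusters a cluster `data.frame` from [exact_group()].
#' @param path output path.
#' @export
render_cluster_report <- function(clusters, path) {
  ref <- if (nrow(clusters)) clusters$reference_cut[1] else NA_character_
  lines <- c(sprintf("# reference\t%s", ref),
             sprintf("%s\t%d\t%.2f", clusters$representative,
                     clusters$count, 100 * clusters$fraction))
  writeLines(lines, path)
  invisible(path)
}

#' Read back a cluster report
#'
#' @param path a file written by [render_cluster_report()].
#' @return a `data.frame(representative, count, percentage)` with the
#'   reference cut in attribute `reference_cut`.
#' @export
parse_cluster_report <- function(path) {
  lines <- readLines(path)
  ref <- sub("^# reference\t", "", lines[1])
  body <- lines[-1]
  out <- if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    data.frame(representative = vapply(parts, `[`, "", 1),
               count = as.integer(vapply(parts, `[`, "", 2)),
               percentage = as.numeric(vapply(parts, `[`, "", 3)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(representative = character(0), count = integer(0),
               percentage = numeric(0))
  }
  attr(out, "reference_cut") <- ref
  out
}

variant_pattern <- "^([ACGT] > [ACGT]|ins[ACGTN]+|del[ACGTN]+)$"

#' Render / parse a variant table
#'
#' Columns `Position`, `Variant` (in `X > Y` / `insSEQ` / `delSEQ`
#' notation), `Frequency` (two decimals) and `Coverage`, sorted by position;
#' `parse_variant_table()` round-trips the format and validates the variant
#' notation.
#'
#' @param calls a `data.frame` with columns `position`, `variant`,
#'   `frequency`, `coverage` (an [snv_frequency()] call or list of calls is
#'   also accepted).
#' @param path file path.
#' @return `parse_variant_table()`: a `data.frame(position, variant,
#'   frequency, coverage)`.
#' @export
render_variant_table <- function(calls, path) {
  if (inherits(calls, "snv_call")) calls <- list(calls)
  if (!is.data.frame(calls)) {
    calls <- do.call(rbind, lapply(calls, function(x)
      data.frame(position = x$position, variant = x$variant,
                 frequency = x$frequency, coverage = x$coverage,
                 stringsAsFactors = FALSE)))
  }
  calls <- calls[order(calls$position), , drop = FALSE]
  lines <- c("Position\tVariant\tFrequency\tCoverage",
             sprintf("%d\t%s\t%.2f\t%d", calls$position, calls$variant,
                     calls$frequency, calls$coverage))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname render_variant_table
#' @export
parse_variant_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != "Position\tVariant\tFrequency\tCoverage") {
    stop("parse error at line 1: missing variant-table header")
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  out <- data.frame(position = integer(0), variant = character(0),
                    frequency = numeric(0), coverage = integer(0))
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    for (i in seq_along(parts)) {
      if (length(parts[[i]]) != 4) {
        stop("parse error at line ", i + 1L, ": expected 4 fields")
      }
      if (!grepl(variant_pattern, parts[[i]][2])) {
        stop("parse error at line ", i + 1L, ": malformed variant notation '",
             parts[[i]][2], "'")
      }
    }
    out <- data.frame(position = as.integer(vapply(parts, `[`, "", 1)),
                      variant = vapply(parts, `[`, "", 2),
                      frequency = as.numeric(vapply(parts, `[`, "", 3)),
                      coverage = as.integer(vapply(parts, `[`, "", 4)),
                      stringsAsFactors = FALSE)
    if (anyNA(out$position) || anyNA(out$frequency) || anyNA(out$coverage)) {
      stop("parse error: non-numeric Position/Frequency/Coverage field")
    }
  }
  out
}

#' Published WI38 variant table
#'
#' The 23 single-nucleotide substitutions and indels reported for the pRNA
#' locus of WI38 fibroblasts (positions on U13369.1), shipped as a
#' plain-text fixture and parsed with [parse_variant_table()].
#'
#' @return a `data.frame(position, variant, frequency, coverage)`.
#' @export
wi38_variants <- function() {
  parse_variant_table(system.file("extdata", "wi38_variants.tsv",
                                  package = "amplistr", mustWork = TRUE))
}
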