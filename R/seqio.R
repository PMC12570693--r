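#' Construct a set of sequenced reads
#'
#' The package-wide container for reads is a plain `data.frame` with
#' character columns `id`, `seq` and `qual`, where `qual` holds the
#' Phred+33-encoded quality string of the same length as `seq`. Bases are
#' uppercased on ingest; IUPAC ambiguity codes other than A/C/G/T are
#' collapsed to `N` (an `N` mismatches every base downstream).
#'
#' @param id character vector of read identifiers.
#' @param seq character vector of sequences over A/C/G/T/N.
#' @param qual character vector of Phred+33 quality strings, or a list of
#'   integer Phred scores (encoded on the fly).
#' @return a `data.frame` with columns `id`, `seq`, `qual`.
#' @export
sequenced_reads <- function(id, seq, qual) {
  if (is.list(qual)) qual <- vapply(qual, int_to_phred, character(1))
  seq <- normalize_bases(seq)
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    stop("FASTQ format error: sequence/quality length mismatch for record '",
         id[bad[1]], "'")
  }
  if (any(grepl("[^ACGTN]", seq))) {
    bad <- which(grepl("[^ACGTN]", seq))[1]
    stop("format error: non-IUPAC character in record '", id[bad], "'")
  }
  data.frame(id = unname(as.character(id)), seq = unname(seq),
             qual = unname(as.character(qual)), stringsAsFactors = FALSE)
}

# uppercase and collapse non-ACGT IUPAC codes to N; reject non-IUPAC
normalize_bases <- function(seq) {
  seq <- toupper(seq)
  has_other <- grepl("[^ACGTN]", seq)
  if (any(has_other)) {
    iupac <- "RYSWKMBDHVU"
    other <- gsub("[ACGTN]", "", seq[has_other])
    if (any(grepl(sprintf("[^%s]", iupac), other))) {
      stop("format error: non-IUPAC character in sequence")
    }
    seq[has_other] <- chartr(iupac, strrep("N", nchar(iupac)), seq[has_other])
  }
  seq
}

#' Decode / encode Phred+33 quality strings
#'
#' @param qual character vector of Phred+33 strings.
#' @return `phred_to_int()`: a list of integer vectors (score = byte - 33);
#'   `int_to_phred()`: a single encoded string.
#' @export
phred_to_int <- function(qual) {
  lapply(qual, function(q) as.integer(utf8ToInt(q)) - 33L)
}

#' @param scores integer vector of Phred scores, all in \[0, 93\].
#' @rdname phred_to_int
#' @export
int_to_phred <- function(scores) {
  if (length(scores) == 0) return("")
  if (any(scores < 0) || any(scores > 93)) {
    stop("encoding error: Phred score outside [0, 93]")
  }
  intToUtf8(as.integer(scores) + 33L)
}

#' Read and write FASTQ (Phred+33)
#'
#' Four-line records, Phred+33 qualities only (no offset auto-detection;
#' NovaSeq-era data is uniformly +33). gzip-compressed input is accepted by
#' extension. Round-trips losslessly with [write_fastq()].
#'
#' @param path file path (`.gz` accepted on read).
#' @return `read_fastq()`: a reads `data.frame` (see [sequenced_reads()]).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("FASTQ format error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  q <- S4Vectors::mcols(x)$qualities
  bad <- which(Biostrings::width(x) != Biostrings::width(q))
  if (length(bad)) {
    stop("FASTQ format error: sequence/quality length mismatch for record '",
         names(x)[bad[1]], "'")
  }
  # short quality lines are NUL-padded by the parser; surface them as the
  # length mismatch they are
  qual <- tryCatch(as.character(q), error = function(e)
    stop("FASTQ format error in '", path,
         "': sequence/quality length mismatch", call. = FALSE))
  if (any(grepl("[^!-~]", qual))) {
    stop("FASTQ format error: quality character outside Phred+33 range ",
         "for record '", names(x)[grepl("[^!-~]", qual)][1], "'")
  }
  sequenced_reads(id = names(x), seq = as.character(x), qual = qual)
}

#' @param reads a reads `data.frame`.
#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) > 0 && any(vapply(phred_to_int(reads$qual), function(q)
      length(q) && max(q) > 93, logical(1)))) {
    stop("encoding error: Phred score > 93")
  }
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read and write FASTA
#'
#' Multi-line sequences are accepted on read; sequences are uppercased;
#' writes wrap at 80 columns.
#'
#' @param path file path.
#' @return `read_fasta()`: a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (any(Biostrings::width(x) == 0)) {
    stop("format error: empty sequence under header '",
         names(x)[Biostrings::width(x) == 0][1], "'")
  }
  out <- toupper(as.character(x))
  names(out) <- names(x)
  out
}

#' @param records named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::BStringSet(toupper(records))
  names(x) <- names(records)
  Biostrings::writeXStringSet(x, path, format = "fasta", width = 80L)
  invisible(path)
}

#' Reverse complement
#'
#' @param x character vector over A/C/G/T/N.
#' @return the reverse complements.
#' @export
reverse_complement <- function(x) {
  cpp_revcomp(x)
}

#' Write a minimal SAM file of alignments against one amplicon
#'
#' Emits an `@HD`/`@SQ` header and one line per mapped alignment: FLAG 0/16
#' by strand, 1-based POS local to the amplicon, the CIGAR, and SEQ/QUAL in
#' reference orientation.
#'
#' @param alignments an alignment `data.frame` from [align_reads()].
#' @param amplicon a [reference_amplicon()].
#' @param path output path.
#' @export
write_sam <- function(alignments, amplicon, path) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", amplicon$name,
                      nchar(amplicon$sequence)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(alignments)) {
    a <- alignments[alignments$mapped, , drop = FALSE]
    if (nrow(a)) {
      flag <- ifelse(a$strand == "-", 16L, 0L)
      lines <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s",
                       a$read_id, flag, amplicon$name, a$ref_start + 1L,
                       a$cigar, a$seq, a$qual)
      writeLines(lines, con)
    }
  }
  invisible(path)
}
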