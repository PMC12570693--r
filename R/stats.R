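#' Reconstruct a count from a printed frequency and coverage
#'
#' Published tables print frequency and coverage rather than raw counts;
#' the count is recovered as `round(frequency * coverage)` to the nearest
#' integer, half away from zero.
#'
#' @param frequency fraction(s) in `[0, 1]`.
#' @param coverage total read count(s).
#' @return integer count(s).
#' @export
counts_from_frequency <- function(frequency, coverage) {
  stopifnot(all(frequency >= 0 & frequency <= 1), all(coverage >= 0))
  as.integer(floor(frequency * coverage + 0.5))
}

#' Two-sample proportion test
#'
#' 2x2 chi-square test without continuity correction (equivalent to the
#' two-sided two-proportion z-test); when any expected cell count is below
#' 5 the test switches to Fisher's exact two-sided test and records
#' `method = "fisher"`.
#'
#' @param k1,n1 successes / total in sample 1.
#' @param k2,n2 successes / total in sample 2.
#' @param label optional comparison label.
#' @return a `prop_test`: `list(label, k1, n1, k2, n2, statistic, p_value,
#'   method)`.
#' @export
two_proportion_test <- function(k1, n1, k2, n2, label = "") {
  stopifnot(k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  if (n1 == 0 || n2 == 0) stop("two_proportion_test: empty sample")
  m <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    p <- stats::fisher.test(m)$p.value
    statistic <- NA_real_
    method <- "fisher"
  } else {
    ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    statistic <- unname(ct$statistic)
    p <- ct$p.value
    method <- "chi2"
  }
  structure(list(label = label, k1 = k1, n1 = n1, k2 = k2, n2 = n2,
                 statistic = statistic, p_value = min(1, p),
                 method = method),
            class = "prop_test")
}

#' @export
print.prop_test <- function(x, ...) {
  cat(sprintf("%s: %d/%d vs %d/%d, %s p = %.3g\n",
              if (nzchar(x$label)) x$label else "proportions",
              x$k1, x$n1, x$k2, x$n2, x$method, x$p_value))
  invisible(x)
}

#' Row-wise comparison of two frequency tables
#'
#' Runs one [two_proportion_test()] per row key over the union of the two
#' tables' (unthresholded) rows; counts are reconstructed from each table's
#' fractions and coverage via [counts_from_frequency()]; a row absent from
#' one table is treated as frequency 0 at that table's coverage.
#'
#' @param tableA,tableB `freq_table` objects (see [classify_table()]).
#' @param bonferroni apply a Bonferroni correction across the rows.
#' @return a `data.frame(row, k1, n1, k2, n2, statistic, p_value, method)`.
#' @export
compare_frequency_tables <- function(tableA, tableB, bonferroni = FALSE) {
  for (tb in list(tableA, tableB)) {
    if (is.null(tb$coverage) || is.na(tb$coverage)) {
      stop("frequency table '", tb$label, "' carries no coverage")
    }
  }
  keys <- union(names(tableA$rows), names(tableB$rows))
  out <- lapply(keys, function(key) {
    fa <- if (key %in% names(tableA$rows)) tableA$rows[[key]] else 0
    fb <- if (key %in% names(tableB$rows)) tableB$rows[[key]] else 0
    tst <- two_proportion_test(counts_from_frequency(fa, tableA$coverage),
                               tableA$coverage,
                               counts_from_frequency(fb, tableB$coverage),
                               tableB$coverage, label = key)
    data.frame(row = key, k1 = tst$k1, n1 = tst$n1, k2 = tst$k2,
               n2 = tst$n2, statistic = tst$statistic,
               p_value = tst$p_value, method = tst$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (bonferroni) out$p_value <- pmin(1, out$p_value * nrow(out))
  out
}
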