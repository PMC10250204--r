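#' Fraction of upstream-first fragments (Fupfi)
#'
#' `upfi / (upfi + dofi)`; `NA` when no ordering-informative fragments exist.
#' Values near 1 mean the upstream intron is usually removed first, near 0
#' the downstream one.
#'
#' @param upfi,dofi Non-negative integer count vectors.
#' @return Numeric vector in `[0, 1]` with `NA` where `upfi + dofi == 0`.
#' @export
fupfi <- function(upfi, dofi) {
  den <- upfi + dofi
  ifelse(den > 0, upfi / den, NA_real_)
}

#' Proportion spliced-in (PSI)
#'
#' `((inup + indo) / 2) / ((inup + indo) / 2 + skip)`: inclusion evidence is
#' the mean of the two inclusion-junction counts, exclusion evidence the
#' skipping-junction count. `NA` when the denominator is 0.
#'
#' @param inup,indo,skip Count vectors.
#' @return Numeric vector in `[0, 1]` or `NA`.
#' @export
psi <- function(inup, indo, skip) {
  inc <- (inup + indo) / 2
  den <- inc + skip
  ifelse(den > 0, inc / den, NA_real_)
}

#' Proportion of intron retention (PIR)
#'
#' For one intron, `((EI + IE) / 2) / ((EI + IE) / 2 + J)`: `EI` and `IE`
#' count fragments spanning the intron's two exon/intron boundaries
#' unspliced, `J` counts spliced junctions across the intron. `NA` when the
#' denominator is 0.
#'
#' @param ei,ie Unspliced boundary counts at the intron's two ends.
#' @param j Spliced-junction count across the intron.
#' @return Numeric vector in `[0, 1]` or `NA`.
#' @export
pir <- function(ei, ie, j) {
  ret <- (ei + ie) / 2
  den <- ret + j
  ifelse(den > 0, ret / den, NA_real_)
}

# append fupfi/psi/pir columns to a counts table; NA rows forced NA
add_metrics <- function(counts) {
  out <- copy(data.table::as.data.table(counts))
  out[, fupfi := fupfi(upfi, dofi)]
  out[, psi := psi(inup, indo, skip)]
  out[, pir_up := pir(ne_up, ei_up, inup)]
  out[, pir_do := pir(ei_do, ns_do, indo)]
  if ("na_row" %in% names(out)) {
    out[na_row == TRUE, `:=`(fupfi = NA_real_, psi = NA_real_,
                             pir_up = NA_real_, pir_do = NA_real_)]
  }
  out[]
}

#' Write / read the per-exon output table
#'
#' Tab-separated, one row per input exon in input order, `NA` literal for
#' unavailable estimates; columns are all raw counts plus `fupfi`, `psi`,
#' `pir_up`, `pir_do`.
#'
#' @param results [aiso_count()] output.
#' @param path File path.
#' @param n_input Expected number of rows (errors on mismatch when given).
#' @return `write_aiso_table()`: `path`, invisibly. `read_aiso_table()`: a
#'   data.table.
#' @export
write_aiso_table <- function(results, path, n_input = NULL) {
  if (!is.null(n_input) && nrow(results) != n_input)
    stop("row count mismatch: ", nrow(results), " results for ",
         n_input, " input exons")
  data.table::fwrite(results, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_aiso_table
#' @export
read_aiso_table <- function(path) {
  data.table::fread(path, sep = "\t", na.strings = "NA")
}

#' Categorize exons by Fupfi
#'
#' Exons with `fupfi >= hi` are `upfi`, `<= lo` are `dofi`, in between
#' `intermediate`; exons with fewer than `min_reads` ordering-informative
#' fragments (or undefined Fupfi) are `NA`.
#'
#' @param fupfi_values Numeric vector of Fupfi values.
#' @param n Vector of `upfi + dofi` counts.
#' @param hi,lo Category thresholds (defaults 0.8 / 0.2).
#' @param min_reads Minimum informative fragments (default 10).
#' @return Character vector in `upfi`, `dofi`, `intermediate`, `NA`.
#' @export
aiso_categorize <- function(fupfi_values, n, hi = 0.8, lo = 0.2,
                            min_reads = 10L) {
  stopifnot(lo >= 0, hi <= 1, lo < hi)
  out <- rep(NA_character_, length(fupfi_values))
  ok <- !is.na(fupfi_values) & n >= min_reads
  out[ok & fupfi_values >= hi] <- "upfi"
  out[ok & fupfi_values <= lo] <- "dofi"
  out[ok & fupfi_values > lo & fupfi_values < hi] <- "intermediate"
  out
}

#' Consistency of AISO categories between two samples
#'
#' For shared exons categorized in both samples, reports, per query
#' category, the fraction keeping that category in the target, the
#' background expectation (the category's genome-wide fraction in the
#' target), and a one-sided binomial p-value for enrichment above
#' background; plus Pearson and Spearman correlations of the Fupfi values.
#'
#' @param fupfi_a,fupfi_b Fupfi vectors over the same exons (same order).
#' @param n_a,n_b Corresponding `upfi + dofi` counts.
#' @param hi,lo,min_reads Categorization parameters (see
#'   [aiso_categorize()]).
#' @return A list with `overlap` (data.table: `category`, `n`, `k`, `frac`,
#'   `background`, `p_value`), `pearson`, `spearman`.
#' @export
aiso_compare <- function(fupfi_a, fupfi_b, n_a, n_b, hi = 0.8, lo = 0.2,
                         min_reads = 10L) {
  stopifnot(length(fupfi_a) == length(fupfi_b))
  ca <- aiso_categorize(fupfi_a, n_a, hi, lo, min_reads)
  cb <- aiso_categorize(fupfi_b, n_b, hi, lo, min_reads)
  shared <- !is.na(ca) & !is.na(cb)
  cats <- c("upfi", "dofi", "intermediate")
  bg <- vapply(cats, function(cc) mean(cb[shared] == cc), 0)
  rows <- lapply(cats, function(cc) {
    sel <- shared & ca == cc
    n <- sum(sel)
    k <- sum(cb[sel] == cc)
    p0 <- bg[[cc]]
    p <- if (n == 0) NA_real_
         else stats::pbinom(k - 1L, n, p0, lower.tail = FALSE)
    data.table(category = cc, n = n, k = k,
               frac = if (n > 0) k / n else NA_real_,
               background = p0, p_value = p)
  })
  both <- !is.na(fupfi_a) & !is.na(fupfi_b) & n_a >= min_reads &
          n_b >= min_reads
  pe <- if (sum(both) > 2) stats::cor(fupfi_a[both], fupfi_b[both],
                                      method = "pearson") else NA_real_
  sp <- if (sum(both) > 2) stats::cor(fupfi_a[both], fupfi_b[both],
                                      method = "spearman") else NA_real_
  list(overlap = data.table::rbindlist(rows), pearson = pe, spearman = sp)
}
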