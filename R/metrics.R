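# The four hairpin-enrichment metrics: pairing density D, binomial occurrence
# probability P, mean contiguous stem length A, and stem GC content G.

#' Pairing density from raw counts
#'
#' `100 * n / k`. Under the "column" convention n and k are paired and total
#' alignment columns; under the "span" convention callers pass the number of
#' paired bases (2n) and the hairpin span length. Rounding happens only at
#' presentation time.
#'
#' @param n Number of matches.
#' @param k Total count the density is taken over.
#' @return Percentage in `[0, 100]` (vectorized).
#' @examples
#' round(density_D(52, 63), 2)  # 82.54
#' @export
density_D <- function(n, k) {
  stopifnot(is.numeric(n), is.numeric(k))
  if (any(k < 1)) stop("k must be >= 1 (density undefined for k = 0)")
  if (any(n < 0 | n > k)) stop("need 0 <= n <= k")
  100 * n / k
}

#' Pairing density of an alignment
#'
#' @param aln A classified `ir_alignment`.
#' @param convention `"column"`: paired columns over total columns (default).
#'   `"span"`: paired bases (2n) over the hairpin span length, the convention
#'   under which a 63-base hairpin with 26 pairs has density 52/63 = 82.54%.
#' @return Percentage.
#' @export
ir_density <- function(aln, convention = c("column", "span")) {
  stopifnot(inherits(aln, "ir_alignment"))
  convention <- match.arg(convention)
  switch(convention,
         column = density_D(aln$n, aln$k),
         span = density_D(2 * aln$n, aln$span_length))
}

#' Binomial point probability of the observed symmetry in log10 space
#'
#' `P(n, k) = 0.25^n * 0.75^(k-n) * choose(k, n)`: the probability that a
#' random arm pair of length k shows exactly n complementary positions, with
#' per-position pairing probability 1/4 on a 4-letter alphabet. Computed via
#' log-gamma so values far below 1e-62 stay finite.
#'
#' @param n Paired-column count(s).
#' @param k Total column count(s), `k >= 1`.
#' @return log10 of the probability (vectorized).
#' @export
log10_probability_P <- function(n, k) {
  if (!is.numeric(n) || !is.numeric(k) || any(is.na(n)) || any(is.na(k)) ||
      any(k < 1) || any(n < 0) || any(n > k) ||
      any(n != floor(n)) || any(k != floor(k))) {
    stop("need integers 0 <= n <= k, k >= 1")
  }
  (lchoose(k, n) + n * log(0.25) + (k - n) * log(0.75)) / log(10)
}

#' @rdname log10_probability_P
#' @return `probability_P()`: the probability itself (may underflow to 0
#'   below ~1e-308; use the log10 form for comparisons).
#' @examples
#' probability_P(1, 1)  # 0.25
#' probability_P(1, 4)  # 0.421875
#' @export
probability_P <- function(n, k) 10^log10_probability_P(n, k)

#' Mantissa/exponent form of a log10 probability
#'
#' @param log10p log10 of a probability.
#' @return List with `mantissa` in `[1, 10)` and integer `exponent`, so that
#'   p = mantissa * 10^exponent.
#' @export
p_mantissa_exponent <- function(log10p) {
  e <- floor(log10p)
  list(mantissa = 10^(log10p - e), exponent = as.integer(e))
}

#' Lengths of maximal contiguous paired runs
#'
#' Runs of consecutive paired columns (WC or wobble), broken by mismatch or
#' gap columns. These are the stems of the predicted hairpin.
#'
#' @param aln A classified `ir_alignment`.
#' @return Integer vector of run lengths (possibly empty).
#' @export
paired_runs <- function(aln) {
  stopifnot(inherits(aln, "ir_alignment"))
  paired <- aln$columns$class %in% c("WC_MATCH", "WOBBLE")
  r <- rle(paired)
  r$lengths[r$values]
}

#' Mean contiguous stem length (A)
#'
#' Average of the maximal paired-run lengths. Undefined (NA) when the
#' alignment has no paired column; such records are rejected downstream.
#'
#' @param aln A classified `ir_alignment`.
#' @return Mean run length in bp, or `NA_real_`.
#' @examples
#' # runs of length 6, 8, 1 and 11 average to 6.5
#' @export
avg_stem_A <- function(aln) {
  runs <- paired_runs(aln)
  if (length(runs) == 0L) return(NA_real_)
  mean(runs)
}

#' Stem GC content (G)
#'
#' Percentage of G-C / C-G pairs among the paired columns that lie inside
#' contiguous paired runs longer than 3 bp (shorter runs are more likely loop
#' than stem). Wobble columns inside qualifying runs count in the denominator
#' only. Undefined (NA) when no run exceeds 3 bp; such records are rejected.
#'
#' @param aln A classified `ir_alignment`.
#' @param min_run Minimum qualifying run length (default 4, i.e. > 3 bp).
#' @return Percentage, or `NA_real_`.
#' @export
stem_gc_G <- function(aln, min_run = 4L) {
  stopifnot(inherits(aln, "ir_alignment"), min_run >= 1L)
  paired <- aln$columns$class %in% c("WC_MATCH", "WOBBLE")
  r <- rle(paired)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  if (!any(keep)) return(NA_real_)
  idx <- unlist(mapply(seq, starts[keep], ends[keep], SIMPLIFY = FALSE))
  gc <- aln$columns$class[idx] == "WC_MATCH" & aln$columns$q[idx] %in% c("G", "C")
  100 * sum(gc) / length(idx)
}

#' Compute the four filter metrics on scanned IR records
#'
#' Adds columns `D`, `log10P`, `A`, `G` and `span_length` to a record table
#' produced by [scan_genome()]. `A` and `G` are `NA` where undefined (no
#' paired column / no stem run > 3 bp); [apply_filters()] rejects those.
#'
#' @param records Record data.frame from [scan_genome()].
#' @param convention Density convention, see [ir_density()].
#' @param gc_min_run Minimum qualifying run length for G.
#' @return The record table with metric columns filled.
#' @export
compute_metrics <- function(records, convention = c("column", "span"),
                            gc_min_run = 4L) {
  convention <- match.arg(convention)
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    records$D <- numeric(0); records$log10P <- numeric(0)
    records$A <- numeric(0); records$G <- numeric(0)
    return(records)
  }
  alns <- records$alignment
  records$D <- vapply(alns, ir_density, numeric(1), convention = convention)
  records$log10P <- log10_probability_P(records$n, records$k)
  records$A <- vapply(alns, avg_stem_A, numeric(1))
  records$G <- vapply(alns, stem_gc_G, numeric(1), min_run = gc_min_run)
  records
}
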