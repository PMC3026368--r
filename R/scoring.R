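#' Default scoring scheme of the inverted-repeat detector
#'
#' A 5x5 substitution matrix over \{A,C,G,U,N\} plus a linear gap penalty.
#' The matrix is indexed (query residue, target residue) where the target is
#' the reverse complement of the scanned sequence, so identical letters are
#' Watson-Crick pairs of the hairpin. It is deliberately asymmetric: the two
#' -2 entries (G-row vs A, U-row vs C) score G.U wobble pairs, which after
#' reverse complementation appear as those letter combinations.
#'
#' Defaults: diagonal A/C/G/U = 5, N-N = 3, N vs anything else = 0, the two
#' wobble entries = -2, every other off-diagonal = -4, gap penalty = -6.
#'
#' @param match Score of a Watson-Crick pair column.
#' @param mismatch Score of a non-pairing column.
#' @param wobble Score of a G.U wobble column.
#' @param n_n Score of an N-N column.
#' @param n_other Score of an N vs non-N column.
#' @param gap Linear per-column gap penalty (negative).
#' @return An object of class `scoring_scheme`: list with `substitution`
#'   (5x5 integer matrix, dimnames ACGUN) and `gap_penalty`.
#' @examples
#' sc <- default_scoring()
#' sc$substitution["G", "A"]  # -2 (wobble)
#' @export
default_scoring <- function(match = 5L, mismatch = -4L, wobble = -2L,
                            n_n = 3L, n_other = 0L, gap = -6L) {
  stopifnot(gap < 0L)
  m <- matrix(as.integer(mismatch), 5L, 5L,
              dimnames = list(RNA_BASES, RNA_BASES))
  diag(m) <- as.integer(match)
  m["N", ] <- as.integer(n_other)
  m[, "N"] <- as.integer(n_other)
  m["N", "N"] <- as.integer(n_n)
  m["G", "A"] <- as.integer(wobble)
  m["U", "C"] <- as.integer(wobble)
  structure(list(substitution = m, gap_penalty = as.integer(gap)),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("Inverted-repeat scoring scheme (query x revcomp target)\n")
  print(x$substitution)
  cat("gap penalty:", x$gap_penalty, "\n")
  invisible(x)
}

#' @noRd
check_scoring <- function(scheme) {
  if (!inherits(scheme, "scoring_scheme") ||
      !is.matrix(scheme$substitution) ||
      !all(dim(scheme$substitution) == c(5L, 5L)) ||
      !is.numeric(scheme$gap_penalty)) {
    stop("'scoring' must be a scoring_scheme (see default_scoring())")
  }
  invisible(scheme)
}
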