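# Core inverted-repeat detector: local self-alignment against the reverse
# complement. Column classes: WC_MATCH (identical non-N letters = Watson-Crick
# pair in hairpin space), WOBBLE (G vs A or U vs C = G.U pair), MISMATCH
# (anything else, including N-N), GAP.

COLUMN_CLASSES <- c("WC_MATCH", "WOBBLE", "MISMATCH", "GAP")

#' Find the optimal inverted repeat within a single sequence
#'
#' Locally aligns `seq` against its own reverse complement under `scoring`
#' using a Smith-Waterman variant whose search domain is restricted so that
#' the two arms of the reported alignment never overlap on the original
#' molecule (a position may only pair with a strictly downstream position).
#' Only the single best alignment is reported. Ties are broken
#' deterministically: the traceback starts at the maximal cell with smallest
#' (row, column), and prefers diagonal over up over left moves.
#'
#' @param seq RNA sequence (single string over ACGUN; see [dna_to_rna()]).
#' @param scoring A [default_scoring()] scheme.
#' @return An `ir_alignment` object, or `NULL` when no alignment scores > 0.
#'   Fields: `score`; `arm1`, `arm2`, `span` (1-based inclusive intervals on
#'   `seq`); `columns` (data.frame `q`, `t`, `class`, gaps as `"-"`); `k`
#'   total columns; `n` paired columns (WC + wobble); `pairing` dot-bracket
#'   string over the span; `L` input length.
#' @examples
#' aln <- self_ir_align(paste0(strrep("G", 10), "AUAU", strrep("C", 10)))
#' aln$score  # 50: ten Watson-Crick columns at +5
#' @export
self_ir_align <- function(seq, scoring = default_scoring()) {
  check_rna(seq)
  check_scoring(scoring)
  L <- nchar(seq)
  if (L < 2L) stop("sequence must have length >= 2")
  q <- encode_rna(seq)
  t <- rev(c(4L, 3L, 2L, 1L, 5L)[q])  # codes of reverse complement
  res <- .sw_self_align(q, t, scoring$substitution, as.integer(scoring$gap_penalty))
  if (res$score <= 0L) return(NULL)
  qch <- ifelse(res$qpos > 0L, RNA_BASES[q[pmax(res$qpos, 1L)]], "-")
  tch <- ifelse(res$tpos > 0L, RNA_BASES[t[pmax(res$tpos, 1L)]], "-")
  qs <- min(res$qpos[res$qpos > 0L])
  ts <- min(res$tpos[res$tpos > 0L])
  aln <- new_ir_alignment(data.frame(q = qch, t = tch, stringsAsFactors = FALSE),
                          qs = qs, ts = ts, L = L, score = res$score)
  classify_columns(aln, scoring)
}

# Shared constructor: derives arm/span geometry and the pairing string from
# the column list. `columns$class` must be filled (classify_columns) before
# n and the pairing string are meaningful; callers run classify afterwards.
#' @noRd
new_ir_alignment <- function(columns, qs, ts, L, score) {
  arm1_len <- sum(columns$q != "-")
  arm2_len <- sum(columns$t != "-")
  qe <- qs + arm1_len - 1L
  te <- ts + arm2_len - 1L
  if (qe + te > L) stop("internal error: alignment arms overlap")
  structure(list(
    score = as.integer(score),
    qs = as.integer(qs), qe = as.integer(qe),
    ts = as.integer(ts), te = as.integer(te),
    arm1 = c(as.integer(qs), as.integer(qe)),
    arm2 = c(L - te + 1L, L - ts + 1L),
    span = c(as.integer(qs), L - ts + 1L),
    span_length = (L - ts + 1L) - qs + 1L,
    L = as.integer(L),
    columns = columns,
    k = nrow(columns),
    n = NA_integer_,
    pairing = NA_character_
  ), class = "ir_alignment")
}

#' Classify alignment columns and count paired columns
#'
#' Labels every column WC_MATCH (identical non-N letters), WOBBLE (G vs A or
#' U vs C, the -2 entries of the default scheme, i.e. G.U pairs in hairpin
#' space), GAP, or MISMATCH (everything else, including N-N), then sets
#' `n` = WC + wobble count and rebuilds the dot-bracket pairing string.
#'
#' @param aln An `ir_alignment`.
#' @param scoring Scoring scheme (kept for interface symmetry; wobble columns
#'   are the fixed letter combinations above).
#' @return The alignment with `columns$class`, `n` and `pairing` filled.
#' @export
classify_columns <- function(aln, scoring = default_scoring()) {
  stopifnot(inherits(aln, "ir_alignment"))
  q <- aln$columns$q
  t <- aln$columns$t
  cls <- rep("MISMATCH", length(q))
  cls[q == "-" | t == "-"] <- "GAP"
  cls[q == t & q != "N" & q != "-"] <- "WC_MATCH"
  cls[(q == "G" & t == "A") | (q == "U" & t == "C")] <- "WOBBLE"
  aln$columns$class <- cls
  aln$n <- sum(cls %in% c("WC_MATCH", "WOBBLE"))
  aln$pairing <- build_pairing(aln)
  aln
}

#' @noRd
build_pairing <- function(aln) {
  p <- rep(".", aln$span_length)
  paired <- aln$columns$class %in% c("WC_MATCH", "WOBBLE")
  off <- aln$span[1] - 1L
  qpos <- aln$qs - 1L
  tcount <- 0L
  for (i in seq_len(nrow(aln$columns))) {
    if (aln$columns$q[i] != "-") {
      qpos <- qpos + 1L
      if (paired[i]) p[qpos - off] <- "("
    }
    if (aln$columns$t[i] != "-") {
      tcount <- tcount + 1L
      if (paired[i]) {
        orig <- aln$L + 1L - (aln$ts + tcount - 1L)
        p[orig - off] <- ")"
      }
    }
  }
  paste(p, collapse = "")
}

#' Dot-bracket pairing string of an alignment
#'
#' `'('` / `')'` mark paired positions on the 5' / 3' arm, `'.'` marks
#' unpaired arm positions and the loop. The string covers the full span and
#' is always balanced.
#'
#' @param aln A classified `ir_alignment`.
#' @return A character scalar.
#' @export
pairing_string <- function(aln) {
  if (is.null(aln)) stop("no alignment (empty input to pairing_string)")
  stopifnot(inherits(aln, "ir_alignment"))
  if (anyNA(aln$columns$class)) aln <- classify_columns(aln)
  aln$pairing
}

#' Recompute an alignment's score from its columns
#'
#' Independent re-scoring check: sums substitution scores over residue
#' columns and the gap penalty over gap columns.
#'
#' @param aln An `ir_alignment`.
#' @param scoring Scoring scheme.
#' @return Integer score.
#' @export
rescore_alignment <- function(aln, scoring = default_scoring()) {
  stopifnot(inherits(aln, "ir_alignment"))
  check_scoring(scoring)
  s <- 0L
  for (i in seq_len(nrow(aln$columns))) {
    qi <- aln$columns$q[i]
    ti <- aln$columns$t[i]
    s <- s + if (qi == "-" || ti == "-") scoring$gap_penalty
             else scoring$substitution[qi, ti]
  }
  as.integer(s)
}

#' @export
print.ir_alignment <- function(x, ...) {
  cat(sprintf("ir_alignment: score %d, span %d..%d (%d bp), arms %d..%d / %d..%d\n",
              x$score, x$span[1], x$span[2], x$span_length,
              x$arm1[1], x$arm1[2], x$arm2[1], x$arm2[2]))
  cat(sprintf("  k = %d columns, n = %d paired (WC %d, wobble %d)\n",
              x$k, x$n, sum(x$columns$class == "WC_MATCH"),
              sum(x$columns$class == "WOBBLE")))
  if (!is.na(x$pairing) && nchar(x$pairing) <= 100L) cat("  ", x$pairing, "\n")
  invisible(x)
}
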