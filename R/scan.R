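# Multi-scale sliding-window genome scanning.

#' Window scheme for multi-scale scanning
#'
#' Window sizes with skip = half the window size, so every position (except a
#' short contig tail) is covered by two windows of each size. Defaults mirror
#' the sizes of known pre-miRNA precursors: 600, 300 and 150 bp.
#'
#' @param sizes Strictly decreasing window sizes in bp, each at least twice
#'   `min_len`.
#' @param min_len Minimum IR span length; truncated tail windows shorter than
#'   this are dropped from enumeration.
#' @return A `window_scheme` object.
#' @export
window_scheme <- function(sizes = c(600L, 300L, 150L), min_len = 50L) {
  sizes <- as.integer(sizes)
  if (length(sizes) == 0L || any(diff(sizes) >= 0L)) {
    stop("window sizes must be strictly decreasing")
  }
  if (any(sizes < 2L * min_len)) {
    stop("every window size must be >= 2 * min_len")
  }
  if (any(sizes %% 2L != 0L)) stop("window sizes must be even (skip = size/2)")
  structure(list(sizes = sizes, skips = sizes %/% 2L,
                 min_len = as.integer(min_len)),
            class = "window_scheme")
}

#' Enumerate scan windows over a contig
#'
#' For each window size s, starts step by s/2 from position 1 while the start
#' lies inside the contig; the final window is truncated at the contig end,
#' and truncated windows shorter than `scheme$min_len` are dropped.
#'
#' @param contig_length Contig length in bp.
#' @param scheme A [window_scheme()].
#' @return data.frame with 1-based `start`, realized `length`, and the `size`
#'   of the originating window track.
#' @export
enumerate_windows <- function(contig_length, scheme = window_scheme()) {
  stopifnot(inherits(scheme, "window_scheme"), contig_length >= 1)
  L <- as.integer(contig_length)
  out <- lapply(seq_along(scheme$sizes), function(i) {
    s <- scheme$sizes[i]
    skip <- scheme$skips[i]
    starts <- seq.int(1L, L, by = skip)
    len <- pmin(s, L - starts + 1L)
    keep <- len >= scheme$min_len
    data.frame(start = starts[keep], length = len[keep], size = s)
  })
  do.call(rbind, out)
}

#' @noRd
empty_records <- function() {
  data.frame(contig = character(0), start = integer(0), end = integer(0),
             arm1_start = integer(0), arm1_end = integer(0),
             arm2_start = integer(0), arm2_end = integer(0),
             window_size = integer(0), window_start = integer(0),
             score = integer(0), k = integer(0), n = integer(0),
             span_length = integer(0),
             pairing = character(0), sequence = character(0),
             stringsAsFactors = FALSE)
}

#' Scan a genome for inverted repeats
#'
#' Slides the window scheme across every contig, runs [self_ir_align()] in
#' each window (at most one candidate per window), and translates window-local
#' alignment coordinates to genomic coordinates. Metrics are left uncomputed;
#' see [compute_metrics()]. Only the forward strand is scanned: an inverted
#' repeat's reverse complement is itself an inverted repeat, so a
#' single-strand scan is complete for detection.
#'
#' @param genome Named character vector of RNA contig sequences
#'   (from [read_fasta()] or [make_genome()]).
#' @param scheme A [window_scheme()].
#' @param scoring A [default_scoring()] scheme.
#' @param quiet Suppress per-contig progress messages.
#' @return data.frame of IR records (1-based inclusive coordinates) with an
#'   `alignment` list-column holding the classified `ir_alignment` objects.
#' @export
scan_genome <- function(genome, scheme = window_scheme(),
                        scoring = default_scoring(), quiet = TRUE) {
  stopifnot(is.character(genome))
  if (length(genome) == 0L) {
    rec <- empty_records(); rec$alignment <- list(); return(rec)
  }
  if (is.null(names(genome)) || anyNA(names(genome)) || any(names(genome) == "")) {
    stop("genome contigs must be named")
  }
  rows <- list()
  alns <- list()
  for (contig in names(genome)) {
    seq <- genome[[contig]]
    check_rna(seq)
    wins <- enumerate_windows(nchar(seq), scheme)
    if (is.null(wins) || nrow(wins) == 0L) next
    for (w in seq_len(nrow(wins))) {
      ws <- wins$start[w]
      wl <- wins$length[w]
      aln <- tryCatch(
        self_ir_align(substr(seq, ws, ws + wl - 1L), scoring),
        error = function(e) {
          warning("window ", contig, ":", ws, " (size ", wins$size[w],
                  ") failed: ", conditionMessage(e))
          NULL
        })
      if (is.null(aln)) next
      off <- ws - 1L
      start <- off + aln$span[1]
      end <- off + aln$span[2]
      rows[[length(rows) + 1L]] <- data.frame(
        contig = contig, start = start, end = end,
        arm1_start = off + aln$arm1[1], arm1_end = off + aln$arm1[2],
        arm2_start = off + aln$arm2[1], arm2_end = off + aln$arm2[2],
        window_size = wins$size[w], window_start = ws,
        score = aln$score, k = aln$k, n = aln$n,
        span_length = aln$span_length,
        pairing = aln$pairing,
        sequence = substr(seq, start, end),
        stringsAsFactors = FALSE)
      alns[[length(alns) + 1L]] <- aln
    }
    if (!quiet) message("scanned ", contig, ": ", length(rows), " records so far")
  }
  if (length(rows) == 0L) {
    rec <- empty_records(); rec$alignment <- list(); return(rec)
  }
  rec <- do.call(rbind, rows)
  rownames(rec) <- NULL
  rec$alignment <- alns
  rec
}
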