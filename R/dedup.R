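# Removal of duplicate IRs produced by adjacent overlapping windows of the
# same size. Applied after all filters, matching the pipeline ordering
# scan -> metrics -> filters -> dedup.

#' Remove same-track duplicates from adjacent overlapping windows
#'
#' Within each (contig, window size) group, every pair of records whose
#' windows are exactly one skip (= size/2) apart and whose genomic spans
#' overlap by at least 1 bp is treated as a duplicate pair, and the record
#' with the shorter span is dropped (ties: lower score, then later window
#' start). Records from different window sizes are never compared. Note the
#' deliberate limitation: genuinely distinct nearby identical IRs seen by
#' adjacent windows are also collapsed — this simple rule cannot distinguish
#' them from scan duplicates.
#'
#' @param records Record table (any stage; must carry `window_size`,
#'   `window_start`, `start`, `end`, `score`).
#' @return The surviving records, ordered by (contig, span start).
#' @export
remove_duplicates <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) return(records)
  drop <- rep(FALSE, nrow(records))
  key <- paste(records$contig, records$window_size, sep = "\r")
  for (grp in split(seq_len(nrow(records)), key)) {
    if (length(grp) < 2L) next
    skip <- records$window_size[grp[1]] %/% 2L
    ord <- grp[order(records$window_start[grp])]
    for (a in seq_along(ord)) {
      for (b in seq_along(ord)) {
        if (a >= b) next
        i <- ord[a]; j <- ord[b]
        if (abs(records$window_start[i] - records$window_start[j]) != skip) next
        if (records$start[i] > records$end[j] || records$start[j] > records$end[i]) next
        li <- records$end[i] - records$start[i]
        lj <- records$end[j] - records$start[j]
        loser <- if (li != lj) {
          if (li < lj) i else j
        } else if (records$score[i] != records$score[j]) {
          if (records$score[i] < records$score[j]) i else j
        } else {
          # equal length and score: drop the later window's record
          if (records$window_start[i] > records$window_start[j]) i else j
        }
        drop[loser] <- TRUE
      }
    }
  }
  out <- records[!drop, , drop = FALSE]
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
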