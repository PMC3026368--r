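# Shared fixture builders (all synthetic, generated in code).

# Handcraft a classified alignment from paired-run composition.
# runs: list of character vectors, each a run of identical-letter (WC) pairs;
# wobble runs can be requested by two-letter codes "GA"/"UC".
# Separated by single (A, C) mismatch columns. Loop defaults to 5 nt.
make_aln_from_runs <- function(runs, loop = 5L) {
  q <- character(0); t <- character(0)
  for (i in seq_along(runs)) {
    for (ch in runs[[i]]) {
      if (nchar(ch) == 2L) {
        q <- c(q, substr(ch, 1, 1)); t <- c(t, substr(ch, 2, 2))
      } else {
        q <- c(q, ch); t <- c(t, ch)
      }
    }
    if (i < length(runs)) { q <- c(q, "A"); t <- c(t, "C") }
  }
  cols <- data.frame(q = q, t = t, stringsAsFactors = FALSE)
  L <- 2L * nrow(cols) + loop
  sub <- oracle_matrix()
  score <- sum(vapply(seq_len(nrow(cols)), function(i) sub[q[i], t[i]],
                      integer(1)))
  aln <- dyadscan:::new_ir_alignment(cols, qs = 1L, ts = 1L, L = L,
                                     score = max(score, 1L))
  classify_columns(aln)
}

# A hairpin string: arm + loop + revcomp(arm)
hairpin_seq <- function(arm, loop = "AACAA") {
  paste0(arm, loop, oracle_revcomp(arm))
}

# Small scanned-and-measured record table from a planted fixture genome.
small_fixture_records <- function(seed = 101L, count = 8L,
                                  background_length = 20000L) {
  spec <- plant_spec(count = count, background_length = background_length,
                     seed = seed)
  sim <- make_genome(spec)
  rec <- scan_genome(sim$genome)
  list(records = compute_metrics(rec), sim = sim)
}
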