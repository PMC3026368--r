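# Synthetic genomes with planted, degraded hairpins and truth annotations.

#' Specification for a synthetic genome with planted hairpins
#'
#' Each hairpin is built as a random 5' arm + loop + exact reverse complement
#' of the arm, then degraded on the 3' arm only (mirroring duplication
#' followed by divergence): wobble conversions turn eligible G-C/U-A pairs
#' into G.U/U.G, substitutions replace the 3' partner with a base that
#' neither Watson-Crick-pairs nor wobbles with its 5' partner (so every
#' substitution is a real mismatch), and indels insert or delete single
#' bases. Degradation counts are deterministic, `round(rate * stem_length)`
#' each, at randomly chosen stem pairs placed at least 3 bp inside the stem
#' ends and at least 3 bp apart, so the aligner never profits from trimming
#' or shifting around them and a planted locus's realized pairing density is
#' known in closed form: D = 100 * (stem - n_sub) / stem when indels are off.
#'
#' Stems get their own GC content (default 0.48; pairing stability enriches
#' real hairpin stems in GC relative to an AT-rich background). The
#' background is i.i.d. with adjustable GC. Plants are placed at random
#' non-overlapping loci at least `min_spacing` bp apart and `margin` bp from
#' contig ends, so each hairpin is wholly contained in at least one window of
#' the smallest default track.
#'
#' @param stem_length Arm length in bp (>= 10 when any degradation is on).
#' @param loop_length Loop length in nt (>= 3; hairpin loops are necessary).
#' @param wobble_fraction Fraction of stem pairs converted to wobbles.
#' @param substitution_rate Fraction of stem pairs broken by substitution.
#' @param indel_rate Fraction of stem pairs hit by a 1-bp insertion/deletion.
#' @param count Number of hairpins to plant.
#' @param background_length Contig length in bp.
#' @param background_gc Background GC fraction.
#' @param stem_gc Stem-arm GC fraction.
#' @param min_spacing Minimum distance between planted loci.
#' @param margin Keep-out distance from contig ends.
#' @param seed Integer seed fixing all randomness.
#' @return A `plant_spec` object.
#' @export
plant_spec <- function(stem_length = 30L, loop_length = 10L,
                       wobble_fraction = 0.07, substitution_rate = 0.10,
                       indel_rate = 0.03, count = 20L,
                       background_length = 100000L, background_gc = 0.36,
                       stem_gc = 0.48, min_spacing = 200L, margin = 500L,
                       seed = 1L) {
  rates <- c(wobble_fraction, substitution_rate, indel_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (stem_length < 1L) stop("stem_length must be >= 1")
  if (loop_length < 3L) stop("loop_length must be >= 3 (hairpin loops are necessary)")
  if (background_gc < 0 || background_gc > 1 || stem_gc < 0 || stem_gc > 1) {
    stop("GC fractions must lie in [0, 1]")
  }
  n_deg <- sum(round(rates * stem_length))
  if (stem_length >= 8L && 3L * n_deg > stem_length - 4L) {
    stop("degradation rates too high for this stem length")
  }
  structure(list(stem_length = as.integer(stem_length),
                 loop_length = as.integer(loop_length),
                 wobble_fraction = wobble_fraction,
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate, count = as.integer(count),
                 background_length = as.integer(background_length),
                 background_gc = background_gc, stem_gc = stem_gc,
                 min_spacing = as.integer(min_spacing),
                 margin = as.integer(margin), seed = as.integer(seed)),
            class = "plant_spec")
}

#' @noRd
sample_bases <- function(n, gc) {
  sample(c("G", "C", "A", "U"), n, replace = TRUE,
         prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
}

# Loops are drawn from the non-pairing two-letter alphabet {A, C}: no A/C
# combination forms a Watson-Crick or wobble pair, so the detector can never
# extend the stem into the loop (not even via gap-shifted registers) and the
# planted stem is exactly the detectable IR. This keeps the generator's
# closed-form contract (n = k = stem_length for undegraded plants) exact; the
# cost in realism is documented in the methods vignette.
#' @noRd
sample_loop <- function(len, gc) {
  sample(c("C", "A"), len, replace = TRUE, prob = c(gc, 1 - gc))
}

# For a 5' base x paired with comp(x) on the 3' arm: which 3' replacements
# produce a wobble, and which guarantee a mismatch (no WC, no wobble).
WOBBLE_PARTNER <- c(A = NA, C = NA, G = "U", U = "G")
MISMATCH_CHOICES <- list(A = c("A", "C", "G"), C = c("A", "C", "U"),
                         G = c("A", "G"), U = c("C", "U"))

#' @noRd
build_plant <- function(spec) {
  s <- spec$stem_length
  arm1 <- sample_bases(s, spec$stem_gc)
  loop <- sample_loop(spec$loop_length, spec$background_gc)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  arm2 <- rev(unname(comp[arm1]))  # arm2[s + 1 - i] pairs arm1[i]
  # degradation sites sit >= 3 bp inside the stem ends and >= 3 bp apart:
  # trimming a flanking block of >= 3 pairs (+15) to shed one -4/-6 column
  # never pays, so the optimal alignment always spans the full stem and the
  # realized density stays in closed form
  avail <- if (s >= 7L) 4:(s - 3L) else integer(0)
  n_wob <- round(spec$wobble_fraction * s)
  n_sub <- round(spec$substitution_rate * s)
  n_ind <- round(spec$indel_rate * s)
  pick <- function(n, pool_filter = NULL) {
    chosen <- integer(0)
    while (n > 0L) {
      pool <- if (is.null(pool_filter)) avail else avail[pool_filter(avail)]
      if (length(pool) == 0L) break
      p <- pool[sample.int(length(pool), 1L)]
      chosen <- c(chosen, p)
      avail <<- avail[abs(avail - p) > 2L]
      n <- n - 1L
    }
    chosen
  }
  wob <- pick(n_wob, function(pos) arm1[pos] %in% c("G", "U"))
  sub <- pick(n_sub)
  ind <- pick(n_ind)
  for (i in wob) arm2[s + 1L - i] <- WOBBLE_PARTNER[[arm1[i]]]
  for (i in sub) {
    ch <- MISMATCH_CHOICES[[arm1[i]]]
    arm2[s + 1L - i] <- ch[sample.int(length(ch), 1L)]
  }
  # apply indels right-to-left so positions stay valid
  for (i in sort(s + 1L - ind, decreasing = TRUE)) {
    if (sample.int(2L, 1L) == 1L) {
      arm2 <- arm2[-i]
    } else {
      arm2 <- append(arm2, sample_bases(1L, spec$background_gc), after = i)
    }
  }
  list(seq = paste(c(arm1, loop, arm2), collapse = ""),
       n_wob = length(wob), n_sub = length(sub), n_ind = length(ind))
}

#' Generate a synthetic genome with planted hairpins
#'
#' Deterministic under `spec$seed`. See [plant_spec()] for the degradation
#' model.
#'
#' @param spec A [plant_spec()].
#' @param contig Contig name used in the output.
#' @return List with `genome` (named character, RNA), `truth` (data.frame of
#'   planted loci: contig, start, end 1-based inclusive, name, score =
#'   realized paired fraction x 1000, strand, seq, n_wob, n_sub, n_ind), and
#'   `plants` (named character vector of the planted sequences as realized).
#' @export
make_genome <- function(spec = plant_spec(), contig = "synth1") {
  stopifnot(inherits(spec, "plant_spec"))
  set.seed(spec$seed)
  L <- spec$background_length
  plants <- lapply(seq_len(spec$count), function(i) build_plant(spec))
  lens <- vapply(plants, function(p) nchar(p$seq), integer(1))
  if (any(L - 2L * spec$margin - lens < 0L)) {
    stop("hairpins cannot fit in the background with the given margin")
  }
  # rejection-sample non-overlapping, spaced placements
  placed <- integer(0)
  for (i in seq_along(plants)) {
    ok <- FALSE
    for (try in seq_len(10000L)) {
      st <- sample.int(L - 2L * spec$margin - lens[i] + 1L, 1L) + spec$margin
      if (all(abs(st - placed) >= spec$min_spacing + max(lens))) {
        placed <- c(placed, st)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place hairpin ", i, "; reduce count or spacing")
  }
  bg <- sample_bases(L, spec$background_gc)
  for (i in seq_along(plants)) {
    chars <- strsplit(plants[[i]]$seq, "", fixed = TRUE)[[1L]]
    bg[placed[i] + seq_along(chars) - 1L] <- chars
  }
  genome <- setNames(paste(bg, collapse = ""), contig)
  s <- spec$stem_length
  truth <- data.frame(
    contig = contig,
    start = placed,
    end = placed + lens - 1L,
    name = sprintf("plant_%02d", seq_along(plants)),
    score = vapply(plants, function(p) {
      round(1000 * (s - p$n_sub - p$n_ind) / s)
    }, numeric(1)),
    strand = "+",
    seq = vapply(plants, `[[`, character(1), "seq"),
    n_wob = vapply(plants, `[[`, integer(1), "n_wob"),
    n_sub = vapply(plants, `[[`, integer(1), "n_sub"),
    n_ind = vapply(plants, `[[`, integer(1), "n_ind"),
    stringsAsFactors = FALSE)
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  list(genome = genome,
       truth = truth,
       plants = setNames(truth$seq, truth$name),
       spec = spec)
}

#' Handcrafted alignment reproducing the worked filter examples
#'
#' A synthetic (not biological) alignment with paired-run lengths exactly
#' 6, 8, 1 and 11 bp separated by single mismatches, 29 columns per arm and a
#' 5-nt loop, i.e. a 63-base hairpin span carrying 26 pairs (52 paired
#' bases). Its mean stem length is (6+8+1+11)/4 = 6.5 bp and its span-
#' convention density is 100*52/63 = 82.54%.
#'
#' @return A classified `ir_alignment`.
#' @export
worked_example_fixture <- function() {
  run_letters <- list(c("G", "C", "A", "U", "G", "C"),
                      c("A", "U", "A", "U", "G", "C", "G", "C"),
                      c("U"),
                      c("G", "C", "G", "C", "A", "U", "A", "U", "G", "C", "A"))
  q <- character(0)
  for (i in seq_along(run_letters)) {
    q <- c(q, run_letters[[i]])
    if (i < length(run_letters)) q <- c(q, "A")  # mismatch separator
  }
  t <- q
  t[c(7L, 16L, 18L)] <- "C"  # (A, C) mismatch columns between the runs
  cols <- data.frame(q = q, t = t, stringsAsFactors = FALSE)
  score <- 26L * 5L + 3L * -4L
  aln <- new_ir_alignment(cols, qs = 1L, ts = 1L, L = 63L, score = score)
  classify_columns(aln)
}
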