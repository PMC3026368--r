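---
title: "Detecting and enriching hairpin-forming inverted repeats with dyadscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and enriching hairpin-forming inverted repeats with dyadscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadscan)
```

## The problem

An inverted repeat (IR) is a stretch of DNA followed, after a spacer, by its
reverse complement. When transcribed, an IR folds back on itself into a
hairpin: a base-paired stem capped by an unpaired loop. Hairpins of the right
shape are the precursors of microRNAs (pre-miRNAs) and other non-coding RNAs,
but genomic DNA contains hundreds of thousands of IRs of varying symmetry, the
overwhelming majority of them non-functional. dyadscan addresses the
enrichment problem: find every sufficiently symmetric IR in a genome, then
filter the candidates toward those that look like pre-miRNA hairpins, and
quantify that trade-off against a user-supplied set of known precursors.

## The detector

The core primitive is a Smith–Waterman local alignment of a sequence against
its own reverse complement. A local alignment between the two strands of the
same molecule reads out directly as a hairpin: aligned columns are base pairs,
the aligned spans map back to the two arms, and the text between the arms is
the loop. Input DNA is translated to the RNA alphabet (T to U; IUPAC ambiguity
codes other than N collapse to N) on ingest.

Scoring (see `default_scoring()`): +5 for a Watson–Crick pair, −4 for a
mismatch, −6 per gap column, N scores 0 against everything except +3 against
N. Two deliberately *asymmetric* entries score −2: query G against target A,
and query U against target C. Because the target is the reverse complement,
these letter combinations are exactly the two orientations of the G·U wobble
pair, which is a real (if weaker) RNA pair. Keeping them mildly negative lets
stems carry wobbles without rewarding them as true matches.

Three mechanics are worth spelling out:

* **Self-overlap.** Since query and target are the same molecule, an
  alignment whose back-mapped arms overlap is geometrically impossible as a
  hairpin. The DP domain is restricted to cells `i + j <= L`, which is exactly
  the condition that the two arms of the reported alignment are disjoint; a
  base may only pair with a strictly downstream base.
* **Determinism.** Ties are broken by fixed rules: traceback starts from the
  maximal cell with the smallest (row, column) lexicographically, and prefers
  diagonal over up over left moves. Two runs on the same input are
  byte-identical.
* **Strand asymmetry.** Wobbles are strand-specific: a G·U pair on one strand
  corresponds to an A·C non-pair on the reverse complement. Optimal scores on
  a sequence and on its reverse complement may therefore differ by the wobble
  contribution (they are identical under a wobble-free scheme, which the test
  suite checks). Detection is nevertheless complete on a single strand,
  because an IR's reverse complement is itself an IR at the same locus.

The gap penalty is linear per gap column; the scheme has no gap-open/extend
distinction.

## Multi-scale scanning

`scan_genome()` slides windows of 600, 300 and 150 bp (the size range of known
pre-miRNA precursors) across each contig, each window stepping by half its own
size, and keeps at most one IR per window — the optimal one. Truncated
windows at contig ends are scanned too, unless shorter than the minimum IR
length (50 bp by default). Half-window stepping guarantees double coverage
everywhere except within one skip of the contig edges. Because the detector
returns one IR per window, the same hairpin is typically reported by several
windows; that redundancy is deliberate and resolved later.

## The four metrics

For each record with `n` paired columns (Watson–Crick + wobble) among `k`
alignment columns (gaps included):

* **D — pairing density** (percent). By default `100 * n / k` over alignment
  columns; a span convention (`100 * 2n / span_length`, paired bases over
  hairpin bases) is also available — a 63-base hairpin with 26 pairs has a
  span density of 52/63 = 82.54%. The published arithmetic for the worked
  example is only consistent with the span convention, but the column
  convention is the cleaner scan-time analogue and is the default; both are a
  single switch away (`compute_metrics(convention = )`).
* **P — occurrence probability**. The binomial point probability
  `P(n, k) = 0.25^n * 0.75^(k-n) * choose(k, n)` that a random arm pair of
  length k shows exactly n complementary positions (alphabet of four, so a
  random position pairs with probability 1/4). Small P flags symmetry that is
  unlikely by chance. Computed and compared in log10 space via `lchoose`, so
  values far below 1e-62 are exact to working precision; thresholds are
  converted once. P is treated as a score, not a hypothesis test — no
  multiple-testing correction is applied, matching its original use.
* **A — mean contiguous stem length** (bp). The mean of maximal runs of
  consecutive paired columns (runs break at mismatch or gap columns). Runs of
  6, 8, 1 and 11 give A = 6.5. Undefined when no column pairs; such records
  are rejected.
* **G — stem GC content** (percent). Among paired columns inside runs longer
  than 3 bp (shorter runs are more likely loop than stem), the percentage
  whose pair is G–C or C–G. Wobble columns inside qualifying runs count in
  the denominator only. Undefined when no run exceeds 3 bp; such records are
  rejected rather than passed, which keeps `G_min = 0` meaningful.

## Filtering, thresholds, and duplicate removal

`apply_filters()` passes a record iff
`span >= L_min`, `D_min <= D <= D_max`, `P <= P_max`, `A >= A_min`,
`G >= G_min`. All bounds are inclusive: a stated maximum of 9.99e-9 is read
as "values through that bound pass". Two built-in profiles
(`filter_params("base")`, `filter_params("optimal")`) carry the published
threshold sets: base D_min 59%, D_max 95%, P_max 9.99e-9, A_min 2.2, G_min
18, L_min 50; optimal D_min 60%, P_max 9.99e-11, A_min 2.3, G_min 24. D_max
exists to discard perfectly self-complementary low-complexity DNA — real
hairpins always have a loop, so 100% density is a red flag.

`remove_duplicates()` runs *after* filtering: within each (contig, window
size) track, records from windows exactly one skip apart whose spans overlap
are duplicate candidates, and the shorter span is dropped (ties: lower score,
then later window). Records from different window sizes are never compared.
The rule is intentionally simple and has a known failure mode it inherits by
design: genuinely distinct nearby identical IRs seen by adjacent windows are
collapsed too. The test suite pins this limitation with a two-identical-
hairpins fixture instead of "fixing" it.

## Validation and tuning

`match_known()` counts Identified IRs (IIRs): a known precursor is identified
when some surviving record's sequence is a substring of it or contains it,
checked against both the precursor and its reverse complement (the scan
reports one strand; databases deposit the transcribed strand). The count is
over known entries, not records. `metric_profile()` runs the detector and all
four metrics directly on a known set and bins the results the way the
original distributions were reported (D rounded to integers, P by decade
exponent, A floored to one decimal, G floored to integers).

`tune_parameters()` automates the threshold search: given a cached unfiltered
scan (so iterations re-filter without re-aligning), it seeks the parameter
set minimizing surviving candidates subject to identifying at least a target
number of known entries (e.g. 90% of the known set). The default method
evaluates the full grid deterministically — the published tuning table is
itself such a grid, laid out by `cmd_tune()` as an IR/IIR matrix when two
parameters are free. A `"coordinate"` hill-climbing method is also provided;
it stops early when the IIR count hits the target exactly, mirroring the
original interactive loop, at the price of not guaranteeing the grid optimum.

## The synthetic-data generator

`make_genome()` builds a test world where every stage has known truth: i.i.d.
background of configurable GC content (default 36%, an AT-rich plant genome)
with planted hairpins — a random arm, a loop, and the arm's exact reverse
complement, degraded on the 3' arm only, mirroring the
duplication-then-divergence origin of IRs. Defaults (30 bp stems, 10 nt
loops, 20 plants in 100 kb, wobble fraction 0.07, substitution rate 0.10,
indel rate 0.03, stem GC 0.48) describe lightly degraded, detectable
hairpins; stems are GC-enriched relative to the background because pairing
stability selects for GC in real stems.

Choices made for exactness, and what they cost in realism:

* Degradation counts are deterministic (`round(rate * stem_length)` per
  operation) rather than binomial draws, substitutions always break their
  pair (the replacement neither Watson–Crick-pairs nor wobbles with its
  partner), and sites sit at least 3 bp inside the stem ends and 3 bp apart.
  Consequently the aligner never profits from trimming or shifting around a
  lesion, and the realized density of a planted locus is exact:
  `D = 100 * (stem - n_sub) / stem` with indels off. The generator is tested
  against this closed form.
* Loops are drawn from {A, C} only — no two loop bases can pair (Watson–Crick
  or wobble), so the detected IR is exactly the planted stem. Real loops are
  four-letter; this generator trades that realism for exact truth
  annotations.
* Plants are placed at least 200 bp apart and 500 bp from contig ends, so
  each hairpin is wholly contained in at least one 150 bp window and windows
  never contend for two plants.
* The background is i.i.d., not Markovian: no repeats, isochores or genes. A
  green recovery test therefore establishes that the pipeline finds lightly
  degraded hairpins over random background at realistic GC — not that it
  would enjoy the same signal-to-noise in a real, repeat-rich genome.

## Numerical and degenerate-input choices

* All randomness flows from a single integer seed (`plant_spec(seed = )`);
  reruns are byte-identical.
* P is carried in log10 space end to end; `probability_P()` itself may
  underflow below ~1e-308 and is provided for convenience only.
* `k = 0` density, all-gap alignments, empty genomes, empty known sets, and
  candidate-free runs all return well-defined empty results rather than
  errors; per-window alignment failures warn and continue.
* Windows shorter than the minimum IR length after truncation are dropped
  from enumeration (they cannot yield a passing record).

## Known limitations

* No thermodynamic (free-energy) folding: the detector emulates a secondary
  structure predictor only through its scoring scheme. Minimum-free-energy
  structures, bulge asymmetry and pseudoknots are out of scope.
* One IR per window: two strong hairpins inside the same window shadow each
  other; the multi-scale tracks mitigate but do not eliminate this.
* The duplicate remover's nearby-identical-IR collapse, described above.
* Genome-scale reproduction of the published candidate/IIR counts for a real
  plant genome against a curated precursor database requires external data
  the build intentionally does not fetch; the published counts are recorded
  in the project notes as a non-gating external check, and the metric-profile
  ranges on a real known set (D 57–89%, A 2.1–10.6 bp, G 18–62%, P exponents
  −7 to −62) serve as the softer cross-check for users who supply their own
  FASTA files.

## A minimal session

```{r example}
spec <- plant_spec(count = 5L, background_length = 20000L, seed = 7L)
sim <- make_genome(spec)
rec <- compute_metrics(scan_genome(sim$genome))
filt <- apply_filters(rec, filter_params("base"))
final <- remove_duplicates(filt$records)
c(scanned = nrow(rec), filtered = nrow(filt$records), deduplicated = nrow(final))
match_known(final, sim$plants)$iir_count
```
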