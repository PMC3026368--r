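test_that("default scoring scheme matches the published matrix", {
  sc <- default_scoring()
  m <- sc$substitution
  expect_equal(unname(diag(m)[1:4]), rep(5L, 4))
  expect_equal(m["N", "N"], 3L)
  expect_equal(unname(m["N", c("A", "C", "G", "U")]), rep(0L, 4))
  expect_equal(unname(m[c("A", "C", "G", "U"), "N"]), rep(0L, 4))
  expect_equal(m["G", "A"], -2L)
  expect_equal(m["U", "C"], -2L)
  expect_equal(m["A", "G"], -4L)  # asymmetric by design
  expect_equal(sc$gap_penalty, -6L)
})

test_that("perfect stem is recovered with all-match columns", {
  # non-self-complementary loop so the IR is exactly the planted stem
  aln <- self_ir_align(paste0(strrep("G", 10), "AAAA", strrep("C", 10)))
  expect_s3_class(aln, "ir_alignment")
  expect_equal(aln$score, 50L)
  expect_equal(aln$k, 10L)
  expect_equal(aln$n, 10L)
  expect_equal(aln$arm1, c(1L, 10L))
  expect_equal(aln$arm2, c(15L, 24L))
  expect_equal(aln$pairing, paste0(strrep("(", 10), "....", strrep(")", 10)))
})

test_that("sequences without complementarity yield no alignment", {
  expect_null(self_ir_align(strrep("A", 10)))
  expect_null(self_ir_align("ACAACA"))
  expect_error(self_ir_align("A"), "length >= 2")
})

test_that("optimal score matches the brute-force oracle on random sequences", {
  set.seed(11)
  for (i in 1:60) {
    s <- random_rna(sample(10:80, 1), gc = runif(1, 0.25, 0.75))
    aln <- self_ir_align(s)
    ora <- oracle_sw(s)
    got <- if (is.null(aln)) 0L else aln$score
    expect_identical(got, ora$score)
  }
})

test_that("spans match the oracle's naive traceback", {
  set.seed(23)
  for (i in 1:15) {
    s <- random_rna(60)
    aln <- self_ir_align(s)
    ora <- oracle_sw(s, traceback = TRUE)
    if (is.null(aln)) {
      expect_identical(ora$score, 0L)
    } else {
      expect_identical(aln$arm1, ora$arm1)
      expect_identical(aln$arm2, ora$arm2)
    }
  }
})

test_that("every emitted alignment re-scores to its reported score", {
  set.seed(31)
  for (i in 1:40) {
    aln <- self_ir_align(random_rna(sample(20:100, 1)))
    if (!is.null(aln)) expect_identical(rescore_alignment(aln), aln$score)
  }
})

test_that("reported alignments have positive score, balanced pairing, sane n/k", {
  set.seed(43)
  for (i in 1:40) {
    aln <- self_ir_align(random_rna(sample(20:100, 1)))
    if (is.null(aln)) next
    expect_gt(aln$score, 0)
    expect_true(aln$n >= 0 && aln$n <= aln$k)
    expect_equal(aln$k, nrow(aln$columns))
    ch <- strsplit(aln$pairing, "", fixed = TRUE)[[1]]
    expect_equal(sum(ch == "("), sum(ch == ")"))
    expect_equal(sum(ch == "("), aln$n)
    # balanced: running depth never negative
    depth <- cumsum((ch == "(") - (ch == ")"))
    expect_true(all(depth >= 0) && depth[length(depth)] == 0)
    # arms disjoint, within span
    expect_lt(aln$arm1[2], aln$arm2[1])
    expect_equal(aln$span, c(aln$arm1[1], aln$arm2[2]))
  }
})

test_that("strand symmetry holds exactly for wobble-free scoring", {
  # Wobbles are strand-specific (a G.U pair becomes an A.C non-pair on the
  # reverse complement), so exact score symmetry only holds when the wobble
  # entries equal the mismatch score; with the default asymmetric matrix the
  # two strands may differ by the wobble bonus.
  sym <- default_scoring(wobble = -4L)
  set.seed(59)
  for (i in 1:25) {
    s <- random_rna(sample(20:80, 1))
    a1 <- self_ir_align(s, sym)
    a2 <- self_ir_align(reverse_complement(s), sym)
    s1 <- if (is.null(a1)) 0L else a1$score
    s2 <- if (is.null(a2)) 0L else a2$score
    expect_identical(s1, s2)
  }
  # under the default scheme, Watson-Crick content alone is strand-stable:
  # scores never differ by more than 3x the wobble columns involved
  set.seed(61)
  for (i in 1:15) {
    s <- random_rna(60)
    a1 <- self_ir_align(s)
    a2 <- self_ir_align(reverse_complement(s))
    if (is.null(a1) || is.null(a2)) next
    wob <- max(sum(a1$columns$class == "WOBBLE"),
               sum(a2$columns$class == "WOBBLE"))
    expect_lte(abs(a1$score - a2$score), (2L + 4L) * wob + 1L)
  }
})

test_that("planted perfect stems are recovered in random background", {
  set.seed(67)
  for (i in 1:10) {
    s_len <- sample(10:20, 1)
    arm <- random_rna(s_len)
    hp <- hairpin_seq(arm)
    bg_left <- random_rna(sample(20:90, 1))
    bg_right <- random_rna(sample(20:90, 1))
    aln <- self_ir_align(paste0(bg_left, hp, bg_right))
    expect_false(is.null(aln))
    expect_gte(aln$n, s_len)  # at least the planted stem pairs
    expect_gte(aln$score, 5L * s_len - 2L)
  }
})

test_that("column classification follows the wobble-aware rules", {
  aln <- make_aln_from_runs(list(c("G", "C", "GA", "UC", "A", "U")))
  expect_equal(aln$columns$class,
               c("WC_MATCH", "WC_MATCH", "WOBBLE", "WOBBLE",
                 "WC_MATCH", "WC_MATCH"))
  expect_equal(aln$n, 6L)  # wobbles count as paired
  # N-N is identical letters but not a pair
  cols <- data.frame(q = c("G", "N", "G"), t = c("G", "N", "G"),
                     stringsAsFactors = FALSE)
  a2 <- classify_columns(
    dyadscan:::new_ir_alignment(cols, qs = 1L, ts = 1L, L = 11L, score = 13L))
  expect_equal(a2$columns$class, c("WC_MATCH", "MISMATCH", "WC_MATCH"))
  expect_equal(a2$n, 2L)
  # (A, C) scores -4: mismatch
  cols3 <- data.frame(q = "A", t = "C", stringsAsFactors = FALSE)
  a3 <- classify_columns(
    dyadscan:::new_ir_alignment(cols3, qs = 1L, ts = 1L, L = 7L, score = 1L))
  expect_equal(a3$columns$class, "MISMATCH")
})

test_that("pairing_string mirrors mismatch dots across the loop", {
  aln <- make_aln_from_runs(list(c("G", "C"), c("G", "C")), loop = 3L)
  # 2 pairs, mismatch, 2 pairs on each arm; 3 nt loop
  expect_equal(pairing_string(aln), "((.((...)).))")
  expect_error(pairing_string(NULL), "empty")
})

test_that("determinism: identical inputs give identical alignments", {
  set.seed(71)
  s <- random_rna(150)
  expect_identical(self_ir_align(s), self_ir_align(s))
})
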