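test_that("match_known implements two-way containment on both orientations", {
  rec <- function(s) data.frame(sequence = s, stringsAsFactors = FALSE)
  known <- c(mir1 = "GGGCCCAAAUUUGGGCCC")
  # identical
  expect_equal(match_known(rec("GGGCCCAAAUUUGGGCCC"), known)$iir_count, 1L)
  # record is an interior slice of the known entry
  expect_equal(match_known(rec("CCCAAAUUUGGG"), known)$iir_count, 1L)
  # record contains the known entry
  expect_equal(match_known(rec(paste0("AU", known[[1]], "UA")), known)$iir_count, 1L)
  # reverse-complement orientation
  expect_equal(match_known(rec(oracle_revcomp("CCCAAAUUUGGG")), known)$iir_count, 1L)
  # partial overlap (neither substring) does not count
  expect_equal(match_known(rec("AAAUUUGGGCCCUUUAAA"), known)$iir_count, 0L)
  # empty records
  expect_equal(match_known(rec(character(0)), known)$iir_count, 0L)
  expect_equal(match_known(rec("ACGU"), setNames(character(0), character(0)))$iir_count, 0L)
})

test_that("IIR counting counts known entries, not records, order-invariantly", {
  known <- c(a = "GGGGCCCCAAAAGGGGCCCC", b = "UUUUGGGGAAAACCCCAAAA")
  recs <- data.frame(sequence = c("GGGGCCCC", "CCCCAAAA", "GGGGCCCC"),
                     stringsAsFactors = FALSE)
  m <- match_known(recs, known)
  expect_equal(m$iir_count, 2L)
  expect_equal(unname(m$hits), c(TRUE, TRUE))
  shuffled <- match_known(recs[c(3, 1, 2), , drop = FALSE], known)
  expect_equal(shuffled$iir_count, m$iir_count)
  dup <- match_known(rbind(recs, recs), known)
  expect_equal(dup$iir_count, m$iir_count)
})

test_that("metric_profile profiles known sequences and flags failures", {
  set.seed(17)
  arm <- random_rna(20)
  known <- c(perfect = hairpin_seq(arm, loop = "AACAA"),
             hopeless = strrep("A", 60))
  prof <- metric_profile(known)
  expect_equal(nrow(prof), 2L)
  expect_true(prof$profiled[1])
  expect_false(prof$profiled[2])
  expect_equal(prof$D[1], 100)  # perfect hairpin, column convention
  expect_equal(prof$A[1], 20)
  expect_equal(prof$P_exponent[1], as.integer(floor(prof$log10P[1])))
  # empty set
  expect_equal(nrow(metric_profile(setNames(character(0), character(0)))), 0L)
})

test_that("metric_distributions bins as published", {
  prof <- data.frame(D = c(82.54, 82.4), log10P = c(-10.2, -10.9),
                     P_exponent = c(-11L, -11L), A = c(6.55, 2.19),
                     G = c(39.9, 40.0))
  d <- metric_distributions(prof)
  expect_equal(as.integer(d$D[c("82", "83")]), c(1L, 1L))  # rounded
  expect_equal(as.integer(d$P_exponent["-11"]), 2L)        # by exponent
  expect_equal(as.integer(d$A[c("2.1", "6.5")]), c(1L, 1L))  # floored 1 dp
  expect_equal(as.integer(d$G[c("39", "40")]), c(1L, 1L))    # floored int
})

test_that("tuner degenerate cases behave as specified", {
  fx <- small_fixture_records(seed = 909L, count = 6L,
                              background_length = 12000L)
  known <- fx$sim$plants
  # free_params empty: start evaluated once
  r0 <- tune_parameters(fx$records, known, filter_params("base"),
                        target_iir = 1L, free = character(0))
  expect_equal(nrow(r0$trace), 1L)
  expect_equal(r0$params, filter_params("base"))
  # target above known count errors
  expect_error(tune_parameters(fx$records, known, filter_params("base"),
                               target_iir = 100L), "exceeds")
  # coordinate search from a local optimum returns the start point
  g <- list(A_min = c(2.2, 2.3), G_min = c(18, 19))
  rc <- tune_parameters(fx$records, known, filter_params("base"),
                        target_iir = 1L, grid = g, method = "coordinate")
  expect_s3_class(rc, "tuning_result")
  expect_true(rc$iir_count >= 1L || !rc$feasible)
})

test_that("exhaustive tuning equals an independent brute-force grid sweep", {
  fx <- small_fixture_records(seed = 1010L, count = 10L,
                              background_length = 25000L)
  known <- fx$sim$plants
  grid <- list(A_min = c(2.2, 3.0, 3.8), G_min = c(18, 30, 42))
  target <- 8L
  res <- tune_parameters(fx$records, known, filter_params("base"),
                         target_iir = target, grid = grid)
  # oracle: plain nested loops over the public pipeline
  best_ir <- Inf; best <- NULL
  for (g in grid$G_min) for (a in grid$A_min) {
    p <- filter_params("base", A_min = a, G_min = g)
    surv <- remove_duplicates(apply_filters(fx$records, p)$records)
    iir <- match_known(surv, known)$iir_count
    if (iir >= target && nrow(surv) < best_ir) {
      best_ir <- nrow(surv); best <- c(A_min = a, G_min = g)
    }
  }
  expect_true(res$feasible)
  expect_equal(res$ir_count, best_ir)
  expect_equal(res$params$A_min, unname(best["A_min"]))
  expect_equal(res$params$G_min, unname(best["G_min"]))
  expect_equal(nrow(res$trace), 9L)
  # the two-free-parameter trace doubles as a Table-style matrix
  expect_equal(dim(res$ir_matrix), c(3L, 3L))
  expect_equal(res$ir_matrix["18", "2.2"],
               res$trace$ir_count[res$trace$A_min == 2.2 &
                                  res$trace$G_min == 18])
})

test_that("re-filtering cached metrics equals filtering a fresh scan", {
  fx <- small_fixture_records(seed = 1111L, count = 4L,
                              background_length = 8000L)
  fresh <- compute_metrics(scan_genome(fx$sim$genome))
  p <- filter_params("base")
  a <- apply_filters(fx$records, p)$records
  b <- apply_filters(fresh, p)$records
  expect_equal(a[names(a) != "alignment"], b[names(b) != "alignment"])
})
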