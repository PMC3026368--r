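# Independent brute-force oracles. These deliberately reimplement the logic
# they check (no calls into the package's alignment/probability code paths).

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGUN", "UGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

oracle_matrix <- function() {
  b <- c("A", "C", "G", "U", "N")
  m <- matrix(-4L, 5, 5, dimnames = list(b, b))
  diag(m) <- 5L
  m["N", ] <- 0L; m[, "N"] <- 0L; m["N", "N"] <- 3L
  m["G", "A"] <- -2L; m["U", "C"] <- -2L
  m
}

# Naive full-matrix Smith-Waterman of seq vs revcomp(seq), all cells retained,
# restricted to the non-self-overlap half-domain (a base pairs only strictly
# downstream bases: i + j <= L). Same deterministic tie rules as specified:
# first max cell in (row, column) order; diagonal > up > left.
oracle_sw <- function(seq, sub = oracle_matrix(), gap = -6L,
                      traceback = FALSE) {
  q <- strsplit(seq, "", fixed = TRUE)[[1L]]
  t <- strsplit(oracle_revcomp(seq), "", fixed = TRUE)[[1L]]
  L <- length(q)
  H <- matrix(0L, L + 1L, L + 1L)
  P <- matrix(0L, L + 1L, L + 1L)
  best <- 0L; bi <- 0L; bj <- 0L
  for (i in seq_len(L)) {
    for (j in seq_len(L - i)) {
      d <- H[i, j] + sub[q[i], t[j]]
      u <- H[i, j + 1L] + gap
      l <- H[i + 1L, j] + gap
      v <- d; p <- 1L
      if (u > v) { v <- u; p <- 2L }
      if (l > v) { v <- l; p <- 3L }
      if (v <= 0L) { v <- 0L; p <- 0L }
      H[i + 1L, j + 1L] <- v
      P[i + 1L, j + 1L] <- p
      if (v > best) { best <- v; bi <- i; bj <- j }
    }
  }
  if (!traceback || best <= 0L) return(list(score = best))
  i <- bi; j <- bj
  qe <- bi; te <- bj
  qs <- bi; ts <- bj
  while (i > 0L && j > 0L && H[i + 1L, j + 1L] > 0L && P[i + 1L, j + 1L] > 0L) {
    p <- P[i + 1L, j + 1L]
    if (p == 1L) { qs <- i; ts <- j; i <- i - 1L; j <- j - 1L }
    else if (p == 2L) { qs <- i; i <- i - 1L }
    else { ts <- j; j <- j - 1L }
  }
  list(score = best, arm1 = c(qs, qe), arm2 = c(L + 1L - te, L + 1L - ts))
}

random_rna <- function(len, gc = 0.5) {
  paste(sample(c("G", "C", "A", "U"), len, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

# ---- exact big-integer arithmetic (base 1e4 limbs, little-endian) ----------

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  s <- a + b
  carry <- 0
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- s[i] %/% 1e4
    s[i] <- s[i] %% 1e4
  }
  while (carry > 0) {
    s <- c(s, carry %% 1e4)
    carry <- carry %/% 1e4
  }
  s
}

big_mul_small <- function(a, m) {
  s <- a * m
  carry <- 0
  for (i in seq_along(s)) {
    s[i] <- s[i] + carry
    carry <- s[i] %/% 1e4
    s[i] <- s[i] %% 1e4
  }
  while (carry > 0) {
    s <- c(s, carry %% 1e4)
    carry <- carry %/% 1e4
  }
  s
}

# log10 of a bigint from its ~20 leading decimal digits (double-precision
# accurate: 20 digits > the 17 significant digits a double can hold).
big_log10 <- function(a) {
  nd <- length(a)
  top <- min(nd, 5L)
  approx <- 0
  for (i in seq_len(top)) approx <- approx * 1e4 + a[nd - i + 1L]
  log10(approx) + 4 * (nd - top)
}

# exact C(k, n) by Pascal's triangle (addition only)
big_choose <- function(k, n) {
  row <- list(c(1))
  for (r in seq_len(k)) {
    new <- vector("list", r + 1L)
    new[[1L]] <- c(1)
    new[[r + 1L]] <- c(1)
    if (r > 1L) {
      for (c in 2:r) new[[c]] <- big_add(row[[c - 1L]], row[[c]])
    }
    row <- new
  }
  row[[n + 1L]]
}

# exact log10 P(n, k): log10( C(k,n) * 3^(k-n) ) - k * log10(4)
oracle_log10_P <- function(n, k) {
  b <- big_choose(k, n)
  for (i in seq_len(k - n)) b <- big_mul_small(b, 3)
  big_log10(b) - k * log10(4)
}

# exhaustive enumeration of all 4^(2k) arm pairs: distribution of the number
# of complementary positions
enum_match_dist <- function(k) {
  N <- 4^(2 * k)
  idx <- 0:(N - 1)
  comp <- c(4L, 3L, 2L, 1L)  # A<->U, C<->G on codes 1..4
  m <- integer(N)
  for (pos in seq_len(k)) {
    a <- (idx %/% 4^(pos - 1)) %% 4 + 1
    b <- (idx %/% 4^(k + pos - 1)) %% 4 + 1
    m <- m + (b == comp[a])
  }
  tabulate(m + 1L, nbins = k + 1L) / N  # index n+1 = P(n matches)
}
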