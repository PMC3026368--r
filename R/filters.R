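# Threshold filtering of IR records on the four metrics plus span length.

#' Filter thresholds for hairpin enrichment
#'
#' Two named profiles are built in. `"base"`: D_min 59%, D_max 95%,
#' P_max 9.99e-9, A_min 2.2 bp, G_min 18%, L_min 50 bp — selected to retain
#' nearly all of a 190-entry known precursor set. `"optimal"`: D_min 60%,
#' P_max 9.99e-11, A_min 2.3, G_min 24 — the tightest set that still retains
#' 90% (171) of that known set while minimizing candidates.
#'
#' All "min" bounds and D_max are inclusive; P passes when P <= P_max.
#'
#' @param profile `"base"` or `"optimal"`.
#' @param D_min,D_max Density bounds (percent).
#' @param P_max Probability upper bound.
#' @param A_min Minimum mean stem length (bp).
#' @param G_min Minimum stem GC content (percent).
#' @param L_min Minimum IR span length (bp).
#' @return A `filter_params` object.
#' @export
filter_params <- function(profile = c("base", "optimal"),
                          D_min = NULL, D_max = NULL, P_max = NULL,
                          A_min = NULL, G_min = NULL, L_min = NULL) {
  profile <- match.arg(profile)
  p <- switch(profile,
    base = list(D_min = 59, D_max = 95, P_max = 9.99e-9,
                A_min = 2.2, G_min = 18, L_min = 50L),
    optimal = list(D_min = 60, D_max = 95, P_max = 9.99e-11,
                   A_min = 2.3, G_min = 24, L_min = 50L))
  for (nm in c("D_min", "D_max", "P_max", "A_min", "G_min", "L_min")) {
    v <- get(nm)
    if (!is.null(v)) p[[nm]] <- v
  }
  if (!(p$D_min >= 0 && p$D_min < p$D_max && p$D_max <= 100)) {
    stop("need 0 <= D_min < D_max <= 100")
  }
  if (!(p$P_max > 0 && p$P_max <= 1)) stop("need 0 < P_max <= 1")
  if (p$A_min < 0) stop("need A_min >= 0")
  if (p$G_min < 0 || p$G_min > 100) stop("need 0 <= G_min <= 100")
  if (p$L_min < 1) stop("need L_min >= 1")
  structure(p, class = "filter_params")
}

#' @export
print.filter_params <- function(x, ...) {
  cat(sprintf(paste0("filter_params: D in [%g, %g]%%, P <= %g, ",
                     "A >= %g bp, G >= %g%%, span >= %d bp\n"),
              x$D_min, x$D_max, x$P_max, x$A_min, x$G_min, as.integer(x$L_min)))
  invisible(x)
}

#' Apply the enrichment filters to IR records
#'
#' A record passes iff span >= L_min AND D_min <= D <= D_max AND P <= P_max
#' AND A >= A_min AND G >= G_min. Records with undefined A (no paired column)
#' or undefined G (no stem run > 3 bp) fail the corresponding filter. The
#' tally counts one rejection per failed filter, so a record may appear in
#' several tallies.
#'
#' @param records Record table with metrics (see [compute_metrics()]).
#' @param params A [filter_params()] object.
#' @return List with `records` (passing rows, with per-filter `pass_*` flag
#'   columns) and `tally` (named integer rejection counts).
#' @export
apply_filters <- function(records, params = filter_params("base")) {
  stopifnot(is.data.frame(records), inherits(params, "filter_params"))
  need <- c("D", "log10P", "A", "G", "span_length")
  if (!all(need %in% names(records))) {
    stop("records lack metric columns; run compute_metrics() first")
  }
  if (nrow(records) == 0L) {
    tally <- setNames(integer(5), c("L", "D", "P", "A", "G"))
    return(list(records = records, tally = tally))
  }
  log10_pmax <- log10(params$P_max)
  pass_L <- records$span_length >= params$L_min
  pass_D <- records$D >= params$D_min & records$D <= params$D_max
  pass_P <- records$log10P <= log10_pmax
  pass_A <- !is.na(records$A) & records$A >= params$A_min
  pass_G <- !is.na(records$G) & records$G >= params$G_min
  tally <- c(L = sum(!pass_L), D = sum(!pass_D), P = sum(!pass_P),
             A = sum(!pass_A), G = sum(!pass_G))
  records$pass_L <- pass_L
  records$pass_D <- pass_D
  records$pass_P <- pass_P
  records$pass_A <- pass_A
  records$pass_G <- pass_G
  keep <- pass_L & pass_D & pass_P & pass_A & pass_G
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, tally = tally)
}
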