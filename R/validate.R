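# Validation against a known precursor set and the parameter-tuning loop.

#' Count identified IRs (IIRs) against a known precursor set
#'
#' A known entry is "identified" when at least one record's sequence is a
#' substring of the entry's sequence or contains it. Containment is checked
#' against both the entry and its reverse complement, since the scan reports
#' one strand while a known set may deposit the transcribed strand. The count
#' is over known entries identified, not over matching records, and is
#' invariant to record order and duplication.
#'
#' @param records Record table carrying a `sequence` column.
#' @param known Named character vector of known RNA sequences (unique names).
#' @return List with `iir_count` and `hits`, a named logical per known entry.
#' @export
match_known <- function(records, known) {
  stopifnot(is.data.frame(records), is.character(known))
  if (length(known) > 0L &&
      (is.null(names(known)) || anyDuplicated(names(known)))) {
    stop("known set must have unique names")
  }
  if (length(known) == 0L) return(list(iir_count = 0L, hits = logical(0)))
  recs <- unique(records$sequence)
  hits <- vapply(seq_along(known), function(i) {
    ent <- known[[i]]
    rc <- reverse_complement(ent)
    for (s in recs) {
      if (grepl(s, ent, fixed = TRUE) || grepl(ent, s, fixed = TRUE) ||
          grepl(s, rc, fixed = TRUE) || grepl(rc, s, fixed = TRUE)) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  names(hits) <- names(known)
  list(iir_count = sum(hits), hits = hits)
}

#' Metric profile of a known precursor set
#'
#' Runs the IR detector and all four metrics directly on each known sequence.
#' Entries yielding no alignment are reported with `profiled = FALSE` rather
#' than dropped.
#'
#' @param known Named character vector of known RNA sequences.
#' @param scoring A [default_scoring()] scheme.
#' @param convention Density convention, see [ir_density()].
#' @return data.frame with id, n, k, D, log10P, P_exponent, A, G, profiled.
#' @export
metric_profile <- function(known, scoring = default_scoring(),
                           convention = c("column", "span")) {
  convention <- match.arg(convention)
  rows <- lapply(seq_along(known), function(i) {
    aln <- self_ir_align(known[[i]], scoring)
    if (is.null(aln)) {
      return(data.frame(id = names(known)[i], n = NA_integer_, k = NA_integer_,
                        D = NA_real_, log10P = NA_real_,
                        P_exponent = NA_integer_, A = NA_real_, G = NA_real_,
                        profiled = FALSE, stringsAsFactors = FALSE))
    }
    lp <- log10_probability_P(aln$n, aln$k)
    data.frame(id = names(known)[i], n = aln$n, k = aln$k,
               D = ir_density(aln, convention), log10P = lp,
               P_exponent = as.integer(floor(lp)),
               A = avg_stem_A(aln), G = stem_gc_G(aln),
               profiled = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(id = character(0), n = integer(0), k = integer(0),
                      D = numeric(0), log10P = numeric(0),
                      P_exponent = integer(0), A = numeric(0), G = numeric(0),
                      profiled = logical(0), stringsAsFactors = FALSE)
  }
  out
}

#' Binned frequency distributions of the four metrics
#'
#' Bins follow the reporting convention of the metric histograms: D rounded
#' to the nearest integer, P bucketed by its power-of-ten exponent, A floored
#' to one decimal place, G floored to the integer below.
#'
#' @param profile Output of [metric_profile()] (or a record table with
#'   metric columns).
#' @return List of four tables: `D`, `P_exponent`, `A`, `G`.
#' @export
metric_distributions <- function(profile) {
  stopifnot(is.data.frame(profile))
  pexp <- if ("P_exponent" %in% names(profile)) profile$P_exponent
          else as.integer(floor(profile$log10P))
  list(D = table(round(profile$D)),
       P_exponent = table(pexp),
       A = table(floor(profile$A * 10) / 10),
       G = table(floor(profile$G)))
}

#' @noRd
tune_grid_default <- function(start, free) {
  g <- list()
  for (nm in free) {
    g[[nm]] <- switch(nm,
      A_min = round(start$A_min + 0.1 * (0:8), 10),
      G_min = start$G_min + 1 * (0:8),
      D_min = start$D_min + 1 * (0:8),
      D_max = start$D_max - 1 * (0:8),
      P_max = start$P_max * 10^-(0:8),
      L_min = start$L_min + 10L * (0:8),
      stop("no default grid for parameter '", nm, "'"))
  }
  g
}

#' @noRd
tune_eval <- function(records, known, params, dedup = TRUE) {
  filt <- apply_filters(records, params)$records
  if (dedup) filt <- remove_duplicates(filt)
  list(ir_count = nrow(filt), iir_count = match_known(filt, known)$iir_count)
}

#' Automated parameter tuning against a known set
#'
#' Searches filter-threshold space for the parameter set that minimizes the
#' number of surviving IR candidates while still identifying at least
#' `target_iir` known entries. Works from a cached unfiltered scan (metrics
#' computed), so iterations re-filter without re-aligning.
#'
#' `method = "exhaustive"` (default) deterministically evaluates every grid
#' point. `method = "coordinate"` hill-climbs from `start` one grid step at a
#' time (feasible points beat infeasible; among feasible, fewer IRs win;
#' among infeasible, more IIRs win) and stops early when `iir_count` hits the
#' target exactly, when no neighbour improves, or at `max_iter`.
#'
#' @param records Unfiltered record table with metrics.
#' @param known Named character vector of known sequences.
#' @param start A [filter_params()] starting point.
#' @param target_iir Required number of identified known entries.
#' @param free Character vector of free parameter names (subset of
#'   D_min, D_max, P_max, A_min, G_min, L_min).
#' @param grid Named list of candidate values per free parameter; defaults to
#'   tightening steps from `start` (A_min by 0.1, G_min/D_min by 1, P_max by
#'   decade).
#' @param method `"exhaustive"` or `"coordinate"`.
#' @param dedup Apply [remove_duplicates()] before counting (default TRUE).
#' @param max_iter Iteration cap for the coordinate method.
#' @return A `tuning_result`: `params` (best feasible), `ir_count`,
#'   `iir_count`, `trace` (one row per evaluation), `feasible`, and — when
#'   exactly two parameters are free — `ir_matrix` / `iir_matrix` with rows
#'   indexed by the second free parameter and columns by the first.
#' @export
tune_parameters <- function(records, known, start = filter_params("base"),
                            target_iir, free = c("A_min", "G_min"),
                            grid = NULL, method = c("exhaustive", "coordinate"),
                            dedup = TRUE, max_iter = 200L) {
  method <- match.arg(method)
  stopifnot(inherits(start, "filter_params"))
  if (target_iir > length(known)) {
    stop("target_iir (", target_iir, ") exceeds known-set size (", length(known), ")")
  }
  if (is.null(grid)) grid <- tune_grid_default(start, free)
  if (!setequal(names(grid), free)) stop("grid names must match 'free'")
  make_params <- function(vals) {
    p <- start
    for (nm in names(vals)) p[[nm]] <- vals[[nm]]
    class(p) <- "filter_params"
    p
  }
  trace <- list()
  record_eval <- function(vals) {
    p <- make_params(vals)
    ev <- tune_eval(records, known, p, dedup = dedup)
    row <- as.data.frame(vals, stringsAsFactors = FALSE)
    row$ir_count <- ev$ir_count
    row$iir_count <- ev$iir_count
    trace[[length(trace) + 1L]] <<- row
    ev
  }

  if (length(free) == 0L) {
    ev <- tune_eval(records, known, start, dedup = dedup)
    trace_df <- data.frame(ir_count = ev$ir_count, iir_count = ev$iir_count)
    return(structure(list(params = start, ir_count = ev$ir_count,
                          iir_count = ev$iir_count,
                          feasible = ev$iir_count >= target_iir,
                          trace = trace_df, target_iir = target_iir),
                     class = "tuning_result"))
  }

  if (method == "exhaustive") {
    combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    for (r in seq_len(nrow(combos))) record_eval(as.list(combos[r, , drop = FALSE]))
  } else {
    idx <- setNames(rep(1L, length(free)), free)
    vals_at <- function(idx) setNames(
      lapply(free, function(nm) grid[[nm]][idx[[nm]]]), free)
    cache <- new.env(parent = emptyenv())
    eval_idx <- function(idx) {
      key <- paste(idx, collapse = ",")
      if (!is.null(cache[[key]])) return(cache[[key]])
      ev <- record_eval(vals_at(idx))
      cache[[key]] <- ev
      ev
    }
    better <- function(a, b) {  # is a strictly better than b?
      fa <- a$iir_count >= target_iir
      fb <- b$iir_count >= target_iir
      if (fa != fb) return(fa)
      if (fa) a$ir_count < b$ir_count else a$iir_count > b$iir_count
    }
    cur <- eval_idx(idx)
    for (iter in seq_len(max_iter)) {
      if (cur$iir_count == target_iir) break
      best_n <- NULL; best_ev <- NULL
      for (nm in free) for (d in c(-1L, 1L)) {
        cand <- idx
        cand[[nm]] <- cand[[nm]] + d
        if (cand[[nm]] < 1L || cand[[nm]] > length(grid[[nm]])) next
        ev <- eval_idx(cand)
        if (better(ev, cur) && (is.null(best_ev) || better(ev, best_ev))) {
          best_n <- cand; best_ev <- ev
        }
      }
      if (is.null(best_n)) break
      idx <- best_n; cur <- best_ev
    }
  }

  trace_df <- do.call(rbind, trace)
  rownames(trace_df) <- NULL
  feas <- trace_df$iir_count >= target_iir
  if (any(feas)) {
    cand <- which(feas)
    best_row <- cand[which.min(trace_df$ir_count[cand])]
    feasible <- TRUE
  } else {
    best_row <- which.max(trace_df$iir_count)
    feasible <- FALSE
  }
  best_vals <- as.list(trace_df[best_row, free, drop = FALSE])
  out <- list(params = make_params(best_vals),
              ir_count = trace_df$ir_count[best_row],
              iir_count = trace_df$iir_count[best_row],
              feasible = feasible, trace = trace_df, target_iir = target_iir)
  if (length(free) == 2L && method == "exhaustive") {
    v1 <- grid[[free[1]]]; v2 <- grid[[free[2]]]
    ir_m <- matrix(trace_df$ir_count, nrow = length(v2), ncol = length(v1),
                   byrow = TRUE, dimnames = list(v2, v1))
    iir_m <- matrix(trace_df$iir_count, nrow = length(v2), ncol = length(v1),
                    byrow = TRUE, dimnames = list(v2, v1))
    out$ir_matrix <- ir_m
    out$iir_matrix <- iir_m
  }
  structure(out, class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("tuning_result: %s optimum, %d IRs / %d IIRs (target %d), %d evaluations\n",
              if (x$feasible) "feasible" else "INFEASIBLE",
              x$ir_count, x$iir_count, x$target_iir, nrow(x$trace)))
  print(x$params)
  invisible(x)
}
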