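# Plain-text serialization: candidate TSV (0-based half-open coordinates,
# every filter input auditable), BED6 companion, flat key-value config, and
# the run summary.

TSV_COLUMNS <- c("contig", "start0", "end0", "strand", "window_size",
                 "window_start0", "score", "k", "n", "D", "log10P", "A", "G",
                 "span_length", "arm1_start0", "arm1_end0", "arm2_start0",
                 "arm2_end0", "pairing", "sequence")

#' Write IR candidate records to TSV
#'
#' One row per IR with 0-based half-open coordinates (`*0` columns). Columns:
#' contig, start0, end0, strand (always '+'), window_size, window_start0,
#' score, k, n, D, log10P, A, G, span_length, arm coordinates, pairing,
#' sequence.
#'
#' @param records Record table with metrics.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(records, path) {
  stopifnot(is.data.frame(records))
  need <- c("D", "log10P", "A", "G")
  for (nm in need) if (!nm %in% names(records)) records[[nm]] <- NA_real_
  out <- data.frame(
    contig = records$contig,
    start0 = records$start - 1L, end0 = records$end,
    strand = rep("+", nrow(records)),
    window_size = records$window_size,
    window_start0 = records$window_start - 1L,
    score = records$score, k = records$k, n = records$n,
    D = records$D, log10P = records$log10P, A = records$A, G = records$G,
    span_length = records$span_length,
    arm1_start0 = records$arm1_start - 1L, arm1_end0 = records$arm1_end,
    arm2_start0 = records$arm2_start - 1L, arm2_end0 = records$arm2_end,
    pairing = records$pairing, sequence = records$sequence,
    stringsAsFactors = FALSE)
  if (nrow(records) == 0L) out <- out[0L, TSV_COLUMNS]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an IR candidate TSV back into a record table
#'
#' Inverse of [write_candidates_tsv()] (coordinates return to the internal
#' 1-based inclusive convention; the alignment list-column is not
#' reconstructed).
#'
#' @param path Path to a candidate TSV.
#' @return Record data.frame.
#' @export
read_candidates_tsv <- function(path) {
  if (!file.exists(path)) stop("candidate file not found: ", path)
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  classes <- c(contig = "character", pairing = "character",
               sequence = "character")
  x <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = classes[names(classes) %in% hdr])
  missing <- setdiff(TSV_COLUMNS, names(x))
  if (length(missing)) {
    stop("candidate TSV lacks column(s): ", paste(missing, collapse = ", "))
  }
  data.frame(contig = x$contig, start = x$start0 + 1L, end = x$end0,
             arm1_start = x$arm1_start0 + 1L, arm1_end = x$arm1_end0,
             arm2_start = x$arm2_start0 + 1L, arm2_end = x$arm2_end0,
             window_size = x$window_size, window_start = x$window_start0 + 1L,
             score = x$score, k = x$k, n = x$n, span_length = x$span_length,
             pairing = x$pairing, sequence = x$sequence,
             D = x$D, log10P = x$log10P, A = x$A, G = x$G,
             stringsAsFactors = FALSE)
}

#' Write records (or truth loci) as BED6
#'
#' 0-based half-open, name, integer score (alignment score, capped at 1000
#' for BED compliance), strand '+'.
#'
#' @param records Record table, or a `truth` table from [make_genome()].
#' @param path Output path.
#' @param names Feature names; defaults to ir_<i> or the truth names.
#' @return `path`, invisibly.
#' @export
write_bed <- function(records, path, names = NULL) {
  stopifnot(is.data.frame(records))
  if (is.null(names)) {
    names <- if ("name" %in% names(records)) records$name
             else sprintf("ir_%d", seq_len(nrow(records)))
  }
  bed <- data.frame(chrom = records$contig, start = records$start - 1L,
                    end = records$end, name = names,
                    score = pmin(as.integer(records$score), 1000L),
                    strand = rep("+", nrow(records)), stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a flat key-value threshold config
#'
#' Keys mirror the CLI flags: d-min, d-max, p-max, a-min, g-min, min-len.
#'
#' @param params A [filter_params()] object.
#' @param path Config path.
#' @return `write_config()`: `path` invisibly; `read_config()`: a
#'   [filter_params()] object.
#' @export
write_config <- function(params, path) {
  stopifnot(inherits(params, "filter_params"))
  writeLines(c(paste0("d-min = ", format(params$D_min, digits = 15)),
               paste0("d-max = ", format(params$D_max, digits = 15)),
               paste0("p-max = ", format(params$P_max, digits = 15)),
               paste0("a-min = ", format(params$A_min, digits = 15)),
               paste0("g-min = ", format(params$G_min, digits = 15)),
               paste0("min-len = ", format(params$L_min, digits = 15))), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- as.numeric(vapply(kv, `[`, character(1), 2L))
  get <- function(key) if (key %in% keys) vals[match(key, keys)] else NULL
  filter_params("base", D_min = get("d-min"), D_max = get("d-max"),
                P_max = get("p-max"), A_min = get("a-min"),
                G_min = get("g-min"), L_min = get("min-len"))
}

#' Write a plain-text run summary
#'
#' Records everything needed to reproduce the run: stage counts, per-filter
#' rejection tallies, thresholds, window sizes, and input digests.
#'
#' @param path Output path.
#' @param counts Named numeric vector of stage counts.
#' @param tally Named rejection tally from [apply_filters()].
#' @param params The [filter_params()] used.
#' @param scheme The [window_scheme()] used.
#' @param inputs Character vector of input file paths (md5-digested).
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(path, counts, tally, params, scheme,
                              inputs = character(0)) {
  lines <- c("# dyadscan run summary",
             paste0("windows = ", paste(scheme$sizes, collapse = ",")),
             paste0("min-len = ", scheme$min_len),
             vapply(names(counts), function(nm)
               paste0("count.", nm, " = ", counts[[nm]]), character(1)),
             vapply(names(tally), function(nm)
               paste0("rejected.", nm, " = ", tally[[nm]]), character(1)),
             paste0("d-min = ", params$D_min), paste0("d-max = ", params$D_max),
             paste0("p-max = ", format(params$P_max, digits = 15)),
             paste0("a-min = ", params$A_min), paste0("g-min = ", params$G_min))
  for (f in inputs) {
    lines <- c(lines, paste0("input.", basename(f), ".md5 = ",
                             unname(tools::md5sum(f))))
  }
  writeLines(lines, path)
  invisible(path)
}
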