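#' @noRd
RNA_BASES <- c("A", "C", "G", "U", "N")

# IUPAC ambiguity letters other than N; all collapse to N on ingest because
# the scoring scheme only defines behaviour for N.
IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Convert raw DNA/RNA text to the internal RNA alphabet
#'
#' Upper-cases the input, maps T to U, and collapses every IUPAC ambiguity
#' code other than N to N. The result contains only A, C, G, U, N.
#'
#' @param text Character vector of raw sequence text (DNA or RNA, any case).
#' @return Character vector of the same length over the alphabet ACGUN.
#' @examples
#' dna_to_rna("acgt")  # "ACGU"
#' dna_to_rna("ACRYT") # "ACNNU"
#' @export
dna_to_rna <- function(text) {
  if (length(text) == 0L) return(character(0))
  if (!is.character(text) || anyNA(text)) stop("sequence text must be character, non-NA")
  out <- toupper(text)
  out <- chartr("T", "U", out)
  out <- chartr(paste(IUPAC_AMBIG, collapse = ""),
                strrep("N", length(IUPAC_AMBIG)), out)
  bad <- grepl("[^ACGUN]", out)
  if (any(bad)) {
    ch <- regmatches(out[bad][1L], regexpr("[^ACGUN]", out[bad][1L]))
    stop("invalid residue '", ch, "' in input sequence")
  }
  out
}

#' Reverse complement of an RNA sequence
#'
#' Complements A<->U, C<->G, N<->N and reverses the order.
#'
#' @param seq Character vector of sequences over ACGUN (see [dna_to_rna()]).
#' @return Character vector of reverse-complemented sequences.
#' @examples
#' reverse_complement("GGAUN") # "NAUCC"
#' @export
reverse_complement <- function(seq) {
  check_rna(seq)
  comp <- chartr("ACGUN", "UGCAN", seq)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' @noRd
check_rna <- function(seq) {
  if (!is.character(seq) || anyNA(seq)) stop("sequence must be character, non-NA")
  if (any(nchar(seq) < 1L)) stop("sequence must have length >= 1")
  if (any(grepl("[^ACGUN]", seq))) {
    stop("sequence contains residues outside ACGUN; run dna_to_rna() first")
  }
  invisible(seq)
}

# integer codes A=1 C=2 G=3 U=4 N=5
#' @noRd
encode_rna <- function(seq) {
  m <- match(strsplit(seq, "", fixed = TRUE)[[1L]], RNA_BASES)
  if (anyNA(m)) stop("sequence contains residues outside ACGUN")
  m
}

#' Read a FASTA file into the internal RNA alphabet
#'
#' Reads (optionally gzip-compressed) FASTA, keeps each header up to the first
#' whitespace, and applies [dna_to_rna()] to every record.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of RNA sequences (possibly empty).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) {
    warning("FASTA file '", path, "' contains no records")
    return(setNames(character(0), character(0)))
  }
  ids <- sub("\\s.*$", "", names(set))
  setNames(dna_to_rna(as.character(set)), ids)
}

#' Write sequences to a FASTA file
#'
#' Sequences on the internal RNA alphabet are written back as DNA (U -> T)
#' by default, matching the genomic-DNA input contract of the scanner.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param as_dna Write U as T (default TRUE).
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, as_dna = TRUE, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- if (as_dna) chartr("U", "T", seqs[[i]]) else seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", names(seqs)[i]),
                 substring(s, starts, pmin(starts + width - 1L, nchar(s)))), con)
  }
  invisible(path)
}
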