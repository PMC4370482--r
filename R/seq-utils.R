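# Sequence primitives. All sequences are uppercase character scalars over the
# IUPAC nucleotide alphabet; all coordinates are 0-based, half-open. Conversion
# to/from 1-based inclusive happens only at file boundaries (GFF, hit tables).

IUPAC_CHARS <- "ACGTRYSWKMBDHVN"
IUPAC_COMP  <- "TGCAYRSWKMVHDBN"

#' Validate a nucleotide sequence
#'
#' Checks that `seq` is a non-empty string over the IUPAC nucleotide alphabet
#' (including ambiguity codes and `N`; optionally the gap character `-`).
#'
#' @param seq character scalar.
#' @param allow_gap allow `-` characters (aligned sequences).
#' @param what label used in error messages.
#' @return `seq`, invisibly.
#' @export
validate_dna <- function(seq, allow_gap = FALSE, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(what, " must be a non-empty character scalar", call. = FALSE)
  alphabet <- if (allow_gap) paste0(IUPAC_CHARS, "-") else IUPAC_CHARS
  bad <- gsub(sprintf("[%s]", alphabet), "", seq)
  if (nzchar(bad))
    stop(what, " contains non-IUPAC characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = " "), call. = FALSE)
  invisible(seq)
}

#' Reverse complement
#'
#' Reverse-complements a nucleotide sequence. IUPAC ambiguity codes are
#' complemented to their IUPAC counterparts (e.g. `R` -> `Y`), never collapsed
#' to `N`; gap characters pass through unchanged.
#'
#' @param seq character scalar (may contain `-`).
#' @return character scalar, the reverse complement.
#' @examples
#' revcomp("AACG")  # "CGTT"
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  comp <- chartr(paste0(IUPAC_CHARS, "-"), paste0(IUPAC_COMP, "-"), seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Extract a genomic interval from a sequence
#'
#' Returns the substring `[start, end)` of `seq` (0-based, half-open),
#' reverse-complemented when `strand` is `-`.
#'
#' @param seq character scalar.
#' @param start,end 0-based half-open bounds.
#' @param strand `"+"` or `"-"`.
#' @return character scalar of length `end - start`.
#' @export
extract_interval <- function(seq, start, end, strand = "+") {
  n <- nchar(seq)
  if (start < 0 || end > n || end <= start)
    stop("interval [", start, ",", end, ") out of range for sequence of length ",
         n, call. = FALSE)
  s <- substr(seq, start + 1L, end)
  if (strand == "-") s <- revcomp(s)
  s
}

# Codon -> amino acid lookup, standard genetic code (table 1).
.codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

#' Artificial translation
#'
#' Translates a nucleotide sequence in the given frame under the standard
#' genetic code. This is *artificial* translation: internal stop codons are
#' rendered `*` and translation continues past them, so that every
#' ORF-disrupting difference in a pseudogenised sequence remains visible in
#' the protein row of an alignment. Codons containing `N`, an ambiguity code
#' or a gap translate to `X`; trailing 1-2 nt are dropped.
#'
#' @param seq nucleotide sequence (may contain ambiguity codes).
#' @param frame 0, 1 or 2: offset of the first codon.
#' @return amino-acid string; stops are `*`.
#' @examples
#' translate_cds("ATGTAAGGG")  # "M*G" -- continues past the stop
#' @export
translate_cds <- function(seq, frame = 0L) {
  stopifnot(frame %in% 0:2)
  s <- substr(seq, frame + 1L, nchar(seq))
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = n)
  codons <- substring(s, starts, starts + 2L)
  aa <- .codon_table[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

.is_stop <- function(codon) codon %in% c("TAA", "TAG", "TGA")

# Deterministic pct identity of an alignment pair: matched columns / columns.
# N against anything is neither a match nor a mismatch (dropped from both
# counts), so unknown bases cannot fabricate identity.
aln_identity <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(x) == length(y))
  keep <- x != "N" & y != "N"
  if (!any(keep)) return(0)
  100 * sum(x[keep] == y[keep] & x[keep] != "-") / sum(keep)
}
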