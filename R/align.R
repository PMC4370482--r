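# Pairwise alignment layer. Exons are placed into homologous regions by
# semi-global alignment (exon global, region local) with affine gap costs,
# on both strands. The scoring scheme is the package default for nucleotide
# comparisons: match +2, mismatch -3, gap open -5, gap extend -2, where a
# gap of length L costs open + L * extend. N scores 0 against everything so
# unknown bases neither create nor destroy identity.

#' Default nucleotide alignment scoring
#'
#' @param match,mismatch,gap_open,gap_extend scoring parameters; gap costs
#'   are positive numbers (a length-L gap costs `gap_open + L * gap_extend`).
#' @return list of class `align_scoring`.
#' @export
align_scoring <- function(match = 2, mismatch = -3, gap_open = 5,
                          gap_extend = 2) {
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "align_scoring")
}

.submat <- function(scoring) {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                                mismatch = scoring$mismatch)
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

#' An aligned sequence pair
#'
#' Container for one pairwise alignment: two equal-length gapped rows and a
#' score. No column may carry a gap in both rows.
#'
#' @param ref_aln,hom_aln gapped rows (gap character `-`).
#' @param score alignment score.
#' @return list of class `alignment_pair`.
#' @export
alignment_pair <- function(ref_aln, hom_aln, score = NA_real_) {
  if (nchar(ref_aln) != nchar(hom_aln))
    stop("alignment rows differ in length", call. = FALSE)
  both <- gregexpr("-", ref_aln, fixed = TRUE)[[1]]
  if (both[1] != -1) {
    hg <- gregexpr("-", hom_aln, fixed = TRUE)[[1]]
    if (hg[1] != -1 && length(intersect(both, hg)) > 0)
      stop("alignment has a column gapped in both rows", call. = FALSE)
  }
  structure(list(ref_aln = ref_aln, hom_aln = hom_aln, score = score),
            class = "alignment_pair")
}

# Single best semi-global placement of `query` (whole) within `subject`
# (local), forward strand only. Returns NULL if subject shorter than query.
.place_one <- function(query, subject, scoring) {
  if (nchar(subject) < nchar(query)) return(NULL)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subject),
    substitutionMatrix = .submat(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    type = "global-local")
  ref_aln <- as.character(Biostrings::alignedPattern(pa))
  hom_aln <- as.character(Biostrings::alignedSubject(pa))
  list(start = Biostrings::start(Biostrings::subject(pa)) - 1L,
       end = Biostrings::end(Biostrings::subject(pa)),
       score = Biostrings::score(pa),
       alignment = alignment_pair(ref_aln, hom_aln, Biostrings::score(pa)),
       pct_identity = aln_identity(ref_aln, hom_aln))
}

#' Find placements of a reference exon within a genomic region
#'
#' Aligns `ref_exon_seq` semi-globally (exon global, region local, affine
#' gaps) against both strands of `region_seq` and reports every placement
#' whose percent identity reaches `min_identity`. Multiple placements (e.g.
#' tandem copies) are found by recursive splitting: after the best placement
#' is accepted, the flanking subregions are searched independently.
#' Placements are sorted by score (descending), ties broken by leftmost
#' region start then `+` strand. Minus-strand placements report region
#' coordinates on the forward strand but an alignment row oriented to the
#' reference.
#'
#' @param ref_exon_seq exon sequence (>= 10 bp).
#' @param region_seq genomic region to search.
#' @param min_identity identity floor (percent) for a reported placement.
#' @param both_strands also search the reverse complement.
#' @param scoring an [align_scoring()].
#' @return list of placements: `start`, `end` (0-based half-open, forward
#'   region coordinates), `strand`, `score`, `pct_identity`,
#'   `alignment` (an [alignment_pair()]).
#' @export
align_exon <- function(ref_exon_seq, region_seq, min_identity = 60,
                       both_strands = TRUE, scoring = align_scoring()) {
  stopifnot(nchar(ref_exon_seq) >= 10)
  if (nchar(region_seq) < nchar(ref_exon_seq)) return(list())
  L <- nchar(region_seq)
  rc <- if (both_strands) revcomp(region_seq) else NULL

  # recursion runs separately per strand; minus-strand hits are found on the
  # reverse complement and mapped back to forward coordinates afterwards
  search_fwd <- function(seqstr, lo, hi, acc) {
    if (hi - lo < nchar(ref_exon_seq)) return(acc)
    p <- .place_one(ref_exon_seq, substr(seqstr, lo + 1L, hi), scoring)
    if (is.null(p) || p$pct_identity < min_identity) return(acc)
    p$start <- p$start + lo; p$end <- p$end + lo
    acc <- c(acc, list(p))
    acc <- search_fwd(seqstr, lo, p$start, acc)
    search_fwd(seqstr, p$end, hi, acc)
  }
  plus <- lapply(search_fwd(region_seq, 0L, L, list()), function(p) {
    p$strand <- "+"; p
  })
  minus <- list()
  if (both_strands) {
    minus <- lapply(search_fwd(rc, 0L, L, list()), function(p) {
      # coordinates found on the reverse complement; express on forward strand
      s <- L - p$end; e <- L - p$start
      p$start <- s; p$end <- e; p$strand <- "-"
      p
    })
  }
  out <- c(plus, minus)
  if (length(out) == 0L) return(out)
  key <- order(-vapply(out, `[[`, 0, "score"),
               vapply(out, `[[`, 0L, "start"),
               vapply(out, `[[`, "", "strand") == "-")
  out[key]
}

#' Global alignment of two coding sequences
#'
#' Needleman-Wunsch global alignment with the package's affine-gap scoring;
#' used to compare a reference CDS with a putative homolog-derived ORF when
#' no exon mapping is involved.
#'
#' @param ref_seq,hom_seq nucleotide sequences.
#' @param scoring an [align_scoring()].
#' @return an [alignment_pair()].
#' @export
align_cds <- function(ref_seq, hom_seq, scoring = align_scoring()) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ref_seq), Biostrings::DNAString(hom_seq),
    substitutionMatrix = .submat(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    type = "global")
  alignment_pair(as.character(Biostrings::alignedPattern(pa)),
                 as.character(Biostrings::alignedSubject(pa)),
                 Biostrings::score(pa))
}
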