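# Putative-ORF reconstruction: map each reference coding exon into a
# homologous genomic region, then join the mapped pieces in the order and
# orientation of the reference gene. A region carrying several copies of the
# locus (tandem duplicates) yields several putative ORFs, labeled "a", "b",
# ... in region coordinate order.

.exon_map_missing <- function(i) {
  list(exon_index = i, start = NA_integer_, end = NA_integer_,
       strand = NA_character_, alignment = NULL,
       pct_identity = NA_real_, found = FALSE)
}

#' Assemble a putative ORF from per-exon placements
#'
#' @param orf_id label ("a", "b", ...).
#' @param exon_maps list of exon maps in reference exon order; each is a
#'   placement from [align_exon()] plus `exon_index` and `found`.
#' @param ref_exon_seqs reference exon sequences (transcription order).
#' @return object of class `putative_orf` with the joined homolog sequence,
#'   a concatenated reference-vs-homolog alignment, and completeness flag.
#' @export
putative_orf <- function(orf_id, exon_maps, ref_exon_seqs) {
  stopifnot(length(exon_maps) == length(ref_exon_seqs))
  ref_rows <- character(length(exon_maps))
  hom_rows <- character(length(exon_maps))
  for (i in seq_along(exon_maps)) {
    em <- exon_maps[[i]]
    if (isTRUE(em$found)) {
      ref_rows[i] <- em$alignment$ref_aln
      hom_rows[i] <- em$alignment$hom_aln
    } else {
      # unmapped exon behaves as a whole-exon deletion in the joined ORF
      ref_rows[i] <- ref_exon_seqs[i]
      hom_rows[i] <- strrep("-", nchar(ref_exon_seqs[i]))
    }
  }
  joined_aln <- alignment_pair(paste(ref_rows, collapse = ""),
                               paste(hom_rows, collapse = ""))
  joined_seq <- gsub("-", "", joined_aln$hom_aln, fixed = TRUE)
  strands <- unique(stats::na.omit(vapply(exon_maps, `[[`, "", "strand")))
  structure(list(orf_id = orf_id, exon_maps = exon_maps,
                 joined_seq = joined_seq, joined_aln = joined_aln,
                 exon_lens = nchar(ref_exon_seqs),
                 strand = if (length(strands) == 1L) strands else NA_character_,
                 complete = all(vapply(exon_maps, `[[`, TRUE, "found"))),
            class = "putative_orf")
}

#' @export
print.putative_orf <- function(x, ...) {
  found <- sum(vapply(x$exon_maps, `[[`, TRUE, "found"))
  cat("putative_orf", x$orf_id, "-", found, "of", length(x$exon_maps),
      "exons mapped", if (x$complete) "(complete)" else "(incomplete)",
      "strand", x$strand, "-", nchar(x$joined_seq), "bp joined\n")
  invisible(x)
}

# Chain placements into collinear ORFs. Placements of all exons must lie in
# consistent order and share one orientation along the region. Chains are
# seeded from exon-1 placements in coordinate order (on the strand's own
# reading direction) and extended greedily with the nearest unused placement
# of each subsequent exon; this yields one chain per locus copy.
.chain_strand <- function(placements_by_exon, region_len, strand) {
  tr <- function(p) if (strand == "+") c(p$start, p$end)
                    else c(region_len - p$end, region_len - p$start)
  per_exon <- lapply(placements_by_exon, function(ps)
    Filter(function(p) p$strand == strand, ps))
  n_exon <- length(per_exon)
  if (length(per_exon[[1]]) == 0L) return(list())
  used <- lapply(per_exon, function(ps) rep(FALSE, length(ps)))
  seeds <- order(vapply(per_exon[[1]], function(p) tr(p)[1], 0))
  chains <- list()
  for (s in seeds) {
    if (used[[1]][s]) next
    used[[1]][s] <- TRUE
    chain <- vector("list", n_exon)
    chain[[1]] <- per_exon[[1]][[s]]
    cursor <- tr(per_exon[[1]][[s]])[2]
    for (e in seq_len(n_exon)[-1]) {
      ps <- per_exon[[e]]
      best <- 0L; best_start <- Inf
      for (k in seq_along(ps)) {
        if (used[[e]][k]) next
        tk <- tr(ps[[k]])
        if (tk[1] >= cursor && tk[1] < best_start) { best <- k; best_start <- tk[1] }
      }
      if (best > 0L) {
        used[[e]][best] <- TRUE
        chain[[e]] <- ps[[best]]
        cursor <- tr(ps[[best]])[2]
      } else chain[e] <- list(NULL)
    }
    chains <- c(chains, list(chain))
  }
  chains
}

#' Enumerate putative ORFs from exon placements
#'
#' Builds every maximal collinear chain of exon placements (consistent order,
#' one shared orientation, non-overlapping) and returns one putative ORF per
#' chain. Chains covering all exons come back with `complete = TRUE`; chains
#' with unmapped exons are reported with `complete = FALSE`. ORFs are
#' labeled `a`, `b`, ... in region coordinate order.
#'
#' @param placements_by_exon list (one element per reference exon, in
#'   transcription order) of placement lists from [align_exon()].
#' @param ref_exon_seqs reference exon sequences.
#' @param region_len length of the searched region in bp.
#' @return list of [putative_orf()] objects.
#' @export
enumerate_orfs <- function(placements_by_exon, ref_exon_seqs, region_len) {
  stopifnot(length(placements_by_exon) == length(ref_exon_seqs))
  n_exon <- length(placements_by_exon)
  chains <- c(.chain_strand(placements_by_exon, region_len, "+"),
              .chain_strand(placements_by_exon, region_len, "-"))
  chains <- Filter(function(ch) any(!vapply(ch, is.null, TRUE)), chains)
  # when at least one chain covers every exon, partial chains are noise
  # (stray sub-threshold-quality placements of single exons); keep only the
  # complete ones. Partial chains are reported when nothing better exists.
  full <- vapply(chains, function(ch) !any(vapply(ch, is.null, TRUE)), TRUE)
  if (any(full)) chains <- chains[full]
  if (length(chains) == 0L) return(list())
  # label in region coordinate order by the chain's leftmost placement
  lefts <- vapply(chains, function(ch) {
    min(vapply(Filter(Negate(is.null), ch), `[[`, 0L, "start"))
  }, 0)
  chains <- chains[order(lefts)]
  out <- vector("list", length(chains))
  for (i in seq_along(chains)) {
    maps <- vector("list", n_exon)
    for (e in seq_len(n_exon)) {
      p <- chains[[i]][[e]]
      if (is.null(p)) maps[[e]] <- .exon_map_missing(e)
      else maps[[e]] <- c(list(exon_index = e), p[c("start", "end", "strand",
                                                    "alignment",
                                                    "pct_identity")],
                          list(found = TRUE))
    }
    out[[i]] <- putative_orf(letters[i], maps, ref_exon_seqs)
  }
  out
}

#' Map a gene model's exons into a homologous region
#'
#' Convenience wrapper: extracts each exon sequence from the reference
#' genome, places all exons in `region_seq` with [align_exon()], chains the
#' placements with [enumerate_orfs()] and returns the exon maps of the best
#' chain (complete chains first, then highest total score).
#'
#' @param gm a [gene_model()].
#' @param ref_genome named character vector holding the reference sequence.
#' @param region_seq homologous genomic region to map into.
#' @param min_identity placement identity floor (percent).
#' @param scoring an [align_scoring()].
#' @return list of exon maps (one per exon, in transcription order).
#' @export
map_exons <- function(gm, ref_genome, region_seq, min_identity = 60,
                      scoring = align_scoring()) {
  orfs <- reconstruct_orfs(gm, ref_genome, region_seq, min_identity, scoring)
  if (length(orfs) == 0L)
    return(lapply(seq_len(nrow(gm$exons)), .exon_map_missing))
  orfs[[which.max(vapply(orfs, function(o) {
    sc <- vapply(Filter(function(m) m$found, o$exon_maps),
                 function(m) m$alignment$score, 0)
    1e9 * o$complete + sum(sc)
  }, 0))]]$exon_maps
}

#' Reconstruct all putative ORFs of a gene in a region
#'
#' @inheritParams map_exons
#' @return list of [putative_orf()] objects (possibly empty).
#' @export
reconstruct_orfs <- function(gm, ref_genome, region_seq, min_identity = 60,
                             scoring = align_scoring()) {
  ex <- exon_seqs(gm, ref_genome)
  placements <- lapply(ex, align_exon, region_seq = region_seq,
                       min_identity = min_identity, scoring = scoring)
  enumerate_orfs(placements, ex, nchar(region_seq))
}

# Column bookkeeping for an alignment pair: per-column 0-based indices into
# the ungapped rows (NA at a row's own gap columns).
.aln_maps <- function(aln) {
  x <- strsplit(aln$ref_aln, "", fixed = TRUE)[[1]]
  y <- strsplit(aln$hom_aln, "", fixed = TRUE)[[1]]
  ref_idx <- cumsum(x != "-") - 1L; ref_idx[x == "-"] <- NA_integer_
  hom_idx <- cumsum(y != "-") - 1L; hom_idx[y == "-"] <- NA_integer_
  list(ref_char = x, hom_char = y, ref_idx = ref_idx, hom_idx = hom_idx)
}

#' Project a position in a joined putative ORF to reference coordinates
#'
#' Maps a 0-based offset in the homolog-derived joined sequence to the
#' 0-based offset in the reference spliced CDS via the per-exon alignments.
#' Positions inside homolog-only insertions map to the offset of the
#' preceding reference base and are flagged `inserted`.
#'
#' @param orf a [putative_orf()] (or a bare [alignment_pair()]).
#' @param hom_offset 0-based offset(s) in the joined homolog sequence.
#' @return data.frame with columns `hom_offset`, `ref_offset`, `inserted`.
#' @export
project_position <- function(orf, hom_offset) {
  aln <- if (inherits(orf, "putative_orf")) orf$joined_aln else orf
  m <- .aln_maps(aln)
  # for every hom position: ref index at its column, or last preceding one
  last_ref <- cummax(ifelse(is.na(m$ref_idx), -1L, m$ref_idx))
  cols <- match(hom_offset, m$hom_idx)
  if (anyNA(cols)) stop("hom_offset out of range", call. = FALSE)
  inserted <- is.na(m$ref_idx[cols])
  ref_off <- ifelse(inserted, last_ref[cols], m$ref_idx[cols])
  data.frame(hom_offset = hom_offset, ref_offset = as.integer(ref_off),
             inserted = inserted)
}

#' Inverse projection: reference offset to joined-ORF offset
#'
#' Identity-inverse of [project_position()] for positions not deleted in the
#' homolog; reference positions aligned to a homolog gap return `NA`.
#'
#' @param orf a [putative_orf()] or [alignment_pair()].
#' @param ref_offset 0-based offset(s) in the reference spliced CDS.
#' @return integer vector of homolog offsets (NA where deleted).
#' @export
unproject_position <- function(orf, ref_offset) {
  aln <- if (inherits(orf, "putative_orf")) orf$joined_aln else orf
  m <- .aln_maps(aln)
  cols <- match(ref_offset, m$ref_idx)
  if (anyNA(cols)) stop("ref_offset out of range", call. = FALSE)
  as.integer(m$hom_idx[cols])
}
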