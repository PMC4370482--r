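# Candidate filtering: decide which genes are lineage-restricted orphans and
# which of those are plausible de novo candidates, i.e. genes with long,
# high-identity *non-coding* genomic homology but no protein-coding homolog
# on an autosome or the X. All thresholds are strict inequalities ("over",
# "greater than"): a hit exactly at a threshold does not qualify.

#' Orphan-classification thresholds
#'
#' A protein-level hit "counts" (argues against orphan status) when its
#' E-value is at most `e_max` and its percent identity is strictly greater
#' than `identity_min`.
#'
#' @param e_max E-value ceiling for a qualifying hit.
#' @param identity_min percent-identity floor (strict) for a qualifying hit.
#' @return list of class `orphan_criteria`.
#' @export
orphan_criteria <- function(e_max = 1e-4, identity_min = 35) {
  stopifnot(e_max > 0, identity_min > 0, identity_min < 100)
  structure(list(e_max = e_max, identity_min = identity_min),
            class = "orphan_criteria")
}

#' Genomic-fragment retention thresholds
#'
#' @param length_min minimum alignment length in bp (strict).
#' @param identity_min minimum percent identity (strict).
#' @return list of class `fragment_criteria`.
#' @export
fragment_criteria <- function(length_min = 4000, identity_min = 80) {
  stopifnot(length_min > 0)
  structure(list(length_min = length_min, identity_min = identity_min),
            class = "fragment_criteria")
}

.qualifying <- function(hits, criteria) {
  hits$e_value <= criteria$e_max & hits$pct_identity > criteria$identity_min
}

#' Is a gene a lineage-restricted orphan?
#'
#' A gene is an orphan when none of its protein-level hits against the
#' out-lineage protein set qualifies under `criteria`. An empty hit table is
#' vacuously orphan.
#'
#' @param gene_id gene identifier (hits are pre-filtered to this query).
#' @param hits hit table (see [read_hits_tabular()]) of this gene's protein
#'   against out-lineage proteins.
#' @param criteria an [orphan_criteria()].
#' @return logical scalar.
#' @export
classify_orphan <- function(gene_id, hits, criteria = orphan_criteria()) {
  hits <- hits[hits$query_id == gene_id | nrow(hits) == 0L, , drop = FALSE]
  !any(.qualifying(hits, criteria))
}

#' Should a candidate be excluded for having a coding homolog?
#'
#' Returns `TRUE` (exclude) when a qualifying protein-level hit within the
#' lineage lands on a subject whose chromosome class is autosomal or X.
#' Qualifying hits confined to Y-linked paralogs do not exclude.
#'
#' @param gene_id gene identifier.
#' @param hits in-lineage protein hit table.
#' @param subject_locations named character vector mapping subject ids to a
#'   chromosome class: `"autosome"`, `"chrX"` or `"chrY"`.
#' @param criteria an [orphan_criteria()].
#' @return logical scalar: `TRUE` means exclude.
#' @export
exclude_coding_homolog <- function(gene_id, hits, subject_locations,
                                   criteria = orphan_criteria()) {
  hits <- hits[hits$query_id == gene_id | nrow(hits) == 0L, , drop = FALSE]
  q <- hits[.qualifying(hits, criteria), , drop = FALSE]
  if (nrow(q) == 0L) return(FALSE)
  loc <- subject_locations[q$subject_id]
  any(!is.na(loc) & loc %in% c("autosome", "chrX"))
}

#' Retain long, high-identity genomic fragments
#'
#' Filters genome-level hits down to the fragments carried forward for ORF
#' reconstruction: alignment length strictly over `length_min` and identity
#' strictly over `identity_min`. Fragments are returned sorted by subject
#' location (subject id, then subject start).
#'
#' @param hits genome-level hit table (see [read_hits_tabular()]).
#' @param criteria a [fragment_criteria()].
#' @return subset of `hits`, sorted by subject location.
#' @export
filter_genomic_fragments <- function(hits, criteria = fragment_criteria()) {
  keep <- hits$align_length > criteria$length_min &
    hits$pct_identity > criteria$identity_min
  out <- hits[keep, , drop = FALSE]
  out[order(out$subject_id, out$s_start), , drop = FALSE]
}

#' Full candidate verdict for one gene
#'
#' Combines the orphan test, the coding-homolog exclusion and the genomic
#' fragment filter into a single verdict: a gene is a de novo candidate iff
#' it is an orphan, has no autosomal/X protein-coding homolog, and at least
#' one genomic fragment survives the fragment filter.
#'
#' @param gene_id gene identifier.
#' @param outgroup_protein_hits protein hits vs the out-lineage protein set.
#' @param lineage_protein_hits protein hits vs the in-lineage protein set.
#' @param genome_hits genome-level nucleotide hits.
#' @param subject_locations chromosome-class map, see
#'   [exclude_coding_homolog()].
#' @param orphan an [orphan_criteria()].
#' @param fragment a [fragment_criteria()].
#' @return list of class `candidate_verdict` with fields `gene_id`,
#'   `is_orphan`, `has_coding_homolog`, `retained_fragments`, `verdict`
#'   (`"candidate"` or `"excluded"`) and `reason`.
#' @export
candidate_verdict <- function(gene_id, outgroup_protein_hits,
                              lineage_protein_hits, genome_hits,
                              subject_locations,
                              orphan = orphan_criteria(),
                              fragment = fragment_criteria()) {
  is_orphan <- classify_orphan(gene_id, outgroup_protein_hits, orphan)
  has_coding <- exclude_coding_homolog(gene_id, lineage_protein_hits,
                                       subject_locations, orphan)
  frags <- filter_genomic_fragments(
    genome_hits[genome_hits$query_id == gene_id | nrow(genome_hits) == 0L, ,
                drop = FALSE], fragment)
  candidate <- is_orphan && !has_coding && nrow(frags) > 0L
  reason <- if (!is_orphan) "protein homolog outside the lineage"
    else if (has_coding) "protein-coding homolog on an autosome or chrX"
    else if (nrow(frags) == 0L) "no genomic fragment passed the length/identity filter"
    else "orphan with long non-coding genomic homology"
  structure(list(gene_id = gene_id, is_orphan = is_orphan,
                 has_coding_homolog = has_coding,
                 retained_fragments = frags,
                 verdict = if (candidate) "candidate" else "excluded",
                 reason = reason),
            class = "candidate_verdict")
}

#' @export
print.candidate_verdict <- function(x, ...) {
  cat("candidate_verdict for", x$gene_id, "->", x$verdict,
      paste0("(", x$reason, ")"), "\n")
  cat("  orphan:", x$is_orphan, " coding homolog:", x$has_coding_homolog,
      " retained fragments:", nrow(x$retained_fragments), "\n")
  invisible(x)
}
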