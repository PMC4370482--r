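# Gene models: a reference CDS as ordered, stranded exons on a genomic
# sequence. Exons are stored in transcription order (reverse genomic-
# coordinate order on the minus strand) so downstream ORF logic is
# strand-free: the spliced CDS is always read 5'->3'.

#' Construct a gene model
#'
#' @param gene_id gene identifier.
#' @param seq_id id of the genomic sequence the exons live on.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends 0-based half-open exon coordinates, given in
#'   transcription order (descending genomic coordinates for `-` strand).
#' @param cds_phase optional integer vector of per-exon phases (0/1/2, the
#'   number of bases to skip to reach the first complete codon); computed
#'   from cumulative exon lengths when omitted.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, seq_id, strand, exon_starts, exon_ends,
                       cds_phase = NULL) {
  stopifnot(length(exon_starts) == length(exon_ends),
            length(exon_starts) >= 1L,
            strand %in% c("+", "-"),
            all(exon_ends > exon_starts), all(exon_starts >= 0))
  ord <- order(exon_starts)
  ov <- any(exon_starts[ord][-1] < exon_ends[ord][-length(ord)])
  if (ov) stop("exons overlap in gene model '", gene_id, "'", call. = FALSE)
  lens <- exon_ends - exon_starts
  if (sum(lens) < 3L) stop("concatenated CDS shorter than one codon", call. = FALSE)
  if (strand == "+" && is.unsorted(exon_starts))
    stop("plus-strand exons must be in ascending coordinate order", call. = FALSE)
  if (strand == "-" && is.unsorted(rev(exon_starts)))
    stop("minus-strand exons must be in descending coordinate order", call. = FALSE)
  if (is.null(cds_phase)) {
    cum <- cumsum(c(0L, lens[-length(lens)]))
    cds_phase <- (3L - cum %% 3L) %% 3L
  }
  structure(list(gene_id = gene_id, seq_id = seq_id, strand = strand,
                 exons = data.frame(start = as.integer(exon_starts),
                                    end = as.integer(exon_ends)),
                 cds_phase = as.integer(cds_phase)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model", x$gene_id, "on", x$seq_id, paste0("(", x$strand, ")"),
      "with", nrow(x$exons), "exon(s),", sum(exon_lengths(x)), "bp CDS\n")
  invisible(x)
}

#' Per-exon CDS lengths of a gene model
#' @param gm a `gene_model`.
#' @return integer vector of exon lengths in transcription order.
#' @export
exon_lengths <- function(gm) as.integer(gm$exons$end - gm$exons$start)

#' Extract per-exon CDS sequences
#'
#' @param gm a `gene_model`.
#' @param genome named character vector of genomic sequences (or a single
#'   unnamed sequence).
#' @return character vector of exon sequences in transcription order, each
#'   already oriented to the coding strand.
#' @export
exon_seqs <- function(gm, genome) {
  seq <- if (is.null(names(genome)) && length(genome) == 1L) genome
         else genome[[gm$seq_id]]
  if (is.null(seq) || is.na(seq))
    stop("sequence '", gm$seq_id, "' not found in genome", call. = FALSE)
  vapply(seq_len(nrow(gm$exons)), function(i)
    extract_interval(seq, gm$exons$start[i], gm$exons$end[i], gm$strand),
    character(1))
}

#' Spliced CDS of a gene model
#'
#' @inheritParams exon_seqs
#' @return the concatenated coding sequence, 5' to 3'.
#' @export
spliced_cds <- function(gm, genome) paste(exon_seqs(gm, genome), collapse = "")

# Map a 0-based offset in the spliced CDS to its exon index (1-based) and
# offset within that exon.
offset_to_exon <- function(gm_or_lens, offset) {
  lens <- if (inherits(gm_or_lens, "gene_model")) exon_lengths(gm_or_lens)
          else as.integer(gm_or_lens)
  cum <- cumsum(lens)
  idx <- findInterval(offset, c(0L, cum), rightmost.closed = FALSE)
  idx <- pmin(pmax(idx, 1L), length(lens))
  within <- offset - c(0L, cum)[idx]
  list(exon = idx, within = within)
}

#' Read exon annotations for one gene from a GFF3 file
#'
#' Collects the `CDS` features (falling back to `exon` when no CDS rows
#' exist) whose `gene_id`, `Parent` or `ID` attribute matches `gene_id`, and
#' assembles them into a [gene_model()]. Exons are sorted into transcription
#' order; coordinates are converted from GFF's 1-based inclusive convention.
#'
#' @param path path to a GFF3 file.
#' @param gene_id gene identifier to extract.
#' @return a `gene_model`.
#' @export
read_gff_exons <- function(path, gene_id) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  match_attr <- function(col) {
    if (!col %in% names(mc)) return(rep(FALSE, length(gr)))
    v <- mc[[col]]
    if (methods::is(v, "List")) {
      vapply(as.list(v), function(x) gene_id %in% unlist(x), logical(1))
    } else {
      !is.na(v) & v == gene_id
    }
  }
  hit <- match_attr("gene_id") | match_attr("Parent") | match_attr("ID")
  sel <- gr[hit & as.character(mc$type) %in% c("CDS", "exon")]
  if (length(sel) == 0L)
    stop("gene '", gene_id, "' not found in ", path, call. = FALSE)
  types <- as.character(S4Vectors::mcols(sel)$type)
  if (any(types == "CDS")) sel <- sel[types == "CDS"]
  chrs <- unique(as.character(GenomicRanges::seqnames(sel)))
  if (length(chrs) != 1L)
    stop("gene '", gene_id, "' has exons on multiple sequences: ",
         paste(chrs, collapse = ", "), call. = FALSE)
  strand <- unique(as.character(BiocGenerics::strand(sel)))
  strand <- if (identical(strand, "-")) "-" else "+"
  st <- BiocGenerics::start(sel) - 1L
  en <- BiocGenerics::end(sel)
  ord <- if (strand == "-") order(-st) else order(st)
  phase <- S4Vectors::mcols(sel)$phase
  phase <- if (!is.null(phase) && !anyNA(phase)) as.integer(phase)[ord] else NULL
  gene_model(gene_id, chrs, strand, st[ord], en[ord], cds_phase = phase)
}

#' Write a gene model's exons as GFF3
#'
#' @param gm a `gene_model`.
#' @param path output path; appends when `append = TRUE`.
#' @param source value for the GFF source column.
#' @param append append to an existing file without rewriting the directive.
#' @return `path`, invisibly.
#' @export
write_gff_exons <- function(gm, path, source = "orfdecay", append = FALSE) {
  n <- nrow(gm$exons)
  ord <- seq_len(n)
  attrs <- sprintf("ID=%s.cds%d;gene_id=%s", gm$gene_id, ord, gm$gene_id)
  lines <- sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t%d\t%s",
                   gm$seq_id, source, gm$exons$start + 1L, gm$exons$end,
                   gm$strand, gm$cds_phase, attrs)
  # GFF bodies list features in ascending coordinate order
  lines <- lines[order(gm$exons$start)]
  if (!append) lines <- c("##gff-version 3", lines)
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
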