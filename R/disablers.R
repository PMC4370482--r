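# Disabler detection: compare a putative homolog-derived ORF against the
# reference CDS by "artificial translation" and report every ORF-disrupting
# difference. Offsets are reported as the 0-based offset of the affected
# codon's first base in the reference spliced CDS (start codon = offset 0);
# under this convention in-frame premature stops sit at multiples of 3.

DISABLER_TYPES <- c("START_LOSS", "STOP_LOSS", "PREMATURE_STOP_SUBSTITUTION",
                    "PREMATURE_STOP_FRAMESHIFT", "FRAMESHIFT_INDEL")

.disabler_row <- function(type, exon, offset, ref_codon, obs, indel_len = NA_integer_,
                          note = "") {
  data.frame(type = type, exon_index = as.integer(exon),
             ref_nt_offset = as.integer(offset), ref_codon = ref_codon,
             obs = obs, indel_len = as.integer(indel_len), note = note,
             stringsAsFactors = FALSE)
}

.empty_disablers <- function() {
  data.frame(type = character(0), exon_index = integer(0),
             ref_nt_offset = integer(0), ref_codon = character(0),
             obs = character(0), indel_len = integer(0), note = character(0),
             stringsAsFactors = FALSE)
}

# Runs of consecutive TRUE values -> (start, length) pairs (0-based starts).
.runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], len = r$lengths[r$values])
}

#' Scan a putative ORF for disablers
#'
#' Performs artificial translation of a homolog-derived ORF against the
#' reference CDS and reports every disabler: loss of the start codon, loss
#' of the terminal stop codon, premature stop codons (by substitution in the
#' reference frame, or arising in a shifted frame downstream of a
#' frame-shifting indel), and frame-shifting indels themselves. Indels whose
#' length is a multiple of 3 preserve frame and are recorded as notes, not
#' disablers. The reading frame is tracked through upstream indels, so a
#' premature stop is only classified as a substitution when the local net
#' frame shift is zero.
#'
#' @param ref_cds reference spliced CDS (starts with ATG, ends with a stop).
#' @param orf a [putative_orf()], an [alignment_pair()] whose reference row
#'   spells `ref_cds`, or a bare homolog sequence (aligned on the fly with
#'   [align_cds()]).
#' @param exon_lens per-exon reference CDS lengths used to assign each
#'   disabler to an exon; taken from the ORF when available, else the CDS is
#'   treated as a single exon.
#' @param orf_id label carried into the report.
#' @return object of class `disabler_report`: fields `orf_id`, `disablers`
#'   (data.frame: type, exon_index, ref_nt_offset, ref_codon, obs,
#'   indel_len, note), `is_coding`, `translation` (artificial translation of
#'   the homolog from its putative start), `notes`, and the alignment.
#' @export
scan_disablers <- function(ref_cds, orf, exon_lens = NULL, orf_id = "orf") {
  if (inherits(orf, "putative_orf")) {
    aln <- orf$joined_aln
    if (is.null(exon_lens)) exon_lens <- orf$exon_lens
    orf_id <- orf$orf_id
  } else if (inherits(orf, "alignment_pair")) {
    aln <- orf
  } else {
    validate_dna(orf, what = "homolog sequence")
    aln <- align_cds(ref_cds, orf)
  }
  if (gsub("-", "", aln$ref_aln, fixed = TRUE) != ref_cds)
    stop("alignment reference row does not spell the supplied CDS", call. = FALSE)
  if (is.null(exon_lens)) exon_lens <- nchar(ref_cds)
  L <- nchar(ref_cds)
  stopifnot(L %% 3 == 0, sum(exon_lens) == L)

  m <- .aln_maps(aln)
  hom <- gsub("-", "", aln$hom_aln, fixed = TRUE)
  dis <- .empty_disablers()
  notes <- character(0)
  exon_of <- function(off) offset_to_exon(exon_lens, off)$exon

  ## --- indels ------------------------------------------------------------
  ins <- .runs(m$ref_char == "-")      # homolog-only insertions
  if (nrow(ins)) for (k in seq_len(nrow(ins))) {
    cols <- ins$start[k] + seq_len(ins$len[k])   # 1-based column indices
    seg <- paste(m$hom_char[cols], collapse = "")
    prev <- if (ins$start[k] == 0L) -1L else m$ref_idx[ins$start[k]]
    off <- prev + 1L
    if (ins$len[k] %% 3L != 0L) {
      dis <- rbind(dis, .disabler_row("FRAMESHIFT_INDEL", exon_of(off), off,
                                      "", seg, ins$len[k],
                                      sprintf("%d-nt insertion", ins$len[k])))
    } else {
      notes <- c(notes, sprintf("in-frame %d-nt insertion at offset %d (%s)",
                                ins$len[k], off, seg))
    }
  }
  del <- .runs(m$hom_char == "-")      # deletions in the homolog
  if (nrow(del)) for (k in seq_len(nrow(del))) {
    cols <- del$start[k] + seq_len(del$len[k])
    seg <- paste(m$ref_char[cols], collapse = "")
    off <- m$ref_idx[cols[1]]
    if (del$len[k] %% 3L != 0L) {
      dis <- rbind(dis, .disabler_row("FRAMESHIFT_INDEL", exon_of(off), off,
                                      seg, "-", -del$len[k],
                                      sprintf("%d-nt deletion", del$len[k])))
    } else {
      notes <- c(notes, sprintf("in-frame %d-nt deletion at offset %d (%s)",
                                del$len[k], off, seg))
    }
  }

  ## --- start and terminal stop codons ------------------------------------
  codon_cols <- function(off) which(!is.na(m$ref_idx) & m$ref_idx >= off &
                                      m$ref_idx <= off + 2L)
  obs_codon <- function(off) paste(m$hom_char[codon_cols(off)], collapse = "")
  start_obs <- obs_codon(0L)
  if (length(codon_cols(0L)) == 3L) {
    if (start_obs != "ATG")
      dis <- rbind(dis, .disabler_row("START_LOSS", 1L, 0L,
                                      substr(ref_cds, 1, 3), start_obs))
  } else {
    notes <- c(notes, "alignment does not cover the start codon; start check skipped")
  }
  stop_off <- L - 3L
  stop_obs <- obs_codon(stop_off)
  if (length(codon_cols(stop_off)) == 3L) {
    if (!.is_stop(stop_obs))
      dis <- rbind(dis, .disabler_row("STOP_LOSS", exon_of(stop_off), stop_off,
                                      substr(ref_cds, L - 2, L), stop_obs))
  } else {
    notes <- c(notes, "alignment does not cover the stop codon; stop check skipped")
  }

  ## --- premature stops, frame tracked through indels ----------------------
  # homolog position aligned to the reference start (first non-gap hom column
  # at ref offset 0) and to the terminal stop codon's first base
  col0 <- which(!is.na(m$ref_idx) & m$ref_idx == 0L)[1]
  hstart <- if (!is.na(col0) && !is.na(m$hom_idx[col0])) m$hom_idx[col0] else {
    later <- which(!is.na(m$hom_idx) & seq_along(m$hom_idx) >= col0)[1]
    if (is.na(later)) NA_integer_ else m$hom_idx[later]
  }
  col_stop <- which(!is.na(m$ref_idx) & m$ref_idx == stop_off)[1]
  h_stop <- if (!is.na(col_stop) && !is.na(m$hom_idx[col_stop])) {
    m$hom_idx[col_stop]
  } else nchar(hom) - 3L
  translation <- ""
  if (!is.na(hstart)) {
    translation <- translate_cds(substr(hom, hstart + 1L, nchar(hom)))
    hom_cols <- match(seq_len(nchar(hom)) - 1L, m$hom_idx)   # col per hom pos
    last_ref <- cummax(ifelse(is.na(m$ref_idx), -1L, m$ref_idx))
    p <- hstart
    while (p + 3L <= nchar(hom) && p < h_stop) {
      codon <- substr(hom, p + 1L, p + 3L)
      if (.is_stop(codon)) {
        colp <- hom_cols[p + 1L]
        refp <- if (is.na(m$ref_idx[colp])) last_ref[colp] else m$ref_idx[colp]
        inserted <- is.na(m$ref_idx[colp])
        net_frame <- ((p - hstart) - refp) %% 3L
        ref_codon <- if (refp >= 0 && refp + 3L <= L)
          substr(ref_cds, refp + 1L, refp + 3L) else ""
        if (net_frame == 0L && !inserted && !.is_stop(ref_codon)) {
          dis <- rbind(dis, .disabler_row("PREMATURE_STOP_SUBSTITUTION",
                                          exon_of(refp), refp, ref_codon, codon))
        } else {
          note <- if (inserted) "stop within inserted sequence"
                  else sprintf("stop in frame shifted by %+d", net_frame)
          dis <- rbind(dis, .disabler_row("PREMATURE_STOP_FRAMESHIFT",
                                          exon_of(max(refp, 0L)), max(refp, 0L),
                                          ref_codon, codon, note = note))
        }
      }
      p <- p + 3L
    }
  } else {
    notes <- c(notes, "putative start position absent from homolog; translation skipped")
  }

  if (nrow(dis)) {
    dis <- dis[order(dis$ref_nt_offset, match(dis$type, DISABLER_TYPES)), ,
               drop = FALSE]
    rownames(dis) <- NULL
  }
  structure(list(orf_id = orf_id, disablers = dis,
                 is_coding = nrow(dis) == 0L, translation = translation,
                 notes = notes, alignment = aln, exon_lens = exon_lens,
                 ref_cds = ref_cds),
            class = "disabler_report")
}

#' @export
print.disabler_report <- function(x, ...) {
  cat("disabler_report for", x$orf_id, "-",
      if (x$is_coding) "intact ORF (coding)" else
        paste(nrow(x$disablers), "disabler(s)"), "\n")
  if (nrow(x$disablers)) print(x$disablers)
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Scan for enablers: changes that restored coding ability
#'
#' Given a non-coding reference ORF (e.g. the ancestral/autosomal state) and
#' a coding derived ORF (the putative de novo gene), reports each difference
#' in the derived sequence that removes a disabler present in the non-coding
#' sequence. The derived ORF defines the reading frame; the non-coding ORF
#' is scanned against it, and every disabler found corresponds to one
#' enabler in the derived lineage.
#'
#' @param noncoding_seq the non-coding ORF sequence.
#' @param coding_seq the derived, coding ORF sequence (valid CDS).
#' @param exon_lens optional per-exon lengths of the coding sequence.
#' @param scoring an [align_scoring()].
#' @return object of class `enabler_report`: `enablers` is the disabler
#'   table of the non-coding sequence augmented with a `change` column
#'   describing the restoring edit; `residual` is the derived sequence's own
#'   disabler report (empty when it is a clean CDS).
#' @export
scan_enablers <- function(noncoding_seq, coding_seq, exon_lens = NULL,
                          scoring = align_scoring()) {
  aln <- align_cds(coding_seq, noncoding_seq, scoring)
  rep_nc <- scan_disablers(coding_seq, aln, exon_lens, orf_id = "noncoding")
  d <- rep_nc$disablers
  change <- character(nrow(d))
  for (i in seq_len(nrow(d))) {
    change[i] <- switch(d$type[i],
      START_LOSS = sprintf("%s -> ATG restored start at offset 0", d$obs[i]),
      STOP_LOSS = sprintf("%s -> %s restored terminal stop", d$obs[i], d$ref_codon[i]),
      PREMATURE_STOP_SUBSTITUTION =
        sprintf("%s -> %s removed premature stop at offset %d",
                d$obs[i], d$ref_codon[i], d$ref_nt_offset[i]),
      PREMATURE_STOP_FRAMESHIFT =
        sprintf("frame restoration removed shifted-frame stop near offset %d",
                d$ref_nt_offset[i]),
      FRAMESHIFT_INDEL =
        sprintf("%+d-nt compensating change restored frame at offset %d",
                -d$indel_len[i], d$ref_nt_offset[i]))
  }
  d$change <- change
  residual <- scan_disablers(coding_seq, alignment_pair(coding_seq, coding_seq),
                             exon_lens, orf_id = "derived")
  structure(list(enablers = d, residual = residual), class = "enabler_report")
}

#' @export
print.enabler_report <- function(x, ...) {
  cat("enabler_report -", nrow(x$enablers), "enabler(s)\n")
  if (nrow(x$enablers)) print(x$enablers[, c("type", "ref_nt_offset", "change")])
  invisible(x)
}

#' Render a disabler report as a fixed-width alignment text block
#'
#' Produces the classic four-row rendering per block: reference translation,
#' reference nucleotides, homolog nucleotides, homolog (artificial)
#' translation, plus a marker row carrying one `^` under the first affected
#' column of each disabler. Output is deterministic.
#'
#' @param report a `disabler_report`.
#' @param width columns per block (rounded down to a multiple of 3).
#' @return character vector of text lines.
#' @export
render_alignment <- function(report, width = 60L) {
  width <- max(3L, (width %/% 3L) * 3L)
  aln <- report$alignment
  m <- .aln_maps(aln)
  n <- length(m$ref_char)
  # amino-acid rows: letter under the middle base of each codon of that row
  aa_row <- function(chars, idx) {
    seqq <- paste(chars[chars != "-"], collapse = "")
    aa <- strsplit(translate_cds(seqq), "", fixed = TRUE)[[1]]
    row <- rep(" ", n)
    mid <- which(!is.na(idx) & idx %% 3L == 1L)
    k <- (idx[mid] - 1L) %/% 3L + 1L
    ok <- k <= length(aa)
    row[mid[ok]] <- aa[k[ok]]
    row
  }
  # homolog translation is frame-anchored at the putative start
  hom_idx_shift <- m$hom_idx
  col0 <- which(!is.na(m$ref_idx) & m$ref_idx == 0L)[1]
  h0 <- if (!is.na(col0) && !is.na(m$hom_idx[col0])) m$hom_idx[col0] else 0L
  hom_idx_shift <- ifelse(!is.na(m$hom_idx) & m$hom_idx >= h0,
                          m$hom_idx - h0, NA_integer_)
  top <- aa_row(m$ref_char, m$ref_idx)
  hom_chars <- m$hom_char
  bot_seq <- paste(hom_chars[!is.na(hom_idx_shift)], collapse = "")
  bot <- rep(" ", n)
  aa <- strsplit(translate_cds(bot_seq), "", fixed = TRUE)[[1]]
  mid <- which(!is.na(hom_idx_shift) & hom_idx_shift %% 3L == 1L)
  k <- (hom_idx_shift[mid] - 1L) %/% 3L + 1L
  ok <- k >= 1L & k <= length(aa)
  bot[mid[ok]] <- aa[k[ok]]

  marks <- rep(" ", n)
  d <- report$disablers
  for (i in seq_len(nrow(d))) {
    col <- if (d$type[i] == "FRAMESHIFT_INDEL" && d$indel_len[i] > 0) {
      # insertion: mark the first inserted column after the preceding ref base
      wh <- which(is.na(m$ref_idx))
      cand <- wh[wh > ifelse(d$ref_nt_offset[i] == 0L, 0L,
                             which(m$ref_idx %in% (d$ref_nt_offset[i] - 1L))[1])]
      if (length(cand)) cand[1] else which(m$ref_idx %in% d$ref_nt_offset[i])[1]
    } else {
      which(!is.na(m$ref_idx) & m$ref_idx == d$ref_nt_offset[i])[1]
    }
    if (is.na(col)) col <- 1L
    while (marks[col] != " " && col < n) col <- col + 1L
    marks[col] <- "^"
  }

  header <- c(sprintf("# %s: %s", report$orf_id,
                      if (report$is_coding) "intact ORF"
                      else sprintf("%d disabler(s)", nrow(report$disablers))),
              "# offsets are 0-based from the start codon's first base in the reference spliced CDS")
  lines <- header
  for (blk in seq.int(1L, n, by = width)) {
    hi <- min(blk + width - 1L, n)
    rng <- blk:hi
    lines <- c(lines,
               sprintf("ref aa  %s", paste(top[rng], collapse = "")),
               sprintf("ref nt  %s", paste(m$ref_char[rng], collapse = "")),
               sprintf("hom nt  %s", paste(m$hom_char[rng], collapse = "")),
               sprintf("hom aa  %s", paste(bot[rng], collapse = "")),
               sprintf("        %s", paste(marks[rng], collapse = "")),
               "")
  }
  lines
}
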