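# Readers and writers for the standard formats the pipeline touches: FASTA,
# GFF3 exon annotations, 12-column tabular homology hits, BED. File formats
# use the conventions of their ecosystem (1-based inclusive for GFF and hit
# tables); everything in memory is 0-based half-open.

#' Read a FASTA file
#'
#' Reads a (multi-record) FASTA file into a named character vector. Sequences
#' are uppercased and `U` is mapped to `T`; the alphabet is validated against
#' the IUPAC nucleotide codes. Record ids (the first whitespace-delimited
#' token of each header) must be unique; the remainder of the header is kept
#' in the `"description"` attribute.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences, with a `description`
#'   attribute (character vector parallel to the records).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    out <- character(0)
    attr(out, "description") <- character(0)
    return(out)
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- chartr("u", "t", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[[i]]))
      stop("empty sequence for record '", ids[[i]], "'", call. = FALSE)
    validate_dna(seqs[[i]], what = paste0("record '", ids[[i]], "'"))
  }
  names(seqs) <- ids
  attr(seqs, "description") <- desc
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector (optionally carrying a `description`
#'   attribute as produced by [read_fasta()]).
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  desc <- attr(seqs, "description")
  headers <- names(seqs)
  if (!is.null(desc)) {
    has <- nzchar(desc)
    headers[has] <- paste(headers[has], desc[has])
  }
  set <- Biostrings::BStringSet(as.character(seqs))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# Standard 12 column names of the tabular homology-hit dialect.
.hit_cols <- c("query_id", "subject_id", "pct_identity", "align_length",
               "mismatches", "gap_opens", "q_start", "q_end",
               "s_start", "s_end", "e_value", "bit_score")

#' Read a 12-column tabular homology hit file
#'
#' Parses the standard 12-column tab-separated homology-hit dialect
#' (query id, subject id, percent identity, alignment length, mismatches,
#' gap opens, query start/end, subject start/end, E-value, bit score).
#' In-file coordinates are 1-based inclusive; they are converted to 0-based
#' half-open on load, and the subject strand is inferred from the coordinate
#' order (`s_start > s_end` in the file means a minus-strand hit).
#'
#' @param path path to the hit table. Lines starting with `#` are skipped.
#' @return data.frame with columns `query_id`, `subject_id`, `pct_identity`,
#'   `align_length`, `mismatches`, `gap_opens`, `q_start`, `q_end`,
#'   `s_start`, `s_end`, `e_value`, `bit_score`, `s_strand` — coordinates
#'   0-based half-open with `start < end` on both query and subject.
#' @export
read_hits_tabular <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (length(keep) == 0L) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), 12), .hit_cols))
    df$s_strand <- character(0)
    return(df)
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop("line ", keep[which(nf != 12L)[1]], ": expected 12 tab-separated ",
         "columns, found ", nf[which(nf != 12L)[1]], call. = FALSE)
  m <- do.call(rbind, fields)
  df <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                   pct_identity = as.numeric(m[, 3]),
                   align_length = as.integer(m[, 4]),
                   mismatches = as.integer(m[, 5]),
                   gap_opens = as.integer(m[, 6]),
                   q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
                   s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
                   e_value = as.numeric(m[, 11]),
                   bit_score = as.numeric(m[, 12]),
                   stringsAsFactors = FALSE)
  minus <- df$s_start > df$s_end
  df$s_strand <- ifelse(minus, "-", "+")
  s_lo <- pmin(df$s_start, df$s_end)
  s_hi <- pmax(df$s_start, df$s_end)
  df$s_start <- s_lo - 1L
  df$s_end <- s_hi
  df$q_start <- df$q_start - 1L
  stopifnot(all(df$pct_identity >= 0 & df$pct_identity <= 100),
            all(df$e_value >= 0))
  df
}

#' Write a hit table in the 12-column tabular dialect
#'
#' Inverse of [read_hits_tabular()]: converts the in-memory 0-based half-open
#' coordinates back to the file's 1-based inclusive convention, encoding a
#' minus-strand subject hit as `s_start > s_end`.
#'
#' @param hits data.frame as returned by [read_hits_tabular()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_tabular <- function(hits, path) {
  s1 <- ifelse(hits$s_strand == "-", hits$s_end, hits$s_start + 1L)
  s2 <- ifelse(hits$s_strand == "-", hits$s_start + 1L, hits$s_end)
  out <- data.frame(hits$query_id, hits$subject_id,
                    format(hits$pct_identity, trim = TRUE),
                    hits$align_length, hits$mismatches, hits$gap_opens,
                    hits$q_start + 1L, hits$q_end, s1, s2,
                    format(hits$e_value, trim = TRUE),
                    format(hits$bit_score, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write genomic intervals to BED
#'
#' @param df data.frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open, BED-native), optional `name`, `score`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  name <- if ("name" %in% names(df)) df$name else "."
  score <- if ("score" %in% names(df)) df$score else 0
  strand <- if ("strand" %in% names(df)) df$strand else "."
  out <- data.frame(df$seq_id, df$start, df$end, name, score, strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
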