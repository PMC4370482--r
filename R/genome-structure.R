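# Windowed dot-plots with off-diagonal repeat-segment calling, and
# anchor-based gene-order synteny blocks. A dot at (i, j) means the w-bp
# window of sequence A starting at i (0-based) and the w-bp window of B
# starting at j differ in at most `max_mismatch` positions; minus-strand
# dots compare A's window against the reverse complement of B's window.

#' Dot-plot parameters
#'
#' @param window window length in bp (>= 4).
#' @param max_mismatch maximum Hamming mismatches per window pair.
#' @param both_strands also compare against the reverse complement of B.
#' @return list of class `dotplot_params`.
#' @export
dotplot_params <- function(window = 14L, max_mismatch = 0L,
                           both_strands = FALSE) {
  stopifnot(window >= 4L, max_mismatch >= 0L, max_mismatch < window)
  structure(list(window = as.integer(window),
                 max_mismatch = as.integer(max_mismatch),
                 both_strands = both_strands), class = "dotplot_params")
}

# All qualifying window pairs of chars vectors x vs y, scanned diagonal by
# diagonal with cumulative sums: O(n*m) elementwise work, vectorized per
# diagonal.
.dot_scan <- function(x, y, w, max_mm) {
  n <- length(x); m <- length(y)
  out_i <- integer(0); out_j <- integer(0)
  for (d in (-(n - w)):(m - w)) {
    lo <- max(0L, -d); hi <- min(n, m - d)   # overlap in x coords [lo, hi)
    len <- hi - lo
    if (len < w) next
    eq <- x[(lo + 1L):hi] == y[(lo + d + 1L):(hi + d)]
    cs <- cumsum(c(0L, !eq))
    mm <- cs[(w + 1L):(len + 1L)] - cs[1:(len - w + 1L)]
    keep <- which(mm <= max_mm)
    if (length(keep)) {
      out_i <- c(out_i, lo + keep - 1L)
      out_j <- c(out_j, lo + d + keep - 1L)
    }
  }
  data.frame(i = out_i, j = out_j)
}

#' Windowed dot-plot of two sequences
#'
#' Emits a dot for every pair of window start positions `(i, j)` whose
#' windows are within `max_mismatch` Hamming distance. When
#' `params$both_strands` is set, B is also scanned as its reverse
#' complement: a minus-strand dot `(i, j)` compares A's window at `i` with
#' the reverse complement of B's window starting at `j` (forward B
#' coordinates).
#'
#' @param seq_a,seq_b nucleotide sequences.
#' @param params a [dotplot_params()].
#' @return object of class `dot_plot`: `params`, `dots` (data.frame `i`,
#'   `j`, `strand`, 0-based window starts), `self` (whether A and B are the
#'   same string), `len_a`, `len_b`.
#' @export
dotplot <- function(seq_a, seq_b = seq_a, params = dotplot_params()) {
  w <- params$window
  if (w > min(nchar(seq_a), nchar(seq_b))) {
    warning("window longer than a sequence; empty dot-plot")
    dots <- data.frame(i = integer(0), j = integer(0), strand = character(0))
    return(structure(list(params = params, dots = dots,
                          self = identical(seq_a, seq_b),
                          len_a = nchar(seq_a), len_b = nchar(seq_b)),
                     class = "dot_plot"))
  }
  x <- .split1(seq_a); y <- .split1(seq_b)
  fwd <- .dot_scan(x, y, w, params$max_mismatch)
  fwd$strand <- rep("+", nrow(fwd))
  dots <- fwd
  if (params$both_strands) {
    m <- nchar(seq_b)
    rc <- .split1(revcomp(seq_b))
    rev_ <- .dot_scan(x, rc, w, params$max_mismatch)
    if (nrow(rev_)) {
      rev_$j <- m - rev_$j - w   # window start on forward B coordinates
      rev_$strand <- "-"
      dots <- rbind(dots, rev_)
    }
  }
  dots <- dots[order(dots$strand, dots$i, dots$j), , drop = FALSE]
  rownames(dots) <- NULL
  structure(list(params = params, dots = dots,
                 self = identical(seq_a, seq_b),
                 len_a = nchar(seq_a), len_b = nchar(seq_b)),
            class = "dot_plot")
}

#' @export
print.dot_plot <- function(x, ...) {
  cat("dot_plot:", nrow(x$dots), "dots, window", x$params$window,
      "max_mismatch", x$params$max_mismatch,
      if (x$self) "(self-comparison)" else "", "\n")
  invisible(x)
}

#' Call repeat segments from a dot-plot
#'
#' Merges runs of same-diagonal dots (off the main diagonal for
#' self-comparisons) into duplicated-segment calls. A run may tolerate gaps
#' of up to `gap` skipped window starts; its length is the span of window
#' starts plus the window. For self-comparisons, mirrored runs (above/below
#' the main diagonal) are reported once, with `a_start <= b_start`.
#'
#' @param plot a [dotplot()] result.
#' @param min_segment minimum segment length in bp.
#' @param gap tolerated gap (in window starts) within a run.
#' @return data.frame with columns `a_start`, `a_end`, `b_start`, `b_end`
#'   (0-based half-open), `strand`, `length`, `n_dots`.
#' @export
call_repeat_segments <- function(plot, min_segment = 100L, gap = 0L) {
  w <- plot$params$window
  d <- plot$dots
  if (plot$self) d <- d[!(d$strand == "+" & d$i == d$j), , drop = FALSE]
  empty <- data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      strand = character(0), length = integer(0),
                      n_dots = integer(0))
  if (nrow(d) == 0L) return(empty)
  # plus-strand runs share j - i; minus-strand runs share i + j
  d$diag <- ifelse(d$strand == "+", d$j - d$i, d$i + d$j)
  segs <- empty
  for (grp in split(d, list(d$strand, d$diag), drop = TRUE)) {
    grp <- grp[order(grp$i), ]
    brk <- c(0L, which(diff(grp$i) > gap + 1L), nrow(grp))
    for (k in seq_len(length(brk) - 1L)) {
      run <- grp[(brk[k] + 1L):brk[k + 1L], ]
      a0 <- run$i[1]; a1 <- run$i[nrow(run)] + w
      js <- range(run$j)
      seg <- data.frame(a_start = a0, a_end = a1,
                        b_start = js[1], b_end = js[2] + w,
                        strand = run$strand[1], length = a1 - a0,
                        n_dots = nrow(run))
      segs <- rbind(segs, seg)
    }
  }
  segs <- segs[segs$length >= min_segment, , drop = FALSE]
  if (plot$self && nrow(segs)) {
    keep <- segs$a_start <= segs$b_start
    segs <- segs[keep, , drop = FALSE]
  }
  segs <- segs[order(segs$a_start, segs$b_start), , drop = FALSE]
  rownames(segs) <- NULL
  segs
}

.norm_gene <- function(name, normalize_pseudogene) {
  n <- toupper(name)
  if (normalize_pseudogene) n <- sub("(_P|P)$", "", n)
  n
}

#' Synteny blocks between two gene-order lists
#'
#' Anchors are gene names present in both region lists (case-insensitive;
#' optionally with a trailing pseudogene suffix `P`/`_P` stripped). Blocks
#' are maximal runs of anchors, taken in A order, whose positions in B are
#' monotone and whose relative strand orientation is uniform: increasing B
#' positions with equal strands form a forward block, decreasing B
#' positions with flipped strands an inverted block.
#'
#' @param list_a,list_b data.frames with columns `gene` and `strand`
#'   (`"+"`/`"-"`), one row per gene in region order.
#' @param normalize_pseudogene strip a trailing `P`/`_P` suffix before
#'   matching names.
#' @return data.frame with one row per block: `orientation`
#'   (`"forward"`/`"inverted"`), `n_anchors`, `anchors` (comma-joined),
#'   `a_first`, `a_last`, `b_first`, `b_last` (1-based indices into the
#'   original lists).
#' @export
synteny_blocks <- function(list_a, list_b, normalize_pseudogene = FALSE) {
  na <- .norm_gene(list_a$gene, normalize_pseudogene)
  nb <- .norm_gene(list_b$gene, normalize_pseudogene)
  if (anyDuplicated(na) || anyDuplicated(nb))
    stop("anchor names must be unique within each region list", call. = FALSE)
  shared <- intersect(na, nb)
  empty <- data.frame(orientation = character(0), n_anchors = integer(0),
                      anchors = character(0), a_first = integer(0),
                      a_last = integer(0), b_first = integer(0),
                      b_last = integer(0))
  if (length(shared) == 0L) return(empty)
  ia <- which(na %in% shared)           # anchor indices in A order
  posb <- match(na[ia], nb)
  rel_same <- list_a$strand[ia] == list_b$strand[posb]
  blocks <- empty
  start <- 1L
  flush <- function(blocks, s, e) {
    rows <- s:e
    rbind(blocks, data.frame(
      orientation = if (rel_same[s]) "forward" else "inverted",
      n_anchors = length(rows),
      anchors = paste(list_a$gene[ia[rows]], collapse = ","),
      a_first = ia[rows[1]], a_last = ia[rows[length(rows)]],
      b_first = posb[rows[1]], b_last = posb[rows[length(rows)]]))
  }
  for (k in seq_along(ia)[-1]) {
    dir_needed <- if (rel_same[start]) 1L else -1L
    ok <- rel_same[k] == rel_same[start] &&
      sign(posb[k] - posb[k - 1L]) == dir_needed
    if (!ok) {
      blocks <- flush(blocks, start, k - 1L)
      start <- k
    }
  }
  blocks <- flush(blocks, start, length(ia))
  rownames(blocks) <- NULL
  blocks
}
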