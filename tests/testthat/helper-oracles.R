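# Independent brute-force oracles used by the property tests. These are
# deliberately written with different algorithms/decompositions than the
# package implementations they check.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Dot-plot oracle: enumerate window pairs row by row (per-window, not
# per-diagonal as the implementation does) and count Hamming mismatches.
brute_dotplot <- function(a, b, w, max_mm) {
  xa <- chars(a); xb <- chars(b)
  nb <- length(xb) - w + 1L
  # windows of b as a (w x nb) matrix of characters
  Bm <- vapply(seq_len(nb), function(j) xb[j:(j + w - 1L)], character(w))
  out_i <- integer(0); out_j <- integer(0)
  for (i in seq_len(length(xa) - w + 1L)) {
    mm <- colSums(Bm != xa[i:(i + w - 1L)])
    hit <- which(mm <= max_mm)
    out_i <- c(out_i, rep(i - 1L, length(hit)))
    out_j <- c(out_j, hit - 1L)
  }
  data.frame(i = out_i, j = out_j)
}

# Quadratic affine-gap DP for the best semi-global score (pattern global,
# subject local; a gap of length L costs open + L * extend; N scores 0).
dp_semiglobal_score <- function(pattern, subject, match = 2, mismatch = -3,
                                open = 5, extend = 2) {
  p <- chars(pattern); s <- chars(subject)
  m <- length(p); n <- length(s)
  NEG <- -1e9
  sub <- function(x, y) if (x == "N" || y == "N") 0
                        else if (x == y) match else mismatch
  M <- matrix(NEG, m + 1L, n + 1L)
  X <- matrix(NEG, m + 1L, n + 1L)   # pattern char against gap
  Y <- matrix(NEG, m + 1L, n + 1L)   # subject char against gap
  M[1, ] <- 0                        # free leading subject
  for (i in 2:(m + 1L)) {
    X[i, 1] <- max(M[i - 1L, 1] - open - extend, X[i - 1L, 1] - extend)
    for (j in 2:(n + 1L)) {
      M[i, j] <- sub(p[i - 1L], s[j - 1L]) +
        max(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      X[i, j] <- max(M[i - 1L, j] - open - extend, X[i - 1L, j] - extend)
      Y[i, j] <- max(M[i, j - 1L] - open - extend, Y[i, j - 1L] - extend)
    }
  }
  max(M[m + 1L, ], X[m + 1L, ])      # free trailing subject
}

# Exhaustive small-parsimony oracle: minimum number of state changes over
# all labelings of internal nodes (and of missing-data leaves).
fitch_exhaustive_score <- function(tree, tip_states) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  fixed <- rep(NA_integer_, nn)
  for (i in seq_len(nt)) {
    st <- tip_states[[tree$tip.label[i]]]
    if (!is.null(st) && !is.na(st))
      fixed[i] <- if (st == "coding") 2L else 1L
  }
  free <- which(is.na(fixed))
  best <- Inf
  for (mask in 0:(2^length(free) - 1L)) {
    lab <- fixed
    lab[free] <- 1L + bitwAnd(bitwShiftR(mask, seq_along(free) - 1L), 1L)
    cost <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, cost)
  }
  best
}

# Bipartition-set Robinson-Foulds oracle.
rf_brute <- function(t1, t2) {
  biparts <- function(tr) {
    nt <- length(tr$tip.label)
    tips_below <- function(node) {
      if (node <= nt) return(tr$tip.label[node])
      kids <- tr$edge[tr$edge[, 1] == node, 2]
      unlist(lapply(kids, tips_below))
    }
    internal <- setdiff(unique(tr$edge[, 2]), seq_len(nt))
    out <- character(0)
    for (v in internal) {
      side <- sort(tips_below(v))
      other <- sort(setdiff(tr$tip.label, side))
      if (length(side) < 2L || length(other) < 2L) next
      key <- min(paste(side, collapse = "|"), paste(other, collapse = "|"))
      out <- c(out, key)
    }
    unique(out)
  }
  b1 <- biparts(t1); b2 <- biparts(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# Independent hit-table re-filter (row-by-row loop, no vectorization).
refilter_fragments <- function(hits, length_min, identity_min) {
  keep <- logical(nrow(hits))
  for (r in seq_len(nrow(hits)))
    keep[r] <- hits$align_length[r] > length_min &&
      hits$pct_identity[r] > identity_min
  out <- hits[keep, , drop = FALSE]
  out[order(out$subject_id, out$s_start), , drop = FALSE]
}

random_hits <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  len <- sample(1000:8000, n, replace = TRUE)
  s0 <- sample(0:100000, n)
  data.frame(
    query_id = "g", subject_id = sample(paste0("chr", 1:4), n, replace = TRUE),
    pct_identity = round(runif(n, 60, 100), 1),
    align_length = len,
    mismatches = 0L, gap_opens = 0L,
    q_start = 0L, q_end = len,
    s_start = s0, s_end = s0 + len,
    e_value = round(10^runif(n, -20, 0), 6), bit_score = round(runif(n, 50, 500), 1),
    s_strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# Small simulation used by several tests: 5-taxon tree of the demo shape.
DEMO_TREE <- "((((Hosa:0.01,Patr:0.01):0.005,Gogo:0.015):0.02,Mamu:0.035):0.01,Caja:0.045);"
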