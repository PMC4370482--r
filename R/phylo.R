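# Distance-based phylogenetics: K2P and TN93 pairwise distances with
# pairwise deletion, neighbor-joining trees, nonparametric bootstrap over
# alignment columns, and Robinson-Foulds comparison. Tree manipulation is
# delegated to ape; the distance closed forms are computed here.

.PURINES <- c("A", "G")

# Per-pair substitution proportions over columns where both sequences carry
# an unambiguous base. Returns counts needed by the K2P and TN93 forms.
.pair_counts <- function(x, y) {
  keep <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n == 0L) stop("no comparable columns between sequences", call. = FALSE)
  diff <- x != y
  ts_ag <- diff & x %in% .PURINES & y %in% .PURINES
  ts_ct <- diff & !(x %in% .PURINES) & !(y %in% .PURINES)
  tv <- diff & !ts_ag & !ts_ct
  bases <- c(x, y)
  freq <- table(factor(bases, levels = c("A", "C", "G", "T"))) / (2 * n)
  list(n = n, P1 = sum(ts_ag) / n, P2 = sum(ts_ct) / n,
       P = sum(ts_ag | ts_ct) / n, Q = sum(tv) / n, freq = as.numeric(freq))
}

.split1 <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Kimura two-parameter distance
#'
#' Computes the K2P distance between two aligned sequences. Columns with a
#' gap or ambiguity code in either sequence are excluded pairwise. With
#' transition proportion P and transversion proportion Q over the included
#' columns, the distance is `-1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))`.
#'
#' @param seq_a,seq_b equal-length aligned sequences.
#' @return the distance (substitutions per site).
#' @export
k2p_distance <- function(seq_a, seq_b) {
  x <- .split1(seq_a); y <- .split1(seq_b)
  if (length(x) != length(y)) stop("sequences differ in length", call. = FALSE)
  ct <- .pair_counts(x, y)
  w1 <- 1 - 2 * ct$P - ct$Q
  w2 <- 1 - 2 * ct$Q
  if (w1 <= 0 || w2 <= 0)
    stop("K2P distance undefined (saturation): 1-2P-Q = ", signif(w1, 3),
         ", 1-2Q = ", signif(w2, 3), call. = FALSE)
  -0.5 * log(w1 * sqrt(w2))
}

#' Tamura-Nei (TN93) distance
#'
#' Standard TN93 closed form from the purine-transition proportion P1, the
#' pyrimidine-transition proportion P2, the transversion proportion Q, and
#' the average base frequencies of the pair; columns with gaps or ambiguity
#' in either sequence are excluded pairwise. Reduces toward K2P when base
#' frequencies are equal.
#'
#' @inheritParams k2p_distance
#' @return the distance (substitutions per site).
#' @export
tn93_distance <- function(seq_a, seq_b) {
  x <- .split1(seq_a); y <- .split1(seq_b)
  if (length(x) != length(y)) stop("sequences differ in length", call. = FALSE)
  ct <- .pair_counts(x, y)
  f <- ct$freq  # A C G T
  gA <- f[1]; gC <- f[2]; gG <- f[3]; gT <- f[4]
  gR <- gA + gG; gY <- gC + gT
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  w1 <- 1 - ct$P1 / k1 - ct$Q / (2 * gR)
  w2 <- 1 - ct$P2 / k2 - ct$Q / (2 * gY)
  w3 <- 1 - ct$Q / (2 * gR * gY)
  if (any(c(w1, w2, w3) <= 0))
    stop("TN93 distance undefined (saturation)", call. = FALSE)
  -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
}

#' Pairwise distance matrix of an alignment
#'
#' @param aln named character vector of equal-length aligned sequences
#'   (>= 3 taxa for subsequent tree building).
#' @param model `"k2p"` or `"tn93"`.
#' @return symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
distance_matrix <- function(aln, model = c("k2p", "tn93")) {
  model <- match.arg(model)
  fn <- if (model == "k2p") k2p_distance else tn93_distance
  taxa <- names(aln)
  stopifnot(!is.null(taxa), length(unique(nchar(aln))) == 1L)
  n <- length(aln)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- fn(aln[[i]], aln[[j]])
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor-joining (via \pkg{ape}); negative branch lengths are
#' clamped to zero, with the clamped edges recorded in the
#' `"clamped_edges"` attribute.
#'
#' @param d symmetric distance matrix with taxa dimnames.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  stopifnot(nrow(d) >= 3L, isTRUE(all.equal(d, t(d))), all(is.finite(d)))
  tr <- ape::nj(as.dist(d))
  neg <- which(tr$edge.length < 0)
  if (length(neg)) tr$edge.length[neg] <- 0
  attr(tr, "clamped_edges") <- neg
  tr
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate and reports, for each internal edge of the point-estimate tree,
#' the percentage of replicates containing the same bipartition. Fully
#' seeded and reproducible. Replicates whose resampled columns yield a
#' saturated (undefined) distance are skipped and excluded from the
#' denominator; their count is recorded in the `"failed_replicates"`
#' attribute.
#'
#' @param aln named character vector of aligned sequences.
#' @param model `"k2p"` or `"tn93"`.
#' @param replicates number of bootstrap replicates.
#' @param seed RNG seed.
#' @return the NJ tree with per-internal-node support (0-100) in
#'   `node.label`.
#' @export
bootstrap_support <- function(aln, model = "k2p", replicates = 500L,
                              seed = 1L) {
  stopifnot(replicates >= 1L)
  mat <- do.call(rbind, lapply(aln, .split1))
  rownames(mat) <- names(aln)
  build <- function(m) {
    seqs <- apply(m, 1L, paste, collapse = "")
    nj_tree(distance_matrix(seqs, model))
  }
  ref <- build(mat)
  set.seed(seed)
  boots <- vector("list", replicates)
  failed <- 0L
  for (b in seq_len(replicates)) {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    boots[[b]] <- tryCatch(build(mat[, cols, drop = FALSE]),
                           error = function(e) NULL)
    if (is.null(boots[[b]])) failed <- failed + 1L
  }
  boots <- Filter(Negate(is.null), boots)
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / length(boots), 1)
  ref$node.label <- as.character(support)
  attr(ref, "failed_replicates") <- failed
  ref
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric bipartition distance (number of internal bipartitions present
#' in exactly one of the two unrooted trees).
#'
#' @param t1,t2 `phylo` trees over the same taxon set.
#' @return integer distance; 0 means identical topologies.
#' @export
robinson_foulds <- function(t1, t2) {
  as.integer(phangorn::RF.dist(t1, t2, check.labels = TRUE))
}
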