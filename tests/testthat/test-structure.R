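test_that("a small self dot-plot enumerates exactly the matching windows", {
  dp <- dotplot("ACGTACGT", "ACGTACGT", dotplot_params(window = 4))
  # window=4: starts 0..4; diagonal 5 dots + (0,4),(4,0)
  expect_identical(nrow(dp$dots), 7L)
  expect_true(all(dp$dots$i[dp$dots$i == dp$dots$j] == 0:4))
  off <- dp$dots[dp$dots$i != dp$dots$j, c("i", "j")]
  expect_identical(unname(as.matrix(off)), matrix(c(0L, 4L, 4L, 0L), 2,
                                                  byrow = TRUE))
  # self-plot symmetry and full main diagonal
  expect_true(all(paste(dp$dots$j, dp$dots$i) %in%
                    paste(dp$dots$i, dp$dots$j)))
})

test_that("dot-plots equal the brute-force all-window-pairs oracle", {
  set.seed(41)
  for (k in 1:6) {
    w <- sample(c(6L, 8L, 11L), 1)
    mm <- sample(0:1, 1)
    a <- rand_seq(sample(60:120, 1))
    b <- if (k %% 2) a else rand_seq(sample(60:120, 1))
    dp <- dotplot(a, b, dotplot_params(window = w, max_mismatch = mm))
    want <- brute_dotplot(a, b, w, mm)
    got <- dp$dots[dp$dots$strand == "+", c("i", "j")]
    expect_identical(got[order(got$i, got$j), , drop = FALSE][, 1:2],
                     want[order(want$i, want$j), , drop = FALSE],
                     ignore_attr = TRUE)
  }
})

test_that("minus-strand dots report forward coordinates of the reverse match", {
  a <- "AAAACGTAAAA"
  b <- paste0("GGGG", revcomp("AACGTA"), "GGGG")
  dp <- dotplot(a, b, dotplot_params(window = 6, max_mismatch = 0,
                                     both_strands = TRUE))
  minus <- dp$dots[dp$dots$strand == "-", ]
  expect_gt(nrow(minus), 0)
  w <- 6L
  for (r in seq_len(nrow(minus))) {
    win_a <- substr(a, minus$i[r] + 1, minus$i[r] + w)
    win_b <- substr(b, minus$j[r] + 1, minus$j[r] + w)
    expect_identical(win_a, revcomp(win_b))
  }
})

test_that("an empty window warning yields an empty plot", {
  expect_warning(dp <- dotplot("ACGT", "ACGT", dotplot_params(window = 10)),
                 "window")
  expect_identical(nrow(dp$dots), 0L)
})

test_that("planted duplications are called as repeat segments", {
  set.seed(43)
  unit <- rand_seq(500)
  s <- paste0(rand_seq(800), unit, rand_seq(1200), unit, rand_seq(400))
  dp <- dotplot(s, s, dotplot_params(window = 11, max_mismatch = 0))
  segs <- call_repeat_segments(dp, min_segment = 300, gap = 2)
  expect_identical(nrow(segs), 1L)
  expect_lte(abs(segs$length - 500), 11)
  expect_equal(segs$a_start, 800, tolerance = 12)
  expect_equal(segs$b_start, 800 + 500 + 1200, tolerance = 12)
  # a plot with no off-diagonal dots yields no segments
  set.seed(44)
  r <- rand_seq(300)
  dp0 <- dotplot(r, r, dotplot_params(window = 11))
  expect_identical(nrow(call_repeat_segments(dp0, min_segment = 50)), 0L)
})

test_that("synteny blocks follow order and orientation of shared anchors", {
  a <- data.frame(gene = c("ZNF680", "ZNF736", "TRIM60P"),
                  strand = c("+", "+", "+"))
  b <- data.frame(gene = c("ZNF680", "ZNF736"), strand = c("+", "+"))
  blk <- synteny_blocks(a, b)
  expect_identical(nrow(blk), 1L)
  expect_identical(blk$orientation, "forward")
  expect_identical(blk$n_anchors, 2L)
  # reversed with flipped strands: one inverted block
  b2 <- data.frame(gene = c("ZNF736", "ZNF680"), strand = c("-", "-"))
  blk2 <- synteny_blocks(a, b2)
  expect_identical(nrow(blk2), 1L)
  expect_identical(blk2$orientation, "inverted")
  expect_identical(blk2$n_anchors, 2L)
  # self comparison: one forward block over everything
  blk3 <- synteny_blocks(a, a)
  expect_identical(nrow(blk3), 1L)
  expect_identical(blk3$n_anchors, nrow(a))
  # pseudogene suffix normalization is opt-in
  b4 <- data.frame(gene = c("ZNF680", "ZNF736", "TRIM60"),
                   strand = c("+", "+", "+"))
  expect_identical(synteny_blocks(a, b4)$n_anchors, 2L)
  expect_identical(synteny_blocks(a, b4, normalize_pseudogene = TRUE)$n_anchors,
                   3L)
})

test_that("block partition matches a brute-force maximal-run oracle", {
  brute_blocks <- function(a, b) {
    na <- toupper(a$gene); nb <- toupper(b$gene)
    ia <- which(na %in% nb)
    posb <- match(na[ia], nb)
    rel <- a$strand[ia] == b$strand[posb]
    n <- length(ia)
    if (n == 0) return(integer(0))
    cut <- logical(n)            # TRUE -> new block starts at k
    cut[1] <- TRUE
    for (k in seq_len(n)[-1]) {
      s <- max(which(cut[seq_len(k - 1)]))
      dir <- if (rel[s]) 1 else -1
      cut[k] <- !(rel[k] == rel[s] && sign(posb[k] - posb[k - 1]) == dir)
    }
    cumsum(cut)                  # block id per shared anchor
  }
  set.seed(47)
  for (k in 1:15) {
    n <- sample(4:10, 1)
    genes <- paste0("G", 1:n)
    a <- data.frame(gene = genes,
                    strand = sample(c("+", "-"), n, replace = TRUE))
    b <- data.frame(gene = sample(genes),
                    strand = sample(c("+", "-"), n, replace = TRUE))
    blk <- synteny_blocks(a, b)
    ids <- brute_blocks(a, b)
    expect_identical(nrow(blk), max(ids))
    expect_identical(blk$n_anchors, as.integer(table(ids)[as.character(seq_len(max(ids)))]),
                     ignore_attr = TRUE)
  }
})
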