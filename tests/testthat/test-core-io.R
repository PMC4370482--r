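test_that("FASTA reading normalizes case and alphabet and enforces unique ids", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a first record", "acgt", ">b", "ACGUNRY"), p)
  recs <- read_fasta(p)
  expect_identical(as.vector(recs), c("ACGT", "ACGTNRY"))
  expect_identical(names(recs), c("a", "b"))
  expect_identical(attr(recs, "description")[1], "first record")

  empty <- withr::local_tempfile(fileext = ".fa")
  file.create(empty)
  expect_length(read_fasta(empty), 0L)

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "GG"), dup)
  expect_error(read_fasta(dup), "duplicate")
})

test_that("FASTA write/read round trip is identity on normalized records", {
  set.seed(42)
  seqs <- stats::setNames(vapply(1:5, function(i) rand_seq(30 + i), ""),
                          paste0("s", 1:5))
  attr(seqs, "description") <- c("", "x y", "", "", "z")
  p <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, p)
  back <- read_fasta(p)
  expect_identical(as.vector(back), as.vector(as.character(seqs)))
  expect_identical(names(back), names(seqs))
  expect_identical(attr(back, "description"), attr(seqs, "description"))
})

test_that("revcomp complements IUPAC codes and is an involution", {
  expect_identical(revcomp("AACG"), "CGTT")
  expect_identical(revcomp("N"), "N")
  expect_identical(revcomp("RY"), "RY")  # R->Y reversed
  set.seed(7)
  for (k in 1:20) {
    s <- rand_seq(sample(1:80, 1))
    expect_identical(revcomp(revcomp(s)), s)
  }
})

test_that("extract_interval obeys 0-based half-open bounds and strand", {
  expect_identical(extract_interval("ACGTT", 1, 4, "+"), "CGT")
  expect_identical(extract_interval("ACGTT", 1, 4, "-"), "ACG")
  expect_identical(extract_interval("ACGTT", 0, 5, "+"), "ACGTT")
  expect_error(extract_interval("ACGTT", 3, 9), "out of range")
  set.seed(11)
  for (k in 1:20) {
    s <- rand_seq(50)
    a <- sample(0:45, 1); b <- a + sample(1:(50 - a), 1)
    expect_identical(nchar(extract_interval(s, a, b)), b - a)
  }
})

test_that("artificial translation continues past stops and masks ambiguity", {
  expect_identical(translate_cds("ATGAAATAA"), "MK*")
  expect_identical(translate_cds("ATGTAAGGG"), "M*G")
  expect_identical(translate_cds("ATGANAGGG"), "MXG")
  expect_identical(translate_cds("ATGAAAC"), "MK")   # trailing nt dropped
  expect_identical(translate_cds("GATGAAA", frame = 1), "MK")
})

test_that("hit tables convert to 0-based half-open and round-trip", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q\ts1\t95.5\t120\t5\t1\t1\t120\t201\t320\t1e-30\t222",
               "q\ts2\t88.0\t90\t10\t0\t5\t94\t500\t411\t0.001\t99"), p)
  h <- read_hits_tabular(p)
  expect_identical(h$s_strand, c("+", "-"))
  expect_identical(h$s_start, c(200L, 410L))
  expect_identical(h$s_end, c(320L, 500L))
  expect_identical(h$q_start, c(0L, 4L))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tabular(h, p2)
  h2 <- read_hits_tabular(p2)
  expect_equal(h2, h)
  # original 1-based inclusive values are recoverable
  raw <- read.delim(p2, header = FALSE)
  expect_identical(as.integer(raw$V9), c(201L, 500L))
  expect_identical(as.integer(raw$V10), c(320L, 411L))

  bad <- withr::local_tempfile()
  writeLines("a\tb\tc", bad)
  expect_error(read_hits_tabular(bad), "line 1")
})

test_that("gene models validate exon structure and splice the CDS", {
  gm <- gene_model("g", "chr1", "+", c(0, 20), c(9, 32))
  genome <- c(chr1 = paste0("ATGAAAGGG", strrep("T", 11), "CCCGGGAAATAA",
                            "TTTT"))
  expect_identical(spliced_cds(gm, genome), "ATGAAAGGGCCCGGGAAATAA")
  expect_identical(exon_lengths(gm), c(9L, 12L))
  expect_error(gene_model("g", "c", "+", c(0, 5), c(6, 10)), "overlap")
  # minus strand: transcription order is descending coordinates
  gmm <- gene_model("g2", "chr1", "-", c(20, 0), c(32, 9))
  expect_identical(
    spliced_cds(gmm, genome),
    paste0(revcomp("CCCGGGAAATAA"), revcomp("ATGAAAGGG")))
})

test_that("GFF3 exon write/read round-trips gene models", {
  gm <- gene_model("vcy2like", "regionA", "+", c(10, 60, 120), c(40, 90, 150))
  p <- withr::local_tempfile(fileext = ".gff3")
  write_gff_exons(gm, p)
  back <- read_gff_exons(p, "vcy2like")
  expect_identical(back$exons, gm$exons)
  expect_identical(back$strand, gm$strand)
  expect_identical(back$cds_phase, gm$cds_phase)
  expect_error(read_gff_exons(p, "nope"), "not found")
  # minus strand round trip preserves transcription order
  gmm <- gene_model("mg", "regionB", "-", c(120, 60), c(150, 90))
  p2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff_exons(gmm, p2)
  backm <- read_gff_exons(p2, "mg")
  expect_identical(backm$exons, gmm$exons)
  expect_identical(backm$strand, "-")
})
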