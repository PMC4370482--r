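small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, tree = DEMO_TREE,
             exon_lengths = c(90L, 120L, 90L, 60L),
             intron_lengths = c(100L, 100L, 100L),
             flank_lengths = c(60L, 60L), ...)
}

test_that("the ancestral locus is a clean multi-exon ORF, reproducibly", {
  cfg <- small_cfg()
  l1 <- make_ancestral_locus(cfg)
  l2 <- make_ancestral_locus(cfg)
  expect_identical(l1$genomic_seq, l2$genomic_seq)
  expect_identical(spliced_cds(l1$gene_model, l1$genomic_seq), l1$cds)
  aa <- translate_cds(l1$cds)
  expect_match(aa, "^M[^*]*\\*$")
  # many random loci all satisfy the no-internal-stop invariant
  for (seed in 1:200) {
    cds <- make_ancestral_locus(small_cfg(seed))$cds
    expect_match(translate_cds(cds), "^M[^*]*\\*$")
  }
})

test_that("planting disablers makes minimal recorded edits", {
  cfg <- small_cfg(2)
  locus <- make_ancestral_locus(cfg)
  plant <- data.frame(
    type = c("START_LOSS", "PREMATURE_STOP_SUBSTITUTION", "FRAMESHIFT_INDEL",
             "STOP_LOSS"),
    exon = c(1L, 2L, 3L, 4L), offset = c(NA, 120L, 220L, NA),
    indel_len = c(NA, NA, -2L, NA))
  dis <- disable_locus(locus, plant, seed = 4)
  tr <- dis$copy$planted
  expect_identical(nrow(tr), 4L)
  expect_identical(tr$type, plant$type)
  cds <- paste(vapply(dis$copy$segs, function(s)
    if (s$kind == "exon") paste(s$chars, collapse = "") else "", ""),
    collapse = "")
  expect_false(substr(cds, 1, 3) == "ATG")
  expect_identical(substr(cds, 121, 123), tr$obs[2])
  expect_true(tr$obs[2] %in% c("TAA", "TAG", "TGA"))
  expect_identical(nchar(cds), nchar(locus$cds) - 2L)
  # scanning the undiverged disabled CDS recovers the planted set exactly
  r <- scan_disablers(locus$cds, cds, exon_lens = cfg$exon_lengths)
  got <- r$disablers[r$disablers$type != "PREMATURE_STOP_FRAMESHIFT", ]
  subs <- tr$type != "FRAMESHIFT_INDEL"
  expect_setequal(paste(got$type[got$type != "FRAMESHIFT_INDEL"],
                        got$ref_nt_offset[got$type != "FRAMESHIFT_INDEL"]),
                  paste(tr$type[subs], tr$cds_offset[subs]))
  # the frameshift is recovered; the aligner may slide the gap within
  # repeated context, so its offset is checked with a small tolerance
  fs <- got[got$type == "FRAMESHIFT_INDEL", ]
  expect_identical(nrow(fs), 1L)
  expect_identical(fs$indel_len, tr$indel_len[3])
  expect_lte(abs(fs$ref_nt_offset - tr$cds_offset[3]), 3L)
  # empty plant spec leaves the locus unchanged
  dis0 <- disable_locus(make_ancestral_locus(cfg), plant[0, ], seed = 1)
  expect_identical(spliced_cds(dis0$gene_model, dis0$genomic_seq), locus$cds)
  # collision is a config error
  expect_error(
    disable_locus(locus, data.frame(type = rep("PREMATURE_STOP_SUBSTITUTION", 2),
                                    exon = 2L, offset = 120L), seed = 1),
    "collides")
})

test_that("zero branch lengths leave every leaf identical to the root", {
  cfg <- small_cfg(3)
  cfg$tree$edge.length[] <- 0
  locus <- make_ancestral_locus(cfg)
  sim <- evolve(locus, cfg)
  for (leaf in names(sim$leaves)) {
    s <- copy_sequence(sim$leaves[[leaf]]$autosome[[1]])$seq[[1]]
    expect_identical(s, unname(locus$genomic_seq))
  }
})

test_that("simulated divergence matches the K2P expectation", {
  # two taxa at total path length 0.2; distance estimates are unbiased
  est <- vapply(1:20, function(seed) {
    cfg <- sim_config(seed = seed, tree = "(A:0.1,B:0.1);",
                      exon_lengths = 4500L, intron_lengths = integer(0),
                      flank_lengths = c(0L, 0L))
    sim <- evolve(make_ancestral_locus(cfg), cfg)
    k2p_distance(copy_sequence(sim$leaves$A$autosome[[1]])$seq[[1]],
                 copy_sequence(sim$leaves$B$autosome[[1]])$seq[[1]])
  }, 0)
  expect_lt(abs(mean(est) - 0.2), 0.01)
})

test_that("indels occur, never straddle exon boundaries, and are bounded", {
  cfg <- small_cfg(4, indel_rate = 0.02, indel_max = 5L)
  locus <- make_ancestral_locus(cfg)
  sim <- evolve(locus, cfg)
  lens <- integer(0)
  for (leaf in names(sim$leaves)) {
    cp <- sim$leaves[[leaf]]$autosome[[1]]
    for (s in cp$segs) {
      if (s$kind == "exon") {
        # ancestral offsets within an exon stay within that exon's range
        anc <- s$anc[!is.na(s$anc)]
        expect_true(all(diff(anc) > 0))
      }
      lens <- c(lens, length(s$chars))
    }
  }
  expect_false(all(lens == rep(vapply(locus$copy$segs, function(s)
    length(s$chars), 0L), length(sim$leaves))))
})

test_that("transposition, duplication and enabling produce the planned copies", {
  plant <- data.frame(type = "PREMATURE_STOP_SUBSTITUTION", exon = 1L,
                      offset = 42L)
  cfg <- small_cfg(5, plant = cbind(plant, branch = "root",
                                    compartment = "autosome"),
                   enable_branch = "Gogo,Hosa,Patr",
                   enable_compartment = "chrY",
                   transpositions = data.frame(branch = "Gogo,Hosa,Mamu,Patr",
                                               from = "autosome", to = "chrY",
                                               inverted = TRUE),
                   duplications = data.frame(branch = "Mamu",
                                             compartment = "chrY",
                                             copies = 2L))
  locus <- make_ancestral_locus(cfg)
  locus <- disable_locus(locus, cfg$plant, seed = 11)
  sim <- evolve(locus, cfg)
  expect_null(sim$leaves$Caja$chrY)       # no Y copy in the outgroup
  expect_length(sim$leaves$Mamu$chrY, 3L) # transposed + 2 tandem copies
  expect_length(sim$leaves$Hosa$chrY, 1L)
  # inverted transposition: emitted Y copies are minus-strand gene models
  ycs <- copy_sequence(sim$leaves$Mamu$chrY[[1]])
  expect_identical(ycs$gene_model$strand, "-")
  # enabled ape Y copies are coding; monkey Y copy retains the disabler
  for (leaf in c("Hosa", "Patr", "Gogo")) {
    cp <- sim$leaves[[leaf]]$chrY[[1]]
    expect_true(cp$enabled)
    cs <- copy_sequence(cp)
    cds <- spliced_cds(cs$gene_model, cs$seq)
    expect_match(translate_cds(cds), "^M[^*]*\\*$")
  }
  mam <- copy_sequence(sim$leaves$Mamu$chrY[[1]])
  mam_cds <- spliced_cds(mam$gene_model, mam$seq)
  r <- scan_disablers(locus$cds, mam_cds, exon_lens = cfg$exon_lengths)
  expect_true(any(r$disablers$type == "PREMATURE_STOP_SUBSTITUTION" &
                    r$disablers$ref_nt_offset == 42L))
  # truth table counts planted rows per surviving copy
  expect_identical(sum(sim$truth$leaf == "Mamu" &
                         sim$truth$compartment == "chrY"), 3L)
  expect_true(all(!sim$truth$present[sim$truth$leaf == "Hosa" &
                                       sim$truth$compartment == "chrY"]))
})

test_that("emitted files are reproducible and GFF round-trips gene models", {
  cfg <- small_cfg(6)
  locus <- make_ancestral_locus(cfg)
  sim <- evolve(locus, cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- emit(sim, d1)
  sim2 <- evolve(make_ancestral_locus(cfg), cfg)
  p2 <- emit(sim2, d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
  }
  # GFF annotations parse back into the emitted exon structures
  fa <- read_fasta(file.path(d1, "Caja_autosome.fa"))
  gm <- read_gff_exons(file.path(d1, "annotations.gff3"),
                       "Caja|autosome|copy1")
  cds <- spliced_cds(gm, stats::setNames(fa[[1]], "Caja|autosome|copy1"))
  want <- copy_sequence(sim$leaves$Caja$autosome[[1]],
                        gene_id = "Caja|autosome|copy1",
                        seq_id = "Caja|autosome|copy1")
  expect_identical(cds, spliced_cds(want$gene_model, want$seq))
})
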