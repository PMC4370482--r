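# A clean 60-codon reference CDS used across the scanner tests.
make_ref_cds <- function(seed = 1, n_codon = 60) {
  set.seed(seed)
  sense <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                     c("A","C","G","T"))[, 3:1], 1,
                         paste, collapse = ""),
                   c("TAA", "TAG", "TGA"))
  paste(c("ATG", sample(sense, n_codon - 2, replace = TRUE), "TAA"),
        collapse = "")
}

sub_at <- function(seq, at, repl) {
  substr(seq, at, at + nchar(repl) - 1L) <- repl
  seq
}

test_that("scanning a sequence against itself reports no disablers", {
  for (seed in 1:3) {
    ref <- make_ref_cds(seed)
    r <- scan_disablers(ref, ref)
    expect_identical(nrow(r$disablers), 0L)
    expect_true(r$is_coding)
    # artificial translation of an intact ORF: starts M, single terminal stop
    expect_match(r$translation, "^M[^*]*\\*$")
  }
})

test_that("start and stop codon replacements are called as in decayed homologs", {
  ref <- make_ref_cds(2)
  # ATG replaced by ATA or GTG; terminal stop replaced by AAA
  for (startrep in c("ATA", "ATT", "GTG")) {
    r <- scan_disablers(ref, sub_at(ref, 1, startrep))
    expect_identical(r$disablers$type, "START_LOSS")
    expect_identical(r$disablers$ref_nt_offset, 0L)
    expect_identical(r$disablers$obs, startrep)
  }
  r2 <- scan_disablers(ref, sub_at(ref, nchar(ref) - 2, "AAA"))
  expect_identical(r2$disablers$type, "STOP_LOSS")
  expect_identical(r2$disablers$obs, "AAA")
  expect_identical(r2$disablers$ref_nt_offset, nchar(ref) - 3L)
})

test_that("a premature stop by substitution is reported at its codon offset", {
  ref <- make_ref_cds(3)
  # mutate codon 15 (offset 42) to TAA and codon 28 (offset 81) to TGA
  hom <- sub_at(sub_at(ref, 43, "TAA"), 82, "TGA")
  r <- scan_disablers(ref, hom)
  expect_identical(r$disablers$type,
                   rep("PREMATURE_STOP_SUBSTITUTION", 2))
  expect_identical(r$disablers$ref_nt_offset, c(42L, 81L))
  # verified independently: translating the homolog shows stops at aa 15, 28
  aa <- translate_cds(hom)
  expect_identical(substr(aa, 15, 15), "*")
  expect_identical(substr(aa, 28, 28), "*")
  expect_false(r$is_coding)
})

test_that("frameshifts are called with shifted-frame stops tracked downstream", {
  ref <- make_ref_cds(4)
  # 2-nt deletion at codon 11 (offset 30)
  hom <- paste0(substr(ref, 1, 30), substr(ref, 33, nchar(ref)))
  r <- scan_disablers(ref, hom)
  fs <- r$disablers[r$disablers$type == "FRAMESHIFT_INDEL", ]
  expect_identical(nrow(fs), 1L)
  expect_identical(fs$indel_len, -2L)
  expect_identical(fs$indel_len %% 3L == 0L, FALSE)
  # every reported shifted-frame stop is verified by translating the homolog
  ps <- r$disablers[r$disablers$type == "PREMATURE_STOP_FRAMESHIFT", ]
  aa <- translate_cds(hom)
  stop_starts <- 3L * (which(chars(aa) == "*") - 1L)  # nt offsets in hom
  # the reference terminal stop maps to hom offset L-5 after the -2 shift
  expect_identical(nrow(ps), sum(stop_starts < nchar(ref) - 5L))
  expect_true(all(ps$obs %in% c("TAA", "TAG", "TGA")))
  # in-frame (3n) indels are notes, not disablers
  hom3 <- paste0(substr(ref, 1, 30), substr(ref, 34, nchar(ref)))
  r3 <- scan_disablers(ref, hom3)
  expect_false("FRAMESHIFT_INDEL" %in% r3$disablers$type)
  expect_true(any(grepl("in-frame 3-nt deletion", r3$notes)))
})

test_that("a 4-nt insertion is a frameshift disabler at the insertion point", {
  ref <- make_ref_cds(5)
  hom <- paste0(substr(ref, 1, 45), "TTTT", substr(ref, 46, nchar(ref)))
  r <- scan_disablers(ref, hom)
  fs <- r$disablers[r$disablers$type == "FRAMESHIFT_INDEL", ]
  expect_identical(nrow(fs), 1L)
  expect_identical(fs$indel_len, 4L)
  expect_identical(fs$obs, "TTTT")
})

test_that("frame bookkeeping only calls substitutions in net-frame-0 context", {
  ref <- make_ref_cds(6)
  # +1 then -1 indel restores frame; plant a TAA after the second indel
  hom <- paste0(substr(ref, 1, 21), "G", substr(ref, 22, 60),
                substr(ref, 62, nchar(ref)))
  hom <- sub_at(hom, 91, "TAA")   # codon 31 region, net frame 0 again
  r <- scan_disablers(ref, hom)
  subs <- r$disablers[r$disablers$type == "PREMATURE_STOP_SUBSTITUTION", ]
  expect_identical(nrow(subs), 1L)
  expect_identical(subs$ref_nt_offset %% 3L, 0L)
  # between the indels (net frame +1) no substitution-type stop is called
  mid <- r$disablers$ref_nt_offset > 21 & r$disablers$ref_nt_offset < 60 &
    r$disablers$type == "PREMATURE_STOP_SUBSTITUTION"
  expect_false(any(mid))
})

test_that("enabler scanning inverts planted disablement one-to-one", {
  cfg <- sim_config(seed = 3, tree = DEMO_TREE,
                    exon_lengths = c(90L, 120L, 90L, 60L),
                    intron_lengths = c(100L, 100L, 100L),
                    flank_lengths = c(50L, 50L))
  locus <- make_ancestral_locus(cfg)
  plant <- data.frame(type = c("START_LOSS", "PREMATURE_STOP_SUBSTITUTION",
                               "STOP_LOSS"),
                      exon = c(1L, 2L, 4L), offset = c(0L, 99L, NA))
  dis <- disable_locus(locus, plant, seed = 9)
  nc_cds <- paste(vapply(dis$copy$segs, function(s)
    if (s$kind == "exon") paste(s$chars, collapse = "") else "", ""),
    collapse = "")
  er <- scan_enablers(nc_cds, locus$cds)
  expect_identical(nrow(er$enablers), nrow(plant))
  expect_identical(sort(er$enablers$ref_nt_offset),
                   sort(dis$copy$planted$cds_offset))
  expect_identical(sort(er$enablers$type), sort(dis$copy$planted$type))
  expect_identical(nrow(er$residual$disablers), 0L)
  # identical sequences: empty report
  er0 <- scan_enablers(locus$cds, locus$cds)
  expect_identical(nrow(er0$enablers), 0L)
})

test_that("alignment rendering is deterministic and marks each disabler once", {
  ref <- make_ref_cds(7)
  hom <- sub_at(sub_at(ref, 1, "GTG"), 31, "TAG")
  r <- scan_disablers(ref, hom)
  txt1 <- render_alignment(r, width = 60)
  txt2 <- render_alignment(r, width = 60)
  expect_identical(txt1, txt2)
  marks <- sum(vapply(gregexpr("\\^", txt1), function(g)
    sum(g > 0), 0L))
  expect_identical(marks, nrow(r$disablers))
  # the start-loss column is marked in the first block
  expect_match(txt1[3], "^ref aa")
})
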