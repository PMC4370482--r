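mk_report <- function(types, offsets) {
  data.frame(type = as.character(types), exon_index = rep(1L, length(types)),
             ref_nt_offset = as.integer(offsets),
             ref_codon = rep("NNN", length(types)),
             obs = rep("NNN", length(types)),
             indel_len = rep(NA_integer_, length(types)),
             note = rep("", length(types)), stringsAsFactors = FALSE)
}

test_that("shared-disabler matrix matches presence patterns across taxa", {
  a <- mk_report(c("START_LOSS", "PREMATURE_STOP_SUBSTITUTION"), c(0, 42))
  b <- mk_report(c("START_LOSS", "PREMATURE_STOP_SUBSTITUTION"), c(0, 42))
  m <- build_shared_matrix(list(A = a, B = b))
  expect_identical(dim(m$matrix), c(2L, 2L))
  expect_true(all(m$matrix == "present"))
  expect_true(all(m$ancestral_candidate))
  # disabler in one taxon only
  m2 <- build_shared_matrix(list(A = mk_report("START_LOSS", 0),
                                 B = mk_report("STOP_LOSS", 87)))
  expect_identical(sort(as.vector(m2$matrix)),
                   c("absent", "absent", "present", "present"))
  expect_false(any(m2$ancestral_candidate))
  # unknown column does not veto ancestral candidacy
  m3 <- build_shared_matrix(list(A = a, B = b, C = NULL))
  expect_true(all(m3$matrix[, "C"] == "unknown"))
  expect_true(all(m3$ancestral_candidate))
})

test_that("shared matrix equals a brute-force pairwise matching oracle", {
  set.seed(31)
  types <- c("START_LOSS", "STOP_LOSS", "PREMATURE_STOP_SUBSTITUTION")
  for (k in 1:10) {
    taxa <- paste0("t", 1:3)
    reps <- lapply(taxa, function(t) {
      n <- sample(0:4, 1)
      mk_report(sample(types, n, replace = TRUE),
                sample(seq(0, 60, by = 3), n))
    })
    names(reps) <- taxa
    m <- build_shared_matrix(reps)
    # oracle: the set of distinct (type, offset) keys, with per-taxon presence
    keys <- unique(do.call(rbind, lapply(reps, function(r)
      r[, c("type", "ref_nt_offset")])))
    expect_identical(nrow(m$keys), nrow(keys))
    for (r in seq_len(nrow(m$keys))) for (t in taxa) {
      want <- any(reps[[t]]$type == m$keys$type[r] &
                    reps[[t]]$ref_nt_offset == m$keys$ref_nt_offset[r])
      expect_identical(unname(m$matrix[r, t] == "present"), want)
    }
    expect_identical(m$ancestral_candidate,
                     apply(m$matrix, 1, function(row) all(row == "present")))
  }
})

test_that("tolerant matching merges nearby offsets of the same type", {
  m <- build_shared_matrix(list(A = mk_report("PREMATURE_STOP_SUBSTITUTION", 42),
                                B = mk_report("PREMATURE_STOP_SUBSTITUTION", 44)),
                           tolerance = 3L)
  expect_identical(nrow(m$keys), 1L)
  expect_true(all(m$matrix == "present"))
})

test_that("all-leaves-equal character needs no events; an ape-stem gain scores 1", {
  st_nc <- data.frame(taxon = c("Hosa", "Patr", "Gogo", "Mamu", "Caja"),
                      coding_ability = "non_coding")
  rec <- infer_ancestral_state(DEMO_TREE, st_nc)
  expect_identical(rec$parsimony_score, 0L)
  expect_identical(nrow(rec$events), 0L)
  st <- st_nc
  st$coding_ability <- c("coding", "coding", "coding", "non_coding",
                         "non_coding")
  rec2 <- infer_ancestral_state(DEMO_TREE, st)
  expect_identical(rec2$parsimony_score, 1L)
  expect_identical(rec2$events$event, "gain_coding")
  expect_identical(rec2$events$branch, "Gogo,Hosa,Patr")
  expect_length(rec2$solutions, 1L)
  expect_error(infer_ancestral_state(DEMO_TREE,
                                     data.frame(taxon = "Hosa",
                                                coding_ability = "coding")),
               "at least two")
})

test_that("parsimony scores equal exhaustive minimization on random trees", {
  set.seed(77)
  for (k in 1:30) {
    n <- sample(4:6, 1)
    tr <- ape::rtree(n, rooted = TRUE)
    states <- sample(c("coding", "non_coding", "unknown"), n, replace = TRUE,
                     prob = c(0.4, 0.4, 0.2))
    if (sum(states != "unknown") < 2) states[1:2] <- c("coding", "non_coding")
    st <- data.frame(taxon = tr$tip.label, coding_ability = states)
    rec <- infer_ancestral_state(tr, st)
    want <- fitch_exhaustive_score(tr, stats::setNames(
      ifelse(states == "unknown", NA, states), tr$tip.label))
    expect_identical(rec$parsimony_score, as.integer(want))
    # every enumerated solution realizes the minimal score
    for (sol in rec$solutions)
      expect_identical(nrow(sol$events), as.integer(want))
  }
})

test_that("history summaries name every event exactly once", {
  st <- data.frame(taxon = c("Hosa", "Patr", "Gogo", "Mamu", "Caja"),
                   coding_ability = c("coding", "coding", "coding",
                                      "non_coding", "non_coding"))
  rec <- infer_ancestral_state(DEMO_TREE, st)
  lab <- c("Gogo,Hosa,Patr" = "after the ape-Old World monkey split")
  s <- summarize_history(rec, lab)
  expect_identical(s, "gain of coding ability after the ape-Old World monkey split")
  expect_length(s, nrow(rec$solutions[[1]]$events))
  rec0 <- infer_ancestral_state(
    DEMO_TREE, data.frame(taxon = c("Hosa", "Caja"),
                          coding_ability = "non_coding"))
  expect_identical(summarize_history(rec0), "no state changes inferred")
})
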