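# End-to-end orchestration: simulate a fully specified evolutionary
# scenario, then run every analysis stage over it (candidate filtering, ORF
# reconstruction, disabler scanning, cross-taxon comparison, tree building,
# dot-plot/synteny) and write a reproducible report. The packaged demo
# scenario mirrors a Y-transposed de novo gene history: an autosomal locus
# disabled in the common ancestor, transposed to the Y before the
# ape-monkey split, and re-enabled on the ape stem.

#' The packaged demo scenario configuration
#'
#' Five primate-like taxa (Hosa, Patr, Gogo, Mamu, Caja) on a fixed tree. A
#' ~4.4 kb four-exon locus is disabled at the root with four disablers
#' (start loss, stop loss, premature stops at CDS offsets 42 and 81),
#' transposed from autosome to Y on the ape+monkey stem, duplicated on the
#' Hosa terminal branch, and re-enabled on the ape stem. Substitution-only
#' divergence (the indel machinery is exercised separately).
#'
#' @param seed master seed.
#' @return a [sim_config()].
#' @export
demo_config <- function(seed = 1L) {
  tree <- "((((Hosa:0.01,Patr:0.01):0.005,Gogo:0.015):0.02,Mamu:0.035):0.01,Caja:0.045);"
  plant <- data.frame(
    branch = "root", compartment = "autosome",
    type = c("START_LOSS", "PREMATURE_STOP_SUBSTITUTION",
             "PREMATURE_STOP_SUBSTITUTION", "STOP_LOSS"),
    exon = c(1L, 1L, 1L, 4L),
    offset = c(0L, 42L, 81L, NA),
    stringsAsFactors = FALSE)
  sim_config(
    seed = seed, tree = tree, kappa = 2,
    exon_lengths = c(90L, 120L, 90L, 60L),
    intron_lengths = c(1200L, 1200L, 1200L),
    flank_lengths = c(400L, 200L),
    indel_rate = 0,
    plant = plant,
    enable_branch = "Gogo,Hosa,Patr",
    enable_compartment = "chrY",
    transpositions = data.frame(branch = "Gogo,Hosa,Mamu,Patr",
                                from = "autosome", to = "chrY",
                                inverted = FALSE),
    duplications = data.frame(branch = "Hosa", compartment = "chrY",
                              copies = 1L))
}

# Demo gene-order lists for the synteny stage: two regions sharing anchors,
# with one inversion (synthetic labels styled after zinc-finger neighbors).
.demo_gene_lists <- function() {
  a <- data.frame(gene = c("ZNF680", "ZNF736", "TRIM60P", "HNRNPCP", "VN1RP"),
                  strand = c("+", "+", "+", "-", "+"))
  b <- data.frame(gene = c("ZNF680", "ZNF736", "HNRNPCP", "TRIM60P", "VN1RP"),
                  strand = c("+", "+", "+", "-", "+"))
  list(a = a, b = b)
}

#' Run the full analysis pipeline on a simulated scenario
#'
#' Executes, in dependency order: simulation (+ file emission), candidate
#' filtering (over hit tables derived from the simulated homologies), ORF
#' reconstruction and disabler scanning of every non-reference copy against
#' the reference (the first enabled Y copy), shared-disabler comparison and
#' parsimony event reconstruction, NJ tree with bootstrap, and dot-plot /
#' synteny structure analysis. A stage failure halts downstream stages.
#'
#' @param config a [sim_config()] describing the scenario.
#' @param outdir output directory.
#' @param stages character vector of stages to run (subset of
#'   `c("filter", "scan", "compare", "tree", "structure")`; simulation
#'   always runs).
#' @param bootstrap_replicates bootstrap replicates for the tree stage.
#' @param reference `"leaf|compartment|copy"` spec of the reference coding
#'   copy; default: first enabled copy found.
#' @return a `run_report`: per-stage status and timings, the output
#'   manifest, and the in-memory stage results.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("filter", "scan", "compare", "tree",
                                    "structure"),
                         bootstrap_replicates = 200L,
                         reference = NULL) {
  t_all <- proc.time()[["elapsed"]]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(stages = list(), manifest = character(0), results = list())
  note <- function(stage, status, t0, outputs = character(0)) {
    report$stages[[stage]] <<- list(
      status = status, elapsed = round(proc.time()[["elapsed"]] - t0, 2),
      outputs = outputs)
    report$manifest <<- c(report$manifest, outputs)
  }

  ## simulate -----------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  locus <- make_ancestral_locus(config)
  root_plants <- config$plant[config$plant$branch == "root", , drop = FALSE]
  if (!is.null(config$plant) && nrow(root_plants))
    locus <- disable_locus(locus, root_plants, seed = config$seed + 7L)
  sim <- evolve(locus, config)
  sim_paths <- emit(sim, file.path(outdir, "sim"))
  note("simulate", "ok", t0, unlist(sim_paths))
  report$results$sim <- sim

  ## locate the reference coding copy ------------------------------------
  ref <- NULL
  for (leaf in names(sim$leaves)) for (comp in names(sim$leaves[[leaf]]))
    for (k in seq_along(sim$leaves[[leaf]][[comp]])) {
      cp <- sim$leaves[[leaf]][[comp]][[k]]
      id <- sprintf("%s|%s|copy%d", leaf, comp, k)
      if (is.null(ref) && ((is.null(reference) && cp$enabled) ||
                           (!is.null(reference) && id == reference)))
        ref <- list(id = id, cp = cp, leaf = leaf, comp = comp)
    }
  if (is.null(ref)) stop("no enabled reference copy in the scenario",
                         call. = FALSE)
  ref_cs <- copy_sequence(ref$cp, gene_id = ref$id, seq_id = ref$id)
  ref_cds <- spliced_cds(ref_cs$gene_model, ref_cs$seq)

  leaf_seq <- function(leaf, comp, k = 1L) {
    copy_sequence(sim$leaves[[leaf]][[comp]][[k]],
                  gene_id = sprintf("%s|%s|copy%d", leaf, comp, k))$seq
  }

  ## filter --------------------------------------------------------------
  if ("filter" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    # genome-level hits of the reference locus against every other leaf
    # compartment, summarized from the known homology of the simulation
    hit_rows <- list()
    for (leaf in names(sim$leaves)) for (comp in names(sim$leaves[[leaf]])) {
      id <- sprintf("%s|%s|copy%d", leaf, comp, 1L)
      if (id == ref$id) next
      s <- leaf_seq(leaf, comp)
      n <- min(nchar(s), nchar(ref_cs$seq))
      ident <- 100 * mean(.split1(substr(ref_cs$seq, 1, n)) ==
                            .split1(substr(s, 1, n)))
      hit_rows[[id]] <- data.frame(
        query_id = ref$id, subject_id = id, pct_identity = round(ident, 2),
        align_length = n, mismatches = round(n * (1 - ident / 100)),
        gap_opens = 0L, q_start = 0L, q_end = n, s_start = 0L, s_end = n,
        e_value = 0, bit_score = 2 * n, s_strand = "+",
        stringsAsFactors = FALSE)
    }
    genome_hits <- do.call(rbind, hit_rows)
    subj_loc <- stats::setNames(
      ifelse(grepl("autosome", genome_hits$subject_id), "autosome", "chrY"),
      genome_hits$subject_id)
    verdict <- candidate_verdict(
      gene_id = ref$id,
      outgroup_protein_hits = genome_hits[0, , drop = FALSE],
      lineage_protein_hits = genome_hits[0, , drop = FALSE],
      genome_hits = genome_hits, subject_locations = subj_loc)
    vpath <- file.path(outdir, "candidate_verdict.tsv")
    utils::write.table(
      data.frame(gene_id = verdict$gene_id, verdict = verdict$verdict,
                 is_orphan = verdict$is_orphan,
                 has_coding_homolog = verdict$has_coding_homolog,
                 n_fragments = nrow(verdict$retained_fragments),
                 reason = verdict$reason),
      vpath, sep = "\t", quote = FALSE, row.names = FALSE)
    bpath <- file.path(outdir, "retained_fragments.bed")
    write_bed(data.frame(seq_id = verdict$retained_fragments$subject_id,
                         start = verdict$retained_fragments$s_start,
                         end = verdict$retained_fragments$s_end,
                         name = verdict$retained_fragments$query_id,
                         score = verdict$retained_fragments$pct_identity,
                         strand = verdict$retained_fragments$s_strand), bpath)
    note("filter", "ok", t0, c(vpath, bpath))
    report$results$verdict <- verdict
  }

  ## scan ----------------------------------------------------------------
  scans <- list()
  if ("scan" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    for (leaf in names(sim$leaves)) for (comp in names(sim$leaves[[leaf]])) {
      for (k in seq_along(sim$leaves[[leaf]][[comp]])) {
        id <- sprintf("%s|%s|copy%d", leaf, comp, k)
        if (id == ref$id) next
        cs <- copy_sequence(sim$leaves[[leaf]][[comp]][[k]],
                            gene_id = id, seq_id = id)
        orfs <- reconstruct_orfs(ref_cs$gene_model, ref_cs$seq, cs$seq[[1]])
        if (length(orfs) == 0L) next
        rep_k <- scan_disablers(ref_cds, orfs[[1]], orf_id = id)
        scans[[id]] <- rep_k
      }
    }
    dtab <- do.call(rbind, lapply(names(scans), function(id) {
      d <- scans[[id]]$disablers
      if (nrow(d) == 0L)
        return(data.frame(orf_id = id, type = "NONE", exon_index = NA,
                          ref_nt_offset = NA, ref_codon = "", obs = "",
                          indel_len = NA, note = "intact ORF"))
      cbind(orf_id = id, d)
    }))
    spath <- file.path(outdir, "disabler_reports.tsv")
    utils::write.table(dtab, spath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("scan", "ok", t0, spath)
    report$results$scans <- scans
  }

  ## compare -------------------------------------------------------------
  if ("compare" %in% stages && length(scans)) {
    t0 <- proc.time()[["elapsed"]]
    # shared-disabler analysis is over the non-coding ORFs: intact (coding)
    # homologs carry no disablers and would dilute the ancestral signal
    noncoding <- Filter(function(r) !r$is_coding, scans)
    mat <- build_shared_matrix(noncoding)
    mpath <- file.path(outdir, "shared_disablers.tsv")
    utils::write.table(cbind(mat$keys, as.data.frame(mat$matrix),
                             ancestral_candidate = mat$ancestral_candidate),
                       mpath, sep = "\t", quote = FALSE, row.names = FALSE)
    # per-species coding ability: Y copy where present, else autosome
    statuses <- NULL
    for (leaf in names(sim$leaves)) {
      comps <- sim$leaves[[leaf]]
      comp <- if ("chrY" %in% names(comps)) "chrY" else "autosome"
      id <- sprintf("%s|%s|copy%d", leaf, comp, 1L)
      coding <- if (id == ref$id) TRUE else
        if (!is.null(scans[[id]])) scans[[id]]$is_coding else NA
      statuses <- rbind(statuses, data.frame(
        taxon = leaf, compartment = comp,
        coding_ability = if (is.na(coding)) "unknown"
                         else if (coding) "coding" else "non_coding",
        evidence = id, stringsAsFactors = FALSE))
    }
    rec <- infer_ancestral_state(config$tree, statuses)
    epath <- file.path(outdir, "events.tsv")
    utils::write.table(rec$solutions[[1]]$events, epath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("compare", "ok", t0, c(mpath, epath))
    report$results$shared <- mat
    report$results$statuses <- statuses
    report$results$reconstruction <- rec
  }

  ## tree ----------------------------------------------------------------
  if ("tree" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    aln <- vapply(names(sim$leaves), function(leaf)
      leaf_seq(leaf, "autosome")[[1]], character(1))
    phy <- bootstrap_support(aln, model = "k2p",
                             replicates = bootstrap_replicates,
                             seed = config$seed + 11L)
    tpath <- file.path(outdir, "nj_tree.nwk")
    ape::write.tree(phy, tpath)
    note("tree", "ok", t0, tpath)
    report$results$tree <- phy
  }

  ## structure -----------------------------------------------------------
  if ("structure" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    # tandem duplication on the reference leaf's Y: self dot-plot of the
    # concatenated copies reveals the duplicated segment off-diagonal
    ycopies <- sim$leaves[[ref$leaf]][[ref$comp]]
    tandem <- paste(vapply(seq_along(ycopies), function(k)
      copy_sequence(ycopies[[k]])$seq[[1]], character(1)), collapse = "")
    dp <- dotplot(tandem, tandem,
                  dotplot_params(window = 14L, max_mismatch = 0L))
    segs <- call_repeat_segments(dp, min_segment = 100L, gap = 5L)
    dpath <- file.path(outdir, "dotplot_dots.tsv")
    utils::write.table(dp$dots, dpath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    gpath <- file.path(outdir, "repeat_segments.tsv")
    utils::write.table(segs, gpath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    gl <- .demo_gene_lists()
    blocks <- synteny_blocks(gl$a, gl$b)
    ypath <- file.path(outdir, "synteny_blocks.tsv")
    utils::write.table(blocks, ypath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("structure", "ok", t0, c(dpath, gpath, ypath))
    report$results$dotplot <- dp
    report$results$repeat_segments <- segs
    report$results$synteny <- blocks
  }

  report$elapsed <- round(proc.time()[["elapsed"]] - t_all, 2)
  report$reference <- ref$id
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report: reference", x$reference, "-", x$elapsed, "s total\n")
  for (s in names(x$stages))
    cat(sprintf("  %-10s %-4s %6.2fs  %d file(s)\n", s, x$stages[[s]]$status,
                x$stages[[s]]$elapsed, length(x$stages[[s]]$outputs)))
  invisible(x)
}

#' Run the packaged demo scenario end to end
#'
#' @param seed master seed.
#' @param outdir output directory (a temporary directory by default).
#' @return the `run_report`.
#' @export
demo_run <- function(seed = 1L, outdir = file.path(tempdir(), "orfdecay_demo")) {
  run_pipeline(demo_config(seed), outdir)
}
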