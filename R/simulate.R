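# Synthetic evolutionary scenarios with ground truth: an ancestral coding
# locus is disabled by planted ORF disruptions, evolves along a species tree
# under a K2P substitution process with optional indels, is transposed or
# duplicated between genomic compartments on designated branches, and is
# optionally re-enabled (coding ability restored) on one branch with
# purifying maintenance thereafter. Every event is recorded in a
# machine-readable truth table so the whole pipeline can be validated with
# no external data.
#
# Branches are named by their child clade's signature: the sorted,
# comma-joined tip labels below the branch (a bare tip label for terminal
# branches); the pre-tree ancestor is the pseudo-branch "root".

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulation configuration
#'
#' @param seed RNG seed (mandatory; every downstream draw derives from it).
#' @param tree Newick string or `phylo` with branch lengths in expected
#'   substitutions per site.
#' @param kappa transition/transversion rate ratio of the K2P process.
#' @param exon_lengths per-exon CDS lengths in bp (sum must be a multiple
#'   of 3).
#' @param intron_lengths intron lengths in bp (`n_exons - 1` values).
#' @param flank_lengths lengths of the 5' and 3' flanking sequence.
#' @param indel_rate indel events per site per unit branch length.
#' @param indel_geom_p geometric length parameter for indels.
#' @param indel_max maximum indel length.
#' @param plant data.frame of disablers to plant: columns `branch`
#'   (signature or `"root"`), `compartment`, `type` (a `DISABLER_TYPES`
#'   value), `exon` (1-based), `offset` (codon-start offset in the spliced
#'   CDS, `NA` = random within the exon), `indel_len` (frameshifts only).
#' @param enable_branch optional branch signature on which disablers are
#'   reverted and the ORF kept intact thereafter.
#' @param enable_compartment compartment whose copies are re-enabled.
#' @param transpositions data.frame: `branch`, `from`, `to`, `inverted`.
#' @param duplications data.frame: `branch`, `compartment`, `copies`
#'   (additional tandem copies created).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed, tree, kappa = 2, exon_lengths = c(90, 120, 90),
                       intron_lengths = NULL, flank_lengths = c(200L, 200L),
                       indel_rate = 0, indel_geom_p = 0.5, indel_max = 10L,
                       plant = NULL, enable_branch = NULL,
                       enable_compartment = "chrY",
                       transpositions = NULL, duplications = NULL) {
  stopifnot(!missing(seed), is.numeric(seed))
  phy <- if (is.character(tree)) ape::read.tree(text = tree) else tree
  stopifnot(inherits(phy, "phylo"), !is.null(phy$edge.length))
  if (is.null(intron_lengths))
    intron_lengths <- rep(150L, max(length(exon_lengths) - 1L, 0L))
  stopifnot(length(intron_lengths) == length(exon_lengths) - 1L,
            sum(exon_lengths) %% 3 == 0, sum(exon_lengths) >= 6)
  sigs <- c(.edge_signatures(phy), "root")
  check_branches <- function(df, what) {
    if (!is.null(df) && !all(df$branch %in% sigs))
      stop("unknown branch in ", what, ": ",
           paste(setdiff(df$branch, sigs), collapse = ", "), call. = FALSE)
  }
  check_branches(plant, "plant spec")
  check_branches(transpositions, "transpositions")
  check_branches(duplications, "duplications")
  if (!is.null(enable_branch) && !enable_branch %in% sigs)
    stop("unknown enable_branch: ", enable_branch, call. = FALSE)
  if (!is.null(plant)) {
    if (is.null(plant$compartment)) plant$compartment <- "autosome"
    if (is.null(plant$indel_len)) plant$indel_len <- NA_integer_
    if (is.null(plant$offset)) plant$offset <- NA_integer_
  }
  structure(list(seed = as.integer(seed), tree = phy, kappa = kappa,
                 exon_lengths = as.integer(exon_lengths),
                 intron_lengths = as.integer(intron_lengths),
                 flank_lengths = as.integer(flank_lengths),
                 indel_rate = indel_rate, indel_geom_p = indel_geom_p,
                 indel_max = as.integer(indel_max),
                 plant = plant, enable_branch = enable_branch,
                 enable_compartment = enable_compartment,
                 transpositions = transpositions,
                 duplications = duplications),
            class = "sim_config")
}

.sense_codons <- local({
  all3 <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                            c("A","C","G","T"), stringsAsFactors = FALSE)[, 3:1],
                1, paste, collapse = "")
  setdiff(all3, STOP_CODONS)
})

.rand_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

#' Generate the ancestral coding locus
#'
#' Builds a random multi-exon coding locus: the spliced CDS starts with ATG,
#' ends with a stop codon and contains no internal in-frame stop; exons are
#' separated by random introns and flanked by random sequence. Fully seeded.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_locus`: `copy` (internal copy object), `cds`
#'   (the ancestral spliced CDS), `exon_lengths`, `genomic_seq`,
#'   `gene_model` (exon coordinates on the ancestral genomic sequence).
#' @export
make_ancestral_locus <- function(config) {
  set.seed(config$seed)
  L <- sum(config$exon_lengths)
  n_codon <- L %/% 3L
  codons <- c("ATG", sample(.sense_codons, n_codon - 2L, replace = TRUE),
              sample(STOP_CODONS, 1L))
  cds <- paste(codons, collapse = "")
  cds_chars <- .split1(cds)
  segs <- list()
  segs[[length(segs) + 1L]] <- list(kind = "flank5",
                                    chars = .rand_bases(config$flank_lengths[1]))
  off <- 0L
  for (e in seq_along(config$exon_lengths)) {
    len <- config$exon_lengths[e]
    segs[[length(segs) + 1L]] <- list(
      kind = "exon", exon_index = e,
      chars = cds_chars[(off + 1L):(off + len)],
      anc = off:(off + len - 1L),
      origin = rep("anc", len))
    off <- off + len
    if (e < length(config$exon_lengths))
      segs[[length(segs) + 1L]] <- list(
        kind = "intron", chars = .rand_bases(config$intron_lengths[e]))
  }
  segs[[length(segs) + 1L]] <- list(kind = "flank3",
                                    chars = .rand_bases(config$flank_lengths[2]))
  # the root copy evolves neutrally; the ORF-integrity (purifying) rule only
  # applies to copies re-enabled via enable_branch
  copy <- list(segs = segs, orientation = "+", enabled = FALSE,
               created_on = "root",
               planted = .planted_empty())
  seq_full <- paste(vapply(segs, function(s) paste(s$chars, collapse = ""), ""),
                    collapse = "")
  lens <- vapply(segs, function(s) length(s$chars), 0L)
  starts <- cumsum(c(0L, lens[-length(lens)]))
  exon_idx <- which(vapply(segs, function(s) s$kind == "exon", TRUE))
  gm <- gene_model("ancestral", "ancestral_locus", "+",
                   starts[exon_idx], starts[exon_idx] + lens[exon_idx])
  structure(list(copy = copy, cds = cds,
                 exon_lengths = config$exon_lengths,
                 genomic_seq = stats::setNames(seq_full, "ancestral_locus"),
                 gene_model = gm),
            class = "sim_locus")
}

.planted_empty <- function() {
  data.frame(type = character(0), exon = integer(0), cds_offset = integer(0),
             orig = character(0), obs = character(0), indel_len = integer(0),
             branch = character(0), stringsAsFactors = FALSE)
}

# Locate the segment index and within-segment position of a CDS offset.
.cds_pos <- function(copy, cds_offset) {
  for (si in seq_along(copy$segs)) {
    s <- copy$segs[[si]]
    if (s$kind != "exon") next
    k <- which(!is.na(s$anc) & s$anc == cds_offset)
    if (length(k)) return(list(seg = si, pos = k[1]))
  }
  NULL
}

# Codon-start offsets in `exon` whose codon is one substitution away from a
# stop codon (candidate sites for planting a premature stop).
.stop_neighbors <- function(codon) {
  hits <- character(0)
  for (s in STOP_CODONS)
    if (sum(.split1(codon) != .split1(s)) == 1L) hits <- c(hits, s)
  hits
}

#' Plant disablers into a coding locus
#'
#' Applies each requested disabler by a minimal edit: a single substitution
#' for start-codon loss, stop-codon loss and premature stops; a single
#' short indel (length not a multiple of 3) for frameshifts. Offsets are
#' codon-start offsets in the spliced CDS; `NA` picks a random eligible
#' position within the requested exon. The exact edits are recorded as the
#' planted truth.
#'
#' @param locus a `sim_locus` from [make_ancestral_locus()] (or an internal
#'   copy object).
#' @param plant_spec data.frame with columns `type`, `exon`, `offset`,
#'   `indel_len` (see [sim_config()]).
#' @param seed RNG seed for the random choices.
#' @param branch provenance label recorded in the truth rows.
#' @return the locus with `copy` disabled and `copy$planted` filled in.
#' @export
disable_locus <- function(locus, plant_spec, seed = 1L, branch = "root") {
  set.seed(seed)
  is_locus <- inherits(locus, "sim_locus")
  copy <- if (is_locus) locus$copy else locus
  exon_lens <- vapply(copy$segs, function(s)
    if (s$kind == "exon") length(s$chars[s$origin == "anc"]) else 0L, 0L)
  exon_lens <- exon_lens[exon_lens > 0L]
  L <- sum(exon_lens)
  cum <- cumsum(c(0L, exon_lens))
  for (r in seq_len(nrow(plant_spec))) {
    type <- plant_spec$type[r]
    exon <- plant_spec$exon[r]
    offset <- plant_spec$offset[r]
    ilen <- if ("indel_len" %in% names(plant_spec)) plant_spec$indel_len[r]
            else NA_integer_
    if (type == "START_LOSS") offset <- 0L
    if (type == "STOP_LOSS") offset <- L - 3L
    if (is.na(offset)) {
      offset <- .pick_offset(copy, type, exon, cum, L)
    }
    if (offset %in% copy$planted$cds_offset)
      stop("planted disabler collides at offset ", offset, call. = FALSE)
    copy <- .apply_plant(copy, type, exon, offset, ilen, branch)
  }
  if (is_locus) { locus$copy <- copy; locus$copy$enabled <- FALSE; locus }
  else { copy$enabled <- FALSE; copy }
}

.pick_offset <- function(copy, type, exon, cum, L) {
  lo <- cum[exon]; hi <- cum[exon + 1L] - 1L
  starts <- seq.int(0L, L - 3L, by = 3L)
  starts <- starts[starts >= lo & starts + 2L <= hi & starts > 0L &
                     starts < L - 3L]
  starts <- setdiff(starts, copy$planted$cds_offset)
  if (type == "PREMATURE_STOP_SUBSTITUTION") {
    ok <- vapply(starts, function(o) {
      cd <- .codon_at(copy, o)
      length(.stop_neighbors(cd)) > 0L && !cd %in% STOP_CODONS
    }, TRUE)
    starts <- starts[ok]
  }
  if (length(starts) == 0L) stop("no eligible planting site in exon ", exon,
                                 call. = FALSE)
  sample(starts, 1L)
}

.codon_at <- function(copy, offset) {
  paste(vapply(offset + 0:2, function(o) {
    p <- .cds_pos(copy, o)
    copy$segs[[p$seg]]$chars[p$pos]
  }, ""), collapse = "")
}

.set_base <- function(copy, offset, base) {
  p <- .cds_pos(copy, offset)
  copy$segs[[p$seg]]$chars[p$pos] <- base
  copy
}

.apply_plant <- function(copy, type, exon, offset, ilen, branch) {
  orig <- ""; obs <- ""
  if (type %in% c("START_LOSS", "STOP_LOSS", "PREMATURE_STOP_SUBSTITUTION")) {
    codon <- .codon_at(copy, offset)
    orig <- codon
    if (type == "PREMATURE_STOP_SUBSTITUTION") {
      # minimal edit: the stop codon closest in Hamming distance (usually 1)
      dists <- vapply(STOP_CODONS, function(s)
        sum(.split1(codon) != .split1(s)), 0L)
      targets <- STOP_CODONS[dists == min(dists)]
      obs <- targets[sample.int(length(targets), 1L)]
    } else {
      # mutate one random codon position so the result is no longer (resp.
      # never was) a valid start/stop
      repeat {
        k <- sample.int(3L, 1L)
        b <- sample(setdiff(c("A", "C", "G", "T"), substr(codon, k, k)), 1L)
        cand <- codon
        substr(cand, k, k) <- b
        valid_after <- if (type == "START_LOSS") cand == "ATG"
                       else cand %in% STOP_CODONS
        if (!valid_after) { obs <- cand; break }
      }
    }
    for (k in 0:2)
      copy <- .set_base(copy, offset + k, substr(obs, k + 1L, k + 1L))
  } else if (type == "FRAMESHIFT_INDEL") {
    if (is.na(ilen)) ilen <- sample(c(-2L, -1L, 1L, 2L), 1L)
    if (ilen %% 3L == 0L) stop("frameshift length must not be a multiple of 3",
                               call. = FALSE)
    p <- .cds_pos(copy, offset)
    seg <- copy$segs[[p$seg]]
    if (ilen < 0L) {                      # deletion of |ilen| bases
      n_del <- min(-ilen, length(seg$chars) - p$pos + 1L)
      idx <- p$pos:(p$pos + n_del - 1L)
      orig <- paste(seg$chars[idx], collapse = "")
      obs <- "-"
      seg$chars <- seg$chars[-idx]
      seg$anc <- seg$anc[-idx]
      seg$origin <- seg$origin[-idx]
      ilen <- -n_del
    } else {                              # insertion after the offset base
      ins <- .rand_bases(ilen)
      orig <- "-"
      obs <- paste(ins, collapse = "")
      at <- p$pos
      seg$chars <- append(seg$chars, ins, after = at)
      seg$anc <- append(seg$anc, rep(NA_integer_, ilen), after = at)
      seg$origin <- append(seg$origin, rep("plant_ins", ilen), after = at)
    }
    copy$segs[[p$seg]] <- seg
  } else stop("unknown disabler type: ", type, call. = FALSE)
  copy$planted <- rbind(copy$planted, data.frame(
    type = type, exon = as.integer(exon), cds_offset = as.integer(offset),
    orig = orig, obs = obs,
    indel_len = if (type == "FRAMESHIFT_INDEL") as.integer(ilen) else NA_integer_,
    branch = branch, stringsAsFactors = FALSE))
  copy
}

## ---------------------------------------------------------------------------
## evolution along the tree

# One K2P substitution step of length t on a character vector.
.mutate_k2p <- function(chars, t, kappa) {
  if (t <= 0 || length(chars) == 0L) return(chars)
  alpha <- kappa / (kappa + 2)
  beta <- 1 / (kappa + 2)
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1            # per transversion target
  u <- stats::runif(length(chars))
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv1 <- c(A = "C", G = "C", C = "A", T = "A")
  tv2 <- c(A = "T", G = "T", C = "G", T = "G")
  out <- chars
  known <- chars %in% c("A", "C", "G", "T")
  i1 <- known & u < p_ts
  i2 <- known & u >= p_ts & u < p_ts + p_tv
  i3 <- known & u >= p_ts + p_tv & u < p_ts + 2 * p_tv
  out[i1] <- ts_map[chars[i1]]
  out[i2] <- tv1[chars[i2]]
  out[i3] <- tv2[chars[i3]]
  out
}

# Indel step: Poisson number of events over the whole copy; deletions are
# clipped at segment ends so no indel straddles an exon boundary. Coding
# (enabled) copies accept indels only outside exons.
.mutate_indels <- function(copy, t, config) {
  if (config$indel_rate <= 0 || t <= 0) return(copy)
  lens <- vapply(copy$segs, function(s) length(s$chars), 0L)
  n_ev <- stats::rpois(1L, config$indel_rate * sum(lens) * t)
  for (k in seq_len(n_ev)) {
    lens <- vapply(copy$segs, function(s) length(s$chars), 0L)
    si <- sample.int(length(lens), 1L, prob = lens)
    seg <- copy$segs[[si]]
    if (copy$enabled && seg$kind == "exon") next
    ilen <- min(stats::rgeom(1L, config$indel_geom_p) + 1L, config$indel_max)
    pos <- sample.int(length(seg$chars), 1L)
    if (stats::runif(1L) < 0.5) {       # deletion
      idx <- pos:min(pos + ilen - 1L, length(seg$chars))
      if (length(idx) >= length(seg$chars)) next
      seg$chars <- seg$chars[-idx]
      if (seg$kind == "exon") {
        seg$anc <- seg$anc[-idx]
        seg$origin <- seg$origin[-idx]
      }
    } else {                            # insertion
      ins <- .rand_bases(ilen)
      seg$chars <- append(seg$chars, ins, after = pos)
      if (seg$kind == "exon") {
        seg$anc <- append(seg$anc, rep(NA_integer_, ilen), after = pos)
        seg$origin <- append(seg$origin, rep("ins", ilen), after = pos)
      }
    }
    copy$segs[[si]] <- seg
  }
  copy
}

# Spliced CDS of a copy (current exon content, insertions included).
.copy_cds <- function(copy) {
  paste(vapply(copy$segs, function(s)
    if (s$kind == "exon") paste(s$chars, collapse = "") else "", ""),
    collapse = "")
}

# Restore any codon that breaks the ORF to its counterpart in `source_cds`
# (keyed by ancestral offset). Used for the enable step (source = ancestral
# CDS) and for purifying maintenance (source = pre-mutation state).
# `exon_lengths` gives the ancestral per-exon CDS lengths so the full exon
# grid can be rebuilt even when edge bases were deleted.
.repair_orf <- function(copy, source_cds, exon_lengths) {
  cum <- cumsum(c(0L, exon_lengths))
  # first drop non-ancestral exon bases and restore deletions, so the exon
  # grid matches the ancestral coordinates
  for (si in seq_along(copy$segs)) {
    s <- copy$segs[[si]]
    if (s$kind != "exon") next
    keep <- s$origin == "anc"
    chars <- s$chars[keep]; anc <- s$anc[keep]
    offs <- cum[s$exon_index]:(cum[s$exon_index + 1L] - 1L)
    cur <- .split1(source_cds)[offs + 1L]
    cur[match(anc, offs)] <- chars
    copy$segs[[si]]$chars <- cur
    copy$segs[[si]]$anc <- offs
    copy$segs[[si]]$origin <- rep("anc", length(offs))
  }
  cds <- .copy_cds(copy)
  L <- nchar(cds)
  src <- source_cds
  fix <- function(off) {
    for (k in 0:2)
      copy <<- .set_base(copy, off + k, substr(src, off + k + 1L, off + k + 1L))
  }
  if (substr(cds, 1, 3) != "ATG") fix(0L)
  if (!substr(cds, L - 2, L) %in% STOP_CODONS) fix(L - 3L)
  # restoring a codon from a stop-free source cannot create new stops, so a
  # single pass over the internal codons suffices
  starts <- seq.int(3L, L - 6L, by = 3L)
  codons <- substring(cds, starts + 1L, starts + 3L)
  for (c0 in starts[codons %in% STOP_CODONS]) fix(c0)
  copy
}

#' Evolve a planted locus along the species tree
#'
#' Traverses the (rooted) configuration tree from the ancestral state:
#' on each branch, transposition and duplication events scheduled for that
#' branch fire first (copying the locus into the destination compartment,
#' reverse-complemented when inverted), then the enable event reverts all
#' disablers and repairs the ORF on the designated compartment, and finally
#' every copy accumulates K2P substitutions and indels over the branch
#' length. Enabled copies are maintained under an idealized purifying rule:
#' any mutation that would re-disable the ORF is undone.
#'
#' @param locus a disabled (or coding) `sim_locus`.
#' @param config the [sim_config()] used to build it.
#' @return object of class `sim_result`: `leaves` (per leaf, per
#'   compartment, a list of copy objects), `truth` (data.frame of planted
#'   disablers per leaf/compartment/copy with a `present` flag), `cds`,
#'   `exon_lengths`, `config`.
#' @export
evolve <- function(locus, config) {
  stopifnot(inherits(locus, "sim_locus"))
  set.seed(config$seed + 1L)
  phy <- stats::reorder(config$tree, "cladewise")
  sigs <- .edge_signatures(phy)
  nt <- length(phy$tip.label)
  root <- nt + 1L
  anc_cds <- locus$cds

  state0 <- list(autosome = list(locus$copy))
  # root-level plants were applied by disable_locus() already when the spec
  # said branch == "root"; branch-level plants fire during traversal below.
  leaves <- list()

  step_branch <- function(state, edge_i) {
    sig <- sigs[edge_i]
    t <- phy$edge.length[edge_i]
    tp <- config$transpositions
    if (!is.null(tp)) for (r in which(tp$branch == sig)) {
      src <- state[[tp$from[r]]]
      if (is.null(src)) stop("transposition from empty compartment ",
                             tp$from[r], call. = FALSE)
      cp <- src[[1]]
      cp$orientation <- if (isTRUE(tp$inverted[r]))
        if (cp$orientation == "+") "-" else "+" else cp$orientation
      cp$created_on <- sig
      state[[tp$to[r]]] <- c(state[[tp$to[r]]], list(cp))
    }
    dp <- config$duplications
    if (!is.null(dp)) for (r in which(dp$branch == sig)) {
      comp <- dp$compartment[r]
      if (!is.null(state[[comp]])) {
        tmpl <- state[[comp]][[1]]
        tmpl$created_on <- sig
        for (k in seq_len(dp$copies[r]))
          state[[comp]] <- c(state[[comp]], list(tmpl))
      }
    }
    pl <- config$plant
    if (!is.null(pl)) for (r in which(pl$branch == sig)) {
      comp <- pl$compartment[r]
      if (!is.null(state[[comp]]))
        state[[comp]] <- lapply(state[[comp]], function(cp)
          .apply_plant(cp, pl$type[r], pl$exon[r],
                       if (is.na(pl$offset[r]))
                         stop("branch-level plants need explicit offsets")
                       else pl$offset[r],
                       pl$indel_len[r], sig))
    }
    if (!is.null(config$enable_branch) && sig == config$enable_branch) {
      comp <- config$enable_compartment
      if (is.null(state[[comp]]))
        stop("enable_branch fires on empty compartment ", comp, call. = FALSE)
      state[[comp]] <- lapply(state[[comp]], function(cp) {
        cp <- .repair_orf(cp, anc_cds, locus$exon_lengths)
        cp$enabled <- TRUE
        cp
      })
    }
    for (comp in names(state)) {
      state[[comp]] <- lapply(state[[comp]], function(cp) {
        pre <- if (cp$enabled) .copy_cds(cp) else NULL
        for (si in seq_along(cp$segs))
          cp$segs[[si]]$chars <- .mutate_k2p(cp$segs[[si]]$chars, t, config$kappa)
        cp <- .mutate_indels(cp, t, config)
        if (cp$enabled) cp <- .repair_orf(cp, pre, locus$exon_lengths)
        cp
      })
    }
    state
  }

  walk <- function(node, state) {
    kids_e <- which(phy$edge[, 1] == node)
    if (length(kids_e) == 0L) return()
    for (e in kids_e) {
      child <- phy$edge[e, 2]
      st <- step_branch(state, e)
      if (child <= nt) leaves[[phy$tip.label[child]]] <<- st
      else walk(child, st)
    }
  }
  walk(root, state0)

  truth <- NULL
  for (leaf in names(leaves)) for (comp in names(leaves[[leaf]])) {
    copies <- leaves[[leaf]][[comp]]
    for (k in seq_along(copies)) {
      cp <- copies[[k]]
      if (nrow(cp$planted)) {
        truth <- rbind(truth, cbind(
          data.frame(leaf = leaf, compartment = comp, copy = k,
                     orientation = cp$orientation,
                     present = !cp$enabled, stringsAsFactors = FALSE),
          cp$planted))
      }
    }
  }
  if (is.null(truth))
    truth <- cbind(data.frame(leaf = character(0), compartment = character(0),
                              copy = integer(0), orientation = character(0),
                              present = logical(0)), .planted_empty())
  structure(list(leaves = leaves, truth = truth, cds = anc_cds,
                 exon_lengths = locus$exon_lengths, config = config),
            class = "sim_result")
}

#' Emitted genomic sequence and gene model of a simulated copy
#'
#' @param cp an internal copy object from a `sim_result`.
#' @param gene_id id for the gene model.
#' @param seq_id id for the emitted sequence.
#' @return list with `seq` (emitted sequence, reverse-complemented for
#'   inverted copies) and `gene_model` (exon coordinates on that sequence,
#'   transcription order, strand reflecting orientation).
#' @export
copy_sequence <- function(cp, gene_id = "sim", seq_id = gene_id) {
  lens <- vapply(cp$segs, function(s) length(s$chars), 0L)
  starts <- cumsum(c(0L, lens[-length(lens)]))
  exon_idx <- which(vapply(cp$segs, function(s) s$kind == "exon", TRUE))
  fwd <- paste(vapply(cp$segs, function(s) paste(s$chars, collapse = ""), ""),
               collapse = "")
  total <- nchar(fwd)
  if (cp$orientation == "+") {
    st <- starts[exon_idx]; en <- st + lens[exon_idx]; strand <- "+"
  } else {
    en <- total - starts[exon_idx]; st <- en - lens[exon_idx]; strand <- "-"
    fwd <- revcomp(fwd)
  }
  gm <- gene_model(gene_id, seq_id, strand, st, en)
  list(seq = stats::setNames(fwd, seq_id), gene_model = gm)
}

#' Write a simulation to disk
#'
#' Emits, per leaf and compartment, a FASTA file with one record per copy;
#' a GFF3 file with the exon annotations of every copy; the truth table as
#' TSV; and a provenance JSON with the resolved configuration. Re-running
#' with the same configuration reproduces identical files.
#'
#' @param sim a `sim_result` from [evolve()].
#' @param outdir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
emit <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  gff <- file.path(outdir, "annotations.gff3")
  first_gff <- TRUE
  for (leaf in sort(names(sim$leaves))) {
    for (comp in sort(names(sim$leaves[[leaf]]))) {
      copies <- sim$leaves[[leaf]][[comp]]
      seqs <- character(0)
      for (k in seq_along(copies)) {
        id <- sprintf("%s|%s|copy%d", leaf, comp, k)
        cs <- copy_sequence(copies[[k]], gene_id = id, seq_id = id)
        seqs[id] <- cs$seq
        write_gff_exons(cs$gene_model, gff, append = !first_gff)
        first_gff <- FALSE
      }
      fa <- file.path(outdir, sprintf("%s_%s.fa", leaf, comp))
      write_fasta(seqs, fa)
      paths[[sprintf("%s_%s", leaf, comp)]] <- fa
    }
  }
  truth_path <- file.path(outdir, "truth.tsv")
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$truth <- truth_path
  paths$gff <- gff
  prov <- file.path(outdir, "provenance.json")
  cfg <- sim$config
  cfg$tree <- ape::write.tree(cfg$tree)
  jsonlite::write_json(cfg[!vapply(cfg, is.null, TRUE)], prov,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  paths$provenance <- prov
  invisible(paths)
}
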