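# Cross-taxon synthesis: shared-disabler matrices (are the same ORF
# disruptions carried by several taxa, arguing for a common non-coding
# ancestor?) and small parsimony reconstruction of where coding ability was
# gained or lost on a species tree.

#' Build a shared-disabler matrix across taxa
#'
#' Matches disablers across taxa by `(type, ref_nt_offset)`, optionally with
#' a tolerance window on the offset, and returns a presence/absence matrix
#' ordered by offset. Rows present in every column with known state are
#' flagged as ancestral candidates: disruptions plausibly inherited from a
#' common non-coding ancestor.
#'
#' @param reports named list (one element per taxon/ORF) of
#'   `disabler_report` objects or bare disabler data.frames; `NULL` elements
#'   mean the taxon's state is unknown.
#' @param tolerance offset tolerance in nt for matching disablers of the
#'   same type across taxa (default 0: exact).
#' @return object of class `shared_disabler_matrix`: `keys` (data.frame of
#'   type and representative offset), `matrix` (character, cells
#'   `"present"`/`"absent"`/`"unknown"`), `ancestral_candidate` (logical per
#'   row).
#' @export
build_shared_matrix <- function(reports, tolerance = 0L) {
  stopifnot(!is.null(names(reports)), all(nzchar(names(reports))))
  taxa <- names(reports)
  tabs <- lapply(reports, function(r) {
    if (is.null(r)) return(NULL)
    if (inherits(r, "disabler_report")) r$disablers else r
  })
  all_d <- do.call(rbind, lapply(seq_along(tabs), function(i) {
    t <- tabs[[i]]
    if (is.null(t) || nrow(t) == 0L) return(NULL)
    data.frame(taxon = taxa[i], type = t$type, offset = t$ref_nt_offset)
  }))
  if (is.null(all_d) || nrow(all_d) == 0L) {
    return(structure(list(keys = data.frame(type = character(0),
                                            ref_nt_offset = integer(0)),
                          matrix = matrix(character(0), 0, length(taxa),
                                          dimnames = list(NULL, taxa)),
                          ancestral_candidate = logical(0)),
                     class = "shared_disabler_matrix"))
  }
  # greedy clustering per type: offsets within `tolerance` of a group's
  # representative (its smallest offset) share a row
  all_d <- all_d[order(all_d$type, all_d$offset), ]
  all_d$key <- NA_integer_
  keys <- data.frame(type = character(0), ref_nt_offset = integer(0))
  for (i in seq_len(nrow(all_d))) {
    hit <- which(keys$type == all_d$type[i] &
                   abs(keys$ref_nt_offset - all_d$offset[i]) <= tolerance)
    if (length(hit)) {
      all_d$key[i] <- hit[1]
    } else {
      keys <- rbind(keys, data.frame(type = all_d$type[i],
                                     ref_nt_offset = all_d$offset[i]))
      all_d$key[i] <- nrow(keys)
    }
  }
  ord <- order(keys$ref_nt_offset, keys$type)
  keys <- keys[ord, , drop = FALSE]
  rownames(keys) <- NULL
  remap <- match(seq_along(ord), ord)
  all_d$key <- remap[all_d$key]
  mat <- matrix("absent", nrow(keys), length(taxa),
                dimnames = list(NULL, taxa))
  for (i in seq_along(taxa)) if (is.null(tabs[[i]])) mat[, i] <- "unknown"
  for (i in seq_len(nrow(all_d)))
    mat[all_d$key[i], all_d$taxon[i]] <- "present"
  known <- mat != "unknown"
  anc <- vapply(seq_len(nrow(mat)), function(r)
    all(mat[r, known[r, ]] == "present") && any(known[r, ]), logical(1))
  structure(list(keys = keys, matrix = mat, ancestral_candidate = anc),
            class = "shared_disabler_matrix")
}

#' @export
print.shared_disabler_matrix <- function(x, ...) {
  cat("shared_disabler_matrix:", nrow(x$keys), "disabler key(s) x",
      ncol(x$matrix), "taxa;", sum(x$ancestral_candidate),
      "ancestral candidate(s)\n")
  if (nrow(x$keys))
    print(cbind(x$keys, as.data.frame(x$matrix),
                ancestral = x$ancestral_candidate))
  invisible(x)
}

# Clade signature of each edge's child node: sorted comma-joined tip labels.
.edge_signatures <- function(tree) {
  nt <- length(tree$tip.label)
  desc <- function(node) {
    if (node <= nt) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    sort(unlist(lapply(kids, desc)))
  }
  vapply(tree$edge[, 2], function(ch) paste(desc(ch), collapse = ","),
         character(1))
}

#' Parsimony reconstruction of coding-ability gains and losses
#'
#' Fitch-style small parsimony on the binary coding/non-coding character
#' over a rooted species tree. Taxa with `unknown` or `absent` status are
#' treated as missing data (either state allowed at zero cost). All minimal
#' labelings are enumerated (up to `max_solutions`) and the gain/loss events
#' implied by each are placed on branches, identified by the tip set of the
#' branch's child clade.
#'
#' @param species_tree a rooted `phylo` tree (or Newick string) whose tips
#'   cover the taxa with known state.
#' @param statuses data.frame with columns `taxon` and `coding_ability`
#'   (`"coding"`, `"non_coding"`, `"absent"`, `"unknown"`); `taxon` values
#'   match tip labels.
#' @param max_solutions cap on enumerated minimal labelings.
#' @return object of class `event_reconstruction`: `parsimony_score`,
#'   `solutions` (list; each has `states` per node and an `events`
#'   data.frame with `branch` clade signature and `event`
#'   `"gain_coding"`/`"loss_coding"`), `events` (the events common to all
#'   minimal solutions), `tree`.
#' @export
infer_ancestral_state <- function(species_tree, statuses,
                                  max_solutions = 256L) {
  tree <- if (is.character(species_tree)) ape::read.tree(text = species_tree)
          else species_tree
  stopifnot(inherits(tree, "phylo"))
  tree <- stats::reorder(tree, "postorder")
  states <- c("non_coding", "coding")
  obs <- stats::setNames(statuses$coding_ability, statuses$taxon)
  obs <- obs[obs %in% states]
  if (length(unique(names(obs))) < 2L || length(obs) < 2L)
    stop("need known coding ability for at least two taxa", call. = FALSE)
  missing_tips <- setdiff(tree$tip.label, names(obs))

  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  root <- nt + 1L
  children <- split(tree$edge[, 2], tree$edge[, 1])
  # Sankoff DP, unit cost for a state change on an edge
  cost <- matrix(Inf, nn, 2L)
  order_nodes <- unique(tree$edge[, 1])  # postorder: children before parents
  for (i in seq_len(nt)) {
    tip <- tree$tip.label[i]
    if (tip %in% names(obs)) {
      cost[i, ] <- ifelse(states == obs[[tip]], 0, Inf)
    } else cost[i, ] <- 0
  }
  trans <- function(s, t) if (s == t) 0 else 1
  for (v in order_nodes) {
    for (s in 1:2) {
      tot <- 0
      for (ch in children[[as.character(v)]]) {
        tot <- tot + min(cost[ch, 1] + trans(s, 1), cost[ch, 2] + trans(s, 2))
      }
      cost[v, s] <- tot
    }
  }
  score <- min(cost[root, ])

  # enumerate all minimal labelings by DFS over optimal choices
  solutions <- list()
  assign_down <- function(states_vec, v, s) {
    states_vec[v] <- s
    kids <- children[[as.character(v)]]
    if (is.null(kids)) return(list(states_vec))
    # per child, the set of optimal states given parent state s
    choice_sets <- lapply(kids, function(ch) {
      vals <- c(cost[ch, 1] + trans(s, 1), cost[ch, 2] + trans(s, 2))
      which(vals == min(vals))
    })
    outs <- list(states_vec)
    for (k in seq_along(kids)) {
      nxt <- list()
      for (sv in outs) for (cs in choice_sets[[k]]) {
        if (length(nxt) + length(solutions) >= max_solutions * 4L) break
        sub <- assign_down(sv, kids[[k]], cs)
        nxt <- c(nxt, sub)
      }
      outs <- nxt
    }
    outs
  }
  root_states <- which(cost[root, ] == score)
  all_assign <- list()
  for (rs in root_states)
    all_assign <- c(all_assign, assign_down(rep(NA_integer_, nn), root, rs))
  all_assign <- all_assign[seq_len(min(length(all_assign), max_solutions))]

  sigs <- .edge_signatures(tree)
  node_name <- function(v) if (v <= nt) tree$tip.label[v] else paste0("node", v)
  solutions <- lapply(all_assign, function(sv) {
    ev <- NULL
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      if (sv[p] != sv[ch]) {
        ev <- rbind(ev, data.frame(
          branch = sigs[e], child = node_name(ch),
          event = if (sv[ch] == 2L) "gain_coding" else "loss_coding",
          stringsAsFactors = FALSE))
      }
    }
    if (is.null(ev)) ev <- data.frame(branch = character(0),
                                      child = character(0),
                                      event = character(0))
    list(states = stats::setNames(states[sv],
                                  vapply(seq_len(nn), node_name, "")),
         events = ev)
  })
  # events shared by all minimal solutions
  keys <- lapply(solutions, function(s) paste(s$events$branch, s$events$event))
  common <- Reduce(intersect, keys)
  events <- solutions[[1]]$events[
    paste(solutions[[1]]$events$branch, solutions[[1]]$events$event) %in% common, ,
    drop = FALSE]
  structure(list(tree = tree, parsimony_score = as.integer(score),
                 solutions = solutions, events = events,
                 missing_taxa = missing_tips),
            class = "event_reconstruction")
}

#' @export
print.event_reconstruction <- function(x, ...) {
  cat("event_reconstruction: parsimony score", x$parsimony_score, "with",
      length(x$solutions), "minimal labeling(s)\n")
  if (nrow(x$solutions[[1]]$events))
    print(x$solutions[[1]]$events)
  else cat("no state changes inferred\n")
  invisible(x)
}

#' Render an event reconstruction as text
#'
#' Each gain/loss event is rendered against a user-supplied map from branch
#' (clade signature: sorted comma-joined tip labels of the branch's child
#' clade) to a human-readable label such as "after the ape-Old World monkey
#' split". No dating is computed.
#'
#' @param reconstruction an `event_reconstruction`.
#' @param named_splits named character vector: clade signature -> label.
#' @param solution which minimal labeling to summarize.
#' @return character vector of summary lines.
#' @export
summarize_history <- function(reconstruction, named_splits = character(0),
                              solution = 1L) {
  ev <- reconstruction$solutions[[solution]]$events
  if (nrow(ev) == 0L) return("no state changes inferred")
  vapply(seq_len(nrow(ev)), function(i) {
    verb <- if (ev$event[i] == "gain_coding") "gain" else "loss"
    where <- if (ev$branch[i] %in% names(named_splits))
      named_splits[[ev$branch[i]]]
    else sprintf("on the branch to {%s}", ev$branch[i])
    sprintf("%s of coding ability %s", verb, where)
  }, character(1))
}
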