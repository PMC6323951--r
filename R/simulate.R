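# Duplication-loss birth-death simulation of gene families along a species
# tree, plus sequence evolution with known ancestral truth. Every downstream
# module (parsimony loss inference, voting reconstruction, proxies,
# comparisons) is testable against the simulated truth without external data.

#' Simulation parameters
#'
#' @param dup_rate Duplication events per gene lineage per unit branch length.
#' @param loss_rate Loss events per gene lineage per unit branch length.
#' @param seq_length Number of alignment columns at the family root.
#' @param subst_rate Substitutions per site per unit branch length.
#' @param indel_rate Single-column insertion/deletion events per site per
#'   unit branch length.
#' @param seed Integer seed; the same seed always reproduces the same family.
#' @return A `sim_params` list.
#' @export
sim_params <- function(dup_rate = 0.1, loss_rate = 0.2, seq_length = 120L,
                       subst_rate = 0.3, indel_rate = 0.02, seed = 1L) {
  stopifnot(dup_rate >= 0, loss_rate >= 0, subst_rate >= 0, indel_rate >= 0,
            seq_length >= 1)
  structure(list(dup_rate = dup_rate, loss_rate = loss_rate,
                 seq_length = as.integer(seq_length),
                 subst_rate = subst_rate, indel_rate = indel_rate,
                 seed = as.integer(seed)),
            class = "sim_params")
}

with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate one gene family along a species tree
#'
#' One gene starts at the species-tree root. Along every species branch each
#' gene lineage independently duplicates (rate `dup_rate`) or dies (rate
#' `loss_rate`) with exponential waiting times; at a speciation every
#' surviving lineage enters each child branch. The full event history is kept
#' in `true_tree` (including extinct lineages and explicit loss tips, placed
#' at the species node at the bottom of the branch on which the lineage
#' died); `observed_tree` is the pruned phylogeny of surviving genes, with
#' events and internal taxa cleared so reconciliation can be tested against
#' the recorded truth. Deterministic given `params$seed`.
#'
#' @param stree A `species_tree` with branch lengths on all non-root nodes.
#' @param params A [sim_params()] object.
#' @param family_id Family identifier for the simulated family.
#' @return A `simulated_family`: `true_tree`, `observed_tree` (`NULL` if the
#'   family went extinct), `true_loss_count`, `true_dup_count`, and -- after
#'   [evolve_sequences()] -- `true_sequences` and `alignment`.
#' @export
simulate_family <- function(stree, params, family_id = "SIM1") {
  nonroot <- setdiff(stree$taxa, stree$root)
  if (any(is.na(stree$blen[nonroot]))) {
    stop("simulation requires branch lengths on every species-tree branch",
         call. = FALSE)
  }
  env <- new.env(parent = emptyenv())
  env$nid <- 0L; env$dups <- 0L; env$losses <- 0L
  env$genes <- integer(0)
  nid <- function() { env$nid <- env$nid + 1L; sprintf("t%d", env$nid) }
  newgene <- function(sp) {
    k <- env$genes[sp]
    k <- if (is.na(k)) 1L else k + 1L
    env$genes[sp] <- k
    sprintf("%s_g%d", sp, k)
  }
  rate <- params$dup_rate + params$loss_rate
  sim_at <- function(taxon) {  # a lineage alive at species node `taxon`
    kids_sp <- species_children(stree, taxon)
    if (!length(kids_sp)) {
      return(gnode(nid(), event = "extant", taxon = taxon,
                   gene_id = newgene(taxon)))
    }
    gnode(nid(), event = "speciation", taxon = taxon,
          children = lapply(kids_sp, function(cs) {
            sim_branch(cs, stree$blen[[cs]])
          }))
  }
  sim_branch <- function(cs, remaining) {  # one lineage on the branch to `cs`
    t <- if (rate > 0) stats::rexp(1L, rate) else Inf
    if (t >= remaining) {
      node <- sim_at(cs)
      node$blen <- remaining
      return(node)
    }
    if (stats::runif(1L) < params$dup_rate / rate) {
      env$dups <- env$dups + 1L
      gnode(nid(), event = "duplication", taxon = cs, blen = t,
            children = list(sim_branch(cs, remaining - t),
                            sim_branch(cs, remaining - t)))
    } else {
      env$losses <- env$losses + 1L
      gnode(nid(), event = "loss", taxon = cs, blen = t)
    }
  }
  root <- with_seed(params$seed, sim_at(stree$root))
  true_tree <- new_gene_tree(family_id, root)
  structure(list(true_tree = true_tree,
                 observed_tree = prune_extinct(true_tree),
                 true_sequences = NULL, alignment = NULL,
                 true_loss_count = env$losses, true_dup_count = env$dups,
                 params = params),
            class = "simulated_family")
}

# Observed phylogeny: drop loss tips and extinct subtrees, splice unary
# nodes (summing branch lengths), clear inferred-later fields on internals.
prune_extinct <- function(true_tree) {
  rec <- function(node) {
    if (!length(node$children)) {
      if (identical(node$event, "extant")) return(node)
      return(NULL)
    }
    kids <- Filter(Negate(is.null), lapply(node$children, rec))
    if (!length(kids)) return(NULL)
    if (length(kids) == 1L) {
      ch <- kids[[1L]]
      ch$blen <- ch$blen + node$blen
      return(ch)
    }
    node$children <- kids
    node$event <- NA_character_
    node$taxon <- NA_character_
    node
  }
  root <- rec(true_tree$root)
  if (is.null(root)) return(NULL)
  root$blen <- 0
  new_gene_tree(true_tree$family_id, root)
}

#' Site-level recovery of simulated ancestral sequences
#'
#' Runs the reconciliation and voting pipeline on a simulated family's
#' observed tree and compares the reconstructed ancestral states with the
#' simulated truth, at every ancestral node of the observed tree (inserted
#' ancestors have no simulated counterpart and are skipped) and every column
#' where the true state is not a gap. Both `X` calls and wrong residues count
#' as misses.
#'
#' @param fam A `simulated_family` after [evolve_sequences()].
#' @param stree The `species_tree` the family was simulated on.
#' @param mode Voting mode, as in [reconstruct_ancestral()].
#' @return List with `matched`, `total` and `accuracy` (NA when the observed
#'   tree has no ancestral nodes).
#' @export
asr_recovery <- function(fam, stree, mode = "children") {
  stopifnot(inherits(fam, "simulated_family"))
  if (is.null(fam$observed_tree) || is.null(fam$alignment)) {
    stop("family must be observed and have sequences evolved", call. = FALSE)
  }
  rt <- assign_stable_ids(infer_losses(map_taxa(fam$observed_tree, stree),
                                       stree))
  asr <- reconstruct_ancestral(rt, fam$alignment, mode = mode)
  matched <- 0L
  total <- 0L
  for (sid in names(asr$rows)) {
    truth <- fam$true_sequences[[asr$node_id[[sid]]]]
    if (is.null(truth)) next  # inserted ancestor: no simulated counterpart
    ts <- strsplit(truth, "")[[1]]
    rs <- strsplit(asr$rows[[sid]], "")[[1]]
    keep <- ts != "-"
    matched <- matched + sum(ts[keep] == rs[keep])
    total <- total + sum(keep)
  }
  list(matched = matched, total = total,
       accuracy = if (total) matched / total else NA_real_)
}

#' Evolve protein sequences over a simulated family
#'
#' The root sequence is uniform over the 20 amino acids. Along each branch of
#' the observed tree, each non-gap site substitutes with probability
#' `1 - exp(-subst_rate * length)` to a uniformly chosen different residue.
#' Indels are single-column events at `indel_rate` per site per unit length:
#' a deletion gaps one site in that lineage onward, an insertion creates a
#' new column that is a gap everywhere outside the receiving lineage. The
#' aligned truth for every observed node is kept; leaf rows become the family
#' alignment.
#'
#' @param fam A `simulated_family` with non-empty `observed_tree`.
#' @param params A [sim_params()] object (the RNG stream is derived from
#'   `params$seed`, offset so it does not replay the family simulation).
#' @return `fam` with `true_sequences` (named list, node_id to aligned
#'   sequence) and `alignment` (a `family_alignment`) filled in.
#' @export
evolve_sequences <- function(fam, params = fam$params) {
  stopifnot(inherits(fam, "simulated_family"))
  if (is.null(fam$observed_tree)) {
    stop("family is extinct: no observed tree to evolve sequences on",
         call. = FALSE)
  }
  L0 <- params$seq_length
  env <- new.env(parent = emptyenv())
  env$cols <- sprintf("c%06d", seq_len(L0))
  env$next_col <- L0
  env$truth <- list()
  mutate <- function(seq, blen) {
    live <- names(seq)[seq != "-"]
    p <- 1 - exp(-params$subst_rate * blen)
    if (p > 0 && length(live)) {
      hit <- live[stats::runif(length(live)) < p]
      for (k in hit) {
        seq[[k]] <- sample(setdiff(AA20, seq[[k]]), 1L)
      }
    }
    n_ev <- if (params$indel_rate > 0 && length(live)) {
      stats::rpois(1L, params$indel_rate * blen * length(live))
    } else 0L
    for (e in seq_len(n_ev)) {
      live <- names(seq)[seq != "-"]
      if (!length(live)) break
      if (stats::runif(1L) < 0.5) {  # deletion
        seq[[sample(live, 1L)]] <- "-"
      } else {                       # insertion: fresh column
        env$next_col <- env$next_col + 1L
        key <- sprintf("c%06d", env$next_col)
        at <- sample(length(env$cols) + 1L, 1L)
        env$cols <- append(env$cols, key, after = at - 1L)
        seq[[key]] <- sample(AA20, 1L)
      }
    }
    seq
  }
  evolve <- function(node, seq) {
    env$truth[[node$node_id]] <- seq
    for (ch in node$children) {
      evolve(ch, mutate(seq, ch$blen))
    }
  }
  with_seed(params$seed + 500000L, {
    root_seq <- stats::setNames(sample(AA20, L0, replace = TRUE), env$cols)
    evolve(fam$observed_tree$root, root_seq)
  })
  finalize <- function(seq) {
    paste(ifelse(env$cols %in% names(seq), seq[env$cols], "-"), collapse = "")
  }
  fam$true_sequences <- lapply(env$truth, finalize)
  leaves <- gt_extant_leaves(fam$observed_tree$root)
  rows <- vapply(leaves, function(l) fam$true_sequences[[l$node_id]],
                 character(1))
  names(rows) <- vapply(leaves, `[[`, character(1), "gene_id")
  fam$alignment <- new_family_alignment(fam$observed_tree$family_id, rows)
  fam
}
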