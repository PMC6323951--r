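# Reconciliation: map gene-tree nodes onto the species tree (LCA mapping),
# label speciation vs duplication, and insert explicit ancestral-gene nodes
# and loss leaves by maximum parsimony (smallest number of deletion events
# that explains the species missing from the family).

#' Map gene-tree nodes to species-tree taxa (LCA reconciliation)
#'
#' Each internal node is mapped to the species-tree last common ancestor of
#' its descendant leaves' species. A node is labeled a duplication when its
#' taxon equals the mapped taxon of at least one child subtree, otherwise a
#' speciation; this is the standard LCA rule and applies unchanged on
#' multifurcating species trees. Event tags already present on the input tree
#' (curated trees) are trusted and kept.
#'
#' @param tree A `gene_tree` whose leaves carry species present in `stree`.
#' @param stree A `species_tree`.
#' @return The `gene_tree` with `taxon` and `event` resolved on every node.
#' @export
map_taxa <- function(tree, stree) {
  rec <- function(node) {
    if (!length(node$children)) {
      if (identical(node$event, "loss")) return(node)
      if (is.na(node$taxon) || !node$taxon %in% stree$taxa) {
        stop(sprintf("unknown species '%s' on leaf '%s'",
                     node$taxon, node$gene_id), call. = FALSE)
      }
      return(node)
    }
    node$children <- lapply(node$children, rec)
    kid_taxa <- vapply(node$children, `[[`, character(1), "taxon")
    node$taxon <- species_lca(stree, kid_taxa)
    if (!node$event %in% c("speciation", "duplication")) {
      node$event <- if (any(kid_taxa == node$taxon)) "duplication" else "speciation"
    }
    node
  }
  tree$root <- rec(tree$root)
  tree
}

#' Infer gene losses and insert explicit ancestral-gene nodes
#'
#' For every gene-tree edge from a node at taxon A to a child at taxon B, the
#' species-tree path A to B is walked and an `inserted_ancestor` node is
#' spliced in at each traversed taxon not already represented, so that every
#' ancestral species a lineage passed through has exactly one explicit
#' ancestral-gene node. A duplication at taxon A is treated as occurring on
#' the branch above A, so each duplicate lineage receives its own node at A.
#' Each traversed taxon's child lineages with no representative in the gene
#' tree receive one loss leaf, placed at the first (topmost) ancestral species
#' inferred to have been missing the gene -- the maximum-parsimony placement.
#' Branch lengths of split edges are divided equally, preserving path lengths.
#'
#' @param tree A `gene_tree` after [map_taxa()].
#' @param stree The `species_tree` used for mapping.
#' @return A `reconciled_tree`: list with elements `tree` (the augmented
#'   `gene_tree`), `loss_count`, `duplication_count`, and `stree`.
#' @examples
#' st <- read_species_tree(text = "(((human,chimp)HC,gorilla)HCG,(mouse,rat)MR)ROOT;")
#' gt <- read_gene_tree(text =
#'   "(G_g1[&&NHX:S=gorilla],(M_g1[&&NHX:S=mouse],R_g1[&&NHX:S=rat]));",
#'   family_id = "FAM1")
#' rt <- infer_losses(map_taxa(gt, st), st)
#' count_losses(rt)  # 1: the gene was lost before the human-chimp ancestor
#' @export
infer_losses <- function(tree, stree) {
  ids <- new.env(parent = emptyenv())
  ids$loss <- 0L
  ids$anc <- 0L
  loss_leaf <- function(taxon) {
    ids$loss <- ids$loss + 1L
    gnode(sprintf("loss%d", ids$loss), event = "loss", taxon = taxon, blen = 0)
  }
  # Chain of inserted_ancestor nodes (plus their loss leaves) along the
  # species path from `A` down to child `ch`; `include_A` for duplication
  # parents whose copies must each occupy A itself.
  splice_edge <- function(A, ch, include_A) {
    B <- ch$taxon
    path <- species_path(stree, A, B)  # A ... B
    ins <- if (include_A) path[-length(path)] else path[c(-1L, -length(path))]
    if (identical(A, B)) ins <- character(0)
    k <- length(ins)
    seg <- ch$blen / (k + 1)
    top <- ch
    top$blen <- seg
    if (k) {
      for (idx in rev(seq_len(k))) {
        C <- ins[[idx]]
        nxt <- path[[match(C, path) + 1L]]
        ids$anc <- ids$anc + 1L
        losses <- lapply(setdiff(species_children(stree, C), nxt), loss_leaf)
        top <- gnode(sprintf("anc%d", ids$anc), event = "inserted_ancestor",
                     taxon = C, blen = seg, children = c(list(top), losses))
      }
    }
    top
  }
  rec <- function(node) {
    if (!length(node$children)) return(node)
    A <- node$taxon
    if (is.na(A) || !node$event %in% c("speciation", "duplication")) {
      stop("infer_losses requires map_taxa() first (unresolved node)",
           call. = FALSE)
    }
    is_dup <- identical(node$event, "duplication")
    kids <- lapply(node$children, rec)
    for (j in seq_along(kids)) {
      B <- kids[[j]]$taxon
      if (!species_is_ancestor(stree, A, B)) {
        stop(sprintf("taxon inconsistency: node at '%s' has child at '%s'",
                     A, B), call. = FALSE)
      }
      if (identical(A, B) && !is_dup) {
        stop(sprintf("taxon inconsistency: speciation at '%s' with child mapped to the same taxon",
                     A), call. = FALSE)
      }
      kids[[j]] <- splice_edge(A, kids[[j]], include_A = is_dup)
    }
    if (!is_dup) {
      covered <- vapply(kids, function(ch) {
        if (identical(ch$taxon, A)) A else species_first_step(stree, A, ch$taxon)
      }, character(1))
      kids <- c(kids, lapply(setdiff(species_children(stree, A), covered),
                             loss_leaf))
    }
    node$children <- kids
    node
  }
  tree$root <- rec(tree$root)
  as_reconciled(tree, stree)
}

#' Wrap an already-annotated gene tree as a reconciled tree
#'
#' Validates that every node carries a resolved event and taxon and recounts
#' loss and duplication events. Used to resume a pipeline from a tree written
#' by [write_gene_tree()] after reconciliation.
#'
#' @param tree An event-resolved `gene_tree` (loss leaves present).
#' @param stree The `species_tree` it was reconciled against.
#' @return A `reconciled_tree`.
#' @export
as_reconciled <- function(tree, stree) {
  df <- as.data.frame(tree)
  if (anyNA(df$event) || anyNA(df$taxon)) {
    stop("tree has unresolved events or taxa; run map_taxa()/infer_losses()",
         call. = FALSE)
  }
  structure(list(tree = tree,
                 loss_count = sum(df$event == "loss"),
                 duplication_count = sum(df$event == "duplication"),
                 stree = stree),
            class = "reconciled_tree")
}

#' Number of inferred gene-loss events
#'
#' @param rt A `reconciled_tree`.
#' @return Non-negative integer count of explicit loss leaves.
#' @export
count_losses <- function(rt) {
  stopifnot(inherits(rt, "reconciled_tree"))
  rt$loss_count
}

#' @export
print.reconciled_tree <- function(x, ...) {
  cat(sprintf("reconciled_tree '%s': %d losses, %d duplications\n",
              x$tree$family_id, x$loss_count, x$duplication_count))
  invisible(x)
}

#' Reconcile a set of families and summarise
#'
#' Runs [map_taxa()], [infer_losses()] and [assign_stable_ids()] over a list
#' of gene trees and returns the reconciled trees plus a per-family summary.
#'
#' @param trees List of `gene_tree` objects.
#' @param stree A `species_tree`.
#' @return List with `families` (named list of `reconciled_tree`) and
#'   `summary` (data frame: family_id, n_extant, n_ancestral, n_duplications,
#'   n_losses).
#' @export
reconcile_families <- function(trees, stree) {
  fams <- lapply(trees, function(gt) {
    assign_stable_ids(infer_losses(map_taxa(gt, stree), stree))
  })
  names(fams) <- vapply(fams, function(rt) rt$tree$family_id, character(1))
  summary <- do.call(rbind, lapply(fams, function(rt) {
    df <- as.data.frame(rt$tree)
    data.frame(family_id = rt$tree$family_id,
               n_extant = sum(df$event == "extant"),
               n_ancestral = sum(df$event %in% c("speciation", "inserted_ancestor")),
               n_duplications = rt$duplication_count,
               n_losses = rt$loss_count,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(families = fams, summary = summary)
}

#' Brute-force Dollo-parsimony loss count
#'
#' Reference implementation by exhaustive enumeration: consider all
#' presence/absence labelings of species-tree nodes in which the gene arises
#' once at `origin` (by default the last common ancestor of the present
#' species), is present at `origin` and at every node in `force_present`,
#' presence is connected (no regain), and leaf labels match `present_species`.
#' Returns the minimum number of presence-to-absence edges. Intended as an
#' independent cross-check of [infer_losses()] on small trees, and to cost
#' counterfactual scenarios (e.g. forcing presence at a taxon the parsimony
#' solution leaves empty).
#'
#' @param stree A `species_tree`.
#' @param present_species Character vector of extant species carrying the gene.
#' @param origin Taxon where the gene arises; default LCA of the evidence.
#' @param force_present Additional taxa required to be labeled present.
#' @param truncate Taxa below which the enumeration does not descend (treated
#'   as present leaves); used when costing one duplicate lineage at a time.
#' @return Minimum loss count (non-negative integer).
#' @examples
#' st <- read_species_tree(text = "(((human,chimp)HC,gorilla)HCG,(mouse,rat)MR)ROOT;")
#' dollo_min_losses(st, c("gorilla", "mouse", "rat"))                      # 1
#' dollo_min_losses(st, c("gorilla", "mouse", "rat"), force_present = "HC") # 2
#' @export
dollo_min_losses <- function(stree, present_species, origin = NULL,
                             force_present = character(0),
                             truncate = character(0)) {
  evidence <- unique(c(present_species, force_present))
  if (!length(evidence)) stop("no present species given", call. = FALSE)
  if (is.null(origin)) origin <- species_lca(stree, evidence)
  # Clade nodes reachable from origin without descending below `truncate`.
  clade <- character(0)
  grow <- function(t) {
    clade <<- c(clade, t)
    if (!t %in% truncate) for (k in species_children(stree, t)) grow(k)
  }
  grow(origin)
  is_term <- vapply(clade, function(t) {
    t %in% truncate || !length(species_children(stree, t))
  }, logical(1))
  fixed <- setNames(rep(NA, length(clade)), clade)
  fixed[clade[is_term]] <- clade[is_term] %in% c(present_species, truncate)
  fixed[intersect(force_present, clade)] <- TRUE
  fixed[[origin]] <- TRUE
  if (any(!vapply(evidence, function(t) t %in% clade, logical(1)))) {
    stop("present/forced taxa fall outside the origin clade", call. = FALSE)
  }
  free <- clade[is.na(fixed)]
  best <- Inf
  n_free <- length(free)
  for (mask in seq_len(2^n_free) - 1L) {
    lab <- fixed
    if (n_free) lab[free] <- as.logical(bitwAnd(rep(mask, n_free),
                                                2^(seq_len(n_free) - 1L)) > 0L)
    # connectivity: present node's parent present (origin exempt)
    ok <- TRUE
    losses <- 0L
    for (t in clade) {
      if (identical(t, origin)) next
      p <- stree$parent[[t]]
      if (lab[[t]] && !lab[[p]]) { ok <- FALSE; break }
      if (!lab[[t]] && lab[[p]]) losses <- losses + 1L
    }
    if (ok && losses < best) best <- losses
  }
  as.integer(best)
}
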