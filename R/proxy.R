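# Proxy genes (least-diverged extant descendants of an ancestral gene) and
# the four-way extant-vs-ancestor genome comparison.

# Distances from a node to every extant leaf in its subtree.
node_leaf_distances <- function(node) {
  acc <- new.env(parent = emptyenv())
  acc$gene <- character(0); acc$species <- character(0); acc$dist <- numeric(0)
  walk <- function(n, d) {
    if (!length(n$children)) {
      if (identical(n$event, "extant")) {
        acc$gene <- c(acc$gene, n$gene_id)
        acc$species <- c(acc$species, n$taxon)
        acc$dist <- c(acc$dist, d)
      }
      return(invisible(NULL))
    }
    for (ch in n$children) walk(ch, d + ch$blen)
  }
  walk(node, 0)
  data.frame(gene_id = acc$gene, species = acc$species, dist = acc$dist,
             stringsAsFactors = FALSE)
}

# Proxy of a subtree's root in one species; NULL when no descendant exists.
node_proxy_gene <- function(node, species) {
  d <- node_leaf_distances(node)
  d <- d[d$species == species, , drop = FALSE]
  if (!nrow(d)) return(NULL)
  d <- d[d$dist == min(d$dist), , drop = FALSE]
  d <- d[order(d$gene_id, method = "radix"), , drop = FALSE]  # deterministic tie-break
  list(gene_id = d$gene_id[[1L]], distance = d$dist[[1L]])
}

#' Proxy gene of an ancestral gene in an extant genome
#'
#' The proxy gene is the least-diverged extant descendant of the ancestral
#' gene in the given species: among the extant leaves of the ancestral node's
#' subtree belonging to that species, the one minimizing the total branch
#' length on the connecting path. Ties are broken by the lexicographically
#' smallest gene identifier. No descendant in that species means the gene was
#' lost there, and there is no proxy.
#'
#' @param rt A `reconciled_tree` with stable IDs.
#' @param id Stable (or node) identifier of a non-loss ancestral node.
#' @param species An extant species identifier.
#' @return List with `gene_id` and `distance`, or `NULL` if no descendant
#'   exists in that species.
#' @export
proxy_gene <- function(rt, id, species) {
  stopifnot(inherits(rt, "reconciled_tree"))
  node <- gt_find(rt$tree$root, id)
  if (is.null(node)) stop(sprintf("no node '%s' in family", id), call. = FALSE)
  if (identical(node$event, "loss")) {
    stop("loss leaves have no proxy genes", call. = FALSE)
  }
  node_proxy_gene(node, species)
}

#' Proxy table for a whole family
#'
#' @param rt A `reconciled_tree` with stable IDs.
#' @param species Species to compute proxies for; defaults to all extant
#'   species of the species tree.
#' @return Data frame: stable_id, species, gene_id, distance (one row per
#'   ancestral gene and species where a proxy exists).
#' @export
proxy_table <- function(rt, species = NULL) {
  stopifnot(inherits(rt, "reconciled_tree"))
  if (is.null(species)) species <- species_leaves(rt$stree)
  acc <- list()
  walk <- function(node) {
    if (node$event %in% c("speciation", "inserted_ancestor", "duplication")) {
      for (sp in species) {
        p <- node_proxy_gene(node, sp)
        if (!is.null(p)) {
          acc[[length(acc) + 1L]] <<- data.frame(
            stable_id = node$stable_id, species = sp, gene_id = p$gene_id,
            distance = p$distance, stringsAsFactors = FALSE)
        }
      }
    }
    for (ch in node$children) walk(ch)
  }
  walk(rt$tree$root)
  out <- do.call(rbind, acc)
  if (is.null(out)) {
    out <- data.frame(stable_id = character(0), species = character(0),
                      gene_id = character(0), distance = numeric(0),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Compare an extant genome with one of its ancestral genomes
#'
#' Partitions gene content into the four sections of an
#' ancestor-vs-descendant comparison: `inherited` -- ancestral genes with at
#' least one descendant in the extant genome (an ancestral gene can have
#' several, via duplication); `lost` -- ancestral genes with none; `gained` --
#' extant genes in families whose lineage never passes through the ancestor
#' (the family arose below it; horizontal transfer or de novo origin are the
#' biological readings); `untraced` -- inventory genes belonging to no family.
#' `inherited` and `lost` partition the ancestral genome; descendants of
#' `inherited` plus `gained` plus `untraced` partition the extant inventory.
#'
#' @param extant An extant species identifier.
#' @param ancestor An ancestral taxon on the lineage of `extant`.
#' @param families List of `reconciled_tree` objects with stable IDs.
#' @param inventory Character vector of all gene identifiers of the extant
#'   genome; must contain every family leaf of that species. Defaults to the
#'   family leaves themselves (no untraced genes).
#' @return A `comparison_report`: list with `ancestor`, `extant`, `inherited`
#'   (named list stable_id -> descendant gene_ids), `lost`, `gained`,
#'   `untraced`.
#' @export
compare_genomes <- function(extant, ancestor, families, inventory = NULL) {
  stopifnot(length(families) >= 1L)
  st <- families[[1L]]$stree
  if (!extant %in% species_leaves(st)) {
    stop(sprintf("'%s' is not an extant species", extant), call. = FALSE)
  }
  if (!species_is_ancestor(st, ancestor, extant) || identical(ancestor, extant)) {
    stop(sprintf("'%s' is not an ancestor of '%s'", ancestor, extant),
         call. = FALSE)
  }
  inherited <- list()
  lost <- character(0)
  gained <- character(0)
  traced_leaves <- character(0)
  all_leaves <- character(0)
  for (rt in families) {
    ix <- gt_index(rt$tree)
    anc_nodes <- which(ix$event %in% c("speciation", "inserted_ancestor") &
                         ix$taxon == ancestor)
    leaf_idx <- which(ix$event == "extant" & ix$taxon == extant)
    all_leaves <- c(all_leaves, ix$gene_id[leaf_idx])
    covered <- integer(0)
    for (v in anc_nodes) {
      below <- intersect(ix$subtree[[v]], leaf_idx)
      if (length(below)) {
        inherited[[ix$stable_id[v]]] <- sort(ix$gene_id[below])
        covered <- c(covered, below)
      } else {
        lost <- c(lost, ix$stable_id[v])
      }
    }
    gained <- c(gained, ix$gene_id[setdiff(leaf_idx, covered)])
    traced_leaves <- c(traced_leaves, ix$gene_id[covered])
  }
  if (is.null(inventory)) {
    inventory <- all_leaves
  } else {
    stray <- setdiff(all_leaves, inventory)
    if (length(stray)) {
      stop(sprintf("inventory is missing family gene(s): %s",
                   paste(stray, collapse = ", ")), call. = FALSE)
    }
  }
  untraced <- setdiff(inventory, all_leaves)
  structure(list(ancestor = ancestor, extant = extant,
                 inherited = inherited, lost = sort(lost),
                 gained = sort(gained), untraced = sort(untraced)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison %s vs ancestor %s: %d inherited, %d lost, %d gained, %d untraced\n",
              x$extant, x$ancestor, length(x$inherited), length(x$lost),
              length(x$gained), length(x$untraced)))
  invisible(x)
}

#' Tabulate a comparison report
#'
#' @param x A `comparison_report`.
#' @param ... Unused.
#' @return Data frame with columns `section` (inherited, lost, gained,
#'   untraced), `stable_id` (ancestral gene, where applicable) and `gene_id`
#'   (extant gene, where applicable).
#' @export
as.data.frame.comparison_report <- function(x, ...) {
  rows <- list()
  for (sid in names(x$inherited)) {
    rows[[length(rows) + 1L]] <- data.frame(
      section = "inherited", stable_id = sid, gene_id = x$inherited[[sid]],
      stringsAsFactors = FALSE)
  }
  add <- function(section, stable_id, gene_id) {
    if (length(stable_id) || length(gene_id)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        section = section,
        stable_id = if (length(stable_id)) stable_id else NA_character_,
        gene_id = if (length(gene_id)) gene_id else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  add("lost", x$lost, character(0))
  add("gained", character(0), x$gained)
  add("untraced", character(0), x$untraced)
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(section = character(0), stable_id = character(0),
                      gene_id = character(0), stringsAsFactors = FALSE)
  }
  out
}
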