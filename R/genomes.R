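# Ancestral genome assembly: the gene set of an internal species-tree node is
# every ancestral-gene node (speciation or inserted ancestor) mapped to that
# taxon across families -- one node per gene lineage crossing the taxon.
# Plus duplication-aware protein naming and top-down GO-term propagation.

#' Assemble the ancestral genome of a species-tree node
#'
#' @param taxon An internal (ancestral) taxon of the species tree.
#' @param families List of `reconciled_tree` objects, all reconciled against
#'   the same species tree and with stable IDs assigned.
#' @param sequences Optional named list of `ancestral_sequences` (one per
#'   family, names = family_id); if given, ungapped reconstructed sequences
#'   are attached.
#' @return An `ancestral_genome`: data frame with one row per ancestral gene
#'   (stable_id, family_id, taxon_id, event, name, sequence), with the taxon
#'   in attribute `taxon`.
#' @export
assemble_genome <- function(taxon, families, sequences = NULL) {
  if (length(families)) {
    st <- families[[1L]]$stree
    if (!taxon %in% st$taxa) {
      stop(sprintf("unknown taxon '%s'", taxon), call. = FALSE)
    }
    if (!length(species_children(st, taxon))) {
      stop(sprintf("'%s' is an extant species; extant genomes are inputs, not reconstructions",
                   taxon), call. = FALSE)
    }
  }
  rows <- lapply(families, function(rt) {
    df <- as.data.frame(rt$tree)
    df <- df[df$event %in% c("speciation", "inserted_ancestor") &
               df$taxon == taxon, , drop = FALSE]
    if (!nrow(df)) return(NULL)
    seqs <- rep(NA_character_, nrow(df))
    if (!is.null(sequences)) {
      asr <- sequences[[rt$tree$family_id]]
      if (!is.null(asr)) seqs <- unname(ungap(asr$rows[df$stable_id]))
    }
    data.frame(stable_id = df$stable_id, family_id = rt$tree$family_id,
               taxon_id = taxon, event = df$event, name = df$name,
               sequence = seqs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(stable_id = character(0), family_id = character(0),
                      taxon_id = character(0), event = character(0),
                      name = character(0), sequence = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  structure(out, taxon = taxon, class = c("ancestral_genome", "data.frame"))
}

#' Propagate protein names through duplications
#'
#' Whenever a new gene arises by duplication (and, likewise, for the family
#' root lineage), the lineage is named for its least-diverged descendant
#' (proxy gene) in the highest-priority well-studied reference genome that
#' has a descendant in the lineage -- provided the lineage left genes in at
#' least two different genomes, as confirmation of its presence. The name is
#' inherited by descendant ancestral genes until the next duplication
#' re-applies the rule; lineages failing the two-genome test stay unnamed.
#'
#' @param rt A `reconciled_tree`.
#' @param reference_priority Ordered character vector of reference species,
#'   most preferred first.
#' @return The `reconciled_tree` with `name` set on ancestral nodes.
#' @export
propagate_names <- function(rt, reference_priority) {
  stopifnot(inherits(rt, "reconciled_tree"))
  if (!length(reference_priority)) {
    stop("reference_priority must name at least one species", call. = FALSE)
  }
  segment_name <- function(node) {
    sp <- vapply(gt_extant_leaves(node), `[[`, character(1), "taxon")
    if (length(unique(sp)) < 2L) return(NA_character_)
    ref <- reference_priority[reference_priority %in% sp][1L]
    if (is.na(ref)) return(NA_character_)
    node_proxy_gene(node, ref)$gene_id
  }
  rec <- function(node, segname) {
    if (node$event %in% c("extant", "loss")) return(node)
    if (is.null(segname)) segname <- segment_name(node)
    node$name <- segname
    node$children <- if (identical(node$event, "duplication")) {
      lapply(node$children, rec, segname = NULL)
    } else {
      lapply(node$children, rec, segname = segname)
    }
    node
  }
  rt$tree$root <- rec(rt$tree$root, NULL)
  rt
}

#' Propagate GO terms from ancient to recent ancestral genes
#'
#' Annotation events are gains and losses of a GO term at specific nodes
#' (e.g. from phylogenetic curation). A node carries a term if the term was
#' gained at the node or one of its ancestors and not lost on the path since
#' the gain; purely top-down set propagation, with no GO-DAG closure. Gains
#' at a node apply before losses at the same node.
#'
#' @param rt A `reconciled_tree` with stable IDs.
#' @param events Data frame with columns `stable_id`, `term`, `direction`
#'   (`"gain"` or `"loss"`).
#' @return Named list: stable_id to character vector of terms, for every
#'   non-loss node.
#' @export
propagate_go <- function(rt, events) {
  stopifnot(inherits(rt, "reconciled_tree"))
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  need <- c("stable_id", "term", "direction")
  if (!all(need %in% names(events))) {
    stop("events must have columns stable_id, term, direction", call. = FALSE)
  }
  if (!all(events$direction %in% c("gain", "loss"))) {
    stop("event direction must be 'gain' or 'loss'", call. = FALSE)
  }
  known <- as.data.frame(rt$tree)$stable_id
  bad <- setdiff(events$stable_id, known)
  if (length(bad)) {
    stop(sprintf("annotation events reference unknown node(s): %s",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  acc <- new.env(parent = emptyenv())
  acc$terms <- list()
  rec <- function(node, carried) {
    if (identical(node$event, "loss")) return(invisible(NULL))
    ev <- events[which(events$stable_id == node$stable_id), , drop = FALSE]
    carried <- union(carried, ev$term[ev$direction == "gain"])
    lost <- ev$term[ev$direction == "loss"]
    orphan <- setdiff(lost, carried)
    if (length(orphan)) {
      stop(sprintf("loss of term(s) %s at node %s without a prior gain",
                   paste(orphan, collapse = ", "), node$stable_id),
           call. = FALSE)
    }
    carried <- setdiff(carried, lost)
    acc$terms[[node$stable_id]] <- carried
    for (ch in node$children) rec(ch, carried)
    invisible(NULL)
  }
  rec(rt$tree$root, character(0))
  acc$terms
}
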