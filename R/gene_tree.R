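# Gene trees: rooted, event-labeled family trees. Nodes are extant genes
# (leaves), ancestral genes (speciation or inserted ancestors), duplications,
# and explicit loss leaves labeled with the first ancestral species inferred
# to have been missing the gene.

GENE_EVENTS <- c("extant", "speciation", "duplication", "inserted_ancestor", "loss")

gnode <- function(node_id, event = NA_character_, taxon = NA_character_,
                  gene_id = NA_character_, blen = 0,
                  stable_id = NA_character_, name = NA_character_,
                  children = list()) {
  list(node_id = node_id, event = event, taxon = taxon, gene_id = gene_id,
       blen = blen, stable_id = stable_id, name = name, children = children)
}

new_gene_tree <- function(family_id, root) {
  structure(list(family_id = family_id, root = root), class = "gene_tree")
}

#' Read a gene family tree from NHX-annotated Newick
#'
#' Leaves are extant genes: the leaf label is the gene identifier and the NHX
#' tag `S=` names its species. Internal nodes may carry `Ev=` (speciation or
#' duplication, trusted if present) and `S=`; untagged internal nodes are left
#' unresolved for [map_taxa()]. Leaves labeled `LOSS` (or tagged `Ev=loss`)
#' are explicit gene-loss markers, as written by [write_gene_tree()]. Missing
#' branch lengths default to 0.
#'
#' @param path Path to a Newick/NHX file.
#' @param text Alternatively, the Newick string itself.
#' @param family_id Family identifier; defaults to the file name without
#'   extension (or `"FAM"` when reading from text).
#' @param stree Optional `species_tree`; if given, every leaf species is
#'   checked against it.
#' @return A `gene_tree` object.
#' @examples
#' gt <- read_gene_tree(text =
#'   "(G_g1[&&NHX:S=gorilla],(M_g1[&&NHX:S=mouse],R_g1[&&NHX:S=rat]));")
#' @export
read_gene_tree <- function(path = NULL, text = NULL, family_id = NULL,
                           stree = NULL) {
  if (is.null(family_id)) {
    family_id <- if (!is.null(path)) {
      sub("\\.[^.]*$", "", basename(path))
    } else "FAM"
  }
  parsed <- nwk_parse(read_text_or_path(path, text))
  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  build <- function(node) {
    counter$i <- counter$i + 1L
    id <- sprintf("n%d", counter$i)
    tags <- node$nhx
    ev <- nhx_tag(tags, "Ev")
    is_leaf <- !length(node$children)
    if (is_leaf && (identical(node$label, "LOSS") || identical(ev, "loss"))) {
      taxon <- nhx_tag(tags, "S")
      if (is.na(taxon)) {
        stop("gene tree format error: loss leaf without S= taxon tag",
             call. = FALSE)
      }
      return(gnode(id, event = "loss", taxon = taxon,
                   blen = node$blen %||% NA_real_))
    }
    if (is_leaf) {
      if (!nzchar(node$label)) {
        stop("gene tree format error: unlabeled leaf (gene_id required)",
             call. = FALSE)
      }
      sp <- nhx_tag(tags, "S")
      if (is.na(sp)) {
        stop(sprintf("gene tree format error: leaf '%s' lacks an S= species tag",
                     node$label), call. = FALSE)
      }
      if (!is.null(stree) && !sp %in% stree$taxa) {
        stop(sprintf("unknown species '%s' on leaf '%s'", sp, node$label),
             call. = FALSE)
      }
      return(gnode(id, event = "extant", taxon = sp, gene_id = node$label,
                   blen = node$blen))
    }
    if (!is.na(ev) && !ev %in% GENE_EVENTS) {
      stop(sprintf("gene tree format error: unknown event tag 'Ev=%s'", ev),
           call. = FALSE)
    }
    kids <- lapply(node$children, build)
    gnode(id, event = ev, taxon = nhx_tag(tags, "S"),
          blen = node$blen, stable_id = nhx_tag(tags, "ID"),
          children = kids)
  }
  root <- build(parsed)
  root <- fix_blen(root)
  new_gene_tree(family_id, root)
}

# Missing branch lengths default to 0 (edge-count fallback for distances).
fix_blen <- function(node) {
  if (is.na(node$blen)) node$blen <- 0
  node$children <- lapply(node$children, fix_blen)
  node
}

#' Serialize a gene tree to NHX-annotated Newick
#'
#' Writes `S=` (taxon), `Ev=` (event kind) and `ID=` (stable identifier) tags
#' where set; loss leaves are written as leaves labeled `LOSS`. The output can
#' be read back with [read_gene_tree()] without information loss.
#'
#' @param tree A `gene_tree`.
#' @param path Output file; omit to return the Newick string.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_gene_tree <- function(tree, path = NULL) {
  fmt <- function(node) {
    if (length(node$children) == 0L &&
        !node$event %in% c("extant", "loss")) {
      stop(sprintf("invalid gene tree: childless internal node '%s' (event %s)",
                   node$node_id, node$event), call. = FALSE)
    }
    tags <- character(0)
    if (!is.na(node$taxon)) tags[["S"]] <- node$taxon
    if (!is.na(node$event)) tags[["Ev"]] <- node$event
    if (!is.na(node$stable_id)) tags[["ID"]] <- node$stable_id
    label <- if (identical(node$event, "loss")) "LOSS" else node$gene_id
    if (is.na(label)) label <- ""
    list(label = label, blen = node$blen, nhx = as.list(tags),
         children = lapply(node$children, fmt))
  }
  out <- paste0(nwk_format(fmt(tree$root)), ";")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

# --- traversal helpers -------------------------------------------------------

# Flat preorder list of nodes (copies), each augmented with parent_id.
gt_nodes <- function(tree) {
  acc <- new.env(parent = emptyenv())
  acc$out <- vector("list", 0L)
  walk <- function(node, parent_id) {
    rec <- node
    rec$children <- NULL
    rec$parent_id <- parent_id
    rec$n_children <- length(node$children)
    acc$out[[length(acc$out) + 1L]] <- rec
    for (ch in node$children) walk(ch, node$node_id)
  }
  walk(tree$root, NA_character_)
  acc$out
}

#' Tabulate the nodes of a gene tree
#'
#' @param x A `gene_tree` (or `reconciled_tree`).
#' @param ... Unused.
#' @return A data frame with one row per node: node_id, parent_id, event,
#'   taxon, gene_id, stable_id, name, branch length and child count, in
#'   preorder.
#' @export
as.data.frame.gene_tree <- function(x, ...) {
  nodes <- gt_nodes(x)
  data.frame(
    node_id = vapply(nodes, `[[`, character(1), "node_id"),
    parent_id = vapply(nodes, `[[`, character(1), "parent_id"),
    event = vapply(nodes, `[[`, character(1), "event"),
    taxon = vapply(nodes, `[[`, character(1), "taxon"),
    gene_id = vapply(nodes, `[[`, character(1), "gene_id"),
    stable_id = vapply(nodes, `[[`, character(1), "stable_id"),
    name = vapply(nodes, `[[`, character(1), "name"),
    blen = vapply(nodes, `[[`, numeric(1), "blen"),
    n_children = vapply(nodes, `[[`, integer(1), "n_children"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.gene_tree <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("gene_tree '%s': %d nodes (%d extant, %d losses)\n",
              x$family_id, nrow(df), sum(df$event %in% "extant"),
              sum(df$event %in% "loss")))
  invisible(x)
}

# Extant leaves under a node (list of node records).
gt_extant_leaves <- function(node) {
  if (!length(node$children)) {
    if (identical(node$event, "extant")) return(list(node))
    return(list())
  }
  unlist(lapply(node$children, gt_extant_leaves), recursive = FALSE)
}

# Find the subtree rooted at the node with the given stable_id or node_id.
gt_find <- function(node, id) {
  if (identical(node$stable_id, id) || identical(node$node_id, id)) return(node)
  for (ch in node$children) {
    hit <- gt_find(ch, id)
    if (!is.null(hit)) return(hit)
  }
  NULL
}
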