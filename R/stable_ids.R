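# Deterministic stable identifiers for ancestral (and extant) gene-tree
# nodes. IDs must survive re-serialization and be independent of child order
# in the input file, so they are preorder indices on a canonicalized tree.

#' Assign deterministic stable identifiers
#'
#' The tree is canonicalized by sorting every node's children by the
#' lexicographically smallest extant gene identifier in their subtree (loss
#' leaves, which contain no genes, sort last, by taxon). Every non-loss node
#' then receives `family_id:NNNN`, its zero-padded preorder index among
#' non-loss nodes of the canonical tree (the root is index 0). Identical
#' trees -- including trees that differ only by child order -- always receive
#' identical identifiers. The returned tree keeps the canonical child order,
#' so serialization is deterministic too.
#'
#' @param x A `gene_tree` or `reconciled_tree` with events resolved.
#' @return The same class of object, with `stable_id` set on non-loss nodes.
#' @export
assign_stable_ids <- function(x) {
  rt <- NULL
  if (inherits(x, "reconciled_tree")) {
    rt <- x
    tree <- x$tree
  } else {
    tree <- x
  }
  if (anyNA(vapply(gt_nodes(tree), `[[`, character(1), "event"))) {
    stop("stable IDs require resolved events; run map_taxa()/infer_losses()",
         call. = FALSE)
  }
  sortkey <- function(node) {
    if (identical(node$event, "extant")) return(node$gene_id)
    if (identical(node$event, "loss")) return(paste0("~LOSS~", node$taxon))
    min(vapply(node$children, sortkey, character(1)))
  }
  canon <- function(node) {
    if (length(node$children)) {
      node$children <- lapply(node$children, canon)
      keys <- vapply(node$children, sortkey, character(1))
      node$children <- node$children[order(keys, method = "radix")]
    }
    node
  }
  tree$root <- canon(tree$root)
  n_nonloss <- sum(vapply(gt_nodes(tree), function(n) n$event != "loss",
                          logical(1)))
  width <- max(4L, nchar(as.character(max(n_nonloss - 1L, 0L))))
  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  number <- function(node) {
    if (!identical(node$event, "loss")) {
      node$stable_id <- sprintf("%s:%0*d", tree$family_id, width, counter$i)
      counter$i <- counter$i + 1L
    }
    node$children <- lapply(node$children, number)
    node
  }
  tree$root <- number(tree$root)
  if (!is.null(rt)) {
    rt$tree <- tree
    return(rt)
  }
  tree
}
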