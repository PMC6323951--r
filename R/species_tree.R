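# Species tree: a rooted, possibly multifurcating taxonomy. Internal nodes are
# the ancestral species whose genomes get reconstructed; every node (extant
# leaf or ancestor) carries a unique taxon label.

new_species_tree <- function(taxa, parent, children, blen, age, root) {
  structure(list(taxa = taxa, parent = parent, children = children,
                 blen = blen, age = age, root = root),
            class = "species_tree")
}

#' Read a rooted species tree from Newick
#'
#' Internal nodes must be labeled: the labels are the taxon identifiers to
#' which ancestral genomes attach. Multifurcations are allowed (and common in
#' real taxonomies, e.g. at the base of eubacteria or eumetazoa). Child order
#' from the file is preserved. Optional node ages (millions of years) may be
#' supplied as NHX tags `A=`.
#'
#' @param path Path to a Newick file.
#' @param text Alternatively, the Newick string itself.
#' @return A `species_tree` object.
#' @examples
#' st <- read_species_tree(text = "(((human,chimp)HC,gorilla)HCG,(mouse,rat)MR)ROOT;")
#' species_leaves(st, "HCG")
#' @export
read_species_tree <- function(path = NULL, text = NULL) {
  root <- nwk_parse(read_text_or_path(path, text))
  taxa <- character(0)
  parent <- character(0)
  children <- list()
  blen <- numeric(0)
  age <- numeric(0)
  walk <- function(node, par, pos) {
    lab <- node$label
    if (!nzchar(lab)) {
      stop(sprintf("species tree format error: unlabeled %s node (child position %s)",
                   if (length(node$children)) "internal" else "leaf", pos),
           call. = FALSE)
    }
    if (lab %in% taxa) {
      stop(sprintf("species tree format error: duplicate taxon_id '%s'", lab),
           call. = FALSE)
    }
    if (length(node$children) == 1L) {
      stop(sprintf("species tree format error: internal node '%s' has a single child",
                   lab), call. = FALSE)
    }
    taxa[[length(taxa) + 1L]] <<- lab
    parent[[lab]] <<- par
    blen[[lab]] <<- node$blen
    age[[lab]] <<- suppressWarnings(as.numeric(nhx_tag(node$nhx, "A")))
    kids <- character(length(node$children))
    for (k in seq_along(node$children)) {
      kids[[k]] <- walk(node$children[[k]], lab, paste0(pos, ".", k))
    }
    children[[lab]] <<- kids
    lab
  }
  rootlab <- walk(root, NA_character_, "1")
  new_species_tree(taxa, parent, children, blen, age, rootlab)
}

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("species_tree: %d taxa (%d extant, %d ancestral), root '%s'\n",
              length(x$taxa), length(species_leaves(x)),
              length(x$taxa) - length(species_leaves(x)), x$root))
  invisible(x)
}

#' Species-tree accessors
#'
#' `species_children` returns the ordered child taxa of a node (empty for an
#' extant species); `species_leaves` the extant species in the clade under
#' `taxon`; `species_ancestors` the chain from `taxon` up to the root
#' (inclusive of both); `species_lca` the last common ancestor of a set of
#' taxa; `species_path` the taxa on the descending path between an ancestor
#' and a descendant (inclusive of both ends); `species_is_ancestor` tests the
#' ancestor-or-equal relation.
#'
#' @param st A `species_tree`.
#' @param taxon,taxa,ancestor,descendant,a,b Taxon identifiers.
#' @name species_tree_accessors
NULL

#' @rdname species_tree_accessors
#' @export
species_children <- function(st, taxon) {
  st$children[[taxon]] %||% character(0)
}

#' @rdname species_tree_accessors
#' @export
species_leaves <- function(st, taxon = st$root) {
  kids <- species_children(st, taxon)
  if (!length(kids)) return(taxon)
  unlist(lapply(kids, function(k) species_leaves(st, k)), use.names = FALSE)
}

#' @rdname species_tree_accessors
#' @export
species_ancestors <- function(st, taxon) {
  stopifnot(taxon %in% st$taxa)
  out <- taxon
  while (!is.na(st$parent[[taxon]])) {
    taxon <- st$parent[[taxon]]
    out <- c(out, taxon)
  }
  out
}

#' @rdname species_tree_accessors
#' @export
species_is_ancestor <- function(st, a, b) {
  a %in% species_ancestors(st, b)
}

#' @rdname species_tree_accessors
#' @export
species_lca <- function(st, taxa) {
  taxa <- unique(taxa)
  bad <- setdiff(taxa, st$taxa)
  if (length(bad)) {
    stop(sprintf("unknown species: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  chain <- species_ancestors(st, taxa[[1L]])
  for (t in taxa[-1L]) {
    chain <- chain[chain %in% species_ancestors(st, t)]
  }
  chain[[1L]]
}

#' @rdname species_tree_accessors
#' @export
species_path <- function(st, ancestor, descendant) {
  chain <- species_ancestors(st, descendant)
  k <- match(ancestor, chain)
  if (is.na(k)) {
    stop(sprintf("'%s' is not an ancestor of '%s'", ancestor, descendant),
         call. = FALSE)
  }
  rev(chain[seq_len(k)])
}

# Root-to-node total branch length (used by the simulator's calibration).
species_depth <- function(st, taxon) {
  chain <- species_ancestors(st, taxon)
  sum(st$blen[chain[-length(chain)]], na.rm = TRUE)
}

# First step from taxon `a` on the path down to `b` (a strict ancestor of b).
species_first_step <- function(st, a, b) {
  species_path(st, a, b)[[2L]]
}
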