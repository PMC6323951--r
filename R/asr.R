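# Ancestral protein sequence reconstruction by per-column plurality voting,
# working from the leaves toward the root. Gaps are votable states, so
# insertions and deletions are reconstructed the same way as substitutions.
# Ties are broken by the nearest outgroup sequences; unresolved sites get the
# unknown symbol 'X'.

# Flatten a gene tree into parallel arrays for fast repeated traversal.
gt_index <- function(tree) {
  acc <- new.env(parent = emptyenv())
  acc$event <- character(0); acc$gene_id <- character(0)
  acc$taxon <- character(0)
  acc$stable_id <- character(0); acc$node_id <- character(0)
  acc$blen <- numeric(0); acc$parent <- integer(0)
  acc$children <- list(); acc$post <- integer(0)
  walk <- function(node, parent) {
    i <- length(acc$event) + 1L
    acc$event[i] <- node$event; acc$gene_id[i] <- node$gene_id
    acc$taxon[i] <- node$taxon
    acc$stable_id[i] <- node$stable_id; acc$node_id[i] <- node$node_id
    acc$blen[i] <- node$blen; acc$parent[i] <- parent
    acc$children[[i]] <- integer(0)
    for (ch in node$children) {
      j <- walk(ch, i)
      acc$children[[i]] <- c(acc$children[[i]], j)
    }
    acc$post <- c(acc$post, i)
    i
  }
  walk(tree$root, NA_integer_)
  n <- length(acc$event)
  depth <- numeric(n)
  for (i in seq_len(n)) {  # preorder: parents precede children
    depth[i] <- if (is.na(acc$parent[i])) 0 else depth[acc$parent[i]] + acc$blen[i]
  }
  subtree <- vector("list", n)
  for (i in acc$post) {
    subtree[[i]] <- if (!length(acc$children[[i]])) i else
      unlist(subtree[acc$children[[i]]], use.names = FALSE)
  }
  list(n = n, event = acc$event, gene_id = acc$gene_id, taxon = acc$taxon,
       stable_id = acc$stable_id, node_id = acc$node_id, blen = acc$blen,
       parent = acc$parent, children = acc$children, postorder = acc$post,
       depth = depth, subtree = subtree)
}

# Ancestor chain of node i (indices, self first).
gt_chain <- function(ix, i) {
  out <- i
  while (!is.na(ix$parent[i])) {
    i <- ix$parent[i]
    out <- c(out, i)
  }
  out
}

# Path branch length between two nodes.
gt_path_length <- function(ix, a, b) {
  ca <- gt_chain(ix, a)
  cb <- gt_chain(ix, b)
  lca <- ca[ca %in% cb][1L]
  ix$depth[a] + ix$depth[b] - 2 * ix$depth[lca]
}

# One column's vote. `votes`: states of the primary voters ('X' abstains,
# loss voters are excluded before the call). `out_states`: states of the
# nearest outgroup leaves, counted only toward already-tied states.
vote_column <- function(votes, out_states) {
  votes <- votes[votes != "X"]
  if (!length(votes)) return("X")
  tab <- table(votes)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1L) return(winners)
  if (length(out_states)) {
    extra <- table(factor(out_states[out_states %in% winners], levels = winners))
    tab2 <- as.integer(tab[winners]) + as.integer(extra)
    w2 <- winners[tab2 == max(tab2)]
    if (length(w2) == 1L) return(w2)
  }
  "X"
}

#' Reconstruct ancestral protein sequences by plurality voting
#'
#' Works column by column from the leaves toward the root. At each ancestral
#' node a vote is tallied: in the default `"children"` mode each immediate
#' child casts one vote with its own state at that column (a leaf votes its
#' alignment state, an internal child its already-reconstructed state); in
#' `"leaves"` mode every extant leaf of the subtree votes. Loss leaves cast no
#' vote and the unknown symbol `X` abstains; the gap `-` is an ordinary
#' votable state, so indels are reconstructed like substitutions. A unique
#' plurality wins. On a tie, the nearest outgroup sequences (extant leaves
#' outside the subtree at minimal path branch length, all ties included) add
#' their votes -- but only to the tied states, so an outgroup cannot introduce
#' a new state. A still-unresolved site becomes `X`. The root has no outgroup,
#' so root ties go straight to `X`.
#'
#' @param rt A `reconciled_tree` with stable identifiers assigned
#'   ([assign_stable_ids()]).
#' @param aln The family's `family_alignment`; every extant leaf must have a
#'   row.
#' @param mode `"children"` (default) or `"leaves"`: who casts the primary
#'   votes.
#' @return An `ancestral_sequences` object: `family_id`, `rows` (named
#'   character vector, stable_id to aligned sequence, one row per non-loss
#'   ancestral node) and `width`.
#' @export
reconstruct_ancestral <- function(rt, aln, mode = c("children", "leaves")) {
  mode <- match.arg(mode)
  stopifnot(inherits(rt, "reconciled_tree"))
  ix <- gt_index(rt$tree)
  internal <- which(!ix$event %in% c("extant", "loss"))
  if (any(is.na(ix$stable_id[internal]))) {
    stop("stable IDs missing; run assign_stable_ids() before reconstruction",
         call. = FALSE)
  }
  leaves <- which(ix$event == "extant")
  missing <- setdiff(ix$gene_id[leaves], names(aln$rows))
  if (length(missing)) {
    stop(sprintf("no alignment row for gene(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  W <- aln$width
  states <- vector("list", ix$n)
  for (i in leaves) {
    s <- strsplit(aln$rows[[ix$gene_id[i]]], "")[[1]]
    if (length(s) != W) {
      stop(sprintf("alignment width mismatch for '%s' (%d != %d)",
                   ix$gene_id[i], length(s), W), call. = FALSE)
    }
    states[[i]] <- s
  }
  # nearest outgroup leaves per internal node (indices; empty at the root)
  outgrp <- vector("list", ix$n)
  for (v in internal) {
    cand <- setdiff(leaves, ix$subtree[[v]])
    if (!length(cand)) { outgrp[[v]] <- integer(0); next }
    d <- vapply(cand, function(l) gt_path_length(ix, v, l), numeric(1))
    outgrp[[v]] <- cand[d == min(d)]
  }
  for (v in ix$postorder) {
    if (!v %in% internal) next
    voters <- if (mode == "children") {
      setdiff(ix$children[[v]], which(ix$event == "loss"))
    } else {
      intersect(ix$subtree[[v]], leaves)
    }
    vm <- do.call(rbind, states[voters])           # voters x W
    om <- do.call(rbind, states[outgrp[[v]]])      # outgroup x W (or NULL)
    states[[v]] <- if (is.null(vm)) rep("X", W) else {
      vapply(seq_len(W), function(col) {
        vote_column(vm[, col], if (is.null(om)) character(0) else om[, col])
      }, character(1))
    }
  }
  rows <- vapply(internal, function(v) paste(states[[v]], collapse = ""),
                 character(1))
  names(rows) <- ix$stable_id[internal]
  structure(list(family_id = rt$tree$family_id, rows = rows, width = W,
                 node_id = setNames(ix$node_id[internal],
                                    ix$stable_id[internal])),
            class = "ancestral_sequences")
}

#' @export
print.ancestral_sequences <- function(x, ...) {
  cat(sprintf("ancestral_sequences '%s': %d rows, width %d\n",
              x$family_id, length(x$rows), x$width))
  invisible(x)
}
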