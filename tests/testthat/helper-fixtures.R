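# Shared fixtures: the five-primate/rodent example tree, random tree and
# family generators, and independent brute-force oracles used to cross-check
# the reconciliation, proxy and GO code paths.

PRIMATE_NWK <- "(((human:1,chimp:1)HC:1,gorilla:2)HCG:1,(mouse:1.5,rat:1.5)MR:1.5)ROOT;"

primate_tree <- function() read_species_tree(text = PRIMATE_NWK)

# Family present in gorilla, mouse and rat only: the worked example whose
# most parsimonious explanation is a single loss before the human-chimp
# common ancestor.
worked_family <- function() {
  read_gene_tree(
    text = "(G_g1[&&NHX:S=gorilla]:2,(M_g1[&&NHX:S=mouse]:1,R_g1[&&NHX:S=rat]:1):1.5);",
    family_id = "FAM1")
}

reconcile1 <- function(gt, st) {
  assign_stable_ids(infer_losses(map_taxa(gt, st), st))
}

# Random rooted species tree with branch lengths; occasionally multifurcating.
rand_species_tree <- function(n_leaves, seed, multif = TRUE) {
  set.seed(seed)
  parts <- sprintf("s%d:%.3f", seq_len(n_leaves),
                   stats::runif(n_leaves, 0.2, 2))
  ai <- 0L
  while (length(parts) > 1L) {
    k <- if (multif && length(parts) >= 3L && stats::runif(1) < 0.25) 3L else 2L
    idx <- sample(length(parts), k)
    ai <- ai + 1L
    parts <- c(parts[-idx],
               sprintf("(%s)a%d:%.3f", paste(parts[idx], collapse = ","), ai,
                       stats::runif(1, 0.2, 2)))
  }
  read_species_tree(text = paste0(parts, ";"))
}

# Duplication-free family: the species tree restricted to a random subset of
# present species, one gene per species (congruent topology).
rand_presence_family <- function(st, seed, present = NULL) {
  set.seed(seed)
  leaves <- species_leaves(st)
  if (is.null(present)) {
    present <- sample(leaves, sample(seq_along(leaves), 1L))
  }
  rec <- function(taxon) {
    kids <- species_children(st, taxon)
    if (!length(kids)) {
      if (!taxon %in% present) return(NULL)
      return(sprintf("%s_g1[&&NHX:S=%s]:%.3f", toupper(taxon), taxon,
                     stats::runif(1, 0.1, 1)))
    }
    sub <- Filter(Negate(is.null), lapply(kids, rec))
    if (!length(sub)) return(NULL)
    if (length(sub) == 1L) return(sub[[1L]])
    sprintf("(%s):%.3f", paste(unlist(sub), collapse = ","),
            stats::runif(1, 0.1, 1))
  }
  txt <- rec(st$root)
  list(tree = read_gene_tree(text = paste0(txt, ";"), family_id = "RF"),
       present = present)
}

# Random binary gene tree over genes drawn (with replacement) from the
# species pool: duplications arise wherever the topology forces them. Gene
# identifiers embed the family id so multi-family pipelines never collide.
rand_gene_tree <- function(st, seed, n_genes = NULL, family_id = "RG") {
  set.seed(seed)
  leaves <- species_leaves(st)
  if (is.null(n_genes)) n_genes <- sample(2:10, 1L)
  sp <- sample(leaves, n_genes, replace = TRUE)
  cnt <- stats::setNames(integer(length(leaves)), leaves)
  parts <- character(n_genes)
  for (i in seq_len(n_genes)) {
    cnt[sp[i]] <- cnt[sp[i]] + 1L
    parts[i] <- sprintf("%s_%s_g%d[&&NHX:S=%s]:%.3f", sp[i], family_id,
                        cnt[sp[i]], sp[i], stats::runif(1, 0.1, 1))
  }
  while (length(parts) > 1L) {
    idx <- sample(length(parts), 2L)
    parts <- c(parts[-idx],
               sprintf("(%s):%.3f", paste(parts[idx], collapse = ","),
                       stats::runif(1, 0.1, 1)))
  }
  read_gene_tree(text = paste0(parts, ";"), family_id = family_id)
}

# Independent loss-count oracle for arbitrary (duplication-bearing) mapped
# gene trees: decompose into duplicate-copy units (cutting at duplication
# nodes), then cost each unit by exhaustive Dollo enumeration with the origin
# forced at the duplication's taxon and nested duplication taxa treated as
# present terminals. Uses only map_taxa() output and dollo_min_losses();
# never the loss-insertion code.
oracle_losses <- function(mapped_tree, st) {
  total <- 0L
  frontier <- function(node) {
    if (identical(node$event, "extant")) {
      return(list(species = node$taxon, dups = character(0)))
    }
    if (identical(node$event, "duplication")) {
      return(list(species = character(0), dups = node$taxon))
    }
    sp <- character(0); du <- character(0)
    for (ch in node$children) {
      f <- frontier(ch)
      sp <- c(sp, f$species); du <- c(du, f$dups)
    }
    list(species = sp, dups = du)
  }
  visit_dups <- function(node) {
    if (identical(node$event, "duplication")) {
      for (ch in node$children) start_unit(ch, node$taxon)
    } else if (!identical(node$event, "extant")) {
      for (ch in node$children) visit_dups(ch)
    }
  }
  start_unit <- function(node, origin) {
    f <- frontier(node)
    total <<- total + dollo_min_losses(
      st, unique(f$species), origin = origin,
      force_present = unique(f$dups), truncate = unique(f$dups))
    visit_dups(node)
  }
  root <- mapped_tree$root
  if (identical(root$event, "duplication")) {
    visit_dups(root)
  } else if (!identical(root$event, "extant")) {
    start_unit(root, root$taxon)
  }
  total
}

# Internal traversal helpers reused by oracles in the tests.
gt_extant_leaves_pub <- function(node) paleogene:::gt_extant_leaves(node)

# Plain Newick (no NHX, sanitized labels) for cross-checks with ape.
plain_newick <- function(tree) {
  fmt <- function(node) {
    lab <- if (identical(node$event, "loss")) {
      paste0("LOSS_", node$node_id)
    } else if (identical(node$event, "extant")) {
      node$gene_id
    } else {
      node$stable_id
    }
    lab <- gsub("[^A-Za-z0-9_]", "_", lab)
    if (!length(node$children)) return(sprintf("%s:%.8f", lab, node$blen))
    sprintf("(%s)%s:%.8f",
            paste(vapply(node$children, fmt, character(1)), collapse = ","),
            lab, node$blen)
  }
  paste0(fmt(tree$root), ";")
}

# Random child-order permutation of a gene tree.
permute_children <- function(tree, seed) {
  set.seed(seed)
  rec <- function(node) {
    if (length(node$children)) {
      node$children <- lapply(node$children, rec)
      node$children <- node$children[sample(length(node$children))]
    }
    node
  }
  tree$root <- rec(tree$root)
  tree
}

# Simulated families drive several property tests; drop extinct replicates.
sim_observed <- function(st, params) {
  fam <- simulate_family(st, params)
  if (is.null(fam$observed_tree)) return(NULL)
  fam
}
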