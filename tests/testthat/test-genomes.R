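# Ancestral genome assembly, duplication-aware naming, and GO propagation.

test_that("worked example genome membership", {
  st <- primate_tree()
  rt <- reconcile1(worked_family(), st)
  expect_identical(nrow(assemble_genome("ROOT", list(rt))), 1L)
  expect_identical(nrow(assemble_genome("HCG", list(rt))), 1L)  # inserted node
  expect_identical(nrow(assemble_genome("HC", list(rt))), 0L)   # lost before HC
  expect_identical(nrow(assemble_genome("MR", list(rt))), 1L)
  expect_error(assemble_genome("human", list(rt)), "extant species")
  expect_identical(nrow(assemble_genome("ROOT", list())), 0L)
})

test_that("a pre-divergence duplication doubles the descendant genome", {
  st <- primate_tree()
  gt <- read_gene_tree(text = paste0(
    "((Ma[&&NHX:S=mouse],Ra[&&NHX:S=rat]),",
    "(Mb[&&NHX:S=mouse],Rb[&&NHX:S=rat]));"), family_id = "DUP")
  rt <- reconcile1(gt, st)
  expect_identical(nrow(assemble_genome("MR", list(rt))), 2L)
})

test_that("genome sizes conserve the ancestral node count", {
  for (seed in 1:10) {
    st <- rand_species_tree(sample(4:6, 1), seed + 60)
    fams <- lapply(1:4, function(i) {
      reconcile1(rand_gene_tree(st, seed * 100 + i,
                                family_id = sprintf("F%d", i)), st)
    })
    internal <- setdiff(st$taxa, species_leaves(st))
    sizes <- vapply(internal, function(tx) {
      nrow(assemble_genome(tx, fams))
    }, integer(1))
    n_anc <- sum(vapply(fams, function(rt) {
      df <- as.data.frame(rt$tree)
      sum(df$event %in% c("speciation", "inserted_ancestor"))
    }, integer(1)))
    expect_identical(sum(sizes), n_anc)
    # the family-root taxon always holds at least one gene
    for (rt in fams) {
      root_taxon <- rt$tree$root$taxon
      if (root_taxon %in% internal) {
        expect_gte(nrow(assemble_genome(root_taxon, fams)), 1L)
      }
    }
  }
})

test_that("names propagate along lineages and restart at duplications", {
  st <- primate_tree()
  # no duplications: every ancestor named after the human descendant
  fam <- rand_presence_family(st, 5, present = species_leaves(st))
  rt <- reconcile1(fam$tree, st)
  named <- propagate_names(rt, c("human", "mouse"))
  df <- as.data.frame(named$tree)
  anc <- df[df$event %in% c("speciation", "inserted_ancestor"), ]
  expect_true(all(anc$name == "HUMAN_g1"))

  # duplication with copy A in human+mouse and copy B in mouse only:
  # A named from human, B unnamed (single genome)
  gt <- read_gene_tree(text = paste0(
    "((Ha[&&NHX:S=human]:1,Ma[&&NHX:S=mouse]:1):1,",
    "Mb[&&NHX:S=mouse]:2);"), family_id = "D1")
  rtd <- propagate_names(reconcile1(gt, st), c("human", "mouse"))
  dfd <- as.data.frame(rtd$tree)
  copyA <- dfd[dfd$event == "speciation" & dfd$taxon == "ROOT" &
                 dfd$n_children > 0, ]
  expect_true(all(copyA$name == "Ha"))
  # copy B's inserted ancestors (lineage to Mb alone) stay unnamed
  mb_branch <- dfd[dfd$event == "inserted_ancestor", ]
  lineageB <- mb_branch[vapply(mb_branch$node_id, function(id) {
    sub <- paleogene:::gt_find(rtd$tree$root, id)
    genes <- vapply(gt_extant_leaves_pub(sub), `[[`, character(1), "gene_id")
    identical(genes, "Mb")
  }, logical(1)), ]
  expect_gt(nrow(lineageB), 0L)
  expect_true(all(is.na(lineageB$name)))

  # both copies with human descendants get distinct names from their own proxy
  gt2 <- read_gene_tree(text = paste0(
    "((Ha[&&NHX:S=human]:1,Ma[&&NHX:S=mouse]:1):1,",
    "(Hb[&&NHX:S=human]:1,Mb[&&NHX:S=mouse]:1):1);"), family_id = "D2")
  rt2 <- propagate_names(reconcile1(gt2, st), "human")
  df2 <- as.data.frame(rt2$tree)
  spec_names <- df2$name[df2$event == "speciation" & df2$taxon == "ROOT"]
  expect_setequal(spec_names, c("Ha", "Hb"))
  expect_error(propagate_names(rt, character(0)), "at least one")
})

test_that("GO terms propagate top-down with gains and losses", {
  st <- primate_tree()
  rt <- reconcile1(worked_family(), st)
  df <- as.data.frame(rt$tree)
  root_id <- rt$tree$root$stable_id
  mr_id <- df$stable_id[df$event == "speciation" & df$taxon == "MR"]
  # gain at root, no losses: everywhere
  ev <- data.frame(stable_id = root_id, term = "GO:0001", direction = "gain")
  terms <- propagate_go(rt, ev)
  expect_true(all(vapply(terms, function(x) "GO:0001" %in% x, logical(1))))
  # loss at the MR node removes it from MR and its descendants only
  ev2 <- rbind(ev, data.frame(stable_id = mr_id, term = "GO:0001",
                              direction = "loss"))
  terms2 <- propagate_go(rt, ev2)
  mr_clade <- c(mr_id, df$stable_id[df$taxon %in% c("mouse", "rat")])
  for (sid in names(terms2)) {
    if (sid %in% mr_clade) {
      expect_false("GO:0001" %in% terms2[[sid]])
    } else {
      expect_true("GO:0001" %in% terms2[[sid]])
    }
  }
  # loss without a prior gain is a validation error
  bad <- data.frame(stable_id = mr_id, term = "GO:0009", direction = "loss")
  expect_error(propagate_go(rt, bad), "without a prior gain")
  expect_error(propagate_go(rt, data.frame(stable_id = "nope", term = "t",
                                           direction = "gain")),
               "unknown node")
})

test_that("randomized GO event sets match a per-node path scan", {
  for (seed in 1:10) {
    st <- rand_species_tree(5, seed + 70)
    rt <- reconcile1(rand_gene_tree(st, seed + 700, n_genes = 6), st)
    df <- as.data.frame(rt$tree)
    ids <- df$stable_id[df$event != "loss"]
    set.seed(seed)
    terms <- sprintf("GO:%04d", 1:3)
    # random gains, then random losses placed below a gain
    ev <- data.frame(stable_id = sample(ids, 4, replace = TRUE),
                     term = sample(terms, 4, replace = TRUE),
                     direction = "gain", stringsAsFactors = FALSE)
    # path map: stable_id -> chain of ancestors (self first)
    parent <- setNames(df$parent_id, df$node_id)
    sid_of <- setNames(df$stable_id, df$node_id)
    nid_of <- setNames(df$node_id, df$stable_id)
    chain <- function(sid) {
      nid <- nid_of[[sid]]
      out <- character(0)
      while (!is.na(nid)) {
        out <- c(out, sid_of[[nid]])
        nid <- parent[[nid]]
      }
      out
    }
    for (g in seq_len(nrow(ev))) {
      below <- ids[vapply(ids, function(s) ev$stable_id[g] %in% chain(s),
                          logical(1))]
      if (length(below) && runif(1) < 0.5) {
        ev <- rbind(ev, data.frame(stable_id = sample(below, 1),
                                   term = ev$term[g], direction = "loss",
                                   stringsAsFactors = FALSE))
      }
    }
    got <- tryCatch(propagate_go(rt, ev), error = function(e) NULL)
    if (is.null(got)) next  # a loss masked by an earlier same-node loss
    # oracle: root-to-node scan applying gains then losses at each step
    for (sid in ids) {
      path <- rev(chain(sid))
      have <- character(0)
      for (p in path) {
        evp <- ev[ev$stable_id == p, , drop = FALSE]
        have <- union(have, evp$term[evp$direction == "gain"])
        have <- setdiff(have, evp$term[evp$direction == "loss"])
      }
      expect_setequal(got[[sid]], have)
    }
  }
})
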