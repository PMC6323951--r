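---
title: "Reconstructing ancestral genes and genomes with paleogene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing ancestral genes and genomes with paleogene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleogene)
```

## The problem

Given a rooted species tree and a library of rooted gene family trees (with
protein alignments), we can infer which protein-coding genes were present in
the genome of each common ancestor of the extant species: every speciation
node in a reconciled gene tree is a gene that existed in an ancestral genome.
`paleogene` implements this reconstruction end to end:

1. **Reconciliation** maps every gene-tree node to a species-tree taxon and
   labels it a speciation or a duplication (`map_taxa()`).
2. **Loss inference** adds an explicit node for every ancestral gene a
   lineage passed through, and an explicit loss leaf wherever a gene
   disappeared, placed by maximum parsimony (`infer_losses()`).
3. **Sequence reconstruction** infers each ancestral protein sequence by
   per-column plurality voting (`reconstruct_ancestral()`).
4. **Genome assembly** collects, for any internal taxon, the ancestral genes
   across families, with stable identifiers, inherited protein names,
   propagated GO terms and proxy genes (`assemble_genome()` and friends).
5. **Comparison** partitions an extant genome against any of its ancestors
   into inherited, lost, gained and untraced genes (`compare_genomes()`).

A birth–death simulator (`simulate_family()`, `evolve_sequences()`) generates
families with a fully known event and sequence history, so every step above
is validated against ground truth without any external data.

## Loss inference by maximum parsimony

A gene absent from some species clade can be explained by one early deletion
or by many late ones; the principle adopted here is the classical
minimum-event (Dollo) criterion: the gene arises once, at the family root's
taxon, and the smallest number of deletions consistent with the observed
leaves is assumed. On the five-species example tree
`(((human,chimp)HC,gorilla)HCG,(mouse,rat)MR)ROOT`, a family with genes only
in gorilla, mouse and rat is explained by **one** loss on the branch to the
human–chimp ancestor `HC`, not two independent losses in human and chimp:

```{r worked}
st <- read_species_tree(text =
  "(((human:1,chimp:1)HC:1,gorilla:2)HCG:1,(mouse:1.5,rat:1.5)MR:1.5)ROOT;")
gt <- read_gene_tree(text =
  "(G_g1[&&NHX:S=gorilla]:2,(M_g1[&&NHX:S=mouse]:1,R_g1[&&NHX:S=rat]:1):1.5);",
  family_id = "FAM1")
rt <- assign_stable_ids(infer_losses(map_taxa(gt, st), st))
count_losses(rt)
subset(as.data.frame(rt$tree), event == "loss", c(event, taxon))
```

The rejected two-loss scenario can be costed explicitly with the bundled
exhaustive-enumeration reference:

```{r dollo}
dollo_min_losses(st, c("gorilla", "mouse", "rat"), force_present = "HC")
```

Implementation notes, all of which are covered by property tests:

* **Explicit ancestral nodes.** For every gene-tree edge spanning several
  species-tree branches, an `inserted_ancestor` node is spliced in at each
  traversed taxon, so "the genes of taxon T" is simply "the non-duplication
  ancestral nodes mapped to T". Loss leaves are attached at the *topmost*
  uncovered taxon — the first ancestral species missing the gene.
* **Duplication semantics.** A duplication mapped to taxon A is treated as
  occurring on the branch above A; each surviving copy receives its own
  ancestral node at A and pays its own losses independently. This makes
  genome membership well-defined as lineages crossing a taxon.
* **Multifurcations.** At a multifurcating species node every uncovered
  child lineage costs one loss; no binary resolution is attempted. For such
  nodes (and for prokaryotes, where undetected horizontal transfer is
  likely) an ancestral gene set should be read as a *supergenome* — possibly
  larger than any single ancestral individual's genome. The package
  documents this caveat rather than modeling transfer: reconciliation is
  pure duplication–loss.
* **Split branch lengths.** When k nodes are spliced into an edge of length
  L, each segment gets L/(k+1); path lengths, and therefore proxy-gene
  distances, are unchanged. Missing input branch lengths default to 0, so
  distances then degrade to edge counts.
* **Trusted event tags.** `Ev=` tags present in input trees (curated
  families) are kept; untagged nodes get the standard LCA rule (duplication
  iff a child subtree maps to the same taxon).

The tests verify the inferred loss count against two independent oracles: an
exhaustive enumeration of presence/absence labelings for duplication-free
families, and a per-duplicate-copy constrained enumeration when duplications
are present; and against simulated histories the inferred count never
exceeds the true one (losses can cancel observationally but never be
created).

## Plurality-vote sequence reconstruction

Ancestral sequences are reconstructed column by column, from the leaves
toward the root. At each ancestral node, each immediate child casts one vote
with its own state — a leaf votes its alignment residue, an internal child
its already-reconstructed state. The gap character is a votable state, so
insertions and deletions are reconstructed exactly like substitutions. The
rules, in order:

1. a unique plurality wins;
2. on a tie, the nearest outgroup sequences — the extant leaves outside the
   node's subtree at minimal path branch length, all ties included — add
   their votes, but only to the already-tied states (an outgroup cannot
   introduce a novel state);
3. a still-unresolved site becomes the unknown symbol `X`. The root has no
   outgroup, so root ties go straight to `X`.

Loss leaves cast no votes, and a child whose own state is `X` abstains,
preventing `X` cascades toward the root.

Two design points were genuinely open. *Who votes:* one vote per immediate
child (the default) rather than one per extant descendant — descendant
voting would let a large clade outvote its sibling at every ancestor; both
are available via `mode = c("children", "leaves")`. *What outgroup votes
count for:* only the tied states, because the rule ordering makes the
outgroup a tie-breaker, not a primary voter. This is a parsimony heuristic,
not a likelihood method: no substitution model, no rates, no posterior
probabilities.

On simulated families (primate tree above; duplication and loss rates 0.05,
single-column indels at 0.01 per site per unit length, 150 columns) the
reconstruction recovers ≥90% of non-gap ancestral sites at 0.05
substitutions/site/unit, and accuracy declines monotonically as the rate
grows through 0.5 and 1.5 — both asserted by the test suite and recomputed
by `scripts/acceptance.R`.

## Stable identifiers, names, GO terms, proxies

* **Stable IDs** are `family:NNNN`, the zero-padded preorder index among
  non-loss nodes of a canonicalized tree (children sorted by smallest
  descendant gene identifier; loss leaves last). They are invariant under
  re-serialization and child-order permutation — the testable core of an
  accession registry, without an external database.
* **Protein names.** When a duplication creates a new gene (confirmed by
  descendants in at least two genomes), the copy is named for its proxy gene
  in the highest-priority reference genome represented in that lineage, and
  the name is inherited until the next duplication re-applies the rule. The
  reference priority is a user-supplied ordered species list; the package
  imposes no fixed ordering of model organisms.
* **GO terms** propagate top-down: a node carries a term gained at an
  ancestor-or-self with no loss event on the path since the gain. Gains
  apply before losses at the same node; a loss without a prior gain is a
  validation error. No GO-DAG ancestor closure is applied — that is an
  ontology concern, not a tree concern.
* **Proxy genes** generalize orthology to ancestors: the proxy of an
  ancestral gene in species S is its least-diverged descendant in S,
  measured as total branch length on the connecting path; distance ties
  break to the lexicographically smallest gene identifier for determinism.

## The simulator: what it does and does not emulate

`simulate_family()` starts one gene at the species-tree root; along each
species branch every lineage independently duplicates or dies with
exponential waiting times (`dup_rate`, `loss_rate` per unit branch length),
and every surviving lineage enters each child branch at speciations. The
full history — including extinct lineages — is retained as the truth;
the observed tree is the pruned phylogeny of surviving genes with events
stripped, exactly what a tree-building pipeline would hand to
reconciliation. Defaults (`dup_rate = 0.1`, `loss_rate = 0.2`,
`subst_rate = 0.3`, `indel_rate = 0.02`, `seq_length = 120`) describe a
moderately dynamic protein family on a tree whose branches are of order one
expected substitution per site; losses outnumber duplications, the prevailing
mode in large-scale reconstructions of gene content evolution.

Sequences evolve by Poisson substitution with uniform exchange among the 20
amino acids — the simplest truth-generating model, chosen deliberately
because the voting reconstruction assumes no model at all — and
single-column indels with global column bookkeeping, so the true alignment
of every ancestral node is available. Calibration tests check the simulator
against closed forms: per-species survival equals exp(−loss_rate·depth) and
the per-branch fraction of changed sites equals 1−exp(−subst_rate·t), both
within three Monte-Carlo standard errors at 1000 and 20 000 draws
respectively.

What the simulator does *not* emulate — and hence what passing tests do not
show about real data: rate heterogeneity across sites and lineages,
empirical amino-acid exchangeabilities, multi-residue indels, alignment
error (the true alignment is given to the reconstruction), horizontal
transfer, incomplete lineage sorting, and family-clustering artifacts.
Recovery numbers on simulated data are therefore upper bounds on what the
same procedures achieve on real proteomes.

## Reproducibility and problem sizes

Every stochastic function takes an explicit integer seed (`sim_params()`;
replicate indices offset it), saves and restores the global RNG state, and
the command-line pipeline (`cmd_simulate()` etc.) is byte-reproducible given
a seed. The validation suite uses problem sizes chosen to exercise every
code path while enumeration oracles stay exhaustive: species trees of 3–6
leaves (occasionally multifurcating), gene families of up to 10–12 genes,
200+ random reconciliation instances, 100 randomized comparison pipelines,
and 1000-replicate simulator calibrations.

## Known limitations

* Pure duplication–loss parsimony: no transfer events, so prokaryotic
  reconstructions are supergenome-style over-estimates near multifurcations.
* Voting ASR is outperformed by maximum-likelihood marginal reconstruction
  for residue inference; its advantage is uniform handling of indels.
* Unrooted input trees, PhyloXML, and identity-based (rather than
  branch-length) proxy definitions are out of scope.
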