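# paleogene

Reconstruction of ancestral genes and genomes from gene family trees.

Whole-genome sequencing plus phylogenetics opens a window onto genomes that
existed millions to billions of years ago: given a rooted species tree and a
comprehensive library of rooted gene family trees, every speciation node in
a reconciled gene tree is a gene that existed in an ancestral genome.
`paleogene` is for molecular evolutionary biologists who want to build and
interrogate such reconstructions: it reconciles gene trees against a
(possibly multifurcating) species tree, infers gene losses by maximum
parsimony with *explicit* ancestral-gene and loss nodes, reconstructs
ancestral protein sequences, assembles per-ancestor gene sets, and compares
extant genomes with their ancestors.

## The core method

**Loss inference.** Gene presence is modeled under Dollo parsimony: a family
arises once, at its root's taxon `A`, and absences are explained by the
smallest number of deletion events. For each gene-tree edge from taxon `A`
down to taxon `B`, the species path is walked and an ancestral-gene node is
inserted at every traversed taxon; each traversed taxon's child lineages
without a representative receive one explicit loss leaf, labeled with the
first ancestral species inferred to lack the gene. A duplication mapped to
`A` occurs on the branch above `A`, so each surviving duplicate copy gets
its own node at `A` and pays its own losses. The ancestral genome of taxon
`T` is then simply the set of non-duplication ancestral nodes mapped to `T`
across families.

**Sequence reconstruction.** Per alignment column, from leaves to root: each
child casts one vote with its own state (gaps are votable, so indels are
reconstructed too); a unique plurality wins; ties add the nearest outgroup
sequences' votes (to the tied states only); still-tied sites become the
unknown symbol `X`.

**Proxy genes.** The proxy of an ancestral gene in an extant genome is its
least-diverged descendant there — minimal total branch length on the
connecting path — generalizing orthology to ancestor/descendant pairs.

A duplication–loss birth–death simulator with known event and sequence
history makes every step testable against ground truth; see the methods
vignette (`vignettes/ancestral-reconstruction.Rmd`) for the model,
parameter, and design discussion.

## Worked example

A species tree of five species and a family present only in gorilla, mouse
and rat:

```r
library(paleogene)
st <- read_species_tree(text =
  "(((human:1,chimp:1)HC:1,gorilla:2)HCG:1,(mouse:1.5,rat:1.5)MR:1.5)ROOT;")
gt <- read_gene_tree(text =
  "(G_g1[&&NHX:S=gorilla]:2,(M_g1[&&NHX:S=mouse]:1,R_g1[&&NHX:S=rat]:1):1.5);",
  family_id = "FAM1")
rt <- assign_stable_ids(infer_losses(map_taxa(gt, st), st))
rt
#> reconciled_tree 'FAM1': 1 losses, 0 duplications
subset(as.data.frame(rt$tree), event != "extant", c(stable_id, event, taxon))
#>   stable_id             event taxon
#> 1 FAM1:0000        speciation  ROOT
#> 2 FAM1:0001        speciation    MR
#> 5 FAM1:0004 inserted_ancestor   HCG
#> 7      <NA>              loss    HC
```

The single most parsimonious loss sits on the branch to the human–chimp
ancestor `HC`; the rival scenario — the gene surviving into `HC` and then
being lost twice — costs two events, as the exhaustive reference confirms:

```r
dollo_min_losses(st, c("gorilla", "mouse", "rat"), force_present = "HC")
#> [1] 2
```

Ancestral sequences, genome content, proxies and comparisons follow from the
reconciled tree:

```r
aln <- read_alignment("FAM1.fasta")   # G_g1=MKAL-D, M_g1=MKALED, R_g1=MKGLED
asr <- reconstruct_ancestral(rt, aln)
asr$rows
#> FAM1:0000 FAM1:0001 FAM1:0004
#>  "MKALXD"  "MKALED"  "MKAL-D"
```

The root sequence keeps the unanimous `MKAL.D` columns, reconstructs the
gorilla-lineage deletion only on the `HCG` lineage, and marks the root's
E/`-` tie `X` (no outgroup above the root). Genome content and comparison:

```r
assemble_genome("ROOT", list(rt), sequences = list(FAM1 = asr))
#>   stable_id family_id taxon_id      event name sequence
#> 1 FAM1:0000      FAM1     ROOT speciation <NA>   MKALXD
proxy_gene(rt, "FAM1:0000", "mouse")
#> $gene_id  [1] "M_g1"
#> $distance [1] 2.5
compare_genomes("human", "ROOT", list(rt))
#> comparison human vs ancestor ROOT: 0 inherited, 1 lost, 0 gained, 0 untraced
```

A command-line front-end wraps the same pipeline stage by stage
(`reconcile`, `asr`, `genome`, `compare`, `simulate`):

```sh
Rscript inst/scripts/paleogene reconcile \
  --species-tree species.nwk --families fams/ --out out/
```

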