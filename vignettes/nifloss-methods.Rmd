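---
title: "Methods: inferring nif gene loss and transfer histories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring nif gene loss and transfer histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nifloss)
```

# The question and the inference chain

Nitrogen fixation in Cyanobacteria is carried out by the molybdenum-dependent
nitrogenase system, encoded by thirteen *nif* genes organised in four operons
(*nifBSU*, *nifHDK*, *nifENXW*, *nifVZT*). Diazotrophs are scattered across
the cyanobacterial species tree; that mosaic can arise from repeated
horizontal acquisition or from an ancestral repertoire repeatedly lost.
`nifloss` operationalises the distinction as a chain of testable steps:

1. identify *nif* candidates in genome annotations through orthogroup
   membership (`tag_nif_candidates()`);
2. detect the four operons in gene order (`call_operons()`);
3. resolve within-operon paralogs by congruence with the species tree
   (`select_copy()`);
4. classify each carrier's history per gene as vertical, intra-phylum
   transfer, or extra-phylum transfer (`classify_gene_history()`);
5. reconstruct the minimum-loss (Dollo) history of the repertoire on the
   species tree (`dollo_reconstruct()`), and contrast it with the number of
   gains a loss-free model would need (`summarize_history()`).

Every step is exercised end-to-end on synthetic genomes with recorded ground
truth (`simulate_scenario()`), so the package's claims are properties checked
by its test suite, not anecdotes.

# Operon detection

The substrate is an ordered gene table: one row per annotated gene, sorted by
start coordinate, with a 0-based per-contig ordinal. Coordinates are 1-based
inclusive (GenBank convention); ordinals give the operon logic a clean
integer index.

**Gap rule.** Two nif-tagged genes join one cluster when strictly fewer than
`max_gap` annotated genes (of any kind, pseudogenes included) lie strictly
between them — the count is the ordinal difference minus one. The default
`max_gap = 4` encodes the "< 4 intervening genes" convention; clustering is
transitive along the contig, never across contigs. The implementation is
verified against a brute-force pairwise-merging oracle on hundreds of random
tables; equivalence is exact, and increasing `max_gap` provably never
increases the number of clusters.

**Bridging.** An isolated nif gene whose nearest nif clusters upstream *and*
downstream (same contig) are both multi-gene clusters is merged with them,
iterated to a fixed point. The rule is deliberately conservative about what
counts as a flanking operon (any multi-gene nif cluster — requiring the
flanks to belong to one canonical template would silently drop the
super-operon case); every bridged member is flagged in output so a reviewer
can audit these merges, and `bridging_enabled = FALSE` switches the rule off.

**Splitting and classification.** Cluster members are assigned to templates
by label; a super-operon yields one call per represented template. A fused
nifEN record satisfies both nifE and nifN. A nifK sitting in a cluster with
nifENXW members but without nifH/nifD is reported under the *nifENXW* call
with a cross-reference flag rather than fabricating a *nifHDK* call. Calls
are `complete` when no template member is missing, `partial` otherwise, and
`split` when co-located fragments of one template occur in a genome.

**Dual operon sets.** Two same-template calls separated by at least
`dual_set_min_separation` genes (default 50) or on different contigs flag a
genome as carrying two operon sets; calls are partitioned into `set1`/`set2`
by genomic co-location. "Distant" is not quantified by the biology, so the
default is set far above any `max_gap` merge range and exposed in
`nif_config()`. Strand is recorded but not used as a splitting criterion by
default (`respect_strand`): the gap rule is about gene counts, and real nif
operons are occasionally annotated with strand flips that do not break
co-transcription evidence.

# Trees

Species trees are built from concatenated marker-protein alignments with
pairwise-deletion protein distances (`protein_distance()`; `p` or the
Poisson correction −ln(1−p)) and an in-package neighbor-joining
implementation. NJ here is deliberately deterministic beyond the textbook
algorithm: ties in the Q criterion are broken by the lexicographically
smallest taxon labels of the joined subtrees, and negative branch estimates
are clamped to zero with the total deficit recorded. On additive matrices the
generating topology is recovered exactly (a property the test suite checks on
random trees, cross-checked against an independent NJ implementation).
Distance-based NJ replaces maximum-likelihood inference deliberately: the
downstream conclusions rest on topology comparisons, which are re-tested here
against simulated ground truth, and users with externally computed trees can
inject them (`run_nif_pipeline(species_tree = ...)`, `ape::read.tree()`).

The Poisson correction −ln(1−p) ignores the finite (20-letter) alphabet, so
it is not exactly additive under the simulator's replacement model; at the
divergences the generator produces (pairwise p ≈ 0.2–0.7) the topological
effect is negligible, and the NJ exactness checks use exact additive
matrices.

Bootstrap support resamples alignment columns with replacement; supports are
bipartition frequencies, reproducible under a fixed seed and invariant to row
order. Robinson–Foulds distances are symmetric differences of non-trivial
bipartition sets on unrooted topologies; monophyly verdicts report the
smallest containing clade and its intruders. Both agree with independent
oracles (phangorn's RF, exhaustive clade scans) on every tested instance.

# Branch-length outliers and history classification

For a set of edges the robust z-score is (length − median)/(1.4826·MAD).
Edges with z > k (default k = 3) are flagged. Pendant and internal edges are
scored against their own scope's distribution: pendant edges are
systematically longer than internal ones, and pooling the two classes
inflates pendant z-scores.

`classify_gene_history()` combines three signals:

* **Extra-phylum transfer** — the long-branch-near-the-root pattern of a
  homolog acquired from outside the phylum: the taxon's pendant branch (or
  the stem of its two-tip cherry) is a z-outlier in the gene tree, attaches
  root-proximally (its parent's depth in edges is below the tree's median
  node depth), and the anomaly is *gene-specific*. The last condition is the
  crucial control: the same statistic is computed on the species tree pruned
  to the gene's carriers, and a lineage whose species-tree branch is
  comparably anomalous (a basal lineage that never split is as long as the
  tree is tall, in every tree) is explained by vertical inheritance. Only
  when the gene-side z exceeds the species-side z by more than k does the
  gene-side anomaly stand. Without this control a single full-height basal
  lineage is called a transfer for every gene it carries.
* **Intra-phylum transfer** — no length anomaly, but placement incongruence:
  removing the taxon lowers the pruned RF distance between gene tree and
  species tree by at least `incongruence_margin` (default 2, the smallest
  possible RF change).
* **Vertical** — neither signal. A long branch that does not attach
  root-proximally is reported `unresolved`.

Gene trees carry no outgroup of their own, so they are rooted on the
species tree's earliest-diverging carrier clade (`basal_clade()`,
`root_gene_tree()`), with midpoint rooting as the fallback when those taxa
are absent or not cladable. Midpoint rooting alone would place the root on
any dominant long branch and make the root-proximal criterion vacuous.

**What the verdicts mean.** The intra-phylum rule is intentionally
sensitive: any taxon whose removal resolves a conflicting split is flagged,
and conflicting splits also arise from plain estimation noise — especially
for the short accessory proteins (nifT is 67 residues). On simulated
vertical-only data the rule therefore still produces intra-phylum calls at
low-support splits; they should be read as "placement unstable", and real
analyses should weigh them against bootstrap support
(`bootstrap_support()`). The extra-phylum rule is the precision-tuned one:
on simulated data (100 scenarios, 20 taxa, one injected transfer each) the
acceptance script measures recall and a false-positive rate of a few
percent, dominated by short genes.

# Paralog selection and dual-set identity

When an operon carries several copies of one gene, each candidate is scored
one at a time: a gene tree is built from the single-copy cohort plus that
candidate, and the candidate's score is the RF distance to the species tree
pruned to the same genomes. Scoring candidates separately avoids paralog
attraction between the copies; the alternative reading (one joint tree with
all copies) is noted but not implemented. Minimal RF wins; ties break by the
shorter external branch, then lexicographic locus tag — a fully deterministic
choice, invariant to candidate order.

Dual operon sets are labelled *nif1*/*nif2* by patristic proximity of each
set's tip to a reference genome's known *nif1* tip, gene by gene, with a
majority vote across genes and the margin reported. Patristic distance (sum
of branch lengths) rather than topological proximity is used because the
transferred set diverges from its donor lineage, not from a fixed topological
position. A genome with a single set is labelled *nif1* (vertical
presumption).

# Dollo reconstruction

Under the single-gain assumption the gain node is the MRCA of the present
taxa (or a pinned ancestor) and the minimal loss set marks each maximal
absent clade with one loss; the count is provably minimal and the test suite
confirms it against exhaustive search over loss-edge subsets. Alongside the
loss count the report gives the number of gains a loss-free model would need
(maximal fully-present clades) — the quantitative form of "loss explains the
mosaic more parsimoniously than repeated acquisition".

Identifiability: when an entire basal clade loses the repertoire, no
reconstruction can distinguish "gain at the root, loss of the clade" from
"gain at the survivors' MRCA". The simulator therefore records both the raw
event log and its observable canonical form (gain at the MRCA of surviving
carriers, losses as maximal absent clades); recovery is scored against the
canonical form. Presence profiles for the repertoire analysis require at
least two template members in a call, so a residual single gene in a
non-diazotroph (reported separately as a homolog carrier) does not perturb
the loss history.

# The synthetic-data generator

`nif_scenario()` fixes the study conditions; `simulate_scenario()` is
bit-reproducible under its seed.

* **Species tree**: Yule (pure-birth) simulation, default 20 taxa, birth
  rate 1, with one final exponential waiting time so every pendant edge is
  positive; an outgroup tip for rooting sits at the root at the ingroup's
  height.
* **Sequences**: root sequence uniform over the 20 amino acids; along each
  edge every site is replaced with probability 1 − exp(−rate·length), the
  new state uniform over the other 19. The default rate 0.3 per site per
  unit branch length yields within-phylum p-distances of roughly 0.2–0.7,
  typical for conserved bacterial proteins across a phylum. The exact
  expected p-distance between two leaves is
  (19/20)·(1 − Π(1 − (20/19)·q_e)) over the path's edges
  (`expected_p_distance()`); the calibration check compares simulation to
  this closed form at three standard errors. A uniform replacement model
  (not WAG/LG) is a documented fidelity limit: topology-level properties do
  not require realistic exchangeabilities.
* **Markers**: 31 marker alignments of 200 columns for species-tree
  estimation.
* **nif genes**: per-gene lengths default to the observed means of the short
  accessory proteins (nifX 137, nifW 106, nifZ 94, nifT 67) and 300
  otherwise.
* **Histories**: the repertoire is gained at the root; each edge loses it
  with probability 0.05 (inherited); a lost leaf keeps a residual nifS or
  nifV with probability 0.05 (the homolog-carrier pattern among real
  non-diazotrophs is similarly rare); a clade of diazotrophs receives a
  duplicated set2 complement from a donor lineage with probability 0.1
  (matching the observed ~1-in-10 frequency of dual-operon genomes, as does
  the 0.1 fused-nifEN probability).
* **Extra-phylum transfers** replace one gene's evolutionary path in one
  carrier with an attachment at the root of that gene's tree, with pendant
  length = multiplier × the carrier tree's mean root-to-tip height (default
  multiplier 5). The multiplier scales the replaced root-to-tip path: a
  homolog acquired from another phylum diverged before the phylum's own
  root, so its branch dwarfs every within-phylum branch. Targets must
  already carry the gene (a diazotroph, or a residual holder — residual
  retention plus path replacement is exactly how a non-diazotroph comes to
  carry a single foreign nif gene); an explicit event targeting a lineage
  without the gene is a configuration error.
* **Gene orders**: 150 unlabelled filler genes per genome (fresh random
  sequences, so orthogrouping cannot merge them), operon blocks anchored at
  least 8 fillers apart in random order (translocation analogue), one or two
  fillers inserted inside an operon with probability 0.3 per junction, dual
  sets placed in opposite thirds of the genome so they sit beyond the
  dual-set separation threshold.

**What passing tests show — and do not.** The generator emulates the
statistical structure the inference assumes: tree-like vertical signal,
whole-repertoire losses, rare residuals, one-donor dual sets, and transfers
that are long-branch root-proximal events. It does not emulate indels (gene
alignments are emitted gap-free), rate heterogeneity across sites or
lineages, empirical amino-acid exchangeabilities, assembly or annotation
error, or transfers from within-phylum donors onto short branches.
Performance numbers from the acceptance script are statements about this
generative model, not about any real genome set.

# The orthogroup stand-in

`build_orthogroups_rbh()` (reciprocal best hits by cosine similarity of
k-mer count vectors, k = 4, single-linkage components, `min_sim = 0.5`) is a
deliberately simple stand-in so the pipeline can run from bare proteomes;
`read_orthogroup_table()` is the fidelity path for users with real
OrthoFinder output. Cosine k-mer similarity decays roughly like the fourth
power of sequence identity, so with the default threshold the stand-in is
reliable when within-family identities are high (≳ 85%) and will fragment
families at larger divergences. Ties in best-hit selection break
lexicographically for determinism.

# Numerical and degenerate-input choices

* NJ ties: lexicographic on subtree labels; negative branch estimates
  clamped to 0, deficit recorded in `clamped_deficit`.
* Saturated distance pairs (p = 1 under the Poisson model) are flagged and
  set to a ceiling (default 10).
* Outgroup rooting splits the stem edge evenly across the new root.
* MAD = 0 (all edge lengths equal): nothing is flagged, with a warning.
* Empty inputs: clustering an annotation with no nif genes returns an empty
  list; a cluster with no template-member labels warns and yields no calls;
  Dollo requires a non-empty present set.
* Problem sizes in the checks (500 random gene tables; 100–200 random trees
  of 4–12 leaves for the NJ/RF/monophyly/Dollo oracles; 100 paralog
  replicates at 12 taxa; 100 loss/transfer scenarios at 20 taxa) were chosen
  as the smallest sets at which the brute-force oracles remain exhaustive
  and the simulation-based rates have useful precision.

# Known limitations

* The intra-phylum verdict inherits the noise sensitivity of RF on short
  alignments; treat it as a screen, not a conclusion.
* The extra-phylum verdict cannot, even in principle, distinguish a foreign
  acquisition from a basal lineage whose gene branch is anomalous *only* in
  the gene tree when the species tree offers no comparable branch — the
  gene-specificity control reduces but does not eliminate this confusion.
* Dollo's single-gain premise is an assumption, not a result; the
  `n_gains_no_loss` column is provided precisely so the reader can compare
  the two extremes.
* The GenBank reader parses gene/CDS feature tables with simple compound
  locations (min/max span); it is not a general GenBank parser (no
  trans-spliced joins, no sequence extraction).
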