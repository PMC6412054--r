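---
title: "Detecting homoplasies with the consistency index: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting homoplasies with the consistency index: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homoplasyscan)
```

## The problem

A phylogeny reconstructed from a nucleotide alignment assumes that most
nucleotide differences arose once, on a single branch. A *homoplasy* — the
same derived nucleotide arising independently in lineages that do not share
it by descent — violates that assumption. Homoplasies appear through
convergent evolution (particularly under strong selection, e.g. antibiotic
pressure), through recombination, and through errors introduced while
generating or processing sequencing data. Before a tree is interpreted, the
sites inconsistent with it should be identified, examined, and possibly
removed.

`homoplasyscan` takes a rooted Newick tree and the alignment its tips come
from, decides per site whether the tip states can be explained without
repeated origins, and emits a report, a filtered alignment, and an annotated
tree.

## Per-site tree length and the consistency index

For one site, let each tip carry the *set* of nucleotides compatible with its
alignment character (see `expand_state()`). A single post-order pass computes
the minimum number of changes the tree needs (Fitch's set method, folding the
children of each node left to right in file order): the running set becomes
the intersection with the next child's set when that intersection is
non-empty, otherwise the union, counting one change. The count after the root
is the site's *tree length* $l$.

With $s$ the number of distinct unambiguous nucleotides observed at the site,
the *consistency index* is

$$\mathrm{CI} = \frac{s - 1}{l}, \qquad \mathrm{CI} := 1 \text{ when } s \le 1 .$$

$s - 1$ is the fewest changes any tree could need, so $\mathrm{CI} \in (0, 1]$
and $\mathrm{CI} = 1$ exactly when the site is perfectly consistent with the
tree. Sites with $\mathrm{CI} < 1$ are flagged as inconsistent. Note the
orientation: the minimum conceivable changes in the numerator, the changes
this tree needs in the denominator. This is the classical (Kluge–Farris)
orientation and the only one for which "CI < 1 means inconsistent" and
"CI = 1 means entirely consistent" both hold; one sometimes sees the ratio
described the other way round in prose, which would put homoplasious sites
*above* 1.

Assumptions worth stating:

* **The tree is taken as given and rooted.** No re-rooting is attempted;
  a mis-rooted or poorly resolved tree yields correspondingly distorted
  per-site lengths. The method is most informative on well-resolved trees.
* **Sites are independent.** Everything is computed per column; removing
  flagged columns cannot create new inconsistency in the remaining columns
  (re-scanning the filtered alignment flags nothing).
* **Ambiguity is benign.** `N`, gaps and IUPAC codes enlarge tip sets, which
  can only reduce a site's tree length: ambiguous data lean towards *not*
  flagging. Gaps are treated like `N` (fully ambiguous) rather than as a
  fifth state; treating deletion as a character state would change tree
  lengths in a way the consistency framework does not model. The number of
  observed states $s$ counts only unambiguous A/C/G/T calls.
* **Invariant sites** ($s \le 1$) get CI 1 by definition and are never
  flagged; this also avoids a 0/0.

### Multifurcations

The downpass description is exact on binary trees (verified against an
independent exhaustive oracle, `oracle_min_changes()`, which enumerates all
$4^{\text{internal}}$ state assignments). On a multifurcation, folding the
children pairwise left to right scores the *caterpillar resolution* of that
node rather than the multifurcation itself. Refining a polytomy can only
lower the parsimony length, so on multifurcating trees the reported tree
length is bounded above by the exact multifurcation minimum and below by
$s - 1$ (an exact treatment of polytomies would need Hartigan's algorithm).
Consequences: consistency indices remain in $(0, 1]$, and on poorly resolved
trees the method errs towards *not* flagging a site — consistent with taking
the displayed resolution of the tree at face value. The test suite asserts
this sandwich property on random polytomous trees.

### Annotation

Every internal node at which the fold took at least one union step for a
flagged site is annotated with that site's 1-based position — these are the
nodes where a change was necessary. Annotations are written as
FigTree-compatible comment blocks (`[&homoplasy=12,40]`) placed after the
node and before its branch length, so the file stays valid for plain Newick
parsers (which skip bracketed comments). Because the fold order is the child
order of the input file, annotation targets are deterministic.

## File handling

* Newick: hand-parsed (the annotation dialect and precise error reporting
  are part of the tool's contract); parse errors report the character
  offset. Unary internal nodes are collapsed on input with branch lengths
  summed — they carry no parsimony information. Polytomies are accepted.
* FASTA: wrapped lines joined, case uppercased, labels cut at the first
  whitespace; unequal lengths, duplicate labels and empty files are loud
  errors naming the offenders. A zero-site filtered alignment is written
  (with a warning) rather than refused.
* Tree and alignment labels are matched by exact string equality after
  stripping surrounding quotes/whitespace; any mismatch errors with the
  symmetric difference of the label sets.
* Report positions, and all user-facing positions, are 1-based.

## The validation harness

The simulator generates data with known, constructed homoplasies so that
detection performance can be measured.

**Outbreak model.** Discrete time; a closed population of `n_individuals`
(default 200) with one initial infected. Per step, each infected individual
infects each susceptible with probability `infectiousness` (default 0.001;
implemented as each susceptible escaping all current infecteds
independently, donor drawn uniformly among infecteds); every infected
sequence gains Poisson(`mutation_rate` = 0.5) mutations per step — on
average one every two steps — each at a brand-new position (infinite
sites); each infected is sampled (removed, sequence recorded) with
probability `sampling_prob` (0.05) per step; the run stops once
`stop_after_sampled` (100) sequences are recorded, restarting afresh if the
epidemic dies out first. These defaults are the study conditions of the
validation experiment and are not tuned per run. Sequences are represented
as growing mutation registries and only materialised at the end: the
ancestral allele per site is uniform on A/C/G/T and the mutant allele
uniform on the remaining three. The true genealogy of the samples is
reconstructed exactly from the transmission events (lineages split at
transmission, end at sampling; unsampled lineages pruned, unary nodes
collapsed), and under infinite sites the mutations are perfectly consistent
with it — the suite asserts zero flags on the true tree.

**Tree rebuilding.** The harness rebuilds trees by neighbour joining on
pairwise Hamming distances (ambiguous positions skipped pairwise), with
negative NJ branch lengths clamped to zero and midpoint rooting. NJ is exact
on additive distances (asserted on perfect-signal alignments) and fast
enough to run hundreds of replicates at desk scale. It is a deliberate,
declared stand-in for a maximum-likelihood rebuild; `run_detection_experiment()`
accepts any `tree_builder` function, so an external ML tool can be
substituted. Detection-rate summaries are therefore judged against a band,
not as exact equality with ML-based figures.

**Homoplasy insertion.** Per insertion, a random pair of *non-nested*
internal nodes is drawn (neither an ancestor of the other, neither the root;
tips excluded); among sites where the donor clade is monomorphic for an
unambiguous nucleotide found nowhere outside the clade, one is chosen
(without replacement across insertions) and the donor allele is written over
every tip of the recipient clade. One design point was genuinely open: drawn
naively, some pairs produce patterns that are *not* homoplasies even on the
unmodified tree — sister clades merge into a single larger clade, and a
pair whose combined complement is itself a clade yields a pattern explained
by one change. Counting such insertions as "homoplasies" would deflate the
measured detection rate with events that nothing could, or should, detect.
The package therefore verifies each candidate insertion with a single-site
parsimony check on the pre-insertion tree and redraws if the resulting
pattern would be consistent: every recorded insertion is a genuine homoplasy
on the tree it was constructed against, and detection failures can then be
attributed to the one honest mechanism — the rebuilt tree rearranging the
donor and recipient clades until they merge.

**Recombination.** Per event, a random non-nested pair and a random
contiguous region (default 100 sites); the per-site majority consensus of
the donor clade (ties broken A < C < G < T; sites with no unambiguous donor
call left untouched) overwrites the region in the recipient clade.
Recombination both creates homoplasies of its own and, at high event counts,
restructures the rebuilt phylogeny; the suite asserts that detection of
previously inserted homoplasies degrades monotonically across an event-count
ladder.

**Scoring.** Per replicate, the number of inserted homoplasies is drawn
uniformly from 0–100 (or fixed via `n_homoplasies`); detection is the
proportion of inserted positions flagged after rebuilding. Replicates with
zero insertions have an undefined proportion and are excluded from the mean
and quantiles but still contribute false positives (flagged, never
inserted). Each replicate runs on its own seed derived from the master seed,
so results are reproducible and order-independent.

## Problem sizes and numerical choices

* The oracle-equivalence property runs 1000 random binary trees of 4–10
  tips with ambiguity-laden patterns; the exhaustive oracle is capped at 12
  tips ($4^{11}$ assignments).
* The detection experiment summaries in `scripts/acceptance.R` use 200
  replicates at the full study conditions; the construction-guarantee and
  recombination-ladder checks use 50 and 3 × 20 replicates respectively.
  These sizes give stable summaries (the mean detection moves by ~0.2
  percentage points across master seeds) while keeping a full run at
  desk scale.
* Quantiles are the default empirical (type 7) quantiles of the
  per-replicate proportions.
* `max.col(..., ties.method = "first")` fixes consensus tie-breaking;
  `sample.int()` draws fix all randomness through R's RNG, so a single
  `set.seed()` reproduces any run byte-for-byte.

## Limitations

* The consistency index flags *inconsistency with the given tree*; it cannot
  say whether a flagged site arose by convergence, recombination or error,
  and it inherits any defects of the tree. With heavy recombination the
  rebuilt phylogeny itself degrades and detection with it — accounting for
  recombination must happen before, or alongside, homoplasy identification.
* Identification is circular in the realistic setting: the alignment
  containing the homoplasies is also the alignment the tree was built from.
  The harness reproduces this circularity deliberately (insert, rebuild,
  detect).
* The simulator emulates a clonal, non-recombining pathogen with an
  unstructured, closed population and no within-host diversity; real data
  add population structure, variable mutation rates, missing data and
  alignment error, none of which the harness models. Passing the simulation
  checks shows the per-site computation and the pipeline are correct, not
  that detection rates transfer to any particular organism.
* Multifurcation tree lengths are caterpillar-resolution scores (see above),
  a conservative choice that never inflates a site's inconsistency.
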