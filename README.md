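# homoplasyscan

Identify homoplasies on a phylogeny with the consistency index.

A homoplasy is an identical nucleotide shared by taxa through something other
than inheritance from a common ancestor — convergent evolution, recombination,
or sequencing error. Homoplasious sites distort the apparent relatedness of
sequences, so anyone building or interpreting a phylogeny from an alignment
(e.g. for bacterial outbreak or transmission studies) wants them found and, if
need be, removed before downstream analysis. `homoplasyscan` does exactly
that: given a rooted Newick phylogeny and the FASTA nucleotide alignment its
tips were built from, it flags every alignment site that is inconsistent with
the tree.

## Method

For each site *i* the package computes the **per-site tree length**
*l<sub>i</sub>*: the minimum number of state changes the tree requires to
explain the tip nucleotides at that site. This uses a Fitch-style post-order
downpass over nucleotide sets: each tip carries the set of nucleotides its
character may represent (`A` → {A}; `N` and `-` → {A,C,G,T}; IUPAC ambiguity
codes their standard expansions); at each internal node the child sets are
intersected where possible, otherwise unioned with the site's change count
incremented. With *s<sub>i</sub>* the number of distinct unambiguous
nucleotides observed at the site, the **consistency index** is

CI<sub>i</sub> = (s<sub>i</sub> − 1) / l<sub>i</sub>  (defined as 1 when
*s<sub>i</sub>* ≤ 1)

A site that can be explained by a single origin per derived state has
CI = 1; CI < 1 means extra, independent origins are needed — the site is
inconsistent with the tree and potentially homoplasious. Three artifacts are
produced: a CSV report of the flagged sites, the alignment with those sites
removed, and the tree with every internal node at which a change was required
annotated (`[&homoplasy=<positions>]`, readable by ape, FigTree or icytree).

The package also ships the validation harness used to measure detection
performance: a discrete-time outbreak simulator (a continuously mutating
sequence passed from infected to susceptible individuals, infinite-sites
mutation, probabilistic sampling), insertion of known homoplasies between
non-nested clades, recombination simulation by consensus transfer, and
neighbour-joining tree rebuilding.

## Worked example

```r
library(homoplasyscan)

tree <- parse_newick("((A,B),(C,D));")
aln <- rbind(A = c("A","A","G"), B = c("T","A","G"),
             C = c("A","T","G"), D = c("T","T","G"))
scan <- find_homoplasies(tree, aln)
scan
#> Homoplasy scan: 4 tips, 3 sites scanned, 1 inconsistent
#> Inconsistent positions: 1
scan$sites
#>   position tree_length n_states consistency_index is_inconsistent counts_acgt
#> 1        1           2        2               0.5            TRUE     2:0:0:2
#> 2        2           1        2               1.0           FALSE     2:0:0:2
#> 3        3           0        1               1.0           FALSE     0:0:4:0
```

Site 1 has pattern A/T/A/T across `((A,B),(C,D))`: the two observed states
would need only one change on a tree grouping the A-carriers, but this tree
needs two, so CI = 1/2 and the site is flagged. Site 2 (A/A/T/T) matches the
clades exactly (CI = 1) and site 3 is invariant. `write_homoplasy_outputs()`
writes the report, the 2-site filtered alignment, and the annotated tree:

```
((A,B)[&homoplasy=1],(C,D)[&homoplasy=1]);
```

— both children of the root required a change at position 1.

The same pipeline is available from a shell via the script in
`inst/scripts/`:

```sh
Rscript inst/scripts/homoplasyfinder.R detect --fasta aln.fasta --tree tree.nwk
Rscript inst/scripts/homoplasyfinder.R detect --fasta aln.fasta --tree tree.nwk --includeConsistent
Rscript inst/scripts/homoplasyfinder.R simulate --replicates 20 --seed 1 --out exp.csv
```

A small simulation run:

```r
ex <- run_detection_experiment(simulation_config(), n_replicates = 5, seed = 1)
ex
#> Detection experiment: 5 replicates (seed 1, rebuilt tree)
#> Mean proportion of inserted homoplasies detected: 99.8 %
#> Empirical 2.5 % / 97.5 % quantiles: 99.0 % / 100.0 %
#> Mean false positives per replicate: 0.00
```

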