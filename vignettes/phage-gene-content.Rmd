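---
title: "Measuring mosaic relatedness in phage genome collections"
author: "phagegcd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring mosaic relatedness in phage genome collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagegcd)
```

## The problem

Tailed double-stranded-DNA phages evolve by rampant horizontal exchange of
gene-sized segments, so a collection of phages isolated on one bacterial
host rarely falls into cleanly separated taxa. Instead of asking how
*similar* two genomes are at the nucleotide level, this package quantifies
how much *gene content* two phages share, and how discontinuous each
phage's relationships to the rest of a collection are. The unit of
comparison is the **phamily (pham)**: a group of genes whose protein
products are recognisably related. Once every gene is assigned to a pham,
each genome reduces to a presence/absence set of phams, and all of the
package's statistics are set arithmetic on those profiles.

## Pham construction

`build_phams()` groups protein sequences by the Jaccard index of their
amino-acid k-mer sets (`protein_similarity()`, k = 4 by default) and
merges with single linkage: two genes land in the same pham when a chain
of pairwise similarities at or above the threshold (default 0.5) connects
them. Single linkage mirrors the transitive semantics of phamily
membership — a pham is "genes related to at least one other member", not
a clique. Pham ids are assigned by each component's lexicographically
smallest gene id, so the output is a pure function of the input set, not
of its order.

This alignment-free k-mer clustering is a deliberately simple, fully
reproducible family detector. It is *not* a reimplementation of the
profile-based clustering used to build the published actinobacteriophage
pham databases, and it will not reproduce published pham tables; what it
preserves is the contract every downstream statistic needs — a partition
of genes into protein families.

A numerical boundary worth knowing: if family members are generated by
mutating a common ancestor at rate $\mu$ per site, a k-mer survives in
one member with probability $(1-\mu)^k$, and the expected Jaccard index
between two members is roughly
$(1-\mu)^{2k} / (2 - (1-\mu)^{2k})$. At $\mu = 0.05$ and $k = 4$ this is
$\approx 0.50$ — exactly the default threshold — so family recovery
degenerates into a percolation coin-flip. At $\mu = 0.02$ the expected
Jaccard is $\approx 0.74$ and recovery is reliably exact; the test suite
exercises family recovery in that regime, and the separated-cluster
recovery tests work at the pham-profile level, where this boundary is
irrelevant.

## Gene content dissimilarity and MaxGCDGap

For two genomes with pham sets $A$ and $B$ and $S = |A \cap B|$,

$$\mathrm{GCD}(A,B) \;=\; 1 - \frac{1}{2}\left(\frac{S}{|A|} +
\frac{S}{|B|}\right),$$

the average of the two directed shared proportions subtracted from 1
(`gcd()`): 0 for identical gene content, 1 when nothing is shared.
`gcd_matrix()` assembles the symmetric all-pairs matrix, and
`band_statistics()` reports the fraction of pairs inside an inclusive
mid-range band (default [0.3, 0.7]) — the comparisons that distinguish a
smooth spectrum of relatedness from well-separated groups. Inclusive
bounds are used because they are the reproducible reading of a stated
range.

`gap_profile()` ranks one phage's GCDs against every other genome in
descending order, **appends the self-comparison value 0**, and takes
consecutive differences; `max_gcd_gap_all()` reports the largest gap
(MaxGCDGap) per phage. Including the self value is a deliberate design
choice: a phage with no relatives at all then shows the maximal possible
gap (from GCD ≈ 1 straight down to 0), matching the intended reading of
MaxGCDGap as "discontinuity in this phage's relationships" — without the
self anchor, a perfectly isolated phage would paradoxically report a gap
near zero. The gaps telescope: they always sum to the phage's largest
GCD, and ties in the ranking cannot affect any gap value (equal values
produce zero gaps), so tie order is fixed by genome id purely for stable
reporting of the flanking pair.

MaxGCDGap values are relative to the collection analysed — adding or
removing genomes moves them — so they should be read as descriptions of a
dataset, not absolute properties of a phage.

## Cluster and subcluster assignment

`assign_clusters()` implements the shared-gene-content rule: two phages
are linked when their GCD is at most 0.65 (at least 35% shared genes),
and clusters are connected components of the link graph. Membership
therefore requires closeness to *at least one* member, which is exactly
single-linkage transitivity; components of size one are singletons.
Raising the threshold can only add edges, so the number of groups is
monotonically non-increasing in the threshold — a property the tests
assert. The alternative reading of "35% of its own genes" (per-genome
rather than averaged proportions) is not the default and is not used
anywhere in the package.

`compute_ani()` is a fragment-based average nucleotide identity: the
query is cut into fixed 1 kb windows, each aligned at its best location
in the subject (global on the fragment, local on the subject, via
`Biostrings::pairwiseAlignment`), fragments above a 0.7 identity floor
count as aligned, and ANI is their mean identity. The measure is
query-directed; `assign_subclusters()` averages both directions and
subdivides a cluster at ≥ 95% ANI with ≥ 50% aligned fraction. Those two
cutoffs are package conventions (surfaced in `default_config()`), chosen
to sit at the conventional species-like ANI boundary, since no published
numeric subcluster cutoff exists for these collections.

## Stoperator scanning and att cores

`scan_consensus()` reports every window of a genome within a Hamming
distance (substitutions only, no indels) of an unambiguous consensus, on
both strands; the default allowance of 2 substitutions follows the
published scanning convention for these repressor-binding sites, and the
three published 13/14-base consensus strings ship verbatim as
`stoperator_presets`. Minus-strand hits are reported at their leftmost
plus-strand coordinate, which makes the coordinate algebra under
reverse-complementing the genome exact (a property test asserts the
mirror map). `intergenic_filter()` annotates hits by the any-overlap
rule — one shared base with a gene makes a hit genic — and removal is
opt-in, since published scans do not state whether filtering preceded
matching.

`find_att_cores()` reports maximal exact common substrings (length ≥ 20
by default) between a phage and a host genome in both orientations,
implemented by merging diagonal runs of shared k-mers; cores longer than
the expected 20-40 bp window are flagged rather than truncated.
Exactness is what makes the operation verifiable against a
dynamic-programming oracle; attachment-site common cores are described
in the literature as identical segments, so nothing looser is needed by
default. `annotate_trna_overlap()` marks cores whose host interval
intersects an annotated tRNA by at least one base.

## The synthetic population generator

`sim_config()` + `simulate_population()` + `emit_genome_sequences()`
generate seeded, fully ground-truthed populations: each planted cluster
has a private core pham pool (retention 0.9 per genome), all clusters
share one accessory pool sampled at an `hgt_rate` per pham (the single
knob that moves the population from well-separated groups toward a
continuum), genomes carry Poisson private orphams, and every pham's
member proteins are mutated copies of a random ancestor. Nucleotide
genomes are uniform-random backgrounds (25% each base) with
non-overlapping planted consensus copies at configured substitution
counts and att cores copied into a synthetic host. One integer seed
drives everything; reruns are bit-identical.

What the generator does *not* emulate: real gene synteny, codon usage
and GC skew, insertion/deletion evolution, or pham content correlated
with nucleotide sequence (emitted genes and emitted backgrounds are
independent). Passing tests therefore demonstrate the correctness of the
statistics and scanners on populations with known structure — not that
the default thresholds are optimal for any particular real collection.
Two practical notes: att cores are planted after motifs, so motif-recall
checks use configurations without att cores to avoid overwriting a
planted site; and the donor genome for att cores is always the first
genome.

Problem sizes in the shipped tests and the acceptance script are kept
small (populations of 9–20 genomes, genomes of 2–20 kb, hosts of
30–50 kb), which is ample for the exact-recovery and oracle-equivalence
properties being checked.

## Numerical and degenerate-input choices

* GC% excludes ambiguous bases from numerator and denominator; stored
  versus recomputed values are expected to agree within 0.15.
* External coordinates are 1-based inclusive everywhere (GFF3/GenBank
  convention); attB rows printed with descending coordinates are stored
  as (min, max) plus an orientation flag.
* Unparseable genome-end descriptions warn and become `unknown`; the
  record is kept.
* Empty gene list → empty pham list; empty pham list → all-zero summary
  with mean reported as 0.
* GCD of an empty profile is an error, not 0 or 1.
* Matrix TSV round-trips are exact to 10 decimals; Nexus DISTANCES
  exports use `TRIANGLE=BOTH` with quoted labels when needed.

## Known limitations

* Pham construction is k-mer based and will split families whose members
  have diverged beyond the percolation boundary discussed above; it
  makes no attempt to match published pham databases.
* ANI is a fragment heuristic, asymmetric by construction, and the
  subcluster cutoffs are conventions rather than published values.
* `find_att_cores()` is exact-match only by design; biological cores
  with internal polymorphism would need the mismatch post-pass that is
  deliberately left off by default.
* Full-database statistics from published collections (tens of
  thousands of genes across hundreds of genomes) are out of scope for
  the shipped fixtures; the packaged tables cover one published
  79-phage collection's metadata and attB sites only.
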