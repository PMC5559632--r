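# phagegcd

Comparative-genomics toolkit for measuring the mosaic genetic
relationships within a collection of bacteriophage genomes.

Tailed dsDNA phages evolve by horizontal exchange of gene-sized
segments, so phage collections rarely split into cleanly separated taxa.
`phagegcd` is written for phage genomicists who want to quantify that
structure: it groups genes into protein phamilies ("phams"), reduces
each genome to a pham presence/absence profile, and computes the
statistics that describe a population's spectrum of relatedness.

The core quantities, for genomes with pham sets *A* and *B* and
*S* = |*A* ∩ *B*|:

* **Gene content dissimilarity**
  GCD(*A*, *B*) = 1 − (S/|A| + S/|B|)/2 — 0 for identical gene content,
  1 when nothing is shared (`gcd()`, `gcd_matrix()`).
* **MaxGCDGap** — rank one phage's GCDs against all others in descending
  order, append the self value 0, take consecutive differences; the
  largest difference measures the discontinuity in that phage's
  relationships (`gap_profile()`, `max_gcd_gap_all()`).
* **Cluster assignment** — phages sharing at least 35% of their genes
  (GCD ≤ 0.65) with at least one member are linked; clusters are the
  connected components, size-one components are singletons
  (`assign_clusters()`), with fragment-ANI subclustering
  (`compute_ani()`, `assign_subclusters()`).

Around these sit a degenerate consensus scanner for repressor-binding
"stoperator" sites (`scan_consensus()`, ≤ 2 substitutions, both
strands), an attachment-site common-core finder with tRNA-overlap
annotation (`find_att_cores()`, `annotate_trna_overlap()`), a seeded
synthetic mosaic-population generator with exported ground truth
(`sim_config()`, `simulate_population()`, `emit_genome_sequences()`),
and a command-line workflow driver (`run_cli()`,
`inst/scripts/phagegcd`). Two packaged fixtures — a 79-phage *Gordonia*
collection metadata table and its 13 predicted attB sites — provide
real published summaries to compute against.

## Worked example

```r
library(phagegcd)

# published-collection summary from the packaged metadata table
recs <- read_metadata_table(phagegcd_fixture("table1_gordonia.tsv"))
genometrics_summary(recs)[c("n_genomes", "n_clusters", "n_clustered",
                            "n_singletons", "n_groups")]
#> $n_genomes    79
#> $n_clusters   14
#> $n_clustered  65
#> $n_singletons 14
#> $n_groups     28

# gene-content statistics on four pham profiles
profiles <- list(
  Attis        = c(1:30, 40:45),
  SoilAssassin = c(1:30, 46:50),
  Kita         = c(10:30, 60:75),
  GMA2         = c(100:140))
m <- gcd_matrix(profiles)
round(m, 3)
#>              Attis SoilAssassin  Kita GMA2
#> Attis        0.000        0.155 0.425    1
#> SoilAssassin 0.155        0.000 0.416    1
#> Kita         0.425        0.416 0.000    1
#> GMA2         1.000        1.000 1.000    0

assign_clusters(m)$assignment
#>        Attis SoilAssassin         Kita         GMA2
#>         "C1"         "C1"         "C1"  "SINGLETON"

round(max_gcd_gap_all(m), 3)
#>        Attis SoilAssassin         Kita         GMA2
#>        0.575        0.584        0.575        1.000
```

Attis and SoilAssassin share most of their phams (GCD 0.155); Kita is
linked to both at GCD ≈ 0.42 ≤ 0.65, so all three form one cluster by
transitivity. GMA2 shares nothing, is a singleton, and its MaxGCDGap is
the maximal 1.0 — the signature of a phage with no relatives in the
dataset.

The same workflow runs from a shell via the wrapper script:

```sh
Rscript inst/scripts/phagegcd phams --genes genes.tsv --out-dir out
Rscript inst/scripts/phagegcd gcd   --genes genes.tsv --phams out/phams.tsv --out-dir out
Rscript inst/scripts/phagegcd maxgap --matrix out/gcd_matrix.tsv --out-dir out
```

Every run writes a JSON manifest recording the thresholds, input
digests and outputs.

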