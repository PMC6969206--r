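# achconnect

Tools for testing the genetic predictions of the **abundant-centre
hypothesis (ACH)** in coastal species that disperse by planktonic larvae.
The ACH predicts that abundance — and, because diversity tracks population
size, intra-population genetic diversity — peaks at the centre of a
species' range and declines toward the edges, where populations should also
show elevated inter-population divergence. Testing that prediction for
rocky-shore mussels requires coupling three strands of evidence:

1. **Larval dispersal.** Passive larvae are advected by surface currents;
   `achconnect` simulates daily releases from coastal points spaced 1 km
   apart, with hourly forward-Euler steps on bilinearly interpolated daily
   velocity fields, settlement when a track enters the capture zone of a
   coastal point (or strikes the shore), and loss when a particle leaves
   the domain or exceeds its pelagic larval duration (PLD, default 30
   days). Trajectories aggregate into an asymmetric connectivity matrix
   `P(i→j) = Σ(i→j) / Σ(i)` — arrivals at *j* over releases from *i* —
   averaged over years.
2. **Stepping-stone networks.** Direct larval exchange between distant
   sites is rare, but multi-generation connection through intermediate
   coastal points is not. The stepping-stone probability between two sites
   is the maximum over paths of the product of single-step probabilities,
   found by Floyd–Warshall shortest paths on edge weights `−log P`.
   Groups of well-connected sites are identified by maximising directed
   weighted Newman modularity, exhaustively over all set partitions for
   small site sets.
3. **Population genetics.** Per-site haplotype diversity
   `h = n/(n−1)(1 − Σ p_k²)` and nucleotide diversity π; pairwise Φ_PT
   (AMOVA on nucleotide-difference matrices), Nei F_ST and Hedrick's
   G″_ST = k(H_T−H_S) / [(kH_T−H_S)(1−H_S)] with shuffle-individuals
   permutation tests and Bonferroni correction; rarefied allelic richness
   with bootstrap CIs; Bruvo distances `1 − 2^−|x−y|` with a minimum
   spanning network; and a pooled-permutation test for diversity
   differences between sites.

A synthetic-data layer makes the whole analysis testable end to end:
`ocean` generators build coastal domains and daily current fields
(alongshore jet + travelling eddies + noise + offshore-divergence
barriers), and `population_scenario()` generators draw centre/edge
haplotype and microsatellite samples with a switchable ACH effect whose
expected diversities are calibrated in closed form.

## Worked example

```r
library(achconnect)

# dispersal -> connectivity -> clusters on a 60 km coast with two
# offshore-divergence zones at 20 and 40 km
pl <- run_dispersal_pipeline(seed = 1)
pl$clusters
#> Modularity partition (exhaustive): 3 clusters, Q = 0.6454
#> $`1`: "7"  "11" "15"
#> $`2`: "27" "31" "35"
#> $`3`: "47" "51" "55"
pl$ari
#> [1] 1
```

The three modularity clusters coincide exactly (adjusted Rand index 1)
with the three coast segments separated by the flow discontinuities: the
barriers act as dispersal breaks, and stepping-stone connectivity is
strong within segments and absent across them.

```r
# genetics: a centre/edge scenario with the ACH effect switched on
sc <- population_scenario(ach_effect = TRUE, edge_multiplier = 0.5,
                          seed = 5)
out <- run_genetics_pipeline(sc, seed = 5)
out$verdict
#>   lineage statistic centre_mean edge_mean n_edge n_edge_low conclusion
#> 1    west       A_r       10.75      8.20      2          2  supported
#> 2    east       A_r       10.65      7.25      2          2  supported
#> 3    west         h        0.84      0.46      2          2  supported
#> 4    east         h        0.86      0.41      2          2  supported
```

Edge sites carry roughly half the centre diversity (the configured
multiplier), every edge site is significantly below its centre sites
(non-overlapping allelic-richness CIs; Bonferroni-adjusted permutation
tests for h), and edge-involving F_ST exceeds the centre–centre level, so
the verdict is "supported" for every lineage × statistic. With
`ach_effect = FALSE` the same analysis concludes "rejected".

The cover analysis reproduces the published worked numbers from the site
table shipped in `inst/extdata/cover_table.csv`: western-lineage cover
0.13% at edge sites vs 58.47% at centre sites, eastern centre 72.59%, and
mixed-site partitioning 66.2% × 0.50 → 33.1% and 52.1% × 0.30 → 15.6%.

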