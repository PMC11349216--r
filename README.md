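# gspcap

Spike-in **g**ene-**s**pecific-**p**rimer **cap**ture of non-polyadenylated
RNAs in droplet-based 5' single-cell RNA-seq — modelled, filtered, counted
and integrated, with a built-in read simulator so everything is testable
offline.

## The problem

RNA polymerase III transcripts such as **nc886** (vtRNA2-1, 102 nt) carry no
polyA tail, so oligo-dT-driven droplet scRNA-seq never sees them. Spiking a
gene-specific primer (GSP) into reverse transcription captures the target:
the GSP is a 76-mer

```
adaptor (22 nt) | N10 spacer | feature barcode (15 nt) | N9 spacer | target anchor (20 nt)
```

whose anchor reverse-complements the target's 3' region, placed to avoid the
Pol III terminator T-run and the box A/box B promoter motifs shared across
hundreds of Pol III loci. The catch: the vast majority of oligo-tagged reads
(>99% in the motivating experiment) come from *non-specific priming*, so
counting the feature barcode alone grossly overestimates expression — even
cells with zero target expression score high. The fix implemented here is
**sequence-verified counting**: a read pair counts only if R2 contains both
the feature barcode *and* the target sequence within a Hamming mismatch
budget *m* (reported strata `pm`, `mm1`, ..., `mm5`), with R1/R2 pass sets
intersected by read ID, 10x-style cell-barcode whitelist correction, and
per-cell UMI deduplication.

## What's in the package

| module | functions |
|---|---|
| oligo design | `target_gene`, `parse_gsp`, `design_gsp`, `mask_polIII_motifs`, `build_templates`, `nc886_target`, `nc886_gsp` |
| read filtering | `find_best_match`, `filter_r1`, `filter_r2`, `reconcile_pairs`, `filter_pairs` |
| counting | `extract_cell_umi`, `correct_barcode`, `count_features`, `merge_with_gex`, MTX readers/writers |
| simulation | `sim_config`, `simulate_run`, `evaluate_counts`, `simulate_gex` |
| integration | `qc_filter`, `lognorm_z`, `quantile_groups`, `rank_sum_compare` |

A CLI ships in `exec/gspcap` (subcommands `design`, `simulate`, `filter`,
`count`, `integrate`).

## Worked example

Simulate the stated validation world — three populations (high / low / zero
expression), 90% non-specific reads, 0.5% error rate — then filter, pair and
count:

```r
library(gspcap)
print(nc886_gsp())
#> <gsp_design> 22/10/15/9/20 nt (adaptor/spacer/barcode/spacer/anchor)
#>   oligo: 5'-CGGAGATGTGTATAAGAGACAGNNNNNNNNNNGTATGTCCGCTCGATNNNNNNNNNAGGGTCAGTAAGCACCCGCG-3'
#>   anchor window: [79,99)

sim <- simulate_run(sim_config(n_cells_per_population = 40,
                               population_means = c(20, 4, 0),
                               nonspecific_fraction = 0.9,
                               reads_per_molecule = 3,
                               error_rate = 0.005, seed = 7))
f1 <- filter_r1(sim$r1, nc886_target())
f2 <- filter_r2(sim$r2, nc886_target(), nc886_gsp())
pairs <- reconcile_pairs(f1$reads, f2$reads)
fc <- count_features(pairs, wl = sim$whitelist, feature_name = "nc886")
evaluate_counts(sim$truth, fc, budget = 1)[c("per_population", "spearman", "zero_pop_mean")]
```

Output of that run (30,130 simulated pairs; R2 AND-filter passes 2,967 of
them while 27,076 carry the barcode but not the target — the non-specific
class the filter exists to remove):

```
     mean_recovered mean_true
high         23.575    20.975
low           4.825     4.225
zero          0.000     0.000
$spearman      0.995
$zero_pop_mean 0
```

The population ordering is recovered, the silenced population stays at
exactly zero, and the slight inflation of the means is sequencing-error
UMIs (use `count_features(..., umi_collapse = "directional")` to absorb
them).

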