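# metconn

Inter-subject **metabolic connectivity** analysis of the default mode network
(DMN) from FDG-PET, as an installable, tested R package.

## The problem this package addresses

In FDG-PET, a subject's image is a single snapshot of cumulative glucose
metabolism, so "connectivity" cannot be computed within a subject the way it
is with fMRI time series. Instead, *metabolic* connectivity is estimated
**across subjects**: for each pair of brain regions, the Pearson correlation
of their mean regional uptake over the subjects of one group. This yields one
weighted, undirected network per group (not per subject), which can then be
characterized with graph theory and compared between groups (e.g. temporal
lobe epilepsy patients vs healthy controls) with label-permutation tests.

The package implements that pipeline end to end for a 14-region DMN atlas
(medial superior frontal, medial-orbital superior frontal, posterior
cingulate, hippocampus, inferior parietal, angular, precuneus — bilaterally,
with their MNI centre coordinates packaged as a TSV):

1. **Extraction** — read MNI-space NIfTI/Analyze volumes, optionally smooth
   (Gaussian, FWHM in mm), normalize each image by its whole-brain mean, and
   average intensity inside each VOI (6 mm spheres at the packaged centres,
   or a user-supplied parcellation label image). A pre-extracted
   subject × VOI TSV can bypass imaging entirely.
2. **Network construction** — per group, the 14 × 14 inter-subject Pearson
   matrix `R`, its Fisher transform `Z = atanh(R)`, and a non-negative weight
   matrix `W` (negatives clamped to 0, or `|r|`).
3. **Graph metrics** — with edge lengths `l = 1/w` and Dijkstra shortest
   paths `d_ij`:
   - global efficiency `E_glob = (1/(n(n-1))) Σ_{i≠j} 1/d_ij`
   - characteristic path length `L = mean(d_ij)` over finite ordered pairs
   - nodal efficiency `E_i = (1/(n-1)) Σ_{j≠i} 1/d_ij`
   - degree centrality (strength) `s_i = Σ_j w_ij`
4. **Inference** — group labels are permuted (pseudo-groups of the original
   sizes), both networks recomputed per permutation, and the observed
   statistic (`Δz` per edge, or a graph-metric difference) referred to its
   permutation null with the add-one estimator `p = (1+b)/(1+m)`.
   Benjamini–Hochberg FDR is applied across the 91 edges (or 14 nodes);
   demographic helpers reproduce the usual pooled-variance t-test and
   2 × 2 chi-square.
5. **Simulation** — multivariate-normal cohorts with a documented base
   correlation structure and optional planted edge effects, plus a voxel
   renderer (128 × 128 × 35 grid, 1.95 × 1.95 × 4.25 mm voxels) so the whole
   imaging path is testable without any data download.

## Worked example

Simulate a 40-patient vs 41-control study in which the HIP.R–PCG.L
correlation is lowered from 0.5 to 0.15 in patients, then analyze it:

```r
library(metconn)
spec <- simulation_spec(
  planted_edges = data.frame(voi_i = "HIP.R", voi_j = "PCG.L",
                             delta_r = -0.35),
  seed = 42)
sim <- generate_cohorts(spec)

net_pat <- intersubject_correlation(sim$cohort_a)
print(net_pat)
#> <group_network> group 'patient': 40 subjects, 14 VOIs, 91 edges
#>   r range 0.209..0.827 (median 0.688); weight mode 'positive'

print(graph_metrics(net_pat))
#> <graph_metrics_report> E_glob = 0.6544, L = 1.5849 (0 pairs disconnected)
#>   nodal efficiency: 0.668 0.63 0.669 0.695 0.676 0.658 0.632 ...
#>   degree centrality: 8.68 8.19 8.57 9.04 8.79 8.55 8.21 ...

res <- edgewise_permutation_test(sim$cohort_a, sim$cohort_b,
                                 n_permutations = 10000, seed = 42)
head(res$table[order(res$table$p), c("edge", "delta", "p", "q")], 3)
#>             edge  delta      p     q
#> 48 PCG.L - HIP.R -0.501 0.0245 0.905
#> 66 HIP.R - IPL.R -0.409 0.0734 0.905
#> 78 IPL.R - ANG.R -0.417 0.0779 0.905
```

Reading this: the planted edge has the most extreme observed Fisher-z
difference (`Δz = −0.50`, decreased in patients) and the smallest raw
permutation p (0.0245), but after BH correction across 91 edges it is not
significant (q = 0.9) — a single moderate effect at this sample size does
not survive a 91-edge FDR family. The graph report shows a densely connected
network (global efficiency 0.65 on weights ≤ 1, no disconnected pairs).

The same analysis runs from the command line:

```sh
Rscript inst/scripts/metconn.R demo --out out/ --seed 42 --permutations 1000
```

`out/analyze/` then contains the per-group `R`/`Z`/`W` matrices (TSV), graph
metric reports (JSON + TSV), edgewise and metric-wise permutation results,
and `config.json` with the exact seed and settings needed to reproduce the
run byte for byte.

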