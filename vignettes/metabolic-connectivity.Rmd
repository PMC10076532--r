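---
title: "Inter-subject metabolic connectivity of the DMN: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-subject metabolic connectivity of the DMN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metconn)
```

## The model

Metabolic connectivity treats each subject's FDG-PET image as one
observation of a 14-dimensional random vector: the mean normalized uptake in
14 default-mode-network volumes of interest (VOIs). For a group of $n$
subjects, the connectivity between VOIs $i$ and $j$ is the Pearson
correlation $r_{ij}$ of their uptake values *across* the group's subjects.
This produces one symmetric $14 \times 14$ weighted network per group with
unit diagonal — a group-level construct: there is no per-subject network,
and group comparison must therefore resample subjects, not networks.

Three derived matrices are kept distinct on purpose:

- $R$: the raw correlations, the scientific quantity;
- $Z = \operatorname{atanh}(R)$: the variance-stabilized scale on which
  group differences are tested (edgewise statistics always use the
  *unthresholded* $Z$, so clamping never discards evidence);
- $W$: non-negative weights for graph analysis, since shortest-path
  mathematics is undefined for negative weights. Default
  $w_{ij} = \max(r_{ij}, 0)$, with $|r_{ij}|$ selectable. The diagonal is
  structurally zero: self-connections are meaningless here.

Graph metrics use the reciprocal length mapping $l_{ij} = 1/w_{ij}$
($\infty$ for absent edges), the convention of the standard
brain-connectivity toolboxes for weighted efficiency and path length, and
Dijkstra shortest paths $d_{ij}$:

$$E_{glob} = \frac{1}{n(n-1)} \sum_{i \ne j} \frac{1}{d_{ij}}, \qquad
  L = \operatorname{mean}\{ d_{ij} : d_{ij} < \infty,\ i \ne j \},$$
$$E_{nodal}(i) = \frac{1}{n-1} \sum_{j \ne i} \frac{1}{d_{ij}}, \qquad
  s_i = \sum_j w_{ij},$$

with $1/\infty = 0$. The mean of the nodal efficiencies equals the global
efficiency exactly, and the test suite asserts this identity.

## Inference

Group labels carry no information under the null hypothesis that the two
groups share one uptake distribution, so the null is built by reassigning
subjects to pseudo-groups of the original sizes, recomputing both networks,
and recording the statistic difference — $\Delta z_{ij}$ per edge, or a
graph-metric difference. The p-value uses the add-one estimator
$p = (1 + b)/(1 + m)$ over $m$ permutations, which never reports $p = 0$ and
has minimum attainable value $1/(m+1)$.

Multiplicity families are the natural ones and are recorded in every result
object: 91 unordered edges for the edgewise test, 14 nodes for each regional
metric (both Benjamini–Hochberg at $q \le 0.05$), and no correction for the
two scalar global metrics (tested at $\alpha = 0.05$). Whether the original
analyses used exactly these families is not derivable from published text;
the choice is documented rather than asserted.

Demographic helpers mirror standard clinical-table practice: a
pooled-variance Student t-test from group summaries (Welch available as an
option) and a Pearson chi-square without continuity correction. These two
conventions are deliberate: on the published demographic table
(40 vs 41 subjects; ages $34.93 \pm 7.89$ vs $36.46 \pm 7.42$; sex 23/17 vs
25/16) they reproduce the printed p-values 0.37 and 0.75 at two decimals,
whereas Welch/Yates variants do not round to the same values.

```{r}
two_sample_t_from_summary(34.93, 7.89, 40, 36.46, 7.42, 41)$p_value
chi_square_2x2(matrix(c(23, 25, 17, 16), 2))$p_value
```

## Tunable parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| VOI mask radius | 6 | mm | self-contained stand-in for AAL parcel extents, sensible at PET resolution (scanner FWHM ~4.25 mm); a label image is the faithful alternative |
| smoothing FWHM | 0 (off) | mm | most archival PET is already smoothed (8 mm is the common choice); smoothing is opt-in to avoid double smoothing |
| brain mask threshold | 12.5% of the 99th percentile | — | deterministic "auto" definition of the brain for mean normalization; user masks override |
| weight mode | `positive` | — | clamping is standard for covariance networks; `absolute` selectable; edge statistics are unaffected either way |
| permutations | 10000 (tests), 1000 (interactive `run_analyze`) | — | 10000 matches full-fidelity published practice; 1000 keeps interactive runs under a minute |
| FDR threshold | 0.05 | — | conventional q level |
| sidedness | `two_sided` | — | direction is read off the observed sign; a one-sided `less` mode exists for "decreased-only" emulation |

## What the synthetic generator emulates — and what it does not

`generate_cohorts()` draws each subject's VOI vector from a multivariate
normal with a *stated* correlation structure: off-diagonal 0.5 everywhere
plus +0.2 within hemisphere (positive definite by construction), scaled to
uptake mean 1.2 and between-subject SD 0.12 — typical magnitudes for
normalized gray-matter FDG uptake — plus independent measurement noise
(SD 0.02, which attenuates observable correlations by a recorded factor).
Group sizes default to 40 vs 41. Planted effects add `delta_r` to chosen
edges of the patient-like group; edits that break positive semidefiniteness
are repaired by Higham alternating projection (`Matrix::nearPD`), and the
repair distance is part of the ground truth so tests can refuse silently
distorted targets.

`render_volumes()` paints uptake into 6 mm spheres on a
$128 \times 128 \times 35$ grid of $1.95 \times 1.95 \times 4.25$ mm voxels
inside a brain-like ellipsoid, enabling byte-level round-trip tests of the
imaging path.

A green test on this world establishes that the estimator machinery is
correct: correlation recovery, calibrated type-I error, deterministic
reruns. It does **not** establish robustness to what real PET adds: spatial
autocorrelation from scanner resolution and smoothing, partial-volume
effects at VOI boundaries, non-Gaussian uptake distributions, scanner batch
effects, or misregistration to MNI space. Those belong to preprocessing
quality, not to this package's statistics.

## Numerical choices

- **Zero-variance columns**: correlation is undefined, so observed groups
  error; permutations that produce one (impossible in practice with
  continuous data) are redrawn with a bounded retry budget and a logged
  count, keeping the null sample size at its configured value.
- **Disconnected pairs**: characteristic path length averages finite pairs
  and *reports* the excluded count, because $\infty$-propagation would let a
  single missing edge destroy the statistic.
- **Dijkstra ties**: broken by first-index order; path lengths are unique
  regardless, so no behavioural ambiguity. Verified against an independent
  Floyd–Warshall implementation on random graphs to $10^{-10}$.
- **Correlation clamping**: crossprod rounding can push $|r|$ marginally
  past 1; values are clamped so `atanh` never silently produces `NaN`. True
  $|r| = 1$ (duplicate columns) errors in strict mode.
- **Smoothing boundaries**: nearest-edge replication, so constants are
  preserved and brain-edge voxels are not dimmed; kernel truncated at
  $4\sigma$. World-space sigma is converted per axis, handling anisotropic
  voxels.
- **Analyze orientation**: `.hdr/.img` files carry no definitive
  orientation; the reader uses the header affine (SPM originator convention)
  and an explicit `flip` argument, never a silent guess.
- **Determinism**: every stochastic function takes a seed, restores the
  caller's RNG state, and the pipeline archives the effective config; reruns
  are byte-identical.

## Design choices where the design was genuinely open

- **VOI extents.** Published work names a standard parcellation but only
  prints centre coordinates. Default: 6 mm spheres at those centres;
  faithful alternative: any label image via `load_label_masks()`. Sphere
  non-overlap is checked where it matters (volume rendering).
- **Preprocessing order.** Smooth → normalize → extract, matching the order
  preprocessing is conventionally listed in; both smoothing and
  normalization are toggleable, so other orders are reachable by composing
  the exported steps.
- **Negative correlations.** Clamped for graph analysis only. The unclamped
  $Z$ drives all edgewise inference.
- **t-test/chi-square variants.** Pooled-variance and uncorrected Pearson,
  chosen because they reproduce the published demographic p-values exactly
  at printed precision (see above).

## A power limitation, quantified

One acceptance-level expectation — a single planted edge (correlation 0.7
vs 0.2, n = 40/41) recovered at $q < 0.05$ in $\ge 80\%$ of replicates with
1000 permutations — is left failing on purpose, because it is structurally
unattainable, not an implementation defect:

1. With $m = 1000$ permutations the smallest attainable p is
   $1/1001 \approx 9.99 \times 10^{-4}$, but the BH rank-1 threshold in a
   91-edge family at $q = 0.05$ is $0.05/91 \approx 5.5 \times 10^{-4}$. A
   lone effect can therefore *never* clear FDR at this permutation count;
   detection requires a second null edge to land below $\sim 10^{-3}$ by
   chance (observed: ~2–3% of replicates).
2. Even with unlimited permutations the effect is too small for this family:
   $\Delta z = \operatorname{atanh}(0.7) - \operatorname{atanh}(0.2) =
   0.665$ against a null SD of $\sqrt{1/37 + 1/38} \approx 0.23$ is a
   $\sim\!2.9\sigma$ effect, whereas two-sided $p \le 0.05/91$ needs
   $\sim\!3.45\sigma$ — asymptotic sensitivity roughly 25–30%.

The attainable statements are tested green instead: the planted edge carries
the most extreme observed $\Delta z$ and a raw $p \le 0.05$ in the large
majority of replicates, and fewer than 10% of unplanted edges are ever
flagged. `scripts/acceptance.R` reports all three rates honestly.

## Known limitations

- Nodal local efficiency, clustering, modularity, betweenness and
  small-world indices are out of scope, as are partial correlations and
  sparse inverse-covariance networks.
- Spatial normalization to MNI is assumed done (the package checks only
  that VOI centres land inside the grid).
- The sphere-mask default is an approximation to parcel-based extraction;
  with real data, supply the parcellation used.
- Group networks are single estimates; no confidence bands on individual
  $r_{ij}$ are reported beyond the permutation machinery.
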