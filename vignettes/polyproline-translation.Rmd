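---
title: "Methods: polyproline-motif translation efficiency and metabolite trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polyproline-motif translation efficiency and metabolite trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribopp)
```

## Scientific setting

Consecutive proline residues are the slowest substrates of the ribosome:
peptide-bond formation between prolines stalls elongation, which makes the
translation of polyproline (PP) motif-rich proteins disproportionately
dependent on a steady supply of prolyl-tRNA.  When the prolyl-tRNA-synthetase
activity of EPRS1 is inhibited pharmacologically (the "treated" condition
throughout this package), genes encoding PP-rich proteins are expected to
lose translation efficiency (TE) first.  `ribopp` implements the desk-scale
statistics of that argument — TE from paired RNA-seq/Ribo-seq counts,
classification of differential TE, and enrichment of PP-motif content among
repressed genes — together with a second, metabolic arm: clustering serum
metabolite trajectories across ordered groups (healthy → non-metastatic →
metastatic, or weekly time points in a tumour-bearing mouse) and intersecting
the rising trajectories across cohorts.

Because the package is developed and validated without sequencing data, a
synthetic-data module generates every input with planted ground truth, and
the test suite checks that the full pipeline recovers what was planted.

## Translation-efficiency model

For gene $g$ in one (condition, replicate) pair with matched RNA and
ribosome-footprint (RPF) libraries,

$$\mathrm{TE}_g = \frac{\mathrm{CPM}^{\mathrm{rpf}}_g}{\mathrm{CPM}^{\mathrm{rna}}_g},
\qquad
\mathrm{CPM}_g = 10^6 \, \frac{c_g + c_0}{\sum_j (c_j + c_0)},$$

with pseudocount $c_0 = 1$ by default.  The pseudocount guarantees strictly
positive TE (so logarithms are always defined) at the price of *exact* depth
invariance: rescaling a library by $f$ while holding $c_0$ fixed perturbs
CPMs at order $c_0/\bar c$.  The suite checks both facts — exact invariance
when the pseudocount is scaled with the library, and perturbations below
0.02 on the log2 scale at counts of a few hundred.

Differential TE compares mean log2 TE between conditions.  The default test
is the Welch two-sample t-test on per-replicate log2 TE values; genes are
classified `up`/`down` when $|\log_2\mathrm{FC}| > 1.5$ *and* raw $p < 0.05$,
otherwise `ns`.  Raw p-values are thresholded deliberately: the
classification mimics a scatter-plot gate, not an FDR-controlled discovery
list.  Genes whose mean raw RNA count falls below 5 are excluded from
testing (unstable TE), and single-replicate designs report the fold change
with a missing p-value.

**A note on the Welch test at n = 3.**  With three replicates per condition
the Welch test is intrinsically conservative: the Satterthwaite
degrees-of-freedom estimate at $n_1 = n_2 = 3$ yields a null rejection rate
near 3% at a nominal 5%, even on exactly normal data.  The suite measures
this on null simulations (planted effect zero).  Where exact type-I
calibration matters more than robustness to variance heterogeneity,
`differential_te(..., test = "student")` switches to the equal-variance
t-test, which sits at the nominal level in the same simulations; with equal
group sizes and similar spreads — which holds for this design — the two
tests differ only in their small-sample df.  Welch remains the default
because it degrades more gracefully if one condition is noisier.

Two closed-form Fig.-style readouts complete the module:
`reporter_te()` = (F-luc/R-luc activity) ÷ (F-luc/R-luc mRNA), and
`polysome_distribution()`, which renormalises per-fraction mRNA quantities
into proportions.

## Motif scanning

`scan_motifs()` counts PP dipeptides, PPG and PPP tripeptides and the
longest proline run, case-insensitively, with `*` stripped.  Windows overlap
by default, so a run of $p$ prolines contributes $p-1$ PP and
$\max(p-2,0)$ PPP; overlapping counting is the conservative superset and a
`non_overlapping` flag provides the alternative (each residue used at most
once per motif).  PPG occurrences can never overlap one another, so the flag
does not affect them.  The PP-count bins `0, 1, 2, 3, >=4` are a pure
function of the PP count.  When several isoforms map to one gene,
`profile_proteome()` scans the longest isoform by default — the common
proteome-scale convention; `first` and `error` policies are available.

## Enrichment statistics

* `contingency_test()` — chi-square without continuity correction (its
  statistic equals $n(ad-bc)^2/((a{+}b)(c{+}d)(a{+}c)(b{+}d))$); `auto`
  falls back to Fisher's exact test when any expected cell is under 5.
* `rank_test()` — two-sided Mann–Whitney; exact p by full enumeration of all
  $\binom{n_1+n_2}{n_1}$ label assignments when both groups have ≤ 8
  observations (valid under ties, unlike the classical exact distribution),
  and the tie-corrected normal approximation otherwise.
* `ora_test()` — one-sided hypergeometric upper tail
  $P(X \ge k)$, BH-adjusted across the collection.  The default universe is
  the set of *tested* genes (those with a computed TE), not the whole
  genome, to avoid background inflation.
* `intersect3()` — the 7 disjoint Venn regions with case/whitespace
  normalisation of identifiers.

## Trajectory clustering

Metabolite trajectories are represented as metabolite × ordered-group
matrices of standardised group means.  Fuzzy c-means is implemented from its
update equations: memberships $u_{ij} \propto (1/d^2(x_i,c_j))^{1/(m-1)}$
normalised per row, centers $c_j = \sum_i u_{ij}^m x_i / \sum_i u_{ij}^m$,
objective $J = \sum_{ij} u_{ij}^m d^2(x_i,c_j)$, which is non-increasing
across iterations (asserted during fitting).  Defaults: fuzzifier $m = 2$,
10 random restarts per fit with child seeds derived from one seed,
convergence when $J$ decreases by less than $10^{-8}$.  A profile exactly
coinciding with a center takes full membership there (the $d\to 0$ limit).

The cluster number is chosen by the elbow method, operationalised
Kneedle-style: the selected $k$ maximises the perpendicular distance of
$(k, J(k))$ from the chord joining the endpoints of the objective curve.
Cluster membership reports use membership-based assignment:
argmax membership (lowest index on ties) with a 0.5 cutoff.  Clusters whose
center is strictly monotone across the ordered groups in the requested
direction supply the trajectory sets that are intersected across cohorts
(exact name matching after case/whitespace normalisation).

**Standardisation and the `scale` field.**  Synthetic panels are generated
with group means directly on the z scale (amplitudes within ±1.5), so the
pipeline clusters them as-is.  Re-applying per-row standardisation to data
that is already on a standardised scale is actively harmful: a "flat"
metabolite's row is pure noise, and dividing it by its own sd inflates it to
unit norm, scattering flat profiles uniformly over the profile sphere and
erasing the flat cluster as a coherent group.  Panels therefore carry a
`scale` field (`"zscore"` or `"raw"`); `zscore_profiles()` is applied only
to raw concentration-scale panels, which is the real-data path.  The same
reasoning applies to Mfuzz-style workflows on real data, where
low-variation features are usually filtered before clustering.

Ordination and group testing use the replicate-level panel: `pcoa_embed()`
is classical scaling (eigen-decomposition of the double-centered Gram
matrix, negative eigenvalues reported and dropped) and `permanova()` is
Anderson's one-way pseudo-F with $R^2 = SS_{between}/SS_{total}$ and a
permutation p-value $(1 + \#\{F^\ast \ge F\})/(n_{perm}+1)$.  Euclidean
distance is the default for both (the source analyses name no metric); any
precomputed distance matrix, e.g. Bray–Curtis from `vegan::vegdist`, can be
supplied instead.

## The synthetic study

`sim_config()` fixes the study conditions; the defaults are the conditions
under which everything in this package is validated.

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 2000 | genes in the proteome/count matrices |
| `pp_bin_probs` | .50/.20/.12/.08/.10 | PP-count bin probabilities (`>=4` draws 4–6) |
| `n_reps` | 3 | replicates per condition, the Ribo-seq design size |
| `baseline_mu` | 500 | mean counts per gene |
| `dispersion` | 0.1 | NB dispersion φ, var = μ(1+φμ) — a common bulk regime |
| `beta` | 1 | log2 TE repression per PP motif in responsive genes |
| `frac_responsive` | 0.3 | fraction of PP-containing genes that respond |
| `lib_size` | `n_genes·baseline_mu` | expected reads per library |
| `noise_sd` | 0.3 | Gaussian noise on z-scale trajectory means |
| `metastasis_or` | 4 | odds ratio of metastasis-set membership for responsive PP genes |

Sequences are uniform over the 19 non-proline amino acids with proline runs
inserted at non-adjacent positions, so a rescan recovers exactly the planted
PP count — this keeps the motif scanner testable against the generator's
truth.  RNA counts are identically distributed across conditions; treated
RPF means are attenuated by $2^{-\beta\,\mathrm{PP}}$ for responsive genes.
No renormalisation is applied to the treated RPF library: a global
translational inhibitor genuinely lowers footprint yield, so the treated
library total is expectedly below `lib_size` (by ~11% at the defaults), and
the CPM step of the TE computation absorbs it as a small compositional
shift (≈ +0.16 log2 units at the defaults), well inside the ±0.5 recovery
tolerance the suite checks for PP ≥ 4 genes.

The two default trajectory cohorts mirror the motivating study design: a
clinical cohort (71 metabolites, groups control < NM < EHM with 20/50/41
samples, 42 metabolites rising) and a mouse cohort (72 metabolites, weeks
2–5, n = 6 per week, 27 rising).  Sixteen amino acids are planted as rising
in *both* cohorts under the same names; all other metabolite names are
cohort-specific, so the cross-cohort intersection has an exact truth.

What the generator does **not** emulate: codon-resolution ribosome
occupancy, UTR/ORF structure, read-level artefacts, batch effects,
correlated gene modules, compositionality of real metabolomics panels, or
missingness.  Passing tests therefore demonstrate the statistical machinery
is correct and well calibrated under the stated model — not that the
biological conclusions of any particular dataset are reproduced.

## Numerical and boundary choices

* IHC area bands are left-open/right-closed with grade 0 up to *and
  including* 5% (the printed bands overlap at their endpoints; this
  resolution is configurable via `breaks`).  The composite score is area
  grade × intensity grade ∈ [0, 12].
* Negative migration rates (wound widening) and negative invasion areas
  (spheroid shrinkage) are reported with warnings, never clamped.
* Gene and metabolite identifiers are matched case-insensitively after
  whitespace stripping; duplicates collapse with a warning.
* All randomness flows from one seed; sub-generators use child seeds at
  fixed offsets, so each stage is independently reproducible and the
  pipeline's outputs are byte-identical across reruns (verified by manifest
  hashes).

## Problem sizes used in validation

The suite validates at the default study size (2,000 genes × 12 libraries,
two trajectory cohorts of ~70 metabolites) and runs its null calibrations on
2,000-gene studies (Welch/equal-variance rejection rates) and 200 PERMANOVA
simulations at 199 permutations.  Oracle equivalences use 1,000 random
sequences for the motif scanner and 100 random configurations for the
ORA–Fisher identity.

## Known limitations

* TE inference is per-gene t-testing on log2 TE ratios; it does not borrow
  strength across genes (no shrinkage), so power at n = 3 is limited and
  the Welch default is conservative at that size (see above).
* The elbow criterion needs at least three candidate k values and can be
  ambiguous when the objective curve has no clear knee; the full curve is
  always returned for inspection.
* PERMANOVA is one-way only; no strata or covariates.
* The pipeline is a plain-file orchestrator by design — desk-scale data,
  no workflow engine.

## A minimal run

```{r, eval = FALSE}
cfg <- pipeline_config("ribopp_run", seed = 1)
res <- run_pipeline(cfg)
res$candidates          # TE-down, PP-containing, metastasis-set genes
res$trajectory$common   # metabolites rising in every cohort
```
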