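# ribopp

Translation of polyproline (PP) motif-containing proteins depends acutely on
prolyl-tRNA supply: consecutive prolines are the ribosome's slowest
substrate, and inhibiting the prolyl-tRNA-synthetase activity of EPRS1
should therefore repress PP-rich genes first.  `ribopp` is an R package for
the two desk-scale analyses that test this idea and its metabolic context in
hepatocellular carcinoma:

1. **Translational arm** — per-gene translation efficiency (TE) from paired
   RNA-seq and ribosome-footprint (RPF) count matrices,

   TE<sub>g</sub> = CPM<sup>rpf</sup><sub>g</sub> / CPM<sup>rna</sup><sub>g</sub>,

   Welch t-test classification of differential TE
   (`up`/`down` at |log₂FC| > 1.5 and p < 0.05), and enrichment statistics
   relating TE classes to PP/PPG/PPP motif content scanned from protein
   FASTA (chi-square, Mann–Whitney U with exact small-sample enumeration,
   three-way set intersection, hypergeometric over-representation analysis
   with BH adjustment).

2. **Metabolic arm** — fuzzy c-means clustering of metabolite trajectories
   across ordered groups (control < NM < EHM patients; weekly time points in
   tumour-bearing mice), cluster number by the elbow method (maximum chord
   distance on the objective curve), membership-based assignment, selection
   of strictly monotone clusters, cross-cohort intersection of rising
   metabolites, plus PCoA ordination and PERMANOVA
   (pseudo-F, R² = SS_between/SS_total, permutation p).

It also ships the closed-form wet-lab readouts used around such studies —
wound-healing migration rate [(W₀−W₁)/W₀ × 100 %], spheroid invasion area
(I₁−I₀), the 0–12 IHC composite score (area grade × intensity grade),
2^−ΔΔCt qPCR fold changes, reporter TE [(F-luc/R-luc) ÷ mRNA ratio] and
polysome fraction distributions — and a fully seeded **synthetic-data
module** that generates every pipeline input (proteome FASTA with planted PP
motifs, negative-binomial counts with motif-dependent translational
repression, trajectory panels with planted shapes, gene sets with planted
enrichment), so the whole workflow is testable without sequencing data.

Intended users: computational biologists replicating or stress-testing this
style of Ribo-seq + metabolomics analysis, and method developers who want a
transparent, oracle-tested reference implementation.

## Worked example

```r
library(ribopp)

study <- simulate_study(sim_config(seed = 1))   # 2000 genes, 2 cohorts
te    <- compute_te(study$counts)
res   <- differential_te(te, control = "control", treated = "treated")
table(res$class)
#> down   ns   up
#>  128 1870    2
```

128 genes lose TE under treatment.  Are PP-motif genes over-represented
among them?

```r
prof <- profile_proteome(write_study(study, "run")["proteome"])
cp   <- prof$contains_pp[match(res$gene, prof$gene)]
down <- res$class == "down"; rest <- res$tested & !down
tab  <- rbind(down = c(sum(down & cp), sum(down & !cp)),
              rest = c(sum(rest & cp), sum(rest & !cp)))
contingency_test(tab)
#> $statistic 132.7907   $p_value 1.004664e-30   $method "chi2"
```

126 of the 128 TE-down genes contain at least one PP dipeptide, against 46 %
of the remaining tested genes — the planted motif-dependent repression is
recovered.  The metabolic arm finds the planted trajectory structure:

```r
panel <- study$panels$cohort1                        # 71 metabolites
choose_k_elbow(panel$abundance, 2:8, seed = 201)$k   # 4 (planted shapes)
fit <- fuzzy_cmeans(panel$abundance, 4, seed = 301)
length(select_monotone_cluster(fit, "increasing"))   # 42 rising metabolites

pm <- permanova(dist(panel$samples), panel$sample_group, 999, seed = 401)
#> F = 449.7, R2 = 0.893, p = 0.001
```

R² = 0.893 means the group factor (control/NM/EHM) explains 89 % of the
total squared-distance variance in the replicate-level profiles.  The
one-call orchestrator runs everything and writes deterministic TSV/CSV/GMT
outputs plus a hashed manifest:

```r
res <- run_pipeline(pipeline_config("ribopp_run", seed = 1))
res$candidates   # TE-down ∩ PP-containing ∩ metastasis gene set
```

A shell wrapper is included: `Rscript inst/scripts/run_pipeline.R
--config cfg.yaml --out DIR --seed 1`.

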