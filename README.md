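# qmpflow

Quantitative microbiome profiling (QMP) of a longitudinal, multi-segment
gut microbiota, and its links to a time-course serum metabolome.

Relative amplicon profiles are compositions: they sum to one, so a bloom
in one taxon silently depresses every other taxon's apparent abundance,
and changes in total microbial biomass are invisible. `qmpflow` is built
for study designs that fix this by pairing sequencing with a qPCR
total-load assay: hosts (here, birds) sampled repeatedly across gut
segments (duodenum, jejunum, ileum, cecum) and days posthatch, with
bacterial and fungal communities per sample, per-sample marker-gene
loads, and a paired serum metabolome. It is aimed at microbiome
researchers who want the full analysis chain of such a study as tested,
reusable functions rather than a pile of one-off scripts.

## What it computes

* **Quantification** — qPCR standard curves
  (`Ct = a + b log10 copies`, efficiency `(10^(-1/b)-1)×100%`), Ct →
  copies/g back-calculation, and the QMP transform
  `AA_ij = p_ij × L_i` that turns proportions `p` and loads `L` into
  absolute abundances; genus-level collapsing of lineages.
* **Community structure** — Shannon diversity, Bray–Curtis
  dissimilarity (`Σ|x−y| / Σ(x+y)`), adjacent-time-point turnover,
  principal coordinates, one-factor PERMANOVA variance partitions, and
  Procrustes/protest comparison of ordinations.
* **Community types** — Dirichlet multinomial mixtures fitted by EM on
  binned log10 absolute abundances, with model selection by a Laplace
  approximation to the model evidence (BIC reported).
* **Source tracking** — EM estimation of the mixing proportions with
  which candidate source communities (plus an unknown source) compose a
  sink; per bird and day, the share of each gut segment contributed by
  its adjacent anterior segment.
* **Assembly processes** — betaMNTD/betaNTI tip-shuffling null models
  and the Bray–Curtis Raup–Crick index, classifying community pairs
  into heterogeneous/homogeneous selection, dispersal limitation,
  homogenizing dispersal, or undominated, and summarising the
  deterministic vs stochastic balance.
* **Occurrence patterns** — per-genus presence trajectories under a
  9-of-10-birds presence rule, classified as colonization /
  disappearance / core / irregular, with cross-segment intersections.
* **Co-occurrence networks** — partial Spearman correlations
  (conditioned on sampling day by default) with BH-adjusted p ≤ 0.05
  edges, topology metrics, keystone (top-degree) taxa,
  generalist/specialist edges, sign ratios, and the QMP-vs-RMP
  correlation-consistency cross-tabulation.
* **Metabolome** — feature filtering (>30% presence, annotated),
  OPLS-DA with VIP ranking (mean squared VIP = 1; VIP > 1.5 cutoff),
  per-metabolite time-association F-tests with FDR control, and
  six-cluster trajectory clustering with chemical-class composition.
* **Integration** — a low-rank softmax model
  `P(metabolite | microbe) = softmax(U·V' + b)` trained on paired
  samples, the top 1% of conditional probabilities as putative
  interactions, per-stratum ratio tables and a bipartite network.

A synthetic-data generator (`sim_config()`, `simulate_microbiome()`,
`simulate_metabolome()`) reproduces the study design — logistic load
curves plateauing by 7 days posthatch, segment-specific community
types, partial anterior→posterior transmission, planted occurrence
patterns, six metabolite trajectory templates, planted
microbe–metabolite blocks — with full ground truth, so every stage is
testable without any sequencing archive.

## Worked example

```r
library(qmpflow)

cfg <- sim_config(seed = 1)              # 10 birds x 4 segments x 8 days
sim <- simulate_microbiome(cfg)

# calibrate a perfect-efficiency 10^3..10^8 dilution series
curve <- fit_standard_curve(3:8, 40 - log10(2)^-1 * (3:8))
curve
#> standard_curve [bacteria]: Ct = 40.0000 + -3.3219 * log10(copies)
#>   r2 = 1.0000, efficiency = 100.0%, calibrated 10^3..10^8 copies

# QMP transform: proportions x measured load = copies per gram
l <- sim$loads[sim$loads$domain == "bacteria", ]
qmp <- qmp_transform(to_relative(sim$tables$bacteria),
                     setNames(l$load, l$sample_id))
qmp
#> feature_table [QMP]: 320 samples x 120 taxa
#>   domains: bacteria
#>   segments: duodenum, jejunum, ileum, cecum
summary(rowSums(qmp$mat))        # row sums are the measured loads
#>      Min.   1st Qu.    Median      Mean   3rd Qu.      Max.
#> 1.192e+06 1.172e+08 5.554e+08 2.713e+09 1.613e+09 2.395e+10

# longitudinal occurrence patterns in the cecum
cen <- pattern_census(qmp, segments = "cecum")
cen$census
#>       colonization core disappearance irregular
#> cecum           30   12             8        70
head(subset(cen$trajectories, category == "colonization"), 2)
#>     genus     category onset_dph   states
#> 3  b_g003 colonization        14 aaappppp
#> 7  b_g007 colonization        14 aaappppp
```

The `states` string is the per-day trajectory (`a` absent, `p` present,
`t` transition): `aaappppp` is a genus undetectable in the first three
sampling days that colonises at 14 days posthatch and stays — the
colonization pattern. The census counts match the generator's planted
categories (30 colonizing, 12 core, 8 disappearing bacterial genera).

## The analysis workflow

The numbered scripts under `analysis/` run the full study on synthetic
data and write their tables under `results/`:

```
01_simulate.R         simulate the study and write all input tables
02_quantify.R         standard curve, Ct -> load, QMP tables
03_structure.R        diversity, turnover, PCoA, variance partition, protest
04_community_types.R  DMM typing with Laplace model selection
05_source_tracking.R  adjacent-segment contributions vs planted truth
06_assembly.R         betaNTI / RC_Bray process classification
07_occurrence.R       occurrence patterns and intersections
08_networks.R         co-occurrence networks, topology, consistency
09_metabolome.R       filtering, OPLS-DA, time association, clusters
10_integration.R      microbe-metabolite co-occurrence model, top 1%
```

Run them in order from the repository root
(`Rscript analysis/01_simulate.R`, ...). `run_pipeline()` executes the
same chain in one call with a manifest and per-stage seeds.

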