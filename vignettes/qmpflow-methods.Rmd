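---
title: "Methods: quantitative profiling of a developing multi-segment gut microbiota"
author: "qmpflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative profiling of a developing multi-segment gut microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`qmpflow` implements a complete quantitative microbiome profiling (QMP)
analysis of a longitudinal, multi-segment gut study — the kind of design in
which birds (or other hosts) are sampled repeatedly across gut segments
(duodenum, jejunum, ileum, cecum) and days posthatch (DPH), with both a
bacterial and a fungal community per sample, a qPCR total-load measurement
per sample, and a paired time-course serum metabolome. The package covers
the full chain: load calibration, absolute-abundance transformation,
community structure statistics, Dirichlet multinomial mixture (DMM)
community typing, source tracking, assembly null models, longitudinal
occurrence patterns, co-occurrence networks, metabolome modelling, and
microbe–metabolite integration. A synthetic-data generator with recorded
ground truth substitutes for sequencing archives so that every stage is
exercisable and testable offline.

# The QMP model

Amplicon sequencing yields compositions: per-sample proportions $p_{ij}$
summing to one. The quantitative profile rescales each sample by its
measured total microbial load $L_i$ (marker-gene copies per gram of
luminal content, from a qPCR assay calibrated on a $10^3$–$10^8$ copy
standard curve):

$$\mathrm{AA}_{ij} = p_{ij} \cdot L_i .$$

The load itself is back-calculated from the calibration line
$\mathrm{Ct} = a + b\,\log_{10}(\text{copies})$, so
$\text{copies} = 10^{(\mathrm{Ct}-a)/b}$ and
$L = \text{copies} \times \text{dilution factor} / \text{sample weight}$.
Amplification efficiency is $E = (10^{-1/b}-1)\times 100\%$; a perfectly
doubling reaction has $b = -1/\log_{10}2 \approx -3.3219$ and $E = 100\%$.

Assumptions worth stating: loads are marker-gene **copies**, not cells —
no 16S/ITS copy-number correction is applied (a per-taxon correction hook
exists but defaults off, because the assay quantifies copies); no
rarefaction precedes the scaling (direct proportion × load is the
default, with an optional rarefaction flag); the dilution factor is a
required user input because extraction and elution volumes are
protocol-specific.

# Synthetic study conditions

`sim_config()` fixes the simulated design: 10 birds × 4 segments ×
8 sampling days {1, 4, 7, 14, 21, 28, 35, 42} DPH, two domains (120
bacterial and 80 fungal genera). The generator emulates the features the
analyses are designed to detect:

* **Loads** follow a logistic curve $L(t)=K/(1+e^{-r(t-t_0)})$ per
  segment and domain, times lognormal noise (sdlog 0.5). Bacterial
  carrying capacities rise along the gut from $10^8$ (duodenum) to
  $10^{10}$ copies/g (cecum) with $r=1.5$/day and $t_0=3.5$ d, so the
  plateau is reached by 7 DPH; fungal loads sit two to three orders
  lower with the ileum above the cecum. These values are chosen as
  realistic for a broiler gut; they are the fixed study conditions, not
  tuning knobs.
* **Community types**: one shared "hatch" type at 1 DPH, then
  segment-specific Dirichlet-multinomial centroids (5 bacterial,
  4 fungal types; Dirichlet precision 500).
* **Transmission**: each segment's relative profile mixes in the
  adjacent anterior segment's realized community at a configured
  proportion (defaults 0.1 / 0.5 / 0.1 along the chain, reflecting
  limited transmission except jejunum→ileum). Mixing acts on the
  *post-masking* profiles so that what a sink receives is exactly what
  its source carries — the property source tracking is asked to recover.
* **Occurrence patterns**: planted per-taxon categories. Colonizing
  taxa are zeroed before a per-taxon onset day; disappearing taxa are
  zeroed from an offset day; core taxa are always present; irregular
  taxa flicker at the bird level (30% dropout per bird × day, shared
  across segments so transmission cannot resurrect a dropped taxon).
  Pattern taxa receive a centroid floor (0.006) and, in their planted
  "present" phase, are clamped just above the detection limit, making
  the planted truth structurally true rather than probably true.
* **Detection limit**: cells below $10^3$ copies/g are zeroed before
  count sampling — the lowest point of the standard curve, making
  occurrence a property of absolute abundance. The value is an
  assumption (no quantitative detection statement exists to import) and
  is exposed in the configuration.
* **Metabolome**: ~1,000 annotated features (plus 80 unannotated ones
  for the filter to remove), six trajectory templates on the log10
  scale (monotone-up, step-up, monotone-down, step-down, up-then-down,
  gradual-down; amplitude 1 log10 unit, Gaussian noise sd 0.25), a
  configurable flat fraction (40%), planted chemical-superclass biases
  per cluster, and two microbe–metabolite blocks coupled linearly on
  the log scale (coupling 0.9) to core cecal bacterial genera.

What the generator does **not** emulate: read-level artefacts (chimeras,
primer bias, taxonomy mis-assignment), true phylogenetic signal in
community assembly (the tree is a random coalescent over taxa, adequate
for null-model calibration but carrying no planted selection signal),
batch effects, and metabolite identification error. Passing tests
therefore demonstrate algorithmic correctness and calibration on data
with known truth — not robustness to the full messiness of real
sequencing data.

# Community structure statistics

Shannon diversity uses the natural log by default (base exposed).
Bray–Curtis dissimilarity is the standard semimetric
$\sum_i |x_i-y_i| / \sum_i (x_i+y_i)$. Principal coordinates are computed
by Gower double-centering of $-D^2/2$ and eigendecomposition; negative
eigenvalues are reported rather than hidden. PERMANOVA uses the
pseudo-$F$ on among/within sums of squared distances with the permutation
p-value $(1+\#\{F^\pi \ge F\})/(1+n_\pi)$; an explicit permutation matrix
can be supplied, which makes exact enumeration testable. The variance
partition over bird, segment and day runs **one factor at a time**
(marginal $R^2$) — a sequential model was the alternative, but marginal
terms are reproducible without knowing an ordering convention, and each
factor's share is interpretable on its own. Procrustes comparisons
(`protest_compare()`) wrap the vegan `procrustes`/`protest` machinery
(symmetric, reflections allowed, permutations over rows of the second
configuration), returning $m_{12}=\sqrt{1-ss}$ and per-sample residuals.

# Community typing (DMM)

Samples are assigned to community types with a Dirichlet multinomial
mixture fitted by EM: the E-step computes responsibilities from component
DM log-likelihoods; the M-step updates mixture weights and each
component's $\alpha$ by Minka's fixed-point iteration (an MM update, so
the observed-data log-likelihood never decreases). Because QMP values are
continuous, they are first binned as $\mathrm{round}(\log_{10}(1+x))$ —
base 10 with a pseudocount of 1, both exposed in the interface since only
"log-transformed" is fixed by convention. Five restarts per candidate
$K$ (first k-means-initialised, the rest random) guard against local
optima; the restart count is a pragmatic choice. Model selection
minimises a Laplace approximation to the negative log evidence computed
in the $\log\alpha$ parameterisation with a diffuse Gaussian prior
(variance 10); each component's Hessian is diagonal-plus-rank-one, so its
determinant comes from the matrix determinant lemma, and the $K-1$ free
mixture weights contribute $\tfrac12\log n$ each. BIC is reported
alongside. The raw-$\alpha$ Hessian was rejected because near-empty
components send diagonal entries to zero and spuriously reward large
$K$. The model is fitted jointly across segments per domain (a
per-segment fit is a trivial wrapper), which matches how spatiotemporal
type distributions are read out.

# Source tracking

`feast_em()` models a sink as a multinomial with probabilities
$\sum_k \alpha_k \gamma_k$ over source profiles plus an unknown source.
The default keeps known-source profiles fixed at their observed
proportions (with a $10^{-8}$ pseudocount) — deterministic and easy to
reason about — while the unknown source's profile is initialised from
sink mass unexplained by the average source and re-estimated each
iteration. Because EM cannot move probability onto taxa where a profile
is exactly zero, the unknown source stays confined to its initial
support and cannot collapse onto the whole sink (the degenerate global
optimum of an unconstrained extra source). Full joint re-estimation of
source profiles is available behind `reestimate_sources = TRUE`. Sinks
are matched to sources from the same bird and day — the stricter design
choice, since pooling sources across birds would blur individual
transmission. Only the adjacent anterior segment's proportion is
reported by `adjacent_segment_contribution()`; the first segment has no
anterior source and yields no rows.

# Assembly null models

The two-step classification uses betaMNTD/betaNTI and RC_Bray.
betaMNTD is abundance-weighted by default (common practice; the
unweighted variant is a flag). The betaNTI null shuffles taxon labels
across tree tips, holding abundances fixed, with 999 draws by default
(tests and scripts use 199, stated where used). RC_Bray draws null
communities that preserve observed richness (taxa sampled by pool
occurrence frequency) and observed total abundance (multinomial over the
drawn taxa by pool mean relative abundance), with
$\mathrm{RC} = 2[P(\mathrm{null} < \mathrm{obs}) + \tfrac12
P(\mathrm{null}=\mathrm{obs})] - 1$. The species pool is the segment's
own samples — the segment is the assembly arena in this design.

The process mapping follows the threshold table: betaNTI $< -2$
heterogeneous selection, $> 2$ homogeneous selection, otherwise RC
$> 0.95$ dispersal limitation, $< -0.95$ homogenizing dispersal, and
$|\mathrm{RC}| < 0.95$ undominated. Two boundary rules are fixed and
documented: betaNTI exactly $\pm 2$ falls to the adjacent selection
class, RC exactly $\pm 0.95$ to undominated. The default mapping of the
betaNTI *sign* to heterogeneous vs homogeneous selection is the one
stated with the figure this analysis reproduces; it is the reverse of
the convention common in the assembly literature, so a
`convention = "stegen"` switch swaps the two selection labels, and the
choice is part of the function contract rather than a hidden constant.
Pairs are compared within segment across all days; deterministic =
selection fractions, stochastic = the other three.

# Occurrence patterns

Per genus, segment and day, the detection count is the number of birds
with abundance above the detection threshold (default: any nonzero QMP
value, consistent with the generator's absolute detection limit). States
follow the 10-bird rule: present when detected in ≥ 9 birds, absent when
≤ 1, transition otherwise — the absence bound is the symmetric complement
of the stated presence bound and is configurable. Categories are a total
function of the state sequence: core (present everywhere), colonization
(absent at hatch, single switch to stably present), disappearance
(present at hatch, single switch to stably absent), irregular (anything
else, including any transition state by default;
`transitions = "absent"/"present"` recodes instead). The irregular
catch-all is the closest total formalisation of a "regular vs mixture"
distinction that is otherwise under-specified.

# Co-occurrence networks

Networks are genus–genus partial Spearman correlations per segment,
built on QMP abundances (RMP networks exist for the consistency
comparison), with bacteria and fungi pooled into one table per segment.
Inclusion requires presence in at least 30% of samples (boundary
inclusive). Because every pair shares the conditioning set, the whole
matrix is computed in one pass: rank-transform, residualise the ranks on
the covariates, correlate the residuals; p-values use the t distribution
with $n-2-k$ degrees of freedom, Benjamini–Hochberg across all pairs in
the network, edges kept at adjusted $p \le 0.05$. The conditioning set
is the single most consequential unstated choice in this kind of
analysis: the default conditions on sampling day (rank-coded) to
suppress correlations driven purely by shared developmental time;
`condition = "none"` and `"custom"` are exposed and the choice is
recorded on every network object.

Topology metrics operate on the unweighted retained-edge graph:
clustering is the average of local coefficients (degree < 2 counts 0),
betweenness is unnormalised, and average separation is the mean shortest
path over *reachable* pairs only. Keystone taxa are the top-degree
vertices, ties broken by summed |rho| then genus name. Edge identity
across segments ignores sign (presence is what is counted); edges in one
network are specialists, in several generalists. The negative/positive
ratio per vertex uses a 0.5 pseudocount on both counts to keep the log
finite. The QMP-vs-RMP consistency cross-tab categorises every shared
pair Pos/Neg/NS in each mode; consistency is the diagonal share of the
total (total-normalised cells; row-normalisation is a trivial variant).

# Metabolome

Features are kept when present in strictly more than 30% of samples and
annotated. All modelling uses $\log_{10}(1+x)$ intensities (transform
exposed). OPLS-DA dummy-codes the groups into a multi-response Y,
removes `n_orth` Y-orthogonal components (the candidate orthogonal
loading is orthogonalised against the span of all predictive weight
vectors, so no between-group direction is removed), then fits a NIPALS
PLS with one predictive component per independent response dimension.
VIP combines predictive weights with per-component explained Y sums of
squares; mean squared VIP is 1 by construction and VIP > 1.5 is the
selection cutoff. Time association is a linear model of log-intensity
on **day as a categorical factor** with an omnibus F-test — the observed
cluster shapes are non-monotone, which a linear-in-time slope would
miss — followed by BH across metabolites (FDR 0.05). Trajectory
clustering z-scores each metabolite's per-day mean profile and cuts a
complete-linkage Euclidean dendrogram at $k=6$; per-day means (rather
than per-sample profiles) match the column structure such heatmaps are
drawn from, and the per-sample variant is a one-line change.

# Microbe–metabolite integration

The co-occurrence model is an explicit low-rank matrix factorisation
with a softmax link:
$P(\text{metabolite } j \mid \text{microbe } i) =
\mathrm{softmax}_j(U_i \cdot V_j + b_j)$, trained on a multinomial
likelihood in which each sample's microbe proportions weight that
sample's metabolite relative intensities (intensities are not counts;
the per-sample normalisation is part of the training contract). The
published neural-network tool this mirrors is treated as a model form to
reimplement reproducibly, not a dependency. Training is full-batch
gradient descent with backtracking, so the loss is non-increasing by
construction and runs are deterministic under a seed. Defaults
(latent dimension 3, 500 epochs, learning rate 0.1) are desk-scale
choices exposed in the interface. Models are fitted per segment × domain
and merged at selection; the top 1% of conditional probabilities across
all scored pairs (global ranking, stable tie-break) form the interaction
set, summarised as per-stratum retained-percent tables and a merged
bipartite network whose top-degree genera are the key taxa.

# Numerical choices and degenerate inputs

* EM convergence: DMM stops on an absolute log-likelihood change
  < 1e-4 (200 iterations max); source-tracking EM on a relative change
  < 1e-11 (3000 iterations) — tight because boundary solutions
  (a sink equal to one source) approach their limit slowly.
* Alpha parameters are floored at 1e-4; responsibilities are computed
  via log-sum-exp.
* Constant variables after ranking are reported as nonsignificant with
  a warning rather than an error; all-zero communities, empty groups,
  single-taxon pools and empty networks raise errors or flagged zero
  results as documented per function.
* BH adjustment is `p.adjust(method = "BH")`; the brute-force oracle in
  the tests agrees to 1e-15 (element order of floating-point
  multiplication differs) and selects identical feature sets.
* All randomness flows through per-stage seeds derived from one master
  seed by hashing the stage name (`stage_seed()`), so any stage subset
  reproduces the full run bit for bit.

# Problem sizes

The default simulated study is 10 birds × 4 segments × 8 days × 2
domains (640 community samples, 200 taxa, ~1,000 metabolites). The test
suite and the acceptance script scale the expensive null models to sizes
chosen for a single-CPU desk run: 199 null draws for betaNTI/RC
calibration checks (999 remains the analysis default), 500 replicates
for the betaNTI normality check, 10 seeds × K ∈ 1..5 for DMM selection
consistency, 20 seeds for source-tracking recovery, 1,000 simulations
for type-I-error calibration, and a reduced-knob end-to-end double run
for bit-reproducibility. The analysis scripts under `analysis/` use 199
null draws and 40 pairs per segment for the assembly stage.

# Known limitations

* The assembly stage's synthetic data carry no planted phylogenetic
  selection signal, so deterministic fractions on simulated data are
  small; the stage is validated by calibration and classification
  contracts, not by reproducing a particular deterministic share.
* DMM community types on the full simulation reflect both composition
  and load magnitude (the binned log-AA matrix mixes the two); planted
  type recovery is validated on dedicated mixture simulations instead.
* OPLS-DA predictive scores are only approximately invariant to the
  orthogonal component count on noisy data (correlation ≈ 0.995 at low
  signal-to-noise, ≥ 0.999 when classes are well separated); this is a
  property of recomputing weights on deflated data, shared with the
  reference implementations.
* The partial-correlation conditioning set, the detection limit, and
  the DMM binning base are all assumption-level choices exposed in the
  configuration; conclusions sensitive to them should be checked under
  the alternatives.
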