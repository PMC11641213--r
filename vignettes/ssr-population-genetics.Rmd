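---
title: "SSR population genetics and core collections with ssrpop"
author: "ssrpop authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SSR population genetics and core collections with ssrpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrpop)
```

# The analysis this package implements

`ssrpop` reimplements, as one tested pipeline, the standard SSR
(microsatellite) population-genetics workflow used in germplasm surveys of
long-lived trees: per-locus and per-population diversity statistics,
Wright's F-statistics with island-model gene flow, a three-level AMOVA,
Nei (1972) distances with UPGMA clustering and PCoA, admixture-model
structure inference with the Evanno ΔK model choice, and a stepwise
expected-heterozygosity core collection. The concrete study design it is
calibrated to is a survey of 416 ancient *Sophora japonica* accessions from
three Chinese provinces (Shandong 374, Hebei 16, Shanxi 26) genotyped at 16
SSR loci carrying 160 alleles in total, with overall differentiation near
$F_{ST} = 0.04$. The raw genotypes of that survey were never deposited —
only its per-locus summary table is public (shipped as
`sophora_locus_reference()`) — so every stage here is exercised on
synthetic genotype matrices whose design constants reproduce the study's
shape. One published inconsistency is inherited knowingly: the
per-population summary prints 375 Shandong accessions while the sampling
table prints 374; we follow the sampling table (374) throughout.

# Data model

A `genotype_matrix` holds, for each accession and locus, an unordered pair
of positive integer allele codes (fragment sizes in bp) or a pair-level
missing sentinel. Missingness is deliberately pair-level: a half-missing
call in an input file is promoted to fully missing with a warning, because
every downstream statistic counts per-locus sample sizes in whole
individuals. Allele codes are opaque — no binning or size calling is
performed. Two community file dialects are supported: a GenAlEx-style CSV
(three header rows: counts; title and population labels; column names;
`0` = missing) and the STRUCTURE two-row-per-individual flat text
(`-9` = missing). Both round-trip exactly and byte-stably.

# The synthetic-data generator

The generator is first-class, tested code, not a fixture. Population
allele frequencies follow the Balding–Nichols construction: per locus an
ancestral frequency vector $p$ is drawn (symmetric Dirichlet(1) by
default) and each population's vector is drawn
$\mathrm{Dir}\!\left(p \cdot \tfrac{1-F}{F}\right)$, which gives the
closed-form variance $\mathrm{Var}(p_{pop}) = F\,p(1-p)$ that the test
suite checks by Monte Carlo. Genotypes are then two independent draws per
locus from the population's vector (Hardy–Weinberg within population), and
calls are dropped missing-completely-at-random. This model was chosen over
an explicit coalescent because it links the `fst_target` parameter to the
expected differentiation in closed form; the study reports only its
observed $F_{ST}$, not a demographic history.

Defaults of `sophora_design()` are the study conditions: population sizes
374/16/26, the 16 published per-locus allele counts (4–19, summing to
160), `fst_target = 0.04`, and `missing_rate = 0.005`, which leaves an
expected 414 of 416 scored individuals per locus, inside the published
410–416 band. Realized multi-locus $F_{ST}$ of simulated panels stays
within 0.02 of the 0.04 target across seeds.

What the generator does *not* emulate: inbreeding (simulated genotypes are
in Hardy–Weinberg proportions, so simulated $F_{IS} \approx 0$ and the
AMOVA's among-individual component is near zero, whereas the real survey
shows heterozygote deficit, $F_{IS} = 0.05$, and a 13% among-individual
component), mutation models, linkage, and any non-random missingness
pattern. Passing tests therefore demonstrate correctness of the statistics
and the recoverability of designed structure — not that real ancient-tree
data look like the simulations. With `admixture_alpha` set, ancestry
proportions are drawn from a Dirichlet with weight $1+\alpha$ on the home
population and $\alpha$ elsewhere, so the $\alpha \to 0$ limit recovers
the unadmixed model with correct labels.

# Diversity statistics

All per-locus statistics use relative allele frequencies
$p_i = \text{copies}/2N$ over the non-missing calls: MAF $=\max p_i$,
$N_a$ = observed alleles, $N_e = 1/\sum p_i^2$,
$I = -\sum p_i \ln p_i$, $H_o$ = fraction of heterozygous individuals,
$H_e = 1 - \sum p_i^2$, and Botstein's
$PIC = 1 - \sum p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$. $H_e$ is the plain
(biased) Nei gene diversity, matching the headline column of the tools the
field uses; the $\tfrac{2N}{2N-1}$-corrected value is exposed as an extra
column. Mean rows are unweighted arithmetic means over loci — a convention
verified against the published table, whose printed means (160 alleles,
mean $N_e$ 4.08, mean $N_m$ 9.74) are reproduced by averaging its printed
per-locus values. A locus with zero scored calls yields `NA` markers, never
silent zeros.

# F-statistics and AMOVA

Per locus, $H_I$ and $H_S$ are *unweighted* means over populations of
observed heterozygosity and gene diversity, and $H_T$ is the gene
diversity of the unweighted mean frequency vector; then
$F_{IS} = (H_S-H_I)/H_S$, $F_{IT} = (H_T-H_I)/H_T$,
$F_{ST} = (H_T-H_S)/H_T$, and $N_m = \tfrac14(1-F_{ST})/F_{ST}$. With
population sizes as skewed as 374/16/26 the unweighted convention is
consequential, so `weighted = TRUE` is available. The mean row averages
per-locus values — including $N_m$, which is *not* recomputed from the mean
$F_{ST}$; this is how the published mean row behaves. Degenerate loci keep
markers: $F_{IS}$ is `NA` at $H_S=0$ and $N_m$ is `Inf` at $F_{ST}=0$
(excluded from the mean with a warning). Note that per-locus $N_m$
recomputed from two-decimal published $F_{ST}$ values does not reproduce
published $N_m$ columns — originals used unrounded $F_{ST}$.

The AMOVA partitions allele-copy variance among populations, among
individuals within populations, and within individuals. Sums of squares
are the nested ANOVA of allele indicator vectors summed over alleles and
loci; on this scale each heterozygous call contributes exactly 1 to the
within-individual SS (tools that use a squared distance of 1 between
different alleles report half these SS; percentages and df are identical).
Degrees of freedom follow the global bookkeeping $k-1$, $N-k$, $N$
(total $2N-1$), with locus-wise complete-case handling of missing calls,
so a 416-accession, 3-population panel always prints df 2/413/416/831.
Variance components use the standard nested estimators with
$n_c = (N - \sum_k N_k^2/N)/(k-1)$; negative estimates are truncated to
zero for percentages, with the raw value kept in its own column. No
permutation p-values are attached (the emulated study reports none).

# Distances, trees, ordination

The Nei (1972) standard distance
$D = -\ln\!\left(J_{xy}/\sqrt{J_x J_y}\right)$ sums the gene identities
over loci *before* the ratio, excluding pairwise-unshared loci. At the
individual level the frequencies are the genotype's 0/0.5/1, the classical
way to apply $D$ between single diploids; a shared-allele distance
($1-$ proportion of shared alleles) ships as the alternative, since the
original tooling offers several individual distances and the study names
only "Nei's genetic distance". Disjoint units ($J_{xy}=0$) receive a
documented ceiling of 10 rather than infinity so UPGMA stays finite.

UPGMA is implemented directly (average linkage, size-weighted update) with
a deterministic tie-break — the lexicographically smallest pair of cluster
representative labels — and merge heights at half the cluster distance, so
tree path lengths reproduce the average-linkage cophenetic distances. The
test suite cross-checks it against `stats::hclust(method = "average")`.
`cut_clusters()` removes the $k-1$ highest merges. PCoA is classical
scaling: Gower double-centering of $-d^2/2$, symmetric
eigendecomposition, coordinates scaled by $\sqrt{\lambda}$; negative
eigenvalues are reported but excluded from coordinates and the
percent-variance denominator, and each axis's sign is fixed by making its
largest-magnitude coordinate positive (checked against
`stats::cmdscale`).

# Admixture model and ΔK

The structure stage is a Gibbs sampler over the standard admixture model:
latent origins $Z$ for every allele copy sampled
$\propto q_{ik}\,p_{kl}(a)$, then cluster allele frequencies
$P \sim \mathrm{Dir}(\lambda + \text{counts})$ and ancestries
$Q \sim \mathrm{Dir}(\alpha + \text{counts})$, with $\lambda = 1$ and
$\alpha$ fixed (not sampled — the emulated study does not report α
handling; it is a plain argument). The model-choice statistic is
$\ln P(D) \approx \overline{\ell} - \mathrm{Var}(\ell)/2$ over the
recorded log-likelihood trace, mirroring the conventional estimator of the
original tool. Defaults are desk-scale (2,000 burn-in + 8,000 iterations,
thinning 10); the study-scale 10,000 + 100,000 settings are ordinary
arguments. Replicate chains are aligned by greedy column matching on
$Q$-correlations before averaging, and the Evanno table computes
$L'(K)$, $|L''(K)|$ and $\Delta K = |L''(K)|/\mathrm{sd}\,L(K)$ with the
endpoints undefined; an all-zero second difference flags the choice as
ambiguous rather than inventing one.

Two practical notes established during development. First, the prior
matters for hard assignment: with $\alpha = 1$ the posterior mean $Q$ of
even well-separated populations is pulled toward $1/K$; the recovery
analyses therefore use $\alpha = 0.1$, the appropriate prior when
individuals are simulated unadmixed. With that setting, two 50-individual
populations simulated at $F = 0.3$ over 20 biallelic loci are recovered at
≥95% hard-assignment accuracy. Second, on the full simulated panel — three
populations at $F = 0.04$ — the structure signal is weak by design, and
ΔK behaves accordingly; the bundled analysis driver documents this rather
than presenting a crisp recovery.

# Core collection

The stepwise construction follows the published procedure literally: at
each step, the mean-over-loci $H_e$ of the set *without* each remaining
accession is recomputed in full (leave-one-out over allele frequencies, not
an individual-heterozygosity shortcut), and the lowest contributor is
removed, ties broken by ascending accession id. The high-contribution tail
of this total order gives nested candidate subsets at the ten published
proportions 50%…5% (sizes `round(p N)`: 208…21, and 104 at 25% of 416).
Internally the leave-one-out values are maintained incrementally from
per-locus allele-count sums, which the tests verify against a plain
reimplementation; the greedy order is identical, just $O(n^2 L)$ instead
of $O(n^3 L)$.

Greedy maximization is not guaranteed optimal. On exhaustively searchable
instances it usually attains the optimum, but tie-rich toy instances can
leave it a percent or two short; the test suite asserts the algorithmic
contract (equality with the leave-one-out specification) everywhere and
the near-optimality bound on its dedicated fixture. Subset evaluation
counts $N_a$ within the subset (so its retention cannot exceed 100%)
while frequency-based parameters routinely exceed 100%, matching the
published pattern.

For the core-vs-original comparison, both t-test variants are provided.
The paired-across-loci test (default) is the sharper instrument and, on
simulated panels, correctly detects that the greedy core shifts every
locus's diversity upward — an effect that is real, not an artifact. The
unpaired variant mirrors how the original study compared two columns of 16
locus values in SPSS and reproduces its "no significant difference"
conclusion on simulated panels. Degenerate cases keep conventions: all
differences zero gives $p = 1$; zero variance around a non-zero mean is
`NA` with a warning.

# Problem sizes and numerics

The shipped analyses and tests use: full-size 416 × 16 panels for design
bookkeeping (AMOVA df, core sizing, $F_{ST}$ calibration over 10 seeds);
100 individuals × 20 biallelic loci for the K = 2 recovery; 120 × 12 for
the ΔK scan (3 replicates, 300 + 1200 iterations); 20,000 replicate draws
for the Balding–Nichols variance check; 200 random subsets for the greedy
dominance comparison. Tolerances: simplex sums to 1e-12, brute-force
oracle agreement to 1e-9, ultrametricity to 1e-9. Tiny float noise in
$F_{ST}$ (|x| < 1e-12) is snapped to zero so the $N_m = \infty$ marker
fires exactly at $H_S = H_T$.

# Known limitations

No rarefaction or null-allele handling; no Weir–Cockerham θ; no
permutation or bootstrap uncertainty; the admixture sampler has no
correlated-frequencies prior, LOCPRIOR, or CLUMPP-style multi-way
alignment; core selection implements only the heterozygosity-maximization
strategy (no M-strategy or distance maximization), with nested subsets
across proportions — whether the original scan re-optimized each
proportion independently is unknown, and nesting is the reproducible
choice. Individual-level Nei distances on 416 accessions are computed
densely; the implementation is adequate to a few thousand accessions but
not beyond.
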