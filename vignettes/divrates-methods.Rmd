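---
title: "Methods: comparative diversification rates and trophic ecology"
author: "divrates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative diversification rates and trophic ecology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divrates)
```

# The scientific problem

Two closely related lineages of populations may diversify at very different
rates. The motivating system is a pair of stickleback lineages in which only
one colonised fresh water: if adaptive divergence happened in one lineage
only, its trait diversification rate should be higher and its populations
should sit around several distinct trait optima. `divrates` implements the
full chain of analysis needed to ask that question from raw data:

1. microsatellite genotypes → pairwise genetic distances → bootstrapped
   UPGMA population trees;
2. lineage ("regime") painting on the tree;
3. maximum-likelihood Brownian-motion (BM) and Ornstein-Uhlenbeck (OU)
   trait-evolution models with lineage-specific rates or optima;
4. parametric-bootstrap (Monte Carlo) likelihood-ratio model selection with
   explicit power estimates;
5. supporting trophic-ecology statistics (trophic position, isotopic niche
   ellipses, Bayesian diet mixing, stomach-content indices, foraging-trial
   metrics).

# Genetic distances

Two complementary distances are computed from allele frequencies:

* **Nei's standard distance** \(D = -\ln(J_{XY}/\sqrt{J_X J_Y})\), where
  \(J_X\), \(J_Y\), \(J_{XY}\) are across-loci arithmetic means of the gene
  identities \(\sum_i x_i^2\), \(\sum_i y_i^2\), \(\sum_i x_i y_i\). It is
  most informative for recent divergence.
* **\(\delta\mu^2\)**, the squared difference in mean allele size (in repeat
  units) averaged across loci. Under the stepwise mutation model (SMM) its
  expectation is \(2\mu t\) with \(t\) the time since the split, so it
  behaves linearly for older divergence.

Implementation choices where the field leaves latitude:

* Allele sizes are converted from base pairs to repeat units on load using a
  per-locus repeat length sidecar, because SMM theory is formulated in
  mutational steps. \(\delta\mu^2\) is invariant to any constant offset per
  locus, so imperfect flanking-region lengths do not matter.
* Missing genotypes are handled pairwise-complete: a locus with no observed
  alleles in either member of a population pair is dropped for that pair
  only.
* A pair sharing no alleles at any locus yields an infinite Nei's D. The
  value is propagated with a warning and flagged on the distance matrix;
  `upgma()` refuses matrices containing it, so the failure is loud and
  occurs at the consumer.
* Bootstrap support resamples **loci** (not individuals) with replacement,
  the convention for microsatellite tree support; replicate r derives its
  seed as `seed + r`, so every replicate is independently replayable.

# Trees and regimes

`upgma()` is written in-package (size-weighted average linkage, node height
= half the merging distance) so that tie-breaking is deterministic: tied
merges pick the lexicographically smallest label pair. Trees interoperate
with `ape` (`phylo` objects, Newick IO, pruning via induced subtrees with
branch lengths summed).

Regimes label every branch. Two painting rules are provided:

* **stem**: a clade whose tips all share a regime carries it from the stem
  branch down; every other branch, and the root, takes the configured root
  regime.
* **parsimony** (default in the pipeline): Fitch parsimony with ties
  resolved towards the parent state; this keeps the backbone of a clade
  containing a nested derived sub-group (freshwater populations inside the
  marine lineage) in the ancestral lineage state.

Before model fitting, trees are rescaled to unit height, so rates
(\(\sigma^2\)) and selection strengths (\(\alpha\)) are in tree-height
units and comparable across the two distance metrics. This rescaling is a
declared convention of the package. Zero-length terminal branches are
floored at \(10^{-8}\) of tree height to keep covariance matrices positive
definite.

# Trait-evolution models

All models are multivariate-normal likelihoods over tip values on the
painted ultrametric tree (height \(T\), shared MRCA height \(s_{ij}\),
patristic distance \(d_{ij}\)).

* **BM1 / BM2.** Covariance \(\sum_k \sigma^2_k C_k\), where \(C_k[i,j]\) is
  the branch length of regime-group k shared on the root-to-MRCA path. The
  root state is profiled by GLS and the overall scale analytically, so BM2
  needs only a one-dimensional search over the log rate ratio.
* **OU1 / OU2 / OU3** (Hansen construction, fixed root state). One shared
  \(\alpha\) and \(\sigma^2\); only the optima \(\theta_k\) differ between
  regime groups:
  \(\mathrm{Cov}[y_i, y_j] = \tfrac{\sigma^2}{2\alpha} e^{-\alpha d_{ij}}
  (1 - e^{-2\alpha s_{ij}})\), and each tip's expectation weights the optima
  along its root-to-tip path by \(e^{-\alpha(T-t_2)} - e^{-\alpha(T-t_1)}\)
  plus \(z_0 e^{-\alpha T}\). The root state defaults to the optimum of the
  root's regime (configurable); the root regime itself defaults to the most
  frequent tip regime and should usually be set to the ancestral lineage.
* Estimation is ML, not REML, for every family. Given \(\alpha\) the optima
  are profiled by GLS and \(\gamma = \sigma^2/2\alpha\) analytically, so the
  OU search is one-dimensional in \(\log\alpha\): a 14-point log grid on
  \([10^{-2}, 50]\) (tree-height units) followed by bounded polish from the
  five best grid points (tolerance \(10^{-4}\) on \(\log\alpha\), which
  resolves the profile log-likelihood far below \(10^{-8}\) near its
  quadratic optimum). A fit at the edge of the grid is flagged as a
  boundary estimate; \(\alpha\) estimates at the upper boundary mean the
  data are effectively independent around the group optima, a known
  identifiability limit of OU models rather than an error.
* Degenerate structures (a parameter group whose regimes own no branch)
  raise an error instead of silently collapsing.

Numerically, \(1 - e^{-2\alpha s}\) is computed with `expm1` so the
\(\alpha \to 0\) limit reproduces the BM likelihood to \(10^{-3}\) at
\(\alpha = 10^{-6}\) (verified in tests).

Simulation (`simulate_trait()`) is an exact preorder recursion: BM children
are \(x_p + N(0, \sigma^2_k \ell)\); OU children are
\(x_p e^{-\alpha\ell} + \theta_k (1 - e^{-\alpha\ell}) +
N(0, \sigma^2(1 - e^{-2\alpha\ell})/2\alpha)\).

Parametric-bootstrap confidence intervals are percentile 2.5/97.5 intervals
over refits of simulated datasets. Percentile intervals for a variance-like
parameter on 24 tips sit at the lower edge of nominal coverage (measured
~88% for the single BM rate); this is a property of the percentile method
retained deliberately for comparability, not a defect of the optimiser.

# Parametric-bootstrap model selection

`pmc_compare()` fits a null and a test model, simulates `n_reps` datasets
under each fitted model, refits both models to every dataset (identical
optimiser settings), and compares the observed
\(\delta = 2(\log L_{test} - \log L_{null})\) to the two simulated
distributions. The p-value is the fraction of the null distribution at or
above \(\delta\); **power** is the fraction of the test distribution above
the null distribution's 95th percentile, computed by the nearest-rank rule.
Refit failures are dropped and counted (never imputed); above 10% the
result is flagged.

Two properties of this machinery deserve emphasis:

* **Calibration.** When the null and test distributions come from the same
  law, the probability that a draw exceeds the other sample's nearest-rank
  95th percentile is 5% by construction. Note that comparing a family
  against literally itself produces likelihood ratios that are identically
  zero (both refits coincide), which is degenerate; the calibration is
  therefore checked with two independently seeded null distributions of the
  nested BM comparison.
* **Why not information criteria.** On trees this size, clade-level drift
  mimics lineage effects; the null LR distribution is far wider than the
  asymptotic chi-square, so AIC-style selection would over-reject. The
  simulated null distribution absorbs exactly this phylogenetic
  pseudoreplication, which is the reason single-optimum OU models are
  surprisingly hard to reject even under strongly clustered data.

`select_best()` applies the staged rule: choose within BM (single vs
separate rates), within OU (1 → 2 → 3 optima), then compare the two
finalists. The final stage reports `"indistinguishable"` when the observed
ratio falls between the bulks of the two distributions (above the null's
95th percentile yet below the test's 5th) — precisely the situation where
high power still cannot separate the finalists.

`subsample_robustness()` re-runs the two-rate analysis over random tip
subsets of one regime across a range of sizes, to check that a rate
difference is not an artefact of unequal population counts and to trace how
power grows with sampling.

# Trophic-ecology statistics

* **Lipid normalization** of fish-muscle \(\delta^{13}C\) uses the
  three-parameter mass-balance model with lipid content predicted from the
  C:N mass ratio (\(L = 93/(1 + (0.246\,C{:}N - 0.775)^{-1})\), constants
  D = 7.018, I = 0.048). At the lipid-free reference ratio (C:N ≈ 3.15) the
  correction bottoms out at \(D\,I \approx 0.34\)‰ — small but not zero;
  the function is idempotent through a per-sample flag.
* **Trophic position** is the two-baseline estimator
  \(T_{POS} = \lambda + (\delta^{15}N_c - [\alpha\,\delta^{15}N_{b1} +
  (1-\alpha)\,\delta^{15}N_{b2}])/\Delta_n\) with \(\alpha\) the
  \(\delta^{13}C\)-based benthic reliance, clamped to [0, 1] with a warning
  (consumers can fall outside the baseline interval through noise);
  defaults \(\lambda = 2\), \(\Delta_n = 3.4\)‰. Baselines are an input
  table, not hard-coded, because which taxa anchor each site is a study
  decision.
* **Standard ellipse area** \(SEA = \pi\sqrt{\det\hat\Sigma}\);
  small-sample corrected \(SEA_C = SEA\,(n-1)/(n-2)\). The Bayesian variant
  draws the covariance from its conjugate inverse-Wishart posterior under a
  vague prior (\(\nu_0 = 3\), scale \(0.01\,I\), flat prior on the mean);
  the posterior mean area converges to \(SEA_C\) as n grows.
* **Mixing model.** Consumer isotopes are normal around the
  contribution-weighted source-plus-fractionation means with variance
  \(\sum_k p_k^2(\sigma^2_{jk} + \tau^2_{jk}) + \xi_j^2\); Dirichlet(1)
  prior on contributions, flat prior on residual SDs over (0, 20).
  Metropolis-within-Gibbs sampling uses a logistic-normal random walk on
  the simplex (with its Jacobian) and log-normal walks on residual SDs;
  proposal scales adapt toward ~30% acceptance during burn-in only, so the
  kept chain satisfies detailed balance. Fractionation defaults are
  3.4 ± 0.98‰ (\(\delta^{15}N\)) and 0.39 ± 1.3‰ (\(\delta^{13}C\)) per
  trophic step and live in the source table, overridable per source.
  Posteriors are compared by the fraction of index-paired draws in which
  one group's contribution exceeds the other's.
* **Diet indices.** \(\%IRI\) pools counts and weights across the stomachs
  of a group (the standard convention) and computes frequency over
  non-empty stomachs by default (configurable). Schoener's
  \(PSI = 1 - 0.5\sum_i |p_i - q_i|\). Foraging **efficacy** is
  \(T_{prey}/(S_V + S_H)\): the unique simple combination of the three
  reported quantities that lies in [0, 1] and increases when fewer strikes
  are needed per prey item; values above 1 are clamped with a warning, and
  strike-less trials are excluded from efficacy but retained with a failed
  success flag. Strike rate is \(S_V\)/duration.

# The synthetic-data generator

`scenario_config()` fixes the study conditions the package is tested
against: 24 populations (8 Japan Sea + 10 Pacific anadromous in two clades,
plus 6 freshwater populations each attached as a *recent sister of a
Pacific anadromous population* — freshwater colonisation in this system is
repeated, not a single event, and those independent transitions are what
give a third-optimum model its statistical leverage), 10 unlinked
microsatellite loci, ~10 diploids per population, and trait truth OU3 with
optima 24.5 / 21.75 / 18.0, \(\alpha T = 8\) and \(\sigma^2 = 16\).
Stationary SD is 1 trait unit and the pull is strong enough that simulated
population means sit tightly around their optima, reproducing the clear
three-group clustering of the observed trait tables; with a weaker pull
(e.g. \(\alpha T = 3\)) simulated freshwater tips land around 20.8 rather
than 18 and the groups smear together, which does not resemble the data the
scenario is meant to emulate.

Genotypes are simulated **forward**: a Wright-Fisher pool of \(2N_e\)
allele copies per locus burns in for \(8N_e\) generations (reaching
mutation-drift equilibrium, where the within-population allele-size
variance is \(2N_e\mu\) and the population mean drifts with variance
\(\mu\) per generation — the regime in which \(E[\delta\mu^2] = 2\mu t\)),
then splits and evolves down the population tree with symmetric ±1
mutation at rate \(\mu\). Defaults \(N_e = 500\), \(\mu = 5\times10^{-4}\)
and split times 1000 / 300 / 200 generations were chosen to reproduce
realistic genetic-distance magnitudes (between-clade Nei's D ~0.5–0.9,
within-clade ~0.15): the times are drift-scaled stand-ins, not literal
generation counts for million-year divergences, which a forward simulator
cannot reach. Consumer isotopes, stomach contents (multinomial per-form
profiles) and foraging trials (Poisson strikes, binomial consumption) are
drawn from explicitly declared truths, so every downstream estimator can be
checked for recovery.

What the generator does **not** emulate: selection, migration or linkage in
the genetic simulator; site-level structure in the isotope data (one
mixture per form, not per form × site); covariance between diet and
isotope noise. Passing tests therefore demonstrate correctness of the
estimators under the declared model, not robustness to those violations.

# Problem sizes and determinism

Every stochastic function takes an explicit seed, derives per-replicate
child seeds (`seed + r`), and restores the caller's RNG state. The test
suite runs the statistical checks at the study's design sizes where that is
affordable (1000 bootstrap replicates for calibration; 100 datasets for
optimum recovery — on a balanced 12 + 12 two-clade tree with clades at half
the root depth, the standard recovery-experiment design, because optimum
estimates are heavy-tailed when \(\hat\alpha\) wanders onto its small-α
ridge — and for CI coverage; 200 loci for the mutation-model check;
20 seeded end-to-end runs at 200 bootstrap replicates) and at reduced sizes
for unit-level properties; each test states its size. The pipeline default
of 1000 bootstrap replicates per comparison matches the reference analysis
and is reduced via `n_reps` for desk-scale runs, with the count recorded in
every result.

# Known limitations

* OU fits share \(\alpha\) and \(\sigma^2\) across regimes (the Hansen
  convention); regime-specific \(\alpha\) or \(\sigma^2\) are out of scope.
* \(\alpha\) is weakly identified upward once regime means absorb the
  structure; interpret large-\(\alpha\) fits as "independent tips around
  group means".
* Multivariate traits, measurement error and non-ultrametric OU weight
  matrices are not supported.
* Ellipse overlap is only available from the point-estimate ellipses, not
  as a Bayesian posterior.
* The mixing model is not concentration-dependent.
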