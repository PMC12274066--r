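---
title: "Models and methods behind phylodrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phylodrift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylodrift)
```

## The scientific question

The mutational hazard hypothesis (MHH) predicts that lineages with small
effective population size (Ne) — where selection is too weak to purge
slightly deleterious insertions — accumulate non-coding DNA, notably
transposable elements (TEs), and therefore evolve larger genomes. Testing
this across many species requires four measurements per species and a way
to compare them that respects shared ancestry:

1. **Genome size**, estimated from C-values where measured and otherwise
   predicted from assembly size;
2. **dN/dS on the terminal branch**, a proxy for long-term Ne (values
   nearer 1 mean weaker purifying selection, hence smaller Ne);
3. **Overall and recent TE content**, from read-level repeat annotations;
4. **Phylogenetically controlled association tests** between these traits.

`phylodrift` implements this chain end to end, together with a generator
that simulates all inputs under a known world, so every stage can be
validated against the truth that generated its data.

## Genome size: the C-value regression

Assembly size underestimates genome size, increasingly so for large
genomes, because repeats collapse during assembly. Where a cytometric
C-value exists it is trusted (1 pg = 0.978e9 bp); otherwise the expected
C-value is predicted from assembly size by weighted least squares fitted
on the species with both measurements.

Two modelling choices are ours, because the procedure leaves them open:

- **Weights.** We use `1/assembly_size^2`, i.e. a multiplicative error
  model, because C-value scatter grows roughly proportionally with size.
  Equal weights (plain OLS) are available via `weights = "equal"` and the
  scheme used is recorded in the fitted model.
- **Floor.** Predictions are floored at the assembly size itself: an
  assembly cannot be longer than the genome it samples.

Records are deduplicated per species before fitting: the most recent
measurement wins, same-date ties are averaged.

## dN/dS: YN98(F3X4), substitution mapping, aggregation

Per-gene codon alignments are analysed under the YN98 codon model with
F3X4 frequencies: states are the 61 sense codons of the universal code,
and the rate from codon *i* to *j* is nonzero only for single-nucleotide
changes,

\[ q_{ij} = \pi_j \,\kappa^{[\mathrm{transition}]}\,
   \omega^{[\mathrm{nonsynonymous}]}, \]

with \(\pi\) built from position-specific nucleotide frequencies and the
matrix rescaled to mean rate 1 (branch lengths in substitutions per codon
site). The likelihood is computed by Felsenstein pruning with site-pattern
compression; gapped codons are missing data. `fit_yn98()` maximizes over
\(\kappa\) and \(\omega\) (log-parameterized, bounded
\(\kappa \in [0.05, 100]\), \(\omega \in [10^{-4}, 10]\)) and then jointly
refines all branch lengths, so each gene carries its own terminal branch
lengths — the topology is fixed by the species tree, the per-gene lengths
are re-estimated under the codon model.

**Expected substitution counts.** For each branch and each label
(synonymous/nonsynonymous), `map_substitutions()` computes the posterior
expected number of labeled substitutions given the alignment: the joint
posterior of the branch's endpoint states is combined with the expected
labeled jump count of an endpoint-conditioned Markov path, the latter
obtained in closed form from the spectral decomposition of the reversible
rate matrix (the integral \(\int_0^t e^{Qs} B e^{Q(t-s)} ds\) with *B* the
labeled part of *Q*). Eigenvalue gaps below 1e-9 fall back to the
symmetric limit form of the integral factor. The mapped counts are
validated in the test suite against endpoint-conditioned Monte-Carlo path
sampling.

**Neutral normalization.** Mapped counts \(K\) are normalized by the
expectation \(O\) of the same label under the matched neutral model
(\(\omega = 1\), same \(\kappa\) and frequencies, rescaled to mean rate 1)
over `l * n_sites` opportunities, where `n_sites` is the number of
unambiguous codons the species contributes. The per-species aggregate over
the *n* retained genes is computed exactly as

\[ dN = \frac{\sum_i K_N(i)}{\sum_i O_N(i)/l(i)}, \qquad
   dS = \frac{\sum_i K_S(i)}{\sum_i O_S(i)/l(i)}, \qquad
   dN/dS = dN / dS . \]

The `O(i)/l(i)` denominator has unusual dimensionality (it divides a count
by a branch length), but it is the definition this analysis chain uses, so
it is implemented verbatim; because the extra `1/l` factors affect dN and
dS identically, they cancel in the ratio, and under a neutral world the
aggregate dN/dS centres on 1 (verified by simulation in the acceptance
tests). A `counts_only` denominator (plain \(\sum O\)) is exposed for
sensitivity analysis; neither is claimed "more correct".

**Filters**, applied before aggregation, all at their conventional values
(see `pipeline_config()`): sequences with more than 10% insertion-derived
columns are dropped per gene ("insertion-derived" = the focal sequence has
a residue where the majority of other sequences are gapped, counted over
the focal residues); genes with a terminal branch shorter than 0.001 for a
species are excluded from that species; an externally produced gene
blacklist (e.g. topology outliers) is honoured; and the trimmed analysis
removes terminal branches outside [0.01, 1] amino-acid substitutions per
site. Threshold boundaries follow the wording that defines them: "more
than", "shorter than" and "above" are strict, so boundary cases are kept.

**GC3 gene sets.** For composition-stratified runs, genes covering at
least 95% of a clade's species are ranked by GC content at third codon
positions (per-species fraction of G/C among ungapped third positions,
averaged); the 50 poorest and 50 richest form two sets, ties broken
lexicographically by gene id so the selection is order-independent.

## TE content

Read-level repeat annotations (read id, annotated bp, repeat class,
divergence from family consensus) are summarized as
`te_fraction = sum(annotated_bp) / sum(read_bp)`, scaled by the genome
size estimated above — not the assembly size, which would re-import the
very underestimation the C-value stage corrects. Recent TE content
restricts to annotations strictly below 5% divergence. Partially annotated
reads contribute only their annotated base pairs. Species whose
BUSCO-duplicated score exceeds 30% are flagged as likely whole/partial
genome duplications, and comparative analyses run with and without them.

## Comparative stage

`compute_contrasts()` implements the Felsenstein pruning recursion
(standardized differences at each internal node, ancestral values as
branch-length-weighted averages, variances extended by
\(v_1 v_2/(v_1+v_2)\)). Because contrast signs are arbitrary, regression
is through the origin; p-values use *n* − 1 degrees of freedom. The
central correctness property — checked over random trees at 1e-8 relative
tolerance — is that the through-origin contrast slope equals the
generalized-least-squares slope under the Brownian tip covariance, with
`ape::pic` as an additional independent cross-check.

`fit_brownian_multivariate()` is the likelihood-based simplification of a
Bayesian coevolution model: traits diffuse as a multivariate Brownian
motion with per-unit-length covariance *R*; the REML estimate is

\[ \hat\mu = (1^\top C^{-1} 1)^{-1} 1^\top C^{-1} Y, \qquad
   \hat R = (Y - 1\hat\mu^\top)^\top C^{-1} (Y - 1\hat\mu^\top)/(n-1), \]

which equals the average outer product of standardized contrasts (also
verified in tests). In place of posterior probabilities,
`bootstrap_support()` re-simulates each trait pair under the fitted model
with that pair's covariance zeroed and reports the fraction of null
correlations below the observed one; supports above 0.9 / below 0.1 are
flagged, mirroring the reading convention of Bayesian coevolution output.
This replaces MCMC with a seeded parametric bootstrap — an acknowledged
simplification: it estimates no ancestral states and its support values
are frequentist tail fractions, not posteriors.

Missing trait values are handled by pairwise deletion (each trait pair is
pruned to its complete cases), matching the per-row sample sizes of
multi-trait comparative tables. Polytomies are resolved arbitrarily with
zero-length branches, with a warning. Natural log is the default
transform; log-log slopes are base-invariant, which is what makes them
comparable across analyses.

## The synthetic world

`simulation_scenario()` fixes the data-generating conditions:

- a pure-birth tree rescaled to mean root-to-tip depth 1 (a stand-in for
  an empirical phylogeny; any newick tree can be substituted);
- three traits diffusing as correlated Brownian motions: latent log-Ne,
  a logit TE fraction, and log genome size. The default covariance
  (correlations −0.7 between log-Ne and TE, −0.5 between log-Ne and
  genome size, +0.6 between TE and genome size, rate 0.25 per unit depth)
  encodes an MHH-true world; setting `omega_link = NULL` severs the
  dN/dS channel and gives an MHH-false world with constant
  \(\omega\);
- per-branch \(\omega = \exp(a + b\,\mathrm{logNe})\) clipped to
  [0.01, 2], evaluated at the child node of each branch, with default
  \(a = \log 0.2\), \(b = -0.5\) — small-Ne lineages evolve at higher
  \(\omega\);
- codon alignments simulated by drawing root codons from \(\pi\) and
  propagating with branch-specific transition kernels;
- repeat landscapes: family ages map to expected divergence
  \(\min(1-e^{-\mathrm{age}}, 0.4)\) (a Jukes-Cantor-style saturation),
  per-copy divergences are binomial around that expectation and inherited
  by reads; reads sample TE and non-TE space uniformly at coverage 0.25,
  the standard low-coverage setting for read-based repeat quantification;
- C-value records with 5% lognormal measurement noise and an assembly
  underestimation fraction growing logarithmically with genome size.

Scale: the default world uses genome sizes in the tens of megabases
(root 2e7 bp) rather than gigabases. This preserves every statistical
property the pipeline is sensitive to — TE fractions, coverage, relative
noise — while keeping read tables at a size appropriate for simulation
studies with hundreds of replicates; the TE estimator is a ratio of
sampled base pairs, so its bias and variance behaviour does not depend on
the absolute genome size, only on read counts.

What the generator does **not** emulate: indels and alignment error,
annotation noise on reads (divergence is generated per copy and inherited
exactly), contamination, per-species mutation-rate or generation-time
heterogeneity in what counts as a "recent" TE (a per-species divergence
rate multiplier would be the natural extension; the default treats rates
as homogeneous), and assembly artefacts beyond smooth size-dependent
underestimation. Passing tests therefore demonstrate internal correctness
and statistical calibration of the estimators under the model's own
assumptions — not robustness to real-data pathologies.

## Numerical choices

- Transition probabilities and mapping integrals use the symmetrized
  spectral decomposition of the reversible rate matrix (`D Q D^{-1}` with
  `D = diag(sqrt(pi))`); probabilities are clipped at 0 and renormalized
  to guard rounding.
- Codon frequencies of exactly zero (possible when F3X4 is built from
  observed counts on short alignments) are floored at 1e-12 and
  renormalized before building the rate matrix, keeping the spectral
  factorization well-posed at negligible mass.
- Pruning rescales partial likelihoods per node when column maxima fall
  below 1e-150 (1e-120 in the mapping pass), tracking log offsets.
- The optimizer converges at a relative function tolerance of about
  1e-9 (`factr = 1e7`); stage one fits kappa/omega from three fixed
  starts, stage two refines branch lengths jointly from the best point.
- Ties in GC3 ranking break lexicographically; contrasts at nodes whose
  two daughters both have zero variance raise an error rather than
  dividing by zero.

## Problem sizes used in the validation suites

The shipped tests and the acceptance script run, per quantity: 100
random trees of 5-50 tips for the contrast/GLS equivalence; 1e5 (tests)
or 2e4 x 3 settings (script) Monte-Carlo paths for the mapping oracle; 20
(tests) or 10 (script) replicates of 6-taxon, 300-codon fits per omega
value — on a fixed balanced tree with 0.2-substitution terminal branches,
inside the pipeline's own trimming window, so that every terminal carries
enough synonymous signal for the per-species rate ratio to be
well-defined (on trees with much shorter terminals and few genes, the
mapped synonymous count can approach zero and the ratio degenerates —
the very instability the short-branch and trimming filters exist to
control); 1000 (tests) or 500 (script) null replicates on a 50-tip tree for
the type-I rate; 100/50 replicates at 200 tips for correlation recovery;
200/100 replicates for the TE estimator; and 300 species for the
genome-size comparison. These sizes give the Monte-Carlo bands quoted in
the tests while keeping a full run in the minutes range; all are fixed by
seed and scale linearly if larger runs are wanted.

## Known limitations

- The YN98 implementation is site-homogeneous: no among-site rate
  variation, branch-site models, or GC-biased gene conversion correction.
- The coevolution fit estimates trait covariances only — no ancestral
  node reconstruction, no divergence-time recalibration.
- The TE stage consumes annotations; it does not discover repeats,
  build consensus sequences, or classify families.
- Blacklist-based outlier removal expects an externally produced list;
  topology-outlier detection itself is out of scope.
- The per-species dN/dS denominator follows the printed definition of the
  aggregation; users wanting the dimensionally plainer variant should set
  `denominator = "counts_only"` and compare.
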