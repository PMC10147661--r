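---
title: "Models and methods behind grnmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind grnmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(grnmap)
```

`grnmap` studies the genotype-phenotype map of three-node synthetic gene
regulatory circuits built from CRISPR-interference parts. This vignette is
the package's own account of the models it implements, the choices that were
genuinely open, and what its tests do and do not establish.

## The genotype space

A circuit couples three reporter nodes — A (orange, mKO2, arabinose-induced),
B (blue, mKate2) and C (green, sfGFP), the latter two driven by constitutive
promoters — through directed CRISPRi repressions. A genotype is an 8-slot
vector: six edge slots in the fixed order A→B, A→C, B→A, B→C, C→A, C→B, each
holding one of six sgRNAs (or absent), plus promoter levels for B and C
drawn from {P_H = 1, P_M = 0.86, P_L = 0.75, knockout = 0}. Only circuits
with 3-6 repressions are in the space; with 6 sgRNAs and 4 promoter levels a
topology with $E$ edges is realised by $p^2 s^E$ genotypes, 3,456 at $E=3$
up to 746,496 at $E=6$, and the whole space holds 1,873,152 genotypes over
42 topologies. One mutation is one slot change (1-Hamming distance); the
neighborhood is closed under the 3-edge floor, so 3-edge genotypes have 39
neighbors and all others 42.

Two conventions were open and are fixed here once: the slot-to-interaction
order above (used everywhere, including perturbation-slot indices in
`robustness_per_perturbation()`), and the treatment of the promoter knockout
as a parameter value rather than a topology change — the topology is defined
solely by the edge mask.

## The mechanistic model

Each present edge contributes three species — free sgRNA, the dCas:sgRNA
complex, and the promoter-bound ternary complex on its target — and each
node carries mRNA, immature protein (PI) and mature reporter (P): $3E + 9$
states. Free dCas and free promoter DNA are eliminated algebraically from
their conservation totals (dCas total keyed by $E$; promoter DNA 30 nM per
node, medium-copy plasmid at 1 nM per copy). Transcription from node A
follows a Hill function of arabinose with leak; constitutive transcription
scales linearly with the source promoter's efficiency and with *free*
promoter DNA. Reporter maturation feeds P from PI; mature and immature
protein share a degradation-tag rate and are both diluted by growth. The
dilution rate is $m(t) = G'(t)/G(t)$ with $G$ a superposition of three
generalized logistic functions (microplate mode), or a constant
$10^{-3}\,\mathrm{min}^{-1}$ (microfluidic mode, where promoter binding is
additionally treated as irreversible). Units are nM, minutes, and % w/v
arabinose; integration is lsoda with rtol $10^{-6}$ / atol $10^{-9}$, from a
6 h arabinose-free preculture under an LB-like single-logistic growth model.

Three structural choices deserve a note, each with a config switch to the
literal textbook form:

* The immature-protein balance removes maturation flux proportional to PI
  (mass-balanced, default) rather than to P; the literal alternative breaks
  mass balance (`literal_pi = TRUE` restores it).
* The Hill drive of node A uses *free* promoter DNA, so repressions into A
  are effective; with total DNA they would be inert, contradicting the
  behavior of circuits that repress the input node
  (`literal_hill_dna = TRUE` restores the total-DNA form).
* The leak of arabinose-controlled transcription is the same dimensionless
  fraction `b` that discounts the inducible term, and the additive leak is
  `b * k2 * [DNA]` from free promoter — leak transcription still requires an
  unoccupied promoter.

Node A's translation rate carries a phenomenological arabinose dependence
(base fraction 0.2, Hill exponent 2, midpoint 0.01%), standing in for
population heterogeneity in arabinose uptake.

## The default parameter set is synthetic

The fitted parameter vector that a wet-lab calibration would supply is not
part of this package; `default_parameters()` is a synthetic stand-in on
literature scales: minutes-scale RNA turnover, nM dissociation constants
with 4-nt-truncated (t4) sgRNAs several-fold weaker than their parents
(0.8-6 nM), slow maturation for mKO2/mKate2 and fast for sfGFP, and
fluorescence scaling factors per reporter. The set was calibrated once
against qualitative anchors — the incoherent feed-forward loop with a weak
A→C guide forms a GREEN stripe at 900 min; adding the C→B repression flips
it to a BLUE stripe; a symmetric strong repression ring oscillates under
constant dilution — and then frozen. Transcription scale (k2 = 0.25 per
promoter copy), Hill induction (n = 1.5, K_m = 0.01%) and dCas totals
(150-300 nM, increasing with $E$) were the levers: they set where along the
nine-dose gradient the strong and weak guides engage their targets, which is
what makes low-high-low profiles possible at all.

Consequences are quantitative and documented honestly: under these defaults
a uniform sample of the space is roughly 50% non-functional, 25% BLUE and
25% GREEN, and random mutational walks from functional genotypes change
phenotype after a median of ~5-8 steps. A calibration fitted to real
microplate data yields a sparser functional fraction (~80/10/10) and
shorter functional walks; those numbers are properties of the fitted
parameter vector, not of the machinery, and the machinery is what the test
suite verifies — against closed forms, conservation laws and brute-force
oracles that hold for any parameter set.

## Phenotype classification

**Stripes.** Reporter readouts at 900 min across nine doses (0 plus eight
log-spaced from $10^{-5}$ to 0.2%) are normalized per reporter by their own
maximum. A candidate node (only B or C; A is the input readout) passes if
the means of the two lowest-dose and two highest-dose normalized values both
sit at least δ = 0.06 below the peak. If both nodes pass — the text behind
the rule is silent here — the larger total flank deficit wins and an exact
tie is non-functional; `classify_stripe(details = TRUE)` exposes the
deficits and a `both_passed` flag. Peaks at the edge of the grid are
allowed: the flank means then include the peak's own neighborhood, which is
the literal reading of the rule.

**Oscillations.** Dynamic phenotypes are read from 2880 min trajectories
sampled every 10 min (mirroring two-day imaging at 10 min intervals) at an
effective arabinose of $10^{-5}$%, with `kr_dsd = 0` and constant dilution.
After discarding the first 25% of samples as transient, the normalized
autocorrelation of each reporter is scanned for a strict local maximum at
positive lag with height ≥ 0.01. Height, not prominence, is thresholded;
a constant series is never oscillatory.

## Genotype-network statistics

All statistics run against a `phenotype_map` — a lazily evaluated, cached,
provenance-hashed labeling — so no genotype is classified twice and caches
from different parameter sets can never be mixed. Components use igraph on
the induced 1-Hamming subgraph; evolvability counts distinct neighbor
labels; robustness is the same-label neighbor fraction; transition
frequencies summarise per-genotype neighbor-label fractions by median and
IQR; the topology summary computes evolvability/robustness both over full
neighborhoods and restricted to fixed-topology neighbors (same edge mask)
and clusters topologies by k-means (k = 5, best of 10 restarts) on that
plane. Random walks pick uniform neighbors until the phenotype changes,
censored at 50 steps (functional) or 300 (non-functional); censored walks
enter the median at the cap and the censoring rate is reported, since the
convention was open. Epistasis enumerates unordered pairs of single changes
at distinct slots with both intermediates and the double mutant in the
space; a pair is epistatic when the double mutant keeps the phenotype but
exactly one intermediate loses it, and the per-genotype denominator is all
evaluated pairs (the normalization was open; the pooled rate is also
reported).

Every one of these statistics is tested to equality against an independent
brute-force implementation (string-surgery neighborhoods, union-find
components, exhaustive pair enumeration) on rule-labeled toy maps of up to
a few hundred genotypes, and the random-walk engine against an exact
Markov absorption computation on a labeling rule whose change probability
depends only on the edge count.

## Calibration

The measurement model maps mean signal to standard deviation piecewise per
reporter (sfGFP constant 10,350 below 7e4, then 0.13x + 1250, then 33,750 —
the pieces meet exactly at both breakpoints; the mKO2 lower breakpoint is
taken at 6e3 where the linear branch equals the 899 floor, resolving an
inconsistency in the printed bounds; mKate2 43 below 500, then 0.03x + 23).
The estimation objective is the weighted sum of squared standardized
residuals over all records, with simulated values passed through the
fluorescence scaling factors; simulation failures contribute a large finite
penalty so population optimizers stay stable. Global estimation is
Latin-hypercube multi-start in log-parameter space with local `nlminb`
polish — a deliberate stand-in for heavier scatter-search machinery behind
the same interface — with literature-plausible log-uniform bounds shipped as
config. Goodness of fit is the chi-square test on objective versus
degrees of freedom.

The synthetic generator mirrors the calibration design: six two-node
circuits (one per sgRNA) across nine doses and 100 time points per
reporter, plus four three-node circuits spanning 3-6 repressions, with
zero-truncated Gaussian noise at the measurement-model standard deviation.
Truncation is the simplest model consistent with a mean-to-s.d.
relationship and non-negative fluorescence, and it has a visible
consequence: at the generating truth the reduced chi-square statistic is
~0.85 rather than 1, because records whose mean lies within about two
standard deviations of zero lose variance to the truncation. Replicate
structure is configurable; the default is a single series per condition.

## Problem sizes

The test suite and the acceptance script run at desk scale, as the
package's own choice of problem size: phenotype fractions from 250-400
uniformly sampled genotypes (binomial standard error ~2.5 points), 10-15
functional random walks, six-parameter noiseless recovery on a reduced
design (6 circuits × 6 doses × 8 time points), and toy maps of 30-120
genotypes for the graph oracles. Full-map quantities — exhaustive
enumeration of all 1.87 M genotypes, non-functional walks at a 300-step
cap, epistasis medians over thousands of genotypes — use exactly the same
code paths and scale linearly in the sample sizes; the compiled ODE core
evaluates a nine-dose dose response in well under 0.1 s, so a full map is a
cluster afternoon, not a different implementation.

## Known limitations

* No stochastic (SSA) simulation and no cell-to-cell variability beyond the
  phenomenological arabinose-translation modifier.
* Truncated sgRNAs share no parameters with their full-length parents; if a
  real calibration ties them, the shared structure must be imposed through
  the bounds/free-parameter lists.
* The stripe classifier imposes no condition on the non-peaking reporters;
  the flank rule alone decides.
* Quantitative stripe descriptors (position, width, asymmetry) and
  oscillation period/amplitude estimation are out of scope.
* Phenotypic (as opposed to genotypic) robustness and evolvability are not
  computed.
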