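---
title: "Methods: isolation-migration inference from coalescence-rate curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isolation-migration inference from coalescence-rate curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`imcoal` analyses the demographic history of a pair of populations through
the lens of two sampled lineages. Under a two-population
isolation-migration (IM) demography with piecewise-constant parameters —
diploid sizes $N_1(t)$, $N_2(t)$ and a symmetric per-lineage migration
probability $m(t)$ per generation — the locations of two ancestral
lineages follow a four-state continuous-time Markov chain with states
*both-in-1*, *both-in-2*, *split* (one lineage in each population) and
the absorbing state *coalesced*. Within an epoch the transition rates are

* coalescence at $1/(2N_i)$ for a pair currently in population $i$
  (standard diploid scaling — this fixes the dictionary between sizes and
  coalescence rates used everywhere in the package);
* separation of a same-population pair at $2m$ (either lineage migrates);
* reunion of a split pair into either population at $m$ each.

Chaining per-epoch matrix exponentials of this generator gives exact
survival curves for the three informative starting configurations, and
hence the model-implied coalescence-rate curves
$\lambda_{11}, \lambda_{12}, \lambda_{22}$ on a time grid:
$\lambda = -\Delta \log S / \Delta t$ per grid interval. These are the
quantities that sequentially Markovian coalescent methods estimate from
whole-genome haplotype data; `imcoal` consumes either such output
(`read_msmc2_final()`) or its own simulated curves.

The cumulative migration probability is defined as
$$M(t) = 1 - \exp\left(-2 \int_0^t m(u)\, du\right),$$
the probability that at least one lineage of a cross-population pair has
switched demes by time $t$. Two conventions deserve note. First, the
factor 2 (each of the two lineages migrates independently at rate $m$) is
a documented choice; the threshold semantics built on $M$ — the median
split time where $M$ crosses 0.5 scanning into the past, and initial
divergence where it crosses 0.99 and 0.999 — do not depend on it beyond a
rescaling of $m$. Second, the integral is accumulated from the first grid
boundary (10 generations by default); the omitted head contributes at
most $2 m \times 10$ and is far below the resolution of any downstream
statistic.

Times are calibrated with a mutation rate of $7.1 \times 10^{-9}$ per bp
per generation and a 2-year generation time (`scaling_config()`), the
calibration appropriate for a self-compatible perennial herb; both are
configurable.

## The simulator is the oracle

`sample_tmrca()` simulates the same lineage chain exactly (competing-risk
exponential waiting times, epoch-boundary aware), so the matrix-exponential
forward model and the Monte-Carlo sampler are two independent computations
of one distribution. Their agreement — Kolmogorov–Smirnov distance below
0.01 at $10^5$ draws across randomized histories — is the central
cross-check of the package and is enforced in the test suite.

Simulated pairwise coalescence times are converted to empirical rate
curves by an occurrence/exposure estimator (`empirical_hazard()`): events
divided by lineage-time at risk per interval, with censored draws
contributing exposure only. Bins with zero exposure are undefined (`NA`),
never silently zero. Draws carry an exchangeable block label so that the
genomic block bootstrap (30 blocks resampled with replacement, 100
replicates) can be mimicked at the TMRCA level. This deliberately replaces
sequence-level simulation: blocks are exchangeable pools of genealogies
rather than literal 1-Mb windows, there is no recombination model within
blocks, and no sequence evolution. What passing tests show is therefore
that the *inference and statistics layers* are correct given
coalescence-time data; they do not exercise haplotype-level artefacts
(phasing error, linked selection) that affect real data upstream of this
package's scope.

## Fitting

`fit_im()` estimates $(N_1, N_2, m)$ per grid interval. The data term
depends on what the input carries:

* **Count-bearing curves** (simulated rates): the Poisson deviance of
  observed versus model-expected coalescence events per interval, using
  the recorded exposures as offsets. This is the statistically calibrated
  choice for occurrence/exposure data — a zero-event bin is exactly as
  informative as its exposure warrants, which matters both for detecting
  true migration shutdowns (many expected events, none observed) and for
  *not* over-interpreting empty young bins.
* **Hazard-only curves** (e.g. MSMC2 tables): squared log-hazard
  residuals $(\log(\hat\lambda + \varepsilon) - \log(\lambda_{obs} +
  \varepsilon))^2$ with $\varepsilon = 10^{-12}$, scale-invariant across
  the five orders of magnitude such curves span.

To these are added the regularization terms: a ridge on migration
($\beta_m \sum m_k^2$, default $10^{-8}$) and a smoothness term on sizes
($\beta_N \sum ((N_k - N_{k-1})/N_{k-1})^2$, default $10^{-6}$). Both
weights are defined against unit-scale residuals; in deviance mode they
are multiplied by the mean events per interval so that their strength
relative to the data is preserved across problem sizes. Count-mode fits
additionally carry two constant-scale smoothness penalties, on
$\log_{10} m$ and on $\log N$ (defaults 0.5 and 6 deviance units per
squared decade/log-unit). These are deliberately *not* scaled with data
size: chance fluctuations of a deviance are size-invariant
($\chi^2$-scale), while genuine demographic signals grow linearly with
the number of draws, so constant penalties suppress the former at any
sample size without ever competing with the latter.

The optimizer sweeps intervals forward in time, solving each interval's
three parameters by bounded quasi-Newton steps given the exactly
propagated lineage-state distribution, then applies two parsimony passes
before repeating (a sweep cycle is accepted only while the global
objective decreases, so the recorded objective trace is non-increasing):

* **Migration parsimony (old to young)**: an interval keeps a migration
  rate different from its older neighbour's only if that is demanded by
  the data (six deviance units, a strong-evidence threshold robust to
  testing across ~60 intervals). Without this, intervals that carry no
  information about $m$ — once cross-population lineages are fully mixed,
  or in data-poor bins — drift to the regularization floor and produce
  artefactual "isolation events".
* **Size parsimony (young to old)**: an interval keeps sizes different
  from its younger neighbour's only if the data reject them *after
  re-fitting the interval's migration rate* under the candidate sizes.
  The re-fit is essential: deep in time the three curves converge to a
  single quasi-stationary decay rate, so only one combination of
  $(N_1, N_2, m)$ is identified and the remaining two directions form a
  ridge along which unconstrained estimates random-walk (characteristically
  one size collapsing while the other inflates). Testing candidates with
  migration profiled out recognizes ridge-equivalent parameterizations
  and pins them to the last identified values.

Migration is optimized on a $\log_{10}$ scale with a numerical floor of
$10^{-12}$ standing in for $m = 0$ — five orders of magnitude below the
$10^{-7}$ isolation-event threshold, so floored rates are unambiguously
"off". Sizes are bounded in $[10, 10^7]$; epochs older than the oldest
grid boundary are pinned to the ancestral size (default 15,000, a value
chosen for its sensitivity to demographic events beyond the LGM;
alternatives can be swept via `fit_config()`). Intervals where an
optimized size sits at a bound are recorded as *failures*; two or more
failure events with sizes oscillating between opposite bounds mark a run
as discarded. `qc_run()` then applies the acceptance policy: failures
disqualify initial-divergence estimates; failures within the Holocene
(11,700 years, the standard chronological boundary) disqualify split
times; current sizes are always accepted because the most recent
coalescence rates are unaffected by older epochs (Markov property).

## Time grid

The default grid has 64 logarithmically spaced boundaries from 10 to
$2 \times 10^6$ generations. A coarser 40-boundary grid was considered
(and is available via `time_grid(40)`), but at that spacing (a factor of
1.37 per interval) a 60-ka glacial window such as the PGP need not
contain any complete grid interval, making a within-window migration
shutdown undetectable *in principle* — the interval-averaged true rate
stays above the event threshold. At 64 boundaries (factor 1.21) the named
glacial windows contain at least one full interval. Replicate summaries
(`envelope()`, `isolation_frequency_histogram()`) use a finer common
80-point grid.

## Derived statistics

Split and initial-divergence times interpolate $M$ linearly against
log-time between bracketing boundaries (matching the logarithmic grid);
isolation events are maximal runs of intervals with $m < 10^{-7}$,
summarized by their midpoints. Pattern classification looks at the window
from the onset of the LGM (22 ka) to the young edge of MIS 10 (337 ka) —
the span over which a core population is stable "between MIS 10 and the
LGM": a trajectory is CORE if its size floor stays at or above 20,000
*and* no isolation event falls in the window; it is PERIPHERAL if the
window contains an isolation event or a bottleneck, defined as a drop of
at least 90% relative to the running pre-decline maximum of `im_N1` over
older *in-window* intervals (estimates beyond the window, where
resolution is poorest, do not define the reference level). The STRONG
sub-label is attributed by overlap of the event span or bottleneck
interval with the PGP (190–130 ka) or MIS 8 (300–243 ka) windows —
overlap rather than midpoint, because a step change smeared across a grid
boundary can push a midpoint a few ka outside the stage that caused it.
MIS 8 and MIS 10 default bounds follow the standard marine-isotope
chronology and are configurable; 90% is a permissive floor for "strong"
bottlenecks, whose reported depths in leading-edge populations reach
96–98%.

Envelopes compute per-point empirical percentiles (median, 12.5–87.5%,
2.5–97.5%) across trajectories resampled onto the common grid — migration
in log space with zeros floored at $10^{-12}$, sizes in linear scale —
using the linear-interpolation quantile convention (R's type 7), then
project the series through a monotone piecewise-cubic (PCHIP) interpolant
in log–log space with no extrapolation beyond the data span.

Group comparisons follow a Shapiro–Wilk gate (both groups, $\alpha =
0.05$) choosing between Welch's t-test and the Wilcoxon rank-sum test,
with Benjamini–Hochberg adjustment across the supplied family.

## Scenario presets and what they encode

`scenario()` presets are the package's study conditions:

* `core`: $N_1 = N_2 = 25{,}000$, $m = 2 \times 10^{-5}$ from the present
  back to 450 ka, then a panmictic ancestor — realizing a stable size
  comfortably above the 20,000 core floor through glacial cycles.
* `peripheral_pgp` / `peripheral_mis8`: migration ceases and sizes drop
  by 95% during the PGP or MIS 8 window. Their interglacial migration
  rate is $5 \times 10^{-6}$, lower than the core's: at $2 \times
  10^{-5}$ the lineage pair is fully mixed (quasi-stationary) before
  reaching the PGP and a migration shutdown there is unidentifiable in
  principle, whereas at $5 \times 10^{-6}$ roughly half of
  cross-population pairs still carry population identity into the window.
  This is an identifiability-driven design choice of the generator, made
  a priori from the mixing timescale $1/(2m)$, and matches the
  qualitative description of peripheral populations as weakly connected.
* `lgm_arctic`: an early-Holocene split followed by a transient 98.3%
  decline relative to the preceding (Holocene Thermal Maximum) peak.
* `holocene_split`: migration shut off 5,000 generations (10 ka) ago,
  with closed-form crossing $5{,}000 + \ln 2 / (2m)$ — the split-time
  recovery benchmark.

The panmictic-ancestor migration rate is $2.5 \times 10^{-4}$: high
enough that $M$ saturates promptly beyond the divergence time, low enough
that the exact jump-chain simulation stays cheap (expected migration
jumps per surviving pair scale as $4 m N$).

The genotype generator draws ancestral frequencies uniformly on
$[0.05, 0.95]$, regional frequencies from the Balding–Nichols beta
distribution at each region's $F_{ST}$, and genotypes with a within-region
inbreeding coefficient ($P(\text{het}) = 2pq(1-F)$), mirroring the
statistical structure the genotype-level estimators assume: regional
differentiation plus selfing-driven homozygosity. It stores its truth for
estimator-recovery tests. It does not model linkage, mutation spectra, or
genotyping error beyond the ROH generator's Bernoulli error switch.

## Genotype statistics

ROH detection reimplements the PLINK scanning-window algorithm at the
parameterization used for this species (35-SNP windows, at most 1
heterozygote and 5 missing calls per window, 5% hit threshold, 50 kb and
35 SNP minima, 500 kb gap splitting, 100 kb/SNP density cap), verified
segment-for-segment against a brute-force reference. $F_{ROH}$ divides
total ROH length by the fixed assembly length 219,291,370 bp (centromeres
included). $F_{IS}$ uses the vcftools-style method-of-moments expected
homozygosity $1 - 2pq\,\frac{2n}{2n-1}$ with regional allele frequencies,
reported per sample and as a regional median (at least four samples per
region). Nucleotide diversity is the unbiased frequency-based estimator
$2\hat p\hat q\, n/(n-1)$ per site — invariant to the arrangement of
heterozygotes, hence to selfing, at fixed allele counts. Weighted
$F_{ST}$ is the Weir–Cockerham two-population variance-components
estimator as a ratio of sums across sites, with optional seeded
subsampling to a fixed per-region size (five, matching the regional-pair
design). The Hardy–Weinberg site filter is an exact one-sided test for
heterozygote *excess* (conditional enumeration given allele counts, no
mid-p); a site is removed when $p < 0.01$ in any region, and homozygote
excess never triggers removal — the one-sided construction makes that
automatic.

## Geographic statistics

Regional centroids are coordinate means; distances are haversine on a
6371-km sphere (the formula is unstated in comparable analyses;
great-circle is the natural choice at continental scale).
Isolation-by-distance is a plain Pearson correlation of pairwise distance
against pairwise $F_{ST}$ within the requested cluster scope, with
outlier regions excludable; the p-values are the usual t-transform and do
not account for the non-independence of pairs sharing a region (a Mantel
permutation is left to the user). Climate correlations use a Bonferroni
family fixed at the 19 bioclimatic variables.

## Problem sizes

The validation experiments run at sizes chosen to keep Monte-Carlo error
well below the decision thresholds they feed: $10^5$ draws per
configuration for oracle agreement and split recovery, $2 \times 10^5$
per configuration split over 30 blocks for the bootstrap, and $5 \times
10^5$ for pattern classification, where the binding constraint is the
effective-size floor deep in the window (at $3 \times 10^5$ draws,
occasional fits graze the 20,000 floor; at $5 \times 10^5$ the floor
margin is comfortable).

## Known limitations

* Deep-time estimates live on an identifiability ridge once lineages are
  quasi-stationary; the parsimony passes hold them at the last identified
  values, which is a bias toward step functions (staircase behaviour) and
  means slow deep-time trends are not resolvable.
* Post-bottleneck epochs whose within-population curves carry no
  survivors are informed only through cross-population re-coalescence;
  sizes there are weakly identified, and occasional bound-hitting
  "failures" — which `qc_run()` flags, mirroring the acceptance policy
  for such runs — are expected behaviour, not defects.
* Grid-aligned step histories are an approximation: a true epoch boundary
  interior to a grid interval is smeared across it, which biases
  interval-averaged rates and can shift event edges by up to one
  interval.
* Full-study quantities (multi-hundred-ka divergence dates from hundreds
  of genomes, regional $F_{ST}$ tables, climate correlations on
  continental raster extractions) require data and compute far beyond
  desk scale; the package validates the machinery on synthetic truth
  instead.
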