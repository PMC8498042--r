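---
title: "Models and methods behind rrgskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rrgskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

rrgskit simulates and analyses a reciprocal recurrent genomic selection
(RRGS) programme for hybrid wheat: two heterotic pools (female and male
inbred lines), a genomic prediction model trained on their single-cross
hybrids, two cycles of genomic selection in the female pool (at the F2 and
the F5:6 stage), and an evaluation of the realized selection gain in
multi-environment field trials whose interpretation is complicated by
genotype-by-environment (GxE) interaction. This vignette describes the
models, the simulator's assumptions, the numerical choices, and what the
package's tests do and do not establish.

## Genomic prediction model

The core predictor is ridge-regression BLUP with additive and dominance
marker effects,

$$y = 1_n\mu + Z_A a + Z_D d + e,\qquad
  a \sim N(0, I\sigma^2_a),\; d \sim N(0, I\sigma^2_d),$$

with heterozygote-centred additive coding: a line's additive covariate is
dosage − 1 ∈ {−1, 0, 1} and its dominance covariate the heterozygosity
indicator. This coding makes the dominance column orthogonal to the
additive one at a locus and gives the standard identities used throughout
(a hybrid's additive row is the mean of the parental centred dosages, its
dominance row the indicator of loci at which the parents differ). For
line models the package also provides GBLUP, $y = 1_n\mu + g + e$ with
$g \sim N(0, G\sigma^2_g)$ and $G$ the VanRaden genomic relationship
matrix computed from panel allele frequencies. On purely additive traits
with matching variance components the two formulations give identical
predictions; this equivalence is the cornerstone correctness oracle in
the test suite (agreement to 1e−6).

Variance components are estimated by an EM-type fixed-point REML on the
equivalent kernel model. The update's stationary points solve the REML
score equations; convergence is declared when the relative change of the
restricted log-likelihood falls below 1e−8 (at most 500 iterations, with
non-convergence reported, and estimates floored at 1e−10 times the
phenotypic variance). The single-kernel case is run in a spectral
parameterisation — one eigendecomposition of the projected kernel, then
O(n) iterations — while GBLUP independently maximises the profiled
restricted likelihood over the variance ratio; the two routes cross-check
each other. When a kernel's Cholesky fails, 1e−8 is added to the
diagonal.

**Predicting from heterozygous candidates.** F2 plants are genotyped but
not inbred, so their gametic contribution to a tester hybrid is
stochastic. The package predicts the *expected* hybrid: the additive
entry is the mean of candidate and tester centred dosages, the dominance
entry the probability that the offspring is heterozygous given the
candidate's genotype (0, ½ or 1 against a homozygous tester). The general
combining ability (GCA) of a candidate is its mean predicted hybrid value
over the tester panel, centred by the grand mean; the tester panel is an
explicit argument, so GCA can be computed against the full male pool or
only the production testers.

## Cross-validation

Genomic repeatability is the mean fold-wise correlation between observed
and predicted values over repeated 5-fold partitions (fold sizes differ
by at most one; exact equality is impossible for general n). For hybrids
the chessboard scheme partitions females and males into fold groups
(default 5 × 3, echoing the asymmetric parent panels); each
female-fold × male-fold cell is predicted from training sets that share
both parents (T2), one parent (T1) or no parent (T0) with the test
hybrids. The simulated ability ordering T2 ≥ T1 ≥ T0 is a standing
property test.

## Phenotypic analysis

Across-environment genotype means (BLUEs) come from a mixed model with
fixed genotype and random environment and block-within-environment
effects; "environment" is a location × year combination throughout
(single-year tables use the location). Outlier control follows the
robust M4r recipe: residuals are standardised by their median and MAD,
converted to two-sided normal p-values, and flagged after
Bonferroni–Holm control at α = 0.05.

The variance-component model separates, via role dummies, line genetic
effects from female GCA, male GCA and SCA effects of hybrids, each with
its environment interaction (the SCA × environment term is included,
since it is separable from the residual whenever environments carry at
least two blocks). Checks pool with the lines unless excluded by flag.
The fit is REML through lme4; on balanced designs with interior estimates
this coincides with the Henderson-III ANOVA estimator, which the tests
verify to 1%. Female-GCA × environment BLUPs from this fit feed the GxE
diagnostics. Heritability uses
$h^2 = \sigma^2_G / (\sigma^2_G + (\sigma^2_{G\times E} + \sigma^2_e)/l)$
with $l$ the average number of environments per genotype. The effective
$l$ is exposed explicitly because published heritabilities are not always
reproducible from printed components with $l$ = number of locations; with
the reported 4-location line components the formula gives 0.82 rather
than the printed 0.76, so the package reports $l$ alongside every
heritability.

## Selection theory

The expected response per step is $R = i\,h\,\sigma_A$. The standardized
selection differential $i(\alpha)$ is computed from the closed-form
truncated-normal mean $\varphi(z)/p$ rather than from printed tables;
the finite-population correction
$i(N,G) = i(\alpha) - (G-N)/(2N(G+1)\,i(\alpha))$ is applied on top, and
$i(G,G)$ is defined as 0. Because historical tables round differently,
two-decimal agreement (±0.01) is the declared check for table-derived
values: the package computes i(60, 629) = 1.77 and i(50, 382) = 1.62
against the tabulated 1.78 and 1.63. A Monte-Carlo order-statistics
oracle (mean of the top N of G standard-normal draws) bounds both
quantities in the tests.

The exploitable GCA standard deviation deflates across generations:
selection within an F2 family sees half the GCA variance available among
fully inbred lines of the cross
($\sigma_{GCA,F2} = \sqrt{\sigma^2_{GCA}/2}$), and the descendants of a
single F2 plant release $1/2 + 1/4 + 1/8 = 7/8$ of the F2-stage variance
by the F5:6 generation. Both factors are verified by forward simulation
(50 families; ratio-of-means estimator, which avoids the upward Jensen
bias a mean-of-ratios estimator shows with noisy denominators). The
observed response is the selection differential
$R_{obs} = \mu_{sel} - \mu_{pop}$, with the base-cycle hybrid mean as the
default stand-in for $\mu_{pop}$ (overridable). Under negative
overdominance ($k = d/a < -1$) selection on combining ability fixes the
favorable allele only above the frequency threshold $(k+1)/(2k)$; a
deterministic single-locus recurrence in the tests confirms the
threshold's location.

## GxE diagnostics

Environments are characterised in the space of female-GCA × environment
BLUPs: pairwise Euclidean distances between environment columns,
complete-linkage clustering (exported as Newick trees), and PCA with a
fixed sign convention (the dominant loading of each component is made
positive; interaction effects are centred but not scaled since they share
units, whereas environmental profiles are centred and scaled). The
vegetation condition index rescales an EVI series between area reference
extremes, $VCI = (EVI - EVI_{min})/(EVI_{max} - EVI_{min})$, clamped to
[0, 1] because observed series may exceed the reference period's
extremes. Profile distances are computed after linear interpolation onto
a common date grid. The association between environmental and
interaction structure is tested with a one-sided (upper) Mantel
permutation test; when $n! \le$ the requested permutation count the null
distribution is enumerated exactly (used down to 4 × 4 panels, where the
tests compare against a brute-force enumeration), otherwise permutations
are sampled and $p = (1 + \#\{r_{perm} \ge r\})/(B+1)$.

## The simulator and what it emulates

Founders are fully inbred lines with allele frequencies drawn uniformly
in [0.05, 0.5] on a wheat-like map of 21 chromosomes × 150 cM with
evenly spaced markers (the real map is unpublished; everything is
configurable). Meiosis follows the Haldane no-interference model:
Poisson crossover counts with uniform positions, verified against the
map function $c = (1 - e^{-2\Delta})/2$. Individuals are carried as
phased haplotype pairs so that selfing and single-seed descent preserve
linkage exactly; heterozygosity halves per selfing generation in
expectation (a Monte-Carlo test at 10⁴ replicates).

Trait architectures are sparse: a configurable number of causal markers
with normal additive effects and per-locus degree of dominance
k ~ N(0.5, 0.3²), i.e. directional partial dominance, which produces
midparent heterosis of the magnitude seen in hybrid wheat; effects are
rescaled so the founder female lines show a target genetic variance
(default 17.2 in squared dt/ha, matching the reported line variance).
Phenotypes add environment, block, iid GxE and residual noise. Stress
environments replace the genetic signal by a vector correlated at
ρ = 0.1 with the true genetic values (one shared draw per genotype
across stress environments), reproducing near-zero cross-environment
correlations between stressed and unstressed sites while stressed sites
still correlate with each other. EVI profiles share a smooth seasonal
template with depressed trajectories and faster plant-available-water
decline under stress.

The generator intentionally omits: epistasis, spatial field trend,
incomplete-block (alpha-lattice) structure beyond blocks within
environments, marker ascertainment, and genotyping error. Passing tests
therefore show that the analysis machinery is correct under the stated
model, not that real wheat data satisfy that model.

## The in-silico RRGS experiment

`run_rrgs_experiment()` chains: founder simulation → training on the
female × male factorial (hybrids and parents) → GCA prediction and
selection of 20 C0 females → round robin → F2 families (total size is
split as evenly as possible across the 20 families, since only the total
629 is reported) → genomic selection of 3 F2 plants per family → SSD to
F5:6 with several descendants per selected plant → visual selection,
modelled as truncation on an auxiliary trait correlated at 0.2 with the
genetic value (an explicit stand-in for selection on agronomics) →
genomic selection of the C1S fraction, with a randomly derived C1R
control branch → hybrids with 3 testers → evaluation at 6 locations of
which 2 stressed. Marker-effect variances used for selection default to
the generating architecture's values ("oracle" mode) so that replicated
runs isolate the breeding-scheme behaviour from REML noise; "reml" mode
is available.

The report carries observed responses with and without the stress
environments, a realized expected response assembled from the realized
per-stage accuracies, intensities and GCA standard deviations (three
ranking events: F2 genomic, visual, F5:6 genomic), the realized
prediction ability of the control females, bootstrap group contrasts
(genotype-level resampling, a deliberately assumption-light substitute
for unspecified significance machinery), heterosis by group, and the GxE
diagnostics. The pipeline-level property test shows that over 100
replicate experiments the mean observed response on matched (non-stress)
environments agrees with the mean realized expected response within 15%,
and that admitting the two stress environments into the evaluation
shrinks the observed contrast — the mechanism behind discordant 6- vs
4-environment selection gains.

## Problem sizes used by the tests

Replicated end-to-end runs use a reduced configuration chosen to keep
the full property suite comfortably repeatable on a laptop: 30 + 6
founders on 240 markers (6 chromosomes), 10 C0 females, 120 F2 plants,
4 SSD descendants per selected F2, a visual pool of 60, 20 C1S and 12
C1R lines, 3 testers, 6 environments with 2 stressed. The programme
*structure* (two genomic selections inside a round robin, visual
truncation, tester hybrids, stress regime) is identical to the
full-scale default configuration, which mirrors the reference programme
(120 + 15 founders, 4,031 markers, 629 F2, 382 visual, 50/30, 6
environments) and is used by the analysis scripts at intermediate scale.

## Known limitations

Single cycle only by default (the machinery can be looped); no
multi-trait index selection; no Bulmer-effect accounting beyond the ½
and 7/8 factors; bootstrap contrasts rather than model-based Wald tests;
no AMMI/GGE methodology for the GxE analysis; EVI series are consumed
pre-extracted (no satellite-image processing).
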