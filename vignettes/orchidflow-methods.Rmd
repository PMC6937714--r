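---
title: "Models and methods in orchidflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in orchidflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

orchidflow analyses gene flow in a mapped, microsatellite-genotyped plant
population: diploid codominant genotypes for every adult, planar
coordinates in metres, and progeny arrays (capsules) of seedlings with
known mothers. This vignette explains each model, its assumptions, the
parameters that matter, and the numerical and design choices behind the
implementation. Nothing here reports an empirical claim beyond what the
package's own tests and acceptance script compute.

## Data model and validation

A `genotype_table` stores an unordered pair of positive integer allele
codes (fragment sizes) per sample and locus; `0` marks a missing allele
and a call must be fully typed or fully missing. Pairs are stored sorted
ascending, which removes phase ambiguity from every downstream comparison.
Coordinates are planar metres and all distances Euclidean — appropriate
for study plots spanning hundreds of metres, where geodesy is irrelevant.

`validate_dataset` applies two filters before any mating or paternity
stage: capsules with fewer than `min_offspring` (default 5) seedlings are
excluded from those stages — tiny families carry almost no likelihood
information and destabilize family-level resampling — but their seedlings
still count in cohort diversity summaries; and offspring sharing no
maternal allele at a fully typed locus are flagged as Mendelian
incompatibilities (fatal at a declared error rate of zero, informational
otherwise).

## Diversity statistics

Per locus, over a chosen group: `Na`, `Ne = 1/Σp²`, `I = −Σ p ln p`,
observed heterozygosity, `He = 1 − Σp²` (the uncorrected convention;
Nei's `2n/(2n−1)` correction sits behind `unbiased = TRUE`), and
`Fis = 1 − Ho/He`, reported as 0 and flagged for monomorphic loci.
Frequencies always exclude missing calls from denominators. The algebraic
identities `Ne = 1/(1 − He)` and `I ≥ ln Ne` (equality iff uniform
frequencies) are exercised as property tests.

The Hardy–Weinberg test is an exact conditional test run by Markov chain
(compiled code). The chain state is the arrangement of the `2n` gene
copies into `n` individuals; a proposal swaps one random allele slot
between two random individuals. Because every arrangement is equally
likely under the null of random union of gametes, this symmetric proposal
is always accepted and the stationary distribution is exactly the
conditional null. The two-sided statistic is the conditional probability
of the genotype table (Levene form), with states no more probable than the
observed table counting toward p; heterozygote excess and deficiency use
the heterozygote count. `dememorization`, `batches` and
`iterations` default to 10,000 each; the Monte Carlo SE comes from batch
means. A floating-point tolerance of `1e-9` on the log-probability
comparison keeps ties stable. For small tables (≤3 alleles, n ≤ 20) the
chain is checked against full enumeration in the test suite.

Paternity exclusion probabilities use the power-sum forms in the allele
frequencies: `PrEx1` (neither parent known) and `PrEx2` (mother known).
Published tables label these "first" and "second" parent ambiguously; the
implementation fixes the mapping by the mathematics — the one-parent-known
probability is always the larger — and verifies both against exhaustive
trio enumeration. Loci combine as `1 − Π(1 − Q_l)`, so monomorphic loci
(zero exclusion power) never change the cumulative value.

## AMOVA and standardized differentiation

`amova` partitions variance at the allele level: each individual
contributes two one-hot pseudo-gamete rows per locus, making the total
degrees of freedom `2N − 1` (the convention matching a published total of
309 for 155 diploids). Sums of squares are invariant to the arbitrary
split of a genotype into two rows. `F_st = σ²_among/σ²_total`, with
negative among-group components truncated to zero (with a warning), as
standard AMOVA software does. The permutation test moves whole
individuals (both gene copies) between sub-populations; the reported p is
`(1 + #{F_perm ≥ F_obs})/(n_perm + 1)`. `G'st` is Nei's `Gst` divided by
its maximum `(k−1)(1−Hs)/(k−1+Hs)` given the within-group diversity.

## O-ring point-pattern analysis

`O(r)` estimates the density of neighbours in the annulus
`[r − w/2, r + w/2)` around a typical plant; under complete spatial
randomness it equals the intensity λ at every radius. Counts are exact
pair counts; the edge correction intersects each annulus with the
rectangular window using continuous geometry — the area integral of the
window-clipped chord is evaluated by a 256-node trapezoid rule, accurate
to about 1e-4 relative, rather than the grid rasterization used by older
software. This keeps the estimator's definition intact and testable
against brute-force pair counting on lattices. Radii run in `ring_width`
steps (default 1 m) and are capped at half the shorter window side
(larger requests are clipped with a warning). Envelopes are rank-based
from `n_sim` fixed-n uniform patterns: with 999 replicates, the 25th
lowest and highest values per radius (i.e. `floor(0.025(n_sim+1))` per
tail); an explicit `tail_rank` reproduces the looser 5%-per-tail variant.
`b_LO` is the OLS slope of `O(r)` on `ln r`, with a degenerate-fit flag
when `O(r)` is constant.

## Kinship, correlograms, Sp, and dispersal curvature

Pairwise kinship uses the Loiselle estimator — the standard choice for
codominant SSRs because it stays well-behaved at rare alleles — with the
small-sample term `p(1−p)/(n−1)` per allele, computed per locus and
combined as the ratio of summed numerators to summed denominators over
the loci co-typed in each pair (a Ritland variant is available behind
`estimator = "ritland"`). Centring on the sample frequencies makes the
all-pair mean approximately zero; the test suite asserts the exact
finite-sample value of that mean.

Correlograms average `F_ij` in half-open distance classes `(lo, hi]`
with default edges 0–20 m by 5 m, 21–50 m by 10 m, 51–350 m by 50 m, and
351–450 m. Pairs beyond the last edge are dropped and reported. The null
envelope permutes spatial locations among individuals (genotypes fixed),
the natural unit when the question is whether genotypes are arranged in
space non-randomly; classes outside the 2.5%/97.5% permutation quantiles
are flagged. `b_LF` is the slope of `F_ij` on `ln d` over all pairs (not
class means), with a delete-one-locus jackknife SE and
`CI = b ± 1.96·SE`; `Sp = −b_LF/(1 − F(1))` uses the first-class mean
kinship and is flagged undefined at `F(1) = 1`.

The dispersal-curvature test removes the linear trend of the class means
on `ln d`, fits a cubic `f(d) = a + b ln d + c₂(ln d)² + c₃(ln d)³` to
the residuals, and evaluates the second derivative `k = 2c₂ + 6c₃ ln d₁`
at `d₁`, the realized mean pair distance of the first class (not the
nominal midpoint — the realized mean is what the data actually average
over). `k > 0` (concave at short range) indicates seed dispersal more
restricted than pollen dispersal; `k ≤ 0` indicates the reverse or no
particular seed restriction. At least five non-empty classes are
required; identical `ln d` values raise a singular-design error.

## Mixed mating and correlated paternity

Each offspring is modelled as a self of its known mother with
probability `1 − t` or an outcross to a pollen pool at population allele
frequencies with probability `t`; loci are independent. Pollen-pool
frequencies default to the adult table, since every candidate father is
genotyped. `t_m` is maximized by EM from the conventional start
`t = 0.9`, constrained to `[0, 1]`; the likelihood is asserted
non-decreasing when `check_monotone = TRUE`. At the `t = 0` boundary the
EM step ratio approaches one, so estimates may sit within ~0.01 of the
boundary MLE — matched against a grid-search oracle in tests. `t_s`
averages per-locus MLEs maximized over the widest range that keeps every
per-offspring mixture density positive; it is deliberately reported
unconstrained (values above 1 occur, as in the standard software's
output) so that `t_m − t_s`, the biparental-inbreeding signal, keeps its
usual interpretation. Offspring with zero likelihood under both modes
(mother-incompatible, e.g. mistyped) are excluded with a warning;
genotyping error is not modelled inside this likelihood.

Correlated paternity follows the sibling-pair model: an outcrossed sib
pair shares its father with probability `r_p` (full sibs) or has
independent fathers from the pool. For a pair with per-locus paternal-
allele weight vectors `u₁, u₂`, the shared-father probability per locus
is `(Σ_a u₁(a)u₂(a)p_a + B₁B₂)/2` against `B₁B₂` for independent
fathers; `r_pm` maximizes the multilocus mixture over all within-family
pairs, `r_ps` maximizes per locus and averages, and `N_ep = 1/r_pm`.
Boundary estimates within 1e-6 of 0 or 1 are snapped to the boundary
(the optimizer stops a hair inside). Sib pairs within a family are not
independent, so `r_ps` is noticeably noisier than `r_pm`; the tests
validate `r_pm` against the analytic share-square identity
`r_p = Σ(donor share)²` on constructed pedigrees. `r_t` is defined here
as the among-locus mean correlation of per-family single-locus selfing
estimates, clamped to `[−1, 1]`; boundary values printed by other
software for this quantity are not independently recoverable, so this
definition is documented rather than matched. Standard errors come from
resampling maternal families with replacement (default 1000 replicates);
the built-in estimators reuse precomputed per-family likelihood
ingredients so the bootstrap stays cheap even with families of 189.

## Paternity assignment

The LOD of a candidate is `Σ_l ln[P(g_o | g_m, g_f, e)/P(g_o | g_m, e)]`.
The error model is per-genotype mistyping: with probability `e` a
genotype (offspring or candidate) is an unconstrained Hardy–Weinberg
draw, giving `L = e·P_HWE + (1−e)[e·T_pool + (1−e)·T_father]`. At
`e = 0`, Mendelian incompatibility yields `−∞` (exclusion), verified
against gamete enumeration. When the mother is untyped at a locus the
parent–offspring pair likelihood is used; missing loci are skipped.
Confidence relies on `delta`, the LOD gap between best and second-best
candidate: `calibrate_confidence` simulates mating events under the
declared design — candidate count, sampling proportion (the true father
may be unsampled), proportion of loci typed, error rate — and sets the
strict/relaxed thresholds as the smallest delta at which the realized
precision reaches 95% / 80%. Unattainable levels give `+∞` with a
warning. Assignment tiers by delta (a pure highest-LOD mode exists
behind `criterion = "lod"`); mothers are excluded as their own pollen
donors unless `allow_selfing = TRUE`. Capsule-level reports use the
modal strict-tier father, its assigned proportion, and the Euclidean
mother–father distance; `dispersal_summary` reports mean, sample SD
(n−1), min and max, with SD flagged undefined for a single assignment.

## The synthetic-data generator

The simulator is first-class, tested code. Its defaults are the study
conditions the package targets: three sub-population rectangles of
140×120, 80×220 and 40×100 m separated by >100 m of unsuitable matrix,
with 56, 39 and 60 adults placed by a Thomas cluster process (8 parents,
mean 10 offspring, 5 m radius — producing the short-range aggregation the
O-ring module should detect); 15 unlinked loci with 2–14 alleles at
Dirichlet(1) founder frequencies; an exponential pollen kernel of scale
300 m (long-range, matching observed pollen flows of order 10²–10³ m)
against an exponential seed kernel of scale 5 m (matching kinship
structure confined below ~10 m); selfing rate 0 by default
(near-complete outcrossing); exactly one pollen donor per capsule
(pollinium transfer), with `n_donors = k` for power studies; and family
sizes 189, 182, 187, 56, 181, 169, 24, 112. Five non-overlapping
generations of forward simulation precede sampling; population sizes per
sub-population are held constant, each offspring draws a mother
uniformly within its sub-population, is placed at mother + seed-kernel
displacement (resampled until inside the natal rectangle), and draws a
father among all adults with probability proportional to the pollen
kernel — so pollen, but not seed, crosses the gaps. The seed-dispersal
scale is justified only by the spatial scale of kinship structure; it
must not be read as an estimate of a real seed kernel.

The generator emits both observable files (genotypes, coordinates,
arrays) and hidden truth (pedigree, donor sets, realized dispersal
distances, per-generation allele frequencies), enabling parameter-
recovery tests: outcrossing-rate recovery against the realized selfing
fraction, `N_ep` against realized donor shares, curvature sign against
the kernel ordering, father-sampling frequencies against kernel weights.
What it does not emulate: clonal growth (only genets are modelled),
mutation, overlapping generations, demographic stochasticity, landscape
resistance beyond the rectangle gaps, and null alleles. Tests passing on
simulated data therefore demonstrate estimator correctness under the
stated model, not robustness to those real-data complications.

## Numerical choices and degenerate inputs

EM tolerance 1e-10 on the parameter with 2000-iteration cap and a
convergence flag; 1-D likelihood maximizations via golden-section
(`optimize`, tol 1e-9) on ranges trimmed to keep densities positive;
boundary snapping at 1e-6; O-ring areas by 256-node trapezoid;
permutation p-values with the +1 correction; envelope ranks
`floor(0.025(n_sim+1))`; half-open distance classes `(lo, hi]` so a pair
at exactly 5 m joins the first class; jackknife SE undefined with fewer
than two informative loci; `Sp` undefined at `F(1) = 1`; monomorphic loci
flagged and excluded from HWE and kinship but retained (as zeros) in
exclusion products.

Test and example problem sizes are deliberately modest — e.g. 8 families
× 150 offspring for mating-system recovery, 99–999 Monte Carlo
replicates, 10 simulation replicates for sign-recovery checks — chosen as
the smallest sizes at which the statistical behaviour under test is
clearly resolved.

## Known limitations

The curvature test has limited power to declare pollen-restricted
dispersal in this landscape: when the seed kernel is much larger than
the sub-population rectangles, seed placement is nearly uniform and
erases within-population spatial-genetic association, leaving only the
among-sub-population divergence step as a (weak) convexity signal, so
`k` scatters around a small negative value and its sign is recovered in
only roughly 7 of 10 replicates. The reverse direction (seed-restricted,
`k > 0`) is recovered reliably. `r_ps` inherits substantial noise from
non-independent sib pairs; `t_s` can exceed 1 by construction; and the
delta calibration assumes candidate genotypes are Hardy–Weinberg draws
from the supplied frequencies, which understates relatedness among real
candidates.
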