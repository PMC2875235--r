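---
title: "Methods: mtDNA control-region population analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mtDNA control-region population analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtPopGen)
```

## Scope

mtPopGen implements the analysis workflow of a classic human mtDNA
control-region survey: haplotypes are recorded as lists of differences from
the revised Cambridge Reference Sequence (rCRS, positions 1--16569), assigned
to haplogroups by motif matching, and summarised with the standard
population-genetic statistics. The package ships an 81-sample survey from
El Jadida (Moroccan Atlantic coast) as a worked fixture; every statistic
discussed below can be recomputed from it.

## Variant notation and the distance policy

HVRI positions are conventionally printed minus 16000 ("129" means 16129);
`"0"` denotes identity to the rCRS in a region. A bare integer is a
transition, `"184C"` a transversion, `"318A/C"` a heteroplasmic/ambiguous
call, `"309.1"`/`"309.2"` C-tract insertions, `"193del"` (or `"193d"`) a
deletion and `"196insT"` an insertion of a stated base. Parsing and canonical
rendering are inverse operations, and the 16000 offset restoration is an
involution.

All counting happens under a `DistancePolicy`. Two haplotypes differ at a
variant key (position, insertion index, kind) when exactly one carries a
variant there or when both do with different rendered states. Heteroplasmic
calls are scored as carrying their stated non-reference state: `318A/C`
differs from the rCRS and from any other state at 16318, while two identical
heteroplasmic calls do not differ. We deliberately do *not* treat overlapping
allele sets (`265A/T` vs `265A/C`) as equal: partially overlapping
heteroplasmies are different observed states, and scoring them as equal is
both harder to justify and empirically at odds with the survey's published
summary statistics.

The default window is **16024--16360 with indels excluded and heteroplasmies
counted**. The window deserves a note: surveys of this era rarely state their
exact Arlequin input range, so we calibrated the default against the
fixture's published summary row. Over a grid of plausible windows
(16024--16360/16365/16383/16400/16569) and indel/ambiguity conventions, only
the 16024--16360 window with indels excluded reproduces all of the published
values simultaneously (59 distinct haplotypes, mean pairwise differences
5.945, Tajima's D -1.777 at 64 segregating sites). Every policy component is
user-configurable, and the distinct-haplotype count is insensitive to the
window choice; the pairwise-difference statistics shift by a few percent
across windows because positions 16362--16399 are polymorphic in the sample.

Nucleotide diversity is reported as MPD divided by the window length
(337 sites by default). The source survey did not state its sequence length,
so its printed nucleotide diversity (0.017) corresponds to a slightly longer
window than our default; we report the window alongside the value rather
than guessing theirs.

## Haplogroup classification

A `MotifTree` lists nodes with a parent and a motif of rCRS-relative
variants; a node's effective motif is the union along its root path. A
haplotype is scored against every node as

  score = matched motif sites - lambda * missing motif sites,

with `lambda = 0.6` by default. Motif sites are matched by variant key
regardless of allele, so a heteroplasmic call satisfies a motif site.
Coding-region motif sites are penalised only for samples whose coding
segments were actually sequenced (`codingTyped`): unobserved is not absent.
This matters for the fixture, where haplogroup H1 hinges on coding position
3010 typed only in candidate H/HV samples. The best score wins; equal scores
on one root path resolve to the deepest node, while equal scores across
paths are reported as ties and never silently broken.

The choice `lambda = 0.6` makes a missing diagnostic site cost a bit more
than half a matched one. Smaller values let deep nodes win on partial
motifs (a sample carrying only `263` would drift from H* to H1); values at
or above 1 let a single matched extra site be cancelled by one missing
site, which breaks apart sister clades that share most of their motif. Any
value in roughly (0.5, 1) classifies the fixture identically; 0.6 is
comfortably inside that plateau.

The packaged tree covers exactly the haplogroups of the fixture, distilled
from the published phylogenies for H, K, J/T/V/R, U, I/M1, X and L. It is a
data file, not code: motifs are kept minimal but discriminating for this
survey (a full PhyloTree-scale classifier, with rank weights and fluctuating
sites, is out of scope). Classifying the 81 fixture haplotypes reproduces
all 81 published labels uniquely, and haplotypes synthesised from any node's
motif classify back to that node.

Macro-pooling maps labels starting `L0`--`L6` to the sub-Saharan L pool and
everything else to the West Eurasian pool; within-L shares divide branch
counts (label prefix L1/L2/L3, ...) by the L-pool size.

## Diversity and neutrality

* Haplotype (gene) diversity: Nei's unbiased
  `H = n/(n-1) * (1 - sum p_i^2)` with Nei's (1987) sampling variance.
* Mean pairwise differences: the average of the policy distance over all
  pairs; its SE uses Tajima's (1983) total (stochastic + sampling)
  no-recombination variance
  `[3n(n+1)MPD + 2(n^2+n+3)MPD^2] / [11(n^2-7n+6)]`.
* Tajima's D from S and MPD with the standard a1, a2, b1, b2, c1, c2, e1,
  e2 constants; undefined (NA) at S = 0.
* Fu's Fs from the Ewens sampling distribution:
  `S' = Pr(K >= k_obs | theta)` with theta set to MPD, computed **entirely
  in log space** via the unsigned-Stirling recurrence and
  `Fs = LSE(terms >= k_obs) - LSE(terms < k_obs)` (the rising-factorial
  denominators cancel). The Stirling numbers overflow doubles long before
  n = 81, and the tail itself underflows; the log-space route is exact to
  floating precision for any n this package will meet. A consequence worth
  knowing: legacy desktop implementations evaluated this tail in fixed
  double precision and saturate near Fs = -25, so published values around
  -25 from that era are floor artifacts. For the fixture (n = 81, k = 59,
  theta = 5.945) the mathematically exact value is about -64.9; the
  package reports the exact value. Our implementation is verified against
  brute-force enumeration of the Ewens distribution over all set
  partitions for n <= 8 and against an arbitrary-precision cross-check of
  the non-saturated regime.

P-values for both statistics use Hudson-style fixed-S conditioning: neutral
constant-size coalescent genealogies for the observed n, exactly S mutations
placed multinomially on branches by length, both statistics recomputed per
replicate, and the lower tail reported (a two-tailed option is provided,
since conventions differ). For the fixture both come out significant
(p < 0.01 at 1000 replicates), matching the published bold values.

## Population structure

Pairwise differences are used directly as squared Euclidean distances (the
classic convention for Phi-statistics on haplotype data). The two-level
AMOVA decomposes the total sum of squares into among- and within-population
components; `Phi_ST = sigma2_a / (sigma2_a + sigma2_w)`. Negative
among-group components are reported as computed and flagged, but truncated
to zero when expressing percentages. Permutation tests shuffle individuals
between populations; p-values come with binomial standard errors and a
Bonferroni helper flags family-wise significance.

## Rho dating

For a clade with tips carrying `c_t` mutations from the ancestral haplotype
(multiplicity `m_t`), `rho = sum(c_t m_t) / sum(m_t)` and the Saillard-type
error is `sigma = sqrt(sum_b (n_b/N)^2 l_b)` over branches (star form:
`sqrt(sum c_t)/N`). Ages are `rho * 3624` years by default. The convention
of counting a shared tip haplotype's terminal mutations once is available
as a toggle (`sharedTipsOnce`), since the underlying bookkeeping is
genuinely ambiguous in the literature. A hook accepts a user-supplied
transform (e.g. a purifying-selection correction); none is built in, which
is one reason this package does not attempt to reproduce externally
calculated clade ages that also depend on complete sequences not printed in
any table. Parameter recovery is validated by simulation: on
coalescent-shaped clades of known age the mean estimate is unbiased and the
+-1.96 sigma intervals cover the truth in >= 90% of replicates.

## Spatial interpolation and correlograms

Frequencies live on unprojected lat/lon coordinates with great-circle
(haversine, r = 6371 km) distances; the source GIS projection being
unstated, a projection-free treatment is the only reproducible choice. IDW
uses power 2 by default, is exact at sample locations and bounded by the
input range. Moran's I uses the standard double-sum form; correlograms bin
pair distances into 14 equal-count classes (equal-count stabilises
per-class power compared to equal-width) with per-class permutation
p-values. A cline is called when the first class is positive and
significant, the I-vs-class rank trend is negative and significant, and at
least one of the last three classes is negative -- each threshold
configurable, since the original software's exact procedure is not
documented. Calibration: synthetic clinal fields are called in >= 90% of
seeded runs and spatially random fields are rejected in >= 90%.

## Synthetic data

The generators exist so that every stage can be tested with inputs whose
statistical structure is known: fixed-S/fixed-theta neutral coalescent
samples (infinite sites on distinct window positions), Poisson-mutation
clades of known age (star or coalescent topology), clinal or flat frequency
fields with Gaussian noise, and motif-derived haplotypes with private
mutations. All are deterministic given a seed. They emulate the *null*
structure the statistics assume -- constant population size, no
recombination, uniform site choice -- and none of the messiness of real
control-region data (mutation-rate heterogeneity along the sequence,
recurrent mutation at hotspots like 16189, phantom mutations, sampling
structure). Passing the simulation-based tests therefore validates the
estimators, not the demographic realism of any particular survey.

## Problem sizes and numerical choices

The test-suite defaults are sized for routine runs: 500 clades for clock
recovery, 2000 fixed-S replicates for the D-test calibration at n = 30,
1000 replicates for the fixture's p-values, 199 permutations per
correlogram class. Score ties in classification are compared with a 1e-9
tolerance; IDW treats a grid node within 1e-9 km of a sample as coincident;
zero-variance inputs yield NA Moran's I (and thus a FALSE cline call)
rather than an error. Degenerate inputs -- populations of size 1 in AMOVA,
monomorphic pairs in Phi-ST, S = 0 for Tajima's D, k_obs = 1 for Fs --
return warnings, zeros, NA or infinities as documented rather than failing.

## Known limitations

* The motif tree is survey-scoped; applying it to other populations
  requires supplying a fuller tree in the same TSV dialect.
* Reduced-median networks, complete-sequence phylogenies and
  externally-calibrated clade ages are out of scope.
* Fu's Fs values published by legacy software below about -25 cannot be
  matched by any mathematically faithful implementation (see above); the
  package knowingly reports the exact statistic instead.
* The coalescent null is constant-size; no growth or bottleneck models.
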