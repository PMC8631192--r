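---
title: "Temperate-phage characterization with ProphageKit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperate-phage characterization with ProphageKit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProphageKit)
```

# Scope

ProphageKit implements the computational backbone of a temperate-phage
characterization study: discovering integrated prophages from their
attachment-site direct repeats, quantifying the GC depletion of the
hypervariable early gene region, measuring intergenomic nucleotide
similarity for genus/species demarcation, reducing phenotype assays
(virulence, host range, one-step growth) to their standard statistics, and
reconciling phage and host phylogenies under an undated
duplication-transfer-loss (DTL) maximum-parsimony model. Every stage has a
matched simulator so that the entire pipeline can be exercised, calibrated
and regression-tested without any external sequence or assay data.

# Conventions

All coordinates are **1-based and closed**, the convention shared by
IRanges, Biostrings and GFF3, which the package uses throughout its
containers (`GenomeRecord` sequences ride on `Biostrings::DNAString`,
features on `GenomicRanges::GRanges`). Adopting the ecosystem's native
convention removes the most common source of off-by-one defects in
coordinate-heavy code. Trees are `ape::phylo` objects; reconciliation
requires them rooted and binary and rejects polytomies explicitly.

All stochastic functions accept a `seed` argument and restore the caller's
RNG state afterwards; a fixed seed gives bitwise-identical output.

# Prophage discovery from att direct repeats

Site-specific integration of a circular temperate phage at a bacterial
attachment site (attB) leaves the prophage flanked by a short direct repeat
(attL/attR). `findMotif()` scans both strands for a motif (default the
12-mer `CAGATTTAGGTT`) within a Hamming-distance tolerance (default 1
mismatch per copy, a deliberate allowance for repeat degeneracy that the
source data do not quantify). `callProphages()` pairs same-strand hits
whose spacing — attR start minus attL start, i.e. the inferred circular
phage length — falls inside a size window (default 30-60 kb, bracketing
the 42-45 kb family modelled). Nested and overlapping candidates are
resolved by keeping the shortest call per attL and then greedily
discarding calls overlapping an accepted one; without this rule, nested
repeats would produce spurious giant calls. Opposite-strand (inverted
repeat) pairings are reported as warnings only, since integrase biology
makes att sites direct repeats.

The reported `length` of a call counts the interior plus a single motif
copy: the circular phage carries exactly one copy of the repeat, so this
is the length of the element that integrated. `findAttB()` annotates motif
hits with whether they fall inside an *intact* tRNA feature (an
interrupted tRNA — one carrying an integrated prophage — no longer counts),
and `rotateToReference()` normalizes excised circular sequences to a
reference origin and strand by voting over shared k-mer seeds.

# GC windows and the early-region contrast

`gcWindows()` profiles GC in fixed bins (default 250 bp); the trailing
partial bin is kept with its own length weight, and `N` bases are excluded
from numerator and denominator alike (whether ambiguous bases were
excluded in the source analysis is unstated; exclusion is this package's
choice). `regionGC()` aggregates GC over labelled early/middle/late
intervals, with "rest" defined as the complement of the early region —
the natural reading of an early-versus-remainder contrast.
`compareEarlyVsRest()` then performs a **paired** two-sided t-test on the
per-genome (early, rest) pairs. The paired design is implied by the
reported degrees of freedom: a t statistic on n − 1 df over an n-genome
panel arises only when each genome contributes one difference. The
statistic is oriented as rest − early, so GC depletion of the early
region yields positive t.

# Intergenomic similarity

`pairSimilarity()` is a deliberately self-contained, VIRIDIC-style
measure: the query is cut into non-overlapping 1 kb fragments; each
fragment is placed on the subject by exact 11-mer seeding (both strands),
requiring at least two seeds to agree on a diagonal (one for fragments too
short to carry two seeds) — the agreement requirement suppresses chance
k-mer matches between unrelated genomes; placement is refined by a
unit-gap-cost alignment within a fixed band (default half-width 32,
adequate at the >70% identity range the thresholds operate in).
Directional similarity is summed identities over summed aligned columns,
scaled by the aligned fraction of the query, and the reported percent
averages both directions — aligned-fraction weighting follows the
intergenomic-similarity definition in spirit. The measure is **not**
bit-identical to VIRIDIC, which delegates alignment to BLASTN; exact
parity would require that backend. `clusterAt()` performs single-linkage
threshold clustering (connected components of the at-or-above-threshold
graph), the operation behind >70% (genus) and <97% (species) demarcation.

# Phenotype statistics

**RBG.** Reduction in bacterial growth over a window `[t0, tx]` is
`1 − ΔOD⁺/ΔOD⁻` with the paired no-phage control in the denominator,
evaluated at the recorded reading nearest each endpoint within half a
sampling interval. `t0` defaults to the first reading (the alternative,
inoculation time, is not recorded in typical plate-reader exports). The
statistic is invariant to blank subtraction and to rescaling of all ODs;
a control that gained no OD makes the ratio undefined and is flagged
rather than divided by. Note that a culture that *loses* turbidity makes
RBG exceed 1; the package reports the raw statistic without clamping.

**Host range.** Grades are a pure function of four observations
(day-1 clearing, plaques at dilution, regrowth, lysogen PCR):
none → `none`; turbid clearing → `weak`; clear zone with plaques →
`strong`; strong with regrowth and PCR-confirmed lysogens →
`lysogenization`. Regrowth without a PCR verdict stays `strong` with a
`lysogeny_untested` flag, and a clear zone without plaques is graded
`weak` since no productive infection was demonstrated.

**One-step growth.** `fitOneStep()` defines a canonical plateau/tangent
estimator rather than chasing parity with any particular curve-fitting
package whose settings are unpublished: the lysis rise is the steepest
segment of log10(PFU); baseline and final plateaus are means of points
within 2% and beyond 95% of the log-range respectively; burst size is the
plateau ratio; the latent period is the intersection of the baseline with
the steepest-segment tangent. The estimator is validated by recovery on
simulated curves (latent within one sampling step, burst within 10% at 5%
lognormal noise), not by comparison to another implementation. A series
whose titre never doubles is declared rise-free: burst is still reported,
the latent period is `NA`.

**ANOVA.** `anovaWithContrasts()` uses sequential (type-I) sums of squares
in the order A, B, A:B and pairwise contrasts on the pooled residual
error. Contrast p-values are unadjusted by default — reproducing the
common reporting style of pairwise contrasts without a named adjustment —
with a Tukey option for stricter use. A 3-phage x 2-host x 3-replicate
design gives the familiar F(2, 12) layout for the phage term.

# Undated DTL reconciliation

The centrepiece is a dynamic program over (phage node p, host node h)
pairs with three tables:

* `C[p,h]` — cheapest reconciliation of p's subtree with p mapped exactly
  at h;
* `IN[p,h]` — cheapest with p at h or anywhere in h's subtree, charging
  one loss per host edge passed;
* `OUT[p,h]` — cheapest placement of p at a host node *incomparable* to h
  (neither ancestor nor descendant).

An internal phage node resolves as **cospeciation** (children descend into
the two distinct host child subtrees; only at internal hosts),
**duplication** (both children stay within the host subtree), or
**transfer** (one child stays, the other lands on an incomparable host
node). The model is undated: transfer targets are constrained only by
incomparability, not by node times, matching reconciliation of undated
trees. Losses are accounted as host-edge passages implied by child
placements rather than free-standing events — this per-edge accounting is
exactly what makes the relative weighting of loss (1 versus 2) against
transfer (1) flip optimal scenarios between cospeciation-plus-loss and
transfer-rich explanations. The minimum over host placements of the phage
root is the reconciliation cost; losses above the root are not charged.

MPR counting runs inside the same DP (sums over cost-tied choices,
products over independent subproblems); enumeration backtracks it in a
deterministic order (cospeciation before duplication before transfer,
host nodes in fixed index order), and every enumerated certificate is
re-checkable bottom-up with `validateReconciliation()`. Cost ties are
compared with a 1e-9 tolerance so fractional cost grids behave.
Correctness is established against an independent brute-force oracle that
enumerates every assignment of internal phage nodes to host nodes and
prices the geometrically valid events directly; the test suite sweeps all
rooted binary tree shapes with up to five tips per side under three cost
settings, including the two loss weightings used downstream.

`clusterMPRs()` partitions an enumerated sample by k-medoids on the
symmetric difference of event sets — the clustering metric is this
package's declared choice, since none is fixed by precedent — and reports
medoids as representative scenarios. `costSpace()` maps optimal
event-count signatures over a (transfer, loss) grid with cospeciation and
duplication fixed, merging adjacent cells with identical signature sets
into regions. `permutationTest()` compares the observed cost with a null
built by uniformly permuting the tip association (default), with an
optional random-topology null; whether published "random tree"
comparisons permute associations or topologies is ambiguous, so both are
provided and the choice is explicit in the API.

# The synthetic-data module

The generators define the study conditions the tests run under:

* **Phage genomes** (`genPhageGenome()`): iid nucleotides, 42-45 kb,
  partitioned into early (first 5 kb — the scale of the hypervariable
  region) / middle / late, with target GC 0.543 in the early region and
  0.599 elsewhere; each region is resampled until its realized GC is
  within 0.01 of target. Any att-motif occurrence (either strand, up to 1
  mismatch) is screened out so attachment sites exist only where
  integration puts them.
* **Host genomes** (`simHostGenome()`): 100 kb iid background at GC 0.60
  with a single tRNA-Leu locus carrying one exact att copy. Real
  rhizobial chromosomes run to several Mb; 100 kb is a deliberate
  desk-scale problem size — detection is per-base, so scan behaviour is
  unchanged, but genome-scale confounders (repeat families, mobile
  elements, compositional heterogeneity) are *not* represented, and the
  screening of near-motif matches enforces an att site unique at the
  detector's tolerance, emulating the uniqueness of the real integration
  locus. Perfect recall/zero false calls on these genomes therefore
  demonstrates the correctness of the pairing logic, not detection
  performance on real chromosomes.
* **Infection dynamics** (`simInfectionOD()`): a three-compartment ODE —
  susceptible cells, lysogens (immune, inheriting the growth rate), free
  phage — integrated with fixed-step RK4 on the 20-minute sampling grid,
  the simplest mechanism that reproduces the lysis-then-recovery
  trajectory of a temperate infection and its contrast with a purely
  lytic one. The source cultures come with no kinetic constants, so the
  defaults (r = 0.25/h, K = 1 OD, adsorption 10 /(OD h), effective burst
  3, lysogenization probability 0.01, decay 0.1/h) are order-of-magnitude
  choices exposed as parameters rather than asserted as measurements.
  Latency is not age-structured; at 20-minute sampling this is invisible.
* **One-step curves** (`simOneStep()`): flat at the infected-centre count
  until the latent period, then a logistic wave in log space over 30
  minutes, rescaled to hit both plateaus exactly so a noise-free curve has
  plateau ratio exactly equal to the burst size.
* **Noise** is multiplicative lognormal throughout — OD and PFU are
  positive and span decades.
* **Cophylogeny scenarios** (`simCophylogeny()`): pure-birth host tree; a
  phage lineage cospeciates at every host split and, per edge traversal,
  may be lost, duplicate, or transfer with the configured probabilities
  (at most one optional event per traversal — adequate at the low rates
  simulated). Transfer recipients are uniform among host edges alive at
  the uniformly drawn event time, excluding the donor's edge, matching
  the undated-DTL notion of transfer used downstream. The full event
  history is logged even for lineages whose descendants die, so the true
  history's cost is always an upper bound on the parsimony minimum
  (pruning a history can only remove or cheapen events). No sequence
  evolution is simulated along the trees.

# Numerical choices and degenerate inputs

* Paired t on identical pairs (zero-variance differences) returns t = 0,
  p = 1 instead of 0/0.
* A saturated ANOVA on a zero-variance response reports F = 0, p = 1.
* Cost ties in the DP use a 1e-9 tolerance; enumeration order is fixed so
  capped samples are reproducible.
* `pairSimilarity()` of a genome with itself is exactly 100 with aligned
  fraction 1 (all fragments, including the trailing partial, align
  end-to-end).
* An all-N sequence has undefined GC and errors; bins that are all N
  yield `NA` without poisoning the genome mean.
* Single-tip trees reconcile at cost 0 with one MPR.

# Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen as
the package's own defaults: 100-kb hosts, 100 + 100 genomes for the
detection experiment, 10-genome GC panels, a 9-tip reconciliation panel
with 999 permutations, exhaustive DTL verification up to 5 tips per side,
and 1000 null simulations for ANOVA calibration.

# Known limitations

* The similarity measure is VIRIDIC-style, not VIRIDIC: absolute values
  can differ from BLASTN-backed pipelines, though thresholds at 70/97 are
  robust for close-versus-far discrimination.
* Detection assumes att copies within the configured Hamming tolerance;
  rearranged or partially deleted prophages (degraded elements) are out
  of scope by design.
* The infection ODE is unstructured in infection age and models a single
  phage population; MOI-dependent lysogenization and resistance evolution
  are not represented.
* The DTL model is undated; time-consistency of transfer scenarios is
  not checked, and dated reconciliation is a non-goal.
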