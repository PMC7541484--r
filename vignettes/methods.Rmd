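---
title: "Models and methods behind paleoproteo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind paleoproteo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoproteo)
```

This vignette explains the models implemented in `paleoproteo`, the
assumptions behind them, the tunable parameters and their defaults, what the
synthetic-data generators do and do not emulate, and the numerical choices
made where the design was genuinely open.

## The scientific setting

Pleistocene bone and dentine retain type I collagen and a shrinking set of
non-collagenous proteins (NCPs) long after ancient DNA has degraded.
Working with such material requires three safeguards before phylogenetic
use: (i) cheap, non-destructive *prescreening* to decide whether collagen
survives at all; (ii) *authentication* that recovered peptides are ancient,
using spontaneous Asn/Gln deamidation as a molecular clock of damage; and
(iii) conservative *consensus calling* so that sequencing noise is not
mistaken for evolutionary signal. The package implements each stage plus
the downstream parsimony phylogenetics, and ships generators that produce
inputs with known truth for all of them.

## Prescreening indices

An ATR-FTIR spectrum of bone powder (4000–525 cm⁻¹, 4 cm⁻¹ resolution)
carries two standard diagenesis indices:

* **IRSF** (infrared splitting factor): the phosphate ν₄ doublet sharpens as
  bioapatite recrystallizes. We measure baseline-corrected heights at the
  ~605 and ~565 cm⁻¹ peaks and the ~590 cm⁻¹ valley and report
  $(h_{605} + h_{565}) / h_{590}$. Values above 4.0 flag an extremely
  degraded or burnt bone.
* **Am/P**: amide I height (~1640 cm⁻¹) over phosphate ν₃ height
  (~1010 cm⁻¹), a proxy for residual collagen. Above 0.07, soluble-collagen
  extraction is likely to succeed.

Band-search windows are 595–615, 555–575 and 580–600 cm⁻¹ for the doublet
and valley, 990–1040 for phosphate ν₃, and 1600–1680 for amide I; the
baseline under each feature is the straight line joining the minima of
flanking windows (525–545/625–650 cm⁻¹ for the doublet region). The
windows bracket canonical bone band positions; heights are taken at window
extrema. These choices make both indices exactly invariant to additive
baseline offsets and to uniform intensity rescaling, which the test suite
verifies as properties.

The elemental screen converts weight percentages to an atomic C:N ratio
with atomic masses 12.011 and 14.007 (this choice reproduces the standard
worked example (10.53/12.011)/(3.37/14.007) = 3.64). A sample with
N wt% > 3.0 and C:N in [3.0, 3.9] is flagged as a good candidate for
radiocarbon dating. Note that published C:N values are generally computed
from unrounded measurements, so recomputing them from rounded printed wt%
does not always match the printed ratio; the package makes no attempt to
force such agreement.

## Peptide chemistry

Masses are derived from elemental compositions (residue formulas plus one
water, plus modification deltas) and monoisotopic atomic masses at ≥ 6
decimals, so the standard MALDI calibration values are reproduced to 4
decimal places (e.g. bradykinin 1–7 at m/z 757.3992). Supported variable
modifications are oxidation (M), hydroxylation (P/K) — both +15.99491 Da —
and deamidation (N/Q), whose increment is computed from the elemental swap
(−NH +O = +0.984016 Da). Leucine and isoleucine share a composition;
ambiguity codes (B, Z, X) are rejected because downstream `X` denotes
missing sequence, not a residue.

Isotope distributions are computed by convolving per-element isotope
polynomials (exponentiation by squaring, truncated to the requested number
of isotopologues) and normalizing. Six isotopologue peaks are used for
envelope fitting: for peptides under ~3500 Da this captures > 99% of the
envelope mass. The test suite checks the convolution against an
independent per-atom sequential-convolution oracle.

## The ZooMS α-value

The deamidation state of the marker peptide at m/z 1105 is summarized as
the *undeamidated fraction* α: the observed envelope is modelled as

$$y \approx c\,[\alpha\,T + (1-\alpha)\,T^+]$$

with $T$ the theoretical isotope distribution and $T^+$ its copy shifted by
the deamidation increment. Because that increment (0.9840 Da) differs from
the isotopologue spacing (1.00336 Da) by only ~0.02 Da — far below
MALDI-TOF peak widths — the shifted envelope is treated as landing on the
next isotopologue slot. The two mixture coefficients are found by
non-negative least squares; with two columns this has a closed-form exact
solution (the unconstrained 2×2 normal equations when feasible, otherwise
the better single-component fit). α is their normalized first coefficient,
clipped to [0, 1], and the reported residual is the L2-normalized misfit.
The estimator is scale-invariant and, on noiseless envelopes, exactly
inverts the generator for any α — a property the tests exercise at
α ∈ {0, 0.25, 0.5, 0.75, 1} and as strict monotonicity across α.

Replicate spectra (triplicate spotting is instrument practice) are averaged
pointwise for peak picking, while α is estimated per replicate and combined
by a weighted mean. The weighting scheme is not fixed by convention, so the
package uses summed envelope intensity as the weight — weak, noisy spots
count less — and exposes it via the per-replicate table. When every
replicate fails (no usable envelope), the result propagates as
not-determinable (`n.d.`) rather than a number.

Peak picking applies rolling-minimum baseline suppression, a short
moving-average smooth (5 points), local-maximum detection, a
signal-to-noise threshold of 3.5 (noise estimated by the MAD of the
baseline-corrected signal) and a relative-intensity threshold of 0.5% of
the base peak — the standard fingerprint-processing settings. Deisotoping
greedily chains peaks spaced ~1 Da (0.9–1.1 Da windows) and keeps each
chain's monoisotopic member with the envelope-summed intensity. Marker
matching takes the nearest peak within ±0.2 Da (an external-calibration
accuracy class; the tolerance is a config parameter, with an equidistant
tie broken deterministically to the lower m/z).

## Deamidation-based endogeneity

Per protein, the deamidation frequency pools ion intensities across Q/N
site observations:
$f = \sum \text{deamidated intensity} \,/\, \sum \text{total intensity}$.
Intensity pooling (rather than an unweighted mean of per-site fractions)
follows the summed-ion-intensity definition of the quantity; it makes $f$
invariant to uniform intensity rescaling. Sites qualify when their total
intensity reaches `min_intensity`, whose default of 0 treats every observed
site as quantifiable; the cutoff is deliberately exposed because
"sufficient intensity" has no standard value.

Only proteins with **more than two** covered Q/N positions enter the
cluster analysis. The two-component univariate Gaussian mixture is fitted
by EM with 50 restarts (initial means are random pairs of distinct data
values, plus one quantile-based start), a variance floor of 1e-7, and a
log-likelihood tolerance of 1e-8; the fit is deterministic given its seed
and its log-likelihood trace is non-decreasing, which the tests assert.
Only this two-component univariate case is implemented — the full
model-based-clustering family would be out of scope — and the fit is
cross-checked against the reference mixture implementation in the test
suite. The component with the larger mean is labelled endogenous; an exact
posterior tie is broken conservatively to contaminant with a warning.
Borderline proteins that a practitioner might promote to endogenous on
literature grounds are a manual step and deliberately not encoded.

## Consensus calling and dataset assembly

Substitution authentication requires, per variant site: at least two
supporting PSMs, the presence of both b- and y-ion series among them, and —
when the variant is the isobaric hydroxyproline–alanine vs proline–serine
pair (detected as an A↔S exchange adjacent to a proline) — a hydroxyl
localization supporting the call. Sites with variant evidence that fails
any rule are called `X`, as are uncovered sites. Variants that coincide
with deamidation chemistry (D at a reference N, E at a reference Q) are
never auto-accepted: they are indistinguishable from damage, so they are
called `X` and listed in a review table. When two different variants each
pass at one site, the higher summed PSM intensity wins and an exact tie
gives `X`. PSM positions are accepted at arbitrary reference offsets, which
accommodates nonspecific (elastase-type) digestion.

Sequences are assumed pre-aligned to fixed mature-chain coordinates —
segment lengths are enforced, not inferred, and signal/propeptide removal
is modelled by accepting mature-chain references only. Dataset 1
concatenates COL1A1 (1–1057) and COL1A2 (1058–2098); dataset 2 appends
AHSG, CHAD, OMD, SPARC, VTN, BGN, CLEC3B and SERPINF1 through position
5003. A taxon missing a protein is padded with `X` (with a warning), which
matches how low-coverage NCPs enter real concatenations; a wrong-length
segment is an error naming the taxon and protein.

## Parsimony phylogenetics

Characters are 20-bit state masks; `X`, `-` and `?` carry the full state
set, so an all-missing site never changes a score. Fitch counts are
computed by intersection/union sweeps vectorized over *site patterns*
(identical columns collapsed with weights), rooted arbitrarily at the
first tip — the score is rooting-invariant, and the degree-3 node of an
unrooted binary tree is handled exactly by sequential pairwise
combination.

The search is exact rather than heuristic: with at most a dozen taxa the
(2n−5)!! unrooted topologies can be enumerated by stepwise leaf addition,
and branch-and-bound prunes on the partial-tree score (a valid lower bound
since adding leaves never decreases parsimony length) while provably
returning the same minimal set — the tests verify this equivalence against
full enumeration, and verify Fitch itself against a brute-force
internal-state-assignment oracle. Bootstrap replicates resample columns
with replacement; when a replicate has several equally parsimonious trees,
each contributes fractionally (1/k) to its splits, so two incompatible
splits can never both exceed 50% and the majority-rule consensus is always
well defined. The consensus keeps exactly the splits occurring in more
than the threshold fraction (strictly greater, default 0.5) and attaches
frequencies as node labels. Bayesian/likelihood stages are not
reimplemented; the package instead exports the matrix and partitions as
NEXUS for external tools.

## The synthetic-data generators

`gen_ftir_spectrum` builds Gaussian bands on a linear baseline; the
phosphate ν₄ doublet sits over a compact raised-cosine fill whose three
amplitudes are solved from a 3×3 linear system so the baseline-corrected
heights at 605, 565 and 590 cm⁻¹ equal the request exactly in the
noiseless case. `gen_maldi_replicates` renders the α-mixture on the
isotopologue slot grid as Gaussian profiles (default FWHM 100 ppm) with
multiplicative per-point noise. `gen_psm_table` draws per-protein
deamidation fractions from two Beta distributions parameterized by mean
and concentration (bounded on [0, 1] with controllable overlap; default
concentration 12 gives clearly separated but not degenerate classes) and
emits intensity pairs per site, including proteins with exactly two
covered sites to exercise the eligibility filter. `gen_consensus_psms`
tiles a reference with non-overlapping peptides so its `depth` argument
equals the realized per-site PSM depth. `simulate_alignment` evolves
i.i.d. sites under an equal-rates, equal-frequency 20-state model — the
simplest model sufficient for parsimony-recovery tests.

All generators are bit-reproducible under a seed and restore the caller's
RNG state. What they deliberately do **not** emulate: chromatography and
retention behaviour, fragment-spectrum content (b/y support enters as
boolean evidence), correlated site rates or among-protein rate variation,
search-engine scoring artefacts, and real FTIR scatter effects. Passing
tests therefore demonstrate correctness of the estimators under the
package's stated statistical model, not robustness to every failure mode
of real instrument data — printed α-values and deamidation tables from
real fossils depend on deposited raw spectra and are not reproducible at
the desk.

## Problem sizes and determinism

The demo pipeline uses two synthetic samples (one well-preserved, one
degraded), three MALDI replicates at 1% noise, a 10+10-protein PSM
scenario, a six-taxon dataset-1 concatenation (2098 positions) and 100
bootstrap replicates — sizes chosen so the full end-to-end run completes
in well under five minutes on a single CPU while exercising every stage;
the `bootstrap_support()` default stays at 1000 replicates. Reports are
written with fixed numeric formatting, so a rerun with the same config and
seed is byte-identical, and the test suite compares two full runs
file-by-file to enforce this.

## Known limitations

* Consensus calling is conservative by construction: a true substitution
  observed once, without both ion series, or confounded with deamidation is
  reported as `X`, trading completeness for authentication.
* The mixture model assumes two Gaussian components on [0, 1]; strongly
  skewed or multimodal contaminant populations would need the richer model
  families of dedicated clustering packages.
* The exact search is limited to 12 taxa; beyond that a heuristic search
  (outside the package's scope) is required.
* FTIR indices depend on band-window conventions; spectra with unusual
  mineral inclusions may need window adjustments before the invariance
  guarantees apply.
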