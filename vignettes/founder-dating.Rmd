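---
title: "Dating mitochondrial founder clades: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating mitochondrial founder clades: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitofounder)
```

`mitofounder` estimates the coalescence ages of mitochondrial DNA clades and
attributes founder haplogroups to entry routes. This vignette documents the
models it implements, the parameters that matter, the numerical choices
made where conventions were open, and what the simulation-based validation
does and does not demonstrate about real data.

## Coordinates, variants, and masking

All positions are 1-based rCRS coordinates on the circular 16,569-bp
mitogenome. The coding region spans 577–16,023; the control region is the
complement, wrapping the origin (16,024–16,569 and 1–576). Variant profiles
record a sample's differences from the reference. For equal-length inputs
the comparison is positional; otherwise an affine-gap global alignment is
used (match 1, mismatch −1, gap open 8, gap extend 1 — conventional values,
all configurable), and an alignment identity below 95% over informative
sites rejects the input as a likely non-mitogenome. Unknown bases (N)
produce no variants and are excluded from the identity denominator.

Indel placement in mtDNA is reported at the 3′-most equivalent position,
the forensic-nomenclature convention; the implementation slides each indel
rightward through its homopolymer context and the tests verify the result
against brute-force enumeration of equivalent gap placements. The default
site mask removes the classically unreliable indels at nps 309, 315,
515–522 and 16,193, the hotspots at 16,182, 16,183 and 16,519, and the
allele-specific 16182C/16183C entries. Masking is idempotent and counts what
it removes.

Heteroplasmy is called when every allele with nonzero frequency lies in the
31–70% band. The published rule says "between 31 and 70%" without stating
endpoint handling; we make both endpoints **inclusive** for determinism and
document that choice here.

## Parsimony trees and haplogroup rules

Haplotype trees are built by greedy agglomeration: identical haplotypes
collapse to one tip with multiplicity, then the variant shared by the
largest number of unplaced haplotypes defines a new internal edge,
recursing. Ties break toward the lowest rCRS position and then the token
string, so construction is deterministic. The established tools in this
niche do not document their internal algorithm, so the greedy construction
is validated instead against an exhaustive oracle: for up to 8 distinct
haplotypes, every rooted topology is scored by Fitch counting (with the
root fixed at the ancestral state) and the greedy score must never beat the
minimum and must equal it on homoplasy-free instances. Homoplasies are
counted unweighted, once per edge on which they occur.

A candidate internal node is proposed as a new haplogroup only when it
subtends at least five samples (multiplicity counts) and at least two
distinct haplotypes (multiplicity does not), and its defining edge carries
at least one coding-region mutation.

Haplogroup classification walks a PhyloTree-style motif tree, scoring every
node by matched-minus-missing expected variants along its root path, with
ties resolved toward greater depth then lexicographic label. The `!` suffix
in motifs marks a back mutation, which cancels the accumulated variant at
that position.

## The ρ statistic and its standard error

For a clade with n sampled tips, edge mutation counts mⱼ and subtended tip
counts nⱼ,

ρ = (1/n) Σⱼ nⱼ mⱼ,  σ² = (1/n²) Σⱼ nⱼ² mⱼ.

ρ is exactly the mean root-to-tip mutation count (an independent
path-walking oracle asserts this on random trees). The σ formula is the
standard genealogy-weighted heuristic that treats per-edge mutation counts
as Poisson; the source literature calls it only "a heuristic estimate of
the standard error calculated from an estimate of the genealogy", so the
Poisson form is our documented choice. On a star genealogy it reduces to
σ² = ρ/n exactly. The 95% CI is ρ ± 1.96σ (z configurable; whether published
tables used ±1σ or ±1.96σ is not stated in the text available to us).

## Maximum-likelihood dating

The likelihood engine implements the reversible TN93 family (JC69, K80,
HKY85, TN93) with discrete-gamma rate heterogeneity — equal-probability
categories whose rates are within-category means, normalized to mean 1 —
and an optional invariant-site class whose complement is rescaled by
1/(1 − p_inv) so branch lengths stay in expected substitutions per site.
Likelihoods are computed by Felsenstein pruning over compressed site
patterns, with two default partitions (coding and control), each carrying
its own model instance. Correctness is pinned three ways: JC69 closed
forms, brute-force summation over all ancestral state assignments on ≤4-tip
trees, and an independent implementation (`phangorn::pml`) on a TN93+Γ
alignment. Thirty-two gamma categories are the default for dating runs; 6
are available to mirror lighter configurations, and small category counts
are used in tests for speed.

Clock-constrained fitting maximizes the likelihood over internal node
heights with tips at height 0 and parent ≥ child, by coordinate-wise
bounded scalar optimization swept to a log-likelihood tolerance of 1e-6,
with optional seeded random restarts; heights are capped at 10
substitutions/site and non-convergence is flagged, never silent. The clade
age is height × 16,569 × years-per-substitution. Masked sites are excluded
from the likelihood but **not** from the genome length used in the clock
conversion — the sources are silent here, and keeping the full length keeps
the clock constant interpretable genome-wide. Confidence intervals come
from the profile likelihood on the clade-root height (1.92 log-unit drop,
re-optimizing all other heights); when no bracket exists the
curvature-based normal interval is substituted and flagged. The profile CI
is verified against a grid search to within 1%.

Model choice uses BIC = −2 logL + k log(n_sites), with k counting free
model parameters (base frequencies are empirical, counted as 3 where free)
plus branch lengths. On data simulated under JC69, JC69 outranks TN93 in
≥90% of replicates.

## From mutations to years

The default clock converts one whole-mitogenome substitution to 3,624
years, linearly. Purifying selection makes young clades look faster; the
published correction is distributed as an external calculator whose
coefficients are not printed in the text we implement from, so the
correction here is a pluggable monotone mapping loaded from a two-column
table (substitutions → years), anchored at (0, 0), interpolated linearly
and extended linearly beyond its last row. All internal validation uses the
uncorrected linear clock.

Cross-method consensus is the intersection of CI endpoints — commutative,
associative, idempotent, and flagged when empty. Which estimates enter the
consensus is the caller's choice; the pipeline defaults to ρ and ML, as the
Bayesian machinery of the original workflow is out of scope here.

## Route attribution

Route attribution is an input heuristic, not an inference: a table maps
haplogroups to northern/southern/intrusive, unlisted haplogroups inherit
the nearest listed ancestor's route through the reference tree, and
region-specific overrides express context-dependent calls (e.g. a
haplogroup intrusive in Australia but a founder in New Guinea). Intrusive
samples are excluded from the denominator of the route fractions but
reported both as counts and as a percentage of the region total, since the
published summaries use both conventions. Display percentages round
half-up; raw fractions are retained in machine output.

## The simulator, and what validation shows

The coalescent generator draws waiting times at rate k(k−1)/2 per N
generations (haploid N, the female effective size), with constant,
exponential-growth and piecewise-constant demographies, plus an exact star
genealogy for expansion scenarios. Generation time defaults to 25 years —
a free parameter needed to tie coalescent units to the clock, not something
our sources fix. Mutations are Poisson per branch at the clock rate, with
positions drawn proportional to per-site rates; hotspot positions default
to a ×20 multiplier and remain eligible even when masked downstream, so the
benefit of masking is itself testable. A single seeded RNG drives each run
and the seed is recorded in every output bundle.

Validation sizes were chosen to keep the default test run within a few
minutes on one CPU: the coalescent mean-TMRCA check uses 5,000 replicates
against 2N(1 − 1/n); end-to-end ρ-dating coverage uses 200 star clades of
n = 50 at a true age of 60,000 years (observed coverage ≈ 0.93–0.97,
consistent with the nominal 0.95); the parsimony oracle comparison uses 200
homoplasy-free instances of ≤6 haplotypes; ML height recovery is checked at
reduced design (8-tip clades, 8 replicates) against its Monte-Carlo error.

What this does **not** show: the simulator emulates the statistical
structure the estimators assume — clean alignments, a strict clock, no
rate-class misspecification beyond the hotspot multiplier, no
recombination (true for mtDNA), no sequencing error, NUMTs, or ancient-DNA
damage. Passing tests demonstrate that the estimators are correctly
implemented and calibrated under their own model, not that real settlement
dates are unbiased: real-data accuracy still hinges on the mutation-rate
calibration, purifying-selection correction, and sampling representativity,
which are inputs here, not outputs.

## Known limitations

* The greedy parsimony construction is not guaranteed optimal under heavy
  homoplasy; the oracle bounds it on small instances only.
* Profile-likelihood intervals re-optimize nuisance heights by coordinate
  sweeps; on large trees this is slow, and the pipeline's ML stage is
  intended for clade-level, not dataset-level, trees.
* The pairwise aligner targets near-complete mitogenomes; it is not a
  read mapper, and structural variants beyond simple indels are out of
  scope.
* Bayesian dating and skyline reconstruction are deliberately excluded;
  the consensus operation accepts any estimate list, so externally
  computed intervals can be intersected with the in-package methods.
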