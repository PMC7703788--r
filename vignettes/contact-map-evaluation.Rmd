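---
title: "Evaluating and integrating residue-residue contact predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating and integrating residue-residue contact predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactlens)
```

## The problem

A residue-residue contact map is the coarsest useful summary of a protein
fold: an `L x L` binary matrix marking pairs whose C&beta; atoms sit
closer than 8.0 &Aring; in the native structure (C&alpha; for glycine).
Modern predictors output a *probability* map instead, estimated from
coevolutionary signal in a multiple sequence alignment (MSA) of the
target's homologs. Four questions then recur in any analysis of such
predictors, and this package implements the machinery for all of them:

1. **How much evolutionary information does the MSA really carry?**
   Raw sequence counts overstate depth because databases are redundant.
2. **Which regions of the target are starved of homologs?** A domain
   under-represented in the full-length alignment is better re-searched
   on its own, predicted separately, and merged back.
3. **How good is a predicted map?** CASP-convention ranked precision,
   coverage, ROC/AUC and false-positive geometry, by sequence-separation
   band.
4. **How far can a convolutional predictor "see"?** The receptive field
   of its stacked filters bounds the contact-contact correlations it can
   exploit.

## Effective sequence count (Neff)

Sequence weighting collapses redundant alignment rows. Row $i$ receives
weight $w_i = |\{j : \mathrm{id}(i,j) \ge 0.62\}|$, counting itself, and

$$ N_\mathrm{eff} \;=\; \sum_{i=1}^{N} \frac{1}{w_i}. $$

An alignment of $N$ identical rows has $N_\mathrm{eff} = 1$; $B$ mutually
dissimilar families of identical rows give exactly $B$. The 62% identity
threshold is the conventional redundancy level for coevolution inputs.

Sequence identity itself is not standardised, so the denominator is a
documented choice: by default we count matches over columns where at
least one of the two rows has a residue, which penalises coverage
differences (a row that only covers half the target cannot be 100%
identical to it). The alternative `denominator = "alignment_length"`
normalises by all `L` columns and is exposed for sensitivity checks.
Gap-vs-gap columns carry no information and are excluded; `X` is treated
conservatively as matching nothing. Domain-level Neff slices the
domain's columns out of every row first (`extract_domain_msa()`),
dropping rows left entirely gapped: they contribute no signal and would
make pairwise identity undefined.

```{r neff}
aln <- gen_msa(msa_recipe(60, data.frame(size = c(10, 10, 10), mutation = 0),
                          seed = 1))
compute_neff(aln)   # three mutation-free blocks -> 3 effective sequences
```

## Ab initio hard domains from coverage

The per-column **coverage profile** counts rows with a residue at each
query position. Using the *median* coverage as a cutoff, a **hard
domain** is a maximal run of at least 30 consecutive positions whose
coverage is *strictly* below the cutoff. Strictness matters: a flat
profile has every position at the median and yields no domains, which is
the sensible degenerate answer. The 30-residue floor is the smallest
fragment worth re-searching as an independent domain.

Two deliberate choices: the even-length median is the mean of the two
central order statistics (comparisons remain well-defined even when it
is fractional), and no smoothing is applied to the profile. Real
profiles occasionally poke above the cutoff for a residue or two inside
an otherwise starved region; the `bridge` parameter can merge runs
separated by at most that many above-cutoff positions, but it defaults
to 0 so the reported segments are exactly the strict runs. Detected
segments never overlap by construction; `plan_domain_prediction()`
guards hand-edited segment lists with an explicit overlap error.

## Domain-map integration

When a domain has been re-aligned and re-predicted, its map is merged
into the full-length map by **probability replacement**: for every pair
with both residues inside the domain, keep the larger of the two
probabilities. This is an elementwise maximum over the domain block, so
the merge never decreases any entry, is idempotent, and commutes across
disjoint domains -- properties the test suite asserts directly. A
one-residue overlap between reported segments is therefore immaterial.

## Multi-threshold maps as a distance distribution

Predicting maps at thresholds 6, 7.5, 8, 8.5 and 10 &Aring; gives each
residue pair a discretised CDF of its distance. Independently trained
per-threshold models need not be monotone, so `monotone_project()` takes
the running maximum across increasing thresholds -- the smallest
pointwise correction that restores a valid CDF, and an idempotent one.
Successive differences plus the tail $1 - P(d < 10)$ then give the
probability mass on the intervals
$(0,6], (6,7.5], (7.5,8], (8,8.5], (8.5,10], (10,\infty)$, which sum to
1 by construction and invert back to the CDF by cumulative summation.
`interval_distribution()` refuses non-monotone stacks rather than
silently producing negative masses.

## CASP-convention evaluation

Pairs are banded by sequence separation: short 6-11, medium 12-23, long
&ge; 24. Within a band, predicted pairs are ranked by probability; the
top $k = \lfloor L \cdot f \rfloor$ (minimum 1) are assessed for
$f \in \{1/5, 1/2, 1, \dots\}$. Because top-$k$ precision is sensitive
to order at tied scores, the tie-break is fully deterministic:
probability descending, separation descending, then `i` ascending.

Three conventions follow CASP assessor practice. Pairs scored exactly 0
are treated as not submitted: they never enter the top list, and the
precision denominator is the number of pairs actually assessed (so a
predictor that reproduces the native map exactly scores 100% at every
fraction, even when a band holds fewer than $k$ contacts). A map with no
positive pair in a band is assessed on the full tie-broken list, so a
null predictor scores the band's contact density rather than erroring.
Pairs with missing native distances are excluded from ranking -- skipped
and replaced by the next-ranked pair -- rather than counted as wrong.

Domain-restricted evaluation slices the square submatrix over the
segment; since $|i-j|$ is invariant under a common offset, pairs keep
their full-chain separation band. AUC is computed by the rank-sum
(Mann-Whitney) identity with mid-ranks at ties, equal to the trapezoidal
area under the empirical ROC; the tests cross-check it against both
`wilcox.test()` and pROC. The one-contact-per-residue filter is the
greedy scan of the ranked list. The top-list size behind the mean
false-positive distance is exposed as a parameter defaulting to
$\lfloor L/5 \rfloor$.

## Receptive fields

For stride-1 convolutions with odd kernel $k$, each layer widens the
input region influencing one output cell by $k - 1$, so $n$ layers see a
square of side $1 + n(k-1)$: 29 for the reference 7-layer, 5&times;5
model and 53 for the 13-layer two-stage composition. The tests verify
the closed form against exhaustive dependency tracing through an
explicit convolution cascade. `run_two_stage()` orchestrates the flow --
five per-threshold predictors, then a final 8 &Aring; predictor fed the
stack plus the original features -- with predictors injected as
callables, validated for shape and range, and symmetrised as
$(M + M^\top)/2$. Whether stage 2 consumes raw or monotonised stage-1
maps is a genuine design unknown, so both are exposed via `monotonise`
(default projects).

## What the synthetic generators emulate -- and what they do not

`gen_msa()` builds alignments from redundancy blocks (rows mutated from
a block consensus at a stated rate) and coverage dips (a stated fraction
of rows gapped over an interval). Mutation-free blocks draw their
consensi from disjoint sub-alphabets, guaranteeing cross-block identity
0 and hence Neff equal to the block count -- a closed form the tests
exploit. Dips of `frac = 0.9` over 40 columns in a 100-row alignment
leave exactly 10 covering rows there, planting a recoverable hard
domain. There is no phylogeny and no substitution model, so these MSAs
validate the *weighting and parsing arithmetic*, not robustness to real
evolutionary structure.

`gen_chain()` produces toy 3D chains: an ideal helical trace (2.3 &Aring;
radius, 100&deg; turn, 3.8 &Aring; virtual bond) or a self-avoiding
random walk with 3.8 &Aring; steps and a 3.0 &Aring; clash floor.
Unconfined walks almost never form long-range contacts, so the walk is
confined to a sphere of radius $3.8 \cdot L^{1/3}$ &Aring; -- roughly
globular protein packing density -- which yields realistic contact
densities in all three separation bands (typically 3-10% long-range at
L = 80). These chains have protein-like geometry but no secondary
structure, so passing tests demonstrate metric correctness, not
predictor quality on real folds.

`gen_predictions()` emulates a probabilistic predictor as
`clip(tp_signal * truth + N(0, noise_sd), 0, 1)`, symmetrised. The
clipping sends about half of the non-contact scores to exactly 0, which
matches the CASP habit of submitting only confident pairs. All three
generators are pure functions of their recipes: the seed is mandatory
and the caller's RNG stream is restored afterwards.

## Numerical choices and problem sizes

Probabilities are compared exactly where the algebra is exact (merging,
projection, interval sums) and to 1e-6 across text round-trips, matching
the 6-decimal RR writer. Contact calls use a strict `<` at the
threshold. The test suite runs the brute-force Neff oracle on 200 random
alignments (N &le; 50, L &le; 100), the run-enumeration oracle on 500
random profiles (L &le; 500), 100 planted-dip recoveries, 100 random
merge triples, 20 chains for the perfect-precision sweep and 200
random-score replicates for the precision-vs-density check -- sizes at
which every oracle is exhaustive yet the whole suite completes in well
under a minute on one core.

## Known limitations

- Identity weighting is O(N&sup2;L) in plain R; alignments beyond a few
  thousand rows will be slow. The weighting is exact, not sampled.
- The hard-domain parser reports strict below-median runs; boundary
  conventions differing by one residue from other tools' inclusive
  reporting are expected and harmless under max-merging.
- No training machinery ships with the two-stage orchestrator;
  predictors are injected functions.
- The synthetic chains carry no secondary structure, so band-specific
  contact statistics (e.g. the short-range density of helices) should
  not be read as protein-realistic.
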