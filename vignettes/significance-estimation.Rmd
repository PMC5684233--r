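---
title: "Significance estimation for spectral-library annotation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Significance estimation for spectral-library annotation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decoyFDR)
```

## The problem

Untargeted metabolomics annotates small molecules by matching acquired
MS/MS spectra against reference spectral libraries with cosine-family
similarity scores. A score alone carries no statement about statistical
reliability: without an estimate of the false discovery rate (FDR), the
score threshold and minimum-matched-peaks settings that decide which
annotations to report are guesswork. decoyFDR implements two routes to
significance estimates for spectral-library search:

1. **Separated target–decoy estimation.** Queries are searched once
   against the target library and once against a decoy library that
   models the null (a chance match). For a score threshold $t$,

   $$\widehat{\mathrm{FDR}}(t) = \mathrm{PIT} \cdot \frac{D(t)}{T(t)},$$

   where $T(t)$ and $D(t)$ count target and decoy best-hits with score at
   least $t$, and PIT (percentage of incorrect targets) is the fraction
   of the *unthresholded* target hit list that is wrong. The q-value of a
   hit is the smallest FDR at which it is still reported — the running
   minimum of $\widehat{\mathrm{FDR}}$ over thresholds at or below the
   hit's score.

2. **Empirical-Bayes mixture.** Best-hit scores $s \in (0, 1]$ are
   modeled as $\pi_0 f_0(s) + (1-\pi_0) f_1(s)$ with a Gamma false
   component $f_0$ on the score itself and a *mirrored* Gamma, Gumbel or
   Weibull true component $f_1$, i.e. the named density evaluated at
   $1 - s$ so its mode sits at high scores. The posterior error
   probability of a hit is
   $\mathrm{PEP}(s) = \pi_0 f_0(s) / (\pi_0 f_0(s) + (1-\pi_0) f_1(s))$,
   the FDR above a threshold is the mean PEP of the hits above it, and
   $\pi_0$ doubles as the PIT estimate used by the target–decoy route
   (for a normalized component density, the area under the scaled false
   component is exactly the mixture weight).

Because small molecules cannot be "reversed" or "shuffled" the way
peptide sequences can, the decoy library is the hard part. Three
constructions are provided, all of which conserve, per target spectrum,
the precursor mass, the number of fragment peaks and the intensity
multiset — so for any precursor window the same number of target and
decoy spectra are eligible by construction:

- **naive** — fragment masses drawn uniformly from all fragment ions of
  the library (a baseline; its calibration failure is itself a result);
- **spectrum-based** — fragments added iteratively, conditional on the
  ions already in the decoy: each added ion pulls five candidate ions
  from the library spectra containing it within 5 p.p.m., and the next
  decoy ion is drawn from that growing candidate set, which mimics
  fragmentation cascades and keeps fragment-rich spectra from dominating;
- **fragmentation-tree re-rooting** — the annotated fragmentation tree
  of the target keeps its structure and all neutral losses, a *new* root
  is selected (never the original root, which would reproduce the true
  spectrum), the new root takes the precursor-ion formula, and all other
  formulas are recomputed by subtracting losses along the re-rooted
  edges. Subtrees whose formulas turn chemically impossible (a negative
  element count), or would duplicate another fragment's formula, are
  re-grafted onto a uniformly chosen valid node. The new root is drawn
  with relative probability $1/(n+1)$, where $n$ is the number of edges
  that would need re-grafting — computed by simulating the propagation
  once per candidate root and counting maximal invalid subtrees.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| fragment match tolerance | max(10 p.p.m., 2 mDa) | rel./abs. | the permissive combination; at low fragment masses 10 p.p.m. is tighter than instrument accuracy, so the absolute floor governs |
| decoy separation | 5 p.p.m. | rel. | two decoy ions closer than this would merge into one observed peak |
| precursor window | 10 p.p.m. | rel. | high-resolution instruments; identical for target and decoy searches |
| scoring variants | cosine / massbank / gnps | — | weights: intensity; mass² · intensity^0.5; sqrt(intensity) with precursor-shifted alignment. Documented conventions behind a strategy parameter, not byte-level reproductions of any production scorer |
| min matched peaks (search) | 6 | count | common reporting default; the FDR benchmark harness uses 2, the permissive end of the useful range, because a single "matched peak" is just the precursor ion and carries no spectral evidence |
| EM tolerance / max iterations | 1e-6 / 500 | log-lik. | see numerical notes |

Peak alignment is an exact maximum-weight bipartite matching on the
tolerance-limited candidate-pair graph (components solved exhaustively; a
greedy fallback guards degenerate components with more than 22 candidate
pairs). Exactness makes the scorer order-independent and lets a
brute-force enumeration serve as its test oracle.

## The synthetic benchmark

Real reference libraries cannot ship with the package, and calibration
can only be judged when every query's true identity is known. The
generator therefore builds a self-contained world in which the decoy
constructions face the same statistical task as on real data:

- **Compounds** are molecular formulas assembled from a small core plus a
  multiset of standard neutral losses (H2O, NH3, CO, CH2O, CO2, ...).
  Fragments are partial-loss subtractions, so distinct compounds share
  fragment ions exactly as real spectra of related compounds do.
- **Trees** are attached by a cascade-biased process (probability 0.6 of
  extending the most recent fragment, otherwise branching uniformly),
  yielding the chain-heavy topologies of sequential fragmentation rather
  than the star-like trees uniform attachment would give. Tree topology
  matters: re-rooting a star nests every fragment one loss deeper, while
  re-rooting a cascade is statistically symmetric with an independent
  re-fragmentation — which is what the null model needs.
- **Queries** come in three classes, each query its own compound (drawn
  without replacement per class, as in a cross-library evaluation):
  perturbed copies of library spectra (true hits; mass jitter uniform in
  ±5 p.p.m., lognormal intensity noise with sdlog 0.3, 10% peak dropout,
  0–5 uniform noise peaks), *isomer near-misses* (a library spectrum with
  30% of its peaks shifted by a random loss mass, the precursor kept —
  a structurally similar isomer absent from the library), and *nulls*
  (an independent re-fragmentation of a library compound's formula:
  same precursor, different fragmentation).
- The default evaluation fixture uses 400 library compounds and 500
  queries (50% true, 10% isomer, 40% null); the p-value uniformity check
  uses 200 compounds and 200 null-only queries. These sizes keep the
  whole suite at desk scale while leaving enough hits (~350–500) for the
  mixture fit, which refuses fewer than 50 scores.

What the generator does **not** emulate: adducts other than [M+H]+,
isotope patterns, chimeric spectra, retention-time structure, instrument-
specific noise, and libraries with many isobaric entries per precursor
window (here precursor windows are almost always singletons). Passing
tests therefore demonstrate the statistical machinery is correct and
calibrated under a clean, known null — not that any particular real
library will be as well-behaved.

Because every benchmark compound is built additively (root = core + sum
of its losses), every re-rooting of a benchmark tree is chemically valid
and the re-grafting path is exercised by dedicated hand-built fixtures
rather than by the generator.

## Numerical choices

- **EM.** Deterministic method-of-moments initialization (false component
  from the lower score half, mirrored true component from the upper
  half, $\pi_0 = 0.5$); component updates are weighted maximum-likelihood
  fits by Nelder–Mead started from the current parameters and kept only
  if they improve the weighted likelihood, so the observed-data
  log-likelihood is non-decreasing up to numerical tolerance; scores are
  clamped to [1e-6, 1 − 1e-6] before fitting because the mirrored
  densities are evaluated at $1 - s$; when no family is forced, all
  three are fitted and the best log-likelihood wins.
- **Ties.** When target and decoy hits tie in score, the decoy sorts
  first (conservative: the estimated FDR at that score is maximized);
  threshold counts use ≥, which makes the estimate independent of the
  within-tie order. Search ties between references break towards the
  lexicographically smaller identifier, for reproducibility.
- **p-values.** Strictly-greater counts (a score above every decoy has
  p = 0); an add-one Laplace variant is exposed for users who need
  strictly positive p-values.
- **Degenerate inputs.** Empty target hit lists warn and return empty
  curves; the empirical-Bayes fit refuses fewer than 50 scores with a
  pointer to the target–decoy route; noise-filtered spectra that are
  empty or precursor-only are flagged for discard and skipped (with
  their trees) by the library-level filter.
- **Seeds.** Every stochastic operation sits behind an explicit seed;
  seeded operations save and restore the caller's RNG state.

## Design decisions that were genuinely open

- *Collision-energy merging*: peaks within the matching tolerance are
  combined keeping the mass of the most intense member and the **maximum**
  intensity. A sum would inflate relative intensities and distort the
  ≥5-peaks-above-2% inclusion filter.
- *Decoy intensity assignment* (naive and spectrum-based): drawn masses
  are sorted and receive the original spectrum's intensities in mass-rank
  order, preserving the intensity-vs-rank profile along with the
  multiset.
- *Naive-method discard rules*: the precursor ceiling and the 5 p.p.m.
  separation are applied to the naive construction as well, so all three
  methods are comparable.
- *Candidate set persistence* (spectrum-based): the candidate set
  persists and grows across iterations rather than being rebuilt per
  step.
- *Original root exclusion* (tree-based): re-rooting at the original
  root would return the noise-filtered target spectrum itself — a decoy
  identical to a true spectrum can absorb true-hit scores into the null
  model, so only genuinely new roots are candidates.
- *Re-graft exhaustion*: after 100 uniform attachment attempts a subtree
  is dropped and logged; peak-count parity is then best-effort and the
  drop is visible in the build report.
- *PIT source*: the pipeline estimates PIT as the fitted $\pi_0$ when at
  least 50 target hits are available, else it falls back to the
  conservative PIT = 1 (the classical separated estimator).

## Known limitations

- High-scoring wrong hits caused by structurally similar isomers are not
  represented in any decoy library — decoys model *random* matches, not
  near-identical chemistry. Estimated q-values therefore undershoot true
  q-values in the region those hits occupy; with the benchmark's 10%
  isomer queries this bias extends well beyond the smallest q-values,
  and the calibration check measures exactly how far. On data without
  such contamination the tree-based decoys track true q-values closely;
  the naive decoys never do. Users should treat very small q-values as
  optimistic whenever isobaric/isomeric compounds are plausible.
- The empirical-Bayes route presupposes its parametric component shapes;
  the mixture weight is only as good as the Gamma fit to the false score
  distribution. The target–decoy route makes no such assumption and is
  the default.
- Fragmentation trees are consumed, not computed: the greedy toy
  annotator exists to build fixtures and benchmarks and is not a
  substitute for a real tree engine.
- Only positive ion mode and [M+H]+ ionization are modeled.
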