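---
title: "Inferring reproductive pathways from single-seed flow cytometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring reproductive pathways from single-seed flow cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcss)
```

## The biological model

In gametophytic apomicts, seeds can arise by two routes that leave
distinct cytological fingerprints in the mature seed. Regular sexual
reproduction combines a reduced egg cell (ploidy f) with one sperm
(ploidy m), and the second sperm fertilizes the binucleate central cell:
the embryo carries f + m chromosome sets and the endosperm 2f + m.
Gametophytic apomixis skips both meiosis and egg fertilization: the embryo
is a clone of the mother (ploidy equal to the maternal x), while the
pseudogamous endosperm still requires fertilization of the (unreduced)
central cell by one or two sperm, giving 2x + m or 2x + 2m.

The flow cytometric seed screen (FCSS) observes exactly these dosages. On
a linear fluorescence scale the endosperm/embryo peak ratio — the *peak
index* — is (2f + m)/(f + m) < 2 for any fertilized reduced egg (1.5 when
f = m) and at least 2 for a parthenogenetic embryo with pseudogamous
endosperm. Together with the embryo's DNA ploidy, called against reference
individuals, the index separates five outcomes: `SEXUAL`, `APOMICTIC`,
fertilization of an unreduced egg (`L_UNREDUCED_EGG`, embryo above the
maternal ploidy at a low index), apomixis from a doubled embryo sac
(`Z_DOUBLED`, embryo at twice the maternal ploidy), and the two
non-informative classes `UNKNOWN` (no distinct endosperm signal) and
`FAILED` (no signal).

### Assumptions

* Fluorescence is proportional to genome copy number (linear gain, no
  fluorochrome base bias): the calibration is a least-squares slope
  through the origin over the reference ratios. This is a deliberate
  simplification; base-composition effects of AT-selective stains are not
  modelled.
* The central cell is binucleate (two fused polar nuclei), so the female
  endosperm dosage is twice the embryo-sac ploidy.
* Where two sperm act, they carry equal genome numbers. The sexual
  decomposition f = endosperm − embryo, m = embryo − f is underdetermined
  without this; the single-sperm-to-endosperm variant is available via
  `run_config(single_sperm_sexual = TRUE)` for sensitivity analysis.
* For apomictic seeds no attempt is made to decide whether one or two
  sperm fertilized the central cell — the dosages are observationally
  confounded with heteroploid pollen, so only the total paternal endosperm
  contribution is reported.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `pi_boundary` | 2.0 | peak-index | theoretical boundary between fertilized-reduced-egg and pseudogamous dosages |
| `maternal_match_tol` | 0.12 | relative | half the relative spacing of adjacent cytotypes at the tetraploid level (4x vs 5x = 25%) |
| `doubled_match_tol` | 0.12 | relative | same logic applied at 2× the maternal ploidy |
| `near_boundary_band` | 0.1 | peak-index | calls with an index within this band of the boundary are flagged, since measurement error there is decisive |
| `ploidy_tolerance` | 0.05 | relative | maximum deviation from a grid point for a ploidy call; grid `{2, 2.5, …, 12}` in half-integer steps to express odd gametic dosages |
| `mc_reps` | 10 000 | replicates | permutation replicates of the association test |
| `shannon_base` | e | — | natural-log Shannon index; the base is conventional and configurable |
| Cruden boundaries | 4.7 / 27.7 / 168.5 / 796.6 | pollen per ovule | ordered class boundaries between cleistogamy, obligate autogamy, facultative autogamy, facultative xenogamy and xenogamy |

The half-integer ploidy grid intentionally extends beyond the reference
range (to 12x) so that, e.g., a doubled pentaploid embryo (10x) measured
against references up to 7x still receives a call.

## Classification rules in full

`classify_pathway()` applies, in order: (1) embryo within
`doubled_match_tol` of twice the maternal ploidy → `Z_DOUBLED` (this takes
precedence because a doubled embryo also fails every other match); (2)
index < boundary and embryo within `maternal_match_tol` of maternal →
`SEXUAL`; (3) index < boundary and embryo above maternal beyond tolerance
→ `L_UNREDUCED_EGG`; (4) index ≥ boundary and embryo matching maternal →
`APOMICTIC`; otherwise `UNKNOWN` with an `unclassifiable` flag. Ambiguous
seeds are labelled, never guessed.

Two genuinely open points were resolved as follows:

* **Distinct endosperm peaks.** How an embryo-only seed is distinguished
  from one whose endosperm peak overlaps the embryo peak is an instrument
  judgement; the histogram route uses an explicit window — the next peak
  above the embryo counts as endosperm only if the ratio lies in
  (1.2, 8] — and flags `endosperm_unresolved` otherwise.
* **Unreduced-egg vs intercytotype seeds.** An embryo above the maternal
  ploidy at a low peak index is equally consistent with an unreduced egg
  fertilized by a regular sperm and with a reduced egg fertilized by a
  heteroploid sperm. Both receive the `L_UNREDUCED_EGG` label. The
  gene-flow screen (below) therefore re-derives the male contribution of
  such seeds under the fertilized-reduced-egg algebra
  (m = 2·embryo − endosperm), because heteroploid pollen is precisely what
  it screens for; `include_unreduced = FALSE` restores the strict
  `SEXUAL`-only reading.

A pathway whose dosage identities cannot be satisfied (a contribution
below −0.25x) marks the seed `inconsistent_contributions` and downgrades
it to `UNKNOWN` in batch runs; the scalar API raises an error instead.
Small negatives from measurement noise are clipped to zero and flagged.

## The association test

Whether sexuality and apomixis co-occur within maternal plants is tested
by permutation: the mode labels of all informative seeds are pooled and
reassigned at random while preserving each plant's number of informative
seeds, conditioning on both margins of the plant-by-mode table. The
statistic is the percentage of sexual-bearing plants that also carry an
apomictic seed (and vice versa); the one-sided p-value
(1 + #{null ≤ observed})/(reps + 1) asks for a *deficit* of mixing and
cannot be zero (add-one correction). An unconditional binomial null is
available behind `null = "binomial"`. The statistic is discrete with
substantial mass at full mixing, so null p-values are conservative rather
than exactly uniform — the test suite checks that rejection never exceeds
the nominal level and that a 3-plant toy instance agrees with exhaustive
enumeration of all 20 label assignments.

The exclusive-mode algebra connects the test to the sampling design: under
random assignment with per-seed probability p, a plant with n sampled
seeds is single-mode with probability p^n, and an observed single-mode
fraction q implies a per-seed probability q^(1/n). The two functions are
exact inverses and are tested as such.

Irregular seeds count as sexual fertilization (`L`) and apomictic
development (`Z`) respectively in the mode matrix, each toggleable, since
how such seeds entered the published randomization is not stated.

## Population, breeding and pollen statistics

Cytotype diversity is the Shannon index over a population's cytotype
composition (natural log; computed via `vegan`). The gene-flow screen
regresses the population mean male genomic contribution of tetraploid
low-index seeds on that diversity; aggregation to population means is the
default because the design's degrees of freedom are population-level, with
a per-seed variant behind a flag. The simulator only delivers heteroploid
pollen from cytotypes actually present in a population, so pure
populations sit at the regression's origin and the screen has genuine
power against mixing.

Seed set under selfing vs outcrossing is modelled as Poisson with a log
link (`stats::glm`, which is iteratively reweighted least squares) with a
cluster-robust (sandwich) covariance over pollen-receptor plants in place
of the random intercept a mixed model would use. The scientific claim the
model supports — outcrossed flowers set far more seed than selfed ones —
is a fixed-effect contrast robust to this substitution, and the two-group
estimate equals the closed-form log rate ratio exactly. Pollen viability
is compared among cytotypes by binomial (logit) regressions on proportions
pooled per cytotype-within-population, weighted by the number of
individuals pooled; the model is refitted with each cytotype as baseline
and pairwise p-values are Bonferroni-multiplied by the number of unordered
pairs (all pairs, the conservative family). Because the weights count
individuals rather than grains, statistical information scales with plants
— separating cytotypes whose true viabilities differ by under ~0.5 logits
needs hundreds of individuals per cytotype, which the test suite
acknowledges by checking the large contrasts.

The pollen/ovule classifier treats the configured values as ordered class
boundaries: a ratio falls in the class above the highest boundary it
reaches, a ratio exactly on a boundary is promoted and flagged, and the
top class is unbounded.

## The simulator

`simulate_study()` draws, per seed: a pathway from the maternal cytotype's
probabilities; gametic chromosome numbers on a half-integer grid (meiotic
disturbance is Gaussian noise before rounding — aneuploidy coarse-grained
to 0.5x, the resolution FCSS supports); a pollen donor (own cytotype, or
another cytotype present in the population at `intercytotype_rate`); and
the resulting true embryo/endosperm dosages per the pathway algebra.
Fluorescence observables are Gaussian peaks at `gain`·x with configurable
CV; tabulated peak means carry the sampling error of an empirical mean
over `events_per_peak` nuclei (CV/√n), which is also what the histogram
route yields after peak extraction. `table2_preset()` fixes the design at
the motivating study's: 115 plants in 22 populations over cytotypes 4x–8x,
3–5 seeds per plant, per-cytotype pathway probabilities equal to the
published frequencies scaled by the 354/432 informative-seed yield. The
preset's population layout spreads plants over mixed and pure populations
in proportion to the per-cytotype seed tallies; it emulates the study's
*design*, not its exact (unpublished) population compositions.

What the simulator does **not** emulate: debris and doublets (the
`min_events`/`max_cv` filters and an optional uniform background stand in
for gating), endosperm-viability selection (seeds are generated, not
selected), spatial pollination kernels, and fluorochrome base bias.
Passing tests therefore demonstrate correctness of the inference given the
dosage model and Gaussian peaks — not robustness to instrument artefacts.

## Numerical choices

* Peak extraction smooths with a centred moving average (default 5 bins),
  takes local maxima above 5% of the tallest smoothed bin, and refines
  each candidate by a Gaussian least-squares fit over ±2 initial widths
  (moment estimates as fallback when the fit fails). Near-duplicate fits
  converging on one peak are merged.
* The calibration slope is the exact one-parameter least-squares solution
  Σxr/Σx², so calling the calibration points themselves returns their
  ploidies with zero residual when the calibration is proportional.
* Ties at the peak-index boundary go to the ≥ side (apomictic region);
  calls within 0.1 of the boundary carry a `near_boundary` flag.
* The regression F statistic satisfies F = r²(n−2)/(1−r²) identically;
  its p-value is the upper F(1, n−2) tail.
* Degenerate inputs: empty histograms yield empty peak lists (the caller
  decides "failed"); an all-one-mode seed pool makes the association test
  abort as undefined; the pipeline converts per-seed inconsistencies to
  flags but aborts on stage-level failures, naming the stage.

## Problem sizes in the test suite

The suite simulates at the study's own scale (432-odd seeds, 115 plants)
for end-to-end checks; calibration properties use 500 trials at 99–199
permutation replicates; the enumeration oracle runs on a 3-plant instance
with 20 distinct assignments; power properties use 40 trials of an
8-population design (gene flow) and 10 replicate pollen studies. These
sizes give stable verdicts at fixed seeds while keeping the default run in
tens of seconds.

## Known limitations

* Absolute genome size (pg) and base-bias correction are out of scope; all
  ploidies are relative DNA ploidies against the reference calibration.
* The equal-sperm assumption biases the sexual decomposition when sperm
  are truly unequal; the bias moves f and m in opposite directions while
  preserving their sum (conservation is exact by construction). At fixed
  embryo ploidy the estimated f and m are perfectly anticorrelated — a
  mathematical artefact of m = 2·embryo − endosperm worth remembering
  before interpreting correlations between the contributions.
* The mixed-model variance structure of the seed-set experiment is
  approximated by cluster-robust errors, not replicated exactly.
* The Monte Carlo test conditions on observed margins; rare-mode studies
  (few informative plants on one side) have little power and wide p-value
  granularity.
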