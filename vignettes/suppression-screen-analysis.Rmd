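---
title: "Methods: scoring chemical suppression screens in SDH-loss yeast"
author: "suppscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring chemical suppression screens in SDH-loss yeast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suppscreen)
```

## The assay and its statistical model

Loss of succinate dehydrogenase (SDH) causes succinate to accumulate.
Succinate competitively inhibits 2-ketoglutarate (2KG)-dependent
dioxygenases, so the succinate:2KG concentration ratio — not either
metabolite alone — governs dioxygenase activity. In yeast, the sulfonate
dioxygenase Jlp1p converts isethionate (ISE) into usable sulfite; when ISE
is the sole sulfur source, growth reports Jlp1p activity directly. SDH-loss
strains (*sdh1∆*, *sdh2∆*) grow poorly on ISE because excess succinate
inhibits Jlp1p, while a *jlp1∆* strain barely grows at all. Ammonium
sulfate (AS) medium, which bypasses Jlp1p, is the control sulfur source.
A compound that restores SDH-loss growth **only on ISE** and **only in the
SDH-loss strains** is a candidate suppressor of the downstream consequences
of succinate accumulation.

`suppscreen` implements the full numeric path of such a screen: plate data
models and CSV I/O, the screening-window statistic and hit calling,
dose-response validation with selectivity classification, differential
protein abundance between strains, and the succinate:2KG ratio analysis —
plus a synthetic-data generator that plants known truth so every stage's
recovery can be measured.

## The screening-window score

For a well with experimental mean $\mu_p$ and standard deviation
$\sigma_p$ against negative-control mean $\mu_n$ and standard deviation
$\sigma_n$ (sample s.d., $n-1$ denominator throughout):

$$ z = 1 - \frac{3(\sigma_p + \sigma_n)}{|\mu_p - \mu_n|}. $$

The statistic is bounded above by 1 (zero-noise ceiling), positive exactly
when the two distributions are separated by three standard deviations of
each, invariant under a common positive rescaling of all four inputs, and
undefined when $\mu_p = \mu_n$ — `zscore()` returns `NA` there rather than
$-\infty$. Because each screened compound occupies a *single* well, its
standard deviation does not exist; the plate's vehicle-control s.d. is
substituted (`sigma_p := sigma_n`, the *mock-s.d. rule*). Controls are
pooled per plate, never across plates, since vehicle wells sit on every
plate.

Hit calling (`call_hits()`) counts timepoints with $z > 0$ **and**
$\mu_p > \mu_n$. The direction requirement is a deliberate choice: $z$
uses an absolute separation, so a strong growth *inhibitor* also scores
$z > 0$; requiring stimulation keeps inhibitors out of the hit list. A
compound is a hit at `min_positive = 6` of `n_timepoints = 7` — the first
reading is taken at inoculation, where no growth difference can exist yet,
which is why the rule tolerates exactly one failing timepoint. Compounds
whose formulation contains sulfate (an alternative sulfur source that
bypasses Jlp1p entirely) or forms a colored solution (corrupting the
absorbance readout) are excluded regardless of score, with the reason
recorded. Ranking uses the median $z$ across timepoints, descending, ties
broken lexicographically by compound id; the absolute-separation median is
used unchanged, so colored or toxic compounds can rank high while the
`n_positive` and exclusion columns make their nature explicit — mirroring
how colored compounds present as spurious hits in a real screen.

## Growth metrics

* `endpoint_growth()` takes the OD at the latest timepoint at or before
  the 24-h target (falling back to the earliest reading, with a warning,
  if all are later).
* `percent_change()` is $100(t-u)/u$ with first-order (delta-method)
  propagation of independent errors:
  $\mathrm{err} = 100\sqrt{(s_t/u)^2 + (t\, s_u/u^2)^2}$. The propagation
  formula itself is a design choice; tests verify it against a large
  Monte-Carlo sample s.d. to within 5 % relative in the first-order regime
  ($s/\mu \le 0.1$). Sample s.d. is the default spread; an `se = TRUE`
  switch divides by $\sqrt{n}$ for callers that report standard errors.
* `detect_diauxic()` finds the fermentative-to-oxidative growth
  transition: on the centered moving average (3-point window) of the
  first-difference rate, it requires two local maxima at least
  `min_phase_rate` (default 0.02 OD/h) separated by a local minimum below
  half the smaller maximum. Series endpoints count as candidate maxima
  because the observation window can truncate a phase. The statistic sees
  only OD differences, so it is invariant to constant offsets.

## Selectivity classification

`growth_effects()` summarises a validation experiment (4 strains × 2 media
× doses × replicates) into per-cell percent changes. Significance uses the
*protected* Tukey convention: within each medium, a two-way ANOVA
(strain × dose) gates the Tukey HSD comparisons on the strain × dose cell
means, and a cell is significant only when the gate (dose or interaction
term, $p < \alpha$) opens and its own Tukey-adjusted $p < \alpha$. The
protection controls the family-wise error of the eight-cell panel; an
unprotected per-cell test at $\alpha = 0.05$ would mislabel genuine
suppressors as nonspecific through chance positives in unaffected cells.

`classify_selectivity()` then applies the verdict logic, in precedence
order: a significant positive response of *jlp1∆* on ISE means the
compound feeds sulfur downstream of the dioxygenase (`bypass_suspect`);
significant positive responses in both SDH-loss strains on ISE and nowhere
else is `selective_suppressor`; all-negative significance is `toxic`; no
significance is `inactive`; anything else `nonspecific`. The classifier is
dose-agnostic — any tested dose may satisfy the pattern.

## Statistics

`one_way_anova()`, `two_way_anova()`, `tukey_hsd()`, `welch_t()` and
`bh_adjust()` delegate to R's standard implementations (`aov`,
`TukeyHSD`/`ptukey`, `t.test`, `p.adjust`) behind a uniform tabular
interface, with stars rendered as `*` < 0.05, `**` < 0.01, `***` < 0.001.
Choices worth noting:

* Two-way ANOVA accepts only balanced complete designs; unbalanced data is
  a hard error rather than a silent Type-I/II/III sums-of-squares choice.
  The designs this package targets (strain × treatment with equal
  replicates) are balanced by construction.
* Tukey on a two-way design is applied to the cell means
  (`tukey_cells()`), matching the per-panel starring convention.
* Multiple-testing adjustment is Benjamini–Hochberg step-up: the field
  default for proteome-wide testing. BH is *not* idempotent — re-adjusting
  adjusted values can change them — so the tested invariants are the true
  ones: monotone order statistics, never below the raw p, capped at 1.
* Degenerate inputs: when an ANOVA decomposition is numerically all-zero
  (every observation equal), term F values are reported as 0 with p = 1
  instead of 0/0. When both groups of a Welch test are constant, p is 1
  for equal means and 0 otherwise.

## Differential abundance

`differential()` compares two strain groups protein by protein: log2
fold-change of group means, Welch t on log2 abundances, BH adjustment, and
the dual significance rule (adjusted $p < 0.05$ **and**
$|\log_2 \mathrm{FC}| > 1.5$; the adjusted p is used deliberately — it is
the stricter, documented reading). Zeros (proteins undetected in a group)
are floored to half the smallest nonzero abundance in the matrix before
logs, so absence yields a large but finite nominal fold-change; such
proteins carry `floored = TRUE` for auditability, and proteins absent
everywhere are excluded with a warning.

`venn()` partitions two significant sets over a shared universe with exact
inclusion–exclusion. A note on the published partition this mirrors: with
$|A| = 1015$, $|B| = 1068$ and 991 shared, arithmetic forces
$1015 - 991 = 24$ unique to A and $1068 - 991 = 77$ unique to B; prose
that assigns 77 to the first comparison and 24 to the second has those two
labels swapped. The package always reports the arithmetic-consistent
counts. `fc_correlation()` computes Pearson (or Spearman) correlation of
the per-protein fold-changes and flags proteins non-significant in both
comparisons — the gray points of the conventional correlation plot.

## Metabolites

`succ_kg_ratio()` forms the per-sample succinate/2KG ratio and summarises
mean ± s.d. over replicates per strain × treatment; it refuses
relative-quantitation records because cross-metabolite ratios require
commensurate units, and errors (naming the sample) when 2KG is zero.
`strain_fold()` reports per-strain fold changes of means against a
reference strain within each treatment level, and `treatment_test()` runs
the two-way strain × treatment ANOVA with Tukey on cells. Ratios are
scale-invariant; folds of the reference against itself are exactly 1.

## The synthetic-data generator

The generator is first-class, tested code, not a fixture. It emulates the
statistical structure the analysis assumes, with planted ground truth.

**Growth curves.** Noiseless growth is a sum of one or two logistic
terms, `od0 + cap1·logistic(rate1·(t−mid1)) [+ cap2·logistic(rate2·(t−mid2))]`
— the minimal family with an identifiable inter-phase deceleration
(diauxic shift). Noise is additive Gaussian, homoscedastic, truncated at
zero: the simplest model consistent with using technical-replicate s.d. in
the window statistic. Default strain × medium kinetics
(`default_kinetics()`) are calibrated qualitatively: in AS all strains
reach similar 24-h density, with WT and *jlp1∆* diauxic; in ISE the
ordering is WT > *sdh1∆* ≈ *sdh2∆* ≫ *jlp1∆* (near-flat). The SDH-loss
ISE curve is a single fermentative phase with capacity 0.90 OD saturating
early (rate 1.2 h⁻¹, midpoint 1.5 h). That early saturation is a
calibration requirement, not an aesthetic choice: a +15 % capacity
suppressor must separate from 4 vehicle controls at OD noise s.d. 0.01 by
more than six control s.d. at every post-inoculation timepoint for the
6-of-7 rule to recover it reliably, which fixes the product
`magnitude × capacity` (≈ 0.12 OD or more) and forces the capacity to be
expressed well before the 4-h reading. The calibration was checked
numerically against the window statistic before the defaults were frozen.

**Compound effects.** `suppressor`/`toxic` scale capacities by
`1 + magnitude` for target strains and media (suppressors default to
*sdh1∆*/*sdh2∆* on ISE with magnitudes in [0.10, 0.20]); `colored` adds a
constant absorbance offset and no growth change; `sulfate_bypass` moves a
strain's capacity a fraction of the way toward its own sulfur-replete AS
capacity, so it lifts every sulfur-limited strain on ISE — including
*jlp1∆*, which is what the selectivity classifier keys on — while leaving
AS growth untouched. The default bypass magnitude of 0.5 represents
substantial, not total, sulfur restoration at screening dose.

**Screen layout.** 80 compounds/plate as single wells (row-major over
columns 1–11), 4 vehicle controls in the last column, 16 plates for 1280
compounds, 7 timepoints over 0–24 h, experimental strain *sdh1∆* on ISE.
The single-well design forces the mock-s.d. path to be exercised. Default
planted composition per 1280 compounds: 2 % suppressors, 16 sulfate-bypass,
4 colored, 64 toxic, the rest inert. Control-well positions are not
reported for the original screen, so the last column is a fixed
configurable default. No edge-well exclusion or evaporation correction is
applied (none is documented for the assay this emulates).

**Proteomes.** Log-normal abundances (baseline log2 mean ~ N(15, 2)), three
groups × 3 replicates, differential proteins shifted by a signed true
log2FC (default |FC| 2.5, replicate noise 0.25 log2 units, ~10 % shifted
upward in the mutant), with the 991/24/77 shared/unique partition as the
default structure and ~6000 proteins total. A small fraction of
down-in-mutant proteins is made fully absent (all-zero) in the mutant
group to exercise the flooring path.

**Metabolites.** Concentrations drawn around strain × treatment means with
10 % coefficient of variation, 3 replicates: succinate 5-fold up and 2KG
reduced to half in the mutants, a treatment that lowers mutant succinate
by 40 % and leaves WT untouched, plus two bystander metabolites.

**What the generator does not emulate** — and hence what passing recovery
tests do and do not show: no plate-position or edge effects, no
heteroscedastic or multiplicative OD noise, no compound carry-over, no
correlated protein noise or batch structure, no missing-at-random
proteomic dropout beyond the all-zero absence mechanism, and no mechanistic
TCA-cycle modelling. Recovery on these synthetics demonstrates that the
statistical machinery is correct under its stated assumptions, not that
real plates are this well behaved.

## Determinism and problem sizes

Every stochastic function takes an explicit integer seed and restores the
caller's RNG state; identical configuration and seed give bit-identical
outputs, including the full `run_pipeline()` bundle. Measurement CSVs are
written with the shortest decimal representation that round-trips each
double exactly.

The test suite sizes its simulations to what the checks need: full
1280-compound screens for recovery, 10⁴ replicates for the ANOVA type-I
rate, 10⁵ permutations for the Tukey oracle, 10⁶ draws for the
error-propagation Monte-Carlo, 200 seeded replicates for the metabolite
fold study, and scaled-down (hundreds of proteins) matrices where only
exactness, not power, is at stake.

## Known limitations

* The verdict logic assumes the standard four-strain, two-media validation
  panel; other panels need their own classifier.
* Two-way ANOVA requires balance; unbalanced real data must be rebalanced
  or analysed elsewhere.
* The colored-compound exclusion relies on library metadata; no spectral
  detection is attempted.
* Wide plate-grid input is read-only and single-plate-per-file; long
  format is canonical.
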