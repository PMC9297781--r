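---
title: "Fragment-length scoring and tumour-informed variant tracking for ctDNA MRD detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-length scoring and tumour-informed variant tracking for ctDNA MRD detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

After curative-intent resection of stage II–IIIA non-small-cell lung
cancer, adjuvant chemotherapy is standard of care even though only about
5.8% of patients derive an absolute disease-free-survival benefit.
Minimal residual disease (MRD) — tumour persisting after surgery — is
detectable in principle as circulating tumour DNA (ctDNA) in
postoperative plasma, but the signal is tiny and single read-outs are
unreliable. `fragmrd` implements a combined detector that fuses two
independent read-outs of the same hybrid-capture sequencing data:

1. **Variant tracking**: somatic variants identified at baseline (tumour
   tissue or preoperative plasma, with germline and clonal-haematopoiesis
   variants removed via the blood cell pellet) are traced in
   postoperative plasma at lowered read cut-offs.
2. **Fragment-length analysis**: ctDNA fragments are systematically
   shorter than non-tumour cell-free DNA (cfDNA), in both the
   mononucleosomal (~167 bp) and dinucleosomal (~334 bp) modes. A
   per-length score converts this shift into a patient-level statistic.

## The fragmentation score

Let $d_T(L)$ and $d_N(L)$ be the empirical probabilities of fragment
length $L$ in a tumour-tagged read set (reads carrying tumour-informed
mutations) and a pooled non-malignant read set. Each bootstrap iteration
draws 10,000 fragments from each set and scores every length

$$ s(L) = \log_2 \frac{d_T(L)}{d_N(L)}, $$

clipped to $[-5, +5]$ (a length absent from one draw but present in the
other sits at the cap), with $s(L) = 0$ whenever the combined sampled
count at $L$ is 20 or fewer. The reported table is the mean over 1000
iterations, which smooths sparse length bins. Per-fragment scores above
zero mark lengths enriched in ctDNA — in practice roughly 130–150 bp and
250–300 bp — while the 180–210 bp range scores negative.

* The **patient-level FS** is the mean of $s(L)$ over one million
  fragments sampled (with replacement) from a patient's plasma pool. A
  patient is FS-positive when their FS strictly exceeds the mean + 2 SD
  of the FS values of the non-malignant controls.
* The **variant-level VFS** is the mean of $s(L)$ over the fragments
  supporting one variant, pre- and postoperative fragments pooled. A
  variant with at least 8 supporting reads is called tumour-derived when
  its VFS strictly exceeds a read-count-matched null threshold (mean +
  2 SD of the VFS of equally many fragments drawn repeatedly from the
  pooled control reads); below 8 reads the call is indeterminate. The
  8-read floor is where the +1/−1/0 performance score (correct /
  incorrect / indeterminate) is maximised.

```{r}
library(fragmrd)
tumour <- sample_fragment_pool(fragment_profile("tumour"), 21705,
                               seed = 1, source = "tumour_reference")
controls <- sample_fragment_pool(fragment_profile("nontumour"), 5e6, seed = 2)
tab <- build_score_table(tumour, controls, seed = 3)
autoplot(tab)
patient_fs(sample_patient_pool(0.05, 1e6, seed = 4), tab, seed = 5)
```

## The combined MRD model

The variant channel counts trackable variants whose postoperative alt
read count reaches a cut-off $r \in [1, 8]$ (a variant already called by
the upstream pipeline counts regardless of $r$), and calls MRD when at
least $k \in [1, 6]$ variants are detected. Both cut-offs are chosen by
exhaustive grid search maximising concordance (accuracy) with recurrence
status on training data. The combined model then chooses, again on
training accuracy, whether both channels must be positive (AND) or one
suffices (OR).

Performance is estimated by 20× repeated 10-fold cross-validation: per
repeat the cohort is randomly partitioned into folds of near-equal size
(3 or 4 patients at N = 36); for each fold the *entire* model — the score
table from the training patients' tumour-tagged fragments only, all
control FS values, the FS threshold, the variant cut-offs and the logic —
is refitted and applied to the held-out patients. A patient's final call
is the majority over the 20 repeats (positive at ≥ 11/20). A
negative-control variant of the analysis reassigns each patient's
fragment pools (hence their FS) to a random other patient, which should
and does degrade accuracy.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_boot` | 1000 (100 in CV) | bootstrap iterations of the score-table build |
| `n_sample` | 10,000 | fragments drawn per pool per iteration |
| `cap` | 5 | score clip (log2 units) |
| `min_count` | 20 | combined sampled count at or below which a length scores 0 |
| `length_cap` | 600 bp | support bound; covers mono- and di-nucleosomal ranges with margin |
| `min_mapq` | 20 | mapping-quality floor when harvesting lengths from alignments |
| FS `n_sample` | 10^6 | fragments per patient-level FS |
| `min_reads` | 8 | VFS determinacy floor |
| grid | r ∈ 1..8 × k ∈ 1..6 | variant-tracking cut-off search space |
| `n_repeats`, `n_folds` | 20, 10 | cross-validation scheme |
| `benefit_rate` | 0.058 | absolute adjuvant-chemotherapy benefit (LACE meta-analysis) |
| `n_iter` | 10,000 | benefit-bootstrap iterations |

## Design choices where the design was open

* **"Combined count ≤ 20" rule.** The zero rule is applied to the
  combined tumour + non-tumour sampled count within each iteration. Both
  draws have the same size, so a per-set rule would behave almost
  identically; the combined rule guards both tails with one knob.
* **Bootstrap draws are with replacement** (that is what a bootstrap is),
  and FS sampling is with replacement even when the pool exceeds 10^6
  fragments, so behaviour is uniform across pool sizes. Both have
  without-replacement switches.
* **Aggregation across iterations is the mean** (a median option exists);
  smoothing is the purpose of the bootstrap and the mean is the natural
  smoother.
* **Sampling from histograms.** Drawing n fragments with replacement from
  a length histogram is implemented as a single multinomial draw —
  statistically identical to fragment-by-fragment sampling and O(distinct
  lengths) rather than O(n), which is what makes 10^6-fragment FS values
  and 1000-iteration builds cheap.
* **VFS null pools all controls** rather than sampling per control; the
  threshold is meant to describe non-malignant reads as a population.
  Thresholds are cached per (score table, read count).
* **Strict inequalities** at both the FS and VFS thresholds ("greater
  than" the mean + 2 SD).
* **Baseline "detected" means pipeline-called** in that compartment; the
  lowered read cut-offs apply only to postoperative tracking of variants
  already informed at baseline. A pipeline call in postoperative plasma
  outranks the raw-read cut-off (the upstream caller already accepted
  it); both behaviours are switchable.
* **Grid-search tie-break**: highest accuracy, then larger `r`, then
  *smaller* `k`. Larger `r` keeps the per-read evidence stringent
  (false-positive control); among equally concordant `k` values the
  smallest is taken because demanding more concordant variants than the
  training data requires systematically penalises held-out patients who
  carry few trackable variants — with the most-stringent-`k` rule, a
  fold whose training set lacks the low-variant-count patients ties
  across `k` and then misses exactly those patients at test time.
* **Logic tie-break is AND** (specificity first): a false-positive MRD
  call risks unnecessary adjuvant therapy.
* **Cut-offs are optimised before the logic**, then the logic given both
  channels' calls; a joint search over (r, k, logic) would differ only
  when variant cut-offs interact with the FS channel through the logic,
  which the training-accuracy criterion cannot resolve any better.
* **Fold assignment** shuffles indices and splits as evenly as possible,
  unstratified by default (a stratified option exists); the whole
  cross-validation runs in one seeded RNG stream, so a single `seed`
  reproduces every partition and every fold fit.
* **Benefit simulation** allocates the expected `benefit_rate * N`
  benefiting patients as fractional counts (the proportional split is
  then exact within an iteration); iterations in which a predicted group
  is empty, or the resample contains no recurrent patient, are excluded
  from the affected summary and reported in a counter.
* **Degenerate inputs**: empty pools, single-label training sets,
  all-one-group predictions and sub-2-control thresholds raise errors or
  warnings rather than producing silent numbers; the log-rank test is
  reported as undefined when every patient lands in one predicted group.

## What the synthetic cohort emulates — and what it does not

The generator produces: discrete truncated-normal length mixtures
(non-tumour 167 ± 10 / 334 ± 25 bp at weights 0.8/0.2; tumour 145 ± 12 /
300 ± 30 at 0.85/0.15 — chosen once to reproduce the qualitative
short-shift of ctDNA); patient plasma pools mixing the two profiles at a
given tumour fraction; compartment-structured variants (germline in BCP +
tissue at AF 0.5, CHIP in BCP and plasma at AF 2–20%, trackable variants
in tissue/preoperative plasma with plasma AF tied to tumour fraction,
postoperative-only artifacts); supporting-fragment lengths drawn from the
origin-appropriate profile; binomial read support at Poisson ~5000×
depth; and recurrence labels coupled to a positive postoperative tumour
fraction (5–15% for recurrent patients by default, 0 otherwise). Cohort
defaults mirror the study structure: 36 patients, 14 recurrences, 15
non-malignant controls. Hidden truth tables let every classifier be
scored against generator truth.

It does **not** emulate: sequence content, sequencing error, GC or
panel-footprint bias, between-patient fragment-length variability beyond
the tumour-fraction mixture, realistic sub-percent postoperative tumour
fractions, CHIP/germline length differences subtler than the two
profiles, or correlated variant read counts. Passing tests on this
cohort therefore demonstrate that the machinery is correct and that the
method recovers a *separable* signal; they do not establish clinical
sensitivity at real-world postoperative tumour fractions, which are far
below the separated regime.

```{r}
cohort <- sample_cohort(cohort_config(), seed = 42)
cv <- run_ttfcv(cohort, seed = 43)
calls <- majority_call(cv)
ev <- evaluate_mrd(calls, cohort$metadata)
autoplot(ev)
sim <- simulate_benefit(
  dplyr::mutate(dplyr::inner_join(tidy(cv), cohort$metadata,
                                  by = "patient_id"),
                positive_prob = combined / n_predictions),
  seed = 44)
tidy(sim)
```

## Problem sizes

The package's own test suite exercises the method at sizes chosen to
keep a laptop run comfortable while leaving the statistics meaningful:
score tables are built at the standard 1000 iterations where the rules
themselves are under test and at 30–100 iterations inside
cross-validation fits (per-fold rebuilds are invariant to this choice
well within the FS reproducibility bound); unit-test cohorts use 12
patients with 5 × 10^4-fragment pools, while end-to-end checks use the
full 36-patient default with 3 × 10^5-fragment pools; FS reproducibility
is assessed on a 5 × 10^6-fragment pool exactly as specified.

## Known limitations

* The score table is genome-wide over length only; no per-bin or
  GC-corrected fragmentation profiles.
* The VFS is reported and validated but deliberately not fused into the
  MRD call: with tumour tissue and BCP sequenced, variants are already
  classified by compartment, and the VFS adds no information in that
  setting. Its intended future role is replacing BCP/tissue sequencing.
* The benefit simulation inherits the strong assumption that the test's
  sensitivity for recurrence equals its sensitivity for
  chemotherapy benefit, and does not correct for adjuvant therapy
  received; treat its output as hypothesis-generating.
* Cross-validated accuracy on synthetic, well-separated cohorts is an
  upper bound, not an estimate, of performance on clinical samples.
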