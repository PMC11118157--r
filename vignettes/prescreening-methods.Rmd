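---
title: "Methods: ex vivo cytokine prescreening of biologic response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ex vivo cytokine prescreening of biologic response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psoscreen)
```

## The assay and its data model

Peripheral blood mononuclear cells from a psoriasis patient are cultured
under three kinds of condition: unstimulated control, stimulation with
heat-inactivated *S. pyogenes* group A ("induced", emulating a clinical
flare trigger), and induced plus one biologic at its steady-state trough
serum concentration (adalimumab 4, golimumab 0.5, certolizumab 20,
ustekinumab 0.25, ixekizumab 3.5, secukinumab 16.7 or 34 — the 150 mg and
300 mg monthly regimens — guselkumab 1.2, risankizumab 2 µg/mL). Culture
supernatants are read on an 18-analyte multiplex immunoassay (pg/mL).
Readings below the assay's detection range carry a `below_range` censor flag
and no concentration.

The unit of analysis is the **patient-biologic course**: one patient
contributes one row per biologic, pairing the ex vivo treated panel with the
clinical outcome on that drug (absolute PASI at day 0 and at the outcome
time). The analysis assumes course rows are exchangeable; repeated rows from
one patient are not modelled as clustered — a deliberate simplification
matching the source analysis, and a known limitation (n = 44 rows overstates
the number of independent observations from 20 patients).

## Biomarker indices and change quantities

An index is a single analyte or a ratio of two (the headline set: IFN-γ,
IL-13, IFN-γ/IL-4, IFN-γ/IL-13, IL-17A/IL-4, IL-17A/IL-13 — Th1/Th17
markers, Th2 markers, and their balance). With baseline value $I_0$ under
induction only and $I_1$ under induction plus biologic:

$$\text{reduction rate} = \frac{I_1 - I_0}{I_0}, \qquad
  \text{reduction difference} = I_1 - I_0.$$

PASI change uses the same orientation (rate $=(\text{after}-\text{before})/
\text{before}$), so in every correlation a **positive** coefficient means
biomarker suppression tracks clinical improvement. The percent improvement
familiar from clinic ("PASI 90") is $-100\times$ the rate; a separate
integer view uses round-half-away-from-zero, which reproduces printed
clinical tables (18.75 → 19). Degenerate inputs error rather than return
infinities: a zero baseline has no defined rate, and a zero observed
denominator in a ratio is a data defect, not a value.

Censoring policy: a `below_range` reading in any input of an index censors
that course's record for that index — the analysis then drops it cell-wise
("pairwise deletion"), never the whole course. An optional LLOQ/2
substitution mode exists (`build_index_change_table(..., lloq = )`) but is
off by default, mirroring the source analysis, which left censored cells
empty. No winsorization or exclusion is applied to the extreme ratios that
arise when a Th2 denominator is very low; users studying IL-17A/IL-13-type
indices on near-floor denominators should treat those values as
rank-informative only.

## Association analysis

Spearman's rank correlation is computed as the Pearson correlation of
midranks (average ranks for ties). Two-sided p-values use the Student-t
approximation $t = r_s\sqrt{(n-2)/(1-r_s^2)}$ on $n-2$ df for $n > 9$ — the
convention of the mainstream statistical packages used in clinical work,
which reproduces the published p-values at n = 44 — and the exact
permutation null (all $n!$ rank orderings) for $n \le 9$. The t
approximation and the exact null agree closely but not perfectly in that
range; the test suite bounds their discrepancy at 0.025 with a median well
under 0.01. A correlation on fewer than 3 pairwise-complete rows, or on a
constant vector, is reported as undefined (`NA`), not an error, inside
matrices.

The Mann–Whitney U test uses midranks, exact enumeration of all
$\binom{n}{n_a}$ group labellings when $n_a n_b \le 20$, and otherwise the
tie-corrected normal approximation without continuity correction (again the
SPSS-style convention; `wilcox.test(correct = FALSE)` is the cross-check in
the tests).

No multiple-testing correction is applied by default, matching the source
analysis; `bh_correct = TRUE` adds Benjamini–Hochberg adjusted p-values for
reanalysis. Significance stars use 0.05/0.01/0.001.

Subgroup analyses stratify course rows by biologic or by disease (PsO-only
vs PsO+PsA, from the patients' psoriatic-arthritis flag). Strata with fewer
than 4 rows are flagged `low_n` but still computed where defined.

## The packaged cohort and how its defects were resolved

`load_paper_fixture()` returns the transcription of the published
20-patient, 44-course cohort: per-patient induced and per-course treated
panels for IFN-γ, IL-13 and IL-4, absolute PASI before/after, disease flags
and course metadata. Three transcription decisions matter for
reproducibility and are worth stating plainly:

* **Two parallel value columns.** The source table prints raw analyte
  columns *and* precomputed ratio columns, and in 22 of 125 ratio cells they
  disagree beyond rounding — the hallmark of a hand-maintained spreadsheet
  in which ratios were computed from unrounded source data while raw cells
  were rounded and occasionally mistyped. The published correlations are
  reproduced by using the raw columns for single-analyte biomarkers and the
  printed ratio columns for ratio biomarkers, so that is the default
  (`ratio_source = "printed"`); `ratio_source = "recomputed"` recomputes
  ratios from the raw analytes instead. Both routes are tested; every
  reported correlation target is reproduced within ±0.03 by the default
  route (`reproduce_paper()` recomputes all 30 published PASI-row cells,
  28 of which agree within ±0.03; the two residuals are IL-4 rate cells
  driven by the next point).
* **One patient's IL-4 sits at the assay floor.** Patient A's IL-4 prints
  as 0.09 pg/mL with blank ratio cells and an explicit below-range flag
  under one biologic. The blanks are honoured: A's IFN-γ/IL-4 records are
  censored for both courses, while the raw 0.09 values are kept for the
  single-analyte IL-4 index.
* **One row swap.** Patient S's two after-treatment ratio cells are printed
  against the wrong rows (each equals the raw-analyte recomputation of the
  other row); the loader swaps them back and the fixture file keeps the
  exact printed form for integrity checks.

## Biologic selection composite

The published protocol states a direction-of-change principle — favour the
biologic that lowers IFN-γ and IL-17A and raises IL-13 and IL-4 — but no
formula. The package's composite, clearly an extension of that principle,
is: per index, divide each biologic's reduction rate by the standard
deviation of that index's rates across the patient's tested biologics (a
within-patient, scale-free standardisation; if the deviation is zero the
raw rate is used), orient it (+1 for indices where lower is better, −1 for
IL-13/IL-4), and average over the indices available for that biologic.
Censored indices are omitted and recorded. Lower composite = more
favourable; ties break alphabetically, so rankings are deterministic and
independent of input order. No clinical validity is claimed for the
composite itself — it is a transparent, monotone summary of the assay.

## The synthetic cohort generator

The generator exists so the whole pipeline — censoring, pairwise deletion,
matrices, subgroups, selection — is exercisable without patient data, with
known ground truth. Per patient it draws a log-normal control panel,
multiplies by a per-analyte induction factor and log-normal noise for the
induced panel, and per tested biologic multiplies the induced panel by a
per-biologic, per-analyte effect (< 1 = suppression) and noise. Defaults
place induced medians near the packaged cohort's ranges (IFN-γ ~90 pg/mL,
IL-13 ~2, IL-4 ~7.5, IL-17A ~40, IL-6 ~1000), group effects by mechanism
(TNF-α inhibitors damp Th1, IL-12/23 and IL-23 blockers damp Th17/Th1,
IL-17A inhibitors strongly damp IL-17A), use log-noise 0.2, a 20-patient
cohort with 2–3 biologics per patient (80/20), and day-0 PASI uniform on
5–40.

The clinical link is a Gaussian copula: the realised IFN-γ/IL-13 reduction
rates are rank-transformed to normal scores $z$, a latent
$z' = \rho_P z + \sqrt{1-\rho_P^2}\,\varepsilon$ with
$\rho_P = 2\sin(\pi\rho_S/6)$ (the exact Pearson–Spearman correspondence
for Gaussian copulas) drives each course's PASI rate through a monotone map
onto $(-1, 0.1)$. This hits the target Spearman correlation $\rho_S$
between the headline index change and the PASI rate regardless of the
index's marginal distribution; the test suite checks recovery within ±0.1
averaged over 20 seeds at roughly 200 courses (91 patients), a size chosen
to keep the whole suite under a minute of simulation while leaving
Monte-Carlo error well under the tolerance. One structural consequence is
worth knowing: because the link attaches to the *realised* ratio, any
analyte in the linked ratio (IL-13 in the denominator) inherits an
opposite-signed association with PASI even when no biologic affects it —
which is also what the real cohort shows. Analytes outside the link (IL-4)
stay null-centred.

Censoring below the per-analyte LLOQ is applied last; the IL-4 default
(0.9 pg/mL) censors roughly 2% of stimulated IL-4 panels, matching the one
censored cell among the 44 published courses. The LLOQ values themselves
are assumptions — the source reports none.

What the generator does **not** emulate: within-patient clustering of
responses across biologics, longitudinal PASI trajectories (only one
before/after pair), analyte-analyte correlation beyond the shared induced
panel, plate/batch effects, and heavy-tailed assay error. Passing tests on
synthetic cohorts therefore demonstrate correctness of the statistical
machinery under the stated model, not clinical validity on real data.

## Outcome-timing rule

When a patient had been on a biologic for at least 180 days at PBMC
testing, the outcome PASI is the recorded score closest in time to the
test; otherwise it is the day-180 score, falling back to the closest
recorded month at or after month 6. `select_outcome_pasi()` implements the
rule; the packaged cohort already stores the selected outcome per course.

## Numerical and testing choices

* Exact permutation nulls are memoised per $n$ (up to $9! = 362{,}880$
  orderings); enumeration oracles in the tests are written independently
  (recursive permutation, `combn` labellings) so the implementation and its
  check share no code.
* Round-half-away-from-zero is used only for reproducing printed integer
  tables; all analysis is done on unrounded values.
* Problem sizes in the test suite: correlation fixtures at n = 44 (the real
  cohort), permutation oracles at n ≤ 6, Mann–Whitney oracles at
  $n_a+n_b \le 10$, synthetic recovery at ~200 courses × 20 seeds.
* Everything stochastic flows from a single integer seed
  (`withr::with_seed`), and pipeline runs are byte-reproducible.

## Known limitations

* 20 patients / 44 course rows is a pilot-scale dataset; correlations carry
  wide sampling error and the per-biologic subgroups are small.
* Course rows from the same patient are treated as independent.
* The two IL-4 rate cells of the published table are not exactly
  recoverable from the printed data (see `reproduce_paper()`); the
  deviation traces to the one patient whose IL-4 sits at the assay floor.
* IL-17A- and IL-6-based published rows cannot be desk-checked (raw values
  unprinted); they are exercised synthetically only.
* The selection composite is an operationalisation for ranking within one
  patient's tested panels; it has no thresholds, no across-patient meaning,
  and no claim of clinical validity.
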