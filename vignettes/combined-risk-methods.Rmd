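---
title: "Methods: combining a polygenic score with Gail-model absolute risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combining a polygenic score with Gail-model absolute risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combrisk)
```

## The problem

Questionnaire-based absolute-risk models of invasive breast cancer (the
Gail model / BCRAT family) drive clinical decisions through guideline
thresholds: a 5-year risk of 1.66% or more opens the chemoprevention
discussion, a lifetime risk of 20% or more the recommendation of
supplemental MRI screening. Common susceptibility SNPs each carry little
information, but a multiplicative score over tens of SNPs shifts enough
individuals across those thresholds to matter. `combrisk` implements the
full assessment chain — normalized polygenic score, absolute-risk
projection, multiplicative combination, and the statistics used to judge
the gain — together with a synthetic cohort generator so that the whole
pipeline is testable end-to-end without access to any study's individual
data.

## The SNP score

For one SNP with per-allele odds ratio $OR$ and risk-allele frequency
$p$, risks are assumed independent and additive on the log-OR scale, so a
genotype with dosage $g \in \{0,1,2\}$ carries relative risk $OR^g$. The
unscaled population-average risk is the Hardy–Weinberg expectation

$$\mu = (1-p)^2 + 2p(1-p)\,OR + p^2 OR^2 ,$$

and the *adjusted risk value* $OR^g/\mu$ has expectation exactly 1 under
HWE — the package verifies this identity on a $(p, OR)$ grid to
$10^{-12}$. The per-subject SNP score is the product of adjusted risk
values over the panel, accumulated in log space to avoid underflow on
large panels. A missing genotype contributes the neutral factor 1 (its
HWE expectation) and is counted in `n_missing`; this is a documented
package choice — sources differ on whether such subjects were imputed or
dropped — and it keeps the score unbiased at the population level while
shrinking individual scores toward 1.

## The absolute-risk engine

The engine is deliberately *coefficient-agnostic*. The official
BCRAT/CARE tables are external artifacts that cannot be redistributed, so
baseline hazards and log-relative-risk coefficients arrive as a JSON
config: an age-banded table of the composite (attributable-risk-adjusted)
incidence $h_1^*$ and competing mortality $h_2$ over $[35, 90)$, and a
per-category log-RR model over the five questionnaire variables, with an
optional under/over-50 split per variable. "Unknown" responses — the
accepted BCRAT answer for biopsies and hyperplasia, which are missing for
>90% of subjects in realistic questionnaire data — contribute log-RR 0.

Risk over $[a, a+\tau)$ is the standard piecewise-constant competing-risk
projection: with band overlaps $\Delta_j$ and $h_j = h_{1j} rr + h_{2j}$,

$$A = \sum_j \frac{h_{1j} rr}{h_j}\left(1 - e^{-h_j \Delta_j}\right)
      \prod_{k<j} e^{-h_k \Delta_k}.$$

Five-year risk uses horizon $\min(5, 90-a)$; lifetime risk runs to age
90. Ages below 35 are refused (the tool's validity restriction); bands
are half-open $[a,b)$ and the projection starts exactly at the integer
age. The tests check this algebra against an independent midpoint-rule
numerical integration (step $10^{-4}$ year, aligned with band edges) to
$10^{-6}$, and against the closed form $1 - e^{-h\tau}$ in the
no-competing-risk limit.

## The combined score and its evaluation

The combined score is the straight product SNP score × absolute risk,
capped at 1: it is compared against the guideline thresholds *as* an
absolute risk, so probability semantics must be preserved. With a
population-mean SNP score of ~1 the cap essentially never binds; when it
does, the log-additivity of the three scores breaks, which the tests
exercise explicitly. All analyses use natural-log scores (the base is a
pure scale choice; OPERA standardizes it away).

**OPERA.** Risk factors measured on different scales are compared through
the odds ratio per adjusted standard deviation: $\mathrm{OPERA} =
\exp(\beta s)$, where $\beta$ is the log score's coefficient in a
logistic case/control regression adjusted for age, and $s$ is the SD of
the age-adjusted log score estimated from the controls. The published
description pins the ingredients but not the regression layout, so the
package implements two: the default fits `status ~ log_score + age` and
takes $s$ as the residual SD of `log_score ~ age` among controls; the
alternative (`method = "residualize"`) residualizes the score on age
first and fits the residual alone. Both are exposed behind one switch;
they agree closely whenever age and score are weakly related. Wald 95%
CIs use 1.96; OPERA is invariant to positive rescaling of the raw score.

**AUC.** Mann–Whitney with ties counted one half, DeLong variance for
CIs, and the paired DeLong test (one degree of freedom) for the change in
AUC between two scores on the same subjects. A brute-force enumeration
over all case-control pairs serves as the oracle in the tests.

**Calibration.** Hosmer–Lemeshow over deciles of fitted risk (ties kept
together), $\chi^2 = \sum (O-E)^2 / (E(1 - E/n_g))$ on $g-2$ df;
degenerate groups are merged with a warning.

**Reclassification.** Risks are classified low/high with the boundary in
the high class (the analysis definitions are <1.66% vs ≥1.66% and <20% vs
≥20%; prose elsewhere sometimes says "1.67 percent or higher", and the
analysis definition governs). The two-category NRI is

$$\mathrm{NRI} = P(\mathrm{up}\mid\mathrm{case})
  - P(\mathrm{down}\mid\mathrm{case})
  + P(\mathrm{down}\mid\mathrm{control})
  - P(\mathrm{up}\mid\mathrm{control}),$$

with the asymptotic variance
$[(p_{up,ca}+p_{dn,ca}) - (p_{up,ca}-p_{dn,ca})^2]/n_{ca} + (\text{control
analog})$ for the CI, and a seeded bootstrap (2,000 resamples) behind a
flag. Published tables report this CI by an unstated method; on the
printed 5-year counts our asymptotic interval is (−0.043, 0.083) against
a published (−0.040, 0.080) — the point estimates agree exactly.
Up-moved fractions are reported under both denominators that appear in
practice (all cases, and previously-low cases), since they answer
different questions.

## The synthetic world

The generator's defaults state the emulated cohort rather than tuning
knobs:

* **Panel.** 75 SNPs; risk-allele frequencies uniform on $[0.05, 0.95]$;
  per-allele log-ORs $\mathcal{N}(0, 0.08)$. The SD was chosen once so
  that the implied log-SNP-score SD ($\approx \sqrt{75 \cdot
  \overline{2p(1-p)} \cdot 0.08^2} \approx 0.42$) matches the ~0.4
  case/control SNP-score SDs reported for real 75-SNP panels.
* **Genotypes.** Binomial(2, p) per SNP (HWE, no LD — matching the
  score's independence assumption); 2% genotype missingness.
* **Questionnaire.** Ages 35–85 from 5-year bands with population-like
  weights; risk-factor marginals resembling a population-based control
  sample; per-field missingness of 25% (family history), 3% (menarche),
  15% (first birth), 94% (biopsies), 93% (hyperplasia) — the pattern of
  real questionnaire data, where biopsy history is almost never
  available. Nulliparity 8% among parity-known subjects (plausible for
  the emulated population; the emulated tables fold nulliparity into
  missing, so a value had to be chosen here).
* **Hazards.** Incidence rising ~1×10⁻³ → 4.5×10⁻³/yr over 35–90 with a
  5% log-normal seeded jitter (kept monotone), competing mortality
  ~2×10⁻³ → 3×10⁻² /yr; the implied mid-life 5-year risks fall in the
  0.5–3% band of published cohort means.
* **Case assignment.** $\mathrm{logit}\,P(\mathrm{case}) = \alpha +
  c\,\log(\text{5-year risk}) + g\,\log(\text{SNP score})$ on a source
  pool 4× the cohort, with defaults $c = g = 1$ and $\alpha$ solved
  numerically. Assignment uses the *uncapped* true log scores, keeping
  the model log-linear and parameter recovery well-defined. The stated
  contract is that the expected case count matches the target; because
  cases are then *sampled*, $\alpha$ is solved for `n_cases ×
  case_margin` (default 1.3) expected cases so the draw is feasible —
  the one deliberate deviation from the minimal description, documented
  here. Controls are age-band-matched 1:1 to the first `n_cases` cases
  with the remainder drawn at random, emulating a matched design with a
  supplementary control series. An optional family-history oversampling
  switch reweights *which* realized cases are kept (enrichment factor
  per affected-relative category), mimicking study-design selection
  without breaking the generative model.

Everything is deterministic under the config seed (stage seeds are
derived from it), and the ground truth — $\alpha$, both effects, per-SNP
log-ORs — is returned with the cohort and written to `truth.json`.

What a green test establishes, and what it does not: the generator
reproduces the *structure* of a matched case-control study (HWE
genotypes, missingness patterns, age matching, logistic risk), so it can
certify the pipeline's algebra, its invariances, CI coverage and null
calibration. It does not emulate genotyping error, duplicate-sample
discordance, population stratification or linkage disequilibrium, and
its hazard and coefficient tables are synthetic — so agreement with any
particular published AUC or OPERA value is *not* claimed, only the
qualitative ordering (combined > clinical alone, combined > SNP alone)
that holds whenever both true effects are positive.

## Numerical choices

* Products of adjusted risk values are accumulated as sums of logs.
* `uniroot` solves for $\alpha$ on $[-40, 40]$ with tolerance $10^{-10}$.
* Ties in AUC count one half; ties in Hosmer–Lemeshow grouping stay in
  one group (quantile breaks de-duplicated).
* Perfect separation in the OPERA logistic fit is detected (non-converged
  fit or coefficient SE > 50) and refused with a diagnostic rather than
  reported.
* Degenerate strata (single-subject SD, empty reclassification
  denominators) are reported as 0 or `NA` with warnings, never silently.
* The pipeline removes partial outputs on failure, so an output directory
  is either complete or untouched by the failed run.

## Known limitations

* The engine does not reproduce the NCI BCRAT table-for-table; users who
  want BCRAT-equivalent numbers must supply the official hazard and
  coefficient tables as the JSON config.
* The two-category NRI only; continuous NRI and IDI are out of scope.
* The SNP score ignores linkage disequilibrium by design; panels with
  correlated SNPs will overstate the score's variance.
* The asymptotic NRI CI is first-order; for very sparse off-diagonal
  cells the bootstrap flag is the better choice.
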