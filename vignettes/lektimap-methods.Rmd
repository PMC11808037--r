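---
title: "Methods: domain mapping and genotype-phenotype association in Netherton syndrome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain mapping and genotype-phenotype association in Netherton syndrome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lektimap)
```

## Scope

`lektimap` analyses cohorts of Netherton syndrome (NS) patients carrying
biallelic *SPINK5* variants. It answers one family of questions: does the
position of a patient's variants — transcript half, LEKTI domain, domain
region — predict their clinical phenotypes, and is homozygous carriage of
"fatal" variants associated with death in infancy? This vignette documents
the model, the conventions and the deliberate design decisions; every
empirical statement here is computed by the test suite or the examples.

## Coordinate model

All variants are interpreted on the coding sequence of transcript
NM_006846.4: 3195 bp encoding 1064 residues plus the stop codon
(3195 = 3 × 1065). The transcript-half split at base 1598 is read as a
CDS (c.-coordinate) boundary, inclusive on the 5' side. This
interpretation was genuinely open — "transcript" could also mean mRNA
numbering — and was adopted because the quoted full range (1–3195 bp)
equals the CDS length exactly, and because the half assignments it
produces for known variants (e.g. c.1431 in half 1, c.1887 in half 2) are
internally consistent with their domain assignments. The boundary is a
parameter of `transcript_model()`, not a constant, so a user who prefers a
different split can supply one.

Anchoring rules, chosen for determinism:

* every variant is anchored at its **5'-most affected coding base**; for a
  range edit (`c.1032_1036dup`) that is the range start, and for an
  intronic or splice-site variant (`c.1431-12G>A`, `c.1887+1G>A`) it is
  the exonic base named in the HGVS string, with the offset ignored;
* the affected codon is `ceiling(anchor / 3)`; the stop codon (1065) is
  representable but lies in no domain;
* large deletions/duplications spanning several domains are out of scope
  (they are excluded upstream by the curation filter `large_event_flag`),
  so the 5'-most-base rule never has to arbitrate a genuinely
  multi-domain event.

HGVS parsing accepts the c.-notation subset that occurs in NS case
reports — `NNN`, `NNN±off`, `NNN_MMM` positions with substitution, `del`,
`dup`, `ins` and `delins` edits — and strips internal whitespace first,
because published tables print forms like `c. 995delT` and
`c. 1887 + 1G>A`. Anything else is a parse error naming the offending
token; there is no silent fallback. Nonsense/missense discrimination for
substitutions requires a caller-supplied predicted protein consequence
(`p.(Arg371*)` patterns): the package ships no reference sequence and
never translates, so a substitution without that annotation is reported
as `unclassified` rather than guessed.

## Domain and region tables

The 15 Kazal-type domains are inclusive amino-acid ranges (Domain-1 =
AA 28–66 … Domain-15 = AA 987–1048); the signal peptide (1–27),
inter-domain linkers and the C-terminal tail (1049–1064) are non-domain.
The five domain regions group domains {1–5}, {6}, {7}, {8–9}, {10–15},
following the bio-reactive proteolytic fragments of LEKTI. Both tables
are ordinary tibbles (`lekti_domains()`, `lekti_regions()`) and any table
with the same schema may be substituted, so the machinery generalises to
other multidomain proteins. Inter-domain positions are reportable as
flanking-pair bins (`D1-2`) for distribution plots but always carry
`domain = NA` for covariate purposes.

## Genotype coding

Per allele: half ∈ {1, 2}; domain number ∈ 1..15 (NA outside domains);
DomainR-5 indicator ∈ {0, 1}; in-domain indicator ∈ {0, 1}. Biallelic
covariates are the products of the two allele values — `halfx` ∈
{1, 2, 4}, `domnum_x` ∈ 1..225, `d5x`, `indom_x` ∈ {0, 1} — which are
symmetric in allele order; for homozygous-only analyses the single-allele
value is used (the product is then its square). Two decisions here were
open and are resolved as follows:

* "Domainx" admits two readings — a product of domain numbers or of
  in-domain indicators. Both are implemented (`domnum_x`, `indom_x`) and
  reported separately, so results always say which coding produced them.
* A non-domain allele has no domain number, so `domnum_x` is **missing**
  (and the row is dropped, counted, from domain-number models) rather
  than coded 0: a product with an undefined ordinal is meaningless, and
  0 would silently create an out-of-scale category.

## Association model

For each phenotype × covariate cell, complete cases (phenotype recorded,
covariate defined, age known) enter a binary logistic regression with the
genotype covariate and age entered simultaneously (no selection, no
centering — raw codes, as an Enter-method fit would use). Age is in
years, continuous, with infant ages as fractions. Odds ratios use the
Wald 95% interval exp(β ± 1.96·SE). The fit is the standard IRLS GLM
(`stats::glm`, binomial) with convergence tolerance 1e-8 and at most 100
iterations; (quasi-)separation is flagged by |β| > 15 and reported via
`converged = FALSE`, never silently. Degenerate cells (constant outcome
or covariate, empty table) are errors at single-fit level and annotated
`note` rows in the grid (`associate_all()`), so one empty cell cannot
abort a report. Nine phenotypes are tested without multiplicity
adjustment — a faithful-replication choice, since the analyses this
package operationalises report unadjusted P values; users can apply
`p.adjust` to the result column when they prefer.

Phenotype records are tri-state (`present` / `absent` / `unknown`): an
absent record is *not* an absent phenotype, and all models are
complete-case per phenotype. Infancy is defined as age < 1 year; the
sources this targets never define it numerically, and the one-year
horizon matches the way surviving infant carriers are footnoted in case
tables. A fatal variant is defined operationally as a variant with at
least one homozygous carrier who died during infancy; deaths in compound
heterozygotes never flag a variant. The mortality analysis is a Pearson
chi-square on the 2×2 zygosity × death table, uncorrected by default with
the Yates correction behind a flag (the statistic 17.5 on the worked
example is significant either way); a zero margin is an error suggesting
an exact test rather than a wrong number.

## Synthetic cohorts

`simulate_cohort()` generates cohorts with the statistical structure the
analysis assumes, so the whole pipeline is testable without patient
data. Defaults are fixed to the study conditions of a large curated NS
case series and are not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `n_patients` | 162 | reference cohort size |
| `homozygous_fraction` | 89/162 | observed homozygote share |
| `region_weights` | (126, 12, 14, 23, 107, 42)/324 | allele counts per region / non-domain |
| `type_weights` | (99, 93, 85, 33, 7, 6, 1)/324 | nonsense … deletion/insertion allele counts |
| `missingness` | per-phenotype NA shares (62/162 … 112/162) | observed record availability |
| intercepts | logit of complete-case prevalence per phenotype | reproduces prevalence among recorded patients |
| `age_range` | 0–18 y uniform | paediatric-skewed convention; no distribution is published |

Each allele draws a region (or non-domain), then a domain within the
region weighted by domain length, then a uniform codon inside it and a
uniform base within the codon; the mutation type determines a concrete
HGVS string (splice variants get a ±1/±2 offset, substitutions get a
synthetic protein consequence). Positions are therefore uniform *within*
regions — the only distributional claim the emulation makes is at region
level. Phenotypes follow the logistic link on the coded covariates with
user-specified effects (`betas`, `beta_age`); a term whose covariate is
undefined for a patient contributes zero. Missingness is masked after
generation, completely at random, matching the complete-case assumption
downstream — MNAR sensitivity studies can supply their own masks.
Generated tables pass through `as_cohort()` itself, so simulated cohorts
are valid pipeline inputs by construction, and the generator restores the
caller's RNG state.

What passing tests on simulated data do **not** show: real cohorts have
recurrent founder alleles (the simulator draws positions independently,
so almost every variant is unique), correlated phenotypes, non-random
missingness, and ages correlated with survival. Recovery results are
therefore statements about the estimator under the assumed model, not
about any real cohort.

`recovery_study()` repeats simulate → code → fit and reports mean bias,
95% CI coverage and rejection rate. The shipped studies use 200
replicates at n = 500 for effect recovery (planted `halfx` effect
−0.5 on the log-odds scale, recovered within ±0.1 with ≥ 90% coverage)
and 200 replicates at n = 300 for null calibration (Wald type-I error
within [0.02, 0.09] at α = 0.05); region-frequency emulation is checked
at n = 10,000 within ±2 percentage points. These sizes were chosen so
Monte-Carlo error is well below the tolerances being asserted.

## Degenerate inputs and numerical conventions

* duplicate patient ids: first record kept, removal counted per criterion;
  the exclusion filter is idempotent;
* empty cohorts, zero-margin tables, constant outcomes: errors naming the
  stage and the responsible filter counts;
* `p.(…)` supplied for an intronic variant: a validation error
  (contradictory annotation), not a silent override;
* report files contain no timestamps, so reruns are byte-identical;
* all randomness flows through a single seeded Mersenne-Twister stream.

## Limitations

No genomic or protein coordinate lifting, no reference-sequence
validation or pathogenicity prediction, no Firth/exact logistic
regression for separated cells, no survival modelling of age at death,
and no attempt to reconstruct any real patient table: the worked-example
fatal cohort is synthetic, built from published aggregate carrier and
mortality tallies only.
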