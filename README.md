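# lektimap

Genotype–phenotype analysis of Netherton syndrome cohorts: mapping SPINK5
cDNA variants onto the domain architecture of the LEKTI protein and testing
the mapped genotypes against clinical phenotypes.

## The problem

Netherton syndrome (NS) is a rare autosomal-recessive ichthyosis caused by
biallelic loss-of-function variants in *SPINK5*, which encodes LEKTI, a
1064-residue serine protease inhibitor built from 15 Kazal-type domains.
Clinical severity varies widely, and a long-standing question is whether
*where* a variant falls in the gene — 5′ vs 3′ half, which domain, which
bio-reactive domain region — predicts *which* phenotypes a patient develops.
`lektimap` is aimed at clinical geneticists and rare-disease epidemiologists
who curate NS case tables (two HGVS cDNA alleles per patient plus tri-state
phenotype records) and want a reproducible, tested pipeline instead of
ad-hoc spreadsheet coding.

## The method

For each allele, the HGVS c. description on transcript NM_006846.4
(CDS 3195 bp) is parsed and anchored at its 5′-most coding base *c*:

- **half** = 1 if *c* ≤ 1598, else 2 (intronic offsets ignored);
- **codon** = ⌈*c*/3⌉, looked up in the 15 inclusive amino-acid domain
  ranges (Domain-1 = AA 28–66 … Domain-15 = AA 987–1048);
- **domain region** = the grouping {D1–5, D6, D7, D8–9, D10–15};
- **mutation type** ∈ {nonsense, missense, splicing, deletion, duplication,
  insertion, deletion/insertion}.

Per-allele values (half code, domain number, DomainR-5 indicator, in-domain
indicator) are multiplied across the two alleles to form the biallelic
covariates Halfx, Domainx (both the domain-number and indicator readings
are exposed) and DomainR-5x; homozygous-only analyses use the single-allele
value. Each phenotype *y* ∈ {0, 1} is then modelled by binary logistic
regression with all covariates entered simultaneously,

  logit P(y = 1) = β₀ + β₁·genotype + β₂·age,

reporting OR = exp(β₁) with the 95% Wald interval exp(β₁ ± 1.96·SE) —
complete cases only, since phenotype records are tri-state (+ / − / NA).
Separately, "fatal variants" (variants with ≥ 1 homozygous carrier who died
in infancy) are identified and homozygous vs heterozygous carriage is
tested against infant death with a Pearson chi-square on the 2×2 table
(Yates correction optional). A seeded synthetic-cohort generator with the
same positional, mutation-type, zygosity and missingness structure supports
power and parameter-recovery studies of the whole pipeline.

## Worked example

```r
library(lektimap)

annotate_variant(c("c.153delT", "c.1431-12G>A", "c.1111C>T",
                   "c.1887+1G>A", "c.995delT"))
#>   hgvs          half codon domain region mutation_type
#> 1 c.153delT        1    51      1      1 deletion
#> 2 c.1431-12G>A     1   477      7      3 splicing
#> 3 c.1111C>T        1   371      6      2 unclassified
#> 4 c.1887+1G>A      2   629     10      5 splicing
#> 5 c.995delT        1   332      5      1 deletion
```

Each row is one allele: `c.153delT` anchors at CDS base 153, codon 51,
inside Domain-1 (region 1) in the 5′ half; the intronic `c.1431-12G>A` is
anchored to coding base 1431 (codon 477, Domain-7, region 3) and classed as
splicing. `c.1111C>T` stays `unclassified` until a predicted protein
consequence (`p.(Arg371*)`) is supplied, which makes it nonsense — the
package never translates the CDS itself.

```r
fc <- fatal_example_cohort()      # 30-patient fatal-variant worked example
report <- run_pipeline(fc)
report$fatal_variants
#>   variant      hom_carriers hom_deaths het_carriers het_deaths
#> 1 c.1111C>T               1          1            4          0
#> 2 c.1431-12G>A            3          3            3          0
#> 3 c.153delT              11          8            5          0
#> 4 c.1887+1G>A             2          1            0          0
#> 5 c.995delT               1          1            0          0
report$fatal_contingency
#>               infancy
#> zygosity       died survived
#>   homozygous     14        4
#>   heterozygous    0       12
#> chi-square = 17.5, df = 1, p = 2.87e-05 (uncorrected)
```

All five fatal variants are flagged; 18 homozygous carriers (14 infant
deaths) against 12 heterozygous carriers (0 deaths) give χ² = 17.5 on 1 df,
p ≈ 3×10⁻⁵ — homozygous carriage of a fatal variant is strongly associated
with death in infancy. `write_report(report, "out/")` emits the TSV/JSON
tables.

```r
sim <- simulate_cohort(simulation_config(n_patients = 162, seed = 7))
phenotype_summary(sim)$allele_regions
#>   region     n_alleles   pct
#> 1 DomainR-1        117 36.1
#> 2 DomainR-2         16  4.94
#> 3 DomainR-3          8  2.47
#> 4 DomainR-4         19  5.86
#> 5 DomainR-5        107 33.0
#> 6 non-domain        57 17.6
```

The simulator reproduces the hotspot structure (regions 1 and 5 dominate)
at realistic sampling noise for a 162-patient cohort.

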