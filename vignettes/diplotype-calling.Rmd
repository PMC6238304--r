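---
title: "Calling CYP2D6 star-allele diplotypes from unphased assay genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling CYP2D6 star-allele diplotypes from unphased assay genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cyp2d6star)
```

## The problem

CYP2D6 metabolises a quarter of commonly prescribed drugs, including
primaquine, the only widely available drug that clears *Plasmodium vivax*
hypnozoites. Primaquine is a prodrug: individuals with reduced CYP2D6
activity may fail radical cure. CYP2D6 genotyping is harder than for most
pharmacogenes because two neighbouring pseudogenes (CYP2D7, CYP2D8) share
more than 90% of its sequence, and because clinically relevant variation
includes whole-gene deletion (allele \*5), duplication, and partial gene
conversion to CYP2D7 in exon 9 (allele \*36), on top of SNPs.

This package models the downstream, computational half of such an assay: it
takes per-sample unphased genotype calls at a small panel of informative
SNPs, plus structural flags from long-range PCR (deletion band, duplication
band) and exon-9 sequencing (conversion evidence), and assigns star-allele
diplotypes; it then summarises cohorts (allele, genotype and SNP
frequencies, metabolizer-class burden, Hardy–Weinberg tests) and provides
assay-QC utilities and a synthetic-data generator so the whole pipeline is
testable without any external download.

## The allele model

The default allele-definition table covers the six alleles segregating in
the target population, over four informative SNP loci (gene-local, 1-based
coordinates on the M33388.1 reference):

| Allele | Defining content | Function class | Activity |
|-------:|------------------|----------------|---------:|
| \*1  | reference | normal | 1.0 |
| \*2  | C2850T (key), G4180C | normal | 1.0 |
| \*4  | C100T, **G1846A** (key, splice defect), G4180C | none | 0.0 |
| \*5  | whole-gene deletion | none | 0.0 |
| \*10 | **C100T** (key), G4180C | decreased | 0.5 |
| \*36 | C100T, G4180C + exon-9 conversion | decreased | 0.5 |

Two further variants seen only by full-exon sequencing (C1039T, G1661C) are
catalogued but deliberately assigned to no allele and excluded from the
informative loci: the definition table does not map them to alleles, and we
do not invent allele content. Their printed frequencies happen to match
\*4+\*10+\*36 and \*2+\*4+\*10+\*36 respectively, which suggests they ride
on those haplotypes, but this is not assumed anywhere.

Activity values follow the standard additive activity-score convention
(normal = 1, decreased = 0.5, none = 0), configurable in the JSON document;
the class labels, not the scores, are what the source assay reports.

```{r}
tab <- load_allele_table()
tab
```

## The caller

The assay is dose-blind beyond three states per SNP, and unphased. The
caller therefore enumerates all unordered allele pairs (15 two-copy pairs
plus 5 hemizygous pairs when the deletion band is present) and keeps those
whose *apparent* genotype matches every non-missing locus:

* the apparent alt dose of a pair at a locus is the number of member
  alleles carrying the variant;
* a deletion carrier is hemizygous, so the surviving haplotype appears
  homozygous at every locus (dose 0 → `ref_ref`, dose 1 → `alt_alt`); a
  heterozygous call alongside the deletion band is flagged inconsistent;
* exon-9 conversion evidence comes from Sanger sequencing and is matched as
  a dose under the same masking: `het` (double peaks) requires exactly one
  \*36, `hom` requires an apparently homozygous conversion (\*36/\*36 or
  \*36 over a deletion), `present` accepts either when zygosity was not
  recorded, and `absent` excludes \*36;
* when exon 9 was not examined (`untested`), \*36 is excluded from the
  candidate set by default: the SNP panel alone cannot distinguish \*36
  from \*10, and proposing \*36 without evidence would make nearly every
  \*10 call ambiguous. `allow_untested_exon9_ambiguity = TRUE` restores the
  fully agnostic behaviour;
* the duplication band only annotates a call
  (`duplication_present_copy_number_unresolved`); the assay cannot resolve
  which allele is duplicated or the copy number, so every sample
  contributes exactly two allele slots.

A unique survivor is the call. Several survivors are ranked by prior
weights (uniform by default; a pair scores `prior(a) * prior(b)`, doubled
for heterozygous pairs, ties broken lexicographically) but the status
remains `ambiguous` or — if an informative locus was missing —
`insufficient_data`. No survivors with complete data is `inconsistent`: the
profile is reported, never force-named. Two degenerate cases are defined
explicitly: deletion band with all loci missing is the homozygous deletion
(\*5/\*5, unique, noted), and masking a locus otherwise never shrinks the
candidate set.

```{r}
s <- sample_record("S1",
  c(C100T = "ref_alt", G1846A = "ref_ref",
    C2850T = "ref_alt", G4180C = "alt_alt"))
call_diplotype(s, tab)
```

## Cohort statistics

`summarize_cohort()` uses only uniquely called samples (excluded counts are
reported, never imputed). Allele counts sum to 2n with \*5 occupying a
slot; SNP frequencies are *derived from allele composition* — the frequency
of C100T is the summed frequency of \*4, \*10 and \*36 over all 2n slots.
This denominator convention (deletion slots included) is what reproduces
the published headline frequencies exactly; the source material itself is
inconsistent at one value (its abstract prints 0.32 for C2850T where its
own counts imply 46/140 = 0.329, printed elsewhere as 0.33), and this
package reports the count-derived value.

Per-locus Hardy–Weinberg exact tests use the standard conditional
enumeration over heterozygote counts (recurrence from the modal
configuration, so large cohorts are exact too); the test suite checks it
against a direct log-factorial enumeration for all configurations with
2n ≤ 20. Genotypes for the HWE test are the *apparent* ones, so
hemizygotes enter as homozygotes — the same ascertainment the assay has.

The bundled cross-population panel transcribes literature frequencies
under the defining-variant convention (the C100T column is the \*10
frequency, C2850T is \*2, G1846A is \*4, and so on; `ND` = not
determined). `compare_populations()` reports per-variant absolute
differences and a mean-absolute-difference divergence per population, with
ND columns excluded row-wise; sorting by divergence reproduces the
qualitative finding that the cohort sits closest to East and Southeast
Asian populations.

```{r}
cohort <- reconstruct_karen_cohort(tab)
calls <- call_batch(cohort, tab, quiet = TRUE)
summ <- summarize_cohort(calls, tab)
summ
round(100 * reduced_function_fraction(summ, tab))
head(compare_populations(summ), 4)
```

## Assay QC

`gc_percent()` rounds half-up to one decimal, matching the assay panel's
reported precision. The bundled panel of 36 primers and probes reproduces
every reported length exactly and primer GC% to ±0.1 (the probe rows are
reported as whole numbers, so they match to ±0.5).

`melting_temperature()` implements nearest-neighbor duplex thermodynamics
with two parameter sets. The default, Breslauer 1986 with
Schildkraut–Lifson salt correction at 50 mM Na⁺ and 50 nM oligo, is the
convention of classic primer-design software (Primer3's original default)
and reproduces the panel's reported primer Tm column within ±5 °C; the
SantaLucia 1998 unified parameters with entropic salt correction are
available via `method = "santalucia1998"`. Reported probe Tm values are
manufacturer-supplied (TaqMan chemistry) and are not expected to match a
naked-duplex model. Both parameter sets are verified in the test suite
against independently computed thermodynamic reference values.

`pairwise_identity()` scores a Needleman–Wunsch global alignment (match
+1, mismatch −1, gap open −2, gap extend −1) with gap columns included in
the denominator — a conservative reading of "sequence similarity".
`classify_amplicon()` calls an amplicon CYP2D6 only when its identity to
the CYP2D6 reference *strictly* exceeds the 95% threshold and every
pseudogene reference; a winner below threshold, or no strict winner, is
`indeterminate`, so a pseudogene can never be mistaken for the gene by a
tie.

The bundled intron-2 references are synthetic 1101-base stand-ins (the
real amplicon's length) at realistic pseudogene identities (~93% and
~91%): they exercise the classifier's decision geometry without shipping
third-party sequence data. A study using this package on real amplicons
should supply the GenBank references (M33388.1, M33387.1) instead.

## The synthetic cohort generator

`simulate_population()` draws each sample's two alleles i.i.d. from an
allele-frequency vector — Hardy–Weinberg equilibrium, the model assumed by
the frequency estimators — then renders assay-level records through the
same composition rules the caller inverts (`render_sample()`), applies
optional per-locus no-calls and duplication flags, and emits a truth table.
The default frequency vector is the study cohort's (0.214, 0.329, 0.021,
0.029, 0.400, 0.007 for \*1/\*2/\*4/\*5/\*10/\*36). All randomness flows
from one seed through inverse-CDF draws, so cohorts are reproducible
bit-for-bit.

What the generator emulates: HWE genotype structure, hemizygote masking,
missingness, truthful or withheld conversion evidence. What it does not:
genotyping error (calls are rendered exactly from the true pair),
population substructure or inbreeding, duplication dosage effects, and
novel alleles. Round-trip tests on simulated data therefore demonstrate
the caller's correctness as an inverse of the composition rules — not
robustness to miscalls, which the source assay addresses upstream by
duplicate genotyping and dual-method concordance.

`reconstruct_karen_cohort()` deterministically expands the published 11
genotype counts (3, 8, 3, 2, 10, 1, 7, 1, 23, 1, 11; total 70) into
rendered records. Duplication flags are left unset for all 70 — the study
reports two carriers but not which genotypes they had, and the flag
affects no frequency. The reconstruction is the package's end-to-end
fixture: calling and summarising it must reproduce every published count
and frequency, which the acceptance tests assert.

## Numerical and design choices

* **Problem sizes in the test suite.** The randomized-record oracle
  comparison runs 1,000 cases; parameter recovery simulates n = 5,000
  (±0.02 tolerance, comfortably above the ~3·SE ≈ 0.021 of a binomial
  proportion at p = 0.4); the identity-threshold simulation uses 100
  mutated 1.1 kb amplicons. These sizes make the checks sharp while the
  whole suite stays around a minute.
* **Determinism.** Ranking ties break lexicographically on the canonical
  pair label; pairs are always reported in ascending star-number order;
  seeds produce byte-identical cohorts.
* **Rounding.** Full precision internally; presentation rounding only at
  serialization (two decimals for allele/SNP frequencies, three for
  per-genotype frequencies, one for GC%; GC rounds half-up).
* **Genotype tokens.** The TSV dialect uses dose letters (R/A) to avoid
  strand ambiguity; a bases dialect ("C/T") is auto-detected against the
  catalog. VCF input is matched by rsID, and structural flags must come
  from a sidecar table since VCF carries no band data.

## Limitations

The caller is limited to the configured allele universe: profiles outside
it are reported `inconsistent`, never assigned a novel name. Copy-number
beyond the binary duplication flag is out of scope (so \*1xN-style calls
are not made), as are phasing from population LD, hybrid-tandem alleles,
and any upstream signal processing (fluorescence clustering, base
calling). The population comparison is descriptive (mean absolute
frequency difference), not a formal test of differentiation.
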