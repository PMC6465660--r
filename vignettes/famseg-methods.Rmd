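---
title: "Rare-variant segregation analysis in multiplex families: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant segregation analysis in multiplex families: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famseg)
```

## The analysis model

`famseg` implements the post-calling half of a familial rare-variant exome
study. The underlying genetic model is a dominant one: in a family with
several affected members, a causal variant is expected to be rare in the
population, protein-altering, predicted deleterious, carried (het or hom) by
every affected member, and absent from unaffected members. Because any one
family yields tens of variants compatible with that pattern by chance, the
design aggregates evidence across families — variants segregating in two or
more families, genes hit by several segregating variants in different
families — and finally asks, per gene, whether affected members carry
qualifying alleles more often than Mendelian transmission alone would
produce.

Three phenotype states are modelled. *Affected* and *unaffected* members
constrain the analysis in opposite directions; *suggestive* members
(intermediate clinical findings, neither clearly affected nor clearly
clean) are deliberately ignored by every filter in both directions: they
neither rescue nor kill a variant. Their genotypes are still carried in
reports for inspection.

The complete-penetrance assumption behind "absent from unaffected members"
is relaxed through *penetrance exemptions*: a configurable list of
unaffected individuals (supplied as ids, not hard-coded families) that every
unaffected-carrier rule skips. This models the obligate-carrier situation
seen when an unaffected parent must connect affected relatives.

## Stage by stage

**Preparation** (`qc_prefilter`, `decompose_multiallelic`, `hwe_exact_p`).
Multiallelic sites are split into one biallelic record per alt allele; each
sample's alt count for record *k* is the number of allele-*k* copies in the
original genotype, so allele copies are conserved. Shared bases between ref
and alt are trimmed — leading bases first (advancing the position), then
trailing, always keeping one base of each. Left-alignment against a
reference genome is not performed: there is no FASTA input anywhere in the
pipeline, and prefix/suffix trimming is sufficient for non-repetitive
contexts; in repeat regions externally normalised input is expected.

The Hardy–Weinberg exclusion uses the exact conditional test (heterozygote
count given fixed allele counts); the p-value sums the probabilities of all
outcomes no more probable than the observed one, with a relative tolerance
of 1e-10 on the tie comparison so that floating-point noise cannot split a
tie. Exclusion is strict (`p < 1e-8` removes; equality retains). The test is
computed over all genotyped samples by default, which matches a joint
dataset of families plus a sequencing cohort but is biased by relatedness
when only family members are present; the sample set is an argument
(`hwe_samples`) for that reason, and whether founders-only would be the
better default is left to the analyst. The minor-allele-count rule removes
variants that do not vary in the family samples (MAC = 0, counting either
allele as potentially minor).

**Rarity and deleteriousness** (`filter_config`, `apply_rare_filters`).
Defaults: population MAF ≤ 1% or ≥ 99% per source (six reference-panel
sources by default; the flipped branch catches annotation against the minor
reference allele and applies only to panel sources, not the in-cohort
control MAF, which is already folded), control MAF < 1%, CADD phred ≥ 20
(about the top 1% most deleterious substitutions genome-wide; the threshold
is inclusive, and a missing score passes only for indels, which CADD
releases frequently leave unscored), retained effect classes =
{frameshift/non-frameshift indel, nonsynonymous, stop gain/loss, splicing,
unknown effect}. Splicing is retained because splice-site variants are
protein-altering under the exonic-or-splice retention convention this
cascade follows. A missing population frequency counts as rare — absence
from large panels is itself evidence of rarity — while a missing effect
class fails, since a protein-altering consequence cannot be confirmed for an
unannotated variant. Both policies are configurable. The adult-onset
secondary-findings genes (BRCA1, BRCA2, MLH1, MSH2, MSH6, PMS2, MUTYH) are
excluded outright. Rules apply in a fixed cascade order and each variant
records the first rule it failed; the retained set is order-independent, and
is monotone in the thresholds (property-tested).

**Segregation** (`remove_global_unaffected_carriers`,
`segregating_variants`). The global unaffected-carrier removal and the
per-family "absent in unaffected" check are kept as two stages for fidelity
to the conventional workflow; under the stated rules the two orderings give
identical retained sets, which a test asserts. Missing genotypes are
asymmetric by design: missing in an affected member fails "present in all
affected" (conservative — carriage cannot be confirmed), missing in an
unaffected member is not carriage (removal requires evidence). Both appear
as explicit branches in `classify_segregation`. Output ordering is fixed at
(family, chromosome, position, alt), lexicographic on the character fields,
so that repeated runs diff cleanly; no claim of karyotype order is made.

**Cross-family aggregation** (`shared_variants`, `multi_variant_genes`).
"Genes containing multiple variants that segregated in two or more
families" is read as: at least two distinct segregating variants whose
contributing families pool to at least two. This admits a gene with two
same-family variants plus one in another family, which matches how such
gene lists are compiled in practice; the stricter reading (every variant
itself shared by two families) is available as `strict = TRUE`. Genes with
two segregating variants inside a single family are a different observation
and are reported separately (`within_family_multihit`). The cohort summary
reports the mean segregating count both exactly and rounded, so headline
integers remain reproducible without hiding precision.

**Gene burden** (`family_burden_test`). The statistic is
S = Σ over families (affected carriers − non-exempt unaffected carriers),
a carrier being a genotyped member with ≥ 1 alt allele at ≥ 1 qualifying
variant of the gene; the qualifying set is, by convention, every rare
variant of the gene surviving the cascade (before segregation filtering),
per family. The null holds founder genotypes at their observed values — in
the rare-variant setting the variant's presence in the family is given, so
resampling founder carriage from population frequencies would test the
wrong hypothesis — and re-drops every meiosis: each non-founder receives
one allele drawn uniformly from each parent's two, independently across
meioses, variants and iterations (no linkage between a gene's variants is
modelled). The permutation p-value uses the +1 convention,
p = (1 + #{S_null ≥ S_obs})/(n + 1), which cannot return 0.

Two design points deserve emphasis:

* *Founder imputation and ascertainment.* When no genotyped founder
  carries a variant but genotyped descendants do, a carrier founder must be
  imputed. The minimal explanation is a single heterozygous founder among
  the ungenotyped founders ancestral to an observed carrier, drawn
  uniformly per iteration. Imputation alone, however, biases the test: the
  founder is imputed *because* carriage was observed, so the observed
  statistic is conditioned on an event the plain null is not, and measured
  type-I error exceeds nominal (0.067 at α = 0.05 over 2,000 null genes).
  The null draws for such variants are therefore rejection-resampled until
  at least one genotyped member carries — the same conditioning the
  observation went through. After this correction the measured type-I error
  is 0.056, inside the 99% binomial band. Observed carriage that is
  Mendelian-inconsistent with genotyped founders (all hom-ref) leaves the
  family's null at its observed founders; such data indicate upstream
  genotyping error and are surfaced rather than repaired.
* *Seed streams.* A single master seed expands into per-gene streams via a
  32-bit FNV-1a hash of the gene symbol, so a scan's results are invariant
  to the order genes are evaluated and stable when the gene set changes.

## The synthetic cohort generator

`simulate_dataset()` emulates the study conditions the pipeline is built
for: 18 families of 2–7 genotyped members over two or three generations,
phenotypes drawn to hit 33 affected / 18 suggestive / 21 unaffected out of
72 in expectation (at least one affected per family), an occasional
ungenotyped relative, rare background variants on a log-uniform MAF
spectrum in [1e-4, 0.2] transmitted by gene dropping from founder genotypes
drawn at the variant's MAF (hence in Hardy–Weinberg proportions in
expectation), a couple of two-alt multiallelic sites, planted variants with
scripted segregation behaviour (fully segregating in chosen families,
incomplete, or null), and three deliberate violators of each preparation
and filter rule — the Hardy–Weinberg violators by explicit genotype-count
distortion (every sample heterozygous), flagged as such in the truth table.
Genotype missingness is applied to background variants only, never to
planted variants or violators, so every truth-table fate is deterministic.
Null-mode plants transmit founder alleles drawn at a 30% carrier rate so
the burden statistic has usable support during calibration.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: sequencing and calling error, depth- or
quality-dependent missingness, linkage disequilibrium between background
variants, realistic exome site density, population structure in the
frequency annotations, and X-chromosome hemizygosity (carriage is "alt
count ≥ 1" everywhere; the generator emits autosomes only). The pipeline's
correctness on real cohorts additionally depends on upstream calling,
normalisation and annotation quality, which are out of scope here.

## Validation problem sizes

The test-suite checks run at sizes chosen to make their statistical
assertions sharp while keeping a full run in minutes: the Hardy–Weinberg
implementation is swept exhaustively against an independent enumeration for
every genotype configuration up to 200 samples (and against a brute-force
allele-placement oracle at tiny sizes); burden calibration uses 2,000
simulated null genes at 400 iterations each (the acceptance script uses
1,000 genes); the nuclear-family exact check uses 10^5 iterations against
the closed-form 1/8; end-to-end recovery runs on the default 18-family
cohort with ~330 variants.

## Known limitations

Annotation is taken at face value, one gene symbol per variant; variants
spanning several genes need an upstream policy. Compound heterozygosity is
not interpreted (within-family multi-hit genes are reported, not modelled).
The burden statistic weighs every qualifying variant equally; no frequency
or deleteriousness weighting. The Hardy–Weinberg filter applied to related
samples is conservative in unpredictable directions; when in doubt restrict
`hwe_samples` to unrelated individuals. The odds-ratio helper treats
alleles as independent observations, which overstates precision for related
carriers — it is a lookup aid for external case–control counts, not a
family association test.
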