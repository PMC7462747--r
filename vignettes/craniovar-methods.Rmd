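---
title: "Methods: variant stratification, burden and family genetics for craniosynostosis"
author: "craniovar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant stratification, burden and family genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craniovar)
```

# The problem

Craniosynostosis (CRS) — premature fusion of one or more cranial sutures —
has a birth prevalence of roughly 1 in 2000. A substantial monogenic
contribution comes from heterozygous variants in single genes (the model
case being the BMP/TGF-β inhibitor *SMAD6*), but with a penetrance far below
1: most carriers never manifest. This combination shapes every analysis this
package performs:

* candidate variants cannot be filtered at the usual "absent from
  controls" stringency, because a low-penetrance causative allele *is*
  expected in population databases — but only up to a computable ceiling;
* burden must be measured as enrichment against a large reference
  population rather than by co-segregation;
* penetrance must be estimated indirectly, from recurrence in siblings
  under the Mendelian transmission probability, because unaffected
  relatives are typically not genotyped;
* the search for modifiers (a second, common locus that determines which
  carriers manifest) needs exact small-sample tests with a direction fixed
  a priori.

# The frequency framework

## Maximum credible allele frequency

For a disease of prevalence $\phi$, a gene accounting for a fraction $g$ of
cases, a single allele accounting for a fraction $a$ of that gene's cases,
an inheritance factor $i$ (0.5 for a heterozygous monoallelic model: a
carrier contributes one of two chromosomes), and penetrance $\pi$, no truly
causative allele can exceed

$$\mathrm{AF}_{\text{max credible}} = \frac{\phi \, g \, a \, i}{\pi}.$$

The default `disease_model()` uses $\phi = 1/2000$, $\pi = 0.2$, $i = 0.5$
and a heterogeneity product $g \times a = 0.036$, giving the threshold
$4.5\times10^{-5}$ used throughout. Only the product $g a$ enters the
formula; the shipped split ($g = 0.12$, $a = 0.30$) is a provisional
factorisation chosen to be plausible for a gene contributing on the order of
a tenth of monogenic CRS, and users modelling another disease should set
all five fields themselves. The formula is exactly multiplicative, which
the tests exploit: doubling penetrance halves the threshold.

## AF_max

Each variant is summarised by $\mathrm{AF}_{\max}$, the greater of

1. the maximum allele frequency in any single reference population in which
   **at least 2 alleles** were observed (a single observation carries no
   frequency information beyond the overall rate), excluding the
   heterogeneous "Other" grouping; and
2. the overall allele frequency, with no minimum-count requirement — this
   clause is a fallback, not a filter.

Consequently $\mathrm{AF}_{\max} \ge \mathrm{AF}_{\text{overall}}$ always,
a property the tests check on random frequency records. Bottleneck
populations (ASJ, FIN) can additionally be excluded via
`stratification_config(excluded_populations = …)`, but are not by default.
A variant is **rare** iff $\mathrm{AF}_{\max}$ is *strictly* below the
threshold; the boundary value itself is not rare.

# Deleteriousness

A variant is **damaging** when it is predicted loss-of-function —
frameshift, stop-gain, or canonical ±1,2 splice donor/acceptor; splice-region
changes outside these positions are deliberately *not* auto-LoF — or when
its **deleteriousness score (DS)** reaches the threshold (default 4 of 6).
The DS is the count of in-silico predictors whose score meets its threshold
in the deleterious direction. The shipped panel (SIFT, PolyPhen-2 HDIV and
HVAR, MutationTaster, MutationAssessor, FATHMM, with dbNSFP-convention
thresholds) is a sensible default, not a doctrine: the panel is a plain
data frame argument and is the source of truth for names, directions and
thresholds.

Two conventions matter in sparse annotation data. An unavailable score
counts as "not deleterious" but the number of available scores is always
reported, so DS 4/4-available is distinguishable from 4/6; and a missense
variant with *no* available scores is flagged unevaluable and classified
not damaging with a warning, rather than silently passing or failing.

The joint filter keeps a variant iff it is rare **and** damaging. It is
idempotent, invariant to input order, monotone in both thresholds (raising
the AF threshold can only grow the kept set; raising the DS threshold can
only shrink it), and reports, per variant, which rule(s) failed.

## 5′ UTR variants

UTR substitutions escape both the LoF classes and missense predictors, yet
can abolish translation by creating an upstream ATG. `detect_upstream_atg()`
applies the edit and compares every trinucleotide window overlapping the
edited base before and after: a uATG is *created* only if a window that was
not ATG becomes ATG. Frame is judged by whether the distance from the new
A to the main-ORF A is a multiple of 3; an out-of-frame uATG opens an
upstream ORF that suppresses the main one. Offsets are 0-based within the
supplied sequence, and the main-ORF distance is given explicitly, so the
function needs no transcript model.

# Cohort statistics

## Fisher's exact test

All burden and association P values come from one in-package exact test
with fixed conventions: one-tailed sums the hypergeometric tail in the
direction of the observed association (or in a direction fixed a priori via
`"greater"`/`"less"`); two-tailed sums all tables, at fixed margins, whose
point probability does not exceed the observed one — the convention of
mainstream statistical software. A zero margin returns $P = 1$ with a
degeneracy note rather than an error. The implementation is enumeration
over the hypergeometric support; the test suite verifies it against an
independent binomial-coefficient oracle on *every* 2×2 table with total
$N \le 30$ (46 376 tables) and against `stats::fisher.test` on random
larger tables.

## Enrichment and contrasts

`lof_enrichment()` is a rate ratio with a one-tailed exact P. For
heterozygous carriers compared against a population allele count, the case
denominator is on the allele scale (2 × probands); with the model cohort's
counts — 9 LoF among 2×795 alleles vs 9 LoF in 29 066 reference alleles —
it reports an 18.3-fold excess at $P < 10^{-7}$. `subtype_contrast()` is
the two-group analogue with a two-tailed P (metopic vs sagittal: 6.1-fold,
$P = 0.002$). `prevalence_table()` produces the suture-class × syndromic
cross-tabulation with margins consistent by construction. Percentages are
conventionally printed at 2 decimals in tables and 1 in prose
(`format_percent()`); fold changes at 1 decimal; P values at 2 significant
figures.

# Family genetics

## Transmission and penetrance

`summarize_transmission()` partitions families by the proband's parental
carrier status: de novo (both parents known noncarriers), maternal,
paternal, or unknown origin (no known carrier parent, at least one parent
unknown or unavailable). Both-parents-carrier families are surfaced as
anomalies, never assigned. The designated proband is the first affected
carrier offspring.

Penetrance is estimated as recurrence / transmission: among additional
(non-proband) offspring of a heterozygous transmitting parent, each
inherits the variant with probability $\tau = 0.5$, so the observed
recurrence risk $r$ among *all* such offspring estimates $\tau\pi$ and
$\hat\pi = r/\tau$ (capped at 1 with a warning). With the model cohort's 2
affected among 25 additional offspring, $\hat\pi = 0.08/0.5 = 0.16$. The
estimate inherits whatever ascertainment bias the counting scheme has;
proband-based ascertainment is the reason the proband is excluded from both
numerator and denominator.

## TDT and the two-locus model

The transmission disequilibrium test uses
$\chi^2 = (b-c)^2/(b+c)$ on transmitted vs untransmitted alleles from
heterozygous parents to affected offspring, with **no continuity
correction** — the uncorrected statistic is the standard TDT and, at the
model counts 12 vs 7, gives $\chi^2 = 1.32$, $P = 0.25$ (the Yates-corrected
value would not reproduce this). `count_tdt_alleles()` assembles the counts
from pedigrees by Mendelian resolution: a heterozygous parent's transmitted
allele is counted only when the offspring genotype and the other parent's
possible contributions force it; both-parents-CT / offspring-CT trios are
reported as unresolved, and genotype configurations with no Mendelian
solution are flagged and excluded.

The two-locus table dichotomises major-gene carriers by modifier risk
allele presence (dominant coding, CC or CT vs TT) against affection. The
one-tailed direction — risk allele increases manifestation — is fixed a
priori, being the hypothesis under replication, not chosen from the data.
Tables from independent studies are merged by elementwise summation
(associative and commutative) with the exact P recomputed on the sums.

# The synthetic-cohort generator

The generator exists so that every stage runs against known ground truth.
Its defaults *are* the study conditions, not tuning knobs.

**Variant tables** (`simulate_variant_table()`): six populations with
gnomAD-exome-scale allele numbers (NFE 113 000 down to OTH 6 000 alleles);
benign variants log-uniform in AF between $10^{-6}$ and $10^{-2}$, so some
fall below the rarity threshold and only the DS separates them; pathogenic
variants below $10^{-5}$ and additionally truncated to at most one observed
allele per population, making them rare *by construction* (hence LoF
sensitivity of the joint filter is exactly 1, and the interesting operating
characteristic is benign leakage). Half the pathogenic variants are LoF,
matching a cohort where roughly half the implicated probands carry
truncating alleles; per-predictor deleterious-call probabilities are 0.9
(pathogenic) vs 0.15 (benign), under which benign DS ≥ 4 has binomial
probability ≈ 0.006. Allele counts are binomial draws at the configured
allele numbers, so realised AC/AN are internally consistent.

**Pedigrees** (`simulate_families()`): nuclear families with one
heterozygous carrier parent (clinically unaffected, as in
proband-ascertained low-penetrance cohorts) or a de novo proband (rate
0.12 ≈ 3/26); transmission 0.5; penetrance 0.16; modifier risk-allele
frequency 0.327 (the non-Finnish-European frequency of the model SNP) with
parental genotypes at Hardy–Weinberg proportions and Mendelian segregation
to offspring. Under ascertainment (the default) each family contains a
forced affected carrier proband and the *additional* offspring are
simulated freely — mirroring clinical ascertainment and keeping recurrence
among additional offspring an unbiased estimator of $\tau\pi$, which is
what makes the parameter-recovery test exact rather than approximate. A
modifier effect, when simulated, is a penetrance pair (with/without risk
allele) applied to the offspring's own genotype, mirroring how the 2×2
analysis dichotomises carriers; an odds-ratio parameterisation would be a
wrapper around the same pair.

**Operating characteristics**
(`evaluate_operating_characteristics()`): across seeded replicates, the
rejection fraction of the one-tailed two-locus test (type-I error under no
effect — expected *below* nominal $\alpha$, the exact test being
conservative at these sample sizes — or power under an effect) and the bias
and RMSE of the penetrance estimator. Replicate seeds are `seed + 1:n_reps`;
all generators confine randomness to a locally seeded RNG and restore the
caller's `.Random.seed`.

What the simulations do **not** emulate: linkage disequilibrium beyond one
biallelic SNP, population substructure within a cohort, relatedness between
families, sequencing or genotyping error, and real predictor-score
correlation structure (scores are drawn independently per predictor).
Passing tests therefore demonstrate the statistical machinery is correct
under the stated model, not that the model captures every feature of real
resequencing data.

# Numerical choices and problem sizes

* Rarity is a strict inequality at the threshold; DS uses
  meets-or-exceeds in the deleterious direction.
* Two-tailed Fisher uses point-probability ≤ observed with the customary
  $1+10^{-7}$ tolerance factor against floating-point ties.
* The exhaustive Fisher validation covers all tables with $N \le 30$;
  stratification property tests use 120–400 simulated variants; marginal
  checks use ≈1500 unascertained families; penetrance recovery uses 700
  families (≥ 500 additional offspring) at $\pi \in \{0.1, 0.16, 0.3\}$;
  the type-I error run uses 1000 replicates of 26 families. These sizes
  give Monte-Carlo standard errors comfortably inside the 3-SE acceptance
  bands while keeping the whole suite fast on a single CPU.
* Stochastic tests fix their seeds. A 95% interval check over three
  penetrance settings fails for ~14% of seeds by design; the suite runs
  the check once with the seed recorded in the test, and the
  interpretation of a rare boundary failure is nominal coverage, not a
  defect.

# Known limitations

* Penetrance estimation implements the transmission arithmetic directly
  and does not correct for ascertainment beyond excluding the proband;
  likelihood-based segregation analysis is out of scope.
* Consequence classes are consumed as input; the package contains no
  annotation engine, and HGVS strings are carried as opaque identifiers.
* The raised-intracranial-pressure style comparison is exposed only as a
  generic `fisher_exact()` on user-supplied counts, because its
  denominators are study-specific.
* The predictor defaults and the heterogeneity split in `disease_model()`
  are explicitly provisional; both are configuration, not findings.
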