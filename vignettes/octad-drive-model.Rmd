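---
title: "Modelling meiotic drive of supernumerary chromosomes in octads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling meiotic drive of supernumerary chromosomes in octads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octadrive)
```

## The biological setting

*Zymoseptoria tritici* is a haploid, heterothallic ascomycete: sexual
reproduction requires a `mat1-1` and a `mat1-2` partner, one of which takes
the female role (forms the ascogonium and donates the mitochondria) while
the other contributes a nucleus as the male. After karyogamy the diploid
zygote undergoes meiosis I and II followed by one post-meiotic mitosis, so
each ascus holds eight ascospores — four pairs of genetically identical
twins. This octad structure is what makes tetrad analysis possible: isolating
and genotyping all eight spores of a single ascus exposes individual
meioses.

The species carries up to eight supernumerary (accessory) chromosomes,
`chr14`–`chr21`, that are dispensable and polymorphic in presence across
isolates. When the two parents carry different complements, the zygote
contains chromosomes without a pairing partner. Under Mendelian
segregation an unpaired chromosome reaches one pole at meiosis I and ends
up in 4 of 8 spores (a 4:0 ratio); a paired chromosome segregates 4:4 by
parental origin. The phenomenon this package models is a *female-restricted
meiotic drive*: unpaired chromosomes inherited from the female parent are
amplified so that both copies pair and segregate into **all eight** spores
(8:0), while the same chromosomes inherited from the male side remain
Mendelian.

## The generative model

`simulate_octad()` tracks individual chromatids through one sexual cycle,
per supernumerary chromosome:

1. **Mechanism step.** Under `female_drive`, each unpaired female-inherited
   chromosome is duplicated with probability `drive_penetrance`; the two
   copies then behave as a bivalent. Under `premeiotic_amplification` every
   female supernumerary is duplicated before karyogamy; with
   `amplification_copy_loss = TRUE` the surplus copy of each paired
   chromosome is discarded again before meiosis I, with `FALSE` the zygote
   stays trisomic for paired chromosomes. The other mechanisms perform no
   amplification.
2. **Replication**: every chromosome copy becomes a pair of sister
   chromatids.
3. **Chromatid loss**: each chromatid is independently lost with
   probability `loss_rate`.
4. **Meiosis I**: bivalents disjoin to opposite poles (failing with
   probability `mi_nondisjunction_rate`, which sends both homologs to one
   pole); univalents go to a uniformly random pole, except under
   `preferential_segregation`, where they reach the designated pole with
   probability `preferential_bias`.
5. **Meiosis II**: sister chromatids disjoin; with probability
   `nondisjunction_rate` both end up in one product.
6. **Twin mitosis**: meiotic product *i* duplicates into spores *2i−1* and
   *2i*, which are identical in every field (post-meiotic mutation is not
   modelled).
7. **Spore killing** (only under that mechanism) removes every spore
   lacking the killer chromosome.
8. All surviving spores receive the female parent's mitochondrial
   haplotype; the six core markers each split 2:2 across the meiotic
   products (4:4 across spores).

Core markers assort freely: each marker independently assigns the
parent-1 allele to a uniformly chosen 2-subset of the four products. This
is the free-recombination limit; it slightly *overstates* the power of the
marker panel to distinguish products compared to markers with centromere
linkage, but it keeps the 4:4 invariant exact.

### Why chromatid-level loss?

Observed deviations from 4:4/4:0 combine chromosome loss, meiosis-II
non-disjunction of sister chromatids and meiosis-I non-disjunction of
homologs, without per-stage rates being identifiable. We implement loss as
one Bernoulli event per *chromatid* at meiosis I. One event deletes one
meiotic product's contribution, i.e. one twin pair of carriers, producing
the characteristic 6:2 patterns for paired chromosomes and 2:6 patterns for
unpaired ones. A convenient consequence is that for paired chromosomes the
per-spore marker-absence frequency equals `loss_rate` exactly, so
`estimate_loss_rate()` is an unbiased estimator of the configured rate.

### Non-disjunction and disomy

With sister chromatids tracked by parental origin, meiosis-II
non-disjunction at one pole yields a *same-parent* disomic twin pair
(copies `(2,0)`), its sister product empty, and four normal spores.
Cross-parent disomy (`(1,1)`, as reported for chromosome 21 with one copy
from each parent) arises from meiosis-I non-disjunction — which here gives
four `(1,1)` and four null spores — or from meiosis-II non-disjunction after
a crossover between centromere and marker, which we do not model on
supernumerary chromosomes (their recombination rates are low). The
classifier is agnostic: `detect_disomy()` flags any spore with two or more
total copies, covering both origins.

### The sexual-role model

Only the *direction* of the density effect is constrained by observation:
the partner inoculated at lower density tends to take the female role. We
adopt the simplest form with the right symmetry,

$$P(\text{parent 1 female}) = \frac{d_2^{\,a}}{d_1^{\,a} + d_2^{\,a}},$$

with exponent $a$ (`density_exponent`) defaulting to 1. Equal densities
give 1/2; the probability is monotone in the density ratio; $a$ tunes how
sharply the role responds.

## Ascus verification

`verify_ascus()` applies the acceptance rule used for real tetrads: exactly
eight spores, every core marker splitting 4:4, and every spore having
exactly one marker-identical twin — asci failing the twin rule are rejected
even at perfect 4:4 ratios. Twin profiles use the six core markers plus the
mitochondrial marker (which is ascus-constant, so it can only reject
foreign spores, never split true twins).

One subtlety of the strict twin rule: with six freely assorting binary
markers, two meiotic products share an identical marker profile with
probability about $6 \times (1/3)^6 \approx 0.8\%$ per ascus. Those asci
contain four true twin pairs but are *unresolvable* by the panel, and the
rule correctly rejects them as ambiguous (`twin_multiple`). Verification of
clean simulated octads is therefore slightly below 100% by design; the
property the tests pin down is that verification succeeds exactly when the
four products carry distinct marker profiles.

## Segregation classification

`classify_octads()` produces one record per (ascus × chromosome) with
carrier counts by parental origin and a unique label, assigned with
priority `disomy` > `total_absence` > `drive_8_0`/`partial_drive` >
`mendelian_4_4`/`mendelian_4_0` > `loss_deviation`. `partial_drive`
(5–7 carriers) is kept as its own class so that incompletely driven asci —
e.g. an unpaired chromosome present in six of eight spores — remain
countable. Pairing status is expressed relative to the female parent
(`unpaired_female` / `unpaired_male`), inferred per ascus from the
mitochondrial haplotype. "Presence" is marker-level (at least one copy),
matching PCR detection; copy number is used only for disomy.

## Statistics

* `binomial_drive_test()` is the exact two-sided binomial test against
  p = 0.5, two-sided by the minimum-likelihood convention (the sum of all
  outcome probabilities not exceeding that of the observation). The
  convention matters: for 6 carriers of 24 the exact two-sided p-value is
  ≈ 0.023, while other two-sided constructions or inputs can give
  substantially larger figures (values near 0.25 are sometimes quoted for
  18-vs-6 splits); we therefore state and test the convention explicitly
  rather than matching any particular reported number.
* `contingency_test()` uses Fisher's exact test and switches to Pearson's
  chi-squared (no continuity correction) when the table total reaches 200
  *and* all expected counts are at least 5 — "large datasets" made
  concrete; the threshold is an argument.
* `randomize_one_per_ascus()` implements the independence correction for
  mitochondrial statistics: all spores of an ascus share one mitochondrial
  genotype, so one spore per ascus is drawn.
* No multiple-testing correction is applied; reports carry raw p-values
  with the star thresholds `*` 0.05, `**` 0.005, `***` 0.0005
  (`sig_stars()`).
* `estimate_loss_rate()` counts, by default, spore × paired-chromosome
  instances (`by = "spore"`), the denominator that matches whole-progeny
  marker screens; `by = "ascus"` exposes the per-meiosis aggregation.
  Heterogeneity across chromosomes is a chi-squared test on the
  loss/no-loss table.

## Mechanism discrimination

`discriminate_mechanisms()` encodes three falsifications: verified complete
octads rule out spore killing; majority 8:0 transmission of female-inherited
unpaired chromosomes rules out Mendelian segregation and preferential
segregation (both capped at 4 carriers because all four meiotic products
become spores); and 4:4 paired segregation without a disomy excess rules
out pre-meiotic amplification, whose trisomic zygotes would scatter extra
copies through the tetrads. "Majority" is implemented as a fraction
above 0.5 of the relevant records — the inputs here are zero-likelihood
contrasts, so any threshold away from the boundaries gives the same answer
on clean data. Two identifiability limits are reported honestly rather than
resolved: preferential segregation is indistinguishable from Mendelian
segregation in complete octads, and pre-meiotic amplification *with*
counteracting copy loss is indistinguishable from the meiotic female drive
(it is disfavoured on parsimony, not excluded by the data).

## The SNP sharing spectrum

`simulate_snp_matrix()` emulates the whole-genome octad view:
alternate-parent SNPs occupy exactly two of four chromatids at every locus
(crossovers reshuffle haplotype blocks but conserve the 2-of-4 count), so
every SNP is truly present in four spores. Departures come from three
modelled sources:

* **Gene conversion** is modelled as post-meiotic segregation of an
  unrepaired heteroduplex: a tract (default 2 kb) flips in a *single spore*
  of a twin pair, moving affected SNPs to 3 or 5 of 8 — the classic 5:3
  octad ratios. Full conversion (6:2) is not modelled separately; it is
  observationally a double event.
* **Coverage**: a per-site depth is Gamma-distributed
  (`coverage_dispersion` = shape) and per-spore counts are Poisson around
  it; the margin is negative-binomial and coverage is correlated within a
  site, which is what makes coverage filters informative — low-depth sites
  both lose presence calls and fail the filter.
* **Dropout**: independent per spore-site miss probability.

`filter_by_coverage()` implements the ">8X" filters with strict inequality
as printed (a flag allows ≥). The "at all occurrences" wording is ambiguous
about spores where the SNP is absent but covered, so both readings exist:
`min_cov_all` (threshold met wherever presence is claimed, site scored in
all eight spores) and `min_cov_all_spores` (threshold met in all eight).
The filters nest, and the k = 4 fraction is non-decreasing along
`none → min_cov_any → min_cov_all` — the enrichment direction the test
suite checks without pinning data-dependent percentages.

## What the generator does and does not emulate

Simulated octads reproduce: twin structure, 4:4 core-marker ratios,
uniparental mitochondria, the 4:0/8:0 contrast, chromatid-scale loss and
non-disjunction patterns, killer-depleted asci, and Mendelian SNP blocks
with conversion and coverage noise. They do **not** emulate: partial
chromosome amplification (an incompletely amplified chromosome observed in
one real ascus), the ~400 kb chr14 insertion polymorphism or any
sequence-level structure, centromere-linked marker segregation, mutation,
or the developmental biology of mating. Passing tests therefore validate
the *logic* of verification, classification and inference, not the full
noise structure of real PCR or sequencing data.

## Numerical and design choices

* Probabilities are validated into `[0, 1]` (`preferential_bias` into
  `[0.5, 1]`); densities must be positive; `n_asci ≥ 0`.
* One master seed; per-ascus substreams are derived by counter, so
  enlarging an experiment never perturbs earlier asci, and every pipeline
  output is byte-identical under a fixed configuration.
* `drive_penetrance` accepts per-chromosome values (e.g. `c(chr14 = 0)`)
  to encode the one chromosome that escapes the drive; no mechanistic model
  of that exception is attempted.
* Degenerate inputs: empty experiments produce schema-valid empty tables;
  empty spore tables and recordless discriminations raise "no data" errors;
  degenerate contingency tables (zero margins) are errors, not NaNs.
* Default problem sizes in the test-suite and worked examples are a few
  hundred to a few thousand octads and a few thousand SNP sites — large
  enough that the exact invariants (50% transmission, 4:0, 8:0) are checked
  over every ascus and stochastic recoveries sit inside exact binomial
  intervals, while a full run stays in the minutes range on one core.

## Worked example

```{r, eval = FALSE}
cfg <- cross_config(ipo323(), ipo94269(), mechanism = "female_drive",
                    n_asci = 100, seed = 42)
octads <- simulate_experiment(cfg)
verification <- verify_octads(octads)
records <- classify_octads(octads, cfg$cross)
discriminate_mechanisms(records, any(verification$valid))
test_transmission(transmission_table(octads, "chr18"))
autoplot(sharing_spectrum(filter_by_coverage(
  simulate_snp_matrix(2000, coverage_mean = 12, seed = 42), "min_cov_any")))
```
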