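# octadrive

Tetrad analysis and simulation of supernumerary-chromosome meiotic drive in
the wheat pathogen *Zymoseptoria tritici*.

## The problem

*Z. tritici* is a haploid ascomycete whose genome carries up to eight
dispensable supernumerary (accessory) chromosomes, `chr14`–`chr21`. Each
meiosis, followed by one post-meiotic mitosis, yields an ascus of eight
ascospores — four identical twin pairs (an *octad*). When the two parents
of a cross carry different chromosome complements, the zygote contains
unpaired chromosomes, and Mendelian expectation is clear: an unpaired
chromosome should reach 4 of the 8 spores (a 4:0 ratio, 50% of all
progeny), a paired chromosome 4:4 by parental origin.

Unpaired chromosomes inherited from the *female* (mitochondria-donating)
parent break this expectation: they are amplified during meiosis and
transmitted to **all eight** spores (8:0) — a female-restricted meiotic
drive — while the same chromosomes inherited from the male parent segregate
4:0, and paired chromosomes segregate 4:4 with occasional losses. The
package provides everything needed to generate, detect and discriminate
this signature at desk scale:

* a **mechanistic octad simulator** (`simulate_octad()`,
  `simulate_experiment()`) tracking individual chromatids through
  amplification, meiosis I/II with loss and non-disjunction, and the twin
  mitosis, under five competing mechanisms: `mendelian`, `female_drive`,
  `premeiotic_amplification`, `preferential_segregation`, `spore_killing`;
* **ascus verification** (`verify_octads()`): eight spores, every core
  marker 4:4, every spore exactly one marker-identical twin;
* **segregation classification** (`classify_octads()`): per (ascus ×
  chromosome) labels `mendelian_4_4`, `mendelian_4_0`, `drive_8_0`,
  `partial_drive`, `disomy`, `loss_deviation`, `total_absence`, plus
  mito-conditioned transmission tables;
* **drive statistics** (`binomial_drive_test()` — exact two-sided binomial
  against p = 0.5; `contingency_test()` — Fisher with a chi-squared
  large-sample switch; `randomize_one_per_ascus()`;
  `estimate_loss_rate()` with chi-squared heterogeneity);
* **mechanism prediction and discrimination**
  (`predict_patterns()`, `discriminate_mechanisms()`), encoding the
  falsification logic: complete octads exclude spore killing, 8:0
  majorities exclude Mendelian and preferential segregation (support ≤ 4),
  clean 4:4 paired segregation excludes pre-meiotic amplification;
* a **SNP octad-sharing module** (`simulate_snp_matrix()`,
  `filter_by_coverage()`, `sharing_spectrum()`) reproducing the 4-of-8
  haplotype-block spectrum with crossovers, gene-conversion (5:3) tracts,
  overdispersed coverage and the strict ">8X" filters.

Everything is tidyverse-native: functions take tibbles and return tibbles,
results have `autoplot()` methods, and test objects have `tidy()` /
`glance()` methods. All tables round-trip through plain TSV
(`write_octads()` / `read_octads()` etc.), and a thin command-line wrapper
lives in `inst/cli/octadrive.R`.

## Worked example

```r
library(octadrive)

cfg <- cross_config(ipo323(), ipo94269(), mechanism = "female_drive",
                    n_asci = 100, seed = 42)
octads  <- simulate_experiment(cfg)     # 800 ascospores, 8 per ascus
v       <- verify_octads(octads)
records <- classify_octads(octads, cfg$cross)
dplyr::count(records, pairing_status, label)
#>   pairing_status  label             n
#> 1 paired          mendelian_4_4   600
#> 2 unpaired_female drive_8_0       102
#> 3 unpaired_male   mendelian_4_0    98
```

In this cross chr18 and chr20 are unpaired (only IPO323 carries them); the
six paired chromosomes segregate 4:4 in every ascus, and every unpaired
instance is 8:0 when its parent took the female role and 4:0 otherwise.
99 of 100 asci verify (the one rejection is an ascus whose four meiotic
products are not all distinguishable by the six-marker panel — the strict
twin rule discards it as ambiguous).

The mito-conditioned transmission table shows the drive signature:

```r
test_transmission(transmission_table(octads, "chr18"))
#>   chromosome mito_genotype present absent   n frac_present  p_value stars
#> 1 chr18      mtIPO323          408      0 408          1.0 3.0e-123 ***
#> 2 chr18      mtIPO94269        196    196 392          0.5 1.0
```

and the discriminator recovers the generating mechanism:

```r
discriminate_mechanisms(records, any(v$valid))
#>   mechanism                consistent
#> 1 mendelian                FALSE    majority 8:0 transmission ...
#> 2 female_drive             TRUE     female-inherited unpaired chromosomes show the 8:0 ...
#> 3 premeiotic_amplification FALSE    paired chromosomes segregate 4:4 without extra copies ...
#> 4 preferential_segregation FALSE    preferential segregation cannot exceed 4 carrier spores ...
#> 5 spore_killing            FALSE    complete eight-spore octads were verified ...
```

A full pipeline (simulate → verify → classify → stats → SNP spectrum) runs
from a YAML configuration:

```r
pc <- read_pipeline_config(system.file("extdata", "demo_config.yaml",
                                       package = "octadrive"))
run_pipeline(pc, "results")
```

See the vignette `vignettes/octad-drive-model.Rmd` for the model, its
assumptions and the design choices.

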