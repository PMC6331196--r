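# Shared fixture builders (everything is generated in code).

# Reference cross with the full chromosome complements: chr18/chr20 unpaired
# from IPO323, six paired chromosomes.
demo_config <- function(mechanism = "mendelian", n_asci = 10, seed = 101, ...) {
  cross_config(ipo323(), ipo94269(), mechanism = mechanism,
               n_asci = n_asci, seed = seed, ...)
}

# Minimal cross with a single unpaired chromosome (fast for large batches).
single_chr_config <- function(mechanism = "mendelian", n_asci = 10, seed = 101,
                              ...) {
  p1 <- parental_strain("P1", "mat1-1", "chr18")
  p2 <- parental_strain("P2", "mat1-2", character(0))
  cross_config(p1, p2, mechanism = mechanism, n_asci = n_asci, seed = seed, ...)
}

# Minimal cross with a single paired chromosome.
single_paired_config <- function(mechanism = "mendelian", n_asci = 10,
                                 seed = 101, ...) {
  p1 <- parental_strain("P1", "mat1-1", "chr21")
  p2 <- parental_strain("P2", "mat1-2", "chr21")
  cross_config(p1, p2, mechanism = mechanism, n_asci = n_asci, seed = seed, ...)
}

# Carrier count per ascus for one chromosome.
carriers_per_ascus <- function(spores, chromosome) {
  tot <- spores[[paste0(chromosome, "_p1")]] + spores[[paste0(chromosome, "_p2")]]
  tapply(tot > 0, spores$ascus_id, sum)
}
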