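test_that("disomy detection uses the >= 2 total-copy rule", {
  df <- tibble::tibble(chr21_p1 = c(1L, 1L, 2L, 0L),
                       chr21_p2 = c(1L, 0L, 0L, 0L))
  expect_equal(detect_disomy(df, "chr21"), c(TRUE, FALSE, TRUE, FALSE))
  expect_error(detect_disomy(df, "chr19"), "format error")
})

test_that("classification reproduces the canonical pattern labels", {
  cr <- build_cross(ipo323(), ipo94269())
  mk_octad <- function(p1, p2, chr = "chr21") {
    n <- length(p1)
    out <- tibble::tibble(ascus_id = rep("X", n),
                          spore_id = paste0("X_s", seq_len(n)),
                          mito = rep("mtIPO323", n))
    out[[paste0(chr, "_p1")]] <- as.integer(p1)
    out[[paste0(chr, "_p2")]] <- as.integer(p2)
    out
  }
  # paired, 4 spores each homolog -> mendelian 4:4
  rec <- classify_chromosome(mk_octad(c(1,1,1,1,0,0,0,0), c(0,0,0,0,1,1,1,1)),
                             "chr21", cr)
  expect_equal(rec$label, "mendelian_4_4")
  expect_equal(rec$pairing_status, "paired")

  # unpaired female chromosome in all 8 spores -> drive_8_0
  oc <- mk_octad(rep(1, 8), rep(0, 8), chr = "chr18")
  rec <- classify_chromosome(oc, "chr18", cr)   # female inferred = IPO323
  expect_equal(rec$label, "drive_8_0")
  expect_equal(rec$pairing_status, "unpaired_female")

  # the chr21 case: 2 disomic + 2 absent + 4 single-copy -> disomy
  rec <- classify_chromosome(mk_octad(c(1,1,0,0,1,1,0,0),
                                      c(1,1,0,0,0,0,1,1)), "chr21", cr)
  expect_equal(rec$label, "disomy")
  expect_equal(rec$disomic_spores, 2L)
  expect_equal(rec$absent_spores, 2L)

  # six carriers of an unpaired chromosome -> partial_drive
  rec <- classify_chromosome(mk_octad(c(1,1,1,1,1,1,0,0), rep(0, 8), "chr20"),
                             "chr20", cr)
  expect_equal(rec$label, "partial_drive")

  # chromosome absent from both parents
  expect_error(
    classify_chromosome(mk_octad(rep(0, 8), rep(0, 8), "chr18"), "chr22", cr),
    "not in the cross")
})

test_that("classifier agrees with a brute-force enumeration oracle", {
  # Independent oracle: re-derivation of the label rules from counts.
  oracle <- function(states_p1, states_p2, paired) {
    tot <- states_p1 + states_p2
    if (any(tot >= 2)) return("disomy")
    carriers <- sum(tot > 0)
    if (carriers == 0) return("total_absence")
    if (paired) {
      if (sum(states_p1 > 0) == 4 && sum(states_p2 > 0) == 4) {
        return("mendelian_4_4")
      }
      return("loss_deviation")
    }
    if (carriers == 8) return("drive_8_0")
    if (carriers > 4) return("partial_drive")
    if (carriers == 4) return("mendelian_4_0")
    "loss_deviation"
  }
  cr <- build_cross(ipo323(), ipo94269())
  check_vec <- function(p1, p2, chr) {
    oc <- tibble::tibble(ascus_id = rep("X", 8),
                         spore_id = paste0("X_s", 1:8),
                         mito = rep("mtIPO323", 8))
    oc[[paste0(chr, "_p1")]] <- as.integer(p1)
    oc[[paste0(chr, "_p2")]] <- as.integer(p2)
    rec <- classify_chromosome(oc, chr, cr)
    expect_equal(rec$label, oracle(p1, p2, chr == "chr21"),
                 info = paste(chr, paste(p1, collapse = ""),
                              paste(p2, collapse = "")))
  }
  # exhaustive over per-spore states {(0,0),(1,0),(0,1)}: 3^8 vectors
  grid <- as.matrix(expand.grid(rep(list(0:2), 8)))
  for (r in seq_len(nrow(grid))) {
    p1 <- as.integer(grid[r, ] == 1)
    p2 <- as.integer(grid[r, ] == 2)
    check_vec(p1, p2, "chr21")
  }
  # random vectors including disomic states, copies <= 2
  set.seed(8)
  for (r in 1:300) {
    p1 <- sample(0:2, 8, replace = TRUE)
    p2 <- sample(0:2, 8, replace = TRUE)
    p2[p1 + p2 > 2] <- 0
    check_vec(p1, p2, sample(c("chr21", "chr18"), 1))
  }
})

test_that("every (ascus x chromosome) instance gets exactly one label", {
  cfg <- demo_config("female_drive", n_asci = 30, seed = 3,
                     loss_rate = 0.05)
  oct <- simulate_experiment(cfg)
  rec <- classify_octads(oct, cfg$cross)
  expect_equal(nrow(rec), 30 * length(cfg$cross$chromosomes))
  expect_equal(anyDuplicated(rec[c("ascus_id", "chromosome")]), 0)
  labels <- c("mendelian_4_4", "mendelian_4_0", "drive_8_0", "partial_drive",
              "loss_deviation", "disomy", "total_absence")
  expect_true(all(rec$label %in% labels))
  expect_equal(sum(table(rec$label)), nrow(rec))
})

test_that("zero-rate simulations classify 100% Mendelian; drive flips female-unpaired", {
  cfg <- demo_config(n_asci = 40, seed = 5)
  rec <- classify_octads(simulate_experiment(cfg), cfg$cross)
  expect_true(all(rec$label[rec$pairing_status == "paired"] == "mendelian_4_4"))
  expect_true(all(rec$label[rec$pairing_status != "paired"] == "mendelian_4_0"))

  cfgd <- demo_config("female_drive", n_asci = 40, seed = 5)
  recd <- classify_octads(simulate_experiment(cfgd), cfgd$cross)
  expect_true(all(recd$label[recd$pairing_status == "unpaired_female"] ==
                    "drive_8_0"))
  expect_true(all(recd$label[recd$pairing_status == "unpaired_male"] ==
                    "mendelian_4_0"))
  expect_true(all(recd$label[recd$pairing_status == "paired"] ==
                    "mendelian_4_4"))
})

test_that("transmission tables split presence by mitochondrial genotype", {
  cfg <- demo_config(n_asci = 100, seed = 9)
  oct <- simulate_experiment(cfg)
  tt <- transmission_table(oct, "chr18")
  # Mendelian: exactly half the spores carry the unpaired chromosome in
  # both mito classes
  expect_true(all(tt$frac_present == 0.5))
  expect_equal(tt$present + tt$absent, tt$n)
  expect_equal(unique(tt$expected_mendelian_fraction), 0.5)

  cfgd <- demo_config("female_drive", n_asci = 100, seed = 9)
  ttd <- transmission_table(simulate_experiment(cfgd), "chr18")
  expect_equal(ttd$frac_present[ttd$mito_genotype == "mtIPO323"], 1)
  expect_equal(ttd$frac_present[ttd$mito_genotype == "mtIPO94269"], 0.5)

  expect_error(transmission_table(oct[0, ], "chr18"), "no data")

  tested <- test_transmission(ttd)
  expect_true(all(tested$p_value >= 0 & tested$p_value <= 1))
  expect_equal(tested$stars[tested$mito_genotype == "mtIPO323"], "***")
})
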