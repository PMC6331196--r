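test_that("zero-rate Mendelian octads segregate 4:4 and 4:0 with conserved copies", {
  cfg <- demo_config(n_asci = 50, seed = 7)
  oct <- simulate_experiment(cfg)
  expect_equal(nrow(oct), 400)

  for (id in unique(oct$ascus_id)) {
    a <- oct[oct$ascus_id == id, ]
    # unpaired chromosomes (chr18, chr20 from parent 1) in exactly 4 spores
    for (ch in c("chr18", "chr20")) {
      expect_equal(sum(a[[paste0(ch, "_p1")]]), 4L)
      expect_equal(sum(a[[paste0(ch, "_p2")]]), 0L)
      expect_equal(sum(a[[paste0(ch, "_p1")]] > 0), 4L)
    }
    # each parental homolog of every paired chromosome in exactly 4 spores
    for (ch in c("chr14", "chr15", "chr16", "chr17", "chr19", "chr21")) {
      expect_equal(sum(a[[paste0(ch, "_p1")]] > 0), 4L)
      expect_equal(sum(a[[paste0(ch, "_p2")]] > 0), 4L)
      expect_equal(sum(a[[paste0(ch, "_p1")]] + a[[paste0(ch, "_p2")]]), 8L)
    }
    # every core marker splits 4:4
    for (m in core_markers()) {
      expect_equal(as.integer(sort(table(a[[m]]))), c(4L, 4L))
    }
  }
})

test_that("twin pairs are identical and mito is uniparental for every mechanism", {
  for (mech in c("mendelian", "female_drive", "premeiotic_amplification",
                 "preferential_segregation", "spore_killing")) {
    cfg <- demo_config(mech, n_asci = 15, seed = 31,
                       loss_rate = 0.05, nondisjunction_rate = 0.05)
    oct <- simulate_experiment(cfg)
    cols <- setdiff(names(oct), c("spore_id", "twin_id"))
    for (id in unique(oct$ascus_id)) {
      a <- oct[oct$ascus_id == id, ]
      # one mito allele per ascus, matching one of the parents
      expect_length(unique(a$mito), 1)
      expect_true(unique(a$mito) %in% c("mtIPO323", "mtIPO94269"))
      # surviving twin pairs agree in every marker and copy-number field
      for (tw in unique(a$twin_id)) {
        pair <- a[a$twin_id == tw, cols]
        if (nrow(pair) == 2) {
          expect_identical(pair[1, ], pair[2, ])
        }
      }
    }
  }
})

test_that("female drive transmits female-inherited unpaired chromosomes to all 8 spores", {
  cfg <- demo_config("female_drive", n_asci = 40, seed = 13)
  oct <- simulate_experiment(cfg)
  for (id in unique(oct$ascus_id)) {
    a <- oct[oct$ascus_id == id, ]
    female_is_p1 <- unique(a$mito) == "mtIPO323"
    for (ch in c("chr18", "chr20")) {   # unpaired, always from parent 1
      carriers <- sum(a[[paste0(ch, "_p1")]] > 0)
      if (female_is_p1) {
        expect_equal(carriers, 8L)              # drive: amplified copy pair
        expect_equal(sum(a[[paste0(ch, "_p1")]]), 8L)
      } else {
        expect_equal(carriers, 4L)              # male-inherited: Mendelian
      }
    }
    # paired chromosomes stay 4:4 under the drive
    expect_equal(sum(a$chr21_p1 > 0), 4L)
    expect_equal(sum(a$chr21_p2 > 0), 4L)
  }
})

test_that("per-chromosome drive penetrance spares chr14", {
  p1 <- ipo94269(); p2 <- ipo323_delta("chr14")
  # chr14 unpaired from IPO94269; penetrance 0 for chr14 only
  cfg <- cross_config(p1, p2, mechanism = "female_drive",
                      drive_penetrance = c(chr14 = 0),
                      n_asci = 30, seed = 17)
  oct <- simulate_experiment(cfg)
  fem94 <- oct[oct$mito == "mtIPO94269", ]
  expect_gt(nrow(fem94), 0)
  expect_true(all(carriers_per_ascus(fem94, "chr14") == 4))
  # chr21 etc stay paired; the IPO323-side unpaired chr18/20 still drive
  fem323 <- oct[oct$mito == "mtIPO323", ]
  if (nrow(fem323) > 0) {
    expect_true(all(carriers_per_ascus(fem323, "chr18") == 8))
  }
})

test_that("meiosis-II non-disjunction produces same-parent disomic twin pairs", {
  # chromatid enumeration: with MII non-disjunction forced at both poles of a
  # paired chromosome, each pole yields one product with both sister
  # chromatids (2 copies from one parent) and one empty product; through the
  # twin mitosis: 2 spores (2,0), 2 spores (0,2), 4 spores (0,0).
  cfg <- single_paired_config(nondisjunction_rate = 1, n_asci = 20, seed = 23)
  oct <- simulate_experiment(cfg)
  for (id in unique(oct$ascus_id)) {
    a <- oct[oct$ascus_id == id, ]
    states <- paste(a$chr21_p1, a$chr21_p2)
    expect_equal(sum(states == "2 0"), 2)
    expect_equal(sum(states == "0 2"), 2)
    expect_equal(sum(states == "0 0"), 4)
    # disomic spores are mutual twins
    dis <- a[a$chr21_p1 == 2, ]
    expect_length(unique(dis$twin_id), 1)
  }
})

test_that("meiosis-I non-disjunction gives cross-parent disomy plus nullisomy", {
  # both homologs to one pole -> each product there carries one chromatid of
  # each parent (1,1); the other pole is empty: 4 spores (1,1), 4 (0,0)
  cfg <- single_paired_config(mi_nondisjunction_rate = 1, n_asci = 10, seed = 29)
  oct <- simulate_experiment(cfg)
  for (id in unique(oct$ascus_id)) {
    a <- oct[oct$ascus_id == id, ]
    states <- paste(a$chr21_p1, a$chr21_p2)
    expect_equal(sum(states == "1 1"), 4)
    expect_equal(sum(states == "0 0"), 4)
  }
})

test_that("preferential segregation never exceeds 4 carrier spores", {
  for (bias in c(0.5, 0.9, 1)) {
    cfg <- single_chr_config("preferential_segregation", n_asci = 100,
                             seed = 37, preferential_bias = bias)
    oct <- simulate_experiment(cfg)
    expect_true(all(carriers_per_ascus(oct, "chr18") <= 4))
  }
})

test_that("spore killing with an unpaired killer leaves incomplete carrier-only asci", {
  cfg <- demo_config("spore_killing", n_asci = 25, seed = 41)
  expect_equal(cfg$killer_chromosome, "chr18")
  oct <- simulate_experiment(cfg)
  for (id in unique(oct$ascus_id)) {
    a <- oct[oct$ascus_id == id, ]
    expect_lt(nrow(a), 8)
    expect_true(all(a$chr18_p1 + a$chr18_p2 > 0))
  }
})

test_that("experiments are reproducible and extend without perturbing earlier asci", {
  cfg <- demo_config(n_asci = 8, seed = 55)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a, b)

  cfg2 <- demo_config(n_asci = 12, seed = 55)
  c12 <- simulate_experiment(cfg2)
  expect_identical(a, c12[c12$ascus_id %in% unique(a$ascus_id), ])

  expect_equal(nrow(simulate_experiment(demo_config(n_asci = 0))), 0)
  expect_named(simulate_experiment(demo_config(n_asci = 0)),
               names(a))
})

test_that("carrier-count distribution matches the chromatid enumeration oracle", {
  # Independent oracle: exhaustive enumeration of the per-chromatid loss x
  # MII outcome space for a single unpaired chromosome (pole choice does not
  # affect carrier counts; all four meiotic products become twin pairs).
  enumerate_carriers <- function(q, r) {
    probs <- setNames(numeric(5), c("0", "2", "4", "6", "8"))
    for (l1 in 0:1) for (l2 in 0:1) {           # chromatid loss indicators
      p_loss <- q^(l1 + l2) * (1 - q)^(2 - l1 - l2)
      surv <- 2 - l1 - l2
      if (surv == 2) {
        # non-disjunction -> both chromatids in one product (2 spores);
        # else one product each (4 spores)
        probs["2"] <- probs["2"] + p_loss * r
        probs["4"] <- probs["4"] + p_loss * (1 - r)
      } else if (surv == 1) {
        probs["2"] <- probs["2"] + p_loss
      } else {
        probs["0"] <- probs["0"] + p_loss
      }
    }
    probs
  }
  q <- 0.1; r <- 0.15
  expected <- enumerate_carriers(q, r)
  cfg <- single_chr_config(loss_rate = q, nondisjunction_rate = r,
                           n_asci = 10000, seed = 61)
  oct <- simulate_experiment(cfg)
  obs <- table(factor(carriers_per_ascus(oct, "chr18"),
                      levels = c(0, 2, 4, 6, 8)))
  keep <- expected > 0
  gof <- suppressWarnings(
    stats::chisq.test(as.integer(obs)[keep], p = expected[keep])
  )
  expect_gt(gof$p.value, 0.01)
})
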