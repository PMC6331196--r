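test_that("the binomial drive test matches exhaustive enumeration for n <= 30", {
  for (n in 1:30) {
    for (k in 0:n) {
      expect_equal(binomial_drive_test(k, n)$p_value, enum_binom_p(k, n),
                   tolerance = 1e-10, info = paste(k, n))
    }
  }
})

test_that("binomial drive test frozen examples and errors", {
  expect_equal(binomial_drive_test(12, 24)$p_value, 1)
  expect_equal(binomial_drive_test(6, 24)$p_value, 2 * pbinom(6, 24, 0.5),
               tolerance = 1e-12)
  expect_equal(binomial_drive_test(6, 24)$p_value, 0.0226558, tolerance = 1e-5)
  expect_equal(binomial_drive_test(24, 24)$p_value, 2 * 0.5^24,
               tolerance = 1e-12)
  expect_error(binomial_drive_test(25, 24), "cannot exceed")
  expect_error(binomial_drive_test(-1, 24), "non-negative")
  t <- binomial_drive_test(20, 24)
  expect_equal(t$null_probability, 0.5)
  expect_equal(t$alternative, "two.sided")
  td <- tidy(t)
  expect_equal(td$p.value, t$p_value)
  expect_equal(nrow(glance(t)), 1)
})

test_that("the Fisher branch matches hypergeometric enumeration for 2x2, N <= 40", {
  expect_equal(contingency_test(matrix(c(5, 0, 0, 5), 2))$p_value, 2 / 252,
               tolerance = 1e-10)
  set.seed(14)
  for (i in 1:60) {
    repeat {
      tab <- matrix(rpois(4, 4), 2)
      if (sum(tab) <= 40 && all(rowSums(tab) > 0) && all(colSums(tab) > 0)) break
    }
    res <- contingency_test(tab)
    expect_equal(res$branch, "fisher")
    expect_equal(res$p_value, enum_fisher_p(tab), tolerance = 1e-8,
                 info = paste(tab, collapse = ","))
  }
})

test_that("the large-sample switch selects chi-squared and records the branch", {
  tab <- matrix(c(3, 7, 3, 7), 2, byrow = TRUE)
  expect_equal(contingency_test(tab)$p_value, 1)          # identical rows
  big <- tab * 1000
  res <- contingency_test(big)
  expect_equal(res$branch, "chi2")
  expect_equal(res$statistic_name, "Pearson's chi-squared test")
  expect_equal(res$p_value, 1)                            # same proportions
  # threshold is configurable; below it with all expected >= 5 still fisher
  res2 <- contingency_test(matrix(c(20, 30, 30, 20), 2),
                           large_sample_threshold = 200)
  expect_equal(res2$branch, "fisher")
  res3 <- contingency_test(matrix(c(20, 30, 30, 20), 2),
                           large_sample_threshold = 50)
  expect_equal(res3$branch, "chi2")
  expect_error(contingency_test(matrix(c(0, 0, 3, 5), 2, byrow = TRUE)),
               "degenerate")
})

test_that("one-spore-per-ascus randomisation is exact and reproducible", {
  cfg <- demo_config(n_asci = 24, seed = 15)
  oct <- simulate_experiment(cfg)
  one <- randomize_one_per_ascus(oct, seed = 99)
  expect_equal(nrow(one), 24)
  expect_equal(anyDuplicated(one$ascus_id), 0)
  expect_identical(one, randomize_one_per_ascus(oct, seed = 99))
  # already one per ascus: selection is the identity (up to grouping order)
  expect_setequal(randomize_one_per_ascus(one, seed = 1)$spore_id,
                  one$spore_id)
  expect_error(randomize_one_per_ascus(dplyr::select(oct, -ascus_id)),
               "ascus_id")
})

test_that("loss-rate estimation recovers the simulated rate and flags heterogeneity", {
  # zero-loss simulation
  cfg0 <- demo_config(n_asci = 10, seed = 21)
  rec0 <- classify_octads(simulate_experiment(cfg0), cfg0$cross)
  expect_equal(estimate_loss_rate(rec0)$rate, 0)

  # 6 paired chromosomes x 8 spores x 210 asci = 10080 scored instances at
  # per-chromatid loss probability 0.037: estimate within the exact central
  # 99% binomial interval around the true rate
  cfg <- demo_config(n_asci = 210, seed = 22, loss_rate = 0.037)
  rec <- classify_octads(simulate_experiment(cfg), cfg$cross)
  est <- estimate_loss_rate(rec)
  expect_equal(est$n_scored, 210 * 6 * 8)
  lo <- qbinom(0.005, est$n_scored, 0.037) / est$n_scored
  hi <- qbinom(0.995, est$n_scored, 0.037) / est$n_scored
  expect_gte(est$rate, lo)
  expect_lte(est$rate, hi)
  # both aggregations are exposed
  est_a <- estimate_loss_rate(rec, by = "ascus")
  expect_lte(est_a$n_scored, est$n_scored)

  # equal per-chromosome loss proportions -> heterogeneity p = 1
  fake <- tibble::tibble(
    ascus_id = rep(sprintf("A%03d", 1:40), each = 2),
    chromosome = rep(c("chr15", "chr16"), 40),
    pairing_status = "paired",
    carriers_p1 = 4L, carriers_p2 = 4L, carriers = 8L,
    disomic_spores = 0L,
    absent_spores = rep(c(1L, 1L, 0L, 0L), 20),
    n_spores = 8L, expected_carriers = 4L,
    label = "loss_deviation"
  )
  het <- estimate_loss_rate(fake)$heterogeneity
  expect_equal(het$p_value, 1)

  expect_error(estimate_loss_rate(rec[rec$pairing_status != "paired", ]),
               "no data")
})
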