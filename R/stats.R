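## Drive statistics ---------------------------------------------------------

.new_zt_test <- function(statistic_name, p_value, counts, null_probability = NA,
                         statistic = NA_real_, branch = NA_character_,
                         alternative = "two.sided") {
  structure(
    list(statistic_name = statistic_name, p_value = p_value,
         statistic = statistic, counts = counts,
         alternative = alternative, null_probability = null_probability,
         branch = branch),
    class = "zt_test"
  )
}

#' @export
print.zt_test <- function(x, ...) {
  cat("<zt_test> ", x$statistic_name, "\n", sep = "")
  if (!is.na(x$statistic)) cat("  statistic =", format(x$statistic), "\n")
  cat("  p-value =", format.pval(x$p_value, digits = 4),
      sig_stars(x$p_value), "\n")
  if (!is.na(x$null_probability)) {
    cat("  two-sided against p0 =", x$null_probability, "\n")
  }
  invisible(x)
}

#' Exact two-sided binomial test against Mendelian segregation
#'
#' Tests whether `k` carrier spores out of `n` scored deviate from the
#' Mendelian expectation `Binomial(n, p0)` with `p0 = 0.5`. The two-sided
#' p-value is the minimum-likelihood sum: the total probability of all
#' outcomes no more likely than the observed one (the convention of
#' [stats::binom.test()]).
#'
#' @param k Number of carrier spores (0 <= k <= n).
#' @param n Number of scored spores (n >= 1).
#' @param null_probability Hypothesised carrier probability (default 0.5).
#' @return A `zt_test` object.
#' @examples
#' binomial_drive_test(24, 24)  # all spores carriers: p = 2 * 2^-24
#' @export
binomial_drive_test <- function(k, n, null_probability = 0.5) {
  if (!is.numeric(k) || !is.numeric(n) || length(k) != 1L || length(n) != 1L ||
      n < 1 || k < 0 || k != floor(k) || n != floor(n)) {
    stop("`k` and `n` must be non-negative integers with n >= 1", call. = FALSE)
  }
  if (k > n) stop("`k` cannot exceed `n`", call. = FALSE)
  .check_prob(null_probability, "null_probability")
  ht <- stats::binom.test(k, n, p = null_probability,
                          alternative = "two.sided")
  .new_zt_test("exact binomial test", unname(ht$p.value),
               counts = list(k = k, n = n),
               null_probability = null_probability)
}

#' Contingency test with the exact/large-sample switch
#'
#' Fisher's exact two-sided test for small tables, replaced by Pearson's
#' chi-squared test (without continuity correction) for large ones. The
#' exact branch is used when the table total is below
#' `large_sample_threshold` *or* any expected cell count is below 5; the
#' result records which branch ran.
#'
#' @param table A matrix (or table) of non-negative integer counts with at
#'   least two rows and columns and no zero margin.
#' @param large_sample_threshold Total-count threshold for the chi-squared
#'   branch (default 200).
#' @return A `zt_test` with `branch` `"fisher"` or `"chi2"`.
#' @examples
#' contingency_test(matrix(c(5, 0, 0, 5), 2))
#' @export
contingency_test <- function(table, large_sample_threshold = 200) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != floor(tab))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("table must be at least 2 x 2", call. = FALSE)
  }
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop("degenerate table: a row or column margin is zero", call. = FALSE)
  }
  n <- sum(tab)
  expected <- outer(rs, cs) / n
  use_fisher <- n < large_sample_threshold || any(expected < 5)
  if (use_fisher) {
    ht <- stats::fisher.test(tab)
    .new_zt_test("Fisher's exact test", unname(ht$p.value),
                 counts = tab, branch = "fisher")
  } else {
    ht <- stats::chisq.test(tab, correct = FALSE)
    .new_zt_test("Pearson's chi-squared test", unname(ht$p.value),
                 counts = tab, statistic = unname(ht$statistic),
                 branch = "chi2")
  }
}

#' Select one random ascospore per ascus
#'
#' All spores of an ascus share the mitochondrial genotype, so asci - not
#' spores - are the independent units for mitochondrial-transmission
#' statistics. This picks exactly one spore per `ascus_id`, uniformly and
#' reproducibly.
#'
#' @param spores Spore table with an `ascus_id` column.
#' @param seed Optional seed for reproducible selection.
#' @return A tibble with one row per distinct `ascus_id`.
#' @examples
#' cfg <- cross_config(ipo323(), ipo94269(), n_asci = 5, seed = 4)
#' nrow(randomize_one_per_ascus(simulate_experiment(cfg), seed = 1))
#' @export
randomize_one_per_ascus <- function(spores, seed = NULL) {
  if (!"ascus_id" %in% names(spores)) {
    stop("spore table must carry an `ascus_id` column", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  spores |>
    dplyr::group_by(.data$ascus_id) |>
    dplyr::slice_sample(n = 1) |>
    dplyr::ungroup()
}

#' Estimate the chromosome-loss rate from paired-chromosome records
#'
#' The loss rate is the fraction of scored instances of paired
#' supernumerary chromosomes showing evidence of loss. With
#' `by = "spore"` (default) an instance is one spore scored for one paired
#' chromosome and a loss is a spore carrying no copy at all, matching
#' marker-absence scoring across whole progeny sets. With `by = "ascus"` an
#' instance is one (ascus, chromosome) record and a loss is a record with at
#' least one absent spore. A chi-squared heterogeneity test compares the
#' per-chromosome loss/no-loss counts.
#'
#' @param records Segregation records from [classify_octads()].
#' @param by `"spore"` or `"ascus"` aggregation (see above).
#' @return An object of class `zt_loss_rate`: `rate`, `n_loss`, `n_scored`,
#'   `by`, `per_chromosome` (tibble) and `heterogeneity` (a `zt_test`, `NA`
#'   p-value when fewer than two chromosomes are scored).
#' @examples
#' cfg <- cross_config(ipo323(), ipo94269(), loss_rate = 0.05,
#'                     n_asci = 30, seed = 11)
#' oct <- simulate_experiment(cfg)
#' estimate_loss_rate(classify_octads(oct, cfg$cross))
#' @export
estimate_loss_rate <- function(records, by = c("spore", "ascus")) {
  by <- match.arg(by)
  paired <- dplyr::filter(records, .data$pairing_status == "paired")
  if (nrow(paired) == 0L) {
    stop("no data: no paired-chromosome records", call. = FALSE)
  }
  per_chr <- paired |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::summarise(
      n_loss = if (by == "spore") sum(.data$absent_spores)
               else sum(.data$absent_spores > 0L),
      n_scored = if (by == "spore") sum(.data$n_spores) else dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(rate = .data$n_loss / .data$n_scored)
  n_loss <- sum(per_chr$n_loss)
  n_scored <- sum(per_chr$n_scored)
  het <- if (nrow(per_chr) >= 2L) {
    tab <- cbind(loss = per_chr$n_loss,
                 no_loss = per_chr$n_scored - per_chr$n_loss)
    ht <- suppressWarnings(stats::chisq.test(tab))
    .new_zt_test("chi-squared heterogeneity of loss across chromosomes",
                 unname(ht$p.value), counts = tab,
                 statistic = unname(ht$statistic), branch = "chi2")
  } else {
    .new_zt_test("chi-squared heterogeneity of loss across chromosomes",
                 NA_real_, counts = NULL)
  }
  structure(
    list(rate = n_loss / n_scored, n_loss = n_loss, n_scored = n_scored,
         by = by, per_chromosome = per_chr, heterogeneity = het),
    class = "zt_loss_rate"
  )
}

#' @export
print.zt_loss_rate <- function(x, ...) {
  cat(sprintf("<zt_loss_rate> %d losses / %d scored %s instances = %.2f%%\n",
              x$n_loss, x$n_scored, x$by, 100 * x$rate))
  if (!is.na(x$heterogeneity$p_value)) {
    cat("  heterogeneity across chromosomes: p =",
        format.pval(x$heterogeneity$p_value, digits = 3), "\n")
  }
  invisible(x)
}
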