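## Segregation classification ----------------------------------------------

.chr_cols <- function(spores, chromosome) {
  cols <- paste0(chromosome, c("_p1", "_p2"))
  if (!all(cols %in% names(spores))) {
    stop("format error: no copy-number columns for ", chromosome,
         " (expected ", paste(cols, collapse = ", "), ")", call. = FALSE)
  }
  cols
}

#' Detect disomic spores for a chromosome
#'
#' A spore is disomic for a chromosome when it carries two or more copies in
#' total, whether both copies come from the same parent (meiosis II
#' non-disjunction) or one from each (homolog non-disjunction, as observed
#' for chromosome 21).
#'
#' @param spores Octad table rows.
#' @param chromosome Chromosome identifier, e.g. `"chr21"`.
#' @return Logical vector, one element per spore.
#' @examples
#' df <- tibble::tibble(chr21_p1 = c(1L, 1L, 0L), chr21_p2 = c(1L, 0L, 0L))
#' detect_disomy(df, "chr21")
#' @export
detect_disomy <- function(spores, chromosome) {
  cols <- .chr_cols(spores, chromosome)
  spores[[cols[1]]] + spores[[cols[2]]] >= 2L
}

# Segregation-pattern label; priority:
# disomy > total_absence > drive_8_0/partial_drive > mendelian > loss_deviation
.segregation_label <- function(status, carriers, carriers_p1, carriers_p2,
                               disomic, n_spores) {
  if (disomic > 0L) return("disomy")
  if (carriers == 0L) return("total_absence")
  if (status == "paired") {
    if (carriers_p1 == 4L && carriers_p2 == 4L && n_spores == 8L) {
      return("mendelian_4_4")
    }
    return("loss_deviation")
  }
  if (carriers == 8L) return("drive_8_0")
  if (carriers >= 5L) return("partial_drive")
  if (carriers == 4L) return("mendelian_4_0")
  "loss_deviation"
}

# female parent index inferred from the ascus mito haplotype
.infer_female <- function(mito, cross) {
  mito <- unique(mito)
  if (length(mito) != 1L) {
    stop("ascus carries more than one mitochondrial haplotype; cannot infer ",
         "the female parent", call. = FALSE)
  }
  hit <- c(cross$parent1$mito, cross$parent2$mito) == mito
  if (sum(hit) != 1L) {
    stop("cannot infer the female parent from mito haplotype '", mito,
         "'; pass `female` explicitly", call. = FALSE)
  }
  which(hit)
}

#' Classify the segregation pattern of one chromosome in one ascus
#'
#' Counts carrier spores by parental origin and assigns a unique pattern
#' label: `disomy` (any spore with >= 2 total copies), `total_absence`,
#' `drive_8_0` (unpaired chromosome in all eight spores), `partial_drive`
#' (5-7 carriers), `mendelian_4_4` / `mendelian_4_0`, or `loss_deviation`
#' (fewer carriers than the Mendelian expectation). Pairing status is
#' expressed relative to the female parent (`paired`, `unpaired_female`,
#' `unpaired_male`).
#'
#' @param octad Spore rows of one ascus (normally a verified octad).
#' @param chromosome Chromosome to classify.
#' @param cross The `zt_cross` the octad came from.
#' @param female Index (1/2) of the female parent; inferred from the mito
#'   haplotype when `NULL`.
#' @param drive_hypothesis When `TRUE`, the expected carrier count recorded
#'   for female-unpaired chromosomes is 8 (the drive expectation) instead of
#'   the Mendelian 4. The label itself is unaffected.
#' @return A one-row tibble (`ascus_id`, `chromosome`, `pairing_status`,
#'   `carriers_p1`, `carriers_p2`, `carriers`, `disomic_spores`,
#'   `absent_spores`, `n_spores`, `expected_carriers`, `label`).
#' @export
classify_chromosome <- function(octad, chromosome, cross, female = NULL,
                                drive_hypothesis = FALSE) {
  stopifnot(inherits(cross, "zt_cross"))
  idx <- match(chromosome, cross$pairing$chromosome)
  if (is.na(idx)) {
    stop("chromosome ", chromosome, " is not in the cross ",
         cross$parent1$name, " x ", cross$parent2$name, call. = FALSE)
  }
  if (is.null(female)) female <- .infer_female(octad$mito, cross)
  status <- cross$pairing$status[idx]
  ctx <- switch(status,
    paired = "paired",
    unpaired_p1 = if (female == 1L) "unpaired_female" else "unpaired_male",
    unpaired_p2 = if (female == 2L) "unpaired_female" else "unpaired_male"
  )
  cols <- .chr_cols(octad, chromosome)
  c1 <- octad[[cols[1]]]
  c2 <- octad[[cols[2]]]
  tot <- c1 + c2
  n <- nrow(octad)
  carriers_p1 <- sum(c1 > 0L)
  carriers_p2 <- sum(c2 > 0L)
  carriers <- sum(tot > 0L)
  disomic <- sum(tot >= 2L)
  expected <- if (drive_hypothesis && ctx == "unpaired_female") 8L else 4L
  tibble::tibble(
    ascus_id = octad$ascus_id[1L],
    chromosome = chromosome,
    pairing_status = ctx,
    carriers_p1 = carriers_p1,
    carriers_p2 = carriers_p2,
    carriers = carriers,
    disomic_spores = disomic,
    absent_spores = sum(tot == 0L),
    n_spores = n,
    expected_carriers = expected,
    label = .segregation_label(if (ctx == "paired") "paired" else "unpaired",
                               carriers, carriers_p1, carriers_p2, disomic, n)
  )
}

#' Classify every (ascus, chromosome) instance of an experiment
#'
#' Applies [classify_chromosome()] to each chromosome of the cross in each
#' ascus. Every instance receives exactly one label.
#'
#' @param spores Octad table.
#' @param cross The `zt_cross` the table came from.
#' @param drive_hypothesis See [classify_chromosome()].
#' @return A tibble of segregation records, one row per ascus x chromosome.
#' @examples
#' cfg <- cross_config(ipo323(), ipo94269(), mechanism = "female_drive",
#'                     n_asci = 2, seed = 5)
#' classify_octads(simulate_experiment(cfg), cfg$cross)
#' @export
classify_octads <- function(spores, cross, drive_hypothesis = FALSE) {
  stopifnot(inherits(cross, "zt_cross"))
  if (nrow(spores) == 0L || length(cross$chromosomes) == 0L) {
    return(tibble::tibble(
      ascus_id = character(0), chromosome = character(0),
      pairing_status = character(0), carriers_p1 = integer(0),
      carriers_p2 = integer(0), carriers = integer(0),
      disomic_spores = integer(0), absent_spores = integer(0),
      n_spores = integer(0), expected_carriers = integer(0),
      label = character(0)
    ))
  }
  spores |>
    dplyr::group_by(.data$ascus_id) |>
    dplyr::group_map(function(df, key) {
      df <- dplyr::mutate(df, ascus_id = key$ascus_id)
      fem <- .infer_female(df$mito, cross)
      dplyr::bind_rows(lapply(cross$chromosomes, function(ch) {
        classify_chromosome(df, ch, cross, female = fem,
                            drive_hypothesis = drive_hypothesis)
      }))
    }) |>
    dplyr::bind_rows()
}

#' Tabulate chromosome presence conditioned on the mitochondrial genotype
#'
#' Counts, separately for each mitochondrial haplotype in the progeny, the
#' ascospores that do and do not carry a chromosome (presence = at least one
#' copy from either parent, the marker-level PCR view). Under Mendelian
#' segregation of an unpaired chromosome the expected presence fraction is
#' 0.5 in both mito classes; under a female-restricted drive it approaches 1
#' among spores carrying the female parent's mitochondria.
#'
#' @param spores Octad (or randomized one-per-ascus) spore table.
#' @param chromosome Chromosome to score.
#' @return A tibble of class `zt_transmission`: one row per mitochondrial
#'   genotype with `present`, `absent`, `n`, `frac_present` and
#'   `expected_mendelian_fraction` (0.5).
#' @examples
#' cfg <- cross_config(ipo323(), ipo94269(), mechanism = "female_drive",
#'                     n_asci = 20, seed = 9)
#' transmission_table(simulate_experiment(cfg), "chr18")
#' @export
transmission_table <- function(spores, chromosome) {
  if (nrow(spores) == 0L) stop("no data: empty spore table", call. = FALSE)
  cols <- .chr_cols(spores, chromosome)
  out <- spores |>
    dplyr::mutate(.present = (.data[[cols[1]]] + .data[[cols[2]]]) > 0L) |>
    dplyr::group_by(mito_genotype = .data$mito) |>
    dplyr::summarise(present = sum(.data$.present),
                     absent = sum(!.data$.present), .groups = "drop") |>
    dplyr::mutate(chromosome = chromosome,
                  n = .data$present + .data$absent,
                  frac_present = .data$present / .data$n,
                  expected_mendelian_fraction = 0.5) |>
    dplyr::relocate("chromosome")
  class(out) <- c("zt_transmission", class(out))
  out
}

#' Exact binomial drive tests for a transmission table
#'
#' Runs [binomial_drive_test()] on each row of a [transmission_table()]
#' (carriers vs scored spores against the Mendelian 0.5) and annotates the
#' significance stars used in the original analyses
#' (`*` p < 0.05, `**` p < 0.005, `***` p < 0.0005).
#'
#' @param transmission A `zt_transmission` tibble.
#' @return The table with `p_value` and `stars` columns added.
#' @export
test_transmission <- function(transmission) {
  stopifnot(inherits(transmission, "zt_transmission") ||
              all(c("present", "n") %in% names(transmission)))
  p <- purrr::map2_dbl(transmission$present, transmission$n,
                       function(k, n) binomial_drive_test(k, n)$p_value)
  dplyr::mutate(transmission, p_value = p, stars = sig_stars(p))
}

#' Significance stars at the thresholds used for segregation tests
#'
#' `*` p < 0.05, `**` p < 0.005, `***` p < 0.0005, `""` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
sig_stars <- function(p) {
  dplyr::case_when(p < 0.0005 ~ "***", p < 0.005 ~ "**",
                   p < 0.05 ~ "*", TRUE ~ "")
}
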