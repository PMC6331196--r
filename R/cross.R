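## Cross construction and configuration -------------------------------------

#' Partition the supernumerary chromosomes of a cross into paired and
#' unpaired sets
#'
#' Chromosomes present in both parents pair in the zygote; chromosomes
#' present in exactly one parent are unpaired. Chromosomes absent from both
#' parents do not appear. The two parents must be of opposite mating types.
#'
#' @param parent1,parent2 `zt_strain` objects (see [parental_strain()]).
#' @return An object of class `zt_cross` with elements `parent1`, `parent2`,
#'   `paired`, `unpaired_from_p1`, `unpaired_from_p2`, `chromosomes` (the
#'   union) and `pairing`, a tibble with one row per chromosome in the cross
#'   (`chromosome`, `status` in `paired`/`unpaired_p1`/`unpaired_p2`,
#'   `origin` = contributing parent name or `NA` for paired).
#' @examples
#' cr <- build_cross(ipo323(), ipo94269())
#' cr$unpaired_from_p1  # chr18 and chr20 lack homologs in IPO94269
#' @export
build_cross <- function(parent1, parent2) {
  if (!inherits(parent1, "zt_strain") || !inherits(parent2, "zt_strain")) {
    stop("parents must be `zt_strain` objects", call. = FALSE)
  }
  if (identical(parent1$mating_type, parent2$mating_type)) {
    stop("incompatible cross: both parents are ", parent1$mating_type,
         "; a cross requires mat1-1 x mat1-2", call. = FALSE)
  }
  paired <- sort(intersect(parent1$chromosomes, parent2$chromosomes))
  up1 <- sort(setdiff(parent1$chromosomes, parent2$chromosomes))
  up2 <- sort(setdiff(parent2$chromosomes, parent1$chromosomes))
  pairing <- tibble::tibble(
    chromosome = c(paired, up1, up2),
    status = c(rep("paired", length(paired)),
               rep("unpaired_p1", length(up1)),
               rep("unpaired_p2", length(up2))),
    origin = c(rep(NA_character_, length(paired)),
               rep(parent1$name, length(up1)),
               rep(parent2$name, length(up2)))
  )
  pairing <- dplyr::arrange(pairing, .data$chromosome)
  structure(
    list(parent1 = parent1, parent2 = parent2,
         paired = paired, unpaired_from_p1 = up1, unpaired_from_p2 = up2,
         chromosomes = sort(c(paired, up1, up2)), pairing = pairing),
    class = "zt_cross"
  )
}

#' @export
print.zt_cross <- function(x, ...) {
  cat("<zt_cross> ", x$parent1$name, " x ", x$parent2$name, "\n", sep = "")
  cat("  paired:            ", paste(x$paired, collapse = ", "), "\n")
  cat("  unpaired (", x$parent1$name, "): ",
      paste(x$unpaired_from_p1, collapse = ", "), "\n", sep = "")
  cat("  unpaired (", x$parent2$name, "): ",
      paste(x$unpaired_from_p2, collapse = ", "), "\n", sep = "")
  invisible(x)
}

.check_prob <- function(x, name, lower = 0, upper = 1) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < lower) || any(x > upper)) {
    stop("`", name, "` must lie in [", lower, ", ", upper, "]", call. = FALSE)
  }
  x
}

#' Configure a simulated cross
#'
#' Bundles the two parents, the transmission mechanism acting on
#' supernumerary chromosomes, the nuisance event rates and the experiment
#' size into a validated configuration used by [simulate_octad()] and
#' [simulate_experiment()].
#'
#' Mechanisms:
#' \describe{
#'   \item{`mendelian`}{Homolog disjunction at meiosis I, chromatid
#'     disjunction at meiosis II; an unpaired chromosome segregates to a
#'     random pole and ends up in 4 of 8 spores.}
#'   \item{`female_drive`}{Each unpaired chromosome inherited from the
#'     *female* parent is duplicated (with probability `drive_penetrance`)
#'     before meiosis I so that its two copies behave as a pair and reach
#'     all 8 spores.}
#'   \item{`premeiotic_amplification`}{Every female supernumerary chromosome
#'     is duplicated before karyogamy. With `amplification_copy_loss = TRUE`
#'     the extra copy of each *paired* chromosome is lost again before
#'     meiosis I (the counteracting-loss scenario); with `FALSE` the zygote
#'     stays trisomic for paired chromosomes, which leaves a detectable
#'     disomy excess in the progeny.}
#'   \item{`preferential_segregation`}{An unpaired chromosome is sent to a
#'     designated spindle pole with probability `preferential_bias`. Because
#'     all four meiotic products become spores, this can never exceed 4
#'     carrier spores.}
#'   \item{`spore_killing`}{After spore formation every spore lacking
#'     `killer_chromosome` is removed, so asci with an unpaired killer are
#'     left with fewer than eight spores.}
#' }
#'
#' @param parent1,parent2 `zt_strain` objects of opposite mating types.
#' @param mechanism One of `"mendelian"`, `"female_drive"`,
#'   `"premeiotic_amplification"`, `"preferential_segregation"`,
#'   `"spore_killing"`.
#' @param loss_rate Per-chromatid probability that a supernumerary chromatid
#'   is lost at meiosis I (removes one twin pair of carriers per event).
#' @param nondisjunction_rate Probability per chromatid pair that meiosis II
#'   non-disjunction sends both sister chromatids into one product.
#' @param mi_nondisjunction_rate Probability per bivalent that homologs fail
#'   to disjoin at meiosis I (both homologs to one pole).
#' @param preferential_bias Probability, in `[0.5, 1]`, of the designated
#'   pole under `preferential_segregation`.
#' @param drive_penetrance Probability that female-drive amplification fires
#'   for an unpaired female chromosome. A single number, or a named vector
#'   of per-chromosome values (unnamed chromosomes default to 1), e.g.
#'   `c(chr14 = 0)` for the chr14 exception.
#' @param density_exponent Positive exponent of the density-dependent
#'   sexual-role model, see [assign_sexual_roles()].
#' @param n_asci Number of asci to simulate in [simulate_experiment()].
#' @param seed Master integer seed; per-ascus substreams are derived from it
#'   by counter, so increasing `n_asci` does not perturb earlier asci.
#' @param killer_chromosome Killer chromosome for `spore_killing`; defaults
#'   to the first unpaired chromosome of the cross.
#' @param amplification_copy_loss See `premeiotic_amplification` above.
#' @return An object of class `zt_config`.
#' @examples
#' cfg <- cross_config(ipo323(), ipo94269(), mechanism = "female_drive",
#'                     n_asci = 10, seed = 1)
#' @export
cross_config <- function(parent1, parent2,
                         mechanism = c("mendelian", "female_drive",
                                       "premeiotic_amplification",
                                       "preferential_segregation",
                                       "spore_killing"),
                         loss_rate = 0, nondisjunction_rate = 0,
                         mi_nondisjunction_rate = 0,
                         preferential_bias = 0.9,
                         drive_penetrance = 1,
                         density_exponent = 1,
                         n_asci = 100, seed = NULL,
                         killer_chromosome = NULL,
                         amplification_copy_loss = TRUE) {
  mechanism <- match.arg(mechanism)
  cross <- build_cross(parent1, parent2)
  .check_prob(loss_rate, "loss_rate")
  .check_prob(nondisjunction_rate, "nondisjunction_rate")
  .check_prob(mi_nondisjunction_rate, "mi_nondisjunction_rate")
  .check_prob(preferential_bias, "preferential_bias", lower = 0.5)
  .check_prob(drive_penetrance, "drive_penetrance")
  if (!is.numeric(density_exponent) || density_exponent <= 0) {
    stop("`density_exponent` must be positive", call. = FALSE)
  }
  if (!is.numeric(n_asci) || length(n_asci) != 1L || n_asci < 0 ||
      n_asci != floor(n_asci)) {
    stop("`n_asci` must be a non-negative integer", call. = FALSE)
  }
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    stopifnot(is.finite(seed))
  }
  if (mechanism == "spore_killing") {
    unpaired <- c(cross$unpaired_from_p1, cross$unpaired_from_p2)
    if (is.null(killer_chromosome)) {
      if (!length(unpaired)) {
        stop("spore_killing requires `killer_chromosome` when the cross has ",
             "no unpaired chromosome", call. = FALSE)
      }
      killer_chromosome <- sort(unpaired)[1]
    }
    if (!killer_chromosome %in% cross$chromosomes) {
      stop("`killer_chromosome` ", killer_chromosome,
           " is not in the cross", call. = FALSE)
    }
  }
  structure(
    list(cross = cross, mechanism = mechanism,
         loss_rate = loss_rate,
         nondisjunction_rate = nondisjunction_rate,
         mi_nondisjunction_rate = mi_nondisjunction_rate,
         preferential_bias = preferential_bias,
         drive_penetrance = drive_penetrance,
         density_exponent = density_exponent,
         n_asci = as.integer(n_asci), seed = seed,
         killer_chromosome = killer_chromosome,
         amplification_copy_loss = isTRUE(amplification_copy_loss)),
    class = "zt_config"
  )
}

#' @export
print.zt_config <- function(x, ...) {
  cat("<zt_config> ", x$cross$parent1$name, " x ", x$cross$parent2$name,
      " | mechanism = ", x$mechanism, "\n", sep = "")
  cat(sprintf("  loss_rate = %g, MII nondisjunction = %g, MI nondisjunction = %g\n",
              x$loss_rate, x$nondisjunction_rate, x$mi_nondisjunction_rate))
  cat(sprintf("  n_asci = %d, seed = %s\n", x$n_asci,
              if (is.null(x$seed)) "<unset>" else x$seed))
  invisible(x)
}

# per-chromosome drive penetrance lookup
.penetrance <- function(pen, chromosome) {
  if (is.null(names(pen))) return(pen[[1]])
  if (chromosome %in% names(pen)) pen[[chromosome]] else 1
}

#' Draw the sexual roles of the two parents from their densities
#'
#' The parent inoculated at lower density tends to take the female
#' (mitochondria-donating) role. The model is
#' `P(parent1 female) = d2^a / (d1^a + d2^a)` for densities `d1`, `d2` and
#' exponent `a`; equal densities give 1/2 and any `d1 < d2` gives a
#' probability above 1/2. The draw consumes the current RNG stream.
#'
#' @param density1,density2 Positive densities (cells per mL).
#' @param exponent Positive shape exponent `a`.
#' @return A list with integer elements `female` and `male` (1 or 2) and
#'   `p_parent1_female`, the probability used.
#' @examples
#' set.seed(1)
#' assign_sexual_roles(1e5, 1e7)
#' @export
assign_sexual_roles <- function(density1, density2, exponent = 1) {
  if (!is.numeric(density1) || !is.numeric(density2) ||
      density1 <= 0 || density2 <= 0) {
    stop("densities must be positive", call. = FALSE)
  }
  if (!is.numeric(exponent) || exponent <= 0) {
    stop("`exponent` must be positive", call. = FALSE)
  }
  # work on log densities to avoid overflow for large exponents
  l1 <- exponent * log(density1)
  l2 <- exponent * log(density2)
  p1 <- 1 / (1 + exp(l1 - l2))
  female <- if (runif(1) < p1) 1L else 2L
  list(female = female, male = 3L - female, p_parent1_female = p1)
}
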