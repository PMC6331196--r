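## Mechanism prediction and discrimination ----------------------------------

#' Predicted carrier-count distribution of a transmission mechanism
#'
#' Gives, for a focal chromosome in a given pairing context, the predicted
#' distribution of the number of carrier spores per octad under each
#' transmission mechanism. With zero nuisance rates the distributions are
#' analytic: Mendelian segregation of an unpaired chromosome is a point mass
#' at 4 of 8; female drive puts mass `penetrance` at 8; preferential
#' segregation has no support above 4 because all four meiotic products
#' become spores; spore killing with an unpaired killer leaves four spores,
#' all carriers, and incomplete octads. With non-zero loss or
#' non-disjunction rates the distribution is estimated by Monte-Carlo
#' simulation of single octads, with a reported standard error.
#'
#' @param mechanism One of the five mechanism names (see [cross_config()]).
#' @param context `"female_unpaired"`, `"male_unpaired"` or `"paired"` -
#'   the pairing status of the focal chromosome relative to the female
#'   parent.
#' @param drive_penetrance,preferential_bias,loss_rate,nondisjunction_rate
#'   Mechanism parameters as in [cross_config()].
#' @param n_sim Number of Monte-Carlo octads for the non-analytic branch.
#' @return An object of class `zt_prediction`: a tibble with `carriers`
#'   (0..8) and `probability`, and attributes `mechanism`, `context`,
#'   `octad_complete`, `method` (`"analytic"` or `"monte_carlo"`) and
#'   `max_se`.
#' @examples
#' predict_patterns("female_drive", "female_unpaired")
#' @export
predict_patterns <- function(mechanism, context = c("female_unpaired",
                                                    "male_unpaired", "paired"),
                             drive_penetrance = 1, preferential_bias = 0.9,
                             loss_rate = 0, nondisjunction_rate = 0,
                             n_sim = 2000) {
  mechanism <- match.arg(mechanism, .MECHANISMS)
  context <- match.arg(context)
  probs <- setNames(numeric(9), 0:8)
  octad_complete <- TRUE
  analytic <- loss_rate == 0 && nondisjunction_rate == 0

  if (analytic) {
    if (context == "paired") {
      probs["8"] <- 1    # every spore carries one parental homolog
    } else if (mechanism == "female_drive" && context == "female_unpaired") {
      probs["8"] <- drive_penetrance
      probs["4"] <- 1 - drive_penetrance
    } else if (mechanism == "premeiotic_amplification" &&
               context == "female_unpaired") {
      probs["8"] <- 1
    } else if (mechanism == "spore_killing") {
      # non-carrier spores are killed; the focal unpaired killer is carried
      # by all four surviving spores and the octad is incomplete
      probs["4"] <- 1
      octad_complete <- FALSE
    } else {
      probs["4"] <- 1
    }
    max_se <- 0
  } else {
    sim <- .simulate_context(mechanism, context, drive_penetrance,
                             preferential_bias, loss_rate,
                             nondisjunction_rate, n_sim)
    tab <- tabulate(sim$carriers + 1L, nbins = 9L)
    probs[] <- tab / n_sim
    octad_complete <- sim$octad_complete
    max_se <- sqrt(max(probs * (1 - probs)) / n_sim)
  }

  out <- tibble::tibble(carriers = 0:8, probability = unname(probs))
  attr(out, "mechanism") <- mechanism
  attr(out, "context") <- context
  attr(out, "octad_complete") <- octad_complete
  attr(out, "method") <- if (analytic) "analytic" else "monte_carlo"
  attr(out, "max_se") <- max_se
  class(out) <- c("zt_prediction", class(out))
  out
}

# Monte-Carlo helper: minimal two-strain cross with one focal chromosome in
# the requested context; parent 1 is forced into the female role.
.simulate_context <- function(mechanism, context, penetrance, bias,
                              loss_rate, nd_rate, n_sim) {
  focal <- "chr18"
  p1_chr <- if (context %in% c("female_unpaired", "paired")) focal else character(0)
  p2_chr <- if (context %in% c("male_unpaired", "paired")) focal else character(0)
  p1 <- parental_strain("P1", "mat1-1", p1_chr)
  p2 <- parental_strain("P2", "mat1-2", p2_chr)
  cfg <- cross_config(p1, p2, mechanism = mechanism,
                      loss_rate = loss_rate, nondisjunction_rate = nd_rate,
                      preferential_bias = bias, drive_penetrance = penetrance,
                      n_asci = 0, seed = NULL,
                      killer_chromosome = if (mechanism == "spore_killing") focal)
  carriers <- integer(n_sim)
  complete <- TRUE
  for (i in seq_len(n_sim)) {
    oc <- .sim_octad_raw(cfg, 1L, "MC")
    tot <- oc[[paste0(focal, "_p1")]] + oc[[paste0(focal, "_p2")]]
    carriers[i] <- sum(tot > 0L)
    if (length(tot) < 8L) complete <- FALSE
  }
  list(carriers = carriers, octad_complete = complete)
}

#' Discriminate transmission mechanisms from observed segregation labels
#'
#' Applies the falsification logic used to pin the drive mechanism down:
#' \itemize{
#'   \item Complete verified octads exclude post-meiotic spore killing,
#'     which would make it impossible to isolate complete tetrads; if
#'     octads are systematically incomplete, only spore killing survives.
#'   \item A majority of 8:0 transmission among female-inherited unpaired
#'     chromosomes excludes plain Mendelian segregation and preferential
#'     segregation, whose carrier support cannot exceed 4 of 8.
#'   \item Paired chromosomes segregating overwhelmingly 4:4 with no disomy
#'     excess exclude pre-meiotic amplification, which would leave the
#'     zygote trisomic for every paired chromosome; conversely a disomy
#'     excess on paired chromosomes excludes the meiotic female drive.
#' }
#' `premeiotic_amplification` here denotes the falsifiable trisomy variant
#' (no counteracting copy loss); the copy-loss variant is observationally
#' identical to `female_drive` at the tetrad level.
#'
#' @param records Segregation records from [classify_octads()] (may be
#'   restricted to verified asci).
#' @param octads_complete Logical: were complete eight-spore octads
#'   verified? Typically `any(verify_octads(spores)$valid)`.
#' @return A tibble of class `zt_mechanisms` with `mechanism`, `consistent`
#'   and `reason`, plus attribute `consistent_set`.
#' @export
discriminate_mechanisms <- function(records, octads_complete) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("no data: empty segregation records", call. = FALSE)
  }
  stopifnot(is.logical(octads_complete), length(octads_complete) == 1L)
  fu <- records$label[records$pairing_status == "unpaired_female"]
  pd <- records$label[records$pairing_status == "paired"]
  drive_frac <- if (length(fu)) mean(fu == "drive_8_0") else NA_real_
  disomy_frac <- if (length(pd)) mean(pd == "disomy") else NA_real_

  res <- list()
  res$spore_killing <- if (octads_complete) {
    c(FALSE, paste("complete eight-spore octads were verified; killing of",
                   "non-carrier spores would make complete tetrads",
                   "impossible to isolate"))
  } else {
    c(TRUE, "octads are systematically incomplete, as spore killing predicts")
  }

  if (!octads_complete) {
    for (m in setdiff(.MECHANISMS, "spore_killing")) {
      res[[m]] <- c(FALSE, paste("octads are incomplete; every mechanism",
                                 "except spore killing preserves all eight",
                                 "ascospores"))
    }
  } else {
    drive_seen <- isTRUE(drive_frac > 0.5)
    disomy_seen <- isTRUE(disomy_frac > 0.5)

    res$mendelian <- if (drive_seen) {
      c(FALSE, paste("majority 8:0 transmission of female-inherited unpaired",
                     "chromosomes; Mendelian segregation caps carriers at 4",
                     "of 8"))
    } else {
      c(TRUE, "segregation ratios match Mendelian expectations")
    }

    res$preferential_segregation <- if (drive_seen) {
      c(FALSE, paste("preferential segregation cannot exceed 4 carrier",
                     "spores because all four meiotic products become",
                     "ascospores"))
    } else {
      c(TRUE, paste("indistinguishable from Mendelian segregation when all",
                    "meiotic products survive"))
    }

    fd_reasons <- character(0)
    if (!is.na(drive_frac) && !drive_seen) {
      fd_reasons <- c(fd_reasons,
                      paste("no 8:0 drive signature among female-inherited",
                            "unpaired chromosomes (indistinguishable from",
                            "zero penetrance)"))
    }
    if (disomy_seen) {
      fd_reasons <- c(fd_reasons,
                      paste("disomy excess on paired chromosomes is not",
                            "predicted by a drive restricted to unpaired",
                            "chromosomes"))
    }
    res$female_drive <- if (length(fd_reasons)) {
      c(FALSE, paste(fd_reasons, collapse = "; "))
    } else {
      c(TRUE, paste("female-inherited unpaired chromosomes show the 8:0",
                    "amplification signature"))
    }

    res$premeiotic_amplification <- if (length(pd) && !disomy_seen) {
      c(FALSE, paste("paired chromosomes segregate 4:4 without extra copies;",
                     "pre-meiotic amplification would make the zygote",
                     "trisomic for every paired chromosome"))
    } else if (disomy_seen) {
      c(TRUE, "disomy excess on paired chromosomes matches zygotic trisomy")
    } else {
      c(TRUE, "no paired chromosomes scored; trisomy prediction untestable")
    }
  }

  out <- tibble::tibble(
    mechanism = .MECHANISMS,
    consistent = vapply(res[.MECHANISMS], function(x) as.logical(x[1]), logical(1)),
    reason = vapply(res[.MECHANISMS], `[`, character(1), 2)
  )
  attr(out, "consistent_set") <- out$mechanism[out$consistent]
  class(out) <- c("zt_mechanisms", class(out))
  out
}
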