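## SNP octad-sharing spectrum ------------------------------------------------

#' Simulate a SNP presence/coverage matrix for one octad
#'
#' Emulates the whole-genome view of a single octad: alternate-parent SNPs
#' fall into Mendelian haplotype blocks carried by exactly four of the eight
#' spores, reshuffled along each chromosome by crossovers. Gene conversion
#' is modelled as post-meiotic segregation of an unrepaired heteroduplex
#' tract: a short run of SNPs flips in a single spore of a twin pair,
#' producing the 3-of-8 / 5-of-8 sharing counts seen beside the Mendelian
#' 4-of-8 class. Read coverage is overdispersed and correlated within a
#' site: a per-site depth is drawn from a Gamma distribution and per-spore
#' counts are Poisson around it (a negative-binomial margin), so low-depth
#' sites are the ones that lose presence calls.
#'
#' @param n_snps Number of SNP sites.
#' @param chromosomes Named numeric vector of chromosome lengths in bp;
#'   SNPs are distributed proportionally to length.
#' @param crossover_rate Expected crossovers per chromosome per meiosis.
#' @param conversion_rate Expected gene-conversion (heteroduplex) tracts per
#'   chromosome per meiosis.
#' @param conversion_tract Tract length in bp.
#' @param coverage_mean Mean read coverage per spore per site.
#' @param coverage_dispersion Gamma shape of the per-site depth (smaller =
#'   more overdispersed coverage).
#' @param dropout_rate Probability that a truly present allele is missed in
#'   one spore independently of coverage.
#' @param context `"paired"`: SNPs ride a normally segregating chromosome
#'   (4-of-8 blocks). `"driven"`: SNPs sit on a chromosome amplified into
#'   all eight spores.
#' @param seed Optional seed.
#' @return A tibble of class `zt_snp_matrix` with columns `snp_id`,
#'   `chromosome`, `position`, `presence_s1..s8` (logical) and
#'   `cov_s1..s8` (integer).
#' @examples
#' m <- simulate_snp_matrix(100, seed = 1)
#' sharing_spectrum(m)
#' @export
simulate_snp_matrix <- function(n_snps,
                                chromosomes = c(chr1 = 6e6),
                                crossover_rate = 2,
                                conversion_rate = 0,
                                conversion_tract = 2000,
                                coverage_mean = 20,
                                coverage_dispersion = 5,
                                dropout_rate = 0,
                                context = c("paired", "driven"),
                                seed = NULL) {
  context <- match.arg(context)
  if (!is.numeric(n_snps) || n_snps < 0 || n_snps != floor(n_snps)) {
    stop("`n_snps` must be a non-negative integer", call. = FALSE)
  }
  .check_prob(dropout_rate, "dropout_rate")
  if (crossover_rate < 0 || conversion_rate < 0) {
    stop("rates must be non-negative", call. = FALSE)
  }
  if (is.null(names(chromosomes)) || any(chromosomes <= 0)) {
    stop("`chromosomes` must be a named vector of positive lengths", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  if (n_snps == 0L) {
    out <- tibble::tibble(snp_id = character(0), chromosome = character(0),
                          position = integer(0))
    for (s in 1:8) out[[paste0("presence_s", s)]] <- logical(0)
    for (s in 1:8) out[[paste0("cov_s", s)]] <- integer(0)
    class(out) <- c("zt_snp_matrix", class(out))
    return(out)
  }

  chr_of <- sample(names(chromosomes), n_snps, replace = TRUE,
                   prob = chromosomes / sum(chromosomes))
  presence <- matrix(FALSE, n_snps, 8L)
  position <- integer(n_snps)

  for (ch in unique(chr_of)) {
    idx <- which(chr_of == ch)
    len <- chromosomes[[ch]]
    pos <- sort(as.integer(ceiling(runif(length(idx), 0, len))))
    position[idx] <- pos

    # chromatid origins: columns 1-2 reference homolog, 3-4 alternate;
    # a crossover swaps distal segments between one chromatid of each
    origins <- matrix(rep(c(0L, 0L, 1L, 1L), each = length(idx)),
                      ncol = 4L)
    n_x <- rpois(1, crossover_rate)
    if (n_x > 0) {
      for (x in runif(n_x, 0, len)) {
        a <- sample.int(2L, 1L)
        b <- 2L + sample.int(2L, 1L)
        distal <- pos > x
        tmp <- origins[distal, a]
        origins[distal, a] <- origins[distal, b]
        origins[distal, b] <- tmp
      }
    }
    if (context == "driven") {
      pres_prod <- matrix(TRUE, length(idx), 4L)
    } else {
      pres_prod <- origins == 1L
    }
    pres <- pres_prod[, rep(1:4, each = 2L), drop = FALSE]  # twin mitosis

    n_t <- rpois(1, conversion_rate)
    if (n_t > 0) {
      for (t in seq_len(n_t)) {
        start <- runif(1, 0, len)
        sel <- pos >= start & pos <= start + conversion_tract
        if (any(sel)) {
          sp <- sample.int(8L, 1L)  # post-meiotic segregation: one spore flips
          pres[sel, sp] <- !pres[sel, sp]
        }
      }
    }
    presence[idx, ] <- pres
  }

  site_depth <- rgamma(n_snps, shape = coverage_dispersion,
                       rate = coverage_dispersion / coverage_mean)
  coverage <- matrix(rpois(n_snps * 8L, rep(site_depth, 8L)), n_snps, 8L)
  detected <- presence & coverage > 0L
  if (dropout_rate > 0) {
    detected <- detected & matrix(runif(n_snps * 8L) >= dropout_rate,
                                  n_snps, 8L)
  }

  ord <- order(chr_of, position)
  out <- tibble::tibble(
    snp_id = sprintf("snp%06d", seq_len(n_snps)),
    chromosome = chr_of[ord],
    position = position[ord]
  )
  for (s in 1:8) out[[paste0("presence_s", s)]] <- detected[ord, s]
  for (s in 1:8) out[[paste0("cov_s", s)]] <- coverage[ord, s]
  class(out) <- c("zt_snp_matrix", class(out))
  out
}

.presence_cols <- paste0("presence_s", 1:8)
.cov_cols <- paste0("cov_s", 1:8)

.check_snp_matrix <- function(matrix) {
  missing <- setdiff(c("snp_id", .presence_cols, .cov_cols), names(matrix))
  if (length(missing)) {
    stop("format error: missing SNP-matrix column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(matrix)
}

#' Filter a SNP matrix by read coverage
#'
#' Coverage filters on the per-spore read counts:
#' \describe{
#'   \item{`none`}{identity.}
#'   \item{`min_cov_any`}{keep SNPs covered above the threshold in at least
#'     one spore.}
#'   \item{`min_cov_all`}{additionally require coverage above the threshold
#'     in *every spore where the allele is called present* and at least one
#'     read in all eight spores ("at all occurrences" reading).}
#'   \item{`min_cov_all_spores`}{require coverage above the threshold in all
#'     eight spores (the stricter reading of the same filter).}
#' }
#' Thresholding is strict (`> threshold`, the ">8X" convention) unless
#' `strict = FALSE` selects `>=`.
#'
#' @param matrix A `zt_snp_matrix` tibble.
#' @param mode Filter mode, see above.
#' @param threshold Coverage threshold (default 8).
#' @param strict Strict (`>`) vs non-strict (`>=`) comparison.
#' @return The filtered tibble, with attributes `filter_mode` and
#'   `threshold`.
#' @export
filter_by_coverage <- function(matrix,
                               mode = c("none", "min_cov_any", "min_cov_all",
                                        "min_cov_all_spores"),
                               threshold = 8, strict = TRUE) {
  mode <- match.arg(mode)
  .check_snp_matrix(matrix)
  cmp <- if (strict) `>` else `>=`
  if (mode != "none") {
    cov <- as.matrix(matrix[.cov_cols])
    pres <- as.matrix(matrix[.presence_cols])
    ok_cov <- cmp(cov, threshold)
    keep <- switch(mode,
      min_cov_any = rowSums(ok_cov) > 0L,
      min_cov_all = rowSums(ok_cov) > 0L &
        rowSums(pres & !ok_cov) == 0L &
        rowSums(cov > 0L) == 8L,
      min_cov_all_spores = rowSums(ok_cov) == 8L
    )
    matrix <- matrix[keep, , drop = FALSE]
  }
  attr(matrix, "filter_mode") <- mode
  attr(matrix, "threshold") <- threshold
  if (!inherits(matrix, "zt_snp_matrix")) {
    class(matrix) <- c("zt_snp_matrix", class(matrix))
  }
  matrix
}

#' SNP sharing spectrum across the eight spores of an octad
#'
#' Counts SNPs by the number of spores in which the alternate allele was
#' detected. Under clean Mendelian segregation all SNPs sit at k = 4;
#' coverage dropouts push SNPs to k < 4, gene conversion to 3 or 5, and
#' drive or disomy above 4.
#'
#' @param matrix A (possibly coverage-filtered) `zt_snp_matrix`.
#' @return A tibble of class `zt_spectrum` with `k` (0..8), `n_snps` and
#'   `fraction`, plus attributes `filter_mode`, `threshold` and `total`.
#' @export
sharing_spectrum <- function(matrix) {
  .check_snp_matrix(matrix)
  k <- rowSums(as.matrix(matrix[.presence_cols]))
  counts <- tabulate(k + 1L, nbins = 9L)
  total <- nrow(matrix)
  out <- tibble::tibble(k = 0:8, n_snps = counts,
                        fraction = if (total > 0) counts / total else rep(NA_real_, 9))
  attr(out, "filter_mode") <- attr(matrix, "filter_mode") %||% "none"
  attr(out, "threshold") <- attr(matrix, "threshold")
  attr(out, "total") <- total
  class(out) <- c("zt_spectrum", class(out))
  out
}
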