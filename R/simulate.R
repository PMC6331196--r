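## Octad simulator ----------------------------------------------------------
##
## One ascus = one meiosis followed by a post-meiotic mitosis. Internally we
## track, per supernumerary chromosome, the fate of individual chromatids
## through: mechanism-specific amplification -> replication (2 chromatids per
## copy) -> per-chromatid loss -> meiosis I pole assignment -> meiosis II
## chromatid disjunction -> twin mitosis. Meiotic product i gives the twin
## spores 2i-1 and 2i.

# Distribute the chromatids of one chromosome into the four meiotic
# products. `parents` is the parent-of-origin (1/2) of each chromosome copy
# entering meiosis: length 2 = bivalent, 1 = univalent, 3 = trivalent (one
# disjoining pair plus a free univalent). Returns a 4 x 2 integer matrix of
# copies per product by parent-of-origin.
.segregate_chromosome <- function(parents, loss_rate, nd_rate, mi_nd_rate,
                                  prefer = FALSE, bias = 0.5) {
  out <- matrix(0L, 4L, 2L)
  n <- length(parents)
  surv <- if (loss_rate > 0) rbinom(n, 2L, 1 - loss_rate) else rep(2L, n)

  pole <- integer(n)
  if (n == 2L) {
    if (mi_nd_rate > 0 && runif(1) < mi_nd_rate) {
      pole[] <- sample.int(2L, 1L)
    } else {
      pole[1L] <- sample.int(2L, 1L)
      pole[2L] <- 3L - pole[1L]
    }
  } else if (n == 1L) {
    pole[1L] <- if (prefer) {
      if (runif(1) < bias) 1L else 2L
    } else {
      sample.int(2L, 1L)
    }
  } else if (n == 3L) {
    pair <- sample.int(3L, 2L)
    ori <- sample.int(2L, 1L)
    pole[pair[1L]] <- ori
    pole[pair[2L]] <- 3L - ori
    pole[setdiff(1:3, pair)] <- sample.int(2L, 1L)
  } else {
    stop("unsupported copy number entering meiosis: ", n)
  }

  for (i in seq_len(n)) {
    k <- surv[i]
    if (k == 0L) next
    prods <- c(2L * pole[i] - 1L, 2L * pole[i])
    par <- parents[i]
    if (k == 2L) {
      if (nd_rate > 0 && runif(1) < nd_rate) {
        pr <- prods[sample.int(2L, 1L)]
        out[pr, par] <- out[pr, par] + 2L
      } else {
        out[prods, par] <- out[prods, par] + 1L
      }
    } else {
      pr <- prods[sample.int(2L, 1L)]
      out[pr, par] <- out[pr, par] + 1L
    }
  }
  out
}

# Copies of one chromosome entering meiosis, after the mechanism step.
# Returns list(parents = parent-of-origin vector, univalent = flag).
.meiotic_copies <- function(chromosome, status, female, cfg) {
  if (status == "paired") {
    if (cfg$mechanism == "premeiotic_amplification" &&
        !cfg$amplification_copy_loss) {
      return(list(parents = c(female, female, 3L - female), univalent = FALSE))
    }
    return(list(parents = c(1L, 2L), univalent = FALSE))
  }
  origin <- if (status == "unpaired_p1") 1L else 2L
  amplified <- FALSE
  if (origin == female) {
    if (cfg$mechanism == "female_drive") {
      amplified <- runif(1) < .penetrance(cfg$drive_penetrance, chromosome)
    } else if (cfg$mechanism == "premeiotic_amplification") {
      amplified <- TRUE
    }
  }
  if (amplified) {
    list(parents = c(origin, origin), univalent = FALSE)
  } else {
    list(parents = origin, univalent = TRUE)
  }
}

# Simulate one octad; returns a plain list of equal-length column vectors
# (cheap to accumulate across many asci).
.sim_octad_raw <- function(cfg, female, ascus_id) {
  cross <- cfg$cross
  chrs <- cross$chromosomes
  nchr <- length(chrs)
  status <- cross$pairing$status[match(chrs, cross$pairing$chromosome)]

  copies <- matrix(0L, 8L, 2L * nchr)
  for (j in seq_len(nchr)) {
    mc <- .meiotic_copies(chrs[j], status[j], female, cfg)
    prods <- .segregate_chromosome(
      mc$parents,
      loss_rate = cfg$loss_rate,
      nd_rate = cfg$nondisjunction_rate,
      mi_nd_rate = cfg$mi_nondisjunction_rate,
      prefer = mc$univalent && cfg$mechanism == "preferential_segregation",
      bias = cfg$preferential_bias
    )
    rows <- rep(1:4, each = 2L)           # twin mitosis
    copies[, 2L * j - 1L] <- prods[rows, 1L]
    copies[, 2L * j] <- prods[rows, 2L]
  }

  # core markers: each splits 2:2 over the meiotic products (4:4 over
  # spores); free assortment across the panel
  fem_strain <- if (female == 1L) cross$parent1 else cross$parent2
  mal_strain <- if (female == 1L) cross$parent2 else cross$parent1
  p1 <- cross$parent1
  p2 <- cross$parent2
  markers <- vector("list", length(.CORE_MARKERS))
  names(markers) <- .CORE_MARKERS
  for (m in .CORE_MARKERS) {
    sel <- sample.int(4L, 2L)             # products carrying the parent1 allele
    al <- rep(p2$core_alleles[[m]], 4L)
    al[sel] <- p1$core_alleles[[m]]
    markers[[m]] <- al[rep(1:4, each = 2L)]
  }

  keep <- rep(TRUE, 8L)
  if (cfg$mechanism == "spore_killing") {
    kj <- match(cfg$killer_chromosome, chrs)
    keep <- (copies[, 2L * kj - 1L] + copies[, 2L * kj]) > 0L
  }

  out <- list(
    ascus_id = rep(ascus_id, sum(keep)),
    spore_id = paste0(ascus_id, "_s", seq_len(8L))[keep],
    twin_id = paste0(ascus_id, "_t", rep(1:4, each = 2L))[keep]
  )
  for (m in .CORE_MARKERS) out[[m]] <- markers[[m]][keep]
  out$mito <- rep(fem_strain$mito, sum(keep))
  for (j in seq_len(nchr)) {
    out[[paste0(chrs[j], "_p1")]] <- copies[keep, 2L * j - 1L]
    out[[paste0(chrs[j], "_p2")]] <- copies[keep, 2L * j]
  }
  attr(out, "female_parent") <- fem_strain$name
  attr(out, "male_parent") <- mal_strain$name
  out
}

.octad_colnames <- function(chromosomes) {
  c("ascus_id", "spore_id", "twin_id", .CORE_MARKERS, "mito",
    as.vector(rbind(paste0(chromosomes, "_p1"), paste0(chromosomes, "_p2"))))
}

.empty_octads <- function(chromosomes) {
  cols <- .octad_colnames(chromosomes)
  out <- lapply(cols, function(cn) {
    if (grepl("_p[12]$", cn)) integer(0) else character(0)
  })
  names(out) <- cols
  tibble::as_tibble(out)
}

#' Simulate a single octad
#'
#' Runs one meiosis plus the post-meiotic mitosis under the configured
#' mechanism and event rates, using the current RNG stream. The result is a
#' tibble with one row per ascospore: the six core-marker alleles, the
#' mitochondrial haplotype (always the female parent's) and, per
#' supernumerary chromosome in the cross, the copy numbers inherited from
#' each parent (`<chr>_p1`, `<chr>_p2`).
#'
#' @param config A [cross_config()] object.
#' @param female Index (1 or 2) of the parent taking the female role; drawn
#'   from the densities via [assign_sexual_roles()] when `NULL`.
#' @param ascus_id Identifier used to build spore and twin ids.
#' @return A tibble with up to 8 rows (fewer if `spore_killing` removed
#'   spores), with attribute `female_parent`.
#' @examples
#' cfg <- cross_config(ipo323(), ipo94269(), n_asci = 1, seed = 1)
#' set.seed(1)
#' simulate_octad(cfg, female = 1)
#' @export
simulate_octad <- function(config, female = NULL, ascus_id = "A0001") {
  stopifnot(inherits(config, "zt_config"))
  if (is.null(female)) {
    female <- assign_sexual_roles(config$cross$parent1$density,
                                  config$cross$parent2$density,
                                  config$density_exponent)$female
  }
  female <- as.integer(female)
  stopifnot(female %in% 1:2)
  raw <- .sim_octad_raw(config, female, ascus_id)
  out <- tibble::as_tibble(raw[names(raw)])
  attr(out, "female_parent") <- attr(raw, "female_parent")
  out
}

# counter-derived per-ascus substream seed (kept below 2^31)
.substream_seed <- function(seed, i) {
  as.integer((as.double(seed %% 2147483647L) * 48271 + i * 69621) %% 2147483647)
}

#' Simulate a whole crossing experiment
#'
#' Simulates `config$n_asci` octads. Each ascus draws its own sexual-role
#' assignment from the parental densities and runs on a per-ascus RNG
#' substream derived from the master seed by counter, so results are fully
#' reproducible and earlier asci are unchanged when `n_asci` grows.
#'
#' @param config A [cross_config()] object.
#' @param seed Master seed; defaults to `config$seed`.
#' @return A tibble of ascospores (8 rows per ascus unless `spore_killing`
#'   removed spores), in the octad-table layout written by [write_octads()].
#' @examples
#' cfg <- cross_config(ipo323(), ipo94269(), n_asci = 3, seed = 7)
#' simulate_experiment(cfg)
#' @export
simulate_experiment <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "zt_config"))
  n <- config$n_asci
  if (n == 0L) return(.empty_octads(config$cross$chromosomes))
  if (is.null(seed)) {
    stop("a seed is required: set `seed` in cross_config() or pass it here",
         call. = FALSE)
  }
  d1 <- config$cross$parent1$density
  d2 <- config$cross$parent2$density
  ids <- sprintf("A%04d", seq_len(n))
  raws <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(.substream_seed(seed, i))
    fem <- assign_sexual_roles(d1, d2, config$density_exponent)$female
    raws[[i]] <- .sim_octad_raw(config, fem, ids[i])
  }
  cols <- names(raws[[1L]])
  out <- lapply(cols, function(cn) unlist(lapply(raws, `[[`, cn), use.names = FALSE))
  names(out) <- cols
  tibble::as_tibble(out)
}
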