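## Parental strains ---------------------------------------------------------

#' Define a parental strain for a cross
#'
#' A strain is described by its mating type, its complement of supernumerary
#' chromosomes, its alleles at the six segregating core markers, its
#' mitochondrial haplotype label and the cell density at which it is
#' inoculated. *Z. tritici* is heterothallic: a cross requires one `mat1-1`
#' and one `mat1-2` parent.
#'
#' Core-marker alleles are arbitrary labels; by default the `mat` allele is
#' the mating-type idiomorph and the other five are derived from the strain
#' name. For the reference strains ([ipo323()], [ipo94269()]) the defaults
#' are the published PCR product sizes, so simulated octad tables look like
#' scored gels.
#'
#' @param name Strain identifier.
#' @param mating_type `"mat1-1"` or `"mat1-2"`.
#' @param chromosomes Character vector of supernumerary chromosomes carried,
#'   a subset of [supernumerary_chromosomes()].
#' @param core_alleles Optional named character vector/list covering all six
#'   [core_markers()].
#' @param mito Mitochondrial haplotype label; defaults to `"mt<name>"`.
#' @param density Inoculation density in cells per mL (positive).
#' @return An object of class `zt_strain`.
#' @examples
#' parental_strain("A", "mat1-1", c("chr14", "chr18"))
#' @export
parental_strain <- function(name, mating_type, chromosomes,
                            core_alleles = NULL,
                            mito = paste0("mt", name),
                            density = 1e7) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a single non-empty string", call. = FALSE)
  }
  mating_type <- match.arg(mating_type, c("mat1-1", "mat1-2"))
  chromosomes <- unique(as.character(chromosomes))
  bad <- setdiff(chromosomes, .SUPER_CHR)
  if (length(bad)) {
    stop("format error: unknown chromosome identifier(s): ",
         paste(bad, collapse = ", "),
         " (valid: ", paste(.SUPER_CHR, collapse = ", "), ")", call. = FALSE)
  }
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) ||
      density <= 0) {
    stop("`density` must be a positive number of cells per mL", call. = FALSE)
  }
  if (is.null(core_alleles)) {
    core_alleles <- .default_core_alleles(name, mating_type)
  }
  core_alleles <- vapply(as.list(core_alleles), as.character, character(1))
  missing <- setdiff(.CORE_MARKERS, names(core_alleles))
  if (length(missing)) {
    stop("core_alleles must cover all six core markers; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(
    list(name = name, mating_type = mating_type,
         chromosomes = sort(chromosomes),
         core_alleles = core_alleles[.CORE_MARKERS],
         mito = as.character(mito), density = density),
    class = "zt_strain"
  )
}

# Allele labels for the two reference isolates are the published PCR product
# sizes (bp); other strains get name-derived labels.
.default_core_alleles <- function(name, mating_type) {
  known <- list(
    IPO323 = c(mat = "mat1-1", m11O21 = "205", m04L20 = "192",
               caa0002 = "412", ggc001 = "254", ac0001 = "187"),
    IPO94269 = c(mat = "mat1-2", m11O21 = "199", m04L20 = "199",
                 caa0002 = "396", ggc001 = "234", ac0001 = "173")
  )
  base <- sub("([^A-Za-z0-9].*$)", "", name)
  if (base %in% names(known)) {
    al <- known[[base]]
    al["mat"] <- mating_type
    return(al)
  }
  al <- setNames(paste0(.CORE_MARKERS, "-", name), .CORE_MARKERS)
  al["mat"] <- mating_type
  al
}

#' Reference strains and whole-chromosome deletion derivatives
#'
#' `ipo323()` carries all eight supernumerary chromosomes (`mat1-1`);
#' `ipo94269()` carries the six with homologs in IPO323 (`mat1-2`);
#' `ipo323_delta(chromosome)` is the isogenic IPO323 strain lacking one
#' supernumerary chromosome, used to put that chromosome into the unpaired
#' state on the IPO94269 side of a cross.
#'
#' @param density Inoculation density in cells per mL.
#' @param chromosome For `ipo323_delta()`, the deleted chromosome, e.g.
#'   `"chr14"`.
#' @return A `zt_strain`.
#' @examples
#' build_cross(ipo323_delta("chr14"), ipo94269())
#' @export
ipo323 <- function(density = 1e7) {
  parental_strain("IPO323", "mat1-1", .SUPER_CHR,
                  mito = "mtIPO323", density = density)
}

#' @rdname ipo323
#' @export
ipo94269 <- function(density = 1e7) {
  parental_strain("IPO94269", "mat1-2",
                  c("chr14", "chr15", "chr16", "chr17", "chr19", "chr21"),
                  mito = "mtIPO94269", density = density)
}

#' @rdname ipo323
#' @export
ipo323_delta <- function(chromosome, density = 1e7) {
  chromosome <- match.arg(chromosome, .SUPER_CHR)
  parental_strain(paste0("IPO323d", sub("^chr", "", chromosome)), "mat1-1",
                  setdiff(.SUPER_CHR, chromosome),
                  core_alleles = .default_core_alleles("IPO323", "mat1-1"),
                  mito = "mtIPO323", density = density)
}

#' @export
print.zt_strain <- function(x, ...) {
  cat("<zt_strain> ", x$name, " (", x$mating_type, ", mito ", x$mito,
      ", ", format(x$density, scientific = TRUE), " cells/mL)\n", sep = "")
  cat("  supernumerary: ",
      if (length(x$chromosomes)) paste(x$chromosomes, collapse = ", ")
      else "(none)", "\n", sep = "")
  invisible(x)
}
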