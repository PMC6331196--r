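## Ascus verification (tetrad QC) -------------------------------------------

.check_marker_columns <- function(spores) {
  missing <- setdiff(.CORE_MARKERS, names(spores))
  if (length(missing)) {
    stop("format error: missing marker column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(spores)
}

#' Assign twin pairs within one ascus from marker profiles
#'
#' The post-meiotic mitosis makes the eight ascospores of an ascus four
#' pairs of identical twins. Spores are paired when their profiles over the
#' chosen marker set are identical; a spore whose profile matches no other
#' spore, or more than one, is flagged. The mitochondrial haplotype is
#' constant within a true ascus, so including it never splits genuine twin
#' pairs but helps reject spores swapped in from another ascus.
#'
#' @param octad Tibble of the spores of a single ascus (at least one row).
#' @param marker_set `"core_plus_mito"` (default) or `"core_only"`.
#' @return A tibble with columns `spore_id`, `twin_id` (the partner's
#'   spore id, or `"none"`/`"multiple"`) and `n_matches`.
#' @examples
#' cfg <- cross_config(ipo323(), ipo94269(), n_asci = 1, seed = 2)
#' find_twins(simulate_experiment(cfg))
#' @export
find_twins <- function(octad, marker_set = c("core_plus_mito", "core_only")) {
  marker_set <- match.arg(marker_set)
  if (nrow(octad) < 1L) stop("octad must contain at least one spore", call. = FALSE)
  if (length(unique(octad$ascus_id)) > 1L) {
    stop("find_twins() works on a single ascus; got ",
         length(unique(octad$ascus_id)), call. = FALSE)
  }
  .check_marker_columns(octad)
  cols <- if (marker_set == "core_plus_mito") c(.CORE_MARKERS, "mito") else .CORE_MARKERS
  profile <- do.call(paste, c(octad[cols], sep = "\r"))
  twin <- character(nrow(octad))
  n_matches <- integer(nrow(octad))
  for (i in seq_along(profile)) {
    hits <- setdiff(which(profile == profile[i]), i)
    n_matches[i] <- length(hits)
    twin[i] <- if (length(hits) == 1L) octad$spore_id[hits]
      else if (length(hits) == 0L) "none" else "multiple"
  }
  tibble::tibble(spore_id = octad$spore_id, twin_id = twin,
                 n_matches = n_matches)
}

#' Verify that eight spores constitute one true octad
#'
#' An ascus is accepted only when (i) it contains exactly eight spores,
#' (ii) every one of the six core markers splits 4:4, and (iii) every spore
#' has exactly one marker-identical twin. Asci failing the twin rule are
#' rejected even when all markers split 4:4. Supernumerary-chromosome and
#' mitochondrial markers are never used for the 4:4 test.
#'
#' @param octad Tibble of the spores of one ascus.
#' @param marker_set Passed to [find_twins()].
#' @return An object of class `zt_verification`: a list with `ascus_id`,
#'   `valid`, `n_spores`, `marker_ratios` (named list of allele counts),
#'   `twin_assignment` (the [find_twins()] tibble) and `failure_reasons`
#'   (subset of `marker_ratio`, `twin_missing`, `twin_multiple`,
#'   `wrong_spore_count`; empty iff valid).
#' @export
verify_ascus <- function(octad, marker_set = c("core_plus_mito", "core_only")) {
  .check_marker_columns(octad)
  if (nrow(octad) < 1L) stop("octad must contain at least one spore", call. = FALSE)
  reasons <- character(0)
  if (nrow(octad) != 8L) reasons <- c(reasons, "wrong_spore_count")

  marker_ratios <- lapply(octad[.CORE_MARKERS], function(a) {
    tab <- table(a)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
    counts
  })
  ratio_ok <- vapply(marker_ratios, function(cnt) {
    length(cnt) == 2L && all(sort(cnt) == c(4L, 4L))
  }, logical(1))
  if (!all(ratio_ok)) reasons <- c(reasons, "marker_ratio")

  twins <- find_twins(octad, marker_set)
  if (any(twins$twin_id == "none")) reasons <- c(reasons, "twin_missing")
  if (any(twins$twin_id == "multiple")) reasons <- c(reasons, "twin_multiple")

  structure(
    list(ascus_id = octad$ascus_id[1L],
         valid = length(reasons) == 0L,
         n_spores = nrow(octad),
         marker_ratios = marker_ratios,
         twin_assignment = twins,
         failure_reasons = reasons),
    class = "zt_verification"
  )
}

#' @export
print.zt_verification <- function(x, ...) {
  cat("<zt_verification> ascus ", x$ascus_id, ": ",
      if (x$valid) "VALID" else paste0("invalid (",
                                       paste(x$failure_reasons, collapse = ", "), ")"),
      " [", x$n_spores, " spores]\n", sep = "")
  invisible(x)
}

#' Verify every ascus of a spore table
#'
#' Applies [verify_ascus()] to each ascus of an octad table.
#'
#' @param spores Octad table (one row per ascospore, see
#'   [simulate_experiment()]).
#' @param marker_set Passed to [find_twins()].
#' @return A tibble with one row per ascus: `ascus_id`, `n_spores`, `valid`
#'   and `failure_reasons` (comma-collapsed, `""` when valid).
#' @examples
#' cfg <- cross_config(ipo323(), ipo94269(), n_asci = 4, seed = 3)
#' verify_octads(simulate_experiment(cfg))
#' @export
verify_octads <- function(spores, marker_set = c("core_plus_mito", "core_only")) {
  marker_set <- match.arg(marker_set)
  .check_marker_columns(spores)
  if (nrow(spores) == 0L) {
    return(tibble::tibble(ascus_id = character(0), n_spores = integer(0),
                          valid = logical(0), failure_reasons = character(0)))
  }
  spores |>
    dplyr::group_by(.data$ascus_id) |>
    dplyr::group_map(function(df, key) {
      v <- verify_ascus(dplyr::mutate(df, ascus_id = key$ascus_id), marker_set)
      tibble::tibble(ascus_id = v$ascus_id, n_spores = v$n_spores,
                     valid = v$valid,
                     failure_reasons = paste(v$failure_reasons, collapse = ","))
    }) |>
    dplyr::bind_rows()
}
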