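## Readers, writers, configuration and the pipeline driver ------------------

#' Write / read octad tables as TSV
#'
#' The on-disk octad table has one row per ascospore with the fixed column
#' order `ascus_id`, `spore_id`, `twin_id`, the six core markers, `mito`,
#' then `<chr>_p1`/`<chr>_p2` copy-number pairs. `read_octads()` validates
#' column completeness (a missing column is a format error naming the
#' column), copy-count ranges (values outside 0..2 are a validation error
#' reporting the row numbers) and warns about asci without exactly eight
#' rows.
#'
#' @param spores Octad tibble from [simulate_experiment()] or compatible.
#' @param path File path.
#' @return `read_octads()` returns the validated tibble; `write_octads()`
#'   returns `path` invisibly.
#' @export
write_octads <- function(spores, path) {
  readr::write_tsv(spores, path)
  invisible(path)
}

#' @rdname write_octads
#' @export
read_octads <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  spores <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("ascus_id", "spore_id", "twin_id", .CORE_MARKERS, "mito")
  missing <- setdiff(required, names(spores))
  if (length(missing)) {
    stop("format error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (cn in required) spores[[cn]] <- as.character(spores[[cn]])
  copy_cols <- grep("^chr[0-9]+_(p1|p2)$", names(spores), value = TRUE)
  for (cn in copy_cols) {
    v <- spores[[cn]]
    bad <- which(is.na(v) | v < 0 | v > 2 | v != floor(v))
    if (length(bad)) {
      stop("validation error: column ", cn, " has copy counts outside 0..2 ",
           "at row(s) ", paste(head(bad, 5), collapse = ", "),
           if (length(bad) > 5) " ..." else "", call. = FALSE)
    }
    spores[[cn]] <- as.integer(v)
  }
  sizes <- table(spores$ascus_id)
  odd <- names(sizes)[sizes != 8L]
  if (length(odd)) {
    warning("ascus id(s) without exactly 8 spores (flagged wrong_spore_count ",
            "downstream): ", paste(head(odd, 5), collapse = ", "),
            call. = FALSE)
  }
  spores
}

#' Write / read segregation-record tables as TSV
#'
#' @param records Records tibble from [classify_octads()].
#' @param path File path.
#' @return The tibble (read) or `path` invisibly (write).
#' @export
write_segregation_records <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}

#' @rdname write_segregation_records
#' @export
read_segregation_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rec <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("ascus_id", "chromosome", "pairing_status", "carriers_p1",
                "carriers_p2", "carriers", "disomic_spores", "absent_spores",
                "n_spores", "label")
  missing <- setdiff(required, names(rec))
  if (length(missing)) {
    stop("format error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rec
}

#' Write / read SNP matrices as TSV
#'
#' Presence flags are stored as 0/1 and restored as logicals.
#'
#' @param matrix A `zt_snp_matrix` tibble.
#' @param path File path.
#' @return The tibble (read) or `path` invisibly (write).
#' @export
write_snp_matrix <- function(matrix, path) {
  .check_snp_matrix(matrix)
  out <- matrix
  for (cn in .presence_cols) out[[cn]] <- as.integer(out[[cn]])
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_snp_matrix
#' @export
read_snp_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  .check_snp_matrix(m)
  for (cn in .presence_cols) m[[cn]] <- as.logical(m[[cn]])
  for (cn in .cov_cols) m[[cn]] <- as.integer(m[[cn]])
  class(m) <- c("zt_snp_matrix", class(m))
  m
}

#' Read a pipeline configuration from YAML
#'
#' The configuration mirrors [cross_config()]: a `parents` list of two
#' strains (`name`, `mating_type`, `chromosomes`, optional `density`,
#' `mito`, `core_alleles`), the mechanism, the event rates, `n_asci` and
#' `seed`, plus an optional `snp` block (`enabled`, `n_snps` and any other
#' [simulate_snp_matrix()] arguments).
#'
#' @param path YAML file path.
#' @return A list of class `zt_pipeline_config` with elements `config`
#'   (a `zt_config`) and `snp` (a list or `NULL`).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y$parents) || length(y$parents) != 2L) {
    stop("config error: `parents` must list exactly two strains", call. = FALSE)
  }
  mk_strain <- function(p) {
    extra <- p[intersect(names(p), c("core_alleles", "mito", "density"))]
    # tolerate YAML scalars like "1.0e7" that parse as strings
    if (!is.null(extra$density)) extra$density <- as.numeric(extra$density)
    do.call(parental_strain, c(
      list(name = p$name, mating_type = p$mating_type,
           chromosomes = unlist(p$chromosomes)),
      extra
    ))
  }
  parents <- lapply(y$parents, mk_strain)
  cfg_args <- y[intersect(names(y), c(
    "mechanism", "loss_rate", "nondisjunction_rate", "mi_nondisjunction_rate",
    "preferential_bias", "drive_penetrance", "density_exponent", "n_asci",
    "seed", "killer_chromosome", "amplification_copy_loss"
  ))]
  if (!is.null(cfg_args$drive_penetrance)) {
    cfg_args$drive_penetrance <- unlist(cfg_args$drive_penetrance)
  }
  config <- do.call(cross_config,
                    c(list(parent1 = parents[[1]], parent2 = parents[[2]]),
                      cfg_args))
  if (!is.null(config$seed) || config$n_asci == 0L) {
    # fine: deterministic runs need a seed only when something is simulated
  } else {
    stop("config error: `seed` is required when n_asci > 0", call. = FALSE)
  }
  snp <- NULL
  if (isTRUE(y$snp$enabled)) {
    snp <- y$snp[setdiff(names(y$snp), "enabled")]
    if (!is.null(snp$chromosomes)) snp$chromosomes <- unlist(snp$chromosomes)
  }
  structure(list(config = config, snp = snp), class = "zt_pipeline_config")
}

.stage_log <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Run the whole analysis pipeline
#'
#' Simulates an experiment, verifies the asci, classifies segregation,
#' computes transmission tables with drive tests, estimates the paired-loss
#' rate and the mechanism verdict, and (optionally) simulates and summarises
#' a SNP sharing spectrum. Each stage writes a TSV into `out_dir`; a stage
#' failure removes the partial outputs. Re-running with the same
#' configuration and seed reproduces byte-identical files. Progress is
#' logged to standard error.
#'
#' @param config A `zt_config`, or a `zt_pipeline_config` from
#'   [read_pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Optional master-seed override.
#' @return Invisibly, a named list of the stage results (`octads`,
#'   `verification`, `records`, `transmission`, `loss`, `mechanisms`,
#'   `spectrum`, `files`).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  snp_opts <- NULL
  if (inherits(config, "zt_pipeline_config")) {
    snp_opts <- config$snp
    config <- config$config
  }
  stopifnot(inherits(config, "zt_config"))
  seed <- seed %||% config$seed
  if (config$n_asci > 0L && is.null(seed)) {
    stop("a seed is required to run the pipeline", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(x, p)
    written <<- c(written, p)
    p
  }

  res <- tryCatch({
    .stage_log("simulate", "cross ", config$cross$parent1$name, " x ",
               config$cross$parent2$name, ", mechanism ", config$mechanism,
               ", n_asci = ", config$n_asci, ", seed = ",
               seed %||% "<none>")
    octads <- simulate_experiment(config, seed = seed)
    emit(octads, "octads.tsv")
    .stage_log("simulate", nrow(octads), " ascospores written")

    verification <- verify_octads(octads)
    emit(verification, "verification.tsv")
    .stage_log("verify", sum(verification$valid), "/", nrow(verification),
               " asci verified")

    records <- classify_octads(octads, config$cross)
    emit(records, "records.tsv")
    .stage_log("classify", nrow(records), " (ascus x chromosome) records")

    unpaired <- c(config$cross$unpaired_from_p1, config$cross$unpaired_from_p2)
    transmission <- NULL
    if (nrow(octads) > 0L && length(unpaired)) {
      transmission <- dplyr::bind_rows(lapply(sort(unpaired), function(ch) {
        test_transmission(transmission_table(octads, ch))
      }))
      emit(transmission, "transmission.tsv")
    }

    loss <- NULL
    if (nrow(records) > 0L && any(records$pairing_status == "paired")) {
      loss <- estimate_loss_rate(records)
      emit(dplyr::mutate(tidy(loss),
                         overall_rate = loss$rate,
                         heterogeneity_p = loss$heterogeneity$p_value),
           "loss_rate.tsv")
      .stage_log("stats", sprintf("paired-chromosome loss rate %.3f%%",
                                  100 * loss$rate))
    }

    mechanisms <- NULL
    if (nrow(records) > 0L) {
      mechanisms <- discriminate_mechanisms(records, any(verification$valid))
      emit(mechanisms, "mechanisms.tsv")
      .stage_log("stats", "consistent mechanisms: ",
                 paste(attr(mechanisms, "consistent_set"), collapse = ", "))
    }

    spectrum <- NULL
    if (!is.null(snp_opts)) {
      snp_args <- snp_opts
      snp_args$seed <- snp_args$seed %||%
        if (!is.null(seed)) .substream_seed(seed, 999983L)
      mode <- snp_args$filter_mode %||% "none"
      threshold <- snp_args$threshold %||% 8
      snp_args$filter_mode <- NULL
      snp_args$threshold <- NULL
      m <- do.call(simulate_snp_matrix, snp_args)
      emit_path <- file.path(out_dir, "snp_matrix.tsv")
      write_snp_matrix(m, emit_path)
      written <- c(written, emit_path)
      spectrum <- sharing_spectrum(filter_by_coverage(m, mode = mode,
                                                      threshold = threshold))
      emit(tibble::as_tibble(spectrum), "spectrum.tsv")
      .stage_log("snpspectrum", attr(spectrum, "total"),
                 " SNPs after filter ", mode)
    }

    list(octads = octads, verification = verification, records = records,
         transmission = transmission, loss = loss, mechanisms = mechanisms,
         spectrum = spectrum, files = written)
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed: ", conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}
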