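#' Read and write time-resolved image stacks as multi-page TIFF
#'
#' One TIFF page per time bin; values are stored as 32-bit floats. A JSON
#' sidecar `<path>.json` records the laser period and harmonic so a stack
#' is self-describing.
#'
#' @param stack array `(n_bins, Y, X)`.
#' @param path output `.tiff` path.
#' @param period,harmonic acquisition metadata written to the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path, period, harmonic = 1) {
  d <- dim(stack)
  # TIFF float samples are stored in [0, 1]; record the count scale in the
  # sidecar and restore it on read
  scale <- max(stack, 1)
  pages <- lapply(seq_len(d[1]), function(b) stack[b, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(period_ns = period, harmonic = harmonic,
                            n_bins = d[1], count_scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @return `read_stack_tiff`: list with `stack` and sidecar metadata
#'   (`period`, `harmonic`), when a sidecar is present.
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stack <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (b in seq_along(pages)) stack[b, , ] <- pages[[b]]
  meta <- list(period = NULL, harmonic = 1, count_scale = 1)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    sj <- jsonlite::read_json(sidecar)
    meta$period <- sj$period_ns
    meta$harmonic <- if (!is.null(sj$harmonic)) sj$harmonic else 1
    if (!is.null(sj$count_scale)) meta$count_scale <- sj$count_scale
  }
  list(stack = stack * meta$count_scale, period = meta$period,
       harmonic = meta$harmonic)
}

default_pocket_config <- function() {
  list(ligand = "LIG", cutoff = 5.0, charge_scheme = "formal",
       n_boot = 10000, seed = 1, sasa_points = 960, probe = 1.4)
}

default_flim_config <- function() {
  list(period = 25, harmonic = 1, threshold = 100, binning = 1, seed = 1)
}

load_config <- function(config, defaults) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  config
}

write_provenance <- function(config, out_dir) {
  config$package_version <- as.character(utils::packageVersion("pocketflim"))
  yaml::write_yaml(config[order(names(config))],
                   file.path(out_dir, "config_used.yaml"))
}

log_line <- function(con, ...) {
  msg <- paste0(...)
  writeLines(msg, con)
  message(msg)
}

#' End-to-end pocket pipeline: structures -> descriptors -> correlations
#'
#' Reads every structure, computes the five pocket descriptors for each
#' model, joins with the lifetime table, and writes a descriptor table, a
#' correlation report (per-model Spearman summary plus bootstrap CI), and
#' a per-protein dipole table. The configuration used (including the seed
#' and package version) is stored in the output directory, so a run can
#' be regenerated exactly.
#'
#' @param config list or YAML path with fields: `structures` (directory of
#'   PDB/mmCIF files or a character vector of paths; the protein id is the
#'   file name without extension), `lifetimes` (CSV path or data.frame
#'   `protein_id`, `tau_ns`), `out_dir`, and optionally `ligand` (default
#'   `"LIG"`), `cutoff` (5), `charge_scheme` (`"formal"`), `n_boot`
#'   (10000), `seed` (1), `sasa_points` (960), `probe` (1.4).
#' @return list with `descriptors`, `report`, `dipoles` data.frames
#'   (also written as CSV under `out_dir`).
#' @export
run_pocket_pipeline <- function(config) {
  config <- load_config(config, default_pocket_config())
  stopifnot(!is.null(config$structures), !is.null(config$lifetimes),
            !is.null(config$out_dir))
  paths <- config$structures
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(pdb|ent|cif|mmcif)$",
                        full.names = TRUE)
  }
  if (length(paths) < 3) stop("need >= 3 structures, got ", length(paths))
  lifetimes <- if (is.character(config$lifetimes)) {
    read_lifetime_table(config$lifetimes)
  } else validate_lifetime_table(config$lifetimes)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(config$out_dir, "run.log"), "w")
  on.exit(close(logf))
  log_line(logf, "pocket pipeline: ", length(paths), " structures")

  tabs <- lapply(paths, function(p) {
    id <- tools::file_path_sans_ext(basename(p))
    st <- read_structure(p)
    props <- compute_all_properties(st, config$ligand, cutoff = config$cutoff,
                                    charge_scheme = config$charge_scheme,
                                    probe = config$probe,
                                    n_points = config$sasa_points)
    cbind(protein_id = id, props, stringsAsFactors = FALSE)
  })
  descriptors <- do.call(rbind, tabs)
  n_missing <- sum(!unique(descriptors$protein_id) %in% lifetimes$protein_id)
  if (n_missing > length(unique(descriptors$protein_id)) / 2) {
    stop("more than half of the structures have no lifetime entry")
  }
  report <- correlation_report(descriptors, lifetimes,
                               n_boot = config$n_boot, seed = config$seed)
  dip <- stats::aggregate(dipole_eA ~ protein_id, descriptors, mean)
  sds <- stats::aggregate(dipole_eA ~ protein_id, descriptors, stats::sd)
  dipoles <- data.frame(protein_id = dip$protein_id,
                        dipole_mean_eA = dip$dipole_eA,
                        dipole_sd_eA = sds$dipole_eA,
                        dipole_mean_D = dip$dipole_eA * EA_TO_DEBYE)

  utils::write.csv(descriptors, file.path(config$out_dir, "descriptors.csv"),
                   row.names = FALSE)
  utils::write.csv(report, file.path(config$out_dir, "correlation.csv"),
                   row.names = FALSE)
  utils::write.csv(dipoles, file.path(config$out_dir, "dipole_by_protein.csv"),
                   row.names = FALSE)
  write_provenance(config, config$out_dir)
  log_line(logf, "descriptors: ", nrow(descriptors), " rows; report: ",
           nrow(report), " descriptors; seed ", config$seed)
  list(descriptors = descriptors, report = report, dipoles = dipoles)
}

#' End-to-end FLIM pipeline: stack -> phasor -> unmixed component images
#'
#' Computes per-pixel phasors for a time-resolved stack, unmixes against
#' two or three reference species (given as lifetimes or as measured
#' reference decays), and writes per-component intensity TIFFs, fraction
#' TIFFs, a phasor scatter CSV, and a JSON summary. Component images sum
#' to the masked total-intensity image by construction.
#'
#' @param config list or YAML path with fields: `stack` (array or TIFF
#'   path), `out_dir`, `references` (data.frame `name`, `tau` in ns, or a
#'   named list of decay CSV paths with columns time_ns, counts), and
#'   optionally `period` (25 ns), `harmonic` (1), `threshold` (100
#'   photons), `binning` (1).
#' @return list with the [unmix_image()] result (`unmix`) and the
#'   `summary` list (also written as `summary.json`).
#' @export
run_flim_pipeline <- function(config) {
  config <- load_config(config, default_flim_config())
  stopifnot(!is.null(config$stack), !is.null(config$references),
            !is.null(config$out_dir))
  stack <- config$stack
  if (is.character(stack)) {
    rd <- read_stack_tiff(stack)
    stack <- rd$stack
    if (!is.null(rd$period)) config$period <- rd$period
  }
  omega <- 2 * pi * config$harmonic / config$period
  refs_in <- config$references
  if (is.data.frame(refs_in)) {
    if (nrow(refs_in) < 2) stop("need at least 2 reference species")
    # evaluate lifetime references through the same binning as the data so
    # that discretization bias cancels in the unmixing
    n_bins <- dim(stack)[1]
    refs <- lapply(seq_len(nrow(refs_in)), function(i) {
      phasor_transform(expected_decay(refs_in$tau[i], n_bins = n_bins,
                                      period = config$period),
                       config$harmonic)
    })
    names(refs) <- refs_in$name
  } else if (is.list(refs_in)) {
    if (length(refs_in) < 2) stop("need at least 2 reference species")
    refs <- lapply(refs_in, function(p) {
      d <- utils::read.csv(p)
      phasor_transform(decay_histogram(d$counts, config$period),
                       config$harmonic)
    })
  } else stop("references must be a data.frame (name, tau) or list of CSVs")

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  um <- unmix_image(stack, refs, period = config$period,
                    harmonic = config$harmonic,
                    intensity_threshold = config$threshold,
                    spatial_binning = config$binning)
  nref <- length(refs)
  nms <- names(refs)
  if (is.null(nms)) nms <- paste0("component", seq_len(nref))
  scale <- max(um$intensity, 1)
  tiff::writeTIFF(um$intensity / scale,
                  file.path(config$out_dir, "total_intensity.tiff"),
                  bits.per.sample = 32L)
  for (j in seq_len(nref)) {
    tiff::writeTIFF(um$components[, , j] / scale,
                    file.path(config$out_dir,
                              paste0("component_", nms[j], ".tiff")),
                    bits.per.sample = 32L)
    tiff::writeTIFF(um$fractions[, , j],
                    file.path(config$out_dir,
                              paste0("fraction_", nms[j], ".tiff")),
                    bits.per.sample = 32L)
  }
  sel <- which(um$mask)
  yx <- arrayInd(sel, dim(um$mask))
  utils::write.csv(data.frame(y = yx[, 1], x = yx[, 2],
                              g = um$g[sel], s = um$s[sel]),
                   file.path(config$out_dir, "phasor.csv"), row.names = FALSE)
  comp_summary <- lapply(seq_len(nref), function(j) {
    lt <- phasor_lifetime(refs[[j]])
    maj <- apply(um$fractions, c(1, 2), which.max)
    list(name = nms[j], tau_phase_ns = lt$tau_phase,
         n_majority_pixels = sum(maj == j & um$mask))
  })
  summary <- list(n_pixels = length(um$mask), n_analyzed = sum(um$mask),
                  n_masked = sum(!um$mask),
                  intensity_threshold = config$threshold,
                  period_ns = config$period, harmonic = config$harmonic,
                  components = comp_summary)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  config$stack <- if (is.character(config$stack)) config$stack else
    "(in-memory array)"
  config$references <- if (is.data.frame(refs_in)) {
    as.list(stats::setNames(refs_in$tau, refs_in$name))
  } else refs_in
  write_provenance(config, config$out_dir)
  list(unmix = um, summary = summary)
}
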