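#' Validate a pipeline configuration
#'
#' Fills unset fields from [default_protocol_config()] only when
#' `allow_defaults` is TRUE; otherwise every protocol parameter must be
#' present.  Errors list the offending fields by name.
#'
#' @param config named list of parameters.
#' @param allow_defaults fill missing fields from the defaults.
#' @return the completed, validated config.
#' @export
validate_config <- function(config, allow_defaults = TRUE) {
  defaults <- default_protocol_config()
  unknown <- setdiff(names(config),
                     c(names(defaults), "pdb_file", "pdb_text", "model_index",
                       "fixture", "output_dir", "equilibrate",
                       "equilibration_schedule"))
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  missing_f <- setdiff(names(defaults), names(config))
  if (!allow_defaults && length(missing_f) > 0) {
    stop("config missing field(s): ", paste(missing_f, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  positive <- c("probe_radius", "neighborhood_radius", "free_radius",
                "spring_constant", "pull_velocity", "max_dummy_displacement",
                "fit_range", "temperature", "timestep_fs", "delta_threshold",
                "patch_linkage_cutoff")
  bad <- positive[vapply(positive, function(f) {
    !is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0
  }, logical(1))]
  if (!is.null(config$temperature) && config$temperature == 0) bad <- setdiff(bad, "temperature")
  if (length(bad) > 0) {
    stop("config field(s) must be positive numbers: ", paste(bad, collapse = ", "))
  }
  if (!(cfg$class_low < cfg$class_high)) {
    stop("config requires class_low < class_high")
  }
  cfg
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file with protocol parameters (see
#'   [default_protocol_config()]) plus input/output fields `pdb_file` or
#'   `fixture`, `output_dir`.
#' @return validated config list.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Run the full resistance-mapping workflow
#'
#' Stages, in order: load the input structure (a PDB file or a named
#' fixture), optional equilibration, SASA surface selection, the per-residue
#' pulling scan, profile fitting and classification, stability-patch
#' detection, and output writing (profile and SASA TSVs, patches JSON, a
#' B-factor-colored PDB, and a reproducibility manifest).  With the in-repo
#' backends a rerun from the same manifest reproduces identical outputs.
#'
#' @param config list from [validate_config()]/[read_config()]; must carry
#'   either `pdb_file`/`pdb_text` or `fixture` (a kind name for
#'   [make_fixture()]), and may carry `output_dir`.
#' @param backend optional [ff_backend()]; defaults to the fixture's backend
#'   or an elastic network on the loaded structure.
#' @return the run manifest (invisibly), a list with the config snapshot,
#'   input hashes, seed base, per-stage outputs, package version and
#'   timestamps.
#' @export
run_pipeline <- function(config, backend = NULL) {
  cfg <- validate_config(config)
  t0 <- Sys.time()
  stage <- "load"
  manifest <- list(tool = "resistmap",
                   version = as.character(utils::packageVersion("resistmap")),
                   seed_base = cfg$seed_base, stages = list())
  out <- tryCatch({
    if (!is.null(cfg$fixture)) {
      fx <- make_fixture(cfg$fixture, seed = cfg$seed_base)
      structure_ <- fx$structure
      if (is.null(backend)) backend <- fx$backend
      manifest$input <- list(fixture = cfg$fixture)
    } else if (!is.null(cfg$pdb_text) || !is.null(cfg$pdb_file)) {
      txt <- cfg$pdb_text %||% paste(readLines(cfg$pdb_file), collapse = "\n")
      structure_ <- read_structure(txt, model_index = cfg$model_index %||% 1)
      manifest$input <- list(
        pdb_file = cfg$pdb_file %||% NA,
        md5 = if (!is.null(cfg$pdb_file)) unname(tools::md5sum(cfg$pdb_file)) else
          digest_text(txt))
      if (is.null(backend)) backend <- build_enm_backend(structure_)
    } else {
      stop("config must provide pdb_file, pdb_text or fixture")
    }
    manifest$stages$load <- list(n_atoms = nrow(structure_$atoms))

    if (isTRUE(cfg$equilibrate)) {
      stage <- "equilibrate"
      sched <- cfg$equilibration_schedule %||%
        list(list(restrain = "all", duration_ps = 100),
             list(restrain = "backbone", duration_ps = 100))
      structure_ <- equilibrate(structure_, backend, schedule = sched,
                                spec = integrator_spec(cfg$timestep_fs,
                                                       cfg$friction_ps,
                                                       cfg$temperature,
                                                       seed = cfg$seed_base))
      manifest$stages$equilibrate <- list(schedule = sched)
    }

    stage <- "surface"
    sasa <- compute_sasa(structure_, cfg$probe_radius, cfg$n_sphere_points)
    surf <- select_surface_residues(sasa, cfg$sasa_threshold)
    manifest$stages$surface <- list(n_selected = length(surf$selected))
    message("surface: ", length(surf$selected), "/", length(sasa),
            " residues above ", cfg$sasa_threshold, " A^2")

    stage <- "scan"
    scan <- scan_surface(structure_, surf, cfg, backend)
    manifest$stages$scan <- list(n_residues = length(scan),
                                 failures = attr(scan, "failures"))

    stage <- "analyze"
    prof <- resistance_profile(scan, fit_range = cfg$fit_range,
                               low = cfg$class_low, high = cfg$class_high)
    patches <- find_stability_patches(structure_, prof, cfg$class_high,
                                      cfg$patch_linkage_cutoff,
                                      cfg$patch_min_size)
    manifest$stages$analyze <- list(n_patches = length(patches))

    stage <- "write"
    outputs <- list()
    if (!is.null(cfg$output_dir)) {
      dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
      p <- function(f) file.path(cfg$output_dir, f)
      writeLines(profile_tsv(prof), p("profile.tsv"))
      writeLines(surface_set_tsv(structure_, surf), p("sasa.tsv"))
      writeLines(patches_json(patches), p("patches.json"))
      vals <- stats::setNames(prof$mean_coefficient, prof$residue_index)
      vals <- pmin(vals, 999.99)
      writeLines(write_colored_structure(structure_, vals), p("colored.pdb"))
      outputs <- list(profile = p("profile.tsv"), sasa = p("sasa.tsv"),
                      patches = p("patches.json"), colored = p("colored.pdb"))
    }
    manifest$stages$write <- outputs
    manifest$profile <- prof
    manifest$patches <- patches
    manifest$surface <- surf
    manifest
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })
  out$config <- cfg[order(names(cfg))]
  out$started <- format(t0, "%Y-%m-%dT%H:%M:%S%z")
  out$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  if (!is.null(cfg$output_dir)) {
    m <- out
    m$profile <- NULL; m$patches <- NULL; m$surface <- NULL
    jsonlite::write_json(m, file.path(cfg$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  invisible(out)
}

digest_text <- function(txt) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}
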