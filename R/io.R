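# Parameter-file IO. Emission is hand-rolled (stable "%.17g" formatting) so a
# regenerated file is byte-identical for the same inputs; reading goes through
# the YAML parser.

fmt_num <- function(x) sprintf("%.17g", x)

emit_scalar <- function(key, value, indent = "") {
  v <- if (is.character(value)) value
  else if (is.logical(value)) tolower(as.character(value))
  else fmt_num(value)
  paste0(indent, key, ": ", v)
}

emit_vector <- function(key, values, indent = "") {
  vals <- if (is.numeric(values)) vapply(values, fmt_num, "") else as.character(values)
  paste0(indent, key, ": [", paste(vals, collapse = ", "), "]")
}

#' Write a natural-history parameter set to a YAML file
#'
#' The documented, versioned key-value schema every simulator entry point can
#' read back via [read_params()]. Writing the same parameter set twice
#' produces byte-identical files.
#'
#' @param params An `nh_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  g <- genotype_levels()
  lines <- c(
    "schema_version: 1",
    emit_scalar("variant_name", params$variant_name),
    emit_scalar("cycle_length", params$cycle_length),
    "clearance:",
    emit_scalar(g[1], params$clearance[[g[1]]], "  "),
    emit_scalar(g[2], params$clearance[[g[2]]], "  "),
    "progression_to_precancer:",
    emit_scalar(g[1], params$progression_to_precancer[[g[1]]], "  "),
    emit_scalar(g[2], params$progression_to_precancer[[g[2]]], "  "),
    "regression_from_precancer:",
    emit_scalar(g[1], params$regression_from_precancer[[g[1]]], "  "),
    emit_scalar(g[2], params$regression_from_precancer[[g[2]]], "  "),
    emit_scalar("progression_to_cancer", params$progression_to_cancer),
    emit_scalar("symptomatic_detection_rate", params$symptomatic_detection_rate),
    emit_scalar("occult_fraction", params$occult_fraction),
    emit_scalar("cyto_sens_precancer", params$cyto_sens_precancer),
    emit_scalar("cyto_sens_cancer", params$cyto_sens_cancer),
    emit_scalar("cyto_spec", params$cyto_spec),
    emit_scalar("hpv_sens", params$hpv_sens),
    emit_scalar("hpv_spec", params$hpv_spec),
    emit_scalar("colposcopy_sens", params$colposcopy_sens),
    emit_scalar("colposcopy_compliance", params$colposcopy_compliance),
    emit_scalar("treatment_compliance", params$treatment_compliance),
    emit_scalar("vaccine_efficacy_16_18", params$vaccine_efficacy_16_18),
    "hpv_incidence:",
    emit_vector("age", params$hpv_incidence$age, "  "),
    emit_vector(g[1], params$hpv_incidence[[g[1]]], "  "),
    emit_vector(g[2], params$hpv_incidence[[g[2]]], "  "),
    "metadata:"
  )
  meta <- params$metadata
  for (k in names(meta)) {
    if (is.null(meta[[k]]) || length(meta[[k]]) != 1 || is.na(meta[[k]])) next
    lines <- c(lines, emit_scalar(k, meta[[k]], "  "))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a natural-history parameter set from a YAML file
#'
#' @param path A file written by [write_params()].
#' @return An `nh_params` object.
#' @export
read_params <- function(path) {
  y <- yaml::read_yaml(path)
  if (!identical(y$schema_version, 1L) && !identical(y$schema_version, 1)) {
    stop("unsupported parameter schema version: ", y$schema_version, call. = FALSE)
  }
  g <- genotype_levels()
  nh_params(
    variant_name = y$variant_name,
    hpv_incidence = tibble::tibble(
      age = as.integer(unlist(y$hpv_incidence$age)),
      hpv16_18 = as.numeric(unlist(y$hpv_incidence[[g[1]]])),
      other_hr = as.numeric(unlist(y$hpv_incidence[[g[2]]]))
    ),
    clearance = unlist(y$clearance)[g],
    progression_to_precancer = unlist(y$progression_to_precancer)[g],
    regression_from_precancer = unlist(y$regression_from_precancer)[g],
    progression_to_cancer = y$progression_to_cancer,
    symptomatic_detection_rate = y$symptomatic_detection_rate,
    occult_fraction = y$occult_fraction,
    cyto_sens_precancer = y$cyto_sens_precancer,
    cyto_sens_cancer = y$cyto_sens_cancer,
    cyto_spec = y$cyto_spec,
    hpv_sens = y$hpv_sens,
    hpv_spec = y$hpv_spec,
    colposcopy_sens = y$colposcopy_sens,
    colposcopy_compliance = y$colposcopy_compliance,
    treatment_compliance = y$treatment_compliance,
    vaccine_efficacy_16_18 = y$vaccine_efficacy_16_18,
    metadata = y$metadata %||% list()
  )
}

#' Generate the shipped parameter fixtures
#'
#' Writes the three calibrated variant parameter files plus the default
#' demography table to a directory. Deterministic: the same seed regenerates
#' byte-identical files.
#'
#' @param dir Output directory.
#' @param variants Variant names.
#' @param seed Master seed.
#' @param calibrate Run the lifetime-risk calibration (default) or write the
#'   uncalibrated base rates.
#' @return Named character vector of the written paths, invisibly.
#' @export
generate_parameter_files <- function(dir, variants = names(builtin_variants()),
                                     seed = 1L, calibrate = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  demography <- make_demography()
  paths <- c(demography = file.path(dir, "demography.csv"))
  write_demography(demography, paths[["demography"]])
  for (v in variants) {
    p <- make_variant(v, seed = seed, calibrate = calibrate, demography = demography)
    path <- file.path(dir, paste0("params_", v, ".yaml"))
    write_params(p, path)
    paths[[v]] <- path
  }
  invisible(paths)
}

#' Locate a parameter fixture shipped with the package
#'
#' @param variant Variant name.
#' @return Path to the installed YAML fixture.
#' @export
shipped_params_path <- function(variant = names(builtin_variants())) {
  variant <- match.arg(variant)
  system.file("extdata", paste0("params_", variant, ".yaml"),
              package = "screendelay", mustWork = TRUE)
}
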