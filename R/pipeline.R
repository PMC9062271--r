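#' Run the full estimation pipeline
#'
#' Orchestrates the computational task sequence on a directory of
#' canonical CSV inputs: read and validate the inventory, build the
#' species-mean SWD table from wood samples, classify growth classes, fit
#' the local proxy-reconstruction calibration (falling back to reference
#' coefficients per component when the healthy adult subset cannot
#' support a fit), estimate per-individual biomass and losses, upscale to
#' per-hectare values, and summarize plots and strata. All intermediate
#' tables are written to the output directory together with a run
#' manifest (input hashes, configuration, calibration provenance, package
#' version, timestamp).
#'
#' @param input_dir directory with `individuals.csv`, `stems.csv`,
#'   `plots.csv` and `wood_samples.csv`.
#' @param output_dir directory for results (created if absent).
#' @param calibration optional `agb_calibration`; when `NULL` (default) a
#'   local calibration is fitted from the data.
#' @param default_swd optional global SWD fallback, g cm^-3.
#' @param reference_level density level defining the `agb_pot` reference
#'   state.
#' @param strict abort when validation reports violations (default TRUE);
#'   otherwise violations are written and offending individuals dropped.
#' @return Invisibly, a list with all intermediate objects:
#'   `inventory`, `violations`, `swd_table`, `calibration`, `biomass`,
#'   `scaled`, `plot_summaries`, `stand_summaries`, `manifest`.
#' @export
run_pipeline <- function(input_dir, output_dir,
                         calibration = NULL, default_swd = NULL,
                         reference_level = "low", strict = TRUE) {
  inputs <- file.path(input_dir, c("individuals.csv", "stems.csv",
                                   "plots.csv", "wood_samples.csv"))
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop("pipeline stage 'read': missing input file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)

  inv <- read_inventory(input_dir)
  violations <- validate_individuals(inv$individuals, inv$stems)
  readr::write_csv(violations, file.path(output_dir, "violations.csv"))
  if (nrow(violations)) {
    if (strict) {
      stop(sprintf("pipeline stage 'validate': %d violation(s); see %s",
                   nrow(violations), file.path(output_dir, "violations.csv")),
           call. = FALSE)
    }
    warning(sprintf("dropping %d individual(s) with validation violations",
                    length(unique(violations$individual_id))), call. = FALSE)
    inv$individuals <- inv$individuals[
      !inv$individuals$individual_id %in% violations$individual_id, ]
    inv$stems <- inv$stems[
      !inv$stems$individual_id %in% violations$individual_id, ]
  }

  samples <- read_wood_samples(file.path(input_dir, "wood_samples.csv"))
  swd_table <- species_mean_table(samples)
  write_swd_table(swd_table, file.path(output_dir, "swd_table.csv"))

  inv$individuals <- classify_inventory(inv$individuals, inv$stems)
  if (is.null(calibration)) {
    calibration <- calibrate_models(inv$individuals, inv$stems, partial = TRUE)
  }
  write_calibration(calibration, file.path(output_dir, "calibration.json"))

  biomass <- estimate_biomass(inv$individuals, inv$stems, swd_table,
                              calibration, default_swd = default_swd)
  readr::write_csv(biomass, file.path(output_dir, "individual_biomass.csv"))

  scaled <- scale_biomass(biomass, inv$plots)
  plot_summaries <- plot_summary(scaled)
  stand_summaries <- stand_summary(plot_summaries, inv$plots,
                                   reference_level = reference_level)
  readr::write_csv(plot_summaries, file.path(output_dir, "plot_summary.csv"))
  readr::write_csv(stand_summaries, file.path(output_dir, "stand_summary.csv"))
  losses_long <- plot_summaries |>
    tidyr::pivot_longer(dplyr::all_of(paste0("loss_", AGB_AGENTS, "_kg_ha")),
                        names_to = "agent", values_to = "loss_kg_ha") |>
    dplyr::mutate(agent = sub("^loss_(.*)_kg_ha$", "\\1", .data$agent)) |>
    dplyr::select("plot_id", "agent", "loss_kg_ha")
  readr::write_csv(losses_long, file.path(output_dir, "plot_losses_long.csv"))

  manifest <- list(
    pipeline = "swd > classify > calibrate > estimate > aggregate",
    inputs = as.list(tools::md5sum(inputs)),
    calibration_provenance = calibration$provenance,
    reference_level = reference_level,
    strict = strict,
    n_individuals = nrow(inv$individuals),
    n_plots = nrow(inv$plots),
    package_version = as.character(utils::packageVersion("woodyAGB")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(
    inventory = inv, violations = violations, swd_table = swd_table,
    calibration = calibration, biomass = biomass, scaled = scaled,
    plot_summaries = plot_summaries, stand_summaries = stand_summaries,
    manifest = manifest
  ))
}
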