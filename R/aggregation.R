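#' Upscaling factor for a realized sampling area
#'
#' One hectare divided by the area actually covered for a growth class on
#' a plot; converts an individual's kg to kg ha^-1 under the nested
#' subplot design.
#'
#' @param realized_area_m2 realized sampling area, m^2, in (0, 10000].
#' @return Dimensionless factor `10000 / realized_area_m2`. Vectorized.
#' @export
upscaling_factor <- function(realized_area_m2) {
  if (any(!is.finite(realized_area_m2)) || any(realized_area_m2 <= 0) ||
      any(realized_area_m2 > 10000)) {
    stop("realized sampling area must be in (0, 10000] m^2", call. = FALSE)
  }
  10000 / realized_area_m2
}

#' Scale per-individual biomass to a per-hectare basis
#'
#' Multiplies every AGB partition (standing, pre-disturbance, each
#' per-agent loss, dead-stem loss) by the upscaling factor of the
#' individual's growth class on its plot, and by the individual's
#' `edge_fraction` (the fraction of the plant falling inside the plot).
#'
#' @param biomass per-individual results from [estimate_biomass()].
#' @param plots plots table with realized areas `area_JU`, `area_SA`,
#'   `area_AA`, `area_AG`.
#' @return `biomass` with all kg columns replaced by `_kg_ha` columns and
#'   an `upscaling_factor` column added.
#' @export
scale_biomass <- function(biomass, plots) {
  area_col <- AGB_AREA_COLUMN[biomass$growth_class]
  plot_row <- match(biomass$plot_id, plots$plot_id)
  if (anyNA(plot_row)) {
    stop("plots table lacks plot(s): ",
         paste(unique(biomass$plot_id[is.na(plot_row)]), collapse = ", "),
         call. = FALSE)
  }
  area <- vapply(seq_along(plot_row), function(i) {
    a <- plots[[area_col[i]]][plot_row[i]]
    if (is.na(a)) {
      stop(sprintf("plot '%s' has no realized sampling area for class %s (column %s)",
                   biomass$plot_id[i], biomass$growth_class[i], area_col[i]),
           call. = FALSE)
    }
    a
  }, numeric(1))
  factor <- upscaling_factor(area) * biomass$edge_fraction
  kg_cols <- c("agb_standing_kg", "agb_ex_kg", "dead_stem_loss_kg",
               paste0("loss_", AGB_AGENTS, "_kg"))
  out <- biomass
  for (col in kg_cols) {
    out[[paste0(col, "_ha")]] <- out[[col]] * factor
    out[[col]] <- NULL
  }
  out$upscaling_factor <- factor
  out
}

#' Summarize a plot (or several) to stand level
#'
#' Sums the upscaled per-hectare partitions over the individuals of each
#' plot and counts individuals by growth class. Conservation
#' (`agb_ex = agb_standing + sum of losses`) is re-checked after
#' aggregation.
#'
#' @param scaled upscaled records from [scale_biomass()].
#' @return A tibble with one row per plot: `plot_id`, `n_individuals`,
#'   per-class counts `n_<class>`, `agb_standing_kg_ha`, `agb_ex_kg_ha`,
#'   `dead_stem_loss_kg_ha` and the six `loss_<agent>_kg_ha` columns.
#' @export
plot_summary <- function(scaled) {
  ha_cols <- c("agb_standing_kg_ha", "agb_ex_kg_ha", "dead_stem_loss_kg_ha",
               paste0("loss_", AGB_AGENTS, "_kg_ha"))
  out <- scaled |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::summarise(
      n_individuals = dplyr::n(),
      dplyr::across(dplyr::all_of(ha_cols), sum),
      .groups = "drop"
    )
  counts <- scaled |>
    dplyr::count(.data$plot_id, .data$growth_class) |>
    tidyr::pivot_wider(names_from = "growth_class", values_from = "n",
                       names_prefix = "n_", values_fill = 0L)
  out <- dplyr::left_join(out, counts, by = "plot_id")
  resid <- abs(out$agb_ex_kg_ha -
                 (out$agb_standing_kg_ha +
                    rowSums(as.matrix(out[, paste0("loss_", AGB_AGENTS, "_kg_ha")]))))
  rel <- resid / pmax(out$agb_ex_kg_ha, .Machine$double.eps)
  if (any(rel > 1e-9)) {
    stop("conservation violated after aggregation for plot(s): ",
         paste(out$plot_id[rel > 1e-9], collapse = ", "), call. = FALSE)
  }
  out
}

#' Summarize strata (vegetation type x disturbance level)
#'
#' Means and standard deviations of the plot-level quantities over the
#' replicate plots of each stratum, plus the maximum potential AGB
#' (`agb_pot`): for each vegetation type, the mean pre-disturbance AGB
#' (`agb_ex`) of its reference stratum at the least-disturbed (by default
#' `"low"`) elephant-density level.
#'
#' @param plot_summaries output of [plot_summary()].
#' @param plots plots table carrying `vegetation` and `density_level`.
#' @param reference_level density level defining the reference state for
#'   `agb_pot` (default `"low"`).
#' @param stat statistic for `agb_pot` over the reference plots:
#'   `"mean"` (default) or `"median"`.
#' @param exclude_plots optional character vector of plot ids to leave out
#'   (e.g. a user-curated outlier list).
#' @return A tibble with one row per stratum: `vegetation`,
#'   `density_level`, `n_plots`, `<quantity>_mean` and `<quantity>_sd`
#'   for each plot-level quantity, and `agb_pot_kg_ha`.
#' @export
stand_summary <- function(plot_summaries, plots, reference_level = "low",
                          stat = c("mean", "median"), exclude_plots = NULL) {
  stat <- match.arg(stat)
  stat_fun <- if (stat == "mean") mean else stats::median
  if (!is.null(exclude_plots)) {
    plot_summaries <- plot_summaries[!plot_summaries$plot_id %in% exclude_plots, ]
  }
  df <- dplyr::inner_join(
    plot_summaries,
    plots[, c("plot_id", "vegetation", "density_level")],
    by = "plot_id"
  )
  ha_cols <- c("agb_standing_kg_ha", "agb_ex_kg_ha", "dead_stem_loss_kg_ha",
               paste0("loss_", AGB_AGENTS, "_kg_ha"))
  out <- df |>
    dplyr::group_by(.data$vegetation, .data$density_level) |>
    dplyr::summarise(
      n_plots = dplyr::n(),
      dplyr::across(dplyr::all_of(ha_cols),
                    list(mean = mean, sd = sd)),
      .groups = "drop"
    )
  ref <- df[df$density_level == reference_level, ]
  if (nrow(ref) == 0L) {
    stop(sprintf("no plots at the reference density level '%s'; cannot derive agb_pot",
                 reference_level), call. = FALSE)
  }
  pot <- ref |>
    dplyr::group_by(.data$vegetation) |>
    dplyr::summarise(agb_pot_kg_ha = stat_fun(.data$agb_ex_kg_ha),
                     .groups = "drop")
  missing_veg <- setdiff(out$vegetation, pot$vegetation)
  if (length(missing_veg)) {
    stop("vegetation type(s) without a reference stratum: ",
         paste(missing_veg, collapse = ", "), call. = FALSE)
  }
  dplyr::left_join(out, pot, by = "vegetation")
}
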