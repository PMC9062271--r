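# Builders for small canonical tables used across the tests.

AGENTS <- c("elephant", "fire", "browsers", "woodcutting", "abiotic", "other")

make_individual <- function(id, plot_id = "P1", species = "Burkea africana",
                            height_cm = 300, cd1_m = NA_real_, cd2_m = NA_real_,
                            edge_fraction = 1, growth_class = NA_character_,
                            losses = c(), comment = NA_character_) {
  row <- tibble::tibble(
    individual_id = id, plot_id = plot_id, species = species,
    growth_class = growth_class, height_cm = height_cm,
    cd1_m = cd1_m, cd2_m = cd2_m, edge_fraction = edge_fraction,
    comment = comment
  )
  for (a in AGENTS) {
    row[[paste0("loss_", a)]] <- if (a %in% names(losses)) losses[[a]] else 0
  }
  row[, c("individual_id", "plot_id", "species", "growth_class", "height_cm",
          "cd1_m", "cd2_m", "edge_fraction", paste0("loss_", AGENTS), "comment")]
}

make_stem <- function(individual_id, stem_id = paste0(individual_id, "-s1"),
                      basal_circ_cm = NA_real_, circ130_cm = NA_real_,
                      alt_circ_cm = NA_real_, alt_height_cm = NA_real_,
                      is_dead = FALSE, topkill_agent_1 = NA_character_,
                      topkill_agent_2 = NA_character_) {
  tibble::tibble(
    individual_id = individual_id, stem_id = stem_id,
    basal_circ_cm = basal_circ_cm, circ130_cm = circ130_cm,
    alt_circ_cm = alt_circ_cm, alt_height_cm = alt_height_cm,
    is_dead = is_dead, topkill_agent_1 = topkill_agent_1,
    topkill_agent_2 = topkill_agent_2
  )
}

empty_stems <- function() make_stem(character(0))[0, ]

make_plot <- function(plot_id = "P1", vegetation = "savanna",
                      density_level = "low", area_JU = 100, area_SA = 500,
                      area_AA = 1000, area_AG = 800, plot_area_m2 = 1000) {
  tibble::tibble(
    plot_id = plot_id, vegetation = vegetation, density_level = density_level,
    lat = -18, lon = 23.4, plot_area_m2 = plot_area_m2,
    area_JU = area_JU, area_SA = area_SA, area_AA = area_AA, area_AG = area_AG
  )
}

loss_kg_cols <- function() paste0("loss_", AGENTS, "_kg")

total_losses_kg <- function(biomass) {
  rowSums(as.matrix(biomass[, loss_kg_cols()]))
}

# A small tidy inventory used by round-trip and validation tests.
tiny_inventory <- function() {
  individuals <- dplyr::bind_rows(
    make_individual("A1", height_cm = 1200, losses = c(elephant = 20)),
    make_individual("S1", height_cm = 300, cd1_m = 1.6, cd2_m = 1.2,
                    losses = c(fire = 12.5)),
    make_individual("J1", height_cm = 90, cd1_m = 0.5, cd2_m = 0.3)
  )
  stems <- dplyr::bind_rows(
    make_stem("A1", basal_circ_cm = 118.2, circ130_cm = 94.2),
    make_stem("A1", stem_id = "A1-s2", basal_circ_cm = 60,
              alt_circ_cm = 45, alt_height_cm = 80)
  )
  plots <- make_plot()
  structure(list(individuals = individuals, stems = stems, plots = plots),
            class = "agb_inventory")
}
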