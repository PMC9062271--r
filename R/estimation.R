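#' Partition pre-disturbance biomass into per-agent losses
#'
#' Multiplies a pre-disturbance AGB value by the visually estimated
#' percentage of biomass lost to each disturbance agent; the standing
#' biomass is the remainder. With the field protocol's cap of 99% total
#' loss, at least 1% of the pre-disturbance value always remains standing
#' (the floor left after total topkill).
#'
#' @param agb_pre pre-disturbance AGB, kg.
#' @param loss_percent named numeric vector of per-agent loss percentages
#'   (names from the agent vocabulary), each in \[0, 99\], summing to at
#'   most 99.
#' @return List with `losses` (named kg vector over all six agents) and
#'   `standing` (kg).
#' @export
partition_canopy_losses <- function(agb_pre, loss_percent) {
  stopifnot(agb_pre >= 0)
  pct <- setNames(numeric(length(AGB_AGENTS)), AGB_AGENTS)
  if (length(loss_percent)) {
    unknown <- setdiff(names(loss_percent), AGB_AGENTS)
    if (length(unknown)) {
      stop("unknown disturbance agents: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    pct[names(loss_percent)] <- loss_percent
  }
  if (any(pct < 0) || any(pct > 99) || sum(pct) > 99 + 1e-9) {
    stop(sprintf("invalid damage assessment: per-agent losses %s (sum %g)",
                 paste(sprintf("%s=%g", names(pct)[pct > 0], pct[pct > 0]),
                       collapse = ", "), sum(pct)), call. = FALSE)
  }
  losses <- agb_pre * pct / 100
  list(losses = losses, standing = agb_pre - sum(losses))
}

#' Reverse damage assessment
#'
#' For canopy-measured individuals the allometric estimate reflects the
#' damaged (standing) state; the pre-disturbance value is recovered by
#' dividing by the retained fraction: `agb_pre = agb_post / (1 - pct/100)`.
#'
#' @param agb_post standing (post-disturbance) AGB, kg.
#' @param total_loss_percent total percentage lost over all agents, in
#'   \[0, 99\].
#' @return Pre-disturbance AGB, kg.
#' @export
reverse_damage <- function(agb_post, total_loss_percent) {
  stopifnot(agb_post >= 0)
  if (any(total_loss_percent < 0) || any(total_loss_percent > 99 + 1e-9)) {
    stop("total loss percentage must be in [0, 99]", call. = FALSE)
  }
  agb_post / (1 - pmin(total_loss_percent, 99) / 100)
}

#' Allocate a dead stem's biomass loss to its topkill agent(s)
#'
#' A dead stem's reconstructed former biomass is attributed to the agent
#' recorded as responsible for the topkill; where two joint agents were
#' listed the loss is split between them (equally by default).
#'
#' @param dead_loss_kg the stem's former AGB, kg.
#' @param agents character vector of one or two agent labels.
#' @param weights optional numeric weights (same length as `agents`),
#'   normalized internally; default equal split.
#' @return Named kg vector over the agents given.
#' @export
assign_topkill_loss <- function(dead_loss_kg, agents, weights = NULL) {
  stopifnot(dead_loss_kg >= 0)
  agents <- agents[!is.na(agents)]
  if (length(agents) < 1L || length(agents) > 2L) {
    stop("a dead stem carries one or two topkill agents", call. = FALSE)
  }
  unknown <- setdiff(agents, AGB_AGENTS)
  if (length(unknown)) {
    stop("unknown topkill agents: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(agents))
  stopifnot(length(weights) == length(agents), all(weights > 0))
  out <- dead_loss_kg * weights / sum(weights)
  # joint agents may coincide; accumulate
  tapply(out, factor(agents, levels = unique(agents)), sum) |>
    as.vector() |> setNames(unique(agents))
}

#' Former biomass of a dead stem
#'
#' Reconstructs the pre-topkill aboveground biomass of a dead stem from
#' its basal circumference (or, failing that, an alternative circumference
#' reading): DBH is estimated through the basal-diameter proportionality,
#' the pre-disturbance height through the height power law, and biomass
#' through the stem-based model.
#'
#' @param basal_circ_cm basal circumference, cm (NA if unavailable).
#' @param alt_circ_cm,alt_height_cm alternative reading and its height,
#'   used when the basal circumference is missing.
#' @param swd specific wood density, g cm^-3.
#' @param calibration an `agb_calibration`.
#' @return Former AGB of the stem, kg.
#' @export
dead_stem_agb <- function(basal_circ_cm, swd, calibration = default_calibration(),
                          alt_circ_cm = NA_real_, alt_height_cm = NA_real_) {
  if (is.na(basal_circ_cm)) {
    if (is.na(alt_circ_cm) || is.na(alt_height_cm)) {
      stop("dead stem has no usable circumference (basal or alternative) measure",
           call. = FALSE)
    }
    basal_circ_cm <- basal_from_alternative(alt_circ_cm, alt_height_cm, calibration)
  }
  dbh <- dbh_from_basal(basal_circ_cm, calibration)
  h_est <- exp(calibration$height$a + calibration$height$b * log(dbh))
  stem_agb(swd, dbh, h_est / 100)
}

# DBH of a living stem: measured circ130 preferred, then estimated from the
# basal circumference, then from an alternative reading; error naming the
# missing proxy otherwise.
living_stem_dbh <- function(st, calibration) {
  if (!is.na(st$circ130_cm)) return(st$circ130_cm / pi)
  basal <- st$basal_circ_cm
  if (is.na(basal)) {
    if (is.na(st$alt_circ_cm) || is.na(st$alt_height_cm)) {
      stop(sprintf(
        "stem '%s' of individual '%s': no circumference proxy (need circ130, basal, or alternative reading)",
        st$stem_id, st$individual_id), call. = FALSE)
    }
    basal <- basal_from_alternative(st$alt_circ_cm, st$alt_height_cm, calibration)
  }
  dbh_from_basal(basal, calibration)
}

#' Estimate biomass and losses for one individual
#'
#' Dispatches on the growth class:
#'
#' * `AA`, `AG1` — stem-based model per living stem, sharing the
#'   individual's height, with DBH measured or estimated; for `AG1` the
#'   pre-disturbance height is first reconstructed from each stem's DBH.
#'   The summed raw model output is the pre-disturbance AGB, from which
#'   per-agent percentage losses are deducted to obtain standing AGB.
#' * `AG2a`, `AG2b` — as above for the living stems (height reconstruction
#'   only for `AG2b`, whose living crowns are themselves damaged), plus
#'   the former biomass of each dead stem, attributed to its topkill
#'   agent(s).
#' * `JU`, `SA`, `GJ`, `GS` — canopy-based model; the raw output is the
#'   standing (damaged-state) AGB, and the pre-disturbance value follows
#'   by reverse damage assessment.
#' * `AG3` — canopy-based model for the shrub-like living regrowth (with
#'   reverse damage assessment for its own losses) plus dead-stem former
#'   biomass, attributed to the topkill agent(s).
#'
#' The visually estimated loss percentages apply to the living part only;
#' dead adult-sized stems are accounted for separately and never
#' contribute to standing biomass.
#'
#' @param ind a one-row individuals table (classified).
#' @param stems stems of that individual (possibly zero rows).
#' @param swd specific wood density resolved for the species, g cm^-3
#'   (may be NA for purely canopy-based classes without dead stems).
#' @param calibration an `agb_calibration`.
#' @return One-row tibble: `individual_id`, `plot_id`, `species`,
#'   `growth_class`, `edge_fraction`, `model_used`, `agb_standing_kg`,
#'   `agb_ex_kg` (pre-disturbance), `loss_<agent>_kg` for the six agents,
#'   and `dead_stem_loss_kg`.
#' @export
estimate_individual <- function(ind, stems, swd,
                                calibration = default_calibration()) {
  gc <- ind$growth_class
  if (is.na(gc) || !gc %in% AGB_CLASSES) {
    stop(sprintf("individual '%s': unknown growth class '%s'",
                 ind$individual_id, gc), call. = FALSE)
  }
  pct <- unlist(ind[, loss_columns()])
  names(pct) <- AGB_AGENTS
  pct[is.na(pct)] <- 0
  living <- stems[is.na(stems$is_dead) | !stems$is_dead, , drop = FALSE]
  dead <- stems[!is.na(stems$is_dead) & stems$is_dead, , drop = FALSE]

  canopy_based <- gc %in% c("JU", "SA", "GJ", "GS", "AG3")
  if (canopy_based) {
    if (is.na(ind$cd1_m) || is.na(ind$cd2_m)) {
      stop(sprintf(
        "individual '%s' (%s): crown diameters required for the canopy-based model",
        ind$individual_id, gc), call. = FALSE)
    }
    cd <- (ind$cd1_m + ind$cd2_m) / 2
    standing_living <- canopy_agb(cd, ind$height_cm)
    pre_living <- reverse_damage(standing_living, sum(pct))
    canopy_losses <- partition_canopy_losses(pre_living, pct)$losses
    model <- "canopy"
  } else {
    if (nrow(living) == 0L) {
      stop(sprintf("individual '%s' (%s): no living stems for the stem-based model",
                   ind$individual_id, gc), call. = FALSE)
    }
    if (is.na(swd)) {
      stop(sprintf("individual '%s': specific wood density unresolved for species '%s'",
                   ind$individual_id, ind$species), call. = FALSE)
    }
    correct_height <- gc %in% c("AG1", "AG2b")
    pre_living <- 0
    for (j in seq_len(nrow(living))) {
      dbh <- living_stem_dbh(living[j, ], calibration)
      h <- if (correct_height) {
        reconstruct_height(dbh, ind$height_cm, calibration)
      } else ind$height_cm
      pre_living <- pre_living + stem_agb(swd, dbh, h / 100)
    }
    part <- partition_canopy_losses(pre_living, pct)
    canopy_losses <- part$losses
    standing_living <- part$standing
    model <- "stem"
  }

  dead_total <- 0
  dead_losses <- setNames(numeric(length(AGB_AGENTS)), AGB_AGENTS)
  if (nrow(dead)) {
    if (is.na(swd)) {
      stop(sprintf("individual '%s': specific wood density unresolved for species '%s'",
                   ind$individual_id, ind$species), call. = FALSE)
    }
    for (j in seq_len(nrow(dead))) {
      st <- dead[j, ]
      loss_j <- dead_stem_agb(st$basal_circ_cm, swd, calibration,
                              alt_circ_cm = st$alt_circ_cm,
                              alt_height_cm = st$alt_height_cm)
      agents <- c(st$topkill_agent_1, st$topkill_agent_2)
      agents <- agents[!is.na(agents)]
      if (!length(agents)) {
        stop(sprintf("dead stem '%s' of individual '%s' lacks a topkill agent",
                     st$stem_id, st$individual_id), call. = FALSE)
      }
      alloc <- assign_topkill_loss(loss_j, agents)
      dead_losses[names(alloc)] <- dead_losses[names(alloc)] + alloc
      dead_total <- dead_total + loss_j
    }
    if (gc == "AG3") model <- "combined"
  }

  losses <- canopy_losses + dead_losses
  out <- tibble::tibble(
    individual_id = ind$individual_id,
    plot_id = ind$plot_id,
    species = ind$species,
    growth_class = gc,
    edge_fraction = ind$edge_fraction,
    model_used = model,
    agb_standing_kg = standing_living,
    agb_ex_kg = standing_living + sum(losses),
    dead_stem_loss_kg = dead_total
  )
  for (a in AGB_AGENTS) out[[paste0("loss_", a, "_kg")]] <- unname(losses[a])
  out
}

#' Estimate biomass for a whole inventory
#'
#' Resolves specific wood density per species (with genus/default
#' fallback), then applies [estimate_individual()] to every record.
#'
#' @param individuals classified individuals table.
#' @param stems stems table.
#' @param swd_table species-mean SWD table from [species_mean_table()].
#' @param calibration an `agb_calibration`.
#' @param default_swd optional global SWD fallback, g cm^-3.
#' @return A tibble with one row per individual (see
#'   [estimate_individual()] for columns).
#' @export
estimate_biomass <- function(individuals, stems, swd_table,
                             calibration = default_calibration(),
                             default_swd = NULL) {
  species <- unique(individuals$species)
  # unresolvable species become NA here and only error if a stem-based
  # estimate actually needs them (canopy-only classes need no SWD)
  swd_by_species <- vapply(species, function(sp) {
    tryCatch(lookup_swd(sp, swd_table, default_swd)$swd_g_cm3,
             error = function(e) NA_real_)
  }, numeric(1))
  stems_by_ind <- split(stems, stems$individual_id)
  empty_stems <- stems[0, , drop = FALSE]
  rows <- lapply(seq_len(nrow(individuals)), function(i) {
    ind <- individuals[i, ]
    st <- stems_by_ind[[ind$individual_id]]
    if (is.null(st)) st <- empty_stems
    estimate_individual(ind, st, swd_by_species[[ind$species]], calibration)
  })
  dplyr::bind_rows(rows)
}
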