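#' Configuration for the synthetic inventory generator
#'
#' Builds the parameter set for [simulate_inventory()]. The defaults
#' emulate a stratified savanna study: 2 vegetation types x 3 elephant
#' density levels, 10 replicate 1000-m^2 plots per site (60 plots), a
#' nested subplot design (juveniles on 100 m^2, saplings on 250-750 m^2,
#' damaged adults on 750-1000 m^2, healthy adults on the full plot), an
#' allometrically coherent tree population, and a disturbance regime in
#' which fire losses decline and elephant losses rise along the elephant
#' density gradient, with density-dependent topkill.
#'
#' @param vegetation_types,density_levels stratification labels.
#' @param plots_per_site replicate plots per stratum.
#' @param plot_area_m2 full plot area, m^2.
#' @param density_per_ha named list per vegetation type of per-class stem
#'   densities (individuals ha^-1) for `JU`, `SA`, `AA`.
#' @param species tibble with `species` and true `swd` (g cm^-3).
#' @param allometry true coefficients `a`, `b` (height power law), `s`
#'   (DBH proportionality) and `t` (taper).
#' @param crown coefficients of the crown-height link
#'   `CD = c0 * (h/100)^gamma` (CD in m, h in cm).
#' @param dbh lognormal parameters (`meanlog`, `sdlog`) and lower
#'   truncation (`min`, cm) of adult main-stem DBH.
#' @param sigma_height lognormal sd of biological height scatter around
#'   the power law.
#' @param sigma_measure lognormal sd of measurement noise applied to all
#'   emitted heights, circumferences and crown diameters.
#' @param sigma_wood lognormal sd on wood-sample dry mass.
#' @param regime per-density-level disturbance parameters; see
#'   [default_disturbance_regime()].
#' @param frac_missing_circ130 fraction of living adult stems whose
#'   breast-height circumference is unavailable (DBH estimated from the
#'   basal circumference).
#' @param frac_alt_reading fraction of stems carrying an additional
#'   alternative circumference reading (feeds the taper calibration).
#' @param frac_alt_only fraction of stems with only an alternative
#'   reading (neither basal nor breast-height circumference).
#' @param extra_stem_lambda Poisson mean of additional stems per adult.
#' @return An object of class `agb_sim_config`.
#' @export
simulation_config <- function(
    vegetation_types = c("savanna", "woodland"),
    density_levels = c("low", "medium", "high"),
    plots_per_site = 10,
    plot_area_m2 = 1000,
    density_per_ha = list(
      savanna  = c(JU = 1500, SA = 600, AA = 120),
      woodland = c(JU = 2000, SA = 800, AA = 180)
    ),
    species = default_species_pool(),
    allometry = list(a = 4.72595, b = 0.63385, s = 0.7968, t = 0.2032),
    crown = list(c0 = 0.45, gamma = 0.85),
    dbh = list(meanlog = log(12), sdlog = 0.45, min = 5),
    sigma_height = 0.15,
    sigma_measure = 0.05,
    sigma_wood = 0.03,
    regime = default_disturbance_regime(density_levels),
    frac_missing_circ130 = 0.2,
    frac_alt_reading = 0.3,
    frac_alt_only = 0.05,
    extra_stem_lambda = 0.35) {
  cfg <- list(
    vegetation_types = vegetation_types,
    density_levels = density_levels,
    plots_per_site = plots_per_site,
    plot_area_m2 = plot_area_m2,
    density_per_ha = density_per_ha,
    species = species,
    allometry = allometry,
    crown = crown,
    dbh = dbh,
    sigma_height = sigma_height,
    sigma_measure = sigma_measure,
    sigma_wood = sigma_wood,
    regime = regime,
    frac_missing_circ130 = frac_missing_circ130,
    frac_alt_reading = frac_alt_reading,
    frac_alt_only = frac_alt_only,
    extra_stem_lambda = extra_stem_lambda
  )
  stopifnot(plots_per_site >= 1, plot_area_m2 > 0,
            all(unlist(density_per_ha) >= 0),
            all(species$swd > 0 & species$swd < 1.5))
  for (p in c("frac_missing_circ130", "frac_alt_reading", "frac_alt_only")) {
    stopifnot(cfg[[p]] >= 0, cfg[[p]] <= 1)
  }
  structure(cfg, class = "agb_sim_config")
}

#' Default species pool for the generator
#'
#' Eight woody species typical of semi-arid southern African savannas,
#' with plausible specific wood densities and relative abundances.
#'
#' @return Tibble with `species`, `swd` (g cm^-3) and `weight`.
#' @export
default_species_pool <- function() {
  tibble::tibble(
    species = c("Burkea africana", "Terminalia sericea", "Combretum collinum",
                "Baikiaea plurijuga", "Philenoptera nelsii",
                "Dichrostachys cinerea", "Combretum hereroense",
                "Ochna pulchra"),
    swd = c(0.74, 0.72, 0.75, 0.84, 0.62, 0.86, 0.78, 0.58),
    weight = c(0.20, 0.18, 0.16, 0.10, 0.12, 0.10, 0.08, 0.06)
  )
}

#' Default disturbance regime
#'
#' Per-density-level disturbance parameters: per-agent attack
#' probabilities, mean Beta-distributed loss fractions given attack, the
#' Beta concentration, the adult topkill probability, the weight of
#' elephant (vs fire) as topkill agent, and the probability that two
#' joint topkill agents are recorded. The defaults inject the qualitative
#' gradient in which fire losses decline, and elephant losses and topkill
#' rise, with increasing elephant density; woodcutting is concentrated at
#' the low-density (communal) sites.
#'
#' @param density_levels labels, ordered from least to most disturbed.
#' @return Named list (one element per level) of parameter lists.
#' @export
default_disturbance_regime <- function(density_levels = c("low", "medium", "high")) {
  base <- list(
    low = list(
      attack = c(elephant = 0.25, fire = 0.60, browsers = 0.30,
                 woodcutting = 0.25, abiotic = 0.15, other = 0.08),
      mean_loss = c(elephant = 0.08, fire = 0.25, browsers = 0.05,
                    woodcutting = 0.20, abiotic = 0.10, other = 0.05),
      phi = 6, topkill_prob = 0.04, topkill_w_elephant = 0.40,
      joint_topkill_prob = 0.15
    ),
    medium = list(
      attack = c(elephant = 0.50, fire = 0.45, browsers = 0.30,
                 woodcutting = 0.08, abiotic = 0.15, other = 0.08),
      mean_loss = c(elephant = 0.15, fire = 0.15, browsers = 0.05,
                    woodcutting = 0.20, abiotic = 0.10, other = 0.05),
      phi = 6, topkill_prob = 0.12, topkill_w_elephant = 0.60,
      joint_topkill_prob = 0.15
    ),
    high = list(
      attack = c(elephant = 0.75, fire = 0.30, browsers = 0.30,
                 woodcutting = 0.03, abiotic = 0.15, other = 0.08),
      mean_loss = c(elephant = 0.25, fire = 0.08, browsers = 0.05,
                    woodcutting = 0.20, abiotic = 0.10, other = 0.05),
      phi = 6, topkill_prob = 0.25, topkill_w_elephant = 0.75,
      joint_topkill_prob = 0.15
    )
  )
  out <- base[density_levels]
  if (anyNA(names(out))) {
    stop("no default regime for density level(s): ",
         paste(density_levels[!density_levels %in% names(base)], collapse = ", "),
         call. = FALSE)
  }
  out
}

#' A noise-free variant of a simulation configuration
#'
#' Sets all biological and measurement noise terms to zero so that every
#' observable lies exactly on the generating allometric relationships;
#' used for end-to-end identity checks of the estimation pipeline.
#'
#' @param config an `agb_sim_config`.
#' @return The configuration with `sigma_height`, `sigma_measure` and
#'   `sigma_wood` set to 0.
#' @export
noise_free <- function(config = simulation_config()) {
  config$sigma_height <- 0
  config$sigma_measure <- 0
  config$sigma_wood <- 0
  config
}

#' Generate the study design (plot table)
#'
#' One plot table row per replicate plot of every stratum, with realized
#' subplot areas drawn per the nested design: juveniles on a fixed
#' 100 m^2 subplot, saplings on 250-750 m^2, damaged (gulliver) adults on
#' 750-1000 m^2, healthy adults on the full plot. Coordinates are jittered
#' around a semi-arid savanna location.
#'
#' @param config an `agb_sim_config`. Uses the current RNG state.
#' @return A canonical plots tibble.
#' @export
generate_design <- function(config = simulation_config()) {
  grid <- expand.grid(
    plot = seq_len(config$plots_per_site),
    density_level = config$density_levels,
    vegetation = config$vegetation_types,
    stringsAsFactors = FALSE
  )
  n <- nrow(grid)
  tibble::tibble(
    plot_id = sprintf("%s-%s-%02d", substr(grid$vegetation, 1, 3),
                      grid$density_level, grid$plot),
    vegetation = grid$vegetation,
    density_level = grid$density_level,
    lat = -18.07 + runif(n, -0.2, 0.2),
    lon = 23.42 + runif(n, -0.2, 0.2),
    plot_area_m2 = config$plot_area_m2,
    area_JU = 100,
    area_SA = runif(n, 250, 750),
    area_AA = config$plot_area_m2,
    area_AG = runif(n, 750, 1000)
  )
}

rlnorm1 <- function(n, sigma) {
  if (sigma == 0) rep(1, n) else rlnorm(n, meanlog = 0, sdlog = sigma)
}

# Two orthogonal crown diameter readings whose arithmetic mean is cd.
split_crown <- function(cd) {
  delta <- runif(length(cd), 0, 0.15)
  list(cd1 = cd * (1 + delta), cd2 = cd * (1 - delta))
}

#' Simulate the undamaged tree population of one plot
#'
#' Draws per-class individual counts as Poisson(density x subplot area),
#' adult main-stem DBH from a truncated lognormal, heights on the
#' height-DBH power law with multiplicative biological scatter, and crown
#' diameters of sub-adults from the crown-height link. Adults may carry
#' several stems. Returns noise-free ("true") individuals and stems
#' tables; damage is added by [apply_disturbances()].
#'
#' @param plot one row of a plots table.
#' @param config an `agb_sim_config`. Uses the current RNG state.
#' @return List with tibbles `individuals` and `stems` (canonical
#'   columns, zero losses, `growth_class` unset).
#' @export
simulate_individuals <- function(plot, config = simulation_config()) {
  al <- config$allometry
  dens <- config$density_per_ha[[plot$vegetation]]
  counts <- c(
    JU = rpois(1, dens[["JU"]] * plot$area_JU / 1e4),
    SA = rpois(1, dens[["SA"]] * plot$area_SA / 1e4),
    AA = rpois(1, dens[["AA"]] * plot$plot_area_m2 / 1e4)
  )
  sp <- function(n) sample(config$species$species, n, replace = TRUE,
                           prob = config$species$weight)
  inds <- list(); stems <- list()
  make_ind <- function(id, species, h, cd1, cd2) {
    row <- tibble::tibble(
      individual_id = id, plot_id = plot$plot_id, species = species,
      growth_class = NA_character_, height_cm = h,
      cd1_m = cd1, cd2_m = cd2, edge_fraction = 1, comment = NA_character_
    )
    for (col in loss_columns()) row[[col]] <- 0
    row[, individual_columns()]
  }
  # sub-adults: height-driven, crown-measured
  for (tier in c("JU", "SA")) {
    n <- counts[[tier]]
    if (n == 0) next
    h <- if (tier == "JU") runif(n, 20, 140) else runif(n, 160, 450)
    cd <- config$crown$c0 * (h / 100)^config$crown$gamma * rlnorm1(n, config$sigma_height)
    cds <- split_crown(cd)
    ids <- sprintf("%s-%s-%03d", plot$plot_id, tier, seq_len(n))
    inds[[tier]] <- make_ind(ids, sp(n), h, cds$cd1, cds$cd2)
  }
  # adults: stem-measured, multi-stem possible
  n <- counts[["AA"]]
  if (n > 0) {
    ids <- sprintf("%s-AA-%03d", plot$plot_id, seq_len(n))
    dbh1 <- pmax(rlnorm(n, config$dbh$meanlog, config$dbh$sdlog), config$dbh$min)
    h <- exp(al$a + al$b * log(dbh1)) * rlnorm1(n, config$sigma_height)
    inds[["AA"]] <- make_ind(ids, sp(n), h, NA_real_, NA_real_)
    stem_rows <- list()
    for (i in seq_len(n)) {
      n_extra <- rpois(1, config$extra_stem_lambda)
      dbh <- c(dbh1[i], pmax(dbh1[i] * runif(n_extra, 0.4, 0.9), 4.5))
      basal <- dbh * pi / al$s
      circ130 <- dbh * pi
      m <- length(dbh)
      circ130[runif(m) < config$frac_missing_circ130] <- NA
      alt_circ <- rep(NA_real_, m); alt_h <- rep(NA_real_, m)
      has_alt <- runif(m) < config$frac_alt_reading
      alt_h[has_alt] <- runif(sum(has_alt), 10, 120)
      alt_circ[has_alt] <- basal[has_alt] * (130 - al$t * alt_h[has_alt]) / 130
      alt_only <- has_alt & runif(m) < config$frac_alt_only
      basal[alt_only] <- NA
      circ130[alt_only] <- NA
      stem_rows[[i]] <- tibble::tibble(
        individual_id = ids[i],
        stem_id = sprintf("%s-s%d", ids[i], seq_len(m)),
        basal_circ_cm = basal, circ130_cm = circ130,
        alt_circ_cm = alt_circ, alt_height_cm = alt_h,
        is_dead = FALSE,
        topkill_agent_1 = NA_character_, topkill_agent_2 = NA_character_
      )
    }
    stems <- stem_rows
  }
  individuals <- dplyr::bind_rows(inds)
  stems <- if (length(stems)) dplyr::bind_rows(stems) else {
    tibble::tibble(
      individual_id = character(), stem_id = character(),
      basal_circ_cm = numeric(), circ130_cm = numeric(),
      alt_circ_cm = numeric(), alt_height_cm = numeric(),
      is_dead = logical(), topkill_agent_1 = character(),
      topkill_agent_2 = character()
    )
  }
  list(individuals = individuals, stems = stems)
}

# Draw per-agent loss percentages for n individuals under one regime level
# and rescale so no total exceeds the 99% cap.
draw_loss_percents <- function(n, reg) {
  pct <- matrix(0, nrow = n, ncol = length(AGB_AGENTS),
                dimnames = list(NULL, AGB_AGENTS))
  for (a in AGB_AGENTS) {
    hit <- runif(n) < reg$attack[[a]]
    k <- sum(hit)
    if (k) {
      mu <- reg$mean_loss[[a]]
      pct[hit, a] <- 100 * rbeta(k, mu * reg$phi, (1 - mu) * reg$phi)
    }
  }
  tot <- rowSums(pct)
  over <- tot > 99
  # shrink marginally below the cap so floating-point summation can never
  # push the recorded total past 99
  if (any(over)) pct[over, ] <- pct[over, ] * (99 * (1 - 1e-12) / tot[over])
  pct
}

#' Apply a disturbance regime to a simulated plot population
#'
#' Draws per-agent loss percentages (Beta-distributed given an attack,
#' rescaled so totals never exceed the 99% cap), and subjects adults to
#' topkill with a density-dependent probability: the main stem is flagged
#' dead with one or two topkill agents; a single-stemmed adult re-emerges
#' as shrub-like root resprout (crown-measured regrowth, AG3-style) while
#' multi-stemmed adults keep their remaining living stems (AG2-style).
#' Heavily crown-damaged living trees have their observed height reduced
#' below the allometric expectation, as severe disturbance does in the
#' field.
#'
#' @param trees list(`individuals`, `stems`) from [simulate_individuals()].
#' @param reg one element of a regime list (see
#'   [default_disturbance_regime()]).
#' @param config an `agb_sim_config`. Uses the current RNG state.
#' @return The modified list(`individuals`, `stems`).
#' @export
apply_disturbances <- function(trees, reg, config = simulation_config()) {
  individuals <- trees$individuals
  stems <- trees$stems
  n <- nrow(individuals)
  if (n == 0) return(trees)
  pct <- draw_loss_percents(n, reg)
  individuals[, loss_columns()] <- as.data.frame(pct)
  is_adult <- grepl("-AA-", individuals$individual_id, fixed = TRUE)
  topkill <- is_adult & runif(n) < reg$topkill_prob
  resprout <- logical(n)
  for (i in which(topkill)) {
    id <- individuals$individual_id[i]
    idx <- which(stems$individual_id == id)
    main <- idx[1]
    agents <- if (runif(1) < reg$joint_topkill_prob) {
      c("elephant", "fire")[order(runif(2))]
    } else {
      sample(c("elephant", "fire"), 1,
             prob = c(reg$topkill_w_elephant, 1 - reg$topkill_w_elephant))
    }
    stems$is_dead[main] <- TRUE
    stems$topkill_agent_1[main] <- agents[1]
    stems$topkill_agent_2[main] <- if (length(agents) > 1) agents[2] else NA_character_
    # a dead stem is measured at the base; alternative-only records are
    # resolved to a basal reading via the taper relation
    if (is.na(stems$basal_circ_cm[main])) {
      stems$basal_circ_cm[main] <- 130 * stems$alt_circ_cm[main] /
        (130 - config$allometry$t * stems$alt_height_cm[main])
    }
    stems$circ130_cm[main] <- NA
    if (length(idx) == 1L) {
      # total topkill: shrub-like regrowth from the root system
      h_re <- runif(1, 50, 250)
      cd <- config$crown$c0 * (h_re / 100)^config$crown$gamma *
        rlnorm1(1, config$sigma_height)
      cds <- split_crown(cd)
      individuals$height_cm[i] <- h_re
      individuals$cd1_m[i] <- cds$cd1
      individuals$cd2_m[i] <- cds$cd2
      resprout[i] <- TRUE
    }
  }
  # severe crown damage shortens adult trees that retain living stems
  # below the allometric expectation (what the height correction undoes)
  tot <- rowSums(individuals[, loss_columns()])
  heavy <- is_adult & !resprout & tot >= 30
  individuals$height_cm[heavy] <-
    individuals$height_cm[heavy] * (1 - 0.4 * tot[heavy] / 100)
  list(individuals = individuals, stems = stems)
}

#' Simulate wood samples for a species pool
#'
#' Per species, 2-10 increment-borer cores / stem pieces (length 8 cm,
#' nominal diameter 5.15 mm with symmetric caliper scatter) whose dry mass
#' is consistent with the species' true SWD up to multiplicative noise.
#'
#' @param species tibble with `species` and true `swd`.
#' @param sigma_wood lognormal sd on dry mass.
#' @return Canonical wood-sample tibble.
#' @export
simulate_wood_samples <- function(species, sigma_wood = 0.03) {
  rows <- lapply(seq_len(nrow(species)), function(i) {
    k <- sample(2:10, 1)
    d_bar <- 0.515
    offsets <- c(-0.02, -0.01, 0, 0.01, 0.02) # symmetric: mean is exact
    len <- 8
    vol <- pi * (d_bar / 2)^2 * len
    sp_i <- species$species[i]
    swd_i <- species$swd[i]
    tibble::tibble(
      species = sp_i,
      sample_id = sprintf("%s-w%02d", gsub("\\s+", "_", sp_i), 1:k),
      length_cm = len,
      d1_cm = d_bar * (1 + offsets[1]), d2_cm = d_bar * (1 + offsets[2]),
      d3_cm = d_bar * (1 + offsets[3]), d4_cm = d_bar * (1 + offsets[4]),
      d5_cm = d_bar * (1 + offsets[5]),
      dry_mass_g = swd_i * vol * rlnorm1(k, sigma_wood)
    )
  })
  dplyr::bind_rows(rows)
}

#' Simulate a complete study
#'
#' Runs the full generator: design, per-plot populations (each plot on a
#' deterministic sub-stream of the seed), disturbances, growth-class
#' assignment, gulliver thinning to the damaged-adult subplot, wood
#' samples, and the ground-truth biomass table. Ground truth is computed
#' by evaluating the estimation workflows on the noise-free observables
#' with the generating ("true") calibration coefficients and true SWD, so
#' end-to-end tests verify protocol logic rather than allometric accuracy.
#' Measurement noise is then applied to the emitted observables only.
#'
#' @param config an `agb_sim_config`.
#' @param seed integer seed fixing the entire output stream.
#' @return An object of class `agb_simulation`: list with `individuals`,
#'   `stems`, `plots` (observables, measurement noise applied),
#'   `wood_samples`, `truth` (per-individual ground-truth biomass),
#'   `true_calibration`, `swd_true`, and `noiseless`
#'   (list of noise-free individuals/stems tables).
#' @export
simulate_inventory <- function(config = simulation_config(), seed = 1) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(seed)
  plots <- generate_design(config)
  inds <- list(); stems <- list()
  for (i in seq_len(nrow(plots))) {
    set.seed((seed + 7919 * i) %% .Machine$integer.max)
    plot <- plots[i, ]
    trees <- simulate_individuals(plot, config)
    trees <- apply_disturbances(trees, config$regime[[plot$density_level]], config)
    inds[[i]] <- trees$individuals
    stems[[i]] <- trees$stems
  }
  individuals <- dplyr::bind_rows(inds)
  stems <- dplyr::bind_rows(stems)
  true_cal <- new_calibration(
    height = list(a = config$allometry$a, b = config$allometry$b,
                  r2 = NA_real_, n = NA_integer_),
    dbh = list(s = config$allometry$s, r2 = NA_real_, n = NA_integer_),
    taper = list(t = config$allometry$t, r2 = NA_real_, n = NA_integer_),
    provenance = "generator"
  )
  individuals$growth_class <- classify_growth_class(individuals, stems,
                                                    calibration = true_cal)
  # gulliver adults were recorded only on the damaged-adult subplot
  set.seed((seed + 104729) %% .Machine$integer.max)
  is_ag <- individuals$growth_class %in% c("AG1", "AG2a", "AG2b", "AG3")
  p_keep <- plots$area_AG[match(individuals$plot_id, plots$plot_id)] /
    plots$plot_area_m2[match(individuals$plot_id, plots$plot_id)]
  keep <- !is_ag | runif(nrow(individuals)) < p_keep
  individuals <- individuals[keep, ]
  stems <- stems[stems$individual_id %in% individuals$individual_id, ]

  swd_true <- tibble::tibble(species = config$species$species,
                             swd_g_cm3 = config$species$swd,
                             n_samples = NA_integer_)
  truth <- estimate_biomass(individuals, stems, swd_true, true_cal)
  wood <- simulate_wood_samples(config$species, config$sigma_wood)

  noiseless <- list(individuals = individuals, stems = stems)
  obs_ind <- individuals
  obs_stems <- stems
  if (config$sigma_measure > 0) {
    s <- config$sigma_measure
    obs_ind$height_cm <- obs_ind$height_cm * rlnorm1(nrow(obs_ind), s)
    obs_ind$cd1_m <- obs_ind$cd1_m * rlnorm1(nrow(obs_ind), s)
    obs_ind$cd2_m <- obs_ind$cd2_m * rlnorm1(nrow(obs_ind), s)
    for (col in c("basal_circ_cm", "circ130_cm", "alt_circ_cm")) {
      obs_stems[[col]] <- obs_stems[[col]] * rlnorm1(nrow(obs_stems), s)
    }
  }
  structure(list(
    individuals = obs_ind, stems = obs_stems, plots = plots,
    wood_samples = wood, truth = truth, true_calibration = true_cal,
    swd_true = swd_true, noiseless = noiseless, seed = seed
  ), class = "agb_simulation")
}

#' @export
print.agb_simulation <- function(x, ...) {
  cat(sprintf(
    "agb_simulation (seed %s): %d individuals, %d stems, %d plots, %d wood samples\n",
    format(x$seed), nrow(x$individuals), nrow(x$stems), nrow(x$plots),
    nrow(x$wood_samples)))
  invisible(x)
}

#' Write the observable field tables of a simulation
#'
#' Emits the canonical observable CSVs (individuals, stems, plots, wood
#' samples) into a directory, plus `ground_truth.csv` holding the
#' per-individual true biomass partitions. The observables never contain
#' ground-truth AGB columns, so estimation runs on them are blinded.
#'
#' @param sim an `agb_simulation`.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
emit_field_tables <- function(sim, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  write_inventory(sim, path)
  readr::write_csv(sim$wood_samples, file.path(path, "wood_samples.csv"), na = "")
  readr::write_csv(sim$truth, file.path(path, "ground_truth.csv"), na = "")
  invisible(path)
}
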