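#' Fresh volume of a wood sample
#'
#' Volume of a wood core or cylindrical stem piece from its length and five
#' caliper diameter readings taken along the sample. The five readings are
#' averaged first and the sample treated as one cylinder:
#' `V = pi * (mean(d)/2)^2 * L`.
#'
#' @param length_cm sample length in cm.
#' @param diameters_cm numeric vector of exactly five diameter readings, cm.
#' @return Fresh volume in cm^3.
#' @export
#' @examples
#' sample_volume(8, rep(0.515, 5)) # a typical increment-borer core
sample_volume <- function(length_cm, diameters_cm) {
  if (length(diameters_cm) != 5L) {
    stop("exactly five diameter readings are required", call. = FALSE)
  }
  check_positive(length_cm, "length_cm")
  check_positive(diameters_cm, "diameters_cm")
  d_bar <- mean(diameters_cm)
  pi * (d_bar / 2)^2 * length_cm
}

#' Specific wood density of a single sample
#'
#' Oven-dry mass per fresh volume (wood specific gravity), g cm^-3.
#'
#' @inheritParams sample_volume
#' @param dry_mass_g oven-dry mass in g.
#' @return SWD in g cm^-3.
#' @export
compute_swd <- function(length_cm, diameters_cm, dry_mass_g) {
  check_positive(dry_mass_g, "dry_mass_g")
  dry_mass_g / sample_volume(length_cm, diameters_cm)
}

#' Species-mean specific wood density table
#'
#' Computes per-sample SWD for a table of wood samples and averages it per
#' species. Values outside (0, 1.5) g cm^-3 are rejected as data-entry
#' errors (the densest known woods are near 1.4).
#'
#' @param samples a data frame with columns `species`, `sample_id`,
#'   `length_cm`, `d1_cm` .. `d5_cm`, `dry_mass_g`.
#' @return A tibble with columns `species`, `swd_g_cm3` (species mean) and
#'   `n_samples`.
#' @export
species_mean_table <- function(samples) {
  required <- c("species", "length_cm", paste0("d", 1:5, "_cm"), "dry_mass_g")
  missing <- setdiff(required, names(samples))
  if (length(missing)) {
    stop("wood-sample table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(samples) == 0L) stop("at least one wood sample is required", call. = FALSE)
  swd <- vapply(seq_len(nrow(samples)), function(i) {
    compute_swd(
      samples$length_cm[i],
      as.numeric(samples[i, paste0("d", 1:5, "_cm")]),
      samples$dry_mass_g[i]
    )
  }, numeric(1))
  if (any(swd >= 1.5)) {
    stop(sprintf("implausible SWD >= 1.5 g cm^-3 for sample(s): %s",
                 paste(samples$sample_id[swd >= 1.5], collapse = ", ")),
         call. = FALSE)
  }
  tibble::tibble(species = samples$species, swd = swd) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      swd_g_cm3 = mean(.data$swd),
      n_samples = dplyr::n(),
      .groups = "drop"
    )
}

#' Look up specific wood density with a fallback chain
#'
#' Resolves SWD for one or more species labels against a species-mean
#' table: the species' own mean if present, otherwise the mean over table
#' entries of the same genus (first whitespace-separated token of the
#' binomial), otherwise a global default. The provenance of each value is
#' reported so gap-filled values can be traced.
#'
#' @param species character vector of species labels.
#' @param table a species-mean table as returned by [species_mean_table()].
#' @param default_swd optional global fallback, g cm^-3.
#' @return A tibble with columns `species`, `swd_g_cm3`, `provenance`
#'   (one of `"species"`, `"genus"`, `"default"`), one row per input.
#' @export
lookup_swd <- function(species, table, default_swd = NULL) {
  if (nrow(table) == 0L && is.null(default_swd)) {
    stop("empty SWD table and no default_swd set", call. = FALSE)
  }
  genus_of <- function(x) vapply(strsplit(x, "\\s+"), `[`, character(1), 1L)
  table_genus <- genus_of(table$species)
  res <- lapply(species, function(sp) {
    hit <- match(sp, table$species)
    if (!is.na(hit)) {
      return(list(swd = table$swd_g_cm3[hit], prov = "species"))
    }
    gmatch <- table_genus == genus_of(sp)
    if (any(gmatch)) {
      return(list(swd = mean(table$swd_g_cm3[gmatch]), prov = "genus"))
    }
    if (!is.null(default_swd)) {
      return(list(swd = default_swd, prov = "default"))
    }
    stop(sprintf("no SWD available for species '%s' (no genus match, no default)", sp),
         call. = FALSE)
  })
  tibble::tibble(
    species = species,
    swd_g_cm3 = vapply(res, function(r) r$swd, numeric(1)),
    provenance = vapply(res, function(r) r$prov, character(1))
  )
}

#' Read a wood-sample table from CSV
#'
#' @param path CSV file with columns `species, sample_id, length_cm,
#'   d1_cm..d5_cm, dry_mass_g`.
#' @return A tibble of wood samples.
#' @export
read_wood_samples <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    species = readr::col_character(),
    sample_id = readr::col_character(),
    .default = readr::col_double()
  ))
}

#' Write a species-mean SWD table to CSV
#'
#' @param table a table from [species_mean_table()].
#' @param path output CSV path.
#' @export
write_swd_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}
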