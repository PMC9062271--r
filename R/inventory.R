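#' Read a tree inventory
#'
#' Reads the three canonical inventory tables (individuals, stems, plots)
#' and returns them as an `agb_inventory` list. Two dialects are supported:
#'
#' * `"canonical_csv"` (normative): `path` is a directory containing
#'   `individuals.csv`, `stems.csv` and `plots.csv` in the canonical
#'   schema (UTF-8, comma separator, `"."` decimal; heights and
#'   circumferences in cm, crown diameters in m, areas in m^2).
#' * `"mendeley_xlsx"`: best-effort adapter for a deposited multi-sheet
#'   workbook; `path` is the `.xlsx` file and `mapping` must supply sheet
#'   names and a canonical-to-source column mapping per table (the sheet's
#'   column names are not standardized). Requires the readxl package.
#'
#' Loss percentages recorded under agent labels outside the fixed
#' vocabulary (elephant, fire, browsers, woodcutting, abiotic, other) are
#' accumulated into `other` with a warning, never dropped.
#'
#' @param path directory (canonical CSV) or workbook file (xlsx).
#' @param dialect `"canonical_csv"` or `"mendeley_xlsx"`.
#' @param mapping for the xlsx dialect: a list with elements `individuals`,
#'   `stems`, `plots`, each a list(`sheet =`, `columns =` named character
#'   vector mapping canonical names to source column names).
#' @return An object of class `agb_inventory`: list with tibbles
#'   `individuals`, `stems`, `plots`.
#' @seealso [write_inventory()], [validate_individuals()]
#' @export
read_inventory <- function(path, dialect = c("canonical_csv", "mendeley_xlsx"),
                           mapping = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "canonical_csv") {
    files <- file.path(path, c("individuals.csv", "stems.csv", "plots.csv"))
    missing <- files[!file.exists(files)]
    if (length(missing)) {
      stop("inventory files not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    individuals <- readr::read_csv(files[1], col_types = individual_col_types())
    stems <- readr::read_csv(files[2], col_types = stem_col_types())
    plots <- readr::read_csv(files[3], col_types = plot_col_types())
  } else {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("the mendeley_xlsx dialect requires the readxl package", call. = FALSE)
    }
    if (is.null(mapping)) {
      stop("the mendeley_xlsx dialect requires an explicit `mapping`", call. = FALSE)
    }
    tabs <- lapply(mapping, function(m) {
      readxl::read_excel(path, sheet = m$sheet)
    })
    mapped <- normalize_mapped_tables(tabs, mapping)
    individuals <- mapped$individuals
    stems <- mapped$stems
    plots <- mapped$plots
  }
  check_inventory_columns(individuals, stems, plots)
  individuals <- normalize_individuals(individuals)
  new_inventory(individuals, stems, plots)
}

#' Rename and coerce externally mapped tables to the canonical schema
#'
#' The workhorse behind the xlsx adapter, exposed so a column mapping can
#' be exercised on plain data frames. Each mapping entry renames source
#' columns to canonical names; canonical columns absent from the mapping
#' are filled with NA.
#'
#' @param tabs list with data frames `individuals`, `stems`, `plots`.
#' @param mapping as in [read_inventory()].
#' @return List of canonical tibbles.
#' @export
normalize_mapped_tables <- function(tabs, mapping) {
  canon <- list(
    individuals = individual_columns(),
    stems = stem_columns(),
    plots = plot_columns()
  )
  out <- lapply(names(canon), function(tab) {
    m <- mapping[[tab]]$columns
    src <- tabs[[tab]]
    missing_src <- setdiff(unname(m), names(src))
    if (length(missing_src)) {
      stop(sprintf("mapping for '%s' names absent source columns: %s",
                   tab, paste(missing_src, collapse = ", ")), call. = FALSE)
    }
    res <- tibble::as_tibble(src)[, unname(m), drop = FALSE]
    names(res) <- names(m)
    for (col in setdiff(canon[[tab]], names(res))) res[[col]] <- NA
    res[, canon[[tab]]]
  })
  names(out) <- names(canon)
  out
}

#' Write an inventory to canonical CSV
#'
#' Writes `individuals.csv`, `stems.csv` and `plots.csv` with a
#' deterministic column order; numeric values are serialized with full
#' round-trip precision so that [read_inventory()] recovers them exactly.
#'
#' @param inventory an `agb_inventory` (or list with the three tables).
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_inventory <- function(inventory, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  readr::write_csv(inventory$individuals[, individual_columns()],
                   file.path(path, "individuals.csv"), na = "")
  readr::write_csv(inventory$stems[, stem_columns()],
                   file.path(path, "stems.csv"), na = "")
  readr::write_csv(inventory$plots[, plot_columns()],
                   file.path(path, "plots.csv"), na = "")
  invisible(path)
}

new_inventory <- function(individuals, stems, plots) {
  structure(list(individuals = individuals, stems = stems, plots = plots),
            class = "agb_inventory")
}

#' @export
print.agb_inventory <- function(x, ...) {
  cat(sprintf("agb_inventory: %d individuals, %d stems, %d plots\n",
              nrow(x$individuals), nrow(x$stems), nrow(x$plots)))
  invisible(x)
}

individual_columns <- function() {
  c("individual_id", "plot_id", "species", "growth_class", "height_cm",
    "cd1_m", "cd2_m", "edge_fraction", loss_columns(), "comment")
}
stem_columns <- function() {
  c("individual_id", "stem_id", "basal_circ_cm", "circ130_cm",
    "alt_circ_cm", "alt_height_cm", "is_dead", "topkill_agent_1",
    "topkill_agent_2")
}
plot_columns <- function() {
  c("plot_id", "vegetation", "density_level", "lat", "lon", "plot_area_m2",
    "area_JU", "area_SA", "area_AA", "area_AG")
}

individual_col_types <- function() {
  readr::cols(
    individual_id = readr::col_character(),
    plot_id = readr::col_character(),
    species = readr::col_character(),
    growth_class = readr::col_character(),
    comment = readr::col_character(),
    .default = readr::col_double()
  )
}
stem_col_types <- function() {
  readr::cols(
    individual_id = readr::col_character(),
    stem_id = readr::col_character(),
    is_dead = readr::col_logical(),
    topkill_agent_1 = readr::col_character(),
    topkill_agent_2 = readr::col_character(),
    .default = readr::col_double()
  )
}
plot_col_types <- function() {
  readr::cols(
    plot_id = readr::col_character(),
    vegetation = readr::col_character(),
    density_level = readr::col_character(),
    .default = readr::col_double()
  )
}

check_inventory_columns <- function(individuals, stems, plots) {
  chk <- function(df, cols, what) {
    missing <- setdiff(cols, names(df))
    if (length(missing)) {
      stop(sprintf("%s table lacks mandatory columns: %s",
                   what, paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  chk(individuals, individual_columns(), "individuals")
  chk(stems, stem_columns(), "stems")
  chk(plots, plot_columns(), "plots")
}

normalize_individuals <- function(individuals) {
  for (col in loss_columns()) {
    individuals[[col]][is.na(individuals[[col]])] <- 0
  }
  individuals$edge_fraction[is.na(individuals$edge_fraction)] <- 1
  individuals
}

total_loss_percent <- function(individuals) {
  rowSums(as.matrix(individuals[, loss_columns()]), na.rm = TRUE)
}

#' Validate inventory records
#'
#' Checks every individual (and its stems) against the protocol's
#' structural constraints and returns the violations found, rather than
#' raising. Checked rules include: positive height and crown diameters;
#' per-agent losses within \[0, 99\] and summing to at most 99 (the cap
#' expressing that even total topkill leaves a live root system);
#' `edge_fraction` in (0, 1\]; positive circumferences; the pairing of
#' alternative circumference and its height; the bound `hx < 130 / t`
#' keeping the taper extrapolation positive; and that every dead stem
#' carries at least one (and at most two) topkill agents.
#'
#' @param individuals individuals table.
#' @param stems stems table.
#' @param taper_t taper coefficient used for the `hx` bound (default the
#'   reference value 0.2032).
#' @return A tibble of violations with columns `individual_id`, `field`,
#'   `message`; zero rows when everything holds.
#' @export
validate_individuals <- function(individuals, stems, taper_t = 0.2032) {
  v <- list()
  add <- function(id, field, message) {
    v[[length(v) + 1L]] <<- tibble::tibble(
      individual_id = id, field = field, message = message
    )
  }
  for (i in seq_len(nrow(individuals))) {
    ind <- individuals[i, ]
    id <- ind$individual_id
    if (is.na(ind$height_cm) || ind$height_cm <= 0) {
      add(id, "height_cm", "height must be present and > 0")
    }
    for (cd in c("cd1_m", "cd2_m")) {
      if (!is.na(ind[[cd]]) && ind[[cd]] <= 0) {
        add(id, cd, "crown diameter must be > 0 when present")
      }
    }
    if (is.na(ind$edge_fraction) || ind$edge_fraction <= 0 || ind$edge_fraction > 1) {
      add(id, "edge_fraction", "edge_fraction must be in (0, 1]")
    }
    pct <- unlist(ind[, loss_columns()])
    pct[is.na(pct)] <- 0
    bad <- pct < 0 | pct > 99
    if (any(bad)) {
      add(id, paste(loss_columns()[bad], collapse = ","),
          "per-agent loss must be in [0, 99]")
    }
    if (sum(pct) > 99) {
      add(id, "loss_total",
          sprintf("sum of losses %g > 99", sum(pct)))
    }
  }
  for (j in seq_len(nrow(stems))) {
    st <- stems[j, ]
    id <- st$individual_id
    for (col in c("basal_circ_cm", "circ130_cm", "alt_circ_cm")) {
      if (!is.na(st[[col]]) && st[[col]] <= 0) {
        add(id, col, "circumference must be > 0 when present")
      }
    }
    if (xor(is.na(st$alt_circ_cm), is.na(st$alt_height_cm))) {
      add(id, "alt_circ_cm",
          "alternative circumference and its height must be recorded together")
    }
    if (!is.na(st$alt_height_cm)) {
      if (st$alt_height_cm < 0 || st$alt_height_cm >= 130 / taper_t) {
        add(id, "alt_height_cm",
            sprintf("hx must satisfy 0 <= hx < %g", 130 / taper_t))
      }
    }
    if (isTRUE(st$is_dead) && is.na(st$topkill_agent_1)) {
      add(id, "topkill_agent_1", "dead stems must carry at least one topkill agent")
    }
    if (!is.na(st$topkill_agent_2) && is.na(st$topkill_agent_1)) {
      add(id, "topkill_agent_2", "second topkill agent without a first")
    }
    if (is.na(st$basal_circ_cm) && is.na(st$circ130_cm) && is.na(st$alt_circ_cm)) {
      add(id, "stem", "stem has no usable circumference measure")
    }
  }
  if (length(v)) dplyr::bind_rows(v) else {
    tibble::tibble(individual_id = character(), field = character(),
                   message = character())
  }
}

#' Classify individuals into growth classes
#'
#' Assigns each woody individual to one of the protocol's growth classes
#' from its stem records, damage assessment and height:
#'
#' * adult-sized stem: basal circumference strictly greater than
#'   `adult_circ_threshold` (default 15 cm; a stem of exactly 15 cm is not
#'   adult-sized). Where only an alternative reading exists the basal
#'   circumference is first extrapolated via the taper model.
#' * `AA` — at least one living adult-sized stem, no dead adult-sized
#'   stems, total loss below `gulliver_loss_threshold` (default 30%).
#' * `AG1` — living adult stems only, total loss at or above the threshold.
#' * `AG2a` / `AG2b` — both living and dead adult stems, with the
#'   living-crown loss below / at-or-above the threshold.
#' * `AG3` — dead adult stem(s), no living adult stems: a topkilled tree
#'   resprouting as a shrub; crown diameters of the living regrowth are
#'   required.
#' * `JU` / `SA` — no adult-sized stems, height below / at-or-above
#'   `juvenile_height_threshold` (default 150 cm, site-specific); their
#'   gulliver counterparts `GJ` / `GS` when the total loss is at or above
#'   the threshold.
#'
#' @param individuals individuals table (the `growth_class` column, if
#'   present, is ignored).
#' @param stems stems table.
#' @param adult_circ_threshold basal-circumference threshold for
#'   adult-sized stems, cm.
#' @param gulliver_loss_threshold total-loss percentage at which an
#'   individual counts as heavily damaged (gulliver).
#' @param juvenile_height_threshold juvenile/sapling height boundary, cm.
#'   The default (150 cm) is a pragmatic, site-specific choice and should
#'   be reviewed for other communities.
#' @param calibration calibration used only to extrapolate a basal
#'   circumference from alternative readings.
#' @return Character vector of growth classes, one per individual.
#' @export
classify_growth_class <- function(individuals, stems,
                                  adult_circ_threshold = 15,
                                  gulliver_loss_threshold = 30,
                                  juvenile_height_threshold = 150,
                                  calibration = default_calibration()) {
  stopifnot(adult_circ_threshold > 0, gulliver_loss_threshold > 0,
            juvenile_height_threshold > 0)
  total_pct <- total_loss_percent(individuals)
  stems_by_ind <- split(stems, stems$individual_id)
  vapply(seq_len(nrow(individuals)), function(i) {
    ind <- individuals[i, ]
    if (is.na(ind$height_cm)) {
      stop(sprintf("individual '%s': height is missing, cannot classify",
                   ind$individual_id), call. = FALSE)
    }
    st <- stems_by_ind[[ind$individual_id]]
    basal <- effective_basal(st, calibration)
    adult <- !is.na(basal) & basal > adult_circ_threshold
    dead <- if (is.null(st)) logical(0) else !is.na(st$is_dead) & st$is_dead
    living_adult <- any(adult & !dead)
    dead_adult <- any(adult & dead)
    heavy <- total_pct[i] >= gulliver_loss_threshold
    if (living_adult && !dead_adult) {
      if (heavy) "AG1" else "AA"
    } else if (living_adult && dead_adult) {
      if (heavy) "AG2b" else "AG2a"
    } else if (dead_adult) {
      missing <- c("cd1_m", "cd2_m")[c(is.na(ind$cd1_m), is.na(ind$cd2_m))]
      if (length(missing)) {
        stop(sprintf(
          "individual '%s': unclassifiable - dead adult stem but no living-tissue proxies (missing: %s)",
          ind$individual_id, paste(missing, collapse = ", ")), call. = FALSE)
      }
      "AG3"
    } else {
      tier <- if (ind$height_cm >= juvenile_height_threshold) "S" else "J"
      if (heavy) paste0("G", tier) else if (tier == "S") "SA" else "JU"
    }
  }, character(1))
}

# Basal circumference per stem, extrapolating from the alternative reading
# where the basal one is absent; NA when no reading allows it.
effective_basal <- function(st, calibration) {
  if (is.null(st) || nrow(st) == 0L) return(numeric(0))
  basal <- st$basal_circ_cm
  use_alt <- is.na(basal) & !is.na(st$alt_circ_cm) & !is.na(st$alt_height_cm)
  if (any(use_alt)) {
    basal[use_alt] <- basal_from_alternative(
      st$alt_circ_cm[use_alt], st$alt_height_cm[use_alt], calibration
    )
  }
  basal
}

#' Classify an inventory in place
#'
#' Convenience wrapper around [classify_growth_class()] that returns the
#' individuals table with its `growth_class` column (re)filled.
#'
#' @inheritParams classify_growth_class
#' @return The individuals table with `growth_class` set.
#' @export
classify_inventory <- function(individuals, stems, ...) {
  individuals$growth_class <- classify_growth_class(individuals, stems, ...)
  individuals
}
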