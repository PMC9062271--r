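#' Select the healthy reference subset for calibration
#'
#' The three proxy-reconstruction regressions are fitted on adult
#' non-gulliver trees (class AA): individuals with living adult-sized
#' stems, no dead stems, and total loss below the gulliver threshold.
#' Returns one row per living stem with whichever proxies that stem
#' carries; each fit later drops rows lacking its own proxies.
#'
#' @param individuals classified individuals table (needs `growth_class`).
#' @param stems stems table.
#' @param max_loss total-loss percentage above which an individual is
#'   excluded from the reference subset (default 30, the gulliver
#'   threshold).
#' @return A tibble with columns `individual_id`, `stem_id`, `dbh_cm`
#'   (from the measured breast-height circumference), `basal_circ_cm`,
#'   `height_cm`, `alt_circ_cm`, `alt_height_cm`, and `is_main` flagging
#'   each individual's dominant (largest-diameter) stem. A tree's height
#'   is driven by its dominant stem, so the height-DBH fit uses only
#'   `is_main` rows, while the DBH and taper fits use every stem.
#' @export
select_reference_subset <- function(individuals, stems, max_loss = 30) {
  if (!"growth_class" %in% names(individuals) ||
      any(is.na(individuals$growth_class))) {
    stop("individuals must be classified before calibration; see classify_inventory()",
         call. = FALSE)
  }
  total_pct <- total_loss_percent(individuals)
  keep <- individuals$growth_class == "AA" & total_pct < max_loss
  ids <- individuals$individual_id[keep]
  has_dead <- stems |>
    dplyr::filter(!is.na(.data$is_dead) & .data$is_dead) |>
    dplyr::pull("individual_id")
  ids <- setdiff(ids, has_dead)
  ref <- stems |>
    dplyr::filter(.data$individual_id %in% ids,
                  is.na(.data$is_dead) | !.data$is_dead) |>
    dplyr::left_join(
      individuals[, c("individual_id", "height_cm")], by = "individual_id"
    ) |>
    dplyr::transmute(
      individual_id = .data$individual_id,
      stem_id = .data$stem_id,
      dbh_cm = .data$circ130_cm / pi,
      basal_circ_cm = .data$basal_circ_cm,
      height_cm = .data$height_cm,
      alt_circ_cm = .data$alt_circ_cm,
      alt_height_cm = .data$alt_height_cm
    )
  if (nrow(ref) < 3L) {
    stop(sprintf(
      "insufficient reference data: %d usable healthy adult stems (>= 3 required)",
      nrow(ref)), call. = FALSE)
  }
  # dominant stem per individual, by best-available diameter proxy
  # (reference coefficients suffice for ranking stems within a tree)
  ref_cal <- default_calibration()
  proxy <- ref$dbh_cm
  use_basal <- is.na(proxy) & !is.na(ref$basal_circ_cm)
  proxy[use_basal] <- dbh_from_basal(ref$basal_circ_cm[use_basal], ref_cal)
  use_alt <- is.na(proxy) & !is.na(ref$alt_circ_cm)
  proxy[use_alt] <- dbh_from_basal(
    basal_from_alternative(ref$alt_circ_cm[use_alt],
                           ref$alt_height_cm[use_alt], ref_cal), ref_cal)
  ref |>
    dplyr::mutate(.proxy = dplyr::coalesce(proxy, -Inf)) |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::mutate(is_main = .data$.proxy == max(.data$.proxy)) |>
    dplyr::ungroup() |>
    dplyr::select(-".proxy")
}

#' Fit the height-from-DBH power law
#'
#' Ordinary least squares of `ln h` on `ln DBH`, giving
#' `h_est = exp(a + b ln DBH)`; R^2 is reported on the log scale.
#'
#' @param dbh_cm DBH values, cm.
#' @param h_cm heights, cm.
#' @return List with `a`, `b`, `r2`, `n`.
#' @export
fit_height_model <- function(dbh_cm, h_cm) {
  ok <- stats::complete.cases(dbh_cm, h_cm)
  dbh_cm <- dbh_cm[ok]; h_cm <- h_cm[ok]
  if (length(dbh_cm) < 3L) {
    stop("height fit requires >= 3 (DBH, height) pairs", call. = FALSE)
  }
  check_positive(dbh_cm, "dbh_cm"); check_positive(h_cm, "h_cm")
  if (length(unique(dbh_cm)) < 2L) {
    stop("height fit is singular: all DBH values identical", call. = FALSE)
  }
  fit <- lm(log(h_cm) ~ log(dbh_cm))
  y <- log(h_cm)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else 1
  list(a = unname(coef(fit)[1]), b = unname(coef(fit)[2]),
       r2 = r2, n = length(dbh_cm))
}

#' Fit the DBH-from-basal-diameter proportionality
#'
#' Least squares through the origin of DBH on basal diameter
#' (`basal_circ / pi`), giving `DBH_est = s * basal_circ / pi`; R^2 is the
#' through-origin (uncentered) coefficient of determination.
#'
#' @param basal_circ_cm basal circumferences, cm.
#' @param dbh_cm measured DBH values, cm.
#' @param intercept fit an intercept as well (non-standard; default FALSE,
#'   matching the pure proportionality used in the protocol).
#' @return List with `s`, `r2`, `n` (and `intercept` when requested).
#' @export
fit_dbh_model <- function(basal_circ_cm, dbh_cm, intercept = FALSE) {
  ok <- stats::complete.cases(basal_circ_cm, dbh_cm)
  basal_circ_cm <- basal_circ_cm[ok]; dbh_cm <- dbh_cm[ok]
  if (length(dbh_cm) < 3L) {
    stop("DBH fit requires >= 3 (basal circumference, DBH) pairs", call. = FALSE)
  }
  check_positive(basal_circ_cm, "basal_circ_cm"); check_positive(dbh_cm, "dbh_cm")
  basal_diam <- basal_circ_cm / pi
  if (intercept) {
    fit <- lm(dbh_cm ~ basal_diam)
    tss <- sum((dbh_cm - mean(dbh_cm))^2)
    r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else 1
    list(s = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r2 = r2, n = length(dbh_cm))
  } else {
    fit <- lm(dbh_cm ~ 0 + basal_diam)
    # uncentered R^2, the usual definition for a through-origin fit
    r2 <- 1 - sum(stats::resid(fit)^2) / sum(dbh_cm^2)
    list(s = unname(coef(fit)[1]), r2 = r2, n = length(dbh_cm))
  }
}

#' Fit the stem-taper coefficient
#'
#' Estimates `t` in `basal_circ = 130 * circ(hx) / (130 - t * hx)` by
#' linearizing to `y = 130 - 130 * circ(hx) / basal_circ` and regressing
#' `y` on `hx` through the origin. Observations whose `hx` would make the
#' denominator non-positive at the fitted `t` are reported with a warning.
#'
#' @param circ_hx_cm circumference at the alternative height, cm.
#' @param hx_cm heights of the alternative readings, cm.
#' @param basal_circ_cm measured basal circumferences, cm.
#' @return List with `t`, `r2`, `n`.
#' @export
fit_taper_model <- function(circ_hx_cm, hx_cm, basal_circ_cm) {
  ok <- stats::complete.cases(circ_hx_cm, hx_cm, basal_circ_cm)
  circ_hx_cm <- circ_hx_cm[ok]; hx_cm <- hx_cm[ok]; basal_circ_cm <- basal_circ_cm[ok]
  if (length(hx_cm) < 3L) {
    stop("taper fit requires >= 3 (circ(hx), hx, basal circumference) tuples",
         call. = FALSE)
  }
  check_positive(circ_hx_cm, "circ_hx_cm"); check_positive(basal_circ_cm, "basal_circ_cm")
  if (any(hx_cm < 0)) stop("hx_cm must be >= 0", call. = FALSE)
  if (all(hx_cm == 0)) {
    stop("taper fit is singular: all readings at the base carry no taper information",
         call. = FALSE)
  }
  y <- 130 - 130 * circ_hx_cm / basal_circ_cm
  t_hat <- sum(hx_cm * y) / sum(hx_cm^2)
  r2 <- if (sum(y^2) > 0) 1 - sum((y - t_hat * hx_cm)^2) / sum(y^2) else 1
  bad <- 130 - t_hat * hx_cm <= 0
  if (any(bad)) {
    warning(sprintf(
      "%d taper observation(s) have hx beyond the fitted model's validity (hx = %s)",
      sum(bad), paste(format(hx_cm[bad]), collapse = ", ")), call. = FALSE)
  }
  list(t = t_hat, r2 = r2, n = length(hx_cm))
}

#' Fit all proxy-reconstruction regressions from an inventory
#'
#' Selects the healthy adult reference subset and fits the height, DBH and
#' taper models, returning a local `agb_calibration`. A fit for which the
#' subset lacks the necessary proxies raises an insufficient-data error
#' naming the fit, unless `partial = TRUE`, in which case the reference
#' coefficient is retained for that component and the calibration is
#' flagged `"mixed"`.
#'
#' @inheritParams select_reference_subset
#' @param partial fall back to reference coefficients for unfittable
#'   components instead of erroring.
#' @return An `agb_calibration` with provenance `"local"` (or `"mixed"`).
#' @export
calibrate_models <- function(individuals, stems, max_loss = 30, partial = FALSE) {
  ref <- select_reference_subset(individuals, stems, max_loss = max_loss)
  fallback <- default_calibration()
  fit_or <- function(expr, name, default) {
    tryCatch(expr, error = function(e) {
      if (partial) default
      else stop(sprintf("cannot fit %s model: %s", name, conditionMessage(e)),
                call. = FALSE)
    })
  }
  main <- ref[ref$is_main, ]
  height <- fit_or(fit_height_model(main$dbh_cm, main$height_cm),
                   "height", fallback$height)
  dbh <- fit_or(fit_dbh_model(ref$basal_circ_cm, ref$dbh_cm),
                "dbh", fallback$dbh)
  taper <- fit_or(
    fit_taper_model(ref$alt_circ_cm, ref$alt_height_cm, ref$basal_circ_cm),
    "taper", fallback$taper)
  prov <- if (is.na(height$n) || is.na(dbh$n) || is.na(taper$n)) "mixed" else "local"
  new_calibration(height, dbh, taper, provenance = prov)
}

#' Write / read a calibration as JSON
#'
#' @param calibration an `agb_calibration`.
#' @param path JSON file path.
#' @return `path` (write) or an `agb_calibration` (read).
#' @export
write_calibration <- function(calibration, path) {
  check_calibration(calibration)
  jsonlite::write_json(unclass(calibration), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_calibration(as.list(x$height), as.list(x$dbh), as.list(x$taper),
                  provenance = x$provenance)
}
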