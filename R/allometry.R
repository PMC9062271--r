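#' Canopy-based aboveground biomass model
#'
#' Generic canopy-based allometric model for shrubs and shrub-like plant
#' parts (Conti et al. 2019), estimating aboveground biomass from mean
#' crown diameter and plant height:
#' \deqn{AGB = \exp(-0.370 + 1.903 \ln CD + 0.652 \ln h) \times 1.403}
#' The trailing constant is the model's published correction factor for the
#' log-scale back-transformation and is applied exactly as printed.
#'
#' Because the crown of living tissue is what is measured, the output
#' already reflects the damaged (post-disturbance) state of the plant;
#' pre-disturbance biomass is obtained separately by reverse damage
#' assessment (see [reverse_damage()]).
#'
#' @param cd_m mean crown diameter in m (arithmetic mean of the widest
#'   living-canopy diameter and the measure orthogonal to it).
#' @param h_cm plant height in cm.
#' @return Aboveground biomass in kg. Vectorized over its arguments.
#' @references Conti G. et al. (2019) Journal of Ecology 107, 2394-2405.
#' @seealso [stem_agb()] for the tree-like counterpart.
#' @export
#' @examples
#' canopy_agb(cd_m = 1, h_cm = 100)
canopy_agb <- function(cd_m, h_cm) {
  check_positive(cd_m, "cd_m")
  check_positive(h_cm, "h_cm")
  exp(-0.370 + 1.903 * log(cd_m) + 0.652 * log(h_cm)) * 1.403
}

#' Stem-based aboveground biomass model
#'
#' Generic pantropical stem-based allometric model (Chave et al. 2014),
#' estimating aboveground biomass from specific wood density, stem diameter
#' at breast height and tree height:
#' \deqn{AGB = 0.0673 \, (SWD \cdot DBH^2 \cdot h)^{0.976}}
#'
#' Unit contract: height enters in m here (the parameter is named `h_m` to
#' make the contract explicit), while the rest of the package carries
#' heights in cm — callers must divide by 100.
#'
#' Because stem dimensions persist through crown damage, the raw model
#' output approximates the pre-disturbance biomass of the stem; observed
#' crown losses must be subtracted afterwards to obtain standing AGB.
#'
#' @param swd specific wood density in g cm^-3.
#' @param dbh_cm stem diameter at breast height (130 cm) in cm.
#' @param h_m tree height in m.
#' @return Aboveground biomass in kg. Vectorized.
#' @references Chave J. et al. (2014) Global Change Biology 20, 3177-3190.
#' @export
#' @examples
#' stem_agb(swd = 0.6, dbh_cm = 30, h_m = 12)
stem_agb <- function(swd, dbh_cm, h_m) {
  check_positive(swd, "swd")
  check_positive(dbh_cm, "dbh_cm")
  check_positive(h_m, "h_m")
  0.0673 * (swd * dbh_cm^2 * h_m)^0.976
}

#' Reference calibration coefficients
#'
#' Returns the set of proxy-reconstruction coefficients used when no local
#' calibration is supplied: a height-from-DBH power law
#' `h_est = exp(a + b ln DBH)`, a through-origin DBH-from-basal-diameter
#' slope `DBH_est = s * basal_circumference / pi`, and a linear stem-taper
#' coefficient `basal_circ = 130 * circ(hx) / (130 - t * hx)`. The default
#' values (a = 4.72595, b = 0.63385, s = 0.7968, t = 0.2032) were fitted to
#' healthy adult trees of a semi-arid African savanna community and carry
#' the provenance flag `"reference"`; refitting them locally with
#' [calibrate_models()] is recommended whenever reference trees are
#' available in the target community.
#'
#' @return An object of class `agb_calibration`: a list with elements
#'   `height` (a, b, r2, n), `dbh` (s, r2, n), `taper` (t, r2, n) and
#'   `provenance`.
#' @seealso [calibrate_models()], [reconstruct_height()], [dbh_from_basal()],
#'   [basal_from_alternative()]
#' @export
default_calibration <- function() {
  new_calibration(
    height = list(a = 4.72595, b = 0.63385, r2 = NA_real_, n = NA_integer_),
    dbh    = list(s = 0.7968, r2 = NA_real_, n = NA_integer_),
    taper  = list(t = 0.2032, r2 = NA_real_, n = NA_integer_),
    provenance = "reference"
  )
}

new_calibration <- function(height, dbh, taper, provenance) {
  structure(
    list(height = height, dbh = dbh, taper = taper, provenance = provenance),
    class = "agb_calibration"
  )
}

#' @export
print.agb_calibration <- function(x, ...) {
  cat("Proxy-reconstruction calibration (", x$provenance, ")\n", sep = "")
  cat(sprintf("  height:  h_est = exp(%.5f + %.5f ln DBH)   R2 = %s, n = %s\n",
              x$height$a, x$height$b, format(x$height$r2), format(x$height$n)))
  cat(sprintf("  dbh:     DBH_est = %.4f * basal_circ / pi  R2 = %s, n = %s\n",
              x$dbh$s, format(x$dbh$r2), format(x$dbh$n)))
  cat(sprintf("  taper:   basal = 130 circ(hx)/(130 - %.4f hx) R2 = %s, n = %s\n",
              x$taper$t, format(x$taper$r2), format(x$taper$n)))
  invisible(x)
}

#' Reconstruct pre-disturbance height from DBH
#'
#' Estimates a tree's pre-disturbance height from its (measured or
#' estimated) DBH through the calibrated power law
#' `h_est = exp(a + b ln DBH)`, and returns the larger of the estimate and
#' the observed height: where the estimate falls below the field reading,
#' the initial height reading is kept.
#'
#' @param dbh_cm DBH in cm.
#' @param h_obs_cm observed height in cm.
#' @param calibration an `agb_calibration`; defaults to
#'   [default_calibration()].
#' @return Reconstructed height in cm. Vectorized.
#' @export
reconstruct_height <- function(dbh_cm, h_obs_cm,
                               calibration = default_calibration()) {
  check_positive(dbh_cm, "dbh_cm")
  check_positive(h_obs_cm, "h_obs_cm")
  check_calibration(calibration)
  pmax(h_obs_cm, exp(calibration$height$a + calibration$height$b * log(dbh_cm)))
}

#' Estimate DBH from basal circumference
#'
#' For stems whose breast-height circumference cannot be measured (broken,
#' burnt, or branching below 130 cm), DBH is estimated from the basal
#' circumference through the calibrated through-origin proportionality
#' `DBH_est = s * basal_circumference / pi`.
#'
#' @param basal_circ_cm basal stem circumference in cm.
#' @inheritParams reconstruct_height
#' @return Estimated DBH in cm. Vectorized.
#' @export
dbh_from_basal <- function(basal_circ_cm, calibration = default_calibration()) {
  check_positive(basal_circ_cm, "basal_circ_cm")
  check_calibration(calibration)
  calibration$dbh$s * basal_circ_cm / pi
}

#' Extrapolate basal circumference from an alternative stem reading
#'
#' Where neither basal nor breast-height circumference could be taken, a
#' circumference `circ(hx)` was read at an alternative height `hx` along
#' the stem; the basal circumference is extrapolated assuming linear stem
#' taper: `basal_circ = 130 * circ(hx) / (130 - t * hx)`.
#'
#' @param circ_hx_cm circumference at the alternative height, cm.
#' @param hx_cm height of the alternative reading above ground, cm; must
#'   satisfy `130 - t * hx > 0`.
#' @inheritParams reconstruct_height
#' @return Extrapolated basal circumference in cm. Vectorized.
#' @export
basal_from_alternative <- function(circ_hx_cm, hx_cm,
                                   calibration = default_calibration()) {
  check_positive(circ_hx_cm, "circ_hx_cm")
  if (any(!is.finite(hx_cm)) || any(hx_cm < 0)) {
    stop("hx_cm must be finite and >= 0", call. = FALSE)
  }
  check_calibration(calibration)
  denom <- 130 - calibration$taper$t * hx_cm
  if (any(denom <= 0)) {
    bad <- hx_cm[denom <= 0]
    stop(sprintf(
      "taper denominator non-positive for hx = %s (t = %g); reading too high on the stem",
      paste(format(bad), collapse = ", "), calibration$taper$t
    ), call. = FALSE)
  }
  130 * circ_hx_cm / denom
}

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("%s must be finite and > 0", name), call. = FALSE)
  }
  invisible(x)
}

check_calibration <- function(calibration) {
  if (!inherits(calibration, "agb_calibration")) {
    stop("`calibration` must be an agb_calibration object; see default_calibration()",
         call. = FALSE)
  }
  invisible(calibration)
}
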