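#' Diffusive flux across the top of the sediment column
#'
#' Fick's-law flux computed from the two shallowest concentrations of a
#' porewater profile (interval midpoints when the profile comes from a
#' sectioned core). With depth positive downward the upward-positive flux is
#' \deqn{J = \phi D_s \frac{C_2 - C_1}{x_2 - x_1}
#'       \times 86400 \times 10^{4} \times 10^{-3},}
#' giving mmol m\eqn{^{-2}} d\eqn{^{-1}}. Sulfate diffusing into the
#' sediment therefore yields a negative flux; methane diffusing out of the
#' sediment a positive one.
#'
#' @param profile A data frame with depth (column `depth_cm` or
#'   `depth_mid_cm`) and concentration (`conc_mM` or `value`) in mM; only
#'   the two shallowest depths are used.
#' @param phi Porosity at the interface.
#' @param D_s Effective diffusivity, cm^2 s^-1 (already tortuosity-corrected
#'   if desired; see [effective_diffusivity()]).
#' @param solute Solute name recorded in the result.
#' @param porosity_correction If `FALSE`, drop the factor `phi` (whether
#'   reported fluxes are porosity-corrected varies between studies).
#' @return One-row tibble: `solute`, `flux_mmol_m2_d` (positive upward),
#'   `depth_shallow_cm`, `depth_deep_cm`.
#' @export
#' @examples
#' prof <- tibble::tibble(depth_cm = c(1.5, 4.5), conc_mM = c(28, 10))
#' diffusive_flux_top(prof, phi = 0.9, D_s = 5e-6)
diffusive_flux_top <- function(profile, phi, D_s, solute = "sulfate",
                               porosity_correction = TRUE) {
  depth_col <- intersect(c("depth_cm", "depth_mid_cm"), names(profile))[1]
  conc_col <- intersect(c("conc_mM", "value"), names(profile))[1]
  if (is.na(depth_col) || is.na(conc_col)) {
    seep_abort("profile needs a depth (depth_cm/depth_mid_cm) and a concentration (conc_mM/value) column",
               "seep_format_error")
  }
  profile <- dplyr::arrange(tibble::as_tibble(profile), .data[[depth_col]])
  if (nrow(profile) < 2) {
    seep_abort("at least two depths are required for a flux",
               "seep_validation_error")
  }
  z <- profile[[depth_col]][1:2]
  C <- profile[[conc_col]][1:2]
  if (diff(z) == 0) {
    seep_abort("zero depth spacing between the first two depths",
               "seep_domain_error")
  }
  grad <- (C[2] - C[1]) / (z[2] - z[1])           # mM cm^-1
  phi_f <- if (porosity_correction) phi else 1
  J <- phi_f * D_s * .SEC_PER_DAY * grad * .FLUX_TO_MMOL_M2_D
  tibble::tibble(solute = solute, flux_mmol_m2_d = J,
                 depth_shallow_cm = z[1], depth_deep_cm = z[2])
}

#' Depth-integrate a volumetric rate profile
#'
#' Trapezoidal integration of a volumetric rate profile over a depth window,
#' converting nmol cm^-3 d^-1 x cm to mmol m^-2 d^-1 (factor 0.01).
#' Duplicate depths (replicate injections) are averaged before integrating;
#' window edges inside the measured range are handled by linear
#' interpolation, and portions of the window outside the measured range are
#' treated as zero rate.
#'
#' @param rates A data frame with depth (`depth_cm` or `depth_mid_cm`) and
#'   rate (`rate_nmol_cm3_d` or `value`) columns.
#' @param z_min,z_max Integration bounds, cm (`z_min < z_max`). Defaults:
#'   the full measured range, capped at 25 cm (the depth window over which
#'   surficial seep activity is typically integrated).
#' @param process `"sulfate_reduction"` or `"methane_oxidation"`.
#' @return One-row tibble: `process`, `value_mmol_m2_d`, `z_min_cm`,
#'   `z_max_cm`.
#' @export
#' @examples
#' r <- tibble::tibble(depth_cm = c(0, 10), rate_nmol_cm3_d = c(200, 0))
#' depth_integrated_rate(r, 0, 10)  # triangle: 10 mmol m^-2 d^-1
depth_integrated_rate <- function(rates, z_min = NULL, z_max = NULL,
                                  process = c("sulfate_reduction",
                                              "methane_oxidation")) {
  process <- match.arg(process)
  depth_col <- intersect(c("depth_cm", "depth_mid_cm"), names(rates))[1]
  rate_col <- intersect(c("rate_nmol_cm3_d", "value"), names(rates))[1]
  if (is.na(depth_col) || is.na(rate_col)) {
    seep_abort("rates need a depth and a rate column", "seep_format_error")
  }
  r <- rates |>
    dplyr::summarise(rate = mean(.data[[rate_col]]),
                     .by = dplyr::all_of(depth_col)) |>
    dplyr::arrange(.data[[depth_col]])
  z <- r[[depth_col]]
  v <- r$rate
  if (is.null(z_min)) z_min <- min(z)
  if (is.null(z_max)) z_max <- min(max(z), 25)
  if (z_min >= z_max) {
    seep_abort("z_min must be < z_max", "seep_domain_error")
  }
  if (z_max <= min(z) || z_min >= max(z)) {
    seep_abort("integration window does not overlap the measured depths",
               "seep_validation_error")
  }
  lo <- max(z_min, min(z))
  hi <- min(z_max, max(z))
  inner <- z[z > lo & z < hi]
  zz <- c(lo, inner, hi)
  vv <- stats::approx(z, v, xout = zz)$y
  integral <- sum(diff(zz) * (vv[-1] + vv[-length(vv)]) / 2)
  tibble::tibble(process = process,
                 value_mmol_m2_d = integral * .RATE_INT_TO_MMOL_M2_D,
                 z_min_cm = z_min, z_max_cm = z_max)
}

#' Compare a diffusive flux against a depth-integrated rate
#'
#' Quality-control check pairing a top-interval diffusive flux with the
#' depth-integrated radiotracer rate that should balance it at steady state
#' (sulfate flux vs. sulfate reduction; methane flux vs. methane oxidation).
#' Agreement is judged on the ratio `|flux| / rate` against a symmetric
#' agreement factor.
#'
#' @param flux A [diffusive_flux_top()] result.
#' @param rate A [depth_integrated_rate()] result.
#' @param agreement_factor Ratio beyond which the pair is flagged
#'   (default 3: agree when the ratio lies in `[1/3, 3]`).
#' @return One-row tibble with the ratio, absolute difference and a flag in
#'   `agree`, `rate_underestimated`, `rate_overestimated`.
#' @export
flux_rate_consistency <- function(flux, rate, agreement_factor = 3) {
  pairing <- c(sulfate = "sulfate_reduction", methane = "methane_oxidation")
  expected <- unname(pairing[flux$solute])
  if (is.na(expected) || !identical(expected, rate$process)) {
    seep_abort(sprintf("mismatched pairing: solute '%s' vs process '%s'",
                       flux$solute, rate$process), "seep_validation_error")
  }
  f <- abs(flux$flux_mmol_m2_d)
  r <- rate$value_mmol_m2_d
  ratio <- if (f == 0 && r == 0) 1 else f / r
  flag <- if (is.finite(ratio) && ratio >= 1 / agreement_factor &&
              ratio <= agreement_factor) {
    "agree"
  } else if (ratio > agreement_factor) {
    "rate_underestimated"
  } else {
    "rate_overestimated"
  }
  tibble::tibble(solute = flux$solute, process = rate$process,
                 abs_flux_mmol_m2_d = f, rate_mmol_m2_d = r,
                 ratio = ratio, abs_difference = abs(f - r), flag = flag)
}

#' Minimum persistence time of mRNA buried below an activity horizon
#'
#' If transcripts recovered at some depth below the deepest measurable
#' activity were deposited at the sediment surface and merely buried, they
#' must have persisted for at least the burial time of that depth offset:
#' \deqn{t = \mathrm{offset} / \omega \times 1000 \ \mathrm{yr},}
#' with `omega` the sedimentation rate in cm kyr^-1. Using the maximum
#' plausible sedimentation rate makes the estimate a lower bound.
#'
#' @param depth_offset_cm Depth below the activity horizon, cm (>= 0).
#' @param omega_cm_kyr Sedimentation rate, cm kyr^-1 (> 0).
#' @return One-row tibble with `years_exact` and `years_floor`.
#' @export
#' @examples
#' mrna_persistence_time(5, 31)  # at least 161 years
mrna_persistence_time <- function(depth_offset_cm, omega_cm_kyr) {
  if (omega_cm_kyr <= 0) {
    seep_abort("sedimentation rate must be positive", "seep_domain_error")
  }
  if (depth_offset_cm < 0) {
    seep_abort("depth offset must be >= 0", "seep_domain_error")
  }
  t <- depth_offset_cm / omega_cm_kyr * 1000
  tibble::tibble(depth_offset_cm = depth_offset_cm,
                 omega_cm_kyr = omega_cm_kyr,
                 years_exact = t, years_floor = floor(t))
}

#' Flag methane concentrations at or above outgassing saturation
#'
#' Methane measured shipboard at 1 atm outgasses above ~1.2 mM, so any
#' higher value is only a lower bound on the in-situ concentration. Flags
#' each depth where the concentration strictly exceeds the saturation
#' threshold.
#'
#' @param profile A data frame with a concentration column (`conc_mM` or
#'   `value`).
#' @param saturation_mM Saturation threshold, mM (default 1.2).
#' @return The profile with logical `saturated` and character `annotation`
#'   (`"lower bound"` where flagged) columns appended.
#' @export
flag_saturation <- function(profile, saturation_mM = 1.2) {
  profile <- tibble::as_tibble(profile)
  conc_col <- intersect(c("conc_mM", "value"), names(profile))[1]
  if (is.na(conc_col)) {
    seep_abort("profile needs a concentration column (conc_mM/value)",
               "seep_format_error")
  }
  dplyr::mutate(profile,
                saturated = .data[[conc_col]] > saturation_mM,
                annotation = dplyr::if_else(.data$saturated, "lower bound",
                                            NA_character_))
}
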