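#' Convert an isotope ratio to delta-13C del notation
#'
#' \deqn{\delta^{13}\mathrm{C}\ (\text{permil}) =
#'   \left[\frac{R_{sample}}{R_{standard}} - 1\right] \times 1000,}
#' with R the heavy-to-light isotope ratio and the standard the Pee Dee
#' Belemnite (VPDB) carbonate. The conventional VPDB ratio 0.0112372 is the
#' default standard.
#'
#' @param R_sample Sample 13C/12C ratio (> 0), vectorised.
#' @param R_standard Standard ratio (> 0).
#' @return delta-13C in permil.
#' @export
#' @examples
#' delta13c(0.0112372 * 0.94)  # roughly -60 permil, a biogenic methane value
delta13c <- function(R_sample, R_standard = 0.0112372) {
  if (any(R_sample <= 0) || any(R_standard <= 0)) {
    seep_abort("isotope ratios must be positive", "seep_domain_error")
  }
  (R_sample / R_standard - 1) * 1000
}

#' Invert del notation back to an isotope ratio
#'
#' Exact inverse of [delta13c()]: `delta13c(ratio_from_delta(d)) == d`.
#'
#' @param delta delta-13C in permil (> -1000).
#' @param R_standard Standard ratio (> 0).
#' @return The sample 13C/12C ratio.
#' @export
ratio_from_delta <- function(delta, R_standard = 0.0112372) {
  if (any(delta <= -1000)) {
    seep_abort("delta must exceed -1000 permil (ratio must stay positive)",
               "seep_domain_error")
  }
  (delta / 1000 + 1) * R_standard
}

#' Classify the upcore trend of a methane delta-13C profile
#'
#' Methane-oxidising communities prefer the light isotope, so residual
#' methane becomes 13C-enriched as it diffuses upward through an oxidation
#' zone: enrichment toward the surface signals net methane oxidation.
#' Conversely, methanogenesis produces light methane, so upcore depletion
#' signals net methanogenesis. The call is the sign of the least-squares
#' slope of delta-13C against depth, subject to a minimum total magnitude
#' over the profile span; fewer than three measured depths, or a trend
#' carried by a single surface excursion (which could reflect aerobic
#' oxidation at the interface), is refused as indeterminate.
#'
#' @param profile A data frame with depth (`depth_cm` or `depth_mid_cm`) and
#'   delta-13C (`delta13C` or `value`, permil) columns; missing values
#'   allowed.
#' @param min_magnitude_permil Minimum fitted change across the profile span
#'   for a determinate call (default 1 permil).
#' @param refuse_single_excursion If `TRUE` (default) a trend whose sign
#'   flips when the shallowest point is dropped is ruled indeterminate.
#' @return One-row tibble: `trend` (`enrichment_upcore`, `depletion_upcore`,
#'   `indeterminate`), `interpretation`, `slope_permil_per_cm`, `n_used`,
#'   `reason`.
#' @export
#' @examples
#' prof <- tibble::tibble(depth_cm = c(1.5, 7.5, 13.5),
#'                        delta13C = c(-65, -60, -55))
#' classify_trend(prof)  # lighter toward the surface: net methanogenesis
classify_trend <- function(profile, min_magnitude_permil = 1,
                           refuse_single_excursion = TRUE) {
  depth_col <- intersect(c("depth_cm", "depth_mid_cm"), names(profile))[1]
  val_col <- intersect(c("delta13C", "value"), names(profile))[1]
  if (is.na(depth_col) || is.na(val_col)) {
    seep_abort("profile needs a depth and a delta13C column", "seep_format_error")
  }
  df <- tibble::tibble(depth = profile[[depth_col]],
                       delta = profile[[val_col]]) |>
    dplyr::filter(!is.na(.data$delta)) |>
    dplyr::arrange(.data$depth)

  out <- function(trend, interp, slope, reason) {
    tibble::tibble(trend = trend, interpretation = interp,
                   slope_permil_per_cm = slope, n_used = nrow(df),
                   reason = reason)
  }
  if (nrow(df) < 3) {
    return(out("indeterminate", NA_character_, NA_real_,
               "fewer than 3 measured depths"))
  }
  slope_of <- function(d) unname(coef(lm(delta ~ depth, data = d))[2])
  slope <- slope_of(df)
  span <- diff(range(df$depth))
  if (abs(slope * span) < min_magnitude_permil) {
    return(out("indeterminate", NA_character_, slope,
               sprintf("fitted change %.2f permil below the %g permil floor",
                       slope * span, min_magnitude_permil)))
  }
  if (refuse_single_excursion && nrow(df) > 3) {
    slope_wo <- slope_of(df[-1, ])
    if (sign(slope_wo) != sign(slope) ||
        abs(slope_wo * diff(range(df$depth[-1]))) < min_magnitude_permil) {
      return(out("indeterminate", NA_character_, slope,
                 "trend carried by a single surface excursion"))
    }
  }
  if (slope > 0) {
    # heavier with depth = lighter toward the surface
    out("depletion_upcore", "net methanogenesis", slope, NA_character_)
  } else {
    out("enrichment_upcore", "net methane oxidation", slope, NA_character_)
  }
}
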