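#' Plot a depth profile with depth increasing downward
#'
#' @param profile A data frame with a depth column (`depth_cm` or
#'   `depth_mid_cm`) and a value column (`conc_mM`, `rate_nmol_cm3_d`,
#'   `delta13C` or `value`).
#' @param colour Optional column name used to colour series (e.g.
#'   `"core_id"`).
#' @return A ggplot.
#' @export
plot_profile <- function(profile, colour = NULL) {
  depth_col <- intersect(c("depth_cm", "depth_mid_cm"), names(profile))[1]
  val_col <- intersect(c("conc_mM", "rate_nmol_cm3_d", "delta13C", "value"),
                       names(profile))[1]
  if (is.na(depth_col) || is.na(val_col)) {
    seep_abort("profile needs a depth and a value column", "seep_format_error")
  }
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data[[val_col]],
                                    y = .data[[depth_col]]))
  if (!is.null(colour)) {
    p <- p + ggplot2::aes(colour = .data[[colour]])
  }
  p +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = val_col, y = "depth (cmbsf)") +
    ggplot2::theme_minimal()
}

#' Plot an inverse rate fit: data, model fit and layer rates
#'
#' @param object A `rate_fit` from [fit_rates_inverse()].
#' @param ... Unused.
#' @return A ggplot showing observed and fitted concentrations over depth,
#'   annotated with the fitted layer rates.
#' @export
autoplot.rate_fit <- function(object, ...) {
  obs <- dplyr::mutate(object$observed, what = "observed")
  fit <- dplyr::mutate(object$fitted, what = "fitted")
  lab <- sprintf("%g-%g cm: %.3g nmol cm-3 d-1",
                 object$layers$depth_top_cm, object$layers$depth_bottom_cm,
                 object$layers$rate_nmol_cm3_d)
  ggplot2::ggplot(dplyr::bind_rows(obs, fit),
                  ggplot2::aes(x = .data$conc_mM, y = .data$depth_cm,
                               colour = .data$what)) +
    ggplot2::geom_path(data = fit) +
    ggplot2::geom_point(data = obs, size = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "concentration (mM)", y = "depth (cmbsf)",
                  colour = NULL, subtitle = paste(lab, collapse = "; ")) +
    ggplot2::theme_minimal()
}

#' Plot an activity summary (transect figure analogue)
#'
#' Bar panel per layer comparing, across cores, the sulfate-reducer and ANME
#' clone percentages, mRNA presence encodings (100/0), |sulfate flux| and
#' methane flux x 10.
#'
#' @param summary An activity summary from [build_activity_summary()].
#' @return A ggplot.
#' @export
plot_activity_summary <- function(summary) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(summary),
    cols = dplyr::any_of(c("pct_SRB_clones", "pct_ANME_clones",
                           "dsrAB_present", "mcrA_present",
                           "abs_sulfate_flux", "methane_flux_x10")),
    names_to = "indicator", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$core_id, y = .data$value,
                                     fill = .data$indicator)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~layer) +
    ggplot2::labs(x = NULL, y = "percent / mmol m-2 d-1") +
    ggplot2::theme_minimal()
}
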