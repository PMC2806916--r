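#' Per-sample clone fractions by phylotype group and ecological role
#'
#' Converts a sample-by-taxon count table into clone percentages per group
#' and per ecological role (SRB, ANME, other), the composition summaries
#' drawn from clone-library bar charts. Role percentages sum to 100 within
#' each sample.
#'
#' @param counts A count table (`sample_id`, `taxon_id`, `count`).
#' @param groups A group map (`taxon_id`, `group`, `role`); every taxon in
#'   `counts` must be mapped.
#' @return A list of two tibbles: `by_group` (per sample and group:
#'   `n_clones`, `pct`) and `by_role` (per sample and role: `n_clones`,
#'   `pct`), each with per-sample totals.
#' @export
group_fractions <- function(counts, groups) {
  counts <- validate_count_table(counts)
  groups <- validate_group_map(groups)
  unmapped <- setdiff(unique(counts$taxon_id), groups$taxon_id)
  if (length(unmapped) > 0) {
    seep_abort(paste0("taxa missing from the group map: ",
                      paste(unmapped, collapse = ", ")), "seep_mapping_error")
  }
  joined <- dplyr::inner_join(counts, groups, by = "taxon_id") |>
    dplyr::mutate(total = sum(.data$count), .by = "sample_id")
  by_group <- joined |>
    dplyr::summarise(n_clones = sum(.data$count), total = .data$total[1],
                     .by = c("sample_id", "group", "role")) |>
    dplyr::mutate(pct = 100 * .data$n_clones / .data$total)
  by_role <- joined |>
    dplyr::summarise(n_clones = sum(.data$count), total = .data$total[1],
                     .by = c("sample_id", "role")) |>
    dplyr::mutate(pct = 100 * .data$n_clones / .data$total)
  list(by_group = by_group, by_role = by_role)
}

#' Assemble the joint geochemistry/community activity summary
#'
#' Joins per-sample role fractions, functional-gene mRNA detections and
#' diffusive fluxes into one row per (core, layer), applying the standard
#' encodings for a transect activity figure: mRNA presence as 100/0, the
#' sulfate flux as an absolute value (seep sulfate fluxes are directed into
#' the sediment, hence negative), and the methane flux multiplied by 10 so
#' both solutes share an axis. A methane flux computed from a profile that
#' is saturation-flagged throughout is reported missing (`NA`) with the
#' reason `"above saturation"`.
#'
#' @param role_fractions The `by_role` tibble from [group_fractions()], with
#'   sample ids of the form used in `keys`; `pct_SRB` is taken from bacterial
#'   samples and `pct_ANME` from archaeal samples via the `domain` column of
#'   `keys`.
#' @param keys A tibble keying samples to the summary rows: columns
#'   `sample_id`, `core_id`, `layer` (`"surface"` or `"deep"`), `domain`
#'   (`"bacteria"` or `"archaea"`).
#' @param mrna_flags Tibble with `core_id`, `layer`, `dsrAB_present`,
#'   `mcrA_present` (logical).
#' @param fluxes Tibble with `core_id`, `layer`, `solute`,
#'   `flux_mmol_m2_d`, and optionally logical `all_saturated` for methane.
#' @return An `activity_summary` tibble, one row per (core, layer).
#' @export
build_activity_summary <- function(role_fractions, keys, mrna_flags, fluxes) {
  needed <- c("sample_id", "core_id", "layer", "domain")
  if (!all(needed %in% names(keys))) {
    seep_abort(paste0("keys needs columns: ", paste(needed, collapse = ", ")),
               "seep_format_error")
  }
  unmatched <- setdiff(unique(role_fractions$sample_id), keys$sample_id)
  if (length(unmatched) > 0) {
    seep_abort(paste0("samples missing from keys: ",
                      paste(unmatched, collapse = ", ")), "seep_join_error")
  }
  frac <- dplyr::inner_join(role_fractions, keys, by = "sample_id")
  pct_srb <- frac |>
    dplyr::filter(.data$domain == "bacteria", .data$role == "SRB") |>
    dplyr::select("core_id", "layer", pct_SRB_clones = "pct")
  pct_anme <- frac |>
    dplyr::filter(.data$domain == "archaea", .data$role == "ANME") |>
    dplyr::select("core_id", "layer", pct_ANME_clones = "pct")

  sulfate <- fluxes |>
    dplyr::filter(.data$solute == "sulfate") |>
    dplyr::mutate(abs_sulfate_flux = abs(.data$flux_mmol_m2_d)) |>
    dplyr::select("core_id", "layer", "abs_sulfate_flux")
  methane <- fluxes |>
    dplyr::filter(.data$solute == "methane") |>
    dplyr::mutate(
      all_saturated = if ("all_saturated" %in% names(fluxes))
        dplyr::coalesce(.data$all_saturated, FALSE) else FALSE,
      methane_flux_x10 = dplyr::if_else(.data$all_saturated, NA_real_,
                                        10 * .data$flux_mmol_m2_d),
      methane_flux_missing_reason = dplyr::if_else(.data$all_saturated,
                                                   "above saturation",
                                                   NA_character_)) |>
    dplyr::select("core_id", "layer", "methane_flux_x10",
                  "methane_flux_missing_reason")

  out <- pct_srb |>
    dplyr::full_join(pct_anme, by = c("core_id", "layer")) |>
    dplyr::left_join(
      dplyr::mutate(mrna_flags,
                    dsrAB_present = 100 * as.numeric(.data$dsrAB_present),
                    mcrA_present = 100 * as.numeric(.data$mcrA_present)),
      by = c("core_id", "layer")) |>
    dplyr::left_join(sulfate, by = c("core_id", "layer")) |>
    dplyr::left_join(methane, by = c("core_id", "layer")) |>
    dplyr::arrange(.data$layer, .data$core_id)
  class(out) <- c("activity_summary", class(out))
  out
}

#' Ordinal concordance between fluxes and community fractions
#'
#' Tests, within each depth layer, whether cores rank the same way by
#' geochemical flux and by the community fraction expected to track it:
#' |sulfate flux| against the percentage of sulfate-reducer clones, and
#' methane flux against the percentage of ANME clones. All core pairs are
#' enumerated (a Kendall-style concordant-pair fraction); tied pairs are
#' excluded from the fraction and reported.
#'
#' @param summary An [build_activity_summary()] result (or any tibble with
#'   `core_id`, `layer`, `abs_sulfate_flux`, `pct_SRB_clones`,
#'   `methane_flux_x10`, `pct_ANME_clones`).
#' @return Tibble with one row per (layer, pairing): number of pairs,
#'   concordant pairs, ties, and the concordant fraction among untied pairs.
#' @export
concordance_check <- function(summary) {
  pairings <- list(
    sulfate_vs_SRB = c("abs_sulfate_flux", "pct_SRB_clones"),
    methane_vs_ANME = c("methane_flux_x10", "pct_ANME_clones")
  )
  purrr::map_dfr(unique(summary$layer), function(ly) {
    rows <- dplyr::filter(summary, .data$layer == ly)
    purrr::imap_dfr(pairings, function(cols, nm) {
      ok <- stats::complete.cases(rows[, cols])
      x <- rows[[cols[1]]][ok]
      y <- rows[[cols[2]]][ok]
      n <- length(x)
      if (n < 2) {
        return(tibble::tibble(layer = ly, pairing = nm, n_cores = n,
                              n_pairs = 0L, concordant = 0L, ties = 0L,
                              concordant_fraction = NA_real_))
      }
      pairs <- utils::combn(n, 2)
      sx <- sign(x[pairs[1, ]] - x[pairs[2, ]])
      sy <- sign(y[pairs[1, ]] - y[pairs[2, ]])
      tied <- sx == 0 | sy == 0
      conc <- !tied & sx == sy
      tibble::tibble(layer = ly, pairing = nm, n_cores = n,
                     n_pairs = ncol(pairs), concordant = sum(conc),
                     ties = sum(tied),
                     concordant_fraction = if (all(tied)) NA_real_ else
                       sum(conc) / sum(!tied))
    })
  })
}
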