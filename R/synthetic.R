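#' Define a synthetic sediment-core scenario
#'
#' Parameterises the contrast between mat-covered, mat-edge and off-mat seep
#' sediments: mat and edge cores carry high near-surface sulfate reduction
#' (sulfate depleted within the top ~5 cm), while cores outside the mat
#' carry roughly an order of magnitude less activity and sulfate profiles
#' that barely decrease with depth. Concentration measurements carry a
#' relative precision of about 3%, reproduced as multiplicative Gaussian
#' noise.
#'
#' @param label `"mat"`, `"edge"` or `"outside"`.
#' @param C_OW_mM Overlying-water sulfate concentration, mM (default 28, a
#'   seawater value; assumed, not a site measurement).
#' @param R0_nmol_cm3_d Surface rate amplitude before any outside scaling,
#'   nmol cm^-3 d^-1.
#' @param decay_length_cm e-folding depth of the rate profile, cm.
#' @param outside_factor Rate scaling applied to `"outside"` scenarios
#'   (default 0.1).
#' @param noise_fraction Relative measurement noise (default 0.03).
#' @param seed Integer seed recorded in the scenario and used by the
#'   generators.
#' @return A `core_scenario` object (list).
#' @export
core_scenario <- function(label = c("mat", "edge", "outside"),
                          C_OW_mM = 28, R0_nmol_cm3_d = 2000,
                          decay_length_cm = 2, outside_factor = 0.1,
                          noise_fraction = 0.03, seed = 1L) {
  label <- match.arg(label)
  if (decay_length_cm <= 0) {
    seep_abort("decay_length_cm must be positive", "seep_domain_error")
  }
  if (noise_fraction < 0) {
    seep_abort("noise_fraction must be >= 0", "seep_domain_error")
  }
  structure(list(label = label, C_OW_mM = C_OW_mM,
                 R0_nmol_cm3_d = R0_nmol_cm3_d,
                 decay_length_cm = decay_length_cm,
                 outside_factor = outside_factor,
                 noise_fraction = noise_fraction, seed = as.integer(seed)),
            class = "core_scenario")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate an exponentially decaying volumetric rate profile
#'
#' \eqn{R(x) = R_0 e^{-x/\lambda}}, mirroring radiotracer sulfate reduction
#' rates that decay with depth in step with the sulfate profile. `"outside"`
#' scenarios scale the amplitude by the scenario's `outside_factor`.
#'
#' @param scn A [core_scenario()].
#' @param grid Depths (cm) at which to sample the profile.
#' @return Tibble `depth_cm`, `rate_nmol_cm3_d` with the seed recorded as an
#'   attribute.
#' @export
make_rate_profile <- function(scn, grid) {
  stopifnot(inherits(scn, "core_scenario"))
  R0 <- scn$R0_nmol_cm3_d *
    if (scn$label == "outside") scn$outside_factor else 1
  out <- tibble::tibble(depth_cm = grid,
                        rate_nmol_cm3_d = R0 * exp(-grid / scn$decay_length_cm))
  attr(out, "seed") <- scn$seed
  out
}

#' Generate a noisy steady-state concentration profile
#'
#' Solves the forward transport model for the scenario's rates and applies
#' multiplicative Gaussian measurement noise of the scenario's
#' `noise_fraction` (truncated at zero; exact zeros stay zero). With
#' `noise_fraction = 0` the forward solution is returned unchanged.
#'
#' @param scn A [core_scenario()].
#' @param sys A [transport_system()].
#' @param rates Rates for [solve_forward()] (per-node vector or layer table).
#' @return Tibble `depth_cm`, `conc_mM` (noisy), `conc_true_mM`.
#' @export
make_concentration_profile <- function(scn, sys, rates) {
  stopifnot(inherits(scn, "core_scenario"))
  truth <- solve_forward(sys, rates)
  noisy <- if (scn$noise_fraction == 0) truth$conc_mM else
    with_seed(scn$seed, {
      pmax(0, truth$conc_mM *
             (1 + rnorm(nrow(truth), 0, scn$noise_fraction)))
    })
  tibble::tibble(depth_cm = truth$depth_cm, conc_mM = noisy,
                 conc_true_mM = truth$conc_mM)
}

#' Default phylotype group maps for synthetic communities
#'
#' Small group inventories matching the clades that dominate seep clone
#' libraries: sulfate reducers (Eel-2, SEEP-SRB1, Desulfobacteraceae,
#' Desulfobulbaceae) for bacteria, anaerobic methanotrophs (ANME-1b,
#' ANME-2a, ANME-2c) for archaea, plus aerobic/planktonic groups.
#'
#' @param domain `"bacteria"` or `"archaea"`.
#' @return A group-map tibble (`taxon_id`, `group`, `role`).
#' @export
default_group_map <- function(domain = c("bacteria", "archaea")) {
  domain <- match.arg(domain)
  if (domain == "bacteria") {
    tibble::tibble(
      taxon_id = c("Eel-2", "SEEP-SRB1", "Desulfobacteraceae",
                   "Desulfobulbaceae", "Alphaproteobacteria",
                   "Gammaproteobacteria", "Bacteroidetes", "Chloroflexi"),
      group = taxon_id,
      role = c("SRB", "SRB", "SRB", "SRB", "other", "other", "other", "other")
    )
  } else {
    tibble::tibble(
      taxon_id = c("ANME-1b", "ANME-2a", "ANME-2c", "Marine Group I",
                   "DHVE8", "MBG-D"),
      group = taxon_id,
      role = c("ANME", "ANME", "ANME", "other", "other", "other")
    )
  }
}

#' Simulate a clone library for a scenario
#'
#' Draws a community composition from a Dirichlet distribution centred on
#' the expected group proportions (concentration parameter controls the
#' between-library wobble), then multinomial clone counts. With
#' `concentration = Inf` the expected proportions are used exactly and
#' counts are assigned by largest-remainder rounding, giving the noise-free
#' limit.
#'
#' @param scn A [core_scenario()] (its seed drives the draws).
#' @param n_clones Library size (>= 1).
#' @param role_profile Named numeric vector of expected proportions per
#'   group (must sum to 1 within 1e-9); names must appear in `group_map`.
#' @param group_map Group map assigning the profiled groups to roles.
#' @param concentration Dirichlet concentration (default 50); `Inf` for the
#'   deterministic limit.
#' @param sample_id Sample label for the count table.
#' @return A list with `counts` (count table tibble) and `groups` (the group
#'   map restricted to profiled taxa).
#' @export
make_community <- function(scn, n_clones, role_profile, group_map,
                           concentration = 50, sample_id = scn$label) {
  stopifnot(inherits(scn, "core_scenario"))
  if (n_clones < 1) seep_abort("n_clones must be >= 1", "seep_domain_error")
  if (abs(sum(role_profile) - 1) > 1e-9) {
    seep_abort("role_profile proportions must sum to 1", "seep_validation_error")
  }
  missing <- setdiff(names(role_profile), group_map$taxon_id)
  if (length(missing) > 0) {
    seep_abort(paste0("profiled groups missing from group map: ",
                      paste(missing, collapse = ", ")), "seep_mapping_error")
  }
  k <- length(role_profile)
  counts <- if (is.infinite(concentration)) {
    # largest-remainder rounding of the exact expectation
    exact <- n_clones * role_profile
    base <- floor(exact)
    left <- n_clones - sum(base)
    if (left > 0) {
      extra <- order(exact - base, decreasing = TRUE)[seq_len(left)]
      base[extra] <- base[extra] + 1
    }
    as.integer(base)
  } else {
    with_seed(scn$seed, {
      g <- rgamma(k, shape = concentration * role_profile, rate = 1)
      g[role_profile == 0] <- 0
      p <- g / sum(g)
      as.integer(rmultinom(1, n_clones, p))
    })
  }
  tbl <- tibble::tibble(sample_id = sample_id,
                        taxon_id = names(role_profile),
                        count = counts)
  list(counts = tbl,
       groups = group_map[group_map$taxon_id %in% names(role_profile), ])
}

#' Sample an OTU abundance multiset from a known pool
#'
#' Draws `sample_size` individuals from a pool of `true_richness` OTUs under
#' a uniform or a log-series-like abundance distribution, returning the
#' observed OTU size multiset. Supports property checks of richness
#' estimators: sampled richness never exceeds the true value, and the
#' bias-corrected Chao1 estimate approaches it as sampling deepens.
#'
#' @param true_richness Number of OTUs in the pool (>= 1).
#' @param distribution `"uniform"` or `"log_series"`.
#' @param sample_size Number of individuals drawn (>= 1).
#' @param seed Integer seed.
#' @return Integer vector of observed OTU sizes (sums to `sample_size`).
#' @export
make_otu_abundances <- function(true_richness,
                                distribution = c("uniform", "log_series"),
                                sample_size, seed = 1L) {
  distribution <- match.arg(distribution)
  if (true_richness < 1 || sample_size < 1) {
    seep_abort("true_richness and sample_size must be >= 1", "seep_domain_error")
  }
  p <- switch(distribution,
              uniform = rep(1 / true_richness, true_richness),
              log_series = {
                w <- 0.8^seq_len(true_richness) / seq_len(true_richness)
                w / sum(w)
              })
  with_seed(seed, {
    draws <- sample.int(true_richness, sample_size, replace = TRUE, prob = p)
    sizes <- tabulate(draws, nbins = true_richness)
    as.integer(sizes[sizes > 0])
  })
}

#' Simulate a full mat transect and run it through the pipeline
#'
#' Builds the three-core transect (mat, edge, outside) at two depth layers,
#' generates rate, concentration and isotope profiles plus bacterial and
#' archaeal clone libraries, and assembles the joint activity summary. The
#' design encodes the study architecture: sulfate flux magnitude and
#' sulfate-reducer/ANME clone fractions are both highest under and at the
#' edge of the mat and collapse just outside it at the surface, while deep
#' communities converge across cores.
#'
#' @param seed Integer seed controlling every stochastic component.
#' @param n_clones Clone-library size per sample (default 60).
#' @param noise_fraction Relative concentration noise (default 0.03).
#' @param concentration Dirichlet concentration for community draws
#'   (default 50; `Inf` for the deterministic limit).
#' @param domain_bottom_cm Model domain depth, cm (default 30).
#' @param dx_cm Node spacing, cm (default 0.1).
#' @return A list: `scenarios`, `profiles` (per-core tibble of noisy and
#'   true concentrations), `rates`, `isotopes`, `fluxes`, `counts`,
#'   `groups`, `keys`, `mrna_flags`, `summary` (activity summary) and
#'   `concordance`.
#' @export
#' @examples
#' tr <- simulate_transect(seed = 1, concentration = Inf, noise_fraction = 0)
#' tr$summary
simulate_transect <- function(seed = 1L, n_clones = 60,
                              noise_fraction = 0.03, concentration = 50,
                              domain_bottom_cm = 30, dx_cm = 0.1) {
  labels <- c("mat", "edge", "outside")
  # rate amplitudes: mat and edge nearly identical (sulfate depleted within
  # the upper few cm), outside collapsed by the scenario's 0.1 factor
  amps <- c(mat = 2000, edge = 1900, outside = 2000)
  scns <- purrr::imap(setNames(labels, labels), function(lb, nm) {
    core_scenario(lb, R0_nmol_cm3_d = amps[[lb]],
                  noise_fraction = noise_fraction,
                  seed = seed + match(lb, labels))
  })
  sys <- transport_system(domain_bottom_cm = domain_bottom_cm, dx_cm = dx_cm,
                          porosity = 0.8, D_O_cm2_s = 5e-6, C_OW_mM = 28)
  phi <- sys$porosity[1]
  D_s <- sys$D_s_cm2_s[1]

  rates <- purrr::map(scns, make_rate_profile, grid = sys$grid)
  profiles <- purrr::map2(scns, rates, function(s, r)
    make_concentration_profile(s, sys, r$rate_nmol_cm3_d))

  # methane: supplied from below (fixed bottom concentration, highest under
  # the mat) and diffusing up to the near-zero interface
  meth_bottom <- c(mat = 8, edge = 7, outside = 0.4)
  meth_profiles <- purrr::imap(scns, function(s, nm) {
    sys_m <- transport_system(domain_bottom_cm = domain_bottom_cm,
                              dx_cm = dx_cm, porosity = 0.8,
                              D_O_cm2_s = 5e-6, C_OW_mM = 0,
                              bottom_boundary = "fixed_value",
                              bottom_value_mM = meth_bottom[[nm]])
    s_m <- s
    s_m$seed <- s$seed + 31
    make_concentration_profile(s_m, sys_m, rep(0, length(sys_m$grid)))
  })

  # surface-interval fluxes from interval midpoints (3 cm sectioning)
  flux_of <- function(prof, solute) {
    mids <- c(1.5, 4.5)
    idx <- vapply(mids, function(z) which.min(abs(prof$depth_cm - z)), 1L)
    diffusive_flux_top(prof[idx, ], phi = phi, D_s = D_s, solute = solute)
  }
  fluxes_surface <- purrr::map(profiles, flux_of, solute = "sulfate")
  meth_fluxes_surface <- purrr::map(meth_profiles, flux_of, solute = "methane")

  # community design: SRB/ANME fractions co-vary with flux magnitude
  role_profiles <- list(
    bacteria = list(
      mat_surface = c("Eel-2" = 0.40, "SEEP-SRB1" = 0.20,
                      "Desulfobacteraceae" = 0.10, "Desulfobulbaceae" = 0.05,
                      "Alphaproteobacteria" = 0.05, "Gammaproteobacteria" = 0.05,
                      "Bacteroidetes" = 0.05, "Chloroflexi" = 0.10),
      edge_surface = c("Eel-2" = 0.35, "SEEP-SRB1" = 0.20,
                       "Desulfobacteraceae" = 0.10, "Desulfobulbaceae" = 0.05,
                       "Alphaproteobacteria" = 0.07, "Gammaproteobacteria" = 0.08,
                       "Bacteroidetes" = 0.05, "Chloroflexi" = 0.10),
      outside_surface = c("Eel-2" = 0.02, "SEEP-SRB1" = 0.03,
                          "Desulfobacteraceae" = 0.03, "Desulfobulbaceae" = 0.02,
                          "Alphaproteobacteria" = 0.35, "Gammaproteobacteria" = 0.30,
                          "Bacteroidetes" = 0.15, "Chloroflexi" = 0.10),
      deep = c("Eel-2" = 0.25, "SEEP-SRB1" = 0.30,
               "Desulfobacteraceae" = 0.15, "Desulfobulbaceae" = 0.05,
               "Alphaproteobacteria" = 0.05, "Gammaproteobacteria" = 0.05,
               "Bacteroidetes" = 0.05, "Chloroflexi" = 0.10)
    ),
    archaea = list(
      mat_surface = c("ANME-1b" = 0.30, "ANME-2a" = 0.25, "ANME-2c" = 0.15,
                      "Marine Group I" = 0.05, "DHVE8" = 0.15, "MBG-D" = 0.10),
      edge_surface = c("ANME-1b" = 0.28, "ANME-2a" = 0.22, "ANME-2c" = 0.15,
                       "Marine Group I" = 0.05, "DHVE8" = 0.18, "MBG-D" = 0.12),
      outside_surface = c("ANME-1b" = 0.01, "ANME-2a" = 0.03, "ANME-2c" = 0.01,
                          "Marine Group I" = 0.80, "DHVE8" = 0.05, "MBG-D" = 0.10),
      deep = c("ANME-1b" = 0.25, "ANME-2a" = 0.30, "ANME-2c" = 0.10,
               "Marine Group I" = 0.05, "DHVE8" = 0.15, "MBG-D" = 0.15)
    )
  )
  layers <- c("surface", "deep")
  keys <- tidyr::expand_grid(core = labels, layer = layers,
                             domain = c("bacteria", "archaea")) |>
    dplyr::mutate(sample_id = paste(.data$core, .data$layer, .data$domain,
                                    sep = "_")) |>
    dplyr::rename(core_id = "core")

  counts <- purrr::pmap_dfr(keys, function(core_id, layer, domain, sample_id) {
    prof_nm <- if (layer == "deep") "deep" else paste0(core_id, "_surface")
    rp <- role_profiles[[domain]][[prof_nm]]
    scn2 <- scns[[core_id]]
    scn2$seed <- scn2$seed + 97 * match(layer, layers) +
      1009 * match(domain, c("bacteria", "archaea"))
    make_community(scn2, n_clones, rp, default_group_map(domain),
                   concentration = concentration,
                   sample_id = sample_id)$counts
  })
  groups <- dplyr::bind_rows(default_group_map("bacteria"),
                             default_group_map("archaea"))

  # isotopes: mat core 13C-enriched upcore (net oxidation), edge depleted
  iso_depths <- c(1.5, 4.5, 7.5, 10.5, 13.5)
  isotopes <- dplyr::bind_rows(
    tibble::tibble(core_id = "mat", depth_cm = iso_depths,
                   delta13C = -52 - 2 * iso_depths),
    tibble::tibble(core_id = "edge", depth_cm = iso_depths,
                   delta13C = -70 + 1.2 * iso_depths),
    tibble::tibble(core_id = "outside", depth_cm = iso_depths,
                   delta13C = NA_real_)
  )

  # mRNA detections: absent only at the surface outside the mat
  mrna_flags <- tidyr::expand_grid(core_id = labels, layer = layers) |>
    dplyr::mutate(dsrAB_present = !(.data$core_id == "outside" &
                                      .data$layer == "surface"),
                  mcrA_present = .data$dsrAB_present)

  # deep-layer fluxes: converged, small; computed from the modeled profiles
  flux_deep <- function(prof, solute) {
    mids <- c(12 + 1.5, 15 + 1.5)
    idx <- vapply(mids, function(z) which.min(abs(prof$depth_cm - z)), 1L)
    diffusive_flux_top(prof[idx, ], phi = phi, D_s = D_s, solute = solute)
  }
  # methane above outgassing saturation in the deep interval is unreliable
  meth_sat_deep <- purrr::map_lgl(meth_profiles, function(p) {
    win <- p$depth_cm >= 12 & p$depth_cm <= 16.5
    all(flag_saturation(p[win, ])$saturated)
  })
  fluxes <- dplyr::bind_rows(
    purrr::imap_dfr(fluxes_surface, function(f, nm)
      dplyr::mutate(f, core_id = nm, layer = "surface", all_saturated = FALSE)),
    purrr::imap_dfr(meth_fluxes_surface, function(f, nm)
      dplyr::mutate(f, core_id = nm, layer = "surface", all_saturated = FALSE)),
    purrr::imap_dfr(profiles, function(p, nm)
      dplyr::mutate(flux_deep(p, "sulfate"), core_id = nm, layer = "deep",
                    all_saturated = FALSE)),
    purrr::imap_dfr(meth_profiles, function(p, nm)
      dplyr::mutate(flux_deep(p, "methane"), core_id = nm, layer = "deep",
                    all_saturated = meth_sat_deep[[nm]]))
  )

  fracs <- group_fractions(counts, groups)
  summary <- build_activity_summary(
    fracs$by_role, dplyr::select(keys, "sample_id", "core_id", "layer",
                                 "domain"),
    mrna_flags, fluxes)
  list(scenarios = scns, system = sys,
       rates = purrr::imap_dfr(rates, ~dplyr::mutate(.x, core_id = .y)),
       profiles = dplyr::bind_rows(
         purrr::imap_dfr(profiles, ~dplyr::mutate(.x, core_id = .y,
                                                  solute = "sulfate")),
         purrr::imap_dfr(meth_profiles, ~dplyr::mutate(.x, core_id = .y,
                                                       solute = "methane"))),
       isotopes = isotopes, fluxes = fluxes, counts = counts, groups = groups,
       keys = keys, mrna_flags = mrna_flags, summary = summary,
       concordance = concordance_check(summary))
}
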