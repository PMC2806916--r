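#' Effective sediment diffusivity with tortuosity correction
#'
#' Molecular diffusion in sediment pore space is slowed by the tortuous path
#' around grains. The correction used here is
#' \deqn{D_s = D_O / (1 - \ln \phi^2),}
#' which equals \eqn{D_O} at porosity 1 and decreases monotonically as the
#' sediment becomes less porous.
#'
#' @param phi Porosity, in `(0, 1]` (scalar or vector).
#' @param D_O Molecular diffusivity at in-situ temperature, cm^2 s^-1.
#' @return Effective diffusivity `D_s` in cm^2 s^-1, same length as `phi`.
#' @export
#' @examples
#' effective_diffusivity(0.8, 5e-6)
effective_diffusivity <- function(phi, D_O) {
  if (any(phi <= 0) || any(phi > 1)) {
    seep_abort("porosity must lie in (0, 1]", "seep_domain_error")
  }
  if (any(D_O <= 0)) {
    seep_abort("molecular diffusivity must be positive", "seep_domain_error")
  }
  D_O / (1 - log(phi^2))
}

#' Define a 1-D steady-state porewater transport system
#'
#' Bundles the sediment column geometry and the transport coefficients of the
#' steady-state porewater mass balance
#' \deqn{\frac{d}{dx}\Big(\phi D_s \frac{dC}{dx}\Big)
#'       - \frac{d(\phi \omega C)}{dx}
#'       + \phi\,\alpha\,(C_{OW} - C) - \phi R = 0,}
#' whose four terms are molecular diffusion, burial (sedimentation and
#' compaction), bioirrigation exchange with overlying water, and net
#' reaction. Depth `x` is cm below the sediment--water interface, positive
#' downward; the top boundary is Dirichlet at the overlying-water
#' concentration, the bottom boundary either zero-gradient (default) or a
#' fixed concentration.
#'
#' @param domain_bottom_cm Depth of the model bottom, cm.
#' @param dx_cm Node spacing, cm (default 0.1).
#' @param porosity Porosity, scalar or one value per node, in `(0, 1]`.
#' @param D_O_cm2_s Molecular diffusivity, cm^2 s^-1.
#' @param omega_cm_kyr Sedimentation rate, cm kyr^-1 (>= 0). The burial term
#'   uses the constant product `porosity[1] * omega` (steady compaction).
#' @param alpha_per_day Bioirrigation exchange coefficient, d^-1, scalar or
#'   per node (>= 0).
#' @param C_OW_mM Overlying-water concentration, mM (top boundary value and
#'   bioirrigation source).
#' @param bottom_boundary `"zero_gradient"` or `"fixed_value"`.
#' @param bottom_value_mM Bottom concentration, mM; required when
#'   `bottom_boundary = "fixed_value"`.
#' @param tortuosity If `TRUE` (default) apply [effective_diffusivity()];
#'   if `FALSE` use `D_O` unmodified.
#' @return An object of class `transport_system`.
#' @export
#' @examples
#' transport_system(domain_bottom_cm = 30, porosity = 0.8,
#'                  D_O_cm2_s = 5e-6, C_OW_mM = 28)
transport_system <- function(domain_bottom_cm,
                             dx_cm = 0.1,
                             porosity = 0.8,
                             D_O_cm2_s = 5e-6,
                             omega_cm_kyr = 0,
                             alpha_per_day = 0,
                             C_OW_mM = 28,
                             bottom_boundary = c("zero_gradient", "fixed_value"),
                             bottom_value_mM = NULL,
                             tortuosity = TRUE) {
  bottom_boundary <- match.arg(bottom_boundary)
  if (domain_bottom_cm <= 0 || dx_cm <= 0) {
    seep_abort("domain_bottom_cm and dx_cm must be positive", "seep_domain_error")
  }
  grid <- seq(0, domain_bottom_cm, by = dx_cm)
  if (abs(grid[length(grid)] - domain_bottom_cm) > 1e-9) {
    grid <- c(grid, domain_bottom_cm)
  }
  n <- length(grid)
  if (n < 3) {
    seep_abort("grid must have at least 3 nodes", "seep_domain_error")
  }
  expand <- function(v, nm) {
    if (length(v) == 1) v <- rep(v, n)
    if (length(v) != n) {
      seep_abort(sprintf("%s must be scalar or one value per node (%d)", nm, n),
                 "seep_validation_error")
    }
    v
  }
  phi <- expand(porosity, "porosity")
  alpha <- expand(alpha_per_day, "alpha_per_day")
  if (any(phi <= 0) || any(phi > 1)) {
    seep_abort("porosity must lie in (0, 1]", "seep_domain_error")
  }
  if (D_O_cm2_s <= 0) seep_abort("D_O_cm2_s must be positive", "seep_domain_error")
  if (omega_cm_kyr < 0) seep_abort("omega_cm_kyr must be >= 0", "seep_domain_error")
  if (any(alpha < 0)) seep_abort("alpha_per_day must be >= 0", "seep_domain_error")
  if (bottom_boundary == "fixed_value" && is.null(bottom_value_mM)) {
    seep_abort("bottom_value_mM required for fixed_value bottom boundary",
               "seep_validation_error")
  }
  D_s <- if (tortuosity) effective_diffusivity(phi, D_O_cm2_s) else rep(D_O_cm2_s, n)
  structure(
    list(grid = grid, dx = dx_cm, porosity = phi,
         D_O_cm2_s = D_O_cm2_s, D_s_cm2_s = D_s,
         omega_cm_kyr = omega_cm_kyr, alpha_per_day = alpha,
         C_OW_mM = C_OW_mM, bottom_boundary = bottom_boundary,
         bottom_value_mM = bottom_value_mM, tortuosity = tortuosity),
    class = "transport_system"
  )
}

#' @export
print.transport_system <- function(x, ...) {
  cat("<transport_system>\n")
  cat(sprintf("  domain: 0-%g cm, %d nodes (dx = %g cm)\n",
              max(x$grid), length(x$grid), x$dx))
  cat(sprintf("  porosity %s, D_O %g cm2/s (tortuosity %s)\n",
              if (length(unique(x$porosity)) == 1) format(x$porosity[1]) else "per-node",
              x$D_O_cm2_s, if (x$tortuosity) "on" else "off"))
  cat(sprintf("  omega %g cm/kyr, alpha %s /d\n", x$omega_cm_kyr,
              if (length(unique(x$alpha_per_day)) == 1)
                format(x$alpha_per_day[1]) else "per-node"))
  cat(sprintf("  top C_OW %g mM, bottom: %s%s\n", x$C_OW_mM, x$bottom_boundary,
              if (x$bottom_boundary == "fixed_value")
                sprintf(" (%g mM)", x$bottom_value_mM) else ""))
  invisible(x)
}

#' Map layered rates onto a transport grid
#'
#' Converts a piecewise-constant layered rate specification (columns
#' `depth_top_cm`, `depth_bottom_cm`, `rate_nmol_cm3_d`) into per-node rates
#' on the system grid, assigning each node the rate of the half-open layer
#' `[top, bottom)` containing it. Gaps inside the domain are zero-filled;
#' layers must not overlap.
#'
#' @param sys A [transport_system()].
#' @param layers A data frame of rate layers, or a numeric vector already on
#'   the grid (returned unchanged after a length check).
#' @return A numeric vector of rates (nmol cm^-3 d^-1), one per grid node.
#' @export
rates_on_grid <- function(sys, layers) {
  if (is.numeric(layers)) {
    if (length(layers) != length(sys$grid)) {
      seep_abort("rate vector length does not match grid", "seep_validation_error")
    }
    return(layers)
  }
  required <- c("depth_top_cm", "depth_bottom_cm", "rate_nmol_cm3_d")
  if (!all(required %in% names(layers))) {
    seep_abort(paste0("rate layers need columns: ", paste(required, collapse = ", ")),
               "seep_format_error")
  }
  layers <- dplyr::arrange(tibble::as_tibble(layers), .data$depth_top_cm)
  if (nrow(layers) > 1 &&
      any(layers$depth_top_cm[-1] < layers$depth_bottom_cm[-nrow(layers)] - 1e-12)) {
    seep_abort("rate layers overlap", "seep_validation_error")
  }
  r <- rep(0, length(sys$grid))
  for (i in seq_len(nrow(layers))) {
    inside <- sys$grid >= layers$depth_top_cm[i] - 1e-12 &
      sys$grid < layers$depth_bottom_cm[i] - 1e-12
    # the bottom-most layer also claims its closing node
    if (i == nrow(layers)) {
      inside <- inside | abs(sys$grid - layers$depth_bottom_cm[i]) < 1e-12
    }
    r[inside] <- layers$rate_nmol_cm3_d[i]
  }
  r
}

# Assemble the tridiagonal finite-difference operator for the steady-state
# balance; returns list(M, b_const, b_rate_coeff) with
#   M C = b_const + b_rate_coeff * R_mM_day  (element-wise on the RHS).
# Second-order central differences; zero-gradient bottom via a mirrored
# ghost node so the scheme stays second order at the boundary.
assemble_system <- function(sys) {
  n <- length(sys$grid)
  h <- sys$dx
  phi <- sys$porosity
  Dday <- sys$D_s_cm2_s * .SEC_PER_DAY
  pd <- phi * Dday
  pd_half <- (pd[-1] + pd[-n]) / 2        # pd_{i+1/2}, length n-1
  phiom <- phi[1] * sys$omega_cm_kyr / .DAYS_PER_KYR  # constant burial product

  M <- matrix(0, n, n)
  b_const <- numeric(n)
  # top Dirichlet
  M[1, 1] <- 1
  b_const[1] <- sys$C_OW_mM
  for (i in 2:(n - 1)) {
    lo <- pd_half[i - 1] / h^2 + phiom / (2 * h)
    up <- pd_half[i] / h^2 - phiom / (2 * h)
    M[i, i - 1] <- lo
    M[i, i + 1] <- up
    M[i, i] <- -(pd_half[i - 1] + pd_half[i]) / h^2 - phi[i] * sys$alpha_per_day[i]
    b_const[i] <- -phi[i] * sys$alpha_per_day[i] * sys$C_OW_mM
  }
  if (sys$bottom_boundary == "fixed_value") {
    M[n, n] <- 1
    b_const[n] <- sys$bottom_value_mM
    rate_rows <- c(FALSE, rep(TRUE, n - 2), FALSE)
  } else {
    # zero gradient: ghost node C_{n+1} = C_{n-1}, burial term vanishes
    M[n, n - 1] <- 2 * pd_half[n - 1] / h^2
    M[n, n] <- -2 * pd_half[n - 1] / h^2 - phi[n] * sys$alpha_per_day[n]
    b_const[n] <- -phi[n] * sys$alpha_per_day[n] * sys$C_OW_mM
    rate_rows <- c(FALSE, rep(TRUE, n - 1))
  }
  list(M = M, b_const = b_const, rate_rows = rate_rows)
}

#' Solve the steady-state transport model forward
#'
#' Computes the steady-state porewater concentration profile implied by a
#' volumetric reaction-rate profile, by solving the discretised balance (see
#' [transport_system()]) as a tridiagonal linear system with second-order
#' central differences. Rates are positive for consumption of the modeled
#' solute (sulfate reduction consumes sulfate; methane production is a
#' negative methane rate). Negative concentrations, if the imposed rates
#' exceed what transport can supply, are reported rather than clipped.
#'
#' @param sys A [transport_system()].
#' @param rates Rate profile in nmol cm^-3 d^-1: a per-node numeric vector or
#'   a layered data frame for [rates_on_grid()].
#' @param solute Solute name recorded in the output (default `"sulfate"`).
#' @return A tibble with columns `depth_cm` and `conc_mM`.
#' @export
#' @examples
#' sys <- transport_system(domain_bottom_cm = 30, C_OW_mM = 28)
#' lay <- tibble::tibble(depth_top_cm = 0, depth_bottom_cm = 5,
#'                       rate_nmol_cm3_d = 246)
#' prof <- solve_forward(sys, lay)
#' penetration_depth(prof, threshold_mM = 0.7)
solve_forward <- function(sys, rates, solute = "sulfate") {
  stopifnot(inherits(sys, "transport_system"))
  r <- rates_on_grid(sys, rates)
  if (any(!is.finite(r))) {
    seep_abort("rates must be finite", "seep_validation_error")
  }
  ops <- assemble_system(sys)
  r_mM_day <- r / 1000  # nmol cm^-3 d^-1 -> mM d^-1
  b <- ops$b_const
  b[ops$rate_rows] <- b[ops$rate_rows] +
    (sys$porosity * r_mM_day)[ops$rate_rows]
  C <- tryCatch(
    solve(ops$M, b),
    error = function(e) seep_abort(paste0("singular transport system: ",
                                          conditionMessage(e)),
                                   "seep_numerical_error")
  )
  tibble::tibble(depth_cm = sys$grid, conc_mM = as.numeric(C),
                 solute = solute)
}

#' Fit layer reaction rates to an observed concentration profile
#'
#' Inverse counterpart of [solve_forward()]: estimates the piecewise-constant
#' volumetric rate over a small number of contiguous depth layers that best
#' reproduces an observed steady-state concentration profile, in the
#' least-squares sense. Because the forward map is affine in the rates, the
#' fit is an exact linear least-squares problem: the design matrix columns
#' are forward solutions for unit rates in each layer (minus the rate-free
#' solution), computed once.
#'
#' @param sys A [transport_system()].
#' @param observed Observed concentrations: a numeric vector on the grid, or
#'   a data frame with `depth_cm` and `conc_mM` (matched to nearest nodes).
#' @param n_layers Number of equal-thickness layers (ignored when `breaks`
#'   given).
#' @param breaks Optional layer boundaries in cm (must start at 0 and end at
#'   the domain bottom).
#' @return An object of class `rate_fit`; see [tidy.rate_fit()] and
#'   [glance.rate_fit()].
#' @export
fit_rates_inverse <- function(sys, observed, n_layers = 3, breaks = NULL) {
  stopifnot(inherits(sys, "transport_system"))
  grid <- sys$grid
  if (is.data.frame(observed)) {
    if (!all(c("depth_cm", "conc_mM") %in% names(observed))) {
      seep_abort("observed needs columns depth_cm, conc_mM", "seep_format_error")
    }
    idx <- vapply(observed$depth_cm, function(z) which.min(abs(grid - z)), 1L)
    obs <- rep(NA_real_, length(grid))
    obs[idx] <- observed$conc_mM
  } else {
    if (length(observed) != length(grid)) {
      seep_abort("observed vector length does not match grid",
                 "seep_validation_error")
    }
    obs <- as.numeric(observed)
  }
  if (is.null(breaks)) {
    if (n_layers < 1 || n_layers > length(grid) - 2) {
      seep_abort("n_layers must be between 1 and the number of interior nodes",
                 "seep_domain_error")
    }
    breaks <- seq(0, max(grid), length.out = n_layers + 1)
  }
  breaks <- sort(unique(breaks))
  if (abs(breaks[1]) > 1e-9 || abs(breaks[length(breaks)] - max(grid)) > 1e-9) {
    seep_abort("breaks must span the domain (0 to domain bottom)",
               "seep_validation_error")
  }
  k <- length(breaks) - 1

  base <- solve_forward(sys, rep(0, length(grid)))$conc_mM
  G <- matrix(0, length(grid), k)
  layer_tbl <- tibble::tibble(depth_top_cm = breaks[-length(breaks)],
                              depth_bottom_cm = breaks[-1])
  # half-open [top, bottom) membership, same tolerance rule as
  # rates_on_grid() so layered forward runs and the fit design agree node
  # for node; the last layer closes the domain
  member <- integer(length(grid))
  for (j in seq_len(k)) {
    inside <- grid >= breaks[j] - 1e-12 & grid < breaks[j + 1] - 1e-12
    if (j == k) inside <- inside | abs(grid - breaks[k + 1]) < 1e-12
    member[inside] <- j
  }
  for (j in seq_len(k)) {
    G[, j] <- solve_forward(sys, as.numeric(member == j))$conc_mM - base
  }
  keep <- !is.na(obs)
  qrG <- qr(G[keep, , drop = FALSE])
  if (qrG$rank < k) {
    dead <- setdiff(seq_len(k), sort(qrG$pivot[seq_len(qrG$rank)]))
    seep_abort(paste0("rate layers unidentifiable from this profile: layer(s) ",
                      paste(dead, collapse = ", ")),
               "seep_estimation_error")
  }
  rate <- qr.coef(qrG, obs[keep] - base[keep])
  fitted <- base + as.numeric(G %*% rate)
  resid <- obs[keep] - fitted[keep]

  layer_tbl$rate_nmol_cm3_d <- as.numeric(rate)
  structure(
    list(layers = layer_tbl,
         fitted = tibble::tibble(depth_cm = grid, conc_mM = fitted),
         observed = tibble::tibble(depth_cm = grid[keep], conc_mM = obs[keep]),
         residual_norm = sqrt(sum(resid^2)),
         n_obs = sum(keep), sys = sys),
    class = "rate_fit"
  )
}

#' @export
print.rate_fit <- function(x, ...) {
  cat("<rate_fit> piecewise-constant rates,", nrow(x$layers), "layer(s)\n")
  print(x$layers)
  cat(sprintf("residual norm %.4g mM over %d observations\n",
              x$residual_norm, x$n_obs))
  invisible(x)
}

#' Tidy a fitted rate profile
#'
#' @param x A `rate_fit` from [fit_rates_inverse()].
#' @param ... Unused.
#' @return One row per layer: bounds, thickness, fitted volumetric rate, and
#'   the layer's depth-integrated rate in mmol m^-2 d^-1.
#' @export
tidy.rate_fit <- function(x, ...) {
  dplyr::mutate(x$layers,
                thickness_cm = .data$depth_bottom_cm - .data$depth_top_cm,
                integrated_mmol_m2_d = .data$rate_nmol_cm3_d *
                  .data$thickness_cm * .RATE_INT_TO_MMOL_M2_D)
}

#' Summarise a fitted rate profile
#'
#' @inheritParams tidy.rate_fit
#' @return A one-row tibble: layer count, observation count, residual norm
#'   and RMSE (mM).
#' @export
glance.rate_fit <- function(x, ...) {
  tibble::tibble(n_layers = nrow(x$layers), n_obs = x$n_obs,
                 residual_norm = x$residual_norm,
                 rmse = x$residual_norm / sqrt(x$n_obs))
}

#' Depth at which a solute falls to a background threshold
#'
#' Finds the shallowest depth where the linearly interpolated concentration
#' reaches `threshold_mM`. Used as the sulfate penetration-depth diagnostic:
#' a model whose predicted penetration greatly exceeds the observed depletion
#' depth indicates a transport process (e.g. upward fluid advection) missing
#' from the model.
#'
#' @param profile A data frame with `depth_cm` and `conc_mM` (e.g. from
#'   [solve_forward()]).
#' @param threshold_mM Background threshold, mM (> 0); 0.7 mM is the typical
#'   sulfate background.
#' @return A one-row tibble: `depth_cm` (the crossing, or the domain bottom
#'   when the profile never reaches the threshold), `beyond_domain` flag and
#'   `domain_bottom_cm`.
#' @export
penetration_depth <- function(profile, threshold_mM = 0.7) {
  if (threshold_mM <= 0) {
    seep_abort("threshold must be positive", "seep_domain_error")
  }
  stopifnot(all(c("depth_cm", "conc_mM") %in% names(profile)))
  profile <- dplyr::arrange(tibble::as_tibble(profile), .data$depth_cm)
  z <- profile$depth_cm
  C <- profile$conc_mM
  bottom <- max(z)
  if (C[1] <= threshold_mM) {
    return(tibble::tibble(depth_cm = z[1], beyond_domain = FALSE,
                          domain_bottom_cm = bottom))
  }
  below <- which(C <= threshold_mM)
  if (length(below) == 0) {
    return(tibble::tibble(depth_cm = bottom, beyond_domain = TRUE,
                          domain_bottom_cm = bottom))
  }
  i <- below[1]
  # linear interpolation between the bracketing nodes
  frac <- (C[i - 1] - threshold_mM) / (C[i - 1] - C[i])
  tibble::tibble(depth_cm = z[i - 1] + frac * (z[i] - z[i - 1]),
                 beyond_domain = FALSE, domain_bottom_cm = bottom)
}
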