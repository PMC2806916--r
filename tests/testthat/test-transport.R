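test_that("effective diffusivity follows the tortuosity correction", {
  expect_equal(effective_diffusivity(1, 5e-6), 5e-6)
  # 1 - ln(0.8^2) = 1.44629...
  expect_equal(effective_diffusivity(0.8, 5e-6), 5e-6 / (1 - log(0.64)),
               tolerance = 1e-12)
  expect_lt(effective_diffusivity(0.5, 5e-6), effective_diffusivity(0.9, 5e-6))
  expect_error(effective_diffusivity(0, 5e-6), class = "seep_domain_error")
  expect_error(effective_diffusivity(1.1, 5e-6), class = "seep_domain_error")
})

test_that("with no reaction, irrigation or burial the solution is linear", {
  sys <- transport_system(domain_bottom_cm = 20, dx_cm = 0.1, porosity = 0.8,
                          C_OW_mM = 28, bottom_boundary = "fixed_value",
                          bottom_value_mM = 4)
  sol <- solve_forward(sys, rep(0, length(sys$grid)))
  line <- 28 + (4 - 28) * sys$grid / 20
  expect_lt(max(abs(sol$conc_mM - line)), 1e-8 * 28)
})

test_that("constant rate with zero-gradient bottom matches the quadratic closed form", {
  L <- 10; n <- 400
  sys <- transport_system(domain_bottom_cm = L, dx_cm = L / n, porosity = 1,
                          C_OW_mM = 28, tortuosity = FALSE)
  R <- 50  # nmol cm^-3 d^-1
  sol <- solve_forward(sys, rep(R, length(sys$grid)))
  Dday <- 5e-6 * 86400
  closed <- 28 - (R / 1000 / Dday) * (L * sys$grid - sys$grid^2 / 2)
  expect_lt(max(abs(sol$conc_mM - closed) / 28), 1e-6)
})

test_that("bioirrigation relaxes the profile toward overlying water", {
  # closed form with fixed bottom: C = C_OW + (C_b - C_OW) sinh(x/l)/sinh(L/l)
  L <- 10; n <- 400
  D <- 5e-6 * 86400
  ell <- L  # well-resolved decay length
  alpha <- D / ell^2
  sys <- transport_system(domain_bottom_cm = L, dx_cm = L / n, porosity = 1,
                          C_OW_mM = 28, alpha_per_day = alpha,
                          tortuosity = FALSE,
                          bottom_boundary = "fixed_value", bottom_value_mM = 5)
  sol <- solve_forward(sys, rep(0, length(sys$grid)))
  closed <- 28 + (5 - 28) * sinh(sys$grid / ell) / sinh(L / ell)
  expect_lt(max(abs(sol$conc_mM - closed) / 28), 1e-6)

  # deep-domain relaxation: 10 decay lengths below the bottom disturbance
  # the profile is back at C_OW to much better than 0.1%
  sys2 <- transport_system(domain_bottom_cm = 30, dx_cm = 0.05, porosity = 1,
                           C_OW_mM = 28, alpha_per_day = D / 0.8^2,
                           tortuosity = FALSE,
                           bottom_boundary = "fixed_value", bottom_value_mM = 5)
  sol2 <- solve_forward(sys2, rep(0, length(sys2$grid)))
  mid <- which.min(abs(sys2$grid - (30 - 10 * 0.8)))
  expect_lt(abs(sol2$conc_mM[mid] - 28), 1e-3 * 28)
})

test_that("grid refinement converges at second order on the exponential-rate case", {
  L <- 20; C0 <- 28; R0 <- 150; lambda <- 3
  D <- effective_diffusivity(0.8, 5e-6) * 86400
  err_at <- function(n) {
    sys <- transport_system(domain_bottom_cm = L, dx_cm = L / n,
                            porosity = 0.8, C_OW_mM = C0)
    r <- R0 * exp(-sys$grid / lambda)
    sol <- solve_forward(sys, r)
    truth <- closed_form_exp_rate(sys$grid, C0, D, R0, lambda, L)
    max(abs(sol$conc_mM - truth))
  }
  e1 <- err_at(100); e2 <- err_at(200)
  order <- log2(e1 / e2)
  expect_gt(order, 1.9)
})

test_that("the forward map is affine in the rates", {
  sys <- transport_system(domain_bottom_cm = 15, dx_cm = 0.1, porosity = 0.8,
                          C_OW_mM = 28, alpha_per_day = 0.05,
                          omega_cm_kyr = 31)
  n <- length(sys$grid)
  set.seed(7)
  r1 <- runif(n, 0, 100); r2 <- runif(n, 0, 50)
  a <- 1.7; b <- -0.4
  lhs <- solve_forward(sys, a * r1 + b * r2)$conc_mM
  s1 <- solve_forward(sys, r1)$conc_mM
  s2 <- solve_forward(sys, r2)$conc_mM
  s0 <- solve_forward(sys, rep(0, n))$conc_mM
  rhs <- a * s1 + b * s2 - (a + b - 1) * s0
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("flux into the domain balances the integrated sink (no irrigation/burial)", {
  sys <- transport_system(domain_bottom_cm = 20, dx_cm = 0.01, porosity = 0.8,
                          C_OW_mM = 28)
  r <- 120 * exp(-sys$grid / 2.5)
  sol <- solve_forward(sys, r)
  phi <- sys$porosity[1]
  Dday <- sys$D_s_cm2_s[1] * 86400
  h <- sys$dx
  # discrete influx at the interface (first face flux plus the top half-cell
  # sink that sits inside the Dirichlet row)
  flux_in <- phi * Dday * (sol$conc_mM[1] - sol$conc_mM[2]) / h +
    phi * r[1] / 1000 * h / 2                      # umol cm^-2 d^-1, downward
  sink <- sum(phi * r / 1000) * h -
    phi * h * (r[1] + r[length(r)]) / 2000         # trapezoid, umol cm^-2 d^-1
  expect_equal(flux_in, sink, tolerance = 1e-6)
})

test_that("noise-free inverse fitting recovers piecewise-constant rates exactly", {
  sys <- transport_system(domain_bottom_cm = 30, dx_cm = 0.1, C_OW_mM = 28)
  lay <- tibble::tibble(depth_top_cm = c(0, 5, 10),
                        depth_bottom_cm = c(5, 10, 30),
                        rate_nmol_cm3_d = c(60, 25, 4))
  truth <- solve_forward(sys, lay)
  fit <- fit_rates_inverse(sys, truth$conc_mM, breaks = c(0, 5, 10, 30))
  expect_equal(fit$layers$rate_nmol_cm3_d, lay$rate_nmol_cm3_d,
               tolerance = 1e-6)
  expect_lt(glance(fit)$residual_norm, 1e-8)
  td <- tidy(fit)
  expect_equal(td$integrated_mmol_m2_d,
               c(60 * 5, 25 * 5, 4 * 20) * 0.01, tolerance = 1e-6)
})

test_that("a flat profile at C_OW yields zero rates", {
  sys <- transport_system(domain_bottom_cm = 20, dx_cm = 0.2, C_OW_mM = 28)
  fit <- fit_rates_inverse(sys, rep(28, length(sys$grid)), n_layers = 2)
  expect_equal(fit$layers$rate_nmol_cm3_d, c(0, 0), tolerance = 1e-10)
})

test_that("inverse fitting accepts observations as depth/concentration tables", {
  sys <- transport_system(domain_bottom_cm = 30, dx_cm = 0.1, C_OW_mM = 28)
  lay <- tibble::tibble(depth_top_cm = 0, depth_bottom_cm = 30,
                        rate_nmol_cm3_d = 12)
  truth <- solve_forward(sys, lay)
  obs <- truth[seq(1, nrow(truth), by = 15), ]  # sparse core sections
  fit <- fit_rates_inverse(sys, obs, n_layers = 1)
  expect_equal(fit$layers$rate_nmol_cm3_d, 12, tolerance = 1e-6)
})

test_that("penetration depth interpolates linearly and flags beyond-domain profiles", {
  prof <- tibble::tibble(depth_cm = c(0, 10), conc_mM = c(28, 0))
  pd <- penetration_depth(prof, 0.7)
  expect_equal(pd$depth_cm, 10 * (28 - 0.7) / 28)
  expect_false(pd$beyond_domain)

  flat <- tibble::tibble(depth_cm = c(0, 10), conc_mM = c(28, 28))
  pd2 <- penetration_depth(flat, 0.7)
  expect_true(pd2$beyond_domain)
  expect_equal(pd2$depth_cm, 10)

  low <- tibble::tibble(depth_cm = c(0, 10), conc_mM = c(0.5, 0.1))
  expect_equal(penetration_depth(low, 0.7)$depth_cm, 0)
  expect_error(penetration_depth(prof, -1), class = "seep_domain_error")
})

test_that("degenerate transport inputs raise typed errors", {
  expect_error(transport_system(domain_bottom_cm = 30, porosity = 1.2),
               class = "seep_domain_error")
  expect_error(transport_system(domain_bottom_cm = 0.1, dx_cm = 0.1),
               class = "seep_domain_error")
  sys <- transport_system(domain_bottom_cm = 10, dx_cm = 0.5)
  expect_error(solve_forward(sys, rep(NA_real_, length(sys$grid))),
               class = "seep_validation_error")
  lay_gap <- tibble::tibble(depth_top_cm = c(0, 4), depth_bottom_cm = c(3, 6),
                            rate_nmol_cm3_d = c(10, 5))
  # gaps are zero-filled, not an error
  r <- rates_on_grid(sys, lay_gap)
  expect_equal(r[sys$grid > 3 & sys$grid < 4], 0)
  lay_overlap <- tibble::tibble(depth_top_cm = c(0, 2),
                                depth_bottom_cm = c(3, 6),
                                rate_nmol_cm3_d = c(10, 5))
  expect_error(rates_on_grid(sys, lay_overlap), class = "seep_validation_error")
})
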