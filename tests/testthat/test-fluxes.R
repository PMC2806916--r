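test_that("top-interval diffusive flux reproduces the hand-computed value and sign convention", {
  prof <- tibble::tibble(depth_cm = c(0, 3), conc_mM = c(28, 10))
  f <- diffusive_flux_top(prof, phi = 0.9, D_s = 5e-6)
  # 0.9 * 5e-6 cm2/s * (-6 mM/cm) * 86400 * 1e4 * 1e-3 = -23.33 downward
  expect_equal(f$flux_mmol_m2_d, 0.9 * 5e-6 * (-6) * 86400 * 10,
               tolerance = 1e-12)
  expect_lt(f$flux_mmol_m2_d, 0)  # sulfate diffuses into the sediment

  # methane increasing downward escapes upward: positive flux
  meth <- tibble::tibble(depth_cm = c(0, 3), conc_mM = c(0.1, 2))
  expect_gt(diffusive_flux_top(meth, 0.9, 5e-6, solute = "methane")$flux_mmol_m2_d, 0)

  flat <- tibble::tibble(depth_cm = c(0, 3), conc_mM = c(5, 5))
  expect_equal(diffusive_flux_top(flat, 0.9, 5e-6)$flux_mmol_m2_d, 0)
})

test_that("flux guards: too few depths, zero spacing, porosity toggle", {
  expect_error(diffusive_flux_top(tibble::tibble(depth_cm = 0, conc_mM = 28),
                                  0.9, 5e-6),
               class = "seep_validation_error")
  expect_error(diffusive_flux_top(tibble::tibble(depth_cm = c(1, 1),
                                                 conc_mM = c(28, 10)),
                                  0.9, 5e-6),
               class = "seep_domain_error")
  prof <- tibble::tibble(depth_cm = c(0, 3), conc_mM = c(28, 10))
  with_phi <- diffusive_flux_top(prof, 0.8, 5e-6)
  without <- diffusive_flux_top(prof, 0.8, 5e-6, porosity_correction = FALSE)
  expect_equal(with_phi$flux_mmol_m2_d, 0.8 * without$flux_mmol_m2_d)
})

test_that("depth-integrated rates use trapezoids with the 0.01 unit factor", {
  const <- tibble::tibble(depth_cm = c(0, 20), rate_nmol_cm3_d = c(100, 100))
  expect_equal(depth_integrated_rate(const, 0, 20)$value_mmol_m2_d, 20)

  tri <- tibble::tibble(depth_cm = c(0, 10), rate_nmol_cm3_d = c(200, 0))
  expect_equal(depth_integrated_rate(tri, 0, 10)$value_mmol_m2_d, 10)

  zero <- tibble::tibble(depth_cm = c(0, 10), rate_nmol_cm3_d = 0)
  expect_equal(depth_integrated_rate(zero, 0, 10)$value_mmol_m2_d, 0)
})

test_that("integration is additive over adjacent windows and averages replicates", {
  r <- tibble::tibble(depth_cm = c(0, 5, 10, 15), rate_nmol_cm3_d = c(80, 40, 20, 10))
  whole <- depth_integrated_rate(r, 0, 15)$value_mmol_m2_d
  parts <- depth_integrated_rate(r, 0, 7)$value_mmol_m2_d +
    depth_integrated_rate(r, 7, 15)$value_mmol_m2_d
  expect_equal(whole, parts, tolerance = 1e-12)

  dup <- dplyr::bind_rows(r, dplyr::mutate(r, rate_nmol_cm3_d = rate_nmol_cm3_d + 10))
  averaged <- depth_integrated_rate(dup, 0, 15)$value_mmol_m2_d
  expect_equal(averaged, depth_integrated_rate(
    dplyr::mutate(r, rate_nmol_cm3_d = rate_nmol_cm3_d + 5), 0, 15)$value_mmol_m2_d)

  expect_error(depth_integrated_rate(r, 20, 30), class = "seep_validation_error")
  expect_error(depth_integrated_rate(r, 5, 5), class = "seep_domain_error")
})

test_that("flux/rate consistency flags follow the 3x agreement factor", {
  fl <- function(v) tibble::tibble(solute = "sulfate", flux_mmol_m2_d = v,
                                   depth_shallow_cm = 1.5, depth_deep_cm = 4.5)
  rt <- function(v) tibble::tibble(process = "sulfate_reduction",
                                   value_mmol_m2_d = v, z_min_cm = 0, z_max_cm = 25)
  expect_equal(flux_rate_consistency(fl(-12), rt(12))$flag, "agree")
  r <- flux_rate_consistency(fl(-12), rt(1))
  expect_equal(r$flag, "rate_underestimated")
  expect_equal(r$ratio, 12)
  expect_equal(flux_rate_consistency(fl(-1), rt(12))$flag, "rate_overestimated")
  degenerate <- flux_rate_consistency(fl(0), rt(0))
  expect_equal(degenerate$ratio, 1)
  expect_equal(degenerate$flag, "agree")
  bad <- tibble::tibble(process = "methane_oxidation", value_mmol_m2_d = 1,
                        z_min_cm = 0, z_max_cm = 25)
  expect_error(flux_rate_consistency(fl(-12), bad), class = "seep_validation_error")
})

test_that("forward-model flux balances the depth-integrated rate (steady-state QC)", {
  # unit porosity: the top flux magnitude must equal the integrated sink
  sys <- transport_system(domain_bottom_cm = 20, dx_cm = 0.01, porosity = 1,
                          C_OW_mM = 28, tortuosity = FALSE)
  r <- tibble::tibble(depth_cm = sys$grid,
                      rate_nmol_cm3_d = 100 * exp(-sys$grid / 3))
  sol <- solve_forward(sys, r$rate_nmol_cm3_d)
  flux <- diffusive_flux_top(sol[1:2, ], phi = 1, D_s = sys$D_s_cm2_s[1])
  rate <- depth_integrated_rate(r, 0, 20)
  expect_equal(abs(flux$flux_mmol_m2_d), rate$value_mmol_m2_d,
               tolerance = 0.01)
  expect_equal(flux_rate_consistency(flux, rate)$flag, "agree")
})

test_that("mRNA persistence time is linear in offset and inverse in sedimentation rate", {
  expect_equal(mrna_persistence_time(5, 31)$years_floor, 161)
  expect_equal(mrna_persistence_time(5, 31)$years_exact, 5 / 31 * 1000)
  expect_equal(mrna_persistence_time(0, 31)$years_exact, 0)
  expect_equal(mrna_persistence_time(31, 31)$years_exact, 1000)
  expect_equal(mrna_persistence_time(10, 31)$years_exact,
               2 * mrna_persistence_time(5, 31)$years_exact)
  expect_equal(mrna_persistence_time(5, 62)$years_exact,
               mrna_persistence_time(5, 31)$years_exact / 2)
  expect_error(mrna_persistence_time(5, 0), class = "seep_domain_error")
})

test_that("methane saturation flags are strict lower-bound markers", {
  prof <- tibble::tibble(depth_cm = 1:3, conc_mM = c(0.5, 1.5, 3.0))
  f <- flag_saturation(prof)
  expect_equal(f$saturated, c(FALSE, TRUE, TRUE))
  expect_equal(f$annotation, c(NA, "lower bound", "lower bound"))
  expect_false(flag_saturation(tibble::tibble(conc_mM = 1.2))$saturated)
  empty <- flag_saturation(tibble::tibble(conc_mM = numeric(0)))
  expect_equal(nrow(empty), 0)
})
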