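test_that("rate profiles follow the exponential shape and outside scaling", {
  grid <- seq(0, 30, by = 0.5)
  scn <- core_scenario("mat", R0_nmol_cm3_d = 250, decay_length_cm = 2.5)
  r <- make_rate_profile(scn, grid)
  expect_equal(r$rate_nmol_cm3_d[1], 250)
  expect_equal(r$rate_nmol_cm3_d[grid == 2.5], 250 * exp(-1))
  zero <- make_rate_profile(core_scenario("mat", R0_nmol_cm3_d = 0), grid)
  expect_true(all(zero$rate_nmol_cm3_d == 0))
  out <- make_rate_profile(core_scenario("outside", R0_nmol_cm3_d = 250,
                                         decay_length_cm = 2.5), grid)
  expect_equal(out$rate_nmol_cm3_d, 0.1 * r$rate_nmol_cm3_d)
})

test_that("concentration generator is exact without noise and calibrated with it", {
  sys <- transport_system(domain_bottom_cm = 20, dx_cm = 0.02, C_OW_mM = 28)
  scn0 <- core_scenario("mat", noise_fraction = 0, seed = 4)
  rates <- make_rate_profile(scn0, sys$grid)
  clean <- make_concentration_profile(scn0, sys, rates$rate_nmol_cm3_d)
  truth <- solve_forward(sys, rates$rate_nmol_cm3_d)
  expect_equal(clean$conc_mM, truth$conc_mM)

  scn <- core_scenario("mat", noise_fraction = 0.03, seed = 4)
  noisy <- make_concentration_profile(scn, sys, rates$rate_nmol_cm3_d)
  ok <- noisy$conc_true_mM > 1   # away from the truncation at zero
  rel <- noisy$conc_mM[ok] / noisy$conc_true_mM[ok]
  expect_gt(sd(rel), 0.027)
  expect_lt(sd(rel), 0.033)
  expect_true(all(noisy$conc_mM >= 0))
})

test_that("generators are pure functions of parameters and seed", {
  sys <- transport_system(domain_bottom_cm = 10, dx_cm = 0.1, C_OW_mM = 28)
  scn <- core_scenario("edge", noise_fraction = 0.03, seed = 9)
  rates <- make_rate_profile(scn, sys$grid)
  a <- make_concentration_profile(scn, sys, rates$rate_nmol_cm3_d)
  b <- make_concentration_profile(scn, sys, rates$rate_nmol_cm3_d)
  expect_identical(a, b)
  scn2 <- scn; scn2$seed <- 10L
  c <- make_concentration_profile(scn2, sys, rates$rate_nmol_cm3_d)
  expect_false(identical(a$conc_mM, c$conc_mM))

  gm <- default_group_map("bacteria")
  rp <- c("Eel-2" = 0.5, "Alphaproteobacteria" = 0.5)
  t1 <- make_community(scn, 60, rp, gm)
  t2 <- make_community(scn, 60, rp, gm)
  expect_identical(t1$counts, t2$counts)
})

test_that("community draws respect degenerate and average-case expectations", {
  gm <- default_group_map("bacteria")
  scn <- core_scenario("mat", seed = 2)
  one <- make_community(scn, 50, c("Eel-2" = 1), gm)
  expect_equal(one$counts$count, 50L)

  # mean SRB fraction across seeded replicates tracks the designed 50%
  rp <- c("Eel-2" = 0.5, "Alphaproteobacteria" = 0.5)
  pcts <- vapply(1:200, function(s) {
    scn_s <- core_scenario("mat", seed = s)
    cc <- make_community(scn_s, 60, rp, gm, concentration = 50)
    fr <- group_fractions(cc$counts, gm)
    srb <- fr$by_role$pct[fr$by_role$role == "SRB"]
    if (length(srb) == 0) 0 else srb
  }, numeric(1))
  expect_gt(mean(pcts), 47)
  expect_lt(mean(pcts), 53)

  expect_error(make_community(scn, 60, c("Eel-2" = 0.6, "SEEP-SRB1" = 0.3), gm),
               class = "seep_validation_error")
})

test_that("OTU pool sampling saturates observed richness and supports Chao1 bounds", {
  # deep uniform sampling recovers the whole pool (coupon collector)
  hits <- vapply(1:100, function(s)
    length(make_otu_abundances(12, "uniform", 1200, seed = s)), 1L)
  expect_true(all(hits == 12))

  single <- make_otu_abundances(10, "uniform", 1, seed = 1)
  expect_equal(single, 1L)
  expect_equal(chao1(single)$n1, 1)

  for (s in 1:20) {
    sizes <- make_otu_abundances(30, "log_series", 50, seed = s)
    r <- chao1(sizes)
    expect_gte(r$s_chao1, r$s_obs)
    expect_lte(r$s_obs, 30)
  }
})

test_that("mean Chao1 approaches true richness as sampling deepens", {
  mean_chao <- function(n) {
    mean(vapply(1:40, function(s)
      chao1(make_otu_abundances(20, "uniform", n, seed = s))$s_chao1,
      numeric(1)))
  }
  shallow <- mean_chao(15)
  deep <- mean_chao(400)
  expect_lt(abs(deep - 20), abs(shallow - 20))
  expect_lt(abs(deep - 20), 1)
})

test_that("a full synthetic transect reproduces the study architecture", {
  tr <- simulate_transect(seed = 3, concentration = Inf, noise_fraction = 0)
  s <- tr$summary
  surf <- s[s$layer == "surface", ]
  # sulfate flux magnitude and SRB fraction both collapse outside the mat
  expect_equal(surf$core_id[which.min(surf$abs_sulfate_flux)], "outside")
  expect_equal(surf$core_id[which.min(surf$pct_SRB_clones)], "outside")
  expect_gt(min(surf$pct_SRB_clones[surf$core_id != "outside"]), 50)
  expect_lt(surf$pct_SRB_clones[surf$core_id == "outside"], 20)
  # deep communities converge across cores
  deep <- s[s$layer == "deep", ]
  expect_equal(length(unique(round(deep$pct_SRB_clones))), 1)
  # mRNA encodings: absent only at the surface outside the mat
  expect_equal(surf$dsrAB_present[surf$core_id == "outside"], 0)
  expect_true(all(deep$dsrAB_present == 100))

  conc <- tr$concordance
  surf_conc <- conc[conc$layer == "surface", ]
  expect_true(all(surf_conc$concordant_fraction == 1))

  # profile architecture: sulfate depleted within the upper few cm under the
  # mat, essentially non-depleting outside it
  sul <- tr$profiles[tr$profiles$solute == "sulfate", ]
  mat7 <- sul$conc_mM[sul$core_id == "mat" & abs(sul$depth_cm - 7) < 0.01]
  out20 <- sul$conc_mM[sul$core_id == "outside" & abs(sul$depth_cm - 20) < 0.01]
  expect_lt(mat7, 4)
  expect_gt(out20, 20)
})

test_that("transect isotope profiles classify as designed", {
  tr <- simulate_transect(seed = 3, concentration = Inf, noise_fraction = 0)
  iso <- tr$isotopes
  mat <- classify_trend(iso[iso$core_id == "mat", ])
  expect_equal(mat$interpretation, "net methane oxidation")
  edge <- classify_trend(iso[iso$core_id == "edge", ])
  expect_equal(edge$interpretation, "net methanogenesis")
  out <- classify_trend(iso[iso$core_id == "outside", ])
  expect_equal(out$trend, "indeterminate")
})
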