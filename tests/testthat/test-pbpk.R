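test_that("Nernst-Brunner rate matches hand arithmetic and its fixed points", {
  # equilibrium and exhausted-mass fixed points
  expect_equal(nernst_brunner_rate(10, 1e6, 50, 50, 5e-6, 3e-3, 1.2, 450), 0)
  expect_equal(nernst_brunner_rate(0, 1e6, 50, 0, 5e-6, 3e-3, 1.2, 450), 0)

  # single sphere, hand-evaluated (D/h) * 4 pi r^2 * Cs in nmol/h:
  # choose the amount so the sphere radius is exactly 2 um
  r_cm <- 2e-4; rho <- 1.2; mw <- 400
  amount_nmol <- (4 / 3) * pi * r_cm^3 * rho / mw * 1e9
  d <- 6e-6; hh <- 30e-4; cs <- 80
  hand <- 3600 * (d / hh) * 4 * pi * r_cm^2 * cs
  expect_equal(nernst_brunner_rate(amount_nmol, 1, cs, 0, d, hh, rho, mw),
               hand, tolerance = 1e-12)

  # supersaturation clips to zero unless asked otherwise
  expect_equal(nernst_brunner_rate(10, 1e6, 50, 60, d, hh, rho, mw), 0)
  expect_lt(nernst_brunner_rate(10, 1e6, 50, 60, d, hh, rho, mw, clip = FALSE), 0)
})

test_that("model assembly enforces the structural invariants", {
  mdl <- build_lung_model()
  expect_equal(mdl$permeability_cm_s[17:24],
               rep(mdl$compound$permeability_tb_cm_s *
                     mdl$compound$alveolar_permeability_multiplier, 8))
  expect_equal(mdl$permeability_cm_s[1:16],
               rep(mdl$compound$permeability_tb_cm_s, 16))
  # TB perfused by the bronchial fraction, alveoli by the full cardiac output
  expect_equal(sum(mdl$blood_flow_ml_h[1:16]),
               mdl$cardiac_output_ml_h * mdl$bronchial_flow_fraction)
  expect_equal(sum(mdl$blood_flow_ml_h[17:24]), mdl$cardiac_output_ml_h)
  # constant flow per tissue volume within the alveolar region
  m <- mdl$morphometry
  tv <- m$epithelium_volume_ml + m$subepithelium_volume_ml
  expect_equal(stats::sd(mdl$blood_flow_ml_h[17:24] / tv[17:24]), 0,
               tolerance = 1e-12)

  bad <- default_airway_morphometry()
  bad$mucociliary_rate_per_h[20] <- 1
  expect_error(build_lung_model(bad), "alveolar")
  expect_error(compound_params(fu_plasma = -1), "positive")
})

test_that("solution doses bypass dissolution entirely", {
  mdl <- build_lung_model()
  sim <- simulate_lung(mdl, dose_event(1e4, formulation = "solution"),
                       t_end_h = 2, dt_out_h = 0.5)
  expect_true(all(sim$solid_nmol == 0))
  sim2 <- simulate_lung(mdl, dose_event(1e4, formulation = "solid_particles"),
                        t_end_h = 2, dt_out_h = 0.5)
  expect_gt(sum(sim2$solid_nmol[1, ]), 0)
})

test_that("mass balance holds to 1e-6 across a random parameter sweep", {
  set.seed(31)
  for (i in 1:5) {
    cp <- compound_params(
      solubility_cs_um = runif(1, 5, 500),
      permeability_tb_cm_s = 10^runif(1, -7, -5),
      fu_plasma = runif(1, 0.05, 1), fu_tissue = runif(1, 0.05, 1),
      kp_epithelium = runif(1, 1, 20), kp_subepithelium = runif(1, 1, 20),
      k_in_per_h = runif(1, 0.1, 5), k_out_per_h = runif(1, 0.1, 5),
      cl_ml_h = runif(1, 1e4, 1e5), vss_ml = runif(1, 5e4, 5e5),
      initial_radius_um = runif(1, 0.5, 3))
    mdl <- build_lung_model(compound = cp)
    frm <- if (i %% 2) "solid_particles" else "solution"
    sim <- simulate_lung(mdl, dose_event(10^runif(1, 3, 6), formulation = frm),
                         t_end_h = 6, dt_out_h = 1)
    expect_lt(sim$mass_balance_rel_error, 1e-6)
    expect_true(all(sim$elf_conc_um >= 0))
  }
})

test_that("single-generation permeability-only run matches the closed form", {
  # trachea-only solution dose; epithelium made an effective sink via a huge
  # partition coefficient; mucociliary clearance switched off
  m <- default_airway_morphometry()
  m$mucociliary_rate_per_h <- 0
  cp <- compound_params(permeability_tb_cm_s = 1e-6,
                        kp_epithelium = 1e9, fu_plasma = 1,
                        k_in_per_h = 1e-6, k_out_per_h = 1e-6)
  mdl <- build_lung_model(m, cp)
  w <- c(1, rep(0, 23))
  dose <- dose_event(1000, deposition_fraction_tb = 1,
                     deposition_fraction_alveolar = 0,
                     formulation = "solution", deposition_weights = w)
  sim <- simulate_lung(mdl, dose, t_end_h = 1, dt_out_h = 0.05)
  k <- 3600 * cp$permeability_tb_cm_s * m$surface_area_cm2[1] / m$elf_volume_ml[1]
  c0 <- 1000 / m$elf_volume_ml[1]
  expected <- c0 * exp(-k * sim$time_h)
  expect_lt(max(abs(sim$elf_conc_um[, 1] - expected) / expected), 1e-6)
})

test_that("a closed system holds its ELF concentration constant", {
  m <- default_airway_morphometry()
  m$mucociliary_rate_per_h <- 0
  cp <- compound_params(permeability_tb_cm_s = 1e-30)
  mdl <- build_lung_model(m, cp)
  sim <- simulate_lung(mdl, dose_event(1000, formulation = "solution"),
                       t_end_h = 4, dt_out_h = 1)
  for (g in c(1, 10, 20)) {
    expect_lt(max(abs(sim$elf_conc_um[, g] - sim$elf_conc_um[1, g])),
              1e-9 * sim$elf_conc_um[1, g])
  }
})

test_that("dissolved fraction is non-decreasing below solubility", {
  mdl <- build_lung_model(compound = compound_params(solubility_cs_um = 1e5))
  sim <- simulate_lung(mdl, dose_event(1e4), t_end_h = 6, dt_out_h = 0.25)
  expect_false(sim$supersaturation_clipped)
  solid_total <- rowSums(sim$solid_nmol)
  expect_true(all(diff(solid_total) <= 1e-9 * sim$dose$total_dose_nmol))
})

test_that("doubling the dose doubles every concentration profile", {
  mdl <- build_lung_model()
  s1 <- simulate_lung(mdl, dose_event(1e3, formulation = "solution"),
                      t_end_h = 4, dt_out_h = 0.5)
  s2 <- simulate_lung(mdl, dose_event(2e3, formulation = "solution"),
                      t_end_h = 4, dt_out_h = 0.5)
  sel <- s1$elf_conc_um > 1e-12
  expect_equal(s2$elf_conc_um[sel] / s1$elf_conc_um[sel],
               rep(2, sum(sel)), tolerance = 1e-6)
  expect_equal(max(s2$plasma_conc_um) / max(s1$plasma_conc_um), 2,
               tolerance = 1e-6)
})

test_that("regional summaries respect weighted-mean ordering and degenerate regions", {
  mdl <- build_lung_model()
  sim <- simulate_lung(mdl, dose_event(1e4), t_end_h = 12, dt_out_h = 0.25)
  rs <- elf_region_summary(sim)
  expect_setequal(rs$region, c("upper_tb", "lower_tb", "alveolar"))
  # default 70/30 deposition: upper TB peak exceeds alveolar peak
  expect_gt(rs$cmax_um[rs$region == "upper_tb"],
            rs$cmax_um[rs$region == "alveolar"])

  one <- elf_region_summary(sim, regions = list(g5 = 5))
  expect_equal(one$cmax_um, max(sim$elf_conc_um[, 5]))
  expect_error(elf_region_summary(sim, regions = list(empty = integer(0))),
               "empty region")
})

test_that("exposure mapping reproduces the ratio arithmetic of a 27.9 uM IC50", {
  conc <- 100 / 3^(0:8)
  fit <- fit_ic50(conc, hill_fraction(conc, 27.9, 1), method = "fourpl")
  cmax <- c(upper_tb = 14, lower_tb = 3.2, alveolar = 0.02)
  risk <- map_exposure_to_ic50(cmax, fit)
  expect_equal(risk$exposure_ratio[1], 14 / fit$ic50_um, tolerance = 1e-12)
  expect_equal(risk$exposure_ratio[1], 0.50, tolerance = 0.02)
  expect_equal(risk$exposure_ratio[2], 0.115, tolerance = 0.02)
  expect_equal(risk$exposure_ratio[3], 7.2e-4, tolerance = 0.05)
  expect_equal(risk$at_risk, c(TRUE, FALSE, FALSE))
  # predicted response at Cmax = IC50 is 0.5 under the 4PL
  mid <- map_exposure_to_ic50(c(r = fit$ic50_um), fit)
  expect_equal(mid$predicted_response, 0.5, tolerance = 1e-3)

  # unestablished fit: regions flagged, never at risk
  flat <- fit_ic50(conc, rep(1, 9))
  r2 <- map_exposure_to_ic50(cmax, flat)
  expect_true(all(r2$note == "no_in_vitro_effect_detected"))
  expect_false(any(r2$at_risk))
})
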