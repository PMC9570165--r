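# a bare-bones subject for unit-conversion oracles
unit_subject <- function(abundance = c(CYP1A2 = 100, CYP2C9 = 0,
                                       CYP2C19 = 0, CYP2D6 = 0, CYP3A4 = 0),
                         mppgl = 40, liver_mass = 1650, hct = 45,
                         weight = 70, q_h = 90) {
  structure(list(sex = "male", age = 40, height = 170, weight = weight,
                 bmi = weight / 1.7^2, haematocrit = hct,
                 cyp_abundance = abundance, albumin_ratio = 1,
                 mppgl = mppgl, liver_mass = liver_mass,
                 hepatic_blood_flow = q_h), class = "subject")
}

test_compound <- function(clint_per_pmol = c(CYP1A2 = 1), ka = 2,
                          fu = 1, bp = 1, vss = 1, fa_fg = 1,
                          clint_other = 0, cl_renal = 0, mm = NULL) {
  compound_profile("probe", dose_mg = 100, ka = ka, fa_fg = fa_fg, fu = fu,
                   bp_ratio = bp, vss = vss,
                   clint_per_pmol = clint_per_pmol,
                   clint_other = clint_other, cl_renal = cl_renal, mm = mm)
}

test_that("IVIVE scale-up reproduces the unit-conversion oracle", {
  sub <- unit_subject()
  cmp <- test_compound(c(CYP1A2 = 1))
  # 100 pmol/mg * 1 uL/min/pmol * 40 mg/g * 1650 g = 6.6 L/min = 396 L/h
  expect_equal(whole_liver_clint(sub, cmp), 396)
  expect_equal(whole_liver_clint(sub, test_compound(c(CYP1A2 = 0))), 0)
  sub2 <- unit_subject(abundance = c(CYP1A2 = 200, CYP2C9 = 0, CYP2C19 = 0,
                                     CYP2D6 = 0, CYP3A4 = 0))
  expect_equal(whole_liver_clint(sub2, cmp),
               2 * whole_liver_clint(sub, cmp))
})

test_that("well-stirred clearance matches its formula and asymptotes", {
  expect_equal(hepatic_clearance(500, 0.1, 90), 90 * 50 / 140)
  expect_equal(hepatic_clearance(1e9, 1, 90), 90, tolerance = 1e-6)
  expect_equal(hepatic_clearance(1, 0.1, 90), 0.1, tolerance = 2e-3)
  expect_error(hepatic_clearance(100, 0.5, 0), "> 0")
})

test_that("single-dose trapezoidal AUC matches the closed form", {
  sub <- unit_subject()
  cmp <- test_compound(c(CYP1A2 = 0.05), fu = 0.5, vss = 2)
  reg <- dose_regimen(100, window_h = 24)
  prof <- simulate_regimen(sub, cmp, reg)
  m <- pk_metrics(prof, c(0, 24))
  expect_equal(m$auc, auc_window_linear(sub, cmp, 24, 100),
               tolerance = 5e-3)
  expect_equal(m$cmax, max(prof$conc))
  # Bateman tmax oracle: ln(ka/ke)/(ka-ke)
  p_ka <- cmp$ka
  ke <- (hepatic_clearance(whole_liver_clint(sub, cmp), 0.5, 90) * 1) /
    (2 * sub$weight)
  expect_equal(m$tmax, log(p_ka / ke) / (p_ka - ke), tolerance = 0.05)
})

test_that("linear PK is dose-proportional and superposition holds", {
  sub <- unit_subject()
  cmp <- test_compound(c(CYP1A2 = 0.1), fu = 0.6, vss = 1.5)
  r1 <- pk_metrics(simulate_regimen(sub, cmp, dose_regimen(100, window_h = 48)),
                   c(0, 48))
  r2 <- pk_metrics(simulate_regimen(sub, cmp, dose_regimen(200, window_h = 48)),
                   c(0, 48))
  expect_equal(r2$auc / r1$auc, 2, tolerance = 1e-9)
  expect_equal(r2$cmax / r1$cmax, 2, tolerance = 1e-9)

  # steady-state interval AUC equals single-dose AUC to infinity
  ss <- pk_metrics(simulate_regimen(sub, cmp, dose_regimen(100, 24, 10, 24)))
  expect_equal(ss$auc, auc_inf_linear(sub, cmp, 100), tolerance = 0.01)
})

test_that("the ka = ke degenerate case uses the analytic limit", {
  sub <- unit_subject()
  cmp <- test_compound(c(CYP1A2 = 0), ka = 0.5, vss = 1, fu = 1)
  # choose renal clearance so that ke = ka exactly
  cmp$cl_renal <- 0.5 * sub$weight * 1
  prof <- simulate_regimen(sub, cmp, dose_regimen(100, window_h = 24))
  expect_true(all(is.finite(prof$conc)))
  # t*exp(-kt) peak at t = 1/k
  m <- pk_metrics(prof, c(0, 24))
  expect_equal(m$tmax, 1 / 0.5, tolerance = 0.05)
})

test_that("pk_metrics integrates simple shapes exactly", {
  flat <- structure(list(times = seq(0, 24, 0.5), conc = rep(10, 49),
                         regimen = dose_regimen(1, 24, 1, 24)),
                    class = "pk_profile")
  m <- pk_metrics(flat, c(0, 24))
  expect_equal(m$auc, 240)
  expect_equal(m$cmax, 10)
  tri <- structure(list(times = seq(0, 24, 0.5),
                        conc = seq(10, 0, length.out = 49),
                        regimen = dose_regimen(1, 24, 1, 24)),
                   class = "pk_profile")
  expect_equal(pk_metrics(tri, c(0, 24))$auc, 120)
  expect_error(pk_metrics(flat, c(0, 48)), "outside")
})

test_that("low-extraction analytic AUC ratio behaves as derived", {
  expect_equal(auc_ratio_low_extraction(c(CYP1A2 = 1), c(CYP1A2 = 0.5)), 2)
  expect_equal(auc_ratio_low_extraction(
    c(CYP1A2 = 0.4, CYP3A4 = 0.3),
    c(CYP1A2 = 1, CYP2C9 = 1, CYP2C19 = 1, CYP2D6 = 1, CYP3A4 = 1)), 1)
  expect_equal(auc_ratio_low_extraction(c(CYP1A2 = 0.95), c(CYP1A2 = 0.37)),
               1 / (0.95 * 0.37 + 0.05))
  expect_error(auc_ratio_low_extraction(c(CYP1A2 = 0.5), c(CYP2C9 = 1)),
               "scalar")
  # inversion round-trip
  s <- scalar_from_auc_ratio(2.52, 0.87)
  expect_equal(auc_ratio_low_extraction(c(CYP2C19 = 0.87), c(CYP2C19 = s)),
               2.52)
})

test_that("engine abundance-ratio agrees with the analytic oracle in the low-extraction limit", {
  h <- healthy_population()
  scalars <- mafld_cyp_scalars()
  m <- build_mafld_spec(h, hct_means = c(male = h$male$hct_mean,
                                         female = h$female$hct_mean),
                        bmi_targets = c(male = h$male$bmi_target,
                                        female = h$female$bmi_target))
  cmp <- test_compound(
    clint_per_pmol = c(CYP1A2 = 0.002, CYP3A4 = 0.0005), fu = 0.3, vss = 1)
  sub_h <- mean_subject(h); sub_m <- mean_subject(m)
  # verify the low-extraction premise
  e_h <- hepatic_clearance(whole_liver_clint(sub_h, cmp), 0.3, 90) / 90
  expect_lt(e_h, 0.1)
  fm <- local({
    per_mg <- sub_h$cyp_abundance * cmp$clint_per_pmol[CYP_ENZYMES]
    per_mg / sum(per_mg)
  })
  ratio_engine <- auc_inf_linear(sub_m, cmp) / auc_inf_linear(sub_h, cmp)
  ratio_oracle <- auc_ratio_low_extraction(fm, scalars)
  expect_equal(ratio_engine, ratio_oracle, tolerance = 0.02)
})

test_that("saturable elimination converges to linear when dose << Km", {
  sub <- unit_subject()
  lin <- test_compound(c(CYP1A2 = 0.05), fu = 0.5, vss = 2)
  clint <- whole_liver_clint(sub, lin)
  km <- 1000   # mg/L unbound; far above any simulated concentration
  mm <- lin; mm$mm <- list(vmax = clint * km, km = km)
  reg <- dose_regimen(100, window_h = 72)
  a_lin <- pk_metrics(simulate_regimen(sub, lin, reg), c(0, 72))$auc
  a_mm <- pk_metrics(simulate_regimen(sub, mm, reg), c(0, 72))$auc
  expect_equal(a_mm / a_lin, 1, tolerance = 0.01)
  # and saturation raises exposure when concentrations approach Km
  mm2 <- lin; mm2$mm <- list(vmax = clint * 0.5, km = 0.5)
  a_sat <- pk_metrics(simulate_regimen(sub, mm2, reg), c(0, 72))$auc
  expect_gt(a_sat, a_lin)
})

test_that("Cmax responds less than AUC to a pure clearance change", {
  h <- healthy_population()
  m <- build_mafld_spec(h, hct_means = c(male = h$male$hct_mean,
                                         female = h$female$hct_mean),
                        bmi_targets = c(male = h$male$bmi_target,
                                        female = h$female$bmi_target))
  cmp <- fixture_compounds(h)$caffeine
  reg <- dose_regimen(150, 24, 1, 96)
  m_h <- pk_metrics(simulate_regimen(mean_subject(h), cmp, reg), c(0, 96))
  m_m <- pk_metrics(simulate_regimen(mean_subject(m), cmp, reg), c(0, 96))
  expect_lte(m_m$cmax / m_h$cmax, m_m$auc / m_h$auc)
  expect_gt(m_m$auc / m_h$auc, 1)
})
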