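test_that("height-weight model evaluates and calibrates correctly", {
  m <- height_weight_model(a = 2.410, x0 = 0.012)
  expect_equal(predict_weight(m, 176), 92.0, tolerance = 1e-3)
  expect_equal(predict_weight(m, 176) / 1.76^2, 29.7, tolerance = 1e-3)

  flat <- height_weight_model(a = log(70), x0 = 0)
  expect_equal(predict_weight(flat, 150), 70)
  expect_equal(predict_weight(flat, 190), 70)
  expect_gt(predict_weight(m, 180), predict_weight(m, 160))

  cal <- calibrate_height_weight(29.7, 0.012, 176)
  expect_equal(cal$a, 2.410, tolerance = 1e-3)
  expect_equal(predict_weight(cal, 176) / 1.76^2, 29.7)
  cal_f <- calibrate_height_weight(27.3, 0.012, 163)
  expect_equal(predict_weight(cal_f, 163) / 1.63^2, 27.3)
  cal0 <- calibrate_height_weight(25, 0, 170)
  expect_equal(cal0$a, log(25 * 1.7^2))
  expect_error(calibrate_height_weight(-1, 0.01, 170), "> 0")
})

test_that("MAFLD spec derivation scales CYPs, haematocrit and BMI targets", {
  h <- healthy_population()
  m <- build_mafld_spec(h)
  expect_equal(unname(m$cyp_abundance_mean["CYP2C9"]),
               unname(h$cyp_abundance_mean["CYP2C9"]) * 0.72)
  expect_equal(unname(m$cyp_abundance_mean["CYP1A2"]),
               unname(h$cyp_abundance_mean["CYP1A2"]) * 0.37)
  expect_equal(m$male$hct_mean, 48.2)
  expect_equal(m$female$hct_mean, 42.6)
  # the explicit haematocrit values are the baseline's 1.12-fold increase
  expect_equal(m$male$hct_mean / h$male$hct_mean, 1.12, tolerance = 1e-3)
  expect_equal(predict_weight(m$male$hw, m$male$height_mean) /
                 (m$male$height_mean / 100)^2, 29.7)
  expect_equal(predict_weight(m$female$hw, m$female$height_mean) /
                 (m$female$height_mean / 100)^2, 27.3)

  ident <- build_mafld_spec(
    h, cyp_scalars = stats::setNames(rep(1, 5), CYP_ENZYMES),
    hct_means = NULL, hct_fold = 1,
    bmi_targets = c(male = h$male$bmi_target, female = h$female$bmi_target))
  expect_equal(ident$cyp_abundance_mean, h$cyp_abundance_mean)
  expect_equal(ident$male$hct_mean, h$male$hct_mean)
  expect_equal(ident$male$hw$a, h$male$hw$a)

  expect_error(build_mafld_spec(h, cyp_scalars = c(CYP1A2 = 0.4)),
               "missing CYP scalar")
})

test_that("sampled subjects satisfy the BMI identity and determinism", {
  spec <- healthy_population()
  set.seed(5)
  for (i in 1:25) {
    s <- sample_subject(spec)
    expect_equal(s$bmi, s$weight / (s$height / 100)^2)
    expect_true(all(s$cyp_abundance >= 0))
    expect_gt(s$haematocrit, 0)
    expect_true(s$age >= 20 && s$age <= 65)
  }
  set.seed(99); a <- sample_subject(spec)
  set.seed(99); b <- sample_subject(spec)
  expect_identical(a, b)
})

test_that("a zero-variance specification samples the mean subject exactly", {
  spec <- healthy_population()
  spec$cyp_abundance_cv[] <- 0
  spec$male$hct_cv <- 0
  spec$male$height_sd <- 0
  spec$male$hw$residual_gsd <- 1
  set.seed(1)
  s <- sample_subject(spec, sex = "male")
  expect_equal(s$height, spec$male$height_mean)
  expect_equal(s$weight, predict_weight(spec$male$hw, spec$male$height_mean))
  expect_equal(s$haematocrit, spec$male$hct_mean)
  expect_equal(s$cyp_abundance, spec$cyp_abundance_mean)
})

test_that("population moments are recovered over many draws", {
  spec <- healthy_population()
  set.seed(31)
  draws <- replicate(4000, sample_subject(spec), simplify = FALSE)
  ab34 <- vapply(draws, function(s) s$cyp_abundance[["CYP3A4"]], numeric(1))
  expect_lt(abs(mean(ab34) / spec$cyp_abundance_mean[["CYP3A4"]] - 1), 0.02)
  fem <- mean(vapply(draws, function(s) s$sex == "female", logical(1)))
  expect_lt(abs(fem - 0.5), 0.02)

  m <- build_mafld_spec(spec)
  set.seed(31)
  draws_m <- replicate(4000, sample_subject(m), simplify = FALSE)
  ab1a2_h <- mean(vapply(draws, function(s) s$cyp_abundance[["CYP1A2"]],
                         numeric(1)))
  ab1a2_m <- mean(vapply(draws_m, function(s) s$cyp_abundance[["CYP1A2"]],
                         numeric(1)))
  expect_lt(abs(ab1a2_m / ab1a2_h - 0.37), 0.02)
})

test_that("cohort sampling honours the exact sex split", {
  spec <- healthy_population()
  set.seed(2)
  cohort <- sample_cohort(spec, 10)
  expect_equal(sum(vapply(cohort, function(s) s$sex == "female",
                          logical(1))), 5L)
})

test_that("population specs round-trip through YAML", {
  spec <- build_mafld_spec(healthy_population())
  path <- tempfile(fileext = ".yaml")
  write_population_yaml(spec, path)
  back <- read_population_yaml(path)
  expect_equal(back$cyp_abundance_mean, spec$cyp_abundance_mean)
  expect_equal(back$male$hw$a, spec$male$hw$a)
  expect_equal(back$name, spec$name)
})
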