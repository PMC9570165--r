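test_that("arithmetic and geometric pooling follow their definitions", {
  recs <- study_records("CYP2C9", "activity", c(0.82, 0.64, 0.40, 1.53, 1.42))
  eff <- pool_ratios(recs, "arithmetic", warn = FALSE)
  expect_equal(eff$pooled_ratio, 0.962)
  expect_equal(eff$n_studies, 5L)
  expect_equal(c(eff$ratio_min, eff$ratio_max), c(0.40, 1.53))

  geo <- pool_ratios(recs, "geometric")
  expect_equal(geo$pooled_ratio, exp(mean(log(recs$ratio))))
  expect_lte(geo$ratio_min, geo$pooled_ratio)
  expect_gte(geo$ratio_max, geo$pooled_ratio)

  one <- pool_ratios(study_records("CYP2D6", "activity", 0.68), warn = FALSE)
  expect_equal(one$pooled_ratio, 0.68)
  expect_equal(c(one$ratio_min, one$ratio_max), c(0.68, 0.68))

  sym <- pool_ratios(study_records("CYP3A4", "activity", c(0.25, 4)),
                     "geometric")
  expect_equal(sym$pooled_ratio, 1.0)
})

test_that("pooling validates its inputs", {
  recs <- study_records("CYP2C9", "activity", c(0.8, 1.2))
  expect_error(pool_ratios(recs[0, ]), "at least one")
  mixed <- rbind(recs, study_records("CYP1A2", "activity", 0.5))
  expect_error(pool_ratios(mixed, warn = FALSE), "mix")
  expect_error(study_records("CYP2C9", "activity", c(1, -2)), "> 0")
  expect_error(study_records("CYP9Z9", "activity", 1), "unknown enzyme")
  expect_warning(pool_ratios(recs), "arithmetic")
})

test_that("geometric pooling is scale-symmetric, permutation-invariant and idempotent", {
  set.seed(11)
  for (i in 1:5) {
    r <- exp(stats::rnorm(7, 0, 0.5))
    a <- pool_ratios(study_records("CYP3A4", "activity", r), "geometric")
    b <- pool_ratios(study_records("CYP3A4", "activity", 1 / r), "geometric")
    expect_equal(a$pooled_ratio * b$pooled_ratio, 1)
    p <- pool_ratios(study_records("CYP3A4", "activity", sample(r)),
                     "geometric")
    expect_equal(p$pooled_ratio, a$pooled_ratio)
  }
  const <- pool_ratios(study_records("CYP1A2", "activity", rep(0.4, 6)),
                       "geometric")
  expect_equal(const$pooled_ratio, 0.4)
})

test_that("geometric pooling recovers a known true ratio from synthetic studies", {
  tab <- generate_study_table("CYP1A2", true_ratio = 0.5, n_studies = 500,
                              log_sd = 0.3, seed = 202)
  est <- pool_ratios(tab, "geometric")$pooled_ratio
  expect_lt(abs(est / 0.5 - 1), 0.05)
})

test_that("observed activity ratio orientation is the reciprocal", {
  expect_equal(
    unname(to_observed_activity_ratio(
      data.frame(enzyme = "CYP2C19", pooled_ratio = 0.4225),
      round_first = TRUE)),
    1 / 0.42)
  expect_equal(unname(to_observed_activity_ratio(
    data.frame(enzyme = "CYP1A2", pooled_ratio = 1))), 1)
  expect_equal(unname(to_observed_activity_ratio(
    data.frame(enzyme = "CYP1A2", pooled_ratio = 0.5))), 2)
  expect_error(to_observed_activity_ratio(
    data.frame(enzyme = "CYP1A2", pooled_ratio = 0)), "> 0")
})

test_that("stratified re-pooling by model system splits the groups", {
  recs <- rbind(
    study_records("CYP3A4", "activity", c(0.4, 0.6),
                  model_system = "human_microsomes"),
    study_records("CYP3A4", "activity", c(0.8, 1.0),
                  model_system = "animal")
  )
  strat <- pool_by_enzyme(recs, by_system = TRUE)
  expect_equal(nrow(strat), 2L)
  expect_setequal(strat$pooled_ratio, c(0.5, 0.9))
})

test_that("the packaged study table round-trips through CSV", {
  path <- system.file("extdata", "invitro_activity_studies.csv",
                      package = "mafldpbpk")
  expect_true(nzchar(path))
  tab <- read_study_table(path)
  expect_equal(as.data.frame(tab), as.data.frame(invitro_activity_studies()))
})
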