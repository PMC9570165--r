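#' @title Population specification and virtual-subject sampling
#' @name population_builder
NULL

#' Exponential height-weight model
#'
#' Weight is modelled as an exponential function of height,
#' `weight = exp(a + height * x0)`, with a multiplicative log-normal
#' residual of geometric SD `residual_gsd` applied at sampling time.
#'
#' @param a intercept exponent (dimensionless)
#' @param x0 slope exponent per cm of height
#' @param residual_gsd geometric SD of the weight residual (1 = none)
#' @return list of class `height_weight_model`
#' @export
height_weight_model <- function(a, x0, residual_gsd = 1.1) {
  stopifnot(is.finite(a), is.finite(x0), residual_gsd >= 1)
  structure(list(a = a, x0 = x0, residual_gsd = residual_gsd),
            class = "height_weight_model")
}

#' Predict weight from height (noise-free)
#'
#' @param model a [height_weight_model()]
#' @param height height in cm, > 0
#' @return weight in kg, `exp(a + height * x0)`
#' @examples
#' m <- height_weight_model(a = 2.410, x0 = 0.012)
#' predict_weight(m, 176)  # ~92 kg, BMI 29.7
#' @export
predict_weight <- function(model, height) {
  stopifnot(all(height > 0))
  exp(model$a + height * model$x0)
}

#' Calibrate the height-weight intercept to a target mean BMI
#'
#' Solves for the intercept `a` such that the noise-free predicted weight at
#' the population mean height gives exactly the target BMI:
#' `a = log(BMI * (h/100)^2) - x0 * h`.
#'
#' @param target_bmi_mean target mean BMI, kg/m^2
#' @param x0 slope exponent per cm (kept fixed during calibration)
#' @param mean_height population mean height, cm
#' @param residual_gsd passed through to the returned model
#' @return a [height_weight_model()]
#' @export
calibrate_height_weight <- function(target_bmi_mean, x0, mean_height,
                                    residual_gsd = 1.1) {
  if (!all(is.finite(c(target_bmi_mean, x0, mean_height))) ||
      target_bmi_mean <= 0 || mean_height <= 0 || x0 < 0) {
    stop("target BMI and mean height must be > 0 and x0 >= 0", call. = FALSE)
  }
  a <- log(target_bmi_mean * (mean_height / 100)^2) - x0 * mean_height
  height_weight_model(a = a, x0 = x0, residual_gsd = residual_gsd)
}

sex_block <- function(height_mean, height_sd, hw, bmi_target,
                      hct_mean, hct_cv) {
  list(height_mean = height_mean, height_sd = height_sd, hw = hw,
       bmi_target = bmi_target, hct_mean = hct_mean, hct_cv = hct_cv)
}

#' Create a population specification
#'
#' Distributional description of a virtual population: demographics,
#' per-sex height and height-weight models, haematocrit, per-CYP hepatic
#' abundances and the IVIVE scaling physiology (microsomal protein per gram
#' liver, liver mass, hepatic blood flow).
#'
#' Abundance and haematocrit variability are log-normal, parameterised by
#' arithmetic mean and CV.
#'
#' @param name population label
#' @param age_range numeric length-2, years
#' @param proportion_female fraction in \[0, 1\]
#' @param male,female per-sex blocks: lists with `height_mean` (cm),
#'   `height_sd` (cm), `hw` (a [height_weight_model()]), `bmi_target`
#'   (kg/m^2), `hct_mean` (percent), `hct_cv`
#' @param cyp_abundance_mean named numeric, pmol per mg microsomal protein,
#'   one entry per enzyme in [CYP_ENZYMES]
#' @param cyp_abundance_cv log-normal CV of abundances (scalar or named)
#' @param albumin_ratio disease/healthy plasma-protein concentration ratio
#' @param mppgl mg microsomal protein per g liver
#' @param liver_mass g
#' @param hepatic_blood_flow L/h
#' @return list of class `population_spec`
#' @export
population_spec <- function(name, age_range = c(20, 65),
                            proportion_female = 0.5,
                            male, female,
                            cyp_abundance_mean, cyp_abundance_cv = 0.4,
                            albumin_ratio = 1.0,
                            mppgl = 40, liver_mass = 1650,
                            hepatic_blood_flow = 90) {
  stopifnot(length(age_range) == 2, age_range[1] <= age_range[2],
            proportion_female >= 0, proportion_female <= 1,
            mppgl > 0, liver_mass > 0, hepatic_blood_flow > 0,
            albumin_ratio > 0)
  if (!all(CYP_ENZYMES %in% names(cyp_abundance_mean))) {
    stop("cyp_abundance_mean must name all of: ",
         paste(CYP_ENZYMES, collapse = ", "), call. = FALSE)
  }
  if (any(cyp_abundance_mean < 0)) stop("abundances must be >= 0")
  if (length(cyp_abundance_cv) == 1L) {
    cyp_abundance_cv <- stats::setNames(rep(cyp_abundance_cv, 5), CYP_ENZYMES)
  }
  for (blk in list(male, female)) {
    stopifnot(blk$height_mean > 0, blk$height_sd >= 0,
              inherits(blk$hw, "height_weight_model"),
              blk$hct_mean > 0, blk$hct_mean < 100, blk$hct_cv >= 0)
  }
  structure(list(
    name = name, age_range = age_range,
    proportion_female = proportion_female,
    male = male, female = female,
    cyp_abundance_mean = cyp_abundance_mean[CYP_ENZYMES],
    cyp_abundance_cv = cyp_abundance_cv[CYP_ENZYMES],
    albumin_ratio = albumin_ratio,
    mppgl = mppgl, liver_mass = liver_mass,
    hepatic_blood_flow = hepatic_blood_flow
  ), class = "population_spec")
}

#' Baseline healthy-volunteer population specification
#'
#' Literature-typical healthy-adult defaults: mean heights 176/163 cm
#' (SD 7/6.5) and mean BMI 24.4/23.5 kg/m^2 for males/females, haematocrit
#' 43.04/38.04 percent (CV 5 percent), hepatic CYP abundances of
#' approximately 52, 73, 14, 8 and 137 pmol/mg for CYP1A2/2C9/2C19/2D6/3A4
#' with 40 percent log-normal CV, MPPGL 40 mg/g, liver mass 1650 g and
#' hepatic blood flow 90 L/h.
#'
#' @param hw_x0 shared height-weight slope exponent per cm
#' @return a [population_spec()]
#' @export
healthy_population <- function(hw_x0 = 0.012) {
  male_hw <- calibrate_height_weight(24.4, hw_x0, 176)
  female_hw <- calibrate_height_weight(23.5, hw_x0, 163)
  population_spec(
    name = "healthy",
    male = sex_block(176, 7, male_hw, 24.4, 43.04, 0.05),
    female = sex_block(163, 6.5, female_hw, 23.5, 38.04, 0.05),
    cyp_abundance_mean = c(CYP1A2 = 52, CYP2C9 = 73, CYP2C19 = 14,
                           CYP2D6 = 8, CYP3A4 = 137)
  )
}

#' Default MAFLD fold-changes applied to the healthy baseline
#'
#' CYP1A2 (0.37, i.e. a 63 percent reduction) and CYP2C9 (0.72, a 28 percent
#' reduction) come from pooled abundance observations. The CYP2C19, CYP2D6
#' and CYP3A4 scalars are CALIBRATED values: back-calculated with the
#' low-extraction analytic ratio so that single-enzyme probe simulations
#' using the fixture fm values reproduce the reference single-dose AUC
#' fold-changes (omeprazole, dextromethorphan, midazolam respectively).
#' They are not observed pooled abundances.
#'
#' @return named numeric vector of MAFLD/healthy abundance fold-changes
#' @export
mafld_cyp_scalars <- function() {
  c(CYP1A2 = 0.37, CYP2C9 = 0.72,
    CYP2C19 = 0.307,   # CALIBRATED from omeprazole 2.52-fold, fm 0.87
    CYP2D6 = 0.731,    # CALIBRATED from dextromethorphan 1.32-fold, fm 0.90
    CYP3A4 = 0.623)    # CALIBRATED from midazolam 1.55-fold, fm 0.94
}

#' Derive a MAFLD population specification from a healthy baseline
#'
#' Multiplies per-CYP abundance means by `cyp_scalars`, sets haematocrit
#' (either explicitly via `hct_means` or by `hct_fold` applied to the
#' baseline), recalibrates the per-sex height-weight intercepts to the MAFLD
#' BMI targets, applies `albumin_ratio`, and copies everything else.
#'
#' @param healthy a healthy [population_spec()]
#' @param cyp_scalars named fold-changes for every enzyme in [CYP_ENZYMES]
#' @param hct_fold fold-change applied to haematocrit means (ignored when
#'   `hct_means` given)
#' @param hct_means optional explicit haematocrit means,
#'   `c(male =, female =)` percent
#' @param bmi_targets per-sex target mean BMI, `c(male =, female =)` kg/m^2
#' @param albumin_ratio disease/healthy plasma-protein ratio
#' @param name label for the derived population
#' @return a [population_spec()]
#' @examples
#' mafld <- build_mafld_spec(healthy_population())
#' mafld$cyp_abundance_mean["CYP2C9"] / 73  # 0.72
#' @export
build_mafld_spec <- function(healthy,
                             cyp_scalars = mafld_cyp_scalars(),
                             hct_fold = 1.12,
                             hct_means = c(male = 48.2, female = 42.6),
                             bmi_targets = c(male = 29.7, female = 27.3),
                             albumin_ratio = 1.0,
                             name = "mafld") {
  stopifnot(inherits(healthy, "population_spec"))
  missing <- setdiff(CYP_ENZYMES, names(cyp_scalars))
  if (length(missing)) {
    stop("missing CYP scalar(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(cyp_scalars[CYP_ENZYMES] <= 0) || hct_fold <= 0) {
    stop("scalars and hct_fold must be > 0", call. = FALSE)
  }
  spec <- healthy
  spec$name <- name
  spec$cyp_abundance_mean <-
    healthy$cyp_abundance_mean * cyp_scalars[CYP_ENZYMES]
  spec$albumin_ratio <- albumin_ratio
  for (sx in c("male", "female")) {
    blk <- spec[[sx]]
    blk$hct_mean <- if (!is.null(hct_means)) {
      unname(hct_means[sx])
    } else {
      blk$hct_mean * hct_fold
    }
    blk$bmi_target <- unname(bmi_targets[sx])
    blk$hw <- calibrate_height_weight(blk$bmi_target, blk$hw$x0,
                                      blk$height_mean,
                                      blk$hw$residual_gsd)
    spec[[sx]] <- blk
  }
  spec
}

# mean/CV parameterised log-normal draws: arithmetic mean preserved
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0 || mean == 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

rnorm_trunc3 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- abs(x - mean) > 3 * sd)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Sample one virtual subject from a population specification
#'
#' Sex is Bernoulli per the configured female proportion (unless forced),
#' age uniform over the range, height truncated-normal (+/- 3 SD), weight
#' from the sex's height-weight model with a log-normal residual,
#' haematocrit and per-CYP abundances log-normal with the configured mean
#' and CV. BMI is derived as `weight / (height/100)^2`. Draws come from the
#' current R random-number stream; seed with `set.seed()` for
#' reproducibility.
#'
#' @param spec a [population_spec()]
#' @param sex optionally force `"male"` or `"female"`
#' @return list of class `subject`
#' @export
sample_subject <- function(spec, sex = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (is.null(sex)) {
    sex <- if (stats::runif(1) < spec$proportion_female) "female" else "male"
  }
  blk <- spec[[sex]]
  age <- stats::runif(1, spec$age_range[1], spec$age_range[2])
  height <- rnorm_trunc3(1, blk$height_mean, blk$height_sd)
  gsd <- blk$hw$residual_gsd
  resid <- if (gsd > 1) stats::rlnorm(1, 0, log(gsd)) else 1
  weight <- predict_weight(blk$hw, height) * resid
  hct <- rlnorm_mean_cv(1, blk$hct_mean, blk$hct_cv)
  ab <- vapply(CYP_ENZYMES, function(e) {
    rlnorm_mean_cv(1, spec$cyp_abundance_mean[[e]], spec$cyp_abundance_cv[[e]])
  }, numeric(1))
  structure(list(
    sex = sex, age = age, height = height, weight = weight,
    bmi = weight / (height / 100)^2, haematocrit = hct,
    cyp_abundance = ab, albumin_ratio = spec$albumin_ratio,
    mppgl = spec$mppgl, liver_mass = spec$liver_mass,
    hepatic_blood_flow = spec$hepatic_blood_flow
  ), class = "subject")
}

#' Sample a cohort of virtual subjects
#'
#' When `exact_sex_split` is TRUE (the default, matching a fixed female
#' proportion trial design) sexes are assigned by deterministic interleave
#' so each cohort carries exactly the configured proportion, reducing
#' between-trial variance.
#'
#' @param spec a [population_spec()]
#' @param n cohort size
#' @param exact_sex_split logical
#' @return list of `subject`s
#' @export
sample_cohort <- function(spec, n, exact_sex_split = TRUE) {
  if (exact_sex_split) {
    n_f <- round(spec$proportion_female * n)
    sexes <- rep("male", n)
    if (n_f > 0) sexes[round(seq(1, n, length.out = n_f))] <- "female"
    lapply(sexes, function(s) sample_subject(spec, sex = s))
  } else {
    lapply(seq_len(n), function(i) sample_subject(spec))
  }
}

#' A deterministic "mean" subject (all CVs ignored)
#'
#' Convenience for analytic cross-checks: the subject whose covariates equal
#' the specification means for the given sex.
#'
#' @param spec a [population_spec()]
#' @param sex `"male"` or `"female"`
#' @return a `subject`
#' @export
mean_subject <- function(spec, sex = "male") {
  blk <- spec[[sex]]
  height <- blk$height_mean
  weight <- predict_weight(blk$hw, height)
  structure(list(
    sex = sex, age = mean(spec$age_range), height = height, weight = weight,
    bmi = weight / (height / 100)^2, haematocrit = blk$hct_mean,
    cyp_abundance = spec$cyp_abundance_mean,
    albumin_ratio = spec$albumin_ratio,
    mppgl = spec$mppgl, liver_mass = spec$liver_mass,
    hepatic_blood_flow = spec$hepatic_blood_flow
  ), class = "subject")
}

#' Write / read population specifications as YAML
#'
#' @param spec a [population_spec()]
#' @param path file path
#' @return `read_population_yaml` returns a [population_spec()];
#'   `write_population_yaml` returns `path` invisibly
#' @export
write_population_yaml <- function(spec, path) {
  x <- unclass(spec)
  for (sx in c("male", "female")) x[[sx]]$hw <- unclass(x[[sx]]$hw)
  x$cyp_abundance_mean <- as.list(x$cyp_abundance_mean)
  x$cyp_abundance_cv <- as.list(x$cyp_abundance_cv)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_population_yaml
#' @export
read_population_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  for (sx in c("male", "female")) {
    x[[sx]]$hw <- height_weight_model(x[[sx]]$hw$a, x[[sx]]$hw$x0,
                                      x[[sx]]$hw$residual_gsd)
  }
  population_spec(
    name = x$name, age_range = unlist(x$age_range),
    proportion_female = x$proportion_female,
    male = x$male, female = x$female,
    cyp_abundance_mean = unlist(x$cyp_abundance_mean),
    cyp_abundance_cv = unlist(x$cyp_abundance_cv),
    albumin_ratio = x$albumin_ratio, mppgl = x$mppgl,
    liver_mass = x$liver_mass, hepatic_blood_flow = x$hepatic_blood_flow
  )
}
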