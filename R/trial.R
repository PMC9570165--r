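#' @title Virtual clinical trials and population comparison
#' @name trial_runner
NULL

#' Define a virtual-trial design
#'
#' The reference design is 20 trials of 10 subjects (n = 200) per
#' population, female proportion 0.5, ages 20-65.
#'
#' @param n_trials number of replicate trials
#' @param n_subjects_per_trial cohort size per trial
#' @param seed integer seed making the trial fully reproducible
#' @return list of class `trial_design`
#' @export
trial_design <- function(n_trials = 20, n_subjects_per_trial = 10,
                         seed = 1L) {
  stopifnot(n_trials >= 1, n_subjects_per_trial >= 1)
  structure(list(n_trials = as.integer(n_trials),
                 n_subjects_per_trial = as.integer(n_subjects_per_trial),
                 seed = as.integer(seed)),
            class = "trial_design")
}

#' Geometric mean with a 95% interval
#'
#' `geomean = exp(mean(log(v)))`. The default interval is the 2.5th/97.5th
#' percentile of the values themselves (a population interval describing
#' between-subject spread); `method = "se"` instead gives the
#' standard-error-based confidence interval of the geometric mean.
#'
#' @param values positive numeric vector
#' @param method `"percentile"` (default) or `"se"`
#' @param level interval coverage (default 0.95)
#' @return named numeric `c(geomean, lower, upper)`
#' @export
summarize_geomean <- function(values, method = c("percentile", "se"),
                              level = 0.95) {
  method <- match.arg(method)
  if (length(values) == 0 || any(!is.finite(values)) || any(values <= 0)) {
    stop("values must be a non-empty positive vector", call. = FALSE)
  }
  lv <- log(values)
  gm <- exp(mean(lv))
  a <- (1 - level) / 2
  if (method == "percentile") {
    q <- stats::quantile(values, c(a, 1 - a), names = FALSE, type = 7)
    ci <- c(q[1], q[2])
  } else {
    se <- stats::sd(lv) / sqrt(length(lv))
    z <- stats::qnorm(1 - a)
    ci <- exp(mean(lv) + c(-z, z) * se)
  }
  c(geomean = gm, lower = ci[1], upper = ci[2])
}

#' Run a virtual clinical trial for one population and compound
#'
#' Samples `n_trials x n_subjects_per_trial` subjects from the population
#' specification (exact female/male split within each cohort), simulates
#' each subject under the regimen, computes AUC/Cmax over the window after
#' the last dose, and summarises both endpoints by geometric mean with 95%
#' intervals. Fully deterministic given the design seed.
#'
#' @param spec a [population_spec()]
#' @param compound a [compound_profile()]
#' @param design a [trial_design()]
#' @param regimen a [dose_regimen()]; default is the compound's single-dose
#'   standard regimen
#' @param interval_method interval type passed to [summarize_geomean()]
#' @return list of class `trial_result`: `metrics` (per-subject data frame),
#'   `summary` (data frame with metric, geomean, lower, upper), plus the
#'   inputs' labels
#' @export
run_virtual_trial <- function(spec, compound, design = trial_design(),
                              regimen = standard_regimen(compound, "single"),
                              interval_method = "percentile") {
  stopifnot(inherits(spec, "population_spec"),
            inherits(compound, "compound_profile"),
            inherits(design, "trial_design"))
  set.seed(design$seed)
  rows <- vector("list", design$n_trials * design$n_subjects_per_trial)
  k <- 0L
  for (tr in seq_len(design$n_trials)) {
    cohort <- sample_cohort(spec, design$n_subjects_per_trial)
    for (i in seq_along(cohort)) {
      k <- k + 1L
      m <- tryCatch(
        pk_metrics(simulate_regimen(cohort[[i]], compound, regimen)),
        error = function(e) {
          stop("simulation failed for trial ", tr, ", subject ", i, ": ",
               conditionMessage(e), call. = FALSE)
        }
      )
      rows[[k]] <- data.frame(trial = tr, subject = i,
                              sex = cohort[[i]]$sex,
                              auc = m$auc, cmax = m$cmax, tmax = m$tmax)
    }
  }
  metrics <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(c("auc", "cmax"), function(metric) {
    s <- summarize_geomean(metrics[[metric]], method = interval_method)
    data.frame(metric = metric, geomean = s[["geomean"]],
               lower = s[["lower"]], upper = s[["upper"]])
  }))
  structure(list(population = spec$name, compound = compound$name,
                 n = nrow(metrics), metrics = metrics, summary = summ),
            class = "trial_result")
}

#' Compare two trial results by geometric-mean ratio
#'
#' Ratio of the test population's geometric mean to the reference's for the
#' chosen metric. Following the bioequivalence-style rule, a difference of
#' more than 20% in either direction (ratio > 1.2 or < 0.8) is flagged as a
#' meaningful (non-equivalent) exposure difference.
#'
#' @param test,reference `trial_result` objects (e.g. MAFLD and healthy)
#' @param metric `"auc"` or `"cmax"`
#' @param threshold upper equivalence bound (default 1.2; the lower bound is
#'   its reciprocal-symmetric partner 0.8)
#' @return one-row data frame of class `comparison_result`: `metric, ratio,
#'   flagged`
#' @export
compare_populations <- function(test, reference, metric = "auc",
                                threshold = 1.2) {
  for (x in list(test, reference)) {
    if (!metric %in% x$summary$metric) {
      stop("metric '", metric, "' not present in both results",
           call. = FALSE)
    }
  }
  g_t <- test$summary$geomean[test$summary$metric == metric]
  g_r <- reference$summary$geomean[reference$summary$metric == metric]
  ratio <- g_t / g_r
  out <- data.frame(
    test = test$population, reference = reference$population,
    compound = test$compound, metric = metric, ratio = ratio,
    flagged = flag_nonequivalence(ratio, threshold)
  )
  class(out) <- c("comparison_result", class(out))
  out
}

#' Flag a geometric-mean ratio as a meaningful exposure difference
#'
#' @param ratio positive geometric-mean ratio(s)
#' @param threshold upper bound (default 1.2); lower bound is `2 - threshold`
#'   on the percentage scale, i.e. 0.8
#' @return logical
#' @export
flag_nonequivalence <- function(ratio, threshold = 1.2) {
  stopifnot(all(ratio > 0))
  lower <- 1 - (threshold - 1)
  ratio > threshold | ratio < lower
}
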