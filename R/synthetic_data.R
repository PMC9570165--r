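#' @title Synthetic inputs and the packaged fixture library
#' @description Everything the pipeline consumes can be generated from
#'   code: synthetic study-ratio tables with a known true effect (for
#'   pooling parameter-recovery checks), the eight fixture compound
#'   profiles, and the healthy/MAFLD population profiles. Fixture compound
#'   parameters are literature-typical approximations assembled for this
#'   package; no quantitative validation number depends on them.
#' @name synthetic_data
NULL

#' Generate a synthetic study-ratio table with known truth
#'
#' Draws `n_studies` MAFLD/control ratios log-normally around a true ratio:
#' `ratio = true_ratio * exp(N(0, log_sd))`, emulating between-study
#' heterogeneity. Deterministic given `seed`.
#'
#' @param enzyme one of [CYP_ENZYMES]
#' @param endpoint study endpoint (default `"activity"`)
#' @param true_ratio the underlying MAFLD/control ratio (> 0)
#' @param n_studies number of synthetic studies (>= 1)
#' @param log_sd between-study SD on the log scale (>= 0)
#' @param seed integer seed
#' @param model_system model system label for all records
#' @return a `study_records` data frame
#' @export
generate_study_table <- function(enzyme, endpoint = "activity",
                                 true_ratio, n_studies,
                                 log_sd = 0.3, seed = 1L,
                                 model_system = "human_microsomes") {
  stopifnot(true_ratio > 0, n_studies >= 1, log_sd >= 0)
  set.seed(seed)
  ratios <- true_ratio * exp(stats::rnorm(n_studies, 0, log_sd))
  study_records(
    enzyme = rep(enzyme, n_studies), endpoint = endpoint, ratio = ratios,
    probe_reaction = paste0("synthetic probe ", seq_len(n_studies)),
    source_ref = paste0("SYN", seq_len(n_studies)),
    model_system = model_system
  )
}

# spread fm over per-pmol clearances so the population-mean subject carries
# exactly the stated metabolic fingerprint
clint_from_fm <- function(fm, clint_total_per_mg, abundance_mean) {
  per_pmol <- vapply(names(fm), function(e) {
    fm[[e]] * clint_total_per_mg / abundance_mean[[e]]
  }, numeric(1))
  list(clint_per_pmol = per_pmol,
       clint_other = (1 - sum(fm)) * clint_total_per_mg)
}

#' The eight fixture probe-substrate profiles
#'
#' Literature-typical oral PK parameters for the probe substrates of the
#' five major CYPs. Doses follow the reference trial design (caffeine 150,
#' clozapine 12.5, s-warfarin 10, rosiglitazone 4, omeprazole 20,
#' dextromethorphan 30, metoprolol 100, midazolam 5 mg). Each compound's
#' per-CYP intrinsic clearances are constructed so that, at the baseline
#' population's mean abundances, its fraction metabolised by each enzyme
#' equals the documented `fm_cyp` fingerprint. These profiles are
#' approximations assembled for this package: they reproduce realistic
#' magnitudes and enzyme fingerprints, not any proprietary compound model.
#'
#' @param baseline the healthy [population_spec()] whose mean abundances
#'   anchor the fm fingerprints
#' @return named list of [compound_profile()]s
#' @export
fixture_compounds <- function(baseline = healthy_population()) {
  ab <- baseline$cyp_abundance_mean
  spec <- list(
    #      dose  ka  fa_fg  fu    bp    vss   clint  fm
    caffeine = list(150, 3.0, 1.00, 0.70, 1.04, 0.50, 2.0,
                    c(CYP1A2 = 0.95)),
    clozapine = list(12.5, 1.5, 0.90, 0.05, 0.85, 5.0, 190,
                     c(CYP1A2 = 0.70, CYP3A4 = 0.25)),
    `s-warfarin` = list(10, 1.0, 1.00, 0.01, 0.55, 0.14, 2.8,
                        c(CYP2C9 = 0.90)),
    rosiglitazone = list(4, 1.8, 0.99, 0.002, 0.80, 0.25, 300,
                         c(CYP2C9 = 0.50)),
    omeprazole = list(20, 2.0, 0.90, 0.045, 0.60, 0.30, 150,
                      c(CYP2C19 = 0.87, CYP3A4 = 0.10)),
    dextromethorphan = list(30, 1.5, 0.90, 0.35, 1.00, 6.0, 80,
                            c(CYP2D6 = 0.90, CYP3A4 = 0.05)),
    metoprolol = list(100, 2.5, 0.95, 0.88, 1.15, 4.2, 60,
                      c(CYP2D6 = 0.80)),
    midazolam = list(5, 3.0, 0.55, 0.02, 0.66, 1.1, 290,
                     c(CYP3A4 = 0.94))
  )
  out <- lapply(names(spec), function(nm) {
    s <- spec[[nm]]
    cl <- clint_from_fm(s[[8]], s[[7]], ab)
    compound_profile(
      name = nm, dose_mg = s[[1]], ka = s[[2]], fa_fg = s[[3]],
      fu = s[[4]], bp_ratio = s[[5]], vss = s[[6]],
      clint_per_pmol = cl$clint_per_pmol, clint_other = cl$clint_other,
      fm_cyp = s[[8]]
    )
  })
  stats::setNames(out, names(spec))
}

#' Write / read a compound profile as YAML
#'
#' @param compound a [compound_profile()]
#' @param path file path
#' @return `read_compound_yaml` returns a [compound_profile()];
#'   `write_compound_yaml` returns `path` invisibly
#' @export
write_compound_yaml <- function(compound, path) {
  x <- unclass(compound)
  x$clint_per_pmol <- as.list(x$clint_per_pmol)
  if (!is.null(x$fm_cyp)) x$fm_cyp <- as.list(x$fm_cyp)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_compound_yaml
#' @export
read_compound_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  compound_profile(
    name = x$name, dose_mg = x$dose_mg, ka = x$ka, fa_fg = x$fa_fg,
    fu = x$fu, bp_ratio = x$bp_ratio, vss = x$vss,
    clint_per_pmol = unlist(x$clint_per_pmol),
    clint_other = x$clint_other, cl_renal = x$cl_renal,
    fm_cyp = if (is.null(x$fm_cyp)) NULL else unlist(x$fm_cyp),
    bp_ref_hct = x$bp_ref_hct,
    mm = x$mm
  )
}

#' Write the complete fixture library to a directory
#'
#' Regenerates, deterministically, every packaged input: the study-level in
#' vitro activity CSV, the in vitro and animal comparator CSVs, the
#' reference exposure CSV, the healthy and MAFLD population YAMLs and the
#' eight compound YAMLs (under `compounds/`). Running it twice produces
#' byte-identical files.
#'
#' @param output_dir directory to write into (created if absent)
#' @return invisible character vector of the files written
#' @export
make_fixture_library <- function(output_dir) {
  if (!dir.exists(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create ", output_dir, call. = FALSE)
  }
  cmp_dir <- file.path(output_dir, "compounds")
  dir.create(cmp_dir, showWarnings = FALSE)
  paths <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(output_dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = TRUE)
    p
  }
  paths <- c(paths,
    wcsv(as.data.frame(invitro_activity_studies()),
         "invitro_activity_studies.csv"),
    wcsv(invitro_comparator_table(), "invitro_comparators.csv"),
    wcsv(animal_comparator_table(), "animal_comparators.csv"),
    wcsv(reference_exposure_table(), "reference_exposure.csv"))
  healthy <- healthy_population()
  mafld <- build_mafld_spec(healthy)
  p1 <- file.path(output_dir, "healthy.yaml")
  p2 <- file.path(output_dir, "mafld.yaml")
  write_population_yaml(healthy, p1)
  write_population_yaml(mafld, p2)
  paths <- c(paths, p1, p2)
  for (cmp in fixture_compounds(healthy)) {
    p <- file.path(cmp_dir, paste0(cmp$name, ".yaml"))
    write_compound_yaml(cmp, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
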