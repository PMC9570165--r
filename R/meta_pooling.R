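#' @title Pooling of study-level MAFLD/control CYP ratios
#' @description Functions to combine study-level MAFLD-to-control ratios of
#'   CYP enzyme abundance or activity into a single proportional-difference
#'   effect per enzyme, and to orient pooled activity effects as
#'   exposure-ratio-like comparators for model validation.
#' @name meta_pooling
NULL

#' CYP isoenzymes modelled throughout the package
#' @export
CYP_ENZYMES <- c("CYP1A2", "CYP2C9", "CYP2C19", "CYP2D6", "CYP3A4")

STUDY_ENDPOINTS <- c("abundance", "activity", "in_vivo_AUC", "in_vivo_Cmax")
MODEL_SYSTEMS <- c("human_microsomes", "human_hepatocytes", "biopsy", "animal")

#' Create a table of study-level ratio records
#'
#' Each record holds one study's MAFLD/control ratio for a CYP enzyme and an
#' endpoint (protein abundance, in vitro activity, or in vivo PK parameter).
#'
#' @param enzyme character, one of [CYP_ENZYMES] (a bare "1A2" etc. is
#'   normalised to "CYP1A2")
#' @param endpoint one of `"abundance"`, `"activity"`, `"in_vivo_AUC"`,
#'   `"in_vivo_Cmax"`
#' @param ratio numeric vector of positive MAFLD/control ratios
#' @param probe_reaction free-text probe reaction, e.g.
#'   "Diclofenac 4'-hydroxylation"
#' @param source_ref citation key
#' @param model_system one of `"human_microsomes"`, `"human_hepatocytes"`,
#'   `"biopsy"`, `"animal"`
#' @return a `data.frame` with class `study_records`
#' @export
study_records <- function(enzyme, endpoint, ratio,
                          probe_reaction = NA_character_,
                          source_ref = NA_character_,
                          model_system = "human_microsomes") {
  enzyme <- normalise_enzyme(enzyme)
  endpoint <- match.arg(endpoint, STUDY_ENDPOINTS, several.ok = TRUE)
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("all ratios must be finite and > 0", call. = FALSE)
  }
  if (!all(model_system %in% MODEL_SYSTEMS)) {
    stop("unknown model_system; must be one of: ",
         paste(MODEL_SYSTEMS, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    enzyme = enzyme, endpoint = endpoint,
    probe_reaction = probe_reaction, ratio = as.numeric(ratio),
    source_ref = source_ref, model_system = model_system,
    stringsAsFactors = FALSE
  )
  class(out) <- c("study_records", class(out))
  out
}

normalise_enzyme <- function(enzyme) {
  enzyme <- toupper(as.character(enzyme))
  enzyme <- ifelse(grepl("^CYP", enzyme), enzyme, paste0("CYP", enzyme))
  bad <- setdiff(unique(enzyme), CYP_ENZYMES)
  if (length(bad)) {
    stop("unknown enzyme(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(CYP_ENZYMES, collapse = ", "), call. = FALSE)
  }
  enzyme
}

#' Read a study-ratio table from CSV
#'
#' Expects columns `enzyme, endpoint, probe_reaction, ratio, source_ref,
#' model_system`. The packaged in vitro activity table is available via
#' `system.file("extdata", "invitro_activity_studies.csv",
#' package = "mafldpbpk")`.
#'
#' @param path path to a CSV file
#' @return a `study_records` data frame
#' @export
read_study_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("enzyme", "endpoint", "probe_reaction", "ratio",
                "source_ref", "model_system")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("study table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  study_records(df$enzyme, df$endpoint, df$ratio, df$probe_reaction,
                df$source_ref, df$model_system)
}

#' Pool study-level ratios into one proportional-difference effect
#'
#' Combines the MAFLD/control ratios of all records (which must share one
#' enzyme and one endpoint) into a single pooled ratio. `method =
#' "arithmetic"` takes the plain mean of the ratios; `method = "geometric"`
#' takes `exp(mean(log(ratio)))`. The reported range is the min/max of the
#' input ratios.
#'
#' The default is arithmetic: although pooled proportional differences of
#' this kind are conventionally described as geometric means, the reference
#' pooled values this package reproduces are arithmetic means of the study
#' ratios, and a warning is emitted to make the labelling mismatch visible.
#' Set `warn = FALSE` to silence it.
#'
#' @param records a `study_records` data frame for a single enzyme+endpoint
#' @param method `"arithmetic"` (default) or `"geometric"`
#' @param warn warn when arithmetic pooling is used (see Details)
#' @return a one-row `data.frame` (class `pooled_effect`) with columns
#'   `enzyme, endpoint, n_studies, pooled_ratio, ratio_min, ratio_max, method`
#' @examples
#' recs <- study_records("CYP2C9", "activity", c(0.82, 0.64, 0.40, 1.53, 1.42))
#' pool_ratios(recs, warn = FALSE)$pooled_ratio  # 0.962
#' @export
pool_ratios <- function(records, method = c("arithmetic", "geometric"),
                        warn = TRUE) {
  method <- match.arg(method)
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("need at least one study record", call. = FALSE)
  }
  if (length(unique(records$enzyme)) != 1L ||
      length(unique(records$endpoint)) != 1L) {
    stop("records mix enzymes or endpoints; pool one enzyme+endpoint at a ",
         "time (see pool_by_enzyme)", call. = FALSE)
  }
  r <- records$ratio
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("all ratios must be finite and > 0", call. = FALSE)
  }
  pooled <- switch(method,
    arithmetic = mean(r),
    geometric = exp(mean(log(r)))
  )
  if (method == "arithmetic" && warn) {
    warning("arithmetic pooling of ratios; field convention would call the ",
            "pooled proportional difference a geometric mean", call. = FALSE)
  }
  out <- data.frame(
    enzyme = records$enzyme[1L], endpoint = records$endpoint[1L],
    n_studies = length(r), pooled_ratio = pooled,
    ratio_min = min(r), ratio_max = max(r), method = method,
    stringsAsFactors = FALSE
  )
  class(out) <- c("pooled_effect", class(out))
  out
}

#' Pool a multi-enzyme study table, one effect per enzyme
#'
#' Splits `records` by enzyme (and optionally by model system, the
#' sensitivity-analysis stratum) and pools each group with [pool_ratios()].
#'
#' @inheritParams pool_ratios
#' @param by_system also stratify by `model_system`
#' @return a `pooled_effect` data frame, one row per group, ordered by enzyme
#' @export
pool_by_enzyme <- function(records, method = c("arithmetic", "geometric"),
                           by_system = FALSE, warn = FALSE) {
  method <- match.arg(method)
  keys <- if (by_system) {
    interaction(records$enzyme, records$endpoint, records$model_system,
                drop = TRUE)
  } else {
    interaction(records$enzyme, records$endpoint, drop = TRUE)
  }
  parts <- split(records, keys)
  out <- do.call(rbind, lapply(parts, function(g) {
    eff <- pool_ratios(g, method = method, warn = warn)
    if (by_system) eff$model_system <- g$model_system[1L]
    eff
  }))
  out <- out[order(match(out$enzyme, CYP_ENZYMES)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pooled_effect", "data.frame")
  out
}

#' Orient a pooled activity effect as an observed exposure-ratio comparator
#'
#' Pooled activity effects are MAFLD/control ratios (< 1 for reduced
#' activity). Simulated exposure comparisons are MAFLD/healthy AUC ratios
#' (> 1 when clearance falls). The reciprocal of the pooled activity ratio
#' therefore serves as the observed comparator on the exposure-ratio scale.
#'
#' @param effect a `pooled_effect` row (or a data frame of them)
#' @param round_first round the pooled ratio to 2 decimals before taking the
#'   reciprocal (matches reference tables whose reciprocal column was
#'   computed from already-rounded pooled values)
#' @return numeric vector of control/MAFLD ratios, named by enzyme
#' @examples
#' to_observed_activity_ratio(data.frame(enzyme = "CYP2C19",
#'   pooled_ratio = 0.42))  # 2.38
#' @export
to_observed_activity_ratio <- function(effect, round_first = FALSE) {
  p <- effect$pooled_ratio
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("pooled ratio must be finite and > 0", call. = FALSE)
  }
  if (round_first) p <- round(p, 2)
  stats::setNames(1 / p, effect$enzyme)
}
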