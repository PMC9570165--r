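#' @title Packaged reference and comparator tables
#' @description In-code constructors for the observed and simulated
#'   reference values this analysis reproduces: the compilation of
#'   study-level in vitro CYP activity ratios, the reference virtual-trial
#'   exposure summaries, and the in vitro / animal comparator tables used
#'   for mean-fold-error validation. Keeping them as plain constructors
#'   makes every downstream number recomputable from these inputs.
#' @name reference_data
NULL

#' Study-level in vitro CYP activity ratios (MAFLD/control)
#'
#' One row per published probe-reaction measurement comparing metabolic
#' activity in an in vitro MAFLD model with its healthy control, across the
#' five major CYPs. These are the inputs to [pool_ratios()]; their
#' arithmetic pooled means are 0.52, 0.96, 0.42, 0.68 and 0.49 for
#' CYP1A2/2C9/2C19/2D6/3A4.
#'
#' @return a `study_records` data frame (22 rows)
#' @export
invitro_activity_studies <- function() {
  rows <- list(
    list("CYP1A2", "7-methoxyresorufin O-demethylation", 0.46, "S1", "human_microsomes"),
    list("CYP1A2", "Phenacetin O-deethylation",           0.58, "S2", "human_microsomes"),
    list("CYP2C9", "Diclofenac 4'-hydroxylation",         0.82, "S1", "human_microsomes"),
    list("CYP2C9", "Testosterone 16b-hydroxylation",      0.64, "S1", "human_microsomes"),
    list("CYP2C9", "Testosterone 16b-hydroxylation",      0.40, "S3", "human_microsomes"),
    list("CYP2C9", "Diclofenac 4'-hydroxylation",         1.53, "S2", "human_microsomes"),
    list("CYP2C9", "Tolbutamide 4-hydroxylation",         1.42, "S2", "human_microsomes"),
    list("CYP2C19", "Androstenedione",                    0.46, "S1", "human_microsomes"),
    list("CYP2C19", "Testosterone 16b-hydroxylation",     0.40, "S3", "human_microsomes"),
    list("CYP2C19", "Androstenedione",                    0.62, "S3", "human_microsomes"),
    list("CYP2C19", "Mephenytoin 4'-hydroxylation",       0.21, "S2", "human_microsomes"),
    list("CYP2D6", "Dextromethorphan O-demethylation",    0.68, "S2", "human_microsomes"),
    list("CYP3A4", "Midazolam 1'-hydroxylation",          0.45, "S4", "human_hepatocytes"),
    list("CYP3A4", "Testosterone 6b-hydroxylation",       0.55, "S1", "human_microsomes"),
    list("CYP3A4", "Testosterone 6b-hydroxylation",       0.57, "S1", "human_microsomes"),
    list("CYP3A4", "Testosterone 2b-hydroxylation",       0.41, "S1", "human_microsomes"),
    list("CYP3A4", "Testosterone 15b-hydroxylation",      0.55, "S3", "human_microsomes"),
    list("CYP3A4", "Testosterone 6b-hydroxylation",       0.44, "S3", "human_microsomes"),
    list("CYP3A4", "Testosterone 2b-hydroxylation",       0.43, "S3", "human_microsomes"),
    list("CYP3A4", "Testosterone 6b-hydroxylation",       0.46, "S5", "human_microsomes"),
    list("CYP3A4", "Midazolam 1'-hydroxylation",          0.41, "S4", "human_hepatocytes"),
    list("CYP3A4", "Midazolam 1'-hydroxylation",          0.61, "S6", "biopsy")
  )
  study_records(
    enzyme = vapply(rows, `[[`, "", 1),
    endpoint = "activity",
    ratio = vapply(rows, `[[`, 0, 3),
    probe_reaction = vapply(rows, `[[`, "", 2),
    source_ref = vapply(rows, `[[`, "", 4),
    model_system = vapply(rows, `[[`, "", 5)
  )
}

#' Reference virtual-trial exposure summary (geometric means and ratios)
#'
#' The published geometric-mean AUC (ng/mL.h) and Cmax (ng/mL) of each
#' probe substrate in matched healthy and MAFLD virtual populations
#' (n = 200 each), after single and multiple oral dosing, together with the
#' printed MAFLD/healthy ratios. The healthy single-dose metoprolol Cmax is
#' carried as NA: the source prints a value inconsistent with its own
#' interval (a typo), so only its printed ratio is retained.
#'
#' @return data frame with columns `compound, enzyme, regimen, metric,
#'   healthy, mafld, printed_ratio`
#' @export
reference_exposure_table <- function() {
  g <- function(compound, enzyme, regimen, metric, healthy, mafld, printed)
    data.frame(compound = compound, enzyme = enzyme, regimen = regimen,
               metric = metric, healthy = healthy, mafld = mafld,
               printed_ratio = printed)
  rbind(
    g("caffeine", "CYP1A2", "single", "cmax", 3399, 3885, 1.14),
    g("caffeine", "CYP1A2", "single", "auc", 23712, 50331, 2.12),
    g("caffeine", "CYP1A2", "multiple", "cmax", 3597, 5568, 1.55),
    g("caffeine", "CYP1A2", "multiple", "auc", 25130, 72715, 2.89),
    g("clozapine", "CYP1A2", "single", "cmax", 54.4, 62.6, 1.15),
    g("clozapine", "CYP1A2", "single", "auc", 436, 788, 1.81),
    g("clozapine", "CYP1A2", "multiple", "cmax", 58.4, 81.3, 1.39),
    g("clozapine", "CYP1A2", "multiple", "auc", 469, 1026, 2.19),
    g("s-warfarin", "CYP2C9", "single", "cmax", 924, 866, 0.94),
    g("s-warfarin", "CYP2C9", "single", "auc", 15458, 15500, 1.00),
    g("s-warfarin", "CYP2C9", "multiple", "cmax", 1877, 1983, 1.06),
    g("s-warfarin", "CYP2C9", "multiple", "auc", 31630, 35778, 1.13),
    g("rosiglitazone", "CYP2C9", "single", "cmax", 245, 241, 0.98),
    g("rosiglitazone", "CYP2C9", "single", "auc", 1152, 1331, 1.16),
    g("rosiglitazone", "CYP2C9", "multiple", "cmax", 248, 247, 0.99),
    g("rosiglitazone", "CYP2C9", "multiple", "auc", 1166, 1364, 1.17),
    g("omeprazole", "CYP2C19", "single", "cmax", 153, 236, 1.54),
    g("omeprazole", "CYP2C19", "single", "auc", 467, 1174, 2.52),
    g("omeprazole", "CYP2C19", "multiple", "cmax", 191, 323, 1.70),
    g("omeprazole", "CYP2C19", "multiple", "auc", 666, 2112, 3.17),
    g("dextromethorphan", "CYP2D6", "single", "cmax", 4.25, 5.08, 1.20),
    g("dextromethorphan", "CYP2D6", "single", "auc", 49.9, 66.0, 1.32),
    g("dextromethorphan", "CYP2D6", "multiple", "cmax", 7.56, 10.1, 1.33),
    g("dextromethorphan", "CYP2D6", "multiple", "auc", 63.6, 89.8, 1.41),
    g("metoprolol", "CYP2D6", "single", "cmax", NA, 172, 1.22),
    g("metoprolol", "CYP2D6", "single", "auc", 841, 1223, 1.45),
    g("metoprolol", "CYP2D6", "multiple", "cmax", 145, 180, 1.24),
    g("metoprolol", "CYP2D6", "multiple", "auc", 863, 1276, 1.48),
    g("midazolam", "CYP3A4", "single", "cmax", 18.7, 20.7, 1.11),
    g("midazolam", "CYP3A4", "single", "auc", 54.7, 84.8, 1.55),
    g("midazolam", "CYP3A4", "multiple", "cmax", 19.9, 23.4, 1.18),
    g("midazolam", "CYP3A4", "multiple", "auc", 56.1, 89.7, 1.60)
  )
}

#' Enzyme-level in vitro comparator table
#'
#' Observed in vitro activity ratios (oriented control/MAFLD, i.e. on the
#' exposure-ratio scale) and the corresponding simulated single-dose probe
#' AUC ratios (MAFLD/healthy), one row per enzyme.
#'
#' @return data frame with columns `enzyme, observed_ratio,
#'   simulated_ratio, printed_mfe`
#' @export
invitro_comparator_table <- function() {
  data.frame(
    enzyme = CYP_ENZYMES,
    observed_ratio = c(1.93, 1.04, 2.38, 1.46, 2.03),
    simulated_ratio = c(2.12, 1.00, 2.52, 1.32, 1.55),
    printed_mfe = c(1.10, 1.04, 1.06, 1.11, 1.31)
  )
}

#' Animal-model PK comparator table
#'
#' Observed MAFLD/control AUC and Cmax ratios from pre-clinical animal
#' studies of each probe substrate, with the corresponding simulated
#' human-population ratios.
#'
#' @return data frame with columns `enzyme, substrate, parameter,
#'   observed_ratio, simulated_ratio, printed_mfe`
#' @export
animal_comparator_table <- function() {
  r <- function(enzyme, substrate, parameter, obs, sim, printed)
    data.frame(enzyme = enzyme, substrate = substrate,
               parameter = parameter, observed_ratio = obs,
               simulated_ratio = sim, printed_mfe = printed)
  rbind(
    r("CYP1A2", "caffeine", "AUC", 2.90, 2.12, 1.37),
    r("CYP1A2", "caffeine", "Cmax", 2.50, 1.14, 2.19),
    r("CYP1A2", "clozapine", "AUC", 1.20, 1.81, 1.50),
    r("CYP1A2", "clozapine", "Cmax", 0.69, 1.15, 1.66),
    r("CYP2C9", "rosiglitazone", "AUC", 2.41, 1.16, 2.08),
    r("CYP2C9", "rosiglitazone", "Cmax", 0.86, 0.982, 1.14),
    r("CYP2C19", "omeprazole", "AUC", 11.1, 2.52, 4.40),
    r("CYP2C19", "omeprazole", "Cmax", 6.50, 1.54, 4.23),
    r("CYP2D6", "dextromethorphan", "AUC", 2.69, 1.32, 2.03),
    r("CYP2D6", "dextromethorphan", "Cmax", 3.31, 1.20, 2.77),
    r("CYP2D6", "metoprolol", "AUC", 2.28, 1.45, 1.57),
    r("CYP2D6", "metoprolol", "Cmax", 1.41, 1.22, 1.16),
    r("CYP3A4", "midazolam", "AUC", 1.55, 1.55, 1.00),
    r("CYP3A4", "midazolam", "Cmax", 1.22, 1.11, 1.10)
  )
}
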