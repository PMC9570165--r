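#' @title Mean-fold-error validation against observed comparators
#' @name validation
NULL

#' Absolute mean fold error between a simulated and observed ratio
#'
#' `max(sim/obs, obs/sim)`, always >= 1 regardless of which ratio is
#' larger. Symmetric and scale-invariant.
#'
#' @param simulated_ratio,observed_ratio positive ratios
#' @return fold error >= 1 (vectorised)
#' @examples
#' mfe(2.12, 1.93)  # 1.10
#' @export
mfe <- function(simulated_ratio, observed_ratio) {
  if (any(!is.finite(simulated_ratio)) || any(simulated_ratio <= 0) ||
      any(!is.finite(observed_ratio)) || any(observed_ratio <= 0)) {
    stop("both ratios must be finite and > 0", call. = FALSE)
  }
  pmax(simulated_ratio / observed_ratio, observed_ratio / simulated_ratio)
}

#' Classify concordance from a mean fold error
#'
#' A fold error within 2-fold (inclusive) is classed `"robust"`, otherwise
#' `"poor"`.
#'
#' @param mfe_value fold error(s) >= 1
#' @return character vector, `"robust"` or `"poor"`
#' @export
classify_concordance <- function(mfe_value) {
  if (any(!is.finite(mfe_value)) || any(mfe_value < 1)) {
    stop("a mean fold error is >= 1 by construction", call. = FALSE)
  }
  ifelse(mfe_value <= 2, "robust", "poor")
}

#' Build validation tables against in vitro and animal comparators
#'
#' The in vitro arm compares each enzyme's simulated MAFLD/healthy probe
#' AUC ratio with the reciprocal of the pooled in vitro activity ratio (via
#' [to_observed_activity_ratio()]); the animal arm compares per-substrate
#' simulated ratios with observed animal MAFLD/control PK ratios, and adds
#' per-enzyme averages of the substrate-level AUC fold errors. Comparators
#' with no matching simulated entry are listed with NA fold errors rather
#' than raising an error.
#'
#' @param simulated data frame with columns `enzyme, substrate, parameter`
#'   (`"AUC"`/`"Cmax"`) and `simulated_ratio` (MAFLD/healthy geometric-mean
#'   ratios)
#' @param observed_invitro a `pooled_effect` data frame of in vitro
#'   activity effects (one per enzyme), or NULL to skip that arm
#' @param observed_animal data frame with columns `enzyme, substrate,
#'   parameter, observed_ratio` of animal PK comparators, or NULL
#' @return list with data frames `invitro` (enzyme-level), `animal`
#'   (substrate/parameter-level) and `animal_enzyme_average` (per-enzyme
#'   mean of substrate AUC fold errors)
#' @export
build_validation_tables <- function(simulated,
                                    observed_invitro = NULL,
                                    observed_animal = NULL) {
  stopifnot(is.data.frame(simulated),
            all(c("enzyme", "parameter", "simulated_ratio") %in%
                  names(simulated)))
  out <- list(invitro = NULL, animal = NULL, animal_enzyme_average = NULL)

  if (!is.null(observed_invitro) && nrow(observed_invitro) > 0) {
    obs <- to_observed_activity_ratio(observed_invitro)
    sim_auc <- simulated[simulated$parameter == "AUC", , drop = FALSE]
    inv <- do.call(rbind, lapply(names(obs), function(enz) {
      sim <- sim_auc$simulated_ratio[sim_auc$enzyme == enz]
      sim <- if (length(sim)) sim[1] else NA_real_
      fe <- if (is.na(sim)) NA_real_ else mfe(sim, obs[[enz]])
      data.frame(enzyme = enz, observed_ratio = unname(obs[[enz]]),
                 simulated_ratio = sim, mfe = fe,
                 concordance = ifelse(is.na(fe), NA_character_,
                                      classify_concordance(fe)))
    }))
    out$invitro <- inv
  }

  if (!is.null(observed_animal) && nrow(observed_animal) > 0) {
    key <- function(d) paste(d$substrate, d$parameter)
    an <- observed_animal
    idx <- match(key(an), key(simulated))
    an$simulated_ratio <- simulated$simulated_ratio[idx]
    ok <- !is.na(an$simulated_ratio)
    an$mfe <- NA_real_
    an$mfe[ok] <- mfe(an$simulated_ratio[ok], an$observed_ratio[ok])
    an$concordance <- NA_character_
    an$concordance[ok] <- classify_concordance(an$mfe[ok])
    out$animal <- an
    auc <- an[an$parameter == "AUC" & !is.na(an$mfe), , drop = FALSE]
    if (nrow(auc)) {
      avg <- stats::aggregate(mfe ~ enzyme, data = auc, FUN = mean)
      names(avg)[2] <- "mean_auc_mfe"
      avg <- avg[order(match(avg$enzyme, CYP_ENZYMES)), , drop = FALSE]
      rownames(avg) <- NULL
      out$animal_enzyme_average <- avg
    }
  }
  out
}
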