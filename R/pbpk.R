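#' @title Minimal PBPK engine: IVIVE scaling, well-stirred liver, oral PK
#' @description One-compartment oral PK with first-order absorption and
#'   hepatic first-pass, where hepatic clearance is scaled from a subject's
#'   per-CYP microsomal abundances (in vitro-in vivo extrapolation) through
#'   the well-stirred liver model. Exposure endpoints (AUC, Cmax) respond to
#'   population differences in CYP abundance, haematocrit and body size;
#'   peripheral compartmentalisation is deliberately omitted because
#'   between-population exposure ratios driven by clearance are insensitive
#'   to it.
#' @name pbpk_engine
NULL

#' Create a compound profile
#'
#' Drug-specific physiochemical and metabolic parameters used by the engine.
#' Per-CYP intrinsic clearances are expressed per pmol of enzyme so that
#' subject-level abundances scale them; `clint_other` captures non-CYP
#' microsomal clearance per mg protein.
#'
#' @param name compound label
#' @param dose_mg default oral dose, mg
#' @param ka first-order absorption rate constant, 1/h
#' @param fa_fg fraction of the dose reaching the liver (absorption x gut
#'   wall escape), in (0, 1]
#' @param fu fraction unbound in plasma, in (0, 1]
#' @param bp_ratio blood-to-plasma concentration ratio at the reference
#'   haematocrit
#' @param bp_ref_hct haematocrit (percent) at which `bp_ratio` was measured
#' @param vss volume of distribution at steady state, L/kg
#' @param clint_per_pmol named numeric, uL/min/pmol per CYP (missing CYPs
#'   are treated as 0)
#' @param clint_other non-CYP hepatic intrinsic clearance, uL/min/mg
#'   microsomal protein
#' @param cl_renal renal (plasma) clearance, L/h
#' @param fm_cyp named fraction of hepatic clearance per CYP (documentation
#'   of the intended metabolic fingerprint; must sum to <= 1)
#' @param mm optional saturable-elimination block `list(vmax, km)`: `vmax`
#'   in mg/h whole liver, `km` in mg/L unbound blood concentration. `NULL`
#'   (default) selects the linear closed-form engine.
#' @return list of class `compound_profile`
#' @export
compound_profile <- function(name, dose_mg, ka, fa_fg, fu, bp_ratio,
                             vss, clint_per_pmol, clint_other = 0,
                             cl_renal = 0, fm_cyp = NULL,
                             bp_ref_hct = 45, mm = NULL) {
  stopifnot(dose_mg > 0, ka > 0, fa_fg > 0, fa_fg <= 1,
            fu > 0, fu <= 1, bp_ratio > 0, vss > 0,
            clint_other >= 0, cl_renal >= 0)
  ci <- stats::setNames(numeric(length(CYP_ENZYMES)), CYP_ENZYMES)
  ci[names(clint_per_pmol)] <- clint_per_pmol
  if (any(ci < 0)) stop("intrinsic clearances must be >= 0", call. = FALSE)
  if (!is.null(fm_cyp) && sum(fm_cyp) > 1 + 1e-9) {
    stop("fm values must sum to <= 1", call. = FALSE)
  }
  if (!is.null(mm)) stopifnot(mm$vmax > 0, mm$km > 0)
  structure(list(
    name = name, dose_mg = dose_mg, ka = ka, fa_fg = fa_fg, fu = fu,
    bp_ratio = bp_ratio, bp_ref_hct = bp_ref_hct, vss = vss,
    clint_per_pmol = ci, clint_other = clint_other, cl_renal = cl_renal,
    fm_cyp = fm_cyp, mm = mm
  ), class = "compound_profile")
}

#' Create a dosing regimen
#'
#' @param dose_mg dose per administration, mg
#' @param interval_h dosing interval, h (> 0)
#' @param n_doses number of doses (>= 1)
#' @param window_h observation window after the last dose, h
#' @return list of class `dose_regimen`
#' @export
dose_regimen <- function(dose_mg, interval_h = 24, n_doses = 1,
                         window_h = 24) {
  stopifnot(dose_mg > 0, interval_h > 0, n_doses >= 1, window_h > 0)
  structure(list(dose_mg = dose_mg, interval_h = interval_h,
                 n_doses = as.integer(n_doses), window_h = window_h),
            class = "dose_regimen")
}

#' Standard single- and multiple-dose regimens for a compound
#'
#' Multiple dosing uses 10 doses at the compound's interval (24 h by
#' default; 12 h for midazolam and dextromethorphan) with a 24 h window
#' after the last dose.
#'
#' @param compound a [compound_profile()]
#' @param type `"single"` or `"multiple"`
#' @param interval_h override the dosing interval
#' @return a [dose_regimen()]
#' @export
standard_regimen <- function(compound, type = c("single", "multiple"),
                             interval_h = NULL) {
  type <- match.arg(type)
  if (is.null(interval_h)) {
    interval_h <- if (tolower(compound$name) %in%
                      c("midazolam", "dextromethorphan")) 12 else 24
  }
  if (type == "single") {
    dose_regimen(compound$dose_mg, interval_h = interval_h, n_doses = 1,
                 window_h = 24)
  } else {
    dose_regimen(compound$dose_mg, interval_h = interval_h, n_doses = 10,
                 window_h = 24)
  }
}

#' Whole-liver intrinsic clearance of a subject for a compound
#'
#' IVIVE scale-up: per-mg microsomal intrinsic clearance (sum over CYPs of
#' abundance x per-pmol clearance, plus non-CYP clearance) is multiplied by
#' MPPGL (mg microsomal protein per g liver) and liver mass (g), then
#' converted from uL/min to L/h.
#'
#' @param subject a `subject` (see [sample_subject()])
#' @param compound a [compound_profile()]
#' @return whole-liver unbound intrinsic clearance, L/h
#' @examples
#' # 100 pmol/mg x 1 uL/min/pmol x 40 mg/g x 1650 g = 6.6 L/min = 396 L/h
#' @export
whole_liver_clint <- function(subject, compound) {
  ab <- subject$cyp_abundance[CYP_ENZYMES]
  if (any(ab < 0)) stop("abundances must be >= 0", call. = FALSE)
  per_mg <- sum(ab * compound$clint_per_pmol[CYP_ENZYMES]) +
    compound$clint_other                       # uL/min/mg
  per_mg * subject$mppgl * subject$liver_mass * 60 / 1e6   # L/h
}

#' Well-stirred hepatic clearance
#'
#' `CL_H = Q_H * fu_b * CLint / (Q_H + fu_b * CLint)`, all in blood terms.
#'
#' @param clint_liver whole-liver unbound intrinsic clearance, L/h
#' @param fu_blood fraction unbound in blood (`fu / bp_ratio`)
#' @param q_h hepatic blood flow, L/h (> 0)
#' @return hepatic blood clearance, L/h
#' @export
hepatic_clearance <- function(clint_liver, fu_blood, q_h) {
  stopifnot(clint_liver >= 0, fu_blood >= 0)
  if (q_h <= 0) stop("hepatic blood flow must be > 0", call. = FALSE)
  q_h * fu_blood * clint_liver / (q_h + fu_blood * clint_liver)
}

# blood:plasma ratio adjusted for the subject's haematocrit, holding the
# red-cell partition fixed at the compound's reference haematocrit
subject_bp_ratio <- function(subject, compound) {
  1 + (compound$bp_ratio - 1) *
    (subject$haematocrit / compound$bp_ref_hct)
}

# fraction unbound under an altered plasma-protein concentration
# (albumin_ratio = disease/healthy); ratio 1 leaves fu unchanged
adjust_fu <- function(fu, albumin_ratio) {
  1 / (1 + albumin_ratio * (1 - fu) / fu)
}

# the scalar PK parameters the closed form needs, derived once per subject
pk_parameters <- function(subject, compound) {
  bp <- subject_bp_ratio(subject, compound)
  fu <- adjust_fu(compound$fu, subject$albumin_ratio)
  fu_b <- fu / bp
  clint <- whole_liver_clint(subject, compound)
  q_h <- subject$hepatic_blood_flow
  cl_h_blood <- hepatic_clearance(clint, fu_b, q_h)
  e_h <- cl_h_blood / q_h
  f_oral <- compound$fa_fg * (1 - e_h)
  cl_plasma <- cl_h_blood * bp + compound$cl_renal
  v <- compound$vss * subject$weight
  list(fu = fu, fu_b = fu_b, bp = bp, clint = clint, q_h = q_h,
       cl_h_blood = cl_h_blood, e_h = e_h, f_oral = f_oral,
       cl_plasma = cl_plasma, v = v, ke = cl_plasma / v,
       ka = compound$ka)
}

# Bateman curve for a unit of F*Dose, vectorised over t (t < 0 -> 0);
# ng/mL given dose mg and V in L. ka == ke handled by its limit.
bateman <- function(t, dose_mg, f_oral, v, ka, ke) {
  out <- numeric(length(t))
  pos <- t >= 0
  tt <- t[pos]
  scale <- 1000 * f_oral * dose_mg / v        # mg/L -> ng/mL
  if (abs(ka - ke) < 1e-8 * max(ka, ke)) {
    out[pos] <- scale * ka * tt * exp(-ka * tt)
  } else {
    out[pos] <- scale * ka / (ka - ke) * (exp(-ke * tt) - exp(-ka * tt))
  }
  out
}

#' Simulate a concentration-time profile for one subject
#'
#' Linear mode (the default, when the compound has no `mm` block) evaluates
#' the closed-form one-compartment first-order-absorption solution with
#' hepatic first-pass (`F = fa_fg * (1 - E_H)`), superposed across doses.
#' With an `mm` block, the same structure is integrated numerically with
#' saturable whole-liver intrinsic clearance `CLint(Cu) = vmax / (km + Cu)`
#' (so the low-concentration limit `vmax/km` plays the role of the linear
#' CLint).
#'
#' @param subject a `subject`
#' @param compound a [compound_profile()]
#' @param regimen a [dose_regimen()]
#' @param dt grid step, h
#' @return list of class `pk_profile` with `times` (h) and `conc` (ng/mL
#'   plasma), covering 0 to last dose + window
#' @export
simulate_regimen <- function(subject, compound, regimen, dt = 0.05) {
  p <- pk_parameters(subject, compound)
  t_end <- (regimen$n_doses - 1) * regimen$interval_h + regimen$window_h
  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  dose_times <- (seq_len(regimen$n_doses) - 1) * regimen$interval_h
  if (is.null(compound$mm)) {
    conc <- Reduce(`+`, lapply(dose_times, function(td) {
      bateman(times - td, regimen$dose_mg, p$f_oral, p$v, p$ka, p$ke)
    }))
  } else {
    conc <- simulate_mm(subject, compound, regimen, p, times, dose_times)
  }
  structure(list(times = times, conc = pmax(conc, 0),
                 subject = subject, compound = compound$name,
                 regimen = regimen),
            class = "pk_profile")
}

# numerical integration with Michaelis-Menten whole-liver clearance;
# states: gut amount (mg), central amount (mg)
simulate_mm <- function(subject, compound, regimen, p, times, dose_times) {
  vmax <- compound$mm$vmax   # mg/h
  km <- compound$mm$km       # mg/L unbound blood
  bp <- p$bp
  rhs <- function(t, y, parms) {
    c_plasma <- y[["central"]] / p$v     # mg/L
    cu_blood <- c_plasma * bp * p$fu_b   # unbound blood conc
    clint_c <- vmax / (km + cu_blood)    # L/h, concentration-dependent
    cl_h <- hepatic_clearance(clint_c, p$fu_b, p$q_h)
    list(c(-p$ka * y[["gut"]],
           p$f_oral * p$ka * y[["gut"]] -
             (cl_h * bp + compound$cl_renal) * c_plasma))
  }
  events <- data.frame(var = "gut", time = dose_times,
                       value = regimen$dose_mg, method = "add")
  t_all <- sort(unique(c(times, dose_times)))
  sol <- deSolve::lsoda(c(gut = 0, central = 0), t_all, rhs, parms = NULL,
                        rtol = 1e-8, atol = 1e-10,
                        events = list(data = events))
  if (attr(sol, "istate")[1] < 0) {
    stop("saturable-elimination integration failed to converge",
         call. = FALSE)
  }
  amount <- stats::approx(sol[, 1], sol[, 3], xout = times)$y
  1000 * amount / p$v                     # ng/mL
}

#' AUC, Cmax and Tmax of a simulated profile over a window
#'
#' AUC by the trapezoidal rule over `window`; Cmax/Tmax from the grid
#' restricted to the window.
#'
#' @param profile a `pk_profile`
#' @param window numeric length-2 `c(start, end)` in h; defaults to the
#'   window after the last dose implied by the profile's regimen
#' @return list of class `pk_metrics` with `auc` (ng/mL.h), `cmax` (ng/mL),
#'   `tmax` (h)
#' @export
pk_metrics <- function(profile, window = NULL) {
  if (is.null(window)) {
    reg <- profile$regimen
    t0 <- (reg$n_doses - 1) * reg$interval_h
    window <- c(t0, t0 + reg$window_h)
  }
  tr <- range(profile$times)
  if (window[1] < tr[1] - 1e-9 || window[2] > tr[2] + 1e-9) {
    stop("requested window is outside the simulated grid", call. = FALSE)
  }
  keep <- profile$times >= window[1] - 1e-9 & profile$times <= window[2] + 1e-9
  tt <- profile$times[keep]
  cc <- profile$conc[keep]
  i <- which.max(cc)
  structure(list(auc = pracma::trapz(tt, cc), cmax = cc[i], tmax = tt[i]),
            class = "pk_metrics")
}

#' Analytic single-dose oral AUC to infinity (linear engine)
#'
#' `AUC_0-inf = F * Dose / CL_total` in ng/mL.h; the independent closed form
#' against which the trapezoidal grid AUC is verified.
#'
#' @param subject a `subject`
#' @param compound a linear [compound_profile()]
#' @param dose_mg dose, mg (defaults to the compound's)
#' @return AUC, ng/mL.h
#' @export
auc_inf_linear <- function(subject, compound, dose_mg = compound$dose_mg) {
  p <- pk_parameters(subject, compound)
  1000 * p$f_oral * dose_mg / p$cl_plasma
}

#' Analytic AUC of the Bateman curve over a finite window
#'
#' Closed-form integral of the one-compartment oral solution from 0 to `t`,
#' used as an oracle for trapezoidal integration.
#'
#' @inheritParams auc_inf_linear
#' @param t upper limit, h
#' @return AUC from 0 to `t`, ng/mL.h
#' @export
auc_window_linear <- function(subject, compound, t,
                              dose_mg = compound$dose_mg) {
  p <- pk_parameters(subject, compound)
  scale <- 1000 * p$f_oral * dose_mg / p$v * p$ka / (p$ka - p$ke)
  scale * ((1 - exp(-p$ke * t)) / p$ke - (1 - exp(-p$ka * t)) / p$ka)
}

#' Analytic AUC ratio for a low-extraction, hepatically cleared oral drug
#'
#' For a linear, low-extraction compound cleared entirely in the liver, the
#' oral AUC is inversely proportional to total intrinsic clearance, so
#' scaling each CYP's abundance by `s_i` changes AUC by
#' `1 / (sum(fm_i * s_i) + 1 - sum(fm_i))`. Used to calibrate disease
#' scalars and as an independent oracle for the simulation engine.
#'
#' @param fm named per-CYP fractions metabolised (sum <= 1)
#' @param scalars named per-CYP abundance fold-changes (> 0)
#' @return dimensionless AUC fold-change (disease/healthy)
#' @examples
#' auc_ratio_low_extraction(c(CYP1A2 = 0.95), c(CYP1A2 = 0.37))  # 2.491
#' @export
auc_ratio_low_extraction <- function(fm, scalars) {
  fm_sum <- sum(fm)
  stopifnot(fm_sum <= 1 + 1e-9, all(fm >= 0))
  s <- scalars[names(fm)]
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop("a scalar must be supplied (> 0) for every fm entry", call. = FALSE)
  }
  1 / (sum(fm * s) + 1 - fm_sum)
}

#' Back-calculate a single-enzyme abundance scalar from a target AUC ratio
#'
#' Inverts [auc_ratio_low_extraction()] for one enzyme:
#' `s = (1/ratio - 1 + fm) / fm`.
#'
#' @param target_ratio disease/healthy AUC fold-change
#' @param fm fraction metabolised by the enzyme
#' @return the abundance fold-change
#' @export
scalar_from_auc_ratio <- function(target_ratio, fm) {
  stopifnot(target_ratio > 0, fm > 0, fm <= 1)
  s <- (1 / target_ratio - 1 + fm) / fm
  if (s <= 0) {
    stop("target ratio unreachable with fm = ", fm, call. = FALSE)
  }
  s
}
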