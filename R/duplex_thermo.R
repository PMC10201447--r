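## Core thermodynamics: NN summation, free energy at temperature,
## two-state bimolecular melting temperature, and the inverse van't
## Hoff analysis of Tm versus strand concentration.

#' Predict duplex thermodynamics from a nearest-neighbor table
#'
#' Sums the tabulated contributions of every propagating NN stack, the
#' helix-initiation parameter, the per-terminal-AU penalty and (for
#' self-complementary strands) the symmetry correction.  Declared G.U
#' wobbles are normalized to A.U before lookup.
#'
#' @param duplex A [duplex_spec()] (or top-strand string, coerced).
#' @param params An `nn_param_set` from [load_parameter_set()] or
#'   [compose_condition_parameters()].
#'
#' @return Object of class `duplex_thermo` with fields `dH` (kcal/mol),
#'   `dS` (kcal/mol/K), `dG37` (kcal/mol), a named `breakdown` of every
#'   dG37 term (one entry per stack occurrence, initiation, terminal AU,
#'   symmetry, and any whole-duplex correction), `self_complementary`,
#'   `n_bp`, `condition_label` and `warnings`.  `dH`/`dS` are `NA` for
#'   composed dG37-only sets.
#' @examples
#' ps <- load_parameter_set()
#' predict_duplex("GGCUGUUC", ps)$dG37    # -8.98
#' @export
predict_duplex <- function(duplex, params) {
  stopifnot(inherits(params, "nn_param_set"))
  duplex <- .as_duplex(duplex)
  warnings <- character(0)
  if (length(duplex$wobble_positions))
    warnings <- c(warnings, paste0(
      "G.U wobble(s) at ", paste(duplex$wobble_positions, collapse = ","),
      " treated as A.U (terminal wobbles count as terminal A.U)"))
  eff <- wobble_normalize(duplex)
  steps <- nn_steps(eff)
  tab <- params$table
  missing_steps <- setdiff(unique(steps), rownames(tab))
  if (length(missing_steps))
    stop("parameter set lacks stack(s): ", paste(missing_steps, collapse = ", "))
  n_tau <- count_terminal_au(eff)

  terms <- c(steps, "initiation", rep("terminal_AU", n_tau),
             if (duplex$self_complementary) "symmetry")
  breakdown <- stats::setNames(tab[terms, "dG37"], make.unique(terms, sep = "#"))
  dG37 <- sum(breakdown)
  if (params$has_enthalpy) {
    dH <- sum(tab[terms, "dH"])
    dS <- sum(tab[terms, "dS"])
  } else {
    dH <- NA_real_; dS <- NA_real_
  }

  correction <- attr(params, "post_correction")
  if (!is.null(correction)) {
    corrected <- switch(correction,
      potassium = potassium_correction(dG37),
      intracellular = intracellular_correction(dG37),
      stop("unknown post correction: ", correction))
    breakdown <- c(breakdown, cation_mode = corrected - dG37)
    dG37 <- sum(breakdown)   # keep the exact-sum invariant of the breakdown
    warnings <- c(warnings, paste0(
      "whole-duplex affine ", correction, " correction applied after the ",
      "Na+ prediction (regression fitted under PEG200-like crowding)"))
  }
  warnings <- c(warnings, attr(params, "condition_warnings"))

  structure(list(dH = dH, dS = dS, dG37 = dG37,
                 breakdown = breakdown,
                 self_complementary = duplex$self_complementary,
                 n_bp = duplex$n_bp,
                 duplex = duplex,
                 condition_label = params$condition_label,
                 warnings = warnings),
            class = "duplex_thermo")
}

#' @export
print.duplex_thermo <- function(x, digits = 2, ...) {
  cat("Duplex thermodynamics [", x$condition_label, "]\n", sep = "")
  cat("  ", x$duplex$top, " (", x$n_bp, " bp",
      if (x$self_complementary) ", self-complementary", ")\n", sep = "")
  if (!is.na(x$dH))
    cat(sprintf("  dH = %.*f kcal/mol; dS = %.*f cal/mol/K\n",
                digits, x$dH, digits, x$dS * 1000))
  cat(sprintf("  dG37 = %.*f kcal/mol\n", digits, x$dG37))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Free energy at an arbitrary temperature
#'
#' Evaluates `dG(T) = dH - T*dS` under the zero-heat-capacity-change
#' approximation (`dCp = 0`), which is justified only near 37 C; a
#' warning is issued when `|T - 310.15| > 25` K.
#'
#' @param thermo A `duplex_thermo`, or any list with numeric `dH`
#'   (kcal/mol) and `dS` (kcal/mol/K).
#' @param T Temperature in kelvin (> 0).
#' @return Free energy in kcal/mol.
#' @export
free_energy_at <- function(thermo, T) {
  stopifnot(is.numeric(T), T > 0)
  if (is.na(thermo$dH) || is.na(thermo$dS))
    stop("dH/dS unavailable (composed dG37-only parameter set); ",
         "free energy is defined only at 37 C for this prediction")
  if (abs(T - .T37) > 25)
    warning("extrapolating ", sprintf("%.0f", abs(T - .T37)),
            " K from 37 C with dCp = 0; treat the result with caution")
  thermo$dH - T * thermo$dS
}

#' Two-state bimolecular melting temperature
#'
#' Inverts the van't Hoff relation
#' `1/Tm = R ln(Ct/s)/dH + dS/dH` for the melting temperature of a
#' bimolecular duplex, where `Ct` is the total strand concentration and
#' `s` the symmetry factor (1 for self-complementary, 4 for
#' non-self-complementary strands).
#'
#' @param thermo A `duplex_thermo` (or list with `dH` in kcal/mol and
#'   `dS` in kcal/mol/K); `dH` must be negative.
#' @param Ct Total strand concentration, mol/L.
#' @param s Symmetry factor, 1 or 4; defaults to the duplex's own
#'   self-complementarity when `thermo` carries it.
#' @return Melting temperature in kelvin.
#' @examples
#' ps <- load_parameter_set()
#' th <- predict_duplex("GGCUGUUC", ps)
#' melting_temperature(th, Ct = 1e-4) - 273.15   # ~46.9 C
#' @export
melting_temperature <- function(thermo, Ct, s = NULL) {
  if (is.null(s))
    s <- if (isTRUE(thermo$self_complementary)) 1 else 4
  stopifnot(s %in% c(1, 4), is.numeric(Ct), Ct > 0)
  if (is.na(thermo$dH))
    stop("Tm prediction requires dH/dS; composed condition sets are ",
         "dG37-only, so Tm under arbitrary crowding is refused")
  if (thermo$dH >= 0)
    stop("no bimolecular melting is defined for dH >= 0")
  Tm <- 1 / (.R_KCAL * log(Ct / s) / thermo$dH + thermo$dS / thermo$dH)
  if (!is.finite(Tm) || Tm <= 0)
    stop("melting temperature is undefined for these parameters ",
         "(check the signs of dH and dS)")
  Tm
}

#' Van't Hoff analysis of melting temperature versus concentration
#'
#' Fits the ordinary least-squares line `1/Tm` versus `ln(Ct/s)`; the
#' slope equals `R/dH` and the intercept `dS/dH`, from which `dH`, `dS`
#' and `dG37` are recovered (with standard errors propagated from the
#' regression by the delta method).  On noiseless input generated from
#' [melting_temperature()] this is an exact round trip.
#'
#' @param points Data frame with columns `Ct` (total strand
#'   concentration, mol/L) and `Tm` (kelvin); at least two distinct
#'   `Ct` values.
#' @param s Symmetry factor, 1 (self-complementary) or 4.
#' @return Object of class `vant_hoff_fit`: list with `dH`, `dS`,
#'   `dG37`, standard errors `dH_se`, `dS_se`, `dG37_se`, the symmetry
#'   factor and the underlying `lm` fit.
#' @export
vant_hoff_fit <- function(points, s = 4) {
  stopifnot(s %in% c(1, 4))
  if (!all(c("Ct", "Tm") %in% names(points)))
    stop("points must have columns Ct and Tm")
  Ct <- points$Ct; Tm <- points$Tm
  stopifnot(all(Ct > 0), all(Tm > 0))
  if (length(unique(Ct)) < 2)
    stop("need at least two distinct strand concentrations")
  x <- log(Ct / s)
  fit <- stats::lm(I(1 / Tm) ~ x)
  a <- stats::coef(fit)[["x"]]          # R/dH
  b <- stats::coef(fit)[["(Intercept)"]]  # dS/dH
  dH <- .R_KCAL / a
  dS <- b * dH
  dG37 <- dH - .T37 * dS
  ## suppress summary.lm's perfect-fit warning: zero-residual input is a
  ## legitimate (noiseless round-trip) case here and yields zero SEs
  V <- suppressWarnings(stats::vcov(fit))
  ## gradients wrt (b, a): dH = R/a; dS = R b/a; dG = R/a - 310.15 R b/a
  gH <- c(0, -.R_KCAL / a^2)
  gS <- c(.R_KCAL / a, -.R_KCAL * b / a^2)
  gG <- gH - .T37 * gS
  se <- function(g) sqrt(drop(t(g) %*% V %*% g))
  structure(list(dH = dH, dS = dS, dG37 = dG37,
                 dH_se = se(gH), dS_se = se(gS), dG37_se = se(gG),
                 s = s, n = length(Ct), fit = fit),
            class = "vant_hoff_fit")
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat("van't Hoff fit (1/Tm vs ln(Ct/s), s =", x$s, ",", x$n, "points)\n")
  cat(sprintf("  dH   = %8.2f +- %.2f kcal/mol\n", x$dH, x$dH_se))
  cat(sprintf("  dS   = %8.2f +- %.2f cal/mol/K\n",
              x$dS * 1000, x$dS_se * 1000))
  cat(sprintf("  dG37 = %8.2f +- %.2f kcal/mol\n", x$dG37, x$dG37_se))
  invisible(x)
}
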