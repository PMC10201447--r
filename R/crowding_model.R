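## Environmental decomposition: compose condition-specific NN free
## energies from bulk, cation, excluded-volume and water-activity
## contributions; osmolality -> water activity conversion.

#' Water activity from measured osmolality
#'
#' Converts an osmometer reading to water activity through the water
#' potential: `ln(a_w) = Psi * M_w / (R T rho_w)` with
#' `Psi(kPa) = osmolality(mmol/kg) * 1e3 / (-400)`.
#'
#' @param osmolality Osmolality in mmol/kg (>= 0).
#' @param T Temperature in kelvin.
#' @return Water activity in `(0, 1]`; 1 for pure water.
#' @examples
#' water_activity_from_osmolality(1000)  # ~0.982
#' @export
water_activity_from_osmolality <- function(osmolality, T = 298.15) {
  if (any(osmolality < 0)) stop("osmolality must be non-negative")
  psi_kpa <- osmolality * 1e3 / (-400)
  ## Psi in Pa, M_w = 0.018 kg/mol, rho_w = 1000 kg/m^3, R = 8.314 J/mol/K
  exp(psi_kpa * 1e3 * 0.018 / (8.314 * T * 1000))
}

.load_cosolute_registry <- function() {
  if (is.null(.crowdnn_env$cosolutes)) {
    tab <- utils::read.delim(.extdata("cosolutes.tsv"),
                             stringsAsFactors = FALSE)
    rownames(tab) <- tab$name
    .crowdnn_env$cosolutes <- tab
  }
  .crowdnn_env$cosolutes
}

#' Describe a cosolute
#'
#' Looks up a bundled cosolute by name, or builds a custom one.  The
#' bundled registry covers the two chemical classes with distinct
#' water-activity slopes: cosolutes without vicinal hydroxyls (PEG200,
#' PEG400, PEG600, 2-methoxyethanol, 1,2-dimethoxyethane; `peg_class`)
#' and those with them (ethylene glycol, glycerol, 1,3-propanediol;
#' `diol_class`).  Monomer counts are 1 for the small cosolutes and
#' `round((M - 18)/44)` for PEGs (4 for PEG200).
#'
#' @param name Cosolute name (see above) or any label for a custom one.
#' @param molar_mass g/mol; required for custom cosolutes.
#' @param n_monomers Number of monomer units `N`; required for custom.
#' @param cls `"peg_class"`, `"diol_class"` or `"custom"`.
#' @param slope_ratio For `cls = "custom"`: the ratio `S_cs/S_PEG` of
#'   the cosolute's water-activity slope to PEG's.
#' @return Object of class `cosolute`.
#' @export
cosolute <- function(name, molar_mass = NULL, n_monomers = NULL,
                     cls = NULL, slope_ratio = NULL) {
  reg <- .load_cosolute_registry()
  if (name %in% rownames(reg) && is.null(molar_mass) && is.null(cls)) {
    row <- reg[name, ]
    out <- list(name = name, molar_mass = row$molar_mass,
                n_monomers = row$n_monomers, cls = row$class,
                slope_ratio = NULL)
  } else {
    if (is.null(molar_mass) || is.null(n_monomers) || is.null(cls))
      stop("unknown cosolute '", name, "'; for a custom cosolute supply ",
           "molar_mass, n_monomers and cls (bundled: ",
           paste(rownames(reg), collapse = ", "), ")")
    cls <- match.arg(cls, c("peg_class", "diol_class", "custom"))
    if (cls == "custom" && is.null(slope_ratio))
      stop("a custom-class cosolute requires slope_ratio (S_cs/S_PEG)")
    out <- list(name = name, molar_mass = molar_mass,
                n_monomers = n_monomers, cls = cls,
                slope_ratio = slope_ratio)
  }
  stopifnot(out$molar_mass > 0, out$n_monomers >= 1)
  structure(out, class = "cosolute")
}

#' Molal concentration of a cosolute from weight percent
#'
#' Weight percent is interpreted as grams of cosolute per 100 g of
#' water, so `C = 10 * wt_pct / molar_mass` mol/kg.  (This convention,
#' rather than mass fraction of the whole solution, reproduces the
#' tabulated excluded-volume reference values.)
#'
#' @param wt_pct Grams of cosolute per 100 g water (>= 0).
#' @param cosolute A [cosolute()] (or a bundled cosolute name).
#' @return Molality in mol/kg.
#' @examples
#' molality(40, "PEG200")  # 2.0
#' @export
molality <- function(wt_pct, cosolute) {
  stopifnot(wt_pct >= 0)
  if (is.character(cosolute)) cosolute <- crowdnn::cosolute(cosolute)
  10 * wt_pct / cosolute$molar_mass
}

#' Excluded volume of an RNA cylinder against a polymeric cosolute
#'
#' `V = N * l^2 * N_A * k * 1e-27` L/mol, where `N` is the number of
#' monomers in the cosolute, `l` the statistical segment length (in
#' angstroms) and `k` a geometrical factor derived from the RNA's
#' length and radius.
#'
#' @param N Monomer count of the cosolute (> 0).
#' @param l Statistical segment length in angstroms (> 0).
#' @param k Geometrical factor (> 0).
#' @return Excluded volume in L/mol.
#' @export
excluded_volume_generic <- function(N, l, k) {
  stopifnot(N > 0, l > 0, k > 0)
  N * l^2 * 6.022e23 * k * 1e-27
}

#' Change in excluded volume upon duplex formation
#'
#' @param V_dup Volume excluded by the duplex, L/mol.
#' @param V_ss Volume excluded by one single strand, L/mol.
#' @return `V_dup - 2 * V_ss`, L/mol.
#' @export
excluded_volume_change <- function(V_dup, V_ss) V_dup - 2 * V_ss

#' Excluded-volume contribution to duplex stability
#'
#' Length-parameterized excluded-volume free energy for RNA duplex
#' formation in a polymeric cosolute solution:
#' `dG37_ev_dup = (-0.019 n - 0.070) * C * N` kcal/mol, where `n` is
#' the number of base pairs, `C` the cosolute molality (mol/kg) and `N`
#' its monomer count.  The linear length dependence was calibrated on
#' 6-12 bp duplexes; a warning is issued outside that range.
#'
#' @param n_bp Number of base pairs (>= 2).
#' @param C Cosolute molality, mol/kg (>= 0).
#' @param N Monomer count of the cosolute (>= 1).
#' @return Free-energy contribution in kcal/mol (always <= 0).
#' @examples
#' excluded_volume_duplex(11, molality(10, "ethylene_glycol"), 1)  # ~-0.45
#' @export
excluded_volume_duplex <- function(n_bp, C, N = 1) {
  stopifnot(n_bp >= 2, C >= 0, N >= 1)
  if (n_bp < 6 || n_bp > 12)
    warning("the length dependence of the excluded-volume term was ",
            "calibrated on 6-12 bp duplexes; n_bp = ", n_bp,
            " is an extrapolation")
  (-0.019 * n_bp - 0.070) * C * N
}

#' Per-parameter excluded-volume term
#'
#' All NN stacks are assumed to carry the same volume effect, so the
#' duplex-level term is divided evenly: it is applied to each of the
#' `n_bp - 1` propagating stacks and to initiation (hence `/ n_bp`),
#' but not to the terminal A-U penalty (already counted via
#' initiation).
#'
#' @param dG_ev_dup Duplex-level excluded-volume term, kcal/mol.
#' @param n_bp Number of base pairs (>= 1).
#' @return Per-parameter term in kcal/mol.
#' @export
excluded_volume_per_nn <- function(dG_ev_dup, n_bp) {
  stopifnot(n_bp >= 1)
  dG_ev_dup / n_bp
}

#' Water-activity contribution
#'
#' Linear response of an NN free-energy parameter to the depression of
#' water activity: `dG37_wa = m_cs * delta_aw`.
#'
#' @param m_cs Prefactor(s) in kcal/mol (per NN stack, initiation or
#'   terminal A-U; cosolute-class specific).
#' @param delta_aw Water-activity depression
#'   `a_w(no cosolute) - a_w(cosolute)`.
#' @return Contribution(s) in kcal/mol.
#' @export
wa_contribution <- function(m_cs, delta_aw) m_cs * delta_aw

#' Per-parameter water-activity prefactors for a cosolute
#'
#' Selects (or scales) the prefactor column of the decomposition table
#' for a cosolute: the `m_peg` column for the PEG-like class, the
#' `m_diol` column for the vicinal-diol class, and
#' `m_peg * slope_ratio` for a custom cosolute.
#'
#' @param cosolute A [cosolute()] (or bundled name).
#' @param decomposition An `nn_decomposition` from [load_decomposition()].
#' @return Named numeric vector of prefactors (kcal/mol) for the 10
#'   stacks, initiation and terminal A-U.
#' @export
m_cs_for <- function(cosolute, decomposition = load_decomposition()) {
  if (is.character(cosolute)) cosolute <- crowdnn::cosolute(cosolute)
  stopifnot(inherits(decomposition, "nn_decomposition"))
  tab <- decomposition$table
  m <- switch(cosolute$cls,
    peg_class  = tab$m_peg,
    diol_class = tab$m_diol,
    custom     = tab$m_peg * cosolute$slope_ratio,
    stop("unknown cosolute class: ", cosolute$cls))
  stats::setNames(m, rownames(tab))
}

.load_aw_lookup <- function() {
  utils::read.delim(.extdata("water_activity.tsv"), stringsAsFactors = FALSE)
}

#' Describe a solution condition
#'
#' Collects the cosolute, its concentration, the water-activity
#' depression, and the cation mode of a solution.  `delta_aw` may be
#' given directly, derived from osmometry (`osmolality_mmol_kg`,
#' optionally with the cosolute-free reference osmolality), or looked
#' up from the small bundled table for the conditions the package was
#' calibrated against.  A missing `delta_aw` with a cosolute present is
#' an error, never silently zero.
#'
#' @param cosolute A [cosolute()], a bundled cosolute name, or `NULL`
#'   for no cosolute.
#' @param wt_pct Grams of cosolute per 100 g water.
#' @param delta_aw Water-activity depression
#'   `a_w(no cosolute) - a_w(cosolute)`; in `[0, 1)`.
#' @param osmolality_mmol_kg Osmolality of the solution, mmol/kg
#'   (alternative to `delta_aw`).
#' @param osmolality_reference_mmol_kg Osmolality of the matched
#'   cosolute-free solution (default 0, i.e. `a_w = 1`).
#' @param na_mM Na+ concentration in mmol/L (sodium mode).
#' @param cation_mode `"sodium"`, `"potassium"` or `"intracellular"`.
#'   Potassium and intracellular predictions are made by computing the
#'   Na+ prediction first and applying the corresponding whole-duplex
#'   affine correction.
#' @param temperature Kelvin; compositions are defined at 310.15 K.
#' @return Object of class `solution_condition`.
#' @export
solution_condition <- function(cosolute = NULL, wt_pct = 0,
                               delta_aw = NULL,
                               osmolality_mmol_kg = NULL,
                               osmolality_reference_mmol_kg = 0,
                               na_mM = 122,
                               cation_mode = c("sodium", "potassium",
                                               "intracellular"),
                               temperature = 310.15) {
  cation_mode <- match.arg(cation_mode)
  if (is.character(cosolute)) cosolute <- crowdnn::cosolute(cosolute)
  stopifnot(wt_pct >= 0)
  if (cation_mode == "sodium" && na_mM <= 0)
    stop("na_mM must be positive in sodium mode")
  no_cosolute <- is.null(cosolute) || wt_pct == 0
  if (is.null(delta_aw)) {
    if (!is.null(osmolality_mmol_kg)) {
      delta_aw <-
        water_activity_from_osmolality(osmolality_reference_mmol_kg,
                                       temperature) -
        water_activity_from_osmolality(osmolality_mmol_kg, temperature)
    } else if (no_cosolute) {
      delta_aw <- 0
    } else {
      lut <- .load_aw_lookup()
      hit <- lut$cosolute == cosolute$name & lut$wt_pct == wt_pct
      if (!any(hit))
        stop("delta_aw unknown for ", wt_pct, " wt% ", cosolute$name,
             "; supply delta_aw or osmolality_mmol_kg explicitly ",
             "(missing water activity is an error, never zero)")
      delta_aw <- lut$delta_aw[which(hit)[1]]
    }
  }
  if (delta_aw < 0 || delta_aw >= 1)
    stop("delta_aw must lie in [0, 1)")
  structure(list(cosolute = cosolute, wt_pct = wt_pct,
                 delta_aw = delta_aw, na_mM = na_mM,
                 cation_mode = cation_mode, temperature = temperature),
            class = "solution_condition")
}

#' @export
print.solution_condition <- function(x, ...) {
  cs <- if (is.null(x$cosolute)) "none"
        else sprintf("%g wt%% %s", x$wt_pct, x$cosolute$name)
  cat("Solution condition: cosolute", cs,
      sprintf("| delta_aw %.4f | %s", x$delta_aw,
              switch(x$cation_mode,
                     sodium = sprintf("%g mM Na+", x$na_mM),
                     potassium = "K+ (affine correction)",
                     intracellular = "intracellular cations (affine correction)")),
      sprintf("| %.2f K\n", x$temperature))
  invisible(x)
}

#' Compose a condition-specific NN parameter set
#'
#' Rebuilds per-parameter dG37 values for an arbitrary solution from
#' the decomposition table: for every propagating stack and for
#' initiation, `bulk + cation + ev_per_nn + m_cs * delta_aw`; for the
#' terminal A-U penalty, `bulk + m_cs * delta_aw` only (no cation, no
#' excluded-volume term).  The symmetry correction is condition
#' independent.  The result is a dG37-only `nn_param_set` usable by
#' [predict_duplex()]; dH/dS are marked unavailable, so
#' [melting_temperature()] refuses composed sets.
#'
#' @param decomposition An `nn_decomposition`.
#' @param solution A [solution_condition()].
#' @param n_bp Duplex length used for the per-parameter
#'   excluded-volume share (the duplex-level term divided by `n_bp`).
#' @return An `nn_param_set` (dG37-only) whose `table` also carries the
#'   per-term `bulk`, `cation`, `ev` and `wa` columns for audit.
#' @examples
#' dec <- load_decomposition()
#' sol <- solution_condition("PEG200", 40)      # the reference condition
#' ps <- compose_condition_parameters(dec, sol, n_bp = 8)
#' @export
compose_condition_parameters <- function(decomposition, solution, n_bp) {
  stopifnot(inherits(decomposition, "nn_decomposition"),
            inherits(solution, "solution_condition"))
  tab <- decomposition$table
  labels <- rownames(tab)
  warnings <- character(0)

  cation <- cation_term(if (solution$cation_mode == "sodium")
                          solution$na_mM else 122,
                        decomposition)
  if (solution$cation_mode != "sodium")
    warnings <- c(warnings, paste0(
      solution$cation_mode, " mode: composed at 122 mM Na+, whole-duplex ",
      "affine correction applied to each prediction"))

  no_cosolute <- is.null(solution$cosolute) || solution$wt_pct == 0
  if (no_cosolute) {
    ev_nn <- 0
    m <- stats::setNames(rep(0, length(labels)), labels)
  } else {
    C <- molality(solution$wt_pct, solution$cosolute)
    ev_dup <- excluded_volume_duplex(n_bp, C, solution$cosolute$n_monomers)
    ev_nn <- excluded_volume_per_nn(ev_dup, n_bp)
    m <- m_cs_for(solution$cosolute, decomposition)
  }
  wa <- wa_contribution(m, solution$delta_aw)

  ev_col <- ifelse(labels == "terminal_AU", 0, ev_nn)
  dG37 <- tab$dG_bulk + cation[labels] + ev_col + wa[labels]

  cs <- if (no_cosolute) "no cosolute"
        else sprintf("%g wt%% %s", solution$wt_pct, solution$cosolute$name)
  label <- sprintf("composed: %s, delta_aw=%.4f, %s, n_bp=%d", cs,
                   solution$delta_aw,
                   switch(solution$cation_mode,
                          sodium = sprintf("%g mM Na+", solution$na_mM),
                          potassium = "K+",
                          intracellular = "intracellular cations"),
                   as.integer(n_bp))

  out_tab <- data.frame(dH = NA_real_, dS = NA_real_, dG37 = dG37,
                        dH_se = NA_real_, dS_se = NA_real_,
                        dG37_se = NA_real_,
                        bulk = tab$dG_bulk,
                        cation = unname(cation[labels]),
                        ev = ev_col, wa = unname(wa[labels]),
                        row.names = labels)
  ## symmetry correction is independent of the solution condition
  ref <- load_parameter_set()$table["symmetry", ]
  out_tab["symmetry", ] <- c(ref$dH, ref$dS, ref$dG37, NA, NA, NA,
                             NA, NA, NA, NA)
  ps <- structure(list(table = out_tab, condition_label = label,
                       has_enthalpy = FALSE, source = decomposition$source),
                  class = "nn_param_set")
  if (solution$cation_mode != "sodium")
    attr(ps, "post_correction") <- solution$cation_mode
  if (length(warnings)) attr(ps, "condition_warnings") <- warnings
  ps
}

#' Predict duplex stability under an arbitrary solution condition
#'
#' One-call pipeline: composes the per-parameter free energies for the
#' given solution at the duplex's own length (so the per-stack
#' excluded-volume shares sum exactly to the duplex-level term) and
#' runs [predict_duplex()].  For potassium/intracellular modes the Na+
#' prediction is computed first and the whole-duplex affine correction
#' applied on top (recorded in the breakdown as `cation_mode`).
#'
#' @param duplex A [duplex_spec()] or top-strand string.
#' @param solution A [solution_condition()].
#' @param decomposition An `nn_decomposition`.
#' @return A `duplex_thermo` (dG37-only; Tm is refused).
#' @examples
#' sol <- solution_condition("ethylene_glycol", 20, delta_aw = 0.047)
#' predict_in_condition("GGAUCGAUCC", sol)$dG37   # ~-13.07
#' @export
predict_in_condition <- function(duplex, solution,
                                 decomposition = load_decomposition()) {
  duplex <- .as_duplex(duplex)
  params <- compose_condition_parameters(decomposition, solution,
                                         n_bp = duplex$n_bp)
  predict_duplex(duplex, params)
}
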