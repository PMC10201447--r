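## Crowding-aware motif rules beyond perfect duplexes: loop-penalty
## rescaling with water activity, and hairpin assembly with
## wobble-normalized stems.

#' Loop penalty under a cosolute
#'
#' Rescales a dilute-solution loop penalty for a crowded solution:
#' `dG37_loop(cosolute) = dG37_loop(no cosolute) * (1 - 11.8 * delta_aw)`.
#' At the 40 wt% PEG200 reference (`delta_aw ~ 0.0489`) the loop
#' destabilization is reduced by ~58%.  The relation is applied to
#' hairpin and internal loops alike.
#'
#' @param loop_dilute Dilute-condition loop penalty, kcal/mol (>= 0 by
#'   convention: loops destabilize).
#' @param delta_aw Water-activity depression of the solution.  Beyond
#'   `1/11.8` the rescaled penalty changes sign; a warning is issued.
#' @return Rescaled penalty in kcal/mol.
#' @export
loop_penalty_crowded <- function(loop_dilute, delta_aw) {
  if (any(delta_aw >= 1 / 11.8))
    warning("delta_aw >= 1/11.8: the rescaled loop penalty changes sign; ",
            "the linear relation is being extrapolated beyond its support")
  loop_dilute * (1 - 11.8 * delta_aw)
}

#' Specify a hairpin
#'
#' A hairpin is described by its stem (a [duplex_spec()]; G.U wobbles
#' allowed), a dilute-solution hairpin-loop penalty, optional
#' internal-loop penalties (all user-supplied, e.g. from classical
#' dilute-solution rules; none are bundled), and optional excluded-
#' volume geometry.
#'
#' @param stem A [duplex_spec()] (or top-strand string) with
#'   `n_bp >= 2`.
#' @param loop_penalty_dilute Hairpin-loop penalty in dilute solution,
#'   kcal/mol (>= 0).
#' @param internal_loop_penalties_dilute Numeric vector of
#'   internal-loop penalties, kcal/mol (>= 0).
#' @param geometry Optional list with elements `l` (segment length,
#'   angstroms), `k_folded` and `k_unfolded` (geometrical factors of the
#'   folded hairpin and the unfolded strand) for the excluded-volume
#'   term.
#' @return Object of class `hairpin_spec`.
#' @export
hairpin_spec <- function(stem, loop_penalty_dilute,
                         internal_loop_penalties_dilute = numeric(0),
                         geometry = NULL) {
  stem <- .as_duplex(stem)
  stopifnot(stem$n_bp >= 2,
            loop_penalty_dilute >= 0,
            all(internal_loop_penalties_dilute >= 0))
  if (!is.null(geometry) &&
      !all(c("l", "k_folded", "k_unfolded") %in% names(geometry)))
    stop("geometry must supply l, k_folded and k_unfolded")
  structure(list(stem = stem,
                 loop_penalty_dilute = loop_penalty_dilute,
                 internal_loop_penalties_dilute =
                   internal_loop_penalties_dilute,
                 geometry = geometry),
            class = "hairpin_spec")
}

#' Hairpin stability under a crowded condition
#'
#' Assembles the unimolecular hairpin free energy at 37 C as: the sum
#' of composed stem NN terms (bulk + cation + water activity; the
#' excluded-volume contribution enters at the structure level, not per
#' stack) plus helix initiation, plus all loop penalties rescaled by
#' [loop_penalty_crowded()], plus a structure-level excluded-volume
#' term computed from the supplied geometry (omitted with a warning if
#' no geometry is given and a cosolute is present).  No terminal A-U
#' penalty is applied to the stem ends (the loop-closing pair is not a
#' free terminus; the open terminus is treated conservatively the same
#' way and this choice is reported).  Initiation is included once: the
#' first stem pair must still nucleate the helix.
#'
#' @param hairpin A [hairpin_spec()].
#' @param solution A [solution_condition()].
#' @param decomposition An `nn_decomposition`.
#' @return List of class `hairpin_thermo` with `dG37`, a term
#'   `breakdown`, and `warnings`.
#' @export
hairpin_stability <- function(hairpin, solution,
                              decomposition = load_decomposition()) {
  stopifnot(inherits(hairpin, "hairpin_spec"),
            inherits(solution, "solution_condition"))
  warnings <- character(0)
  stem <- wobble_normalize(hairpin$stem)
  if (length(hairpin$stem$wobble_positions))
    warnings <- c(warnings, "stem G.U wobbles treated as A.U")
  steps <- nn_steps(stem)
  tab <- decomposition$table
  cation <- cation_term(if (solution$cation_mode == "sodium")
                          solution$na_mM else 122, decomposition)
  no_cosolute <- is.null(solution$cosolute) || solution$wt_pct == 0
  m <- if (no_cosolute)
    stats::setNames(rep(0, nrow(tab)), rownames(tab))
  else m_cs_for(solution$cosolute, decomposition)
  per_param <- tab$dG_bulk + cation[rownames(tab)] +
    wa_contribution(m, solution$delta_aw)
  names(per_param) <- rownames(tab)

  stem_terms <- stats::setNames(per_param[steps],
                                make.unique(steps, sep = "#"))
  breakdown <- c(stem_terms, initiation = unname(per_param["initiation"]))

  loops <- c(hairpin = hairpin$loop_penalty_dilute,
             if (length(hairpin$internal_loop_penalties_dilute))
               stats::setNames(hairpin$internal_loop_penalties_dilute,
                               paste0("internal_loop",
                                      seq_along(hairpin$internal_loop_penalties_dilute))))
  loops_crowded <- loop_penalty_crowded(loops, solution$delta_aw)
  names(loops_crowded) <- paste0("loop:", names(loops))
  breakdown <- c(breakdown, loops_crowded)

  if (!no_cosolute) {
    if (is.null(hairpin$geometry)) {
      msg <- paste0("no excluded-volume geometry supplied for the hairpin; ",
                    "the structure-level excluded-volume term was omitted")
      warning(msg)
      warnings <- c(warnings, msg)
    } else {
      g <- hairpin$geometry
      N <- solution$cosolute$n_monomers
      dV <- excluded_volume_generic(N, g$l, g$k_folded) -
        excluded_volume_generic(N, g$l, g$k_unfolded)
      C <- molality(solution$wt_pct, solution$cosolute)
      ## dG_ev = R T rho dV C with rho(water) = 1 kg/L
      breakdown <- c(breakdown,
                     ev = .R_KCAL * solution$temperature * 1 * dV * C)
    }
  }
  warnings <- c(warnings,
                "no terminal A-U penalty applied to hairpin stem ends")

  structure(list(dG37 = sum(breakdown), breakdown = breakdown,
                 hairpin = hairpin, warnings = warnings),
            class = "hairpin_thermo")
}

#' @export
print.hairpin_thermo <- function(x, ...) {
  cat("Hairpin stability: dG37 =", sprintf("%.2f", x$dG37), "kcal/mol\n")
  print(round(x$breakdown, 3))
  for (w in x$warnings) cat("  note:", w, "\n")
  invisible(x)
}
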