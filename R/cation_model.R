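## Cation handling: the 122 mM Na+ reference term, affine K+ and
## intracellular corrections, and a plug-in hook for other Na+
## concentrations.

#' Per-parameter cation contribution
#'
#' The package stores the cation term at its two anchors only: all
#' zeros at 10 mM Na+ (where the NN free energies were taken as the
#' bulk values) and the tabulated column at 122 mM Na+.  Any other
#' concentration requires a registered per-parameter model (see
#' [register_cation_model()]); interpolation is never performed
#' silently.  The terminal A-U contribution is always zero (terminal
#' pairs are treated as independent of Na+ concentration).
#'
#' @param na_mM Na+ concentration, mmol/L.
#' @param decomposition An `nn_decomposition`.
#' @param model Name of a registered cation model to use for
#'   non-anchor concentrations (optional).
#' @return Named numeric vector (kcal/mol) over the 10 stacks,
#'   initiation and terminal A-U.
#' @export
cation_term <- function(na_mM, decomposition = load_decomposition(),
                        model = NULL) {
  stopifnot(inherits(decomposition, "nn_decomposition"))
  labels <- rownames(decomposition$table)
  if (is.null(model)) {
    if (isTRUE(all.equal(na_mM, 10)))
      return(stats::setNames(rep(0, length(labels)), labels))
    if (isTRUE(all.equal(na_mM, 122)))
      return(stats::setNames(decomposition$table$dG_cat_122, labels))
    stop("the cation term is anchored only at 10 and 122 mM Na+; for ",
         na_mM, " mM register a per-parameter model with ",
         "register_cation_model() and pass its name (no interpolation ",
         "is performed)")
  }
  fn <- .crowdnn_env$cation_models[[model]]
  if (is.null(fn))
    stop("no cation model registered under name '", model, "'")
  out <- vapply(labels, function(lb) {
    if (lb == "terminal_AU") 0 else as.numeric(fn(lb, na_mM))
  }, numeric(1))
  stats::setNames(out, labels)
}

#' Register a sodium-dependence model
#'
#' Registers a user-supplied function giving the per-parameter cation
#' free energy at arbitrary Na+ concentration (for example an
#' exponential-decay fit from the literature).  The contract is
#' `fn(parameter_label, na_mM) -> kcal/mol`; the terminal A-U
#' contribution is forced to zero regardless of the model.
#'
#' @param name Model name used in [cation_term()].
#' @param fn Function of `(parameter_label, na_mM)` returning kcal/mol.
#' @return The name, invisibly.
#' @export
register_cation_model <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  if (is.null(.crowdnn_env$cation_models))
    .crowdnn_env$cation_models <- list()
  .crowdnn_env$cation_models[[name]] <- fn
  invisible(name)
}

#' Potassium correction of a whole-duplex prediction
#'
#' Transfers a duplex dG37 predicted for Na+ to the matching K+
#' solution by the affine regression
#' `dG37(K+) = 0.93 * dG37(Na+) + 0.45` (fitted at duplex level under
#' 40 wt% PEG200 crowding: ~7% weaker charge screening by K+ plus an
#' average terminal destabilization of 0.45 kcal/mol).
#'
#' @param dG37_pred_Na Whole-duplex dG37 predicted in Na+, kcal/mol.
#' @return Corrected dG37 in kcal/mol.
#' @export
potassium_correction <- function(dG37_pred_Na) 0.93 * dG37_pred_Na + 0.45

#' Intracellular-cation correction of a whole-duplex prediction
#'
#' Transfers a duplex dG37 predicted for Na+ to the intracellular
#' cation composition (140 mM K+, 10 mM Na+, 0.5 mM Mg2+, trace Ca2+)
#' by the affine regression
#' `dG37(intracellular) = 0.92 * dG37(Na+) - 0.12` (duplex-level fit
#' under 40 wt% PEG200; the small negative intercept reflects terminal
#' stabilization by Mg2+).
#'
#' @param dG37_pred_Na Whole-duplex dG37 predicted in Na+, kcal/mol.
#' @return Corrected dG37 in kcal/mol.
#' @export
intracellular_correction <- function(dG37_pred_Na) 0.92 * dG37_pred_Na - 0.12
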