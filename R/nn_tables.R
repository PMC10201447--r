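## Parameter tables: the 13-parameter NN set determined in 40 wt% PEG200
## with 100 mM NaCl, and its decomposition into bulk / cation /
## excluded-volume / water-activity components.
##
## Tables ship as TSV data assets under inst/extdata; numeric values are
## never hard-coded in the package source.  Entropies are printed in
## cal mol^-1 K^-1 and converted to kcal mol^-1 K^-1 exactly once, at
## load time.

.PARAM_LABELS <- function() c(.NN_LABELS, "initiation", "terminal_AU", "symmetry")

## Tolerance for closure checks on printed (rounded) table values.
.TABLE_TOL <- 0.015

.known_parameter_sets <- function() {
  c(peg200_40wt_100mM_Na = "nn_peg200_40wt_100mM_Na.tsv")
}

#' Load a nearest-neighbor parameter set
#'
#' Loads and validates a full 13-parameter NN table: per-stack dH
#' (kcal/mol), dS (converted to kcal/mol/K at load) and dG37 (kcal/mol),
#' plus helix initiation, the per-terminal-AU penalty and the
#' self-complementarity (symmetry) correction.  Validation enforces
#' Hess-law closure, `dG37 = dH - 310.15 dS`, on every row to within
#' 0.015 kcal/mol (the rounding of printed values); a violating row is a
#' hard failure naming the row.
#'
#' @param condition_id Name of a bundled set (currently
#'   `"peg200_40wt_100mM_Na"`, the 40 wt% PEG200 / 100 mM NaCl table) or
#'   the path to a user TSV with columns `parameter`, `dH_kcal`,
#'   `dS_cal`, `dG37_kcal` (optional `*_se` columns).
#'
#' @return An object of class `nn_param_set`: a list with elements
#'   `table` (data frame indexed by parameter label with columns `dH`,
#'   `dS`, `dG37` and standard errors), `condition_label`,
#'   `has_enthalpy` and `source`.
#' @examples
#' ps <- load_parameter_set("peg200_40wt_100mM_Na")
#' ps$table["GC/CG", "dG37"]   # -3.07
#' @export
load_parameter_set <- function(condition_id = "peg200_40wt_100mM_Na") {
  known <- .known_parameter_sets()
  if (condition_id %in% names(known)) {
    path <- .extdata(known[[condition_id]])
    label <- condition_id
  } else if (file.exists(condition_id)) {
    path <- condition_id
    label <- basename(condition_id)
  } else {
    stop("unknown condition_id '", condition_id, "'; bundled sets: ",
         paste(names(known), collapse = ", "),
         " (or give the path to a parameter TSV)")
  }
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  .build_param_set(raw, condition_label = label, source = path)
}

.build_param_set <- function(raw, condition_label, source = NA_character_) {
  need <- c("parameter", "dH_kcal", "dS_cal", "dG37_kcal")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("parameter table lacks column(s): ", paste(miss, collapse = ", "))
  want <- .PARAM_LABELS()
  miss <- setdiff(want, raw$parameter)
  if (length(miss))
    stop("parameter table lacks row(s): ", paste(miss, collapse = ", "))
  tab <- data.frame(
    dH = raw$dH_kcal,
    dS = raw$dS_cal / 1000,        # cal -> kcal, the only conversion point
    dG37 = raw$dG37_kcal,
    dH_se = if ("dH_se" %in% names(raw)) raw$dH_se else NA_real_,
    dS_se = if ("dS_se" %in% names(raw)) raw$dS_se / 1000 else NA_real_,
    dG37_se = if ("dG37_se" %in% names(raw)) raw$dG37_se else NA_real_,
    row.names = raw$parameter)
  tab <- tab[want, ]
  dev <- abs(tab$dH - .T37 * tab$dS - tab$dG37)
  bad <- which(dev > .TABLE_TOL)
  if (length(bad))
    stop(sprintf(paste0("Hess-law violation in parameter table row '%s': ",
                        "dH - 310.15*dS = %.4f but dG37 = %.4f ",
                        "(deviation %.4f > %.3f kcal/mol)"),
                 rownames(tab)[bad[1]],
                 tab$dH[bad[1]] - .T37 * tab$dS[bad[1]],
                 tab$dG37[bad[1]], dev[bad[1]], .TABLE_TOL))
  structure(list(table = tab,
                 condition_label = condition_label,
                 has_enthalpy = TRUE,
                 source = source),
            class = "nn_param_set")
}

#' @export
print.nn_param_set <- function(x, ...) {
  cat("Nearest-neighbor parameter set [", x$condition_label, "]\n", sep = "")
  if (!x$has_enthalpy)
    cat("  (dG37-only composed set; dH/dS unavailable)\n")
  tab <- x$table
  tab$dS_cal <- tab$dS * 1000
  print(round(tab[, c("dH", "dS_cal", "dG37")], 3))
  invisible(x)
}

#' Load the bulk/cation/excluded-volume/water-activity decomposition
#'
#' Loads the per-parameter decomposition of the 40 wt% PEG200 NN free
#' energies: `dG_bulk` (the value at 10 mM Na+), `dG_cat_122` (the
#' additional stabilization at 122 mM Na+), `dG_ev` (the
#' sequence-averaged excluded-volume term, -0.22 kcal/mol, absent for
#' the terminal A-U row), `dG_wa` (the water-activity term at 40 wt%
#' PEG200) and the two cosolute-class prefactors `m_peg` (PEG /
#' 2-methoxyethanol / 1,2-dimethoxyethane) and `m_diol` (ethylene
#' glycol / glycerol / 1,3-propanediol).
#'
#' Load-time validation enforces: (i) the four components of every row
#' sum to the corresponding dG37 of the reference parameter set within
#' 0.015 kcal/mol; (ii) terminal A-U carries no cation and no
#' excluded-volume term; (iii) the row-wise ratio `m_diol/m_peg` is
#' constant within +-0.01 (it equals the slope ratio of the two
#' cosolute classes).
#'
#' @param path Optional path to a user decomposition TSV (columns
#'   `parameter`, `dG_bulk`, `dG_cat_122`, `dG_ev`, `dG_wa`, `m_peg`,
#'   `m_diol`); defaults to the bundled table.
#' @param reference Parameter set the decomposition must close against;
#'   defaults to the bundled 40 wt% PEG200 set.
#'
#' @return Object of class `nn_decomposition`: list with `table` (data
#'   frame indexed by parameter label), `slope_ratio` (mean
#'   m_diol/m_peg), `delta_aw_ref` (the back-inferred water-activity
#'   depression of the reference condition) and `source`.
#' @export
load_decomposition <- function(path = NULL,
                               reference = load_parameter_set()) {
  if (is.null(path)) path <- .extdata("nn_decomposition_peg200.tsv")
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("parameter", "dG_bulk", "dG_cat_122", "dG_ev", "dG_wa",
            "m_peg", "m_diol")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("decomposition table lacks column(s): ", paste(miss, collapse = ", "))
  want <- c(.NN_LABELS, "initiation", "terminal_AU")
  miss <- setdiff(want, raw$parameter)
  if (length(miss))
    stop("decomposition table lacks row(s): ", paste(miss, collapse = ", "))
  tab <- raw[match(want, raw$parameter), need[-1]]
  rownames(tab) <- want

  if (!is.na(tab["terminal_AU", "dG_ev"]))
    stop("terminal_AU must not carry an excluded-volume term (it is ",
         "already counted via initiation)")
  if (tab["terminal_AU", "dG_cat_122"] != 0)
    stop("terminal_AU must not carry a cation term (terminal pairs are ",
         "independent of Na+ concentration)")

  sums <- tab$dG_bulk + tab$dG_cat_122 +
    ifelse(is.na(tab$dG_ev), 0, tab$dG_ev) + tab$dG_wa
  ref <- reference$table[want, "dG37"]
  dev <- abs(sums - ref)
  bad <- which(dev > .TABLE_TOL)
  if (length(bad))
    stop(sprintf(paste0("decomposition row '%s' does not close: components ",
                        "sum to %.4f but the reference dG37 is %.4f"),
                 want[bad[1]], sums[bad[1]], ref[bad[1]]))

  ratio <- tab$m_diol / tab$m_peg
  if (max(abs(ratio - mean(ratio))) > 0.01)
    stop("m_diol/m_peg ratio is not constant across rows (max deviation ",
         sprintf("%.4f", max(abs(ratio - mean(ratio)))), " > 0.01)")

  daw <- tab$dG_wa / tab$m_peg
  structure(list(table = tab,
                 slope_ratio = mean(ratio),
                 delta_aw_ref = mean(daw),
                 reference_condition = reference$condition_label,
                 source = path),
            class = "nn_decomposition")
}

#' @export
print.nn_decomposition <- function(x, ...) {
  cat("NN free-energy decomposition [reference:", x$reference_condition, "]\n")
  print(round(x$table, 3))
  cat(sprintf("slope ratio m_diol/m_peg = %.3f; reference delta_aw = %.4f\n",
              x$slope_ratio, x$delta_aw_ref))
  invisible(x)
}
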