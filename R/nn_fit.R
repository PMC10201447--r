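## Parameter determination: linear least-squares fitting of the
## 13-parameter NN model from per-duplex thermodynamics, and a
## synthetic-data generator for recovery tests.

#' Build the nearest-neighbor design matrix
#'
#' One row per duplex; columns are the counts of the 10 canonical
#' stacks, the initiation indicator (always 1) and the terminal A-U
#' count.  The self-complementarity indicator is carried separately:
#' its coefficient is constrained to the dilute-solution symmetry value
#' and never estimated.
#'
#' @param duplexes List of [duplex_spec()] objects (or character vector
#'   of top strands).
#' @return Object of class `nn_design`: list with the count matrix `X`
#'   (columns in the fixed order `nn_step_labels()`, `initiation`,
#'   `terminal_AU`), logical `self_complementary`, the `sequences`,
#'   the design `rank` and 2-norm condition number `kappa`.
#' @export
build_design <- function(duplexes) {
  if (is.character(duplexes)) duplexes <- lapply(duplexes, duplex_spec)
  duplexes <- lapply(duplexes, .as_duplex)
  cols <- c(.NN_LABELS, "initiation", "terminal_AU")
  X <- t(vapply(duplexes, function(d) {
    steps <- nn_steps(d)
    cnt <- table(factor(steps, levels = .NN_LABELS))
    c(as.numeric(cnt), 1, count_terminal_au(d))
  }, numeric(length(cols))))
  colnames(X) <- cols
  rownames(X) <- vapply(duplexes, function(d) d$top, character(1))
  dec <- svd(X, nu = 0, nv = ncol(X))
  sv <- dec$d
  rank <- sum(sv > max(dim(X)) * .Machine$double.eps * sv[1])
  if (rank < ncol(X)) {
    ## name the unidentifiable parameter combinations from the null space
    ns <- dec$v[, (rank + 1):ncol(X), drop = FALSE]
    combos <- apply(ns, 2, function(v) {
      idx <- which(abs(v) > 1e-8)
      paste(sprintf("%+.2f*%s", v[idx], cols[idx]), collapse = " ")
    })
    stop("rank-deficient design (rank ", rank, " < ", ncol(X), "); ",
         "unidentifiable combination(s): ", paste(combos, collapse = "; "),
         ".  Supply at least 12 linearly independent duplexes.")
  }
  structure(list(X = X,
                 self_complementary = vapply(duplexes, `[[`, logical(1),
                                             "self_complementary"),
                 sequences = rownames(X),
                 rank = rank,
                 kappa = sv[1] / sv[length(sv)]),
            class = "nn_design")
}

#' @export
print.nn_design <- function(x, ...) {
  cat("NN design:", nrow(x$X), "duplexes x", ncol(x$X),
      "free parameters; rank", x$rank,
      sprintf("; condition number %.1f\n", x$kappa))
  invisible(x)
}

#' Fit nearest-neighbor parameters by linear least squares
#'
#' Ordinary (unweighted) least squares of measured per-duplex dG37 and
#' dH on the stack-count design, after subtracting the fixed symmetry
#' contribution from the responses of self-complementary duplexes.
#' dG37 and dH are fitted independently; dS is derived from the fitted
#' dG37 and dH via `dG37 = dH - 310.15 dS`.  Returns the fitted
#' parameter set together with a per-sequence predicted-vs-measured
#' residual report (percent differences for dH, dS, dG37 and the Tm
#' difference at `Ct`).
#'
#' @param design An `nn_design` from [build_design()].
#' @param dG37 Measured dG37 per duplex, kcal/mol.
#' @param dH Measured dH per duplex, kcal/mol (optional; without it the
#'   fit is dG37-only).
#' @param symmetry Fixed symmetry correction: named vector with `dG37`
#'   (kcal/mol), `dH` (kcal/mol) and `dS_cal` (cal/mol/K); defaults to
#'   the dilute-solution values (0.43, 0, -1.4).
#' @param weights Optional per-duplex weights for a weighted fit (the
#'   default is unweighted).
#' @param Ct Total strand concentration for the Tm column of the
#'   residual report, mol/L.
#' @return Object of class `nn_fit`: list with `params` (an
#'   `nn_param_set`), the `residuals` report data frame, and summary
#'   mean absolute percent differences `pct_dH`, `pct_dS`, `pct_dG37`
#'   and mean `dTm_C`.
#' @export
fit_parameters <- function(design, dG37, dH = NULL,
                           symmetry = c(dG37 = 0.43, dH = 0, dS_cal = -1.4),
                           weights = NULL, Ct = 1e-4) {
  stopifnot(inherits(design, "nn_design"))
  X <- design$X
  n <- nrow(X)
  stopifnot(length(dG37) == n, is.null(dH) || length(dH) == n)
  if (!all(is.finite(dG37)) || (!is.null(dH) && !all(is.finite(dH))))
    stop("non-finite responses")
  sym <- design$self_complementary
  yG <- dG37 - symmetry[["dG37"]] * sym
  w <- if (is.null(weights)) rep(1, n) else weights

  fitG <- stats::lm.wfit(X, yG, w)
  coefG <- fitG$coefficients
  seG <- .ols_se(X, fitG$residuals, w)

  if (!is.null(dH)) {
    yH <- dH - symmetry[["dH"]] * sym
    fitH <- stats::lm.wfit(X, yH, w)
    coefH <- fitH$coefficients
    seH <- .ols_se(X, fitH$residuals, w)
    coefS <- (coefH - coefG) / .T37            # dS from Eq of state
    seS <- sqrt(seH^2 + seG^2) / .T37
  } else {
    coefH <- seH <- coefS <- seS <- rep(NA_real_, ncol(X))
  }

  tab <- data.frame(dH = coefH, dS = coefS, dG37 = coefG,
                    dH_se = seH, dS_se = seS, dG37_se = seG,
                    row.names = colnames(X))
  tab["symmetry", ] <- c(symmetry[["dH"]], symmetry[["dS_cal"]] / 1000,
                         symmetry[["dG37"]], NA, NA, NA)
  params <- structure(list(table = tab,
                           condition_label = "fitted",
                           has_enthalpy = !is.null(dH),
                           source = NA_character_),
                      class = "nn_param_set")

  predG <- drop(X %*% coefG) + symmetry[["dG37"]] * sym
  report <- data.frame(sequence = design$sequences,
                       self_complementary = sym,
                       dG37_measured = dG37, dG37_predicted = predG,
                       dG37_pct = 100 * abs(predG - dG37) / abs(dG37))
  if (!is.null(dH)) {
    predH <- drop(X %*% coefH) + symmetry[["dH"]] * sym
    dS_meas <- (dH - dG37) / .T37
    dS_pred <- (predH - predG) / .T37
    s <- ifelse(sym, 1, 4)
    tm <- function(h, ds) 1 / (.R_KCAL * log(Ct / s) / h + ds / h)
    report$dH_measured <- dH; report$dH_predicted <- predH
    report$dH_pct <- 100 * abs(predH - dH) / abs(dH)
    report$dS_pct <- 100 * abs(dS_pred - dS_meas) / abs(dS_meas)
    report$Tm_measured_C <- tm(dH, dS_meas) - 273.15
    report$Tm_predicted_C <- tm(predH, dS_pred) - 273.15
    report$dTm_C <- abs(report$Tm_predicted_C - report$Tm_measured_C)
  }
  structure(list(params = params, residuals = report,
                 pct_dG37 = mean(report$dG37_pct),
                 pct_dH = if (!is.null(dH)) mean(report$dH_pct) else NA_real_,
                 pct_dS = if (!is.null(dH)) mean(report$dS_pct) else NA_real_,
                 dTm_C = if (!is.null(dH)) mean(report$dTm_C) else NA_real_),
            class = "nn_fit")
}

.ols_se <- function(X, resid, w) {
  df <- nrow(X) - ncol(X)
  s2 <- sum(w * resid^2) / df
  XtX <- crossprod(sqrt(w) * X)
  sqrt(diag(solve(XtX)) * s2)
}

#' @export
print.nn_fit <- function(x, ...) {
  cat("NN least-squares fit on", nrow(x$residuals), "duplexes\n")
  cat(sprintf("  mean |%%diff|: dG37 %.1f%%", x$pct_dG37))
  if (!is.na(x$pct_dH))
    cat(sprintf(", dH %.1f%%, dS %.1f%%; mean |dTm| %.2f C",
                x$pct_dH, x$pct_dS, x$dTm_C))
  cat("\n")
  invisible(x)
}

#' Simulate a duplex set with measured-like thermodynamics
#'
#' Generates random fully complementary RNA duplexes spanning the study
#' design (6-12 bp, a mix of self- and non-self-complementary strands,
#' unbiased stack coverage with every stack present in at least
#' `min_coverage` duplexes, full-rank design) and simulated measured
#' responses `dG37` and `dH` equal to the NN-model values under
#' `params` plus independent Gaussian noise.  Generated duplexes are
#' constrained to be stable enough for melting analysis
#' (`dG37 <= stability_max_dG37`), mirroring the selection of
#' analyzable two-state sequences.  Optionally emits per-duplex melting
#' datasets (Tm versus Ct over a ~100-fold concentration range).
#'
#' @param params `nn_param_set` used as ground truth.
#' @param n_duplexes Total number of duplexes (>= 12).
#' @param n_selfcomp How many of them are self-complementary.
#' @param lengths Candidate duplex lengths in bp.
#' @param sd_dG37,sd_dH Gaussian noise s.d. on the responses, kcal/mol.
#' @param seed Random seed (required; all randomness is seeded).
#' @param stability_max_dG37 Reject duplexes whose true dG37 exceeds
#'   this bound, kcal/mol.
#' @param min_coverage Minimum number of duplexes containing each stack.
#' @param melting If `TRUE`, also simulate per-duplex melting datasets
#'   (12 Ct points over a 100-fold range around 1e-4 M, Tm noise
#'   `sd_Tm`).
#' @param sd_Tm Tm noise s.d. in kelvin for the melting datasets.
#' @param max_tries Attempts at a covering, full-rank set.
#' @return List with `duplexes`, `design` (`nn_design`), noisy
#'   responses `dG37` and `dH`, the noiseless `truth` (data frame),
#'   and optionally `melting` (list of data frames `Ct`, `Tm`).
#' @export
simulate_duplex_set <- function(params, n_duplexes = 45,
                                n_selfcomp = round(n_duplexes * 20 / 45),
                                lengths = 6:12, sd_dG37 = 0.3, sd_dH = 3,
                                seed, stability_max_dG37 = -4,
                                min_coverage = 5, melting = FALSE,
                                sd_Tm = 0.3, max_tries = 200) {
  stopifnot(inherits(params, "nn_param_set"), n_duplexes >= 12,
            n_selfcomp <= n_duplexes)
  if (missing(seed)) stop("a random seed is required for reproducibility")
  set.seed(seed)
  even <- lengths[lengths %% 2 == 0]
  if (n_selfcomp > 0 && !length(even))
    stop("self-complementary duplexes need an even length in `lengths`")

  gen_one <- function(selfcomp) {
    repeat {
      n <- if (selfcomp) sample(even, 1) else sample(lengths, 1)
      top <- if (selfcomp) {
        half <- sample(.RNA_ALPHABET, n %/% 2, replace = TRUE)
        paste(c(half, vapply(rev(half), function(b) .WC[[b]],
                             character(1))), collapse = "")
      } else paste(sample(.RNA_ALPHABET, n, replace = TRUE), collapse = "")
      d <- duplex_spec(top)
      if (predict_duplex(d, params)$dG37 <= stability_max_dG37) return(d)
    }
  }

  for (try in seq_len(max_tries)) {
    duplexes <- c(replicate(n_duplexes - n_selfcomp, gen_one(FALSE),
                            simplify = FALSE),
                  replicate(n_selfcomp, gen_one(TRUE), simplify = FALSE))
    X <- t(vapply(duplexes, function(d) {
      cnt <- table(factor(nn_steps(d), levels = .NN_LABELS))
      as.numeric(cnt)
    }, numeric(10)))
    coverage <- colSums(X > 0)
    design <- tryCatch(build_design(duplexes), error = function(e) NULL)
    if (min(coverage) >= min_coverage && !is.null(design)) break
    if (try == max_tries)
      stop("could not satisfy the coverage/rank constraints in ",
           max_tries, " attempts; relax min_coverage or enlarge the set")
  }

  truth <- do.call(rbind, lapply(duplexes, function(d) {
    th <- predict_duplex(d, params)
    data.frame(sequence = d$top, dG37 = th$dG37, dH = th$dH, dS = th$dS)
  }))
  dG37 <- truth$dG37 + stats::rnorm(n_duplexes, 0, sd_dG37)
  dH <- truth$dH + stats::rnorm(n_duplexes, 0, sd_dH)

  out <- list(duplexes = duplexes, design = design,
              dG37 = dG37, dH = dH, truth = truth, seed = seed)
  if (melting) {
    out$melting <- lapply(seq_along(duplexes), function(i) {
      s <- if (duplexes[[i]]$self_complementary) 1 else 4
      Ct <- exp(seq(log(1e-5), log(1e-3), length.out = 12))
      th <- list(dH = truth$dH[i], dS = truth$dS[i],
                 self_complementary = duplexes[[i]]$self_complementary)
      Tm <- vapply(Ct, function(ct) melting_temperature(th, ct, s),
                   numeric(1)) + stats::rnorm(12, 0, sd_Tm)
      data.frame(Ct = Ct, Tm = Tm)
    })
    names(out$melting) <- truth$sequence
  }
  out
}
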