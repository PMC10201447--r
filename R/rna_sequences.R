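## Sequence canonicalization: NN-step enumeration, self-complementarity,
## terminal A-U counting, G-U wobble normalization.

.RNA_ALPHABET <- c("A", "C", "G", "U")

## Watson-Crick complement, single characters.
.WC <- c(A = "U", C = "G", G = "C", U = "A")

## The 10 canonical propagating Watson-Crick NN stacks.  Any dinucleotide
## read along either strand of a fully complementary duplex maps onto
## exactly one of these labels; the reverse-strand reading of a stack
## (e.g. UG/AC) is the same physical stack as its canonical label (CA/GU).
.NN_LABELS <- c("AA/UU", "AU/UA", "UA/AU", "CA/GU", "GU/CA",
                "CU/GA", "GA/CU", "CG/GC", "GC/CG", "GG/CC")

## dinucleotide (read 5'->3' on one strand) -> canonical stack label
.NN_CANON <- c(
  AA = "AA/UU", UU = "AA/UU",
  AU = "AU/UA",
  UA = "UA/AU",
  CA = "CA/GU", UG = "CA/GU",
  GU = "GU/CA", AC = "GU/CA",
  CU = "CU/GA", AG = "CU/GA",
  GA = "GA/CU", UC = "GA/CU",
  CG = "CG/GC",
  GC = "GC/CG",
  GG = "GG/CC", CC = "GG/CC"
)

#' Canonical nearest-neighbor stack labels
#'
#' Returns the 10 canonical Watson-Crick nearest-neighbor stack labels
#' used throughout the package, in their conventional order.
#'
#' @return Character vector of length 10 (e.g. `"GC/CG"`).
#' @export
nn_step_labels <- function() .NN_LABELS

.validate_rna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(what, " must be a single non-empty string")
  seq <- toupper(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% .RNA_ALPHABET)
  if (length(bad)) {
    hint <- if (any(ch[bad] == "T")) " (DNA 'T' is rejected; this is an RNA-only tool)" else ""
    stop(sprintf("invalid RNA character '%s' at position %d in %s%s",
                 ch[bad[1]], bad[1], what, hint))
  }
  seq
}

#' Reverse complement of an RNA sequence
#'
#' @param seq RNA string, 5'->3', alphabet `A`, `C`, `G`, `U`
#'   (case-insensitive).  `T` and ambiguity codes are rejected.
#'
#' @return The Watson-Crick complement read 5'->3'.
#' @examples
#' reverse_complement("GGCUGUUC")  # "GAACAGCC"
#' @export
reverse_complement <- function(seq) {
  seq <- .validate_rna(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  paste(rev(unname(.WC[ch])), collapse = "")
}

.is_wc_pair <- function(a, b) paste0(a, b) %in% c("AU", "UA", "CG", "GC")
.is_gu_pair <- function(a, b) paste0(a, b) %in% c("GU", "UG")

#' Specify a fully complementary RNA duplex
#'
#' Builds a validated duplex description from a top strand and (by
#' default) its reverse complement.  Only fully paired duplexes are
#' accepted: every position must pair Watson-Crick (A.U or G.C) unless
#' it is declared as a G.U wobble via `wobble_positions`.  Mismatches,
#' bulges and dangling ends are rejected.
#'
#' @param top_strand RNA string, 5'->3'.
#' @param bottom_strand RNA string, 5'->3'; defaults to the reverse
#'   complement of `top_strand`.
#' @param wobble_positions Integer vector of pair indices (1 = 5' end of
#'   the top strand) held by G.U wobble pairs.
#'
#' @return An object of class `duplex_spec` with fields `top`, `bottom`,
#'   `n_bp`, `self_complementary` and `wobble_positions`.
#' @examples
#' d <- duplex_spec("GGCUGUUC")
#' d$self_complementary            # FALSE
#' duplex_spec("GGAUCGAUCC")$self_complementary  # TRUE
#' @export
duplex_spec <- function(top_strand, bottom_strand = NULL,
                        wobble_positions = integer(0)) {
  top <- .validate_rna(top_strand, "top_strand")
  bottom <- if (is.null(bottom_strand)) reverse_complement(top)
            else .validate_rna(bottom_strand, "bottom_strand")
  n <- nchar(top)
  if (nchar(bottom) != n)
    stop("top and bottom strands differ in length (", n, " vs ",
         nchar(bottom), "); only fully paired duplexes are supported")
  wobble_positions <- sort(unique(as.integer(wobble_positions)))
  if (length(wobble_positions) &&
      (min(wobble_positions) < 1L || max(wobble_positions) > n))
    stop("wobble position outside 1..", n)
  tc <- strsplit(top, "", fixed = TRUE)[[1]]
  bc <- strsplit(bottom, "", fixed = TRUE)[[1]]
  for (i in seq_len(n)) {
    a <- tc[i]; b <- bc[n - i + 1L]   # bottom is written 5'->3'
    if (i %in% wobble_positions) {
      if (!.is_gu_pair(a, b))
        stop(sprintf("declared wobble at position %d is %s.%s, not G.U", i, a, b))
    } else if (!.is_wc_pair(a, b)) {
      msg <- if (.is_gu_pair(a, b))
        sprintf("position %d pairs %s.%s; declare it in wobble_positions to treat it as a G.U wobble", i, a, b)
      else
        sprintf("position %d pairs %s.%s, which is neither Watson-Crick nor a declared G.U wobble", i, a, b)
      stop(msg)
    }
  }
  structure(list(top = top, bottom = bottom, n_bp = n,
                 self_complementary = identical(top, reverse_complement(top)) &&
                   length(wobble_positions) == 0L,
                 wobble_positions = wobble_positions),
            class = "duplex_spec")
}

.as_duplex <- function(x) {
  if (inherits(x, "duplex_spec")) x else duplex_spec(x)
}

#' @export
print.duplex_spec <- function(x, ...) {
  cat("RNA duplex (", x$n_bp, " bp",
      if (x$self_complementary) ", self-complementary", ")\n", sep = "")
  cat("  5'-", x$top, "-3'\n", sep = "")
  cat("  3'-", paste(rev(strsplit(x$bottom, "")[[1]]), collapse = ""),
      "-5'\n", sep = "")
  if (length(x$wobble_positions))
    cat("  G.U wobble at position(s):",
        paste(x$wobble_positions, collapse = ", "), "\n")
  invisible(x)
}

#' Replace declared G.U wobbles by A.U for parameter lookup
#'
#' G.U wobble pairs carry two hydrogen bonds, like A.U, and are
#' approximated as energetically equivalent to A.U.  This returns an
#' effective duplex in which the G of each declared wobble pair is
#' replaced by A (the U is kept), on whichever strand holds it.  The
#' wobble positions are preserved on the output for reporting.
#'
#' @param duplex A [duplex_spec()] with `wobble_positions` declared.
#' @return A `duplex_spec` whose declared wobbles have been substituted;
#'   carries attribute `wobble_normalized = TRUE`.
#' @export
wobble_normalize <- function(duplex) {
  duplex <- .as_duplex(duplex)
  if (!length(duplex$wobble_positions) ||
      isTRUE(attr(duplex, "wobble_normalized"))) return(duplex)
  n <- duplex$n_bp
  tc <- strsplit(duplex$top, "", fixed = TRUE)[[1]]
  bc <- strsplit(duplex$bottom, "", fixed = TRUE)[[1]]
  for (i in duplex$wobble_positions) {
    j <- n - i + 1L
    if (tc[i] == "G" && bc[j] == "U") tc[i] <- "A"
    else if (tc[i] == "U" && bc[j] == "G") bc[j] <- "A"
    else stop(sprintf("declared wobble at position %d is %s.%s, not G.U",
                      i, tc[i], bc[j]))
  }
  out <- duplex_spec(paste(tc, collapse = ""), paste(bc, collapse = ""))
  out$wobble_positions <- duplex$wobble_positions  # for reporting only
  attr(out, "wobble_normalized") <- TRUE
  out
}

#' Enumerate canonical nearest-neighbor steps of a duplex
#'
#' Returns the `n_bp - 1` dinucleotide stacks of a fully complementary
#' duplex, canonicalized to the 10 standard labels (reverse-strand
#' readings such as UG/AC map to CA/GU).  Declared G.U wobbles are
#' normalized to A.U first.
#'
#' @param duplex A [duplex_spec()] (or a string, coerced).
#' @return Character vector of length `n_bp - 1` of canonical labels.
#' @examples
#' sort(nn_steps(duplex_spec("GAUUACGCCUG")))  # all 10 labels once
#' @export
nn_steps <- function(duplex) {
  duplex <- wobble_normalize(.as_duplex(duplex))
  if (duplex$n_bp < 2L) stop("need at least 2 base pairs to form a stack")
  ch <- strsplit(duplex$top, "", fixed = TRUE)[[1]]
  dinuc <- paste0(ch[-duplex$n_bp], ch[-1L])
  unname(.NN_CANON[dinuc])
}

#' Count duplex ends closed by an A.U pair
#'
#' Counts how many of the two duplex termini are closed by an A.U pair
#' (or by a G.U wobble, which is normalized to A.U and then counts as a
#' terminal A.U).  Used for the per-terminal-AU penalty.
#'
#' @param duplex A [duplex_spec()] (or a string, coerced).
#' @return Integer in `0:2`.
#' @export
count_terminal_au <- function(duplex) {
  duplex <- wobble_normalize(.as_duplex(duplex))
  ch <- strsplit(duplex$top, "", fixed = TRUE)[[1]]
  sum(ch[c(1L, duplex$n_bp)] %in% c("A", "U"))
}

#' Read duplex top strands from a FASTA file
#'
#' Each record is interpreted as the top strand of a fully
#' complementary duplex (the bottom strand is its reverse complement).
#' Requires the Biostrings package.
#'
#' @param path Path to a (multi-)FASTA file; `T` is rejected.
#' @return Named list of [duplex_spec()] objects (names = record ids).
#' @export
read_duplex_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the Biostrings package")
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  out <- lapply(unname(seqs), duplex_spec)
  names(out) <- names(seqs)
  out
}
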