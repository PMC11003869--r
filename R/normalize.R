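#' Centered log-ratio (CLR) transform of ADT counts
#'
#' Per-cell (across-feature) CLR: for cell i and feature a,
#' `clr(a, i) = log(x(a, i) + pseudocount) - mean_a log(x(., i) + pseudocount)`.
#' Each cell's values sum to zero, removing per-cell depth effects in the
#' compositional ADT counts.
#'
#' @param counts features x cells non-negative matrix, or a
#'   [TitrationExperiment-class].
#' @param pseudocount Positive offset added before the log (default 1).
#' @return For a matrix input, a dense features x cells CLR matrix with
#'   attribute `pseudocount`; for a `TitrationExperiment`, the object with a
#'   new `"clr"` assay.
#' @examples
#' clrTransform(matrix(c(0, 3), ncol = 1))
#' @export
clrTransform <- function(counts, pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 ||
      pseudocount <= 0)
    stop("pseudocount must be a positive scalar", call. = FALSE)
  if (is(counts, "TitrationExperiment")) {
    clr <- clrTransform(assay(counts, "counts"), pseudocount)
    assay(counts, "clr") <- clr
    return(counts)
  }
  m <- as_dense(counts)
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  lg <- log(m + pseudocount)
  out <- sweep(lg, 2, colMeans(lg), "-")
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Per-ADT sequencing read load
#'
#' Fraction of total ADT reads consumed by each antibody; antibodies above
#' `load_threshold` (default 10\%) are flagged as candidates for a
#' concentration decrease.
#'
#' @param counts features x cells count matrix, or a
#'   [TitrationExperiment-class].
#' @param load_threshold Flagging threshold on the read fraction.
#' @return A [S4Vectors::DataFrame] (`adt`, `fraction`, `flagged`) sorted in
#'   input feature order; fractions sum to 1.
#' @examples
#' readLoad(matrix(c(9, 1), nrow = 2))
#' @export
readLoad <- function(counts, load_threshold = 0.10) {
  check_scalar(load_threshold, "load_threshold", min = 0, max = 1,
               strict_min = TRUE)
  if (is(counts, "TitrationExperiment"))
    counts <- assay(counts, "counts")
  m <- as_dense(counts)
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  tot <- sum(m)
  if (tot == 0) stop("all-zero count matrix", call. = FALSE)
  frac <- rowSums(m) / tot
  nm <- rownames(m)
  if (is.null(nm)) nm <- sprintf("ADT%03d", seq_len(nrow(m)))
  DataFrame(adt = nm, fraction = as.numeric(frac),
            flagged = as.numeric(frac) > load_threshold)
}
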