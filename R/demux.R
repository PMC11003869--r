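#' Counts-per-ten-thousand (CPTT) normalization
#'
#' Scales each cell's counts to a fixed total (default 10,000). Cells with no
#' reads stay all-zero and are reported in the `"zero_cells"` attribute.
#'
#' @param counts features x cells non-negative count matrix.
#' @param scale Target per-cell total.
#' @return A dense features x cells matrix whose non-zero columns each sum
#'   to `scale`, with attribute `zero_cells` (column indices left all-zero).
#' @examples
#' cpttNormalize(matrix(c(1, 1, 2), ncol = 1))
#' @export
cpttNormalize <- function(counts, scale = 10000) {
  check_scalar(scale, "scale", min = 0, strict_min = TRUE)
  m <- as_dense(counts)
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  tot <- colSums(m)
  zero <- which(tot == 0)
  tot[tot == 0] <- 1
  out <- sweep(m, 2, tot, "/") * scale
  attr(out, "zero_cells") <- zero
  out
}

#' Call hashtag identities (singlet / doublet / unassigned)
#'
#' Applies fraction thresholds to CPTT-normalized HTO reads: a cell is a
#' doublet when its multi-hash fraction exceeds `multi_max_fraction`
#' (default 0.30), otherwise a confident singlet when the top-hash fraction
#' exceeds `singlet_min_fraction` (default 0.40), otherwise unassigned.
#' Cells with no HTO reads are unassigned. The doublet rule is evaluated
#' first, so a cell satisfying both is a doublet. Ties on the top hash are
#' broken by lowest hash index and flagged.
#'
#' @param hto_counts hashes x cells count matrix, or a
#'   [TitrationExperiment-class] with an HTO modality.
#' @param config A [demuxConfig()].
#' @return A [DemuxResult-class].
#' @examples
#' m <- matrix(c(100, 0, 0, 50, 50, 0), nrow = 3,
#'             dimnames = list(paste0("HTO", 1:3), c("a", "b")))
#' demuxCalls(callHashes(m))
#' @export
callHashes <- function(hto_counts, config = demuxConfig()) {
  if (is(hto_counts, "TitrationExperiment"))
    hto_counts <- htoCounts(hto_counts)
  m <- as_dense(hto_counts)
  if (nrow(m) < 2) stop("need at least 2 HTO channels", call. = FALSE)
  if (ncol(m) == 0) stop("empty HTO matrix", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- sprintf("HTO%02d", seq_len(nrow(m)))
  norm <- cpttNormalize(m, scale = config$normalization_scale)
  frac <- norm / config$normalization_scale
  tot <- colSums(m)
  ord1 <- apply(frac, 2, which.max)           # lowest index on ties
  f_top <- frac[cbind(ord1, seq_len(ncol(m)))]
  f2 <- vapply(seq_len(ncol(m)), function(i) {
    v <- frac[, i]; v[ord1[i]] <- -Inf
    max(v)
  }, numeric(1))
  ord2 <- vapply(seq_len(ncol(m)), function(i) {
    v <- frac[, i]; v[ord1[i]] <- -Inf
    which.max(v)
  }, integer(1))
  tie <- vapply(seq_len(ncol(m)), function(i)
    sum(frac[, i] == f_top[i]) > 1, logical(1))
  multi <- if (config$multi_mode == "non_top_total") 1 - f_top else f2
  call <- unname(ifelse(tot == 0, "unassigned",
          ifelse(multi > config$multi_max_fraction, "doublet",
          ifelse(f_top > config$singlet_min_fraction, "singlet",
                 "unassigned"))))
  calls <- DataFrame(
    call = call,
    hash = ifelse(call == "singlet", rownames(m)[ord1], NA),
    top_hash = rownames(m)[ord1],
    second_hash = rownames(m)[ord2],
    f_top = f_top, f_second = f2, tie = tie,
    row.names = colnames(m))
  new("DemuxResult", calls = calls, config = unclass(config))
}

#' Apply RNA quality-control filters
#'
#' Keeps a cell iff `n_genes > min_genes` AND `rna_count > min_rna_counts`
#' AND `percent_mt < max_percent_mt`, all strict inequalities.
#'
#' @param covariates A data.frame/DataFrame with per-cell columns `n_genes`,
#'   `rna_count`, `percent_mt`, or a [TitrationExperiment-class] whose
#'   `colData` carries them.
#' @param config A [qcConfig()].
#' @return A logical keep-mask, named by cell when names are available.
#' @examples
#' applyQC(data.frame(n_genes = c(501, 500), rna_count = c(1001, 5000),
#'                    percent_mt = c(24.9, 10)))
#' @export
applyQC <- function(covariates, config = qcConfig()) {
  if (is(covariates, "TitrationExperiment"))
    covariates <- as.data.frame(colData(covariates))
  need <- c("n_genes", "rna_count", "percent_mt")
  miss <- setdiff(need, names(covariates))
  if (length(miss))
    stop(sprintf("missing QC covariate(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  bad <- !complete.cases(covariates[, need])
  if (any(bad)) {
    nm <- rownames(covariates)
    if (is.null(nm)) nm <- as.character(seq_len(nrow(covariates)))
    stop(sprintf("missing QC covariate value for cell(s): %s",
                 paste(head(nm[bad], 5), collapse = ", ")), call. = FALSE)
  }
  keep <- covariates$n_genes > config$min_genes &
    covariates$rna_count > config$min_rna_counts &
    covariates$percent_mt < config$max_percent_mt
  names(keep) <- rownames(covariates)
  keep
}
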