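#' @import methods
#' @import S4Vectors
#' @import SummarizedExperiment
#' @import SingleCellExperiment
NULL

#' TitrationExperiment: a multi-concentration CITE-seq titration container
#'
#' Extends [SingleCellExperiment::SingleCellExperiment] with the conventions
#' the titration pipeline relies on: the main assay `"counts"` holds ADT
#' counts (features x cells), an alternative experiment `"HTO"` holds hashtag
#' counts over the same cells, `rowData` carries at least an `is_isotype`
#' flag, and `colData` carries `concentration` (fold units, one of the tested
#' grid stored in `metadata()$concentrations`) plus optional `cluster`,
#' QC covariates (`n_genes`, `rna_count`, `percent_mt`) and, for synthetic
#' data, planted truth columns.
#'
#' @export
setClass("TitrationExperiment", contains = "SingleCellExperiment")

setValidity("TitrationExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% names(assays(object)))
    msg <- c(msg, "assay 'counts' (ADT counts) is required")
  else {
    cnt <- assays(object)[["counts"]]
    if (min(cnt) < 0) msg <- c(msg, "ADT counts must be non-negative")
  }
  if (!"is_isotype" %in% names(rowData(object)))
    msg <- c(msg, "rowData must contain logical column 'is_isotype'")
  if (!"concentration" %in% names(colData(object)))
    msg <- c(msg, "colData must contain 'concentration'")
  else {
    grid <- metadata(object)$concentrations
    if (!is.null(grid) &&
        !all(object$concentration %in% grid))
      msg <- c(msg, "all cell concentrations must lie on the tested grid")
  }
  # NB: the HTO-same-cells invariant is enforced at construction; the altExp
  # accessors cannot be used here because they update/validate recursively.
  if (length(msg)) msg else TRUE
})

#' Construct a TitrationExperiment
#'
#' @param adt_counts features x cells non-negative integer matrix of ADT
#'   counts (dense or sparse).
#' @param hto_counts optional hashes x cells matrix of HTO counts.
#' @param col_data per-cell metadata; must include `concentration`.
#' @param row_data per-ADT metadata; must include logical `is_isotype`.
#' @param concentrations the tested concentration grid (fold units).
#' @param metadata additional experiment-level metadata.
#' @return A [TitrationExperiment-class] object.
#' @examples
#' cnt <- matrix(rpois(30, 5), nrow = 3,
#'               dimnames = list(paste0("ADT", 1:3), paste0("c", 1:10)))
#' te <- TitrationExperiment(cnt,
#'   col_data = S4Vectors::DataFrame(concentration = rep(1, 10)),
#'   row_data = S4Vectors::DataFrame(is_isotype = c(FALSE, FALSE, TRUE)),
#'   concentrations = 1)
#' @export
TitrationExperiment <- function(adt_counts, hto_counts = NULL,
                                col_data = NULL, row_data = NULL,
                                concentrations = NULL, metadata = list()) {
  if (is.null(col_data))
    col_data <- DataFrame(row.names = colnames(adt_counts))
  if (is.null(row_data))
    row_data <- DataFrame(is_isotype = rep(FALSE, nrow(adt_counts)),
                          row.names = rownames(adt_counts))
  if (is.null(concentrations) && "concentration" %in% names(col_data))
    concentrations <- sort(unique(col_data$concentration))
  metadata$concentrations <- as.numeric(concentrations)
  sce <- SingleCellExperiment(assays = list(counts = adt_counts),
                              colData = col_data, rowData = row_data,
                              metadata = metadata)
  if (!is.null(hto_counts)) {
    stopifnot(ncol(hto_counts) == ncol(adt_counts))
    altExp(sce, "HTO") <- SingleCellExperiment(
      assays = list(counts = hto_counts))
  }
  te <- as(sce, "TitrationExperiment")
  validObject(te)
  te
}

#' @describeIn TitrationExperiment ADT count matrix (features x cells).
#' @param x,object A `TitrationExperiment`.
#' @export
adtCounts <- function(x) assay(x, "counts")

#' @describeIn TitrationExperiment HTO count matrix (hashes x cells).
#' @export
htoCounts <- function(x) {
  if (!"HTO" %in% altExpNames(x))
    stop("no HTO modality present", call. = FALSE)
  assay(altExp(x, "HTO"), "counts")
}

#' @describeIn TitrationExperiment names of isotype-control features.
#' @export
isotypeFeatures <- function(x) rownames(x)[rowData(x)$is_isotype]

#' @describeIn TitrationExperiment the tested concentration grid.
#' @export
concentrationGrid <- function(x) metadata(x)$concentrations

#' @describeIn TitrationExperiment planted per-ADT ground truth (synthetic
#'   data only), or NULL.
#' @export
adtTruth <- function(x) metadata(x)$adt_truth

setMethod("show", "TitrationExperiment", function(object) {
  callNextMethod()
  cat(sprintf("concentrations(%d): %s\n",
              length(concentrationGrid(object)),
              paste(concentrationGrid(object), collapse = " ")))
  cat(sprintf("isotype channels: %d\n", sum(rowData(object)$is_isotype)))
})

#' DemuxResult: per-cell hashtag demultiplexing calls
#'
#' Slots: `calls`, a `DataFrame` with one row per cell (`call` in
#' singlet/doublet/unassigned, `hash`, `second_hash`, `f_top`, `f_second`,
#' `tie`), and `config`, the [demuxConfig()] used.
#'
#' @export
setClass("DemuxResult",
         representation(calls = "DataFrame", config = "list"))

setValidity("DemuxResult", function(object) {
  ok <- all(object@calls$call %in% c("singlet", "doublet", "unassigned"))
  if (!ok) return("calls must be singlet/doublet/unassigned")
  if (any(object@calls$call == "singlet" & is.na(object@calls$hash)))
    return("singlets must carry a hash id")
  TRUE
})

#' @describeIn DemuxResult the per-cell call table.
#' @param x,object A `DemuxResult`.
#' @export
demuxCalls <- function(x) x@calls

setMethod("show", "DemuxResult", function(object) {
  tab <- table(object@calls$call)
  cat(sprintf("DemuxResult: %d cells (%s)\n", nrow(object@calls),
              paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = ", ")))
})

#' RankingResult: per-concentration gain ranking of ADTs
#'
#' Slots: `ranking`, a `DataFrame` (`concentration`, `adt`, `gain`, `rank`);
#' `config`, the [rankingConfig()] used.
#'
#' @export
setClass("RankingResult",
         representation(ranking = "DataFrame", config = "list"))

#' @describeIn RankingResult the long ranking table.
#' @param x,object A `RankingResult`.
#' @export
adtRanking <- function(x) x@ranking

setMethod("show", "RankingResult", function(object) {
  cat(sprintf("RankingResult: %d ADTs x %d concentrations\n",
              length(unique(object@ranking$adt)),
              length(unique(object@ranking$concentration))))
})

#' DoseResponseSet: isotype-referenced dose-response profiles
#'
#' Slots: `profiles`, a `DataFrame` with one row per (ADT, concentration)
#' carrying `dynamic_range` (CLR units), `background`, `specificity_t`,
#' `positive_fraction`, `best_cluster`, `load_fraction`; `classes`, a
#' `DataFrame` with one row per ADT carrying the dose class
#' (dose_dependent / saturating / weak); `config`, the [decisionConfig()].
#'
#' @export
setClass("DoseResponseSet",
         representation(profiles = "DataFrame", classes = "DataFrame",
                        config = "list"))

#' @describeIn DoseResponseSet per-(ADT, concentration) profile table.
#' @param x,object A `DoseResponseSet`.
#' @export
doseProfiles <- function(x) x@profiles

#' @describeIn DoseResponseSet per-ADT dose class table.
#' @export
doseClasses <- function(x) x@classes

setMethod("show", "DoseResponseSet", function(object) {
  tab <- table(object@classes$dose_class)
  cat(sprintf("DoseResponseSet: %d ADTs x %d concentrations (%s)\n",
              nrow(object@classes),
              length(unique(object@profiles$concentration)),
              paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = ", ")))
})

#' PanelDecision: per-ADT panel actions
#'
#' Slots: `decisions`, a `DataFrame` (`adt`, `action`, `concentration`,
#' `rationale` comma-separated rule codes); `config`.
#'
#' @export
setClass("PanelDecision",
         representation(decisions = "DataFrame", config = "list"))

setValidity("PanelDecision", function(object) {
  d <- object@decisions
  acts <- c("keep", "exclude_nonspecific", "exclude_uninformative",
            "spike_in_recommend")
  if (!all(d$action %in% acts)) return("unknown action")
  if (any(d$rationale == "")) return("every decision needs a rationale code")
  if (anyDuplicated(d$adt)) return("duplicate ADT ids")
  TRUE
})

#' @describeIn PanelDecision the decision table.
#' @param x,object A `PanelDecision`.
#' @export
panelDecisions <- function(x) x@decisions

#' @describeIn PanelDecision identifiers of ADTs kept in the panel.
#' @export
keptADTs <- function(x) x@decisions$adt[x@decisions$action == "keep"]

setMethod("show", "PanelDecision", function(object) {
  tab <- table(object@decisions$action)
  cat(sprintf("PanelDecision: %d ADTs (%s)\n", nrow(object@decisions),
              paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = ", ")))
})

#' ConsistencyReport: cross-batch marker consistency
#'
#' Slots: `markers`, a `DataFrame` (`marker`, `ad_t`, optional `log10_t`,
#' `floored`, `n_used`); `emd`, a named list of per-marker symmetric pairwise
#' EMD matrices (possibly empty); `config`.
#'
#' @export
setClass("ConsistencyReport",
         representation(markers = "DataFrame", emd = "list",
                        config = "list"))

#' @describeIn ConsistencyReport the per-marker statistic table.
#' @param x,object A `ConsistencyReport`.
#' @export
markerConsistency <- function(x) x@markers

setMethod("show", "ConsistencyReport", function(object) {
  cat(sprintf("ConsistencyReport: %d markers\n", nrow(object@markers)))
})

#' ModeratedFit: empirical-Bayes moderated t-test fit
#'
#' Slots: `table`, a `DataFrame` with one row per feature (`mean_a`,
#' `mean_b`, `diff`, `s2`, `df`, `s2_post`, `t`, `df_total`, `p`, `q`);
#' `prior_df` (d0, possibly Inf) and `prior_var` (s0^2) estimated across
#' features.
#'
#' @export
setClass("ModeratedFit",
         representation(table = "DataFrame", prior_df = "numeric",
                        prior_var = "numeric"))

setValidity("ModeratedFit", function(object) {
  tb <- object@table
  need <- c("mean_a", "mean_b", "s2", "s2_post", "t", "p", "q")
  if (!all(need %in% names(tb))) return("missing fit columns")
  TRUE
})

#' @describeIn ModeratedFit the per-feature statistics table.
#' @param x,object A `ModeratedFit`.
#' @export
fitTable <- function(x) x@table

#' @describeIn ModeratedFit estimated prior degrees of freedom d0.
#' @export
priorDf <- function(x) x@prior_df

#' @describeIn ModeratedFit estimated prior variance s0^2.
#' @export
priorVar <- function(x) x@prior_var

setMethod("show", "ModeratedFit", function(object) {
  cat(sprintf(
    "ModeratedFit: %d features, prior df d0 = %s, prior var s0^2 = %.4g\n",
    nrow(object@table),
    if (is.finite(object@prior_df)) sprintf("%.2f", object@prior_df)
    else "Inf",
    object@prior_var))
})
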