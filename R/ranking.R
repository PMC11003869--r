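#' Rank ADTs per concentration by classifier gain
#'
#' For each concentration independently, fits a multiclass gradient-boosted
#' decision-tree classifier (xgboost, exact greedy, single thread) predicting
#' the cluster label from CLR-normalized ADT values, and scores each antibody
#' by its total gain (sum of split-loss reductions attributed to it). Ranks
#' are descending in gain; antibodies never used in a split receive gain 0;
#' ties are broken by ADT identifier. Class imbalance is handled by
#' per-class inverse-frequency cell weights. Deterministic given
#' `config$seed`.
#'
#' @param clr features x cells CLR matrix (e.g. from [clrTransform()]), or a
#'   [TitrationExperiment-class] with a `"clr"` assay.
#' @param cluster_labels Per-cell cluster labels (>= 2 clusters with >= 20
#'   cells each per concentration).
#' @param concentration_labels Per-cell concentration labels.
#' @param config A [rankingConfig()].
#' @return A [RankingResult-class].
#' @export
rankADTs <- function(clr, cluster_labels = NULL,
                     concentration_labels = NULL,
                     config = rankingConfig()) {
  if (is(clr, "TitrationExperiment")) {
    te <- clr
    if (!"clr" %in% names(assays(te)))
      stop("run clrTransform() first", call. = FALSE)
    if (is.null(cluster_labels)) cluster_labels <- te$cluster
    if (is.null(concentration_labels))
      concentration_labels <- te$concentration
    clr <- assay(te, "clr")
  }
  m <- as_dense(clr)
  if (is.null(rownames(m))) rownames(m) <- sprintf("ADT%03d", seq_len(nrow(m)))
  stopifnot(length(cluster_labels) == ncol(m),
            length(concentration_labels) == ncol(m))
  concs <- sort(unique(concentration_labels))
  out <- vector("list", length(concs))
  for (ci in seq_along(concs)) {
    sel <- concentration_labels == concs[ci]
    labs <- factor(cluster_labels[sel])
    if (nlevels(labs) < 2)
      stop(sprintf("concentration %s has a single cluster", concs[ci]),
           call. = FALSE)
    tabk <- table(labs)
    if (any(tabk < 20))
      warning(sprintf(
        "concentration %s: some clusters have < 20 cells", concs[ci]),
        call. = FALSE)
    y <- as.integer(labs) - 1L
    w <- as.numeric(length(y) / (nlevels(labs) * tabk[as.integer(labs)]))
    dtrain <- xgboost::xgb.DMatrix(t(m[, sel, drop = FALSE]),
                                   label = y, weight = w, nthread = 1)
    params <- list(objective = "multi:softprob",
                   num_class = nlevels(labs),
                   max_depth = config$max_depth,
                   eta = config$learning_rate,
                   subsample = 1, colsample_bytree = config$colsample,
                   tree_method = "exact",
                   nthread = 1, seed = config$seed)
    booster <- xgboost::xgb.train(params = params, data = dtrain,
                                  nrounds = config$n_rounds, verbose = 0)
    imp <- xgboost::xgb.importance(model = booster)
    gain <- setNames(rep(0, nrow(m)), rownames(m))
    if (!is.null(imp) && nrow(imp) > 0)
      gain[imp$Feature] <- imp$Gain
    ord <- order(-gain, names(gain))
    out[[ci]] <- data.frame(concentration = concs[ci],
                            adt = names(gain)[ord],
                            gain = as.numeric(gain[ord]),
                            rank = seq_along(gain))
  }
  new("RankingResult", ranking = DataFrame(do.call(rbind, out)),
      config = unclass(config))
}

#' Persistently bottom-ranked ADTs
#'
#' Flags antibodies whose rank falls in the bottom `bottom_fraction`
#' (default 50\%) at every tested concentration — the candidates examined
#' for rescue or exclusion.
#'
#' @param ranking A [RankingResult-class].
#' @param concentrations Optional concentration grid to require; defaults to
#'   the concentrations present in the ranking.
#' @return Character vector of flagged ADT identifiers.
#' @export
persistentBottom <- function(ranking, concentrations = NULL) {
  rk <- as.data.frame(adtRanking(ranking))
  bf <- ranking@config$bottom_fraction
  present <- unique(rk$concentration)
  if (!is.null(concentrations)) {
    miss <- setdiff(concentrations, present)
    if (length(miss))
      stop(sprintf("missing ranking for concentration(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    rk <- rk[rk$concentration %in% concentrations, ]
    present <- concentrations
  }
  flagged <- NULL
  for (cc in present) {
    sub <- rk[rk$concentration == cc, ]
    cutoff <- ceiling((1 - bf) * nrow(sub))
    bottom <- sub$adt[sub$rank > cutoff]
    flagged <- if (is.null(flagged)) bottom else intersect(flagged, bottom)
  }
  sort(flagged)
}
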