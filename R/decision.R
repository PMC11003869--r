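#' Isotype-referenced dynamic range of one ADT at one concentration
#'
#' The dynamic range is the separation between an antibody's signal in its
#' best (most positive) cluster and the nonspecific background estimated
#' from the isotype controls: the maximum over clusters of the cluster mean
#' CLR minus the mean CLR of all isotype channels over all cells at that
#' concentration, floored at 0.
#'
#' @param clr features x cells CLR matrix restricted or not to one
#'   concentration.
#' @param cluster_labels Per-cell cluster labels.
#' @param isotype_ids Row names of the isotype channels (>= 1).
#' @param adt Row name of the antibody.
#' @param cells Optional logical/integer subset of cells (e.g. one
#'   concentration); default all.
#' @return A list with `dr` (dynamic range, CLR units), `best_cluster`, and
#'   `isotype_ref` (the isotype mean used as background reference).
#' @export
dynamicRange <- function(clr, cluster_labels, isotype_ids, adt,
                         cells = NULL) {
  m <- as_dense(clr)
  if (length(isotype_ids) == 0)
    stop(paste("no isotype channels; re-run with a global-minimum-cluster",
               "fallback reference"), call. = FALSE)
  if (!all(isotype_ids %in% rownames(m)))
    stop("unknown isotype channel id", call. = FALSE)
  if (!adt %in% rownames(m)) stop("unknown ADT id", call. = FALSE)
  if (!is.null(cells)) {
    m <- m[, cells, drop = FALSE]
    cluster_labels <- cluster_labels[cells]
  }
  if (length(unique(cluster_labels)) < 2)
    stop("need at least 2 clusters", call. = FALSE)
  iso_ref <- mean(m[isotype_ids, , drop = FALSE])
  cl_means <- tapply(m[adt, ], cluster_labels, mean)
  best <- names(cl_means)[which.max(cl_means)]
  list(dr = max(0, max(cl_means) - iso_ref), best_cluster = best,
       isotype_ref = iso_ref)
}

#' Specificity score against pooled isotype controls
#'
#' Standardized two-sample Anderson-Darling statistic between an antibody's
#' CLR values (conventionally at the lowest tested concentration) and the
#' pooled isotype-control CLR values on the same cells. Values below the
#' decision threshold mean the staining pattern is statistically
#' indistinguishable from the isotypes (nonspecific).
#'
#' @param adt_values Numeric CLR values of the antibody.
#' @param isotype_values Pooled numeric CLR values of the isotype channels.
#' @param max_cells Optional per-group subsample ceiling (seeded) to bound
#'   the statistic's sample size; NULL uses everything.
#' @param seed Subsampling seed.
#' @return The standardized statistic S (scalar).
#' @export
specificityScore <- function(adt_values, isotype_values, max_cells = NULL,
                             seed = 1L) {
  if (length(isotype_values) == 0)
    stop("empty isotype pool", call. = FALSE)
  if (length(adt_values) == 0) stop("empty ADT sample", call. = FALSE)
  if (!is.null(max_cells)) {
    with_seed(derive_seed(seed, "decide"), {
      adt_values <- subsample_vec(adt_values, max_cells)
      isotype_values <- subsample_vec(isotype_values, max_cells)
    })
  }
  adKSample(list(adt_values, isotype_values))$T
}

#' Profile dose-response behaviour of every ADT
#'
#' For each targeting antibody and each tested concentration computes the
#' isotype-referenced dynamic range, the background level (isotype-
#' referenced mean CLR over non-best-cluster cells), the specificity
#' statistic against the pooled isotypes, the positive-cell fraction in the
#' best cluster (cells above the isotype pool's 95th percentile), and the
#' antibody's read-load fraction; then assigns each antibody its dose class
#' via [classifyDoseBehavior()].
#'
#' @param te A [TitrationExperiment-class] with a `"clr"` assay and
#'   `cluster` labels.
#' @param config A [decisionConfig()].
#' @return A [DoseResponseSet-class].
#' @export
doseResponseProfile <- function(te, config = decisionConfig()) {
  if (!"clr" %in% names(assays(te)))
    stop("run clrTransform() first", call. = FALSE)
  clr <- assay(te, "clr")
  counts <- assay(te, "counts")
  iso <- isotypeFeatures(te)
  if (length(iso) == 0)
    stop(paste("no isotype channels; re-run with a global-minimum-cluster",
               "fallback reference"), call. = FALSE)
  adts <- setdiff(rownames(te), iso)
  concs <- concentrationGrid(te)
  clusters <- te$cluster
  rows <- list()
  for (cc in concs) {
    sel <- te$concentration == cc
    sub <- clr[, sel, drop = FALSE]
    cl <- clusters[sel]
    iso_pool <- as.numeric(sub[iso, , drop = FALSE])
    iso_ref <- mean(iso_pool)
    iso_q95 <- quantile(iso_pool, 0.95, names = FALSE)
    load <- readLoad(counts[, sel, drop = FALSE],
                     load_threshold = config$load_threshold)
    load_frac <- setNames(load$fraction, load$adt)
    cl_idx <- split(seq_len(ncol(sub)), cl)
    for (a in adts) {
      v <- sub[a, ]
      cl_means <- vapply(cl_idx, function(ix) mean(v[ix]), numeric(1))
      best <- names(cl_means)[which.max(cl_means)]
      dr <- max(0, max(cl_means) - iso_ref)
      non_best <- cl != best
      bg <- mean(v[non_best]) - iso_ref
      s <- specificityScore(v, iso_pool, max_cells = config$ad_max_cells,
                            seed = config$seed)
      pos <- mean(v[cl == best] > iso_q95)
      rows[[length(rows) + 1L]] <- data.frame(
        adt = a, concentration = cc, dynamic_range = dr,
        background = bg, specificity_t = s, positive_fraction = pos,
        best_cluster = best, load_fraction = load_frac[[a]])
    }
  }
  prof <- do.call(rbind, rows)
  classes <- do.call(rbind, lapply(adts, function(a) {
    p <- prof[prof$adt == a, ]
    p <- p[order(p$concentration), ]
    data.frame(adt = a,
               dose_class = classifyDoseBehavior(p$dynamic_range,
                                                 p$concentration, config))
  }))
  new("DoseResponseSet", profiles = DataFrame(prof),
      classes = DataFrame(classes), config = unclass(config))
}

#' Classify an antibody's dose-response behaviour
#'
#' `weak` when the maximal dynamic range never reaches `signal_min`;
#' otherwise `dose_dependent` when the Spearman correlation of dynamic range
#' with log concentration reaches `dose_corr_min` and the relative spread
#' (DRmax - DRmin)/DRmax exceeds `flat_rel_spread`; otherwise `saturating`
#' (flat across the tested grid).
#'
#' @param dr Dynamic ranges ordered by concentration.
#' @param concentrations The matching concentrations (>= 3).
#' @param config A [decisionConfig()].
#' @return One of `"dose_dependent"`, `"saturating"`, `"weak"`.
#' @examples
#' classifyDoseBehavior(c(0.2, 0.8, 1.5, 2.2, 2.6), c(0.25, 0.5, 1, 2, 4))
#' @export
classifyDoseBehavior <- function(dr, concentrations,
                                 config = decisionConfig()) {
  if (length(dr) < 3 || length(dr) != length(concentrations))
    stop("need dynamic range at >= 3 concentrations", call. = FALSE)
  ord <- order(concentrations)
  dr <- dr[ord]; concentrations <- concentrations[ord]
  if (max(dr) < config$signal_min) return("weak")
  spread <- (max(dr) - min(dr)) / max(dr)
  rc <- suppressWarnings(cor(dr, log(concentrations), method = "spearman"))
  if (!is.na(rc) && rc >= config$dose_corr_min &&
      spread > config$flat_rel_spread) "dose_dependent" else "saturating"
}

#' Decide action and working concentration for one ADT
#'
#' Applies the concentration-selection decision tree to one antibody's
#' dose-response profile. Rules fire in order and append their codes to the
#' rationale:
#' \enumerate{
#'   \item BLACKLIST, or NONSPECIFIC_BOTTOM (indistinguishable from isotypes
#'     at the lowest concentration AND persistently bottom-ranked AND not
#'     whitelisted) excludes the antibody.
#'   \item WEAK profiles go to spike-in (WEAK_WHITELIST_SPIKEIN) when
#'     whitelisted, else are excluded as uninformative (WEAK_EXCLUDE).
#'   \item Dose-dependent profiles choose the smallest concentration
#'     retaining `retention_fraction` of the maximal dynamic range
#'     (DOSE_RETENTION), after rejecting concentrations whose staining is
#'     isotype-like (NONSPECIFIC_AT_C); a read-load flag at the chosen
#'     concentration demotes one step (LOAD_DEMOTE). A whitelisted antibody
#'     nonspecific everywhere is excluded with CONFLICT.
#'   \item Saturating profiles with elevated background at 1x
#'     (SAT_BACKGROUND_STEPDOWN) step one concentration below 1x; otherwise
#'     they keep 1x (SAT_DEFAULT_1X).
#' }
#' A SPARSE code is appended (without changing the action) when the
#' positive-cell fraction in the best cluster at the chosen concentration
#' falls below `sparse_pos_min`.
#'
#' @param profile data.frame rows of [doseProfiles()] for one ADT (all
#'   concentrations).
#' @param dose_class The ADT's dose class from [doseClasses()].
#' @param is_bottom Is the ADT persistently bottom-ranked?
#' @param config A [decisionConfig()].
#' @param adt The antibody identifier.
#' @return A one-row data.frame (`adt`, `action`, `concentration`,
#'   `rationale`).
#' @export
selectConcentration <- function(profile, dose_class, is_bottom,
                                config = decisionConfig(), adt = NULL) {
  profile <- as.data.frame(profile)
  profile <- profile[order(profile$concentration), ]
  if (is.null(adt)) adt <- profile$adt[1]
  concs <- profile$concentration
  dr <- profile$dynamic_range
  nonspec_c <- profile$specificity_t < config$specificity_t_min
  nonspecific <- nonspec_c[1]          # lowest tested concentration
  white <- adt %in% config$whitelist
  black <- adt %in% config$blacklist
  codes <- character()
  decide <- function(action, conc, codes) data.frame(
    adt = adt, action = action,
    concentration = if (is.null(conc)) NA_real_ else conc,
    rationale = paste(codes, collapse = ","))

  if (black)
    return(decide("exclude_nonspecific", NULL, c(codes, "BLACKLIST")))
  if (nonspecific && isTRUE(is_bottom) && !white)
    return(decide("exclude_nonspecific", NULL,
                  c(codes, "NONSPECIFIC_BOTTOM")))
  if (dose_class == "weak") {
    if (white)
      return(decide("spike_in_recommend", NULL,
                    c(codes, "WEAK_WHITELIST_SPIKEIN")))
    return(decide("exclude_uninformative", NULL, c(codes, "WEAK_EXCLUDE")))
  }
  sparse_code <- function(conc) {
    pos <- profile$positive_fraction[match(conc, concs)]
    if (!is.na(pos) && pos < config$sparse_pos_min) "SPARSE" else NULL
  }
  if (dose_class == "dose_dependent") {
    admissible <- which(!nonspec_c)
    if (length(admissible) == 0)
      return(decide("exclude_nonspecific", NULL, c(codes, "CONFLICT")))
    if (any(nonspec_c)) codes <- c(codes, "NONSPECIFIC_AT_C")
    target <- config$retention_fraction * max(dr)
    ok <- admissible[dr[admissible] >= target]
    idx <- if (length(ok)) min(ok) else admissible[which.max(dr[admissible])]
    codes <- c(codes, "DOSE_RETENTION")
    if (profile$load_fraction[idx] > config$load_threshold && idx > 1) {
      idx <- idx - 1L
      codes <- c(codes, "LOAD_DEMOTE")
    }
    return(decide("keep", concs[idx],
                  c(codes, sparse_code(concs[idx]))))
  }
  # saturating
  one_idx <- which.min(abs(concs - 1))
  bg1 <- profile$background[one_idx]
  if (!is.na(bg1) && bg1 > config$signal_min / 2 && one_idx > 1) {
    conc <- concs[one_idx - 1L]
    return(decide("keep", conc,
                  c(codes, "SAT_BACKGROUND_STEPDOWN", sparse_code(conc))))
  }
  decide("keep", concs[one_idx],
         c(codes, "SAT_DEFAULT_1X", sparse_code(concs[one_idx])))
}

#' Build the panel decision table
#'
#' Runs [selectConcentration()] for every targeting antibody using its
#' dose-response profile, dose class and persistent-bottom flag, and
#' assembles the panel: kept antibodies with working concentrations, the
#' spike-in list, and exclusions with machine-readable rationales. The
#' profiles are stored in the result's config for decision audit replay.
#'
#' @param profiles A [DoseResponseSet-class] from [doseResponseProfile()].
#' @param ranking A [RankingResult-class] (used for persistent-bottom
#'   flags), or NULL to treat no antibody as bottom-ranked.
#' @param config A [decisionConfig()].
#' @return A [PanelDecision-class].
#' @export
buildPanel <- function(profiles, ranking = NULL,
                       config = decisionConfig()) {
  prof <- as.data.frame(doseProfiles(profiles))
  classes <- as.data.frame(doseClasses(profiles))
  if (anyDuplicated(classes$adt)) stop("duplicate ADT ids", call. = FALSE)
  bottom <- if (is.null(ranking)) character() else persistentBottom(ranking)
  rows <- lapply(classes$adt, function(a) {
    selectConcentration(prof[prof$adt == a, ],
                        classes$dose_class[classes$adt == a],
                        a %in% bottom, config, adt = a)
  })
  dec <- DataFrame(do.call(rbind, rows))
  new("PanelDecision", decisions = dec,
      config = c(unclass(config),
                 list(persistent_bottom = bottom, profiles = prof,
                      classes = classes)))
}

#' Replay a panel decision audit
#'
#' Re-evaluates every decision from the stored profiles, classes and flags;
#' returns TRUE when every action and concentration reproduces exactly.
#'
#' @param panel A [PanelDecision-class] from [buildPanel()].
#' @return TRUE, or a character description of the first divergence.
#' @export
replayDecisions <- function(panel) {
  cfg <- panel@config
  conf <- do.call(decisionConfig, cfg[intersect(names(cfg),
    names(formals(decisionConfig)))])
  prof <- cfg$profiles; classes <- cfg$classes
  dec <- as.data.frame(panelDecisions(panel))
  for (i in seq_len(nrow(dec))) {
    a <- dec$adt[i]
    redo <- selectConcentration(prof[prof$adt == a, ],
                                classes$dose_class[classes$adt == a],
                                a %in% cfg$persistent_bottom, conf, adt = a)
    if (redo$action != dec$action[i] ||
        !identical(is.na(redo$concentration), is.na(dec$concentration[i])) ||
        (!is.na(redo$concentration) &&
         redo$concentration != dec$concentration[i]))
      return(sprintf("decision for %s does not replay", a))
  }
  TRUE
}
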