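#' Configuration constructors
#'
#' Every numeric constant used by the pipeline stages lives in one of these
#' validated constructors, never hard-coded in stage logic. Each returns a
#' classed list; invalid values raise an error naming the offending field.
#'
#' @name titrADT-configs
NULL

#' Synthetic titration generator configuration
#'
#' Defines the study conditions emulated by [simulateTitration()]: a dilution
#' series of antibody concentrations (fold units relative to the working
#' concentration), per-cell sequencing-depth variability, negative-binomial
#' count noise, hashing with doublets and ambient hashtag reads, and isotype
#' control channels.
#'
#' @param n_cells_per_concentration Cells simulated per concentration.
#' @param n_clusters Number of transcriptome-defined cell clusters.
#' @param concentrations Strictly increasing positive fold concentrations;
#'   the default dilution series is 0.25x, 0.5x, 1x, 2x, 4x.
#' @param n_adts Number of targeting ADT channels (excludes isotypes).
#' @param n_isotypes Number of isotype-control channels (background only).
#' @param n_htos Number of hashtag channels.
#' @param doublet_rate Fraction of droplets containing two cells.
#' @param ambient_hto_fraction Fraction of a droplet's HTO reads drawn from
#'   the ambient (uniform over hashes) pool rather than its own hash(es).
#' @param depth_lognormal_params Numeric `(mu, sigma)` of the log-normal
#'   per-cell relative depth factor.
#' @param nb_dispersion Negative-binomial dispersion shared by ADT channels
#'   (variance = mu + dispersion * mu^2).
#' @param hto_depth Expected HTO reads per unit depth.
#' @param seed Integer seed governing the single top-level generator stream.
#' @return A `titration_config` list.
#' @export
titrationConfig <- function(n_cells_per_concentration = 2000,
                            n_clusters = 6,
                            concentrations = c(0.25, 0.5, 1, 2, 4),
                            n_adts = 40,
                            n_isotypes = 9,
                            n_htos = 8,
                            doublet_rate = 0.08,
                            ambient_hto_fraction = 0.05,
                            depth_lognormal_params = c(0, 0.3),
                            nb_dispersion = 0.4,
                            hto_depth = 300,
                            seed = 1L) {
  check_scalar(n_cells_per_concentration, "n_cells_per_concentration",
               min = 1, integer = TRUE)
  check_scalar(n_clusters, "n_clusters", min = 1, integer = TRUE)
  if (length(concentrations) < 1L || any(!is.finite(concentrations)) ||
      any(concentrations <= 0))
    stop_field("concentrations", "must be positive finite scalars")
  if (is.unsorted(concentrations, strictly = TRUE))
    stop_field("concentrations", "must be strictly increasing")
  check_scalar(n_adts, "n_adts", min = 1, integer = TRUE)
  check_scalar(n_isotypes, "n_isotypes", min = 0, integer = TRUE)
  check_scalar(n_htos, "n_htos", min = 1, integer = TRUE)
  check_scalar(doublet_rate, "doublet_rate", min = 0, max = 1)
  check_scalar(ambient_hto_fraction, "ambient_hto_fraction", min = 0, max = 1)
  if (length(depth_lognormal_params) != 2L ||
      any(!is.finite(depth_lognormal_params)) ||
      depth_lognormal_params[2] < 0)
    stop_field("depth_lognormal_params", "must be finite (mu, sigma >= 0)")
  check_scalar(nb_dispersion, "nb_dispersion", min = 0, strict_min = TRUE)
  check_scalar(hto_depth, "hto_depth", min = 0, strict_min = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(
    n_cells_per_concentration = as.integer(n_cells_per_concentration),
    n_clusters = as.integer(n_clusters),
    concentrations = as.numeric(concentrations),
    n_adts = as.integer(n_adts),
    n_isotypes = as.integer(n_isotypes),
    n_htos = as.integer(n_htos),
    doublet_rate = doublet_rate,
    ambient_hto_fraction = ambient_hto_fraction,
    depth_lognormal_params = as.numeric(depth_lognormal_params),
    nb_dispersion = nb_dispersion,
    hto_depth = hto_depth,
    seed = as.integer(seed)
  ), class = "titration_config")
}

#' Hashtag demultiplexing configuration
#'
#' Thresholds operate on per-cell HTO read fractions after counts-per-ten-
#' thousand (CPTT) normalization: a barcode is a doublet when more than
#' `multi_max_fraction` of its normalized reads fall outside its top hash,
#' a confident singlet when the top hash exceeds `singlet_min_fraction`,
#' and unassigned otherwise.
#'
#' @param singlet_min_fraction Minimum top-hash fraction for a singlet call.
#' @param multi_max_fraction Maximum tolerated multi-hash fraction.
#' @param normalization_scale Per-cell total after CPTT normalization.
#' @param multi_mode `"non_top_total"` (default) tests the total non-top
#'   fraction against `multi_max_fraction`; `"second_hash"` tests only the
#'   second-largest hash fraction.
#' @return A `demux_config` list.
#' @export
demuxConfig <- function(singlet_min_fraction = 0.40,
                        multi_max_fraction = 0.30,
                        normalization_scale = 10000,
                        multi_mode = c("non_top_total", "second_hash")) {
  check_scalar(singlet_min_fraction, "singlet_min_fraction",
               min = 0, max = 1, strict_min = TRUE)
  if (singlet_min_fraction >= 1)
    stop_field("singlet_min_fraction", "must be < 1")
  check_scalar(multi_max_fraction, "multi_max_fraction",
               min = 0, max = 1, strict_min = TRUE)
  if (multi_max_fraction >= 1) stop_field("multi_max_fraction", "must be < 1")
  check_scalar(normalization_scale, "normalization_scale",
               min = 1, integer = TRUE)
  multi_mode <- match.arg(multi_mode)
  structure(list(singlet_min_fraction = singlet_min_fraction,
                 multi_max_fraction = multi_max_fraction,
                 normalization_scale = as.integer(normalization_scale),
                 multi_mode = multi_mode),
            class = "demux_config")
}

#' RNA quality-control configuration
#'
#' Strict-inequality thresholds on per-cell RNA covariates: keep a cell iff
#' genes detected > `min_genes`, RNA counts > `min_rna_counts`, and
#' mitochondrial percentage < `max_percent_mt`.
#'
#' @param min_genes,min_rna_counts,max_percent_mt Thresholds.
#' @return A `qc_config` list.
#' @export
qcConfig <- function(min_genes = 500, min_rna_counts = 1000,
                     max_percent_mt = 25) {
  check_scalar(min_genes, "min_genes", min = 0, strict_min = TRUE,
               integer = TRUE)
  check_scalar(min_rna_counts, "min_rna_counts", min = 0, strict_min = TRUE,
               integer = TRUE)
  check_scalar(max_percent_mt, "max_percent_mt", min = 0, strict_min = TRUE)
  structure(list(min_genes = as.integer(min_genes),
                 min_rna_counts = as.integer(min_rna_counts),
                 max_percent_mt = max_percent_mt),
            class = "qc_config")
}

#' Marker-ranking configuration
#'
#' Hyperparameters of the per-concentration gradient-boosted classifier used
#' to rank ADTs by gain, and the bottom-rank fraction used to flag
#' persistently uninformative markers.
#'
#' @param n_rounds Boosting rounds.
#' @param max_depth Tree depth.
#' @param learning_rate Shrinkage (eta).
#' @param colsample Fraction of ADTs sampled per tree; values below 1 force
#'   the booster to spread splits over all informative markers instead of a
#'   winner-take-all few, which stabilizes the gain ranking.
#' @param seed Seed for the booster.
#' @param bottom_fraction Rank fraction (from the bottom) an ADT must occupy
#'   at every concentration to be flagged persistently uninformative.
#' @return A `ranking_config` list.
#' @export
rankingConfig <- function(n_rounds = 30, max_depth = 3, learning_rate = 0.3,
                          colsample = 0.5, seed = 1L,
                          bottom_fraction = 0.50) {
  check_scalar(n_rounds, "n_rounds", min = 1, integer = TRUE)
  check_scalar(max_depth, "max_depth", min = 1, integer = TRUE)
  check_scalar(learning_rate, "learning_rate", min = 0, strict_min = TRUE)
  check_scalar(colsample, "colsample", min = 0, max = 1, strict_min = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  check_scalar(bottom_fraction, "bottom_fraction", min = 0, max = 1,
               strict_min = TRUE)
  if (bottom_fraction >= 1) stop_field("bottom_fraction", "must be < 1")
  structure(list(n_rounds = as.integer(n_rounds),
                 max_depth = as.integer(max_depth),
                 learning_rate = learning_rate, colsample = colsample,
                 seed = as.integer(seed),
                 bottom_fraction = bottom_fraction),
            class = "ranking_config")
}

#' Panel decision-tree configuration
#'
#' Thresholds of the concentration-selection decision tree. For
#' dose-dependent antibodies the smallest concentration retaining
#' `retention_fraction` of the observed dynamic range is chosen; antibodies
#' consuming more than `load_threshold` of total ADT reads are demoted one
#' concentration step; an antibody whose lowest-concentration distribution is
#' statistically indistinguishable from the pooled isotype controls
#' (standardized Anderson-Darling statistic below `specificity_t_min`) is
#' flagged nonspecific.
#'
#' @param retention_fraction Fraction of the maximal dynamic range that must
#'   be retained at the chosen concentration.
#' @param load_threshold Maximum tolerated fraction of total ADT reads.
#' @param signal_min Minimum dynamic range (CLR units) to call a marker
#'   detectable.
#' @param flat_rel_spread Maximum relative spread (DRmax-DRmin)/DRmax still
#'   called flat (saturating).
#' @param dose_corr_min Minimum Spearman correlation of dynamic range with
#'   log concentration to call a profile dose-dependent.
#' @param specificity_t_min Standardized Anderson-Darling threshold below
#'   which staining is indistinguishable from isotypes.
#' @param sparse_pos_min Minimum positive-cell fraction in the best cluster
#'   before a SPARSE annotation is recorded.
#' @param whitelist ADT identifiers protected from exclusion; defaults to the
#'   seven canonical spike-in antibodies.
#' @param blacklist ADT identifiers force-excluded.
#' @param ad_max_cells Per-group subsample ceiling for the specificity
#'   statistic (keeps its computation O(n log n) at fixed power).
#' @param seed Seed for the deterministic specificity subsample.
#' @return A `decision_config` list.
#' @export
decisionConfig <- function(retention_fraction = 0.75,
                           load_threshold = 0.10,
                           signal_min = 0.5,
                           flat_rel_spread = 0.25,
                           dose_corr_min = 0.9,
                           specificity_t_min = 2,
                           sparse_pos_min = 0.10,
                           whitelist = c("CD34", "CD16", "CD4", "CD90",
                                         "CD45", "CD11b", "CD127"),
                           blacklist = character(),
                           ad_max_cells = 4000,
                           seed = 1L) {
  check_scalar(retention_fraction, "retention_fraction", min = 0, max = 1,
               strict_min = TRUE)
  check_scalar(load_threshold, "load_threshold", min = 0, max = 1,
               strict_min = TRUE)
  check_scalar(signal_min, "signal_min", min = 0)
  check_scalar(flat_rel_spread, "flat_rel_spread", min = 0, max = 1,
               strict_min = TRUE)
  check_scalar(dose_corr_min, "dose_corr_min", min = -1, max = 1)
  check_scalar(specificity_t_min, "specificity_t_min")
  check_scalar(sparse_pos_min, "sparse_pos_min", min = 0, max = 1,
               strict_min = TRUE)
  check_scalar(ad_max_cells, "ad_max_cells", min = 10, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  whitelist <- as.character(whitelist); blacklist <- as.character(blacklist)
  if (length(intersect(whitelist, blacklist)) > 0)
    stop_field("whitelist", "must not intersect blacklist")
  structure(list(retention_fraction = retention_fraction,
                 load_threshold = load_threshold, signal_min = signal_min,
                 flat_rel_spread = flat_rel_spread,
                 dose_corr_min = dose_corr_min,
                 specificity_t_min = specificity_t_min,
                 sparse_pos_min = sparse_pos_min,
                 whitelist = whitelist, blacklist = blacklist,
                 ad_max_cells = as.integer(ad_max_cells),
                 seed = as.integer(seed)),
            class = "decision_config")
}

#' Cross-batch consistency configuration
#'
#' @param n_subsample_donor Per-donor subsample for across-donor comparisons.
#' @param n_subsample_cross Per-donor/technology subsample for
#'   cross-technology comparisons.
#' @param seed Subsampling seed.
#' @param n_bins Histogram bins for the Earth Mover's Distance.
#' @param log10_transform Report log10 of the standardized statistic.
#' @param log10_floor Floor (log10 units) for non-positive statistics.
#' @return A `consistency_config` list.
#' @export
consistencyConfig <- function(n_subsample_donor = 2500,
                              n_subsample_cross = 2450,
                              seed = 1L, n_bins = 200,
                              log10_transform = TRUE, log10_floor = -2) {
  check_scalar(n_subsample_donor, "n_subsample_donor", min = 1,
               integer = TRUE)
  check_scalar(n_subsample_cross, "n_subsample_cross", min = 1,
               integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  check_scalar(n_bins, "n_bins", min = 10, integer = TRUE)
  if (!is.logical(log10_transform) || length(log10_transform) != 1L)
    stop_field("log10_transform", "must be TRUE or FALSE")
  check_scalar(log10_floor, "log10_floor")
  structure(list(n_subsample_donor = as.integer(n_subsample_donor),
                 n_subsample_cross = as.integer(n_subsample_cross),
                 seed = as.integer(seed), n_bins = as.integer(n_bins),
                 log10_transform = log10_transform,
                 log10_floor = log10_floor),
            class = "consistency_config")
}

#' Differential-abundance filter configuration
#'
#' @param min_abs_difference Minimum absolute difference of min-max-scaled
#'   per-cluster feature means between groups.
#' @param alpha Significance level applied to BH-adjusted q values.
#' @return A `diff_filter_config` list.
#' @export
diffFilterConfig <- function(min_abs_difference = 0.10, alpha = 0.05) {
  check_scalar(min_abs_difference, "min_abs_difference", min = 0, max = 1)
  check_scalar(alpha, "alpha", min = 0, max = 1, strict_min = TRUE)
  if (alpha >= 1) stop_field("alpha", "must be < 1")
  structure(list(min_abs_difference = min_abs_difference, alpha = alpha),
            class = "diff_filter_config")
}
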