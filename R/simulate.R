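#' Plant per-ADT ground truth for the titration generator
#'
#' Builds the truth table consumed by [simulateTitration()]. Each targeting
#' antibody belongs to one behavioural class the concentration-selection
#' decision tree must discriminate:
#' \describe{
#'   \item{specific_dose_dependent}{half-saturation (kd) above the tested
#'     range, so specific signal keeps growing across the dilution series.}
#'   \item{specific_saturating}{kd far below the lowest concentration, so
#'     all tested doses sit on the plateau.}
#'   \item{nonspecific}{no specific binding; background identical in law to
#'     the isotype controls.}
#'   \item{weak}{specific binding with a rate below `weak_rate_max`, chosen
#'     so the expected CLR separation stays under the default detection
#'     floor at every tested concentration.}
#'   \item{isotype}{isotype-control channel; background only.}
#' }
#'
#' Expected count for cell i (depth d_i, cluster k) on antibody a at fold
#' concentration c is
#' `d_i * (background_rate_a * c + specific_rate_a * [k in targets_a] * c/(c + kd_a))`:
#' nonspecific binding grows linearly with antibody amount while specific
#' binding saturates with Michaelis-Menten occupancy.
#'
#' @param n_specific_dose,n_specific_sat,n_nonspecific,n_weak,n_isotypes
#'   Channel counts per class.
#' @param n_clusters Number of cell clusters targets are drawn from.
#' @param background_rate Per-unit-depth, per-fold nonspecific rate shared by
#'   all channels (isotype-like background).
#' @param specific_rate_range Range of per-unit-depth specific rates for
#'   specific classes.
#' @param weak_rate_max Upper bound on the specific rate of "weak" channels.
#' @param kd_dose_range,kd_sat_range kd ranges (fold units) for the
#'   dose-dependent and saturating classes.
#' @param adt_names Optional channel names; defaults to ADT1.., ISO1.. .
#' @param seed Seed.
#' @return A [S4Vectors::DataFrame] with columns `adt`, `cls`, `is_isotype`,
#'   `kd`, `specific_rate`, `background_rate`, `target_clusters`
#'   (comma-separated ids, empty for nonspecific/isotype).
#' @export
makeAdtTruth <- function(n_specific_dose = 10, n_specific_sat = 10,
                         n_nonspecific = 5, n_weak = 5, n_isotypes = 9,
                         n_clusters = 6,
                         background_rate = 0.5,
                         specific_rate_range = c(50, 200),
                         weak_rate_max = 1.2,
                         kd_dose_range = c(2, 8),
                         kd_sat_range = c(0.02, 0.1),
                         adt_names = NULL, seed = 1L) {
  with_seed(seed, {
    cls <- c(rep("specific_dose_dependent", n_specific_dose),
             rep("specific_saturating", n_specific_sat),
             rep("nonspecific", n_nonspecific),
             rep("weak", n_weak),
             rep("isotype", n_isotypes))
    n <- length(cls)
    n_target <- n - n_isotypes
    if (is.null(adt_names))
      adt_names <- c(sprintf("ADT%03d", seq_len(n_target)),
                     if (n_isotypes > 0) sprintf("ISO%02d", seq_len(n_isotypes)))
    stopifnot(length(adt_names) == n)
    kd <- numeric(n)
    kd[cls == "specific_dose_dependent"] <-
      runif(sum(cls == "specific_dose_dependent"),
            kd_dose_range[1], kd_dose_range[2])
    kd[cls == "specific_saturating"] <-
      runif(sum(cls == "specific_saturating"),
            kd_sat_range[1], kd_sat_range[2])
    kd[cls == "weak"] <- runif(sum(cls == "weak"), 1, 2)
    kd[kd == 0] <- 1
    spec <- numeric(n)
    is_spec <- cls %in% c("specific_dose_dependent", "specific_saturating")
    spec[is_spec] <- runif(sum(is_spec),
                           specific_rate_range[1], specific_rate_range[2])
    spec[cls == "weak"] <- runif(sum(cls == "weak"), weak_rate_max / 4,
                                 weak_rate_max)
    targets <- character(n)
    has_t <- cls %in% c("specific_dose_dependent", "specific_saturating",
                        "weak")
    for (i in which(has_t)) {
      kt <- sample(seq_len(n_clusters), size = sample(1:2, 1))
      targets[i] <- paste(sort(kt), collapse = ",")
    }
    DataFrame(adt = adt_names, cls = cls,
              is_isotype = cls == "isotype",
              kd = kd, specific_rate = spec,
              background_rate = rep(background_rate, n),
              target_clusters = targets)
  })
}

parse_targets <- function(s) {
  if (is.na(s) || s == "") integer() else as.integer(strsplit(s, ",")[[1]])
}

#' Simulate a multi-concentration CITE-seq titration dataset
#'
#' Generates ADT and HTO count matrices with planted ground truth under the
#' binding model documented in [makeAdtTruth()]: saturating specific binding
#' plus concentration-proportional background, negative-binomial count noise
#' with shared dispersion, log-normal per-cell depth, donor/concentration
#' hashing with doublets (two cells' ADT and HTO profiles summed) and a
#' uniform ambient HTO pool. Deterministic under a fixed
#' `config$seed`; the caller's RNG state is untouched.
#'
#' @param config A [titrationConfig()].
#' @param truth Optional truth table from [makeAdtTruth()]; when NULL a
#'   default mix is planted matching `config$n_adts`/`config$n_isotypes`
#'   (60\% dose-dependent-or-saturating, 20\% nonspecific, 20\% weak).
#' @return A [TitrationExperiment-class] with planted truth in
#'   `rowData`/`metadata()$adt_truth` and per-cell truth (`cluster`,
#'   `true_hash`, `true_doublet`) plus QC covariates in `colData`.
#' @examples
#' te <- simulateTitration(titrationConfig(n_cells_per_concentration = 100,
#'                                         n_adts = 10, seed = 7))
#' te
#' @export
simulateTitration <- function(config = titrationConfig(), truth = NULL) {
  if (!inherits(config, "titration_config"))
    config <- do.call(titrationConfig, config)
  if (is.null(truth)) {
    n_t <- config$n_adts
    counts <- diff(round(cumsum(c(0.3, 0.3, 0.2, 0.2)) * n_t))
    counts <- c(n_t - sum(counts), counts)
    truth <- makeAdtTruth(counts[1], counts[2], counts[3], counts[4],
                          n_isotypes = config$n_isotypes,
                          n_clusters = config$n_clusters,
                          seed = derive_seed(config$seed, "adt"))
  }
  n_feat <- nrow(truth)
  concs <- config$concentrations
  n_per <- config$n_cells_per_concentration
  n_cells <- n_per * length(concs)

  cells <- with_seed(derive_seed(config$seed, "cells"), {
    concentration <- rep(concs, each = n_per)
    cluster <- sample(seq_len(config$n_clusters), n_cells, replace = TRUE)
    depth <- exp(rnorm(n_cells, config$depth_lognormal_params[1],
                       config$depth_lognormal_params[2]))
    hash <- sample(seq_len(config$n_htos), n_cells, replace = TRUE)
    is_doublet <- runif(n_cells) < config$doublet_rate
    # shadow partner of each doublet: same capture (concentration), forced
    # onto a different hash so the doublet is detectable by construction
    cluster2 <- sample(seq_len(config$n_clusters), n_cells, replace = TRUE)
    depth2 <- exp(rnorm(n_cells, config$depth_lognormal_params[1],
                        config$depth_lognormal_params[2]))
    hash2 <- hash
    for (i in which(is_doublet)) {
      hash2[i] <- sample(setdiff(seq_len(config$n_htos), hash[i]), 1)
    }
    list(concentration = concentration, cluster = cluster, depth = depth,
         hash = hash, is_doublet = is_doublet, cluster2 = cluster2,
         depth2 = depth2, hash2 = hash2)
  })

  mean_mat <- function(cluster, depth, conc) {
    # features x cells expected counts under the binding model
    occ <- outer(truth$kd, conc, function(kd, c) c / (c + kd))
    bg <- outer(truth$background_rate, conc)
    tgt <- matrix(0, n_feat, length(cluster))
    for (a in seq_len(n_feat)) {
      tk <- parse_targets(truth$target_clusters[a])
      if (length(tk)) tgt[a, cluster %in% tk] <- 1
    }
    mu <- (bg + occ * truth$specific_rate * tgt) *
      rep(depth, each = n_feat)
    mu
  }

  adt <- with_seed(derive_seed(config$seed, "adt") + 1L, {
    mu1 <- mean_mat(cells$cluster, cells$depth, cells$concentration)
    size <- 1 / config$nb_dispersion
    m <- matrix(rnbinom(length(mu1), mu = mu1, size = size),
                n_feat, n_cells)
    dbl <- which(cells$is_doublet)
    if (length(dbl)) {
      mu2 <- mean_mat(cells$cluster2[dbl], cells$depth2[dbl],
                      cells$concentration[dbl])
      m[, dbl] <- m[, dbl] +
        matrix(rnbinom(length(mu2), mu = mu2, size = size),
               n_feat, length(dbl))
    }
    m
  })

  hto <- with_seed(derive_seed(config$seed, "hto"), {
    nh <- config$n_htos
    amb <- config$ambient_hto_fraction
    p <- matrix(amb / nh, nh, n_cells)
    for (i in seq_len(n_cells)) {
      if (cells$is_doublet[i]) {
        dtot <- cells$depth[i] + cells$depth2[i]
        p[cells$hash[i], i] <- p[cells$hash[i], i] +
          (1 - amb) * cells$depth[i] / dtot
        p[cells$hash2[i], i] <- p[cells$hash2[i], i] +
          (1 - amb) * cells$depth2[i] / dtot
      } else {
        p[cells$hash[i], i] <- p[cells$hash[i], i] + (1 - amb)
      }
    }
    dtot <- cells$depth + ifelse(cells$is_doublet, cells$depth2, 0)
    totals <- rpois(n_cells, dtot * config$hto_depth)
    m <- matrix(0L, nh, n_cells)
    for (i in seq_len(n_cells)) {
      if (totals[i] > 0) m[, i] <- rmultinom(1, totals[i], p[, i])[, 1]
    }
    m
  })

  qc <- with_seed(derive_seed(config$seed, "qc"), {
    n_genes <- round(exp(rnorm(n_cells, log(2500), 0.35)))
    rna_count <- round(n_genes * runif(n_cells, 2.5, 4))
    percent_mt <- rgamma(n_cells, shape = 4, scale = 2)
    list(n_genes = as.integer(n_genes), rna_count = as.integer(rna_count),
         percent_mt = percent_mt)
  })

  barcodes <- sprintf("cell%05d", seq_len(n_cells))
  dimnames(adt) <- list(truth$adt, barcodes)
  dimnames(hto) <- list(sprintf("HTO%02d", seq_len(config$n_htos)), barcodes)
  cd <- DataFrame(concentration = cells$concentration,
                  cluster = cells$cluster,
                  true_hash = sprintf("HTO%02d", cells$hash),
                  second_true_hash = ifelse(
                    cells$is_doublet, sprintf("HTO%02d", cells$hash2), NA),
                  true_doublet = cells$is_doublet,
                  depth = cells$depth,
                  n_genes = qc$n_genes, rna_count = qc$rna_count,
                  percent_mt = qc$percent_mt,
                  row.names = barcodes)
  rd <- truth
  rownames(rd) <- truth$adt
  TitrationExperiment(adt, hto_counts = hto, col_data = cd, row_data = rd,
                      concentrations = concs,
                      metadata = list(adt_truth = truth,
                                      generator_config = unclass(config)))
}

#' Simulate batch-labelled marker intensity tables
#'
#' Fixture generator for the cross-batch consistency statistics: markers
#' flagged consistent are drawn i.i.d. from one two-component Gaussian
#' mixture in every batch; inconsistent markers receive per-batch location,
#' scale, or modality perturbations described by `shift_spec`.
#'
#' @param n_batches Number of batches (>= 2).
#' @param n_markers Number of markers.
#' @param n_per_batch Observations per marker per batch.
#' @param shift_spec A data.frame with columns `marker` (index or name),
#'   `type` (`"location"`, `"scale"` or `"modality"`), `magnitude`; the
#'   perturbation is applied to every batch after the first. NULL or empty
#'   means all markers are consistent.
#' @param seed Seed.
#' @return A data.frame (`marker`, `batch`, `value`) with attribute
#'   `truth`: a data.frame (`marker`, `consistent`).
#' @export
simulateBatchIntensities <- function(n_batches = 2, n_markers = 20,
                                     n_per_batch = 1000, shift_spec = NULL,
                                     seed = 1L) {
  if (n_batches < 2) stop_field("n_batches", "must be >= 2")
  if (n_markers < 1) stop_field("n_markers", "must be positive")
  if (n_per_batch < 1) stop_field("n_per_batch", "must be positive")
  with_seed(seed, {
    marker_names <- sprintf("M%03d", seq_len(n_markers))
    spec <- list()
    if (!is.null(shift_spec) && nrow(shift_spec) > 0) {
      mk <- shift_spec$marker
      if (is.numeric(mk)) mk <- marker_names[mk]
      spec <- split(shift_spec, mk)
    }
    out <- vector("list", n_markers)
    for (m in seq_len(n_markers)) {
      mu1 <- runif(1, 0, 2); mu2 <- mu1 + runif(1, 1.5, 3)
      sd1 <- runif(1, 0.3, 0.6); sd2 <- runif(1, 0.3, 0.6)
      w <- runif(1, 0.3, 0.7)
      draw <- function(n, dmu = 0, dsd = 1, dmod = 0) {
        comp <- rbinom(n, 1, min(1, max(0, w + dmod)))
        x <- ifelse(comp == 1, rnorm(n, mu1, sd1 * dsd),
                    rnorm(n, mu2, sd2 * dsd))
        x + dmu
      }
      pert <- spec[[marker_names[m]]]
      vals <- lapply(seq_len(n_batches), function(b) {
        if (b == 1 || is.null(pert)) return(draw(n_per_batch))
        dmu <- sum(pert$magnitude[pert$type == "location"])
        dsd <- prod(ifelse(pert$type == "scale", pert$magnitude, 1))
        dmod <- sum(pert$magnitude[pert$type == "modality"])
        draw(n_per_batch, dmu = dmu, dsd = dsd, dmod = dmod)
      })
      out[[m]] <- data.frame(
        marker = marker_names[m],
        batch = rep(sprintf("batch%d", seq_len(n_batches)),
                    each = n_per_batch),
        value = unlist(vals))
    }
    res <- do.call(rbind, out)
    attr(res, "truth") <- data.frame(
      marker = marker_names,
      consistent = !(marker_names %in% names(spec)))
    res
  })
}
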