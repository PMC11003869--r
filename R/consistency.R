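#' k-sample Anderson-Darling statistic (Scholz-Stephens, midrank version)
#'
#' Computes the rank-based k-sample Anderson-Darling criterion with midrank
#' tie handling. Writing N for the pooled size, z_j for the L distinct
#' pooled values with multiplicities l_j, B_j for the midrank cumulative
#' count and M_ij for the midrank cumulative count within sample i,
#'
#' \deqn{A^2 = \frac{N-1}{N} \sum_i \frac{1}{n_i} \sum_j \frac{l_j}{N}
#'   \frac{(N M_{ij} - n_i B_j)^2}{B_j (N - B_j) - N l_j / 4}}
#'
#' Under the hypothesis that all k samples share one distribution the
#' criterion has mean close to k - 1; the combinatorial null variance
#' sigma_N^2 standardizes it to `T = (A2 - (k - 1)) / sigma_N`, the
#' dissimilarity score ("t value") used throughout the consistency module.
#'
#' @param samples A list of k >= 2 numeric vectors, each of length >= 5.
#' @return A list with `A2` (the criterion), `T` (standardized statistic),
#'   `sigma` (null standard deviation), `k`, `N`.
#' @examples
#' adKSample(list(rnorm(50), rnorm(50)))
#' @export
adKSample <- function(samples) {
  if (!is.list(samples) || length(samples) < 2)
    stop("need a list of at least 2 samples", call. = FALSE)
  n <- lengths(samples)
  if (any(n < 5))
    stop("each sample needs at least 5 observations", call. = FALSE)
  samples <- lapply(samples, function(s) {
    s <- as.numeric(s)
    if (any(!is.finite(s))) stop("samples must be finite", call. = FALSE)
    s
  })
  k <- length(samples)
  pooled <- unlist(samples, use.names = FALSE)
  N <- length(pooled)
  zstar <- sort(unique(pooled))
  if (length(zstar) < 2)
    stop("pooled data are constant; statistic undefined", call. = FALSE)
  lj <- tabulate(match(pooled, zstar), nbins = length(zstar))
  below <- cumsum(c(0, lj[-length(lj)]))
  Bj <- below + lj / 2
  denom <- Bj * (N - Bj) - N * lj / 4
  A2 <- 0
  for (i in seq_len(k)) {
    ci <- tabulate(match(samples[[i]], zstar), nbins = length(zstar))
    Mij <- cumsum(c(0, ci[-length(ci)])) + ci / 2
    term <- lj / N * (N * Mij - n[i] * Bj)^2 / denom
    term[denom <= 0] <- 0
    A2 <- A2 + sum(term) / n[i]
  }
  A2 <- A2 * (N - 1) / N
  # combinatorial null variance (Scholz & Stephens)
  H <- sum(1 / n)
  hvec <- cumsum(1 / seq_len(N - 1))
  h <- hvec[N - 1]
  i_idx <- seq_len(N - 2)
  g <- sum((hvec[N - 1] - hvec[i_idx]) / (N - i_idx))
  a <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * H
  b <- (2 * g - 4) * k^2 + 8 * h * k +
    (2 * g - 14 * h - 4) * H - 8 * h + 4 * g - 6
  cc <- (6 * h + 2 * g - 2) * k^2 + (4 * h - 4 * g + 6) * k +
    (2 * h - 6) * H + 4 * h
  d <- (2 * h + 6) * k^2 - 4 * h * k
  sigma2 <- (a * N^3 + b * N^2 + cc * N + d) /
    ((N - 1) * (N - 2) * (N - 3))
  sigma <- sqrt(sigma2)
  list(A2 = A2, T = (A2 - (k - 1)) / sigma, sigma = sigma, k = k, N = N)
}

subsample_vec <- function(x, n, warn_label = NULL) {
  if (length(x) <= n) {
    if (length(x) < n && !is.null(warn_label))
      warning(sprintf("batch %s smaller than subsample size; using all %d",
                      warn_label, length(x)), call. = FALSE)
    return(x)
  }
  x[sample.int(length(x), n)]
}

#' Per-marker cross-batch consistency scores
#'
#' For each marker, subsamples every batch to the configured size (without
#' replacement, seeded), applies [adKSample()] across batches, and reports
#' the standardized Anderson-Darling statistic as a dissimilarity score,
#' optionally log10-transformed (non-positive statistics are mapped to the
#' configured floor and flagged). Optionally also computes the pairwise
#' binned Earth Mover's Distance matrix between batches.
#'
#' @param intensities Long-format data.frame with columns `marker`, `batch`,
#'   `value` (as produced by [simulateBatchIntensities()]).
#' @param config A [consistencyConfig()]; `n_subsample_donor` is the
#'   per-batch subsample size.
#' @param compute_emd Also compute pairwise EMD matrices per marker.
#' @return A [ConsistencyReport-class].
#' @export
donorConsistency <- function(intensities, config = consistencyConfig(),
                             compute_emd = FALSE) {
  need <- c("marker", "batch", "value")
  if (!all(need %in% names(intensities)))
    stop("intensities must have columns marker, batch, value",
         call. = FALSE)
  markers <- unique(intensities$marker)
  res <- vector("list", length(markers))
  emds <- list()
  with_seed(derive_seed(config$seed, "subsample"), {
    for (mi in seq_along(markers)) {
      sub <- intensities[intensities$marker == markers[mi], ]
      by_batch <- split(sub$value, sub$batch)
      if (length(by_batch) < 2)
        stop(sprintf("marker %s has fewer than 2 batches", markers[mi]),
             call. = FALSE)
      drawn <- lapply(names(by_batch), function(b)
        subsample_vec(by_batch[[b]], config$n_subsample_donor,
                      warn_label = b))
      st <- adKSample(drawn)
      floored <- FALSE
      l10 <- NA_real_
      if (config$log10_transform) {
        if (st$T <= 0) {
          l10 <- config$log10_floor; floored <- TRUE
        } else l10 <- log10(st$T)
      }
      res[[mi]] <- data.frame(marker = markers[mi], ad_t = st$T,
                              A2 = st$A2, log10_t = l10, floored = floored,
                              n_used = sum(lengths(drawn)))
      if (compute_emd) {
        nb <- length(drawn)
        em <- matrix(0, nb, nb,
                     dimnames = list(names(by_batch), names(by_batch)))
        for (i in seq_len(nb - 1)) for (j in (i + 1):nb) {
          em[i, j] <- em[j, i] <- emd1d(drawn[[i]], drawn[[j]],
                                        n_bins = config$n_bins)
        }
        emds[[as.character(markers[mi])]] <- em
      }
    }
  })
  new("ConsistencyReport", markers = DataFrame(do.call(rbind, res)),
      emd = emds, config = unclass(config))
}

#' Binned 1-D Earth Mover's Distance (W1)
#'
#' Histograms both samples on a shared grid and returns the first Wasserstein
#' distance `sum_j |cumulative difference_j| * bin width`. For a pure
#' translation by a bin-aligned delta this equals delta (to bin resolution);
#' it is symmetric and zero iff the binned histograms agree.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @param n_bins Number of bins (default 200).
#' @param range Optional `c(lo, hi)` grid limits; by default the pooled
#'   0.1-99.9 percentile range. Values outside are clipped into edge bins.
#' @return The W1 distance (same units as the data).
#' @examples
#' emd1d(rnorm(1000), rnorm(1000) + 1)
#' @export
emd1d <- function(sample_a, sample_b, n_bins = 200, range = NULL) {
  if (length(sample_a) == 0 || length(sample_b) == 0)
    stop("samples must be non-empty", call. = FALSE)
  check_scalar(n_bins, "n_bins", min = 2, integer = TRUE)
  pooled <- c(sample_a, sample_b)
  if (is.null(range)) {
    range <- as.numeric(quantile(pooled, c(0.001, 0.999), names = FALSE))
  }
  lo <- range[1]; hi <- range[2]
  if (hi <= lo) return(0)
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  w <- breaks[2] - breaks[1]
  bin_of <- function(x) pmin(pmax(ceiling((x - lo) / w), 1L), n_bins)
  pa <- tabulate(bin_of(sample_a), nbins = n_bins) / length(sample_a)
  pb <- tabulate(bin_of(sample_b), nbins = n_bins) / length(sample_b)
  sum(abs(cumsum(pa - pb))) * w
}

#' Rank-quantile alignment of batched intensities
#'
#' Maps each batch's values through its empirical CDF onto the pooled
#' reference quantiles (rank-based quantile normalization), a light-weight
#' distributional alignment that is strictly monotone within batch.
#'
#' @param intensities Long-format data.frame (`marker`, `batch`, `value`) or
#'   a list of numeric vectors (one per batch) for a single marker.
#' @return The same structure with values replaced by aligned values (column
#'   `value` rewritten; for list input, a list).
#' @export
rankAlign <- function(intensities) {
  align_one <- function(batches) {
    if (length(batches) < 2) {
      warning("single batch; alignment is the identity", call. = FALSE)
      return(batches)
    }
    pooled <- sort(unlist(batches, use.names = FALSE))
    lapply(batches, function(x) {
      p <- (rank(x, ties.method = "average") - 0.5) / length(x)
      as.numeric(quantile(pooled, p, type = 7, names = FALSE))
    })
  }
  if (is.list(intensities) && !is.data.frame(intensities))
    return(align_one(intensities))
  need <- c("marker", "batch", "value")
  if (!all(need %in% names(intensities)))
    stop("intensities must have columns marker, batch, value",
         call. = FALSE)
  out <- intensities
  for (m in unique(out$marker)) {
    sel <- out$marker == m
    sub <- out[sel, ]
    by_batch <- split(seq_len(nrow(sub)), sub$batch)
    aligned <- align_one(lapply(by_batch, function(ix) sub$value[ix]))
    for (b in seq_along(by_batch))
      sub$value[by_batch[[b]]] <- aligned[[b]]
    out$value[sel] <- sub$value
  }
  out
}
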