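# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); used to solve the empirical-Bayes moment equation.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

# Estimate (d0, s0^2) from per-feature sample variances s2 on df degrees of
# freedom by matching moments of log s2 (scaled-inverse-chi-squared prior):
# Var[log s2] = trigamma(df/2) + trigamma(d0/2),
# E[log s2]  = log s0^2 + digamma(df/2) - log(df/2)
#              - digamma(d0/2) + log(d0/2).
estimate_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  s2 <- s2[ok]; df <- if (length(df) == 1) rep(df, length(s2)) else df[ok]
  if (length(s2) < 2) return(list(d0 = Inf, s0sq = mean(s2)))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(e) - mean(trigamma(df / 2))
  if (!is.finite(evar) || evar <= 0) {
    d0 <- Inf
    s0sq <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    if (!is.finite(d0) || d0 <= 0) {
      # moment-matching fallback on the variance of s2 itself
      d0 <- max(1, 2 * mean(s2)^2 / max(var(s2) - var(s2) / 2, 1e-8))
      s0sq <- mean(s2)
      return(list(d0 = d0, s0sq = s0sq))
    }
    s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0sq = s0sq)
}

#' Empirical-Bayes moderated two-sample t-test
#'
#' Per-feature two-group comparison with variance shrinkage: the pooled
#' sample variance s2_g (df = nA + nB - 2) is shrunk toward a global prior
#' variance s0^2 with prior degrees of freedom d0, both estimated across
#' features by matching moments of log s2 (digamma/trigamma equations,
#' Newton-solved; simple moment matching as fallback). The moderated
#' statistic
#' `t = (meanA - meanB) / (s_post * sqrt(1/nA + 1/nB))` with
#' `s_post^2 = (d0 s0^2 + df s2) / (d0 + df)` is referred to a t
#' distribution on d0 + df degrees of freedom; p values are BH-adjusted
#' across features.
#'
#' Features with zero variance in both groups and equal means get t = 0,
#' p = 1 rather than an error.
#'
#' @param values_a,values_b features x samples matrices for the two groups
#'   (same features; each group >= 2 samples).
#' @param prior_df Optional override for d0 (0 gives the ordinary pooled
#'   t-test; Inf fixes every posterior variance at s0^2).
#' @param prior_var Optional override for s0^2.
#' @return A [ModeratedFit-class].
#' @examples
#' a <- matrix(rnorm(200), 20); b <- matrix(rnorm(200, 0.5), 20)
#' fitTable(moderatedTTest(a, b))[1:3, c("t", "p", "q")]
#' @export
moderatedTTest <- function(values_a, values_b, prior_df = NULL,
                           prior_var = NULL) {
  a <- as_dense(values_a); b <- as_dense(values_b)
  if (nrow(a) != nrow(b)) stop("feature sets differ", call. = FALSE)
  na <- ncol(a); nb <- ncol(b)
  if (na < 2 || nb < 2)
    stop("each group needs >= 2 observations", call. = FALSE)
  if (nrow(a) < 5)
    warning("fewer than 5 features; prior estimation is unstable",
            call. = FALSE)
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  ss <- rowSums((a - mean_a)^2) + rowSums((b - mean_b)^2)
  df <- na + nb - 2
  s2 <- ss / df
  est <- estimate_prior(s2, df)
  d0 <- if (!is.null(prior_df)) prior_df else est$d0
  s0sq <- if (!is.null(prior_var)) prior_var else est$s0sq
  s2_post <- if (is.infinite(d0)) rep(s0sq, length(s2)) else
    (d0 * s0sq + df * s2) / (d0 + df)
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  diff <- mean_a - mean_b
  t <- ifelse(se == 0, ifelse(diff == 0, 0, sign(diff) * Inf), diff / se)
  df_total <- d0 + df
  p <- ifelse(se == 0 & diff == 0, 1, 2 * pt(-abs(t), df = df_total))
  q <- bhFDR(p)
  nm <- rownames(a)
  if (is.null(nm)) nm <- sprintf("F%04d", seq_len(nrow(a)))
  tb <- DataFrame(feature = nm, mean_a = mean_a, mean_b = mean_b,
                  diff = diff, s2 = s2, df = rep(df, length(s2)),
                  s2_post = s2_post, t = t,
                  df_total = rep(df_total, length(s2)), p = p, q = q,
                  row.names = nm)
  new("ModeratedFit", table = tb, prior_df = d0, prior_var = s0sq)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q values via `stats::p.adjust(method = "BH")`, with
#' input validation.
#'
#' @param pvalues Numeric p values in `[0, 1]`.
#' @return Adjusted q values, monotone in p, clipped to `[0, 1]`.
#' @examples
#' bhFDR(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhFDR <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "BH")
}

#' Filter moderated-t hits by significance and abundance difference
#'
#' A feature is a hit when its BH-adjusted q value is below `alpha` and the
#' absolute difference of its min-max-scaled group means is at least
#' `min_abs_difference`. Scaling uses the per-cluster min and max of the
#' pooled group means across features, so the difference is a fraction of
#' the cluster's abundance scale.
#'
#' @param fit A [ModeratedFit-class] for one cluster.
#' @param config A [diffFilterConfig()].
#' @return A data.frame of hits with `scaled_diff` appended.
#' @export
diffFilter <- function(fit, config = diffFilterConfig()) {
  tb <- as.data.frame(fitTable(fit))
  pool <- c(tb$mean_a, tb$mean_b)
  lo <- min(pool); hi <- max(pool)
  denom <- if (hi > lo) hi - lo else 1
  scaled_diff <- (tb$mean_a - tb$mean_b) / denom
  tb$scaled_diff <- scaled_diff
  tb[tb$q < config$alpha &
       abs(scaled_diff) >= config$min_abs_difference, , drop = FALSE]
}

#' Per-state cell-frequency comparison between sample groups
#'
#' Two-sided two-sample Student's t-test (equal variances) per cell state on
#' per-sample composition fractions; states with P <= 0.05 are flagged.
#'
#' @param freq samples x states matrix of per-sample frequencies (each row
#'   sums to 1; zero-count states carry frequency 0, not NA).
#' @param groups Two-level group label per sample (>= 2 samples per group).
#' @param alpha Flagging level (default 0.05, inclusive).
#' @return A data.frame (`state`, `t`, `p`, `flagged`).
#' @export
frequencyTTest <- function(freq, groups, alpha = 0.05) {
  m <- as_dense(freq)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("need exactly 2 groups", call. = FALSE)
  if (any(table(groups) < 2))
    stop("each group needs >= 2 samples", call. = FALSE)
  if (any(abs(rowSums(m) - 1) > 1e-6))
    warning("per-sample frequencies do not sum to 1", call. = FALSE)
  g1 <- groups == levels(groups)[1]
  res <- lapply(seq_len(ncol(m)), function(j) {
    x <- m[g1, j]; y <- m[!g1, j]
    if (var(x) == 0 && var(y) == 0) {
      tt <- list(statistic = c(t = 0), p.value = 1)
      if (mean(x) != mean(y)) tt <- list(
        statistic = c(t = sign(mean(x) - mean(y)) * Inf), p.value = 0)
    } else {
      tt <- t.test(x, y, var.equal = TRUE)
    }
    data.frame(state = colnames(m)[j] %||% sprintf("state%d", j),
               t = unname(tt$statistic), p = tt$p.value,
               flagged = tt$p.value <= alpha)
  })
  do.call(rbind, res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
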