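test_that("d0 = 0 reproduces the ordinary pooled t-test exactly", {
  set.seed(20)
  a <- matrix(rnorm(1000 * 6), 1000)
  b <- matrix(rnorm(1000 * 8, 0.2), 1000)
  fit <- moderatedTTest(a, b, prior_df = 0)
  tb <- as.data.frame(fitTable(fit))
  # textbook pooled two-sample t per feature
  na <- 6; nb <- 8
  sp2 <- (rowSums((a - rowMeans(a))^2) + rowSums((b - rowMeans(b))^2)) /
    (na + nb - 2)
  t_ref <- (rowMeans(a) - rowMeans(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  expect_lt(max(abs(tb$t - t_ref)), 1e-10)
})

test_that("d0 = Inf pins every posterior variance at the prior", {
  set.seed(21)
  a <- matrix(rnorm(200 * 5), 200); b <- matrix(rnorm(200 * 5), 200)
  fit <- moderatedTTest(a, b, prior_df = Inf, prior_var = 0.8)
  expect_true(all(fitTable(fit)$s2_post == 0.8))
})

test_that("posterior variances lie between the sample and prior variances", {
  set.seed(22)
  a <- matrix(rnorm(300 * 10), 300); b <- matrix(rnorm(300 * 10), 300)
  fit <- moderatedTTest(a, b)
  tb <- as.data.frame(fitTable(fit))
  s0 <- priorVar(fit)
  expect_true(all(
    tb$s2_post >= pmin(tb$s2, s0) - 1e-12 &
      tb$s2_post <= pmax(tb$s2, s0) + 1e-12))
})

test_that("prior parameters are recovered from simulated truth", {
  set.seed(23)
  d0_true <- 8; s0_true <- 0.5
  n_feat <- 2000; n <- 50
  sig2 <- d0_true * s0_true / rchisq(n_feat, d0_true)
  a <- matrix(rnorm(n_feat * n, 0, sqrt(sig2)), n_feat)
  b <- matrix(rnorm(n_feat * n, 0, sqrt(sig2)), n_feat)
  fit <- moderatedTTest(a, b)
  expect_lt(abs(priorDf(fit) - d0_true) / d0_true, 0.25)
  expect_lt(abs(priorVar(fit) - s0_true) / s0_true, 0.10)
})

test_that("moderated fit agrees with the limma empirical-Bayes cross-check", {
  skip_if_not_installed("limma")
  set.seed(24)
  n_feat <- 500; n <- 8
  sig2 <- 4 * 0.3 / rchisq(n_feat, 4)
  a <- matrix(rnorm(n_feat * n, 0, sqrt(sig2)), n_feat)
  b <- matrix(rnorm(n_feat * n, 0.3, sqrt(sig2)), n_feat)
  fit <- moderatedTTest(a, b)
  design <- cbind(1, rep(c(0, 1), each = n))
  lf <- limma::eBayes(limma::lmFit(cbind(a, b), design))
  expect_equal(priorDf(fit), lf$df.prior, tolerance = 0.05)
  expect_equal(priorVar(fit), lf$s2.prior, tolerance = 0.02)
  expect_equal(unname(as.data.frame(fitTable(fit))$t), -unname(lf$t[, 2]),
               tolerance = 1e-8)
})

test_that("zero-variance equal-mean features give t = 0, p = 1", {
  a <- rbind(matrix(rnorm(40), 4), c(2, 2, 2, 2, 2, 2, 2, 2, 2, 2))
  b <- rbind(matrix(rnorm(40), 4), c(2, 2, 2, 2, 2, 2, 2, 2, 2, 2))
  fit <- moderatedTTest(a[, 1:5], b[, 1:5], prior_df = 0)
  tb <- as.data.frame(fitTable(fit))
  expect_identical(tb$t[5], 0)
  expect_identical(tb$p[5], 1)
})

test_that("BH adjustment matches the hand-evaluated step-up and is order invariant", {
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFDR(0.3), 0.3)
  expect_equal(bhFDR(rep(1, 5)), rep(1, 5))
  set.seed(25)
  p <- runif(50)
  q <- bhFDR(p)
  perm <- sample(50)
  expect_equal(bhFDR(p[perm]), q[perm])
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bhFDR(c(0.5, 1.2)), "0, 1")
})

test_that("diff filter recovers planted shifts and shrinks monotonically", {
  set.seed(26)
  n_feat <- 100; n <- 30
  shift <- c(rep(3, 5), rep(0, 95))
  a <- matrix(rnorm(n_feat * n, shift, 0.5), n_feat)
  b <- matrix(rnorm(n_feat * n, 0, 0.5), n_feat)
  rownames(a) <- rownames(b) <- sprintf("F%03d", 1:n_feat)
  fit <- moderatedTTest(a, b)
  hits <- diffFilter(fit)
  expect_true(all(sprintf("F%03d", 1:5) %in% hits$feature))
  # raising the abundance threshold shrinks the hit set monotonically
  n_hits <- vapply(c(0.05, 0.1, 0.3, 0.6), function(th)
    nrow(diffFilter(fit, diffFilterConfig(min_abs_difference = th))),
    numeric(1))
  expect_true(all(diff(n_hits) <= 0))
  # null data produce (almost) no hits
  fit0 <- moderatedTTest(matrix(rnorm(n_feat * n), n_feat),
                         matrix(rnorm(n_feat * n), n_feat))
  expect_lte(nrow(diffFilter(fit0)), 2)
})

test_that("frequency t-test flags planted compositional shifts", {
  set.seed(27)
  # identical groups: no flags
  f <- matrix(rep(c(0.3, 0.3, 0.4), each = 8), nrow = 8)
  f <- f + rnorm(24, 0, 0.005); f <- f / rowSums(f)
  colnames(f) <- c("s1", "s2", "s3")
  res <- frequencyTTest(f, rep(c("g1", "g2"), 4))
  expect_true(all(!res$flagged | res$p > 0.04))
  # one state strongly shifted between groups
  g <- rep(c("g1", "g2"), each = 6)
  f2 <- cbind(s1 = c(rep(0.55, 6), rep(0.25, 6)),
              s2 = 0.2, s3 = NA)
  f2[, 3] <- 1 - f2[, 1] - f2[, 2]
  f2 <- f2 + matrix(rnorm(36, 0, 0.01), 12); f2 <- f2 / rowSums(f2)
  res2 <- frequencyTTest(f2, g)
  expect_true(res2$flagged[res2$state == "s1"])
  # matches the textbook statistic
  x <- f2[g == "g1", 1]; y <- f2[g == "g2", 1]
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
               (length(x) + length(y) - 2))
  t_ref <- (mean(x) - mean(y)) / (sp * sqrt(1 / 6 + 1 / 6))
  expect_equal(res2$t[res2$state == "s1"], t_ref, tolerance = 1e-12)
  expect_error(frequencyTTest(f2[1:3, ], c("g1", "g2", "g2")), ">= 2")
})
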