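# Reference values computed with an independent implementation of the
# midrank k-sample Anderson-Darling statistic (standardized form).
test_that("standardized AD statistic matches independent reference values", {
  a <- c(1, 2, 3, 4, 5, 6)
  b <- c(1.5, 2.5, 3.5, 4.5, 5.5, 6.5)
  expect_equal(adKSample(list(a, b))$T, -1.1101552661170608,
               tolerance = 1e-9)
  expect_equal(adKSample(list(a, c(10, 11, 12, 13, 14, 15)))$T,
               5.758347340196102, tolerance = 1e-9)
  # midrank tie handling
  expect_equal(adKSample(list(c(1, 1, 2, 2, 3), c(1, 2, 2, 3, 3)))$T,
               -0.7883543716281316, tolerance = 1e-9)
  # k = 3 with unequal sizes
  expect_equal(adKSample(list(a, b, c(0.5, 1.2, 2.2, 3.1, 0.9)))$T,
               1.1858471996368591, tolerance = 1e-9)
  # literally identical samples sit at the minimum attainable value, far
  # below any dissimilarity threshold
  expect_equal(adKSample(list(a, a))$T, -1.5222970092197332,
               tolerance = 1e-9)
  expect_lt(adKSample(list(a, a))$T, 0)
})

test_that("AD statistic input contracts hold", {
  expect_error(adKSample(list(1:10)), "at least 2")
  expect_error(adKSample(list(1:3, 1:10)), "at least 5")
  expect_error(adKSample(list(rep(1, 6), rep(1, 6))), "constant")
})

test_that("AD statistic is invariant under common monotone transforms", {
  set.seed(6)
  s <- list(rnorm(40), rnorm(40, 0.5), rexp(40))
  t1 <- adKSample(s)$T
  t2 <- adKSample(lapply(s, function(x) exp(x)))$T
  t3 <- adKSample(lapply(s, function(x) 5 * x - 2))$T
  expect_equal(t1, t2, tolerance = 1e-12)
  expect_equal(t1, t3, tolerance = 1e-12)
})

test_that("exhaustive permutation distribution centers at k - 1 and brackets the observed statistic", {
  vals <- c(0.3, 0.9, 1.4, 2.2, 2.9, 3.7, 4.1, 4.8, 5.5, 6.2, 7.0, 7.9)
  combs <- combn(12, 6)
  a2 <- apply(combs, 2, function(ix)
    adKSample(list(vals[ix], vals[-ix]))$A2)
  expect_equal(mean(a2), 1, tolerance = 1e-8)  # null mean = k - 1
  # a clearly separated split lies in the extreme upper tail
  obs <- adKSample(list(vals[1:6], vals[7:12]))$A2
  p_perm <- mean(a2 >= obs - 1e-12)
  expect_lt(p_perm, 0.01)
  expect_equal(max(a2), obs, tolerance = 1e-9)  # perfect separation is maximal
})

test_that("AD statistic grows with n under a fixed location alternative", {
  set.seed(7)
  t_by_n <- vapply(c(50, 200, 800), function(n)
    adKSample(list(rnorm(n), rnorm(n, 1)))$T, numeric(1))
  expect_true(all(diff(t_by_n) > 0))
})

test_that("donor consistency separates planted inconsistent markers", {
  spec <- data.frame(marker = 1:4, type = "location", magnitude = 1.2)
  tab <- simulateBatchIntensities(3, 16, n_per_batch = 1200,
                                  shift_spec = spec, seed = 8)
  rep <- donorConsistency(tab, consistencyConfig(n_subsample_donor = 800,
                                                 seed = 1))
  mk <- as.data.frame(markerConsistency(rep))
  truth <- attr(tab, "truth")
  bad <- mk$ad_t[match(truth$marker[!truth$consistent], mk$marker)]
  good <- mk$ad_t[match(truth$marker[truth$consistent], mk$marker)]
  # AUROC of separating classes by t
  auroc <- mean(outer(bad, good, ">"))
  expect_gte(auroc, 0.95)
  # determinism under the same seed
  rep2 <- donorConsistency(tab, consistencyConfig(n_subsample_donor = 800,
                                                  seed = 1))
  expect_equal(mk$ad_t, as.data.frame(markerConsistency(rep2))$ad_t)
})

test_that("identical batches give minimal dissimilarity and floored log10", {
  x <- rnorm(200)
  tab <- data.frame(marker = "M", batch = rep(c("a", "b"), each = 200),
                    value = c(x, x))
  rep <- donorConsistency(tab, consistencyConfig(n_subsample_donor = 200))
  mk <- as.data.frame(markerConsistency(rep))
  expect_lt(mk$ad_t, 0)
  expect_true(mk$floored)
  expect_equal(mk$log10_t, -2)
})

test_that("EMD matches the analytic translation case and metric properties", {
  set.seed(9)
  x <- runif(4000, 1, 3)
  delta <- 0.5
  # fixed grid so delta is bin-aligned: width = 5/200 = 0.025
  w1 <- emd1d(x, x + delta, n_bins = 200, range = c(0, 5))
  expect_equal(w1, delta, tolerance = 5 / 200 + 0.01)
  expect_identical(emd1d(x, x), 0)
  # symmetry and triangle inequality on random triples
  for (i in 1:5) {
    a <- rnorm(300); b <- rnorm(300, 1); c <- rexp(300)
    rg <- range(c(a, b, c))
    dab <- emd1d(a, b, range = rg); dba <- emd1d(b, a, range = rg)
    dac <- emd1d(a, c, range = rg); dcb <- emd1d(c, b, range = rg)
    expect_equal(dab, dba, tolerance = 1e-12)
    expect_lte(dab, dac + dcb + 1e-9)
  }
})

test_that("EMD agrees with a sorted-quantile coupling oracle", {
  set.seed(10)
  for (i in 1:5) {
    a <- rnorm(2000); b <- rnorm(2000, runif(1, -1, 1), runif(1, 0.5, 2))
    rg <- range(c(a, b))
    w_binned <- emd1d(a, b, n_bins = 400, range = rg)
    w_exact <- mean(abs(sort(a) - sort(b)))  # W1 via quantile coupling
    expect_equal(w_binned, w_exact, tolerance = diff(rg) / 400 * 3 + 0.02)
  }
})

test_that("rank alignment reduces batch EMD and is monotone within batch", {
  set.seed(11)
  b1 <- rnorm(1500); b2 <- 1.4 * rnorm(1500) + 0.8
  aligned <- rankAlign(list(b1, b2))
  before <- emd1d(b1, b2)
  after <- emd1d(aligned[[1]], aligned[[2]])
  expect_lt(after, before)
  ord <- order(b2)
  expect_true(all(diff(aligned[[2]][ord]) >= 0))
  # near-identity on already-identical batches
  x <- rnorm(800)
  al <- rankAlign(list(x, x))
  expect_lt(max(abs(al[[1]] - x)), 0.05)
  expect_warning(rankAlign(list(x)), "single batch")
})

test_that("alignment reduces per-marker EMD for most shifted markers", {
  spec <- data.frame(marker = 1:10, type = "location",
                     magnitude = runif(10, 0.5, 2))
  tab <- simulateBatchIntensities(2, 10, n_per_batch = 800,
                                  shift_spec = spec, seed = 12)
  improved <- vapply(unique(tab$marker), function(m) {
    sub <- tab[tab$marker == m, ]
    parts <- split(sub$value, sub$batch)
    al <- rankAlign(parts)
    emd1d(al[[1]], al[[2]]) < emd1d(parts[[1]], parts[[2]])
  }, logical(1))
  expect_gte(mean(improved), 0.95)
})
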