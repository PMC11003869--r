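test_that("dose behaviour classification follows the stated rules", {
  concs <- c(0.25, 0.5, 1, 2, 4)
  expect_identical(
    classifyDoseBehavior(c(0.2, 0.8, 1.5, 2.2, 2.6), concs),
    "dose_dependent")
  expect_identical(
    classifyDoseBehavior(c(2.0, 2.1, 1.9, 2.0, 2.1), concs),
    "saturating")
  expect_identical(
    classifyDoseBehavior(c(0.05, 0.04, 0.06, 0.05, 0.05), concs),
    "weak")
  expect_error(classifyDoseBehavior(c(1, 2), c(1, 2)), ">= 3")
})

test_that("dynamic range is near zero without signal and collapses under label permutation", {
  te <- filtered_titration(small_titration(n_per = 250, seed = 41))
  clr <- assay(te, "clr")
  iso <- isotypeFeatures(te)
  tr <- truth_df(te)
  sel <- te$concentration == 1
  # an isotype-like (nonspecific) ADT has DR ~ 0
  ns <- tr$adt[tr$cls == "nonspecific"][1]
  d0 <- dynamicRange(clr, te$cluster, iso, ns, cells = sel)
  expect_lt(d0$dr, 0.35)
  # a strong specific ADT has a large DR that collapses when labels permute
  sp <- tr$adt[tr$cls == "specific_saturating"][1]
  d1 <- dynamicRange(clr, te$cluster, iso, sp, cells = sel)
  expect_gt(d1$dr, 1)
  # permutation removes the cluster-specific enrichment; what survives is
  # only the population-average offset of the marker over the isotypes
  set.seed(1)
  dperm <- dynamicRange(clr, sample(te$cluster), iso, sp, cells = sel)
  expect_lt(dperm$dr, d1$dr * 0.75)
  expect_error(dynamicRange(clr, te$cluster, character(), sp), "isotype")
})

test_that("CLR dynamic range matches a Monte-Carlo oracle of the binding model", {
  # kd = 1, background 0 for the ADT: linear-scale signal ratio between
  # c = 4 and c = 0.25 is (4/5)/(0.25/1.25) = 4; the CLR-scale profile is
  # checked against an independent simulation of the same model
  truth <- S4Vectors::DataFrame(
    adt = c("A", "ISO1", "ISO2"),
    cls = c("specific_dose_dependent", "isotype", "isotype"),
    is_isotype = c(FALSE, TRUE, TRUE), kd = c(1, 1, 1),
    specific_rate = c(120, 0, 0), background_rate = c(0, 0.5, 0.5),
    target_clusters = c("1", "", ""))
  te <- simulateTitration(titrationConfig(
    n_cells_per_concentration = 1500, n_adts = 1, n_isotypes = 2,
    n_clusters = 2, doublet_rate = 0, seed = 17), truth = truth)
  te <- clrTransform(te)
  occ <- function(c) c / (c + 1)
  expect_equal(occ(4) / occ(0.25), 4, tolerance = 1e-12)
  prof <- as.data.frame(doseProfiles(doseResponseProfile(te)))
  a <- prof[prof$adt == "A", ]
  a <- a[order(a$concentration), ]
  expect_gt(a$dynamic_range[5] / a$dynamic_range[1], 1)
  # independent oracle: simulate the stated model directly and recompute the
  # isotype-referenced dynamic range from first principles
  set.seed(99)
  oracle_dr <- vapply(c(0.25, 0.5, 1, 2, 4), function(cc) {
    n <- 20000
    depth <- exp(rnorm(n, 0, 0.4))
    in_target <- rep(c(TRUE, FALSE), length.out = n)
    muA <- depth * 120 * in_target * cc / (cc + 1)
    xA <- rnbinom(n, mu = muA, size = 1 / 0.4)
    xI1 <- rnbinom(n, mu = depth * 0.5 * cc, size = 1 / 0.4)
    xI2 <- rnbinom(n, mu = depth * 0.5 * cc, size = 1 / 0.4)
    lg <- log(cbind(xA, xI1, xI2) + 1)
    clr <- lg - rowMeans(lg)
    iso_ref <- mean(clr[, 2:3])
    max(mean(clr[in_target, 1]), mean(clr[!in_target, 1])) - iso_ref
  }, numeric(1))
  expect_equal(a$dynamic_range, oracle_dr, tolerance = 0.06)
})

test_that("specificity score separates isotype-like from specific ADTs", {
  te <- filtered_titration(small_titration(n_per = 250, seed = 42))
  clr <- assay(te, "clr")
  iso <- isotypeFeatures(te)
  tr <- truth_df(te)
  sel <- te$concentration == min(concentrationGrid(te))
  iso_pool <- as.numeric(clr[iso, sel])
  ns <- tr$adt[tr$cls == "nonspecific"]
  sp <- tr$adt[tr$cls %in% c("specific_dose_dependent",
                             "specific_saturating")]
  s_ns <- vapply(ns, function(a)
    specificityScore(clr[a, sel], iso_pool), numeric(1))
  s_sp <- vapply(sp, function(a)
    specificityScore(clr[a, sel], iso_pool), numeric(1))
  expect_true(all(s_sp > 2))
  expect_gt(mean(s_ns < 2), 0.5)
  # identical copies of one sample attain a deeply negative statistic
  x <- clr[ns[1], sel]
  expect_lt(specificityScore(x, x), 0)
  expect_error(specificityScore(numeric(), 1:10), "ADT")
  expect_error(specificityScore(1:10, numeric()), "isotype")
})

make_profile <- function(dr, conc = c(0.25, 0.5, 1, 2, 4), spec_t = 10,
                         bg = 0, load = 0.01, pos = 0.8, adt = "X") {
  data.frame(adt = adt, concentration = conc, dynamic_range = dr,
             background = bg, specificity_t = spec_t,
             positive_fraction = pos, best_cluster = "1",
             load_fraction = load)
}

test_that("dose-dependent selection retains 75% of the dynamic range", {
  p <- make_profile(c(0.2, 0.8, 1.5, 2.2, 2.6))
  d <- selectConcentration(p, "dose_dependent", FALSE)
  expect_identical(d$action, "keep")
  expect_identical(d$concentration, 2)  # smallest c with DR >= 0.75 * 2.6
  expect_match(d$rationale, "DOSE_RETENTION")
  # read-load flag at the chosen concentration demotes one step
  p2 <- make_profile(c(0.2, 0.8, 1.5, 2.2, 2.6),
                     load = c(0.01, 0.01, 0.01, 0.2, 0.01))
  d2 <- selectConcentration(p2, "dose_dependent", FALSE)
  expect_identical(d2$concentration, 1)
  expect_match(d2$rationale, "LOAD_DEMOTE")
  # nonspecific concentrations are rejected from the candidate set
  p3 <- make_profile(c(0.2, 0.8, 1.5, 2.2, 2.6),
                     spec_t = c(10, 10, 10, 1, 10))
  d3 <- selectConcentration(p3, "dose_dependent", FALSE)
  expect_identical(d3$concentration, 4)
  expect_match(d3$rationale, "NONSPECIFIC_AT_C")
})

test_that("saturating profiles keep 1x unless background is elevated", {
  d <- selectConcentration(make_profile(rep(2, 5)), "saturating", FALSE)
  expect_identical(d$concentration, 1)
  expect_match(d$rationale, "SAT_DEFAULT_1X")
  # elevated background at 1x steps down to 0.5x (the CD29-style outcome)
  p <- make_profile(rep(2, 5), bg = c(0, 0, 0.6, 0.8, 1))
  d2 <- selectConcentration(p, "saturating", FALSE)
  expect_identical(d2$concentration, 0.5)
  expect_match(d2$rationale, "SAT_BACKGROUND_STEPDOWN")
})

test_that("weak, blacklist, nonspecific-bottom and conflict rules fire in order", {
  p <- make_profile(rep(0.1, 5))
  cfgw <- decisionConfig(whitelist = "X")
  d <- selectConcentration(p, "weak", FALSE, cfgw)
  expect_identical(d$action, "spike_in_recommend")
  expect_match(d$rationale, "WEAK_WHITELIST_SPIKEIN")
  d2 <- selectConcentration(p, "weak", FALSE)
  expect_identical(d2$action, "exclude_uninformative")
  # blacklist dominates everything
  d3 <- selectConcentration(make_profile(c(1, 2, 3, 4, 5)),
                            "dose_dependent", FALSE,
                            decisionConfig(blacklist = "X",
                                           whitelist = character()))
  expect_identical(d3$action, "exclude_nonspecific")
  expect_match(d3$rationale, "BLACKLIST")
  # nonspecific at lowest concentration + persistent bottom -> exclude
  p4 <- make_profile(c(1, 2, 3, 4, 5), spec_t = 1)
  d4 <- selectConcentration(p4, "dose_dependent", TRUE)
  expect_identical(d4$action, "exclude_nonspecific")
  expect_match(d4$rationale, "NONSPECIFIC_BOTTOM")
  # whitelisted ADT nonspecific everywhere -> CONFLICT, never silent
  p5 <- make_profile(c(1, 2, 3, 4, 5), spec_t = 0)
  d5 <- selectConcentration(p5, "dose_dependent", TRUE, cfgw)
  expect_identical(d5$action, "exclude_nonspecific")
  expect_match(d5$rationale, "CONFLICT")
})

test_that("raising retention_fraction never selects a lower concentration", {
  p <- make_profile(c(0.2, 0.8, 1.5, 2.2, 2.6))
  chosen <- vapply(c(0.5, 0.6, 0.75, 0.9, 0.99), function(rf)
    selectConcentration(p, "dose_dependent", FALSE,
                        decisionConfig(retention_fraction = rf,
                                       whitelist = character()))$concentration,
    numeric(1))
  expect_true(all(diff(chosen) >= 0))
})

test_that("panel assembly recovers planted classes and replays its audit", {
  te <- filtered_titration(small_titration(n_per = 300, seed = 43))
  tr <- truth_df(te)
  weak_ids <- tr$adt[tr$cls == "weak"]
  cfg <- decisionConfig(whitelist = weak_ids)
  prof <- doseResponseProfile(te, cfg)
  rr <- rankADTs(te, config = rankingConfig(seed = 1))
  pan <- buildPanel(prof, rr, cfg)
  dec <- as.data.frame(panelDecisions(pan))
  cls <- setNames(tr$cls, tr$adt)
  spec <- dec$adt[cls[dec$adt] %in% c("specific_dose_dependent",
                                      "specific_saturating")]
  expect_true(all(dec$action[dec$adt %in% spec] == "keep"))
  ns <- dec$adt[cls[dec$adt] == "nonspecific"]
  expect_true(all(grepl("exclude", dec$action[dec$adt %in% ns])))
  wk <- dec$adt[cls[dec$adt] == "weak"]
  expect_true(all(dec$action[dec$adt %in% wk] == "spike_in_recommend"))
  expect_true(all(nchar(dec$rationale) > 0))
  expect_true(isTRUE(replayDecisions(pan)))
  # determinism: same inputs give identical decisions
  pan2 <- buildPanel(doseResponseProfile(te, cfg),
                     rankADTs(te, config = rankingConfig(seed = 1)), cfg)
  expect_identical(dec, as.data.frame(panelDecisions(pan2)))
})

test_that("all-isotype-like input yields an empty keep list", {
  cfg <- titrationConfig(n_cells_per_concentration = 200, n_adts = 6,
                         seed = 44)
  truth <- makeAdtTruth(0, 0, 6, 0, n_isotypes = 5,
                        seed = 1)
  te <- clrTransform(simulateTitration(cfg, truth = truth))
  prof <- doseResponseProfile(te)
  pan <- buildPanel(prof, NULL)
  expect_length(keptADTs(pan), 0)
})
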