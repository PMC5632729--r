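# Junction profiling, the A/B/C typology, origin regression and
# group comparisons.

test_that("the planted ycf1 overhang is measured exactly and survives
          rotation and reverse complement", {
  cfg <- fast_cfg(601)
  sim <- generateAncestor(cfg)
  prof <- profileJunctions(sim$plastome, truePartition(sim$truth))
  expect_equal(ycf1ToJsa(prof), 991)
  expect_identical(typeLabel(prof), "A")
  expect_true(all(ndhStatus(prof) == "intact"))
  # rotate + flip, re-detect, re-canonicalize: identical profile
  rot <- plastomics:::.rotate_plastome(sim$plastome,
                                       truePartition(sim$truth), 2024L)
  flip <- plastomics:::.flip_plastome(rot$plastome, rot$partition)
  can <- canonicalizePlastome(flip$plastome,
                              detectInvertedRepeat(flip$plastome))
  prof2 <- profileJunctions(can$plastome, can$partition)
  expect_identical(ycf1ToJsa(prof2), ycf1ToJsa(prof))
  expect_identical(ndhStatus(prof2), ndhStatus(prof))
})

test_that("ndh inventory reflects pseudogenes and absences and drives
          the typology", {
  cfg <- fast_cfg(602)
  sim <- generateAncestor(cfg)
  simC <- applyScenario(sim, scenarioConfig(
    "C", pseudogenize = c(ndhF = 0.5), remove = c("ndhD", "ndhE")), cfg)
  prof <- profileJunctions(simC$plastome, truePartition(simC$truth))
  st <- ndhStatus(prof)
  expect_identical(unname(st["ndhF"]), "pseudogene")
  expect_identical(unname(st["ndhD"]), "absent")
  expect_identical(typeLabel(prof), "C")
  simB <- applyScenario(sim, scenarioConfig("B"), cfg)
  profB <- profileJunctions(simB$plastome, truePartition(simB$truth))
  expect_identical(typeLabel(profB), "B")
  expect_identical(retainedNdhLength(profB), 0)
})

test_that("the typology rules follow their definitions, including the
          selectable B-vs-C boundary", {
  all_int <- setNames(rep("intact", 11), plastomics:::NDH_GENES)
  expect_identical(classifyJunctionType(all_int), "A")
  all_abs <- setNames(rep("absent", 11), plastomics:::NDH_GENES)
  expect_identical(classifyJunctionType(all_abs), "B")
  one_psi <- all_abs; one_psi["ndhF"] <- "pseudogene"
  expect_identical(classifyJunctionType(one_psi), "C")
  expect_identical(classifyJunctionType(one_psi, rule = "intact"), "B")
  partial <- all_int; partial["ndhA"] <- "absent"
  expect_identical(classifyJunctionType(partial), "C")
})

test_that("missing ycf1 yields a flagged profile, not an error", {
  ft <- featureTable("ndhF", "protein_coding", "-", FALSE,
                     list(c(13100, 13400)))
  g <- AnnotatedPlastome("noy", paste0(
    random_dna(10000, 603), random_dna(1500, 604),
    random_dna(2000, 605),
    plastomics:::.revcomp_chr(random_dna(1500, 604))), ft)
  part <- RegionPartition(c(1L, 10000L), c(10001L, 11500L),
                          c(11501L, 13500L), c(13501L, 15000L), 15000L)
  expect_message(prof <- profileJunctions(g, part), "ycf1")
  expect_true(is.na(ycf1ToJsa(prof)))
})

test_that("origin regression recovers a noiseless slope to machine
          precision and degrades on permuted responses", {
  for (b in c(0.136, 2.5, -0.4)) {
    x <- seq(100, 1000, length.out = 8)
    f <- fitOriginRegression(x, b * x)
    expect_equal(f@slope, b, tolerance = 1e-12)
    expect_equal(f@rSquared, 1, tolerance = 1e-12)
    expect_lt(f@pValue, 0.05)
  }
  # duplicated single point: slope = y/x
  f2 <- fitOriginRegression(rep(200, 5), rep(30, 5))
  expect_equal(f2@slope, 30 / 200)
  # permuted y (fixed seed): R^2 collapses
  set.seed(10)
  x <- 1:10; y <- sample(0.136 * x)
  f3 <- fitOriginRegression(x, y)
  expect_lt(f3@rSquared, 0.9)
  expect_error(fitOriginRegression(1:2, 1:2), "3 points")
  expect_error(fitOriginRegression(rep(0, 5), 1:5), "all x are zero")
})

test_that("pairwise Mann-Whitney comparisons behave at the designed
          extremes", {
  # identical groups: p ~ 1
  r1 <- compareIRLengths(c(1:5, 1:5), rep(c("A", "B"), each = 5))
  expect_gt(r1$p, 0.9)
  # disjoint ranges, n = 5 each: the exact minimal two-sided p
  r2 <- compareIRLengths(c(1:5, 11:15), rep(c("A", "B"), each = 5))
  expect_equal(r2$p, 2 / choose(10, 5))
  # three separated groups: all pairs significant
  vals <- c(991, 1005, 989, 1010, 996,
            1700, 1820, 1760, 1690, 1800,
            1310, 1290, 1350, 1330, 1400)
  grp <- rep(c("A", "B", "C"), each = 5)
  r3 <- compareIRLengths(vals, grp)
  expect_identical(nrow(r3), 3L)
  expect_true(all(r3$p < 0.05))
  # undersized group skipped with warning
  expect_warning(r4 <- compareIRLengths(c(1, 2, 3, 4), c("A", "A", "A", "B")),
                 "fewer than 2")
})

test_that("junction-shift regression on a noiseless type-C cohort
          recovers the planted slope with R^2 = 1", {
  coh <- simulateCohort(6, seed = 610, scenario = "C", slope = 0.136)
  profs <- lapply(coh, function(x)
    profileJunctions(x$plastome, truePartition(x$truth)))
  expect_true(all(vapply(profs, typeLabel, "") == "C"))
  rr <- junctionShiftRegression(profs, referenceYcf1ToJsa = 991)
  expect_equal(rr$fit@slope, 0.136, tolerance = 0.002)
  expect_gt(rr$fit@rSquared, 0.9999)
  # truth ledger agrees with the measured retained lengths
  expect_equal(rr$points$retainedNdh,
               vapply(coh, function(x) retainedNdhLength(x$truth), 1))
})
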