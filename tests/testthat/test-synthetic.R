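# The simulator itself: determinism, architecture, mutation laws,
# scenario machinery.

test_that("the same configuration produces byte-identical output", {
  cfg <- simConfig(seed = 701)
  a <- generateAncestor(cfg)
  b <- generateAncestor(cfg)
  expect_identical(as.character(genomeSeq(a$plastome)),
                   as.character(genomeSeq(b$plastome)))
  expect_identical(plantedSSRs(a$truth), plantedSSRs(b$truth))
  pa <- evolvePair(a, cfg); pb <- evolvePair(b, cfg)
  expect_identical(as.character(genomeSeq(pa$genome1)),
                   as.character(genomeSeq(pb$genome1)))
  expect_identical(mutationLedger(pa$truth), mutationLedger(pb$truth))
})

test_that("the emitted genome is a valid circular quadripartite molecule
          whose detected partition equals the planted one", {
  cfg <- simConfig(seed = 702)
  sim <- generateAncestor(cfg)
  part <- detectInvertedRepeat(sim$plastome)
  tp <- truePartition(sim$truth)
  expect_identical(as.integer(c(start(irbRegion(part)), end(irbRegion(part)))),
                   as.integer(c(start(irbRegion(tp)), end(irbRegion(tp)))))
  expect_identical(irLength(part), irLength(tp))
  expect_identical(lscLength(part), cfg$lsc)
  expect_identical(sscLength(part), cfg$ssc)
  expect_identical(irLength(part), cfg$ir)
  # IRa is the exact reverse complement of IRb
  s <- as.character(genomeSeq(sim$plastome))
  irb <- substr(s, start(irbRegion(tp)), end(irbRegion(tp)))
  ira <- substr(s, start(iraRegion(tp)), end(iraRegion(tp)))
  expect_identical(ira, plastomics:::.revcomp_chr(irb))
  # the GenBank writer/reader round-trips it (the simulated path
  # exercises the real reader)
  tf <- tempfile(fileext = ".gb")
  writeGenBank(sim$plastome, tf)
  expect_identical(as.character(genomeSeq(readPlastome(tf))), s)
})

test_that("a zero-rate configuration leaves descendants identical to the
          ancestor", {
  cfg <- simConfig(seed = 703, pSubCoding = 0, pSubNonCoding = 0,
                   indelCoding = 0, indelNonCoding = 0)
  sim <- generateAncestor(cfg)
  pair <- evolvePair(sim, cfg)
  expect_identical(as.character(genomeSeq(pair$genome1)),
                   as.character(genomeSeq(sim$plastome)))
  expect_identical(as.character(genomeSeq(pair$genome2)),
                   as.character(genomeSeq(sim$plastome)))
  expect_identical(nrow(mutationLedger(pair$truth)), 0L)
})

test_that("substitution counts per locus follow the configured binomial
          law over replicates", {
  cfg <- simConfig(seed = 704, pSubNonCoding = 0.02, indelNonCoding = 0,
                   plantSSRs = NULL, plantRepeats = NULL,
                   hotspots = c(x = 1)[0])
  sim <- generateAncestor(cfg)
  rows <- plantedLoci(sim$truth)
  target <- rows$locus[rows$kind == "spacer" & rows$region == "LSC"]
  nsub <- 0; nsite <- 0
  for (i in 1:10) {
    cfg2 <- cfg; cfg2$seed <- cfg$seed + i
    pr <- evolvePair(sim, cfg2)
    led <- mutationLedger(pr$truth)
    led <- led[led$locus %in% target & led$type == "sub", ]
    nsub <- nsub + nrow(led)
  }
  nsite <- 10 * 2 * sum(nchar(rows$seq[rows$locus %in% target]))
  p <- 0.02 / 2
  expect_lt(abs(nsub - nsite * p), 3 * sqrt(nsite * p * (1 - p)))
})

test_that("indels respect coding frames and never overlap planted
          elements", {
  cfg <- simConfig(seed = 705, indelCoding = 1.5, indelNonCoding = 3)
  sim <- generateAncestor(cfg)
  pair <- evolvePair(sim, cfg)
  led <- mutationLedger(pair$truth)
  ind <- led[led$type %in% c("ins", "del"), ]
  expect_gt(nrow(ind), 10)
  rows <- plantedLoci(sim$truth)
  coding_rows <- rows$id[rows$kind %in% c("exon", "ycf1_body", "psi_ycf1") &
                           rows$category %in% "protein_coding"]
  expect_true(all(ind$length[ind$row %in% coding_rows] %% 3 == 0))
  # descendants still carry every planted SSR (indels avoided them)
  for (g in list(pair$genome1, pair$genome2)) {
    found <- findSSRs(g)
    planted <- plantedSSRs(pair$truth)
    expect_true(all(paste(planted$motif, planted$unitCount) %in%
                      paste(found$motif, found$unitCount)))
  }
})

test_that("overfull regions are a configuration error", {
  expect_error(generateAncestor(simConfig(seed = 706, lsc = 5000)),
               "overflow")
})

test_that("scenarios produce the architectures they claim and reject
          absent genes", {
  cfg <- fast_cfg(707)
  sim <- generateAncestor(cfg)
  simB <- applyScenario(sim, scenarioConfig("B", irShift = 400L), cfg)
  expect_false(any(plastomics:::NDH_GENES %in%
                     features(simB$plastome)$name))
  profB <- profileJunctions(simB$plastome, truePartition(simB$truth))
  expect_equal(ycf1ToJsa(profB), 991 + 400)
  simA <- applyScenario(sim, scenarioConfig("A"), cfg)
  expect_identical(as.character(genomeSeq(simA$plastome)),
                   as.character(genomeSeq(sim$plastome)))
  expect_error(applyScenario(sim, scenarioConfig(
    "C", pseudogenize = c(ndhZ = 0.5), remove = character()), cfg),
    "absent gene")
})

test_that("the predicted-SV oracle matches measured divergence within
          Monte-Carlo tolerance on one configuration", {
  cfg <- simConfig(seed = 708, plantSSRs = NULL, plantRepeats = NULL,
                   hotspots = c(x = 1)[0])
  sim <- generateAncestor(cfg)
  pred <- predictedLocusSV(sim$truth)
  obs <- NULL
  for (i in 1:3) {
    cfg2 <- cfg; cfg2$seed <- cfg$seed + i
    pr <- evolvePair(sim, cfg2)
    loci <- extractSyntenicLoci(pr$genome1, pr$genome2,
                                truePartition(pr$truth),
                                truePartition(pr$truth))
    loci <- loci[loci$class %in% c("spacer", "intron"), , drop = FALSE]
    for (j in seq_len(nrow(loci))) {
      l <- trimTerminalGaps(alignLocus(as.list(loci[j, ])))
      ev <- countEvents(l)
      obs <- rbind(obs, data.frame(name = l$name,
                                   sv = svPercent(ev[1], ev[2], ev[3])))
    }
  }
  m <- merge(obs, pred, by.x = "name", by.y = "locus")
  se <- sd(m$sv - m$predictedSV) / sqrt(nrow(m))
  expect_lt(abs(mean(m$sv) - mean(m$predictedSV)), 3 * se)
})
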