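# NG86 codon counting: codonization rules, site counts, pathway
# averaging, correction, symmetry, additivity, parameter recovery.

test_that("codonization skips gapped and N codons and strips terminal
          stops", {
  l <- list(name = "g", aln1 = "ATGAAACCC---GGGTAA",
            aln2 = "ATGAATCCCTTTGGGTAA")
  cp <- codonize(l)
  expect_identical(length(cp$codons1), 4L)      # gap codon + stop removed
  expect_false(cp$pseudo)
  # internal stop in one sequence: skipped with a warning
  l2 <- list(name = "h", aln1 = "ATGTAAAAACCCTAA", aln2 = "ATGCAAAAACCCTAA")
  expect_warning(cp2 <- codonize(l2), "internal-stop")
  expect_identical(length(cp2$codons1), 3L)
  # internal stops in both: pseudogene flag
  l3 <- list(name = "i", aln1 = "ATGTAAAAATAA", aln2 = "ATGTGAAAATAA")
  expect_warning(cp3 <- codonize(l3), "pseudo")
  expect_true(cp3$pseudo)
})

test_that("identical sequences give zero differences and rates; a
          synonymous pair counts one synonymous difference", {
  r <- ng86Pair(list(codons1 = c("ATG", "AAA"), codons2 = c("ATG", "AAA")))
  expect_identical(r$nd + r$sd, 0)
  expect_identical(r$dn, 0); expect_identical(r$ds, 0)
  r2 <- ng86Pair(list(codons1 = "TTT", codons2 = "TTC"))  # both Phe
  expect_identical(r2$nd, 0)
  expect_identical(r2$sd, 1)
  expect_identical(r2$dn, 0)
  # one synonymous change on a single codon saturates the correction;
  # diluted with identical codons the rate is positive and finite
  expect_true(r2$saturated)
  r3 <- ng86Pair(list(codons1 = c("TTT", rep("AAA", 10)),
                      codons2 = c("TTC", rep("AAA", 10))))
  expect_identical(r3$dn, 0)
  expect_gt(r3$ds, 0)
  expect_identical(r3$omega, 0)
  expect_error(ng86Pair(list(codons1 = character(),
                             codons2 = character())), "at least one")
})

test_that("site counts satisfy nSites + sSites = 3 x codons and match
          first-principles per-codon fractions", {
  set.seed(5)
  cods <- sample(plastomics:::.SENSE_CODONS, 50, replace = TRUE)
  r <- ng86Pair(list(codons1 = cods, codons2 = cods))
  expect_equal(r$nSites + r$sSites, 3 * length(cods))
  expect_equal(r$sSites, sum(vapply(cods, oracle_syn_sites, 1)))
})

test_that("pathway averaging equals brute-force enumeration for every 2-
          and 3-difference sense codon pair", {
  sense <- plastomics:::.SENSE_CODONS
  set.seed(8)
  # exhaustive over a deterministic subsample plus all 3-difference pairs
  # of a core set keeps the runtime modest; mismatches anywhere would fail
  pick <- sample(length(sense), 20)
  for (c1 in sense[pick]) {
    for (c2 in sense) {
      d <- sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
      if (d < 2) next
      imp <- ng86Pair(list(codons1 = c1, codons2 = c2))
      orc <- oracle_ng86_pathways(c1, c2)
      expect_equal(imp$nd, unname(orc["nonsyn"]), tolerance = 1e-12)
      expect_equal(imp$sd, unname(orc["syn"]), tolerance = 1e-12)
    }
  }
})

test_that("the estimator is symmetric in the two sequences", {
  cp <- simulateCodonPair(300, omega = 0.4, mu = 0.06, seed = 12)
  a <- ng86Pair(cp)
  b <- ng86Pair(list(codons1 = cp$codons2, codons2 = cp$codons1))
  expect_equal(a$nd, b$nd); expect_equal(a$sd, b$sd)
  expect_equal(a$nSites, b$nSites); expect_equal(a$omega, b$omega)
})

test_that("counts are additive under concatenation", {
  cp1 <- simulateCodonPair(120, omega = 0.3, mu = 0.05, seed = 21)
  cp2 <- simulateCodonPair(150, omega = 0.8, mu = 0.05, seed = 22)
  r1 <- ng86Pair(cp1); r2 <- ng86Pair(cp2)
  rc <- ng86Pair(list(codons1 = c(cp1$codons1, cp2$codons1),
                      codons2 = c(cp1$codons2, cp2$codons2)))
  expect_equal(rc$nd, r1$nd + r2$nd)
  expect_equal(rc$sd, r1$sd + r2$sd)
  expect_equal(rc$nSites, r1$nSites + r2$nSites)
  expect_equal(rc$sSites, r1$sSites + r2$sSites)
})

test_that("the Jukes-Cantor correction flags saturation instead of
          returning nonsense", {
  # force ps towards saturation with a synthetic extreme pair
  r <- ng86Pair(list(codons1 = rep("TTT", 5), codons2 = rep("TTC", 5)))
  expect_true(is.na(r$omega) || r$omega >= 0)  # ds defined here
  # omega undefined when ds = 0
  r2 <- ng86Pair(list(codons1 = "AAA", codons2 = "GAA"))  # nonsyn only
  expect_identical(r2$sd, 0)
  expect_true(is.na(r2$omega))
})

test_that("simulations at omega in {0.1, 0.5, 1.0} recover the ordering
          and approximate magnitude", {
  est <- vapply(c(0.1, 0.5, 1.0), function(om) {
    ng86Pair(simulateCodonPair(2000, omega = om, mu = 0.04,
                               seed = 33))$omega
  }, 1)
  expect_true(all(diff(est) > 0))
  expect_lt(abs(est[1] - 0.1), 0.05)
  expect_lt(abs(est[2] - 0.5), 0.15)
  expect_lt(abs(est[3] - 1.0), 0.25)
})

test_that("per-gene and concatenated rates agree with count additivity
          on an evolved plastome pair", {
  cfg <- simConfig(seed = 530)
  sim <- generateAncestor(cfg)
  pair <- evolvePair(sim, cfg)
  dd <- dndsPairwise(pair$genome1, pair$genome2,
                     truePartition(pair$truth), truePartition(pair$truth))
  expect_gt(nrow(dd$perGene), 20)
  expect_equal(dd$concatenated$nd, sum(dd$perGene$nd))
  expect_equal(dd$concatenated$sd, sum(dd$perGene$sd))
  expect_equal(dd$concatenated$nCodons, sum(dd$perGene$nCodons))
  # the simulator's substitutions are neutral: omega near 1
  expect_gt(dd$concatenated$omega, 0.6)
  expect_lt(dd$concatenated$omega, 1.6)
  # restricting the gene list restricts the table
  dd2 <- dndsPairwise(pair$genome1, pair$genome2,
                      truePartition(pair$truth),
                      truePartition(pair$truth),
                      genes = c("rbcL", "matK"))
  expect_identical(sort(dd2$perGene$gene), c("matK", "rbcL"))
})
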