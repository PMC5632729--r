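# Syntenic locus extraction, alignment, event counting, SV%, hotspot
# ranking and summary statistics.

test_that("two identical plastomes pair every locus with itself", {
  sim <- generateAncestor(fast_cfg(501))
  part <- truePartition(sim$truth)
  loci <- extractSyntenicLoci(sim$plastome, sim$plastome, part, part)
  expect_gt(nrow(loci), 40)
  expect_identical(loci$seq1, loci$seq2)
  expect_true(all(c("coding", "spacer", "intron") %in% loci$class))
  # short non-coding loci are dropped
  expect_true(all(nchar(loci$seq1[loci$class != "coding"]) >= 150 |
                    nchar(loci$seq2[loci$class != "coding"]) >= 150))
  # intron loci exist for the intron-bearing genes
  expect_true("ndhA intron" %in% loci$name)
  expect_true("clpP intron 1" %in% loci$name)
})

test_that("a gene missing from one genome drops the gene and its named
          spacers from the pairing", {
  sim <- generateAncestor(fast_cfg(502))
  part <- truePartition(sim$truth)
  cfgC <- fast_cfg(502)
  simC <- applyScenario(sim, scenarioConfig(
    "C", pseudogenize = c(ndhF = 0.5), remove = "ndhD"), cfgC)
  loci <- extractSyntenicLoci(sim$plastome, simC$plastome, part,
                              truePartition(simC$truth))
  expect_false("ndhD" %in% loci$name)
  expect_false(any(grepl("ndhD", loci$name)))
  expect_false("ndhF" %in% loci$name)   # pseudogenized: not intact in both
})

test_that("alignment of identical sequences is the gapless identity and
          small cases reach the optimal affine-gap score", {
  l <- alignLocus(list(name = "x", class = "spacer",
                       seq1 = "ACGTACGTACGT", seq2 = "ACGTACGTACGT"))
  expect_identical(l$aln1, l$aln2)
  expect_false(grepl("-", l$aln1))
  # one-base deletion: single 1-base gap, optimal score per DP oracle
  l2 <- alignLocus(list(name = "y", class = "spacer",
                        seq1 = "ACGTACGT", seq2 = "ACGACGT"))
  expect_identical(nchar(l2$aln1), 8L)
  gaps <- gregexpr("-", l2$aln2)[[1]]
  expect_identical(length(gaps), 1L)
  sc <- oracle_affine_score("ACGTACGT", "ACGACGT")
  aligned_score <- {
    a <- strsplit(l2$aln1, "")[[1]]; b <- strsplit(l2$aln2, "")[[1]]
    s <- 0; ing <- FALSE
    for (i in seq_along(a)) {
      if (a[i] == "-" || b[i] == "-") {
        s <- s - (if (ing) 1 else 5); ing <- TRUE
      } else { s <- s + (if (a[i] == b[i]) 1 else -1); ing <- FALSE }
    }
    s
  }
  expect_equal(aligned_score, sc)
})

test_that("codon-aware alignment opens frame-preserving gaps at codon
          boundaries", {
  cds1 <- "ATGAAACCCGGGACGTGGTTTTAA"
  cds2 <- "ATGAAAGGGACGTGGTTTTAA"     # codon CCC deleted
  l <- alignLocus(list(name = "g", class = "coding",
                       seq1 = cds1, seq2 = cds2))
  expect_true(l$frameOk)
  expect_identical(nchar(l$aln1), 24L)
  g <- gregexpr("-+", l$aln2)[[1]]
  expect_identical(attr(g, "match.length"), 3L)       # one 3-base gap
  expect_identical((as.integer(g) - 1L) %% 3L, 0L)    # codon boundary
  # out-of-frame coding locus falls back with a warning
  expect_warning(
    l3 <- alignLocus(list(name = "h", class = "coding",
                          seq1 = "ATGAAACCCTAA", seq2 = "ATGAACCCTAA")),
    "frame")
  expect_false(isTRUE(l3$frameOk))
})

test_that("terminal-gap trimming removes only flanking gap columns and
          is idempotent", {
  l <- list(name = "t", aln1 = "---ACGT", aln2 = "GGGACGT")
  t1 <- trimTerminalGaps(l)
  expect_identical(t1$aln1, "ACGT")
  expect_identical(t1$aln2, "ACGT")
  t2 <- trimTerminalGaps(t1)
  expect_identical(t2$aln1, t1$aln1)
  l3 <- list(name = "u", aln1 = "--AC-GTT", aln2 = "GGACCGT-")
  t3 <- trimTerminalGaps(l3)
  expect_identical(t3$aln1, "AC-GT")   # internal gap untouched
  expect_warning(trimTerminalGaps(list(name = "v", aln1 = "---",
                                       aln2 = "AAA")), "empty")
})

test_that("event counting matches hand counts and the column-walker
          oracle, and is symmetric", {
  expect_identical(countEvents("ACGT", "ACGT"),
                   c(conserved = 4L, substitutions = 0L, indelEvents = 0L))
  expect_identical(countEvents("AC--GTA", "ACTTGCA"),
                   c(conserved = 4L, substitutions = 1L, indelEvents = 1L))
  # a 3-base gap is one event; N columns are ignored entirely
  expect_identical(countEvents("AAA---CCN", "AAATTTCCA"),
                   c(conserved = 5L, substitutions = 0L, indelEvents = 1L))
  expect_error(countEvents("A-C", "A-C"), "double-gap")
  set.seed(91)
  for (r in 1:20) {
    n <- sample(20:60, 1)
    a <- sample(c("A", "C", "G", "T", "-"), n, TRUE,
                prob = c(.22, .22, .22, .22, .12))
    b <- ifelse(a == "-", sample(c("A", "C"), n, TRUE),
                sample(c("A", "C", "G", "T", "-", "N"), n, TRUE,
                       prob = c(.2, .2, .2, .2, .1, .1)))
    a2 <- paste(a, collapse = ""); b2 <- paste(b, collapse = "")
    expect_identical(countEvents(a2, b2), oracle_count_events(a2, b2))
    expect_identical(countEvents(a2, b2)[1:2], countEvents(b2, a2)[1:2])
  }
})

test_that("SV% applies the exact formula and rejects an empty
          denominator", {
  expect_equal(svPercent(95, 3, 2), 5)
  expect_equal(svPercent(100, 0, 0), 0)
  expect_equal(svPercent(0, 1, 1), 100)
  expect_error(svPercent(0, 0, 0), "undefined")
})

test_that("hotspot ranking is descending with stable alphabetical tie
          breaks and restricted to non-coding loci", {
  recs <- data.frame(
    name = c("b-spacer", "a-spacer", "z intron", "gene1"),
    class = c("spacer", "spacer", "intron", "coding"),
    svPercent = c(5, 9, 5, 99))
  top <- rankHotspots(recs, k = 2)
  expect_identical(top$name, c("a-spacer", "b-spacer"))
  expect_warning(rankHotspots(recs, k = 10), "non-coding")
  top_all <- suppressWarnings(rankHotspots(recs, k = 10))
  expect_identical(top_all$name, c("a-spacer", "b-spacer", "z intron"))
})

test_that("planted mutational hotspots dominate the top-10 ranking on an
          evolved pair", {
  cfg <- simConfig(seed = 510)
  sim <- generateAncestor(cfg)
  pair <- evolvePair(sim, cfg)
  recs <- computeDivergence(pair$genome1, pair$genome2)
  top <- rankHotspots(recs, 10)
  planted <- names(plastomics:::.default_hotspots())
  expect_gte(length(intersect(top$name, planted)), 8)
  # non-coding SV clearly exceeds coding SV under the study regime
  expect_gt(mean(recs$svPercent[recs$class != "coding"]),
            mean(recs$svPercent[recs$class == "coding"]))
})

test_that("divergence statistics recover designed correlation and group
          structure", {
  # perfectly anti-monotone pair -> Spearman r = -1
  recs <- data.frame(
    name = letters[1:20], class = rep(c("spacer", "coding"), 10),
    region = rep(c("LSC", "IR"), 10),
    svPercent = 1:20, gcPercent = 40 - (1:20),
    substitutions = 1:20, indelEvents = (1:20) %/% 2)
  st <- divergenceStatistics(recs)
  expect_equal(st$correlations$rho[st$correlations$pair == "SV~GC"], -1)
  # independent columns (fixed seed): no significant correlation
  set.seed(17)
  recs2 <- data.frame(
    name = paste0("l", 1:200), class = "spacer", region = "LSC",
    svPercent = runif(200), gcPercent = runif(200),
    substitutions = rpois(200, 5), indelEvents = rpois(200, 2))
  st2 <- divergenceStatistics(recs2)
  expect_gt(st2$correlations$p[st2$correlations$pair == "SV~GC"], 0.05)
  expect_lt(abs(st2$correlations$rho[st2$correlations$pair == "SV~GC"]),
            0.15)
  # identical groups: Mann-Whitney p ~ 1
  recs3 <- recs2
  recs3$class <- rep(c("spacer", "coding"), 100)
  recs3$svPercent <- rep(recs2$svPercent[1:100], each = 2)
  st3 <- divergenceStatistics(recs3)
  expect_gt(st3$groupTests$p[1], 0.8)
  # constant variable -> correlation reported as undefined
  recs4 <- recs2; recs4$gcPercent <- 33
  st4 <- divergenceStatistics(recs4)
  expect_true(is.na(st4$correlations$rho[
    st4$correlations$pair == "SV~GC"]))
})
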