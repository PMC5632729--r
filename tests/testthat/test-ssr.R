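# SSR census: thresholds, maximality, primitivity, context, oracle
# equivalence and planted recovery.

test_that("unit-count thresholds behave inclusively at the boundary", {
  flank1 <- "GCGTC"; flank2 <- "CGTCG"
  hit <- findSSRs(paste0(flank1, strrep("A", 8), flank2))
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$motif, "A")
  expect_identical(hit$unitCount, 8L)
  expect_identical(hit$start, 6L)
  expect_identical(nrow(findSSRs(paste0(flank1, strrep("A", 7), flank2))),
                   0L)
  hit2 <- findSSRs(paste0(flank1, strrep("AT", 5), "GG", flank2))
  expect_identical(hit2$motif, "AT")
  expect_identical(hit2$unitCount, 5L)
  # the strict reading shifts every boundary by one unit
  expect_identical(nrow(findSSRs(paste0(flank1, strrep("A", 8), flank2),
                                 thresholds = ssrThresholds(strict = TRUE))),
                   0L)
  expect_error(findSSRs("ACGT", thresholds = c(0L, 5L, 3L, 3L, 3L, 3L)),
               "thresholds")
})

test_that("motifs are primitive and runs are counted under the primitive
          unit only", {
  # a pure A-run must never be reported as motif "AA" or "AAA"
  loci <- findSSRs(paste0("GCGTC", strrep("A", 12), "CGTCG"))
  expect_identical(loci$motif, "A")
  # an AT-run must not also surface under unit size 4 as "ATAT"
  loci2 <- findSSRs(paste0("GCGGC", strrep("AT", 6), "GCGGC"))
  expect_identical(loci2$motif, "AT")
  expect_identical(nrow(loci2), 1L)
  expect_true(plastomics:::.is_primitive_motif("ACT"))
  expect_false(plastomics:::.is_primitive_motif("ATAT"))
})

test_that("runs containing N are broken at the N", {
  s <- paste0("GCGTC", strrep("A", 6), "N", strrep("A", 6), "CGTCG")
  expect_identical(nrow(findSSRs(s)), 0L)
})

test_that("raising any threshold never increases the census
          (monotonicity)", {
  s <- random_dna(4000, 31, at = 0.7)
  base <- nrow(findSSRs(s))
  for (u in 1:6) {
    thr <- ssrThresholds()
    thr[u] <- thr[u] + 1L
    expect_lte(nrow(findSSRs(s, thresholds = thr)), base)
  }
})

test_that("the census equals a brute-force enumeration of maximal
          tandem runs on random sequence", {
  for (sd in c(51, 52, 53)) {
    s <- random_dna(5000, sd, at = 0.7)
    prod <- findSSRs(s)
    orc <- oracle_ssrs(s)
    cols <- c("motif", "unitLength", "unitCount", "start", "end")
    expect_equal(prod[cols], orc[cols], ignore_attr = TRUE)
  }
})

test_that("an origin-spanning run on a circular genome is counted once", {
  # run of 10 As crossing the origin: 4 at the end, 6 at the start
  core <- random_dna(300, 61, at = 0.5)
  s <- paste0(strrep("A", 6), substr(core, 7, 294), strrep("A", 4))
  p <- AnnotatedPlastome("circ", s)
  loci <- findSSRs(p)
  a_runs <- loci[loci$motif == "A", ]
  expect_identical(nrow(a_runs), 1L)
  expect_identical(a_runs$unitCount, 10L)
  expect_true(a_runs$end > nchar(s))     # stored unwrapped across origin
})

test_that("planted SSRs are recovered exactly on simulator output, with
          nothing unplanned", {
  sim <- generateAncestor(simConfig(seed = 71))
  found <- findSSRs(sim$plastome)
  planted <- plantedSSRs(sim$truth)
  cols <- c("motif", "unitCount", "start", "end")
  expect_equal(found[order(found$start), cols],
               planted[order(planted$start), cols], ignore_attr = TRUE)
  s <- ssrSummary(found)
  expect_identical(s$total, nrow(planted))
})

test_that("genomic context separates coding, non-coding and spanning
          loci", {
  ft <- featureTable("g1", "protein_coding", "+", FALSE, list(c(31, 90)))
  s <- paste0(random_dna(30, 81, 0.5),
              "ATG", strrep("AT", 6), random_dna(33, 82, 0.5),
              random_dna(60, 83, 0.5))
  p <- AnnotatedPlastome("ctx", s, ft)
  loci <- data.frame(motif = c("AT", "AT", "AT"),
                     unitLength = 2L, unitCount = 6L,
                     start = c(34L, 101L, 25L),
                     end = c(45L, 112L, 36L))
  out <- classifySSRContext(loci, p)
  expect_identical(out$context, c("coding", "non_coding", "spanning"))
})

test_that("the summary counts classes and motifs without merging
          reverse complements", {
  loci <- data.frame(motif = c("A", "T"), unitLength = c(1L, 1L),
                     unitCount = c(9L, 10L), start = c(1L, 50L),
                     end = c(9L, 59L))
  s <- ssrSummary(loci)
  expect_identical(unname(s$byClass["mono"]), 2L)
  expect_identical(s$byMotif$count[s$byMotif$motif == "A"], 1L)
  expect_identical(s$byMotif$count[s$byMotif$motif == "T"], 1L)
  empty <- ssrSummary(loci[0, ])
  expect_identical(empty$total, 0L)
  expect_true(all(empty$byClass == 0L))
})

test_that("IR-duplicated SSRs can be collapsed to one copy", {
  sim <- generateAncestor(simConfig(seed = 72))
  part <- truePartition(sim$truth)
  all_loci <- findSSRs(sim$plastome)
  collapsed <- findSSRs(sim$plastome, partition = part,
                        collapseIRDuplicates = TRUE)
  inside_ira <- all_loci$start >= start(iraRegion(part)) &
    all_loci$end <= end(iraRegion(part))
  expect_identical(nrow(collapsed), nrow(all_loci) - sum(inside_ira))
})
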