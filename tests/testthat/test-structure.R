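# Quadripartite structure detection, canonicalization, AT content.

# a minimal genome assembled by hand: LSC 10 kb + IRb 3 kb + SSC 2 kb +
# revcomp(IRb), with boundary bases forced to stop IR extension
make_toy_quadripartite <- function(seed = 1) {
  lsc <- random_dna(10000, seed)
  irb <- random_dna(3000, seed + 1)
  ssc <- random_dna(2000, seed + 2)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  fix <- function(s, i, not) {
    v <- strsplit(s, "")[[1]]
    v[i] <- setdiff(c("A", "C", "G", "T"), not)[1]
    paste(v, collapse = "")
  }
  # stop extension at every IR boundary (see vignette on boundary pinning)
  for (o in 1:2) {
    lsc <- fix(lsc, o, comp[[substr(lsc, 10000 - o + 1, 10000 - o + 1)]])
    ssc <- fix(ssc, o, comp[[substr(ssc, 2000 - o + 1, 2000 - o + 1)]])
  }
  ira <- paste(rev(unname(comp[strsplit(irb, "")[[1]]])), collapse = "")
  paste0(lsc, irb, ssc, ira)
}

test_that("a planted IR pair is recovered exactly, with the shorter
          inter-IR segment labelled SSC", {
  g <- make_toy_quadripartite(11)
  p <- AnnotatedPlastome("toy", g)
  part <- detectInvertedRepeat(p)
  expect_identical(c(start(lscRegion(part)), end(lscRegion(part))),
                   c(1L, 10000L))
  expect_identical(c(start(irbRegion(part)), end(irbRegion(part))),
                   c(10001L, 13000L))
  expect_identical(c(start(sscRegion(part)), end(sscRegion(part))),
                   c(13001L, 15000L))
  expect_identical(irLength(part), 3000L)
  # sum rule
  expect_identical(lscLength(part) + sscLength(part) + 2L * irLength(part),
                   genomeLength(p))
  # junctions coincide with the SSC endpoints
  expect_identical(jsb(part), start(sscRegion(part)))
  expect_identical(jsa(part), end(sscRegion(part)))
})

test_that("region lengths are invariant under rotation and reverse
          complement", {
  g <- make_toy_quadripartite(12)
  p <- AnnotatedPlastome("toy", g)
  ref <- detectInvertedRepeat(p)
  rot <- plastomics:::.rotate_chr(g, 4322L)   # rotate by 4321 bases
  pr <- AnnotatedPlastome("rot", rot)
  part_r <- detectInvertedRepeat(pr)
  expect_identical(irLength(part_r), irLength(ref))
  expect_identical(lscLength(part_r), lscLength(ref))
  expect_identical(sscLength(part_r), sscLength(ref))
  rc <- plastomics:::.revcomp_chr(rot)
  part_rc <- detectInvertedRepeat(AnnotatedPlastome("rc", rc))
  expect_identical(irLength(part_rc), irLength(ref))
  expect_identical(sscLength(part_rc), sscLength(ref))
})

test_that("an IR-lacking genome is reported as such, not a crash", {
  expect_error(detectInvertedRepeat(
    AnnotatedPlastome("plain", random_dna(8000, 3))), "no IR detected")
  expect_error(detectInvertedRepeat(
    AnnotatedPlastome("short", "ACGT")), "too short")
})

test_that("canonicalization is idempotent and undoes rotation and
          flipping, remapping features consistently", {
  sim <- generateAncestor(fast_cfg(421))
  p <- sim$plastome
  part <- truePartition(sim$truth)
  can0 <- canonicalizePlastome(p, part)
  expect_identical(as.character(genomeSeq(can0$plastome)),
                   as.character(genomeSeq(p)))
  rot <- plastomics:::.rotate_plastome(p, part, 4321L)
  flip <- plastomics:::.flip_plastome(rot$plastome, rot$partition)
  can <- canonicalizePlastome(flip$plastome,
                              detectInvertedRepeat(flip$plastome))
  expect_identical(as.character(genomeSeq(can$plastome)),
                   as.character(genomeSeq(p)))
  f1 <- features(p); f2 <- features(can$plastome)
  ord2 <- order(f2$name, vapply(f2$segments, function(s) min(start(s)), 1L))
  ord1 <- order(f1$name, vapply(f1$segments, function(s) min(start(s)), 1L))
  expect_identical(f1$name[ord1], f2$name[ord2])
  for (k in seq_along(ord1))
    expect_identical(as.integer(start(f1$segments[[ord1[k]]])),
                     as.integer(start(f2$segments[[ord2[k]]])))
})

test_that("a feature spanning the rotation origin is remapped to a
          contiguous interval", {
  sim <- generateAncestor(fast_cfg(422))
  part <- truePartition(sim$truth)
  # rotate so the origin falls inside psbA (the first LSC gene)
  fp <- features(sim$plastome)
  i <- which(fp$name == "psbA")[1]
  mid <- floor((start(fp$segments[[i]])[1] + end(fp$segments[[i]])[1]) / 2)
  rot <- plastomics:::.rotate_plastome(sim$plastome, part, mid)
  segs <- features(rot$plastome)$segments[[i]]
  expect_identical(width(segs), width(fp$segments[[i]]))  # still contiguous
  expect_true(end(segs)[1] > genomeLength(sim$plastome))  # unwrapped
  back <- canonicalizePlastome(rot$plastome,
                               detectInvertedRepeat(rot$plastome))
  expect_identical(as.character(genomeSeq(back$plastome)),
                   as.character(genomeSeq(sim$plastome)))
})

test_that("AT content follows its definition and rejects degenerate
          input", {
  expect_equal(atContent("ATAT"), 100)
  expect_equal(atContent("GCGC"), 0)
  expect_equal(atContent("ATGC"), 50)
  expect_equal(atContent("ATGCNN"), 50)       # N excluded on both sides
  expect_error(atContent("NNNN"), "undefined")
  expect_error(atContent(""), "empty")
  # AT + GC partition: complements sum to 100 for N-free sequence
  s <- random_dna(500, 77)
  expect_equal(atContent(s) + (100 - atContent(s)), 100)
  expect_equal(atContent(s), atContent(plastomics:::.revcomp_chr(s)))
})

test_that("the region summary reports the comparative-table column set", {
  sim <- generateAncestor(fast_cfg(423))
  tab <- regionSummary(sim$plastome, truePartition(sim$truth))
  expect_identical(tab$total_bp, genomeLength(sim$plastome))
  expect_identical(tab$lsc_bp + tab$ssc_bp + 2L * tab$ir_bp, tab$total_bp)
  expect_true(all(c("at_total", "at_lsc", "at_ssc", "at_ir") %in%
                    colnames(tab)))
  expect_true(tab$at_total > 50 && tab$at_total < 75)
})
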