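## Quadripartite structure: inverted-repeat detection, canonical
## linearization, AT content, and the per-region summary table.

#' Detect the inverted-repeat pair of a plastome
#'
#' Finds the maximal pair of inverted, near-identical segments of a
#' (circular) plastome by exact-seed hashing and banded extension, and
#' partitions the genome into LSC / IRb / SSC / IRa: the shorter of the two
#' inter-IR segments is labelled SSC, the longer LSC. Candidate windows must
#' reach `minIrLen` and an identity of at least `1 - maxMismatchRate`;
#' window ends are then refined base-by-base so that each boundary sits on
#' an exact-matching terminal run (a mismatch within the terminal 8 bp
#' trims the window), which pins boundaries to the base even when the
#' mismatch budget would allow a sloppy overhang. Ties between equally long
#' candidates are broken by the smaller start coordinate.
#'
#' @param p an [AnnotatedPlastome-class].
#' @param minIrLen minimum IR length in bp (default 1000).
#' @param maxMismatchRate maximum tolerated mismatch fraction between the
#'   two IR copies (default 0.001, i.e. identity >= 99.9\%).
#' @return a [RegionPartition-class] in the input coordinate system
#'   (intervals may be stored unwrapped across the origin).
#' @examples
#' sim <- generateAncestor(simConfig(seed = 7))
#' part <- detectInvertedRepeat(sim$plastome)
#' irLength(part)
#' @export
detectInvertedRepeat <- function(p, minIrLen = 1000,
                                 maxMismatchRate = 0.001) {
  L <- genomeLength(p)
  if (L < 2L * minIrLen)
    stop("sequence too short for an IR of ", minIrLen, " bp")
  s <- as.character(genomeSeq(p))
  s2 <- if (isCircular(p)) paste0(s, s) else s
  max_mm <- as.integer(floor(maxMismatchRate * L / 2)) + 4L
  hits <- cpp_maximal_pairs(s2, 2L, as.integer(minIrLen), max_mm,
                            as.integer(min(31L, minIrLen)))
  if (!nrow(hits)) stop("no IR detected (no inverted pair >= ", minIrLen,
                        " bp at the required identity)")

  best <- NULL
  seen <- character()
  ord <- order(-(hits$end1 - hits$start1), hits$start1)
  for (idx in ord) {
    h <- hits[idx, ]
    tr <- .refine_ir_ends(s2, h$start1, h$end1, h$start2, h$end2)
    len <- tr$e1 - tr$s1 + 1L
    if (len < minIrLen) next
    if (tr$mm > maxMismatchRate * len) next
    a1 <- .mod1(tr$s1, L); a2 <- .mod1(tr$s2, L)
    key <- paste(min(a1, a2), max(a1, a2), len)
    if (key %in% seen) next
    seen <- c(seen, key)
    ## mod-L disjointness of the two copies
    cov1 <- .mod1(seq(a1, a1 + len - 1L), L)
    cov2 <- .mod1(seq(a2, a2 + len - 1L), L)
    if (length(intersect(cov1, cov2))) next
    gA <- .modw(a2 - (a1 + len - 1L) - 1L, L)
    gB <- .modw(a1 - (a2 + len - 1L) - 1L, L)
    if (gA + gB + 2L * len != L) next
    if (gA == 0L || gB == 0L) next
    cand <- list(a1 = a1, a2 = a2, len = len, gA = gA, gB = gB)
    if (is.null(best) || cand$len > best$len ||
        (cand$len == best$len && min(a1, a2) < min(best$a1, best$a2)))
      best <- cand
  }
  if (is.null(best))
    stop("no IR detected (no inverted pair >= ", minIrLen,
         " bp at the required identity)")

  with(best, {
    if (gA <= gB) {   # SSC follows copy1: copy1 is IRb
      irb <- c(a1, a1 + len - 1L)
      ssc <- c(a1 + len, a1 + len + gA - 1L)
      ira <- c(a2, a2 + len - 1L)
      lsc <- c(a2 + len, a2 + len + gB - 1L)
    } else {
      irb <- c(a2, a2 + len - 1L)
      ssc <- c(a2 + len, a2 + len + gB - 1L)
      ira <- c(a1, a1 + len - 1L)
      lsc <- c(a1 + len, a1 + len + gA - 1L)
    }
    norm <- function(iv) { st <- .mod1(iv[1], L); IRanges(st, st + (iv[2] - iv[1])) }
    RegionPartition(norm(lsc), norm(irb), norm(ssc), norm(ira), L)
  })
}

## modular width in [0, L)
.modw <- function(x, L) ((x %% L) + L) %% L

## trim window ends so each terminal 8 bp of the copy1/copy2 comparison is
## an exact match; returns refined copy1/copy2 coordinates and mismatches
.refine_ir_ends <- function(s2, s1, e1, s2., e2., w = 8L) {
  c1 <- .chars(substr(s2, s1, e1))
  c2 <- rev(.comp_chars(.chars(substr(s2, s2., e2.))))
  eq <- c1 == c2 & c1 %in% c("A", "C", "G", "T")
  n <- length(eq)
  i1 <- 1L; i2 <- n
  repeat {
    if (i2 - i1 + 1L < 1L) break
    tl <- eq[i1:min(i1 + w - 1L, i2)]
    tr <- eq[max(i2 - w + 1L, i1):i2]
    if (!all(tl)) { i1 <- i1 + max(which(!tl)); next }
    if (!all(tr)) { i2 <- i2 - (length(tr) - min(which(!tr)) + 1L); next }
    break
  }
  if (i2 < i1) return(list(s1 = s1, e1 = s1 - 1L, s2 = s2., e2 = e2., mm = 0L))
  mm <- sum(!eq[i1:i2])
  list(s1 = s1 + i1 - 1L, e1 = s1 + i2 - 1L,
       s2 = s2. + (n - i2), e2 = e2. - (i1 - 1L), mm = mm)
}

#' Canonicalize a plastome's linearization
#'
#' Rotates (and if necessary reverse-complements) a circular plastome so
#' that the linearization reads LSC, IRb, SSC, IRa with the LSC starting at
#' coordinate 1, remapping all features consistently. The SSC orientation
#' is chosen so that ndhF (when present) lies on the SSC side nearer the
#' IRb/SSC junction; when no ndh gene exists the orientation with the
#' lexicographically smaller SSC string is used, so output is
#' deterministic. Idempotent on already-canonical input.
#'
#' @param p an [AnnotatedPlastome-class].
#' @param part the matching [RegionPartition-class]; computed with
#'   [detectInvertedRepeat()] when missing.
#' @param ... passed on to [detectInvertedRepeat()] when `part` is missing.
#' @return a list with elements `plastome` and `partition`.
#' @export
canonicalizePlastome <- function(p, part = NULL, ...) {
  if (is.null(part)) part <- detectInvertedRepeat(p, ...)
  L <- genomeLength(p)
  res <- .rotate_plastome(p, part, start(part@lsc))
  if (!.ssc_oriented(res$plastome, res$partition)) {
    res <- .flip_plastome(res$plastome, res$partition)
    res <- .rotate_plastome(res$plastome, res$partition,
                            start(res$partition@lsc))
  }
  res
}

## TRUE if the SSC orientation already satisfies the canonical rule
.ssc_oriented <- function(p, part) {
  ft <- features(p)
  L <- genomeLength(p)
  ndh <- which(ft$name == "ndhF" & !ft$pseudo)
  if (!length(ndh)) ndh <- which(grepl("^ndh", ft$name) & !ft$pseudo)
  if (length(ndh)) {
    segs <- ft$segments[[ndh[1]]]
    mid <- .mod1(as.integer(floor((min(start(segs)) + max(end(segs))) / 2)), L)
    dB <- .modw(mid - jsb(part), L)
    dA <- .modw(jsa(part) - mid, L)
    return(dB <= dA)
  }
  sscseq <- .circ_substr(as.character(genomeSeq(p)), start(part@ssc),
                         end(part@ssc))
  sscseq <= .revcomp_chr(sscseq)
}

## rotate a plastome (and its partition) so `newStart` becomes base 1
.rotate_plastome <- function(p, part, newStart) {
  L <- genomeLength(p)
  newStart <- .mod1(newStart, L)
  shift <- newStart - 1L
  s <- .rotate_chr(as.character(genomeSeq(p)), newStart)
  remap <- function(ir) {
    st <- .mod1(start(ir) - shift, L)
    IRanges(st, st + width(ir) - 1L)
  }
  ft <- features(p)
  if (nrow(ft)) ft$segments <- as(lapply(ft$segments, remap), "IRangesList")
  part2 <- RegionPartition(remap(part@lsc), remap(part@irb),
                           remap(part@ssc), remap(part@ira), L)
  list(plastome = AnnotatedPlastome(identifier(p), s, ft, isCircular(p)),
       partition = part2)
}

## reverse-complement a plastome (and its partition), remapping features
.flip_plastome <- function(p, part) {
  L <- genomeLength(p)
  s <- .revcomp_chr(as.character(genomeSeq(p)))
  remap <- function(ir) {
    st <- L - .mod1(end(ir), L) + 1L
    IRanges(st, st + width(ir) - 1L)
  }
  ft <- features(p)
  if (nrow(ft)) {
    ft$segments <- as(lapply(ft$segments, function(sg) rev(remap(sg))),
                      "IRangesList")
    ft$strand <- ifelse(ft$strand == "+", "-", "+")
  }
  part2 <- RegionPartition(remap(part@lsc), remap(part@ira),
                           remap(part@ssc), remap(part@irb), L)
  list(plastome = AnnotatedPlastome(identifier(p), s, ft, isCircular(p)),
       partition = part2)
}

#' AT content of a nucleotide sequence
#'
#' `100 * (#A + #T) / (#A + #C + #G + #T)`; `N` is excluded from both
#' numerator and denominator.
#'
#' @param seq a character scalar, [Biostrings::DNAString], or
#'   [AnnotatedPlastome-class].
#' @return percentage in `[0, 100]`.
#' @examples
#' atContent("ATAT")   # 100
#' atContent("GCGC")   # 0
#' @export
atContent <- function(seq) {
  if (is(seq, "AnnotatedPlastome")) seq <- genomeSeq(seq)
  if (is(seq, "DNAString")) seq <- as.character(seq)
  if (!nzchar(seq)) stop("empty sequence")
  v <- .chars(toupper(seq))
  at <- sum(v %in% c("A", "T"))
  acgt <- sum(v %in% c("A", "C", "G", "T"))
  if (acgt == 0L) stop("AT content undefined: no unambiguous bases")
  100 * at / acgt
}

#' Per-region structure summary of a plastome
#'
#' The classic comparative-table row: total, LSC, SSC and IR lengths plus
#' AT content overall and per region.
#'
#' @param p an [AnnotatedPlastome-class].
#' @param part a [RegionPartition-class]; detected when missing.
#' @param ... passed to [detectInvertedRepeat()] when `part` is missing.
#' @return a one-row data.frame.
#' @export
regionSummary <- function(p, part = NULL, ...) {
  if (is.null(part)) part <- detectInvertedRepeat(p, ...)
  s <- as.character(genomeSeq(p))
  sub <- function(ir) .circ_substr(s, start(ir), end(ir))
  data.frame(
    identifier = identifier(p),
    total_bp = genomeLength(p),
    lsc_bp = lscLength(part),
    ssc_bp = sscLength(part),
    ir_bp = irLength(part),
    at_total = round(atContent(s), 2),
    at_lsc = round(atContent(sub(part@lsc)), 2),
    at_ssc = round(atContent(sub(part@ssc)), 2),
    at_ir = round(atContent(sub(part@irb)), 2),
    stringsAsFactors = FALSE
  )
}
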