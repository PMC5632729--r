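## Pairwise sequence divergence: syntenic locus extraction, alignment,
## event counting, the SV% statistic, hotspot ranking, and the
## accompanying correlation / group-comparison statistics.

#' @importFrom Biostrings pairwiseAlignment alignedPattern alignedSubject
#'   nucleotideSubstitutionMatrix translate AAString GENETIC_CODE
#' @importFrom stats cor.test wilcox.test
NULL

## feature footprint (min start / max end over segments)
.footprints <- function(p) {
  ft <- features(p)
  if (!nrow(ft))
    return(data.frame(name = character(), category = character(),
                      pseudo = logical(), start = integer(),
                      end = integer()))
  data.frame(
    name = ft$name, category = ft$category, pseudo = ft$pseudo,
    strand = ft$strand,
    start = vapply(ft$segments, function(s) min(start(s)), 1L),
    end = vapply(ft$segments, function(s) max(end(s)), 1L),
    idx = seq_len(nrow(ft)), stringsAsFactors = FALSE)
}

## name/sequence table of one genome's loci (coding, spacer, intron)
.locus_table <- function(p, part) {
  s <- as.character(genomeSeq(p))
  fp <- .footprints(p)
  ## one IR copy only: drop features fully inside IRa
  if (!is.null(part)) {
    ira <- part@ira
    fp <- fp[!(fp$start >= start(ira) & fp$end <= end(ira)), , drop = FALSE]
  }
  fp <- fp[order(fp$start, fp$end), , drop = FALSE]
  ft <- features(p)

  out <- list()
  add <- function(name, class, a, b, seq)
    out[[length(out) + 1L]] <<- data.frame(
      name = name, class = class, start = a, end = b, seq = seq,
      stringsAsFactors = FALSE)

  ## coding loci: spliced CDS of intact protein-coding genes
  cod <- fp[fp$category == "protein_coding" & !fp$pseudo, , drop = FALSE]
  for (nm in unique(cod$name)) {
    i <- cod$idx[cod$name == nm][1L]
    add(nm, "coding", cod$start[cod$name == nm][1L],
        cod$end[cod$name == nm][1L], featureSequence(p, i))
  }
  ## spacers between consecutive feature footprints
  if (nrow(fp) > 1L) {
    for (k in seq_len(nrow(fp) - 1L)) {
      a <- fp$end[k] + 1L; b <- fp$start[k + 1L] - 1L
      if (b < a) next
      add(paste0(fp$name[k], "-", fp$name[k + 1L]), "spacer", a, b,
          substr(s, a, b))
    }
  }
  ## introns of multi-segment features
  for (i in seq_len(nrow(ft))) {
    segs <- ft$segments[[i]]
    if (length(segs) < 2L || ft$pseudo[i]) next
    gsegs <- segs[order(start(segs))]
    n_int <- length(gsegs) - 1L
    for (k in seq_len(n_int)) {
      a <- end(gsegs)[k] + 1L; b <- start(gsegs)[k + 1L] - 1L
      if (b < a) next
      ## number introns in transcription order
      tx_k <- if (ft$strand[i] == "-") n_int - k + 1L else k
      nm <- if (n_int > 1L) paste(ft$name[i], "intron", tx_k)
            else paste(ft$name[i], "intron")
      add(nm, "intron", a, b, substr(s, a, b))
    }
  }
  tab <- do.call(rbind, out)
  tab[!duplicated(tab$name), , drop = FALSE]
}

#' Extract syntenic loci from a plastome pair
#'
#' Pairs up protein-coding genes named identically and intact in both
#' genomes, intergenic spacers whose flanking feature names match, and
#' introns of shared multi-exon genes. Loci resident in the IR are taken
#' from one copy only (IRb); non-coding loci shorter than
#' `minNonCodingLen` bp in either genome are dropped.
#'
#' @param p1,p2 canonical annotated [AnnotatedPlastome-class] objects.
#' @param part1,part2 matching [RegionPartition-class]s (detected when
#'   missing).
#' @param minNonCodingLen minimum non-coding locus length (default 150).
#' @return data.frame with columns `name`, `class` (`coding`, `spacer`,
#'   `intron`), `region` (`LSC`, `IR`, `SSC`), `seq1`, `seq2`.
#' @export
extractSyntenicLoci <- function(p1, p2, part1 = NULL, part2 = NULL,
                                minNonCodingLen = 150) {
  if (is.null(part1)) part1 <- detectInvertedRepeat(p1)
  if (is.null(part2)) part2 <- detectInvertedRepeat(p2)
  t1 <- .locus_table(p1, part1)
  t2 <- .locus_table(p2, part2)
  shared <- intersect(t1$name, t2$name)
  if (!length(shared)) {
    warning("no shared loci between ", identifier(p1), " and ",
            identifier(p2))
    return(data.frame(name = character(), class = character(),
                      region = character(), seq1 = character(),
                      seq2 = character(), stringsAsFactors = FALSE))
  }
  i1 <- match(shared, t1$name); i2 <- match(shared, t2$name)
  res <- data.frame(
    name = shared, class = t1$class[i1],
    seq1 = t1$seq[i1], seq2 = t2$seq[i2], stringsAsFactors = FALSE)
  keep <- res$class == "coding" |
    pmin(nchar(res$seq1), nchar(res$seq2)) >= minNonCodingLen
  res <- res[keep & nchar(res$seq1) > 0L & nchar(res$seq2) > 0L, ,
             drop = FALSE]
  ## region of the locus midpoint in genome 1
  mid <- (t1$start[match(res$name, t1$name)] +
            t1$end[match(res$name, t1$name)]) / 2
  reg <- function(m) {
    if (m >= start(part1@irb) && m <= end(part1@irb)) "IR"
    else if (m >= start(part1@ira) && m <= end(part1@ira)) "IR"
    else if (m >= start(part1@ssc) && m <= end(part1@ssc)) "SSC"
    else "LSC"
  }
  res$region <- vapply(mid, reg, "")
  rownames(res) <- NULL
  res[order(res$name), c("name", "class", "region", "seq1", "seq2")]
}

#' Globally align one syntenic locus
#'
#' Non-coding loci get a global affine-gap nucleotide alignment
#' (match +1 / mismatch -1 / gap open 4 / gap extend 1 by default).
#' Coding loci are aligned codon-aware: terminal stop codons are set
#' aside, the translated products are aligned (BLOSUM62), and the codons
#' are threaded back through the protein alignment, so every gap is a
#' multiple of 3 at a codon boundary. A coding locus whose length is not
#' a codon multiple in either genome, or which carries an internal stop
#' in both, is flagged and aligned as non-coding.
#'
#' @param locus a one-row data.frame from [extractSyntenicLoci()] (or any
#'   list with `name`, `class`, `seq1`, `seq2`).
#' @param match,mismatch,gapOpening,gapExtension nucleotide scores.
#' @return the locus with `aln1`, `aln2` (gapped strings) and `frameOk`
#'   (logical: codon-aware alignment succeeded) added.
#' @export
alignLocus <- function(locus, match = 1, mismatch = -1, gapOpening = 4,
                       gapExtension = 1) {
  s1 <- locus$seq1; s2 <- locus$seq2
  stopifnot(nzchar(s1), nzchar(s2))
  frameOk <- FALSE
  if (identical(locus$class, "coding")) {
    ok <- nchar(s1) %% 3L == 0L && nchar(s2) %% 3L == 0L
    if (!ok) {
      warning("locus '", locus$name,
              "' is out of frame; aligning as non-coding")
    } else {
      aa <- .codon_aware_align(s1, s2, locus$name)
      if (!is.null(aa)) {
        locus$aln1 <- aa[1L]; locus$aln2 <- aa[2L]
        locus$frameOk <- TRUE
        return(locus)
      }
    }
  }
  sm <- nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                     baseOnly = FALSE)
  pa <- pairwiseAlignment(s1, s2, type = "global",
                          substitutionMatrix = sm,
                          gapOpening = gapOpening,
                          gapExtension = gapExtension)
  locus$aln1 <- as.character(alignedPattern(pa))
  locus$aln2 <- as.character(alignedSubject(pa))
  locus$frameOk <- frameOk
  locus
}

## codon-aware alignment via translated products; NULL when a premature
## stop in both copies makes the locus a pseudogene candidate
.codon_aware_align <- function(s1, s2, name = "") {
  strip_stop <- function(s) {
    last <- substr(s, nchar(s) - 2L, nchar(s))
    if (last %in% STOP_CODONS) list(seq = substr(s, 1L, nchar(s) - 3L),
                                    stop = last)
    else list(seq = s, stop = NULL)
  }
  a <- strip_stop(s1); b <- strip_stop(s2)
  aa1 <- suppressWarnings(as.character(
    translate(DNAString(a$seq), if.fuzzy.codon = "solve")))
  aa2 <- suppressWarnings(as.character(
    translate(DNAString(b$seq), if.fuzzy.codon = "solve")))
  if (grepl("\\*", aa1) && grepl("\\*", aa2)) {
    warning("locus '", name, "' has internal stops in both genomes ",
            "(pseudogene candidate)")
    return(NULL)
  }
  aa1 <- gsub("\\*", "X", aa1); aa2 <- gsub("\\*", "X", aa2)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  pa <- pairwiseAlignment(AAString(aa1), AAString(aa2), type = "global",
                          substitutionMatrix = get("BLOSUM62"),
                          gapOpening = 10, gapExtension = 0.5)
  g1 <- .chars(as.character(alignedPattern(pa)))
  g2 <- .chars(as.character(alignedSubject(pa)))
  thread <- function(gapped, nt) {
    out <- character(length(gapped))
    pos <- 1L
    for (i in seq_along(gapped)) {
      if (gapped[i] == "-") out[i] <- "---"
      else { out[i] <- substr(nt, pos, pos + 2L); pos <- pos + 3L }
    }
    .paste0v(out)
  }
  n1 <- thread(g1, a$seq); n2 <- thread(g2, b$seq)
  ## re-append the terminal stop codons as aligned columns
  if (!is.null(a$stop) || !is.null(b$stop)) {
    n1 <- paste0(n1, if (is.null(a$stop)) "---" else a$stop)
    n2 <- paste0(n2, if (is.null(b$stop)) "---" else b$stop)
  }
  c(n1, n2)
}

#' Trim terminal gap columns from an aligned locus
#'
#' Removes leading and trailing alignment columns in which either row is a
#' gap; internal columns are untouched. Idempotent.
#'
#' @param locus a locus with `aln1`/`aln2` from [alignLocus()].
#' @return the locus with trimmed `aln1`/`aln2`; a locus that trims to
#'   nothing keeps empty alignment strings and triggers a warning.
#' @export
trimTerminalGaps <- function(locus) {
  a <- .chars(locus$aln1); b <- .chars(locus$aln2)
  gap <- a == "-" | b == "-"
  keep <- which(!gap)
  if (!length(keep)) {
    warning("locus '", locus$name, "' trims to an empty alignment")
    locus$aln1 <- ""; locus$aln2 <- ""
    return(locus)
  }
  i1 <- min(keep); i2 <- max(keep)
  locus$aln1 <- .paste0v(a[i1:i2])
  locus$aln2 <- .paste0v(b[i1:i2])
  locus
}

#' Count divergence events in a trimmed pairwise alignment
#'
#' Conserved sites are columns with identical non-gap bases;
#' substitutions are columns with differing non-gap bases; an indel event
#' is one maximal run of contiguous gap columns (a k-base gap is one
#' event). Columns containing `N` are ignored entirely. Symmetric in the
#' two rows.
#'
#' @param locus a locus with trimmed `aln1`/`aln2`, or two aligned
#'   strings.
#' @param aln2 second aligned string when `locus` is given as a string.
#' @return named integer vector: `conserved`, `substitutions`,
#'   `indelEvents`.
#' @export
countEvents <- function(locus, aln2 = NULL) {
  if (is.null(aln2)) { a <- .chars(locus$aln1); b <- .chars(locus$aln2) }
  else { a <- .chars(locus); b <- .chars(aln2) }
  stopifnot(length(a) == length(b))
  gap_a <- a == "-"; gap_b <- b == "-"
  if (any(gap_a & gap_b))
    stop("double-gap column: not a pairwise alignment")
  hasN <- a == "N" | b == "N"
  both <- !gap_a & !gap_b & !hasN
  conserved <- sum(both & a == b)
  substitutions <- sum(both & a != b)
  gapcol <- (gap_a | gap_b)
  indel_events <- if (any(gapcol)) {
    r <- rle(gapcol); sum(r$values)
  } else 0L
  c(conserved = conserved, substitutions = substitutions,
    indelEvents = as.integer(indel_events))
}

#' Sequence variability (SV\%)
#'
#' `SV% = (substitutions + indel events) /
#' (conserved sites + substitutions + indel events) x 100`.
#'
#' @param conserved,substitutions,indelEvents non-negative counts.
#' @return percentage in `[0, 100]`.
#' @examples
#' svPercent(95, 3, 2)   # 5
#' @export
svPercent <- function(conserved, substitutions, indelEvents) {
  stopifnot(conserved >= 0, substitutions >= 0, indelEvents >= 0)
  den <- conserved + substitutions + indelEvents
  if (den == 0) stop("SV undefined: empty alignment")
  100 * (substitutions + indelEvents) / den
}

#' Full divergence screen of a plastome pair
#'
#' Extracts syntenic loci, aligns each (codon-aware for coding loci),
#' trims terminal gaps, counts events and computes SV\% and GC content
#' per locus.
#'
#' @inheritParams extractSyntenicLoci
#' @param ... alignment parameters passed to [alignLocus()].
#' @return data.frame of per-locus divergence records: `name`, `class`,
#'   `region`, `alnLength`, `conserved`, `substitutions`, `indelEvents`,
#'   `svPercent`, `gcPercent`, `frameOk`.
#' @export
computeDivergence <- function(p1, p2, part1 = NULL, part2 = NULL,
                              minNonCodingLen = 150, ...) {
  loci <- extractSyntenicLoci(p1, p2, part1, part2, minNonCodingLen)
  recs <- lapply(seq_len(nrow(loci)), function(i) {
    l <- as.list(loci[i, ])
    l <- alignLocus(l, ...)
    l <- trimTerminalGaps(l)
    if (!nzchar(l$aln1)) return(NULL)
    ev <- countEvents(l)
    if (sum(ev) == 0) return(NULL)
    data.frame(
      name = l$name, class = l$class, region = l$region,
      alnLength = nchar(l$aln1),
      conserved = ev[["conserved"]],
      substitutions = ev[["substitutions"]],
      indelEvents = ev[["indelEvents"]],
      svPercent = svPercent(ev[["conserved"]], ev[["substitutions"]],
                            ev[["indelEvents"]]),
      gcPercent = 100 - atContent(paste0(l$seq1, l$seq2)),
      frameOk = isTRUE(l$frameOk), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Rank mutational hotspots
#'
#' The top-k non-coding loci (spacers and introns) by SV\%, descending;
#' ties broken by locus name so the ranking is stable across runs.
#'
#' @param records data.frame from [computeDivergence()].
#' @param k number of loci to return (default 10).
#' @return the top-k rows, ordered.
#' @export
rankHotspots <- function(records, k = 10) {
  nc <- records[records$class %in% c("spacer", "intron"), , drop = FALSE]
  nc <- nc[order(-nc$svPercent, nc$name), , drop = FALSE]
  if (nrow(nc) < k)
    warning("only ", nrow(nc), " non-coding loci available (k = ", k, ")")
  head(nc, k)
}

#' Correlation and group-comparison statistics of a divergence screen
#'
#' Spearman rank correlations of (SV, GC), (indel events, substitutions),
#' (indel events, GC) and (substitutions, GC), plus two-sided
#' Mann-Whitney tests of coding vs non-coding SV and single-copy vs IR SV
#' (non-coding loci). Raw two-sided p-values are reported without
#' multiplicity correction.
#'
#' @param records data.frame from [computeDivergence()].
#' @return list with `correlations` and `groupTests` data.frames.
#' @export
divergenceStatistics <- function(records) {
  sp <- function(x, y, label) {
    if (length(unique(x)) < 2L || length(unique(y)) < 2L)
      return(data.frame(pair = label, rho = NA_real_, p = NA_real_,
                        note = "constant variable",
                        stringsAsFactors = FALSE))
    ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = FALSE))
    data.frame(pair = label, rho = unname(ct$estimate), p = ct$p.value,
               note = "", stringsAsFactors = FALSE)
  }
  correlations <- rbind(
    sp(records$svPercent, records$gcPercent, "SV~GC"),
    sp(records$indelEvents, records$substitutions, "InDels~substitutions"),
    sp(records$indelEvents, records$gcPercent, "InDels~GC"),
    sp(records$substitutions, records$gcPercent, "substitutions~GC"))

  mw <- function(x, y, label) {
    if (length(x) < 2L || length(y) < 2L)
      return(data.frame(comparison = label, W = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                       exact = FALSE))
    data.frame(comparison = label, W = unname(wt$statistic),
               p = wt$p.value, stringsAsFactors = FALSE)
  }
  codingSV <- records$svPercent[records$class == "coding"]
  ncSV <- records$svPercent[records$class != "coding"]
  ncIR <- records$svPercent[records$class != "coding" &
                              records$region == "IR"]
  ncSC <- records$svPercent[records$class != "coding" &
                              records$region != "IR"]
  groupTests <- rbind(
    mw(ncSV, codingSV, "non-coding SV vs coding SV"),
    mw(ncSC, ncIR, "single-copy SV vs IR SV (non-coding)"))
  list(correlations = correlations, groupTests = groupTests)
}
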