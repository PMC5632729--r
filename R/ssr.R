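## Simple-sequence-repeat census: maximal perfect tandem runs of 1-6 bp
## units above per-class minimum unit counts, with genomic-context
## classification.

#' SSR unit-count thresholds
#'
#' The census counts a maximal perfect tandem run only when its number of
#' unit copies reaches the threshold for its motif class. The defaults are
#' the inclusive reading of the usual plastome criteria: >= 8 units for
#' mononucleotide, >= 5 for dinucleotide and >= 3 for tri- through
#' hexanucleotide motifs. Pass `strict = TRUE` for the strict-inequality
#' reading (> 8/5/3, i.e. 9/6/4).
#'
#' @param mono,di,multi minimum unit counts per class.
#' @param strict logical; use the strict-inequality reading.
#' @return integer vector of length 6 (unit sizes 1..6).
#' @export
ssrThresholds <- function(mono = 8, di = 5, multi = 3, strict = FALSE) {
  thr <- c(mono, di, multi, multi, multi, multi)
  if (strict) thr <- thr + 1
  if (any(thr < 1)) stop("SSR thresholds must be >= 1")
  as.integer(thr)
}

#' Find simple sequence repeats
#'
#' Reports every maximal perfect tandem run of a primitive 1-6 bp motif
#' whose unit count reaches its class threshold, exactly once. Runs are
#' maximal (not extendable on either side); a run reportable under several
#' unit sizes is reported only under its primitive unit; runs containing
#' `N` are broken at the `N`; on circular sequences a run across the origin
#' is counted once. The reported span covers the full unit copies starting
#' at the run's first base (a trailing partial unit extends the run but not
#' the span), so span length = motif length x unit count.
#'
#' @param p an [AnnotatedPlastome-class] or character sequence.
#' @param thresholds per-class minimum unit counts, see [ssrThresholds()].
#' @param partition optional [RegionPartition-class]; required by
#'   `collapseIRDuplicates`.
#' @param collapseIRDuplicates when `TRUE`, loci lying entirely inside IRa
#'   are dropped so each IR-resident SSR is counted once; the default
#'   counts per occurrence (both IR copies).
#' @return a data.frame with columns `motif`, `unitLength`, `unitCount`,
#'   `start`, `end` (end may exceed the genome length for an
#'   origin-spanning run).
#' @examples
#' findSSRs(paste0("GCGTC", strrep("A", 9), "GTCGT"))
#' @export
findSSRs <- function(p, thresholds = ssrThresholds(), partition = NULL,
                     collapseIRDuplicates = FALSE) {
  if (any(thresholds < 1)) stop("SSR thresholds must be >= 1")
  circular <- TRUE
  if (is(p, "AnnotatedPlastome")) {
    s <- as.character(genomeSeq(p)); circular <- isCircular(p)
  } else {
    s <- toupper(as.character(p)); circular <- FALSE
  }
  L <- nchar(s)
  s2 <- if (circular) paste0(s, s) else s
  x <- .chars(s2)
  ok <- x %in% c("A", "C", "G", "T")
  n2 <- length(x)

  out <- list()
  for (u in 1:6) {
    if (n2 <= u) break
    thr <- thresholds[u]
    eq <- x[seq_len(n2 - u)] == x[(u + 1L):n2] &
      ok[seq_len(n2 - u)] & ok[(u + 1L):n2]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values)
    for (h in hit) {
      a <- starts[h]
      reg_len <- min(r$lengths[h] + u, L)   # a run cannot exceed the circle
      count <- reg_len %/% u
      if (count < thr) next
      if (a > L) next                        # image in the doubled copy
      motif <- substr(s2, a, a + u - 1L)
      if (!.is_primitive_motif(motif)) next
      out[[length(out) + 1L]] <- data.frame(
        motif = motif, unitLength = u, unitCount = count,
        start = a, end = a + count * u - 1L, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(motif = character(), unitLength = integer(),
               unitCount = integer(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)

  if (circular && nrow(res)) {
    ## a run that begins at base 1 of the linearization is spurious when it
    ## is the tail of an origin-spanning run already reported
    cross <- res[res$end > L, , drop = FALSE]
    if (nrow(cross)) {
      drop <- res$start == 1L & vapply(seq_len(nrow(res)), function(i) {
        any(cross$unitLength == res$unitLength[i] &
              .mod1(cross$end, L) >= res$end[i] & cross$start != res$start[i])
      }, TRUE)
      res <- res[!drop, , drop = FALSE]
    }
  }

  if (collapseIRDuplicates) {
    if (is.null(partition))
      stop("collapseIRDuplicates requires a RegionPartition")
    ira <- partition@ira
    inside <- res$start >= start(ira) & res$end <= end(ira)
    res <- res[!inside, , drop = FALSE]
  }
  res <- res[order(res$start, res$unitLength), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify the genomic context of SSR loci
#'
#' A locus is `coding` when its span lies entirely inside functional gene
#' segments (CDS / tRNA / rRNA exons), `non_coding` when entirely outside,
#' and `spanning` otherwise.
#'
#' @param loci data.frame from [findSSRs()].
#' @param p the annotated [AnnotatedPlastome-class].
#' @return `loci` with a `context` column added.
#' @export
classifySSRContext <- function(loci, p) {
  cov <- .coding_coverage(p)
  loci$context <- vapply(seq_len(nrow(loci)), function(i) {
    .span_context(loci$start[i], loci$end[i], cov)
  }, "")
  loci
}

## logical coverage vector of functional coding segments (mod L)
.coding_coverage <- function(p) {
  L <- genomeLength(p)
  cov <- logical(L)
  ft <- features(p)
  if (nrow(ft)) {
    idx <- which(ft$category %in% c("protein_coding", "tRNA", "rRNA") &
                   !ft$pseudo)
    for (i in idx) {
      segs <- ft$segments[[i]]
      for (k in seq_along(segs))
        cov[.mod1(seq(start(segs)[k], end(segs)[k]), L)] <- TRUE
    }
  }
  cov
}

.span_context <- function(a, b, cov) {
  pos <- .mod1(seq(a, b), length(cov))
  inside <- cov[pos]
  if (all(inside)) "coding" else if (!any(inside)) "non_coding"
  else "spanning"
}

#' Summarize an SSR census
#'
#' Class totals (mono- through hexanucleotide) and per-motif totals.
#' Reverse-complement motifs are deliberately not merged (A- and T-runs are
#' counted separately, as repeat-census tools report them).
#'
#' @param loci data.frame from [findSSRs()].
#' @return a list with `total`, `byClass` (named integer vector) and
#'   `byMotif` (data.frame of motif counts).
#' @export
ssrSummary <- function(loci) {
  classes <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  byClass <- vapply(1:6, function(u) sum(loci$unitLength == u), 1L)
  names(byClass) <- classes
  byMotif <- if (nrow(loci)) {
    tb <- table(loci$motif)
    data.frame(motif = names(tb), count = as.integer(tb),
               stringsAsFactors = FALSE)
  } else data.frame(motif = character(), count = integer(),
                    stringsAsFactors = FALSE)
  list(total = nrow(loci), byClass = byClass, byMotif = byMotif)
}
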