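## Dispersed-repeat census: maximal forward, palindromic and reverse repeat
## pairs under joint length / hamming-distance / identity criteria.

.REPEAT_KINDS <- c(forward = 1L, palindromic = 2L, reverse = 3L)

#' Find dispersed repeats
#'
#' Detects all maximal repeat pairs of three kinds -- `forward` (copy2
#' equals copy1), `palindromic` (copy2 equals the reverse complement of
#' copy1) and `reverse` (copy2 equals the plain reversal of copy1) -- with
#' copy length `>= minLen`, at most `maxHamming` mismatches and identity
#' `>= minIdentity` percent (both criteria are enforced jointly). Each
#' unordered pair is reported once with `start1 < start2`. Pairs whose two
#' copies overlap (tandem arrays, fold-back palindromes) are excluded, as
#' are hits whose two copies are the genome's own IR pair (reciprocal
#' overlap of at least 90\% with IRb and IRa) when a partition is supplied.
#'
#' The scan is exact-seed (7-mer) hashing with banded extension; any pair
#' satisfying the default criteria contains an exact run of at least 7 bp,
#' so the seeding loses nothing relative to a brute-force all-pairs scan.
#'
#' @param p an [AnnotatedPlastome-class] or character sequence (assumed
#'   canonical; the scan is on the given linearization).
#' @param minLen minimum copy length in bp (default 30; values below 8 are
#'   rejected, seeding is impossible there).
#' @param maxHamming maximum mismatches between the two copies (default 3).
#' @param kinds subset of `c("forward", "palindromic", "reverse")`.
#' @param partition optional [RegionPartition-class] used to exclude the IR
#'   self-match.
#' @param minIdentity minimum percent identity (default 90).
#' @return a data.frame with columns `kind`, `start1`, `end1`, `start2`,
#'   `end2`, `length`, `mismatches`, `identity`.
#' @examples
#' s <- paste0(strrep("ACGTT", 20), "AGAGCTCGGATCAATCGGCATTACCGGCTAAGCTA")
#' # no planted duplication: nothing to find in 100 random-ish bases
#' nrow(findRepeats(s, minLen = 30))
#' @export
findRepeats <- function(p, minLen = 30, maxHamming = 3,
                        kinds = c("forward", "palindromic", "reverse"),
                        partition = NULL, minIdentity = 90) {
  if (minLen < 8) stop("minLen below 8 makes seeding impossible")
  kinds <- match.arg(kinds, several.ok = TRUE)
  s <- if (is(p, "AnnotatedPlastome")) as.character(genomeSeq(p))
       else toupper(as.character(p))

  res <- list()
  for (k in kinds) {
    hits <- cpp_maximal_pairs(s, .REPEAT_KINDS[[k]], as.integer(minLen),
                              as.integer(maxHamming), 7L)
    if (nrow(hits)) {
      hits$kind <- k
      res[[k]] <- hits
    }
  }
  res <- if (length(res)) do.call(rbind, res) else
    data.frame(start1 = integer(), end1 = integer(), start2 = integer(),
               end2 = integer(), mismatches = integer(),
               kind = character(), stringsAsFactors = FALSE)
  res$length <- res$end1 - res$start1 + 1L
  res$identity <- ifelse(res$length > 0,
                         100 * (1 - res$mismatches / res$length), NA_real_)
  res <- res[!is.na(res$identity) & res$identity >= minIdentity, ,
             drop = FALSE]

  if (!is.null(partition) && nrow(res)) {
    self_ir <- (.reciprocal_overlap(res$start1, res$end1, partition@irb) >= 0.9 &
                .reciprocal_overlap(res$start2, res$end2, partition@ira) >= 0.9) |
               (.reciprocal_overlap(res$start1, res$end1, partition@ira) >= 0.9 &
                .reciprocal_overlap(res$start2, res$end2, partition@irb) >= 0.9)
    res <- res[!self_ir, , drop = FALSE]
  }

  res <- res[order(res$start1, res$start2, res$kind),
             c("kind", "start1", "end1", "start2", "end2", "length",
               "mismatches", "identity")]
  rownames(res) <- NULL
  res
}

## vectorized reciprocal overlap of [a,b] with a single IRanges interval
.reciprocal_overlap <- function(a, b, iv) {
  ov <- pmax(0L, pmin(b, end(iv)) - pmax(a, start(iv)) + 1L)
  pmin(ov / (b - a + 1L), ov / width(iv))
}

#' Bin repeat hits by copy length
#'
#' @param hits data.frame from [findRepeats()].
#' @return named integer vector over the bins `30-49`, `50-69`, `70-89`,
#'   `>=90` bp.
#' @export
binRepeatsByLength <- function(hits) {
  br <- c(30, 50, 70, 90, Inf)
  lab <- c("30-49", "50-69", "70-89", ">=90")
  cnt <- if (nrow(hits))
    table(cut(hits$length, breaks = br, labels = lab, right = FALSE))
  else setNames(rep(0L, 4L), lab)
  out <- as.integer(cnt)
  names(out) <- lab
  out
}

#' Genomic-context proportions of repeat hits
#'
#' A hit is `coding` or `non_coding` only when both copies lie fully in
#' that class; otherwise it is `spanning`. Proportions are percentages and
#' sum to 100.
#'
#' @param hits data.frame from [findRepeats()].
#' @param p the annotated [AnnotatedPlastome-class].
#' @return a list with `context` (per-hit classes, parallel to `hits`) and
#'   `proportions` (named percentages).
#' @export
repeatContextProportions <- function(hits, p) {
  lev <- c("coding", "non_coding", "spanning")
  if (!nrow(hits))
    return(list(context = character(),
                proportions = setNames(rep(NA_real_, 3), lev)))
  cov <- .coding_coverage(p)
  c1 <- vapply(seq_len(nrow(hits)), function(i)
    .span_context(hits$start1[i], hits$end1[i], cov), "")
  c2 <- vapply(seq_len(nrow(hits)), function(i)
    .span_context(hits$start2[i], hits$end2[i], cov), "")
  ctx <- ifelse(c1 == "coding" & c2 == "coding", "coding",
         ifelse(c1 == "non_coding" & c2 == "non_coding", "non_coding",
                "spanning"))
  prop <- 100 * vapply(lev, function(l) mean(ctx == l), 1)
  list(context = ctx, proportions = prop)
}
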