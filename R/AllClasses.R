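#' @import methods
#' @importFrom S4Vectors DataFrame mcols
#' @importFrom IRanges IRanges IRangesList start end width
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
NULL

#' AnnotatedPlastome: a circular plastid genome with typed gene features
#'
#' The central container of the package: a (usually circular) plastome
#' sequence over the alphabet `{A,C,G,T,N}` together with an ordered feature
#' table. Coordinates are 1-based closed intervals on the current
#' linearization. On circular sequences a feature segment may span the
#' origin; such a segment is stored "unwrapped", i.e. with `end > length`,
#' so that `width = end - start + 1` is always the true segment length and
#' all rotation arithmetic is modular.
#'
#' @slot identifier accession or name of the plastome.
#' @slot sequence a [Biostrings::DNAString] with the genome sequence.
#' @slot features a [S4Vectors::DataFrame] with one row per feature and
#'   columns `name` (gene symbol), `category` (one of `protein_coding`,
#'   `tRNA`, `rRNA`, `intron`, `other`), `strand` (`+`/`-`), `pseudo`
#'   (logical) and `segments` (an [IRanges::IRangesList], exon intervals in
#'   transcription order).
#' @slot circular logical; `TRUE` for circular molecules.
#'
#' @seealso [readPlastome()], [countUniqueGenes()], [detectInvertedRepeat()]
#' @export
setClass("AnnotatedPlastome",
  representation(
    identifier = "character",
    sequence   = "DNAString",
    features   = "DataFrame",
    circular   = "logical"
  )
)

.FEATURE_CATEGORIES <- c("protein_coding", "tRNA", "rRNA", "intron", "other")

setValidity("AnnotatedPlastome", function(object) {
  msg <- character()
  L <- length(object@sequence)
  if (L < 1L) msg <- c(msg, "sequence must be non-empty")
  ft <- object@features
  need <- c("name", "category", "strand", "pseudo", "segments")
  if (!all(need %in% colnames(ft))) {
    msg <- c(msg, paste0("features must have columns: ",
                         paste(need, collapse = ", ")))
  } else if (nrow(ft) > 0L) {
    if (!all(ft$category %in% .FEATURE_CATEGORIES))
      msg <- c(msg, "unknown feature category")
    if (!all(ft$strand %in% c("+", "-")))
      msg <- c(msg, "feature strand must be '+' or '-'")
    segs <- ft$segments
    if (any(lengths(segs) == 0L))
      msg <- c(msg, "every feature needs at least one segment")
    st <- unlist(start(segs)); en <- unlist(end(segs))
    if (length(st) && (any(st < 1L) || any(st > L)))
      msg <- c(msg, "segment starts must lie in [1, genome length]")
    if (length(en) && any(en - st + 1L > L))
      msg <- c(msg, "a segment cannot be longer than the genome")
    if (!object@circular && length(en) && any(en > L))
      msg <- c(msg, "origin-spanning segments require a circular sequence")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotatedPlastome
#'
#' @param identifier accession or display name.
#' @param sequence a [Biostrings::DNAString] or character scalar
#'   (characters outside `ACGT` other than `N` are mapped to `N` with a
#'   warning; the downstream counters need a closed alphabet).
#' @param features a feature table as returned by [featureTable()]; defaults
#'   to an empty table.
#' @param circular logical flag, default `TRUE`.
#' @return an [AnnotatedPlastome-class] object.
#' @examples
#' p <- AnnotatedPlastome("toy", "ATGAAATAGCCC",
#'   featureTable("g1", "protein_coding", "+", FALSE, list(c(1, 9))))
#' genomeLength(p)
#' @export
AnnotatedPlastome <- function(identifier, sequence,
                              features = featureTable(), circular = TRUE) {
  if (is.character(sequence)) {
    sequence <- toupper(sequence)
    bad <- gsub("[ACGTN]", "", sequence)
    if (nzchar(bad)) {
      warning("mapping ambiguity characters {",
              paste(unique(strsplit(bad, "")[[1]]), collapse = ","),
              "} to N in '", identifier, "'")
      sequence <- gsub("[^ACGTN]", "N", sequence)
    }
    sequence <- DNAString(sequence)
  }
  new("AnnotatedPlastome", identifier = as.character(identifier),
      sequence = sequence, features = features,
      circular = isTRUE(circular))
}

#' Build a feature table
#'
#' Convenience constructor for the `features` slot of an
#' [AnnotatedPlastome-class]. All arguments are recycled to a common length.
#'
#' @param name gene symbols.
#' @param category feature categories (`protein_coding`, `tRNA`, `rRNA`,
#'   `intron`, `other`).
#' @param strand `"+"` or `"-"`.
#' @param pseudo logical pseudogene flags.
#' @param segments a list with one element per feature: either an
#'   [IRanges::IRanges], a numeric vector `c(start, end)`, or a two-column
#'   matrix of starts and ends (exons in transcription order).
#' @return a [S4Vectors::DataFrame] suitable for the `features` slot.
#' @export
featureTable <- function(name = character(), category = character(),
                         strand = character(), pseudo = logical(),
                         segments = list()) {
  n <- length(name)
  segs <- lapply(segments, function(s) {
    if (is(s, "IRanges")) return(s)
    m <- matrix(as.integer(s), ncol = 2, byrow = TRUE)
    IRanges(start = m[, 1], end = m[, 2])
  })
  DataFrame(
    name = as.character(name),
    category = rep_len(as.character(category), n),
    strand = rep_len(as.character(strand), n),
    pseudo = rep_len(as.logical(pseudo), n),
    segments = as(segs, "IRangesList")
  )
}

#' RegionPartition: the quadripartite architecture of a plastome
#'
#' Coordinates (1-based closed) of the large single-copy (LSC), the two
#' inverted-repeat copies (IRb, IRa) and the small single-copy (SSC) region
#' on a linearization of the genome, plus the two IR/SSC junctions. On the
#' canonical linearization the order is LSC, IRb, SSC, IRa with LSC starting
#' at 1; on other rotations intervals may be stored unwrapped (`end` beyond
#' the genome length). The junction `jSB` (IRb/SSC) is the first SSC base
#' and `jSA` (SSC/IRa) the last SSC base, so both coincide with the SSC's
#' endpoints.
#'
#' @slot lsc,irb,ssc,ira [IRanges::IRanges] of length 1 each.
#' @slot genomeLength integer.
#' @export
setClass("RegionPartition",
  representation(lsc = "IRanges", irb = "IRanges", ssc = "IRanges",
                 ira = "IRanges", genomeLength = "integer")
)

setValidity("RegionPartition", function(object) {
  msg <- character()
  for (s in c("lsc", "irb", "ssc", "ira"))
    if (length(slot(object, s)) != 1L)
      msg <- c(msg, paste0(s, " must be a single interval"))
  if (!length(msg)) {
    tot <- width(object@lsc) + width(object@ssc) + 2L * width(object@irb)
    if (tot != object@genomeLength)
      msg <- c(msg, "region lengths do not sum to the genome length")
    if (width(object@irb) != width(object@ira))
      msg <- c(msg, "the two IR copies must have equal length")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RegionPartition
#'
#' @param lsc,irb,ssc,ira [IRanges::IRanges] of length 1, or numeric
#'   `c(start, end)` pairs.
#' @param genomeLength genome length in bp.
#' @return a [RegionPartition-class].
#' @export
RegionPartition <- function(lsc, irb, ssc, ira, genomeLength) {
  as1 <- function(x) if (is(x, "IRanges")) x else IRanges(x[1], x[2])
  new("RegionPartition", lsc = as1(lsc), irb = as1(irb), ssc = as1(ssc),
      ira = as1(ira), genomeLength = as.integer(genomeLength))
}

#' JunctionProfile: IR/SSC junction architecture and ndh inventory
#'
#' @slot identifier plastome id.
#' @slot jsa,jsb integer junction coordinates (see
#'   [RegionPartition-class]).
#' @slot ycf1ToJsa signed distance in bp from the 5' end of ycf1 to the
#'   IRa/SSC junction, positive when the junction lies downstream of the 5'
#'   end within the gene body (i.e. ycf1 overhangs into the IR); `NA` when
#'   ycf1 is not annotated.
#' @slot ndhStatus named character vector over the 11 ndh genes
#'   (ndhA..ndhK), each `intact`, `pseudogene` or `absent`.
#' @slot retainedNdhLength summed bp of annotated ndh sequence (intact
#'   genes plus pseudogene remnants).
#' @slot typeLabel plastome type `A`, `B` or `C`.
#' @export
setClass("JunctionProfile",
  representation(identifier = "character", jsa = "integer", jsb = "integer",
                 ycf1ToJsa = "numeric", ndhStatus = "character",
                 retainedNdhLength = "numeric", typeLabel = "character")
)

NDH_GENES <- paste0("ndh", LETTERS[1:11])

setValidity("JunctionProfile", function(object) {
  msg <- character()
  if (!identical(sort(names(object@ndhStatus)), sort(NDH_GENES)))
    msg <- c(msg, "ndhStatus must be named by the 11 ndh genes")
  if (!all(object@ndhStatus %in% c("intact", "pseudogene", "absent")))
    msg <- c(msg, "ndhStatus values must be intact/pseudogene/absent")
  if (object@typeLabel %in% "A" && !all(object@ndhStatus == "intact"))
    msg <- c(msg, "type A requires all 11 ndh genes intact")
  if (!is.na(object@retainedNdhLength) && object@retainedNdhLength < 0)
    msg <- c(msg, "retainedNdhLength must be non-negative")
  if (length(msg)) msg else TRUE
})

#' OriginFit: an origin-constrained least-squares fit
#'
#' @slot slope fitted slope of `y = slope * x`.
#' @slot rSquared coefficient of determination against the
#'   origin-constrained fit, `1 - RSS / sum(y^2)`, in `[0, 1]`.
#' @slot n number of points.
#' @slot pValue permutation p-value (fixed seed).
#' @export
setClass("OriginFit",
  representation(slope = "numeric", rSquared = "numeric", n = "integer",
                 pValue = "numeric")
)

setValidity("OriginFit", function(object) {
  if (!is.na(object@rSquared) &&
      (object@rSquared < -1e-9 || object@rSquared > 1 + 1e-9))
    "rSquared must lie in [0, 1]" else TRUE
})

setMethod("show", "OriginFit", function(object) {
  cat(sprintf("OriginFit: y = %.4g x  (R2 = %.3f, n = %d, perm. P = %.4g)\n",
              object@slope, object@rSquared, object@n, object@pValue))
})

#' SimTruth: the complete planted ground truth of a simulated plastome
#'
#' Returned alongside every simulator product; the ledger fully describes
#' the emitted sequences so every downstream estimate can be checked
#' against it.
#'
#' @slot partition the planted [RegionPartition-class].
#' @slot loci data.frame of genomic building blocks (one row per segment:
#'   gene exons, introns, spacers) with planted coordinates and rates.
#' @slot ssrs data.frame of planted SSR loci (motif, unitCount, start, end).
#' @slot repeats data.frame of planted dispersed repeats (kind, coordinates
#'   of both copies, mismatches).
#' @slot mutations data.frame ledger of substitutions and indels applied by
#'   [evolvePair()] (empty for a fresh ancestor).
#' @slot scenario scenario label `A`, `B` or `C`.
#' @slot retainedNdhLength planted retained ndh length in bp.
#' @slot config the [simConfig()] list that produced the genome.
#' @export
setClass("SimTruth",
  representation(partition = "RegionPartition", loci = "data.frame",
                 ssrs = "data.frame", repeats = "data.frame",
                 mutations = "data.frame", scenario = "character",
                 retainedNdhLength = "numeric", config = "list")
)

## ---- show methods -------------------------------------------------------

setMethod("show", "AnnotatedPlastome", function(object) {
  cat("AnnotatedPlastome '", object@identifier, "': ",
      length(object@sequence), " bp, ",
      if (object@circular) "circular" else "linear", ", ",
      nrow(object@features), " features\n", sep = "")
  if (nrow(object@features)) {
    tab <- table(object@features$category)
    cat("  ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n",
        sep = "")
  }
})

setMethod("show", "RegionPartition", function(object) {
  fmt <- function(r) sprintf("[%d, %d] (%d bp)", start(r), end(r), width(r))
  cat("RegionPartition on ", object@genomeLength, " bp\n",
      "  LSC ", fmt(object@lsc), "\n  IRb ", fmt(object@irb),
      "\n  SSC ", fmt(object@ssc), "\n  IRa ", fmt(object@ira),
      "\n  J_SB = ", jsb(object), ", J_SA = ", jsa(object), "\n", sep = "")
})

setMethod("show", "JunctionProfile", function(object) {
  n_int <- sum(object@ndhStatus == "intact")
  n_psi <- sum(object@ndhStatus == "pseudogene")
  cat("JunctionProfile '", object@identifier, "' [type ", object@typeLabel,
      "]\n  ndh: ", n_int, " intact, ", n_psi, " pseudogene, ",
      11L - n_int - n_psi, " absent; retained ", object@retainedNdhLength,
      " bp\n  ycf1 5' -> J_SA: ", object@ycf1ToJsa, " bp\n", sep = "")
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth: scenario ", object@scenario, ", ",
      nrow(object@loci), " planted segments, ",
      nrow(object@ssrs), " SSRs, ", nrow(object@repeats),
      " dispersed repeats, ", nrow(object@mutations), " mutations\n",
      sep = "")
})
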