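## IR/SSC junction architecture: the ycf1-to-J_SA distance, the ndh gene
## inventory, the A/B/C plastome typology, and the origin-constrained
## regression of IR boundary shift on retained ndh length.

#' Profile the IR/SSC junction architecture of a plastome
#'
#' Reads the junction coordinates off the partition, measures the signed
#' distance from the 5' end of ycf1 to the SSC/IRa junction along the
#' gene (positive when the junction lies downstream of the 5' end inside
#' the gene body, i.e. ycf1 overhangs into the IR), inventories the 11
#' ndh genes (`intact` / `pseudogene` / `absent`, the record's pseudogene
#' flag respected) and assigns the plastome type.
#'
#' @param p a canonical annotated [AnnotatedPlastome-class].
#' @param part the matching [RegionPartition-class]; detected when
#'   missing.
#' @param rule typology rule, see [classifyJunctionType()].
#' @return a [JunctionProfile-class].
#' @export
profileJunctions <- function(p, part = NULL, rule = c("remnant", "intact")) {
  if (is.null(part)) part <- detectInvertedRepeat(p)
  rule <- match.arg(rule)
  ft <- features(p)

  ycf1ToJsa <- NA_real_
  idx <- which(ft$name == "ycf1" & !ft$pseudo)
  if (!length(idx)) {
    message("ycf1 not annotated in '", identifier(p),
            "'; ycf1-to-J_SA distance undefined")
  } else {
    segs <- ft$segments[[idx[1L]]]
    fivep <- if (ft$strand[idx[1L]] == "-") end(segs)[1L] else start(segs)[1L]
    ycf1ToJsa <- if (ft$strand[idx[1L]] == "-") fivep - jsa(part)
                 else jsa(part) - fivep
  }

  status <- vapply(NDH_GENES, function(gn) {
    hit <- which(ft$name == gn)
    if (!length(hit)) "absent"
    else if (any(!ft$pseudo[hit])) "intact"
    else "pseudogene"
  }, "")

  prof <- new("JunctionProfile", identifier = identifier(p),
              jsa = jsa(part), jsb = jsb(part), ycf1ToJsa = ycf1ToJsa,
              ndhStatus = status, retainedNdhLength = .retained_ndh(p),
              typeLabel = classifyJunctionType(status, rule))
  prof
}

#' Classify a plastome into junction types A / B / C
#'
#' Type `A` has all 11 ndh genes intact; type `B` has lost the ndh
#' complement entirely (no intact genes and no annotated remnants, under
#' the default `"remnant"` rule); everything in between -- partial loss or
#' pseudogenization -- is type `C`. The alternative `"intact"` rule labels
#' any plastome with zero intact ndh genes as `B` even when pseudogene
#' remnants remain; the distinction between the two readings is real in
#' published material, so the rule is selectable rather than guessed.
#'
#' @param x a [JunctionProfile-class] or a named status vector over the
#'   11 ndh genes (`intact` / `pseudogene` / `absent`).
#' @param rule `"remnant"` (default) or `"intact"`.
#' @return `"A"`, `"B"` or `"C"`.
#' @export
classifyJunctionType <- function(x, rule = c("remnant", "intact")) {
  rule <- match.arg(rule)
  status <- if (is(x, "JunctionProfile")) x@ndhStatus else x
  stopifnot(length(status) == 11L)
  n_intact <- sum(status == "intact")
  n_pseudo <- sum(status == "pseudogene")
  if (n_intact == 11L) return("A")
  if (rule == "remnant") {
    if (n_intact == 0L && n_pseudo == 0L) "B" else "C"
  } else {
    if (n_intact == 0L) "B" else "C"
  }
}

#' Fit a least-squares line through the origin
#'
#' `slope = sum(xy) / sum(x^2)`; the coefficient of determination is
#' computed against the origin-constrained fit, `R^2 = 1 - RSS /
#' sum(y^2)`; significance is assessed by a fixed-seed permutation test
#' of the y values.
#'
#' @param x,y numeric vectors (e.g. retained ndh length and IR boundary
#'   shift); `n >= 3` required.
#' @param nPerm number of permutations.
#' @param seed permutation RNG seed.
#' @return an [OriginFit-class].
#' @examples
#' f <- fitOriginRegression(1:10, 0.136 * (1:10))
#' f@slope       # 0.136
#' f@rSquared    # 1
#' @export
fitOriginRegression <- function(x, y, nPerm = 999, seed = 1) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 points")
  if (all(x == 0)) stop("slope undefined: all x are zero")
  fit1 <- function(xx, yy) {
    b <- sum(xx * yy) / sum(xx^2)
    r2 <- 1 - sum((yy - b * xx)^2) / sum(yy^2)
    c(b = b, r2 = r2)
  }
  obs <- fit1(x, y)
  perm <- .with_seed(seed, {
    vapply(seq_len(nPerm), function(i) fit1(x, sample(y))[["r2"]], 1)
  })
  p <- (1 + sum(perm >= obs[["r2"]])) / (nPerm + 1)
  new("OriginFit", slope = obs[["b"]],
      rSquared = max(0, min(1, obs[["r2"]])),
      n = length(x), pValue = p)
}

#' Compare junction shifts among plastome types
#'
#' Two-sided Mann-Whitney tests of the ycf1-to-J_SA distances (or any
#' supplied junction measurement) between every pair of plastome types.
#'
#' @param values numeric vector of junction measurements.
#' @param groups parallel vector of type labels.
#' @return data.frame with one row per type pair: `groupA`, `groupB`,
#'   `nA`, `nB`, `W`, `p` (pairs with fewer than 2 values per group are
#'   skipped with a warning).
#' @export
compareIRLengths <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  labs <- sort(unique(groups))
  rows <- list()
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (j <= i) next
    a <- values[groups == labs[i]]; b <- values[groups == labs[j]]
    if (length(a) < 2L || length(b) < 2L) {
      warning("skipping ", labs[i], " vs ", labs[j],
              ": fewer than 2 values in a group")
      next
    }
    wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided",
                                       exact = TRUE))
    rows[[length(rows) + 1L]] <- data.frame(
      groupA = labs[i], groupB = labs[j], nA = length(a), nB = length(b),
      W = unname(wt$statistic), p = wt$p.value, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(groupA = character(), groupB = character(),
                      nA = integer(), nB = integer(), W = numeric(),
                      p = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Junction-shift regression over a plastome cohort
#'
#' Convenience wrapper: given junction profiles of a type-C cohort and a
#' type-A reference value of the ycf1-to-J_SA distance, regresses the IR
#' boundary shift (profile distance minus reference) on the retained ndh
#' length through the origin.
#'
#' @param profiles list of [JunctionProfile-class] objects (type C).
#' @param referenceYcf1ToJsa the stable type-A ycf1-to-J_SA distance used
#'   as the zero point (default 991 bp).
#' @param ... passed to [fitOriginRegression()].
#' @return list with `fit` (an [OriginFit-class]) and `points` (the
#'   regression data.frame).
#' @export
junctionShiftRegression <- function(profiles, referenceYcf1ToJsa = 991,
                                    ...) {
  pts <- data.frame(
    identifier = vapply(profiles, identifier, ""),
    retainedNdh = vapply(profiles, retainedNdhLength, 1),
    irShift = vapply(profiles, ycf1ToJsa, 1) - referenceYcf1ToJsa,
    type = vapply(profiles, typeLabel, ""), stringsAsFactors = FALSE)
  fit <- fitOriginRegression(pts$retainedNdh, pts$irShift, ...)
  list(fit = fit, points = pts)
}
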