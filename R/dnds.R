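## Pairwise dN/dS by Nei-Gojobori (1986) codon counting with Jukes-Cantor
## correction. Synonymous site fractions are averaged over the two
## sequences; codons differing at several positions are resolved by
## averaging over all minimal mutational pathways, with pathways through
## stop codons excluded. The standard (plastid) genetic code is the
## default.

## translation table: codon -> amino acid (one-letter, "*" = stop)
.codon_aa <- local({
  tab <- NULL
  function(code = Biostrings::GENETIC_CODE) {
    if (is.null(tab)) tab <<- code
    tab
  }
})

## fraction of synonymous changes at each position of each sense codon;
## changes to stop codons count as non-synonymous (so that synonymous +
## non-synonymous sites always total 3 per codon)
.syn_site_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    code <- .codon_aa()
    bases <- c("A", "C", "G", "T")
    m <- matrix(0, nrow = length(.ALL_CODONS), ncol = 3,
                dimnames = list(.ALL_CODONS, NULL))
    for (cod in .ALL_CODONS) {
      aa <- code[[cod]]
      for (posn in 1:3) {
        ref <- substr(cod, posn, posn)
        syn <- 0L
        for (b in setdiff(bases, ref)) {
          alt <- cod
          substr(alt, posn, posn) <- b
          if (!(alt %in% STOP_CODONS) && code[[alt]] == aa)
            syn <- syn + 1L
        }
        m[cod, posn] <- syn / 3
      }
    }
    tab <<- m
    tab
  }
})

#' Split an aligned coding locus into comparable codon pairs
#'
#' Chops a trimmed, frame-preserving codon-aware alignment into aligned
#' codon pairs. Codon pairs containing a gap or `N` are skipped; the
#' terminal stop codon pair is removed; a codon that is an internal stop
#' in one sequence is skipped with a warning; internal stops in both
#' sequences flag the locus as a pseudogene and nothing is returned.
#'
#' @param locus an aligned, trimmed locus (needs `aln1`, `aln2`, `name`).
#' @return list with `codons1`, `codons2` (character vectors of equal
#'   length) and `pseudo` (logical flag).
#' @export
codonize <- function(locus) {
  a <- locus$aln1; b <- locus$aln2
  if (nchar(a) %% 3L != 0L)
    stop("alignment of '", locus$name, "' is not a codon multiple")
  n <- nchar(a) / 3L
  starts <- seq(1L, by = 3L, length.out = n)
  c1 <- substring(a, starts, starts + 2L)
  c2 <- substring(b, starts, starts + 2L)
  ok <- !grepl("[-N]", c1) & !grepl("[-N]", c2)
  ## terminal stop pair
  if (n >= 1L && (c1[n] %in% STOP_CODONS || c2[n] %in% STOP_CODONS))
    ok[n] <- FALSE
  stop1 <- c1 %in% STOP_CODONS & ok
  stop2 <- c2 %in% STOP_CODONS & ok
  if (any(stop1 & stop2) ||
      (sum(stop1) > 0L && sum(stop2) > 0L)) {
    warning("locus '", locus$name,
            "' carries internal stops in both sequences; flagged pseudo")
    return(list(codons1 = character(), codons2 = character(),
                pseudo = TRUE))
  }
  if (any(stop1 | stop2)) {
    warning("skipping ", sum(stop1 | stop2), " internal-stop codon(s) in '",
            locus$name, "'")
    ok <- ok & !stop1 & !stop2
  }
  list(codons1 = c1[ok], codons2 = c2[ok], pseudo = FALSE)
}

## average synonymous/non-synonymous step counts over all minimal
## pathways between two codons; pathways via stop codons are excluded
## (unless every pathway is blocked, in which case all are used)
.pathway_counts <- function(c1, c2) {
  code <- .codon_aa()
  pos <- which(.chars(c1) != .chars(c2))
  d <- length(pos)
  if (d == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (d == 1L) list(pos) else
    if (d == 2L) list(pos, rev(pos)) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2),
                  c(3,2,1)), function(o) pos[o])
  eval_path <- function(order) {
    cur <- c1
    syn <- 0; nonsyn <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% STOP_CODONS && nxt != c2) return(NULL)
      if (code[[cur]] == code[[nxt]]) syn <- syn + 1
      else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  res <- Filter(Negate(is.null), lapply(perms, eval_path))
  if (!length(res)) {
    ## all pathways blocked by stops: fall back to using every pathway
    eval_any <- function(order) {
      cur <- c1; syn <- 0; nonsyn <- 0
      for (p in order) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (code[[cur]] == code[[nxt]]) syn <- syn + 1 else nonsyn <- nonsyn + 1
        cur <- nxt
      }
      c(syn = syn, nonsyn = nonsyn)
    }
    res <- lapply(perms, eval_any)
  }
  colMeans(do.call(rbind, res))
}

#' Pairwise dN/dS of aligned codon pairs (NG86)
#'
#' Nei-Gojobori counting: expected synonymous site counts are per-codon
#' synonymous-change fractions summed over positions and averaged over
#' the two sequences; observed synonymous/non-synonymous differences
#' average over all minimal mutational pathways (stop-codon pathways
#' excluded); the proportions are Jukes-Cantor corrected,
#' `d = -(3/4) ln(1 - (4/3) p)`.
#'
#' @param codons result of [codonize()], or a list with `codons1` and
#'   `codons2`.
#' @return one-row data.frame: `nCodons`, `nSites`, `sSites`, `nd`, `sd`,
#'   `pn`, `ps`, `dn`, `ds`, `omega`, `saturated`.
#' @examples
#' ng86Pair(list(codons1 = "TTT", codons2 = "TTC"))  # synonymous: dn = 0
#' @export
ng86Pair <- function(codons) {
  c1 <- codons$codons1; c2 <- codons$codons2
  if (length(c1) != length(c2) || length(c1) < 1L)
    stop("need at least one comparable codon pair")
  st <- .syn_site_table()
  s1 <- sum(st[c1, , drop = FALSE])
  s2 <- sum(st[c2, , drop = FALSE])
  sSites <- (s1 + s2) / 2
  nSites <- 3 * length(c1) - sSites
  diffs <- vapply(seq_along(c1), function(i) {
    if (c1[i] == c2[i]) c(syn = 0, nonsyn = 0)
    else .pathway_counts(c1[i], c2[i])
  }, c(syn = 0, nonsyn = 0))
  sd_ <- sum(diffs["syn", ]); nd_ <- sum(diffs["nonsyn", ])
  pn <- nd_ / nSites; ps <- sd_ / sSites
  jc <- function(p) {
    if (is.nan(p)) return(NA_real_)
    if (p >= 0.75) return(NA_real_)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  dn <- jc(pn); ds <- jc(ps)
  data.frame(nCodons = length(c1), nSites = nSites, sSites = sSites,
             nd = nd_, sd = sd_, pn = pn, ps = ps, dn = dn, ds = ds,
             omega = if (!is.na(ds) && ds > 0 && !is.na(dn)) dn / ds
                     else NA_real_,
             saturated = (!is.na(pn) && pn >= 0.75) ||
               (!is.na(ps) && ps >= 0.75),
             stringsAsFactors = FALSE)
}

#' Per-gene and concatenated pairwise dN/dS of a plastome pair
#'
#' Extracts the shared intact protein-coding genes (optionally a supplied
#' subset), aligns each codon-aware, and computes NG86 rates per gene and
#' on the concatenation (genes in sorted name order; counts are additive,
#' so the concatenated estimate equals NG86 on the pooled codon pairs).
#'
#' @inheritParams extractSyntenicLoci
#' @param genes optional character vector restricting the gene set.
#' @return list with `perGene` (data.frame, one row per gene) and
#'   `concatenated` (one-row data.frame, gene = `"concatenated"`).
#' @export
dndsPairwise <- function(p1, p2, part1 = NULL, part2 = NULL, genes = NULL) {
  loci <- extractSyntenicLoci(p1, p2, part1, part2)
  loci <- loci[loci$class == "coding", , drop = FALSE]
  if (!is.null(genes)) loci <- loci[loci$name %in% genes, , drop = FALSE]
  if (!nrow(loci)) stop("no shared intact protein-coding genes")
  loci <- loci[order(loci$name), , drop = FALSE]
  all1 <- character(); all2 <- character()
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    l <- as.list(loci[i, ])
    l <- trimTerminalGaps(alignLocus(l))
    if (!isTRUE(l$frameOk)) next
    cp <- codonize(l)
    if (cp$pseudo || !length(cp$codons1)) next
    rec <- ng86Pair(cp)
    rec$gene <- l$name
    rows[[length(rows) + 1L]] <- rec
    all1 <- c(all1, cp$codons1); all2 <- c(all2, cp$codons2)
  }
  perGene <- do.call(rbind, rows)
  perGene <- perGene[, c("gene", setdiff(colnames(perGene), "gene"))]
  conc <- ng86Pair(list(codons1 = all1, codons2 = all2))
  conc$gene <- "concatenated"
  conc <- conc[, colnames(perGene)]
  list(perGene = perGene, concatenated = conc)
}

#' Simulate an aligned codon pair with known omega
#'
#' Evolves two descendants from a random sense-codon ancestor: each site
#' is proposed a mutation with probability `mu` per descendant; proposals
#' are accepted outright when synonymous, with probability `omega` when
#' non-synonymous, and never when creating a stop. The NG86 estimator
#' applied to the output should recover the ordering (and approximate
#' magnitude) of `omega`.
#'
#' @param nCodons number of codons.
#' @param omega true dN/dS.
#' @param mu per-site proposal probability per lineage.
#' @param seed RNG seed.
#' @return list with `codons1`, `codons2` (suitable for [ng86Pair()]).
#' @export
simulateCodonPair <- function(nCodons = 1000, omega = 0.5, mu = 0.05,
                              seed = 1) {
  .with_seed(seed, {
    code <- .codon_aa()
    anc <- sample(.SENSE_CODONS, nCodons, replace = TRUE)
    evolve <- function(cods) {
      for (i in seq_along(cods)) {
        for (posn in 1:3) {
          if (stats::runif(1L) >= mu) next
          cur <- cods[i]
          alt <- cur
          substr(alt, posn, posn) <-
            sample(setdiff(c("A", "C", "G", "T"),
                           substr(cur, posn, posn)), 1L)
          if (alt %in% STOP_CODONS) next
          syn <- code[[cur]] == code[[alt]]
          if (syn || stats::runif(1L) < omega) cods[i] <- alt
        }
      }
      cods
    }
    list(codons1 = evolve(anc), codons2 = evolve(anc))
  })
}
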