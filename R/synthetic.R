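## Synthetic plastome simulator with a complete planted-truth ledger.
##
## The generator emits a circular quadripartite genome (LSC + IRb + SSC +
## revcomp(IRb)) carrying a scaled-down but structurally faithful plastid
## gene complement: the 11 ndh genes in their native regions (ndhC/J/K in
## the LSC, ndhB with its intron in the IR, the rest in the SSC), rRNA
## genes in the IR, intron-bearing genes (rps16, clpP, trnL, ndhA, ndhB),
## ndhF adjacent to the IRb/SSC junction, and ycf1 spanning the SSC/IRa
## junction with a configurable overhang whose reverse complement appears
## as a ycf1 pseudogene fragment at the IRb end -- exactly the architecture
## the junction-profiling module measures. Spacers are random sequence,
## regenerated until the production SSR and repeat finders report nothing
## but the planted elements, so planted-truth recovery is exact.

STOP_CODONS <- c("TAA", "TAG", "TGA")

.ALL_CODONS <- as.vector(outer(outer(c("T","C","A","G"), c("T","C","A","G"),
                               paste0), c("T","C","A","G"), paste0))
.SENSE_CODONS <- setdiff(.ALL_CODONS, STOP_CODONS)

## run expr with a private, restored RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.random_cds <- function(len) {
  stopifnot(len %% 3 == 0, len >= 9)
  paste0("ATG",
         paste(sample(.SENSE_CODONS, len / 3 - 2, replace = TRUE),
               collapse = ""),
         "TAA")
}

.pick_base_not <- function(forbidden) {
  sample(setdiff(c("A", "C", "G", "T"), forbidden), 1L)
}

## ---- default gene complement (scaled-down lengths, all exons in frame) --

.default_gene_set <- function() {
  g <- function(name, cat, strand, region, parts) {
    list(name = name, category = cat, strand = strand, region = region,
         parts = parts)
  }
  e <- function(...) { v <- c(...); v }
  list(
    ## LSC
    g("psbA",  "protein_coding", "-", "LSC", c(exon = 600)),
    g("trnK",  "tRNA",           "+", "LSC", c(exon = 72)),
    g("matK",  "protein_coding", "+", "LSC", c(exon = 900)),
    g("rps16", "protein_coding", "-", "LSC", c(exon = 219, intron = 300, exon = 141)),
    g("psbK",  "protein_coding", "+", "LSC", c(exon = 180)),
    g("trnS",  "tRNA",           "+", "LSC", c(exon = 87)),
    g("psbC",  "protein_coding", "+", "LSC", c(exon = 690)),
    g("rbcL",  "protein_coding", "+", "LSC", c(exon = 849)),
    g("atpB",  "protein_coding", "-", "LSC", c(exon = 699)),
    g("clpP",  "protein_coding", "-", "LSC",
      c(exon = 213, intron = 250, exon = 279, intron = 250, exon = 69)),
    g("psbB",  "protein_coding", "+", "LSC", c(exon = 759)),
    g("ndhC",  "protein_coding", "-", "LSC", c(exon = 360)),
    g("ndhK",  "protein_coding", "-", "LSC", c(exon = 450)),
    g("ndhJ",  "protein_coding", "-", "LSC", c(exon = 480)),
    g("rps8",  "protein_coding", "+", "LSC", c(exon = 399)),
    g("rpl14", "protein_coding", "+", "LSC", c(exon = 369)),
    g("trnT",  "tRNA",           "+", "LSC", c(exon = 72)),
    g("trnL",  "tRNA",           "+", "LSC", c(exon = 50, intron = 200, exon = 35)),
    ## IRb
    g("rrn16", "rRNA",           "+", "IRb", c(exon = 900)),
    g("rrn23", "rRNA",           "+", "IRb", c(exon = 1500)),
    g("ndhB",  "protein_coding", "-", "IRb", c(exon = 381, intron = 230, exon = 360)),
    ## SSC (genomic order from the IRb/SSC junction)
    g("ndhF",  "protein_coding", "-", "SSC", c(exon = 600)),
    g("rpl32", "protein_coding", "+", "SSC", c(exon = 168)),
    g("ccsA",  "protein_coding", "+", "SSC", c(exon = 321)),
    g("ndhD",  "protein_coding", "-", "SSC", c(exon = 399)),
    g("psaC",  "protein_coding", "-", "SSC", c(exon = 246)),
    g("ndhE",  "protein_coding", "-", "SSC", c(exon = 303)),
    g("ndhG",  "protein_coding", "-", "SSC", c(exon = 351)),
    g("ndhI",  "protein_coding", "-", "SSC", c(exon = 399)),
    g("ndhA",  "protein_coding", "-", "SSC", c(exon = 450, intron = 400, exon = 450)),
    g("ndhH",  "protein_coding", "-", "SSC", c(exon = 489)),
    g("rps15", "protein_coding", "-", "SSC", c(exon = 270))
  )
}

.default_ssr_plan <- function() {
  data.frame(
    motif = c("A", "T", "A", "AT", "TA", "AG", "AAT", "ATC", "AGGT",
              "AATAG", "AATCGC", "T"),
    unitCount = c(10L, 12L, 8L, 6L, 5L, 5L, 4L, 3L, 3L, 3L, 3L, 9L),
    stringsAsFactors = FALSE)
}

.default_repeat_plan <- function() {
  data.frame(
    kind = c("forward", "forward", "palindromic", "palindromic",
             "reverse", "forward"),
    length = c(40L, 32L, 36L, 48L, 34L, 50L),
    stringsAsFactors = FALSE)
}

.default_hotspots <- function() {
  c("ndhA intron" = 6, "trnK-matK" = 5.5, "clpP-psbB" = 5,
    "rps8-rpl14" = 4.5, "trnT-trnL" = 4, "psbK-trnS" = 3.5,
    "trnS-psbC" = 3, "ndhF-rpl32" = 2.8, "clpP intron 1" = 2.6,
    "rpl32-ccsA" = 2.4)
}

#' Build a simulation configuration
#'
#' The configuration fixes the study conditions for a simulated plastome:
#' region length targets, the gene complement, per-locus substitution and
#' indel rates, the planted SSR and dispersed-repeat elements, the ycf1
#' junction overhang, and the ndh-loss scenario. The same configuration
#' always produces byte-identical output.
#'
#' @param seed integer RNG seed.
#' @param lsc,ssc,ir target region lengths in bp (spacers are sized so the
#'   targets are met exactly; an overfull region is a configuration error).
#' @param genes gene complement, as [simConfig()]'s default shows; each
#'   entry has `name`, `category`, `strand`, `region` and a `parts` vector
#'   of exon/intron lengths in transcription order.
#' @param ycf1Body,ycf1Overhang bp of ycf1 in the SSC and in the IRa
#'   (distance from the ycf1 5' end to the SSC/IRa junction; 991 bp is the
#'   stable type-A architecture). The body is adjusted by up to 2 bp so
#'   the CDS length is a codon multiple.
#' @param pSubCoding,pSubNonCoding per-site substitution probabilities
#'   between the two descendants of a pair (each descendant receives half).
#' @param indelCoding,indelNonCoding expected indel events per locus
#'   between the two descendants.
#' @param irRateFactor multiplier applied to IR-resident loci (the IR
#'   evolves in concert and more slowly than single-copy regions).
#' @param indelMeanLength mean of the geometric indel length law.
#' @param hotspots named multipliers of `pSubNonCoding` /
#'   `indelNonCoding` for selected non-coding loci (the planted mutational
#'   hotspots).
#' @param minSpacer minimum spacer length in bp.
#' @param atRichness AT fraction of random non-coding sequence.
#' @param plantSSRs,plantRepeats data.frames describing planted elements
#'   (`motif`/`unitCount`; `kind`/`length`), or `NULL` to plant nothing.
#' @param scenario an ndh-loss scenario from [scenarioConfig()].
#' @return a `simConfig` list.
#' @export
simConfig <- function(seed = 1L, lsc = 12600L, ssc = 8400L, ir = 5400L,
                      genes = .default_gene_set(),
                      ycf1Body = 1200L, ycf1Overhang = 991L,
                      pSubCoding = 0.0085, pSubNonCoding = 0.011,
                      indelCoding = 0.1, indelNonCoding = 0.5,
                      irRateFactor = 0.25, indelMeanLength = 3,
                      hotspots = .default_hotspots(),
                      minSpacer = 150L, atRichness = 0.64,
                      plantSSRs = .default_ssr_plan(),
                      plantRepeats = .default_repeat_plan(),
                      scenario = scenarioConfig("A")) {
  ## keep the ycf1 CDS a codon multiple by nudging the body length
  total <- ycf1Body + ycf1Overhang
  ycf1Body <- ycf1Body + (3L - total %% 3L) %% 3L
  cfg <- list(seed = as.integer(seed), lsc = as.integer(lsc),
              ssc = as.integer(ssc), ir = as.integer(ir), genes = genes,
              ycf1Body = as.integer(ycf1Body),
              ycf1Overhang = as.integer(ycf1Overhang),
              pSubCoding = pSubCoding, pSubNonCoding = pSubNonCoding,
              indelCoding = indelCoding, indelNonCoding = indelNonCoding,
              irRateFactor = irRateFactor,
              indelMeanLength = indelMeanLength, hotspots = hotspots,
              minSpacer = as.integer(minSpacer), atRichness = atRichness,
              plantSSRs = plantSSRs, plantRepeats = plantRepeats,
              scenario = scenario)
  stopifnot(cfg$pSubCoding >= 0, cfg$pSubCoding < 1,
            cfg$pSubNonCoding >= 0, cfg$pSubNonCoding < 1,
            cfg$lsc > 0, cfg$ssc > 0, cfg$ir > 0)
  class(cfg) <- "simConfig"
  cfg
}

#' Describe an ndh-loss scenario
#'
#' @param label `"A"` (all 11 ndh genes intact, no junction shift), `"B"`
#'   (every ndh gene deleted, IR expanded by `irShift` bp) or `"C"` (the
#'   named ndh genes truncated to pseudogene remnants or deleted; the
#'   SSC/IRa junction then shifts by `slope` times the retained ndh length,
#'   plus optional gaussian noise).
#' @param pseudogenize named numeric vector: gene -> retained 5' fraction.
#' @param remove character vector of ndh genes to delete outright.
#' @param slope junction-shift bp per retained ndh bp (default 0.136).
#' @param noiseSd gaussian noise (bp) added to the shift; 0 for exact.
#' @param irShift fixed IR expansion for scenario B, in bp.
#' @return a scenario list for [simConfig()] / [applyScenario()].
#' @export
scenarioConfig <- function(label = c("A", "B", "C"),
                           pseudogenize = c(ndhF = 0.5, ndhA = 0.6),
                           remove = c("ndhD", "ndhE", "ndhG"),
                           slope = 0.136, noiseSd = 0, irShift = 600L) {
  label <- match.arg(label)
  list(label = label, pseudogenize = pseudogenize, remove = remove,
       slope = slope, noiseSd = noiseSd, irShift = as.integer(irShift))
}

## ---- segment-table construction -----------------------------------------

## rows: region, kind (spacer/exon/intron/psi_ycf1/ycf1_body), gene,
## partTx, strand, category, pseudo, locus, frameOff, pSub, indelRate,
## seq; plus planted-element bookkeeping in attr "elements"
.build_rows <- function(cfg) {
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- list(...)

  ## ycf1 sense sequence: head (overhang, in IRa) + tail (body, in SSC)
  ycf1_len <- cfg$ycf1Body + cfg$ycf1Overhang
  ycf1_sense <- .random_cds(ycf1_len)
  ycf1_head <- substr(ycf1_sense, 1L, cfg$ycf1Overhang)
  ycf1_tail <- substr(ycf1_sense, cfg$ycf1Overhang + 1L, ycf1_len)

  spacer_name <- function(left, right) paste0(left, "-", right)

  for (region in c("LSC", "IRb", "SSC")) {
    genes <- Filter(function(g) g$region == region, cfg$genes)
    gene_len <- sum(vapply(genes, function(g) sum(g$parts), 1))
    extra_fixed <- switch(region, IRb = cfg$ycf1Overhang,
                          SSC = cfg$ycf1Body, 0L)
    target <- switch(region, LSC = cfg$lsc, IRb = cfg$ir, SSC = cfg$ssc)
    n_sp <- length(genes) + 1L
    budget <- target - gene_len - extra_fixed - n_sp * cfg$minSpacer
    if (budget < 0)
      stop("configuration error: genes overflow region ", region,
           " by ", -budget, " bp")
    extra <- as.vector(stats::rmultinom(1L, budget, rep(1, n_sp)))
    sp_len <- cfg$minSpacer + extra

    ## neighbour names for spacer loci (the IRa mirror supplies the
    ## neighbours at the region edges of the canonical linearization)
    gnames <- vapply(genes, `[[`, "", "name")
    left_names <- switch(region,
      LSC = c("rrn16", gnames), IRb = c("trnL", gnames),
      SSC = c("ycf1", gnames))
    right_names <- switch(region,
      LSC = c(gnames, "rrn16"), IRb = c(gnames, "ycf1"),
      SSC = c(gnames, "ycf1"))

    for (i in seq_len(n_sp)) {
      nm <- spacer_name(left_names[i], right_names[i])
      add(region = region, kind = "spacer", gene = NA_character_,
          partTx = NA_integer_, strand = "+", category = NA_character_,
          pseudo = FALSE, locus = nm, frameOff = NA_integer_,
          seq = .random_dna(sp_len[i], cfg$atRichness))
      if (i <= length(genes)) {
        g <- genes[[i]]
        n_ex <- sum(names(g$parts) == "exon")
        cds_len <- sum(g$parts[names(g$parts) == "exon"])
        sense_parts <- character(length(g$parts))
        if (g$category == "protein_coding") {
          cds <- .random_cds(cds_len)
          off <- 0L
          for (k in seq_along(g$parts)) {
            if (names(g$parts)[k] == "exon") {
              sense_parts[k] <- substr(cds, off + 1L, off + g$parts[[k]])
              off <- off + g$parts[[k]]
            } else sense_parts[k] <- .random_dna(g$parts[[k]], cfg$atRichness)
          }
        } else {
          for (k in seq_along(g$parts))
            sense_parts[k] <- .random_dna(g$parts[[k]], 0.5)
        }
        ord <- seq_along(g$parts)
        if (g$strand == "-") ord <- rev(ord)       # genomic order
        intr_i <- 0L
        part_locus <- character(length(g$parts))
        for (k in seq_along(g$parts)) {
          if (names(g$parts)[k] == "intron") {
            intr_i <- intr_i + 1L
            part_locus[k] <- if (sum(names(g$parts) == "intron") > 1L)
              paste(g$name, "intron", intr_i) else paste(g$name, "intron")
          } else part_locus[k] <- g$name
        }
        for (k in ord) {
          typ <- names(g$parts)[k]
          sq <- sense_parts[k]
          if (g$strand == "-") sq <- .revcomp_chr(sq)
          add(region = region, kind = typ, gene = g$name,
              partTx = k, strand = g$strand, category = g$category,
              pseudo = FALSE, locus = part_locus[k],
              frameOff = NA_integer_,   # filled in after assembly below
              seq = sq)
        }
      }
    }
    if (region == "IRb")
      add(region = "IRb", kind = "psi_ycf1", gene = "ycf1",
          partTx = 1L, strand = "+", category = "protein_coding",
          pseudo = TRUE, locus = "ycf1", frameOff = 0L, seq = ycf1_head)
    if (region == "SSC")
      add(region = "SSC", kind = "ycf1_body", gene = "ycf1",
          partTx = 2L, strand = "-", category = "protein_coding",
          pseudo = FALSE, locus = "ycf1",
          frameOff = cfg$ycf1Overhang %% 3L,
          seq = .revcomp_chr(ycf1_tail))
  }

  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  df$id <- seq_len(nrow(df))

  ## frame offsets for exon rows (cumulative CDS length before each exon)
  for (gn in unique(stats::na.omit(df$gene))) {
    idx <- which(df$gene == gn & df$kind == "exon")
    if (!length(idx)) next
    idx <- idx[order(df$partTx[idx])]
    lens <- nchar(df$seq[idx])
    df$frameOff[idx] <- as.integer(c(0L, cumsum(lens))[seq_along(idx)] %% 3L)
  }

  ## per-row mutation rates
  df$len <- nchar(df$seq)
  coding <- df$kind %in% c("exon", "ycf1_body", "psi_ycf1") &
    df$category %in% "protein_coding"
  df$pSub <- ifelse(coding, cfg$pSubCoding, cfg$pSubNonCoding)
  df$indelRate <- ifelse(coding, cfg$indelCoding, cfg$indelNonCoding)
  hot <- cfg$hotspots[df$locus]
  hot[is.na(hot)] <- 1
  df$pSub <- df$pSub * hot
  df$indelRate <- df$indelRate * hot
  in_ir <- df$region == "IRb"
  df$pSub[in_ir] <- df$pSub[in_ir] * cfg$irRateFactor
  df$indelRate[in_ir] <- 0      # IR indels disabled: junctions stay put
  df
}

## ---- planting ------------------------------------------------------------

## embed planted elements into spacer rows; returns rows + element tables
## with row ids and in-row coordinates (absolute coords are added after
## assembly)
.plant_elements <- function(rows, cfg) {
  ssrs <- cfg$plantSSRs
  reps <- cfg$plantRepeats
  n_ssr <- if (is.null(ssrs)) 0L else nrow(ssrs)
  n_rep <- if (is.null(reps)) 0L else nrow(reps)
  host_pool <- which(rows$kind == "spacer" & rows$region != "IRb")
  need <- n_ssr + 2L * n_rep
  host_pool <- host_pool[order(-rows$len[host_pool])]
  if (length(host_pool) < need)
    stop("not enough spacers to host the planted elements")
  hosts <- sample(host_pool[seq_len(max(need, min(length(host_pool),
                                                  need + 4L)))], need)

  ssr_tab <- rep_tab <- NULL
  hi <- 1L
  if (n_ssr) {
    recs <- list()
    for (i in seq_len(n_ssr)) {
      row <- hosts[hi]; hi <- hi + 1L
      motif <- ssrs$motif[i]; cnt <- ssrs$unitCount[i]
      u <- nchar(motif); el <- u * cnt
      sl <- rows$len[row]
      pos <- max(4L, (sl - el) %/% 2L)
      sp <- .chars(rows$seq[row])
      sp[pos:(pos + el - 1L)] <- .chars(strrep(motif, cnt))
      sp[pos - 1L] <- .pick_base_not(substr(motif, u, u))
      sp[pos + el] <- .pick_base_not(substr(motif, 1L, 1L))
      rows$seq[row] <- .paste0v(sp)
      recs[[i]] <- data.frame(motif = motif, unitLength = u,
                              unitCount = cnt, row = rows$id[row],
                              relStart = pos, relEnd = pos + el - 1L,
                              stringsAsFactors = FALSE)
    }
    ssr_tab <- do.call(rbind, recs)
  }
  if (n_rep) {
    recs <- list()
    for (i in seq_len(n_rep)) {
      rowA <- hosts[hi]; rowB <- hosts[hi + 1L]; hi <- hi + 2L
      if (rows$id[rowA] > rows$id[rowB]) { tmp <- rowA; rowA <- rowB; rowB <- tmp }
      kind <- reps$kind[i]; len <- reps$length[i]
      for (attempt in 1:50) {
        copy1 <- .random_dna(len, 0.5)
        copy2 <- switch(kind, forward = copy1,
                        palindromic = .revcomp_chr(copy1),
                        reverse = .rev_chr(copy1))
        ## exactly three clustered central mismatches: together with the
        ## enforced mismatching flanks this makes the maximal-window
        ## family collapse to the planted pair alone (see vignette)
        c2 <- .chars(copy2)
        mid <- len %/% 2L
        for (m in (mid - 1L):(mid + 1L)) c2[m] <- .pick_base_not(c2[m])
        copy2 <- .paste0v(c2)
        emb <- function(sp, cp) {
          pos <- max(4L, (length(sp) - nchar(cp)) %/% 2L)
          sp[pos:(pos + nchar(cp) - 1L)] <- .chars(cp)
          list(sp = sp, pos = pos)
        }
        eA <- emb(.chars(rows$seq[rowA]), copy1)
        eB <- emb(.chars(rows$seq[rowB]), copy2)
        spA <- eA$sp; spB <- eB$sp
        posA <- eA$pos; posB <- eB$pos
        endA <- posA + len - 1L; endB <- posB + len - 1L
        ## enforce two mismatching flank bases at every copy boundary so
        ## the maximal window cannot extend past the planted pair
        if (kind == "forward") {
          for (o in 1:2) {
            spB[posB - o] <- .pick_base_not(spA[posA - o])
            spB[endB + o] <- .pick_base_not(spA[endA + o])
          }
        } else if (kind == "palindromic") {
          for (o in 1:2) {
            spB[endB + o] <- .pick_base_not(.COMP[[spA[posA - o]]])
            spB[posB - o] <- .pick_base_not(.COMP[[spA[endA + o]]])
          }
        } else {
          for (o in 1:2) {
            spB[endB + o] <- .pick_base_not(spA[posA - o])
            spB[posB - o] <- .pick_base_not(spA[endA + o])
          }
        }
        ## the copies and enforced flanks are protected from later
        ## resampling, so they must be SSR-free from the start
        winA <- .paste0v(spA[(posA - 2L):(endA + 2L)])
        winB <- .paste0v(spB[(posB - 2L):(endB + 2L)])
        if (nrow(findSSRs(winA)) == 0L && nrow(findSSRs(winB)) == 0L) {
          rows$seq[rowA] <- .paste0v(spA)
          rows$seq[rowB] <- .paste0v(spB)
          break
        }
        if (attempt == 50L)
          stop("could not draw an SSR-free repeat copy of ", len, " bp")
      }
      recs[[i]] <- data.frame(kind = kind, length = len, mismatches = 3L,
                              row1 = rows$id[rowA], rel1 = posA,
                              row2 = rows$id[rowB], rel2 = posB,
                              stringsAsFactors = FALSE)
    }
    rep_tab <- do.call(rbind, recs)
  }
  rows$len <- nchar(rows$seq)
  list(rows = rows,
       ssrs = if (is.null(ssr_tab))
         data.frame(motif = character(), unitLength = integer(),
                    unitCount = integer(), row = integer(),
                    relStart = integer(), relEnd = integer()) else ssr_tab,
       repeats = if (is.null(rep_tab))
         data.frame(kind = character(), length = integer(),
                    mismatches = integer(), row1 = integer(),
                    rel1 = integer(), row2 = integer(), rel2 = integer())
       else rep_tab)
}

## ---- assembly ------------------------------------------------------------

## rows -> plastome + partition + per-row absolute offsets
.assemble <- function(rows, cfg, identifier = "sim") {
  rows$len <- nchar(rows$seq)

  ## enforce mismatching bases just outside the IR boundaries so the
  ## detected IR equals the planted IR exactly; the edited bases belong to
  ## the region's first spacer, never to coding sequence
  fix2 <- function(headRow, tailRow) {
    head_sp <- .chars(rows$seq[headRow]); tail_sp <- .chars(rows$seq[tailRow])
    nt <- length(tail_sp)
    for (o in 1:2) {
      if (head_sp[o] == .COMP[[tail_sp[nt - o + 1L]]])
        head_sp[o] <- .pick_base_not(.COMP[[tail_sp[nt - o + 1L]]])
    }
    rows$seq[headRow] <<- .paste0v(head_sp)
  }
  lsc_rows <- which(rows$region == "LSC")
  ssc_rows <- which(rows$region == "SSC")
  fix2(lsc_rows[1L], lsc_rows[length(lsc_rows)])
  fix2(ssc_rows[1L], ssc_rows[length(ssc_rows)])
  rows$len <- nchar(rows$seq)

  lsc_str <- .paste0v(rows$seq[rows$region == "LSC"])
  irb_str <- .paste0v(rows$seq[rows$region == "IRb"])
  ssc_str <- .paste0v(rows$seq[rows$region == "SSC"])
  genome <- paste0(lsc_str, irb_str, ssc_str, .revcomp_chr(irb_str))
  L <- nchar(genome)
  lscW <- nchar(lsc_str); irW <- nchar(irb_str); sscW <- nchar(ssc_str)

  part <- RegionPartition(c(1L, lscW), c(lscW + 1L, lscW + irW),
                          c(lscW + irW + 1L, lscW + irW + sscW),
                          c(lscW + irW + sscW + 1L, L), L)

  ## absolute row offsets (row i occupies absStart..absEnd)
  ord <- order(match(rows$region, c("LSC", "IRb", "SSC")), rows$id)
  rows <- rows[ord, ]
  rows$absStart <- cumsum(c(1L, rows$len))[seq_len(nrow(rows))]
  rows$absEnd <- rows$absStart + rows$len - 1L

  ## features
  ft_name <- character(); ft_cat <- character(); ft_strand <- character()
  ft_pseudo <- logical(); ft_segs <- list()
  addf <- function(nm, cat, strand, pseudo, segs) {
    ft_name <<- c(ft_name, nm); ft_cat <<- c(ft_cat, cat)
    ft_strand <<- c(ft_strand, strand); ft_pseudo <<- c(ft_pseudo, pseudo)
    ft_segs[[length(ft_segs) + 1L]] <<- segs
  }
  irbS <- start(part@irb); irbE <- end(part@irb)
  iraS <- start(part@ira)
  mirror <- function(iv)   # map an IRb interval to its IRa image
    IRanges(iraS + (irbE - end(iv)), iraS + (irbE - start(iv)))

  for (gn in unique(stats::na.omit(rows$gene))) {
    if (gn == "ycf1") next
    idx <- which(rows$gene %in% gn & rows$kind == "exon")
    strand <- rows$strand[idx[1]]
    exons <- IRanges(rows$absStart[idx], rows$absEnd[idx])
    txo <- order(rows$partTx[idx])
    exons <- exons[txo]
    addf(gn, rows$category[idx[1]], strand, any(rows$pseudo[idx]), exons)
    if (rows$region[idx[1]] == "IRb") {   # duplicated IR copy
      ## mirroring maps each exon to its IRa image and flips the strand;
      ## the segment order already reads in transcription order
      addf(gn, rows$category[idx[1]], if (strand == "+") "-" else "+",
           any(rows$pseudo[idx]), mirror(exons))
    }
  }
  ## ycf1: pseudo fragment at the IRb end + the real gene across J_SA
  psi <- which(rows$kind == "psi_ycf1")
  body <- which(rows$kind == "ycf1_body")
  if (length(psi)) {
    addf("ycf1", "protein_coding", "+", TRUE,
         IRanges(rows$absStart[psi], rows$absEnd[psi]))
    addf("ycf1", "protein_coding", "-", FALSE,
         IRanges(rows$absStart[body],
                 rows$absEnd[body] + (rows$absEnd[psi] - rows$absStart[psi] + 1L)))
  }
  ft <- featureTable(ft_name, ft_cat, ft_strand, ft_pseudo, ft_segs)
  p <- AnnotatedPlastome(identifier, genome, ft, circular = TRUE)
  list(plastome = p, partition = part, rows = rows)
}

## absolute coordinates of planted elements, given assembled rows
.absolute_elements <- function(asm, planted) {
  rows <- asm$rows
  ssrs <- planted$ssrs
  if (nrow(ssrs)) {
    o <- rows$absStart[match(ssrs$row, rows$id)] - 1L
    ssrs$start <- ssrs$relStart + o
    ssrs$end <- ssrs$relEnd + o
  } else { ssrs$start <- integer(); ssrs$end <- integer() }
  reps <- planted$repeats
  if (nrow(reps)) {
    o1 <- rows$absStart[match(reps$row1, rows$id)] - 1L
    o2 <- rows$absStart[match(reps$row2, rows$id)] - 1L
    reps$start1 <- reps$rel1 + o1
    reps$end1 <- reps$start1 + reps$length - 1L
    reps$start2 <- reps$rel2 + o2
    reps$end2 <- reps$start2 + reps$length - 1L
  } else {
    reps$start1 <- reps$end1 <- reps$start2 <- reps$end2 <- integer()
  }
  list(ssrs = ssrs, repeats = reps)
}

## compare found vs planted; returns offending absolute positions (empty
## when the genome is clean)
.cleanliness_offenders <- function(asm, truth_elem) {
  bad <- integer()
  found <- findSSRs(asm$plastome)
  key <- function(d) paste(d$motif, d$unitCount, d$start, d$end)
  planted_keys <- key(truth_elem$ssrs)
  fk <- key(found)
  extra <- found[!(fk %in% planted_keys), , drop = FALSE]
  missing <- truth_elem$ssrs[!(planted_keys %in% fk), , drop = FALSE]
  if (nrow(extra)) bad <- c(bad, unlist(Map(seq, extra$start, extra$end)))
  if (nrow(missing)) bad <- c(bad, unlist(Map(seq, missing$start, missing$end)))

  foundR <- findRepeats(asm$plastome, partition = asm$partition)
  keyR <- function(d) paste(d$kind, d$start1, d$end1, d$start2, d$end2)
  pk <- keyR(truth_elem$repeats)
  fkR <- keyR(foundR)
  extraR <- foundR[!(fkR %in% pk), , drop = FALSE]
  missR <- truth_elem$repeats[!(pk %in% fkR), , drop = FALSE]
  if (nrow(extraR))
    bad <- c(bad, unlist(Map(seq, extraR$start1, extraR$end1)),
             unlist(Map(seq, extraR$start2, extraR$end2)))
  if (nrow(missR))
    bad <- c(bad, unlist(Map(seq, missR$start1, missR$end1)),
             unlist(Map(seq, missR$start2, missR$end2)))
  unique(bad)
}

#' Generate a synthetic ancestral plastome
#'
#' Builds the quadripartite genome described by a [simConfig()]: genes are
#' placed in order with random repeat-free spacers sized to meet the region
#' length targets exactly, the planted SSR and dispersed-repeat elements
#' are embedded, and the assembled genome is verified with the package's
#' own SSR and repeat finders -- any unplanned hit (random sequence does
#' occasionally contain a short SSR) causes the offending segments to be
#' resampled until the census reports exactly the planted elements. The
#' result is deterministic for a given configuration.
#'
#' @param cfg a [simConfig()].
#' @param identifier plastome id for the output.
#' @return a list with `plastome` (an [AnnotatedPlastome-class]) and
#'   `truth` (a [SimTruth-class] ledger).
#' @export
generateAncestor <- function(cfg, identifier = paste0("sim", cfg$seed)) {
  .with_seed(cfg$seed, {
    rows <- .build_rows(cfg)
    planted <- .plant_elements(rows, cfg)
    rows <- planted$rows
    vc <- .verify_clean(rows, planted, cfg, identifier)
    asm <- vc$asm
    elem <- .absolute_elements(asm, planted)
    truth <- new("SimTruth", partition = asm$partition, loci = asm$rows,
                 ssrs = elem$ssrs, repeats = elem$repeats,
                 mutations = data.frame(), scenario = "A",
                 retainedNdhLength = .retained_ndh(asm$plastome),
                 config = unclass(cfg))
    list(plastome = asm$plastome, truth = truth)
  })
}

## regenerate the random content of the given row ids (keeping any planted
## element they host)
.resample_rows <- function(rows, ids, planted, cfg) {
  for (id in ids) {
    i <- which(rows$id == id)
    if (!length(i)) next
    k <- rows$kind[i]
    if (k == "spacer") {
      ## regenerate random sequence, but protect any hosted planted
      ## element together with its enforced flank bases
      old <- .chars(rows$seq[i])
      new <- .chars(.random_dna(rows$len[i], cfg$atRichness))
      protect <- rep(FALSE, rows$len[i])
      s_idx <- which(planted$ssrs$row == id)
      for (j in s_idx) {
        e <- planted$ssrs[j, ]
        protect[max(1L, e$relStart - 1L):min(rows$len[i], e$relEnd + 1L)] <- TRUE
      }
      r_idx <- which(planted$repeats$row1 == id)
      for (j in r_idx) {
        e <- planted$repeats[j, ]
        protect[max(1L, e$rel1 - 2L):
                  min(rows$len[i], e$rel1 + e$length + 1L)] <- TRUE
      }
      r_idx <- which(planted$repeats$row2 == id)
      for (j in r_idx) {
        e <- planted$repeats[j, ]
        protect[max(1L, e$rel2 - 2L):
                  min(rows$len[i], e$rel2 + e$length + 1L)] <- TRUE
      }
      new[protect] <- old[protect]
      rows$seq[i] <- .paste0v(new)
    } else if (k %in% c("exon", "intron")) {
      gn <- rows$gene[i]
      g_idx <- which(rows$gene %in% gn & rows$kind %in% c("exon", "intron"))
      exo <- g_idx[rows$kind[g_idx] == "exon"]
      exo <- exo[order(rows$partTx[exo])]
      if (rows$category[i] == "protein_coding") {
        cds <- .random_cds(sum(rows$len[exo]))
        off <- 0L
        for (e2 in exo) {
          sq <- substr(cds, off + 1L, off + rows$len[e2])
          off <- off + rows$len[e2]
          rows$seq[e2] <- if (rows$strand[e2] == "-") .revcomp_chr(sq) else sq
        }
      } else {
        for (e2 in exo) rows$seq[e2] <- .random_dna(rows$len[e2], 0.5)
      }
      for (in2 in g_idx[rows$kind[g_idx] == "intron"])
        rows$seq[in2] <- .random_dna(rows$len[in2], cfg$atRichness)
    } else if (k %in% c("psi_ycf1", "ycf1_body")) {
      psi <- which(rows$kind == "psi_ycf1")
      body <- which(rows$kind == "ycf1_body")
      sense <- .random_cds(rows$len[psi] + rows$len[body])
      rows$seq[psi] <- substr(sense, 1L, rows$len[psi])
      rows$seq[body] <- .revcomp_chr(substr(sense, rows$len[psi] + 1L,
                                            nchar(sense)))
    }
  }
  rows
}

## shared verification loop: assemble `rows`, check that the production
## SSR / repeat finders report exactly the planted elements, resample
## offending segments until clean
.verify_clean <- function(rows, planted, cfg, identifier) {
  asm <- NULL
  for (iter in 1:25) {
    asm <- .assemble(rows, cfg, identifier)
    elem <- .absolute_elements(asm, planted)
    bad <- .cleanliness_offenders(asm, elem)
    if (!length(bad)) return(list(asm = asm, rows = rows))
    rowsS <- asm$rows
    hit_rows <- unique(rowsS$id[vapply(seq_len(nrow(rowsS)), function(i)
      any(bad >= rowsS$absStart[i] & bad <= rowsS$absEnd[i]), TRUE)])
    ira <- asm$partition@ira
    bad_ira <- bad[bad >= start(ira) & bad <= end(ira)]
    if (length(bad_ira)) {   # a hit inside IRa maps back to its IRb source
      mirrored <- start(asm$partition@irb) + (end(ira) - bad_ira)
      hit_rows <- unique(c(hit_rows,
        rowsS$id[vapply(seq_len(nrow(rowsS)), function(i)
          any(mirrored >= rowsS$absStart[i] &
                mirrored <= rowsS$absEnd[i]), TRUE)]))
    }
    rows <- .resample_rows(rows, hit_rows, planted, cfg)
  }
  stop("could not generate an element-clean genome in 25 attempts")
}

## reconstruct the ycf1 sense CDS from its two rows
.ycf1_sense <- function(rows) {
  psi <- which(rows$kind == "psi_ycf1")
  body <- which(rows$kind == "ycf1_body")
  paste0(rows$seq[psi], .revcomp_chr(rows$seq[body]))
}

## move `shift` bases of the ycf1 body into the IR overhang (IR expansion)
.shift_jsa <- function(rows, shift) {
  if (shift == 0L) return(rows)
  psi <- which(rows$kind == "psi_ycf1")
  body <- which(rows$kind == "ycf1_body")
  sense <- .ycf1_sense(rows)
  ov <- nchar(rows$seq[psi]) + shift
  if (ov < 1L || ov > nchar(sense) - 30L)
    stop("junction shift of ", shift, " bp exceeds the ycf1 body")
  rows$seq[psi] <- substr(sense, 1L, ov)
  rows$seq[body] <- .revcomp_chr(substr(sense, ov + 1L, nchar(sense)))
  rows$len <- nchar(rows$seq)
  rows
}

## retained ndh length directly from a segment table (IR copies once)
.retained_ndh_rows <- function(rows) {
  idx <- which(rows$gene %in% NDH_GENES & rows$kind == "exon")
  sum(nchar(rows$seq[idx]))
}

#' Evolve a plastome pair from a common ancestor
#'
#' Applies two independent draws of the mutation process to the ancestor
#' (a star genealogy, so expected pairwise divergence is additive): every
#' site of a locus is substituted with probability `pSub/2` per descendant
#' (uniform alternative base; the start and stop codons of a CDS are
#' protected and substitutions creating internal stops are redrawn), and
#' each locus receives a Poisson(`indelRate/2`) number of indels per
#' descendant with geometric lengths, positions uniform, coding indels
#' codon-aligned and a multiple of 3, and indels never overlapping planted
#' elements. IR-resident loci mutate in concert (the mutation is present
#' in both IR copies) at a reduced rate, and IR indels are disabled so
#' junctions stay put. Annotations are lifted through all indels.
#'
#' @param ancestor result of [generateAncestor()].
#' @param cfg the [simConfig()] that produced the ancestor.
#' @return a list with `genome1`, `genome2` (each an
#'   [AnnotatedPlastome-class]) and `truth` (a [SimTruth-class] whose
#'   `mutations` ledger records every planted substitution and indel).
#' @export
evolvePair <- function(ancestor, cfg) {
  truth <- ancestor$truth
  base_rows <- truth@loci
  planted <- list(rows = base_rows, ssrs = truth@ssrs,
                  repeats = truth@repeats)
  .with_seed(cfg$seed + 500000L, {
    out <- list()
    ledger <- list()
    cds_len <- vapply(base_rows$gene, function(g) {
      if (is.na(g)) return(NA_integer_)
      idx <- base_rows$gene %in% g &
        base_rows$kind %in% c("exon", "psi_ycf1", "ycf1_body")
      sum(nchar(base_rows$seq[idx]))
    }, 1L)
    locus_len <- tapply(nchar(base_rows$seq), base_rows$locus, sum)

    for (k in 1:2) {
      rows <- base_rows
      for (i in seq_len(nrow(rows))) {
        coding <- rows$kind[i] %in% c("exon", "psi_ycf1", "ycf1_body") &&
          identical(rows$category[i], "protein_coding")
        mut <- .mutate_part(
          rows$seq[i], strand = rows$strand[i], coding = coding,
          frameOff = rows$frameOff[i], cdsLen = cds_len[i],
          pSub = rows$pSub[i] / 2,
          indelMean = cfg$indelMeanLength,
          nIndel = stats::rpois(1L, rows$indelRate[i] / 2 *
                                  nchar(rows$seq[i]) /
                                  locus_len[[rows$locus[i]]]),
          mask = .planted_mask(rows$id[i], planted, nchar(rows$seq[i])))
        rows$seq[i] <- mut$seq
        if (nrow(mut$ledger)) {
          mut$ledger$genome <- k
          mut$ledger$locus <- rows$locus[i]
          mut$ledger$row <- rows$id[i]
          ledger[[length(ledger) + 1L]] <- mut$ledger
        }
      }
      rows$len <- nchar(rows$seq)
      asm <- .assemble(rows, cfg, paste0(identifier(ancestor$plastome),
                                         "_d", k))
      out[[k]] <- asm$plastome
    }
    mutations <- if (length(ledger)) do.call(rbind, ledger) else
      data.frame(type = character(), pos = integer(), length = integer(),
                 ref = character(), alt = character(), genome = integer(),
                 locus = character(), row = integer())
    truth2 <- new("SimTruth", partition = truth@partition,
                  loci = base_rows, ssrs = truth@ssrs,
                  repeats = truth@repeats, mutations = mutations,
                  scenario = truth@scenario,
                  retainedNdhLength = truth@retainedNdhLength,
                  config = unclass(cfg))
    list(genome1 = out[[1L]], genome2 = out[[2L]], truth = truth2)
  })
}

## in-row positions that indels must avoid (planted elements +- 2 bp)
.planted_mask <- function(id, planted, len) {
  mask <- rep(FALSE, len)
  s_idx <- which(planted$ssrs$row == id)
  for (j in s_idx) {
    e <- planted$ssrs[j, ]
    mask[max(1L, e$relStart - 2L):min(len, e$relEnd + 2L)] <- TRUE
  }
  for (col in c("row1", "row2")) {
    rel <- if (col == "row1") "rel1" else "rel2"
    r_idx <- which(planted$repeats[[col]] == id)
    for (j in r_idx) {
      e <- planted$repeats[j, ]
      mask[max(1L, e[[rel]] - 4L):
             min(len, e[[rel]] + e$length + 3L)] <- TRUE
    }
  }
  mask
}

## mutate one genomic segment; works in sense space for coding parts so
## reading frames and stop codons can be respected
.mutate_part <- function(seq, strand, coding, frameOff, cdsLen,
                         pSub, indelMean, nIndel, mask) {
  n <- nchar(seq)
  ledger <- list()
  sense <- if (coding && strand == "-") .revcomp_chr(seq) else seq
  x <- .chars(sense)
  if (coding && strand == "-") mask <- rev(mask)
  frameOff <- if (is.na(frameOff)) 0L else frameOff

  ## substitutions (planted elements are left untouched so the planted
  ## truth survives into the descendants)
  hit <- which(stats::runif(n) < pSub)
  for (pos in hit) {
    if (length(mask) == length(x) && mask[pos]) next
    if (coding) {
      gpos <- frameOff + pos                   # position within the CDS
      if (gpos <= 3L || gpos > cdsLen - 3L) next
    }
    ref <- x[pos]
    if (!ref %in% c("A", "C", "G", "T")) next
    alts <- setdiff(c("A", "C", "G", "T"), ref)
    alt <- sample(alts, 1L)
    if (coding) {
      cs <- pos - ((frameOff + pos - 1L) %% 3L)  # codon start in part coords
      if (cs >= 1L && cs + 2L <= length(x)) {
        for (try in seq_along(alts)) {
          cod <- x[cs:(cs + 2L)]
          cod[pos - cs + 1L] <- alt
          if (!(.paste0v(cod) %in% STOP_CODONS)) break
          alt <- alts[(match(alt, alts) %% length(alts)) + 1L]
        }
        cod <- x[cs:(cs + 2L)]
        cod[pos - cs + 1L] <- alt
        if (.paste0v(cod) %in% STOP_CODONS) next
      }
    }
    x[pos] <- alt
    ledger[[length(ledger) + 1L]] <- data.frame(
      type = "sub", pos = pos, length = 1L, ref = ref, alt = alt,
      stringsAsFactors = FALSE)
  }

  ## indels
  for (ii in seq_len(nIndel)) {
    raw <- 1L + stats::rgeom(1L, prob = 1 / indelMean)
    del <- stats::runif(1L) < 0.5
    l <- if (coding) 3L * raw else raw
    placed <- FALSE
    for (try in 1:20) {
      if (coding) {
        ## codon-aligned position within this part, clear of start/stop
        cand <- which((frameOff + seq_len(length(x)) - 1L) %% 3L == 0L)
        cand <- cand[frameOff + cand > 3L &
                       frameOff + cand + l - 1L <= cdsLen - 3L &
                       cand + l - 1L <= length(x)]
      } else {
        cand <- seq_len(max(0L, length(x) - l - 2L))
        cand <- cand[cand > 2L]
      }
      if (!length(cand)) break
      pos <- sample(cand, 1L)
      span <- pos:(pos + l - 1L)
      mcur <- if (length(mask) == length(x)) mask else rep(FALSE, length(x))
      if (any(mcur[span[span <= length(mcur)]])) next
      if (del) {
        ref <- .paste0v(x[span])
        x <- x[-span]
        mask <- mcur[-span]
        ledger[[length(ledger) + 1L]] <- data.frame(
          type = "del", pos = pos, length = l, ref = ref, alt = "",
          stringsAsFactors = FALSE)
      } else {
        ins <- if (coding)
          paste(sample(.SENSE_CODONS, l / 3L, replace = TRUE),
                collapse = "") else .random_dna(l, 0.6)
        x <- append(x, .chars(ins), after = pos - 1L)
        mask <- append(mcur, rep(FALSE, l), after = pos - 1L)
        ledger[[length(ledger) + 1L]] <- data.frame(
          type = "ins", pos = pos, length = l, ref = "", alt = ins,
          stringsAsFactors = FALSE)
      }
      placed <- TRUE
      break
    }
  }

  sense2 <- .paste0v(x)
  list(seq = if (coding && strand == "-") .revcomp_chr(sense2) else sense2,
       ledger = if (length(ledger)) do.call(rbind, ledger) else
         data.frame(type = character(), pos = integer(), length = integer(),
                    ref = character(), alt = character()))
}

#' Apply an ndh-loss scenario to a type-A ancestor
#'
#' Scenario `A` is a no-op. Scenario `B` deletes all 11 ndh genes and
#' expands the IR into the SSC by the configured amount. Scenario `C`
#' deletes or pseudogenizes (truncates to a 5' remnant flagged as a
#' pseudogene) the configured ndh subset and then shifts the SSC/IRa
#' junction by `slope x retained-ndh-length` (plus optional noise),
#' mirroring the linear coupling between IR boundary shift and retained
#' ndh sequence. Junction shifts are realized by transferring ycf1 body
#' sequence into the IR overhang, so the ycf1-to-J_SA distance moves by
#' exactly the planted amount.
#'
#' @param ancestor result of [generateAncestor()] (a type-A genome).
#' @param scenario a [scenarioConfig()]; defaults to the one in the
#'   ancestor's configuration.
#' @param cfg the [simConfig()] of the ancestor.
#' @return a list with `plastome` and `truth`, like [generateAncestor()].
#' @export
applyScenario <- function(ancestor, scenario = NULL, cfg = NULL) {
  if (is.null(cfg)) cfg <- do.call(simConfig, ancestor$truth@config[
    intersect(names(ancestor$truth@config), names(formals(simConfig)))])
  if (is.null(scenario)) scenario <- cfg$scenario
  if (scenario$label == "A") {
    return(list(plastome = ancestor$plastome, truth = ancestor$truth))
  }
  truth <- ancestor$truth
  rows <- truth@loci
  planted <- list(rows = rows, ssrs = truth@ssrs, repeats = truth@repeats)
  .with_seed(cfg$seed + 900000L, {
    if (scenario$label == "B") {
      rows <- rows[!(rows$gene %in% NDH_GENES), , drop = FALSE]
      rows <- .shift_jsa(rows, scenario$irShift)
    } else {
      missing <- setdiff(c(names(scenario$pseudogenize), scenario$remove),
                         rows$gene)
      if (length(missing))
        stop("scenario references absent gene(s): ",
             paste(missing, collapse = ", "))
      rows <- rows[!(rows$gene %in% scenario$remove), , drop = FALSE]
      for (gn in names(scenario$pseudogenize)) {
        f <- scenario$pseudogenize[[gn]]
        idx <- which(rows$gene %in% gn & rows$kind %in% c("exon", "intron"))
        exo <- idx[rows$kind[idx] == "exon"]
        exo <- exo[order(rows$partTx[exo])]
        strand <- rows$strand[exo[1L]]
        sense <- .paste0v(vapply(exo, function(i)
          if (strand == "-") .revcomp_chr(rows$seq[i]) else rows$seq[i], ""))
        rem <- substr(sense, 1L, max(30L, round(f * nchar(sense))))
        keep <- idx[1L]
        rows$seq[keep] <- if (strand == "-") .revcomp_chr(rem) else rem
        rows$kind[keep] <- "exon"; rows$partTx[keep] <- 1L
        rows$pseudo[keep] <- TRUE
        rows$locus[keep] <- gn
        drop_idx <- setdiff(idx, keep)
        if (length(drop_idx)) rows <- rows[-drop_idx, , drop = FALSE]
      }
      retained <- .retained_ndh_rows(rows)
      shift <- as.integer(round(scenario$slope * retained +
                                  if (scenario$noiseSd > 0)
                                    stats::rnorm(1L, 0, scenario$noiseSd)
                                  else 0))
      rows <- .shift_jsa(rows, shift)
    }
    rows$len <- nchar(rows$seq)
    vc <- .verify_clean(rows, planted, cfg,
                        paste0(identifier(ancestor$plastome), "_",
                               tolower(scenario$label)))
    asm <- vc$asm
    elem <- .absolute_elements(asm, planted)
    truth2 <- new("SimTruth", partition = asm$partition, loci = asm$rows,
                  ssrs = elem$ssrs, repeats = elem$repeats,
                  mutations = data.frame(), scenario = scenario$label,
                  retainedNdhLength = .retained_ndh_rows(vc$rows),
                  config = unclass(cfg))
    list(plastome = asm$plastome, truth = truth2)
  })
}

#' Simulate a cohort of plastomes with known junction architecture
#'
#' Generates `n` independent ancestors (varying seeds and region-length
#' targets) and applies the requested scenario to each; for scenario `C`
#' the deleted/pseudogenized ndh subset is varied across the cohort so the
#' retained ndh lengths span a range, which is what the origin-constrained
#' regression of junction shift on retained length needs.
#'
#' @param n cohort size.
#' @param seed integer seed.
#' @param scenario `"A"`, `"B"` or `"C"`, or a vector over the cohort.
#' @param slope,noiseSd passed to [scenarioConfig()] for scenario C.
#' @param plant logical: plant SSR/repeat elements (default `FALSE`; the
#'   cohort is mainly for junction work where planting only costs time).
#' @return a list of `list(plastome, truth)` results.
#' @export
simulateCohort <- function(n = 10, seed = 1, scenario = "C",
                           slope = 0.136, noiseSd = 0, plant = FALSE) {
  scenario <- rep_len(scenario, n)
  ssc_pool <- c("ndhD", "ndhE", "ndhG", "ndhI", "ndhH")
  lapply(seq_len(n), function(i) {
    sc <- if (scenario[i] == "C") {
      k <- (i - 1L) %% (length(ssc_pool) + 1L)
      scenarioConfig("C",
        pseudogenize = stats::setNames(0.3 + 0.06 * (i %% 6),
                                       if (i %% 2L) "ndhF" else "ndhA"),
        remove = if (k > 0L) ssc_pool[seq_len(k)] else character(),
        slope = slope, noiseSd = noiseSd)
    } else scenarioConfig(scenario[i])
    cfg <- simConfig(seed = seed + 101L * i,
                     lsc = 12600L + 40L * (i %% 7L),
                     ssc = 8400L + 30L * (i %% 5L),
                     ir = 5400L + 20L * (i %% 3L),
                     plantSSRs = if (plant) .default_ssr_plan() else NULL,
                     plantRepeats = if (plant) .default_repeat_plan() else NULL,
                     scenario = sc)
    anc <- generateAncestor(cfg, identifier = paste0("cohort", i))
    applyScenario(anc, sc, cfg)
  })
}

#' Predicted SV\% of the simulated loci
#'
#' Closed-form expectation of the sequence-variability statistic under the
#' simulator's mutation model, per locus: each descendant substitutes a
#' site with probability `pSub/2` (two mutated copies still agree with
#' probability 1/3), indel events arrive at `indelRate` per locus pair,
#' and deletions shorten the conserved column count. Used as the
#' Monte-Carlo oracle for divergence-recovery tests.
#'
#' @param truth a [SimTruth-class] from [generateAncestor()].
#' @return data.frame with `locus`, `len`, `predictedSV`.
#' @export
predictedLocusSV <- function(truth) {
  rows <- truth@loci
  cfg <- truth@config
  loci <- unique(rows$locus)
  out <- lapply(loci, function(lc) {
    r <- rows[rows$locus == lc, , drop = FALSE]
    lenTot <- sum(nchar(r$seq))
    q <- r$pSub / 2
    pdiff <- 2 * q * (1 - q) + q^2 * (2 / 3)
    coding <- any(r$kind %in% c("exon", "psi_ycf1", "ycf1_body") &
                    r$category %in% "protein_coding")
    lambda <- sum(r$indelRate * nchar(r$seq)) / lenTot
    mean_len <- if (coding) 3 * cfg$indelMeanLength else cfg$indelMeanLength
    del_bases <- lambda / 2 * mean_len
    nsub <- sum(nchar(r$seq) * pdiff) - (if (coding) 6 * mean(pdiff) else 0) -
      del_bases * mean(pdiff)
    data.frame(locus = lc, len = lenTot, coding = coding,
               predictedSV = 100 * (nsub + lambda) /
                 (lenTot - del_bases + lambda),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## total annotated ndh sequence (exon segments; duplicate IR copies once)
.retained_ndh <- function(p) {
  ft <- features(p)
  tot <- 0
  for (gn in NDH_GENES) {
    idx <- which(ft$name == gn)
    if (!length(idx)) next
    tot <- tot + max(vapply(idx, function(i)
      sum(width(ft$segments[[i]])), 1))
  }
  tot
}
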