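# Independent brute-force oracles. These deliberately re-derive each
# quantity from its definition with simple exhaustive scans, sharing no
# code with the production implementations they check.

# maximal perfect tandem runs on a circle (or line), unit sizes 1..6
oracle_ssrs <- function(s, thresholds = ssrThresholds(), circular = FALSE) {
  x <- strsplit(toupper(s), "")[[1]]
  L <- length(x)
  at <- function(i) x[((i - 1) %% L) + 1]
  ok <- function(i) at(i) %in% c("A", "C", "G", "T")
  out <- list()
  for (u in 1:6) {
    maxspan <- if (circular) L else L - u
    for (st in seq_len(if (circular) L else max(0, L - u))) {
      # left-maximal: position st-1 must not extend the run
      ext <- if (circular) ok(st - 1) && ok(st - 1 + u) &&
        at(st - 1) == at(st - 1 + u)
      else st > 1 && (st - 1 + u) <= L && ok(st - 1) && ok(st - 1 + u) &&
        at(st - 1) == at(st - 1 + u)
      if (isTRUE(ext)) next
      run <- 0
      while (run < maxspan) {
        i <- st + run
        if (!circular && (i + u) > L) break
        if (!(ok(i) && ok(i + u) && at(i) == at(i + u))) break
        run <- run + 1
      }
      reg_len <- min(run + u, L)
      cnt <- reg_len %/% u
      if (run == 0 || cnt < thresholds[u]) next
      motif <- paste(vapply(st:(st + u - 1), at, ""), collapse = "")
      # primitive motif only
      prim <- TRUE
      for (d in seq_len(u - 1)) {
        if (u %% d == 0 &&
            identical(strrep(substr(motif, 1, d), u %/% d), motif)) {
          prim <- FALSE; break
        }
      }
      if (!prim) next
      out[[length(out) + 1]] <- data.frame(
        motif = motif, unitLength = u, unitCount = cnt, start = st,
        end = st + cnt * u - 1, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) unique(do.call(rbind, out)) else
    data.frame(motif = character(), unitLength = integer(),
               unitCount = integer(), start = integer(), end = integer())
  res <- res[order(res$start, res$unitLength), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# all maximal repeat-pair windows (disjoint copies) from the definition:
# scan every diagonal / antidiagonal of the full comparison matrix
oracle_repeats <- function(s, minLen = 30, maxHamming = 3,
                           kinds = c("forward", "palindromic", "reverse")) {
  x <- strsplit(toupper(s), "")[[1]]
  n <- length(x)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rows <- list()
  windows_from <- function(m, lo) {   # m: logical match vector from `lo`
    mm <- which(!m) + lo - 1L
    aug <- c(lo - 1L, mm, lo + length(m))
    ww <- list()
    for (t in seq_len(max(0, length(aug) - maxHamming - 1L))) {
      w1 <- aug[t] + 1L
      w2 <- aug[t + maxHamming + 1L] - 1L
      if (w2 - w1 + 1L >= minLen)
        ww[[length(ww) + 1L]] <- c(w1, w2, sum(mm >= w1 & mm <= w2))
    }
    unique(ww)
  }
  add <- function(kind, w1, w2, a2, b2, mm) {
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, start1 = w1, end1 = w2, start2 = a2, end2 = b2,
      length = w2 - w1 + 1L, mismatches = mm, stringsAsFactors = FALSE)
  }
  if ("forward" %in% kinds) {
    for (d in seq_len(n - 1)) {
      if (n - d < minLen) break
      idx <- seq_len(n - d)
      m <- x[idx] == x[idx + d] & x[idx] %in% names(comp) &
        x[idx + d] %in% names(comp)
      for (w in windows_from(m, 1L)) {
        if (w[2] - w[1] + 1L > d) next          # overlapping copies
        add("forward", w[1], w[2], w[1] + d, w[2] + d, w[3])
      }
    }
  }
  for (kind in intersect(kinds, c("palindromic", "reverse"))) {
    for (cc in 3:(2 * n - 1)) {                 # cc = a + b (1-based)
      lo <- max(1L, cc - n); hi <- min(n, cc - 1L)
      if (hi - lo + 1L < 2L * minLen) next
      a <- lo:hi
      b <- cc - a
      m <- if (kind == "palindromic")
        x[a] %in% names(comp) & x[b] %in% names(comp) &
          x[a] == comp[x[b]]
      else x[a] %in% names(comp) & x[b] %in% names(comp) & x[a] == x[b]
      for (w in windows_from(m, lo)) {
        if (2L * w[2] >= cc) next               # copies must be disjoint
        add(kind, w[1], w[2], cc - w[2], cc - w[1], w[3])
      }
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(), start1 = integer(), end1 = integer(),
               start2 = integer(), end2 = integer(), length = integer(),
               mismatches = integer(), stringsAsFactors = FALSE)
  res$identity <- ifelse(res$length > 0,
                         100 * (1 - res$mismatches / res$length), NA)
  res <- res[res$identity >= 90, , drop = FALSE]
  res <- res[order(res$start1, res$start2, res$kind), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# optimal global affine-gap alignment score by Gotoh dynamic programming
oracle_affine_score <- function(s1, s2, match = 1, mismatch = -1,
                                gapOpen = 4, gapExt = 1) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (j in 2:(m + 1)) Y[1, j] <- -gapOpen - gapExt * (j - 1)
  for (i in 2:(n + 1)) X[i, 1] <- -gapOpen - gapExt * (i - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sc <- if (a[i - 1] == b[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1],
                     Y[i - 1, j - 1]) + sc
      X[i, j] <- max(M[i - 1, j] - gapOpen - gapExt, X[i - 1, j] - gapExt)
      Y[i, j] <- max(M[i, j - 1] - gapOpen - gapExt, Y[i, j - 1] - gapExt)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# event counting re-derived as a single-pass column walker
oracle_count_events <- function(a1, a2) {
  a <- strsplit(a1, "")[[1]]; b <- strsplit(a2, "")[[1]]
  conserved <- 0L; subs <- 0L; indels <- 0L
  in_gap <- FALSE
  for (i in seq_along(a)) {
    if (a[i] == "-" || b[i] == "-") {
      if (!in_gap) indels <- indels + 1L
      in_gap <- TRUE
    } else {
      in_gap <- FALSE
      if (a[i] == "N" || b[i] == "N") next
      if (a[i] == b[i]) conserved <- conserved + 1L
      else subs <- subs + 1L
    }
  }
  c(conserved = conserved, substitutions = subs, indelEvents = indels)
}

# NG86 pathway counts by recursive depth-first enumeration
oracle_ng86_pathways <- function(c1, c2,
                                 code = Biostrings::GENETIC_CODE) {
  stops <- c("TAA", "TAG", "TGA")
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  paths <- list()
  recurse <- function(cur, remaining, syn, nonsyn, blocked) {
    if (!length(remaining)) {
      paths[[length(paths) + 1L]] <<- c(syn = syn, nonsyn = nonsyn,
                                        blocked = blocked)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      hit_stop <- nxt %in% stops && nxt != c2
      step_syn <- code[[cur]] == code[[nxt]]
      recurse(nxt, setdiff(remaining, p),
              syn + as.integer(step_syn), nonsyn + as.integer(!step_syn),
              blocked || hit_stop)
    }
  }
  recurse(c1, pos, 0L, 0L, FALSE)
  tab <- do.call(rbind, paths)
  open <- tab[tab[, "blocked"] == 0, , drop = FALSE]
  use <- if (nrow(open)) open else tab
  c(syn = mean(use[, "syn"]), nonsyn = mean(use[, "nonsyn"]))
}

# per-codon synonymous site fraction from first principles
oracle_syn_sites <- function(cod, code = Biostrings::GENETIC_CODE) {
  stops <- c("TAA", "TAG", "TGA")
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(cod, p, p))) {
      alt <- cod
      substr(alt, p, p) <- b
      if (!(alt %in% stops) && code[[alt]] == code[[cod]]) s <- s + 1 / 3
    }
  }
  s
}
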