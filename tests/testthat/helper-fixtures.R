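# Shared fixtures built in code.

# the tests address feature segments with start()/end()/width(); make the
# IRanges generics win over stats::start/stats::end
suppressMessages(library(IRanges))

# hand-written GenBank text with three genes, one on the minus strand,
# one pseudogene; 1-based inclusive coordinates as in the format
write_three_gene_gb <- function(path, origin_spanning = FALSE) {
  seq <- paste0(
    "ATGAAACCCGGGTTTTAA",            # 1..18   gene alpha (+)
    "ACGTACGTACGTACGTACGT",          # 19..38  spacer
    "TTACATGGGCCCTTTCAT",            # 39..56  gene beta (-): revcomp CDS
    "AACCGGTTAACCGGTT",              # 57..72  spacer
    "ATGCCCAAATAG"                   # 73..84  gene gamma (+), pseudo
  )
  loc_alpha <- if (origin_spanning) "join(79..84,1..12)" else "1..18"
  lines <- c(
    sprintf("LOCUS       toyplast %d bp    DNA     circular PLN 01-JAN-2000",
            nchar(seq)),
    "DEFINITION  hand-written three-gene fixture.",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(seq)),
    sprintf("     CDS             %s", loc_alpha),
    '                     /gene="alpha"',
    "     CDS             complement(39..56)",
    '                     /gene="beta"',
    "     CDS             73..84",
    '                     /gene="gamma"',
    "                     /pseudo",
    "ORIGIN"
  )
  body <- character()
  for (a in seq(1, nchar(seq), by = 60)) {
    b <- min(a + 59, nchar(seq))
    chunk <- tolower(substr(seq, a, b))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    body <- c(body, sprintf("%9d %s", a, paste(groups, collapse = " ")))
  }
  writeLines(c(lines, body, "//"), path)
  invisible(seq)
}

# deterministic random DNA for oracle tests
random_dna <- function(n, seed, at = 0.6) {
  withr_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); force(expr)
  }
  withr_seed(seed, paste(
    sample(c("A", "C", "G", "T"), n, replace = TRUE,
           prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
    collapse = ""))
}

# embed a string into a host at position pos (1-based), replacing content
embed_at <- function(host, insert, pos) {
  paste0(substr(host, 1, pos - 1), insert,
         substr(host, pos + nchar(insert), nchar(host)))
}

# plant a repeat pair with 3 clustered central mismatches and enforced
# mismatching flanks, mirroring the simulator's planting scheme
plant_pair <- function(host, kind, len, pos1, pos2, seed) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  copy1 <- random_dna(len, seed, at = 0.5)
  v <- strsplit(copy1, "")[[1]]
  c2 <- switch(kind,
               forward = v,
               palindromic = rev(unname(comp[v])),
               reverse = rev(v))
  mid <- len %/% 2
  set.seed(seed + 1)
  for (m in (mid - 1):(mid + 1))
    c2[m] <- sample(setdiff(c("A", "C", "G", "T"), c2[m]), 1)
  host <- embed_at(host, copy1, pos1)
  host <- embed_at(host, paste(c2, collapse = ""), pos2)
  x <- strsplit(host, "")[[1]]
  pick_not <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  e1 <- pos1 + len - 1; e2 <- pos2 + len - 1
  if (kind == "forward") {
    for (o in 1:2) {
      x[pos2 - o] <- pick_not(x[pos1 - o])
      x[e2 + o] <- pick_not(x[e1 + o])
    }
  } else {
    tr <- if (kind == "palindromic") function(b) comp[[b]] else identity
    for (o in 1:2) {
      x[e2 + o] <- pick_not(tr(x[pos1 - o]))
      x[pos2 - o] <- pick_not(tr(x[e1 + o]))
    }
  }
  list(seq = paste(x, collapse = ""),
       truth = data.frame(kind = kind, start1 = pos1, end1 = e1,
                          start2 = pos2, end2 = e2, mismatches = 3L,
                          stringsAsFactors = FALSE))
}

# small, fast simulation config for tests that only need structure
fast_cfg <- function(seed, ...) {
  simConfig(seed = seed, plantSSRs = NULL, plantRepeats = NULL,
            hotspots = c(dummy = 1)[0], ...)
}
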