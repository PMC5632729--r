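## Internal sequence helpers. Character-level utilities are kept here so the
## scanning code (SSR, repeats, simulator) can work on plain vectors without
## round-tripping through XString objects in inner loops.

#' @importFrom stats setNames
NULL

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.revcomp_chr <- function(x) {
  if (nchar(x) == 0L) return(x)
  paste(rev(.COMP[strsplit(x, "", fixed = TRUE)[[1]]]), collapse = "")
}

.rev_chr <- function(x) {
  paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
}

.comp_chars <- function(v) unname(.COMP[v])

## 1-based modular coordinate: maps any integer onto [1, L]
.mod1 <- function(x, L) ((x - 1L) %% L) + 1L

## substring of a circular sequence given as a single string; end may
## exceed nchar(s) (wraps around the origin). width must be <= L.
.circ_substr <- function(s, start, end) {
  L <- nchar(s)
  start <- .mod1(start, L)
  end2 <- start + (end - start)
  if (end2 <= L) return(substr(s, start, end2))
  paste0(substr(s, start, L), substr(s, 1L, end2 - L))
}

## rotate a linear string so that position `newStart` becomes position 1
.rotate_chr <- function(s, newStart) {
  L <- nchar(s)
  newStart <- .mod1(newStart, L)
  if (newStart == 1L) return(s)
  paste0(substr(s, newStart, L), substr(s, 1L, newStart - 1L))
}

## random DNA string from a seeded RNG (AT-rich by default, like a plastome)
.random_dna <- function(n, at = 0.64) {
  if (n <= 0L) return("")
  p <- c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## split a string into its character vector
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

.paste0v <- function(v) paste(v, collapse = "")

## check primitivity of a repeat motif (not a power of a shorter unit)
.is_primitive_motif <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L &&
        identical(strrep(substr(motif, 1L, d), u %/% d), motif))
      return(FALSE)
  }
  TRUE
}

## stable file-format guess from extension
.format_from_path <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json")) "json" else "tsv"
}
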