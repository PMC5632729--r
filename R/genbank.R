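## GenBank flat-file input/output.
##
## A deliberately small, strict reader and writer for the single-record
## GenBank subset that annotated plastomes use: LOCUS, FEATURES with
## join()/complement() locations, /gene and /pseudo qualifiers, and an
## ORIGIN sequence block. No installed package parses this format from a
## local file, so it is implemented here; the writer and reader round-trip
## exactly, which the simulator relies on.

#' Read an annotated plastome from a GenBank flat file
#'
#' Parses a single-record GenBank file into an [AnnotatedPlastome-class].
#' `CDS`, `tRNA` and `rRNA` features become features of category
#' `protein_coding`, `tRNA` and `rRNA`; `misc_feature` rows become
#' `intron` (when their `/note` says so) or `other`; bare `gene` rows are
#' kept only when no typed feature of the same name exists (pseudogenes are
#' often annotated this way). Duplicate gene names -- the IR copies -- are
#' preserved as distinct features. GenBank 1-based closed coordinates are
#' kept as-is; a `join` across the origin of a circular record is unwrapped
#' into a single segment with `end` beyond the sequence length.
#'
#' @param path path to a GenBank flat file containing one record.
#' @param flagIncompleteCds logical; when `TRUE` (default) a non-pseudo CDS
#'   whose total length is not a multiple of 3, or which contains an
#'   internal stop codon, is flagged as a pseudogene (the record's own
#'   `/pseudo` qualifier is always respected).
#' @return an [AnnotatedPlastome-class].
#' @examples
#' cfg <- simConfig(seed = 1)
#' sim <- generateAncestor(cfg)
#' tf <- tempfile(fileext = ".gb")
#' writeGenBank(sim$plastome, tf)
#' p <- readPlastome(tf)
#' genomeLength(p)
#' @export
readPlastome <- function(path, flagIncompleteCds = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty GenBank file: ", path)

  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L)
    stop("malformed GenBank file (no LOCUS line): ", path)
  if (length(locus_i) > 1L)
    stop("multi-record GenBank files are not supported: ", path)
  locus <- strsplit(trimws(lines[locus_i[1]]), "[[:space:]]+")[[1]]
  id <- if (length(locus) >= 2L) locus[2] else "unnamed"
  circular <- any(grepl("circular", locus, ignore.case = TRUE))

  ## ---- sequence ---------------------------------------------------------
  ori_i <- grep("^ORIGIN", lines)
  if (length(ori_i) != 1L)
    stop("record without a sequence (no ORIGIN block): ", path)
  end_i <- grep("^//", lines)
  end_i <- end_i[end_i > ori_i][1]
  if (is.na(end_i)) end_i <- length(lines) + 1L
  seq_lines <- lines[seq(ori_i + 1L, end_i - 1L)]
  seqc <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(seqc))
    stop("record without a sequence: ", path)
  L <- nchar(seqc)

  ## ---- features ---------------------------------------------------------
  feat_i <- grep("^FEATURES", lines)
  rows <- list()
  if (length(feat_i) == 1L) {
    block <- lines[seq(feat_i + 1L, ori_i - 1L)]
    cur <- NULL
    flush <- function(cur) if (!is.null(cur)) rows[[length(rows) + 1L]] <<- cur
    for (k in seq_along(block)) {
      ln <- block[k]
      if (grepl("^ {5}[A-Za-z]", ln) && !grepl("^ {6,}", ln)) {
        flush(cur)
        key <- trimws(substr(ln, 6, 20))
        loc <- trimws(substr(ln, 21, nchar(ln)))
        cur <- list(key = key, loc = loc, quals = character(),
                    line = feat_i + k)
      } else if (grepl("^ {21}", ln) || grepl("^\t", ln)) {
        txt <- trimws(ln)
        if (is.null(cur)) next
        if (startsWith(txt, "/")) {
          cur$quals <- c(cur$quals, txt)
        } else if (length(cur$quals) == 0L) {
          cur$loc <- paste0(cur$loc, txt)   # continued location
        } else {
          n <- length(cur$quals)            # continued qualifier value
          cur$quals[n] <- paste0(cur$quals[n], txt)
        }
      } else if (nzchar(trimws(ln))) {
        stop("malformed GenBank feature table at line ", feat_i + k,
             ": '", ln, "'")
      }
    }
    flush(cur)
  }

  keep <- c("CDS", "tRNA", "rRNA", "misc_feature", "gene")
  rows <- Filter(function(r) r$key %in% keep, rows)

  qual_val <- function(quals, name) {
    hit <- grep(paste0("^/", name, "(=|$)"), quals, value = TRUE)
    if (!length(hit)) return(NA_character_)
    v <- sub(paste0("^/", name, "=?"), "", hit[1])
    gsub('^"|"$', "", v)
  }

  parsed <- lapply(rows, function(r) {
    loc <- .parse_location(r$loc, L, circular, line = r$line)
    nm <- qual_val(r$quals, "gene")
    if (is.na(nm)) nm <- qual_val(r$quals, "locus_tag")
    if (is.na(nm)) nm <- paste0(tolower(r$key), "_", r$line)
    pseudo <- any(grepl("^/pseudo", r$quals))
    note <- qual_val(r$quals, "note")
    category <- switch(r$key,
      CDS = "protein_coding", tRNA = "tRNA", rRNA = "rRNA",
      misc_feature = if (!is.na(note) && grepl("intron", note)) "intron"
                     else "other",
      gene = {
        if (grepl("^trn", nm)) "tRNA"
        else if (grepl("^rrn", nm)) "rRNA"
        else "protein_coding"
      })
    list(key = r$key, name = nm, category = category,
         strand = loc$strand, pseudo = pseudo, segments = loc$segments)
  })

  ## drop bare 'gene' rows shadowed by a typed feature of the same name
  typed_names <- vapply(Filter(function(x) x$key != "gene", parsed),
                        `[[`, "", "name")
  parsed <- Filter(function(x) x$key != "gene" ||
                     !(x$name %in% typed_names), parsed)

  if (length(parsed)) {
    ft <- featureTable(
      name = vapply(parsed, `[[`, "", "name"),
      category = vapply(parsed, `[[`, "", "category"),
      strand = vapply(parsed, `[[`, "", "strand"),
      pseudo = vapply(parsed, `[[`, TRUE, "pseudo"),
      segments = lapply(parsed, `[[`, "segments")
    )
  } else ft <- featureTable()

  p <- AnnotatedPlastome(id, seqc, ft, circular)
  if (flagIncompleteCds) p <- .flag_incomplete_cds(p)
  p
}

## Parse a GenBank location string into strand + transcription-order
## segments (IRanges, end possibly > L for an origin-spanning join).
.parse_location <- function(loc, L, circular, line = NA) {
  loc <- gsub("[<>]", "", gsub("[[:space:]]", "", loc))
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc))
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  if (!length(parts))
    stop("malformed location at line ", line, ": '", loc, "'")
  m <- regmatches(parts, regexec("^([0-9]+)(\\.\\.([0-9]+))?$", parts))
  if (any(lengths(m) == 0L))
    stop("malformed location at line ", line, ": '", loc, "'")
  st <- vapply(m, function(x) as.integer(x[2]), 1L)
  en <- vapply(m, function(x) {
    if (nzchar(x[4])) as.integer(x[4]) else as.integer(x[2])
  }, 1L)
  if (any(is.na(st)) || any(en < st) || any(en > L))
    stop("location out of bounds at line ", line, ": '", loc, "'")
  ## unwrap a join across the origin into one segment with end > L
  if (circular && length(st) > 1L) {
    i <- 1L
    while (i < length(st)) {
      if (en[i] == L && st[i + 1L] == 1L) {
        en[i] <- L + en[i + 1L]
        st <- st[-(i + 1L)]; en <- en[-(i + 1L)]
      } else i <- i + 1L
    }
  }
  segs <- IRanges(start = st, end = en)
  if (strand == "-") segs <- rev(segs)   # transcription order
  list(strand = strand, segments = segs)
}

## flag non-pseudo CDS features with broken reading frames
.flag_incomplete_cds <- function(p) {
  ft <- p@features
  if (!nrow(ft)) return(p)
  idx <- which(ft$category == "protein_coding" & !ft$pseudo)
  for (i in idx) {
    cds <- featureSequence(p, i)
    n <- nchar(cds)
    bad <- (n %% 3L != 0L)
    if (!bad && n >= 6L) {
      codons <- substring(cds, seq(1L, n - 3L, by = 3L),
                          seq(3L, n - 1L, by = 3L))
      bad <- any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA"))
    }
    if (bad) {
      warning("CDS '", ft$name[i], "' in '", p@identifier,
              "' fails the completeness check; flagging as pseudogene")
      ft$pseudo[i] <- TRUE
    }
  }
  p@features <- ft
  p
}

#' Extract the spliced, strand-corrected sequence of a feature
#'
#' @param p an [AnnotatedPlastome-class].
#' @param i feature row index.
#' @return a character scalar: exon segments concatenated in transcription
#'   order, reverse-complemented for minus-strand features.
#' @export
featureSequence <- function(p, i) {
  ft <- p@features
  segs <- ft$segments[[i]]
  s <- as.character(p@sequence)
  pieces <- vapply(seq_along(segs), function(k) {
    .circ_substr(s, start(segs)[k], end(segs)[k])
  }, "")
  if (ft$strand[i] == "-") pieces <- vapply(pieces, .revcomp_chr, "")
  paste(pieces, collapse = "")
}

#' Count unique genes per category
#'
#' Counts distinct gene names per feature category; genes duplicated in the
#' two IR copies (and trans-spliced genes annotated in pieces, e.g. rps12)
#' are counted once. Pseudogenes are excluded from the functional counts
#' and reported separately.
#'
#' @param p an [AnnotatedPlastome-class] with features.
#' @return a list with `counts` (named integer vector over categories) and
#'   `pseudogenes` (character vector of distinct pseudogene names).
#' @export
countUniqueGenes <- function(p) {
  ft <- p@features
  if (!nrow(ft)) stop("plastome has no features")
  func <- ft[!ft$pseudo & ft$category != "intron", , drop = FALSE]
  counts <- vapply(setdiff(.FEATURE_CATEGORIES, "intron"), function(cat) {
    length(unique(func$name[func$category == cat]))
  }, 1L)
  pseudo_names <- unique(ft$name[ft$pseudo])
  ## a gene with at least one functional copy (IR duplicate) is functional
  pseudo_names <- setdiff(pseudo_names, func$name)
  list(counts = counts, pseudogenes = sort(pseudo_names))
}

#' Write an AnnotatedPlastome as a GenBank flat file
#'
#' Emits the same single-record subset that [readPlastome()] consumes:
#' round-tripping preserves the sequence and every feature's coordinates,
#' strand, category and pseudogene flag.
#'
#' @param p an [AnnotatedPlastome-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGenBank <- function(p, path) {
  L <- genomeLength(p)
  s <- as.character(p@sequence)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf(
    "LOCUS       %s %d bp    DNA     %s PLN %s",
    p@identifier, L, if (p@circular) "circular" else "linear",
    "01-JAN-2000"), con)
  writeLines(sprintf("DEFINITION  %s plastome.", p@identifier), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)

  ft <- p@features
  if (nrow(ft)) for (i in seq_len(nrow(ft))) {
    key <- switch(ft$category[i],
                  protein_coding = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  "misc_feature")
    segs <- ft$segments[[i]]
    if (ft$strand[i] == "-") segs <- rev(segs)   # back to genome order
    pieces <- character()
    for (k in seq_along(segs)) {
      a <- start(segs)[k]; b <- end(segs)[k]
      if (b > L) {  # split origin-spanning segment back into two pieces
        pieces <- c(pieces, sprintf("%d..%d", a, L),
                    sprintf("1..%d", b - L))
      } else pieces <- c(pieces, sprintf("%d..%d", a, b))
    }
    loc <- if (length(pieces) > 1L)
      sprintf("join(%s)", paste(pieces, collapse = ",")) else pieces
    if (ft$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-16s%s", key, loc), con)
    writeLines(sprintf('                     /gene="%s"', ft$name[i]), con)
    if (ft$category[i] == "intron")
      writeLines('                     /note="intron"', con)
    if (ft$pseudo[i])
      writeLines("                     /pseudo", con)
  }

  writeLines("ORIGIN", con)
  pos <- seq(1L, L, by = 60L)
  for (a in pos) {
    b <- min(a + 59L, L)
    chunk <- substr(s, a, b)
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", a, tolower(paste(groups, collapse = " "))),
               con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Write a tabular report
#'
#' Writes any data.frame-like report to TSV or JSON with a deterministic
#' row order (sorted by the first column, then the second when tied), so
#' that repeated runs produce byte-identical files.
#'
#' @param records a data.frame (or object coercible to one) whose rows
#'   share a schema.
#' @param path output path.
#' @param format `"tsv"`, `"json"`, or `"auto"` (from the file extension).
#' @return `path`, invisibly.
#' @seealso [readReport()]
#' @export
writeReport <- function(records, path, format = c("auto", "tsv", "json")) {
  format <- .format_from_path(path, match.arg(format))
  records <- as.data.frame(records)
  if (nrow(records) > 1L) {
    ord <- if (ncol(records) >= 2L)
      order(records[[1]], records[[2]]) else order(records[[1]])
    records <- records[ord, , drop = FALSE]
  }
  rownames(records) <- NULL
  if (format == "tsv") {
    utils::write.table(records, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(records, path, digits = NA, na = "null",
                         auto_unbox = FALSE, pretty = TRUE)
  }
  invisible(path)
}

#' Read back a report written by [writeReport()]
#'
#' @inheritParams writeReport
#' @return a data.frame.
#' @export
readReport <- function(path, format = c("auto", "tsv", "json")) {
  format <- .format_from_path(path, match.arg(format))
  if (format == "tsv") {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}
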