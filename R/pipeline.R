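## End-to-end orchestration of the comparative analysis over one plastome
## pair, with a flat validated configuration and deterministic outputs.

.PIPELINE_DEFAULTS <- list(
  input1 = NULL, input2 = NULL, outDir = "plastomics_out",
  seed = 1L, minIrLen = 1000L, maxMismatchRate = 0.001,
  ssrMono = 8L, ssrDi = 5L, ssrMulti = 3L, ssrStrict = FALSE,
  repeatMinLen = 30L, repeatMaxHamming = 3L, minNonCodingLen = 150L,
  topHotspots = 10L, referenceYcf1ToJsa = 991
)

#' Read and validate a pipeline configuration
#'
#' The configuration is a flat key set (YAML file or list); unknown keys
#' are errors, not warnings -- a silently ignored threshold typo would
#' fake a reproduction.
#'
#' @param config path to a YAML file, or a named list.
#' @return the validated configuration list with defaults filled in.
#' @export
readRunConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(.PIPELINE_DEFAULTS))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.PIPELINE_DEFAULTS, config)
  if (is.null(cfg$input1) || is.null(cfg$input2))
    stop("configuration must name input1 and input2 (GenBank files)")
  cfg
}

#' Run the full comparative pipeline on a plastome pair
#'
#' Reads and canonicalizes both plastomes, then runs every analysis stage
#' -- structure, SSR census, dispersed-repeat census, divergence / SV
#' hotspot screen, pairwise dN/dS, junction profiling -- writing one TSV
#' report per stage plus a combined JSON summary carrying the package
#' version, parameters and seed. Rerunning with the same configuration
#' reproduces byte-identical outputs. A stage failure aborts with an
#' error naming the stage; reports of completed stages remain on disk.
#'
#' @param config a configuration for [readRunConfig()].
#' @return (invisibly) a list with all stage results and report paths.
#' @export
runPipeline <- function(config) {
  cfg <- readRunConfig(config)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  res <- list(config = cfg,
              version = as.character(utils::packageVersion("plastomics")))

  ps <- stage("read", {
    lapply(c(cfg$input1, cfg$input2), function(f) {
      if (!file.exists(f)) stop("input file not found: ", f)
      p <- readPlastome(f)
      canonicalizePlastome(p, minIrLen = cfg$minIrLen,
                           maxMismatchRate = cfg$maxMismatchRate)
    })
  })

  res$structure <- stage("structure", {
    tab <- do.call(rbind, lapply(ps, function(x)
      regionSummary(x$plastome, x$partition)))
    writeReport(tab, file.path(cfg$outDir, "structure.tsv"))
    tab
  })

  res$ssr <- stage("ssr", {
    thr <- ssrThresholds(cfg$ssrMono, cfg$ssrDi, cfg$ssrMulti,
                         strict = cfg$ssrStrict)
    out <- lapply(ps, function(x) {
      loci <- classifySSRContext(
        findSSRs(x$plastome, thresholds = thr, partition = x$partition),
        x$plastome)
      writeReport(loci, file.path(
        cfg$outDir, paste0("ssr_", identifier(x$plastome), ".tsv")))
      list(loci = loci, summary = ssrSummary(loci))
    })
    names(out) <- vapply(ps, function(x) identifier(x$plastome), "")
    out
  })

  res$repeats <- stage("repeats", {
    out <- lapply(ps, function(x) {
      hits <- findRepeats(x$plastome, minLen = cfg$repeatMinLen,
                          maxHamming = cfg$repeatMaxHamming,
                          partition = x$partition)
      ctx <- repeatContextProportions(hits, x$plastome)
      hits$context <- if (length(ctx$context)) ctx$context else character()
      writeReport(hits, file.path(
        cfg$outDir, paste0("repeats_", identifier(x$plastome), ".tsv")))
      list(hits = hits, bins = binRepeatsByLength(hits),
           contexts = ctx$proportions)
    })
    names(out) <- vapply(ps, function(x) identifier(x$plastome), "")
    out
  })

  res$divergence <- stage("divergence", {
    recs <- computeDivergence(ps[[1]]$plastome, ps[[2]]$plastome,
                              ps[[1]]$partition, ps[[2]]$partition,
                              minNonCodingLen = cfg$minNonCodingLen)
    hot <- rankHotspots(recs, k = cfg$topHotspots)
    writeReport(recs, file.path(cfg$outDir, "divergence.tsv"))
    writeReport(hot[order(-hot$svPercent, hot$name), ],
                file.path(cfg$outDir, "hotspots.tsv"))
    list(records = recs, hotspots = hot,
         statistics = divergenceStatistics(recs))
  })

  res$dnds <- stage("dnds", {
    dd <- dndsPairwise(ps[[1]]$plastome, ps[[2]]$plastome,
                       ps[[1]]$partition, ps[[2]]$partition)
    writeReport(rbind(dd$perGene, dd$concatenated),
                file.path(cfg$outDir, "dnds.tsv"))
    dd
  })

  res$junctions <- stage("junctions", {
    profs <- lapply(ps, function(x)
      profileJunctions(x$plastome, x$partition))
    tab <- do.call(rbind, lapply(profs, function(pr) data.frame(
      identifier = identifier(pr), type = typeLabel(pr),
      jsb = pr@jsb, jsa = pr@jsa, ycf1ToJsa = ycf1ToJsa(pr),
      retainedNdh = retainedNdhLength(pr),
      ndhIntact = sum(ndhStatus(pr) == "intact"),
      stringsAsFactors = FALSE)))
    writeReport(tab, file.path(cfg$outDir, "junctions.tsv"))
    list(profiles = profs, table = tab)
  })

  summary <- list(
    version = res$version,
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), c("input1", "input2", "outDir"))],
    inputs = vapply(ps, function(x) identifier(x$plastome), ""),
    structure = res$structure,
    ssrTotals = vapply(res$ssr, function(x) x$summary$total, 1L),
    repeatTotals = vapply(res$repeats, function(x) nrow(x$hits), 1L),
    meanCodingSV = mean(res$divergence$records$svPercent[
      res$divergence$records$class == "coding"]),
    meanNonCodingSV = mean(res$divergence$records$svPercent[
      res$divergence$records$class != "coding"]),
    topHotspots = res$divergence$hotspots$name,
    concatenatedDnDs = res$dnds$concatenated[
      , c("dn", "ds", "omega")],
    junctionTypes = vapply(res$junctions$profiles, typeLabel, "")
  )
  jsonlite::write_json(summary, file.path(cfg$outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  invisible(res)
}
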