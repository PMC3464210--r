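#' Default demonstration pipeline configuration
#'
#' A desk-scale end-to-end run: one inversion planted on a 300-kb toy
#' chromosome with 2/3/5-kb mate-pair libraries, plus the complex karyotype
#' matrix scored under the three outgroup X ancestries.
#'
#' @param seed master RNG seed.
#' @return Configuration list (YAML-serialisable).
#' @export
demoPipelineConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    matepair = list(
      genome_length = 300000L,
      breakpoints = c(90000L, 210000L),
      junction_gap = 0L,
      libraries = list(list(insert = 2000, sd = 200),
                       list(insert = 3000, sd = 300),
                       list(insert = 5000, sd = 500)),
      coverage = 4,
      min_support = 2L
    ),
    phylo = list(
      outgroup = "outgroup",
      x_options = c("X+", "Xbcd", "Xag")
    )
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
}

#' Run the end-to-end analysis pipeline
#'
#' simulate -> detect -> encode -> distance -> phylo -> report, with a
#' reproducibility manifest (config hash, seeds, package version, output
#' digests).  Identical configuration and seed give byte-identical outputs.
#'
#' @param config configuration list (see [demoPipelineConfig]) or a path to
#'   a YAML file with the same structure.
#' @param outDir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return The manifest, invisibly; all outputs are written under `outDir`.
#' @export
runPipeline <- function(config = demoPipelineConfig(), outDir, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("stage config: seed is mandatory")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  seed <- as.integer(config$seed)
  outputs <- character(0)
  addOut <- function(...) outputs <<- c(outputs, ...)

  ## --- simulate ------------------------------------------------------------
  mpcfg <- config$matepair
  sim <- .stage("simulate", {
    if (is.null(mpcfg)) stop("missing matepair section")
    s <- simulateInversionGenome(mpcfg$genome_length, mpcfg$breakpoints[1L],
                                 mpcfg$breakpoints[2L],
                                 gapLength = mpcfg$junction_gap %||% 0L,
                                 seed = seed)
    refFa <- file.path(outDir, "reference.fa")
    derFa <- file.path(outDir, "derived.fa")
    r <- Biostrings::DNAStringSet(s$reference); names(r) <- "ref"
    d <- Biostrings::DNAStringSet(s$derived); names(d) <- "derived"
    Biostrings::writeXStringSet(r, refFa)
    Biostrings::writeXStringSet(d, derFa)
    jsonlite::write_json(s$truth, file.path(outDir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    addOut(refFa, derFa, file.path(outDir, "truth.json"))
    s
  })
  libs <- .stage("simulate", lapply(mpcfg$libraries, function(l)
    librarySpec(l$insert, l$sd %||% (0.1 * l$insert))))
  pairs <- .stage("simulate", lapply(seq_along(libs), function(k) {
    mp <- simulateMatePairLibrary(sim$derived, libs[[k]],
                                  coverage = mpcfg$coverage,
                                  seed = seed + 100L * k)
    writeFastqPair(mp$read1, mp$read2,
                   file.path(outDir, sprintf("lib%d", k)))
    addOut(file.path(outDir, sprintf("lib%d_%d.fq", k, 1:2)))
    mp
  }))
  say("simulate: ", length(libs), " libraries, ",
      sum(vapply(pairs, function(p) length(p$read1), 0L)), " pairs")

  ## --- mate-pair breakpoint calls -------------------------------------------
  calls <- .stage("matepair-call", {
    res <- callBreakpoints(pairs, sim$reference, libs,
                           minSupport = mpcfg$min_support %||% 2L)
    writeCallsBED(res$calls, file.path(outDir, "calls.bed"),
                  file.path(outDir, "calls.tsv"))
    addOut(file.path(outDir, "calls.bed"), file.path(outDir, "calls.tsv"))
    res$calls
  })
  say("matepair-call: ", length(calls), " breakpoint calls")

  ## --- encode + distances ----------------------------------------------------
  pcfg <- config$phylo
  kmat <- .stage("phylo", {
    if (is.null(pcfg$outgroup)) stop("missing outgroup")
    if (!is.null(config$karyotypes))
      readKaryotypeTSV(config$karyotypes, gambiaeComplexCatalog(),
                       outgroup = pcfg$outgroup)
    else gambiaeKaryotypeMatrix(outgroupLabel = pcfg$outgroup)
  })
  .stage("encode", {
    perms <- lapply(rownames(kmat@states), function(tx)
      encodeKaryotype(kmat@states[tx, ], kmat@catalog))
    names(perms) <- rownames(kmat@states)
    writePermsJSON(perms, file.path(outDir, "perms.json"))
    writeKaryotypeTSV(kmat, file.path(outDir, "karyotypes.tsv"))
    addOut(file.path(outDir, "perms.json"), file.path(outDir, "karyotypes.tsv"))
  })
  .stage("distance", {
    dm <- pairwiseDistanceMatrix(kmat)
    utils::write.table(data.frame(taxon = rownames(dm$total), dm$total,
                                  check.names = FALSE),
                       file.path(outDir, "distances.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    addOut(file.path(outDir, "distances.tsv"))
  })

  ## --- scenarios --------------------------------------------------------------
  scen <- .stage("phylo", {
    res <- bestScenario(kmat, pcfg$x_options %||% c("X+", "Xbcd", "Xag"))
    writeScenarioReport(res, file.path(outDir, "scenarios.json"),
                        file.path(outDir, "scenarios.txt"))
    addOut(file.path(outDir, "scenarios.json"), file.path(outDir, "scenarios.txt"))
    if (!is.na(res$winner)) {
      winTree <- res$scenarios[[res$winner]]@trees[[1L]]
      rooted <- rootTree(winTree, pcfg$outgroup)
      ape::write.tree(rooted, file.path(outDir, "winner.nwk"))
      addOut(file.path(outDir, "winner.nwk"))
    }
    res
  })
  say("phylo: winner ", scen$winner)

  ## --- manifest ---------------------------------------------------------------
  manifest <- .stage("manifest", {
    cfgFile <- file.path(outDir, "config.yaml")
    yaml::write_yaml(config, cfgFile)
    outputs <- sort(unique(outputs))
    m <- list(
      package = as.character(utils::packageVersion("chromoPhylo")),
      seed = seed,
      configDigest = unname(tools::md5sum(cfgFile)),
      winner = scen$winner,
      files = as.list(tools::md5sum(outputs))
    )
    jsonlite::write_json(m, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    m
  })
  say("manifest: ", length(manifest$files), " files")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
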