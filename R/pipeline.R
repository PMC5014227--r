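#' @include AllClasses.R kmer-classifier.R annotation.R synteny.R landscape.R
#' @include saturation.R assembly-metrics.R io.R
NULL

.pipelineDefaults <- function() list(
  seed = 1,
  genome = list(),                 # overrides for genomeSpec()
  # ~4.5x clone coverage: a gene-bearing MTP resource is tiled with low
  # redundancy, so ordinary genes stay below the frequent-model threshold.
  library = list(nClones = 350, insertMean = 5e4, insertSd = 5e3,
                 nodeSplit = 6),
  screening = list(nPools = 30, detectProb = 0.6, fpRate = 0.002),
  hits = list(noise = 0.05),
  # minKmerCount = 1: the rarity filter removes sequencing-error k-mers in
  # read-derived targets; synthetic targets are error-free single copies.
  classifier = list(k = 19, minKmerCount = 1, confidenceThreshold = 0.75,
                    canonical = TRUE),
  annotation = list(minNodeLen = 200, evalueCutoff = 1e-20,
                    frequentBacThreshold = 10),
  landscape = list(window = 1e5, step = 1e4, gdQuantile = 0.75,
                   rfQuantile = 0.25, minBacsPerWindow = 5),
  saturation = list(nPermutations = 2000, model = "negexp"),
  stats = list(minNodeLen = 200)
)

#' Pipeline configuration
#'
#' Nested configuration for \code{\link{runPipeline}}. Unknown keys at
#' either level are rejected. The defaults run the whole pipeline on the
#' package's reference synthetic study conditions; the landscape window
#' and step default to a scale suited to the synthetic chromosomes
#' (100 kb / 10 kb), not the field scale of
#' \code{\link{landscapeConfig}}.
#'
#' @param ... named overrides; each of \code{seed}, \code{genome},
#'   \code{library}, \code{screening}, \code{hits}, \code{classifier},
#'   \code{annotation}, \code{landscape}, \code{saturation}, \code{stats}
#'   may be a list of field overrides.
#' @return list of class \code{"PipelineConfig"}.
#' @examples
#' cfg <- pipelineConfig(seed = 7, library = list(nClones = 50))
#' @export
pipelineConfig <- function(...) {
  over <- list(...)
  base <- .pipelineDefaults()
  bad <- setdiff(names(over), names(base))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (k in names(over)) {
    if (is.list(base[[k]]) && is.list(over[[k]])) {
      if (k != "genome") {
        badf <- setdiff(names(over[[k]]), names(base[[k]]))
        if (length(badf))
          stop("unknown key(s) in '", k, "': ",
               paste(badf, collapse = ", "), call. = FALSE)
      } else {
        badf <- setdiff(names(over[[k]]), names(formals(genomeSpec)))
        if (length(badf))
          stop("unknown key(s) in 'genome': ",
               paste(badf, collapse = ", "), call. = FALSE)
      }
      base[[k]][names(over[[k]])] <- over[[k]]
    } else base[[k]] <- over[[k]]
  }
  structure(base, class = "PipelineConfig")
}

#' Serialize / deserialize a pipeline configuration
#'
#' JSON round-trip is lossless for the supported keys; unknown keys in the
#' file are rejected on read.
#' @param config a \code{\link{pipelineConfig}}.
#' @param path file path.
#' @return \code{writePipelineConfig}: \code{path} invisibly;
#'   \code{readPipelineConfig}: the configuration.
#' @export
writePipelineConfig <- function(config, path) {
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(pipelineConfig, x)
}

#' Run the full synthetic-resource pipeline
#'
#' Executes, in order: simulate (genome, BAC library, probe screening,
#' cross-species hit table), classify (discriminative k-mer arm
#' assignment), annotate (built-in gene matching + filters + counts),
#' synteny (plurality voting), landscape (window statistics + deviant
#' regions), saturate (accumulation curve + asymptote) and stats (per-BAC
#' and per-label assembly statistics). All stage outputs are written as
#' FASTA/TSV under \code{outdir} and recorded in a JSON manifest.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outdir output directory (created if needed).
#' @param inputs optional named list of externally supplied stage inputs
#'   (\code{genome}, \code{library}, \code{screening}, \code{hitTable});
#'   any that are present skip the corresponding simulation and are
#'   consumed unchanged by the downstream stages. A \code{library} without
#'   a \code{genome} is rejected because annotation and landscape need the
#'   gene models and map.
#' @return (invisibly) list with the in-memory stage results and
#'   \code{manifest}, the per-stage file listing also written to
#'   \code{manifest.json}.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir = tempfile(),
                        inputs = list()) {
  badIn <- setdiff(names(inputs),
                   c("genome", "library", "screening", "hitTable"))
  if (length(badIn))
    stop("unknown external input(s): ", paste(badIn, collapse = ", "),
         call. = FALSE)
  if (!is.null(inputs$library) && is.null(inputs$genome))
    stop("external 'library' requires an external 'genome' (stage ",
         "'annotate' needs its gene models)", call. = FALSE)
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  addStage <- function(stage, files, params) {
    manifest[[stage]] <<- list(outputs = files, parameters = params)
  }
  pth <- function(...) file.path(outdir, ...)
  seed <- config$seed

  ## 1. simulate
  genome <- if (!is.null(inputs$genome)) inputs$genome else {
    gspec <- do.call(genomeSpec, c(config$genome,
                                   if (!"seed" %in% names(config$genome))
                                     list(seed = deriveSeed(seed, 1))))
    simulateGenome(gspec)
  }
  lib <- if (!is.null(inputs$library)) inputs$library else
    do.call(simulateBacLibrary,
            c(list(genome = genome), config$library,
              list(seed = deriveSeed(seed, 2))))
  screening <- if (!is.null(inputs$screening)) inputs$screening else
    do.call(simulateProbeScreening,
            c(list(genome = genome, library = lib), config$screening,
              list(seed = deriveSeed(seed, 3))))
  hitTable <- if (!is.null(inputs$hitTable)) inputs$hitTable else
    simulateHitTable(lib, genome, noise = config$hits$noise,
                     seed = deriveSeed(seed, 4))
  writeFastaFile(armTargets(genome), pth("arm_targets.fasta"))
  geneSeqs <- geneSequences(genome)
  writeFastaFile(geneSeqs, pth("gene_models.fasta"))
  writeTsv(geneTable(genome), pth("gene_models.tsv"), config)
  writeTsv(mapTable(genome), pth("genetic_map.tsv"), config)
  writeBacLibrary(lib, pth("bac_nodes.fasta"), pth("bac_truth.tsv"))
  writeDetectionMatrix(screening, pth("detection_matrix.tsv"))
  writeTsv(hitTable, pth("hit_table.tsv"), config)
  addStage("simulate",
           c("arm_targets.fasta", "gene_models.fasta", "gene_models.tsv",
             "genetic_map.tsv", "bac_nodes.fasta", "bac_truth.tsv",
             "detection_matrix.tsv", "hit_table.tsv"),
           c(config$genome, config$library, config$screening, config$hits))

  ## 2. classify
  ccfg <- do.call(classifierConfig, config$classifier)
  index <- buildKmerIndex(armTargets(genome), ccfg)
  assignments <- classifyLibrary(index, lib, ccfg)
  writeTsv(assignments, pth("assignments.tsv"), config)
  addStage("classify", "assignments.tsv", config$classifier)

  ## 3. annotate
  acfg <- do.call(annotationConfig, config$annotation)
  raw <- matchGenesBuiltin(lib, geneSeqs, minSpan = acfg$minNodeLen)
  nl <- setNames(width(lib@nodes), names(lib@nodes))
  classOf <- setNames(geneTable(genome)$class, geneTable(genome)$gene_id)
  filtered <- filterHits(raw, nl, acfg, classOf = classOf)
  freq <- flagFrequentModels(filtered, acfg)
  counts <- countGenes(freq$retained, assignments)
  writeTsv(counts$perBac, pth("annotation_per_bac.tsv"), config)
  writeTsv(data.frame(gene_model_id = freq$excluded),
           pth("excluded_models.tsv"), config)
  addStage("annotate", c("annotation_per_bac.tsv", "excluded_models.tsv"),
           config$annotation)

  ## 4. synteny
  votes <- voteBacs(hitTable, acfg$evalueCutoff)
  writeTsv(votes, pth("synteny_votes.tsv"), config)
  addStage("synteny", "synteny_votes.tsv",
           list(evalueCutoff = acfg$evalueCutoff))

  ## 5. landscape
  lcfg <- do.call(landscapeConfig, config$landscape)
  anchored <- anchoredBacs(genome, lib, freq$retained)
  wst <- windowStats(anchored, lcfg, chromLen = genome@truth$chromLen)
  regions <- detectDeviantRegions(wst, lcfg)
  writeTsv(wst, pth("windows.tsv"), config)
  writeTsv(regions, pth("deviant_regions.tsv"), config)
  addStage("landscape", c("windows.tsv", "deviant_regions.tsv"),
           config$landscape)

  ## 6. saturate
  curve <- accumulationCurve(screening,
                             nPermutations = config$saturation$nPermutations,
                             seed = deriveSeed(seed, 5))
  est <- fitAsymptote(curve, model = config$saturation$model)
  writeTsv(as.data.frame(curve), pth("accumulation_curve.tsv"), config)
  writeLines(jsonlite::toJSON(unclass(est), auto_unbox = TRUE, digits = NA),
             pth("saturation_estimate.json"))
  addStage("saturate", c("accumulation_curve.tsv",
                         "saturation_estimate.json"), config$saturation)

  ## 7. stats
  st <- bacStats(lib, config$stats$minNodeLen)
  tab <- aggregateTable(st, assignments, counts)
  writeTsv(st, pth("bac_stats.tsv"), config)
  writeTsv(tab, pth("summary_table.tsv"), config)
  addStage("stats", c("bac_stats.tsv", "summary_table.tsv"), config$stats)

  manifestPath <- pth("manifest.json")
  writeLines(jsonlite::toJSON(list(version = .PKG_VERSION(),
                                   config = unclass(config),
                                   stages = manifest),
                              auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), manifestPath)
  invisible(list(genome = genome, library = lib, screening = screening,
                 hitTable = hitTable, index = index,
                 assignments = assignments, annotation = counts,
                 excluded = freq$excluded, retainedHits = freq$retained,
                 votes = votes, windows = wst, regions = regions,
                 curve = curve, saturation = est, bacStats = st,
                 summaryTable = tab, manifest = manifest,
                 outdir = outdir))
}

#' Gene model sequences of a simulated genome
#'
#' @param genome a \code{\linkS4class{SimGenome}}.
#' @return named \code{DNAStringSet}, one entry per gene.
#' @export
geneSequences <- function(genome) {
  g <- genome@genes
  if (!nrow(g)) return(DNAStringSet())
  seqs <- vapply(seq_len(nrow(g)), function(i) {
    substr(as.character(genome@chromosomes[[g$chrom[i]]]), g$start[i],
           g$end[i])
  }, character(1))
  DNAStringSet(setNames(seqs, g$gene_id))
}

#' Anchored-BAC table for landscape analysis
#'
#' Combines the library truth (chromosome + insert midpoint), the
#' interpolated genetic map and the retained HC gene hits into the input
#' format of \code{\link{windowStats}}.
#'
#' @param genome a \code{\linkS4class{SimGenome}}.
#' @param library a \code{\linkS4class{BacLibrary}} with truth.
#' @param retainedHits hits from \code{\link{flagFrequentModels}} (or any
#'   data.frame with \code{bac_id}, \code{gene_model_id}, \code{class}).
#' @return data.frame: \code{bac_id}, \code{chrom}, \code{bp}, \code{cM},
#'   \code{n_hc_models}, \code{model_ids} (list column of HC model ids).
#' @export
anchoredBacs <- function(genome, library, retainedHits) {
  tr <- bacTruth(library)
  if (!nrow(tr)) stop("library carries no truth table", call. = FALSE)
  bp <- (tr$start + tr$end) / 2
  cM <- vapply(seq_len(nrow(tr)), function(i)
    cmAt(genome, tr$chrom[i], bp[i]), numeric(1))
  hc <- retainedHits[retainedHits$class == "HC", , drop = FALSE]
  ml <- split(hc$gene_model_id, hc$bac_id)
  ids <- lapply(tr$bac_id, function(b) unique(ml[[b]]))
  data.frame(bac_id = tr$bac_id, chrom = tr$chrom, bp = bp, cM = cM,
             n_hc_models = lengths(ids),
             model_ids = I(ids))
}
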