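# Three-stage run driver: identification per snapshot, clustering across
# snapshots, report generation.  Each stage can run alone against saved
# intermediates so that e.g. re-clustering with a new threshold does not
# repeat the identification.

.identifySnapshot <- function(ensemble, frame, params, startSel,
                              ballsPerAtom, seed) {
  graph <- NULL
  ris <- NULL
  for (attempt in 0:3) {
    ris <- buildRIS(ensemble, frame, ballsPerAtom, seed + attempt)
    graph <- tryCatch(buildVoronoiGraph(ris), error = function(e) e)
    if (!inherits(graph, "error")) break
  }
  if (inherits(graph, "error"))
    stop("snapshot ", frame, ": ", conditionMessage(graph))
  labeling <- labelVertices(graph, params)
  p0 <- startingPoint(ensemble, frame, residues = startSel$residues,
                      atoms = startSel$atoms, xyz = startSel$xyz)
  sv <- optimizeStart(graph, p0, params@startMaxDist,
                      params@startMinClearance)
  pws <- findPathways(graph, ris, labeling, sv$vertex, params, frame)
  list(pathways = as.list(pws),
       startVertexPos = graph@vertices[sv$vertex, ],
       startStage = sv$stage, errorBound = ris@errorBound)
}

#' Identify tunnels in every snapshot of an ensemble
#'
#' @param ensemble a [TunnelEnsemble-class] with radii assigned
#' @param params a [SearchParams-class]
#' @param residues,atoms,xyz starting-point selection (see
#'   [startingPoint()])
#' @param ballsPerAtom balls per atom for the RIS (see [buildRIS()])
#' @param seed base seed for the RIS perturbations
#' @param workers parallel workers (snapshots are independent; results are
#'   merged in frame order, so the worker count never changes the result)
#' @param verbose print per-snapshot progress
#' @return a [TunnelRun-class] holding the raw per-snapshot pathways
#' @export
identifyTunnels <- function(ensemble, params = searchParams(),
                            residues = NULL, atoms = NULL, xyz = NULL,
                            ballsPerAtom = 12L, seed = 1L, workers = 1L,
                            verbose = FALSE) {
  frames <- seq_len(nSnapshots(ensemble))
  startSel <- list(residues = residues, atoms = atoms, xyz = xyz)
  runOne <- function(f) {
    res <- .identifySnapshot(ensemble, f, params, startSel, ballsPerAtom,
                             seed + 1000L * (f - 1L))
    if (verbose)
      message(sprintf("snapshot %d: %d pathway(s), start stage %d", f,
                      length(res$pathways), res$startStage))
    res
  }
  results <- if (workers > 1L) {
    parallel::mclapply(frames, runOne, mc.cores = workers)
  } else {
    lapply(frames, runOne)
  }
  err <- vapply(results, inherits, logical(1), "try-error")
  if (any(err)) stop("snapshot identification failed: ", results[[which(err)[1]]])
  pws <- PathwaySet(unlist(lapply(results, `[[`, "pathways"),
                           recursive = FALSE))
  new("TunnelRun", ensemble = ensemble, params = params,
      clusterParams = list(),
      pathways = pws,
      startVertexPos = do.call(rbind, lapply(results, `[[`,
                                             "startVertexPos")),
      errorBounds = vapply(results, `[[`, numeric(1), "errorBound"),
      seed = as.integer(seed), keep = integer(0), labels = integer(0))
}

#' Cluster the identified pathways
#'
#' Builds the reference frame and descriptors from all raw pathways, removes
#' redundant pathways per snapshot with the descriptor distance, computes
#' the pairwise distance matrix of the non-redundant set and clusters it by
#' average linkage.  With `sampleSize` below the pathway count the sampled
#' clustering + k-NN classification is used instead of exact clustering of
#' the full set.
#'
#' @param run a [TunnelRun-class] from [identifyTunnels()]
#' @param threshold clustering threshold (tree cut height)
#' @param nPoints,q,zStart,zEnd,mergeAngle,smoothness descriptor parameters
#'   (see [pathwayDescriptors()], [pathwayDistance()])
#' @param redundancyThreshold redundancy filter distance (`NA`: use
#'   `threshold`)
#' @param sampleSize,topN,k sampled-classification parameters (`NULL`
#'   `sampleSize` disables sampling)
#' @param distFile optional path for the distance-matrix cache
#' @return the run with clustering slots filled
#' @export
clusterTunnels <- function(run, threshold = 3.5, nPoints = 20L, q = 1,
                           zStart = 0, zEnd = 0, mergeAngle = 20,
                           smoothness = 20, redundancyThreshold = NA_real_,
                           sampleSize = NULL, topN = 6L, k = 5L,
                           distFile = NULL) {
  if (!length(run@pathways))
    stop("no pathways to cluster; run identifyTunnels first")
  if (is.na(redundancyThreshold)) {
    redundancyThreshold <- run@params@redundancyThreshold
    if (is.na(redundancyThreshold)) redundancyThreshold <- threshold
  }
  frame <- buildReferenceFrame(run@pathways, run@startVertexPos,
                               mergeAngle, smoothness)
  desc <- pathwayDescriptors(run@pathways, frame, nPoints, zStart, zEnd)
  Dall <- distanceMatrix(desc, q = q)
  sn <- pathwaySnapshots(run@pathways)
  keep <- integer(0)
  for (f in sort(unique(sn))) {
    idx <- which(sn == f)
    rr <- removeRedundant(PathwaySet(as.list(run@pathways[idx])),
                          Dall[idx, idx, drop = FALSE],
                          redundancyThreshold)
    keep <- c(keep, idx[rr$kept])
  }
  keep <- sort(keep)
  D <- Dall[keep, keep, drop = FALSE]
  kept <- PathwaySet(as.list(run@pathways[keep]))
  if (!is.null(sampleSize) && sampleSize < length(keep)) {
    cls <- classifyLarge(
      new("PathwayDescriptorSet",
          points = desc@points[, , keep, drop = FALSE],
          dEnd = desc@dEnd[keep], zStart = zStart, zEnd = zEnd,
          origin = desc@origin),
      kept, nSnapshots(run@ensemble), sampleSize, topN, k, threshold, q,
      run@seed)
    labels <- clusterLabels(cls)
    run@clusters <- cls
  } else {
    cl <- clusterPathways(D, threshold)
    labels <- clusterLabels(cl)
    run@clusters <- cl
  }
  if (!is.null(distFile)) writeDistanceCache(D, distFile)
  run@frame <- frame
  run@descriptors <- desc
  run@keep <- keep
  run@distances <- D
  run@labels <- as.integer(labels)
  run@clusterParams <- list(threshold = threshold, nPoints = nPoints, q = q,
                            zStart = zStart, zEnd = zEnd,
                            mergeAngle = mergeAngle, smoothness = smoothness,
                            redundancyThreshold = redundancyThreshold,
                            sampleSize = sampleSize, topN = topN, k = k,
                            openRadius = 1.4)
  run
}

#' Re-cut a clustered run at a new threshold
#'
#' Reuses the stored tree and distance matrix; identification is untouched.
#'
#' @param run a clustered [TunnelRun-class]
#' @param threshold new cut height
#' @return the run with updated labels
#' @export
recutTunnels <- function(run, threshold) {
  if (is.null(run@clusters) || !is(run@clusters, "TunnelClusters"))
    stop("run has no stored cluster tree; run clusterTunnels first")
  run@clusters <- recutClusters(run@clusters, threshold)
  run@labels <- clusterLabels(run@clusters)
  run@clusterParams$threshold <- threshold
  run
}

#' Summarize and write all outputs of a clustered run
#'
#' @param run a clustered [TunnelRun-class]
#' @param dir output directory
#' @param openRadius bottleneck radius from which a tunnel counts as open
#' @param writeImages render PNG heat maps
#' @return the run with the summary table attached
#' @export
reportTunnels <- function(run, dir, openRadius = 1.4, writeImages = TRUE) {
  if (!length(run@keep)) stop("run is not clustered; run clusterTunnels")
  run@clusterParams$openRadius <- openRadius
  writeOutputs(run, dir, writeImages = writeImages)
  run@summary <- clusterSummary(PathwaySet(as.list(run@pathways[run@keep])),
                                run@labels, nSnapshots(run@ensemble),
                                openRadius)
  run
}

# ---- flat key=value run configuration -------------------------------------

.configKeys <- c(
  "input", "startResidues", "startAtoms", "startXyz",
  "probeRadius", "shellProbeRadius", "shellDepth", "costExponent",
  "maxRadius", "startMaxDist", "startMinClearance", "ballSpacing",
  "redundancyThreshold", "clusteringThreshold", "nPoints", "q", "zStart",
  "zEnd", "mergeAngle", "smoothness", "sampleSize", "topN", "k",
  "radiiTable", "seed", "outDir", "workers", "ballsPerAtom", "openRadius",
  "keepWater", "keepHetatm"
)

#' Read a flat key=value run configuration
#'
#' Unknown keys are errors, not warnings.  Values given in `overrides`
#' replace values from the file.
#'
#' @param file configuration file path (`NULL` for overrides only)
#' @param overrides named list of overriding values
#' @return validated named list of configuration values
#' @export
readRunConfig <- function(file = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(file)) {
    lines <- readLines(file)
    lines <- trimws(sub("#.*", "", lines))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) < 2) stop("malformed config line: '", ln, "'")
      cfg[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  bad <- setdiff(names(cfg), .configKeys)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  cfg
}

.cfgNum <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else as.numeric(cfg[[key]])
}
.cfgInt <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else as.integer(cfg[[key]])
}

#' Run the full three-stage analysis from a configuration
#'
#' `stages` selects which of identify/cluster/report run; earlier-stage
#' results are saved as RDS intermediates under `outDir` and reloaded when a
#' later stage runs alone, so e.g. re-clustering with a new threshold does
#' not repeat the identification.
#'
#' @param config configuration list from [readRunConfig()]
#' @param stages subset of `c("identify", "cluster", "report")`
#' @return the resulting [TunnelRun-class]
#' @export
runTunnels <- function(config,
                       stages = c("identify", "cluster", "report")) {
  stages <- match.arg(stages, c("identify", "cluster", "report"),
                      several.ok = TRUE)
  outDir <- config$outDir
  if (is.null(outDir)) stop("configuration must set outDir")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  idFile <- file.path(outDir, "identify.rds")
  clFile <- file.path(outDir, "cluster.rds")
  run <- NULL
  if ("identify" %in% stages) {
    if (is.null(config$input)) stop("configuration must set input")
    paths <- strsplit(config$input, "[,;[:space:]]+")[[1]]
    ens <- readEnsemble(paths,
                        keepWater = isTRUE(as.logical(config$keepWater)),
                        keepHetatm = isTRUE(as.logical(config$keepHetatm)))
    radii <- if (is.null(config$radiiTable)) defaultRadii()
             else defaultRadii(config$radiiTable)
    ens <- assignRadii(ens, radii)
    params <- searchParams(
      costExponent = .cfgNum(config, "costExponent", 2),
      maxRadius = .cfgNum(config, "maxRadius", 5),
      probeRadius = .cfgNum(config, "probeRadius", 0.9),
      shellProbeRadius = .cfgNum(config, "shellProbeRadius", 3),
      shellDepth = .cfgNum(config, "shellDepth", 4),
      startMaxDist = .cfgNum(config, "startMaxDist", 3),
      startMinClearance = .cfgNum(config, "startMinClearance", 2),
      ballSpacing = .cfgNum(config, "ballSpacing", 0.5),
      redundancyThreshold = .cfgNum(config, "redundancyThreshold",
                                    NA_real_))
    toNumVec <- function(x) if (is.null(x)) NULL else
      as.numeric(strsplit(x, "[,[:space:]]+")[[1]])
    run <- identifyTunnels(
      ens, params,
      residues = toNumVec(config$startResidues),
      atoms = toNumVec(config$startAtoms),
      xyz = toNumVec(config$startXyz),
      ballsPerAtom = .cfgInt(config, "ballsPerAtom", 12L),
      seed = .cfgInt(config, "seed", 1L),
      workers = .cfgInt(config, "workers", 1L))
    saveRDS(run, idFile)
  }
  if ("cluster" %in% stages) {
    if (is.null(run)) {
      if (!file.exists(idFile))
        stop("cluster stage needs the identification intermediate (",
             idFile, "); run the identify stage first")
      run <- readRDS(idFile)
    }
    run <- clusterTunnels(
      run,
      threshold = .cfgNum(config, "clusteringThreshold", 3.5),
      nPoints = .cfgInt(config, "nPoints", 20L),
      q = .cfgNum(config, "q", 1),
      zStart = .cfgNum(config, "zStart", 0),
      zEnd = .cfgNum(config, "zEnd", 0),
      mergeAngle = .cfgNum(config, "mergeAngle", 20),
      smoothness = .cfgNum(config, "smoothness", 20),
      redundancyThreshold = .cfgNum(config, "redundancyThreshold",
                                    NA_real_),
      sampleSize = if (is.null(config$sampleSize)) NULL
                   else as.integer(config$sampleSize),
      topN = .cfgInt(config, "topN", 6L),
      k = .cfgInt(config, "k", 5L),
      distFile = file.path(outDir, "distances.bin"))
    saveRDS(run, clFile)
  }
  if ("report" %in% stages) {
    if (is.null(run) || !length(run@keep)) {
      if (!file.exists(clFile))
        stop("report stage needs the clustering intermediate (", clFile,
             "); run the cluster stage first")
      run <- readRDS(clFile)
    }
    run <- reportTunnels(run, outDir,
                         openRadius = .cfgNum(config, "openRadius", 1.4))
  }
  run
}
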