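# Cluster ranking, per-cluster statistics, profiles, lining/bottleneck
# residues, heat-map matrices and output file generation.

#' Cluster priority
#'
#' Sum of the throughputs of a cluster's pathways divided by the total
#' number of analyzed snapshots; when a cluster holds several pathways from
#' the same snapshot only the highest throughput counts.
#'
#' @param throughputs per-pathway throughputs
#' @param snapshots per-pathway snapshot indices
#' @param labels per-pathway cluster labels
#' @param totalSnapshots total number of analyzed snapshots
#' @return named vector of priorities, one per cluster label
#' @export
clusterPriority <- function(throughputs, snapshots, labels, totalSnapshots) {
  stopifnot(totalSnapshots >= 1)
  out <- vapply(split(seq_along(labels), labels), function(idx) {
    best <- tapply(throughputs[idx], snapshots[idx], max)
    sum(best) / totalSnapshots
  }, numeric(1))
  out
}

# indices of the best (highest-throughput) pathway per snapshot in a cluster
.bestPerSnapshot <- function(throughputs, snapshots, idx) {
  idx[vapply(split(seq_along(idx), snapshots[idx]), function(k)
    k[which.max(throughputs[idx][k])], integer(1))]
}

#' Per-cluster summary statistics
#'
#' All statistics are computed over the best (highest-throughput) pathway
#' per snapshot, mirroring the priority rule.  `openCount` counts snapshots
#' whose best bottleneck radius reaches `openRadius` (default 1.4 A, the
#' water-probe convention).
#'
#' @param pathways a [PathwaySet-class]
#' @param labels per-pathway cluster labels
#' @param totalSnapshots total number of analyzed snapshots
#' @param openRadius bottleneck radius from which a tunnel counts as open
#' @return data.frame ranked by descending priority (ties by cluster id)
#' @export
clusterSummary <- function(pathways, labels, totalSnapshots,
                           openRadius = 1.4) {
  tp <- pathwayThroughputs(pathways)
  sn <- pathwaySnapshots(pathways)
  bn <- pathwayBottlenecks(pathways)
  ln <- pathwayLengths(pathways)
  cv <- pathwayCurvatures(pathways)
  rows <- lapply(sort(unique(labels)), function(cl) {
    idx <- which(labels == cl)
    best <- .bestPerSnapshot(tp, sn, idx)
    data.frame(
      cluster = cl,
      priority = sum(tp[best]) / totalSnapshots,
      snapshotCount = length(best),
      openCount = sum(bn[best] >= openRadius),
      meanBottleneck = mean(bn[best]),
      maxBottleneck = max(bn[best]),
      meanLength = mean(ln[best]),
      meanCurvature = mean(cv[best]),
      meanThroughput = mean(tp[best])
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$priority, out$cluster), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("rank", setdiff(names(out), "rank"))]
}

#' Pathway profile
#'
#' Radius in regular intervals along the pathway axis, together with the
#' distance of every sample from the reference origin S (for aligned,
#' straight-line profiles).  With the default `spacing = NULL` the profile
#' reports the pathway's own balls (already placed at regular intervals), so
#' its minimum is exactly the bottleneck radius; an explicit spacing
#' resamples the axis and queries fresh clearances.
#'
#' @param pathway a [Pathway-class]
#' @param ris the snapshot's [RIS-class]
#' @param spacing sampling interval (Angstrom) or `NULL`
#' @param origin reference point S (default: the pathway's first axis point)
#' @return data.frame with columns `arc`, `distFromS`, `radius`
#' @export
computeProfile <- function(pathway, ris, spacing = NULL, origin = NULL) {
  if (is.null(origin)) origin <- pathway@axis[1, ]
  if (is.null(spacing)) {
    pts <- pathway@axis
    arc <- c(0, cumsum(rowNorms(diff(pts))))
    radius <- pathway@radii
  } else {
    rs <- polylineResample(pathway@axis, spacing, appendEnd = FALSE)
    pts <- rs$points
    arc <- rs$arc
    radius <- clearance(ris, pts)
  }
  data.frame(
    arc = arc,
    distFromS = rowNorms(sweep(pts, 2, origin)),
    radius = radius
  )
}

#' Pathway-lining and bottleneck residues
#'
#' An atom (and its residue) is pathway-lining when the distance from its
#' vdw surface to the surface of some pathway ball is strictly smaller than
#' `liningThreshold`; bottleneck residues are evaluated against the
#' bottleneck ball only.  A spatial grid index accelerates the search.
#'
#' @param pathway a [Pathway-class]
#' @param ensemble the source [TunnelEnsemble-class]
#' @param snapshot frame index
#' @param liningThreshold,bottleneckThreshold surface-distance thresholds
#' @return data.frame with columns `resid`, `resname`, `chain`, `kind`
#'   (`"lining"` or `"bottleneck"`)
#' @export
contactResidues <- function(pathway, ensemble, snapshot = NULL,
                            liningThreshold = 3, bottleneckThreshold = 3) {
  if (is.null(snapshot)) snapshot <- pathway@snapshotIndex
  xyz <- snapshotCoords(ensemble, snapshot)
  at <- ensemble@atoms
  # gap from each atom center to nearest ball surface, then subtract the
  # atom radius to get surface-to-surface distance
  gap <- .cpp_nearest_gap(xyz, pathway@axis, pathway@radii)
  surfDist <- gap - ensemble@radii
  liningAtoms <- which(surfDist < liningThreshold)
  bpoint <- matrix(bottleneckPoint(pathway), 1, 3)
  bgap <- rowNorms(sweep(xyz, 2, as.vector(bpoint))) -
    bottleneckRadius(pathway) - ensemble@radii
  bottleneckAtoms <- which(bgap < bottleneckThreshold)
  resRows <- function(sel, kind) {
    if (!length(sel)) return(NULL)
    u <- unique(data.frame(resid = at$resid[sel], resname = at$resname[sel],
                           chain = at$chain[sel],
                           stringsAsFactors = FALSE))
    u$kind <- kind
    u
  }
  out <- rbind(resRows(liningAtoms, "lining"),
               resRows(bottleneckAtoms, "bottleneck"))
  if (is.null(out))
    out <- data.frame(resid = integer(0), resname = character(0),
                      chain = character(0), kind = character(0))
  rownames(out) <- NULL
  out
}

#' Residue occurrence fractions over a cluster
#'
#' @param pathways a [PathwaySet-class]
#' @param labels cluster labels
#' @param cluster cluster id
#' @param ensemble the source [TunnelEnsemble-class]
#' @param ... passed to [contactResidues()]
#' @return data.frame with per-residue occurrence fractions by contact kind
#' @export
residueFrequencies <- function(pathways, labels, cluster, ensemble, ...) {
  idx <- which(labels == cluster)
  if (!length(idx))
    return(data.frame(resid = integer(0), resname = character(0),
                      chain = character(0), kind = character(0),
                      fraction = numeric(0)))
  all <- lapply(idx, function(i)
    unique(contactResidues(pathways[[i]], ensemble, ...)))
  tab <- do.call(rbind, all)
  agg <- stats::aggregate(list(count = rep(1, nrow(tab))),
                          tab[, c("resid", "resname", "chain", "kind")],
                          sum)
  agg$fraction <- agg$count / length(idx)
  agg$count <- NULL
  agg[order(agg$kind, -agg$fraction, agg$resid), ]
}

#' Heat-map matrices
#'
#' Returns (a) one matrix per cluster: snapshot x distance-bin radii of the
#' best pathway per snapshot (straight-line profile, distance measured from
#' S), and (b) a global cluster x snapshot matrix of bottleneck radii.
#' Entries are `NA` where no pathway of the cluster exists in a snapshot.
#'
#' @param pathways a [PathwaySet-class]
#' @param labels cluster labels
#' @param totalSnapshots number of snapshots (matrix width)
#' @param profiles optional list of per-pathway profiles (as produced by
#'   [computeProfile()] with a common origin) for the per-cluster maps
#' @param binWidth distance-bin width of the per-cluster maps (Angstrom)
#' @return list with `bottleneck` (cluster x snapshot matrix) and
#'   `profiles` (named list of per-cluster matrices, possibly empty)
#' @export
heatmapMatrices <- function(pathways, labels, totalSnapshots,
                            profiles = NULL, binWidth = 1) {
  tp <- pathwayThroughputs(pathways)
  sn <- pathwaySnapshots(pathways)
  bn <- pathwayBottlenecks(pathways)
  clusters <- sort(unique(labels))
  B <- matrix(NA_real_, length(clusters), totalSnapshots,
              dimnames = list(cluster = clusters, snapshot = NULL))
  for (ci in seq_along(clusters)) {
    idx <- which(labels == clusters[ci])
    best <- .bestPerSnapshot(tp, sn, idx)
    B[ci, sn[best]] <- bn[best]
  }
  profMats <- list()
  if (!is.null(profiles)) {
    maxD <- max(vapply(profiles, function(p) max(p$distFromS), numeric(1)))
    breaks <- seq(0, maxD + binWidth, by = binWidth)
    nb <- length(breaks) - 1
    for (ci in seq_along(clusters)) {
      idx <- which(labels == clusters[ci])
      best <- .bestPerSnapshot(tp, sn, idx)
      M <- matrix(NA_real_, totalSnapshots, nb)
      for (i in best) {
        p <- profiles[[i]]
        bin <- pmin(pmax(findInterval(p$distFromS, breaks,
                                      rightmost.closed = TRUE), 1), nb)
        M[sn[i], ] <- as.numeric(tapply(p$radius, factor(bin,
                                                         levels = seq_len(nb)),
                                        min))
      }
      profMats[[as.character(clusters[ci])]] <- M
    }
  }
  list(bottleneck = B, profiles = profMats)
}

.writeHeatmapPNG <- function(M, file, xlab, ylab, main) {
  grDevices::png(file, width = 800, height = 400)
  on.exit(grDevices::dev.off())
  z <- t(M)
  graphics::image(seq_len(nrow(z)), seq_len(ncol(z)), z,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = xlab, ylab = ylab, main = main)
  invisible(file)
}

.tunnelBallPDB <- function(pathway, clusterId, serialOffset = 0L) {
  k <- nrow(pathway@axis)
  atoms <- data.frame(
    serial = serialOffset + seq_len(k),
    name = "H",
    element = "H",
    resname = "TUN",
    resid = clusterId,
    chain = "T",
    record = "HETATM",
    stringsAsFactors = FALSE
  )
  # ball radius is stored in the B-factor column; cluster id in the residue
  # number, so third-party tools can parse the tunnels
  formatPDBAtoms(atoms, pathway@axis, bfactor = pathway@radii)
}

#' Write all run outputs
#'
#' Writes the cluster summary CSV, the per-pathway CSV, profile CSVs,
#' bottleneck/throughput histogram data, residue lists, one tunnel PDB per
#' cluster (balls as pseudo-atoms, radius in the B-factor column, cluster id
#' as residue number), bottleneck heat-map data and image, PyMOL/VMD loader
#' scripts, and a run manifest with every parameter and seed.
#'
#' @param run a completed [TunnelRun-class] (see [runTunnels()])
#' @param dir output directory (created if needed)
#' @param writeImages also render PNG heat maps (default `TRUE`)
#' @return invisibly, the output directory
#' @export
writeOutputs <- function(run, dir, writeImages = TRUE) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory '", dir, "'")
  probe <- file.path(dir, ".write_test")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("output directory '", dir, "' is not writable")
  unlink(probe)

  keep <- run@keep
  pws <- PathwaySet(as.list(run@pathways[keep]))
  labels <- run@labels
  total <- nSnapshots(run@ensemble)
  summary <- clusterSummary(pws, labels, total,
                            openRadius = run@clusterParams$openRadius)
  write.csv(summary, file.path(dir, "summary.csv"), row.names = FALSE,
            quote = FALSE)

  pdf_ <- data.frame(
    pathway = seq_along(pws),
    snapshot = pathwaySnapshots(pws),
    cluster = labels,
    bottleneckRadius = pathwayBottlenecks(pws),
    length = pathwayLengths(pws),
    curvature = pathwayCurvatures(pws),
    throughput = pathwayThroughputs(pws),
    cost = pathwayCosts(pws)
  )
  write.csv(format(pdf_, digits = 10, trim = TRUE),
            file.path(dir, "pathways.csv"), row.names = FALSE, quote = FALSE)

  # histogram data
  bn <- pdf_$bottleneckRadius
  hb <- graphics::hist(bn, breaks = seq(0, max(bn) + 0.25, by = 0.25),
                       plot = FALSE)
  ht <- graphics::hist(pdf_$throughput, breaks = seq(0, 1, by = 0.05),
                       plot = FALSE)
  write.csv(data.frame(binStart = hb$breaks[-length(hb$breaks)],
                       binEnd = hb$breaks[-1], count = hb$counts),
            file.path(dir, "bottleneck_histogram.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(data.frame(binStart = ht$breaks[-length(ht$breaks)],
                       binEnd = ht$breaks[-1], count = ht$counts),
            file.path(dir, "throughput_histogram.csv"), row.names = FALSE,
            quote = FALSE)

  # heat maps
  hm <- heatmapMatrices(pws, labels, total)
  bm <- hm$bottleneck
  write.csv(cbind(data.frame(cluster = rownames(bm)), as.data.frame(bm)),
            file.path(dir, "bottleneck_heatmap.csv"), row.names = FALSE,
            quote = FALSE)
  if (writeImages)
    .writeHeatmapPNG(bm, file.path(dir, "bottleneck_heatmap.png"),
                     "snapshot", "cluster", "Bottleneck radius (A)")

  # residues (per cluster)
  resTab <- do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    rf <- residueFrequencies(pws, labels, cl, run@ensemble)
    if (nrow(rf)) cbind(cluster = cl, rf) else NULL
  }))
  if (is.null(resTab))
    resTab <- data.frame(cluster = integer(0), resid = integer(0),
                         resname = character(0), chain = character(0),
                         kind = character(0), fraction = numeric(0))
  write.csv(resTab, file.path(dir, "residues.csv"), row.names = FALSE,
            quote = FALSE)

  # profile CSVs (arc-length profiles of the best pathway per snapshot)
  tp <- pathwayThroughputs(pws); sn <- pathwaySnapshots(pws)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    best <- .bestPerSnapshot(tp, sn, idx)
    prof <- do.call(rbind, lapply(best, function(i) {
      pw <- pws[[i]]
      data.frame(snapshot = pw@snapshotIndex,
                 arc = c(0, cumsum(rowNorms(diff(pw@axis)))),
                 radius = pw@radii)
    }))
    write.csv(format(prof, digits = 8, trim = TRUE),
              file.path(dir, sprintf("profile_cluster_%03d.csv", cl)),
              row.names = FALSE, quote = FALSE)
  }

  # tunnel PDBs (best pathway per snapshot, one file per cluster)
  pdbFiles <- character(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    best <- .bestPerSnapshot(tp, sn, idx)
    lines <- character(0)
    off <- 0L
    for (i in best) {
      lines <- c(lines, .tunnelBallPDB(pws[[i]], cl, off))
      off <- off + nrow(pws[[i]]@axis)
    }
    f <- sprintf("tunnel_cluster_%03d.pdb", cl)
    writeLines(c(lines, "END"), file.path(dir, f))
    pdbFiles <- c(pdbFiles, f)
  }

  # visualization scripts
  writeLines(c(
    "# PyMOL loader for tunnelscape results",
    sprintf("load %s, tunnel_%s", pdbFiles, sub("\\.pdb$", "", pdbFiles)),
    "hide everything, tunnel_*",
    "show spheres, tunnel_*",
    "alter tunnel_*, vdw=b",
    "rebuild"
  ), file.path(dir, "view_tunnels.py"))
  writeLines(c(
    "# VMD loader for tunnelscape results",
    sprintf("mol new %s", pdbFiles),
    "mol modstyle 0 top VDW"
  ), file.path(dir, "view_tunnels.tcl"))

  # manifest: everything needed to reproduce the run bit for bit
  p <- run@params
  cp <- run@clusterParams
  manifest <- c(
    "tunnelscape run manifest",
    paste0("radiiTable=", run@ensemble@radiiTable),
    paste0("snapshots=", total),
    paste0("seed=", run@seed),
    paste0("costExponent=", p@costExponent),
    paste0("maxRadius=", p@maxRadius),
    paste0("probeRadius=", p@probeRadius),
    paste0("shellProbeRadius=", p@shellProbeRadius),
    paste0("shellDepth=", p@shellDepth),
    paste0("startMaxDist=", p@startMaxDist),
    paste0("startMinClearance=", p@startMinClearance),
    paste0("ballSpacing=", p@ballSpacing),
    paste0("redundancyThreshold=", cp$redundancyThreshold),
    paste0("clusteringThreshold=", cp$threshold),
    paste0("nPoints=", cp$nPoints),
    paste0("q=", cp$q),
    paste0("zStart=", cp$zStart),
    paste0("zEnd=", cp$zEnd),
    paste0("mergeAngle=", cp$mergeAngle),
    paste0("smoothness=", cp$smoothness),
    paste0("openRadius=", cp$openRadius),
    paste0("risErrorBound=", paste(format(run@errorBounds, digits = 6),
                                   collapse = ","))
  )
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
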