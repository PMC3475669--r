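#' @describeIn TunnelEnsemble number of atoms
#' @param x a `TunnelEnsemble`
#' @export
nAtoms <- function(x) nrow(x@atoms)

#' @describeIn TunnelEnsemble number of snapshots (frames)
#' @export
nSnapshots <- function(x) dim(x@coords)[3]

#' @describeIn TunnelEnsemble atom metadata table
#' @export
atomTable <- function(x) x@atoms

#' Coordinates of one snapshot
#' @param x a `TunnelEnsemble`
#' @param snapshot 1-based frame index
#' @return `n_atoms x 3` matrix (Angstrom)
#' @export
snapshotCoords <- function(x, snapshot = 1L) {
  stopifnot(is(x, "TunnelEnsemble"),
            snapshot >= 1, snapshot <= nSnapshots(x))
  x@coords[, , snapshot, drop = FALSE][, , 1]
}

#' @describeIn TunnelEnsemble assigned van der Waals radii
#' @export
vdwRadii <- function(x) x@radii

setMethod("show", "TunnelEnsemble", function(object) {
  cat("TunnelEnsemble:", nAtoms(object), "atoms,",
      nSnapshots(object), "snapshot(s)\n")
  if (!anyNA(object@radii))
    cat("  vdw radii assigned (table:", object@radiiTable, "), min",
        format(min(object@radii)), "A\n")
  else cat("  vdw radii not yet assigned\n")
})

setMethod("show", "RIS", function(object) {
  cat("RIS:", nrow(object@centers), "balls of radius",
      format(object@radius), "A for", length(unique(object@atomIndex)),
      "atoms\n  pathway-radius overestimation bound:",
      format(object@errorBound, digits = 4), "A (seed",
      object@seed, ")\n")
})

setMethod("show", "VoronoiGraph", function(object) {
  cat("VoronoiGraph:", nrow(object@vertices), "vertices,",
      nrow(object@edges), "edges (", object@nRealSites, "ball sites +",
      nrow(object@sites) - object@nRealSites, "shell sites)\n")
})

setMethod("show", "SearchParams", function(object) {
  cat("SearchParams: n =", object@costExponent,
      "| r_max =", object@maxRadius,
      "| r_B =", object@probeRadius,
      "| r_S =", object@shellProbeRadius,
      "| d_s =", object@shellDepth, "\n",
      " d_max =", object@startMaxDist,
      "| r_min =", object@startMinClearance,
      "| ball spacing =", object@ballSpacing, "A\n")
})

setMethod("show", "Pathway", function(object) {
  cat(sprintf(
    "Pathway (snapshot %d): length %.2f A, bottleneck %.3f A, cost %.3f, throughput %.3f\n",
    object@snapshotIndex, object@length, bottleneckRadius(object),
    object@cost, object@throughput))
})

setMethod("show", "TunnelClusters", function(object) {
  cat("TunnelClusters:", length(object@labels), "pathways in",
      length(unique(object@labels)), "clusters at threshold",
      object@threshold, "\n")
})

#' @describeIn Pathway radius of the narrowest ball
#' @param x a `Pathway`
#' @export
bottleneckRadius <- function(x) x@radii[x@bottleneckIndex]

#' @describeIn Pathway position of the narrowest ball
#' @export
bottleneckPoint <- function(x) x@axis[x@bottleneckIndex, ]

#' Per-pathway vectors over a PathwaySet
#' @param x a `PathwaySet`
#' @export
pathwayCosts <- function(x) vapply(x, slot, numeric(1), "cost")

#' @rdname pathwayCosts
#' @export
pathwayThroughputs <- function(x) vapply(x, slot, numeric(1), "throughput")

#' @rdname pathwayCosts
#' @export
pathwayBottlenecks <- function(x) vapply(x, bottleneckRadius, numeric(1))

#' @rdname pathwayCosts
#' @export
pathwaySnapshots <- function(x) vapply(x, slot, integer(1), "snapshotIndex")

#' @rdname pathwayCosts
#' @export
pathwayLengths <- function(x) vapply(x, slot, numeric(1), "length")

#' @rdname pathwayCosts
#' @export
pathwayCurvatures <- function(x) vapply(x, slot, numeric(1), "curvature")

#' @describeIn TunnelClusters cluster labels
#' @param x a `TunnelClusters` or `PathwayClassification`
#' @export
clusterLabels <- function(x) x@labels
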