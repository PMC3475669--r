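#' Aligned structure ensemble
#'
#' Container for one structure or an aligned conformational ensemble with
#' consistently numbered atoms.  Atom metadata is shared across snapshots;
#' only the coordinates vary per frame.
#'
#' @slot atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`, `record`.
#' @slot coords numeric array `n_atoms x 3 x n_snapshots`, in Angstrom.
#' @slot radii per-atom van der Waals radii (Angstrom); `NA` until
#'   [assignRadii()] has been called.
#' @slot radiiTable name of the radii set used (recorded in all reports).
#' @slot sourcePaths file identifiers the ensemble was read from.
#' @export
setClass("TunnelEnsemble",
  slots = c(
    atoms = "data.frame",
    coords = "array",
    radii = "numeric",
    radiiTable = "character",
    sourcePaths = "character"
  )
)

setValidity("TunnelEnsemble", function(object) {
  n <- nrow(object@atoms)
  d <- dim(object@coords)
  if (length(d) != 3 || d[1] != n || d[2] != 3)
    return("coords must be an n_atoms x 3 x n_snapshots array")
  if (d[3] < 1) return("ensemble needs at least one snapshot")
  if (anyDuplicated(object@atoms$serial))
    return("atom serials must be unique within a snapshot")
  if (!all(is.finite(object@coords)))
    return("coordinates must be finite")
  if (length(object@radii) != n)
    return("radii must have one entry per atom")
  ok <- is.na(object@radii) | object@radii > 0
  if (!all(ok)) return("assigned vdw radii must be positive")
  TRUE
})

#' Equal-radius ball representation of a structure (RIS)
#'
#' All atoms are approximated from the inside by balls whose common radius is
#' the smallest van der Waals radius in the snapshot.  The representation
#' surface never lies above the van der Waals surface, so pathway radii can
#' only be overestimated, by at most `errorBound`.
#'
#' @slot centers ball centers (perturbed), `m x 3`.
#' @slot centers0 unperturbed ball centers, `m x 3`.
#' @slot radius common ball radius (smallest vdw radius), Angstrom.
#' @slot atomIndex source atom row for every ball.
#' @slot errorBound upper bound on the pathway-radius overestimation
#'   (approximation gap plus the center perturbation allowance), Angstrom.
#' @slot seed seed of the deterministic center perturbation.
#' @export
setClass("RIS",
  slots = c(
    centers = "matrix",
    centers0 = "matrix",
    radius = "numeric",
    atomIndex = "integer",
    errorBound = "numeric",
    seed = "integer"
  )
)

setValidity("RIS", function(object) {
  if (nrow(object@centers) == 0) return("RIS has no balls")
  if (object@radius <= 0) return("ball radius must be positive")
  if (object@errorBound < 0) return("error bound must be non-negative")
  if (length(object@atomIndex) != nrow(object@centers))
    return("atomIndex must map every ball to an atom")
  TRUE
})

#' Voronoi vertex/edge graph of the RIS
#'
#' Vertices are circumcenters of the Delaunay tetrahedra of the RIS centers
#' (plus a shell of far dummy sites standing in for the unbounded exterior
#' cells); edges connect tetrahedra sharing a face.  Vertex clearances are
#' distances to the nearest RIS ball surface and may be negative inside
#' overlapping atoms.
#'
#' @slot sites all Voronoi sites: the RIS centers followed by the far dummy
#'   shell sites.
#' @slot nRealSites number of RIS centers among the sites.
#' @slot ballRadius the common RIS ball radius.
#' @slot vertices Voronoi vertex positions, `V x 3`.
#' @slot vertexSites defining site quadruple per vertex, `V x 4`.
#' @slot clearances distance from each vertex to the nearest ball surface.
#' @slot edges data.frame: `from`, `to` (vertex indices), `site1..3`
#'   (defining face sites), `minClearance`, `length`.
#' @slot shellRadius radius of the dummy-site shell.
#' @export
setClass("VoronoiGraph",
  slots = c(
    sites = "matrix",
    nRealSites = "integer",
    ballRadius = "numeric",
    vertices = "matrix",
    vertexSites = "matrix",
    clearances = "numeric",
    edges = "data.frame",
    shellRadius = "numeric"
  )
)

setValidity("VoronoiGraph", function(object) {
  if (nrow(object@vertices) != length(object@clearances))
    return("one clearance per vertex required")
  e <- object@edges
  need <- c("from", "to", "site1", "site2", "site3", "minClearance", "length")
  if (!all(need %in% names(e))) return("edge table is missing columns")
  if (nrow(e) > 0) {
    v <- nrow(object@vertices)
    if (any(e$from < 1 | e$from > v | e$to < 1 | e$to > v))
      return("edge endpoints out of range")
  }
  TRUE
})

#' Pathway search parameters
#'
#' @slot costExponent exponent n of the cost density 1/r(l)^n; 0 <= n <= 100.
#' @slot maxRadius cap applied to r(l) inside the cost integral (Angstrom).
#' @slot probeRadius probe radius r_B: edges narrower than this are removed.
#' @slot shellProbeRadius shell probe radius r_S used to find bulk solvent.
#' @slot shellDepth depth d_s of the surface layer below each bulk ball.
#' @slot startMaxDist search radius d_max of the starting-point optimization.
#' @slot startMinClearance required clearance r_min of the starting vertex.
#' @slot ballSpacing spacing of the balls placed along a pathway axis.
#' @slot redundancyThreshold pathway-distance threshold of the redundancy
#'   filter (defaults to the clustering threshold when `NA`).
#' @export
setClass("SearchParams",
  slots = c(
    costExponent = "numeric",
    maxRadius = "numeric",
    probeRadius = "numeric",
    shellProbeRadius = "numeric",
    shellDepth = "numeric",
    startMaxDist = "numeric",
    startMinClearance = "numeric",
    ballSpacing = "numeric",
    redundancyThreshold = "numeric"
  )
)

setValidity("SearchParams", function(object) {
  if (object@costExponent < 0 || object@costExponent > 100)
    return("costExponent must lie in [0, 100]")
  if (object@probeRadius <= 0) return("probeRadius must be positive")
  if (object@shellProbeRadius < object@probeRadius)
    return("shellProbeRadius must be >= probeRadius")
  if (object@maxRadius < 0.1) return("maxRadius must be >= 0.1 Angstrom")
  if (object@ballSpacing <= 0) return("ballSpacing must be positive")
  TRUE
})

#' Bulk-solvent and surface vertex labelling
#'
#' @slot bulk indices of bulk solvent vertices (reachable from the exterior
#'   by the shell probe).
#' @slot surface indices of surface vertices (reachable from a bulk ball by
#'   the probe within the confinement sphere of depth d_s).
#' @slot surfaceBoundary surface vertices with an edge to a non-surface
#'   vertex.
#' @slot bulkBoundary bulk vertices with an edge to a non-bulk vertex.
#' @slot bulkBallRadius radius of the bulk ball at each bulk vertex.
#' @export
setClass("VertexLabeling",
  slots = c(
    bulk = "integer",
    surface = "integer",
    surfaceBoundary = "integer",
    bulkBoundary = "integer",
    bulkBallRadius = "numeric"
  )
)

setValidity("VertexLabeling", function(object) {
  if (!all(object@surfaceBoundary %in% object@surface))
    return("surfaceBoundary must be a subset of surface")
  if (!all(object@bulkBoundary %in% object@bulk))
    return("bulkBoundary must be a subset of bulk")
  if (length(object@bulkBallRadius) != length(object@bulk))
    return("one bulk ball radius per bulk vertex required")
  TRUE
})

#' A single tunnel/channel pathway
#'
#' @slot snapshotIndex 1-based snapshot (frame) the pathway was found in.
#' @slot axis axis polyline sampled at regular intervals, `k x 3`.
#' @slot radii maximal non-colliding ball radius at every axis point
#'   (unclamped; the cost integral caps radii at `maxRadius` internally).
#' @slot cost integral of 1/r(l)^n along the axis.
#' @slot throughput exp(-cost), in (0, 1].
#' @slot length axis length (Angstrom).
#' @slot curvature axis length divided by the straight end-to-end distance.
#' @slot bottleneckIndex axis index of the narrowest ball.
#' @slot startVertex Voronoi start vertex the search used.
#' @export
setClass("Pathway",
  slots = c(
    snapshotIndex = "integer",
    axis = "matrix",
    radii = "numeric",
    cost = "numeric",
    throughput = "numeric",
    length = "numeric",
    curvature = "numeric",
    bottleneckIndex = "integer",
    startVertex = "integer"
  )
)

setValidity("Pathway", function(object) {
  if (nrow(object@axis) != length(object@radii))
    return("one radius per axis point required")
  if (object@cost < 0) return("cost must be non-negative")
  if (abs(object@throughput - exp(-object@cost)) > 1e-9)
    return("throughput must equal exp(-cost)")
  TRUE
})

#' List of pathways
#' @export
setClass("PathwaySet", contains = "SimpleList",
         prototype = prototype(elementType = "Pathway"))

#' Reference frame for pathway descriptors
#'
#' @slot origin the point S: center of gravity of the starting Voronoi
#'   vertices from all snapshots.
#' @slot directions unit directions of the direction-point set P, one row
#'   per point.
#' @slot lengths running-average straight lengths of the direction points.
#' @slot weights number of pathways merged into each direction point.
#' @slot mergeAngle angle threshold (degrees) used to build P.
#' @slot smoothness angle threshold (degrees) used to average d_end.
#' @export
setClass("ReferenceFrame",
  slots = c(
    origin = "numeric",
    directions = "matrix",
    lengths = "numeric",
    weights = "numeric",
    mergeAngle = "numeric",
    smoothness = "numeric"
  )
)

setValidity("ReferenceFrame", function(object) {
  if (length(object@lengths) != nrow(object@directions) ||
      length(object@weights) != nrow(object@directions))
    return("directions, lengths and weights must align")
  if (any(object@weights < 1)) return("weights must be >= 1")
  if (length(object@lengths) && any(object@lengths <= 0))
    return("averaged straight lengths must be positive")
  TRUE
})

#' Fixed-length pathway descriptors
#'
#' Each pathway is reduced to N sample points G_1..G_N (centers of gravity of
#' axis points binned by distance from the frame origin S), giving 3N
#' coordinates per pathway.
#'
#' @slot points array `N x 3 x n_pathways`.
#' @slot dEnd per-pathway averaged straight length d_end.
#' @slot zStart,zEnd sizes of the ignored start/end intervals.
#' @slot origin the frame origin S.
#' @export
setClass("PathwayDescriptorSet",
  slots = c(
    points = "array",
    dEnd = "numeric",
    zStart = "numeric",
    zEnd = "numeric",
    origin = "numeric"
  )
)

#' Average-link cluster tree with a threshold cut
#'
#' @slot merge,height agglomeration tree in `stats::hclust` encoding.
#' @slot labels cluster membership after cutting all merges above
#'   `threshold`.
#' @slot threshold the cut height.
#' @export
setClass("TunnelClusters",
  slots = c(
    merge = "matrix",
    height = "numeric",
    labels = "integer",
    threshold = "numeric"
  )
)

#' Sampled clustering + k-NN classification result
#'
#' @slot labels class per pathway: 1..topN are the top-priority clusters,
#'   topN + 1 is the catch-all "other" class.
#' @slot sampleIndex indices of the exactly clustered sample.
#' @slot sampleClusters the exact cluster tree of the sample.
#' @slot topN,k,seed the classification parameters.
#' @export
setClass("PathwayClassification",
  slots = c(
    labels = "integer",
    sampleIndex = "integer",
    sampleClusters = "TunnelClusters",
    topN = "integer",
    k = "integer",
    seed = "integer"
  )
)

#' Full analysis run container
#'
#' Filled progressively by the identification, clustering and reporting
#' stages; see [runTunnels()].
#'
#' @export
setClass("TunnelRun",
  slots = c(
    ensemble = "TunnelEnsemble",
    params = "SearchParams",
    clusterParams = "list",
    pathways = "PathwaySet",
    startVertexPos = "matrix",
    errorBounds = "numeric",
    seed = "integer",
    frame = "ANY",
    descriptors = "ANY",
    keep = "integer",
    distances = "ANY",
    clusters = "ANY",
    labels = "integer",
    summary = "ANY"
  ),
  prototype = prototype(frame = NULL, descriptors = NULL, distances = NULL,
                        clusters = NULL, summary = NULL)
)
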