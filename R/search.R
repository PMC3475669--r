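# Lowest-cost tunnel search in one snapshot: cost function, starting-point
# optimization, bulk/surface labelling, two-step Dijkstra, pathway ball
# placement and trimming, and redundancy removal.

#' Search parameter constructor
#'
#' Defaults: cost exponent n = 2 (the established balance between pathway
#' width and length), probe radius r_B = 0.9 A, shell probe r_S = 3 A, shell
#' depth d_s = 4 A, starting-point search radius d_max = 3 A with required
#' clearance r_min = 2 A, axis ball spacing 0.5 A and a cost-integral radius
#' cap r_max = 5 A.
#'
#' @param costExponent,maxRadius,probeRadius,shellProbeRadius,shellDepth
#'   see [SearchParams-class]
#' @param startMaxDist,startMinClearance,ballSpacing,redundancyThreshold
#'   see [SearchParams-class]
#' @return a [SearchParams-class]
#' @export
searchParams <- function(costExponent = 2, maxRadius = 5, probeRadius = 0.9,
                         shellProbeRadius = 3, shellDepth = 4,
                         startMaxDist = 3, startMinClearance = 2,
                         ballSpacing = 0.5, redundancyThreshold = NA_real_) {
  new("SearchParams", costExponent = costExponent, maxRadius = maxRadius,
      probeRadius = probeRadius, shellProbeRadius = shellProbeRadius,
      shellDepth = shellDepth, startMaxDist = startMaxDist,
      startMinClearance = startMinClearance, ballSpacing = ballSpacing,
      redundancyThreshold = redundancyThreshold)
}

#' Trapezoidal cost integral of a clearance profile
#'
#' Computes `integral_0^L dl / r(l)^n` with `r(l)` clamped to
#' `[0.1, maxRadius]`, using the trapezoidal rule with
#' `T = max(8, ceiling(L / 0.1))` trapezoids (grid spacing at most 0.1 A,
#' never fewer than 8 trapezoids).
#'
#' @param r clearance profile: a single number (constant corridor), a
#'   numeric vector of clearances at uniform positions spanning `[0, L]`,
#'   or a `function(l)`.
#' @param L corridor length (Angstrom)
#' @param costExponent exponent n
#' @param maxRadius radius cap r_max
#' @return the cost (non-negative scalar)
#' @export
costIntegral <- function(r, L, costExponent = 2, maxRadius = 5) {
  stopifnot(L >= 0)
  if (L == 0) return(0)
  T <- max(8L, ceiling(L / 0.1))
  l <- seq(0, L, length.out = T + 1L)
  rv <- if (is.function(r)) {
    vapply(l, r, numeric(1))
  } else if (length(r) == 1L) {
    rep(r, T + 1L)
  } else {
    stats::approx(seq(0, L, length.out = length(r)), r, xout = l)$y
  }
  rv <- pmin(pmax(rv, 0.1), maxRadius)
  f <- rv^(-costExponent)
  sum((f[-1] + f[-length(f)]) / 2) * (L / T)
}

#' Cost of Voronoi edges
#'
#' @param graph a [VoronoiGraph-class]
#' @param ris the [RIS-class] the graph was built from
#' @param params a [SearchParams-class]
#' @param edges edge indices (default: all)
#' @return numeric vector of edge costs
#' @export
edgeCost <- function(graph, ris, params, edges = seq_len(nrow(graph@edges))) {
  e <- graph@edges[edges, , drop = FALSE]
  es <- as.matrix(e[, c("site1", "site2", "site3")])
  # flag faces with dummy sites: closed form needs all-real defining sites
  es[es[, 3] > graph@nRealSites, ] <- -1L
  storage.mode(es) <- "integer"
  .cpp_edge_costs(cbind(e$from, e$to), es, graph@vertices, graph@sites,
                  graph@ballRadius, ris@centers,
                  rep(ris@radius, nrow(ris@centers)),
                  params@costExponent, params@maxRadius)
}

#' Remove edges not traversable by a probe
#'
#' @param graph a [VoronoiGraph-class]
#' @param probeRadius probe radius r_B
#' @return the graph with only edges of minimum clearance >= `probeRadius`;
#'   vertices are retained.
#' @export
filterEdges <- function(graph, probeRadius) {
  graph@edges <- graph@edges[graph@edges$minClearance >= probeRadius, ,
                             drop = FALSE]
  rownames(graph@edges) <- NULL
  graph
}

#' Initial starting point from a user selection
#'
#' Center of gravity of the selected entities, each contributing with the
#' same weight; a residue's position is the unweighted mean of its atoms.
#'
#' @param ensemble a [TunnelEnsemble-class]
#' @param snapshot frame index
#' @param residues integer vector of residue ids (optional)
#' @param atoms integer vector of atom serials (optional)
#' @param xyz explicit point(s), 3-vector or `k x 3` matrix (optional)
#' @return 3-vector (Angstrom)
#' @export
startingPoint <- function(ensemble, snapshot = 1L, residues = NULL,
                          atoms = NULL, xyz = NULL) {
  entities <- list()
  coords <- snapshotCoords(ensemble, snapshot)
  at <- ensemble@atoms
  for (r in residues) {
    sel <- which(at$resid == r)
    if (!length(sel)) stop("residue ", r, " not found")
    entities[[length(entities) + 1L]] <- colMeans(coords[sel, , drop = FALSE])
  }
  for (a in atoms) {
    sel <- which(at$serial == a)
    if (!length(sel)) stop("atom serial ", a, " not found")
    entities[[length(entities) + 1L]] <- coords[sel, ]
  }
  if (!is.null(xyz)) {
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    for (i in seq_len(nrow(xyz)))
      entities[[length(entities) + 1L]] <- xyz[i, ]
  }
  if (!length(entities)) stop("empty starting-point selection")
  colMeans(do.call(rbind, entities))
}

#' Starting-vertex optimization
#'
#' Four-stage cascade: (1) the closest vertex within `startMaxDist` of the
#' initial point whose clearance is at least `startMinClearance`; (2) failing
#' that, the vertex with maximal clearance within `startMaxDist`; (3) failing
#' that, both stages repeated with a 3 A search radius; (4) finally the
#' vertex closest to the initial point.  Ties break to the lowest vertex
#' index.
#'
#' @param graph a [VoronoiGraph-class]
#' @param point initial starting point (3-vector)
#' @param startMaxDist search radius d_max
#' @param startMinClearance required clearance r_min
#' @return list with elements `vertex` (index) and `stage` (1..4)
#' @export
optimizeStart <- function(graph, point, startMaxDist = 3,
                          startMinClearance = 2) {
  d <- rowNorms(sweep(graph@vertices, 2, point))
  cl <- graph@clearances
  pick <- function(dmax) {
    inRange <- which(d <= dmax)
    good <- inRange[cl[inRange] >= startMinClearance]
    if (length(good)) return(list(vertex = good[which.min(d[good])], sub = 1L))
    if (length(inRange))
      return(list(vertex = inRange[which.max(cl[inRange])], sub = 2L))
    NULL
  }
  res <- pick(startMaxDist)
  if (!is.null(res)) return(list(vertex = res$vertex, stage = res$sub))
  res <- pick(3)
  if (!is.null(res)) return(list(vertex = res$vertex, stage = 3L))
  list(vertex = which.min(d), stage = 4L)
}

#' Label bulk-solvent and surface vertices
#'
#' Bulk solvent vertices are found by flood fill from the exterior (the
#' dummy-shell region) over edges traversable by the shell probe r_S; each
#' receives a bulk ball of maximal radius not intersecting the RIS.  Surface
#' vertices are found by a bounded flood fill with the probe r_B from every
#' bulk ball, confined to the sphere of radius `r + d_s` around the ball
#' center.  Boundary subsets follow from adjacency to unlabelled vertices.
#'
#' @param graph a [VoronoiGraph-class] (unfiltered)
#' @param params a [SearchParams-class]
#' @return a [VertexLabeling-class]
#' @export
labelVertices <- function(graph, params) {
  e <- graph@edges
  V <- nrow(graph@vertices)
  # exterior seeds: vertices whose defining sites include a dummy site
  seeds <- which(apply(graph@vertexSites > graph@nRealSites, 1, any))
  if (!length(seeds)) stop("no exterior vertices found; the Voronoi shell ",
                           "construction failed")
  eS <- e[e$minClearance >= params@shellProbeRadius, c("from", "to")]
  g <- igraph::graph_from_edgelist(as.matrix(eS), directed = FALSE)
  if (igraph::vcount(g) < V) g <- igraph::add_vertices(g, V - igraph::vcount(g))
  comp <- igraph::components(g)$membership
  bulk <- which(comp %in% unique(comp[seeds]))
  # restrict to vertices that actually touch a shell-probe edge or are seeds
  touched <- unique(c(eS$from, eS$to, seeds))
  bulk <- sort(intersect(bulk, touched))
  if (!length(bulk)) stop("no bulk solvent vertices; check shellProbeRadius")
  isBulk <- logical(V)
  isBulk[bulk] <- TRUE
  bulkR <- graph@clearances[bulk]
  surf <- .cpp_surface_fill(as.matrix(e[, c("from", "to")]), e$minClearance,
                            graph@vertices, isBulk, replace(numeric(V),
                                                            bulk, bulkR),
                            params@probeRadius, params@shellDepth)
  surface <- which(surf)
  # boundary sets use all Voronoi edges
  inSurf <- logical(V); inSurf[surface] <- TRUE
  adjOther <- function(memb) {
    a <- memb[e$from] & !memb[e$to]
    b <- memb[e$to] & !memb[e$from]
    sort(unique(c(e$from[a], e$to[b])))
  }
  new("VertexLabeling", bulk = as.integer(bulk),
      surface = as.integer(surface),
      surfaceBoundary = as.integer(adjOther(inSurf)),
      bulkBoundary = as.integer(adjOther(isBulk)),
      bulkBallRadius = bulkR)
}

# Lowest-cost paths on an undirected weighted graph (Dijkstra via igraph).
# Returns a list of vertex-index paths, one per target (NULL if unreachable).
lowestCostPaths <- function(edges, weights, from, to, nVertices) {
  g <- igraph::make_empty_graph(n = nVertices, directed = FALSE)
  g <- igraph::add_edges(g, t(as.matrix(edges)))
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = from, to = to, weights = weights,
                           output = "vpath"))
  costs <- igraph::distances(g, v = from, to = to, weights = weights)
  list(paths = lapply(sp$vpath, as.integer), costs = as.numeric(costs))
}

.pathwayFromAxis <- function(axisPoints, ris, params, snapshotIndex,
                             startVertex) {
  rs <- polylineResample(axisPoints, params@ballSpacing)
  radii <- clearance(ris, rs$points)
  # terminal trimming: drop balls from the path end until one with radius
  # <= r_S is reached
  k <- length(radii)
  while (k > 2 && radii[k] > params@shellProbeRadius) k <- k - 1L
  pts <- rs$points[seq_len(k), , drop = FALSE]
  radii <- radii[seq_len(k)]
  if (nrow(pts) < 2) return(NULL)
  seg <- diff(pts)
  segLen <- sqrt(rowSums(seg * seg))
  len <- sum(segLen)
  # cost along the trimmed axis with the standard quadrature per segment
  cost <- 0
  for (i in seq_along(segLen)) {
    L <- segLen[i]
    if (L <= 0) next
    T <- max(8L, ceiling(L / 0.1))
    ts <- seq(0, 1, length.out = T + 1L)
    samp <- outer(1 - ts, pts[i, ]) + outer(ts, pts[i + 1L, ])
    rv <- pmin(pmax(clearance(ris, samp), 0.1), params@maxRadius)
    f <- rv^(-params@costExponent)
    cost <- cost + sum((f[-1] + f[-length(f)]) / 2) * (L / T)
  }
  straight <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
  new("Pathway", snapshotIndex = as.integer(snapshotIndex), axis = pts,
      radii = radii, cost = cost, throughput = exp(-cost), length = len,
      curvature = if (straight > 0) len / straight else Inf,
      bottleneckIndex = which.min(radii),
      startVertex = as.integer(startVertex))
}

#' Find tunnel pathways in one snapshot
#'
#' Two-step search on the probe-filtered Voronoi graph: Dijkstra from the
#' starting vertex to every reachable surface boundary vertex, then a single
#' lowest-cost continuation (restricted to surface and bulk vertices) to a
#' bulk solvent boundary vertex.  Balls are placed along each axis at
#' `ballSpacing` intervals with maximal non-colliding radii, trailing balls
#' wider than r_S are trimmed, and cost, throughput, bottleneck, length and
#' curvature are computed.
#'
#' @param graph a [VoronoiGraph-class] (unfiltered; filtering at r_B happens
#'   internally)
#' @param ris the source [RIS-class]
#' @param labeling a [VertexLabeling-class]
#' @param startVertex starting Voronoi vertex index
#' @param params a [SearchParams-class]
#' @param snapshotIndex frame index recorded in the pathways
#' @return a [PathwaySet-class] (possibly empty: no tunnels in the snapshot)
#' @export
findPathways <- function(graph, ris, labeling, startVertex, params,
                         snapshotIndex = 1L) {
  V <- nrow(graph@vertices)
  fg <- filterEdges(graph, params@probeRadius)
  e <- fg@edges
  if (!nrow(e)) return(PathwaySet())
  w <- edgeCost(fg, ris, params)
  # step 1 runs inside the structure: bulk solvent vertices are excluded
  # (the continuation into the bulk is exactly what step 2 adds)
  isBulk <- logical(V); isBulk[labeling@bulk] <- TRUE
  e1sel <- !isBulk[e$from] & !isBulk[e$to]
  e1 <- e[e1sel, , drop = FALSE]
  w1 <- w[e1sel]
  if (!nrow(e1)) return(PathwaySet())
  reach <- intersect(labeling@surfaceBoundary, unique(c(e1$from, e1$to)))
  if (!length(reach)) return(PathwaySet())
  step1 <- lowestCostPaths(e1[, c("from", "to")], w1, startVertex, reach, V)
  ok <- is.finite(step1$costs) & lengths(step1$paths) > 0
  if (!any(ok)) return(PathwaySet())
  # step 2: continuation through surface/bulk vertices only
  allowed <- sort(unique(c(labeling@surface, labeling@bulk)))
  inAllowed <- logical(V); inAllowed[allowed] <- TRUE
  e2sel <- inAllowed[e$from] & inAllowed[e$to]
  e2 <- e[e2sel, c("from", "to")]
  w2 <- w[e2sel]
  targets <- intersect(labeling@bulkBoundary,
                       unique(c(e2$from, e2$to)))
  paths <- list()
  for (i in which(ok)) {
    p1 <- step1$paths[[i]]
    endV <- p1[length(p1)]
    if (length(targets) && nrow(e2)) {
      s2 <- lowestCostPaths(e2, w2, endV, targets, V)
      ok2 <- is.finite(s2$costs) & lengths(s2$paths) > 0
      if (any(ok2)) {
        # cheapest continuation; ties to the lowest target vertex index
        best <- which(ok2)[which.min(s2$costs[ok2])]
        p2 <- s2$paths[[best]]
        p1 <- c(p1, p2[-1])
      }
    }
    if (length(p1) >= 2) paths[[length(paths) + 1L]] <- p1
  }
  out <- list()
  for (p in paths) {
    pw <- .pathwayFromAxis(graph@vertices[p, , drop = FALSE], ris, params,
                           snapshotIndex, startVertex)
    if (!is.null(pw)) out[[length(out) + 1L]] <- pw
  }
  PathwaySet(out)
}

#' PathwaySet constructor
#' @param pathways list of [Pathway-class] objects
#' @export
PathwaySet <- function(pathways = list()) {
  new("PathwaySet", S4Vectors::SimpleList(pathways))
}

#' Remove redundant pathways
#'
#' Greedy cost-ascending selection: the lowest-cost pathway is retained and
#' all pathways within `threshold` of it are discarded; the procedure
#' repeats on the remainder.  Ties break to the earliest pathway index.
#'
#' @param pathways a [PathwaySet-class] (typically from one snapshot)
#' @param distance pathway distance: a function(pathwayA, pathwayB) or a
#'   precomputed symmetric matrix
#' @param threshold redundancy distance threshold
#' @return list with `pathways` (the retained [PathwaySet-class]) and
#'   `kept` (indices into the input)
#' @export
removeRedundant <- function(pathways, distance, threshold) {
  n <- length(pathways)
  if (n == 0) return(list(pathways = pathways, kept = integer(0)))
  costs <- pathwayCosts(pathways)
  ord <- order(costs, seq_len(n))
  alive <- rep(TRUE, n)
  kept <- integer(0)
  distAt <- function(i, j) {
    if (is.matrix(distance)) distance[i, j]
    else distance(pathways[[i]], pathways[[j]])
  }
  for (i in ord) {
    if (!alive[i]) next
    kept <- c(kept, i)
    alive[i] <- FALSE
    for (j in which(alive))
      if (distAt(i, j) <= threshold) alive[j] <- FALSE
  }
  kept <- sort(kept)
  list(pathways = PathwaySet(as.list(pathways[kept])), kept = kept)
}

# Simple geometric axis distance used by the redundancy filter: mean
# distance between corresponding points of the two axes resampled at N
# equal arc-length fractions.
axisDistance <- function(a, b, n = 20L) {
  sa <- polylineResample(a@axis, max(a@length, 1e-6) / (n - 1))$points
  sb <- polylineResample(b@axis, max(b@length, 1e-6) / (n - 1))$points
  k <- min(nrow(sa), nrow(sb))
  mean(rowNorms(sa[seq_len(k), , drop = FALSE] -
                  sb[seq_len(k), , drop = FALSE]))
}
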