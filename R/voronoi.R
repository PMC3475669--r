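# Equal-radius ball representation (RIS) and its Voronoi vertex/edge graph.

# max perturbation of a center coordinate (strictly below 0.001 A)
.perturbHalfWidth <- 5e-4
.perturbNormBound <- sqrt(3) * .perturbHalfWidth

# Covering angle (degrees -> radians here) of the k-point golden-angle
# direction set: the largest angular distance of any sphere point to its
# nearest direction.  Evaluated numerically once per k and cached.
.coveringAngleCache <- new.env(parent = emptyenv())
.coveringAngle <- function(k) {
  key <- as.character(k)
  if (!is.null(.coveringAngleCache[[key]])) return(.coveringAngleCache[[key]])
  dirs <- fibonacciSphere(k)
  test <- fibonacciSphere(4000)
  cosang <- test %*% t(dirs)
  theta <- max(acos(pmin(1, apply(cosang, 1, max))))
  .coveringAngleCache[[key]] <- theta
  theta
}

# Worst-case gap between an atom's vdw sphere surface and the surface of its
# ball arrangement: one ball at the center plus k balls at distance d = R - r.
.atomGap <- function(R, r, k) {
  if (R - r <= 1e-9) return(0)
  if (k <= 0) return(R - r)                       # center ball only
  theta <- .coveringAngle(k)
  d <- R - r
  gapShell <- sqrt(R^2 + d^2 - 2 * R * d * cos(theta)) - r
  min(R - r, max(0, gapShell))
}

#' Build the equal-radius ball representation of a snapshot
#'
#' Atoms whose radius equals the smallest radius in the snapshot are
#' represented by a single ball; larger atoms by up to `ballsPerAtom` balls
#' of the smallest radius, one at the atom center and the rest on a sphere
#' of radius `R_atom - r_min` in fixed near-uniform directions, so every
#' ball lies inside its atom.  All centers are then perturbed by a seeded
#' pseudorandom offset below 0.001 Angstrom per coordinate to avoid
#' co-spherical degeneracies.  The reported `errorBound` caps the possible
#' overestimation of pathway radii (worst surface gap of the arrangement
#' plus the perturbation allowance).
#'
#' @param ensemble a [TunnelEnsemble-class] with radii assigned
#' @param snapshot frame index
#' @param ballsPerAtom maximal number of balls per atom (>= 1)
#' @param seed perturbation seed (recorded in the RIS and the run manifest)
#' @return a [RIS-class]
#' @export
buildRIS <- function(ensemble, snapshot = 1L, ballsPerAtom = 12L, seed = 1L) {
  stopifnot(is(ensemble, "TunnelEnsemble"), ballsPerAtom >= 1)
  if (anyNA(ensemble@radii))
    stop("assign vdw radii before building the RIS (see assignRadii)")
  xyz <- snapshotCoords(ensemble, snapshot)
  if (nrow(xyz) == 0) stop("empty snapshot")
  radii <- ensemble@radii
  rmin <- min(radii)
  tol <- 1e-9
  centers <- vector("list", nrow(xyz))
  atomIdx <- vector("list", nrow(xyz))
  kShell <- ballsPerAtom - 1L
  dirs <- if (kShell > 0) fibonacciSphere(kShell) else NULL
  gapMax <- 0
  for (i in seq_len(nrow(xyz))) {
    if (radii[i] - rmin <= tol) {
      centers[[i]] <- matrix(xyz[i, ], 1, 3)
    } else {
      d <- radii[i] - rmin
      shell <- if (kShell > 0)
        sweep(dirs * d, 2, xyz[i, ], "+") else NULL
      centers[[i]] <- rbind(matrix(xyz[i, ], 1, 3), shell)
      gapMax <- max(gapMax, .atomGap(radii[i], rmin, kShell))
    }
    atomIdx[[i]] <- rep(i, nrow(centers[[i]]))
  }
  centers <- do.call(rbind, centers)
  atomIdx <- unlist(atomIdx)
  pert <- matrix((lcgRunif(3 * nrow(centers), seed) - 0.5) *
                   2 * .perturbHalfWidth, ncol = 3)
  new("RIS", centers = centers + pert, centers0 = centers, radius = rmin,
      atomIndex = as.integer(atomIdx),
      errorBound = gapMax + .perturbNormBound, seed = as.integer(seed))
}

#' Distance to the nearest RIS ball surface
#'
#' Negative inside a ball.  Uses a uniform-grid spatial index, so the cost
#' per query is sublinear in the number of balls.
#'
#' @param ris a [RIS-class]
#' @param points 3-vector or `k x 3` matrix
#' @return numeric vector of clearances (Angstrom)
#' @export
clearance <- function(ris, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  .cpp_nearest_gap(points, ris@centers,
                   rep(ris@radius, nrow(ris@centers)))
}

# clearance against the true vdw spheres of the source snapshot
vdwClearance <- function(ensemble, snapshot, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  .cpp_nearest_gap(points, snapshotCoords(ensemble, snapshot),
                   ensemble@radii)
}

#' Build the Voronoi vertex/edge graph of an RIS
#'
#' The Delaunay triangulation of the ball centers (plus a shell of far dummy
#' sites standing in for the unbounded exterior cells) yields one Voronoi
#' vertex per tetrahedron (its circumcenter) and one edge per interior face.
#' The minimum clearance along an edge between real-site tetrahedra follows
#' in closed form from the three defining sites (every edge point is
#' equidistant from them and they are its nearest sites); edges touching
#' dummy sites are sampled against the global clearance field.
#'
#' @param ris a [RIS-class]
#' @param shellMargin distance (Angstrom) of the dummy-site shell beyond the
#'   structure's bounding sphere; results must not depend on it.
#' @param nShellSites number of dummy shell sites.
#' @return a [VoronoiGraph-class]
#' @export
buildVoronoiGraph <- function(ris, shellMargin = 30, nShellSites = 42L) {
  centers <- ris@centers
  if (nrow(centers) < 5) stop("need at least 5 ball centers")
  centroid <- colMeans(centers)
  rStruct <- max(rowNorms(sweep(centers, 2, centroid)))
  shellRadius <- rStruct + shellMargin
  dummies <- sweep(fibonacciSphere(nShellSites) * shellRadius, 2, centroid,
                   "+")
  sites <- rbind(centers, dummies)
  dt <- .cpp_delaunay(sites)
  if (dt$status != 0)
    stop("degenerate Delaunay triangulation; rebuild the RIS with a ",
         "different perturbation seed")
  tet <- dt$tetra
  verts <- dt$circumcenter
  nReal <- nrow(centers)
  if (!any(apply(tet <= nReal, 1, all)))
    stop("degenerate site configuration (e.g. coplanar centers): no ",
         "tetrahedra among the ball sites; rebuild the RIS with a ",
         "different perturbation seed")
  cl <- .cpp_nearest_gap(verts, centers, rep(ris@radius, nReal))

  # edges: tetrahedra sharing a face
  m <- nrow(tet)
  faces <- rbind(tet[, c(1, 2, 3)], tet[, c(1, 2, 4)],
                 tet[, c(1, 3, 4)], tet[, c(2, 3, 4)])
  owner <- rep(seq_len(m), 4)
  key <- paste(faces[, 1], faces[, 2], faces[, 3])
  ord <- order(key, owner)
  key <- key[ord]; owner <- owner[ord]; faces <- faces[ord, , drop = FALSE]
  sameAsNext <- c(key[-1] == key[-length(key)], FALSE)
  i1 <- which(sameAsNext)
  from <- owner[i1]
  to <- owner[i1 + 1]
  fsites <- faces[i1, , drop = FALSE]
  elen <- rowNorms(verts[from, , drop = FALSE] - verts[to, , drop = FALSE])

  minCl <- numeric(length(from))
  realFace <- fsites[, 3] <= nReal  # sites sorted, so col 3 is the largest
  if (any(realFace)) {
    A <- verts[from[realFace], , drop = FALSE]
    B <- verts[to[realFace], , drop = FALSE]
    dmin <- rep(Inf, sum(realFace))
    for (k in 1:3) {
      S <- sites[fsites[realFace, k], , drop = FALSE]
      AB <- B - A
      len2 <- rowSums(AB * AB)
      t <- rowSums((S - A) * AB) / pmax(len2, 1e-300)
      t <- pmin(1, pmax(0, t))
      proj <- A + AB * t
      dmin <- pmin(dmin, rowNorms(S - proj))
    }
    minCl[realFace] <- dmin - ris@radius
  }
  if (any(!realFace)) {
    # sample the clearance field along far-shell edges
    idx <- which(!realFace)
    ts <- seq(0, 1, length.out = 25)
    A <- verts[from[idx], , drop = FALSE]
    B <- verts[to[idx], , drop = FALSE]
    pts <- do.call(rbind, lapply(ts, function(t) A * (1 - t) + B * t))
    g <- .cpp_nearest_gap(pts, centers, rep(ris@radius, nReal))
    minCl[idx] <- apply(matrix(g, nrow = length(idx)), 1, min)
  }
  edges <- data.frame(from = from, to = to, site1 = fsites[, 1],
                      site2 = fsites[, 2], site3 = fsites[, 3],
                      minClearance = minCl, length = elen)
  new("VoronoiGraph", sites = sites, nRealSites = as.integer(nReal),
      ballRadius = ris@radius, vertices = verts, vertexSites = tet,
      clearances = cl, edges = edges, shellRadius = shellRadius)
}

#' Minimum clearance along Voronoi edges
#'
#' @param graph a [VoronoiGraph-class]
#' @param edges edge indices (default: all)
#' @return numeric vector of minimum clearances
#' @export
edgeMinClearance <- function(graph, edges = seq_len(nrow(graph@edges))) {
  graph@edges$minClearance[edges]
}
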