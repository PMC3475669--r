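# Pathway descriptors, weighted pathway distances, average-link clustering
# and the sampled-clustering + k-NN scale-out for very large pathway sets.

#' Build the reference frame for pathway descriptors
#'
#' The origin S is the center of gravity of the starting Voronoi vertices
#' from all snapshots.  Pathways are processed in ascending cost order; the
#' extreme point X of each (the axis point farthest from S) either founds a
#' new direction point (when its angle to every existing one exceeds
#' `mergeAngle`) or updates the nearest direction point's straight length by
#' a running weighted mean and increments its weight.
#'
#' @param pathways a [PathwaySet-class] with all (pre-redundancy) pathways
#' @param startVertexPos matrix of per-snapshot starting-vertex positions
#' @param mergeAngle angle threshold (degrees) for merging extreme points
#' @param smoothness angle threshold (degrees) later used for d_end
#' @return a [ReferenceFrame-class]
#' @export
buildReferenceFrame <- function(pathways, startVertexPos, mergeAngle = 20,
                                smoothness = 20) {
  stopifnot(length(pathways) >= 1)
  if (is.null(dim(startVertexPos)))
    startVertexPos <- matrix(startVertexPos, ncol = 3)
  S <- colMeans(startVertexPos)
  ord <- order(pathwayCosts(pathways), seq_along(pathways))
  dirs <- NULL
  lens <- numeric(0)
  wts <- numeric(0)
  for (i in ord) {
    ax <- pathways[[i]]@axis
    d <- rowNorms(sweep(ax, 2, S))
    xi <- which.max(d)
    X <- ax[xi, ]
    sx <- d[xi]
    if (sx <= 1e-12) next
    if (is.null(dirs)) {
      dirs <- matrix((X - S) / sx, 1, 3)
      lens <- sx
      wts <- 1
      next
    }
    ang <- anglesToRows(dirs, X - S)
    j <- which.min(ang)
    if (ang[j] > mergeAngle) {
      dirs <- rbind(dirs, (X - S) / sx)
      lens <- c(lens, sx)
      wts <- c(wts, 1)
    } else {
      lens[j] <- (sx + wts[j] * lens[j]) / (wts[j] + 1)
      wts[j] <- wts[j] + 1
    }
  }
  new("ReferenceFrame", origin = S, directions = dirs, lengths = lens,
      weights = wts, mergeAngle = mergeAngle, smoothness = smoothness)
}

# d_end for one pathway: weighted mean of the averaged straight lengths of
# the direction points within `smoothness` degrees of the pathway's extreme
# direction (the nearest direction point if none is within).
.dEnd <- function(frame, X) {
  v <- X - frame@origin
  ang <- anglesToRows(frame@directions, v)
  q <- which(ang <= frame@smoothness)
  if (!length(q)) q <- which.min(ang)
  sum(frame@weights[q] * frame@lengths[q]) / sum(frame@weights[q])
}

#' Convert pathways into fixed-length point descriptors
#'
#' For each pathway the distance d_end (local average of straight lengths)
#' is split into `N + 2` intervals `I_start, I_1..I_N, I_end`; `G_i` is the
#' center of gravity of the axis points whose distance from S falls in
#' `I_i`.  Empty inner bins are filled by linear interpolation between the
#' neighbouring non-empty points (ends extrapolated from the nearest
#' segment) so every descriptor has exactly `N` points.
#'
#' @param pathways a [PathwaySet-class]
#' @param frame a [ReferenceFrame-class] built from the full pathway set
#' @param nPoints number of descriptor points N
#' @param zStart,zEnd sizes of the ignored start/end intervals (Angstrom)
#' @return a [PathwayDescriptorSet-class]
#' @export
pathwayDescriptors <- function(pathways, frame, nPoints = 20L, zStart = 0,
                               zEnd = 0) {
  n <- length(pathways)
  N <- as.integer(nPoints)
  pts <- array(NA_real_, c(N, 3, n))
  dEnds <- numeric(n)
  S <- frame@origin
  for (p in seq_len(n)) {
    ax <- pathways[[p]]@axis
    d <- rowNorms(sweep(ax, 2, S))
    X <- ax[which.max(d), ]
    dEnd <- .dEnd(frame, X)
    if (dEnd <= zStart + zEnd)
      stop("d_end (", format(dEnd), ") must exceed zStart + zEnd")
    dEnds[p] <- dEnd
    h <- (dEnd - zStart - zEnd) / N
    bin <- floor((d - zStart) / h) + 1
    bin[d < zStart] <- 0                  # I_start
    bin[d >= dEnd - zEnd] <- N + 1        # I_end
    bin[bin > N] <- N + 1
    G <- matrix(NA_real_, N, 3)
    for (i in seq_len(N)) {
      sel <- bin == i
      if (any(sel)) G[i, ] <- colMeans(ax[sel, , drop = FALSE])
    }
    pts[, , p] <- .fillEmptyBins(G)
  }
  new("PathwayDescriptorSet", points = pts, dEnd = dEnds, zStart = zStart,
      zEnd = zEnd, origin = S)
}

# linear interpolation / extrapolation over empty descriptor bins
.fillEmptyBins <- function(G) {
  good <- which(!is.na(G[, 1]))
  if (!length(good)) stop("pathway has no axis points in any descriptor bin")
  if (length(good) == 1)
    return(matrix(G[good, ], nrow(G), 3, byrow = TRUE))
  for (j in 1:3)
    G[, j] <- stats::approx(good, G[good, j], xout = seq_len(nrow(G)),
                            rule = 1)$y
  # extrapolate the ends from the nearest segment
  lo <- good[1]; hi <- good[length(good)]
  if (lo > 1) {
    slope <- G[lo + 1, ] - G[lo, ]
    for (i in seq_len(lo - 1)) G[i, ] <- G[lo, ] - (lo - i) * slope
  }
  if (hi < nrow(G)) {
    slope <- G[hi, ] - G[hi - 1, ]
    for (i in (hi + 1):nrow(G)) G[i, ] <- G[hi, ] + (i - hi) * slope
  }
  G
}

#' Linear weight function coefficients
#'
#' Solves `w(x) = a x + b` with `w(1) / w(0) = q` and `w(0.5) = 1`:
#' `b = 2 / (q + 1)`, `a = 2 (q - 1) / (q + 1)`.
#'
#' @param q ratio between end-point and start-point weights (> 0)
#' @return named vector `c(a, b)`
#' @export
weightCoefficients <- function(q) {
  if (!is.numeric(q) || q <= 0) stop("weighting parameter q must be positive")
  c(a = 2 * (q - 1) / (q + 1), b = 2 / (q + 1))
}

#' Weighted distance between two pathway descriptors
#'
#' `d(A, B) = (1/N) sum_i w(x_i) |G_Ai - G_Bi|` with `x_i = (i - 0.5) / N`.
#' The equivalent geometric form moves each `G_i` to
#' `K_i = S + w(x_i) (G_i - S)` and averages `|K_Ai - K_Bi|`; both forms are
#' available and agree to machine precision.
#'
#' @param descriptors a [PathwayDescriptorSet-class]
#' @param i,j pathway indices
#' @param q weighting parameter
#' @param form `"weighted"` (weighted point distances) or `"kpoint"`
#' @return the distance (non-negative scalar)
#' @export
pathwayDistance <- function(descriptors, i, j, q = 1,
                            form = c("weighted", "kpoint")) {
  form <- match.arg(form)
  A <- descriptors@points[, , i]
  B <- descriptors@points[, , j]
  N <- nrow(A)
  w <- .binWeights(N, q)
  if (form == "weighted") {
    mean(w * rowNorms(A - B))
  } else {
    S <- descriptors@origin
    KA <- sweep(sweep(A, 2, S) * w, 2, S, "+")
    KB <- sweep(sweep(B, 2, S) * w, 2, S, "+")
    mean(rowNorms(KA - KB))
  }
}

.binWeights <- function(N, q) {
  ab <- weightCoefficients(q)
  x <- (seq_len(N) - 0.5) / N
  ab["a"] * x + ab["b"]
}

#' Pairwise pathway distance matrix
#'
#' @param descriptors a [PathwayDescriptorSet-class]
#' @param q weighting parameter
#' @param file optional path: the matrix is also persisted as a text-headed
#'   binary cache for re-clustering without recomputation
#' @return symmetric matrix of pathway distances
#' @export
distanceMatrix <- function(descriptors, q = 1, file = NULL) {
  pts <- descriptors@points
  n <- dim(pts)[3]
  N <- dim(pts)[1]
  w <- .binWeights(N, q)
  D <- matrix(0, n, n)
  if (n > 1) {
    flatx <- t(pts[, 1, ]); flaty <- t(pts[, 2, ]); flatz <- t(pts[, 3, ])
    for (i in seq_len(n - 1)) {
      jj <- (i + 1):n
      dd <- sqrt((flatx[jj, , drop = FALSE] -
                    matrix(flatx[i, ], length(jj), N, byrow = TRUE))^2 +
                 (flaty[jj, , drop = FALSE] -
                    matrix(flaty[i, ], length(jj), N, byrow = TRUE))^2 +
                 (flatz[jj, , drop = FALSE] -
                    matrix(flatz[i, ], length(jj), N, byrow = TRUE))^2)
      D[i, jj] <- as.vector(dd %*% w) / N
      D[jj, i] <- D[i, jj]
    }
  }
  if (!is.null(file)) writeDistanceCache(D, file)
  D
}

#' @rdname distanceMatrix
#' @param D a distance matrix to persist
#' @export
writeDistanceCache <- function(D, file) {
  con <- file(file, "wb")
  on.exit(close(con))
  hdr <- sprintf("tunnelscape-distmatrix 1 %d float64\n", nrow(D))
  writeBin(charToRaw(hdr), con)
  writeBin(as.vector(D), con)
  invisible(file)
}

#' @rdname distanceMatrix
#' @export
readDistanceCache <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ch <- readBin(con, "raw", 1)
    if (!length(ch) || ch == charToRaw("\n")) break
    hdr <- c(hdr, rawToChar(ch))
  }
  parts <- strsplit(paste(hdr, collapse = ""), " ")[[1]]
  if (parts[1] != "tunnelscape-distmatrix")
    stop("not a tunnelscape distance cache")
  n <- as.integer(parts[3])
  matrix(readBin(con, "double", n * n), n, n)
}

#' Average-link hierarchical clustering with threshold cut
#'
#' Agglomerates with average linkage (ties in the minimal pair break to the
#' lowest indices), stores the full merge tree in `stats::hclust` encoding,
#' and cuts it at `threshold`: clusters are the components remaining after
#' removing all merges higher than the threshold.  Use [recutClusters()] to
#' re-cut the stored tree at a new threshold without re-clustering.
#'
#' @param D symmetric distance matrix with zero diagonal
#' @param threshold cut height
#' @return a [TunnelClusters-class]
#' @export
clusterPathways <- function(D, threshold) {
  if (!is.matrix(D) || nrow(D) != ncol(D) ||
      max(abs(D - t(D))) > 1e-8)
    stop("distance matrix must be symmetric")
  n <- nrow(D)
  if (n == 1) {
    return(new("TunnelClusters", merge = matrix(integer(0), 0, 2),
               height = numeric(0), labels = 1L, threshold = threshold))
  }
  act <- as.list(seq_len(n))           # members of each active cluster
  id <- -seq_len(n)                    # hclust ids (negative = singleton)
  size <- rep(1L, n)
  W <- D
  diag(W) <- Inf
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  alive <- rep(TRUE, n)
  for (s in seq_len(n - 1)) {
    sub <- which(alive)
    Wsub <- W[sub, sub, drop = FALSE]
    k <- which.min(Wsub)               # column-major: lowest i, then j
    i <- sub[(k - 1) %% length(sub) + 1]
    j <- sub[(k - 1) %/% length(sub) + 1]
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    height[s] <- W[i, j]
    merge[s, ] <- sort(c(id[i], id[j]))
    # Lance-Williams average-link update into slot i
    others <- sub[sub != i & sub != j]
    if (length(others)) {
      W[i, others] <- (size[i] * W[i, others] + size[j] * W[j, others]) /
        (size[i] + size[j])
      W[others, i] <- W[i, others]
    }
    size[i] <- size[i] + size[j]
    id[i] <- s
    alive[j] <- FALSE
    act[[i]] <- c(act[[i]], act[[j]])
  }
  cl <- new("TunnelClusters", merge = merge, height = height,
            labels = integer(n), threshold = threshold)
  recutClusters(cl, threshold)
}

#' @rdname clusterPathways
#' @param clusters a [TunnelClusters-class]
#' @export
recutClusters <- function(clusters, threshold) {
  n <- nrow(clusters@merge) + 1L
  tree <- list(merge = clusters@merge, height = clusters@height,
               order = seq_len(n),
               labels = NULL, method = "average", call = NULL,
               dist.method = "pathway")
  class(tree) <- "hclust"
  labs <- if (n == 1) 1L else
    as.integer(stats::cutree(tree, h = threshold))
  clusters@labels <- labs
  clusters@threshold <- threshold
  clusters
}

# deterministic k-nearest-neighbour vote: distance ties resolve to the
# lowest training index, vote ties to the lowest class index
.knnClassify <- function(train, labels, test, k) {
  k <- min(k, nrow(train))
  apply(test, 1, function(x) {
    d <- sqrt(colSums((t(train) - x)^2))
    nn <- order(d, seq_along(d))[seq_len(k)]
    tab <- table(factor(labels[nn], levels = sort(unique(labels))))
    as.integer(names(tab)[which.max(tab)])
  })
}

#' Sampled clustering with k-NN classification for large pathway sets
#'
#' A seeded random sample is clustered exactly by average linkage; the
#' `topN` clusters with highest priority become classes 1..topN and all
#' remaining clusters collapse into class `topN + 1` ("other").  A k-nearest
#' neighbour classifier on the flattened descriptor coordinates (3N features
#' per pathway) assigns every remaining pathway to one of these classes.
#'
#' @param descriptors a [PathwayDescriptorSet-class] for all pathways
#' @param pathways the corresponding [PathwaySet-class] (throughputs and
#'   snapshot indices feed the priority ranking of the sampled clusters)
#' @param totalSnapshots total number of analyzed snapshots
#' @param sampleSize number of pathways to cluster exactly
#' @param topN number of top-priority clusters kept as individual classes
#' @param k neighbours for the classifier
#' @param threshold clustering threshold for the sample
#' @param q weighting parameter of the pathway distance
#' @param seed sampling seed
#' @return a [PathwayClassification-class]
#' @export
classifyLarge <- function(descriptors, pathways, totalSnapshots, sampleSize,
                          topN, k = 5L, threshold, q = 1, seed = 1L) {
  n <- dim(descriptors@points)[3]
  stopifnot(sampleSize >= 2, sampleSize <= n)
  sampleIdx <- sort(withSeed(seed, sample.int(n, sampleSize)))
  sub <- new("PathwayDescriptorSet",
             points = descriptors@points[, , sampleIdx, drop = FALSE],
             dEnd = descriptors@dEnd[sampleIdx],
             zStart = descriptors@zStart, zEnd = descriptors@zEnd,
             origin = descriptors@origin)
  D <- distanceMatrix(sub, q = q)
  cl <- clusterPathways(D, threshold)
  labs <- clusterLabels(cl)
  prio <- clusterPriority(pathwayThroughputs(pathways)[sampleIdx],
                          pathwaySnapshots(pathways)[sampleIdx],
                          labs, totalSnapshots)
  nClust <- length(prio)
  if (topN > nClust) {
    warning("topN exceeds the number of sampled clusters (", nClust,
            "); clamping")
    topN <- nClust
  }
  rank <- order(-prio, as.integer(names(prio)))
  topClusters <- as.integer(names(prio))[rank[seq_len(topN)]]
  classOf <- rep(as.integer(topN) + 1L, nClust)
  names(classOf) <- names(prio)
  classOf[as.character(topClusters)] <- seq_len(topN)
  sampleClasses <- classOf[as.character(labs)]
  feat <- function(idx) {
    t(apply(descriptors@points[, , idx, drop = FALSE], 3, as.vector))
  }
  labels <- integer(n)
  labels[sampleIdx] <- sampleClasses
  rest <- setdiff(seq_len(n), sampleIdx)
  if (length(rest))
    labels[rest] <- .knnClassify(feat(sampleIdx), sampleClasses,
                                 feat(rest), k)
  new("PathwayClassification", labels = labels,
      sampleIndex = as.integer(sampleIdx), sampleClusters = cl,
      topN = as.integer(topN), k = as.integer(k), seed = as.integer(seed))
}
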