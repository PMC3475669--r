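# Independent oracles and small object builders used across the test files.

# Pathway with prescribed axis and cost (throughput follows by definition).
fakePathway <- function(axis, cost = 1, snapshot = 1L) {
  axis <- as.matrix(axis)
  seg <- diff(axis)
  len <- sum(sqrt(rowSums(seg * seg)))
  straight <- sqrt(sum((axis[nrow(axis), ] - axis[1, ])^2))
  radii <- rep(1, nrow(axis))
  new("Pathway", snapshotIndex = as.integer(snapshot), axis = axis,
      radii = radii, cost = cost, throughput = exp(-cost), length = len,
      curvature = if (straight > 0) len / straight else 1,
      bottleneckIndex = 1L, startVertex = 1L)
}

# RIS directly from ball centers (no perturbation, zero error bound).
makeRIS <- function(centers, radius) {
  centers <- as.matrix(centers)
  new("RIS", centers = centers, centers0 = centers, radius = radius,
      atomIndex = seq_len(nrow(centers)), errorBound = 0, seed = 1L)
}

# Brute-force Delaunay by the empty-circumsphere test over all 4-subsets.
bruteDelaunay <- function(pts) {
  n <- nrow(pts)
  combs <- utils::combn(n, 4)
  out <- list()
  for (k in seq_len(ncol(combs))) {
    idx <- combs[, k]
    a <- pts[idx[1], ]; b <- pts[idx[2], ]
    c <- pts[idx[3], ]; d <- pts[idx[4], ]
    A <- 2 * rbind(b - a, c - a, d - a)
    if (abs(det(A)) < 1e-9) next
    cc <- solve(A, c(sum(b^2) - sum(a^2), sum(c^2) - sum(a^2),
                     sum(d^2) - sum(a^2)))
    r2 <- sum((a - cc)^2)
    others <- setdiff(seq_len(n), idx)
    if (all(colSums((t(pts[others, , drop = FALSE]) - cc)^2) > r2))
      out[[length(out) + 1L]] <- sort(idx)
  }
  do.call(rbind, out)
}

# Exhaustive lowest-cost simple path on a small undirected graph.
enumLowestCost <- function(edges, w, from, to, n) {
  adj <- lapply(seq_len(n), function(v)
    which(edges[, 1] == v | edges[, 2] == v))
  best <- Inf
  rec <- function(v, visited, cost) {
    if (cost >= best) return(invisible())
    if (v == to) { best <<- cost; return(invisible()) }
    for (ei in adj[[v]]) {
      u <- if (edges[ei, 1] == v) edges[ei, 2] else edges[ei, 1]
      if (!visited[u]) {
        visited[u] <- TRUE
        rec(u, visited, cost + w[ei])
        visited[u] <- FALSE
      }
    }
  }
  visited <- logical(n)
  visited[from] <- TRUE
  rec(from, visited, 0)
  best
}

# Naive average-link agglomeration recomputing every cluster distance from
# scratch (no Lance-Williams shortcut).
naiveAverageLink <- function(D, threshold) {
  clusters <- as.list(seq_len(nrow(D)))
  repeat {
    if (length(clusters) == 1) break
    best <- Inf; bi <- 0; bj <- 0
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best - 1e-12) { best <- d; bi <- i; bj <- j }
      }
    }
    if (best > threshold) break
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  labels <- integer(nrow(D))
  for (i in seq_along(clusters)) labels[clusters[[i]]] <- i
  labels
}

# label-invariant partition comparison
samePartition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}

randomDistanceMatrix <- function(n) {
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0.1, 10)
  D + t(D)
}
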