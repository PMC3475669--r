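# Small numeric helpers shared across modules.

# Near-uniform unit directions on the sphere (golden-angle spiral).
# Deterministic: the same n always yields the same point set.
fibonacciSphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Deterministic uniforms in [0, 1) from a 32-bit LCG, independent of R's RNG
# stream so that geometry perturbations never disturb user-level randomness.
lcgRunif <- function(n, seed) {
  state <- as.numeric(seed) %% 2^32
  out <- numeric(n)
  for (i in seq_len(n)) {
    state <- (1664525 * state + 1013904223) %% 2^32
    out[i] <- state / 2^32
  }
  out
}

# Evaluate expr with a temporary RNG seed, restoring the caller's stream.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

rowNorms <- function(m) sqrt(rowSums(m * m))

# Distance from each of the three points in `sites` (k x 3) to segment a-b.
pointSegmentDistance <- function(sites, a, b) {
  ab <- b - a
  len2 <- sum(ab * ab)
  if (len2 <= 0) return(rowNorms(sweep(sites, 2, a)))
  t <- pmin(1, pmax(0, as.vector(sweep(sites, 2, a) %*% ab) / len2))
  proj <- outer(t, ab) + matrix(a, nrow(sites), 3, byrow = TRUE)
  rowNorms(sites - proj)
}

# Resample a polyline at (approximately) regular arc-length intervals.
# Returns the sampled points, their arc positions, and the original length.
polylineResample <- function(points, spacing, appendEnd = TRUE) {
  stopifnot(nrow(points) >= 2, spacing > 0)
  seg <- diff(points)
  segLen <- sqrt(rowSums(seg * seg))
  keep <- segLen > 1e-12
  if (!all(keep)) {
    points <- points[c(TRUE, keep), , drop = FALSE]
    seg <- diff(points)
    segLen <- sqrt(rowSums(seg * seg))
  }
  cum <- c(0, cumsum(segLen))
  L <- cum[length(cum)]
  s <- seq(0, L, by = spacing)
  if (appendEnd && L - s[length(s)] > 1e-9) s <- c(s, L)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, length(segLen))
  frac <- (s - cum[idx]) / segLen[idx]
  pts <- points[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  list(points = pts, arc = s, length = L)
}

angleBetween <- function(u, v) {
  cu <- u / sqrt(sum(u * u))
  cv <- v / sqrt(sum(v * v))
  acos(pmin(1, pmax(-1, sum(cu * cv)))) * 180 / pi
}

# angles (degrees) between one vector and the rows of a matrix
anglesToRows <- function(dirs, x) {
  xu <- x / sqrt(sum(x * x))
  d <- dirs / rowNorms(dirs)
  acos(pmin(1, pmax(-1, as.vector(d %*% xu)))) * 180 / pi
}

orthonormalBasis <- function(d) {
  d <- d / sqrt(sum(d * d))
  a <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * d) * d
  u <- u / sqrt(sum(u * u))
  v <- c(
    d[2] * u[3] - d[3] * u[2],
    d[3] * u[1] - d[1] * u[3],
    d[1] * u[2] - d[2] * u[1]
  )
  list(u = u, v = v, d = d)
}

# Fixed-column PDB ATOM/HETATM record formatting (used for multi-MODEL
# ensembles and tunnel-ball files; single-structure reading goes via bio3d).
formatPDBAtoms <- function(atoms, xyz, bfactor = NULL, occupancy = NULL) {
  n <- nrow(atoms)
  if (is.null(bfactor)) bfactor <- rep(0, n)
  if (is.null(occupancy)) occupancy <- rep(1, n)
  name <- atoms$name
  # PDB convention: 4-char atom names start in column 13, shorter in 14
  namef <- ifelse(nchar(name) >= 4, substr(name, 1, 4),
                  sprintf(" %-3s", name))
  rec <- ifelse(!is.null(atoms$record) & atoms$record == "HETATM",
                "HETATM", "ATOM  ")
  sprintf("%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec,
          atoms$serial %% 100000, namef, "",
          substr(atoms$resname, 1, 3), substr(atoms$chain, 1, 1),
          atoms$resid %% 10000, "",
          xyz[, 1], xyz[, 2], xyz[, 3], occupancy, bfactor,
          substr(atoms$element, 1, 2))
}
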