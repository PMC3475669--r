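# Synthetic shell fixtures with analytically known tunnel ground truth.
#
# A hollow spherical shell of overlapping pseudo-atoms encloses a central
# cavity; channels are drilled along chosen directions and a ring of gate
# atoms at mid-shell depth sets the channel's minimum free radius exactly,
# per frame, so bottleneck and gating schedules are known by construction.
# With a single pseudo-atom element the RIS approximation is exact (the
# error bound reduces to the center-perturbation allowance), which isolates
# search and clustering tests from approximation error; the mixed-radii
# variant exercises the RIS bound itself.

#' Generate a shell ensemble with drilled channels of known bottleneck
#'
#' @param innerRadius cavity radius (Angstrom)
#' @param outerRadius outer radius of the shell surface (Angstrom)
#' @param atomRadius pseudo-atom vdw radius; pseudo-atoms are carbon-like by
#'   default
#' @param spacing tangential atom spacing within a shell layer (Angstrom);
#'   must stay small enough that the wall is probe-tight
#' @param layerStep radial distance between shell layers
#' @param channels list of channels, each a list with `direction` (3-vector)
#'   and `schedule` (per-frame bottleneck radii, recycled to `frames`)
#' @param frames number of snapshots
#' @param ringAtoms number of gate atoms forming the bottleneck ring
#' @param drillClearance free radius of the drilled corridor (default: the
#'   largest scheduled bottleneck + 0.3, so the ring always controls the
#'   bottleneck)
#' @param mixedRadii alternate shell atoms between carbon and nitrogen so
#'   the RIS has to approximate the larger element
#' @param seed recorded for provenance; the generator itself is
#'   deterministic
#' @return list with `ensemble` (a [TunnelEnsemble-class], radii
#'   unassigned) and `truth` (data.frame: frame, channel, bottleneck)
#' @export
makeShellEnsemble <- function(innerRadius = 6, outerRadius = 11.2,
                              atomRadius = 1.7, spacing = 2.0,
                              layerStep = 1.4,
                              channels = list(list(direction = c(0, 0, 1),
                                                   schedule = 1.5)),
                              frames = 1L, ringAtoms = 14L,
                              drillClearance = NULL, mixedRadii = FALSE,
                              seed = 1L) {
  stopifnot(outerRadius > innerRadius + 2 * atomRadius, frames >= 1)
  schedules <- lapply(channels, function(ch) {
    s <- rep_len(ch$schedule, frames)
    if (any(s <= 0)) stop("bottleneck schedule must be positive")
    s
  })
  maxSched <- if (length(channels))
    max(unlist(schedules)) else 0
  if (is.null(drillClearance)) drillClearance <- maxSched + 0.3
  if (length(channels) &&
      drillClearance + atomRadius >= outerRadius - innerRadius)
    stop("infeasible geometry: drill radius exceeds the shell thickness")
  if (maxSched > drillClearance)
    stop("infeasible geometry: scheduled bottleneck wider than the drill")

  layerR <- seq(innerRadius + atomRadius, outerRadius - atomRadius,
                by = layerStep)
  shell <- do.call(rbind, lapply(layerR, function(R) {
    n <- ceiling(4 * pi * R^2 / spacing^2)
    fibonacciSphere(n) * R
  }))
  # drill the channels: remove shell atoms too close to a channel axis ray
  keep <- rep(TRUE, nrow(shell))
  dirs <- lapply(channels, function(ch) {
    d <- ch$direction
    d / sqrt(sum(d * d))
  })
  for (d in dirs) {
    proj <- as.vector(shell %*% d)
    axDist <- sqrt(pmax(rowSums(shell^2) - proj^2, 0))
    keep <- keep & !(proj > 0 & axDist < drillClearance + atomRadius)
  }
  shell <- shell[keep, , drop = FALSE]
  nShell <- nrow(shell)
  ringR <- (innerRadius + outerRadius) / 2

  nRing <- length(channels) * ringAtoms
  atoms <- data.frame(
    serial = seq_len(nShell + nRing),
    name = "C",
    element = "C",
    resname = c(rep("SHL", nShell), rep("RNG", nRing)),
    resid = c(seq_len(nShell),
              rep(9000L + seq_along(channels), each = ringAtoms)),
    chain = "A",
    record = "ATOM",
    stringsAsFactors = FALSE
  )
  if (mixedRadii) {
    alt <- seq_len(nShell) %% 2 == 0
    atoms$name[seq_len(nShell)][alt] <- "N"
    atoms$element[seq_len(nShell)][alt] <- "N"
  }
  coords <- array(NA_real_, c(nShell + nRing, 3, frames))
  phi <- 2 * pi * (seq_len(ringAtoms) - 1) / ringAtoms
  for (f in seq_len(frames)) {
    xyz <- shell
    for (ci in seq_along(channels)) {
      d <- dirs[[ci]]
      basis <- orthonormalBasis(d)
      rr <- schedules[[ci]][f] + atomRadius
      ring <- matrix(d * ringR, ringAtoms, 3, byrow = TRUE) +
        outer(cos(phi) * rr, basis$u) + outer(sin(phi) * rr, basis$v)
      xyz <- rbind(xyz, ring)
    }
    coords[, , f] <- xyz
  }
  truth <- do.call(rbind, lapply(seq_along(channels), function(ci)
    data.frame(frame = seq_len(frames), channel = ci,
               bottleneck = schedules[[ci]])))
  ens <- new("TunnelEnsemble", atoms = atoms, coords = coords,
             radii = rep(NA_real_, nrow(atoms)), radiiTable = "unassigned",
             sourcePaths = sprintf("synthetic-shell-seed%d", seed))
  list(ensemble = ens, truth = truth)
}
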