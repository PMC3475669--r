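test_that("cluster priority follows the best-per-snapshot throughput rule", {
  # two pathways in snapshot 1 (0.5, 0.3) and one in snapshot 2 (0.2),
  # 10 snapshots in total -> (0.5 + 0.2) / 10
  prio <- clusterPriority(throughputs = c(0.5, 0.3, 0.2),
                          snapshots = c(1L, 1L, 2L),
                          labels = c(1L, 1L, 1L), totalSnapshots = 10)
  expect_equal(unname(prio), 0.07)
  # a single pathway with throughput t and M snapshots -> t / M
  expect_equal(unname(clusterPriority(0.4, 1L, 1L, 8)), 0.05)
  # two clusters rank by priority
  p2 <- clusterPriority(c(0.5, 0.9), c(1L, 1L), c(1L, 2L), 10)
  expect_equal(unname(p2), c(0.05, 0.09))
})

test_that("cluster summary statistics use the best pathway per snapshot", {
  mk <- function(cost, snap, radius) {
    p <- fakePathway(rbind(c(0, 0, 0), c(0, 0, 5)), cost, snap)
    p@radii <- rep(radius, 2)
    p@bottleneckIndex <- 1L
    p
  }
  # cluster 1: snapshot 1 has two members (costs 1 and 2 -> keep cost 1),
  # snapshot 2 one member
  ps <- PathwaySet(list(mk(1, 1L, 2.0), mk(2, 1L, 0.5), mk(3, 2L, 1.0)))
  s <- clusterSummary(ps, labels = c(1L, 1L, 1L), totalSnapshots = 4,
                      openRadius = 1.4)
  expect_equal(s$snapshotCount, 2)
  expect_equal(s$meanBottleneck, mean(c(2.0, 1.0)))
  expect_equal(s$maxBottleneck, 2.0)
  expect_equal(s$openCount, 1)        # only the 2.0 A snapshot is open
  expect_equal(s$priority, (exp(-1) + exp(-3)) / 4)
  expect_equal(s$meanThroughput, mean(c(exp(-1), exp(-3))))
})

test_that("profiles sample radii at regular intervals along the axis", {
  sc <- sharedSingleChannel()
  best <- which.min(pathwayCosts(sc$pathways))
  pw <- sc$pathways[[best]]
  # default: the pathway's own regularly spaced balls
  prof <- computeProfile(pw, sc$ris)
  expect_equal(nrow(prof), nrow(pw@axis))
  expect_true(all(diff(prof$arc) > 0))
  expect_true(all(prof$radius > 0))
  # the profile minimum is the bottleneck radius
  expect_equal(min(prof$radius), bottleneckRadius(pw), tolerance = 1e-12)
  # explicit spacing resamples the axis
  prof2 <- computeProfile(pw, sc$ris, spacing = 0.4)
  expect_equal(nrow(prof2), floor(pw@length / 0.4) + 1)
  # inside the drilled channel the radius stays near the gate radius
  mid <- prof$radius[prof$distFromS > 7 & prof$distFromS < 10]
  expect_true(all(mid < 3.5))
})

test_that("lining contacts use strict inequality and match brute force", {
  # one pathway ball at the origin, radius 1; atom tangent at distance 3
  pw <- fakePathway(rbind(c(0, 0, 0), c(0, 0, 1)), cost = 1)
  pw@radii <- c(1, 1)
  atoms <- data.frame(serial = 1:2, name = "C", element = "C",
                      resname = "UNK", resid = 1:2, chain = "A",
                      record = "ATOM", stringsAsFactors = FALSE)
  # atom 1 surface-to-surface distance 0 (tangent); atom 2 exactly at the
  # threshold 3 -> excluded by the strict comparison
  xyz <- rbind(c(0, 0, -3.7), c(0, 0, 6.7))   # r_atom = 1.7
  ens <- new("TunnelEnsemble", atoms = atoms, coords = array(xyz, c(2, 3, 1)),
             radii = c(1.7, 1.7), radiiTable = "toy", sourcePaths = "mem")
  res <- contactResidues(pw, ens, 1, liningThreshold = 3,
                         bottleneckThreshold = 0.5)
  lining <- res[res$kind == "lining", ]
  expect_equal(lining$resid, 1L)

  # spatial-index result equals an all-pairs scan on a 100-atom fixture
  set.seed(71)
  n <- 100
  atoms2 <- data.frame(serial = 1:n, name = "C", element = "C",
                       resname = "UNK", resid = 1:n, chain = "A",
                       record = "ATOM", stringsAsFactors = FALSE)
  xyz2 <- matrix(runif(3 * n, -8, 8), n, 3)
  ens2 <- new("TunnelEnsemble", atoms = atoms2,
              coords = array(xyz2, c(n, 3, 1)),
              radii = rep(1.7, n), radiiTable = "toy", sourcePaths = "mem")
  axis <- cbind(seq(-5, 5, by = 0.5), 0, 0)
  pw2 <- fakePathway(axis, cost = 1)
  pw2@radii <- runif(nrow(axis), 0.5, 2)
  pw2@bottleneckIndex <- which.min(pw2@radii)
  res2 <- contactResidues(pw2, ens2, 1, liningThreshold = 2.5,
                          bottleneckThreshold = 2.5)
  bruteLining <- which(vapply(seq_len(n), function(i) {
    d <- sqrt(colSums((t(pw2@axis) - xyz2[i, ])^2)) - pw2@radii - 1.7
    min(d) < 2.5
  }, logical(1)))
  expect_setequal(res2$resid[res2$kind == "lining"], bruteLining)
  bp <- bottleneckPoint(pw2)
  bruteBottle <- which(sqrt(colSums((t(xyz2) - bp)^2)) -
                         bottleneckRadius(pw2) - 1.7 < 2.5)
  expect_setequal(res2$resid[res2$kind == "bottleneck"], bruteBottle)
})

test_that("heat-map matrices mark missing snapshots and mirror bottlenecks", {
  mk <- function(cost, snap, radius) {
    p <- fakePathway(rbind(c(0, 0, 0), c(0, 0, 5)), cost, snap)
    p@radii <- rep(radius, 2); p
  }
  ps <- PathwaySet(list(mk(1, 1L, 1.1), mk(1, 3L, 1.3), mk(2, 2L, 0.8)))
  hm <- heatmapMatrices(ps, labels = c(1L, 1L, 2L), totalSnapshots = 4)
  expect_equal(dim(hm$bottleneck), c(2, 4))
  expect_equal(unname(hm$bottleneck[1, ]), c(1.1, NA, 1.3, NA))
  expect_equal(sum(!is.na(hm$bottleneck[1, ])), 2)
  expect_equal(unname(hm$bottleneck[2, 2]), 0.8)
})

test_that("gating schedules are reproduced in the bottleneck heat map", {
  tc <- sharedTwoChannelRun()
  run <- tc$run
  kept <- PathwaySet(as.list(run@pathways[run@keep]))
  hm <- heatmapMatrices(kept, run@labels, 4)
  truth <- tc$fx$truth
  # identify the gated cluster (channel 1: open at 1.5, closed at 0.5)
  openFrames <- truth$frame[truth$channel == 1 & truth$bottleneck >= 0.9]
  gated <- which(apply(hm$bottleneck, 1, function(r) any(is.na(r))))
  expect_length(gated, 1)
  expect_setequal(which(!is.na(hm$bottleneck[gated, ])), openFrames)
  # the steady channel is present in every frame at its drilled radius
  steady <- setdiff(seq_len(nrow(hm$bottleneck)), gated)
  expect_true(all(abs(hm$bottleneck[steady, ] - 1.2) < 0.26))
})

test_that("run outputs are complete, parseable and byte-stable", {
  tc <- sharedTwoChannelRun()
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  reportTunnels(tc$run, d1, writeImages = FALSE)
  reportTunnels(tc$run, d2, writeImages = FALSE)
  need <- c("summary.csv", "pathways.csv", "bottleneck_heatmap.csv",
            "bottleneck_histogram.csv", "throughput_histogram.csv",
            "residues.csv", "manifest.txt", "view_tunnels.py",
            "view_tunnels.tcl")
  expect_true(all(file.exists(file.path(d1, need))))
  s <- read.csv(file.path(d1, "summary.csv"))
  expect_equal(nrow(s), length(unique(tc$run@labels)))
  expect_equal(s$rank, order(-s$priority, s$cluster))
  # identical run -> byte-identical text outputs
  for (f in need) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # tunnel PDB parses under fixed-column rules with radius in B-factor
  pdbs <- dir(d1, pattern = "^tunnel_cluster_.*pdb$", full.names = TRUE)
  expect_equal(length(pdbs), length(unique(tc$run@labels)))
  balls <- bio3d::read.pdb(pdbs[1])
  expect_true(all(balls$atom$b > 0))
  expect_equal(unique(balls$atom$resid), "TUN")
  # per-cluster bottleneck residues include the gate ring pseudo-residues
  res <- read.csv(file.path(d1, "residues.csv"))
  expect_true(any(res$resname == "RNG" & res$kind == "bottleneck"))
})
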