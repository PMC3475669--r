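test_that("cost integral reproduces closed forms, clamping and limit cases", {
  for (n in c(0, 1, 2)) {
    expect_equal(costIntegral(1.0, 10, n, 5), 10 / 1.0^n, tolerance = 1e-9)
  }
  expect_equal(costIntegral(2.0, 10, 2, 5), 10 / 4, tolerance = 1e-9)
  # cap: r = 2 clamped to r_max = 1.5
  expect_equal(costIntegral(2.0, 10, 2, 1.5), 10 / 1.5^2, tolerance = 1e-6)
  # floor: r below 0.1 clamped up
  expect_equal(costIntegral(0.01, 1, 2, 5), 1 / 0.1^2, tolerance = 1e-6)
  # n = 0 counts pure length whatever the radius profile
  expect_equal(costIntegral(function(l) 1 + sin(l), 7, 0, 5), 7,
               tolerance = 1e-9)
  # varying profile matches a fine independent quadrature
  f <- function(l) 0.5 + 0.4 * cos(l / 2)
  l <- seq(0, 10, length.out = 20001)
  ref <- sum(1 / pmin(pmax(f(l), 0.1), 5)^2) * 10 / 20000
  expect_equal(costIntegral(f, 10, 2, 5), ref, tolerance = 1e-4)
})

test_that("throughput is exp(-cost), in (0,1], decreasing in cost", {
  sc <- sharedSingleChannel()
  tp <- pathwayThroughputs(sc$pathways)
  co <- pathwayCosts(sc$pathways)
  expect_equal(tp, exp(-co), tolerance = 1e-12)
  expect_true(all(tp > 0 & tp <= 1))
  # strictly decreasing in cost (ties in cost give tied throughput)
  expect_false(is.unsorted(rev(tp[order(co)])))
})

test_that("edge filtering matches a brute-force scan and nests with r_B", {
  sc <- sharedSingleChannel()
  g <- sc$graph
  for (rB in c(0.6, 0.9, 1.2)) {
    kept <- filterEdges(g, rB)@edges
    oracle <- g@edges[g@edges$minClearance >= rB, ]
    expect_equal(nrow(kept), nrow(oracle))
    expect_equal(kept$minClearance, oracle$minClearance)
  }
  expect_equal(nrow(filterEdges(g, min(g@edges$minClearance))@edges),
               nrow(g@edges))             # threshold below all: unchanged
  expect_equal(nrow(filterEdges(g, max(g@edges$minClearance) + 1)@edges), 0)
  # decreasing r_B only ever grows the kept-edge set
  k12 <- which(g@edges$minClearance >= 1.2)
  k09 <- which(g@edges$minClearance >= 0.9)
  k06 <- which(g@edges$minClearance >= 0.6)
  expect_true(all(k12 %in% k09) && all(k09 %in% k06))
})

test_that("starting point is the equal-weight center of the selection", {
  atoms <- data.frame(serial = 1:3, name = "C", element = "C",
                      resname = "UNK", resid = c(1L, 1L, 2L), chain = "A",
                      record = "ATOM", stringsAsFactors = FALSE)
  xyz <- rbind(c(-1, 0, 0), c(1, 0, 0), c(4, 0, 0))
  ens <- new("TunnelEnsemble", atoms = atoms, coords = array(xyz, c(3, 3, 1)),
             radii = rep(1.7, 3), radiiTable = "toy", sourcePaths = "mem")
  expect_equal(startingPoint(ens, xyz = c(1, 2, 3)), c(1, 2, 3))
  expect_equal(startingPoint(ens, atoms = c(1, 2)), c(0, 0, 0))
  # residue 1 averages to (0,0,0); with atom serial 3 at (4,0,0) the two
  # entities weigh equally
  expect_equal(startingPoint(ens, residues = 1, atoms = 3), c(2, 0, 0))
  expect_error(startingPoint(ens, residues = 99), "99")
  expect_error(startingPoint(ens), "empty")
})

test_that("starting-vertex optimization applies the four-stage cascade", {
  g <- new("VoronoiGraph", sites = matrix(0, 1, 3), nRealSites = 1L,
           ballRadius = 1,
           vertices = rbind(c(0.5, 0, 0), c(1, 0, 0), c(2, 0, 0),
                            c(6, 0, 0)),
           vertexSites = matrix(1L, 4, 4),
           clearances = c(2.5, 3, 0.8, 5),
           edges = data.frame(from = integer(0), to = integer(0),
                              site1 = integer(0), site2 = integer(0),
                              site3 = integer(0), minClearance = numeric(0),
                              length = numeric(0)),
           shellRadius = 10)
  # stage 1: nearest vertex within d_max with clearance >= r_min
  expect_equal(optimizeStart(g, c(0, 0, 0), 3, 2),
               list(vertex = 1L, stage = 1L))
  # stage 2: none clears r_min -> max clearance within d_max
  g2 <- g; g2@clearances <- c(0.3, 0.8, 0.5, 5)
  expect_equal(optimizeStart(g2, c(0, 0, 0), 3, 1),
               list(vertex = 2L, stage = 2L))
  # stage 3: nothing within d_max, repeat with 3 A
  g3 <- g; g3@vertices <- rbind(c(2.5, 0, 0), c(6, 0, 0), c(7, 0, 0),
                                c(8, 0, 0))
  expect_equal(optimizeStart(g3, c(0, 0, 0), 1, 2)$stage, 3L)
  expect_equal(optimizeStart(g3, c(0, 0, 0), 1, 2)$vertex, 1L)
  # stage 4: everything beyond 3 A -> globally closest vertex
  g4 <- g; g4@vertices <- rbind(c(5, 0, 0), c(6, 0, 0), c(7, 0, 0),
                                c(9, 0, 0))
  expect_equal(optimizeStart(g4, c(0, 0, 0), 1, 2),
               list(vertex = 1L, stage = 4L))
})

test_that("step-1 lowest costs equal exhaustive path enumeration", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(5:12, 1)
    m <- sample(n:(n * 2), 1)
    edges <- t(replicate(m, sample(n, 2)))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    w <- runif(nrow(edges), 0.1, 5)
    res <- tunnelscape:::lowestCostPaths(edges, w, 1, 2:n, n)
    for (t in 2:n) {
      expect_equal(res$costs[t - 1], enumLowestCost(edges, w, 1, t, n),
                   tolerance = 1e-10)
    }
  }
})

test_that("bulk/surface labelling matches the fixture geometry", {
  sc <- sharedSingleChannel()
  g <- sc$graph; lab <- sc$labeling
  centroid <- colMeans(g@sites[seq_len(g@nRealSites), ])
  vr <- sqrt(rowSums(sweep(g@vertices, 2, centroid)^2))
  # exterior far vertices are bulk, the interior cavity is not
  expect_true(all(vr[lab@bulk] > 6 | g@clearances[lab@bulk] >= 3))
  cavity <- which(vr < 4)
  expect_false(any(cavity %in% lab@bulk))
  expect_false(any(cavity %in% lab@surface))       # deeper than d_s
  # bulk balls never intersect the RIS
  expect_true(all(lab@bulkBallRadius >= 0))
  expect_true(all(abs(g@clearances[lab@bulk] - lab@bulkBallRadius) < 1e-12))
  # surface vertices hug the structure: all within d_s-ish of the wall
  expect_true(all(g@clearances[lab@surface] <
                    sc$params@shellProbeRadius + sc$params@shellDepth))
  # boundary definition: an edge to a vertex outside the set
  e <- g@edges
  inSurf <- logical(nrow(g@vertices)); inSurf[lab@surface] <- TRUE
  for (v in lab@surfaceBoundary) {
    nb <- c(e$to[e$from == v], e$from[e$to == v])
    expect_true(any(!inSurf[nb]))
  }
})

test_that("drilled channels are recovered and sealed shells yield nothing", {
  sc <- sharedSingleChannel()
  expect_gte(length(sc$pathways), 1)
  best <- which.min(pathwayCosts(sc$pathways))
  bn <- pathwayBottlenecks(sc$pathways)[best]
  tol <- sc$ris@errorBound + sc$params@ballSpacing / 2
  expect_lt(abs(bn - 1.5), tol)
  # the axis runs outward through the channel: endpoint near the +z mouth
  endp <- sc$pathways[[best]]@axis[nrow(sc$pathways[[best]]@axis), ]
  expect_gt(endp[3], 6)

  sealed <- makeShellEnsemble(frames = 1, channels = list())
  ens <- assignRadii(sealed$ensemble)
  ris <- buildRIS(ens, 1, seed = 1)
  g <- buildVoronoiGraph(ris)
  lab <- labelVertices(g, sc$params)
  sv <- optimizeStart(g, c(0, 0, 0), 3, 2)
  expect_length(findPathways(g, ris, lab, sv$vertex, sc$params, 1L), 0)
})

test_that("redundancy removal keeps the greedy cost-ascending survivors", {
  p1 <- fakePathway(rbind(c(0, 0, 0), c(0, 0, 10)), cost = 1)
  p2 <- fakePathway(rbind(c(0, 0, 0), c(0, 0, 10)), cost = 2)
  ps <- PathwaySet(list(p2, p1))
  D <- matrix(0, 2, 2)
  out <- removeRedundant(ps, D, threshold = 0.5)
  expect_equal(out$kept, 2L)                       # the cost-1 pathway
  # three mutually distant pathways all survive
  D3 <- matrix(10, 3, 3); diag(D3) <- 0
  ps3 <- PathwaySet(list(p1, p2, fakePathway(rbind(c(0, 0, 0), c(10, 0, 0)),
                                             cost = 3)))
  expect_equal(removeRedundant(ps3, D3, threshold = 1)$kept, 1:3)
  # chain A-B-C with d(A,B) < t, d(B,C) < t, d(A,C) > t and costs A<B<C
  D_ <- rbind(c(0, 1, 5), c(1, 0, 1), c(5, 1, 0))
  psA <- PathwaySet(list(fakePathway(rbind(c(0, 0, 0), c(1, 0, 0)), 1),
                         fakePathway(rbind(c(0, 0, 0), c(2, 0, 0)), 2),
                         fakePathway(rbind(c(0, 0, 0), c(3, 0, 0)), 3)))
  expect_equal(removeRedundant(psA, D_, threshold = 2)$kept, c(1L, 3L))
})

test_that("pathway cost equals the sum of its edge costs", {
  # additivity of the quadrature over a split corridor
  whole <- costIntegral(function(l) 1 + 0.2 * sin(l), 8, 2, 5)
  parts <- costIntegral(function(l) 1 + 0.2 * sin(l), 4, 2, 5) +
    costIntegral(function(l) 1 + 0.2 * sin(l + 4), 4, 2, 5)
  expect_equal(whole, parts, tolerance = 1e-4)
})
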