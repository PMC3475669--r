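straightPathway <- function(dir, len, cost, snapshot = 1L, from = c(0, 0, 0),
                            by = 0.5) {
  dir <- dir / sqrt(sum(dir^2))
  s <- seq(0, len, by = by)
  fakePathway(outer(s, dir) + matrix(from, length(s), 3, byrow = TRUE),
              cost = cost, snapshot = snapshot)
}

test_that("reference frame merges extreme points by angle with running means", {
  S <- matrix(0, 1, 3)
  p1 <- straightPathway(c(0, 0, 1), 10, cost = 1)
  frame1 <- buildReferenceFrame(PathwaySet(list(p1)), S)
  expect_equal(nrow(frame1@directions), 1)
  expect_equal(frame1@weights, 1)
  expect_equal(frame1@lengths, 10)

  # collinear straight lengths 10 and 12 merge into one averaged point
  p2 <- straightPathway(c(0, 0, 1), 12, cost = 2)
  frame2 <- buildReferenceFrame(PathwaySet(list(p2, p1)), S,
                                mergeAngle = 45)
  expect_equal(nrow(frame2@directions), 1)
  expect_equal(frame2@weights, 2)
  expect_equal(frame2@lengths, 11)   # (12 + 1*10)/2, cost order: p1 first
  # processing is cost-ordered, so input order is irrelevant
  frame2b <- buildReferenceFrame(PathwaySet(list(p1, p2)), S,
                                 mergeAngle = 45)
  expect_equal(frame2@lengths, frame2b@lengths)

  # 90 degrees apart with a 20 degree merge angle: two direction points
  p3 <- straightPathway(c(1, 0, 0), 8, cost = 3)
  frame3 <- buildReferenceFrame(PathwaySet(list(p1, p3)), S, mergeAngle = 20)
  expect_equal(nrow(frame3@directions), 2)
})

test_that("descriptors bin axis points by distance from S and fill gaps", {
  S <- matrix(0, 1, 3)
  pw <- straightPathway(c(0, 0, 1), 10, cost = 1, by = 0.25)
  frame <- buildReferenceFrame(PathwaySet(list(pw)), S)
  desc <- pathwayDescriptors(PathwaySet(list(pw)), frame, nPoints = 4)
  expect_equal(dim(desc@points), c(4, 3, 1))
  expect_equal(desc@dEnd, 10)
  # G_i are the centroids of the axis points that fall into each bin
  d <- seq(0, 10, by = 0.25)
  h <- 10 / 4
  for (i in 1:4) {
    sel <- d >= (i - 1) * h & d < i * h
    # points at exactly d_end fall into I_end
    expect_equal(desc@points[i, 3, 1], mean(d[sel & d < 10]))
    expect_equal(desc@points[i, 1, 1], 0)
  }

  # a gap in the axis: missing bins are interpolated linearly
  sgap <- c(seq(0, 2.5, by = 0.25), seq(7.5, 10, by = 0.25))
  pwGap <- fakePathway(cbind(0, 0, sgap), cost = 1)
  descG <- pathwayDescriptors(PathwaySet(list(pwGap)), frame, nPoints = 8)
  expect_true(all(is.finite(descG@points)))
  zs <- descG@points[, 3, 1]
  expect_equal(dim(descG@points)[1], 8)
  expect_true(all(diff(zs) > 0))       # monotone along the straight axis

  expect_error(pathwayDescriptors(PathwaySet(list(pw)), frame, nPoints = 4,
                                  zStart = 6, zEnd = 6), "d_end")
})

test_that("weight coefficients satisfy the two stated constraints", {
  expect_equal(weightCoefficients(1), c(a = 0, b = 1))
  expect_equal(weightCoefficients(3), c(a = 1, b = 0.5))
  for (q in c(0.5, 1, 3)) {
    ab <- weightCoefficients(q)
    w <- function(x) ab["a"] * x + ab["b"]
    expect_equal(unname(w(1) / w(0)), q)
    expect_equal(unname(w(0.5)), 1)
  }
  expect_error(weightCoefficients(0), "positive")
  expect_error(weightCoefficients(-2), "positive")
})

test_that("pathway distance: identity, offsets, symmetry, K-point form", {
  S <- matrix(0, 1, 3)
  pA <- straightPathway(c(0, 0, 1), 10, cost = 1)
  frame <- buildReferenceFrame(PathwaySet(list(pA)), S)
  descA <- pathwayDescriptors(PathwaySet(list(pA)), frame, nPoints = 10)
  # descriptor B = descriptor A shifted by a constant vector
  off <- c(1.5, -2, 0.5)
  pts <- array(NA_real_, c(10, 3, 3))
  pts[, , 1] <- descA@points[, , 1]
  pts[, , 2] <- descA@points[, , 1] +
    matrix(off, 10, 3, byrow = TRUE)
  pts[, , 3] <- descA@points[, , 1]
  desc <- new("PathwayDescriptorSet", points = pts, dEnd = rep(10, 3),
              zStart = 0, zEnd = 0, origin = as.vector(S))
  expect_equal(pathwayDistance(desc, 1, 3), 0)
  # constant offset with q = 1: the distance is the offset norm
  expect_equal(pathwayDistance(desc, 1, 2, q = 1), sqrt(sum(off^2)),
               tolerance = 1e-9)
  for (q in c(0.5, 1, 3)) {
    dw <- pathwayDistance(desc, 1, 2, q, form = "weighted")
    dk <- pathwayDistance(desc, 1, 2, q, form = "kpoint")
    expect_equal(dw, dk, tolerance = 1e-9)
    expect_equal(pathwayDistance(desc, 2, 1, q), dw)
  }
  D <- distanceMatrix(desc, q = 2)
  expect_equal(D[1, 2], pathwayDistance(desc, 1, 2, q = 2))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
})

test_that("descriptor distance matrix survives the disk cache round trip", {
  D <- randomDistanceMatrix(7)
  f <- tempfile()
  writeDistanceCache(D, f)
  expect_equal(readDistanceCache(f), D)
})

test_that("average-link clustering agrees with hand agglomeration", {
  # two tight pairs far apart
  D <- matrix(10, 4, 4)
  D[1, 2] <- D[2, 1] <- 1
  D[3, 4] <- D[4, 3] <- 1
  diag(D) <- 0
  expect_equal(length(unique(clusterLabels(clusterPathways(D, 2)))), 2)
  expect_equal(length(unique(clusterLabels(clusterPathways(D, 20)))), 1)
  expect_equal(length(unique(clusterLabels(clusterPathways(D, 0.5)))), 4)
  expect_error(clusterPathways(matrix(c(0, 1, 2, 0), 2, 2), 1), "symmetric")
})

test_that("clustering equals naive agglomeration and hclust on random inputs", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    D <- randomDistanceMatrix(n)
    cl <- clusterPathways(D, 1)
    href <- stats::hclust(stats::as.dist(D), method = "average")
    expect_equal(cl@height, href$height, tolerance = 1e-10)
    for (th in c(0.5, 2, 4, 6, 12)) {
      mine <- clusterLabels(recutClusters(cl, th))
      expect_true(samePartition(mine, naiveAverageLink(D, th)))
      expect_true(samePartition(mine, stats::cutree(href, h = th)))
    }
  }
})

test_that("re-cutting the stored tree matches fresh clustering", {
  D <- randomDistanceMatrix(8)
  cl4 <- clusterPathways(D, 4)
  re <- recutClusters(cl4, 1.5)
  fresh <- clusterPathways(D, 1.5)
  expect_identical(clusterLabels(re), clusterLabels(fresh))
  expect_identical(re@merge, cl4@merge)
})

test_that("sampled classification degenerates to exact clustering", {
  S <- matrix(0, 1, 3)
  mk <- function(dir, k, cost0) lapply(seq_len(k), function(i)
    straightPathway(dir + runif(3, -0.02, 0.02), 10, cost = cost0 + i / 10,
                    snapshot = i))
  set.seed(41)
  pws <- PathwaySet(c(mk(c(0, 0, 1), 5, 1), mk(c(1, 0, 0), 5, 2)))
  frame <- buildReferenceFrame(pws, S)
  desc <- pathwayDescriptors(pws, frame, nPoints = 8)
  exact <- clusterPathways(distanceMatrix(desc), 3)
  full <- classifyLarge(desc, pws, totalSnapshots = 5, sampleSize = 10,
                        topN = 2, k = 1, threshold = 3, seed = 9)
  expect_true(samePartition(clusterLabels(full), clusterLabels(exact)))

  # a duplicated pathway with k = 1 lands in its twin's class
  dup <- PathwaySet(c(as.list(pws), list(pws[[1]])))
  dFrame <- buildReferenceFrame(dup, S)
  dDesc <- pathwayDescriptors(dup, dFrame, nPoints = 8)
  cls <- classifyLarge(dDesc, dup, totalSnapshots = 5, sampleSize = 10,
                       topN = 2, k = 1, threshold = 3, seed = 9)
  expect_equal(clusterLabels(cls)[11], clusterLabels(cls)[1])
  # determinism under a fixed seed
  cls2 <- classifyLarge(dDesc, dup, totalSnapshots = 5, sampleSize = 10,
                        topN = 2, k = 1, threshold = 3, seed = 9)
  expect_identical(clusterLabels(cls), clusterLabels(cls2))
  expect_warning(
    classifyLarge(desc, pws, totalSnapshots = 5, sampleSize = 10,
                  topN = 50, k = 1, threshold = 3, seed = 1),
    "clamp")
})

test_that("our deterministic k-NN matches class::knn on tie-free data", {
  skip_if_not_installed("class")
  set.seed(51)
  train <- matrix(rnorm(60), 20, 3)
  labels <- rep(1:2, each = 10)
  test <- matrix(rnorm(30), 10, 3)
  mine <- tunnelscape:::.knnClassify(train, labels, test, k = 3)
  ref <- as.integer(as.character(class::knn(train, test,
                                            factor(labels), k = 3)))
  expect_equal(mine, ref)
})

test_that("descriptor pipeline is permutation invariant", {
  S <- matrix(0, 1, 3)
  set.seed(61)
  pws <- lapply(1:6, function(i)
    straightPathway(runif(3, -1, 1), 8 + i, cost = i / 2, snapshot = i))
  ord <- sample(6)
  f1 <- buildReferenceFrame(PathwaySet(pws), S)
  f2 <- buildReferenceFrame(PathwaySet(pws[ord]), S)
  expect_equal(f1@lengths, f2@lengths)
  expect_equal(f1@directions, f2@directions)
  d1 <- pathwayDescriptors(PathwaySet(pws), f1, nPoints = 6)
  d2 <- pathwayDescriptors(PathwaySet(pws[ord]), f2, nPoints = 6)
  expect_equal(d1@points[, , ord], d2@points)
})
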