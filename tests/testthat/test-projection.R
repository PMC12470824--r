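# Voxelization, traversal, cones and system-matrix assembly.

test_that("makeGrid covers the requested extent", {
  g <- makeGrid(c(50, 50, 5), 1)
  expect_equal(gridDims(g), c(50L, 50L, 5L))
  g3 <- makeGrid(c(3, 1, 1), 1)
  expect_equal(voxelCenters(g3)[, 1], c(-1, 0, 1))
  expect_error(makeGrid(c(3, 1, 1), 0), "positive")
  expect_error(makeGrid(c(3, 1, 1), 0.7), "divide")
})

test_that("ray traversal conserves length and handles misses", {
  g <- makeGrid(c(3, 1, 1), 1)
  tr <- rayPathLengths(c(-1.5, 0, 0), c(1.5, 0, 0), g)
  expect_equal(tr$voxel, 0:2)
  expect_equal(tr$length, rep(1, 3))

  # planar diagonal across a single unit voxel
  g1 <- makeGrid(c(1, 1, 1), 1)
  tr2 <- rayPathLengths(c(-0.5, -0.5, 0), c(0.5, 0.5, 0), g1)
  expect_equal(sum(tr2$length), sqrt(2), tolerance = 1e-12)

  expect_equal(nrow(rayPathLengths(c(10, 10, 10), c(11, 11, 11), g)), 0L)
  expect_error(rayPathLengths(c(1, 1, 1), c(1, 1, 1), g), "differ")
})

test_that("random segments traverse with exact length conservation", {
  set.seed(14)
  g <- makeGrid(c(20, 16, 6), c(1, 2, 1.5))
  for (q in 1:1000) {
    p1 <- runif(3, -15, 15)
    p2 <- runif(3, -15, 15)
    if (all(p1 == p2)) next
    tr <- rayPathLengths(p1, p2, g)
    # clip segment to the grid box analytically
    lo <- gridOrigin(g); hi <- lo + gridSpacing(g) * gridDims(g)
    d <- p2 - p1; t0 <- 0; t1 <- 1
    for (k in 1:3) {
      if (d[k] != 0) {
        tt <- sort(c((lo[k] - p1[k]) / d[k], (hi[k] - p1[k]) / d[k]))
        t0 <- max(t0, tt[1]); t1 <- min(t1, tt[2])
      } else if (p1[k] < lo[k] || p1[k] > hi[k]) t1 <- -Inf
    }
    expected <- max(t1 - t0, 0) * sqrt(sum(d^2))
    expect_equal(sum(tr$length), expected, tolerance = 1e-9)
  }
})

test_that("the event cone passes through the true source", {
  cone <- coneFromEvent(makeEventRow(rs = c(0, 0, 0), ra = c(0, -1, 0),
                                     Es = energiesFromAngle(81, pi / 2)$E1,
                                     Ea = energiesFromAngle(81, pi / 2)$E2))
  # candidate source (1,0,0) lies on the 90-degree cone
  v <- c(1, 0, 0) - cone$apex
  ang <- acos(sum(v * cone$axis) / sqrt(sum(v^2)))
  expect_equal(ang, cone$halfAngle, tolerance = 1e-12)

  d <- eventData(blurFreeDataset())
  worst <- 0
  for (q in seq_len(min(200, nrow(d)))) {
    cone <- coneFromEvent(d[q, , drop = FALSE])
    v <- as.numeric(d[q, c("x0", "y0", "z0")]) - cone$apex
    ang <- acos(min(1, max(-1, sum(v * cone$axis) / sqrt(sum(v^2)))))
    worst <- max(worst, abs(ang - cone$halfAngle))
  }
  expect_lt(worst, 1e-6)
})

test_that("cone voxel weights follow the Gaussian angular kernel", {
  cone <- list(apex = c(0, 0, 0), axis = c(0, 1, 0), halfAngle = pi / 2)
  sg <- 2 * pi / 180
  expect_equal(coneVoxelWeight(cone, cbind(5, 0, 0), sg), 1)
  # angular offset of exactly 3 sigma
  offAng <- pi / 2 - 3 * sg
  p <- 5 * c(sin(offAng), cos(offAng), 0)
  expect_equal(coneVoxelWeight(cone, rbind(p), sg), exp(-4.5),
               tolerance = 1e-9)
  expect_lt(coneVoxelWeight(cone, cbind(0, -5, 0), sg), 1e-6)
  expect_equal(coneVoxelWeight(cone, cbind(0, 0, 0), sg), 0)
})

test_that("assembled rows match the brute-force oracle exactly", {
  set.seed(31)
  grid <- makeGrid(c(10, 10, 3), c(1, 1, 1))
  muVec <- numeric(prod(gridDims(grid)))
  muVec[sample(length(muVec), 40)] <- runif(40, 0.005, 0.03)
  muVol <- reconVolume(grid, array(muVec, dim = gridDims(grid)))
  ev <- randomEvents(20)
  sg <- 2 * pi / 180
  A <- assembleMatrix(ev, grid, muVol, sigmaCone = sg)
  for (q in 1:20) {
    row <- systemMatrixRow(eventData(ev)[q, , drop = FALSE], grid, muVol,
                           sigmaCone = sg)
    oracle <- bruteForceRow(eventData(ev)[q, , drop = FALSE], grid,
                            muVec, sg)
    expect_identical(row$voxel, oracle$voxel)
    expect_equal(row$weight, oracle$weight, tolerance = 1e-12)
    # and the batch assembly agrees with the single-row path bitwise
    full <- as.numeric(A@mat[q, ])
    expect_identical(which(full > 0) - 1L, row$voxel)
    expect_identical(unname(full[full > 0]), row$weight)
  }
})

test_that("zero-mu maps drop the survival factor; more mu never helps", {
  grid <- makeGrid(c(10, 10, 3), 1)
  ev <- randomEvents(5)
  A0 <- assembleMatrix(ev, grid, NULL)
  muVol <- reconVolume(grid, array(0.02, dim = gridDims(grid)))
  A1 <- assembleMatrix(ev, grid, muVol)
  muVol2 <- reconVolume(grid, array(0.04, dim = gridDims(grid)))
  A2 <- assembleMatrix(ev, grid, muVol2)
  # survival factors only shrink entries (compare common voxels, row 1)
  r0 <- as.numeric(A1@mat[1, ]); r2 <- as.numeric(A2@mat[1, ])
  common <- r0 > 0 & r2 > 0
  expect_true(all(r2[common] <= r0[common] + 1e-15))
})

test_that("matrix shape, sensitivity and permutation behave", {
  grid <- makeGrid(c(10, 10, 3), 1)
  ev <- randomEvents(8)
  A <- assembleMatrix(ev, grid, NULL)
  expect_equal(nEvents(A), 8L)
  s <- sensitivity(A)
  expect_equal(length(s), prod(gridDims(grid)))
  perm <- comptonEvents(eventData(ev)[8:1, ])
  Ap <- assembleMatrix(perm, grid, NULL)
  expect_equal(sensitivity(Ap), s, tolerance = 1e-15)
  expect_equal(as.numeric(Ap@mat[8, ]), as.numeric(A@mat[1, ]))
  # untouched voxels have exactly zero sensitivity
  expect_true(any(s == 0))
})

test_that("back-projection peaks at the source for many noiseless events", {
  # point-like single source: one small insert at (10, 5)
  ins <- data.frame(x = 10, y = 5, radius = 0.6,
                    material = "au_solution", concentration = 1)
  ph <- buildPhantom(inserts = ins)
  ev <- simulateDataset(ph, detectorGeometry(),
                        simulationConfig(nEmissions = 1.2e5, seed = 33,
                                         blurScatter = 0,
                                         blurAbsorber = 0))
  expect_gte(nEvents(ev), 5000)
  grid <- makeGrid(c(50, 50, 5), c(2, 2, 1))
  bp <- backproject(ev, grid)
  ctrPeak <- voxelCenters(grid)[which.max(intensities(bp)), ]
  expect_lt(sqrt((ctrPeak[1] - 10)^2 + (ctrPeak[2] - 5)^2), 2.5)
  # single event: a ring/arc through the source voxel, not a blob
  one <- comptonEvents(eventData(ev)[1, , drop = FALSE])
  row <- backproject(one, grid)
  expect_gt(sum(intensities(row) > 0.5 * max(intensities(row))), 5)
  expect_equal(intensities(backproject(comptonEvents(
    eventData(ev)[0, ]), grid)),
    array(0, dim = gridDims(grid)))
})
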