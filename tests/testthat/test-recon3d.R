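# Anisotropic diffusion, wavelet denoising and isosurface extraction.

test_that("diffusion keeps constants fixed and is conservative", {
  g <- makeGrid(c(6, 6, 4), 1)
  cfg <- recon3dConfig(nDiffusionSteps = 5)
  const <- reconVolume(g, array(3.2, c(6, 6, 4)))
  expect_equal(intensities(anisotropicTVDiffuse(const, cfg)),
               intensities(const))

  set.seed(2)
  v <- reconVolume(g, array(runif(144), c(6, 6, 4)))
  out <- v
  for (q in 1:5) {
    nxt <- anisotropicTVDiffuse(out, recon3dConfig(nDiffusionSteps = 1))
    expect_equal(mean(intensities(nxt)), mean(intensities(out)),
                 tolerance = 1e-6)
    expect_lte(var(as.numeric(intensities(nxt))),
               var(as.numeric(intensities(out))) + 1e-15)
    # maximum principle
    expect_lte(max(intensities(nxt)), max(intensities(out)) + 1e-9)
    expect_gte(min(intensities(nxt)), min(intensities(out)) - 1e-9)
    out <- nxt
  }

  expect_equal(intensities(anisotropicTVDiffuse(
    v, recon3dConfig(nDiffusionSteps = 0))), intensities(v))
  expect_error(anisotropicTVDiffuse(v, recon3dConfig(stepSize = 50,
                                                     lambdaTV3d = 1)),
               "stability bound")
})

test_that("small contrasts are smoothed more per unit contrast", {
  g <- makeGrid(c(20, 1, 1), 1)
  mk <- function(h) {
    f <- array(0, c(20, 1, 1)); f[11:20, , ] <- h
    reconVolume(g, f)
  }
  cfg <- recon3dConfig(nDiffusionSteps = 1)
  for (h in c(0.1, 10)) {
    out <- anisotropicTVDiffuse(mk(h), cfg)
    drop <- (h - (intensities(out)[11, 1, 1] -
                  intensities(out)[10, 1, 1])) / h
    assign(paste0("rel", h), drop)
  }
  expect_gt(rel0.1, rel10)  # edge-preserving behavior
})

test_that("the Haar analysis matches the hand-computed transform", {
  row <- c(4, 4, 2, 2)
  slice <- matrix(rep(row, 4), 4, 4, byrow = TRUE)
  w <- dwt2(t(slice), "haar", 1)  # transform along the first dimension
  # 1D Haar of (4,4,2,2): approximation (5.657, 2.828), detail (0, 0);
  # the second (constant) direction contributes a further sqrt(2) each
  expect_equal(w$LL[, 1] / sqrt(2), c(8, 4) / sqrt(2),
               tolerance = 1e-12)
  expect_equal(unname(w$LL[, 1]), c(5.656854, 2.828427) * sqrt(2),
               tolerance = 1e-6)
  expect_equal(max(abs(w$levels[[1]]$HL)), 0)
  expect_equal(max(abs(w$levels[[1]]$HH)), 0)

  const <- matrix(5, 8, 8)
  wc <- dwt2(const, "haar", 2)
  for (j in 1:2) {
    expect_equal(max(abs(wc$levels[[j]]$LH)), 0)
    expect_equal(max(abs(wc$levels[[j]]$HL)), 0)
    expect_equal(max(abs(wc$levels[[j]]$HH)), 0)
  }
  expect_error(dwt2(const, "sym9", 1), "supported")
})

test_that("orthonormal families preserve energy and invert exactly", {
  set.seed(6)
  s <- matrix(rnorm(256), 16, 16)
  for (fam in c("haar", "db2", "db4")) {
    w <- dwt2(s, fam, 2)
    energy <- sum(w$LL^2) + sum(vapply(w$levels, function(l)
      sum(l$LH^2) + sum(l$HL^2) + sum(l$HH^2), numeric(1)))
    expect_equal(energy, sum(s^2), tolerance = 1e-8)
    expect_equal(idwt2(w), s, tolerance = 1e-8)
  }
  # padding path: odd dimensions still invert
  s2 <- matrix(rnorm(5 * 7), 5, 7)
  expect_equal(idwt2(dwt2(s2, "haar", 2)), s2, tolerance = 1e-10)
})

test_that("soft thresholding follows the truth table", {
  expect_equal(softThreshold(5, 2), 3)
  expect_equal(softThreshold(-5, 2), -3)
  expect_equal(softThreshold(1, 2), 0)
  x <- rnorm(100)
  expect_true(all(abs(softThreshold(x, 0.3)) <= abs(x)))
})

test_that("wavelet denoising contracts noise and recovers structure", {
  g <- makeGrid(c(16, 16, 2), 1)
  set.seed(3)
  clean <- array(0, c(16, 16, 2))
  clean[5:12, 5:12, ] <- 1
  noisy <- clean + array(rnorm(512, sd = 0.1), c(16, 16, 2))
  v <- reconVolume(g, noisy)

  # T = 0 is the identity
  id <- waveletDenoise(v, recon3dConfig(waveletThreshold = 0))
  expect_equal(intensities(id), noisy, tolerance = 1e-8)

  # pure-noise slice: energy cannot grow
  noise <- reconVolume(g, array(rnorm(512), c(16, 16, 2)))
  out <- waveletDenoise(noise, recon3dConfig(waveletThreshold = 0.5))
  expect_lte(sum(intensities(out)^2), sum(intensities(noise)^2))

  # denoised image is closer to the clean one than the input
  den <- waveletDenoise(v, recon3dConfig(waveletThreshold = 0.15))
  expect_lt(sum((intensities(den) - clean)^2),
            sum((noisy - clean)^2))
})

test_that("isosurfaces of analytic volumes have the right geometry", {
  g <- makeGrid(c(20, 20, 20), 1)
  ctr <- voxelCenters(g)
  ball <- array(pmax(0, 1 - sqrt(rowSums(ctr^2)) / 10), dim = gridDims(g))
  mesh <- extractIsosurface(reconVolume(g, ball), 0.5)
  rr <- sqrt(rowSums(meshVertices(mesh)^2))
  expect_true(all(abs(rr - 5) < 1))
  expect_equal(meshComponents(mesh), 1L)
  # unit outward normals, roughly radial for the ball
  nn <- meshNormals(mesh)
  expect_equal(sqrt(rowSums(nn^2)), rep(1, nrow(nn)), tolerance = 1e-9)
  outward <- rowSums(nn * meshVertices(mesh)) /
    sqrt(rowSums(meshVertices(mesh)^2))
  expect_gt(min(outward), 0.8)

  # no level crossing inside the grid (constant volume): empty mesh
  empty <- extractIsosurface(reconVolume(g, array(1, gridDims(g))), 0.5)
  expect_equal(nrow(meshVertices(empty)), 0L)
  expect_error(extractIsosurface(reconVolume(g, array(0, gridDims(g))),
                                 0.5), "positive")

  # two disjoint blobs give two components
  two <- array(0, gridDims(g))
  two <- array(pmax(1 - sqrt((ctr[, 1] - 5)^2 + ctr[, 2]^2 +
                               ctr[, 3]^2) / 3,
                    1 - sqrt((ctr[, 1] + 5)^2 + ctr[, 2]^2 +
                               ctr[, 3]^2) / 3,
                    0), dim = gridDims(g))
  mesh2 <- extractIsosurface(reconVolume(g, two), 0.5)
  expect_equal(meshComponents(mesh2), 2L)

  # nested level sets: vertex count non-increasing in the level
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8), function(lv)
    nrow(meshVertices(extractIsosurface(reconVolume(g, ball), lv))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the 3D pipeline composes and degrades to the identity", {
  g <- makeGrid(c(16, 16, 4), 1)
  set.seed(4)
  f <- array(runif(1024), c(16, 16, 4))
  v <- reconVolume(g, f)
  off <- recon3dConfig(lambdaTV3d = 0, nDiffusionSteps = 0,
                       waveletThreshold = 0, isoThreshold = 0.5)
  res <- reconstruct3d(v, off, normalize = FALSE)
  expect_equal(intensities(res$volume), f, tolerance = 1e-8)
  refMesh <- extractIsosurface(v, 0.5)
  expect_equal(meshVertices(res$mesh), meshVertices(refMesh),
               tolerance = 1e-8)
  expect_equal(length(res$xozSlices), 16L)
  expect_equal(res$xozSlices[[3]], intensities(res$volume)[, 3, ])

  zero <- reconVolume(g, array(0, c(16, 16, 4)))
  expect_error(reconstruct3d(zero, recon3dConfig()), "positive")
})
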