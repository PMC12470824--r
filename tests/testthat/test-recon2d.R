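# List-mode MLEM and the TV-regularized fused iteration.

test_that("MLEM closed-form update on the identity toy system", {
  A <- denseSystemMatrix(rbind(matrix(rep(c(1, 0), 3), 3, byrow = TRUE),
                               matrix(rep(c(0, 1), 5), 5, byrow = TRUE)))
  # with the generic unit sensitivity the counts are recovered directly
  expect_equal(mlemStep(c(1, 1), A, s = c(1, 1)), c(3, 5))
  # with the column-sum sensitivity the toy is already the ML solution
  f1 <- mlemStep(c(1, 1), A)
  expect_equal(f1, c(1, 1), tolerance = 1e-9)
  expect_error(mlemStep(c(0, 0), A), "all-zero")
})

test_that("the count identity holds after every plain step", {
  set.seed(12)
  for (q in 1:3) {
    m <- matrix(runif(60, 0, 2) * rbinom(60, 1, 0.6), 10, 6)
    m[m == 0 & row(m) == col(m)] <- 0.5  # keep rows non-empty
    A <- denseSystemMatrix(m)
    f <- runif(6, 0.1, 2)
    for (it in 1:5) {
      f <- mlemStep(f, A)
      expect_equal(sum(sensitivity(A) * f), nrow(m), tolerance = 1e-8)
    }
  }
})

test_that("the ML fixed point is stationary (brute-force verified)", {
  # invertible 3-voxel toy: the interior ML optimum solves A f = 1
  # (then the gradient sum_i a_ij / (Af)_i - s_j vanishes exactly),
  # so fstar = solve(A, 1) is a closed-form oracle; a brute-force
  # likelihood maximization over a grid confirms it
  set.seed(77)
  m <- diag(3) + matrix(runif(9, 0, 0.3), 3, 3)
  A <- denseSystemMatrix(m)
  fstar <- solve(m, rep(1, 3))
  expect_true(all(fstar > 0))
  nll <- function(lf) -listModeLogLik(exp(lf), A)
  opt <- optim(log(fstar * 1.5), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  expect_equal(exp(opt$par), fstar, tolerance = 1e-4)
  expect_equal(mlemStep(fstar, A), fstar, tolerance = 1e-10)
  # and MLEM converges to the same optimum from a flat start
  f <- rep(1, 3)
  for (it in 1:500) f <- mlemStep(f, A)
  expect_equal(f, fstar, tolerance = 1e-4)
})

test_that("log-likelihood is non-decreasing over plain MLEM iterations", {
  set.seed(15)
  for (q in 1:5) {
    m <- matrix(runif(48, 0, 1) * rbinom(48, 1, 0.7), 8, 6)
    m[rowSums(m) == 0, 1] <- 0.3
    A <- denseSystemMatrix(m)
    f <- runif(6, 0.5, 1.5)
    ll <- listModeLogLik(f, A)
    for (it in 1:20) {
      f <- mlemStep(f, A)
      llNew <- listModeLogLik(f, A)
      expect_gte(llNew, ll - 1e-10)
      ll <- llNew
    }
  }
})

test_that("total variation matches hand calculations", {
  g <- makeGrid(c(3, 1, 1), 1)
  expect_equal(tvValue(reconVolume(g, array(2, c(3, 1, 1)))), 0)
  expect_equal(tvValue(reconVolume(g, array(c(0, 1, 1), c(3, 1, 1)))), 1)
  f <- array(runif(27), c(3, 3, 3))
  expect_equal(tvValue(3 * f), 3 * tvValue(f), tolerance = 1e-12)
})

test_that("Bregman updates behave in both modes", {
  z <- array(0, c(4, 4, 2))
  cfg <- recon2dConfig()
  up <- bregmanUpdate(list(x = z, y = z, z = z),
                      list(x = z, y = z, z = z), cfg)
  expect_equal(up$d$x, z)
  expect_equal(up$b$x, z)
  expect_equal(up$div, z)

  gx <- array(1, c(4, 4, 2))
  up2 <- bregmanUpdate(list(x = gx, y = z, z = z),
                       list(x = z, y = z, z = z), cfg)
  expect_equal(sqrt(sum(up2$d$x^2)), 1, tolerance = 1e-9)

  shr <- recon2dConfig(tvMode = "shrinkage", beta = 1)
  small <- array(0.5, c(4, 4, 2))  # below 1/beta everywhere
  up3 <- bregmanUpdate(list(x = small, y = z, z = z),
                       list(x = z, y = z, z = z), shr)
  expect_equal(up3$d$x, z)
})

test_that("divergence is the negative adjoint of the forward gradient", {
  set.seed(19)
  f <- array(rnorm(60), c(5, 4, 3))
  d <- list(x = array(rnorm(60), c(5, 4, 3)),
            y = array(rnorm(60), c(5, 4, 3)),
            z = array(rnorm(60), c(5, 4, 3)))
  g <- ccxfct:::.forwardDiff(f)
  div <- ccxfct:::.divergence(d$x, d$y, d$z)
  # <grad f, d> = -<f, div d>
  lhs <- sum(g$x * d$x + g$y * d$y + g$z * d$z)
  rhs <- -sum(f * div)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("lambda = 0 fused trajectory equals the baseline bit-for-bit", {
  set.seed(23)
  grid <- makeGrid(c(10, 10, 3), 1)
  ev <- randomEvents(40)
  A <- assembleMatrix(ev, grid, NULL)
  rec0 <- reconstruct2d(NULL, grid, cfg = recon2dConfig(nIter = 6,
                                                        lambdaTV = 0),
                        A = A)
  f <- reconVolume(grid, array(as.numeric(sensitivity(A) > 0),
                               dim = gridDims(grid)))
  for (it in 1:6) {
    f <- mlemStep(f, A)
    expect_identical(intensities(rec0$volumes[[it]]), intensities(f))
  }
})

test_that("TV regularization lowers the iterate's total variation", {
  grid <- makeGrid(c(50, 50, 5), c(2, 2, 1))
  ev <- simulateDataset(buildPhantom(), detectorGeometry(),
                        simulationConfig(nEmissions = 1e5, seed = 7))
  kept <- filterEffective(ev)$events
  A <- assembleMatrix(kept, grid, NULL)
  plain <- reconstruct2d(NULL, grid,
                         cfg = recon2dConfig(nIter = 10, lambdaTV = 0),
                         A = A)
  reg <- reconstruct2d(NULL, grid,
                       cfg = recon2dConfig(nIter = 10, lambdaTV = 0.01),
                       A = A)
  expect_lte(tvValue(reg$volumes[[10]]), tvValue(plain$volumes[[10]]))
  # nonnegativity of every iterate and full snapshot trail
  expect_equal(length(reg$volumes), 10L)
  expect_true(all(vapply(reg$volumes,
                         function(v) min(intensities(v)) >= 0,
                         logical(1))))
})
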