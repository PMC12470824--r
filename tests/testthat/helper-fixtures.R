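# Shared fixtures and independent oracles used across test files.

# One-row canonical event data.frame.
makeEventRow <- function(id = 1L, side = "A", r0 = c(NA, NA, NA),
                         rs, ra, Es, Ea) {
  data.frame(event_id = id, side = side,
             x0 = r0[1], y0 = r0[2], z0 = r0[3],
             xs = rs[1], ys = rs[2], zs = rs[3],
             xa = ra[1], ya = ra[2], za = ra[3],
             Es = Es, Ea = Ea, stringsAsFactors = FALSE)
}

# Build a SystemMatrix by hand from a dense matrix (rows = events).
denseSystemMatrix <- function(m, grid = NULL) {
  if (is.null(grid)) grid <- makeGrid(c(ncol(m), 1, 1), 1)
  sp <- as(as(as(Matrix::Matrix(m, sparse = TRUE), "dMatrix"),
              "generalMatrix"), "CsparseMatrix")
  new("SystemMatrix", mat = sp, grid = grid,
      eventId = seq_len(nrow(m)))
}

# Independent brute-force evaluation of a system-matrix row: every voxel
# evaluated with no sparsity shortcut, mirroring the documented model
# a_ij = coneWeight * depositionFactor * pathSurvival.
bruteForceRow <- function(event, grid, muVec, sigmaCone, floorRel = 1e-6,
                          deposition = TRUE) {
  cone <- coneFromEvent(event)
  ctr <- voxelCenters(grid)
  ellRef <- mean(gridSpacing(grid))
  M <- nrow(ctr)
  a <- numeric(M)
  inv2s2 <- 1 / (2 * sigmaCone * sigmaCone)
  for (j in seq_len(M)) {
    d <- ctr[j, ] - cone$apex
    # plain double-precision accumulation (no extended-precision sum)
    r2 <- d[1] * d[1] + d[2] * d[2] + d[3] * d[3]
    r <- sqrt(r2)
    if (r == 0) next
    ca <- (d[1] * cone$axis[1] + d[2] * cone$axis[2] +
             d[3] * cone$axis[3]) / r
    ca <- min(1, max(-1, ca))
    delta <- acos(ca) - cone$halfAngle
    w <- exp(-(delta * delta) * inv2s2)
    u <- -d / r
    tlo <- -Inf; thi <- Inf
    for (k in 1:3) {
      if (abs(u[k]) > 1e-300) {
        h <- 0.5 * gridSpacing(grid)[k] / abs(u[k])
        tlo <- max(tlo, -h); thi <- min(thi, h)
      }
    }
    ell <- thi - tlo
    dep <- if (deposition) {
      if (muVec[j] > 0) 1 - exp(-muVec[j] * ell) else ell / ellRef
    } else muVec[j] * ell
    surv <- 1
    if (any(muVec > 0)) {
      seg <- rayPathLengths(ctr[j, ], cone$apex, grid)
      od <- 0
      for (q in seq_len(nrow(seg)))
        od <- od + muVec[seg$voxel[q] + 1L] * seg$length[q]
      surv <- exp(-od)
    }
    a[j] <- w * dep * surv
  }
  amax <- max(a)
  keep <- which(a >= floorRel * amax & a > 0)
  data.frame(voxel = keep - 1L, weight = a[keep])
}

# Random valid events whose cones intersect a grid centered at the
# origin: apex outside the grid on +x, axis pointing roughly back.
randomEvents <- function(n, E0 = 68.8) {
  theta <- runif(n, 0.2, 2.6)
  en <- energiesFromAngle(E0, theta)
  rs <- cbind(runif(n, 55, 70), runif(n, -8, 8), runif(n, -8, 8))
  dirb <- cbind(runif(n, 0.5, 1), runif(n, -0.4, 0.4),
                runif(n, -0.4, 0.4))
  dirb <- dirb / sqrt(rowSums(dirb^2))
  ra <- rs + dirb * runif(n, 15, 30)
  comptonEvents(data.frame(event_id = seq_len(n), side = "A",
                           x0 = NA, y0 = NA, z0 = NA,
                           xs = rs[, 1], ys = rs[, 2], zs = rs[, 3],
                           xa = ra[, 1], ya = ra[, 2], za = ra[, 3],
                           Es = en$E1, Ea = en$E2))
}

# Small blur-free simulated dataset, cached per session.
blurFreeDataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulateDataset(
        buildPhantom(), detectorGeometry(),
        simulationConfig(nEmissions = 5e4, seed = 21,
                         blurScatter = 0, blurAbsorber = 0))
    }
    cache
  }
})
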