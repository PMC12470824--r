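# Phantom construction and the Monte Carlo event generator.

test_that("default phantom has the documented material layout", {
  ph <- buildPhantom()
  expect_equal(materialAt(ph, cbind(0, 0, 0)), "water")
  expect_equal(materialAt(ph, cbind(24, 0, 0)), "air")
  expect_equal(materialAt(ph, cbind(30, 0, 0)), "exterior")
  expect_equal(materialAt(ph, cbind(15, 0, 0)), "au_solution")
  expect_equal(nrow(ph@inserts), 7L)
})

test_that("invalid phantom layouts are rejected", {
  bad <- data.frame(x = c(0, 1), y = 0, radius = 2.5,
                    material = "au_solution", concentration = 0.5)
  expect_error(buildPhantom(inserts = bad), "overlap")
  far <- data.frame(x = 24, y = 0, radius = 2.5,
                    material = "au_solution", concentration = 0.5)
  expect_error(buildPhantom(inserts = far), "inside")
})

test_that("detector sides are mirror images with the documented boxes", {
  g <- detectorGeometry()
  a <- detectorBoxes(g, "A")
  b <- detectorBoxes(g, "B")
  expect_equal(a$scatter[, 1], c(lo = 60, hi = 65))
  expect_equal(a$absorber[, 1], c(lo = 85, hi = 90))
  expect_equal(unname(b$scatter[, 1]), c(-65, -60))
  expect_equal(a$scatter[, 2:3], b$scatter[, 2:3])
})

test_that("emission multiplicity follows concentration x volume", {
  ins <- data.frame(x = c(-10, 10), y = 0, radius = 2.5,
                    material = "au_solution",
                    concentration = c(0.2, 0.4))
  ph <- buildPhantom(inserts = ins)
  set.seed(3)
  pos <- sampleEmissions(ph, 1e6)
  n1 <- sum(pos[, 1] < 0)
  expect_equal(n1 / 1e6, 1 / 3, tolerance = 0.01)
  # all positions inside some insert
  d1 <- sqrt((pos[, 1] + 10)^2 + pos[, 2]^2)
  d2 <- sqrt((pos[, 1] - 10)^2 + pos[, 2]^2)
  expect_true(all(pmin(d1, d2) <= 2.5 + 1e-12))
  expect_true(all(abs(pos[, 3]) <= 2.5))
  expect_error(sampleEmissions(buildPhantom(inserts = data.frame(
    x = 0, y = 0, radius = 2.5, material = "water", concentration = 0)),
    10), "positive concentration")
})

test_that("the event stream is deterministic under a fixed seed", {
  ph <- buildPhantom()
  cfg <- simulationConfig(nEmissions = 5000, seed = 5)
  e1 <- simulateDataset(ph, detectorGeometry(), cfg)
  e2 <- simulateDataset(ph, detectorGeometry(), cfg)
  expect_identical(eventData(e1), eventData(e2))
  e3 <- simulateDataset(ph, detectorGeometry(),
                        simulationConfig(nEmissions = 5000, seed = 6))
  expect_false(identical(eventData(e1), eventData(e3)))
})

test_that("blur-free events are kinematically self-consistent", {
  ev <- blurFreeDataset()
  d <- eventData(ev)
  expect_gt(nrow(d), 500)
  # exact energy conservation at the fluorescence line
  expect_equal(d$Es + d$Ea, rep(68.8, nrow(d)))
  # energy-derived angle equals the geometric angle rs-r0 / ra-rs
  ti <- scatterAngleFromEnergies(d$Es, d$Ea)
  v1 <- cbind(d$xs - d$x0, d$ys - d$y0, d$zs - d$z0)
  v2 <- cbind(d$xa - d$xs, d$ya - d$ys, d$za - d$zs)
  ca <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  expect_equal(ti, acos(pmin(1, pmax(-1, ca))), tolerance = 1e-6)
})

test_that("forced forward scattering keeps the ray straight", {
  ph <- buildPhantom()
  cfg <- simulationConfig(nEmissions = 2000, seed = 9, blurScatter = 0,
                          blurAbsorber = 0, angleLaw = "fixed",
                          fixedTheta = 0)
  ev <- simulateDataset(ph, detectorGeometry(), cfg)
  d <- eventData(ev)
  expect_gt(nrow(d), 10)
  # absorption point lies on the line r0 -> rs extended
  v1 <- cbind(d$xs - d$x0, d$ys - d$y0, d$zs - d$z0)
  v2 <- cbind(d$xa - d$xs, d$ya - d$ys, d$za - d$zs)
  cross <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
                 v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
                 v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  sine <- sqrt(rowSums(cross^2)) /
    (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  expect_lt(max(sine), 1e-9)
  expect_equal(d$Es, rep(0, nrow(d)))
})

test_that("efficiency bookkeeping is consistent", {
  ev <- blurFreeDataset()
  eff <- eventMetadata(ev)$efficiency
  expect_equal(eff$eta, eff$etaS * eff$etaA)
  expect_equal(eff$absorbed, nEvents(ev))
  expect_lte(eff$scattered, eff$reached)
  expect_lte(eff$absorbed, eff$scattered)
  # muSi = 0: nothing scatters
  ev0 <- simulateDataset(buildPhantom(), detectorGeometry(),
                         simulationConfig(nEmissions = 1000, seed = 4,
                                          muSi = 0))
  expect_equal(nEvents(ev0), 0L)
  expect_equal(eventMetadata(ev0)$efficiency$etaS, 0)
})

test_that("single-emission transport reports rejection tags", {
  ph <- buildPhantom()
  cfg <- simulationConfig(seed = 1)
  set.seed(10)
  tags <- character(50)
  for (q in 1:50) {
    r <- simulateEvent(c(15, 0, 0), ph, detectorGeometry(), cfg)
    tags[q] <- r$status
    if (r$status == "accepted") expect_equal(nrow(r$event), 1L)
  }
  expect_true(all(tags %in% c("accepted", "no-scatter", "absorber-miss")))
  expect_true("no-scatter" %in% tags)
})

test_that("mirroring the phantom matches side statistics within MC error", {
  ins <- data.frame(x = 10, y = 0, radius = 2.5,
                    material = "au_solution", concentration = 1)
  insM <- transform(ins, x = -x)
  cfg <- simulationConfig(nEmissions = 2e4, seed = 13)
  nA <- nEvents(simulateDataset(buildPhantom(inserts = ins),
                                detectorGeometry(), cfg))
  nB <- nEvents(simulateDataset(buildPhantom(inserts = insM),
                                detectorGeometry(), cfg))
  expect_lt(abs(nA - nB), 4 * sqrt(nA + nB))
})
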