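# Seeded list-mode Monte Carlo event generator.  Emulates the bilateral
# Compton-camera acquisition: fluorescence photons are emitted uniformly
# inside the Au inserts (multiplicity proportional to concentration x
# volume), importance-directed at a scatter-layer entry face, attenuated
# through the phantom, Compton-scattered at an exponentially sampled depth
# in the Si layer with a Klein-Nishina angle, and accepted if the
# scattered photon is absorbed in the same side's CdZnTe layer.  Energies
# are blurred with per-layer Gaussian resolution.

#' Simulation configuration
#'
#' @param nEmissions number of fluorescence photons to emit (> 0).
#' @param sourceEnergy excitation source energy, keV (81, just above the
#'   Au K-edge at 80.7 keV; recorded, not transported).
#' @param fluorescenceEnergy imaged fluorescence line, keV (default Au
#'   K-alpha1, 68.8).
#' @param blurScatter,blurAbsorber relative Gaussian energy resolution
#'   sigma/E per layer (defaults 0.05 and 0.02).
#' @param seed RNG seed; a fixed seed gives a bit-identical event stream.
#' @param angleLaw scattering-angle sampling law: `"klein_nishina"`
#'   (default), `"isotropic"` (uniform in cos theta) or `"fixed"`.
#' @param fixedTheta angle used when `angleLaw = "fixed"`, radians.
#' @param muSi Compton linear attenuation of the Si scatterer, 1/mm.
#' @param muAbsorber linear attenuation of the CdZnTe absorber, 1/mm.
#' @param muTable phantom material attenuation lookup
#'   ([defaultMuTable()]).
#' @return classed list of validated settings.
#' @export
simulationConfig <- function(nEmissions = 1e5, sourceEnergy = 81,
                             fluorescenceEnergy = 68.8,
                             blurScatter = 0.05, blurAbsorber = 0.02,
                             seed = 1L,
                             angleLaw = c("klein_nishina", "isotropic",
                                          "fixed"),
                             fixedTheta = pi / 2,
                             muSi = defaultMuTable()[["si"]],
                             muAbsorber = defaultMuTable()[["cdznte"]],
                             muTable = defaultMuTable()) {
  angleLaw <- match.arg(angleLaw)
  stopifnot(nEmissions > 0, blurScatter >= 0, blurAbsorber >= 0,
            fluorescenceEnergy > 0, muSi >= 0, muAbsorber >= 0)
  structure(list(nEmissions = as.integer(nEmissions),
                 sourceEnergy = sourceEnergy,
                 fluorescenceEnergy = fluorescenceEnergy,
                 blurScatter = blurScatter, blurAbsorber = blurAbsorber,
                 seed = as.integer(seed), angleLaw = angleLaw,
                 fixedTheta = fixedTheta, muSi = muSi,
                 muAbsorber = muAbsorber, muTable = muTable),
            class = "ccxfct_simconfig")
}

#' Sample fluorescence emission points
#'
#' Emission counts per insert follow a multinomial with probabilities
#' proportional to concentration x insert volume; positions are uniform
#' within each insert cylinder.
#'
#' @param phantom a [PhantomSpec-class] with at least one insert of
#'   positive concentration.
#' @param n number of emissions (> 0).
#' @return n x 3 matrix of positions (mm), in insert-block order.
#' @export
sampleEmissions <- function(phantom, n) {
  stopifnot(n > 0)
  ins <- phantom@inserts
  wt <- ins$concentration * ins$radius^2   # common pi*h factor drops out
  if (all(wt <= 0)) stop("no insert with positive concentration")
  counts <- as.integer(stats::rmultinom(1, n, wt))
  pos <- matrix(0, n, 3)
  row <- 1L
  for (k in seq_len(nrow(ins))) {
    nk <- counts[k]
    if (nk == 0L) next
    r <- ins$radius[k] * sqrt(stats::runif(nk))
    a <- stats::runif(nk, 0, 2 * pi)
    pos[row:(row + nk - 1L), ] <- cbind(
      ins$x[k] + r * cos(a), ins$y[k] + r * sin(a),
      stats::runif(nk, -phantom@height / 2, phantom@height / 2))
    row <- row + nk
  }
  pos
}

# Ray/box intersection, vectorized over rays.  p: n x 3 origins, d: n x 3
# directions; returns cbind(t0, t1) (t1 <= t0 where there is no hit).
.boxInterval <- function(p, d, box) {
  t0 <- rep(-Inf, nrow(p)); t1 <- rep(Inf, nrow(p))
  for (k in 1:3) {
    dk <- d[, k]
    para <- abs(dk) < 1e-300
    ta <- (box[1, k] - p[, k]) / dk
    tb <- (box[2, k] - p[, k]) / dk
    lo <- pmin(ta, tb); hi <- pmax(ta, tb)
    lo[para] <- ifelse(p[para, k] >= box[1, k] & p[para, k] <= box[2, k],
                       -Inf, Inf)
    hi[para] <- ifelse(p[para, k] >= box[1, k] & p[para, k] <= box[2, k],
                       Inf, -Inf)
    t0 <- pmax(t0, lo); t1 <- pmin(t1, hi)
  }
  cbind(t0, t1)
}

# Optical depth through the phantom inserts along segments p0 -> p1
# (air background contributes nothing).  Vectorized over segments.
.phantomOpticalDepth <- function(phantom, p0, p1, muTable) {
  L <- sqrt(rowSums((p1 - p0)^2))
  od <- numeric(nrow(p0))
  ins <- phantom@inserts
  dz <- p1[, 3] - p0[, 3]
  # z-slab parameter interval of the phantom
  zlo <- -phantom@height / 2; zhi <- phantom@height / 2
  tz0 <- ifelse(abs(dz) < 1e-300,
                ifelse(p0[, 3] >= zlo & p0[, 3] <= zhi, 0, 1), NA)
  tz1 <- tz0
  nz <- abs(dz) >= 1e-300
  a <- (zlo - p0[nz, 3]) / dz[nz]; b <- (zhi - p0[nz, 3]) / dz[nz]
  tz0[nz] <- pmin(a, b); tz1[nz] <- pmax(a, b)
  tz0 <- pmax(tz0, 0); tz1 <- pmin(tz1, 1)
  for (k in seq_len(nrow(ins))) {
    mu <- if (ins$material[k] == "au_solution")
      muTable[["au_solution"]] + ins$concentration[k] *
        muTable[["au_per_percent"]]
    else muTable[[ins$material[k]]]
    if (mu <= 0) next
    ex <- p0[, 1] - ins$x[k]; ey <- p0[, 2] - ins$y[k]
    dx <- p1[, 1] - p0[, 1]; dy <- p1[, 2] - p0[, 2]
    A <- dx^2 + dy^2
    B <- 2 * (ex * dx + ey * dy)
    C <- ex^2 + ey^2 - ins$radius[k]^2
    disc <- B^2 - 4 * A * C
    hit <- disc > 0 & A > 0
    if (!any(hit)) next
    sq <- sqrt(disc[hit])
    ta <- pmax(((-B[hit] - sq) / (2 * A[hit])), tz0[hit], 0)
    tb <- pmin(((-B[hit] + sq) / (2 * A[hit])), tz1[hit], 1)
    seg <- pmax(tb - ta, 0) * L[hit]
    od[hit] <- od[hit] + mu * seg
  }
  od
}

# Sample Klein-Nishina scattering angles at photon energy E (keV) by
# rejection against the bound at forward scattering.
.sampleKleinNishina <- function(n, E) {
  k <- E / electronRestEnergy()
  out <- numeric(0)
  fmax <- 2  # value of eps^2 (eps + 1/eps - sin^2) at cos = 1
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 16L)
    ct <- stats::runif(m, -1, 1)
    eps <- 1 / (1 + k * (1 - ct))
    f <- eps^2 * (eps + 1 / eps - (1 - ct^2))
    keep <- stats::runif(m) * fmax < f
    out <- c(out, ct[keep])
  }
  acos(out[seq_len(n)])
}

# Orthonormal vectors perpendicular to each row of unit matrix d (n x 3).
.perpBasis <- function(d) {
  ref <- matrix(rep(c(0, 0, 1), each = nrow(d)), ncol = 3)
  flip <- abs(d[, 3]) > 0.9
  ref[flip, ] <- matrix(rep(c(0, 1, 0), each = sum(flip)), ncol = 3)
  u <- cbind(d[, 2] * ref[, 3] - d[, 3] * ref[, 2],
             d[, 3] * ref[, 1] - d[, 1] * ref[, 3],
             d[, 1] * ref[, 2] - d[, 2] * ref[, 1])
  u <- u / sqrt(rowSums(u^2))
  v <- cbind(d[, 2] * u[, 3] - d[, 3] * u[, 2],
             d[, 3] * u[, 1] - d[, 1] * u[, 3],
             d[, 1] * u[, 2] - d[, 2] * u[, 1])
  list(u = u, v = v)
}

# Vectorized transport of emissions through one acquisition.  Returns the
# accepted-event table plus per-stage counts.  Consumes the current RNG
# stream in a fixed draw order (side, face point, attenuation, depth,
# angle, azimuth, absorber depth, blur).
.transportBatch <- function(pos, phantom, geometry, config) {
  n <- nrow(pos)
  E <- config$fluorescenceEnergy
  side <- sample(c("A", "B"), n, replace = TRUE)
  boxes <- list(A = detectorBoxes(geometry, "A"),
                B = detectorBoxes(geometry, "B"))
  # entry-face target point, uniform on the face nearest the phantom
  half <- geometry@scatterSize / 2
  ty <- stats::runif(n, -half[1], half[1])
  tz <- stats::runif(n, -half[2], half[2])
  tx <- ifelse(side == "A", geometry@standoff, -geometry@standoff)
  target <- cbind(tx, ty, tz)

  # phantom attenuation en route to the scatterer (rejection weighting)
  od <- .phantomOpticalDepth(phantom, pos, target, config$muTable)
  reached <- stats::runif(n) < exp(-od)

  dirv <- target - pos
  dirv <- dirv / sqrt(rowSums(dirv^2))

  # interaction depth in the Si slab
  chord <- numeric(n)
  for (s in c("A", "B")) {
    idx <- side == s
    if (!any(idx)) next
    tt <- .boxInterval(target[idx, , drop = FALSE],
                       dirv[idx, , drop = FALSE], boxes[[s]]$scatter)
    chord[idx] <- pmax(tt[, 2] - pmax(tt[, 1], 0), 0)
  }
  depth <- if (config$muSi > 0) stats::rexp(n, rate = config$muSi)
           else rep(Inf, n)
  scattered <- reached & depth < chord
  rs <- target + depth * dirv

  # scattering angle and azimuth
  theta <- switch(config$angleLaw,
    klein_nishina = .sampleKleinNishina(n, E),
    isotropic = acos(stats::runif(n, -1, 1)),
    fixed = rep(config$fixedTheta, n))
  phi <- stats::runif(n, 0, 2 * pi)
  en <- energiesFromAngle(E, theta)
  pb <- .perpBasis(dirv)
  dscat <- cos(theta) * dirv +
    sin(theta) * (cos(phi) * pb$u + sin(phi) * pb$v)

  # absorber intersection and absorption depth
  tIn <- rep(Inf, n); tOut <- rep(-Inf, n)
  for (s in c("A", "B")) {
    idx <- side == s
    if (!any(idx)) next
    tt <- .boxInterval(rs[idx, , drop = FALSE],
                       dscat[idx, , drop = FALSE], boxes[[s]]$absorber)
    tIn[idx] <- tt[, 1]; tOut[idx] <- tt[, 2]
  }
  hits <- scattered & tIn > 0 & tOut > tIn
  adepth <- if (config$muAbsorber > 0) stats::rexp(n, rate = config$muAbsorber)
            else rep(Inf, n)
  absorbed <- hits & adepth < (tOut - tIn)
  ra <- rs + (tIn + adepth) * dscat

  # Gaussian per-layer energy blur
  Es <- pmax(en$E1 * (1 + config$blurScatter * stats::rnorm(n)), 0)
  Ea <- pmax(en$E2 * (1 + config$blurAbsorber * stats::rnorm(n)), 1e-9)

  keep <- which(absorbed)
  data <- data.frame(event_id = seq_along(keep), side = side[keep],
                     x0 = pos[keep, 1], y0 = pos[keep, 2],
                     z0 = pos[keep, 3],
                     xs = rs[keep, 1], ys = rs[keep, 2], zs = rs[keep, 3],
                     xa = ra[keep, 1], ya = ra[keep, 2], za = ra[keep, 3],
                     Es = Es[keep], Ea = Ea[keep],
                     stringsAsFactors = FALSE)
  list(data = data,
       counts = c(emitted = n, reached = sum(reached),
                  scattered = sum(scattered), absorbed = sum(absorbed)))
}

#' Transport a single emission through the detector
#'
#' One-photon version of the transport used by [simulateDataset()]; uses
#' (and advances) the current RNG state.
#'
#' @param emission length-3 emission position, mm (inside the phantom).
#' @param phantom a [PhantomSpec-class].
#' @param geometry a [DetectorGeometry-class].
#' @param config a [simulationConfig()].
#' @return list with `status` (`"accepted"`, `"no-scatter"` or
#'   `"absorber-miss"`) and, when accepted, `event` (one-row canonical
#'   data.frame).
#' @export
simulateEvent <- function(emission, phantom, geometry, config) {
  b <- .transportBatch(matrix(emission, 1, 3), phantom, geometry, config)
  if (nrow(b$data) == 1L) return(list(status = "accepted", event = b$data))
  st <- if (b$counts[["scattered"]] == 0L) "no-scatter" else "absorber-miss"
  list(status = st, event = NULL)
}

#' Simulate a list-mode dataset
#'
#' Seeds the RNG from `config$seed`, samples emissions with
#' [sampleEmissions()], transports them and returns the accepted events
#' together with the efficiency bookkeeping: scattering efficiency
#' `etaS` (scattered / reached scatterer), absorption efficiency `etaA`
#' (absorbed / scattered) and overall `eta = etaS * etaA`.
#'
#' @param phantom a [PhantomSpec-class].
#' @param geometry a [DetectorGeometry-class].
#' @param config a [simulationConfig()].
#' @return a [ComptonEvents-class]; the efficiency summary is in
#'   `eventMetadata(x)$efficiency`.
#' @examples
#' ph <- buildPhantom()
#' ev <- simulateDataset(ph, detectorGeometry(),
#'                       simulationConfig(nEmissions = 2000, seed = 1))
#' eventMetadata(ev)$efficiency
#' @export
simulateDataset <- function(phantom, geometry = detectorGeometry(),
                            config = simulationConfig()) {
  set.seed(config$seed)
  pos <- sampleEmissions(phantom, config$nEmissions)
  b <- .transportBatch(pos, phantom, geometry, config)
  cn <- b$counts
  etaS <- if (cn[["reached"]] > 0) cn[["scattered"]] / cn[["reached"]] else 0
  etaA <- if (cn[["scattered"]] > 0) cn[["absorbed"]] / cn[["scattered"]]
          else 0
  eff <- list(emitted = cn[["emitted"]], reached = cn[["reached"]],
              scattered = cn[["scattered"]], absorbed = cn[["absorbed"]],
              etaS = etaS, etaA = etaA, eta = etaS * etaA)
  new("ComptonEvents", data = b$data,
      metadata = list(seed = config$seed, efficiency = eff,
                      fluorescenceEnergy = config$fluorescenceEnergy,
                      config = config))
}
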