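# System- and image-quality metrics: energy-derived vs geometry-derived
# scattering angles, the angular resolution measure (ARM) and its FWHM,
# detector energy resolution, and per-ROI CNR/SNR on reconstructed
# slices.

#' Energy-derived scattering angle, degrees
#'
#' `theta_i = arccos(1 - m_e c^2 * Es / ((Es + Ea) * Ea))`; identical to
#' [scatterAngleFromEnergies()] converted to degrees.  Kinematically
#' impossible pairs give `NA` (count in `attr(, "nInvalid")`) rather than
#' an error, so they can be excluded from distributions.
#'
#' @param events a [ComptonEvents-class] or canonical data.frame.
#' @return numeric vector of degrees with attribute `nInvalid`.
#' @export
thetaI <- function(events) {
  d <- if (is(events, "ComptonEvents")) events@data else events
  E0 <- d$Es + d$Ea
  arg <- 1 - electronRestEnergy() * (1 / d$Ea - 1 / E0)
  ok <- abs(arg) <= 1 + 1e-9
  th <- rep(NA_real_, length(arg))
  th[ok] <- acos(pmin(1, pmax(-1, arg[ok]))) / .DEG
  attr(th, "nInvalid") <- sum(!ok)
  th
}

#' Geometry-derived cone angle, degrees
#'
#' Angle between the incoming direction `rs - r0` and the outgoing
#' direction `ra - rs`, in `[0, 180]`.
#'
#' @param events a [ComptonEvents-class] or canonical data.frame; the
#'   truth columns x0/y0/z0 are used unless `r0` is given.
#' @param r0 optional fixed source position (length 3, mm).
#' @return numeric vector of degrees.
#' @export
thetaC <- function(events, r0 = NULL) {
  d <- if (is(events, "ComptonEvents")) events@data else events
  rs <- as.matrix(d[, c("xs", "ys", "zs")])
  ra <- as.matrix(d[, c("xa", "ya", "za")])
  src <- if (is.null(r0)) as.matrix(d[, c("x0", "y0", "z0")])
         else matrix(r0, nrow(d), 3, byrow = TRUE)
  v1 <- rs - src
  v2 <- ra - rs
  n1 <- sqrt(rowSums(v1^2)); n2 <- sqrt(rowSums(v2^2))
  if (any(n1 == 0 | n2 == 0)) stop("degenerate geometry: coincident points")
  ca <- rowSums(v1 * v2) / (n1 * n2)
  acos(pmin(1, pmax(-1, ca))) / .DEG
}

#' Angular resolution measure (ARM), degrees
#'
#' Signed per-event difference `theta_i - theta_c` between the
#' energy-derived and geometry-derived scattering angles.  `NA` where
#' the kinematics are invalid.
#'
#' @inheritParams thetaC
#' @return numeric vector of degrees with attribute `nInvalid`.
#' @export
armValues <- function(events, r0 = NULL) {
  ti <- thetaI(events)
  tc <- thetaC(events, r0)
  out <- ti - tc
  attr(out, "nInvalid") <- attr(ti, "nInvalid")
  out
}

#' FWHM of a sample distribution
#'
#' Histogram-based full width at half maximum: bin width by a
#' Freedman-Diaconis-style rule with a fixed floor, peak bin, and
#' half-maximum crossings by linear interpolation between bin centers.
#' A Gaussian-moment estimate `2*sqrt(2*log(2))*sd` is reported
#' alongside, and secondary peaks (local maxima above half maximum
#' separated from the main peak by a dip below it) set the multimodality
#' flag.
#'
#' @param samples numeric vector (>= 100 values).
#' @param binFloor minimum bin width in the sample's units (default 0.1,
#'   i.e. 0.1 degrees for ARM input).
#' @return list with `fwhm`, `fwhmGaussian`, `binWidth`, `multimodal`,
#'   `peak` (mode location).
#' @export
fwhmEstimate <- function(samples, binFloor = 0.1) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 100L) stop("need at least 100 samples")
  if (stats::sd(samples) == 0)
    stop("degenerate sample: all values identical")
  bw <- max(2 * stats::IQR(samples) / length(samples)^(1 / 3), binFloor)
  brk <- seq(min(samples) - bw, max(samples) + bw, by = bw)
  hh <- graphics::hist(samples, breaks = brk, plot = FALSE)
  # 3-bin moving average stabilizes the peak height and the crossings
  # against counting noise (documented part of the estimator)
  cnt <- hh$counts
  if (length(cnt) >= 3L)
    cnt <- as.numeric(stats::filter(cnt, rep(1 / 3, 3), sides = 2,
                                    circular = FALSE))
  cnt[is.na(cnt)] <- hh$counts[is.na(cnt)]
  mid <- hh$mids
  if (max(cnt) == 0 || length(unique(cnt)) == 1L)
    stop("degenerate histogram: no peak")
  pk <- which.max(cnt)
  # peak height from a local quadratic fit (robust against the upward
  # bias of a max over noisy bins)
  win <- max(1L, pk - 4L):min(length(cnt), pk + 4L)
  height <- if (length(win) >= 5L) {
    co <- stats::lm.fit(cbind(1, win - pk, (win - pk)^2), cnt[win])$coefficients
    if (is.finite(co[3]) && co[3] < 0)
      max(co[1] - co[2]^2 / (4 * co[3]), cnt[pk] * 0.8)
    else cnt[pk]
  } else cnt[pk]
  height <- min(height, cnt[pk] * 1.2)
  half <- height / 2
  # left crossing
  li <- pk
  while (li > 1L && cnt[li - 1L] >= half) li <- li - 1L
  xl <- if (li == 1L) mid[1L] - bw / 2 else {
    f0 <- cnt[li - 1L]; f1 <- cnt[li]
    mid[li - 1L] + (half - f0) / (f1 - f0) * bw
  }
  ri <- pk
  nb <- length(cnt)
  while (ri < nb && cnt[ri + 1L] >= half) ri <- ri + 1L
  xr <- if (ri == nb) mid[nb] + bw / 2 else {
    f0 <- cnt[ri]; f1 <- cnt[ri + 1L]
    mid[ri] + (f0 - half) / (f0 - f1) * bw
  }
  # multimodality: another local max >= half outside the main lobe
  multim <- FALSE
  if (nb >= 3L) {
    locmax <- which(cnt >= c(-1, cnt[-nb]) & cnt >= c(cnt[-1], -1) &
                    cnt >= half)
    for (q in locmax) {
      if (q == pk) next
      between <- cnt[seq(min(q, pk), max(q, pk))]
      if (any(between < half)) { multim <- TRUE; break }
    }
  }
  list(fwhm = xr - xl,
       fwhmGaussian = 2 * sqrt(2 * log(2)) * stats::sd(samples),
       binWidth = bw, multimodal = multim, peak = mid[pk])
}

#' Detector energy resolution, percent
#'
#' `R = sigma_E / mu_E * 100` with the n-1 sample standard deviation.
#'
#' @param samples energies, keV (>= 2 values, positive mean).
#' @return percentage.
#' @examples
#' energyResolution(c(90, 110))  # 14.142
#' @export
energyResolution <- function(samples) {
  if (length(samples) < 2L) stop("need at least 2 samples")
  m <- mean(samples)
  if (m <= 0) stop("mean energy must be positive")
  stats::sd(samples) / m * 100
}

#' ROI specification for slice metrics
#'
#' @param centers k x 2 matrix of ROI centers in slice coordinates (mm).
#' @param radius ROI disk radius, mm (scalar or per-ROI).
#' @param exclusionMargin extra margin (mm) excluded from the background
#'   around every ROI (default 1).
#' @param labels optional ROI labels.
#' @return classed list.
#' @export
roiSpec <- function(centers, radius, exclusionMargin = 1, labels = NULL) {
  centers <- rbind(centers)
  radius <- rep_len(radius, nrow(centers))
  if (is.null(labels)) labels <- paste0("roi", seq_len(nrow(centers)))
  structure(list(centers = centers, radius = radius,
                 exclusionMargin = exclusionMargin, labels = labels),
            class = "ccxfct_roispec")
}

#' ROIs at the default phantom insert positions
#'
#' @param phantom a [PhantomSpec-class].
#' @param auOnly keep only the Au inserts (default TRUE).
#' @param exclusionMargin background exclusion margin, mm.
#' @return a [roiSpec()] labeled by concentration.
#' @export
phantomROIs <- function(phantom, auOnly = TRUE, exclusionMargin = 1) {
  ins <- phantom@inserts
  if (auOnly) ins <- ins[ins$concentration > 0, , drop = FALSE]
  roiSpec(cbind(ins$x, ins$y), ins$radius, exclusionMargin,
          labels = sprintf("c%.1f", ins$concentration))
}

#' Per-ROI CNR and SNR of a slice
#'
#' `CNR = (mu_ROI - mu_bg) / sigma_bg`, `SNR = mu_ROI / sigma_bg`.  The
#' background is the slice minus all ROI disks dilated by the exclusion
#' margin.  The `meetsCNR4` column flags the conventional CNR >= 4
#' detectability threshold.
#'
#' @param image 2D matrix (a z-slice of a [ReconVolume-class]).
#' @param grid the [VoxelGrid-class] the slice lives on (for mm
#'   coordinates).
#' @param rois a [roiSpec()].
#' @return data.frame with one row per ROI: `roi`, `meanROI`, `cnr`,
#'   `snr`, `meetsCNR4`.
#' @export
cnrSnr <- function(image, grid, rois) {
  ctr <- voxelCenters(grid)
  nx <- grid@dims[1]; ny <- grid@dims[2]
  px <- matrix(ctr[seq_len(nx * ny), 1], nx, ny)
  py <- matrix(ctr[seq_len(nx * ny), 2], nx, ny)
  stopifnot(all(dim(image) == c(nx, ny)))
  k <- nrow(rois$centers)
  inAny <- matrix(FALSE, nx, ny)
  masks <- vector("list", k)
  for (q in seq_len(k)) {
    d2 <- (px - rois$centers[q, 1])^2 + (py - rois$centers[q, 2])^2
    masks[[q]] <- d2 <= rois$radius[q]^2
    inAny <- inAny | (d2 <= (rois$radius[q] + rois$exclusionMargin)^2)
    if (sum(masks[[q]]) < 5L)
      stop("ROI ", rois$labels[q], " contains fewer than 5 voxels")
  }
  bg <- image[!inAny]
  if (length(bg) < 10L) stop("background has fewer than 10 voxels")
  sbg <- stats::sd(bg)
  if (sbg == 0) stop("degenerate background: zero standard deviation")
  mbg <- mean(bg)
  res <- data.frame(roi = rois$labels,
                    meanROI = vapply(masks, function(m) mean(image[m]),
                                     numeric(1)))
  res$cnr <- (res$meanROI - mbg) / sbg
  res$snr <- res$meanROI / sbg
  res$meetsCNR4 <- res$cnr >= 4
  res
}

#' Aggregate CNR/SNR over replicate reconstructions
#'
#' @param tables list of data.frames from [cnrSnr()] (replicates).
#' @return data.frame with per-ROI mean and sd of CNR and SNR and the
#'   replicate count.
#' @export
aggregateCnrSnr <- function(tables) {
  stopifnot(length(tables) >= 1L)
  roi <- tables[[1L]]$roi
  cnr <- sapply(tables, `[[`, "cnr")
  snr <- sapply(tables, `[[`, "snr")
  cnr <- matrix(cnr, nrow = length(roi))
  snr <- matrix(snr, nrow = length(roi))
  data.frame(roi = roi,
             cnrMean = rowMeans(cnr),
             cnrSd = apply(cnr, 1, stats::sd),
             snrMean = rowMeans(snr),
             snrSd = apply(snr, 1, stats::sd),
             replicates = length(tables))
}
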