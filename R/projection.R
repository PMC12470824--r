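# Voxelization, Compton-cone construction, ray traversal and dynamic
# system-matrix assembly.  Each effective event constrains its source to a
# cone (apex = scatter point, axis = back-pointing scatter-to-absorber
# line, half-angle = kinematic scattering angle); the system matrix
# discretizes cone membership x interaction probability x attenuation
# survival per voxel.

#' Construct a voxel grid
#'
#' @param extent either a length-3 vector of box edge lengths (mm,
#'   centered at the origin) or a 2 x 3 matrix `rbind(lo, hi)` of corner
#'   coordinates.  Default: the phantom bounding box, 50 x 50 x 5 mm.
#' @param spacing voxel size, mm; scalar or length 3.  Must divide the
#'   extent to within rounding.
#' @return a [VoxelGrid-class].
#' @examples
#' makeGrid()                      # 50 x 50 x 5 voxels of 1 mm
#' makeGrid(c(3, 1, 1), 1)        # centers at x = -1, 0, 1
#' @export
makeGrid <- function(extent = c(50, 50, 5), spacing = 1) {
  if (any(spacing <= 0)) stop("spacing must be positive")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (is.matrix(extent)) {
    lo <- extent[1, ]; hi <- extent[2, ]
  } else {
    lo <- -extent / 2; hi <- extent / 2
  }
  len <- hi - lo
  if (any(len <= 0)) stop("extent must have positive volume")
  dims <- as.integer(round(len / spacing))
  if (any(abs(dims * spacing - len) > 1e-6 * pmax(len, 1)))
    stop("spacing must divide the extent")
  new("VoxelGrid", origin = as.numeric(lo), spacing = spacing, dims = dims)
}

#' Voxel centers in linear-index order
#'
#' @param grid a [VoxelGrid-class].
#' @return M x 3 matrix of voxel centers (mm), ordered by the linear
#'   index `j = ix + nx*(iy + ny*iz)` (x fastest).
#' @export
voxelCenters <- function(grid) {
  ax <- lapply(1:3, function(k)
    grid@origin[k] + (seq_len(grid@dims[k]) - 0.5) * grid@spacing[k])
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                        KEEP.OUT.ATTRS = FALSE))
}

#' Back-projection cone of a Compton event
#'
#' The possible source positions of an event lie on the cone with apex at
#' the scatter point `rs`, axis `unit(rs - ra)` (pointing back toward the
#' source side) and half-angle equal to the kinematic scattering angle
#' from the deposited energies.
#'
#' @param event one-row data.frame (or [ComptonEvents-class] of length 1)
#'   with the canonical columns.
#' @return list with elements `apex` (mm), `axis` (unit vector) and
#'   `halfAngle` (radians).
#' @export
coneFromEvent <- function(event) {
  if (is(event, "ComptonEvents")) event <- event@data
  stopifnot(nrow(event) == 1L)
  rs <- as.numeric(event[1, c("xs", "ys", "zs")])
  ra <- as.numeric(event[1, c("xa", "ya", "za")])
  ax <- rs - ra
  n <- sqrt(sum(ax^2))
  if (n == 0) stop("degenerate event: rs == ra")
  list(apex = rs, axis = ax / n,
       halfAngle = scatterAngleFromEnergies(event$Es[1], event$Ea[1]))
}

.coneBatch <- function(events) {
  d <- if (is(events, "ComptonEvents")) events@data else events
  rs <- as.matrix(d[, c("xs", "ys", "zs")])
  ra <- as.matrix(d[, c("xa", "ya", "za")])
  ax <- rs - ra
  n <- sqrt(rowSums(ax^2))
  if (any(n == 0)) stop("degenerate event: rs == ra")
  list(apex = unname(rs), axis = unname(ax / n),
       halfAngle = scatterAngleFromEnergies(d$Es, d$Ea))
}

#' Ordered voxel traversal of a segment
#'
#' Intersects the segment from `p1` to `p2` with the grid and returns the
#' voxels crossed with their chord lengths; the lengths sum to the length
#' of the segment clipped to the grid.
#'
#' @param p1,p2 length-3 endpoints, mm (`p1 != p2`).
#' @param grid a [VoxelGrid-class].
#' @return data.frame with columns `voxel` (0-based linear index) and
#'   `length` (mm), in traversal order from `p1`; zero rows when the
#'   segment misses the grid.
#' @export
rayPathLengths <- function(p1, p2, grid) {
  stopifnot(length(p1) == 3L, length(p2) == 3L)
  if (all(p1 == p2)) stop("p1 and p2 must differ")
  r <- .ray_path_cpp(as.numeric(p1), as.numeric(p2), grid@origin,
                     grid@spacing, grid@dims)
  data.frame(voxel = r$voxel, length = r$length)
}

#' Gaussian cone-membership weight of a voxel center
#'
#' Discretizes the cone-surface probability with a Gaussian angular
#' kernel: `w = exp(-Delta^2 / (2 sigma^2))` where `Delta` is the angular
#' distance of the voxel center from the cone surface (angle to the axis
#' minus the half-angle).  `w = 1` exactly on the surface; a voxel at the
#' apex gets weight 0 by convention.
#'
#' @param cone list as returned by [coneFromEvent()].
#' @param centers n x 3 matrix of voxel centers, mm.
#' @param sigmaCone angular kernel width, radians (> 0).
#' @return numeric vector of weights in `[0, 1]`.
#' @export
coneVoxelWeight <- function(cone, centers, sigmaCone) {
  stopifnot(sigmaCone > 0)
  centers <- rbind(centers)
  d <- sweep(centers, 2, cone$apex)
  r <- sqrt(rowSums(d^2))
  ca <- pmin(1, pmax(-1, as.numeric(d %*% cone$axis) / r))
  delta <- acos(ca) - cone$halfAngle
  w <- exp(-delta^2 / (2 * sigmaCone^2))
  w[r == 0] <- 0
  w
}

.DEG <- pi / 180

#' Assemble the sparse system matrix
#'
#' For each event i and voxel j the contribution is
#' `a_ij = w_ij * e_ij * P_ij`: the Gaussian cone weight
#' ([coneVoxelWeight()]), the deposition factor
#' `e_ij = 1 - exp(-mu_j * l_j)` over the voxel chord `l_j` toward the
#' apex (degrading to the geometric weight `l_j / l_ref` when
#' `mu_j = 0`), and the Beer-Lambert survival `P_ij` along the
#' voxel-center-to-apex path through the attenuation map.  Entries below
#' `floorRel` times the row maximum are dropped.
#'
#' @param events a [ComptonEvents-class] (non-empty).
#' @param grid a [VoxelGrid-class].
#' @param muVol attenuation map: [ReconVolume-class] on `grid` (1/mm), or
#'   `NULL` for no attenuation.
#' @param sigmaCone angular kernel width, radians (default 2 degrees).
#' @param floorRel row-relative sparsity floor (default 1e-6).
#' @param deposition use the deposition-fraction form (default); if
#'   `FALSE`, the pure `mu_j * l_j` interaction weight.
#' @param chunkSize events per assembly block (memory control only; the
#'   result is independent of it).
#' @return a [SystemMatrix-class]; errors if every row is empty.
#' @export
assembleMatrix <- function(events, grid, muVol = NULL, sigmaCone = 2 * .DEG,
                           floorRel = 1e-6, deposition = TRUE,
                           chunkSize = 2000L) {
  if (nEvents(events) == 0L) stop("no events to assemble")
  cones <- .coneBatch(events)
  mu <- if (is.null(muVol)) numeric(prod(grid@dims)) else {
    if (!identical(voxelGrid(muVol)@dims, grid@dims))
      stop("mu map grid does not match reconstruction grid")
    as.numeric(intensities(muVol))
  }
  diag3 <- sqrt(sum((grid@spacing * grid@dims)^2))
  survBound <- exp(-max(mu) * diag3)
  ellRef <- mean(grid@spacing)
  m <- nEvents(events)
  M <- prod(grid@dims)
  starts <- seq(1L, m, by = as.integer(chunkSize))
  # rows come out of the kernel in order with ascending voxel indices, so
  # the chunks concatenate directly into CSR (dgRMatrix) storage
  jList <- vector("list", length(starts))
  xList <- vector("list", length(starts))
  rowCounts <- integer(m)
  for (b in seq_along(starts)) {
    s <- starts[b]
    e <- min(s + chunkSize - 1L, m)
    idx <- s:e
    tr <- .assemble_cpp(cones$apex[idx, , drop = FALSE],
                        cones$axis[idx, , drop = FALSE],
                        cones$halfAngle[idx],
                        grid@origin, grid@spacing, grid@dims, mu,
                        sigmaCone, floorRel, ellRef, deposition, survBound)
    jList[[b]] <- tr$j - 1L
    xList[[b]] <- tr$x
    rowCounts[idx] <- tabulate(tr$i, nbins = length(idx))
  }
  jAll <- unlist(jList, use.names = FALSE)
  jList <- NULL
  xAll <- unlist(xList, use.names = FALSE)
  xList <- NULL
  if (length(xAll) == 0L)
    stop("all system-matrix rows are empty; check geometry configuration")
  mat <- new("dgRMatrix", p = as.integer(c(0L, cumsum(rowCounts))),
             j = jAll, x = xAll, Dim = c(m, as.integer(M)))
  new("SystemMatrix", mat = mat, grid = grid,
      eventId = as.integer(events@data$event_id))
}

#' Single system-matrix row
#'
#' Convenience wrapper around [assembleMatrix()] for one event; returns
#' the sparse row as a data.frame.
#'
#' @inheritParams assembleMatrix
#' @param event one-row event (data.frame or [ComptonEvents-class]).
#' @return data.frame with columns `voxel` (0-based linear index) and
#'   `weight`; may have zero rows.
#' @export
systemMatrixRow <- function(event, grid, muVol = NULL, sigmaCone = 2 * .DEG,
                            floorRel = 1e-6, deposition = TRUE) {
  if (is(event, "ComptonEvents")) event <- event@data
  ev <- new("ComptonEvents", data = event[1, , drop = FALSE],
            metadata = list())
  A <- tryCatch(
    assembleMatrix(ev, grid, muVol, sigmaCone, floorRel, deposition),
    error = function(e) NULL)
  if (is.null(A))
    return(data.frame(voxel = integer(), weight = numeric()))
  row <- A@mat[1, ]
  nz <- which(row > 0)
  data.frame(voxel = nz - 1L, weight = row[nz])
}

#' Simple cone back-projection
#'
#' Sums the system-matrix rows into voxel space:
#' `b_j = sum_i a_ij`.  This is the pre-iteration display image.
#'
#' @inheritParams assembleMatrix
#' @return a [ReconVolume-class]; all-zero when `events` is empty.
#' @export
backproject <- function(events, grid, muVol = NULL, sigmaCone = 2 * .DEG,
                        floorRel = 1e-6, deposition = TRUE) {
  if (nEvents(events) == 0L) return(reconVolume(grid, 0))
  A <- assembleMatrix(events, grid, muVol, sigmaCone, floorRel, deposition)
  reconVolume(grid, array(sensitivity(A), dim = as.integer(grid@dims)))
}
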