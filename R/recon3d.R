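# 3D post-processing: edge-preserving anisotropic TV diffusion, slice-wise
# wavelet-domain soft thresholding, and isosurface extraction for
# visualization.

#' 3D post-processing configuration
#'
#' @param lambdaTV3d diffusion strength (default 0.01).
#' @param epsilonDiff gradient regularizer epsilon in the diffusion flux
#'   (default 1e-6).
#' @param nDiffusionSteps explicit time steps (default 10; 0 = identity).
#' @param stepSize time step (default 0.1).
#' @param waveletFamily `"haar"`, `"db2"` or `"db4"`.
#' @param levels wavelet decomposition depth J (default 2).
#' @param waveletThreshold soft threshold T applied to detail subbands
#'   (default 0.01).
#' @param isoThreshold isosurface level as a fraction of the volume
#'   maximum (default 0.001).
#' @return classed list of settings.
#' @export
recon3dConfig <- function(lambdaTV3d = 0.01, epsilonDiff = 1e-6,
                          nDiffusionSteps = 10, stepSize = 0.1,
                          waveletFamily = "haar", levels = 2,
                          waveletThreshold = 0.01, isoThreshold = 0.001) {
  stopifnot(lambdaTV3d >= 0, epsilonDiff > 0, nDiffusionSteps >= 0,
            stepSize > 0, levels >= 1, waveletThreshold >= 0,
            isoThreshold > 0, isoThreshold < 1)
  structure(list(lambdaTV3d = lambdaTV3d, epsilonDiff = epsilonDiff,
                 nDiffusionSteps = as.integer(nDiffusionSteps),
                 stepSize = stepSize, waveletFamily = waveletFamily,
                 levels = as.integer(levels),
                 waveletThreshold = waveletThreshold,
                 isoThreshold = isoThreshold),
            class = "ccxfct_recon3dconfig")
}

#' Anisotropic TV diffusion
#'
#' Explicit integration of the edge-preserving curvature flow
#' `df/dt = lambda * div(grad f / (|grad f| + eps))`: per-axis face
#' conductance `1/(|grad f| + eps)`, so smooth regions (small gradients)
#' diffuse strongly while edges (large gradients) are preserved.  The
#' per-face update weight is limited at `1/(2*ndim)` so that every step
#' is a convex average of neighbors: the scheme conserves the mean,
#' never increases the variance and obeys the discrete maximum
#' principle.  Step sizes for which even the limited scheme would break
#' monotonicity raise an error stating the bound.
#'
#' @param v a [ReconVolume-class] or 3D array.
#' @param cfg a [recon3dConfig()].
#' @return diffused volume, same class as the input.
#' @export
anisotropicTVDiffuse <- function(v, cfg = recon3dConfig()) {
  isVol <- is(v, "ReconVolume")
  f <- if (isVol) intensities(v) else v
  h <- if (isVol) voxelGrid(v)@spacing else c(1, 1, 1)
  dt <- cfg$stepSize; lam <- cfg$lambdaTV3d; eps <- cfg$epsilonDiff
  cfl <- dt * lam * 2 * sum(1 / h^2)
  if (cfl > 1)
    stop(sprintf(paste0(
      "diffusion step violates the stability bound: ",
      "stepSize * lambda * 2 * sum(1/h^2) = %.3g > 1; ",
      "reduce stepSize below %.3g"), cfl, h[1]^2 / (lam * 6)))
  if (cfg$nDiffusionSteps == 0L || lam == 0) return(v)
  d <- dim(f)
  wcap <- 1 / 6  # 2 * ndim faces
  for (step in seq_len(cfg$nDiffusionSteps)) {
    upd <- array(0, d)
    for (k in 1:3) {
      if (d[k] == 1L) next
      idx1 <- lapply(d, seq_len); idx1[[k]] <- 1:(d[k] - 1)
      idx2 <- lapply(d, seq_len); idx2[[k]] <- 2:d[k]
      lo <- do.call(`[`, c(list(f), idx1))
      hi <- do.call(`[`, c(list(f), idx2))
      diff <- hi - lo
      g <- abs(diff) / h[k]
      w <- pmin(dt * lam / (h[k]^2 * (g + eps)), wcap)
      flux <- w * diff
      tmp <- array(0, d)
      tmp <- do.call(`[<-`, c(list(tmp), idx1,
                              list(do.call(`[`, c(list(tmp), idx1)) + flux)))
      tmp <- do.call(`[<-`, c(list(tmp), idx2,
                              list(do.call(`[`, c(list(tmp), idx2)) - flux)))
      upd <- upd + tmp
    }
    f <- f + upd
  }
  if (isVol) reconVolume(voxelGrid(v), f) else f
}

## ---- separable orthonormal DWT (periodic extension) ----

.waveletFilter <- function(family) {
  switch(family,
    haar = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) /
      (4 * sqrt(2)),
    db4 = c(0.230377813308855, 0.714846570552542, 0.630880767929590,
            -0.027983769416984, -0.187034811718881, 0.030841381835987,
            0.032883011666983, -0.010597401784997),
    stop("unknown wavelet family '", family,
         "'; supported: haar, db2, db4"))
}

# Analysis step on the columns of matrix x (periodic): returns
# rbind(approx, detail), each nrow(x)/2 rows.
.dwtCols <- function(x, h) {
  n <- nrow(x); L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)  # highpass from lowpass
  a <- matrix(0, n / 2, ncol(x)); dd <- a
  for (m in seq_len(L)) {
    idx <- ((2 * seq_len(n / 2) - 2 + (m - 1)) %% n) + 1
    a <- a + h[m] * x[idx, , drop = FALSE]
    dd <- dd + g[m] * x[idx, , drop = FALSE]
  }
  rbind(a, dd)
}

# Synthesis step: inverse of .dwtCols.
.idwtCols <- function(ad, h) {
  n2 <- nrow(ad); n <- n2; half <- n / 2
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  a <- ad[seq_len(half), , drop = FALSE]
  dd <- ad[half + seq_len(half), , drop = FALSE]
  x <- matrix(0, n, ncol(ad))
  for (m in seq_len(L)) {
    idx <- ((2 * seq_len(half) - 2 + (m - 1)) %% n) + 1
    for (cc in seq_len(ncol(ad))) {
      x[idx, cc] <- x[idx, cc] + h[m] * a[, cc] + g[m] * dd[, cc]
    }
  }
  x
}

#' Multilevel 2D discrete wavelet transform of a slice
#'
#' Standard separable decomposition with periodic extension; energy is
#' preserved for the orthonormal families.  Slices whose dimensions are
#' not divisible by `2^J` are edge-padded (the inverse transform crops
#' back).
#'
#' @param slice 2D numeric matrix.
#' @param family wavelet family (`"haar"`, `"db2"`, `"db4"`).
#' @param J decomposition depth (>= 1).
#' @return list of class `ccxfct_dwt2`: per level `LH`, `HL`, `HH`
#'   detail matrices, final approximation `LL`, plus bookkeeping.
#' @export
dwt2 <- function(slice, family = "haar", J = 1) {
  h <- .waveletFilter(family)
  origDim <- dim(slice)
  mult <- 2^J
  padTo <- ceiling(origDim / mult) * mult
  if (any(padTo != origDim)) {
    padded <- matrix(0, padTo[1], padTo[2])
    padded[seq_len(origDim[1]), seq_len(origDim[2])] <- slice
    if (padTo[1] > origDim[1])
      padded[(origDim[1] + 1):padTo[1], seq_len(origDim[2])] <-
        matrix(slice[origDim[1], ], padTo[1] - origDim[1], origDim[2],
               byrow = TRUE)
    if (padTo[2] > origDim[2])
      padded[, (origDim[2] + 1):padTo[2]] <-
        padded[, origDim[2], drop = TRUE]
    slice <- padded
  }
  levels <- vector("list", J)
  cur <- slice
  for (j in seq_len(J)) {
    tmp <- .dwtCols(cur, h)                    # rows transformed
    tmp <- t(.dwtCols(t(tmp), h))              # then columns
    hr <- nrow(cur) / 2; hc <- ncol(cur) / 2
    levels[[j]] <- list(LH = tmp[seq_len(hr), hc + seq_len(hc)],
                        HL = tmp[hr + seq_len(hr), seq_len(hc)],
                        HH = tmp[hr + seq_len(hr), hc + seq_len(hc)])
    cur <- tmp[seq_len(hr), seq_len(hc)]
  }
  structure(list(LL = cur, levels = levels, family = family, J = J,
                 origDim = origDim),
            class = "ccxfct_dwt2")
}

#' Inverse multilevel 2D wavelet transform
#'
#' @param w a decomposition from [dwt2()].
#' @return reconstructed matrix with the original slice dimensions.
#' @export
idwt2 <- function(w) {
  h <- .waveletFilter(w$family)
  cur <- w$LL
  for (j in rev(seq_len(w$J))) {
    lv <- w$levels[[j]]
    hr <- nrow(cur); hc <- ncol(cur)
    tmp <- rbind(cbind(cur, lv$LH), cbind(lv$HL, lv$HH))
    tmp <- t(.idwtCols(t(tmp), h))
    cur <- .idwtCols(tmp, h)
  }
  cur[seq_len(w$origDim[1]), seq_len(w$origDim[2]), drop = FALSE]
}

#' Soft thresholding
#'
#' `ST(c, T) = sign(c) * (|c| - T)` for `|c| >= T`, 0 otherwise.
#'
#' @param c coefficient(s).
#' @param T threshold (>= 0).
#' @return shrunk coefficient(s).
#' @examples
#' softThreshold(c(5, -5, 1), 2)  # 3, -3, 0
#' @export
softThreshold <- function(c, T) {
  stopifnot(T >= 0)
  sign(c) * pmax(abs(c) - T, 0)
}

#' Slice-wise wavelet denoising
#'
#' For every z-slice: [dwt2()], soft threshold on the detail subbands
#' only (approximation untouched), [idwt2()].
#'
#' @param v a [ReconVolume-class] or 3D array.
#' @param cfg a [recon3dConfig()].
#' @return denoised volume, same class and dimensions as the input.
#' @export
waveletDenoise <- function(v, cfg = recon3dConfig()) {
  isVol <- is(v, "ReconVolume")
  f <- if (isVol) intensities(v) else v
  out <- f
  for (k in seq_len(dim(f)[3])) {
    w <- dwt2(f[, , k], cfg$waveletFamily, cfg$levels)
    for (j in seq_len(w$J)) {
      w$levels[[j]]$LH <- softThreshold(w$levels[[j]]$LH,
                                        cfg$waveletThreshold)
      w$levels[[j]]$HL <- softThreshold(w$levels[[j]]$HL,
                                        cfg$waveletThreshold)
      w$levels[[j]]$HH <- softThreshold(w$levels[[j]]$HH,
                                        cfg$waveletThreshold)
    }
    out[, , k] <- idwt2(w)
  }
  if (isVol) reconVolume(voxelGrid(v), out) else out
}

## ---- isosurface extraction (marching tetrahedra) ----

# Decomposition of the unit cube into 6 tetrahedra sharing the main
# diagonal (corner ids 1..8 = (ix, iy, iz) offsets in binary order
# x fastest: 1=(0,0,0), 2=(1,0,0), 3=(0,1,0), 4=(1,1,0), 5=(0,0,1), ...).
.TETS <- matrix(c(1, 2, 4, 8,
                  1, 2, 8, 6,
                  1, 6, 8, 5,
                  1, 4, 3, 8,
                  1, 3, 7, 8,
                  1, 7, 5, 8), ncol = 4, byrow = TRUE)

#' Extract an isosurface from a volume
#'
#' Marching-tetrahedra extraction at `isoFraction * max(v)`; the sample
#' lattice is the voxel centers.  Vertices are returned in world (mm)
#' coordinates; normals point outward (toward decreasing intensity) and
#' are computed from the interpolated central-difference gradient.
#'
#' @param v a [ReconVolume-class] (or 3D array with `grid` supplied).
#' @param isoFraction level as a fraction of the volume maximum, in
#'   (0, 1).
#' @param grid grid when `v` is a plain array.
#' @return an [IsoMesh-class]; empty (0 vertices) when no voxel exceeds
#'   the level.
#' @export
extractIsosurface <- function(v, isoFraction = 0.001, grid = NULL) {
  if (is(v, "ReconVolume")) { grid <- voxelGrid(v); f <- intensities(v) }
  else f <- v
  if (is.null(grid)) stop("grid required for array input")
  if (max(f) <= 0) stop("volume maximum must be positive")
  level <- isoFraction * max(f)
  d <- dim(f)
  if (any(d < 2L) || !any(f > level))
    return(new("IsoMesh", vertices = matrix(0, 0, 3),
               faces = matrix(0L, 0, 3), normals = matrix(0, 0, 3),
               level = level))

  nx <- d[1] - 1L; ny <- d[2] - 1L; nz <- d[3] - 1L
  # corner index arrays for all cells, linearized over the full lattice
  cellIdx <- as.matrix(expand.grid(ix = seq_len(nx), iy = seq_len(ny),
                                   iz = seq_len(nz)))
  lin <- function(ix, iy, iz) ix + d[1] * (iy - 1L) + d[1] * d[2] * (iz - 1L)
  off <- as.matrix(expand.grid(ox = 0:1, oy = 0:1, oz = 0:1))
  corner <- matrix(0L, nrow(cellIdx), 8L)
  for (cc in 1:8)
    corner[, cc] <- lin(cellIdx[, 1] + off[cc, 1], cellIdx[, 2] + off[cc, 2],
                        cellIdx[, 3] + off[cc, 3])
  fv <- as.numeric(f)
  # drop cells that cannot intersect the level
  cmin <- fv[corner[, 1]]; cmax <- cmin
  for (cc in 2:8) {
    cmin <- pmin(cmin, fv[corner[, cc]])
    cmax <- pmax(cmax, fv[corner[, cc]])
  }
  act <- which(cmin < level & cmax >= level)
  if (!length(act))
    return(new("IsoMesh", vertices = matrix(0, 0, 3),
               faces = matrix(0L, 0, 3), normals = matrix(0, 0, 3),
               level = level))
  corner <- corner[act, , drop = FALSE]

  ctr <- voxelCenters(grid)
  triA <- NULL; triB <- NULL; triC <- NULL  # matrices of lattice-id pairs

  addTris <- function(inV, outV) {
    # inV: list of lattice ids inside per row? handled by caller
  }
  edgeKeyList <- list()
  tris <- list()
  for (tq in seq_len(nrow(.TETS))) {
    vids <- corner[, .TETS[tq, ], drop = FALSE]
    vals <- matrix(fv[vids], ncol = 4)
    ins <- vals >= level
    nin <- rowSums(ins)
    # one vertex inside -> one triangle (apex = inside vertex)
    for (caseN in c(1L, 3L)) {
      rows <- which(nin == caseN)
      if (!length(rows)) next
      inside <- if (caseN == 1L) ins[rows, , drop = FALSE]
                else !ins[rows, , drop = FALSE]
      apexCol <- max.col(inside, ties.method = "first")
      others <- matrix(0L, length(rows), 3)
      for (r in seq_along(rows))
        others[r, ] <- setdiff(1:4, apexCol[r])
      a <- vids[cbind(rows, apexCol)]
      e1 <- cbind(a, vids[cbind(rows, others[, 1])])
      e2 <- cbind(a, vids[cbind(rows, others[, 2])])
      e3 <- cbind(a, vids[cbind(rows, others[, 3])])
      tris[[length(tris) + 1L]] <- list(e1, e2, e3)
    }
    rows <- which(nin == 2L)
    if (length(rows)) {
      insR <- ins[rows, , drop = FALSE]
      p <- t(apply(insR, 1, function(z) c(which(z), which(!z))))
      i1 <- vids[cbind(rows, p[, 1])]; i2 <- vids[cbind(rows, p[, 2])]
      o1 <- vids[cbind(rows, p[, 3])]; o2 <- vids[cbind(rows, p[, 4])]
      # quad vertices on edges (i1,o1), (i1,o2), (i2,o2), (i2,o1)
      eA <- cbind(i1, o1); eB <- cbind(i1, o2)
      eC <- cbind(i2, o2); eD <- cbind(i2, o1)
      tris[[length(tris) + 1L]] <- list(eA, eB, eC)
      tris[[length(tris) + 1L]] <- list(eA, eC, eD)
    }
  }
  if (!length(tris))
    return(new("IsoMesh", vertices = matrix(0, 0, 3),
               faces = matrix(0L, 0, 3), normals = matrix(0, 0, 3),
               level = level))
  E1 <- do.call(rbind, lapply(tris, `[[`, 1))
  E2 <- do.call(rbind, lapply(tris, `[[`, 2))
  E3 <- do.call(rbind, lapply(tris, `[[`, 3))
  allE <- rbind(E1, E2, E3)
  # canonical edge key (unordered pair) -> shared interpolated vertex
  key <- paste(pmin(allE[, 1], allE[, 2]), pmax(allE[, 1], allE[, 2]))
  uk <- !duplicated(key)
  vidx <- match(key, key[uk])
  ue <- allE[uk, , drop = FALSE]
  va <- fv[ue[, 1]]; vb <- fv[ue[, 2]]
  tt <- (level - va) / (vb - va)
  tt[!is.finite(tt)] <- 0.5
  tt <- pmin(1, pmax(0, tt))
  verts <- ctr[ue[, 1], , drop = FALSE] +
    tt * (ctr[ue[, 2], , drop = FALSE] - ctr[ue[, 1], , drop = FALSE])
  nTri <- nrow(E1)
  faces <- cbind(vidx[seq_len(nTri)],
                 vidx[nTri + seq_len(nTri)],
                 vidx[2 * nTri + seq_len(nTri)])
  good <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
          faces[, 1] != faces[, 3]
  faces <- faces[good, , drop = FALSE]

  normals <- .vertexNormals(f, grid, verts)
  new("IsoMesh", vertices = unname(verts), faces = unname(faces),
      normals = normals, level = level)
}

# Outward unit normals: minus the trilinearly interpolated central-
# difference gradient (intensity decreases outward).
.vertexNormals <- function(f, grid, verts) {
  d <- dim(f)
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  if (d[1] > 1) {
    gx[2:(d[1] - 1), , ] <- (f[3:d[1], , ] - f[1:(d[1] - 2), , ]) / 2
    gx[1, , ] <- f[2, , ] - f[1, , ]; gx[d[1], , ] <- f[d[1], , ] -
      f[d[1] - 1, , ]
  }
  if (d[2] > 1) {
    gy[, 2:(d[2] - 1), ] <- (f[, 3:d[2], ] - f[, 1:(d[2] - 2), ]) / 2
    gy[, 1, ] <- f[, 2, ] - f[, 1, ]; gy[, d[2], ] <- f[, d[2], ] -
      f[, d[2] - 1, ]
  }
  if (d[3] > 1) {
    gz[, , 2:(d[3] - 1)] <- (f[, , 3:d[3]] - f[, , 1:(d[3] - 2)]) / 2
    gz[, , 1] <- f[, , 2] - f[, , 1]; gz[, , d[3]] <- f[, , d[3]] -
      f[, , d[3] - 1]
  }
  ig <- floor(sweep(sweep(verts, 2, grid@origin), 2, grid@spacing, "/") +
              0.5)
  ig <- pmax(pmin(sweep(ig, 2, c(0, 0, 0), "+"),
                  matrix(rep(d - 1L, each = nrow(verts)), ncol = 3)), 1)
  idx <- cbind(ig[, 1], ig[, 2], ig[, 3])
  n <- -cbind(gx[idx], gy[idx], gz[idx])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Connected components of a mesh's face graph
#'
#' @param mesh an [IsoMesh-class].
#' @return integer: number of connected components (0 for empty mesh).
#' @export
meshComponents <- function(mesh) {
  nf <- nrow(mesh@faces)
  if (nf == 0L) return(0L)
  nv <- nrow(mesh@vertices)
  parent <- seq_len(nv)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (r in seq_len(nf)) {
    a <- find(mesh@faces[r, 1])
    b <- find(mesh@faces[r, 2])
    cc <- find(mesh@faces[r, 3])
    parent[b] <- a; parent[find(cc)] <- a
  }
  roots <- vapply(unique(as.integer(mesh@faces)), find, integer(1))
  length(unique(roots))
}

#' Full 3D post-processing pipeline
#'
#' Select an iterate from a 2D reconstruction, run anisotropic TV
#' diffusion, slice-wise wavelet denoising and isosurface extraction,
#' and cut XOZ-plane slices of the processed volume.
#'
#' @param recon a `ccxfct_recon2d` result (from [reconstruct2d()]), a
#'   list of [ReconVolume-class], or a single volume.
#' @param cfg a [recon3dConfig()].
#' @param iterate 1-based index of the iterate to use (default: last).
#' @param normalize rescale the iterate to unit maximum first (default
#'   TRUE: the MLEM intensity scale is arbitrary, and the wavelet and
#'   isosurface thresholds are defined on the normalized scale).
#' @return list with `volume` (processed [ReconVolume-class]), `mesh`
#'   (an [IsoMesh-class]) and `xozSlices` (list of 2D matrices, one per
#'   y index).
#' @export
reconstruct3d <- function(recon, cfg = recon3dConfig(), iterate = NULL,
                          normalize = TRUE) {
  vols <- if (inherits(recon, "ccxfct_recon2d")) recon$volumes
          else if (is(recon, "ReconVolume")) list(recon)
          else recon
  if (!length(vols)) stop("no input volume")
  if (is.null(iterate)) iterate <- length(vols)
  v <- vols[[iterate]]
  if (normalize && max(intensities(v)) > 0)
    v <- reconVolume(voxelGrid(v), intensities(v) / max(intensities(v)))
  v <- anisotropicTVDiffuse(v, cfg)
  v <- waveletDenoise(v, cfg)
  mesh <- extractIsosurface(v, cfg$isoThreshold)
  f <- intensities(v)
  xoz <- lapply(seq_len(dim(f)[2]), function(iy) f[, iy, ])
  list(volume = v, mesh = mesh, xozSlices = xoz)
}
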