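#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom Matrix Matrix dgRMatrix dgCMatrix
#' @importFrom Matrix colSums crossprod sparseMatrix
#' @useDynLib ccxfct, .registration = TRUE
NULL

#' VoxelGrid: axis-aligned voxelization of the reconstruction region
#'
#' A `VoxelGrid` describes an axis-aligned box partitioned into voxels.
#' `origin` is the minimum corner (mm), `spacing` the voxel edge lengths
#' (mm) and `dims` the voxel counts per axis.  Voxels are indexed 0-based
#' with linear index `j = ix + nx*(iy + ny*iz)`; voxel boundaries are
#' half-open `[low, high)`.
#'
#' @slot origin numeric(3), minimum corner in mm.
#' @slot spacing numeric(3), voxel size in mm, all > 0.
#' @slot dims integer(3), voxel counts, all >= 1.
#' @export
setClass("VoxelGrid",
  representation(origin = "numeric", spacing = "numeric", dims = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@origin) != 3L) msg <- c(msg, "origin must have length 3")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive finite numbers")
    if (length(object@dims) != 3L || any(object@dims < 1L))
      msg <- c(msg, "dims must be 3 integers >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' ReconVolume: per-voxel intensities on a VoxelGrid
#'
#' Couples a 3D array of voxel intensities with the [VoxelGrid-class]
#' describing its geometry.  `intensities(v)` returns the array,
#' `voxelGrid(v)` the grid.
#'
#' @slot grid a [VoxelGrid-class].
#' @slot data 3D numeric array with `dim == dims(grid)`.
#' @export
setClass("ReconVolume",
  representation(grid = "VoxelGrid", data = "array"),
  validity = function(object) {
    if (!identical(dim(object@data), as.integer(object@grid@dims)))
      return("data dimensions must equal grid dims")
    TRUE
  })

#' ComptonEvents: list-mode Compton event records
#'
#' Holds one row per effective Compton event: scatter position `rs`
#' (columns xs, ys, zs, mm), absorption position `ra` (xa, ya, za, mm),
#' deposited energies `Es`, `Ea` (keV), detector side (`"A"` or `"B"`),
#' and -- for simulated data -- the ground-truth emission point `r0`
#' (x0, y0, z0, `NA` when unknown).
#'
#' @slot data data.frame with the canonical columns
#'   `event_id side x0 y0 z0 xs ys zs xa ya za Es Ea`.
#' @slot metadata list of provenance (seed, config, efficiency counts).
#' @export
setClass("ComptonEvents",
  representation(data = "data.frame", metadata = "list"),
  validity = function(object) {
    need <- c("event_id", "side", "x0", "y0", "z0", "xs", "ys", "zs",
              "xa", "ya", "za", "Es", "Ea")
    miss <- setdiff(need, names(object@data))
    if (length(miss))
      return(paste("missing columns:", paste(miss, collapse = ", ")))
    d <- object@data
    if (nrow(d)) {
      if (any(d$Es < 0, na.rm = TRUE)) return("Es must be >= 0")
      if (any(d$Ea <= 0, na.rm = TRUE)) return("Ea must be > 0")
      same <- d$xs == d$xa & d$ys == d$ya & d$zs == d$za
      if (any(same, na.rm = TRUE))
        return("scatter and absorption points must differ")
      if (!all(d$side %in% c("A", "B"))) return("side must be 'A' or 'B'")
    }
    TRUE
  })

#' SystemMatrix: sparse event-by-voxel contribution matrix
#'
#' Row i holds the contributions a_ij of every voxel j to Compton event i
#' (cone-membership weight x deposition factor x attenuation survival).
#' The column sums are the voxel sensitivities s_j.
#'
#' @slot mat a `Matrix::dgCMatrix`, events x voxels, entries >= 0.
#' @slot grid the [VoxelGrid-class] the columns refer to.
#' @slot eventId integer vector of event ids, one per row.
#' @export
setClass("SystemMatrix",
  representation(mat = "Matrix", grid = "VoxelGrid", eventId = "integer"),
  validity = function(object) {
    if (nrow(object@mat) != length(object@eventId))
      return("one event id per row required")
    if (ncol(object@mat) != prod(object@grid@dims))
      return("column count must equal voxel count of grid")
    TRUE
  })

#' IsoMesh: triangulated isosurface
#'
#' @slot vertices n x 3 matrix of vertex positions (mm, world coordinates).
#' @slot faces m x 3 integer matrix of 1-based vertex indices.
#' @slot normals n x 3 matrix of unit outward vertex normals.
#' @slot level the absolute intensity level the surface was extracted at.
#' @export
setClass("IsoMesh",
  representation(vertices = "matrix", faces = "matrix", normals = "matrix",
                 level = "numeric"),
  validity = function(object) {
    if (nrow(object@faces) && (max(object@faces) > nrow(object@vertices) ||
        min(object@faces) < 1L))
      return("face indices out of range")
    TRUE
  })

setMethod("show", "VoxelGrid", function(object) {
  cat("VoxelGrid:", paste(object@dims, collapse = " x "), "voxels, spacing",
      paste(signif(object@spacing, 4), collapse = " x "), "mm\n")
  cat("  origin (mm):", paste(signif(object@origin, 6), collapse = ", "), "\n")
})

setMethod("show", "ReconVolume", function(object) {
  cat("ReconVolume:", paste(object@grid@dims, collapse = " x "),
      "voxels; intensity range [",
      signif(min(object@data), 4), ",", signif(max(object@data), 4), "]\n")
})

setMethod("show", "ComptonEvents", function(object) {
  n <- nrow(object@data)
  cat("ComptonEvents:", n, "events")
  if (n) {
    tot <- object@data$Es + object@data$Ea
    cat("; total energy", signif(mean(tot), 4), "+/-",
        signif(stats::sd(tot), 3), "keV")
  }
  cat("\n")
  if (length(object@metadata))
    cat("  metadata fields:", paste(names(object@metadata), collapse = ", "),
        "\n")
})

setMethod("show", "SystemMatrix", function(object) {
  cat("SystemMatrix:", nrow(object@mat), "events x", ncol(object@mat),
      "voxels,", length(object@mat@x), "stored entries\n")
})

setMethod("show", "IsoMesh", function(object) {
  cat("IsoMesh:", nrow(object@vertices), "vertices,", nrow(object@faces),
      "faces at level", signif(object@level, 4), "\n")
})

#' Number of events
#' @param x a [ComptonEvents-class] or [SystemMatrix-class].
#' @return integer count.
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname nEvents
#' @export
setMethod("nEvents", "ComptonEvents", function(x) nrow(x@data))

#' @rdname nEvents
#' @export
setMethod("nEvents", "SystemMatrix", function(x) nrow(x@mat))

#' Event table accessor
#' @param x a [ComptonEvents-class].
#' @return the canonical event data.frame.
#' @export
eventData <- function(x) {
  stopifnot(is(x, "ComptonEvents"))
  x@data
}

#' Event metadata accessor
#' @param x a [ComptonEvents-class].
#' @return the metadata list.
#' @export
eventMetadata <- function(x) {
  stopifnot(is(x, "ComptonEvents"))
  x@metadata
}

#' Grid accessors
#' @param x an object holding a [VoxelGrid-class].
#' @return `voxelGrid`: the grid; `gridDims`, `gridSpacing`, `gridOrigin`:
#'   the corresponding slot.
#' @export
setGeneric("voxelGrid", function(x) standardGeneric("voxelGrid"))

#' @rdname voxelGrid
#' @export
setMethod("voxelGrid", "ReconVolume", function(x) x@grid)

#' @rdname voxelGrid
#' @export
setMethod("voxelGrid", "SystemMatrix", function(x) x@grid)

#' @rdname voxelGrid
#' @export
setMethod("voxelGrid", "VoxelGrid", function(x) x)

#' @rdname voxelGrid
#' @param x a grid-bearing object.
#' @export
gridDims <- function(x) voxelGrid(x)@dims

#' @rdname voxelGrid
#' @export
gridSpacing <- function(x) voxelGrid(x)@spacing

#' @rdname voxelGrid
#' @export
gridOrigin <- function(x) voxelGrid(x)@origin

#' Voxel intensity accessor
#' @param x a [ReconVolume-class].
#' @return 3D numeric array.
#' @export
intensities <- function(x) {
  stopifnot(is(x, "ReconVolume"))
  x@data
}

#' Construct a ReconVolume
#' @param grid a [VoxelGrid-class].
#' @param data 3D array matching the grid; a scalar is recycled.
#' @return a [ReconVolume-class].
#' @export
reconVolume <- function(grid, data = 0) {
  if (length(data) == 1L)
    data <- array(data, dim = as.integer(grid@dims))
  new("ReconVolume", grid = grid, data = data)
}

#' Sensitivity vector s_j of a system matrix
#'
#' @param x a [SystemMatrix-class].
#' @return numeric vector of column sums, one per voxel.
#' @export
sensitivity <- function(x) {
  stopifnot(is(x, "SystemMatrix"))
  m <- x@mat
  if (is(m, "dgRMatrix"))
    .csr_colsums(m@p, m@j, m@x, ncol(m))
  else
    Matrix::colSums(m)
}

# Forward (A v) and adjoint (t(A) v) products that stay in CSR for the
# row-sparse matrices the assembler emits.
.sysMatvec <- function(A, v) {
  m <- A@mat
  if (is(m, "dgRMatrix")) .csr_matvec(m@p, m@j, m@x, as.numeric(v))
  else as.numeric(m %*% v)
}

.sysTmatvec <- function(A, v) {
  m <- A@mat
  if (is(m, "dgRMatrix")) .csr_tmatvec(m@p, m@j, m@x, as.numeric(v),
                                       ncol(m))
  else as.numeric(Matrix::crossprod(m, v))
}

#' Mesh accessors
#' @param x an [IsoMesh-class].
#' @return the requested component.
#' @export
meshVertices <- function(x) { stopifnot(is(x, "IsoMesh")); x@vertices }

#' @rdname meshVertices
#' @export
meshFaces <- function(x) { stopifnot(is(x, "IsoMesh")); x@faces }

#' @rdname meshVertices
#' @export
meshNormals <- function(x) { stopifnot(is(x, "IsoMesh")); x@normals }
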