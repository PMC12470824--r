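# Phantom and detector geometry.  The phantom is the standard XFCT test
# object: an air-filled cylinder (R = 25 mm, height 5 mm, axis = z) with
# six 2.5 mm-radius cylindrical inserts of Au-nanoparticle solution at
# 0.2-1.2 % w/v plus a central deionized-water control.  Two identical
# two-layer Compton cameras (Si scatterer + CdZnTe absorber) flank the
# phantom symmetrically along +/- x.

#' PhantomSpec: cylinder-with-inserts phantom
#'
#' @slot outerRadius outer cylinder radius, mm.
#' @slot height cylinder height, mm (axis = z, centered at the origin).
#' @slot inserts data.frame with columns `x`, `y` (center, mm), `radius`
#'   (mm), `material` (label) and `concentration` (% w/v; 0 for water).
#' @slot backgroundMaterial material filling the outer cylinder (air).
#' @export
setClass("PhantomSpec",
  representation(outerRadius = "numeric", height = "numeric",
                 inserts = "data.frame", backgroundMaterial = "character"),
  validity = function(object) {
    ins <- object@inserts
    if (!all(c("x", "y", "radius", "material", "concentration") %in%
             names(ins)))
      return("inserts need columns x, y, radius, material, concentration")
    if (any(ins$concentration < 0)) return("concentrations must be >= 0")
    r <- sqrt(ins$x^2 + ins$y^2)
    if (any(r + ins$radius > object@outerRadius + 1e-9))
      return("inserts must lie entirely inside the outer cylinder")
    if (nrow(ins) > 1L) {
      cc <- utils::combn(nrow(ins), 2L)
      d <- sqrt((ins$x[cc[1, ]] - ins$x[cc[2, ]])^2 +
                (ins$y[cc[1, ]] - ins$y[cc[2, ]])^2)
      if (any(d < ins$radius[cc[1, ]] + ins$radius[cc[2, ]] - 1e-9))
        return("inserts overlap")
    }
    TRUE
  })

#' DetectorGeometry: bilateral two-layer Compton camera layout
#'
#' Each side has a Si scatter layer (20 x 20 x 5 mm) whose entry face
#' sits `standoff` mm from the phantom center, and a CdZnTe absorber
#' (50 x 50 x 5 mm) a further `gap` mm behind it.  The two sides are
#' mirror images through the phantom center; detector boxes are
#' axis-aligned with their thickness (5 mm) along x.
#'
#' @slot standoff phantom-center to scatter-layer entry face distance, mm.
#' @slot gap scatter-layer exit face to absorber entry face distance, mm.
#' @slot scatterSize transverse width, height, thickness of the scatter
#'   layer, mm.
#' @slot absorberSize likewise for the absorber, mm.
#' @export
setClass("DetectorGeometry",
  representation(standoff = "numeric", gap = "numeric",
                 scatterSize = "numeric", absorberSize = "numeric"),
  validity = function(object) {
    if (object@standoff <= 0 || object@gap < 0)
      return("standoff must be > 0 and gap >= 0")
    if (length(object@scatterSize) != 3L || length(object@absorberSize) != 3L)
      return("layer sizes must have length 3")
    TRUE
  })

#' Build the default six-insert Au phantom
#'
#' Default layout: six Au inserts at 60 degree spacing on a 15 mm-radius
#' circle with concentrations 0.2, 0.4, ..., 1.2 % w/v, plus the central
#' water control; air background.
#'
#' @param outerRadius outer cylinder radius, mm.
#' @param height cylinder height, mm.
#' @param inserts optional replacement insert table (see
#'   [PhantomSpec-class]).
#' @param insertCircleRadius radius of the circle the default inserts sit
#'   on, mm.
#' @param insertRadius radius of each default insert, mm.
#' @param concentrations Au concentrations of the six default inserts,
#'   % w/v.
#' @return a validated [PhantomSpec-class].
#' @examples
#' ph <- buildPhantom()
#' materialAt(ph, cbind(0, 0, 0))    # water control
#' materialAt(ph, cbind(24, 0, 0))   # air between inserts
#' @export
buildPhantom <- function(outerRadius = 25, height = 5, inserts = NULL,
                         insertCircleRadius = 15, insertRadius = 2.5,
                         concentrations = seq(0.2, 1.2, by = 0.2)) {
  if (is.null(inserts)) {
    ang <- (seq_along(concentrations) - 1L) * 2 * pi / length(concentrations)
    inserts <- data.frame(
      x = c(insertCircleRadius * cos(ang), 0),
      y = c(insertCircleRadius * sin(ang), 0),
      radius = insertRadius,
      material = c(rep("au_solution", length(concentrations)), "water"),
      concentration = c(concentrations, 0),
      stringsAsFactors = FALSE)
  }
  new("PhantomSpec", outerRadius = outerRadius, height = height,
      inserts = inserts, backgroundMaterial = "air")
}

#' Build the bilateral detector geometry
#'
#' @param standoff phantom-to-scatter-layer distance, mm (default 60).
#' @param gap scatter-to-absorber gap, mm (default 20).
#' @param scatterSize,absorberSize layer dimensions
#'   (width, height, thickness), mm.
#' @return a [DetectorGeometry-class].
#' @export
detectorGeometry <- function(standoff = 60, gap = 20,
                             scatterSize = c(20, 20, 5),
                             absorberSize = c(50, 50, 5)) {
  new("DetectorGeometry", standoff = standoff, gap = gap,
      scatterSize = scatterSize, absorberSize = absorberSize)
}

#' Axis-aligned detector boxes for one side
#'
#' @param geometry a [DetectorGeometry-class].
#' @param side `"A"` (+x) or `"B"` (-x).
#' @return list with elements `scatter` and `absorber`, each a 2 x 3
#'   matrix `rbind(lo, hi)` in mm.
#' @export
detectorBoxes <- function(geometry, side = c("A", "B")) {
  side <- match.arg(side)
  sgn <- if (side == "A") 1 else -1
  box <- function(x0, size) {
    w <- size[1] / 2; h <- size[2] / 2; t <- size[3]
    lo <- c(min(sgn * x0, sgn * (x0 + t)), -w, -h)
    hi <- c(max(sgn * x0, sgn * (x0 + t)),  w,  h)
    rbind(lo = lo, hi = hi)
  }
  s <- geometry@standoff
  list(scatter = box(s, geometry@scatterSize),
       absorber = box(s + geometry@scatterSize[3] + geometry@gap,
                      geometry@absorberSize))
}

#' Test points against an axis-aligned box
#' @param pts n x 3 matrix, mm.
#' @param box 2 x 3 matrix `rbind(lo, hi)`.
#' @return logical vector.
#' @export
pointInBox <- function(pts, box) {
  pts <- rbind(pts)
  pts[, 1] >= box[1, 1] & pts[, 1] <= box[2, 1] &
  pts[, 2] >= box[1, 2] & pts[, 2] <= box[2, 2] &
  pts[, 3] >= box[1, 3] & pts[, 3] <= box[2, 3]
}

#' Material lookup at 3D points
#'
#' @param phantom a [PhantomSpec-class].
#' @param pts n x 3 matrix of positions, mm.
#' @return character vector: insert material, the background material
#'   inside the outer cylinder, or `"exterior"` outside it.
#' @export
materialAt <- function(phantom, pts) {
  pts <- rbind(pts)
  out <- rep("exterior", nrow(pts))
  inZ <- abs(pts[, 3]) <= phantom@height / 2
  inCyl <- inZ & (pts[, 1]^2 + pts[, 2]^2 <= phantom@outerRadius^2)
  out[inCyl] <- phantom@backgroundMaterial
  ins <- phantom@inserts
  for (k in seq_len(nrow(ins))) {
    hit <- inCyl & ((pts[, 1] - ins$x[k])^2 + (pts[, 2] - ins$y[k])^2 <=
                    ins$radius[k]^2)
    out[hit] <- ins$material[k]
  }
  out
}

#' Default linear attenuation coefficients at the Au K-alpha1 line
#'
#' Scalar per-material linear attenuation coefficients (1/mm) at the
#' working fluorescence energy (~68.8 keV): air is negligible, water
#' ~0.019/mm, silicon's Compton (scattering) component ~0.04/mm, CdZnTe
#' (photoabsorption-dominated) ~2.5/mm.  `au_per_percent` is the extra
#' attenuation per % w/v of Au in solution.  These are order-of-magnitude
#' working constants, fully user-replaceable; no energy dependence is
#' modelled.
#'
#' @return named numeric vector of mu values, 1/mm.
#' @export
defaultMuTable <- function() {
  c(air = 0, exterior = 0, water = 0.019, au_solution = 0.019,
    au_per_percent = 0.002, si = 0.04, cdznte = 2.5)
}

#' Linear attenuation coefficient at 3D points
#'
#' Inserts of material `"au_solution"` get
#' `mu = mu_water-base + concentration * au_per_percent`.
#'
#' @inheritParams materialAt
#' @param muTable named mu lookup, 1/mm (see [defaultMuTable()]).
#' @return numeric vector of mu values, 1/mm.
#' @export
muAt <- function(phantom, pts, muTable = defaultMuTable()) {
  pts <- rbind(pts)
  mat <- materialAt(phantom, pts)
  unknown <- setdiff(unique(mat), names(muTable))
  if (length(unknown))
    stop("no mu entry for material(s): ", paste(unknown, collapse = ", "))
  mu <- unname(muTable[mat])
  ins <- phantom@inserts
  au <- which(ins$material == "au_solution")
  for (k in au) {
    hit <- mat == "au_solution" &
      (pts[, 1] - ins$x[k])^2 + (pts[, 2] - ins$y[k])^2 <= ins$radius[k]^2 &
      abs(pts[, 3]) <= phantom@height / 2
    mu[hit] <- muTable[["au_solution"]] +
      ins$concentration[k] * muTable[["au_per_percent"]]
  }
  mu
}

#' Rasterize the phantom's mu values onto a grid
#'
#' Evaluates [muAt()] at every voxel center.
#'
#' @param phantom a [PhantomSpec-class].
#' @param grid a [VoxelGrid-class].
#' @param muTable named mu lookup, 1/mm.
#' @return a [ReconVolume-class] of attenuation coefficients.
#' @export
muMap <- function(phantom, grid, muTable = defaultMuTable()) {
  ctr <- voxelCenters(grid)
  mu <- muAt(phantom, ctr, muTable)
  reconVolume(grid, array(mu, dim = as.integer(grid@dims)))
}
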