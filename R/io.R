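# Artifact I/O: volumes as flat binary + text header or per-slice text,
# meshes as ASCII PLY/OBJ, optional PNG slice renders.

#' Write a volume as flat binary with a text header
#'
#' Produces `<pathBase>.raw` (doubles, x fastest) and `<pathBase>.hdr`
#' (text: dims, spacing, origin).
#'
#' @param vol a [ReconVolume-class].
#' @param pathBase output path without extension.
#' @return invisibly, the header path.
#' @export
writeVolume <- function(vol, pathBase) {
  g <- voxelGrid(vol)
  con <- file(paste0(pathBase, ".raw"), "wb")
  writeBin(as.numeric(intensities(vol)), con, size = 8)
  close(con)
  writeLines(c(paste("dims", paste(g@dims, collapse = " ")),
               paste("spacing", paste(g@spacing, collapse = " ")),
               paste("origin", paste(g@origin, collapse = " "))),
             paste0(pathBase, ".hdr"))
  invisible(paste0(pathBase, ".hdr"))
}

#' Read a volume written by [writeVolume()]
#'
#' @param pathBase path without extension.
#' @return a [ReconVolume-class].
#' @export
readVolume <- function(pathBase) {
  hdr <- readLines(paste0(pathBase, ".hdr"))
  gv <- function(key) {
    ln <- grep(paste0("^", key, " "), hdr, value = TRUE)
    as.numeric(strsplit(ln, " ")[[1]][-1])
  }
  dims <- as.integer(gv("dims"))
  grid <- new("VoxelGrid", origin = gv("origin"), spacing = gv("spacing"),
              dims = dims)
  con <- file(paste0(pathBase, ".raw"), "rb")
  x <- readBin(con, "numeric", n = prod(dims), size = 8)
  close(con)
  reconVolume(grid, array(x, dim = dims))
}

#' Write a volume as per-slice text matrices
#'
#' One `# slice z=<index>` block per z index, rows = x, columns = y.
#'
#' @param vol a [ReconVolume-class].
#' @param path output text file.
#' @return invisibly, the path.
#' @export
writeVolumeSlices <- function(vol, path) {
  f <- intensities(vol)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(dim(f)[3])) {
    writeLines(paste0("# slice z=", k), con)
    utils::write.table(format(f[, , k], digits = 9, trim = TRUE), con,
                       row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Export a mesh as ASCII PLY
#'
#' @param mesh an [IsoMesh-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeMeshPLY <- function(mesh, path) {
  nv <- nrow(mesh@vertices); nf <- nrow(mesh@faces)
  hdr <- c("ply", "format ascii 1.0",
           paste("element vertex", nv),
           "property float x", "property float y", "property float z",
           "property float nx", "property float ny", "property float nz",
           paste("element face", nf),
           "property list uchar int vertex_indices", "end_header")
  vl <- apply(cbind(mesh@vertices, mesh@normals), 1, function(r)
    paste(sprintf("%.6f", r), collapse = " "))
  fl <- apply(mesh@faces - 1L, 1, function(r)
    paste(c(3L, r), collapse = " "))
  writeLines(c(hdr, vl, fl), path)
  invisible(path)
}

#' Export a mesh as Wavefront OBJ
#'
#' @inheritParams writeMeshPLY
#' @export
writeMeshOBJ <- function(mesh, path) {
  vl <- apply(mesh@vertices, 1, function(r)
    paste("v", paste(sprintf("%.6f", r), collapse = " ")))
  nl <- apply(mesh@normals, 1, function(r)
    paste("vn", paste(sprintf("%.6f", r), collapse = " ")))
  fl <- apply(mesh@faces, 1, function(r)
    paste("f", paste(sprintf("%d//%d", r, r), collapse = " ")))
  writeLines(c(vl, nl, fl), path)
  invisible(path)
}

#' Render a z-slice to PNG
#'
#' @param vol a [ReconVolume-class].
#' @param path output PNG path.
#' @param z slice index (default: middle).
#' @return invisibly, the path.
#' @export
renderSlicePNG <- function(vol, path, z = NULL) {
  f <- intensities(vol)
  if (is.null(z)) z <- ceiling(dim(f)[3] / 2)
  grDevices::png(path, width = 480, height = 480)
  on.exit(grDevices::dev.off())
  graphics::image(f[, , z], col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, useRaster = TRUE)
  invisible(path)
}

#' Write a flat key-value text report
#'
#' @param x named vector or flat list.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeKeyValue <- function(x, path) {
  writeLines(paste(names(x), vapply(x, function(v)
    paste(format(v, digits = 10), collapse = " "), character(1)),
    sep = " = "), path)
  invisible(path)
}
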