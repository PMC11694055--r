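# Conic surface with decreasing widths: slice construction from a
# red-spot profile and watertight lathe meshing with OBJ/PLY export.

#' Build the conic surface from a red-spot profile
#'
#' One circular slice per threshold with a positive count, its radius
#' encoding the count: \code{radius = rMax * count / counts[1]} in linear
#' mode, or \code{rMax * sqrt(count / counts[1])} in sqrt mode (so the
#' slice area is count-proportional). A terminal zero-radius apex closes
#' the surface at the profile's depth bound. An all-zero profile yields
#' the empty surface.
#'
#' @param object a monotone \linkS4class{RedSpotProfile}.
#' @param radiusMode "linear" (default) or "sqrt".
#' @param rMax model-unit radius of the widest (top) slice.
#' @return a \linkS4class{ConicSurface}.
#' @examples
#' conicSlices(buildConic(table1Profiles()[["benign_10pct"]]))
#' @rdname buildConic
#' @export
setMethod("buildConic", "RedSpotProfile",
  function(object, radiusMode = c("linear", "sqrt"), rMax = 1) {
    radiusMode <- match.arg(radiusMode)
    validObject(object)   # rejects non-monotone profiles
    cnt <- object@counts
    if (cnt[1] == 0L)
      return(new("ConicSurface",
                 slices = data.frame(depth = numeric(), radius = numeric()),
                 radiusMode = radiusMode, rMax = rMax))
    pos <- cnt > 0L
    ratio <- cnt[pos] / cnt[1]
    radius <- if (radiusMode == "linear") rMax * ratio else rMax * sqrt(ratio)
    apex <- as.numeric(depthBound(object))
    slices <- data.frame(depth = c(object@thresholds[pos], apex),
                         radius = c(radius, 0))
    new("ConicSurface", slices = slices, radiusMode = radiusMode, rMax = rMax)
  })

#' Lathe a conic surface into a triangle mesh
#'
#' Revolves the slices into a watertight mesh: each positive-radius slice
#' becomes an \code{nSides}-gon ring at vertical coordinate
#' \code{-depth * zRescale} (depth runs down the negative vertical axis),
#' consecutive rings are stitched with quads split into triangles, the
#' apex is closed with a fan, and the top ring is capped. Vertex count is
#' \code{nSides * nRings + 1}; triangle count
#' \code{2 nSides (nRings - 1) + nSides + (nSides - 2)}.
#'
#' @param surface a \linkS4class{ConicSurface} with at least one slice.
#' @param nSides polygonal resolution of each ring (>= 3).
#' @param zRescale factor applied to depths before negation (e.g. 0.002
#'   maps a 1000-unit depth scale onto the \[0, -2\] display range).
#' @return list with elements \code{vertices} (V x 3 matrix) and
#'   \code{faces} (F x 3 integer matrix, 1-based, consistently wound).
#' @export
meshFromConic <- function(surface, nSides = 64L, zRescale = 1) {
  s <- surface@slices
  if (!nrow(s)) stop("cannot mesh an empty conic surface")
  nSides <- as.integer(nSides)
  if (nSides < 3L) stop("nSides must be >= 3")
  rings <- s[s$radius > 0, , drop = FALSE]
  apexDepth <- max(s$depth)
  ang <- 2 * pi * (seq_len(nSides) - 1L) / nSides
  verts <- do.call(rbind, lapply(seq_len(nrow(rings)), function(i)
    cbind(rings$radius[i] * cos(ang), rings$radius[i] * sin(ang),
          -rings$depth[i] * zRescale)))
  verts <- rbind(verts, c(0, 0, -apexDepth * zRescale))
  apex <- nrow(verts)
  nxt <- c(seq_len(nSides)[-1L], 1L)
  faces <- list()
  # top cap (fan across ring 1, facing up)
  faces[[1]] <- cbind(rep(1L, nSides - 2L), seq(3L, nSides), seq(2L, nSides - 1L))
  # side walls between consecutive rings
  nr <- nrow(rings)
  if (nr > 1L) for (i in seq_len(nr - 1L)) {
    a <- (i - 1L) * nSides
    b <- i * nSides
    faces[[length(faces) + 1L]] <- rbind(
      cbind(a + seq_len(nSides), a + nxt, b + nxt),
      cbind(a + seq_len(nSides), b + nxt, b + seq_len(nSides)))
  }
  # apex fan closing the last ring
  a <- (nr - 1L) * nSides
  faces[[length(faces) + 1L]] <- cbind(a + seq_len(nSides), a + nxt,
                                       rep(apex, nSides))
  faces <- do.call(rbind, faces)
  storage.mode(faces) <- "integer"
  list(vertices = verts, faces = faces)
}

#' Check that a triangle mesh is watertight and consistently wound
#'
#' A closed orientable surface has every undirected edge shared by exactly
#' two triangles, traversed once in each direction.
#'
#' @param mesh list with \code{vertices} and \code{faces}.
#' @return TRUE/FALSE.
#' @export
isWatertight <- function(mesh) {
  f <- mesh$faces
  dirEdges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  keyFwd <- paste(dirEdges[, 1], dirEdges[, 2])
  keyRev <- paste(dirEdges[, 2], dirEdges[, 1])
  und <- paste(pmin(dirEdges[, 1], dirEdges[, 2]),
               pmax(dirEdges[, 1], dirEdges[, 2]))
  all(table(und) == 2L) && !anyDuplicated(keyFwd) &&
    all(keyRev %in% keyFwd)
}

#' Write a mesh as ASCII OBJ
#'
#' @param mesh list with \code{vertices} and \code{faces}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeOBJ <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# conic lesion surface", con)
  writeLines(sprintf("v %.8g %.8g %.8g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' Read an ASCII OBJ mesh
#'
#' Minimal reader for the subset \code{\link{writeOBJ}} emits (v and
#' triangular f records).
#'
#' @param path OBJ path.
#' @return list with \code{vertices} and \code{faces}.
#' @export
readOBJ <- function(path) {
  ln <- readLines(path)
  vs <- ln[startsWith(ln, "v ")]
  fs <- ln[startsWith(ln, "f ")]
  vertices <- do.call(rbind, lapply(strsplit(vs, "\\s+"), function(x)
    as.numeric(x[2:4])))
  faces <- do.call(rbind, lapply(strsplit(fs, "\\s+"), function(x)
    as.integer(sub("/.*", "", x[2:4]))))
  list(vertices = vertices, faces = faces)
}

#' Write a mesh as ASCII PLY
#'
#' @param mesh list with \code{vertices} and \code{faces}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePLY <- function(mesh, path) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nv),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nf),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.8g %.8g %.8g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' Write a depth point cloud as ASCII PLY with vertex colors
#'
#' Red points are written (178, 24, 43), blue (33, 102, 172) and neutral
#' (247, 247, 247) — the end and mid colors of the diverging red-blue
#' scale.
#'
#' @param cloud a \linkS4class{DepthPointCloud}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCloudPLY <- function(cloud, path) {
  pal <- rbind(red = c(178L, 24L, 43L), blue = c(33L, 102L, 172L),
               neutral = c(247L, 247L, 247L))
  rgb <- pal[as.character(cloud@colorClass), , drop = FALSE]
  n <- nrow(cloud@coords)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", n),
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green",
               "property uchar blue", "end_header"), con)
  writeLines(sprintf("%.8g %.8g %.8g %d %d %d", cloud@coords[, 1],
                     cloud@coords[, 2], cloud@coords[, 3],
                     rgb[, 1], rgb[, 2], rgb[, 3]), con)
  invisible(path)
}

#' Write a depth point cloud as CSV
#'
#' @param cloud a \linkS4class{DepthPointCloud}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCloudCSV <- function(cloud, path) {
  utils::write.csv(data.frame(x = cloud@coords[, 1], y = cloud@coords[, 2],
                              z = cloud@coords[, 3],
                              color = as.character(cloud@colorClass)),
                   path, row.names = FALSE)
  invisible(path)
}
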