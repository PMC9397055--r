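#' Export a solid geometry as STL
#'
#' Writes a triangulated surface of every primitive (filament cylinders as
#' prisms with flat end caps cut at the footprint boundary, spheres as
#' UV-spheres) in millimetre units. Overlapping primitive shells are written
#' as-is (the union is not re-meshed), which downstream slicers and viewers
#' accept. Binary STL by default.
#'
#' @param geometry a [solid_geometry].
#' @param path output file path.
#' @param n_segments circumferential facet count.
#' @param ascii write ASCII STL instead of binary.
#' @return `path`, invisibly.
#' @export
write_stl <- function(geometry, path, n_segments = 32L, ascii = FALSE) {
  stopifnot(inherits(geometry, "solid_geometry"))
  tris <- geometry_triangles(geometry, n_segments)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid scaffold", con)
    apply(tris, 1, function(t9) {
      v <- matrix(t9, 3, 3, byrow = TRUE)
      n <- tri_normal(v)
      writeLines(c(
        sprintf("  facet normal %e %e %e", n[1], n[2], n[3]),
        "    outer loop",
        sprintf("      vertex %e %e %e", v[, 1], v[, 2], v[, 3]),
        "    endloop",
        "  endfacet"), con)
    })
    writeLines("endsolid scaffold", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(sprintf("%-80s", "scaffoldflow binary STL (mm)")), con)
    writeBin(as.integer(nrow(tris)), con, size = 4, endian = "little")
    for (r in seq_len(nrow(tris))) {
      v <- matrix(tris[r, ], 3, 3, byrow = TRUE)
      writeBin(as.numeric(c(tri_normal(v), t(v))), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

tri_normal <- function(v) {
  n <- c(
    (v[2, 2] - v[1, 2]) * (v[3, 3] - v[1, 3]) - (v[2, 3] - v[1, 3]) * (v[3, 2] - v[1, 2]),
    (v[2, 3] - v[1, 3]) * (v[3, 1] - v[1, 1]) - (v[2, 1] - v[1, 1]) * (v[3, 3] - v[1, 3]),
    (v[2, 1] - v[1, 1]) * (v[3, 2] - v[1, 2]) - (v[2, 2] - v[1, 2]) * (v[3, 1] - v[1, 1])
  )
  len <- sqrt(sum(n^2))
  if (len > 0) n / len else c(0, 0, 1)
}

geometry_triangles <- function(geometry, n_segments) {
  out <- list()
  fp <- geometry$footprint
  theta <- 2 * pi * seq_len(n_segments) / n_segments
  for (p in seq_len(nrow(geometry$primitives))) {
    pr <- geometry$primitives[p, ]
    if (pr$type == "sphere") {
      out[[length(out) + 1L]] <- sphere_triangles(pr, n_segments)
      next
    }
    axis <- if (pr$type == "cyl_x") "x" else "y"
    cross_at <- if (axis == "x") pr$y else pr$x
    len <- footprint_chords(fp, axis, cross_at)
    if (len <= 0) next
    mid <- if (axis == "x") mean(fp$xlim) else mean(fp$ylim)
    a0 <- mid - len / 2; a1 <- mid + len / 2
    cr <- cross_at + pr$r * cos(theta)
    zz <- pmin(pmax(pr$z + pr$r * sin(theta), fp$zlim[1]), fp$zlim[2])
    ring <- function(a) if (axis == "x") cbind(a, cr, zz) else cbind(cr, a, zz)
    r0 <- ring(a0); r1 <- ring(a1)
    nxt <- c(seq_len(n_segments)[-1], 1L)
    quads <- cbind(r0, r1, r1[nxt, , drop = FALSE], r0[nxt, , drop = FALSE])
    tris <- rbind(quads[, c(1:3, 4:6, 7:9)], quads[, c(1:3, 7:9, 10:12)])
    ctr0 <- if (axis == "x") c(a0, cross_at, pr$z) else c(cross_at, a0, pr$z)
    ctr1 <- if (axis == "x") c(a1, cross_at, pr$z) else c(cross_at, a1, pr$z)
    cap0 <- cbind(matrix(ctr0, n_segments, 3, byrow = TRUE), r0[nxt, ], r0)
    cap1 <- cbind(matrix(ctr1, n_segments, 3, byrow = TRUE), r1, r1[nxt, ])
    out[[length(out) + 1L]] <- rbind(tris, cap0, cap1)
  }
  if (!length(out)) matrix(numeric(), 0, 9) else do.call(rbind, out)
}

sphere_triangles <- function(pr, n_segments) {
  n_phi <- max(4L, n_segments %/% 2L)
  phi <- seq(0, pi, length.out = n_phi + 1L)
  theta <- 2 * pi * (0:n_segments) / n_segments
  pt <- function(ph, th) c(pr$x + pr$r * sin(ph) * cos(th),
                           pr$y + pr$r * sin(ph) * sin(th),
                           pr$z + pr$r * cos(ph))
  tris <- list()
  for (i in seq_len(n_phi)) {
    for (j in seq_len(n_segments)) {
      v00 <- pt(phi[i], theta[j]); v01 <- pt(phi[i], theta[j + 1])
      v10 <- pt(phi[i + 1], theta[j]); v11 <- pt(phi[i + 1], theta[j + 1])
      if (i > 1L) tris[[length(tris) + 1L]] <- c(v00, v01, v10)
      if (i < n_phi) tris[[length(tris) + 1L]] <- c(v01, v11, v10)
    }
  }
  do.call(rbind, tris)
}

#' Export a voxel domain (and optional flow fields) as legacy VTK image data
#'
#' Writes an ASCII legacy VTK structured-points file with the occupancy
#' codes and, when a `flow_solution` is supplied, the velocity vector and
#' pressure fields (solid cells carry zeros). Readable by ParaView/VTK.
#'
#' @param domain a [voxel_domain].
#' @param path output `.vtk` file path.
#' @param solution optional `flow_solution` on the same domain.
#' @return `path`, invisibly.
#' @export
write_vtk_image <- function(domain, path, solution = NULL) {
  d <- dim(domain$occ)
  con <- file(path, "w")
  on.exit(close(con))
  h <- domain$spacing
  writeLines(c("# vtk DataFile Version 3.0",
               "scaffoldflow voxel domain", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %g %g %g", h / 2, h / 2, h / 2),
               sprintf("SPACING %g %g %g", h, h, h),
               sprintf("POINT_DATA %d", prod(d)),
               "SCALARS occupancy int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(paste(as.integer(domain$occ), collapse = " "), con)
  if (!is.null(solution)) {
    z <- function(a) { a[is.na(a)] <- 0; a }
    writeLines("SCALARS pressure double 1", con)
    writeLines("LOOKUP_TABLE default", con)
    writeLines(paste(format(z(solution$p), digits = 8), collapse = " "), con)
    writeLines("VECTORS velocity double", con)
    vel <- rbind(as.numeric(z(solution$ux)), as.numeric(z(solution$uy)),
                 as.numeric(z(solution$uz)))
    writeLines(paste(format(vel, digits = 8), collapse = " "), con)
  }
  invisible(path)
}

#' Export a wall stress field as VTK polydata
#'
#' Writes the wall surface elements as a VTK point cloud with the WSS
#' magnitude, element area and outward normal attached, for rendering the
#' WSS distribution over the scaffold surface.
#'
#' @param wss a `wall_stress_field`.
#' @param path output `.vtk` file path.
#' @return `path`, invisibly.
#' @export
write_vtk_surface <- function(wss, path) {
  stopifnot(inherits(wss, "wall_stress_field"))
  n <- nrow(wss)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "scaffoldflow wall shear stress", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", n)), con)
  writeLines(apply(cbind(wss$x, wss$y, wss$z), 1, paste, collapse = " "), con)
  writeLines(sprintf("VERTICES %d %d", n, 2L * n), con)
  writeLines(sprintf("1 %d", seq_len(n) - 1L), con)
  writeLines(c(sprintf("POINT_DATA %d", n),
               "SCALARS wss_Pa double 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(format(wss$tau, digits = 8), collapse = " "), con)
  writeLines(c("SCALARS area_mm2 double 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(format(wss$area, digits = 8), collapse = " "), con)
  writeLines("NORMALS normal double", con)
  writeLines(apply(cbind(wss$nx, wss$ny, wss$nz), 1,
                   function(v) paste(format(v, digits = 6), collapse = " ")), con)
  invisible(path)
}

#' Export a wall stress field as CSV
#'
#' One row per wall element: position (mm), outward normal, area (mm^2) and
#' WSS (Pa).
#'
#' @param wss a `wall_stress_field`.
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_wss_csv <- function(wss, path) {
  utils::write.csv(as.data.frame(wss), path, row.names = FALSE)
  invisible(path)
}
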