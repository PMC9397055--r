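#' Geometric characteristics of a scaffold solid
#'
#' Computes the material volume, fluid-solid interface area, porosity (void
#' fraction) and specific surface area of a [solid_geometry] with respect to
#' a bounding envelope:
#' \deqn{\phi = 1 - V_{material} / V_{domain}, \qquad S = SA / V_{domain}.}
#'
#' Two evaluation paths are available. For pure 0/90 filament lattices
#' (all primitives axis-aligned cylinders, at most one active layer per
#' orientation at any height) the material volume is computed by exact
#' per-height inclusion-exclusion over the two orthogonal filament families,
#' integrated along z by midpoint quadrature; this is the default and is
#' accurate to the quadrature step. Other geometries (or `method = "voxel"`)
#' use centre-point voxel integration at the requested `spacing`. Interface
#' area is always evaluated by quadrature over the primitive surfaces,
#' discarding sample points buried inside other primitives or outside the
#' footprint; filament end cuts flush with the lateral envelope boundary are
#' not counted as fluid-facing surface, while faces created by trimming the
#' stack at the top/bottom envelope planes are.
#'
#' @param geometry a [solid_geometry].
#' @param envelope bounding envelope (a footprint descriptor); defaults to
#'   the geometry's own footprint. The geometry must fit inside it.
#' @param method `"auto"` (analytic when applicable, else voxel),
#'   `"analytic"` or `"voxel"`.
#' @param spacing voxel edge (mm) for the voxel path; default
#'   `fibre_diameter / 24` or `r / 20` for spheres.
#' @param compute_sa logical; set `FALSE` to skip the (more expensive)
#'   surface-area quadrature.
#' @param nz number of z quadrature intervals for the analytic path.
#' @param sa_n_theta,sa_ds angular and axial surface-quadrature resolution.
#' @return An object of class `geometry_metrics`: a list with `V_domain`,
#'   `V_material`, `SA` (mm^2), `porosity` (fraction in `[0, 1]`) and
#'   `specific_surface` (mm^-1).
#' @examples
#' m <- compute_geometry_metrics(build_rectangular_scaffold(reference_scaffold("1A")),
#'                               compute_sa = FALSE)
#' m$porosity
#' @export
compute_geometry_metrics <- function(geometry, envelope = NULL,
                                     method = c("auto", "analytic", "voxel"),
                                     spacing = NULL, compute_sa = TRUE,
                                     nz = 8000L, sa_n_theta = 48L, sa_ds = 0.05) {
  method <- match.arg(method)
  stopifnot(inherits(geometry, "solid_geometry"))
  check_watertight(geometry)
  if (is.null(envelope)) envelope <- geometry$footprint
  check_fits_envelope(geometry, envelope)
  V_domain <- envelope$volume

  prim <- geometry$primitives
  if (nrow(prim) == 0L) {
    return(new_geometry_metrics(V_domain, 0, 0))
  }

  lattice_ok <- is_filament_lattice(geometry)
  if (method == "analytic" && !lattice_ok) {
    stop("analytic metrics require a pure 0/90 filament lattice; use method = \"voxel\"",
         call. = FALSE)
  }
  use_analytic <- method == "analytic" || (method == "auto" && lattice_ok)

  V_material <- if (use_analytic) {
    analytic_material_volume(geometry, nz = nz)
  } else {
    if (is.null(spacing)) spacing <- min(prim$r) / 10
    voxel_material_volume(geometry, spacing)
  }

  SA <- if (compute_sa) {
    surface_area_quadrature(geometry, n_theta = sa_n_theta, ds = sa_ds)
  } else NA_real_

  new_geometry_metrics(V_domain, V_material, SA)
}

new_geometry_metrics <- function(V_domain, V_material, SA) {
  structure(
    list(V_domain = V_domain, V_material = V_material, SA = SA,
         porosity = 1 - V_material / V_domain,
         specific_surface = SA / V_domain),
    class = "geometry_metrics"
  )
}

#' @export
print.geometry_metrics <- function(x, ...) {
  cat("<geometry_metrics>\n")
  cat(sprintf("  V_domain        : %.4g mm^3\n", x$V_domain))
  cat(sprintf("  V_material      : %.4g mm^3\n", x$V_material))
  cat(sprintf("  porosity        : %.2f %%\n", 100 * x$porosity))
  if (is.finite(x$SA)) {
    cat(sprintf("  interface area  : %.4g mm^2\n", x$SA))
    cat(sprintf("  specific surface: %.4g mm^-1\n", x$specific_surface))
  }
  invisible(x)
}

check_watertight <- function(geometry) {
  prim <- geometry$primitives
  if (nrow(prim) == 0L) return(invisible(TRUE))
  bad <- which(!is.finite(prim$r) | prim$r <= 0 |
                 !is.finite(prim$x) | !is.finite(prim$y) | !is.finite(prim$z))
  if (length(bad)) {
    stop(sprintf("non-watertight solid: primitive %d has a non-positive radius or non-finite centre",
                 bad[1]), call. = FALSE)
  }
  invisible(TRUE)
}

check_fits_envelope <- function(geometry, envelope, tol = 1e-9) {
  fp <- geometry$footprint
  ok <- fp$xlim[1] >= envelope$xlim[1] - tol && fp$xlim[2] <= envelope$xlim[2] + tol &&
    fp$ylim[1] >= envelope$ylim[1] - tol && fp$ylim[2] <= envelope$ylim[2] + tol &&
    fp$zlim[1] >= envelope$zlim[1] - tol && fp$zlim[2] <= envelope$zlim[2] + tol
  if (!ok) stop("geometry does not fit inside the envelope", call. = FALSE)
  invisible(TRUE)
}

# A geometry qualifies for the analytic per-height path when every primitive
# is an axis filament, all radii are equal, and layers of the same
# orientation never overlap in z (at most one active layer per family at any
# height).
is_filament_lattice <- function(geometry) {
  prim <- geometry$primitives
  if (nrow(prim) == 0L) return(FALSE)
  if (!all(prim$type %in% c("cyl_x", "cyl_y"))) return(FALSE)
  if (length(unique(prim$r)) != 1L) return(FALSE)
  d <- 2 * prim$r[1]
  for (ty in c("cyl_x", "cyl_y")) {
    zc <- sort(unique(prim$z[prim$type == ty]))
    if (length(zc) > 1L && min(diff(zc)) < d - 1e-12) return(FALSE)
  }
  TRUE
}

# chord length of the footprint along `axis` at cross-position `at`
footprint_chords <- function(fp, axis, at) {
  if (fp$kind == "box") {
    full <- if (axis == "x") diff(fp$xlim) else diff(fp$ylim)
    rep(full, length(at))
  } else {
    ce <- if (axis == "x") fp$centre[2] else fp$centre[1]
    se <- if (axis == "x") fp$semi[2] else fp$semi[1]
    along <- if (axis == "x") fp$semi[1] else fp$semi[2]
    u <- 1 - ((at - ce) / se)^2
    2 * along * sqrt(pmax(u, 0))
  }
}

# Exact material volume of a 0/90 filament lattice by per-height
# inclusion-exclusion: at height z, the solid cross-section is the union of
# one strip family per orientation; area = sum of strip areas minus the area
# of their (rectangular) crossings that lie inside the footprint.
analytic_material_volume <- function(geometry, nz = 8000L) {
  prim <- geometry$primitives
  fp <- geometry$footprint
  r <- prim$r[1]
  zlim <- fp$zlim
  dz <- diff(zlim) / nz
  zm <- zlim[1] + dz * (seq_len(nz) - 0.5)

  fam <- function(ty) {
    p <- prim[prim$type == ty, ]
    if (nrow(p) == 0L) {
      return(list(pos = numeric(), len = numeric(), zc = numeric(),
                  W = matrix(0, nz, 0)))
    }
    cross <- if (ty == "cyl_x") p$y else p$x
    pos <- sort(unique(cross))
    zc <- sort(unique(p$z))
    len <- footprint_chords(fp, if (ty == "cyl_x") "x" else "y", pos)
    clim <- if (ty == "cyl_x") fp$ylim else fp$xlim
    W <- matrix(0, nz, length(pos))
    for (z0 in zc) {
      k <- which(abs(zm - z0) < r)
      if (!length(k)) next
      half <- sqrt(r^2 - (zm[k] - z0)^2)
      lo <- outer(-half, pos, `+`)   # pos - half
      hi <- outer(half, pos, `+`)
      W[k, ] <- W[k, ] + pmax(pmin(hi, clim[2]) - pmax(lo, clim[1]), 0)
    }
    list(pos = pos, len = len, zc = zc, W = W)
  }
  fx <- fam("cyl_x")  # strips across y
  fy <- fam("cyl_y")  # strips across x

  A <- as.numeric(fx$W %*% fx$len) + as.numeric(fy$W %*% fy$len)
  if (length(fx$pos) && length(fy$pos)) {
    # crossing (x_j, y_i) of an x-filament at y_i with a y-filament at x_j
    crossings <- cbind(rep(fy$pos, each = length(fx$pos)),
                       rep(fx$pos, times = length(fy$pos)),
                       0)
    M <- matrix(as.numeric(points_in_footprint(crossings, fp, include_z = FALSE)),
                nrow = length(fx$pos))
    A <- A - rowSums((fx$W %*% M) * fy$W)
  }
  sum(A) * dz
}

# Voxelize the material of a solid into a logical occupancy array over the
# footprint bounding box (centre-point inclusion test). Returns the array
# plus grid metadata. Shared by the voxel metrics path and voxelize().
voxelize_solid <- function(geometry, spacing, clip_footprint = TRUE) {
  fp <- geometry$footprint
  nx <- max(1L, round(diff(fp$xlim) / spacing))
  ny <- max(1L, round(diff(fp$ylim) / spacing))
  nzv <- max(1L, round(diff(fp$zlim) / spacing))
  xc <- fp$xlim[1] + spacing * (seq_len(nx) - 0.5)
  yc <- fp$ylim[1] + spacing * (seq_len(ny) - 0.5)
  zc <- fp$zlim[1] + spacing * (seq_len(nzv) - 0.5)
  occ <- array(FALSE, dim = c(nx, ny, nzv))

  fp_mask <- if (clip_footprint && fp$kind == "ellipse") {
    rho2 <- outer(((xc - fp$centre[1]) / fp$semi[1])^2,
                  ((yc - fp$centre[2]) / fp$semi[2])^2, `+`)
    rho2 <= 1
  } else matrix(TRUE, nx, ny)

  prim <- geometry$primitives
  for (p in seq_len(nrow(prim))) {
    pr <- prim[p, ]
    if (pr$type == "cyl_x") {
      j <- which(abs(yc - pr$y) <= pr$r)
      k <- which(abs(zc - pr$z) <= pr$r)
      if (!length(j) || !length(k)) next
      disc <- outer((yc[j] - pr$y)^2, (zc[k] - pr$z)^2, `+`) <= pr$r^2
      for (kk in seq_along(k)) {
        jj <- j[disc[, kk]]
        if (length(jj)) occ[, jj, k[kk]] <- occ[, jj, k[kk]] | fp_mask[, jj]
      }
    } else if (pr$type == "cyl_y") {
      i <- which(abs(xc - pr$x) <= pr$r)
      k <- which(abs(zc - pr$z) <= pr$r)
      if (!length(i) || !length(k)) next
      disc <- outer((xc[i] - pr$x)^2, (zc[k] - pr$z)^2, `+`) <= pr$r^2
      for (kk in seq_along(k)) {
        ii <- i[disc[, kk]]
        if (length(ii)) occ[ii, , k[kk]] <- occ[ii, , k[kk]] | fp_mask[ii, ]
      }
    } else if (pr$type == "sphere") {
      i <- which(abs(xc - pr$x) <= pr$r)
      j <- which(abs(yc - pr$y) <= pr$r)
      k <- which(abs(zc - pr$z) <= pr$r)
      for (kk in k) {
        rem2 <- pr$r^2 - (zc[kk] - pr$z)^2
        disc <- outer((xc[i] - pr$x)^2, (yc[j] - pr$y)^2, `+`) <= rem2
        sub <- occ[i, j, kk, drop = FALSE]
        dim(sub) <- dim(disc)
        occ[i, j, kk] <- sub | (disc & fp_mask[i, j])
      }
    }
  }
  list(occ = occ, origin = c(fp$xlim[1], fp$ylim[1], fp$zlim[1]),
       spacing = spacing, dims = c(nx, ny, nzv),
       centres = list(x = xc, y = yc, z = zc))
}

voxel_material_volume <- function(geometry, spacing) {
  v <- voxelize_solid(geometry, spacing)
  sum(v$occ) * spacing^3
}

# Quadrature of the exposed (fluid-facing) surface area of the union solid.
surface_area_quadrature <- function(geometry, n_theta = 48L, ds = 0.05) {
  prim <- geometry$primitives
  fp <- geometry$footprint
  total <- 0
  lattice <- is_filament_lattice(geometry)
  for (p in seq_len(nrow(prim))) {
    pr <- prim[p, ]
    if (pr$type == "sphere") {
      total <- total + sphere_exposed_area(pr, p, geometry, n_theta)
    } else {
      total <- total + cylinder_exposed_area(pr, p, geometry, n_theta, ds, lattice)
      total <- total + cylinder_cap_area(pr, geometry, ds)
    }
  }
  total
}

# fraction-weighted area of a sphere surface outside all other primitives
sphere_exposed_area <- function(pr, p, geometry, n_theta) {
  n_phi <- max(8L, n_theta %/% 2L)
  phi_edges <- seq(0, pi, length.out = n_phi + 1L)
  phi <- (phi_edges[-1] + phi_edges[-(n_phi + 1L)]) / 2
  band_area <- pr$r^2 * diff(-cos(phi_edges)) * (2 * pi / n_theta)
  theta <- 2 * pi * (seq_len(n_theta) - 0.5) / n_theta
  pts <- cbind(
    pr$x + pr$r * as.vector(outer(sin(phi), cos(theta))),
    pr$y + pr$r * as.vector(outer(sin(phi), sin(theta))),
    pr$z + pr$r * as.vector(outer(cos(phi), rep(1, n_theta)))
  )
  w <- rep(band_area, times = n_theta)
  keep <- points_in_footprint(pts, geometry$footprint) &
    !points_in_material(pts, geometry$primitives, exclude = p)
  sum(w[keep])
}

cylinder_exposed_area <- function(pr, p, geometry, n_theta, ds, lattice) {
  fp <- geometry$footprint
  axis <- if (pr$type == "cyl_x") "x" else "y"
  cross_at <- if (axis == "x") pr$y else pr$x
  len <- footprint_chords(fp, axis, cross_at)
  if (len <= 0) return(0)
  n_s <- max(2L, ceiling(len / ds))
  svals <- len * ((seq_len(n_s) - 0.5) / n_s - 0.5)  # centred on footprint chord
  mid <- if (axis == "x") mean(fp$xlim) else mean(fp$ylim)
  theta <- 2 * pi * (seq_len(n_theta) - 0.5) / n_theta
  cr1 <- cross_at + pr$r * cos(theta)     # cross-direction coordinate
  zz <- pr$z + pr$r * sin(theta)
  s_rep <- rep(svals, times = n_theta)
  if (axis == "x") {
    pts <- cbind(mid + s_rep, rep(cr1, each = n_s), rep(zz, each = n_s))
  } else {
    pts <- cbind(rep(cr1, each = n_s), mid + s_rep, rep(zz, each = n_s))
  }
  keep <- points_in_footprint(pts, fp)
  keep[keep] <- if (lattice) {
    !points_in_crossing_filaments(pts[keep, , drop = FALSE], pr, geometry)
  } else {
    !points_in_material(pts[keep, , drop = FALSE], geometry$primitives, exclude = p)
  }
  sum(keep) * (len / n_s) * (2 * pi * pr$r / n_theta)
}

# flat faces created where the fused stack is trimmed by the top/bottom
# envelope planes
cylinder_cap_area <- function(pr, geometry, ds) {
  fp <- geometry$footprint
  area <- 0
  for (zcut in fp$zlim) {
    if (abs(zcut - pr$z) >= pr$r) next
    half <- sqrt(pr$r^2 - (zcut - pr$z)^2)
    axis <- if (pr$type == "cyl_x") "x" else "y"
    cross_at <- if (axis == "x") pr$y else pr$x
    len <- footprint_chords(fp, axis, cross_at)
    if (len <= 0) next
    n_s <- max(2L, ceiling(len / ds))
    n_c <- max(2L, ceiling(2 * half / (ds / 2)))
    svals <- len * ((seq_len(n_s) - 0.5) / n_s - 0.5)
    cvals <- cross_at + 2 * half * ((seq_len(n_c) - 0.5) / n_c - 0.5)
    mid <- if (axis == "x") mean(fp$xlim) else mean(fp$ylim)
    zin <- zcut + sign(pr$z - zcut) * 1e-9
    if (axis == "x") {
      pts <- cbind(rep(mid + svals, times = n_c), rep(cvals, each = n_s), zin)
    } else {
      pts <- cbind(rep(cvals, each = n_s), rep(mid + svals, times = n_c), zin)
    }
    keep <- points_in_footprint(pts, fp)
    keep[keep] <- !points_in_crossing_filaments(pts[keep, , drop = FALSE], pr, geometry)
    area <- area + sum(keep) * (len / n_s) * (2 * half / n_c)
  }
  area
}

# Fast buried-point test for filament lattices: a point on an x-filament can
# only be buried inside a crossing filament of the other orientation in a
# layer whose centre height is within one fibre diameter; the candidate
# crossing filaments are the nearest one or two positions.
points_in_crossing_filaments <- function(pts, pr, geometry) {
  prim <- geometry$primitives
  other <- if (pr$type == "cyl_x") "cyl_y" else "cyl_x"
  po <- prim[prim$type == other, ]
  inside <- rep(FALSE, nrow(pts))
  if (nrow(po) == 0L || nrow(pts) == 0L) return(inside)
  pos <- sort(unique(if (other == "cyl_y") po$x else po$y))
  axis_coord <- if (other == "cyl_y") pts[, 1] else pts[, 2]
  for (z0 in sort(unique(po$z))) {
    if (abs(z0 - pr$z) >= 2 * pr$r) next
    dz2 <- (pts[, 3] - z0)^2
    i0 <- findInterval(axis_coord, pos)
    for (cand in 0:1) {
      idx <- pmin(pmax(i0 + cand, 1L), length(pos))
      inside <- inside | ((axis_coord - pos[idx])^2 + dz2 <= po$r[1]^2)
    }
  }
  inside
}
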