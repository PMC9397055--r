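#' @title Solid scaffold geometries
#' @name solid_geometry
#'
#' @description A `solid_geometry` is the union of simple solid primitives
#' (axis-aligned cylindrical filaments and, for test fixtures, spheres)
#' clipped to a prismatic footprint (a box or an elliptical cylinder).
#' Filament endpoints are cut flush with the footprint boundary: no
#' hemispherical end caps are added.
#'
#' Primitives are stored as one row each with columns `type`
#' (`"cyl_x"`, `"cyl_y"` or `"sphere"`), `x`, `y`, `z` (centre), `r`
#' (radius, mm) and `layer` (filament layer index, `NA` for spheres).
NULL

new_solid_geometry <- function(primitives, footprint, spec = NULL) {
  structure(
    list(primitives = primitives, footprint = footprint, spec = spec),
    class = "solid_geometry"
  )
}

#' @export
print.solid_geometry <- function(x, ...) {
  cat(sprintf("<solid_geometry: %d primitives, %s footprint>\n",
              nrow(x$primitives), x$footprint$kind))
  invisible(x)
}

#' Prismatic footprint of a solid
#'
#' @param dims for `footprint_box`, the full x/y/z extents (mm); for
#'   `footprint_ellipse`, `axes` are the two full in-plane axes and
#'   `height` the z extent.
#' @return a footprint descriptor used by [solid_geometry] objects and as
#'   the bounding envelope in [compute_geometry_metrics()].
#' @keywords internal
footprint_box <- function(dims) {
  list(kind = "box", xlim = c(0, dims[1]), ylim = c(0, dims[2]),
       zlim = c(0, dims[3]), volume = prod(dims))
}

#' @rdname footprint_box
#' @param axes,height ellipse axes and height, mm.
#' @keywords internal
footprint_ellipse <- function(axes, height) {
  a <- axes[1] / 2; b <- axes[2] / 2
  list(kind = "ellipse", centre = c(a, b), semi = c(a, b),
       xlim = c(0, axes[1]), ylim = c(0, axes[2]), zlim = c(0, height),
       volume = pi * a * b * height)
}

# z centres of the filament layers: the fused stack ((n-1)*pitch + d tall)
# is centred inside the footprint height and trimmed flush where it overhangs.
layer_z_centres <- function(spec) {
  h <- spec$dimensions[3]
  stack_h <- (spec$n_layers - 1) * spec$layer_pitch + spec$fibre_diameter
  z0 <- (h - stack_h) / 2 + spec$fibre_diameter / 2
  z0 + spec$layer_pitch * (seq_len(spec$n_layers) - 1)
}

# Filament centre positions across a span W at uniform period, centred.
uniform_filament_positions <- function(W, period) {
  n <- floor(W / period) + 1L
  span <- (n - 1L) * period
  (W - span) / 2 + period * (seq_len(n) - 1L)
}

# Filament centre positions across an elliptical semi-span, graded by ring.
# Rings are concentric similar ellipses with boundaries at equal fractions of
# the semi-axes; a filament's spacing to the next one is set by the ring that
# contains its own centre (marching outwards from a central filament).
graded_filament_positions <- function(semi, spec) {
  nr <- spec$ring_count
  ring_of <- function(rho) pmin(nr, 1L + floor(pmax(rho, 0) * nr))
  d <- spec$fibre_diameter
  pos <- 0
  y <- 0
  repeat {
    s <- d + spec$pore_sizes[ring_of(abs(y) / semi)]
    y <- y + s
    if (y >= semi) break
    pos <- c(pos, y)
  }
  sort(unique(c(-rev(pos), pos)))
}

filament_layers <- function(spec, centre, semi_x, semi_y, positions_x, positions_y) {
  zc <- layer_z_centres(spec)
  r <- spec$fibre_diameter / 2
  rows <- vector("list", spec$n_layers)
  for (i in seq_len(spec$n_layers)) {
    if (i %% 2L == 1L) {
      # odd layers: filaments along x, spread across y
      rows[[i]] <- data.frame(type = "cyl_x", x = centre[1],
                              y = positions_y, z = zc[i], r = r, layer = i)
    } else {
      rows[[i]] <- data.frame(type = "cyl_y", x = positions_x,
                              y = centre[2], z = zc[i], r = r, layer = i)
    }
  }
  do.call(rbind, rows)
}

#' Build a rectangular 0/90 lay-down scaffold solid
#'
#' Constructs the union solid of `n_layers` layers of parallel cylindrical
#' filaments on a rectangular footprint. Filament axes in each layer are
#' rotated 90 degrees from the previous layer; the in-plane centre-to-centre
#' spacing is `pore_size + fibre_diameter` and each layer holds
#' `floor(width / spacing) + 1` filaments, centred on the footprint.
#' Consecutive layers are fused: their vertical centre spacing is
#' `layer_pitch`, giving an interpenetration of
#' `fibre_diameter - layer_pitch`. The solid is trimmed flush to the
#' bounding dimensions.
#'
#' @param spec a [scaffold_spec()] with `kind = "rectangular"`.
#' @return A [solid_geometry] object.
#' @examples
#' geom <- build_rectangular_scaffold(reference_scaffold("1A"))
#' geom
#' @export
build_rectangular_scaffold <- function(spec) {
  validate_scaffold_spec(spec)
  if (spec$kind != "rectangular") {
    stop("invalid scaffold_spec: field `kind` must be \"rectangular\"", call. = FALSE)
  }
  dims <- spec$dimensions
  period <- spec$pore_sizes[1] + spec$fibre_diameter
  prim <- filament_layers(
    spec,
    centre = dims[1:2] / 2,
    semi_x = dims[1] / 2, semi_y = dims[2] / 2,
    positions_x = uniform_filament_positions(dims[1], period),
    positions_y = uniform_filament_positions(dims[2], period)
  )
  new_solid_geometry(prim, footprint_box(dims), spec)
}

#' Build a pore-size-graded ring scaffold solid
#'
#' Constructs the union solid of a 0/90-style filament stack on an elliptical
#' footprint partitioned into `ring_count` concentric annuli (boundaries at
#' equal fractions of the semi-axes). Within annulus `r` the local
#' centre-to-centre filament spacing is `pore_sizes[r] + fibre_diameter`, so
#' the clear pore size grows from the innermost to the outermost ring.
#' Layers alternate orientation and fuse exactly as in
#' [build_rectangular_scaffold()]; filaments are cut flush with the
#' elliptical boundary.
#'
#' @param spec a [scaffold_spec()] with `kind = "graded_ring"`.
#' @return A [solid_geometry] object.
#' @examples
#' geom <- build_graded_ring_scaffold(reference_scaffold("2"))
#' geom
#' @export
build_graded_ring_scaffold <- function(spec) {
  validate_scaffold_spec(spec)
  if (spec$kind != "graded_ring") {
    stop("invalid scaffold_spec: field `kind` must be \"graded_ring\"", call. = FALSE)
  }
  dims <- spec$dimensions
  centre <- dims[1:2] / 2
  pos_x <- centre[1] + graded_filament_positions(dims[1] / 2, spec)
  pos_y <- centre[2] + graded_filament_positions(dims[2] / 2, spec)
  prim <- filament_layers(spec, centre,
                          semi_x = dims[1] / 2, semi_y = dims[2] / 2,
                          positions_x = pos_x, positions_y = pos_y)
  new_solid_geometry(prim, footprint_ellipse(dims[1:2], dims[3]), spec)
}

#' Build a scaffold solid from a specification
#'
#' Dispatches to [build_rectangular_scaffold()] or
#' [build_graded_ring_scaffold()] on `spec$kind`.
#'
#' @param spec a [scaffold_spec()].
#' @return A [solid_geometry].
#' @export
build_scaffold <- function(spec) {
  switch(spec$kind,
         rectangular = build_rectangular_scaffold(spec),
         graded_ring = build_graded_ring_scaffold(spec))
}

#' Sphere test solid
#'
#' A single-sphere solid in a box footprint, used as a closed-form fixture
#' for the geometry metrics.
#'
#' @param centre sphere centre (mm), length 3.
#' @param radius sphere radius (mm).
#' @param box_dims footprint box extents (mm), length 3.
#' @return A [solid_geometry].
#' @export
sphere_solid <- function(centre, radius, box_dims) {
  prim <- data.frame(type = "sphere", x = centre[1], y = centre[2],
                     z = centre[3], r = radius, layer = NA_integer_)
  new_solid_geometry(prim, footprint_box(box_dims), NULL)
}

#' Empty solid
#'
#' A geometry with no material inside a box footprint (porosity 1).
#'
#' @param box_dims footprint box extents (mm), length 3.
#' @return A [solid_geometry].
#' @export
empty_solid <- function(box_dims) {
  prim <- data.frame(type = character(), x = numeric(), y = numeric(),
                     z = numeric(), r = numeric(), layer = integer())
  new_solid_geometry(prim, footprint_box(box_dims), NULL)
}

#' Rigidly translate a solid geometry
#'
#' Shifts all primitives and the footprint by `offset` (mm). Porosity and
#' specific surface with respect to the (co-translated) envelope are
#' invariant under this operation.
#'
#' @param geometry a [solid_geometry].
#' @param offset numeric length-3 displacement, mm.
#' @return A translated [solid_geometry].
#' @export
translate_geometry <- function(geometry, offset) {
  stopifnot(inherits(geometry, "solid_geometry"), length(offset) == 3)
  g <- geometry
  g$primitives$x <- g$primitives$x + offset[1]
  g$primitives$y <- g$primitives$y + offset[2]
  g$primitives$z <- g$primitives$z + offset[3]
  fp <- g$footprint
  fp$xlim <- fp$xlim + offset[1]
  fp$ylim <- fp$ylim + offset[2]
  fp$zlim <- fp$zlim + offset[3]
  if (fp$kind == "ellipse") fp$centre <- fp$centre + offset[1:2]
  g$footprint <- fp
  g
}

# Is each point (matrix n x 3, mm) inside the footprint cross-section?
points_in_footprint <- function(pts, fp, include_z = TRUE) {
  inside <- pts[, 1] >= fp$xlim[1] & pts[, 1] <= fp$xlim[2] &
    pts[, 2] >= fp$ylim[1] & pts[, 2] <= fp$ylim[2]
  if (fp$kind == "ellipse") {
    rho2 <- ((pts[, 1] - fp$centre[1]) / fp$semi[1])^2 +
      ((pts[, 2] - fp$centre[2]) / fp$semi[2])^2
    inside <- inside & rho2 <= 1
  }
  if (include_z) inside <- inside & pts[, 3] >= fp$zlim[1] & pts[, 3] <= fp$zlim[2]
  inside
}

# Is each point inside the material union (ignoring footprint clip)?
# `exclude` drops one primitive row (used for surface-exposure tests).
points_in_material <- function(pts, primitives, exclude = 0L) {
  inside <- rep(FALSE, nrow(pts))
  for (p in seq_len(nrow(primitives))) {
    if (p == exclude) next
    pr <- primitives[p, ]
    idx <- which(!inside)
    if (!length(idx)) break
    hit <- switch(pr$type,
      cyl_x = (pts[idx, 2] - pr$y)^2 + (pts[idx, 3] - pr$z)^2 <= pr$r^2,
      cyl_y = (pts[idx, 1] - pr$x)^2 + (pts[idx, 3] - pr$z)^2 <= pr$r^2,
      sphere = (pts[idx, 1] - pr$x)^2 + (pts[idx, 2] - pr$y)^2 +
        (pts[idx, 3] - pr$z)^2 <= pr$r^2,
      stop("unknown primitive type: ", pr$type)
    )
    inside[idx[hit]] <- TRUE
  }
  inside
}

# Is each point inside the solid (material AND footprint)?
points_in_solid <- function(pts, geometry) {
  points_in_footprint(pts, geometry$footprint) &
    points_in_material(pts, geometry$primitives)
}
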