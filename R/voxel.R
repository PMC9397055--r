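#' Labelled voxel flow domains
#'
#' A `voxel_domain` is an isotropic voxel lattice holding the discretized
#' fluid/solid occupancy of a scaffold plus the open entry/exit channel
#' padding along the flow axis. Occupancy codes are `0` fluid, `1` scaffold
#' solid, `2` enclosure wall (the lateral duct shell, excluded from wall
#' shear statistics) and `3` fluid pockets disconnected from the inlet
#' (flagged and excluded from flow). Flow is always along the third (z)
#' axis, i.e. through the scaffold thickness, perpendicular to the filament
#' layers. The inlet is the low-z face, the outlet the high-z face; lateral
#' faces are labelled `"wall"` (no-slip shell) or `"periodic"`.
#'
#' @name voxel_domain
NULL

new_voxel_domain <- function(occ, spacing, lateral, entry_length, exit_length,
                             scaffold_range, spec = NULL, pore_sizes = NULL,
                             excluded_pockets = 0L, outlet_reachable = TRUE) {
  structure(
    list(
      occ = occ, spacing = spacing, flow_axis = 3L, lateral = lateral,
      entry_length = entry_length, exit_length = exit_length,
      scaffold_range = scaffold_range,
      L = (diff(scaffold_range) + 1L) * spacing,
      spec = spec, pore_sizes = pore_sizes,
      excluded_pockets = excluded_pockets,
      outlet_reachable = outlet_reachable
    ),
    class = "voxel_domain"
  )
}

#' @export
print.voxel_domain <- function(x, ...) {
  d <- dim(x$occ)
  cat(sprintf("<voxel_domain: %d x %d x %d voxels @ %.4g mm, lateral %s>\n",
              d[1], d[2], d[3], x$spacing, x$lateral))
  cat(sprintf("  fluid %d / solid %d / wall %d cells; scaffold k %d..%d (L = %.4g mm)\n",
              sum(x$occ == 0L) + sum(x$occ == 3L), sum(x$occ == 1L), sum(x$occ == 2L),
              x$scaffold_range[1], x$scaffold_range[2], scaffold_length_mm(x)))
  if (x$excluded_pockets > 0L)
    cat(sprintf("  %d disconnected fluid voxels excluded from flow\n", x$excluded_pockets))
  invisible(x)
}

#' Scaffold extent along the flow axis, mm
#'
#' The `L` of the Darcy relation: number of scaffold voxel planes along the
#' flow axis times the voxel spacing.
#'
#' @param domain a [voxel_domain].
#' @return length in mm.
#' @export
scaffold_length_mm <- function(domain) {
  (diff(domain$scaffold_range) + 1L) * domain$spacing
}

#' Voxelize a scaffold solid into a flow domain
#'
#' Discretizes a [solid_geometry] by a centre-point inclusion test on an
#' isotropic voxel grid, pads the domain with open entry and exit channel
#' lengths along the flow axis, and labels lateral boundaries. For box
#' footprints with `lateral = "wall"` a one-voxel no-slip shell is added
#' around the sides; elliptical footprints use the cells outside the
#' footprint as the enclosure wall. Fluid voxels not 6-connected to the
#' inlet face are flagged as disconnected pockets and excluded from flow.
#'
#' The resolution floor is three voxels across the smallest pore and three
#' across the fibre diameter.
#'
#' @param geometry a [solid_geometry].
#' @param spacing voxel edge length, mm.
#' @param entry_length,exit_length open channel length added before/after
#'   the scaffold along the flow axis, mm.
#' @param lateral `"wall"` or `"periodic"` lateral boundary label.
#' @param connectivity_filter flag disconnected pockets (default `TRUE`).
#' @return A [voxel_domain].
#' @examples
#' dom <- voxelize(build_rectangular_scaffold(
#'   scaffold_spec("rectangular", c(2.52, 2.52, 1.26), 4, 0.33, 0.30, 0.31)),
#'   spacing = 0.09)
#' dom
#' @export
voxelize <- function(geometry, spacing, entry_length = 1, exit_length = 1,
                     lateral = c("wall", "periodic"),
                     connectivity_filter = TRUE) {
  lateral <- match.arg(lateral)
  stopifnot(inherits(geometry, "solid_geometry"), spacing > 0)
  spec <- geometry$spec
  if (!is.null(spec)) {
    if (spacing > spec$fibre_diameter / 3 + 1e-12) {
      stop(sprintf(paste0("spacing %g mm too coarse: at least 3 voxels are needed ",
                          "across the fibre diameter (%g mm)"),
                   spacing, spec$fibre_diameter), call. = FALSE)
    }
    if (spacing > min(spec$pore_sizes) / 3 + 1e-12) {
      stop(sprintf(paste0("spacing %g mm too coarse: at least 3 voxels are needed ",
                          "across the smallest pore (%g mm)"),
                   spacing, min(spec$pore_sizes)), call. = FALSE)
    }
  }
  vox <- voxelize_solid(geometry, spacing)
  mat <- vox$occ
  d <- dim(mat)
  fp <- geometry$footprint

  occ_s <- array(0L, dim = d)
  occ_s[mat] <- 1L
  if (fp$kind == "ellipse") {
    rho2 <- outer(((vox$centres$x - fp$centre[1]) / fp$semi[1])^2,
                  ((vox$centres$y - fp$centre[2]) / fp$semi[2])^2, `+`)
    outside <- rho2 > 1
    occ_s[array(outside, dim = d)] <- 2L
  }

  n_entry <- max(0L, round(entry_length / spacing))
  n_exit <- max(0L, round(exit_length / spacing))
  shell <- fp$kind == "box" && lateral == "wall"
  pad <- if (shell) 1L else 0L
  nx <- d[1] + 2L * pad; ny <- d[2] + 2L * pad
  nz <- d[3] + n_entry + n_exit
  occ <- array(0L, dim = c(nx, ny, nz))
  if (shell) {
    occ[c(1L, nx), , ] <- 2L
    occ[, c(1L, ny), ] <- 2L
  }
  if (fp$kind == "ellipse") {
    # enclosure wall continues through the entry/exit channel
    wall2d <- array(outside, dim = d[1:2])
    for (k in seq_len(nz)) occ[, , k][wall2d] <- 2L
  }
  ks <- n_entry + seq_len(d[3])
  occ[pad + seq_len(d[1]), pad + seq_len(d[2]), ks] <-
    pmax(occ[pad + seq_len(d[1]), pad + seq_len(d[2]), ks], occ_s)

  dom <- new_voxel_domain(
    occ, spacing, lateral,
    entry_length = n_entry * spacing, exit_length = n_exit * spacing,
    scaffold_range = c(n_entry + 1L, n_entry + d[3]),
    spec = spec,
    pore_sizes = if (!is.null(spec)) spec$pore_sizes else NULL
  )
  if (connectivity_filter) dom <- filter_connected(dom) else {
    dom$outlet_reachable <- TRUE
  }
  dom
}

#' Exclude fluid pockets disconnected from the inlet
#'
#' Flood-fills the fluid phase 6-connectedly from the inlet face (honouring
#' periodic lateral boundaries) and recodes unreachable fluid voxels as
#' disconnected pockets (code 3), which the solver treats as solid. The
#' operation is idempotent.
#'
#' @param domain a [voxel_domain].
#' @return The filtered [voxel_domain]; `$excluded_pockets` counts the
#'   excluded voxels and `$outlet_reachable` records whether any outlet-face
#'   fluid voxel is connected to the inlet.
#' @export
filter_connected <- function(domain) {
  d <- dim(domain$occ)
  reach <- flood_fill_from_inlet(as.integer(domain$occ), as.integer(d),
                                 domain$lateral == "periodic",
                                 domain$lateral == "periodic")
  reach <- array(reach, dim = d)
  pocket <- domain$occ == 0L & !reach
  domain$occ[pocket] <- 3L
  domain$excluded_pockets <- domain$excluded_pockets + sum(pocket)
  domain$outlet_reachable <- any(reach[, , d[3]])
  domain
}

#' Analytic channel fixtures for solver validation
#'
#' Straight ducts with a closed-form laminar solution, used to validate the
#' flow solver: an infinite parallel-plate channel (`"parallel_plate"`,
#' periodic in x, no-slip plates across y, closed form
#' \eqn{u_{max} = 1.5\,\bar u}, \eqn{\tau_w = 6 \mu \bar u / h},
#' \eqn{k_0 = h^2/12}) and a circular tube (`"circular_tube"`,
#' \eqn{u_{max} = 2\,\bar u}, \eqn{\tau_w = 4\mu\bar u/R},
#' \eqn{k_0 = R^2/8}).
#'
#' @param kind `"parallel_plate"` or `"circular_tube"`.
#' @param gap_or_radius plate gap or tube radius, mm (at least 4 voxels).
#' @param length measurement-section length along the flow axis, mm.
#' @param spacing voxel edge, mm.
#' @param entry_length,exit_length developing-flow margins, mm; default two
#'   gap widths / four radii.
#' @return A [voxel_domain] whose walls are labelled as specimen surface
#'   (code 1), with `pore_sizes` set to the gap / diameter for Reynolds
#'   numbers.
#' @examples
#' make_channel_fixture("parallel_plate", 0.3, 1, 0.015)
#' @export
make_channel_fixture <- function(kind = c("parallel_plate", "circular_tube"),
                                 gap_or_radius, length, spacing,
                                 entry_length = NULL, exit_length = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(length) || length <= 0) {
    stop("degenerate fixture: `length` must be > 0", call. = FALSE)
  }
  if (gap_or_radius < 4 * spacing) {
    stop(sprintf("under-resolved duct: gap/radius %g mm needs spacing <= %g mm (4 voxels)",
                 gap_or_radius, gap_or_radius / 4), call. = FALSE)
  }
  if (is.null(entry_length)) {
    entry_length <- if (kind == "parallel_plate") 2 * gap_or_radius else 4 * gap_or_radius
  }
  if (is.null(exit_length)) exit_length <- entry_length
  n_len <- max(1L, round(length / spacing))
  n_entry <- round(entry_length / spacing)
  n_exit <- round(exit_length / spacing)
  nz <- n_len + n_entry + n_exit

  if (kind == "parallel_plate") {
    n_gap <- round(gap_or_radius / spacing)
    nx <- 3L
    ny <- n_gap + 2L
    occ <- array(0L, dim = c(nx, ny, nz))
    occ[, c(1L, ny), ] <- 1L
    lateral <- "periodic"
    pore <- gap_or_radius
  } else {
    n_r <- gap_or_radius / spacing
    n_d <- round(2 * n_r)
    nx <- ny <- n_d + 2L
    cx <- (nx) / 2 + 0.5  # grid centre in voxel-centre coordinates
    xs <- seq_len(nx)
    disc <- outer((xs - cx)^2, (xs - cx)^2, `+`) <= n_r^2
    occ <- array(1L, dim = c(nx, ny, nz))
    for (k in seq_len(nz)) occ[, , k][disc] <- 0L
    lateral <- "wall"
    pore <- 2 * gap_or_radius
  }
  new_voxel_domain(
    occ, spacing, lateral,
    entry_length = n_entry * spacing, exit_length = n_exit * spacing,
    scaffold_range = c(n_entry + 1L, n_entry + n_len),
    spec = NULL, pore_sizes = pore
  )
}

#' Periodic unit-cell domain of a rectangular scaffold
#'
#' Rectangular 0/90 scaffolds are periodic in-plane with period
#' `pore_size + fibre_diameter`; one period through the full layer stack,
#' with periodic lateral boundaries, reproduces the scaffold interior at a
#' small fraction of the full domain size. The voxel spacing is snapped so
#' that an integer number of voxels covers the period exactly.
#'
#' @param spec a rectangular [scaffold_spec()].
#' @param spacing requested voxel edge, mm (snapped to the period).
#' @param entry_length,exit_length open channel padding, mm.
#' @return A [voxel_domain] with periodic lateral labels.
#' @examples
#' extract_unit_cell(reference_scaffold("1A"), spacing = 0.055)
#' @export
extract_unit_cell <- function(spec, spacing, entry_length = 1, exit_length = 1) {
  validate_scaffold_spec(spec)
  if (spec$kind != "rectangular") {
    stop("unit-cell extraction requires a rectangular (in-plane periodic) scaffold",
         call. = FALSE)
  }
  period <- spec$pore_sizes[1] + spec$fibre_diameter
  n_p <- max(1L, round(period / spacing))
  h <- period / n_p
  cell_spec <- spec
  cell_spec$dimensions <- c(period, period, spec$dimensions[3])
  geom <- new_solid_geometry(
    filament_layers(cell_spec, centre = c(period, period) / 2,
                    semi_x = period / 2, semi_y = period / 2,
                    positions_x = period / 2, positions_y = period / 2),
    footprint_box(cell_spec$dimensions), cell_spec
  )
  dom <- voxelize(geom, h, entry_length = entry_length, exit_length = exit_length,
                  lateral = "periodic")
  dom$unit_cell <- TRUE
  dom
}

#' Voxel-estimated porosity of the scaffold section
#'
#' Fraction of in-footprint voxels in the scaffold extent that are void
#' (disconnected pockets count as void: they are geometry, not flow).
#'
#' @param domain a [voxel_domain].
#' @return porosity fraction in `[0, 1]`.
#' @export
voxel_porosity <- function(domain) {
  ks <- seq(domain$scaffold_range[1], domain$scaffold_range[2])
  occ <- domain$occ[, , ks, drop = FALSE]
  inside <- occ != 2L
  sum(occ == 0L | occ == 3L) / sum(inside)
}
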