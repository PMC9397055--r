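#' Wall shear stress on scaffold surfaces
#'
#' Computes the wall shear stress (WSS) magnitude
#' \eqn{\tau_w = \mu \, |\partial u_t / \partial n|} on every wall surface
#' element of the scaffold, where \eqn{u_t} is the velocity component
#' tangential to the wall and the derivative is taken along the outward
#' normal by one-sided differencing into the fluid.
#'
#' Wall elements are the voxel faces separating scaffold solid from fluid
#' within the scaffold extent (enclosure-wall faces are excluded). Because
#' the voxelized surface is a staircase, each element carries (i) a local
#' outward normal estimated from the occupancy distribution in the
#' surrounding 5x5x5 neighbourhood and (ii) an effective area equal to the
#' voxel face area projected onto that normal; by the divergence theorem the
#' projected areas sum to the smooth fluid-solid interface area. The normal
#' velocity gradient is evaluated by sampling the velocity field along the
#' local normal at one (`order = 1`) or two (`order = 2`, default) points
#' into the fluid by trilinear interpolation.
#'
#' @param solution a `flow_solution` from [solve_steady_flow()] (should be
#'   converged).
#' @param domain the [voxel_domain] it was solved on.
#' @param fluid the [fluid_properties] used.
#' @param order one-sided normal-derivative order: 1 (single sample at one
#'   voxel spacing) or 2 (two samples, default).
#' @return An object of class `wall_stress_field`: a data frame with one
#'   row per wall element (`x`, `y`, `z` face-centre position in mm,
#'   `nx`, `ny`, `nz` outward normal, `area` in mm^2, `tau` in Pa), with
#'   attributes `total_area` (mm^2) and `excluded` (elements dropped for
#'   lack of usable fluid samples).
#' @examples
#' \donttest{
#' dom <- make_channel_fixture("parallel_plate", 0.3, 1, 0.03)
#' sol <- solve_steady_flow(dom, fluid_properties(), solver_config(0.001))
#' wss <- compute_wss(sol, dom, fluid_properties())
#' mean(wss$tau)  # ~ 6 mu U / h = 0.09 Pa
#' }
#' @export
compute_wss <- function(solution, domain, fluid, order = 2L) {
  stopifnot(inherits(solution, "flow_solution"), inherits(domain, "voxel_domain"),
            inherits(fluid, "fluid_properties"))
  occ <- domain$occ
  d <- dim(occ)
  h <- domain$spacing                       # mm
  solid <- occ != 0L
  periodic <- domain$lateral == "periodic"

  shift <- function(a, di, dj, dk, fill) {
    out <- array(fill, dim = d)
    src_i <- seq_len(d[1]) + di; src_j <- seq_len(d[2]) + dj; src_k <- seq_len(d[3]) + dk
    if (periodic) {
      src_i <- (src_i - 1L) %% d[1] + 1L
      src_j <- (src_j - 1L) %% d[2] + 1L
      oi <- seq_len(d[1]); oj <- seq_len(d[2])
    } else {
      oi <- which(src_i >= 1L & src_i <= d[1]); src_i <- src_i[oi]
      oj <- which(src_j >= 1L & src_j <= d[2]); src_j <- src_j[oj]
    }
    ok <- which(src_k >= 1L & src_k <= d[3]); src_k <- src_k[ok]
    out[oi, oj, ok] <- a[src_i, src_j, src_k]
    out
  }

  # scaffold-solid cells with a fluid 6-neighbour, inside the scaffold extent
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  in_extent <- array(FALSE, dim = d)
  in_extent[, , seq(domain$scaffold_range[1], domain$scaffold_range[2])] <- TRUE

  faces <- NULL
  for (q in seq_len(6)) {
    fl <- shift(occ == 0L, dirs[q, 1], dirs[q, 2], dirs[q, 3], fill = FALSE)
    hit <- which(occ == 1L & fl & in_extent, arr.ind = TRUE)
    if (nrow(hit)) {
      faces <- rbind(faces, cbind(hit, q = q))
    }
  }
  if (is.null(faces) || nrow(faces) == 0L) {
    stop("no wall surface elements found in the scaffold extent", call. = FALSE)
  }

  # outward normal per solid surface cell: opposite of the occupancy moment
  # over the 5x5x5 neighbourhood (weights 1/|offset|)
  nx_a <- array(0, dim = d); ny_a <- array(0, dim = d); nz_a <- array(0, dim = d)
  for (di in -2:2) for (dj in -2:2) for (dk in -2:2) {
    if (di == 0 && dj == 0 && dk == 0) next
    w <- 1 / sqrt(di^2 + dj^2 + dk^2)
    s <- shift(solid, di, dj, dk, fill = TRUE)  # outside the grid counts solid
    nx_a <- nx_a + w * di * s
    ny_a <- ny_a + w * dj * s
    nz_a <- nz_a + w * dk * s
  }

  cell_idx <- faces[, 1:3, drop = FALSE]
  lin <- cell_idx[, 1] + d[1] * (cell_idx[, 2] - 1L + d[2] * (cell_idx[, 3] - 1L))
  nvec <- cbind(-nx_a[lin], -ny_a[lin], -nz_a[lin])
  nn <- sqrt(rowSums(nvec^2))
  ehat <- dirs[faces[, "q"], , drop = FALSE]
  degen <- nn < 1e-9
  nvec[degen, ] <- ehat[degen, , drop = FALSE]
  nvec <- nvec / sqrt(rowSums(nvec^2))
  # keep normals on the fluid side of the face
  flipped <- rowSums(nvec * ehat) < 0
  nvec[flipped, ] <- ehat[flipped, , drop = FALSE]

  area <- h^2 * pmax(rowSums(nvec * ehat), 0)

  # face-centre positions in voxel-centre coordinates (units of h)
  pos <- sweep(cell_idx, 2, c(0.5, 0.5, 0.5)) + 0.5 * ehat

  ux <- solution$ux; uy <- solution$uy; uz <- solution$uz
  ux[is.na(ux)] <- 0; uy[is.na(uy)] <- 0; uz[is.na(uz)] <- 0

  interp <- function(p) {
    # trilinear interpolation at voxel-coordinate points p (units of h,
    # voxel i centre at i - 0.5); clamped at the grid boundary
    g <- p - 0.5
    i0 <- floor(g); f <- g - i0
    val <- matrix(0, nrow(p), 3)
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      ii <- i0[, 1] + cx; jj <- i0[, 2] + cy; kk <- i0[, 3] + cz
      if (periodic) {
        ii <- ii %% d[1]; jj <- jj %% d[2]
      } else {
        ii <- pmin(pmax(ii, 0), d[1] - 1); jj <- pmin(pmax(jj, 0), d[2] - 1)
      }
      kk <- pmin(pmax(kk, 0), d[3] - 1)
      w <- (cx * f[, 1] + (1 - cx) * (1 - f[, 1])) *
        (cy * f[, 2] + (1 - cy) * (1 - f[, 2])) *
        (cz * f[, 3] + (1 - cz) * (1 - f[, 3]))
      li <- 1L + ii + d[1] * (jj + d[2] * kk)
      val <- val + w * cbind(ux[li], uy[li], uz[li])
    }
    val
  }

  chi <- array(as.numeric(!solid), dim = d)
  interp_chi <- function(p) {
    g <- p - 0.5
    i0 <- floor(g); f <- g - i0
    val <- numeric(nrow(p))
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      ii <- i0[, 1] + cx; jj <- i0[, 2] + cy; kk <- i0[, 3] + cz
      if (periodic) {
        ii <- ii %% d[1]; jj <- jj %% d[2]
      } else {
        ii <- pmin(pmax(ii, 0), d[1] - 1); jj <- pmin(pmax(jj, 0), d[2] - 1)
      }
      kk <- pmin(pmax(kk, 0), d[3] - 1)
      w <- (cx * f[, 1] + (1 - cx) * (1 - f[, 1])) *
        (cy * f[, 2] + (1 - cy) * (1 - f[, 2])) *
        (cz * f[, 3] + (1 - cz) * (1 - f[, 3]))
      val <- val + w * chi[1L + ii + d[1] * (jj + d[2] * kk)]
    }
    val
  }

  h_m <- h * 1e-3
  if (order >= 2L) {
    # two-point one-sided fit of the tangential velocity along the normal,
    # taken as deep into the near-wall layer as the local pore allows
    # (cleaner samples away from the staircase), capped at 5 spacings
    ladder <- list(c(3, 5), c(2.5, 4), c(2, 3), c(1.5, 2.5), c(1, 2))
    dudn <- matrix(NA_real_, nrow(pos), 3)
    todo <- rep(TRUE, nrow(pos))
    for (ab in ladder) {
      if (!any(todo)) break
      idx <- which(todo)
      p1 <- pos[idx, , drop = FALSE] + ab[1] * nvec[idx, , drop = FALSE]
      p2 <- pos[idx, , drop = FALSE] + ab[2] * nvec[idx, , drop = FALSE]
      clean <- interp_chi(p1) > 0.999 & interp_chi(p2) > 0.999
      use <- idx[clean]
      if (length(use)) {
        u1 <- interp(pos[use, , drop = FALSE] + ab[1] * nvec[use, , drop = FALSE])
        u2 <- interp(pos[use, , drop = FALSE] + ab[2] * nvec[use, , drop = FALSE])
        dudn[use, ] <- (u1 * ab[2]^2 - u2 * ab[1]^2) /
          (ab[1] * ab[2] * (ab[2] - ab[1]) * h_m)
        todo[use] <- FALSE
      }
    }
    if (any(todo)) {
      # tight spots: first-order from the sample one spacing into the fluid
      idx <- which(todo)
      dudn[idx, ] <- interp(pos[idx, , drop = FALSE] + nvec[idx, , drop = FALSE]) / h_m
    }
  } else {
    dudn <- interp(pos + nvec) / h_m
  }
  tang <- dudn - rowSums(dudn * nvec) * nvec
  tau <- fluid$dynamic_viscosity * sqrt(rowSums(tang^2))

  keep <- is.finite(tau)
  excluded <- sum(!keep)
  out <- data.frame(
    x = pos[keep, 1] * h, y = pos[keep, 2] * h, z = pos[keep, 3] * h,
    nx = nvec[keep, 1], ny = nvec[keep, 2], nz = nvec[keep, 3],
    area = area[keep], tau = tau[keep]
  )
  structure(out, class = c("wall_stress_field", "data.frame"),
            total_area = sum(out$area), excluded = excluded)
}

#' WSS-threshold cell-viability indicator
#'
#' The fraction of the scaffold wall surface area experiencing a wall shear
#' stress strictly below a threshold (default 30 mPa, the cut-off above
#' which WSS is regarded as detrimental to cell proliferation and
#' differentiation). The fraction is area-weighted over the wall surface
#' elements; this is a surface-area fraction of a wall quantity.
#'
#' @param wss a `wall_stress_field` from [compute_wss()].
#' @param threshold WSS threshold in Pa (default 0.030 = 30 mPa); must be
#'   > 0.
#' @param histogram_edges bin edges (Pa) for the summary histogram; default
#'   covers 0 to the field maximum with an edge at the threshold.
#' @return An object of class `viability_summary`: list with `threshold`
#'   (Pa), `viable_fraction` (percent of wall area, in `[0, 100]`),
#'   `mean_tau`, `max_tau` (Pa) and `histogram` (data frame `lo`, `hi`,
#'   `pct`).
#' @examples
#' f <- structure(data.frame(area = c(1, 1), tau = c(0.010, 0.050)),
#'                class = c("wall_stress_field", "data.frame"))
#' viability_fraction(f)$viable_fraction  # 50: equal-area split
#' @export
viability_fraction <- function(wss, threshold = 0.030, histogram_edges = NULL) {
  stopifnot(inherits(wss, "wall_stress_field"))
  if (nrow(wss) == 0L) stop("empty wall stress field", call. = FALSE)
  if (is.na(threshold) || threshold <= 0) {
    stop("threshold must be > 0", call. = FALSE)
  }
  total <- sum(wss$area)
  if (total <= 0) stop("total wall area is zero", call. = FALSE)
  viable <- 100 * sum(wss$area[wss$tau < threshold]) / total
  if (is.null(histogram_edges)) {
    top <- max(wss$tau, if (is.finite(threshold)) threshold else 0, 1e-9) *
      (1 + 1e-9)
    histogram_edges <- seq(0, top, length.out = 9L)
    if (is.finite(threshold)) {
      histogram_edges <- sort(unique(c(histogram_edges, threshold)))
    }
  }
  structure(
    list(threshold = threshold,
         viable_fraction = viable,
         mean_tau = sum(wss$tau * wss$area) / total,
         max_tau = max(wss$tau),
         histogram = wss_histogram(wss, histogram_edges)),
    class = "viability_summary"
  )
}

#' @export
print.viability_summary <- function(x, ...) {
  cat(sprintf("<viability_summary: %.1f%% of wall surface area below %g mPa>\n",
              x$viable_fraction, 1000 * x$threshold))
  cat(sprintf("  mean WSS %.3g mPa, max WSS %.3g mPa\n",
              1000 * x$mean_tau, 1000 * x$max_tau))
  invisible(x)
}

#' Area-weighted WSS histogram
#'
#' Percentage of the wall surface area per WSS bin. Bins are half-open
#' `[lo, hi)`; the final bin is closed. Percentages are relative to the
#' total wall area of the field, so edges spanning all values sum to 100.
#'
#' @param wss a `wall_stress_field`.
#' @param bin_edges strictly increasing WSS bin edges, Pa.
#' @return data frame with columns `lo`, `hi` (Pa) and `pct`.
#' @examples
#' f <- structure(data.frame(area = c(1, 1), tau = c(0.010, 0.050)),
#'                class = c("wall_stress_field", "data.frame"))
#' wss_histogram(f, c(0, 0.030, 0.060))
#' @export
wss_histogram <- function(wss, bin_edges) {
  stopifnot(inherits(wss, "wall_stress_field"))
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0)) {
    stop("bin_edges must be strictly increasing", call. = FALSE)
  }
  total <- sum(wss$area)
  nb <- length(bin_edges) - 1L
  pct <- numeric(nb)
  for (b in seq_len(nb)) {
    inb <- wss$tau >= bin_edges[b] &
      (if (b < nb) wss$tau < bin_edges[b + 1] else wss$tau <= bin_edges[b + 1])
    pct[b] <- 100 * sum(wss$area[inb]) / total
  }
  data.frame(lo = bin_edges[-length(bin_edges)], hi = bin_edges[-1], pct = pct)
}
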