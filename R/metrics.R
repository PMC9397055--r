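#' Pressure drop across the scaffold
#'
#' Plane-averaged pressure difference between two virtual probe planes one
#' voxel upstream and one voxel downstream of the scaffold extent, linearly
#' extrapolated by half a voxel onto the scaffold faces using the local
#' axial pressure gradient (plane averaging suppresses voxel noise).
#'
#' @param solution a converged `flow_solution`.
#' @param domain the [voxel_domain] it was solved on.
#' @return pressure drop in Pa.
#' @export
pressure_drop <- function(solution, domain) {
  d <- dim(domain$occ)
  k1 <- domain$scaffold_range[1]; k2 <- domain$scaffold_range[2]
  if (k1 - 1L < 1L || k2 + 1L > d[3]) {
    stop("probe plane outside domain: entry/exit channel required around the scaffold",
         call. = FALSE)
  }
  pm <- function(k) mean(solution$p[, , k][domain$occ[, , k] == 0L])
  p_up <- pm(k1 - 1L)
  if (k1 - 2L >= 1L) p_up <- 1.5 * pm(k1 - 1L) - 0.5 * pm(k1 - 2L)
  p_dn <- pm(k2 + 1L)
  if (k2 + 2L <= d[3]) p_dn <- 1.5 * pm(k2 + 1L) - 0.5 * pm(k2 + 2L)
  p_up - p_dn
}

#' Darcy intrinsic permeability
#'
#' \eqn{k_0 = u \mu L / \Delta P}: the intrinsic permeability of the
#' scaffold from the superficial (inlet) velocity, fluid viscosity,
#' scaffold length along the flow axis and measured pressure drop. Valid in
#' the creeping-flow regime (see [darcy_validity()]).
#'
#' @param u superficial inlet velocity, m/s.
#' @param mu dynamic viscosity, Pa s.
#' @param L scaffold length along the flow axis, m.
#' @param dP pressure drop across the scaffold, Pa; must be > 0.
#' @return permeability in m^2.
#' @examples
#' darcy_permeability(0.001, 0.0045, 0.01, 45)  # 1e-9 m^2
#' @export
darcy_permeability <- function(u, mu, L, dP) {
  if (!is.finite(L) || L <= 0) stop("L must be > 0", call. = FALSE)
  if (!is.finite(dP) || dP <= 0) {
    stop("no resistance measured: pressure drop must be > 0", call. = FALSE)
  }
  u * mu * L / dP
}

#' Interstitial Reynolds number
#'
#' \eqn{Re = \rho u d / \mu} with the pore size \eqn{d} as the length
#' scale: the ratio of inertial to viscous forces inside the pores.
#'
#' @param rho fluid density, kg/m^3.
#' @param u superficial velocity, m/s.
#' @param d pore size, m.
#' @param mu dynamic viscosity, Pa s.
#' @return dimensionless Reynolds number.
#' @examples
#' reynolds_number(1056, 0.001, 0.0003, 0.0045)  # ~0.07
#' @export
reynolds_number <- function(rho, u, d, mu) {
  if (any(!is.finite(c(rho, u, d, mu))) || any(c(rho, u, d, mu) <= 0)) {
    stop("all of rho, u, d, mu must be > 0", call. = FALSE)
  }
  rho * u * d / mu
}

#' Validity of the Darcy relation
#'
#' Darcy's linear pressure-drop relation breaks down once the interstitial
#' Reynolds number exceeds 8.6; the check is inclusive at the boundary
#' (exactly 8.6 is still valid).
#'
#' @param Re interstitial Reynolds number, >= 0.
#' @return `TRUE` if the Darcy relation is applicable.
#' @examples
#' darcy_validity(c(0.95, 8.6, 10))
#' @export
darcy_validity <- function(Re) {
  if (any(!is.finite(Re)) || any(Re < 0)) stop("Re must be >= 0", call. = FALSE)
  Re <= 8.6
}

#' Velocity sweep: perfusion metrics over a range of inlet velocities
#'
#' Runs the steady flow solve at each inlet velocity and assembles one
#' perfusion report row per velocity: pressure drop, Darcy permeability,
#' interstitial Reynolds number (using the largest pore size as the
#' conservative length scale for graded designs), its validity flag,
#' mean/max wall shear stress and the WSS-threshold viable surface
#' fraction. A failed solve is flagged in its row and the sweep continues.
#'
#' @param domain a [voxel_domain].
#' @param fluid a [fluid_properties].
#' @param velocities inlet velocities in m/s (default 1, 3, 5, 7, 9 mm/s).
#' @param wss_threshold viability threshold, Pa.
#' @param scaffold_id label recorded in the report.
#' @param config_args extra arguments passed to [solver_config()].
#' @param keep_solutions return the flow solutions as an attribute.
#' @return A `perfusion_report` data frame sorted by velocity with columns
#'   `scaffold`, `u_mm_s`, `dP_Pa`, `k0_m2`, `Re`, `darcy_valid`,
#'   `mean_wss_mPa`, `max_wss_mPa`, `viable_pct` (surface-area fraction),
#'   `converged`, `failed`.
#' @export
velocity_sweep <- function(domain, fluid, velocities = c(1, 3, 5, 7, 9) * 1e-3,
                           wss_threshold = 0.030, scaffold_id = "scaffold",
                           config_args = list(), keep_solutions = FALSE) {
  if (length(velocities) == 0L || any(!is.finite(velocities)) || any(velocities <= 0)) {
    stop("velocities must be a non-empty vector of positive values (m/s)",
         call. = FALSE)
  }
  velocities <- sort(velocities)
  d_pore <- if (!is.null(domain$pore_sizes)) max(domain$pore_sizes) * 1e-3 else NA_real_
  L <- scaffold_length_mm(domain) * 1e-3
  rows <- vector("list", length(velocities))
  sols <- if (keep_solutions) vector("list", length(velocities)) else NULL
  dP_prev <- NULL; u_prev <- NULL
  for (i in seq_along(velocities)) {
    u <- velocities[i]
    # pre-scale the lattice pressure headroom from the previous velocity
    if (!is.null(dP_prev) && is.null(config_args$expected_pressure_drop) &&
        is.null(config_args$tau_plus)) {
      config_args_i <- c(config_args,
                         list(expected_pressure_drop = dP_prev * u / u_prev))
    } else {
      config_args_i <- config_args
    }
    row <- data.frame(scaffold = scaffold_id, u_mm_s = round(1000 * u, 9),
                      dP_Pa = NA_real_,
                      k0_m2 = NA_real_, Re = NA_real_, darcy_valid = NA,
                      mean_wss_mPa = NA_real_, max_wss_mPa = NA_real_,
                      viable_pct = NA_real_, converged = NA, failed = TRUE)
    res <- tryCatch({
      cfg <- do.call(solver_config, c(list(inlet_velocity = u), config_args_i))
      sol <- solve_steady_flow(domain, fluid, cfg)
      dP <- pressure_drop(sol, domain)
      dP_prev <- dP; u_prev <- u
      wss <- compute_wss(sol, domain, fluid)
      via <- viability_fraction(wss, threshold = wss_threshold)
      Re <- if (is.na(d_pore)) NA_real_ else
        reynolds_number(fluid$density, u, d_pore, fluid$dynamic_viscosity)
      row$dP_Pa <- dP
      row$k0_m2 <- darcy_permeability(u, fluid$dynamic_viscosity, L, dP)
      row$Re <- Re
      row$darcy_valid <- if (is.na(Re)) NA else darcy_validity(Re)
      row$mean_wss_mPa <- 1000 * via$mean_tau
      row$max_wss_mPa <- 1000 * via$max_tau
      row$viable_pct <- via$viable_fraction
      row$converged <- sol$converged
      row$failed <- FALSE
      if (keep_solutions) sols[[i]] <- sol
      row
    }, error = function(e) {
      warning(sprintf("solve at %g mm/s failed: %s", 1000 * u, conditionMessage(e)),
              call. = FALSE)
      row
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  class(out) <- c("perfusion_report", "data.frame")
  if (keep_solutions) attr(out, "solutions") <- sols
  out
}

#' Per-scaffold summary of viability across a velocity sweep
#'
#' Averages the viable surface fraction over the velocity grid for each
#' scaffold (the velocity grids must match across scaffolds) and reports
#' all pairwise differences of the scaffold means.
#'
#' @param reports a single `perfusion_report` covering several scaffolds,
#'   a list of reports, or a data frame with columns `scaffold`, `u_mm_s`,
#'   `viable_pct`.
#' @return list with `summary` (data frame `scaffold`, `mean_viable_pct`)
#'   and `pairwise` (data frame `scaffold_a`, `scaffold_b`, `mean_a`,
#'   `mean_b`, `difference`).
#' @examples
#' r <- data.frame(scaffold = rep(c("A", "B"), each = 2),
#'                 u_mm_s = c(1, 3, 1, 3), viable_pct = c(90, 80, 99, 97))
#' summarize_table(r)$summary
#' @export
summarize_table <- function(reports) {
  if (is.list(reports) && !is.data.frame(reports)) {
    reports <- do.call(rbind, lapply(reports, as.data.frame))
  }
  stopifnot(all(c("scaffold", "u_mm_s", "viable_pct") %in% names(reports)))
  grids <- split(reports$u_mm_s, reports$scaffold)
  ref <- sort(grids[[1]])
  same <- vapply(grids, function(g) length(g) == length(ref) &&
                   isTRUE(all.equal(sort(g), ref)), logical(1))
  if (!all(same)) {
    stop("mismatched velocity grids across scaffolds", call. = FALSE)
  }
  means <- vapply(split(reports$viable_pct, reports$scaffold), mean, numeric(1))
  summary <- data.frame(scaffold = names(means), mean_viable_pct = unname(means),
                        row.names = NULL)
  pairs <- if (length(means) > 1L) {
    cmb <- utils::combn(names(means), 2)
    data.frame(scaffold_a = cmb[1, ], scaffold_b = cmb[2, ],
               mean_a = unname(means[cmb[1, ]]), mean_b = unname(means[cmb[2, ]]),
               difference = unname(means[cmb[1, ]] - means[cmb[2, ]]))
  } else {
    data.frame(scaffold_a = character(), scaffold_b = character(),
               mean_a = numeric(), mean_b = numeric(), difference = numeric())
  }
  list(summary = summary, pairwise = pairs)
}
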