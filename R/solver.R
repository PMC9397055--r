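#' Fluid properties
#'
#' Constant properties of the incompressible Newtonian perfusate. Defaults
#' are whole blood at 37 C: density 1056 kg/m^3, dynamic viscosity
#' 0.0045 Pa s.
#'
#' @param density fluid density, kg/m^3.
#' @param dynamic_viscosity dynamic viscosity, Pa s.
#' @return An object of class `fluid_properties`.
#' @examples
#' blood <- fluid_properties()
#' blood$dynamic_viscosity / blood$density  # kinematic viscosity, m^2/s
#' @export
fluid_properties <- function(density = 1056, dynamic_viscosity = 0.0045) {
  if (!is.finite(density) || density <= 0) stop("density must be > 0", call. = FALSE)
  if (!is.finite(dynamic_viscosity) || dynamic_viscosity <= 0) {
    stop("dynamic_viscosity must be > 0", call. = FALSE)
  }
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "fluid_properties")
}

#' Solver configuration
#'
#' Settings for the steady-state solve. The solver marches the discrete
#' kinetic system to its steady state (no random initialization: zero
#' velocity, uniform pressure), monitoring a root-mean-square momentum
#' residual every `check_every` steps. Convergence requires the residual to
#' fall below `convergence_tolerance` (default 1e-4) and the relative change
#' of the velocity field between successive checks to fall below
#' `rel_change_tolerance` (default 1e-6) simultaneously.
#'
#' @param inlet_velocity uniform (plug) inlet velocity, m/s; must be > 0.
#' @param convergence_tolerance RMS momentum-residual tolerance.
#' @param rel_change_tolerance relative velocity-field change tolerance.
#' @param max_iterations iteration cap; non-convergence returns the current
#'   solution flagged `converged = FALSE` with a warning.
#' @param check_every residual evaluation interval, steps.
#' @param tau_plus even relaxation time of the two-relaxation-time collision
#'   operator; `NULL` (default) selects it automatically so that both the
#'   lattice Mach number stays below `max_lattice_velocity` and the lattice
#'   density (pressure) variation stays below `max_density_variation`,
#'   re-solving with a rescaled relaxation time if the measured pressure
#'   drop exceeds the headroom.
#' @param max_lattice_velocity cap on the inlet velocity in lattice units
#'   (compressibility-error control).
#' @param max_density_variation cap on `|rho - 1|` in lattice units; keeps
#'   the quasi-incompressible approximation tight so that the pressure drop
#'   and permeability are velocity-scale free.
#' @param expected_pressure_drop optional a-priori estimate of the pressure
#'   drop (Pa), used to pre-scale the lattice pressure headroom (e.g. the
#'   extrapolated drop from a lower velocity in a sweep).
#' @param verbose print residuals during the solve.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(inlet_velocity,
                          convergence_tolerance = 1e-4,
                          rel_change_tolerance = 1e-6,
                          max_iterations = 60000L,
                          check_every = 50L,
                          tau_plus = NULL,
                          max_lattice_velocity = 0.05,
                          max_density_variation = 0.005,
                          expected_pressure_drop = NULL,
                          verbose = FALSE) {
  if (!is.finite(inlet_velocity) || inlet_velocity <= 0) {
    stop("inlet_velocity must be > 0", call. = FALSE)
  }
  if (!is.finite(convergence_tolerance) || convergence_tolerance <= 0) {
    stop("convergence_tolerance must be > 0", call. = FALSE)
  }
  structure(
    list(inlet_velocity = inlet_velocity,
         convergence_tolerance = convergence_tolerance,
         rel_change_tolerance = rel_change_tolerance,
         max_iterations = as.integer(max_iterations),
         check_every = as.integer(check_every),
         tau_plus = tau_plus,
         max_lattice_velocity = max_lattice_velocity,
         max_density_variation = max_density_variation,
         expected_pressure_drop = expected_pressure_drop,
         verbose = isTRUE(verbose)),
    class = "solver_config"
  )
}

#' Solve steady incompressible flow through a voxel domain
#'
#' Solves the steady incompressible Navier-Stokes equations (no body force)
#' through the pore network of a [voxel_domain] with a D3Q19
#' two-relaxation-time lattice-Boltzmann scheme: halfway bounce-back no-slip
#' on all solid surfaces, a uniform plug velocity on the inlet face, a
#' zero-resistance (zero gauge pressure, free outflow) outlet, and either
#' no-slip or periodic lateral boundaries as labelled on the domain. The
#' scheme is iterated to steady state; at the interstitial Reynolds numbers
#' of scaffold perfusion (well below 1) the converged field is a creeping
#' laminar flow.
#'
#' The two-relaxation-time collision uses the magic parameter 3/16, which
#' places the bounce-back wall exactly halfway between fluid and solid
#' voxel centres independently of viscosity.
#'
#' @param domain a [voxel_domain] with an inlet-to-outlet fluid path.
#' @param fluid a [fluid_properties].
#' @param config a [solver_config].
#' @return An object of class `flow_solution`: velocity component arrays
#'   `ux`, `uy`, `uz` (m/s) and pressure `p` (Pa, gauge) on the voxel grid
#'   (`NA` in solid cells), the `residual_history` data frame, `converged`
#'   flag, iteration count, and the lattice scaling (`dx_m`, `dt_s`,
#'   `tau_plus`, `u_lattice`).
#' @examples
#' \donttest{
#' dom <- make_channel_fixture("parallel_plate", 0.3, 1, 0.03)
#' sol <- solve_steady_flow(dom, fluid_properties(), solver_config(0.001))
#' max(sol$uz, na.rm = TRUE) / 0.001  # ~1.5: plane-Poiseuille peak ratio
#' }
#' @export
solve_steady_flow <- function(domain, fluid, config) {
  stopifnot(inherits(domain, "voxel_domain"), inherits(fluid, "fluid_properties"),
            inherits(config, "solver_config"))
  if (!isTRUE(domain$outlet_reachable)) {
    stop("impermeable domain: no fluid path connects the inlet to the outlet",
         call. = FALSE)
  }
  nu <- fluid$dynamic_viscosity / fluid$density      # m^2/s
  dx <- domain$spacing * 1e-3                        # m
  tau_floor <- 0.503
  auto <- is.null(config$tau_plus)
  if (auto) {
    tau <- 1
    # Mach cap
    u_lat0 <- config$inlet_velocity * (tau - 0.5) / 3 * dx / nu
    if (u_lat0 > config$max_lattice_velocity) {
      tau <- 0.5 + 3 * config$max_lattice_velocity * nu /
        (config$inlet_velocity * dx)
    }
    # pressure-headroom cap from an a-priori pressure-drop estimate
    if (!is.null(config$expected_pressure_drop) &&
        is.finite(config$expected_pressure_drop) &&
        config$expected_pressure_drop > 0) {
      c_req <- sqrt(3 * config$expected_pressure_drop /
                      (fluid$density * config$max_density_variation))
      tau <- min(tau, 0.5 + 3 * nu / (dx * c_req))
    }
  } else {
    tau <- config$tau_plus
  }
  if (tau <= tau_floor) {
    stop("stable lattice scaling not achievable: refine the voxel spacing",
         call. = FALSE)
  }

  run_once <- function(tau) {
    dt <- (tau - 0.5) / 3 * dx^2 / nu                # s
    u_lat <- config$inlet_velocity * dt / dx
    res <- lbm_solve(as.integer(domain$occ), as.integer(dim(domain$occ)),
                     domain$lateral == "periodic", domain$lateral == "periodic",
                     u_lat, tau, 3 / 16,
                     config$convergence_tolerance, config$rel_change_tolerance,
                     config$max_iterations, config$check_every, config$verbose)
    list(res = res, dt = dt, u_lat = u_lat, tau = tau,
         drho = max(abs(res$rho - 1), na.rm = TRUE))
  }

  out <- run_once(tau)
  if (auto) {
    # the quasi-incompressible approximation needs the realized lattice
    # density variation to stay below the configured cap; if the measured
    # pressure drop blew the headroom, rescale the relaxation time and
    # re-solve (deterministic, at most 3 attempts)
    for (attempt in 1:2) {
      if (out$drho <= 1.2 * config$max_density_variation) break
      tau_new <- 0.5 + (out$tau - 0.5) * 0.9 *
        sqrt(config$max_density_variation / out$drho)
      tau_new <- max(tau_new, tau_floor + 1e-3)
      if (abs(tau_new - out$tau) < 1e-6) break
      out <- run_once(tau_new)
    }
    if (out$drho > 2 * config$max_density_variation) {
      warning(sprintf(paste0("lattice density variation %.3g exceeds the %.3g cap; ",
                             "refine the voxel spacing for this pressure drop"),
                      out$drho, config$max_density_variation), call. = FALSE)
    }
  }
  res <- out$res; dt <- out$dt; u_lat <- out$u_lat; tau <- out$tau

  d <- dim(domain$occ)
  scale_u <- dx / dt
  sol <- structure(
    list(
      ux = array(res$ux * scale_u, dim = d),
      uy = array(res$uy * scale_u, dim = d),
      uz = array(res$uz * scale_u, dim = d),
      p = array((res$rho - 1) / 3 * fluid$density * scale_u^2, dim = d),
      residual_history = data.frame(step = res$hist_step,
                                    residual = res$hist_residual,
                                    rel_change = res$hist_rel_change),
      converged = res$converged,
      iterations = res$steps,
      n_fluid = res$n_fluid,
      inlet_velocity = config$inlet_velocity,
      fluid = fluid,
      lattice = list(dx_m = dx, dt_s = dt, tau_plus = tau, u_lattice = u_lat)
    ),
    class = "flow_solution"
  )
  if (!sol$converged) {
    warning(sprintf("flow solve did not converge in %d iterations (residual %.3g)",
                    sol$iterations, utils::tail(res$hist_residual, 1)), call. = FALSE)
  }
  sol
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("<flow_solution: %d fluid voxels, %d iterations, %s>\n",
              x$n_fluid, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  inlet velocity %.3g m/s; max speed %.3g m/s\n",
              x$inlet_velocity,
              sqrt(max(x$ux^2 + x$uy^2 + x$uz^2, na.rm = TRUE))))
  invisible(x)
}

#' Evaluate the convergence criteria on a residual history
#'
#' The solve is converged when the latest root-mean-square momentum residual
#' is below `tolerance` and, simultaneously, the relative change of the
#' velocity field between successive checks is below `rel_tolerance`.
#'
#' @param residual_history data frame with columns `residual` and
#'   `rel_change` (as recorded in a `flow_solution`), at least two rows.
#' @param tolerance RMS residual tolerance (default 1e-4).
#' @param rel_tolerance relative velocity-change tolerance (default 1e-6).
#' @return `TRUE` if both criteria hold at the latest check.
#' @examples
#' h <- data.frame(residual = c(1e-2, 1e-5), rel_change = c(1e-3, 1e-7))
#' check_convergence(h, 1e-4)
#' @export
check_convergence <- function(residual_history, tolerance = 1e-4,
                              rel_tolerance = 1e-6) {
  if (!is.data.frame(residual_history) || nrow(residual_history) < 2L) {
    stop("residual_history must contain at least 2 recorded residuals", call. = FALSE)
  }
  last <- residual_history[nrow(residual_history), ]
  isTRUE(last$residual < tolerance) && isTRUE(last$rel_change < rel_tolerance)
}

#' Mass and divergence diagnostics of a flow solution
#'
#' Reports the global mass balance (relative difference between the mass
#' flux `rho u` through the inlet and outlet faces) and the maximum and RMS
#' discrete velocity divergence over interior fluid voxels (normalized by
#' `inlet_velocity / spacing`).
#'
#' @param solution a `flow_solution`.
#' @param domain the [voxel_domain] it was solved on.
#' @return list with `mass_imbalance`, `max_divergence`, `rms_divergence`
#'   (dimensionless).
#' @export
flow_diagnostics <- function(solution, domain) {
  d <- dim(domain$occ)
  fluid <- domain$occ == 0L
  rho <- 1 + 3 * solution$p / (solution$fluid$density *
                                 (solution$lattice$dx_m / solution$lattice$dt_s)^2)
  uz <- solution$uz * rho
  flux_in <- sum(uz[, , 1][fluid[, , 1]])
  flux_out <- sum(uz[, , d[3]][fluid[, , d[3]]])
  imb <- abs(flux_in - flux_out) / abs(flux_in)

  # central-difference divergence on voxels whose 6 neighbours are all fluid
  ix <- 2:(d[1] - 1); iy <- 2:(d[2] - 1); iz <- 2:(d[3] - 1)
  interior <- fluid[ix, iy, iz] &
    fluid[ix - 1, iy, iz] & fluid[ix + 1, iy, iz] &
    fluid[ix, iy - 1, iz] & fluid[ix, iy + 1, iz] &
    fluid[ix, iy, iz - 1] & fluid[ix, iy, iz + 1]
  h <- domain$spacing * 1e-3
  div <- (solution$ux[ix + 1, iy, iz] - solution$ux[ix - 1, iy, iz] +
            solution$uy[ix, iy + 1, iz] - solution$uy[ix, iy - 1, iz] +
            solution$uz[ix, iy, iz + 1] - solution$uz[ix, iy, iz - 1]) / (2 * h)
  div <- div[interior] / (solution$inlet_velocity / h)
  list(mass_imbalance = imb,
       max_divergence = if (length(div)) max(abs(div)) else NA_real_,
       rms_divergence = if (length(div)) sqrt(mean(div^2)) else NA_real_)
}
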