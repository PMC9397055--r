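test_that("plane-Poiseuille flow reproduces the closed-form profile", {
  dom <- plate_fixture()
  sol <- plate_solution()
  expect_true(sol$converged)
  kmid <- round(mean(dom$scaffold_range))
  prof <- sol$uz[2, , kmid]
  # centreline velocity 1.5 x mean within 2%
  expect_equal(max(prof, na.rm = TRUE) / 0.001, 1.5, tolerance = 0.02)
  # symmetric about the mid-plane
  p <- prof[!is.na(prof)]
  expect_equal(p, rev(p), tolerance = 1e-6)
  # closed-form pressure drop 12 mu U L / h^2 within 3%
  dP <- pressure_drop(sol, dom)
  L <- scaffold_length_mm(dom) * 1e-3
  expect_equal(dP, 12 * 0.0045 * 0.001 * L / 0.0003^2, tolerance = 0.03)
})

test_that("Hagen-Poiseuille flow reproduces the parabolic peak", {
  dom <- tube_fixture()
  sol <- tube_solution()
  kmid <- round(mean(dom$scaffold_range))
  expect_equal(max(sol$uz[, , kmid], na.rm = TRUE) / 0.001, 2, tolerance = 0.03)
})

test_that("global mass balance and discrete divergence are tight", {
  for (fix in list(list(plate_fixture(), plate_solution()),
                   list(tube_fixture(), tube_solution()))) {
    dg <- flow_diagnostics(fix[[2]], fix[[1]])
    expect_lt(dg$mass_imbalance, 1e-3)
    expect_lt(dg$rms_divergence, 0.005)
    expect_lt(dg$max_divergence, 0.06)
  }
})

test_that("solver matches a directly assembled discrete Laplacian on a duct", {
  skip_if_not_installed("Matrix")
  # square duct: 8x8 fluid cross-section, no-slip walls halfway outside the
  # boundary voxel centres (the bounce-back wall position)
  n <- 8L
  h <- 0.05e-3
  dom <- voxelize(empty_solid(c(n * 0.05, n * 0.05, 1)), 0.05,
                  entry_length = 0.5, exit_length = 0.5, lateral = "wall")
  sol <- solve_steady_flow(dom, blood, solver_config(0.001))
  dP <- pressure_drop(sol, dom)
  L <- scaffold_length_mm(dom) * 1e-3
  k_lbm <- darcy_permeability(0.001, 0.0045, L, dP)

  # oracle: fully developed duct flow solves  -mu lap(w) = G  on the cross
  # section; ghost nodes across the wall satisfy w_ghost = -w (no slip at
  # the halfway wall). Unit pressure gradient; k = mu * mean(w).
  idx <- function(i, j) i + n * (j - 1L)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_len(n)) for (i in seq_len(n)) {
    diag_c <- 4
    for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
      if (nb[1] >= 1L && nb[1] <= n && nb[2] >= 1L && nb[2] <= n) {
        ii <- c(ii, idx(i, j)); jj <- c(jj, idx(nb[1], nb[2])); xx <- c(xx, -1)
      } else {
        diag_c <- diag_c + 1  # ghost = -w folds into the diagonal
      }
    }
    ii <- c(ii, idx(i, j)); jj <- c(jj, idx(i, j)); xx <- c(xx, diag_c)
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx / h^2) * 0.0045
  w <- Matrix::solve(A, rep(1, n * n))
  k_fd <- 0.0045 * mean(as.numeric(w))
  expect_equal(k_lbm, k_fd, tolerance = 0.02)
})

test_that("Stokes-regime linearity: doubling the inlet velocity doubles the field", {
  dom <- unit_cell_1a()
  s1 <- unit_cell_1a_solution(0.001)
  s2 <- cached("uc1a_sol_0.002",
               solve_steady_flow(dom, blood, solver_config(0.002)))
  expect_equal(pressure_drop(s2, dom) / pressure_drop(s1, dom), 2,
               tolerance = 0.01)
  scale_err <- max(abs(s2$uz - 2 * s1$uz), na.rm = TRUE) /
    max(abs(s2$uz), na.rm = TRUE)
  expect_lt(scale_err, 0.01)
})

test_that("solution respects the 90-degree symmetry of the 0/90 unit cell", {
  spec <- scaffold_spec("rectangular", c(2.52, 2.52, 0.64), 2, 0.33, 0.30, 0.31)
  uc <- extract_unit_cell(spec, 0.055)
  s1 <- solve_steady_flow(uc, blood, solver_config(0.001))
  rot <- uc
  d <- dim(uc$occ)
  rot$occ <- aperm(uc$occ, c(2, 1, 3))[d[2]:1, , , drop = FALSE]
  rot <- filter_connected(rot)
  s2 <- solve_steady_flow(rot, blood, solver_config(0.001))
  expect_equal(pressure_drop(s2, rot), pressure_drop(s1, uc), tolerance = 1e-3)
})

test_that("convergence requires both residual and velocity-change criteria", {
  # monotone decay crossing the tolerance
  h1 <- data.frame(residual = 10^seq(-1, -5, length.out = 9),
                   rel_change = 10^seq(-2, -8, length.out = 9))
  expect_true(check_convergence(h1, 1e-4))
  # flat plateau above tolerance
  h2 <- data.frame(residual = rep(1e-3, 5), rel_change = rep(1e-3, 5))
  expect_false(check_convergence(h2, 1e-4))
  # oscillating residuals straddling the tolerance: false until both hold
  h3 <- data.frame(residual = c(1e-3, 5e-5, 2e-3, 8e-5),
                   rel_change = c(1e-3, 1e-5, 1e-3, 1e-5))
  expect_false(check_convergence(h3, 1e-4))
  h4 <- rbind(h3, data.frame(residual = 5e-5, rel_change = 5e-7))
  expect_true(check_convergence(h4, 1e-4))
  expect_error(check_convergence(h1[1, , drop = FALSE], 1e-4), "at least 2")
})

test_that("impermeable domains and invalid configurations are rejected", {
  g <- build_rectangular_scaffold(small_rect_spec())
  dom <- voxelize(g, 0.09)
  blocked <- dom
  blocked$occ[, , blocked$scaffold_range[1]] <- 1L   # seal one plane
  blocked <- filter_connected(blocked)
  expect_false(blocked$outlet_reachable)
  expect_error(solve_steady_flow(blocked, blood, solver_config(0.001)),
               "impermeable")
  expect_error(solver_config(0), "inlet_velocity")
  expect_error(solver_config(0.001, convergence_tolerance = -1),
               "convergence_tolerance")
})

test_that("hitting the iteration cap returns an unconverged flagged solution", {
  dom <- plate_fixture()
  expect_warning(
    sol <- solve_steady_flow(dom, blood,
                             solver_config(0.001, max_iterations = 200L)),
    "did not converge")
  expect_false(sol$converged)
  expect_false(check_convergence(sol$residual_history, 1e-4))
})
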