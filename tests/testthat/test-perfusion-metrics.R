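test_that("Darcy permeability is direct substitution with guarded inputs", {
  expect_equal(darcy_permeability(0.001, 0.0045, 0.01, 45), 1e-9)
  expect_error(darcy_permeability(0.001, 0.0045, 0.01, 0), "no resistance")
  expect_error(darcy_permeability(0.001, 0.0045, 0, 45), "L")
})

test_that("interstitial Reynolds number evaluates rho u d / mu", {
  # largest pore at the highest inlet velocity stays below the Darcy bound
  expect_equal(reynolds_number(1056, 0.009, 0.00045, 0.0045), 0.9504)
  expect_equal(reynolds_number(1056, 0.001, 0.0003, 0.0045), 0.0704)
  expect_error(reynolds_number(1056, 0, 0.0003, 0.0045), "> 0")
})

test_that("Darcy validity is inclusive at 8.6 and monotone", {
  expect_true(darcy_validity(0.9504))
  expect_true(darcy_validity(8.6))
  expect_false(darcy_validity(10))
  re <- sort(c(0.01, 0.5, 3, 8.6, 8.61, 20))
  v <- darcy_validity(re)
  expect_true(all(diff(as.integer(v)) <= 0))  # valid below, invalid above
  expect_error(darcy_validity(-1), ">= 0")
})

test_that("pressure probes sit one voxel outside the scaffold extent", {
  dom <- plate_fixture()
  sol <- plate_solution()
  dP <- pressure_drop(sol, dom)
  L <- scaffold_length_mm(dom) * 1e-3
  expect_equal(dP, 12 * 0.0045 * 0.001 * L / 0.0003^2, tolerance = 0.03)
  # without entry/exit channel there is no probe plane
  g <- build_rectangular_scaffold(small_rect_spec())
  bare <- voxelize(g, 0.09, entry_length = 0, exit_length = 0)
  sol_b <- solve_steady_flow(bare, blood, solver_config(0.001))
  expect_error(pressure_drop(sol_b, bare), "probe plane")
})

test_that("fixture permeabilities match the channel closed forms", {
  dP_p <- pressure_drop(plate_solution(), plate_fixture())
  k_p <- darcy_permeability(0.001, 0.0045,
                            scaffold_length_mm(plate_fixture()) * 1e-3, dP_p)
  expect_equal(k_p, 0.0003^2 / 12, tolerance = 0.03)
  dP_t <- pressure_drop(tube_solution(), tube_fixture())
  k_t <- darcy_permeability(0.001, 0.0045,
                            scaffold_length_mm(tube_fixture()) * 1e-3, dP_t)
  expect_equal(k_t, 0.0005^2 / 8, tolerance = 0.03)
})

test_that("summarize_table reproduces the printed per-scaffold averages", {
  # published viable-percentage table: five velocities x four scaffolds
  tab <- data.frame(
    scaffold = rep(c("case1c", "case1b", "case1a", "case2"), each = 5),
    u_mm_s = rep(c(1, 3, 5, 7, 9), times = 4),
    viable_pct = c(83.4, 75.3, 70.3, 56.0, 22.8,
                   82.6, 74.8, 69.1, 56.8, 24.9,
                   82.7, 75.3, 68.9, 54.9, 15.4,
                   99.8, 98.1, 90.9, 81.0, 59.5))
  s <- summarize_table(tab)
  means <- setNames(s$summary$mean_viable_pct, s$summary$scaffold)
  expect_equal(means[["case1c"]], 61.56)
  expect_equal(means[["case1b"]], 61.64)
  expect_equal(means[["case1a"]], 59.44)
  expect_equal(means[["case2"]], 85.86)
  # the graded design improves on the best rectangular design by the
  # difference of the printed means
  pair <- s$pairwise
  d <- pair$difference[pair$scaffold_a == "case1b" & pair$scaffold_b == "case2"]
  if (length(d) == 0) {
    d <- -pair$difference[pair$scaffold_a == "case2" & pair$scaffold_b == "case1b"]
  }
  expect_equal(abs(d), 24.22, tolerance = 1e-8)

  # row order invariance
  set.seed(42)
  s2 <- summarize_table(tab[sample(nrow(tab)), ])
  expect_equal(sort(s2$summary$mean_viable_pct), sort(s$summary$mean_viable_pct))
  # identical columns differ by zero
  two <- rbind(tab[tab$scaffold == "case2", ],
               transform(tab[tab$scaffold == "case2", ], scaffold = "copy"))
  expect_equal(summarize_table(two)$pairwise$difference, 0)
  # mismatched grids are rejected
  bad <- rbind(tab, data.frame(scaffold = "case2", u_mm_s = 11, viable_pct = 50))
  expect_error(summarize_table(bad), "mismatched")
})

test_that("velocity sweeps flag failures and reject empty grids", {
  g <- build_rectangular_scaffold(small_rect_spec())
  dom <- voxelize(g, 0.09)
  blocked <- dom
  blocked$occ[, , blocked$scaffold_range[1]] <- 1L
  blocked <- filter_connected(blocked)
  # one warning per failed velocity
  expect_warning(
    expect_warning(sw <- velocity_sweep(blocked, blood, velocities = c(1e-3, 3e-3)),
                   "failed"),
    "failed")
  expect_equal(nrow(sw), 2L)
  expect_true(all(sw$failed))
  expect_error(velocity_sweep(dom, blood, velocities = numeric()), "non-empty")
  expect_error(velocity_sweep(dom, blood, velocities = c(1e-3, -1)), "positive")
})
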