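test_that("rectangular builder follows the 0/90 lay-down convention", {
  spec <- reference_scaffold("1A")
  g <- build_rectangular_scaffold(spec)
  prim <- g$primitives
  expect_equal(length(unique(prim$layer)), 10L)
  # filaments per layer: floor(width / (pore + diameter)) + 1
  expect_equal(sum(prim$layer == 1L), floor(20 / 0.63) + 1L)  # 32
  # alternating orientation
  expect_true(all(prim$type[prim$layer %% 2 == 1] == "cyl_x"))
  expect_true(all(prim$type[prim$layer %% 2 == 0] == "cyl_y"))
  # in-plane centre-to-centre spacing = pore + diameter
  ys <- sort(prim$y[prim$layer == 1L])
  expect_equal(unique(round(diff(ys), 9)), 0.63)
  # consecutive layers fused: vertical spacing = pitch < diameter
  zc <- sort(unique(prim$z))
  expect_equal(unique(round(diff(zc), 9)), 0.31)

  # larger pore at equal footprint -> fewer filaments per layer
  gC <- build_rectangular_scaffold(reference_scaffold("1C"))
  expect_equal(sum(gC$primitives$layer == 1L), floor(20 / 0.78) + 1L)  # 26
  expect_lt(sum(gC$primitives$layer == 1L), sum(prim$layer == 1L))
})

test_that("degenerate single-filament spec yields one trimmed cylinder", {
  spec <- scaffold_spec("rectangular", c(1, 1, 0.4), 1, 0.33, 2, 0.31)
  g <- build_rectangular_scaffold(spec)
  expect_equal(nrow(g$primitives), 1L)
  m <- compute_geometry_metrics(g)
  expect_equal(m$V_material, pi * 0.165^2 * 1, tolerance = 1e-4)
  # flush-cut ends: only the lateral surface counts
  expect_equal(m$SA, 2 * pi * 0.165 * 1, tolerance = 1e-3)
})

test_that("porosity of the reference rectangular designs is increasing in pore size", {
  por <- vapply(c("1A", "1B", "1C"), function(case) {
    m <- compute_geometry_metrics(build_scaffold(reference_scaffold(case)),
                                  compute_sa = FALSE)
    100 * m$porosity
  }, numeric(1))
  expect_true(all(diff(por) > 0))
  # frozen constructive values (cross-checked against Monte-Carlo point
  # sampling of the same solids)
  expect_equal(unname(por), c(56.08, 58.91, 64.29), tolerance = 1e-3)
})

test_that("metrics reproduce closed forms for spheres and report empty solids", {
  s <- sphere_solid(c(0.5, 0.5, 0.5), 0.1, c(1, 1, 1))
  m <- compute_geometry_metrics(s, spacing = 0.005)
  expect_equal(m$V_material, 4 * pi * 0.1^3 / 3, tolerance = 0.01)
  expect_equal(m$SA, 4 * pi * 0.1^2, tolerance = 0.01)
  expect_equal(m$specific_surface, 4 * pi * 0.1^2 / 1, tolerance = 0.01)

  e <- compute_geometry_metrics(empty_solid(c(2, 2, 2)))
  expect_equal(e$porosity, 1)
  expect_equal(e$SA, 0)
  expect_equal(e$specific_surface, 0)
})

test_that("graded-ring builder honours the ring gradient", {
  # one ring reduces to a uniform-pore circular scaffold
  s1 <- scaffold_spec("graded_ring", c(10, 10, 3.1), 10, 0.33, 0.5, 0.31)
  g1 <- build_graded_ring_scaffold(s1)
  xs <- sort(unique(g1$primitives$x[g1$primitives$type == "cyl_y"]))
  expect_equal(unique(round(diff(xs), 9)), 0.83)  # pore + fibre everywhere
  expect_equal(g1$footprint$kind, "ellipse")

  # enlarging only the outermost pore increases porosity
  base <- reference_scaffold("2")
  mod <- base
  mod$pore_sizes[6] <- 1.2
  p0 <- compute_geometry_metrics(build_graded_ring_scaffold(base),
                                 compute_sa = FALSE)$porosity
  p1 <- compute_geometry_metrics(build_graded_ring_scaffold(mod),
                                 compute_sa = FALSE)$porosity
  expect_gt(p1, p0)

  # the graded design is more porous than every uniform rectangular design
  rect <- vapply(c("1A", "1B", "1C"), function(case) {
    compute_geometry_metrics(build_scaffold(reference_scaffold(case)),
                             compute_sa = FALSE)$porosity
  }, numeric(1))
  expect_gt(p0, max(rect))
})

test_that("porosity is invariant under rigid translation with its envelope", {
  spec <- scaffold_spec("rectangular", c(2.52, 2.52, 1.26), 4, 0.33, 0.30, 0.31)
  g <- build_rectangular_scaffold(spec)
  gt <- translate_geometry(g, c(0.37, -1.12, 2.05))
  m0 <- compute_geometry_metrics(g, compute_sa = FALSE)
  m1 <- compute_geometry_metrics(gt, compute_sa = FALSE)
  expect_equal(m1$porosity, m0$porosity, tolerance = 1e-9)
  # voxel path: the grid phase changes, porosity agrees to staircase noise
  v0 <- compute_geometry_metrics(g, method = "voxel", spacing = 0.018,
                                 compute_sa = FALSE)
  v1 <- compute_geometry_metrics(gt, method = "voxel", spacing = 0.018,
                                 compute_sa = FALSE)
  expect_equal(v1$porosity, v0$porosity, tolerance = 0.005)
})

test_that("voxel-estimated porosity converges to the constructive value", {
  spec <- scaffold_spec("rectangular", c(2.52, 2.52, 1.26), 4, 0.33, 0.30, 0.31)
  g <- build_rectangular_scaffold(spec)
  exact <- compute_geometry_metrics(g, compute_sa = FALSE)$porosity
  err <- vapply(c(0.036, 0.018), function(h) {
    abs(compute_geometry_metrics(g, method = "voxel", spacing = h,
                                 compute_sa = FALSE)$porosity - exact)
  }, numeric(1))
  expect_lt(err[2], 0.75 * err[1])      # ~first-order surface convergence
  expect_lt(err[2], 0.0015)             # close at 18 um
})

test_that("invalid specifications are rejected naming the offending field", {
  expect_error(scaffold_spec("rectangular", c(20, 20, 3.1), 10, -0.33, 0.3, 0.31),
               "fibre_diameter")
  expect_error(scaffold_spec("rectangular", c(20, 20, 3.1), 10, 0.33, -0.3, 0.31),
               "pore_sizes")
  expect_error(scaffold_spec("rectangular", c(20, 20, 3.1), 0, 0.33, 0.3, 0.31),
               "n_layers")
  expect_error(scaffold_spec("rectangular", c(20, 20, 3.1), 10, 0.33, 0.3, 0.5),
               "layer_pitch")
  expect_error(scaffold_spec("rectangular", c(20, 20, 3.1), 10, 0.33, c(0.3, 0.4), 0.31),
               "pore_sizes")
  expect_error(scaffold_spec("graded_ring", c(31, 26.7, 3.1), 10, 0.33,
                             c(0.5, 0.4), 0.31),
               "pore_sizes")  # not increasing
  expect_error(scaffold_spec("graded_ring", c(31, 26.7, 3.1), 10, 0.33,
                             c(0.4, 0.5), 0.31, ring_count = 3),
               "ring_count")
  expect_error(build_rectangular_scaffold(reference_scaffold("2")), "rectangular")
  expect_error(build_graded_ring_scaffold(reference_scaffold("1A")), "graded_ring")
})
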