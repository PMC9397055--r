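# Shared fixtures and a solve cache so expensive steady-flow solutions are
# computed once per test run and reused across test files.

blood <- fluid_properties(1056, 0.0045)

.solve_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .solve_cache)) {
    assign(key, force(expr), envir = .solve_cache)
  }
  get(key, envir = .solve_cache)
}

# plane-Poiseuille fixture: 20 voxels across the 0.3 mm gap
plate_fixture <- function() {
  cached("plate_dom", make_channel_fixture("parallel_plate", 0.3, 1, 0.015))
}

plate_solution <- function() {
  cached("plate_sol",
         solve_steady_flow(plate_fixture(), blood, solver_config(0.001)))
}

# Hagen-Poiseuille fixture: 0.5 mm radius tube, 10 voxels per radius
tube_fixture <- function() {
  cached("tube_dom", make_channel_fixture("circular_tube", 0.5, 1, 0.05))
}

tube_solution <- function() {
  cached("tube_sol",
         solve_steady_flow(tube_fixture(), blood, solver_config(0.001)))
}

# interior unit cell of the 0.300 mm pore rectangular design
unit_cell_1a <- function(spacing = 0.055) {
  cached(paste0("uc1a_dom_", spacing),
         extract_unit_cell(reference_scaffold("1A"), spacing))
}

unit_cell_1a_solution <- function(u = 0.001) {
  cached(paste0("uc1a_sol_", u),
         solve_steady_flow(unit_cell_1a(), blood, solver_config(u)))
}

# a small rectangular design (4 layers, small footprint) for fast
# whole-domain tests
small_rect_spec <- function(pore = 0.30) {
  scaffold_spec("rectangular", c(2.52, 2.52, 1.26), 4, 0.33, pore,
                layer_pitch = 0.31)
}
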