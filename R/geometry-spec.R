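#' Parametric scaffold design specification
#'
#' A `scaffold_spec` describes an extrusion-printed scaffold before any solid
#' is built. Two kinds are supported: `"rectangular"` scaffolds with a 0/90
#' lay-down pattern and a single pore size, and `"graded_ring"` scaffolds on
#' an elliptical footprint whose pore size increases ring by ring from the
#' centre outwards.
#'
#' Pore size follows the standard extrusion-scaffold convention: it is the
#' clear edge-to-edge spacing between adjacent parallel filaments within one
#' layer, so the in-plane centre-to-centre filament spacing equals
#' `pore size + fibre diameter`. Consecutive layers are rotated by
#' `laydown_angle_increment` (90 degrees for the 0/90 pattern) and their
#' vertical centre spacing is `layer_pitch`; a pitch smaller than the fibre
#' diameter means consecutive layers interpenetrate and fuse into one body.
#'
#' @param kind `"rectangular"` or `"graded_ring"`.
#' @param dimensions numeric length-3, bounding length x width x height in mm.
#'   For `graded_ring` the first two entries are the full axes of the
#'   elliptical footprint.
#' @param n_layers number of filament layers (>= 1).
#' @param fibre_diameter filament diameter in mm.
#' @param pore_sizes clear filament spacing(s) in mm: a single value for
#'   `rectangular`, an ordered innermost-to-outermost vector (strictly
#'   increasing) with one entry per ring for `graded_ring`.
#' @param layer_pitch vertical centre-to-centre spacing of consecutive layers
#'   in mm; defaults to `height / n_layers`. Must not exceed
#'   `fibre_diameter` (layers must touch or fuse).
#' @param laydown_angle_increment rotation between consecutive layers in
#'   degrees; only 90 (the 0/90 pattern) is supported.
#' @param ring_count number of concentric rings (`graded_ring` only);
#'   defaults to `length(pore_sizes)`.
#'
#' @return An object of class `scaffold_spec`.
#' @examples
#' # Case 1A-style design: 20 x 20 x 3.1 mm, 10 layers, 0.33 mm fibres,
#' # 0.30 mm pores, fused at 0.31 mm pitch
#' spec <- scaffold_spec("rectangular", c(20, 20, 3.1), 10, 0.33, 0.30, 0.31)
#' spec
#' @export
scaffold_spec <- function(kind = c("rectangular", "graded_ring"),
                          dimensions,
                          n_layers,
                          fibre_diameter,
                          pore_sizes,
                          layer_pitch = NULL,
                          laydown_angle_increment = 90,
                          ring_count = NULL) {
  kind <- match.arg(kind)
  if (length(dimensions) != 3L || any(!is.finite(dimensions)) || any(dimensions <= 0)) {
    stop("`dimensions` must be three positive finite values (mm)", call. = FALSE)
  }
  if (is.null(layer_pitch)) layer_pitch <- dimensions[3] / n_layers
  spec <- structure(
    list(
      kind = kind,
      dimensions = as.numeric(dimensions),
      n_layers = as.integer(n_layers),
      fibre_diameter = as.numeric(fibre_diameter),
      pore_sizes = as.numeric(pore_sizes),
      layer_pitch = as.numeric(layer_pitch),
      laydown_angle_increment = as.numeric(laydown_angle_increment),
      ring_count = if (is.null(ring_count)) length(pore_sizes) else as.integer(ring_count)
    ),
    class = "scaffold_spec"
  )
  validate_scaffold_spec(spec)
  spec
}

#' Validate a scaffold specification
#'
#' Checks every `scaffold_spec` invariant and stops with a message naming
#' the offending field on the first violation.
#'
#' @param spec a [scaffold_spec()] object.
#' @return `spec`, invisibly, if valid.
#' @export
validate_scaffold_spec <- function(spec) {
  stopifnot(inherits(spec, "scaffold_spec"))
  bad <- function(field, why) {
    stop(sprintf("invalid scaffold_spec: field `%s` %s", field, why), call. = FALSE)
  }
  if (!is.finite(spec$fibre_diameter) || spec$fibre_diameter <= 0) {
    bad("fibre_diameter", "must be > 0")
  }
  if (length(spec$pore_sizes) < 1L || any(!is.finite(spec$pore_sizes)) ||
      any(spec$pore_sizes <= 0)) {
    bad("pore_sizes", "must all be > 0")
  }
  if (is.na(spec$n_layers) || spec$n_layers < 1L) bad("n_layers", "must be >= 1")
  if (!is.finite(spec$layer_pitch) || spec$layer_pitch <= 0) {
    bad("layer_pitch", "must be > 0")
  }
  if (spec$layer_pitch > spec$fibre_diameter + 1e-12) {
    bad("layer_pitch", sprintf(
      "must be <= fibre_diameter (%g > %g): consecutive layers must touch or fuse",
      spec$layer_pitch, spec$fibre_diameter))
  }
  if (spec$laydown_angle_increment != 90) {
    bad("laydown_angle_increment", "only the 0/90 pattern (90 degrees) is supported")
  }
  if (spec$kind == "rectangular") {
    if (length(spec$pore_sizes) != 1L) {
      bad("pore_sizes", "must be a single value for rectangular scaffolds")
    }
  } else {
    if (spec$ring_count != length(spec$pore_sizes)) {
      bad("ring_count", sprintf("(%d) must equal length(pore_sizes) (%d)",
                                spec$ring_count, length(spec$pore_sizes)))
    }
    if (length(spec$pore_sizes) > 1L && any(diff(spec$pore_sizes) <= 0)) {
      bad("pore_sizes", "must be strictly increasing from innermost to outermost ring")
    }
  }
  invisible(spec)
}

#' @export
print.scaffold_spec <- function(x, ...) {
  cat(sprintf("<scaffold_spec: %s>\n", x$kind))
  cat(sprintf("  dimensions     : %g x %g x %g mm\n",
              x$dimensions[1], x$dimensions[2], x$dimensions[3]))
  cat(sprintf("  layers         : %d (pitch %.3g mm, fibre %.3g mm)\n",
              x$n_layers, x$layer_pitch, x$fibre_diameter))
  cat(sprintf("  pore size(s)   : %s mm\n", paste(x$pore_sizes, collapse = "/")))
  if (x$kind == "graded_ring") cat(sprintf("  rings          : %d\n", x$ring_count))
  invisible(x)
}

#' Reference scaffold designs
#'
#' Ready-made [scaffold_spec()] objects for the four reference designs: three
#' rectangular 0/90 scaffolds (`"1A"`, `"1B"`, `"1C"`: 20 x 20 x 3.1 mm,
#' 10 layers, 0.33 mm fibre, pores 0.300 / 0.350 / 0.45 mm, 0.31 mm pitch)
#' and the six-ring graded elliptical design (`"2"`: 31 x 26.7 x 3.1 mm,
#' pores 0.476/0.629/0.670/0.730/0.803/0.979 mm).
#'
#' @param case one of `"1A"`, `"1B"`, `"1C"`, `"2"`.
#' @param scale footprint scale factor applied to the in-plane dimensions
#'   (height, fibre, pitch and pore sizes are unchanged). Useful for
#'   desk-scale studies of the graded design; 1 reproduces the full design.
#' @return A [scaffold_spec()].
#' @examples
#' reference_scaffold("1B")
#' @export
reference_scaffold <- function(case = c("1A", "1B", "1C", "2"), scale = 1) {
  case <- match.arg(case)
  if (case == "2") {
    scaffold_spec(
      kind = "graded_ring",
      dimensions = c(31 * scale, 26.7 * scale, 3.1),
      n_layers = 10,
      fibre_diameter = 0.33,
      pore_sizes = c(0.476, 0.629, 0.670, 0.730, 0.803, 0.979),
      layer_pitch = 0.31
    )
  } else {
    pore <- switch(case, "1A" = 0.300, "1B" = 0.350, "1C" = 0.45)
    scaffold_spec(
      kind = "rectangular",
      dimensions = c(20 * scale, 20 * scale, 3.1),
      n_layers = 10,
      fibre_diameter = 0.33,
      pore_sizes = pore,
      layer_pitch = 0.31
    )
  }
}
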