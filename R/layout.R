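#' Specification of a square tethering-nanospot lattice
#'
#' The tethering chip carries PEG-lipid brush spots on a square lattice. The
#' default pitch of 1414 nm reproduces the chip's printed areal density of
#' 5.0e5 spots/mm^2 (density = (1e6 / pitch_nm)^2 per mm^2); spot diameter
#' defaults to 200 nm, brush heights to 2-3 nm per spot.
#'
#' @param field_width_nm,field_height_nm scanned field size in nm.
#' @param pitch_nm centre-to-centre spot spacing in nm.
#' @param spot_diameter_nm spot diameter in nm.
#' @param brush_height_low_nm,brush_height_high_nm bounds of the per-spot
#'   brush height (drawn uniformly, one height per spot).
#' @param lattice lattice type; only `"square"` is supported.
#' @return An object of class `layout_spec`.
#' @export
layout_spec <- function(field_width_nm = 5000, field_height_nm = 5000,
                        pitch_nm = 1414, spot_diameter_nm = 200,
                        brush_height_low_nm = 2, brush_height_high_nm = 3,
                        lattice = "square") {
  lattice <- match.arg(lattice, "square")
  lens <- c(field_width_nm, field_height_nm, pitch_nm, spot_diameter_nm)
  if (!all(is.finite(lens)) || any(lens <= 0))
    stop("all layout lengths must be positive and finite")
  if (pitch_nm < spot_diameter_nm)
    stop("pitch_nm must be >= spot_diameter_nm (non-overlapping spots)")
  stopifnot(brush_height_low_nm > 0,
            brush_height_high_nm >= brush_height_low_nm)
  structure(list(field_width_nm = field_width_nm,
                 field_height_nm = field_height_nm,
                 pitch_nm = pitch_nm,
                 spot_diameter_nm = spot_diameter_nm,
                 brush_height_low_nm = brush_height_low_nm,
                 brush_height_high_nm = brush_height_high_nm,
                 lattice = lattice),
            class = "layout_spec")
}

#' Areal spot density of a layout
#'
#' @param spec a [layout_spec()] or a pitch in nm.
#' @return Density in spots per mm^2, `(1e6 / pitch_nm)^2`.
#' @export
spot_density <- function(spec) {
  pitch <- if (inherits(spec, "layout_spec")) spec$pitch_nm else spec
  (1e6 / pitch)^2
}

#' Build a nanospot layout (lattice of spot centres with brush heights)
#'
#' Spot centres tile the field at the given pitch, the first centre at
#' (pitch/2, pitch/2); a spot is included when its centre fits the lattice,
#' i.e. there are `floor(field / pitch)` spots per side. Brush heights are
#' drawn uniformly in `[low, high]`, one value per spot.
#'
#' @param spec a [layout_spec()].
#' @param seed integer seed for the brush-height draw.
#' @return A `nanospot_layout`: a data.frame with columns `spot_id`, `x_nm`,
#'   `y_nm`, `diameter_nm`, `brush_height_nm` and the spec stored as
#'   attribute `"spec"`.
#' @export
make_layout <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "layout_spec"))
  nx <- floor(spec$field_width_nm / spec$pitch_nm)
  ny <- floor(spec$field_height_nm / spec$pitch_nm)
  if (nx < 1 || ny < 1)
    stop("field smaller than one pitch: no spots fit the layout")
  cx <- (seq_len(nx) - 0.5) * spec$pitch_nm
  cy <- (seq_len(ny) - 0.5) * spec$pitch_nm
  g <- expand.grid(x_nm = cx, y_nm = cy, KEEP.OUT.ATTRS = FALSE)
  set.seed(derive_seed(seed, "brush_heights"))
  out <- data.frame(spot_id = seq_len(nrow(g)),
                    x_nm = g$x_nm, y_nm = g$y_nm,
                    diameter_nm = spec$spot_diameter_nm,
                    brush_height_nm = runif(nrow(g),
                                            spec$brush_height_low_nm,
                                            spec$brush_height_high_nm))
  structure(out, spec = spec, seed = as.integer(seed),
            class = c("nanospot_layout", "data.frame"))
}

#' @export
print.nanospot_layout <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("Nanospot layout: %d spots, pitch %.4g nm, spot diameter %.4g nm\n",
              nrow(x), spec$pitch_nm, spec$spot_diameter_nm))
  cat(sprintf("  field %.4g x %.4g nm, density %.4g spots/mm^2\n",
              spec$field_width_nm, spec$field_height_nm, spot_density(spec)))
  NextMethod()
}

#' Write / read a nanospot layout CSV
#'
#' Columns: `spot_id, x_nm, y_nm, diameter_nm, brush_height_nm`.
#'
#' @param layout a `nanospot_layout` (or compatible data.frame).
#' @param path file path.
#' @return `read_layout` returns the layout data.frame.
#' @export
write_layout <- function(layout, path) {
  write.csv(as.data.frame(layout)[, c("spot_id", "x_nm", "y_nm",
                                      "diameter_nm", "brush_height_nm")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  df <- read.csv(path)
  need <- c("spot_id", "x_nm", "y_nm", "diameter_nm", "brush_height_nm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("layout CSV missing columns: ",
                         paste(miss, collapse = ", "))
  class(df) <- c("nanospot_layout", "data.frame")
  df
}
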