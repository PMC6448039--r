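#' Surface electrode array layout
#'
#' Coordinates of the seven recording electrodes on a generic 2 mm x 2 mm
#' map of the dorsal column nuclei surface. x is lateral (positive = right
#' of the midline), y is rostro-caudal (positive = rostral), both in mm.
#' e3, e4, e5 sit on the midline (x = 0) with e4 at the map center; e1/e2
#' lie left and e6/e7 right at x = +/-0.82 mm (0.47 mm medial-edge gap plus
#' the 0.35 mm electrode radius). The lateral electrodes are staggered
#' between the midline ones: e1/e6 rostral, e2/e7 caudal.
#'
#' @param lateral_x Lateral electrode center offset from the midline (mm).
#' @param midline_spacing Rostro-caudal spacing of e3/e4/e5 (mm).
#' @param diameter Electrode diameter (mm).
#' @return A data frame with columns `electrode`, `x`, `y`, `diameter`.
#' @export
electrode_layout <- function(lateral_x = 0.82, midline_spacing = 0.75,
                             diameter = 0.7) {
  data.frame(
    electrode = 1:7,
    x = c(-lateral_x, -lateral_x, 0, 0, 0, lateral_x, lateral_x),
    y = c(midline_spacing / 2, -midline_spacing / 2,
          midline_spacing, 0, -midline_spacing,
          midline_spacing / 2, -midline_spacing / 2),
    diameter = diameter
  )
}
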