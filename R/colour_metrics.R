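#' Tetrahedral colour-space vertices
#'
#' Explicit vertex coordinates (rows uv, sw, mw, lw) of a regular
#' tetrahedron centred on the achromatic origin with vertex distance 0.75
#' — the usual convention for avian tetracolour space. Shipped explicitly
#' so saturation values are reproducible bit for bit; comparisons are
#' invariant to the convention up to a global scale.
#'
#' @param vertex_distance distance of each vertex from the origin.
#' @return 4 x 3 matrix of vertex coordinates.
#' @export
tetra_vertices <- function(vertex_distance = 0.75) {
  r <- vertex_distance
  # apex on +z for uv; the other three at z = -r/3 spaced 120 degrees
  rho <- r * sqrt(8) / 3
  ang <- c(90, 210, 330) * pi / 180
  v <- rbind(uv = c(0, 0, r),
             sw = c(rho * cos(ang[1]), rho * sin(ang[1]), -r / 3),
             mw = c(rho * cos(ang[2]), rho * sin(ang[2]), -r / 3),
             lw = c(rho * cos(ang[3]), rho * sin(ang[3]), -r / 3))
  colnames(v) <- c("x", "y", "z")
  v
}

#' Relative single-cone catches
#'
#' The four single-cone catches divided by their sum (double cone excluded):
#' the coordinates of the stimulus on the chromaticity simplex. Invariant to
#' overall intensity.
#'
#' @param q a `quantum_catch_set` or named numeric with uv, sw, mw, lw.
#' @return Named numeric (uv, sw, mw, lw) summing to 1.
#' @export
relative_catches <- function(q) {
  q4 <- unclass(q)[c("uv", "sw", "mw", "lw")]
  if (any(!is.finite(q4)) || any(q4 < 0))
    stop("catches must be finite and nonnegative", call. = FALSE)
  s <- sum(q4)
  if (s <= 0)
    stop("degenerate stimulus: all chromatic catches are zero", call. = FALSE)
  q4 / s
}

#' Map relative catches into tetrahedral colour space
#'
#' The convex combination `sum(rel_i * v_i)` of the tetrahedron vertices:
#' equal stimulation of all four cones lands on the achromatic origin, pure
#' stimulation of one cone on its vertex.
#'
#' @param rel four nonnegative reals summing to 1 (uv, sw, mw, lw order).
#' @param vertices vertex matrix from [tetra_vertices()].
#' @return Named numeric (x, y, z).
#' @export
tetra_coords <- function(rel, vertices = tetra_vertices()) {
  if (length(rel) != 4 || any(rel < -1e-12) || abs(sum(rel) - 1) > 1e-9)
    stop("rel must be 4 nonnegative values summing to 1", call. = FALSE)
  drop(crossprod(vertices, as.numeric(rel)))
}

#' Saturation: distance from the achromatic point
#'
#' The Euclidean distance of the stimulus from the achromatic grey point in
#' tetrahedral colour space. Larger values are more saturated colours; an
#' achromatic stimulus (equal relative catches) scores 0 and a pure-vertex
#' stimulus scores the vertex distance (0.75 by default).
#'
#' @inheritParams relative_catches
#' @param vertices vertex matrix from [tetra_vertices()].
#' @export
saturation <- function(q, vertices = tetra_vertices()) {
  sqrt(sum(tetra_coords(relative_catches(q), vertices)^2))
}

#' Opponent hue ratio: long versus short wavelengths
#'
#' `((lw + mw) - (sw + uv)) / (lw + mw + sw + uv)`: positive when the
#' stimulus drives the long-wavelength side of the spectrum more. Used when
#' no particular colour direction is expected (achromatic background
#' experiments).
#'
#' @inheritParams relative_catches
#' @return Value in [-1, 1].
#' @export
hue_longshort <- function(q) {
  q4 <- unclass(q)[c("uv", "sw", "mw", "lw")]
  s <- sum(q4)
  if (s <= 0)
    stop("degenerate stimulus: zero chromatic catch", call. = FALSE)
  ((q4[["lw"]] + q4[["mw"]]) - (q4[["sw"]] + q4[["uv"]])) / s
}

#' Opponent hue ratio: red versus blue
#'
#' `(lw - sw) / (lw + sw)`: higher values mean a relatively red stimulus,
#' lower values relatively blue. Used when backgrounds differ along the
#' red--blue axis.
#'
#' @inheritParams relative_catches
#' @return Value in [-1, 1].
#' @export
hue_redblue <- function(q) {
  q2 <- unclass(q)[c("lw", "sw")]
  s <- sum(q2)
  if (s <= 0)
    stop("degenerate stimulus: lw + sw is zero", call. = FALSE)
  (q2[["lw"]] - q2[["sw"]]) / s
}

#' Double-cone luminance
#'
#' Perceived lightness for the avian receiver: the double-cone quantum
#' catch, unchanged (1.0 = a perfect reflector). Not intensity-invariant,
#' unlike the chromatic metrics.
#'
#' @param q a `quantum_catch_set` with a `dbl` component.
#' @export
luminance <- function(q) {
  unname(unclass(q)[["dbl"]])
}
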