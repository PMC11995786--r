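# Shared temporal interpolation helper.
#
# Interpolating cubic spline (natural boundary conditions, zero smoothing:
# knot values are reproduced exactly). With fewer than 4 knots the order
# reduces automatically (2 or 3 knots -> the natural spline degenerates
# towards a line / low-order polynomial; 1 knot -> constant). Outside the
# knot range the value is held constant at the nearest knot.
interp_knots <- function(x, y, xout) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  if (length(x) == 1L) return(rep(y, length.out = length(xout)))
  o <- order(x)
  x <- x[o]; y <- y[o]
  xout <- pmin(pmax(xout, x[1L]), x[length(x)])
  stats::splinefun(x, y, method = "natural")(xout)
}
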