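#' Radionuclide physical decay
#'
#' Constructs a decay descriptor holding the physical half-life and the
#' corresponding decay constant \eqn{\lambda_{phys} = \ln(2)/T_{1/2}}.
#' All catalog functions contain the physical decay as an explicit factor,
#' so fitted \eqn{\lambda_i} are biological clearance rates.
#'
#' @param half_life_h Physical half-life in hours. Must be > 0.
#' @return An object of class `radionuclide`: a list with `half_life_h`
#'   and `lambda_phys` (1/h).
#' @examples
#' lu177()$lambda_phys
#' radionuclide(half_life_h = 6.0)  # e.g. Ga-68 would be ~1.13 h instead
#' @export
radionuclide <- function(half_life_h) {
  if (!is.numeric(half_life_h) || length(half_life_h) != 1L ||
      !is.finite(half_life_h) || half_life_h <= 0) {
    rlang::abort("`half_life_h` must be a single positive number.")
  }
  structure(
    list(half_life_h = half_life_h, lambda_phys = log(2) / half_life_h),
    class = "radionuclide"
  )
}

#' @rdname radionuclide
#' @details `lu177()` returns the default Lu-177 decay used throughout:
#'   half-life 6.647 d = 159.528 h.
#' @export
lu177 <- function() radionuclide(half_life_h = 6.647 * 24)

#' @export
print.radionuclide <- function(x, ...) {
  cat(sprintf("<radionuclide> T1/2 = %.4g h, lambda_phys = %.6g /h\n",
              x$half_life_h, x$lambda_phys))
  invisible(x)
}

as_decay <- function(decay) {
  if (inherits(decay, "radionuclide")) return(decay)
  if (is.numeric(decay) && length(decay) == 1L) return(radionuclide(decay))
  rlang::abort("`decay` must be a <radionuclide> object (see `radionuclide()`).")
}
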