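#' Running-wheel geometry
#'
#' Describes the wheel that generated the switch-closure stream. One reed
#' switch closure corresponds to one full revolution, so the circumference is
#' the distance travelled per closure. The default diameter is the 11.5-cm
#' wheel used for mouse home-cage running.
#'
#' @param diameter_m Wheel diameter in meters. Default `0.115`.
#'
#' @return An object of class `wheel_geometry`: a list with `diameter_m` and
#'   the derived `circumference_m` (`pi * diameter_m`).
#' @examples
#' g <- wheel_geometry()
#' g$circumference_m # 0.3613...
#' @export
wheel_geometry <- function(diameter_m = 0.115) {
  if (!is.numeric(diameter_m) || length(diameter_m) != 1L || !is.finite(diameter_m) ||
      diameter_m <= 0) {
    stop("`diameter_m` must be a single positive number", call. = FALSE)
  }
  structure(
    list(diameter_m = diameter_m, circumference_m = pi * diameter_m),
    class = "wheel_geometry"
  )
}

#' @export
print.wheel_geometry <- function(x, ...) {
  cat(sprintf("<wheel_geometry> diameter %.4f m, circumference %.6f m\n",
              x$diameter_m, x$circumference_m))
  invisible(x)
}

#' Convert revolution counts to distance
#'
#' Each switch closure marks one revolution, so distance is
#' `revolutions * pi * diameter`.
#'
#' @param revolutions Non-negative revolution count(s); vectorized.
#' @param geometry A [wheel_geometry()].
#'
#' @return Distance in meters, same length as `revolutions`.
#' @examples
#' distance_from_revolutions(1000) # 361.28 m on the default wheel
#' @export
distance_from_revolutions <- function(revolutions, geometry = wheel_geometry()) {
  if (!inherits(geometry, "wheel_geometry")) {
    stop("`geometry` must be a wheel_geometry object", call. = FALSE)
  }
  if (!is.numeric(revolutions) || any(!is.finite(revolutions)) ||
      any(revolutions < 0)) {
    stop("`revolutions` must be finite and non-negative", call. = FALSE)
  }
  revolutions * geometry$circumference_m
}
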