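#' Parametric description of a helical flagellum
#'
#' The flagellum is a circular helix of amplitude \code{b}, pitch
#' \code{lambda}, filament (cross-section) radius \code{r} and
#' \code{n_turns} turns, so its axial extent is \code{L = n_turns * lambda}.
#' An optional taper rate \code{k_E > 0} makes the amplitude grow from zero
#' at the head junction as \code{b * (1 - exp(-(k_E x)^2))}, which is how a
#' rigid helical tail meets the motor axis; \code{taper_rate = 0} means an
#' untapered (constant-amplitude) helix.
#'
#' @param amplitude helix amplitude b (length units), > 0.
#' @param pitch helix pitch lambda (length units), > 0.
#' @param n_turns number of turns, > 0; need not be an integer.
#' @param radius filament cross-section radius r, 0 < r < amplitude.
#' @param taper_rate amplitude growth rate k_E (1/length); 0 = untapered.
#' @param chirality +1 for a right-handed helix, -1 for its mirror image
#'   through the x-z plane.
#' @param phase phase offset of the helix (radians).
#' @return An object of class \code{"filament_spec"}.
#' @examples
#' fl <- filament_spec(amplitude = 1, pitch = 8, n_turns = 2, radius = 1/16)
#' fl$L  # axial extent, = 16
#' @export
filament_spec <- function(amplitude, pitch, n_turns, radius,
                          taper_rate = 0, chirality = 1L, phase = 0) {
  stopifnot(is.numeric(amplitude), amplitude > 0,
            is.numeric(pitch), pitch > 0,
            is.numeric(n_turns), n_turns > 0,
            is.numeric(radius), radius > 0,
            is.numeric(taper_rate), taper_rate >= 0,
            chirality %in% c(-1L, 1L, -1, 1),
            is.numeric(phase))
  if (radius >= amplitude)
    stop("filament radius must be smaller than the helix amplitude")
  structure(list(
    b = amplitude, lambda = pitch, n_turns = n_turns, r = radius,
    k = 2 * pi / pitch, k_E = taper_rate,
    chirality = as.integer(sign(chirality)), phase = phase,
    L = n_turns * pitch), class = "filament_spec")
}

#' Spherical head of a model swimmer
#'
#' @param radius head radius R (length units), > 0.
#' @return An object of class \code{"head_spec"}.
#' @export
head_spec <- function(radius) {
  stopifnot(is.numeric(radius), radius > 0)
  structure(list(R = radius), class = "head_spec")
}

#' Head-plus-flagellum assembly
#'
#' Describes the model robotic bacterium: a spherical head with a helical
#' flagellum attached on the +x axis.  The flagellum centerline starts at
#' \code{x0 = R + gap} and the motor imposes a relative angular velocity
#' \code{motor_rate} (omega) between head and flagellum about the x axis,
#' \code{omega = Omega_head - Omega_flagellum}.
#'
#' @param head a \code{\link{head_spec}}.
#' @param filament a \code{\link{filament_spec}}.
#' @param gap axial clearance between head surface and the first centerline
#'   point (length units, default 0).
#' @param motor_rate motor angular rate omega (rad/time).
#' @param viscosity dynamic viscosity mu (force time / length^2), > 0.
#' @return An object of class \code{"assembly_spec"}.
#' @examples
#' asm <- assembly_spec(head_spec(2), filament_spec(1, 8, 2, 1/16))
#' @export
assembly_spec <- function(head, filament, gap = 0, motor_rate = 1,
                          viscosity = 1) {
  stopifnot(inherits(head, "head_spec"), inherits(filament, "filament_spec"),
            is.numeric(gap), gap >= 0,
            is.numeric(motor_rate), is.finite(motor_rate),
            is.numeric(viscosity), viscosity > 0)
  structure(list(head = head, filament = filament, gap = gap,
                 omega = motor_rate, mu = viscosity),
            class = "assembly_spec")
}

#' @export
print.filament_spec <- function(x, ...) {
  cat("Helical filament: b =", x$b, ", lambda =", x$lambda,
      ", turns =", x$n_turns, ", r =", x$r, "\n")
  cat("  axial length L =", x$L,
      if (x$k_E > 0) sprintf(", tapered (k_E = %g)", x$k_E) else ", untapered",
      ", chirality", ifelse(x$chirality > 0, "+1 (right-handed)", "-1"), "\n")
  invisible(x)
}

#' @export
print.head_spec <- function(x, ...) {
  cat("Spherical head: R =", x$R, "\n")
  invisible(x)
}

#' @export
print.assembly_spec <- function(x, ...) {
  cat("Swimmer assembly (head + flagellum), gap =", x$gap,
      ", omega =", x$omega, ", mu =", x$mu, "\n")
  print(x$head); print(x$filament)
  invisible(x)
}
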