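# Resistive force theory: local drag models for slender filaments.
# The force per unit length on a filament segment moving at velocity u is
# df = [C_T t t^T + C_N (I - t t^T)] u ds, with tangential and normal
# coefficients depending logarithmically on the slenderness.

#' RFT drag coefficients
#'
#' Builds the tangential/normal drag coefficient pair for a slender
#' filament of cross-section radius r in a fluid of viscosity mu:
#' \describe{
#'   \item{gray_hancock}{reference length q = pitch, with the classical
#'     coefficients \code{C_T = 2 pi mu / (log(2q/r) - 0.5)},
#'     \code{C_N = 4 pi mu / (log(2q/r) + 0.5)} (the pair used by the
#'     standard helical-propulsion simulators).}
#'   \item{lighthill}{q = 0.09 pitch with Lighthill's replacement
#'     expressions \code{C_T = 2 pi mu / log(2q/r)},
#'     \code{C_N = 4 pi mu / (log(2q/r) + 0.5)}.}
#' }
#' Logarithms are natural.  \code{swap_half = TRUE} moves the 0.5 terms of
#' the gray_hancock pair to the opposite coefficients (\code{C_T} with
#' +0.5, \code{C_N} with -0.5), a variant that circulates in parts of the
#' literature; it markedly overestimates the normal-to-tangential drag
#' ratio and is provided for comparison only.
#'
#' @param model_id "gray_hancock" or "lighthill".
#' @param pitch helix pitch lambda (sets the reference length q).
#' @param radius filament cross-section radius r.
#' @param mu viscosity.
#' @param swap_half alternative sign placement for gray_hancock.
#' @return An object of class \code{"drag_model"} with fields
#'   \code{C_T}, \code{C_N}, \code{q}, \code{mu}, \code{model_id}.
#' @examples
#' drag_coefficients("gray_hancock", pitch = 8, radius = 1/16)
#' @export
drag_coefficients <- function(model_id = c("gray_hancock", "lighthill"),
                              pitch, radius, mu = 1,
                              swap_half = FALSE) {
  model_id <- match.arg(model_id)
  stopifnot(pitch > 0, radius > 0, mu > 0)
  q <- if (model_id == "gray_hancock") pitch else 0.09 * pitch
  lg <- log(2 * q / radius)
  coef <- switch(model_id,
    gray_hancock = if (swap_half)
      c(CT = 2 * pi * mu / (lg + 0.5), CN = 4 * pi * mu / (lg - 0.5))
    else
      c(CT = 2 * pi * mu / (lg - 0.5), CN = 4 * pi * mu / (lg + 0.5)),
    lighthill = c(CT = 2 * pi * mu / lg, CN = 4 * pi * mu / (lg + 0.5)))
  if (!all(is.finite(coef)) || any(coef <= 0))
    stop("non-slender filament: log(2q/r) too small for the ", model_id,
         " coefficients (need 2q/r well above 1)")
  structure(list(model_id = model_id, C_T = unname(coef["CT"]),
                 C_N = unname(coef["CN"]), q = q, mu = mu),
            class = "drag_model")
}

#' @export
print.drag_model <- function(x, ...) {
  cat(sprintf("RFT drag model '%s': C_T = %.5g, C_N = %.5g (q = %g, mu = %g)\n",
              x$model_id, x$C_T, x$C_N, x$q, x$mu))
  invisible(x)
}

#' Filament resistance matrix under resistive force theory
#'
#' Integrates the local drag law over the helix centerline for the six
#' unit rigid motions and assembles the 6x6 resistance matrix.  The pole
#' is the axial midpoint of the filament projected on its axis, which is
#' the symmetry point at which the stroke-averaged matrix takes the
#' rotational-symmetry zero pattern.  The axial scalars are exposed as
#' \code{A} (drag), \code{B} (coupling) and \code{C} (torque) through
#' \code{\link{axial_coefficients}}.
#'
#' @param spec an untapered \code{\link{filament_spec}}.
#' @param model a \code{\link{drag_coefficients}} model.
#' @param n_segments quadrature segments, at least \code{16 * n_turns}.
#' @param phase helix phase.
#' @return A \code{resistance_matrix} with provenance \code{"rft"}.
#' @examples
#' fl <- filament_spec(1, 8, 2, 1/16)
#' gm <- drag_coefficients("gray_hancock", 8, 1/16)
#' axial_coefficients(filament_resistance_rft(fl, gm))
#' @export
filament_resistance_rft <- function(spec, model, n_segments = 64 * spec$n_turns,
                                    phase = spec$phase) {
  stopifnot(inherits(spec, "filament_spec"), inherits(model, "drag_model"))
  if (spec$k_E > 0)
    stop("tapered filaments are not supported under RFT; use the coupled solver")
  if (n_segments < 16 * spec$n_turns)
    stop("n_segments too small: need at least 16 per helix turn")
  fq <- helix_quadrature(spec, n_segments / spec$n_turns, phase, x0 = 0)
  pole <- c(spec$L / 2, 0, 0)
  r <- sweep(fq$points, 2, pole)
  CT <- model$C_T; CN <- model$C_N
  M <- matrix(0, 6, 6)
  n <- nrow(fq$points)
  for (j in seq_len(n)) {
    t <- fq$tangents[j, ]
    Dj <- CN * diag(3) + (CT - CN) * tcrossprod(t)   # local drag tensor
    Xr <- skew3(r[j, ])
    w <- fq$weights[j]
    M[1:3, 1:3] <- M[1:3, 1:3] + w * Dj
    M[1:3, 4:6] <- M[1:3, 4:6] - w * Dj %*% Xr
    M[4:6, 1:3] <- M[4:6, 1:3] + w * Xr %*% Dj
    M[4:6, 4:6] <- M[4:6, 4:6] - w * Xr %*% Dj %*% Xr
  }
  new_resistance_matrix(M, pole, model$mu, "rft")
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}
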