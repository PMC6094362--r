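# Force-free / torque-free swimming of the head + flagellum assembly.
# The motor imposes a relative rotation omega = Omega_head - Omega_flagellum
# about the x axis; requiring zero net viscous force and torque determines
# the swimming speed U and the head rotation rate Omega.

#' Closed-form resistance scalars of a sphere
#'
#' Stokes' law drag \code{A0 = 6 pi mu R} and rotational resistance
#' \code{C0 = 8 pi mu R^3} of an isolated sphere.
#'
#' @param R sphere radius.
#' @param mu viscosity.
#' @return Named list with \code{A0} and \code{C0}.
#' @export
sphere_coefficients <- function(R, mu = 1) {
  list(A0 = 6 * pi * mu * R, C0 = 8 * pi * mu * R^3)
}

new_swim_solution <- function(U, Omega, T_motor, omega, res_F, res_L,
                              method, coefficients) {
  structure(list(U = U, Omega = Omega, T_motor = T_motor, omega = omega,
                 residual_force = res_F, residual_torque = res_L,
                 method = method, coefficients = coefficients),
            class = "swim_solution")
}

#' @export
print.swim_solution <- function(x, ...) {
  cat(sprintf("Swim solution (%s): U = %.6g, Omega = %.6g, T_motor = %.6g (omega = %g)\n",
              x$method, x$U, x$Omega, x$T_motor, x$omega))
  cat(sprintf("  residuals: force %.3g, torque %.3g\n",
              x$residual_force, x$residual_torque))
  invisible(x)
}

#' Swimming speed under the additive approximation
#'
#' Purcell's additive approach: the assembly resistance is taken to be the
#' sum of the head scalars (A0, C0) and the isolated-flagellum axial
#' scalars (A, B, C).  Imposing zero net axial force and torque gives
#' \deqn{U = C0 B omega / ((C0+C)(A0+A) - B^2)}
#' and the head rotation rate Omega accordingly; the motor torque follows
#' from the head torque balance \code{T = C0 |Omega|}.
#'
#' @param A0,C0 head drag and torque coefficients (e.g. from
#'   \code{\link{sphere_coefficients}}).
#' @param A,B,C isolated-flagellum axial scalars (from
#'   \code{\link{axial_coefficients}} of a coupled-solver or RFT matrix).
#' @param omega motor rate.
#' @param method tag recorded in the solution (default "additive").
#' @return A \code{swim_solution}; residuals are identically zero because
#'   the 2x2 balance is solved in closed form.
#' @export
solve_additive <- function(A0, C0, A, B, C, omega, method = "additive") {
  A0 <- unname(A0); C0 <- unname(C0)
  A <- unname(A); B <- unname(B); C <- unname(C)
  den <- (C0 + C) * (A0 + A) - B^2
  if (!is.finite(den) || den <= 0)
    stop("degenerate coefficient set: (C0+C)(A0+A) - B^2 must be positive")
  U <- C0 * B * omega / den
  Omega <- (1 - (A0 + A) * C0 / den) * omega
  new_swim_solution(U, Omega, C0 * abs(Omega), omega, 0, 0, method,
                    list(A0 = A0, C0 = C0, A = A, B = B, C = C))
}

#' Swimming speed from the globally coupled hydrodynamics
#'
#' The "global approach": partwise resistance blocks (each part's
#' contribution computed in the presence of the other part held fixed)
#' replace the isolated-body scalars, so head-flagellum hydrodynamic
#' interactions are fully retained.  The axial momentum balance
#' \deqn{R [U; Omega] = [Bhat2; C2] omega}
#' is solved directly (and cross-checked against the closed form obtained
#' by eliminating Omega).  The motor torque is the axial viscous torque
#' integrated over the flagellum nodes of the solved flow.
#'
#' @param disc a labeled assembly \code{\link{discretization}} or a
#'   \code{function(phase)} returning one.
#' @param omega motor rate.
#' @param pole reference pole (head center by convention).
#' @param mu viscosity.
#' @param n_phase stroke-averaging phase count.
#' @param parts optional precomputed \code{\link{partwise_resistance}};
#'   when supplied together with a \code{discretization}, the dense system
#'   is still solved once more for the motor torque.
#' @param closed_form if TRUE, evaluate the eliminated closed form instead
#'   of the direct 2x2 solve (the two agree to machine precision).
#' @return A \code{swim_solution} with method "global"; the
#'   \code{coefficients} field carries the partwise scalars.
#' @export
solve_global <- function(disc, omega, pole = c(0, 0, 0), mu = 1,
                         n_phase = 1, parts = NULL, closed_form = FALSE) {
  if (is.null(parts)) parts <- partwise_resistance(disc, pole, mu, n_phase)
  sc <- as.list(parts$scalars)
  Bh <- sc$Bhat1 + sc$Bhat2
  Bb <- sc$Bbar1 + sc$Bbar2
  Rax <- matrix(c(sc$A1 + sc$A2, Bb, Bh, sc$C1 + sc$C2), 2, 2)
  rhs <- c(sc$Bhat2, sc$C2) * omega
  if (closed_form) {
    Csum <- sc$C1 + sc$C2; Asum <- sc$A1 + sc$A2
    den <- Csum * Asum - Bh * Bb
    U <- (Csum * sc$Bhat2 - Bh * sc$C2) * omega / den
    Omega <- (Asum * sc$C2 - Bb * sc$Bhat2) * omega / den
  } else {
    sol <- solve(Rax, rhs)
    U <- sol[1]; Omega <- sol[2]
  }
  res <- Rax %*% c(U, Omega) - rhs
  Tm <- NA_real_
  if (inherits(disc, "discretization") || is.function(disc)) {
    d <- if (is.function(disc)) disc(0) else disc
    Tm <- motor_torque(d, U, Omega, omega, pole, mu)
  }
  new_swim_solution(U, Omega, Tm, omega, abs(res[1]), abs(res[2]),
                    "global", parts$scalars)
}

# Axial viscous torque on the flagellum in the solved swimming state:
# head nodes move with (U e_x, Omega e_x), flagellum nodes with
# (U e_x, (Omega - omega) e_x).  The motor must supply the opposite of the
# viscous torque on the flagellum about the axis.
motor_torque <- function(disc, U, Omega, omega, pole, mu) {
  r <- sweep(disc$nodes, 2, pole)
  w_ax <- ifelse(disc$label == 1L, Omega, Omega - omega)
  vel <- cbind(U, -w_ax * r[, 3], w_ax * r[, 2])
  G <- stokes_matrix(disc, mu)
  f <- solve(G, as.numeric(t(vel)))
  n <- nrow(disc$nodes)
  fy <- f[seq(2, 3 * n, 3)] * disc$weight
  fz <- f[seq(3, 3 * n, 3)] * disc$weight
  lx <- r[, 2] * fz - r[, 3] * fy
  abs(sum(lx[disc$label == 2L]))
}

#' Instantaneous free-swimming rigid motion
#'
#' General phase-resolved solve: given the shape (gait) velocity of every
#' boundary node relative to the body frame, finds the instantaneous rigid
#' motion (6-vector) that annihilates the net viscous force and torque.
#' The collocation equations and the six zero-force/zero-torque
#' constraints are assembled into one augmented dense system.
#'
#' @param disc a \code{\link{discretization}}.
#' @param shape_velocity n x 3 matrix of nodal shape velocities (for the
#'   robotic swimmer: rigid rotation of the flagellum nodes at rate
#'   -omega about x relative to the head, zero on the head).
#' @param mu viscosity.
#' @param pole reference pole.
#' @return A list of class \code{"rigid_motion"} with \code{U} (3),
#'   \code{Omega} (3), \code{pole}, nodal \code{density}, and the force
#'   and torque \code{residual}s of the solved state.
#' @export
solve_free_swimming <- function(disc, shape_velocity, mu = 1,
                                pole = c(0, 0, 0)) {
  stopifnot(inherits(disc, "discretization"))
  shape_velocity <- as.matrix(shape_velocity)
  n <- nrow(disc$nodes)
  stopifnot(nrow(shape_velocity) == n, ncol(shape_velocity) == 3)
  G <- stokes_matrix(disc, mu)
  P <- rigid_velocity_basis(disc$nodes, pole)
  # constraint rows: weighted sums of densities (force, torque about pole)
  W <- t(P * rep(disc$weight, each = 3))
  Asys <- rbind(cbind(G, -P), cbind(W, matrix(0, 6, 6)))
  rhs <- c(as.numeric(t(shape_velocity)), rep(0, 6))
  sol <- solve(Asys, rhs)
  f <- sol[seq_len(3 * n)]
  rig <- sol[3 * n + 1:6]
  ft <- net_force_torque(disc, f, pole)
  structure(list(U = rig[1:3], Omega = rig[4:6], pole = pole,
                 density = matrix(f, ncol = 3, byrow = TRUE),
                 residual = as.numeric(ft)),
            class = "rigid_motion")
}

#' Integrate a rigid-body trajectory
#'
#' Advances position and orientation from a sequence of body-frame rigid
#' velocities held constant over each step.  The orientation is updated
#' with the exponential map (Rodrigues' rotation) and the position with
#' the midpoint rule, so a constant velocity pair with U not parallel to
#' Omega traces a circular helix of radius |U_perp| / |Omega|.
#'
#' @param U n x 3 matrix (or 3-vector recycled) of body-frame linear
#'   velocities per step.
#' @param Omega n x 3 matrix (or 3-vector) of body-frame angular
#'   velocities per step.
#' @param dt time step per increment (scalar or length n), > 0.
#' @param x0 initial position.
#' @return List with \code{positions} ((n+1) x 3) and \code{rotations}
#'   (list of n+1 rotation matrices, body to lab).
#' @export
integrate_trajectory <- function(U, Omega, dt, x0 = c(0, 0, 0)) {
  U <- matrix(U, ncol = 3, byrow = !is.matrix(U))
  Omega <- matrix(Omega, ncol = 3, byrow = !is.matrix(Omega))
  n <- max(nrow(U), nrow(Omega), length(dt))
  if (nrow(U) == 1) U <- U[rep(1, n), , drop = FALSE]
  if (nrow(Omega) == 1) Omega <- Omega[rep(1, n), , drop = FALSE]
  stopifnot(nrow(U) == n, nrow(Omega) == n)
  dt <- rep(dt, length.out = n)
  if (any(dt <= 0)) stop("time steps must be positive")
  pos <- matrix(0, n + 1, 3)
  pos[1, ] <- x0
  Rot <- vector("list", n + 1)
  Rot[[1]] <- diag(3)
  for (k in seq_len(n)) {
    Rhalf <- Rot[[k]] %*% rotation_exp(Omega[k, ] * dt[k] / 2)
    pos[k + 1, ] <- pos[k, ] + dt[k] * as.numeric(Rhalf %*% U[k, ])
    Rot[[k + 1]] <- Rot[[k]] %*% rotation_exp(Omega[k, ] * dt[k])
  }
  list(positions = pos, rotations = Rot)
}

# Rodrigues' formula: exp of the skew matrix of v.
rotation_exp <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-300) return(diag(3))
  K <- skew3(v / th)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}
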