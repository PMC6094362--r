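test_that("additive swimming solution follows the closed form", {
  # vanishing head: no torque balance to push against -> no translation
  sol0 <- solve_additive(A0 = 10, C0 = 0, A = 5, B = -2, C = 8, omega = 1)
  expect_equal(sol0$U, 0)
  # no coupling: pure counter-rotation, Omega = C/(C0+C) omega
  solB <- solve_additive(A0 = 10, C0 = 4, A = 5, B = 0, C = 8, omega = 2)
  expect_equal(solB$U, 0)
  expect_equal(solB$Omega, 8 / 12 * 2)
  expect_equal(solB$T_motor, 4 * abs(solB$Omega))
  # linearity in the motor rate
  s1 <- solve_additive(10, 4, 5, -2, 8, omega = 1)
  s3 <- solve_additive(10, 4, 5, -2, 8, omega = 3)
  expect_equal(s3$U, 3 * s1$U)
  expect_equal(s3$Omega, 3 * s1$Omega)
  expect_equal(s3$T_motor, 3 * s1$T_motor)
  expect_error(solve_additive(1, 1, 1, 10, 1, 1), "degenerate")
})

test_that("global solve degenerates to the additive one with isolated blocks", {
  A0 <- 12 * pi; C0 <- 64 * pi
  A <- 27.2; B <- -7.8; C <- 48.8
  fake <- structure(list(scalars = c(A1 = A0, A2 = A, Bhat1 = 0, Bhat2 = B,
                                     Bbar1 = 0, Bbar2 = B, C1 = C0, C2 = C)),
                    class = "partwise_resistance")
  g <- solve_global(NULL, omega = 1.3, parts = fake)
  a <- solve_additive(A0, C0, A, B, C, omega = 1.3)
  expect_equal(g$U, a$U, tolerance = 1e-12)
  expect_equal(g$Omega, a$Omega, tolerance = 1e-12)
  # direct 2x2 solve and eliminated closed form agree to machine precision
  g2 <- solve_global(NULL, omega = 1.3, parts = fake, closed_form = TRUE)
  expect_equal(g$U, g2$U, tolerance = 1e-14)
  expect_equal(g$Omega, g2$Omega, tolerance = 1e-14)
})

test_that("coupled swim solution balances forces and flips with chirality", {
  asm <- tiny_assembly()
  disc <- assemble(asm, nodes_per_turn = 16, n_head = 200)
  sol <- solve_global(disc, omega = 1)
  expect_lt(sol$residual_force, 1e-8)
  expect_lt(sol$residual_torque, 1e-8)
  expect_gt(sol$T_motor, 0)
  # mirrored helix swims the other way at the same rotation magnitude
  asm_m <- assembly_spec(head_spec(2),
                         filament_spec(1, 8, 2, 1 / 16, chirality = -1))
  dm <- assemble(asm_m, nodes_per_turn = 16, n_head = 200)
  sm <- solve_global(dm, omega = 1)
  # the Fibonacci head layout is not exactly mirror symmetric, so the
  # sign flip holds to discretization accuracy
  expect_equal(sm$U, -sol$U, tolerance = 5e-3)
  expect_equal(sm$Omega, sol$Omega, tolerance = 5e-3)
  # linearity in omega
  s2 <- solve_global(disc, omega = 2)
  expect_equal(s2$U, 2 * sol$U, tolerance = 1e-10)
})

test_that("free-swimming solve honors uniqueness and matches the 2x2 path", {
  asm <- tiny_assembly()
  disc <- assemble(asm, nodes_per_turn = 16, n_head = 150)
  n <- nrow(disc$nodes)
  # zero gait -> no motion
  fs0 <- solve_free_swimming(disc, matrix(0, n, 3))
  expect_equal(max(abs(c(fs0$U, fs0$Omega))), 0, tolerance = 1e-10)
  # gait equal to a rigid motion is cancelled exactly
  rig <- cbind(0.3, -0.1, 0.2)[rep(1, n), ]
  fsr <- solve_free_swimming(disc, rig)
  expect_equal(fsr$U, -c(0.3, -0.1, 0.2), tolerance = 1e-8)
  expect_equal(fsr$Omega, c(0, 0, 0), tolerance = 1e-8)
  # rotation of the flagellum at -omega about x relative to the head
  omega <- 1
  sv <- matrix(0, n, 3)
  fl2 <- disc$label == 2L
  sv[fl2, 2] <- omega * disc$nodes[fl2, 3]
  sv[fl2, 3] <- -omega * disc$nodes[fl2, 2]
  fs <- solve_free_swimming(disc, sv)
  expect_lt(max(abs(fs$residual)), 1e-9)
  g <- solve_global(disc, omega = omega)
  expect_equal(fs$U[1], g$U, tolerance = 0.02)
  expect_equal(fs$Omega[1], g$Omega, tolerance = 0.02)
})

test_that("trajectory integration follows rigid-body kinematics", {
  # pure translation
  tr <- integrate_trajectory(c(1, 0, 0), c(0, 0, 0), dt = rep(1, 10))
  expect_equal(tr$positions[11, ], c(10, 0, 0))
  # constant U with transverse component + spin about x: circular helix of
  # radius |U_perp|/|Omega| and pitch 2 pi U_par/|Omega|
  nstep <- 2000
  tr2 <- integrate_trajectory(matrix(c(1, 0.1, 0), nstep, 3, byrow = TRUE),
                              matrix(c(1, 0, 0), nstep, 3, byrow = TRUE),
                              dt = rep(4 * pi / nstep, nstep))
  p <- tr2$positions
  rad <- sqrt((p[, 2] - mean(range(p[, 2])))^2 +
              (p[, 3] - mean(range(p[, 3])))^2)
  expect_equal(max(rad), 0.1, tolerance = 0.01)
  expect_equal(p[nstep + 1, 1], 4 * pi, tolerance = 1e-6)
  expect_error(integrate_trajectory(c(1, 0, 0), c(0, 0, 0), dt = 0),
               "positive")
})

test_that("composite swimmer traces a helical trajectory", {
  asm <- assembly_spec(head_spec(1),
                       filament_spec(1.27, 8, 1.5, 0.2, taper_rate = 1))
  disc <- assemble(asm, nodes_per_turn = 10, n_head = 100)
  n <- nrow(disc$nodes)
  phases <- seq(0, 2 * pi, length.out = 9)[-9]
  mo <- lapply(phases, function(ph) {
    d <- assemble(asm, nodes_per_turn = 10, n_head = 100, phase = ph)
    sv <- matrix(0, n, 3)
    fl2 <- d$label == 2L
    sv[fl2, 2] <- d$nodes[fl2, 3]
    sv[fl2, 3] <- -d$nodes[fl2, 2]
    solve_free_swimming(d, sv)
  })
  U <- t(vapply(mo, `[[`, numeric(3), "U"))
  W <- t(vapply(mo, `[[`, numeric(3), "Omega"))
  tr <- integrate_trajectory(U[rep(1:8, 4), ], W[rep(1:8, 4), ],
                             dt = rep(2 * pi / 8, 32))
  p <- tr$positions
  # net axial progress with bounded transverse wobble: a helix-like path
  expect_gt(abs(p[33, 1] - p[1, 1]), 5 * max(abs(p[, 2]), abs(p[, 3])))
  expect_gt(max(abs(p[, 2])), 0)
})
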