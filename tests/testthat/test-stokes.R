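test_that("regularized kernel reduces to the Oseen tensor and is finite", {
  S <- stokeslet_kernel(c(2, 0, 0), c(0, 0, 0))
  expect_equal(S[1, 1], 1 / (8 * pi))
  expect_equal(S, t(S))
  expect_equal(stokeslet_kernel(c(0, 1, 2), c(3, -1, 0)),
               stokeslet_kernel(c(3, -1, 0), c(0, 1, 2)))
  Sself <- stokeslet_kernel(c(1, 1, 1), c(1, 1, 1), eps = 0.1)
  expect_equal(Sself, diag(3) / (4 * pi * 0.1))
  expect_error(stokeslet_kernel(c(1, 1, 1), c(1, 1, 1)), "singular")
})

test_that("sphere solves reproduce Stokes' law and transport identities", {
  d <- sphere_nodes(head_spec(1), 400)
  n <- nrow(d$nodes)
  sol <- solve_boundary_velocities(d, matrix(rep(c(1, 0, 0), each = n), n))
  expect_equal(sol$force[1], 6 * pi, tolerance = 0.01)
  # transverse components vanish up to the slight asymmetry of the layout
  expect_lt(max(abs(sol$force[2:3])), 1e-3 * sol$force[1])
  # zero velocity -> zero everything
  z <- solve_boundary_velocities(d, matrix(0, n, 3))
  expect_equal(max(abs(z$density)), 0, tolerance = 1e-12)
  # torque transport: L(pole') = L(pole) - delta x F
  delta <- c(0.3, -0.2, 0.5)
  s1 <- solve_boundary_velocities(d, matrix(rep(c(0, 1, 0), each = n), n),
                                  pole = c(0, 0, 0))
  s2 <- solve_boundary_velocities(d, matrix(rep(c(0, 1, 0), each = n), n),
                                  pole = delta)
  expect_equal(s2$torque,
               s1$torque - c(delta[2] * s1$force[3] - delta[3] * s1$force[2],
                             delta[3] * s1$force[1] - delta[1] * s1$force[3],
                             delta[1] * s1$force[2] - delta[2] * s1$force[1]),
               tolerance = 1e-8)
})

test_that("sphere resistance matrix matches closed forms at calibration", {
  rm6 <- resistance_matrix(sphere_nodes(head_spec(1), 600))
  M <- rm6$matrix
  expect_equal(diag(M)[1:3], rep(6 * pi, 3), tolerance = 0.01)
  expect_equal(diag(M)[4:6], rep(8 * pi, 3), tolerance = 0.01)
  expect_lt(norm(M - t(M), "F") / norm(M, "F"), 1e-3)
  # scale invariance of the calibration
  rm2 <- resistance_matrix(sphere_nodes(head_spec(2), 600))
  expect_equal(rm2$matrix[1, 1], 12 * pi, tolerance = 0.01)
  expect_equal(rm2$matrix[4, 4], 64 * pi, tolerance = 0.01)
})

test_that("partwise blocks sum exactly and share the coupling sum", {
  disc <- assemble(tiny_assembly(), nodes_per_turn = 16, n_head = 200)
  parts <- partwise_resistance(disc)
  whole <- resistance_matrix(disc)
  expect_equal(parts$R1$matrix + parts$R2$matrix, parts$total$matrix,
               tolerance = 1e-12)
  expect_equal(parts$total$matrix, whole$matrix, tolerance = 1e-9)
  sc <- parts$scalars
  expect_equal(sc[["Bhat1"]] + sc[["Bhat2"]],
               sc[["Bbar1"]] + sc[["Bbar2"]], tolerance = 0.01)
  # the whole assembly matrix is symmetric; the parts are not
  Mt <- parts$total$matrix
  expect_lt(norm(Mt - t(Mt), "F") / norm(Mt, "F"), 1e-3)
  M1 <- parts$R1$matrix
  expect_gt(norm(M1 - t(M1), "F") / norm(M1, "F"), 1e-3)
  # grand resistance positive definite
  ev <- eigen((Mt + t(Mt)) / 2, only.values = TRUE)$values
  expect_true(all(ev > 0))
})

test_that("widely separated parts decouple to isolated matrices", {
  asm <- assembly_spec(head_spec(2), filament_spec(1, 8, 2, 1 / 16),
                       gap = 100)
  disc <- assemble(asm, nodes_per_turn = 16, n_head = 200)
  parts <- partwise_resistance(disc)
  iso_head <- resistance_matrix(sphere_nodes(head_spec(2), 200))
  expect_equal(parts$scalars[["A1"]], iso_head$matrix[1, 1],
               tolerance = 0.02)
  expect_equal(parts$scalars[["C1"]], iso_head$matrix[4, 4],
               tolerance = 0.02)
  fl <- asm$filament
  iso_fl <- axial_coefficients(isolated_helix_matrix(fl, 16))
  # residual interaction decays like 3 R_head / (2 d) ~ 3 percent here
  expect_equal(parts$scalars[["A2"]], iso_fl[["A"]], tolerance = 0.035)
  expect_equal(parts$scalars[["C2"]], iso_fl[["C"]], tolerance = 0.035)
})

test_that("two-sphere screening matches the exact and far-field solutions", {
  # independent anchor: classical contact value of the bispherical series
  expect_equal(two_sphere_exact(1, 2.0001), 0.6451, tolerance = 2e-3)
  expect_equal(two_sphere_exact(1, 500), 1, tolerance = 3e-3)
  # reflections estimate against its hand-derived series
  for (rho in c(2.5, 4, 8))
    expect_equal(two_sphere_reflections(1, rho),
                 oracle_two_sphere_reflections(1, rho), tolerance = 1e-12)
  rhos <- c(2.2, 3, 4, 8)
  ratios <- vapply(rhos, function(r) {
    ts <- two_sphere_benchmark(1, r, n_nodes = 300)
    ts$drag / ts$isolated
  }, numeric(1))
  # screening: below the isolated drag, rising monotonically with rho
  expect_true(all(ratios < 1))
  expect_true(all(diff(ratios) > 0))
  # solver agrees with the exact bispherical solution to 1%
  for (i in seq_along(rhos))
    expect_equal(ratios[i], two_sphere_exact(1, rhos[i]), tolerance = 0.01)
  # far-field reflections estimate is adequate from moderate separations
  for (i in which(rhos >= 3))
    expect_equal(ratios[i], two_sphere_reflections(1, rhos[i]),
                 tolerance = 0.03)
  # reciprocal problem: velocity under total force 2 Fbar
  ts <- two_sphere_benchmark(1, 3, Fbar = 6 * pi, n_nodes = 300)
  expect_equal(ts$velocity, 1 / (ts$drag / (6 * pi)), tolerance = 1e-6)
  expect_error(two_sphere_benchmark(1, 1.9), "overlap")
})

test_that("helix resistance grows with length and converges on refinement", {
  abc <- sapply(1:3, function(nt)
    axial_coefficients(isolated_helix_matrix(
      filament_spec(1, 2.42, nt, 1 / 16), 24)))
  expect_true(all(diff(abc["A", ]) > 0))
  expect_true(all(diff(-abc["B", ]) > 0))
  expect_true(all(diff(abc["C", ]) > 0))
  fl <- filament_spec(1, 8, 2, 1 / 16)
  a1 <- axial_coefficients(isolated_helix_matrix(fl, 32))
  a2 <- axial_coefficients(isolated_helix_matrix(fl, 64))
  expect_equal(a1, a2, tolerance = 0.01)
})

test_that("stroke-averaged helix matrix takes the rotational-symmetry pattern", {
  fl <- filament_spec(1, 2.42, 3, 1 / 16)
  hm <- isolated_helix_matrix(fl, 24, n_phase = 8)
  M <- hm$matrix
  zero_mask <- matrix(FALSE, 6, 6)
  zero_mask[c(2, 3, 5, 6), c(1, 4)] <- TRUE
  zero_mask[c(1, 4), c(2, 3, 5, 6)] <- TRUE
  zero_mask[2, 3] <- zero_mask[3, 2] <- TRUE
  zero_mask[5, 6] <- zero_mask[6, 5] <- TRUE
  expect_lt(max(abs(M[zero_mask])) / norm(M, "F"), 1e-6)
  # transverse isotropy after averaging
  expect_equal(M[2, 2], M[3, 3], tolerance = 1e-8)
  expect_equal(M[5, 5], M[6, 6], tolerance = 1e-8)
})

test_that("calibration routines reproduce the packaged constants", {
  expect_equal(calibrate_head_eps_factor(600), microswim_eps_factor(),
               tolerance = 1e-4)
})
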