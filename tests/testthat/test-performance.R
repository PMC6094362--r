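test_that("correcting factor is unity for isolated blocks and geometry-only", {
  A0 <- 12 * pi; A <- 27.2; B <- -7.8
  iso_parts <- c(A1 = A0, A2 = A, Bhat1 = 0, Bhat2 = B,
                 Bbar1 = 0, Bbar2 = B)
  expect_equal(correction_factor(A0, A, B, iso_parts), 1)
  expect_error(correction_factor(A0, A, 0, iso_parts), "degenerate")
  # rescaling mu scales every resistance coefficient linearly: upsilon
  # is invariant (it depends on geometry only)
  parts <- c(A1 = 31.8, A2 = 18.8, Bhat1 = 0.13, Bhat2 = -5.45,
             Bbar1 = 3.1, Bbar2 = -8.43)
  u1 <- correction_factor(A0, A, B, parts)
  u2 <- correction_factor(3 * A0, 3 * A, 3 * B, 3 * parts)
  expect_equal(u1, u2, tolerance = 1e-12)
})

test_that("additive efficiency closed forms equal their definitions", {
  A0 <- 12 * pi; C0 <- 64 * pi
  A <- 27.2; B <- -7.8; C <- 48.8; omega <- 1.7
  sol <- solve_additive(A0, C0, A, B, C, omega)
  eff <- efficiencies(sol, A0, C0, A, B, C, parts = NULL, omega = omega)
  # with the additive solution and T_motor = C0 Omega, the global-variant
  # formulas reduce algebraically to the additive closed forms
  expect_equal(eff$global, eff$additive, tolerance = 1e-10)
  expect_equal(eff$corrected, eff$additive, tolerance = 1e-12)  # upsilon=1
  # identities that hold for any solution
  expect_equal(eff$global[eff$measure == "eta_pr2"], sol$U / omega)
  expect_equal(eff$global[eff$measure == "w"],
               1 / eff$global[eff$measure == "eta_sw"], tolerance = 1e-10)
  expect_equal(attr(eff, "upsilon"), 1)
})

test_that("efficiencies scale with the motor rate as their definitions say", {
  A0 <- 12 * pi; C0 <- 64 * pi; A <- 27.2; B <- -7.8; C <- 48.8
  e1 <- efficiencies(solve_additive(A0, C0, A, B, C, 1),
                     A0, C0, A, B, C, omega = 1)
  e2 <- efficiencies(solve_additive(A0, C0, A, B, C, 2),
                     A0, C0, A, B, C, omega = 2)
  dimless <- c("eta_en1", "eta_en2", "eta_pr1", "eta_pr2")
  for (m in dimless)
    expect_equal(e2$global[e2$measure == m], e1$global[e1$measure == m],
                 tolerance = 1e-12)
  expect_equal(e2$global[e2$measure == "eta_sw"],
               e1$global[e1$measure == "eta_sw"] / 2, tolerance = 1e-12)
  expect_equal(e2$global[e2$measure == "w"],
               e1$global[e1$measure == "w"] * 2, tolerance = 1e-12)
})

test_that("a propeller without coupling yields zero useful output", {
  sol <- solve_additive(10, 4, 5, 0, 8, 1)
  eff <- efficiencies(sol, 10, 4, 5, 0, 8, parts = NULL, omega = 1)
  for (m in c("eta_en1", "eta_pr2", "eta_sw"))
    expect_equal(eff$global[eff$measure == m], 0)
  expect_identical(eff$global[eff$measure == "w"], Inf)
})

test_that("length sweep produces one labeled row per method and point", {
  asm <- helix_family_assembly(2)
  sw <- sweep_lengths(asm, c(2, 3), nodes_per_turn = 12, n_head = 120)
  expect_equal(nrow(sw), 6)
  expect_setequal(unique(sw$method), c("global", "additive", "corrected"))
  expect_true(all(c("U", "Omega", "T_motor", "upsilon", "eta_en1",
                    "eta_sw", "w", "A_sum", "B_sum") %in% names(sw)))
  # corrected speed is upsilon times the additive speed
  g2 <- sw[sw$n_turns == 2, ]
  expect_equal(g2$U[g2$method == "corrected"],
               g2$upsilon[1] * g2$U[g2$method == "additive"],
               tolerance = 1e-12)
  # a failing grid point is dropped with a warning, the sweep continues
  expect_warning(sw2 <- sweep_lengths(asm, c(-1, 2), nodes_per_turn = 12,
                                      n_head = 120), "failed")
  expect_equal(unique(sw2$n_turns), 2)
})

test_that("length optimizer recovers analytic optima and flags boundaries", {
  # synthetic concave metric with a known maximizer
  opt <- optimize_length(metric_fn = function(nt) 5 - (nt - 7.3)^2,
                         bracket = c(1, 20), n_grid = 8, tol = 1e-4)
  expect_true(opt$interior)
  expect_equal(opt$n_turns, 7.3, tolerance = 1e-3)
  # monotone metric: boundary returned with the no-interior-optimum flag
  mono <- optimize_length(metric_fn = function(nt) nt,
                          bracket = c(1, 20), n_grid = 6)
  expect_false(mono$interior)
  expect_equal(mono$n_turns, 20)
})
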