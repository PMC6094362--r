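# Independent oracles and small builders shared across the test files.

# Closed-form slender-helix RFT scalars, derived independently of the
# package's quadrature: for a uniform helix of amplitude b, axial length L
# and wavenumber k, with beta = b k, pitch angle cos(theta) =
# 1/sqrt(1+beta^2) and contour length Lambda = L sqrt(1+beta^2),
#   A = Lambda (C_T cos^2 + C_N sin^2)
#   B = s Lambda (C_T - C_N) b sin cos        (s = chirality)
#   C = Lambda b^2 (C_N cos^2 + C_T sin^2)
oracle_helix_rft <- function(b, lambda, n_turns, chirality, C_T, C_N) {
  k <- 2 * pi / lambda
  beta <- b * k
  c2 <- 1 / (1 + beta^2)
  s2 <- 1 - c2
  Lam <- n_turns * lambda * sqrt(1 + beta^2)
  c(A = Lam * (C_T * c2 + C_N * s2),
    B = chirality * Lam * (C_T - C_N) * b * sqrt(s2 * c2),
    C = Lam * b^2 * (C_N * c2 + C_T * s2))
}

# Method-of-reflections drag factor for two equal spheres translating
# together along their line of centers: each sphere is advected by the
# other's Stokeslet + source-doublet field with the Faxen curvature
# correction, and the mutual reflections sum as a geometric series:
#   lambda = 1 / (1 + 3R/(2 rho) - (R/rho)^3)
oracle_two_sphere_reflections <- function(R, rho) {
  beta <- R / rho
  1 / (1 + 1.5 * beta - beta^3)
}

# Low-resolution builders used where the test checks structure or a
# qualitative trend rather than a converged number.
tiny_assembly <- function(n_turns = 2, taper_rate = 0) {
  assembly_spec(head_spec(2),
                filament_spec(1, 8, n_turns, 1 / 16,
                              taper_rate = taper_rate))
}

helix_family_assembly <- function(n_turns) {
  assembly_spec(head_spec(2), filament_spec(1, 2.42, n_turns, 1 / 16))
}

isolated_helix_matrix <- function(fl, nodes_per_turn = 32, n_phase = 1) {
  gen <- function(ph) filament_discretization(fl, nodes_per_turn, ph, 0)
  resistance_matrix(if (n_phase > 1) gen else gen(0),
                    pole = c(fl$L / 2, 0, 0), n_phase = n_phase)
}
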