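# Shared toy systems for the test suite.  Everything is built in code;
# no stored fixtures beyond the packaged reference tables.

# gas-phase diatomic with a soft bond; the +0.36 A surrogate shift is
# ~2 sigma at 300 K, so both one- and two-sided reweighting converge at
# desk-scale sample sizes
soft_diatomic_spec <- function(k_b = 10, b0 = 1.153) {
  list(atoms = data.frame(mass = c(12, 12), charge = c(0.2, -0.2),
                          lj_epsilon = 0, lj_rmin_half = 1),
       bonds = data.frame(i = 1, j = 2, k_b = k_b, b0 = b0))
}

# MM / tailored MM' / surrogate-target trio built around the soft diatomic
surrogate_trio <- function(bond_shift = 0.36, morse = FALSE,
                           morse_depth = 50) {
  mm <- build_solute(soft_diatomic_spec(), seed = 1)
  tgt <- make_surrogate_target(mm, bond_shifts = bond_shift, morse = morse,
                               morse_depth = morse_depth)
  rep_ <- minimize_geometry(tgt, start = mm$frame0)
  mmp <- make_tailored_parameters(mm, rep_)
  list(mm = mm, tgt = tgt, mmp = mmp, minrep = rep_)
}

# deterministic quadrature of a 1-dof bond partition function with the
# b^2 radial measure (independent oracle for the diatomic free energies)
bond_partition <- function(u_of_b, beta, upper = 30) {
  stats::integrate(function(b) b^2 * exp(-beta * u_of_b(b)), 0, upper,
                   rel.tol = 1e-10)$value
}

random_gas_frame <- function(model, sd = 0.3) {
  n <- nrow(model$topology$atoms)
  new_frame(model$frame0$coordinates + matrix(rnorm(3 * n, 0, sd), n, 3))
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
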