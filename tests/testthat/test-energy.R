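test_that("bonded terms follow the K(x - x0)^2 convention", {
  spec <- soft_diatomic_spec(k_b = 300, b0 = 1.0)
  m <- build_solute(spec, seed = 1)
  at_min <- new_frame(rbind(c(0, 0, 0), c(1.0, 0, 0)))
  expect_equal(bonded_energy(m, at_min), 0)
  displaced <- new_frame(rbind(c(0, 0, 0), c(1.1, 0, 0)))
  expect_equal(bonded_energy(m, displaced), 3.0, tolerance = 1e-12)

  # triatomic at its equilibrium geometry scores zero
  tri <- build_solute(toy_triatomic_spec(), seed = 1)
  th0 <- 104.52 * pi / 180
  geo <- rbind(c(0, 0, 0), c(1, 0, 0), c(cos(th0), sin(th0), 0))
  expect_equal(bonded_energy(tri, new_frame(geo)), 0, tolerance = 1e-20)

  # isometry invariance
  set.seed(1)
  f <- random_gas_frame(tri)
  R <- rotation_matrix(rnorm(3), 1.1)
  rotated <- new_frame(sweep(f$coordinates %*% t(R), 2, c(3, -2, 5), `+`))
  expect_equal(bonded_energy(tri, rotated), bonded_energy(tri, f),
               tolerance = 1e-9)
})

test_that("switched LJ matches the well depth and the switch support", {
  spec <- list(atoms = data.frame(mass = c(1, 1), charge = c(0, 0),
                                  lj_epsilon = 0.2, lj_rmin_half = 1.5),
               bonds = data.frame(i = integer(), j = integer(),
                                  k_b = numeric(), b0 = numeric()))
  m <- build_solute(spec, seed = 1)
  pair_at <- function(r) new_frame(rbind(c(0, 0, 0), c(r, 0, 0)))
  expect_equal(lj_energy(m, pair_at(3.0)), -0.2, tolerance = 1e-12)

  s <- nonbonded_settings(r_on = 4, r_off = 5)
  expect_identical(lj_energy(m, pair_at(5.0), s), 0)
  expect_identical(lj_energy(m, pair_at(6.2), s), 0)
  # cubic switch: S(r_on) = 1, S(r_off) = 0, continuous at both ends
  eps <- 1e-9
  u_unswitched <- function(r) lj_energy(m, pair_at(r))
  expect_equal(lj_energy(m, pair_at(4 - eps), s), u_unswitched(4 - eps))
  expect_equal(lj_energy(m, pair_at(4 + eps), s), u_unswitched(4 + eps),
               tolerance = 1e-6)
  expect_equal(lj_energy(m, pair_at(5 - eps), s), 0, tolerance = 1e-6)
  expect_error(lj_energy(m, pair_at(1e-9)), class = "alchemr_overlap")
})

test_that("soft-core LJ has the stated closed form and endpoints", {
  spec <- list(atoms = data.frame(mass = c(1, 1), charge = c(0, 0),
                                  lj_epsilon = 1, lj_rmin_half = 2^(1 / 6) / 2),
               bonds = data.frame(i = integer(), j = integer(),
                                  k_b = numeric(), b0 = numeric()))
  m <- build_solute(spec, seed = 1)  # sigma = 1
  overlap <- new_frame(rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_equal(
    softcore_lj_energy(m, overlap, alchemical_state(1, 0.5),
                       nonbonded_settings(softcore_delta = 0.5)),
    0.5 * 4 * (4096 - 64), tolerance = 1e-9)
  expect_identical(
    softcore_lj_energy(m, overlap, alchemical_state(1, 1)), 0)

  set.seed(2)
  for (r in c(0.9, 1.3, 2.5)) {
    f <- new_frame(rbind(c(0, 0, 0), c(r, 0, 0)))
    expect_equal(softcore_lj_energy(m, f, alchemical_state(0, 0)),
                 lj_energy(m, f), tolerance = 1e-12)
  }
  expect_error(nonbonded_settings(softcore_delta = -1),
               class = "alchemr_validation")
})

test_that("soft-core energy is continuous in lambda", {
  spec <- list(atoms = data.frame(mass = c(1, 1), charge = c(0, 0),
                                  lj_epsilon = 0.3, lj_rmin_half = 1.6),
               bonds = data.frame(i = integer(), j = integer(),
                                  k_b = numeric(), b0 = numeric()))
  m <- build_solute(spec, seed = 1)
  # a moderate-energy separation: continuity in lambda means the jump
  # across a 1e-4 grid never exceeds 1e-3 kcal/mol
  f <- new_frame(rbind(c(0, 0, 0), c(2.9, 0, 0)))
  lam <- seq(0, 1, by = 1e-4)
  u <- vapply(lam, function(l)
    softcore_lj_energy(m, f, alchemical_state(1, l)), 0)
  expect_lt(max(abs(diff(u))), 1e-3)
})

test_that("Coulomb energy uses the package constant and lambda scaling", {
  spec <- list(atoms = data.frame(mass = c(1, 1), charge = c(1, -1),
                                  lj_epsilon = 0, lj_rmin_half = 1),
               bonds = data.frame(i = integer(), j = integer(),
                                  k_b = numeric(), b0 = numeric()))
  m <- build_solute(spec, seed = 1)
  f <- new_frame(rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(coulomb_energy(m, f), -332.0716, tolerance = 1e-10)
  expect_equal(coulomb_energy(m, f, alchemical_state(1, 0)), 0)

  # periodic image identity: (0,0,0) vs (edge,0,0) coincide under
  # minimum image and must be flagged as an overlap
  box <- build_solvent_box(8, edge = 7, seed = 1)
  X <- box$frame0$coordinates
  X[4, ] <- X[1, ] + c(7, 0, 0)
  expect_error(
    coulomb_energy(box, new_frame(X), alchemical_state(),
                   nonbonded_settings(use_min_image = TRUE)),
    class = "alchemr_overlap")
})

test_that("solute-solvent electrostatics vanish at lambda_elec = 1", {
  sys <- solvate(build_solute(toy_triatomic_spec(), seed = 1),
                 build_solvent_box(8, edge = 7, seed = 2))
  d <- decompose_energy(sys, sys$frame0, alchemical_state(1, 0),
                        default_settings(sys))
  expect_equal(d$solute_solvent_elec, 0)
  expect_equal(d$solute_solute, 0)
})

test_that("energy decomposition conserves the single-pass total", {
  sys <- solvate(build_solute(toy_triatomic_spec(), seed = 1),
                 build_solvent_box(8, edge = 7, seed = 2))
  s <- default_settings(sys)
  for (st in list(alchemical_state(0, 0), alchemical_state(0.5, 0),
                  alchemical_state(1, 0.5))) {
    d <- decompose_energy(sys, sys$frame0, st, s)
    expect_equal(d$total,
                 d$solute_solute + d$solute_solvent_elec +
                   d$solute_solvent_vdw + d$solvent_solvent +
                   d$bonded_solute + d$drude_spring,
                 tolerance = 1e-9)
    expect_equal(d$total, total_energy(sys, sys$frame0, st, s),
                 tolerance = 1e-9)
  }
})

test_that("bookend delta-U ignores components that cancel between levels", {
  sys <- solvate(build_solute(toy_triatomic_spec(), seed = 1),
                 build_solvent_box(8, edge = 7, seed = 2))
  expect_equal(bookend_delta_u(sys, sys, sys$frame0), 0)

  # perturbing only solvent-solvent interactions leaves delta-U unchanged
  sys_b <- sys
  sys_b$parameters$atom_types[["OW"]]$lj_epsilon <- 0.30
  tgt <- make_surrogate_target(
    {m <- sys; m$level <- "MM"; m}, bond_shifts = 0.1)
  before <- bookend_delta_u(sys, tgt, sys$frame0)
  tgt_b <- tgt
  tgt_b$parameters$atom_types[["OW"]]$lj_epsilon <- 0.30
  after <- bookend_delta_u(sys_b, tgt_b, sys$frame0)
  expect_equal(after, before, tolerance = 1e-9)
})

test_that("recentering wraps the box around the solute without changing energies", {
  sys <- solvate(build_solute(toy_triatomic_spec(), seed = 1),
                 build_solvent_box(8, edge = 7, seed = 2))
  set.seed(4)
  f <- new_frame(sys$frame0$coordinates +
                   matrix(rnorm(3 * nrow(sys$frame0$coordinates), 0, 0.5),
                          ncol = 3))
  g <- recenter(f, sys)
  sol <- which(sys$topology$atoms$group == "solute")
  expect_equal(colMeans(g$coordinates[sol, ]), rep(3.5, 3),
               tolerance = 1e-9)
  s <- default_settings(sys, bookend = TRUE)
  expect_equal(total_energy(sys, g, settings = s),
               total_energy(sys, f, settings = s), tolerance = 1e-9)
  g2 <- recenter(g, sys)
  expect_equal(g2$coordinates, g$coordinates, tolerance = 1e-12)

  gas <- build_solute(toy_triatomic_spec(), seed = 1)
  expect_identical(recenter(gas$frame0, gas), gas$frame0)
})

test_that("analytic gradients agree with finite differences", {
  tri <- build_solute(toy_triatomic_spec(), seed = 1)
  sys <- solvate(tri, build_solvent_box(8, edge = 7, seed = 2))
  set.seed(11)
  check_grad <- function(model, frame, state, settings) {
    g <- energy_gradient(model, frame, state, settings)
    X <- frame$coordinates
    h <- 1e-5
    for (pick in seq_len(6)) {
      i <- sample.int(nrow(X), 1); k <- sample.int(3, 1)
      Xp <- X; Xp[i, k] <- Xp[i, k] + h
      Xm <- X; Xm[i, k] <- Xm[i, k] - h
      fd <- (total_energy(model, new_frame(Xp, frame$drude), state, settings) -
             total_energy(model, new_frame(Xm, frame$drude), state, settings)) /
        (2 * h)
      expect_lt(abs(g[i, k] - fd), 1e-6 * max(1, abs(fd)))
    }
  }
  for (rep_ in 1:25) {
    f <- random_gas_frame(tri, sd = 0.15)
    check_grad(tri, f, alchemical_state(), nonbonded_settings())
  }
  for (rep_ in 1:25) {
    f <- new_frame(sys$frame0$coordinates +
                     matrix(rnorm(3 * nrow(sys$frame0$coordinates), 0, 0.05),
                            ncol = 3))
    st <- if (rep_ %% 2) alchemical_state(0.3, 0) else alchemical_state(1, 0.4)
    check_grad(sys, f, st, default_settings(sys))
  }
})

test_that("gas-phase energy is invariant under rigid motions", {
  tri <- build_solute(toy_triatomic_spec(), seed = 1)
  set.seed(5)
  for (i in 1:10) {
    f <- random_gas_frame(tri)
    R <- rotation_matrix(rnorm(3), runif(1, 0, 2 * pi))
    moved <- new_frame(sweep(f$coordinates %*% t(R), 2, rnorm(3, 0, 10), `+`))
    expect_equal(total_energy(tri, moved), total_energy(tri, f),
                 tolerance = 1e-9)
  }
})
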