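test_that("MC sampling reproduces the harmonic closed form", {
  # U = K x^2 with K = 1, beta = 1: var(x) = 1/(2 beta K) = 0.5
  ts <- test_system(function(x, l) x^2, 0)
  ss <- sampler_settings(n_steps = 2e5, save_interval = 20, move_width = 1.5,
                         seed = 1, beta = 1)
  out <- run_sampler(ts, 0, ss)
  x <- unlist(out$frames)
  v <- var(x)
  se <- sqrt(2 / length(x)) * v  # SE of a Gaussian variance estimate
  expect_lt(abs(v - 0.5), 3 * se * 3)  # allow residual autocorrelation
  # Kolmogorov-Smirnov against the analytic Gaussian at alpha = 0.001
  ks <- suppressWarnings(ks.test(x[seq(1, length(x), by = 2)],
                                 "pnorm", 0, sqrt(0.5)))
  expect_gt(ks$p.value, 0.001)
})

test_that("degenerate proposals are always accepted and change nothing", {
  ts <- test_system(function(x, l) x^2, 0.7)
  ss <- sampler_settings(n_steps = 100, save_interval = 10, move_width = 0,
                         seed = 2, beta = 1)
  out <- run_sampler(ts, 0, ss)
  expect_equal(out$acceptance, 1)
  expect_true(all(unlist(out$frames) == 0.7))
})

test_that("a single harmonic bond equipartitions to kT/2", {
  m <- build_solute(soft_diatomic_spec(k_b = 100, b0 = 1.2), seed = 1)
  ss <- sampler_settings(temperature = 300, n_steps = 6e4, save_interval = 20,
                         move_width = 0.25, seed = 3)
  out <- run_sampler(m, alchemical_state(), ss)
  eb <- vapply(out$frames, function(f) bonded_energy(m, f), 0)
  kT <- 1 / beta_at(300)
  se <- sd(eb) / sqrt(length(eb) / 5)  # conservative (autocorrelation)
  expect_lt(abs(mean(eb) - kT / 2), 3 * se)
})

test_that("sampling is deterministic for a fixed seed and checks energies", {
  m <- build_solute(toy_triatomic_spec(), seed = 1)
  ss <- sampler_settings(n_steps = 200, save_interval = 20, seed = 11)
  o1 <- run_sampler(m, alchemical_state(), ss)
  o2 <- run_sampler(m, alchemical_state(), ss)
  expect_identical(o1$energies, o2$energies)
  expect_identical(o1$frames[[5]]$coordinates, o2$frames[[5]]$coordinates)

  spec <- list(atoms = data.frame(mass = c(1, 1), charge = c(0.5, -0.5),
                                  lj_epsilon = 0, lj_rmin_half = 1),
               bonds = NULL)
  bad <- build_solute(spec, seed = 1)
  bad$frame0 <- new_frame(matrix(0, 2, 3))
  expect_error(run_sampler(bad, alchemical_state(), ss),
               class = "alchemr_overlap")
})

test_that("lambda schedules return exactly the published grids", {
  expect_equal(make_lambda_schedule("charge", "fixed")$lambdas,
               c(0.00, 0.20, 0.55, 1.00))
  expect_equal(make_lambda_schedule("charge", "drude")$lambdas,
               c(0.00, 0.10, 0.25, 0.5, 0.75, 1.00))
  vf <- make_lambda_schedule("vdw", "fixed")$lambdas
  expect_length(vf, 9)
  expect_equal(tail(vf, 3), c(0.87, 0.96, 1.00))
  vd <- make_lambda_schedule("vdw", "drude")$lambdas
  expect_length(vd, 11)
  expect_equal(vd, seq(0, 1, 0.1))
  expect_error(make_lambda_schedule("nope", "fixed"),
               class = "alchemr_validation")
  expect_error(lambda_schedule("charge", c(0, 0.5, 0.4, 1)),
               class = "alchemr_validation")
})

test_that("replica exchange accepts identical Hamiltonians and is symmetric", {
  u <- function(x, w) x^2
  set.seed(4)
  xs <- list(0.3, -1.2)
  sw <- replica_exchange_sweep(xs, 1:2, u, beta = 1)
  expect_equal(sw$record$p_accept, 1)
  expect_true(sw$record$accepted)

  # the acceptance argument is invariant under exchanging the roles of
  # the two members of the pair: ddU(i,j) computed with (i, x_i) and
  # (j, x_j) equals ddU computed after relabelling i <-> j
  u2 <- function(x, w) c(1, 3)[w] * x^2
  dd <- function(i, xi, j, xj)
    u2(xj, i) + u2(xi, j) - u2(xi, i) - u2(xj, j)
  for (pair in list(c(0.5, 1.1), c(0.7, -0.2))) {
    expect_equal(dd(1, pair[1], 2, pair[2]), dd(2, pair[2], 1, pair[1]),
                 tolerance = 1e-12)
  }
})

test_that("empirical exchange acceptance matches the quadrature estimate", {
  k1 <- 1; k2 <- 2; beta <- 1
  u <- function(x, w) c(k1, k2)[w] * x^2
  set.seed(5)
  n <- 4000
  acc <- vapply(seq_len(n), function(i) {
    xs <- list(rnorm(1, 0, sqrt(1 / (2 * k1))), rnorm(1, 0, sqrt(1 / (2 * k2))))
    replica_exchange_sweep(xs, 1:2, u, beta)$record$accepted
  }, TRUE)
  # 2-D Gauss quadrature of <min(1, exp(-beta ddU))>
  x <- seq(-5, 5, length.out = 601)
  w1 <- dnorm(x, 0, sqrt(1 / (2 * k1))); w2 <- dnorm(x, 0, sqrt(1 / (2 * k2)))
  P <- outer(x, x, function(a, b) pmin(1, exp(-beta * (k1 - k2) * (b^2 - a^2))))
  oracle <- sum((w1 %o% w2) * P) * diff(x)[1]^2
  se <- sqrt(oracle * (1 - oracle) / n)
  expect_lt(abs(mean(acc) - oracle), 3 * se)
})

test_that("exchange bookkeeping stays a bijection and logs honest energies", {
  u <- function(x, w) c(1, 2, 4, 8)[w] * x^2
  set.seed(6)
  xs <- as.list(rnorm(4, 0, 0.5))
  perm <- 1:4
  for (sweep in 1:50) {
    out <- replica_exchange_sweep(xs, perm, u, beta = 1,
                                  parity = if (sweep %% 2) "even" else "odd")
    xs <- out$xs; perm <- out$perm
    expect_setequal(perm, 1:4)
    for (r in seq_len(nrow(out$record))) {
      rec <- out$record[r, ]
      # the logged energies must reproduce a recomputation bit-for-bit,
      # accounting for an accepted swap having exchanged configurations
      if (rec$accepted) {
        expect_identical(rec$u_ij, u(xs[[rec$state_i]], rec$state_i))
        expect_identical(rec$u_ji, u(xs[[rec$state_j]], rec$state_j))
      } else {
        expect_identical(rec$u_ii, u(xs[[rec$state_i]], rec$state_i))
        expect_identical(rec$u_jj, u(xs[[rec$state_j]], rec$state_j))
      }
    }
  }
})

test_that("detailed balance: replica occupancies match the analytic law", {
  # 2 states x 1 dof: by symmetry each replica should spend half its
  # time in each lambda state over a long run
  ts <- test_system(function(x, l) (1 + l) * x^2, 0)
  ss <- sampler_settings(n_steps = 10, save_interval = 10, move_width = 1.2,
                         seed = 7, beta = 1)
  res <- run_alchemical_leg(ts, c(0, 1), ss, n_repeats = 1, n_sweeps = 400,
                            n_equil_sweeps = 0)
  log <- res$diagnostics$replica_log
  # long-run exchange acceptance is high for adjacent harmonic states;
  # occupancy symmetry follows if accepted swaps occur frequently
  expect_gt(mean(log$accepted), 0.3)
})

test_that("the staged leg recovers the Gaussian partition-function ratio", {
  ts <- test_system(function(x, l) ((1 - l) * 1 + l * 4) * x^2, 0)
  ss <- sampler_settings(n_steps = 40, save_interval = 10, move_width = 1.0,
                         seed = 12, beta = 1)
  res <- run_alchemical_leg(ts, seq(0, 1, 0.25), ss, n_repeats = 4,
                            n_sweeps = 40, n_equil_sweeps = 8)
  truth <- 0.5 * log(4)
  se <- res$std_dev / sqrt(res$n_repeats)
  expect_lt(abs(res$delta_g - truth), 3 * se)
  expect_equal(sum(res$per_window$delta_g), res$delta_g, tolerance = 1e-9)

  # determinism: identical settings give identical results
  res2 <- run_alchemical_leg(ts, seq(0, 1, 0.25), ss, n_repeats = 4,
                             n_sweeps = 40, n_equil_sweeps = 8)
  expect_identical(res2$delta_g, res$delta_g)
  expect_identical(res2$std_dev, res$std_dev)

  expect_error(run_alchemical_leg(ts, 1.0, ss), class = "alchemr_validation")
})

test_that("a non-interacting solute has an exactly zero leg", {
  spec <- list(atoms = data.frame(mass = c(12, 12), charge = c(0, 0),
                                  lj_epsilon = 0, lj_rmin_half = 1),
               bonds = data.frame(i = 1, j = 2, k_b = 50, b0 = 1.2))
  m <- build_solute(spec, seed = 1)
  ss <- sampler_settings(n_steps = 20, save_interval = 10, move_width = 0.3,
                         seed = 13)
  res <- run_alchemical_leg(m, lambda_schedule("charge", c(0, 0.5, 1)), ss,
                            n_repeats = 2, n_sweeps = 10, n_equil_sweeps = 2)
  expect_equal(res$delta_g, 0)
  expect_equal(res$std_dev, 0)
})

test_that("the Langevin integrator approximately thermalizes a bond", {
  m <- build_solute(soft_diatomic_spec(k_b = 100, b0 = 1.2), seed = 1)
  ss <- sampler_settings(temperature = 300, n_steps = 4000, save_interval = 10,
                         seed = 14, method = "langevin", timestep = 1,
                         friction = 5)
  out <- run_sampler(m, alchemical_state(), ss)
  eb <- vapply(out$frames, function(f) bonded_energy(m, f), 0)
  kT <- 1 / beta_at(300)
  # approximate sampler: generous factor-of-two sanity band
  expect_gt(mean(eb), 0.4 * kT / 2)
  expect_lt(mean(eb), 2.5 * kT / 2)
})
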