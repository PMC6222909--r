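fake_leg <- function(dg, sd = 0.1, stages = c("charge", "vdw")) {
  r <- alchemr:::new_fe_result(dg, "BAR", std_dev = sd, n_repeats = 4)
  r$diagnostics$stage_totals <- tibble::tibble(stage = stages,
                                               delta_g = dg * c(0.7, 0.3))
  r
}

test_that("the hydration cycle subtracts legs and combines uncertainty", {
  cyc <- hydration_cycle(fake_leg(3.0, 0.2), fake_leg(8.5, 0.3))
  expect_equal(cyc$dg_hyd, -5.5)
  expect_equal(cyc$dg_hyd, cyc$dg_annih_gas - cyc$dg_annih_aq,
               tolerance = 1e-9)
  expect_equal(cyc$sd, sqrt(0.2^2 + 0.3^2))

  same <- hydration_cycle(fake_leg(2.2), fake_leg(2.2))
  expect_equal(same$dg_hyd, 0)

  expect_error(hydration_cycle(fake_leg(1, stages = "charge"),
                               fake_leg(1, stages = c("charge", "vdw"))),
               class = "alchemr_validation")
})

test_that("bookend corrections move the cycle by the end-point differences", {
  cyc <- hydration_cycle(fake_leg(3.0, 0.1), fake_leg(8.5, 0.1))
  zero <- exp_zwanzig(work_samples(rep(0, 100), beta = 1))
  unchanged <- bookend_correct(cyc, zero, zero, route = "direct")
  expect_equal(unchanged$dg_hyd, cyc$dg_hyd)

  gas <- alchemr:::new_fe_result(1.25, "EXP")
  aq <- alchemr:::new_fe_result(-0.75, "EXP")
  corr <- bookend_correct(cyc, gas, aq, route = "nbb")
  expect_equal(corr$dg_hyd, cyc$dg_hyd + (-0.75) - 1.25)
  expect_identical(corr$route, "nbb")
  expect_error(bookend_correct(cyc, NULL, aq), class = "alchemr_validation")
})

test_that("agreement metrics reproduce the packaged reference tables", {
  t1_fc <- glance(reference_metrics("table1_mm_hydration", "fc"))
  expect_equal(round(t1_fc$rmsd, 2), 0.89)
  expect_equal(round(t1_fc$msd, 2), 0.65)
  expect_equal(round(t1_fc$r2, 2), 0.97)

  t1_dr <- glance(reference_metrics("table1_mm_hydration", "drude"))
  expect_equal(round(t1_dr$rmsd, 2), 0.53)
  expect_equal(round(t1_dr$msd, 2), 0.04)
  expect_equal(round(t1_dr$r2, 2), 0.99)

  t2 <- glance(reference_metrics("table2_qmmm_fixed", "OM2",
                                 exclusions = c("ethanol", "acetamide")))
  expect_equal(round(t2$rmsd, 1), 1.3)
  expect_equal(round(t2$rmsd_starred, 1), 1.0)

  tab1 <- read_reference_table("table1_mm_hydration")
  expect_equal(tab1$ddg_fc_minus_drude[tab1$label == "water"], -1.14)
  expect_equal(tab1$fc[tab1$label == "water"] -
                 tab1$drude[tab1$label == "water"], -1.14)
  expect_equal(tab1$fc_sd[tab1$label == "water"], 0.04)
})

test_that("metrics handle identities, degeneracies and invariants", {
  d <- tibble::tibble(label = letters[1:5], reference = c(1, 2, 3, 4, 5),
                      predicted = c(1, 2, 3, 4, 5))
  g <- glance(fep_metrics(d))
  expect_equal(g$rmsd, 0)
  expect_equal(g$msd, 0)
  expect_equal(g$r2, 1)

  expect_error(fep_metrics(d[1, ]), class = "alchemr_validation")
  expect_error(fep_metrics(d[1:3, ], exclusions = c("a", "b")),
               class = "alchemr_validation")

  set.seed(31)
  for (i in 1:20) {
    dd <- tibble::tibble(label = letters[1:6], reference = rnorm(6),
                         predicted = rnorm(6))
    g <- glance(fep_metrics(dd))
    expect_gte(g$rmsd, abs(g$msd))
    expect_true(g$r2 >= 0 && g$r2 <= 1)
  }
})

test_that("scale_fit finds the least-squares multiplicative factor", {
  d <- tibble::tibble(label = letters[1:4], reference = c(1, -2, 3, 0.5),
                      predicted = 2 * c(1, -2, 3, 0.5))
  sf <- scale_fit(d)
  expect_equal(sf$scale, 0.5, tolerance = 1e-12)
  expect_equal(glance(sf$after)$rmsd, 0, tolerance = 1e-12)

  already <- tibble::tibble(label = letters[1:3], reference = c(1, 2, 3),
                            predicted = c(1, 2, 3))
  expect_equal(scale_fit(already)$scale, 1, tolerance = 1e-12)

  set.seed(32)
  d2 <- tibble::tibble(label = letters[1:8], reference = rnorm(8, 0, 2),
                       predicted = rnorm(8, 0, 2))
  s_grid <- seq(-3, 3, by = 1e-4)
  rmsd_of <- vapply(s_grid, function(s)
    sqrt(mean((s * d2$predicted - d2$reference)^2)), 0)
  expect_lt(abs(scale_fit(d2)$scale - s_grid[which.min(rmsd_of)]), 1e-4)

  zeros <- tibble::tibble(label = c("a", "b"), reference = c(1, 2),
                          predicted = c(0, 0))
  expect_error(scale_fit(zeros), class = "alchemr_validation")
})

test_that("tidiers and autoplot provide the broom-style surface", {
  ws <- work_samples(rnorm(100, 1), rnorm(100, -1), beta = 1)
  res <- bar_estimate(ws)
  expect_s3_class(tidy(res), "tbl_df")
  expect_identical(glance(res)$method, "BAR")

  mt <- reference_metrics("table1_mm_hydration", "fc")
  expect_s3_class(autoplot(mt), "ggplot")
  expect_s3_class(autoplot(res), "ggplot")

  cyc <- hydration_cycle(fake_leg(3.0), fake_leg(8.5))
  expect_equal(glance(cyc)$dg_hyd, -5.5)
  expect_equal(nrow(tidy(cyc)), 3)
})

test_that("the CLI runs metrics, simulates deterministically, tailors", {
  expect_equal(alchemr_cli(character()), 2L)
  expect_equal(alchemr_cli(c("frobnicate")), 2L)

  out <- capture.output(
    status <- alchemr_cli(c("metrics", "--fixture", "table1_mm_hydration",
                            "--column", "fc")))
  expect_equal(status, 0L)
  expect_match(paste(out, collapse = "\n"), "RMSD 0.89")

  # simulate twice with one seed -> identical outputs
  sysfile <- withr::local_tempfile()
  write_system(build_solute(toy_triatomic_spec(), seed = 1), sysfile)
  o1 <- withr::local_tempfile(); o2 <- withr::local_tempfile()
  expect_equal(suppressMessages(
    alchemr_cli(c("simulate", "--system", sysfile, "--steps", "200",
                  "--seed", "5", "--out", o1))), 0L)
  expect_equal(suppressMessages(
    alchemr_cli(c("simulate", "--system", sysfile, "--steps", "200",
                  "--seed", "5", "--out", o2))), 0L)
  expect_identical(readLines(paste0(o1, ".xyz")), readLines(paste0(o2, ".xyz")))
  expect_identical(readLines(paste0(o1, "_energies.csv")),
                   readLines(paste0(o2, "_energies.csv")))

  # tailor subcommand end-to-end
  base <- build_solute(soft_diatomic_spec(), seed = 1)
  tgt <- make_surrogate_target(base, bond_shifts = 0.36)
  bf <- withr::local_tempfile(); tf <- withr::local_tempfile()
  of <- withr::local_tempfile()
  write_system(base, bf); write_system(tgt, tf)
  expect_equal(suppressMessages(
    alchemr_cli(c("tailor", "--system", bf, "--target", tf, "--out", of))),
    0L)
  mmp <- read_system(of)
  expect_identical(mmp$level, "MM'")
  expect_equal(mmp$parameters$bond_params$b0, 1.513, tolerance = 1e-5)

  # estimate subcommand over a written log
  trio <- surrogate_trio()
  set.seed(41)
  frames <- lapply(1:50, function(k) random_gas_frame(trio$mm, sd = 0.05))
  lg <- bookend_log(trio$mm, trio$tgt, frames)
  lf <- withr::local_tempfile(fileext = ".csv")
  rf <- withr::local_tempfile(fileext = ".json")
  write_energy_log(lg, lf)
  expect_equal(suppressMessages(
    alchemr_cli(c("estimate", "--log-a", lf, "--method", "EXP",
                  "--beta", "1", "--out", rf))), 0L)
  expect_true(file.exists(rf))
  expect_equal(suppressMessages(
    alchemr_cli(c("estimate", "--log-a", lf, "--method", "WAT",
                  "--out", rf))), 2L)
})

test_that("a dipolar solute in a small polar box is favourably hydrated", {
  # independent oracle: with a single solvent molecule the annihilation
  # free energy reduces to a Widom-style average over uniform rigid
  # solvent placements, Delta_G(on -> off) = kT ln <exp(-beta U_int)>
  sol <- build_solute(toy_triatomic_spec(), seed = 1)
  box1 <- build_solvent_box(1, edge = 6, seed = 2)
  box1$frame0$coordinates <- sweep(box1$frame0$coordinates, 2,
                                   box1$frame0$coordinates[1, ] - c(1, 1, 1),
                                   `-`)
  sys <- solvate(sol, box1)
  expect_equal(nrow(sys$topology$atoms), 6)
  beta <- beta_at(300)
  edge <- 6
  # per-atom parameters of the solute (rows 1:3) and water (rows 4:6)
  q_s <- c(-0.8, 0.4, 0.4); q_w <- c(-0.8, 0.4, 0.4)
  eps_s <- c(0.15, 0.03, 0.03); eps_w <- c(0.15, 0.03, 0.03)
  rmh_s <- c(1.75, 0.6, 0.6); rmh_w <- c(1.75, 0.6, 0.6)
  Xs <- sys$frame0$coordinates[1:3, ]
  th0 <- 104.52 * pi / 180
  water_local <- rbind(c(0, 0, 0), c(1, 0, 0), c(cos(th0), sin(th0), 0))
  set.seed(42)
  n <- 2e4
  u_int <- vapply(seq_len(n), function(i) {
    centre <- runif(3, 0, edge)
    R <- rotation_matrix(rnorm(3), runif(1, 0, 2 * pi))
    Xw <- sweep(water_local %*% t(R), 2, centre, `+`)
    u <- 0
    for (a in 1:3) for (b in 1:3) {
      dv <- Xs[a, ] - Xw[b, ]
      dv <- dv - edge * round(dv / edge)
      r <- sqrt(sum(dv^2))
      x6 <- ((rmh_s[a] + rmh_w[b]) / r)^6
      u <- u + 332.0716 * q_s[a] * q_w[b] / r +
        sqrt(eps_s[a] * eps_w[b]) * (x6^2 - 2 * x6)
    }
    u
  }, 0)
  u_int <- pmin(u_int, 500)  # hard-core overlaps contribute exp(-large) ~ 0
  dg_annih_oracle <- (alchemr:::logsumexp(-beta * u_int) - log(n)) / beta
  # favourable interactions dominate: removing them costs free energy
  expect_gt(dg_annih_oracle, 0)

  # the pipeline agrees on the sign: annihilating the solute in the
  # 1-water box costs free energy, so dG_hyd = dG_gas - dG_aq < 0
  ss <- sampler_settings(n_steps = 150, save_interval = 15, move_width = 0.4,
                         seed = 6)
  sched <- list(lambda_schedule("charge", c(0, 0.5, 1)),
                lambda_schedule("vdw", c(0, 0.5, 1)))
  aq <- run_alchemical_leg(sys, sched, ss, n_repeats = 2, n_sweeps = 25,
                           n_equil_sweeps = 5)
  gas <- run_alchemical_leg(sol, sched, ss, n_repeats = 2, n_sweeps = 5,
                            n_equil_sweeps = 1)
  expect_equal(gas$delta_g, 0)  # all intra-solute pairs are excluded
  cyc <- hydration_cycle(gas, aq)
  expect_lt(cyc$dg_hyd, 0)
})
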