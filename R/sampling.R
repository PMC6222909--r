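#' Sampler settings
#'
#' Settings for the Metropolis Monte Carlo sampler (the primary,
#' exact-stationary-distribution sampler) and the optional Langevin
#' (BAOAB) integrator.  `beta` overrides the temperature with an
#' explicit inverse temperature for unit-reduced test systems.
#'
#' @param temperature temperature (K).
#' @param n_steps number of MC steps (or MD steps).
#' @param save_interval save a frame every this many steps.
#' @param move_width MC displacement half-width (A); `timestep` (fs) and
#'   `friction` (ps^-1) apply to the Langevin integrator.
#' @param seed integer RNG seed.
#' @param drude_mode `"scf_each_step"` relaxes Drude particles to the
#'   energy minimum before every energy use (the cold-Drude limit);
#'   `"lagged"` performs a single damped relaxation step per move,
#'   emulating extended-Lagrangian dynamics where the particles lag the
#'   minimum.
#' @param method `"mc"` (default) or `"langevin"` (approximate).
#' @param beta explicit inverse temperature (mol/kcal) or `NULL`.
#' @param timestep,friction Langevin parameters.
#' @return a `sampler_settings` object.
#' @export
sampler_settings <- function(temperature = 300, n_steps = 1000,
                             save_interval = 10, move_width = 0.15,
                             seed = 1L, drude_mode = c("scf_each_step", "lagged"),
                             method = c("mc", "langevin"), beta = NULL,
                             timestep = 1, friction = 1) {
  drude_mode <- match.arg(drude_mode)
  method <- match.arg(method)
  if (temperature <= 0) abort("temperature must be > 0",
                              class = "alchemr_validation")
  if (n_steps < save_interval || save_interval < 1)
    abort("need n_steps >= save_interval >= 1", class = "alchemr_validation")
  structure(list(temperature = temperature, n_steps = n_steps,
                 save_interval = save_interval, move_width = move_width,
                 seed = as.integer(seed), drude_mode = drude_mode,
                 method = method,
                 beta = beta %||% beta_at(temperature),
                 timestep = timestep, friction = friction),
            class = "sampler_settings")
}

#' Analytic 1-dof test systems
#'
#' A lambda-parameterized one-dimensional Hamiltonian `u(x, lambda)`
#' with a starting configuration, accepted everywhere a
#' [system_model()] is: by [run_sampler()], [replica_exchange_sweep()]
#' and [run_alchemical_leg()].  Used to exercise the machinery against
#' closed-form statistical mechanics.
#'
#' @param u function of `(x, lambda)` returning energy (kcal/mol).
#' @param x0 starting configuration (numeric vector).
#' @return a `test_system` object.
#' @export
#' @examples
#' # harmonic dof with lambda-interpolated stiffness k0 -> k1
#' ts <- test_system(function(x, l) ((1 - l) * 1 + l * 4) * x^2, 0)
test_system <- function(u, x0 = 0) {
  structure(list(u = u, x0 = as.numeric(x0)), class = "test_system")
}

# single-coordinate Metropolis chain over a plain numeric vector
metropolis_chain <- function(u_fn, x0, n_steps, move_width, beta,
                             save_interval) {
  x <- x0
  e <- u_fn(x)
  if (!is.finite(e))
    abort("non-finite energy at the start of sampling",
          class = "alchemr_nonfinite")
  d <- length(x)
  saved <- vector("list", n_steps %/% save_interval)
  energies <- numeric(length(saved))
  n_acc <- 0L
  si <- 0L
  for (step in seq_len(n_steps)) {
    j <- if (d > 1) sample.int(d, 1) else 1L
    xp <- x
    xp[j] <- x[j] + runif(1, -move_width, move_width)
    ep <- u_fn(xp)
    if (is.finite(ep) && (ep <= e || runif(1) < exp(-beta * (ep - e)))) {
      x <- xp; e <- ep; n_acc <- n_acc + 1L
    }
    if (step %% save_interval == 0) {
      si <- si + 1L
      saved[[si]] <- x
      energies[si] <- e
    }
  }
  list(samples = saved, energies = energies, x = x,
       acceptance = n_acc / n_steps)
}

#' Run a sampler at one alchemical state
#'
#' Metropolis Monte Carlo sampling from the Boltzmann distribution of
#' the lambda-scaled Hamiltonian.  Deterministic for a fixed seed.  For
#' a [system_model()] each step displaces one randomly chosen atom;
#' `drude_mode = "scf_each_step"` relaxes Drude particles before each
#' energy use.  For a [test_system()] the configuration vector is
#' sampled directly and `state` is the bare lambda value.
#'
#' @param model a [system_model()] or [test_system()].
#' @param state an [alchemical_state()] (or numeric lambda for test
#'   systems).
#' @param settings a [sampler_settings()].
#' @param start optional starting [new_frame()] (molecular systems).
#' @return a list with `frames` (list of frames or numeric vectors),
#'   `energies`, `acceptance`.
#' @export
run_sampler <- function(model, state, settings, start = NULL) {
  set.seed(settings$seed)
  run_sampler_nostore(model, state, settings, start)
}

# same, but without touching the seed (used inside replica exchange,
# which manages per-window RNG streams itself)
run_sampler_nostore <- function(model, state, settings, start = NULL) {
  beta <- settings$beta
  if (inherits(model, "test_system")) {
    lam <- if (is.numeric(state)) state else state$lambda_elec
    out <- metropolis_chain(function(x) model$u(x, lam), start %||% model$x0,
                            settings$n_steps, settings$move_width, beta,
                            settings$save_interval)
    return(list(frames = out$samples, energies = out$energies,
                acceptance = out$acceptance, x = out$x))
  }
  cs <- as_compiled(model)
  nb <- if (inherits(model, "system_model")) default_settings(model)
        else nonbonded_settings()
  f0 <- start %||% model$frame0
  if (is.null(f0)) abort("no starting frame", class = "alchemr_validation")
  if (settings$method == "langevin")
    return(langevin_baoab(cs, f0, state, settings, nb))

  relax <- function(fr) {
    if (any(cs$pol) && settings$drude_mode == "scf_each_step")
      drude_relax(cs, fr, tol = 1e-6, max_iter = 200, state = state,
                  settings = nb)$frame
    else fr
  }
  lag_step <- function(fr) {
    if (any(cs$pol) && settings$drude_mode == "lagged") {
      g <- drude_gradient(cs, fr, state, nb)
      d <- fr$drude
      d[cs$pol, ] <- d[cs$pol, , drop = FALSE] -
        0.5 * g[cs$pol, , drop = FALSE] / cs$kd[cs$pol]
      new_frame(fr$coordinates, d, fr$replica_index, fr$step)
    } else fr
  }
  fr <- relax(f0)
  e <- total_energy(cs, fr, state, nb)
  if (!is.finite(e))
    abort("non-finite energy at the start of sampling",
          class = "alchemr_nonfinite")
  n <- cs$n
  frames <- list(); energies <- numeric(); n_acc <- 0L
  for (step in seq_len(settings$n_steps)) {
    a <- sample.int(n, 1)
    Xp <- fr$coordinates
    Xp[a, ] <- Xp[a, ] + runif(3, -settings$move_width, settings$move_width)
    frp <- new_frame(Xp, fr$drude, fr$replica_index, step)
    frp <- relax(frp)
    ep <- total_energy(cs, frp, state, nb)
    if (is.finite(ep) && (ep <= e || runif(1) < exp(-beta * (ep - e)))) {
      fr <- lag_step(frp); e <- total_energy(cs, fr, state, nb)
      n_acc <- n_acc + 1L
    }
    if (step %% settings$save_interval == 0) {
      frames[[length(frames) + 1]] <- fr
      energies[length(energies) + 1] <- e
    }
  }
  list(frames = frames, energies = energies,
       acceptance = n_acc / settings$n_steps, x = fr)
}

# BAOAB Langevin integrator; approximate (finite-timestep) sampler kept
# for parity with dynamics-based workflows
langevin_baoab <- function(cs, f0, state, settings, nb) {
  dt <- settings$timestep * 1e-3      # fs -> ps
  gamma <- settings$friction          # ps^-1
  kT <- 1 / settings$beta
  m <- cs$mass * 2.39e-3              # amu -> kcal/mol ps^2 / A^2 (approx)
  X <- f0$coordinates
  V <- matrix(rnorm(length(X), 0, sqrt(kT / m)), ncol = 3)
  c1 <- exp(-gamma * dt)
  c2 <- sqrt((1 - c1^2)) * sqrt(kT / m)
  frames <- list(); energies <- numeric()
  fr <- f0
  for (step in seq_len(settings$n_steps)) {
    G <- energy_gradient(cs, fr, state, nb)
    V <- V - 0.5 * dt * G / m
    X <- X + 0.5 * dt * V
    V <- c1 * V + c2 * matrix(rnorm(length(X)), ncol = 3)
    X <- X + 0.5 * dt * V
    fr <- new_frame(X, fr$drude, fr$replica_index, step)
    G <- energy_gradient(cs, fr, state, nb)
    V <- V - 0.5 * dt * G / m
    if (step %% settings$save_interval == 0) {
      frames[[length(frames) + 1]] <- fr
      energies[length(energies) + 1] <- total_energy(cs, fr, state, nb)
    }
  }
  list(frames = frames, energies = energies, acceptance = NA_real_, x = fr)
}

#' Alchemical lambda schedules
#'
#' The staged annihilation grids: the charge stage uses
#' `0, 0.20, 0.55, 1` for the fixed-charge family and
#' `0, 0.10, 0.25, 0.5, 0.75, 1` for the Drude family; the van der
#' Waals stage uses `0, 0.15, 0.30, 0.45, 0.60, 0.75, 0.87, 0.96, 1`
#' (fixed) and the 11-point uniform grid (Drude).
#'
#' @param stage `"charge"` or `"vdw"`.
#' @param ff_family `"fixed"` or `"drude"`.
#' @return a `lambda_schedule` object with fields `stage`, `ff_family`,
#'   `lambdas`.
#' @export
#' @examples
#' make_lambda_schedule("charge", "fixed")$lambdas
#' lambda_schedule("vdw", c(0, 0.5, 1))
make_lambda_schedule <- function(stage, ff_family) {
  if (!stage %in% c("charge", "vdw"))
    abort("unknown stage; valid tags: charge, vdw",
          class = "alchemr_validation")
  if (!ff_family %in% c("fixed", "drude"))
    abort("unknown ff_family; valid tags: fixed, drude",
          class = "alchemr_validation")
  lam <- switch(paste(stage, ff_family),
    "charge fixed" = c(0, 0.20, 0.55, 1),
    "charge drude" = c(0, 0.10, 0.25, 0.5, 0.75, 1),
    "vdw fixed" = c(0, 0.15, 0.30, 0.45, 0.60, 0.75, 0.87, 0.96, 1),
    "vdw drude" = seq(0, 1, by = 0.1))
  structure(list(stage = stage, ff_family = ff_family, lambdas = lam),
            class = "lambda_schedule")
}

#' @rdname make_lambda_schedule
#' @param lambdas strictly increasing grid from 0 to 1 (custom
#'   desk-scale schedules).
#' @export
lambda_schedule <- function(stage, lambdas, ff_family = "custom") {
  if (!stage %in% c("charge", "vdw"))
    abort("unknown stage; valid tags: charge, vdw",
          class = "alchemr_validation")
  if (lambdas[1] != 0 || lambdas[length(lambdas)] != 1 ||
      any(diff(lambdas) <= 0))
    abort("lambdas must increase strictly from 0 to 1",
          class = "alchemr_validation")
  structure(list(stage = stage, ff_family = ff_family, lambdas = lambdas),
            class = "lambda_schedule")
}

lambda_state_for <- function(stage, lambda) {
  if (stage == "charge") alchemical_state(lambda_elec = lambda)
  else alchemical_state(lambda_elec = 1, lambda_vdw = lambda)
}

#' One replica-exchange sweep
#'
#' Attempts swaps between adjacent lambda states of the given parity
#' (`"even"`: pairs (1,2), (3,4), ...; `"odd"`: (2,3), (4,5), ...)
#' with the Metropolis criterion
#' `min(1, exp(-beta (U_i(x_j) + U_j(x_i) - U_i(x_i) - U_j(x_j))))`.
#' The record logs every energy evaluation and accept flag; the
#' replica-to-state assignment stays a bijection.
#'
#' @param xs list of configurations, element `s` currently at state `s`.
#' @param perm integer vector: `perm[s]` is the replica id at state `s`.
#' @param energies function `(x, state_index)` returning the potential
#'   energy of configuration `x` under state `state_index`.
#' @param beta inverse temperature (mol/kcal).
#' @param parity `"even"` or `"odd"`.
#' @return list with updated `xs`, `perm` and a `record` tibble.
#' @export
replica_exchange_sweep <- function(xs, perm, energies, beta,
                                   parity = c("even", "odd")) {
  parity <- match.arg(parity)
  n <- length(xs)
  first <- if (parity == "even") 1L else 2L
  rec <- list()
  s <- first
  while (s + 1 <= n) {
    u_ii <- energies(xs[[s]], s)
    u_jj <- energies(xs[[s + 1]], s + 1)
    u_ij <- energies(xs[[s + 1]], s)      # state s evaluating neighbour's x
    u_ji <- energies(xs[[s]], s + 1)
    ddu <- u_ij + u_ji - u_ii - u_jj
    p <- min(1, exp(-beta * ddu))
    acc <- runif(1) < p
    if (acc) {
      tmp <- xs[[s]]; xs[[s]] <- xs[[s + 1]]; xs[[s + 1]] <- tmp
      tmp <- perm[s]; perm[s] <- perm[s + 1]; perm[s + 1] <- tmp
    }
    rec[[length(rec) + 1]] <- tibble(
      state_i = s, state_j = s + 1, u_ii = u_ii, u_jj = u_jj,
      u_ij = u_ij, u_ji = u_ji, p_accept = p, accepted = acc)
    s <- s + 2L
  }
  list(xs = xs, perm = perm,
       record = if (length(rec)) dplyr::bind_rows(rec) else
         tibble(state_i = integer(), state_j = integer(), u_ii = numeric(),
                u_jj = numeric(), u_ij = numeric(), u_ji = numeric(),
                p_accept = numeric(), accepted = logical()))
}

#' Run one staged alchemical leg with replica exchange
#'
#' Runs lambda-Hamiltonian replica exchange across all windows of the
#' given schedule(s), accumulates forward and reverse energy differences
#' for every adjacent window pair, estimates each window's free energy
#' with [bar_estimate()], totals the stages, and reports the mean and
#' sample standard deviation over `n_repeats` independent repeats
#' (distinct seeds: `seed + 1000 * repeat + window`).
#'
#' @param model a [system_model()] or [test_system()].
#' @param schedules a [make_lambda_schedule()] result, a list of them
#'   (charge stage then vdw stage), or a bare numeric lambda vector.
#' @param settings a [sampler_settings()]; `n_steps` counts MC steps per
#'   window between exchange attempts, `save_interval` frames are saved
#'   within each segment.
#' @param n_repeats number of independent repeats (default 4).
#' @param n_sweeps number of exchange sweeps.
#' @param n_equil_sweeps sweeps discarded as equilibration.
#' @return an `fe_result` (aggregated over repeats) with per-window
#'   breakdown; the full replica log of the last repeat is attached as
#'   `diagnostics$replica_log`.
#' @export
run_alchemical_leg <- function(model, schedules, settings, n_repeats = 4,
                               n_sweeps = 50, n_equil_sweeps = 10) {
  schedules <- normalize_schedules(schedules)
  windows <- schedule_states(schedules)
  n_win <- nrow(windows)
  if (n_win < 2)
    abort("need at least 2 lambda states", class = "alchemr_validation")
  beta <- settings$beta

  is_test <- inherits(model, "test_system")
  cs <- if (is_test) NULL else as_compiled(model)
  nb <- if (!is_test && inherits(model, "system_model"))
    default_settings(model) else nonbonded_settings()
  states <- lapply(seq_len(n_win), function(w)
    if (is_test) windows$lambda[w]
    else lambda_state_for(windows$stage[w], windows$lambda[w]))
  u_of <- function(x, w) {
    if (is_test) model$u(x, states[[w]])
    else total_energy(cs, x, states[[w]], nb)
  }

  repeats <- vector("list", n_repeats)
  last_log <- NULL
  for (r in seq_len(n_repeats)) {
    # per-window RNG streams
    streams <- lapply(seq_len(n_win), function(w) {
      set.seed(settings$seed + 1000L * r + w)
      get(".Random.seed", envir = globalenv())
    })
    xs <- lapply(seq_len(n_win), function(w)
      if (is_test) model$x0 else model$frame0)
    perm <- seq_len(n_win)
    fwd <- rep(list(numeric()), n_win - 1)
    rev_ <- rep(list(numeric()), n_win - 1)
    set.seed(settings$seed + 1000L * r)
    exchange_stream <- get(".Random.seed", envir = globalenv())
    logs <- list()

    seg <- modifyList(settings, list(seed = 0L))
    class(seg) <- "sampler_settings"
    for (sweep in seq_len(n_sweeps)) {
      for (w in seq_len(n_win)) {
        assign(".Random.seed", streams[[w]], envir = globalenv())
        out <- run_sampler_nostore(model, states[[w]], seg, start = xs[[w]])
        streams[[w]] <- get(".Random.seed", envir = globalenv())
        xs[[w]] <- out$x
        if (sweep > n_equil_sweeps) {
          for (x_s in out$frames) {
            if (w < n_win)
              fwd[[w]] <- c(fwd[[w]], u_of(x_s, w + 1) - u_of(x_s, w))
            if (w > 1)
              rev_[[w - 1]] <- c(rev_[[w - 1]], u_of(x_s, w - 1) - u_of(x_s, w))
          }
        }
      }
      assign(".Random.seed", exchange_stream, envir = globalenv())
      sw <- replica_exchange_sweep(xs, perm, u_of, beta,
                                   parity = if (sweep %% 2) "even" else "odd")
      exchange_stream <- get(".Random.seed", envir = globalenv())
      xs <- sw$xs; perm <- sw$perm
      logs[[sweep]] <- dplyr::mutate(sw$record, sweep = sweep, repeat_ = r)
    }
    per_window <- lapply(seq_len(n_win - 1), function(w)
      bar_estimate(work_samples(fwd[[w]], rev_[[w]], beta = beta)))
    repeats[[r]] <- per_window
    last_log <- dplyr::bind_rows(logs)
  }
  res <- aggregate_repeats(repeats)
  res$diagnostics$replica_log <- last_log
  res$diagnostics$windows <- windows
  res$diagnostics$stage_totals <- stage_totals(windows, res$per_window)
  res
}

normalize_schedules <- function(schedules) {
  if (is.numeric(schedules))
    schedules <- list(structure(list(stage = "charge", ff_family = "test",
                                     lambdas = schedules),
                                class = "lambda_schedule"))
  if (inherits(schedules, "lambda_schedule")) schedules <- list(schedules)
  for (s in schedules) {
    l <- s$lambdas
    if (l[1] != 0 || l[length(l)] != 1 || any(diff(l) <= 0))
      abort("lambda schedules must increase strictly from 0 to 1",
            class = "alchemr_validation")
  }
  schedules
}

# windows across stages: consecutive states; adjacent stages share the
# physical end point only notionally (state definitions differ), so each
# stage contributes its own chain of windows
schedule_states <- function(schedules) {
  dplyr::bind_rows(lapply(schedules, function(s)
    tibble(stage = s$stage, lambda = s$lambdas)))
}

stage_totals <- function(windows, per_window) {
  # window w sits between states w and w+1; attribute it to the stage of
  # state w (stages never interleave)
  st <- windows$stage[seq_len(nrow(windows) - 1)]
  keep <- windows$stage[seq_len(nrow(windows) - 1)] ==
    windows$stage[2:nrow(windows)]
  out <- tibble(stage = st, delta_g = per_window$delta_g, within_stage = keep)
  dplyr::summarise(dplyr::group_by(out[out$within_stage, ], .data$stage),
                   delta_g = sum(.data$delta_g), .groups = "drop")
}
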