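#' Alchemical coupling state
#'
#' `lambda_elec` scales solute charges to zero (0 = fully charged,
#' 1 = charges off); `lambda_vdw` turns off the solute van der Waals
#' interactions through the soft-core form (0 = full vdW, 1 = off).
#' Following the staged annihilation protocol, charges are removed
#' before vdW: `lambda_vdw > 0` requires `lambda_elec = 1`.
#'
#' @param lambda_elec electrostatic coupling parameter in \[0, 1\].
#' @param lambda_vdw van der Waals coupling parameter in \[0, 1\].
#' @return an `alchemical_state` object.
#' @export
alchemical_state <- function(lambda_elec = 0, lambda_vdw = 0) {
  if (lambda_elec < 0 || lambda_elec > 1 || lambda_vdw < 0 || lambda_vdw > 1)
    abort("lambda values must lie in [0, 1]", class = "alchemr_validation")
  if (lambda_vdw > 0 && lambda_elec != 1)
    abort("protocol constraint violated: lambda_vdw > 0 requires lambda_elec = 1",
          class = "alchemr_validation")
  structure(list(lambda_elec = lambda_elec, lambda_vdw = lambda_vdw),
            class = "alchemical_state")
}

#' Nonbonded settings
#'
#' `r_on`/`r_off` bound the cubic switching region applied to
#' Lennard-Jones interactions (infinite values disable switching, as in
#' bookend evaluations, which use full minimum-image sums without
#' cutoffs).  Coulomb interactions are never switched.
#' `softcore_delta` is the separation-shift parameter of the soft-core
#' LJ form.
#'
#' @param r_on switch-on distance (A).
#' @param r_off switch-off distance (A); must exceed `r_on`.
#' @param use_min_image apply minimum-image convention (requires a box).
#' @param softcore_delta soft-core shift parameter (> 0), default 0.5.
#' @return a `nonbonded_settings` object.
#' @export
nonbonded_settings <- function(r_on = Inf, r_off = Inf, use_min_image = FALSE,
                               softcore_delta = 0.5) {
  if (!(r_on > 0) || (is.finite(r_off) && r_off <= r_on))
    abort("need 0 < r_on < r_off", class = "alchemr_validation")
  if (softcore_delta <= 0)
    abort("softcore_delta must be > 0", class = "alchemr_validation")
  structure(list(r_on = r_on, r_off = r_off, use_min_image = use_min_image,
                 softcore_delta = softcore_delta),
            class = "nonbonded_settings")
}

#' @rdname nonbonded_settings
#' @param model a [system_model()].
#' @param bookend bookend evaluations use no cutoff and no switching;
#'   sampling evaluations use a switched region scaled to the box
#'   (`r_on = 0.35 * edge`, `r_off = 0.45 * edge`).
#' @export
default_settings <- function(model, bookend = FALSE) {
  if (is.null(model$box_edge))
    nonbonded_settings(Inf, Inf, use_min_image = FALSE)
  else if (bookend)
    nonbonded_settings(Inf, Inf, use_min_image = TRUE)
  else
    nonbonded_settings(0.35 * model$box_edge, 0.45 * model$box_edge,
                       use_min_image = TRUE)
}

# ---- compiled system ------------------------------------------------------

# Flattens a system_model into plain arrays for fast repeated energy
# evaluation: per-atom parameters, bonded term tables (with surrogate
# overrides applied), the non-excluded atom pair list split by group
# class, and the expanded charge-site pair list (cores + Drude particles).
compile_system <- function(model) {
  top <- model$topology
  par <- model$parameters
  n <- nrow(top$atoms)
  at <- par$atom_types[top$atoms$type]
  q <- vapply(at, `[[`, 0, "charge") * model$charge_scale
  eps <- vapply(at, `[[`, 0, "lj_epsilon")
  rmh <- vapply(at, `[[`, 0, "lj_rmin_half")
  alpha <- vapply(at, `[[`, 0, "polarizability")
  kd <- vapply(at, `[[`, 0, "drude_spring")
  qd <- ifelse(alpha > 0, -sqrt(alpha * kd), 0)
  mass <- vapply(at, `[[`, 0, "mass")
  is_solute <- top$atoms$group == "solute"

  bonds <- NULL
  if (nrow(top$bonds)) {
    bp <- lookup_bond_param(par, top$atoms$type[top$bonds[, 1]],
                            top$atoms$type[top$bonds[, 2]])
    bonds <- list(i = top$bonds[, 1], j = top$bonds[, 2],
                  k = bp$k_b, b0 = bp$b0)
    if (!is.null(model$bond_overrides)) {
      bonds$k <- model$bond_overrides$k_b
      bonds$b0 <- model$bond_overrides$b0
    }
  }
  angles <- NULL
  if (nrow(top$angles)) {
    ap <- lookup_angle_param(par, top$atoms$type[top$angles[, 1]],
                             top$atoms$type[top$angles[, 2]],
                             top$atoms$type[top$angles[, 3]])
    angles <- list(i = top$angles[, 1], j = top$angles[, 2],
                   k_atom = top$angles[, 3], k = ap$k_theta, th0 = ap$theta0)
    if (!is.null(model$angle_overrides)) {
      angles$k <- model$angle_overrides$k_theta
      angles$th0 <- model$angle_overrides$theta0
    }
  }

  # non-excluded atom pairs
  if (n > 1) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pi_ <- idx[, 1]; pj_ <- idx[, 2]
    if (nrow(top$exclusions)) {
      exkey <- paste(top$exclusions[, 1], top$exclusions[, 2])
      keep <- !(paste(pmin(pi_, pj_), pmax(pi_, pj_)) %in% exkey)
      pi_ <- pi_[keep]; pj_ <- pj_[keep]
    }
  } else {
    pi_ <- integer(); pj_ <- integer()
  }
  ns_i <- is_solute[pi_]; ns_j <- is_solute[pj_]
  pair_class <- ifelse(ns_i & ns_j, "ss", ifelse(ns_i | ns_j, "sv", "vv"))

  # charge-site pair expansion: core-core always, plus Drude combinations
  sp_i <- pi_; sp_j <- pj_
  sd_i <- rep(FALSE, length(pi_)); sd_j <- rep(FALSE, length(pj_))
  pol <- alpha > 0
  add_i <- c(); add_j <- c(); add_di <- c(); add_dj <- c()
  if (any(pol)) {
    w <- which(pol[pj_])
    add_i <- c(add_i, pi_[w]); add_j <- c(add_j, pj_[w])
    add_di <- c(add_di, rep(FALSE, length(w))); add_dj <- c(add_dj, rep(TRUE, length(w)))
    w <- which(pol[pi_])
    add_i <- c(add_i, pi_[w]); add_j <- c(add_j, pj_[w])
    add_di <- c(add_di, rep(TRUE, length(w))); add_dj <- c(add_dj, rep(FALSE, length(w)))
    w <- which(pol[pi_] & pol[pj_])
    add_i <- c(add_i, pi_[w]); add_j <- c(add_j, pj_[w])
    add_di <- c(add_di, rep(TRUE, length(w))); add_dj <- c(add_dj, rep(TRUE, length(w)))
  }
  cp_i <- c(sp_i, add_i); cp_j <- c(sp_j, add_j)
  cd_i <- c(sd_i, add_di); cd_j <- c(sd_j, add_dj)
  # site charges: core carries q - q_D for polarizable atoms
  q_core <- ifelse(pol, q - qd, q)
  cq_i <- ifelse(cd_i, qd[cp_i], q_core[cp_i])
  cq_j <- ifelse(cd_j, qd[cp_j], q_core[cp_j])
  c_scale_pow <- as.integer(is_solute[cp_i]) + as.integer(is_solute[cp_j])

  cs <- list(n = n, q = q, q_core = q_core, eps = eps, rmh = rmh,
             alpha = alpha, kd = kd, qd = qd, mass = mass, pol = pol,
             is_solute = is_solute, bonds = bonds, angles = angles,
             morse = model$morse, morse_depth = model$morse_depth,
             pair_i = pi_, pair_j = pj_, pair_class = pair_class,
             cpair_i = cp_i, cpair_j = cp_j, cdr_i = cd_i, cdr_j = cd_j,
             cq_i = cq_i, cq_j = cq_j, c_scale_pow = c_scale_pow,
             box_edge = model$box_edge)
  # precomputed selections for the bookend component energy
  cs$bk <- list(
    bonds_sol = if (!is.null(bonds)) which(is_solute[bonds$i]) else integer(),
    angles_sol = if (!is.null(angles)) which(is_solute[angles$j]) else integer(),
    pair_ss = which(pair_class == "ss"),
    cpair_ssv = which(is_solute[cp_i] | is_solute[cp_j]))
  cs
}

# solute-solute nonbonded + solute bonded + electrostatic solute-solvent
# energy, evaluated with no cutoff (minimum image when periodic): the
# bookend components that do not cancel between Hamiltonian levels.
bookend_part_energy <- function(cs, frame, state = NULL) {
  X <- frame$coordinates
  e <- 0
  bk <- cs$bk
  if (length(bk$bonds_sol)) {
    i <- cs$bonds$i[bk$bonds_sol]; j <- cs$bonds$j[bk$bonds_sol]
    dv <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
    b <- sqrt(rowSums(dv^2))
    k <- cs$bonds$k[bk$bonds_sol]; b0 <- cs$bonds$b0[bk$bonds_sol]
    if (isTRUE(cs$morse)) {
      a <- sqrt(k / cs$morse_depth)
      e <- e + sum(cs$morse_depth * (1 - exp(-a * (b - b0)))^2)
    } else e <- e + sum(k * (b - b0)^2)
  }
  if (length(bk$angles_sol)) {
    sub <- lapply(cs$angles, `[`, bk$angles_sol)
    th <- angle_values(X, sub)
    e <- e + sum(sub$k * (th - sub$th0)^2)
  }
  if (length(bk$pair_ss)) {
    i <- cs$pair_i[bk$pair_ss]; j <- cs$pair_j[bk$pair_ss]
    eps <- sqrt(cs$eps[i] * cs$eps[j])
    live <- eps > 0
    if (any(live)) {
      i <- i[live]; j <- j[live]; eps <- eps[live]
      dv <- pair_dvec(X, i, j, cs$box_edge)
      r <- sqrt(rowSums(dv^2))
      x6 <- ((cs$rmh[i] + cs$rmh[j]) / r)^6
      e <- e + sum(eps * (x6^2 - 2 * x6))
    }
  }
  if (length(bk$cpair_ssv)) {
    sel <- bk$cpair_ssv
    dv <- site_pair_dvec(cs, frame, cs$box_edge, sel)
    r <- sqrt(rowSums(dv^2))
    e <- e + sum(K_COULOMB * cs$cq_i[sel] * cs$cq_j[sel] / r)
  }
  # drude self-energy of solute sites (differs if levels differ in k_D)
  if (any(cs$pol & cs$is_solute)) {
    w <- cs$pol & cs$is_solute
    e <- e + sum(0.5 * cs$kd[w] * rowSums(frame$drude[w, , drop = FALSE]^2))
  }
  e
}

min_image <- function(dx, edge) {
  if (is.null(edge)) dx else dx - edge * round(dx / edge)
}

pair_dvec <- function(X, i, j, edge) {
  dx <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
  if (!is.null(edge)) dx <- dx - edge * round(dx / edge)
  dx
}

switch_fn <- function(r, r_on, r_off) {
  if (!is.finite(r_off)) return(rep(1, length(r)))
  s <- numeric(length(r))
  s[r <= r_on] <- 1
  mid <- r > r_on & r < r_off
  if (any(mid)) {
    r2 <- r[mid]^2; ron2 <- r_on^2; roff2 <- r_off^2
    s[mid] <- (roff2 - r2)^2 * (roff2 + 2 * r2 - 3 * ron2) / (roff2 - ron2)^3
  }
  s
}

switch_fn_deriv <- function(r, r_on, r_off) {
  if (!is.finite(r_off)) return(rep(0, length(r)))
  ds <- numeric(length(r))
  mid <- r > r_on & r < r_off
  if (any(mid)) {
    r2 <- r[mid]^2; ron2 <- r_on^2; roff2 <- r_off^2
    ds[mid] <- 12 * r[mid] * (roff2 - r2) * (ron2 - r2) / (roff2 - ron2)^3
  }
  ds
}

check_no_overlap <- function(r, what) {
  if (any(r < 1e-6))
    abort(paste0("overlapping atoms (r < 1e-6 A) in an included ", what,
                 " pair"),
          class = "alchemr_overlap")
  invisible(r)
}

# ---- public energy operations --------------------------------------------

as_compiled <- function(model) {
  if (inherits(model, "system_model")) compile_system(model) else model
}

#' Bonded energy
#'
#' Sum of `k_b (b - b0)^2` over bonds and `k_theta (theta - theta0)^2`
#' over angles (no 1/2 prefactor).  Surrogate targets may use Morse
#' bonds instead of harmonic ones.
#'
#' @param model a [system_model()] (or an internal compiled system).
#' @param frame a [new_frame()].
#' @return energy in kcal/mol (non-negative for harmonic terms).
#' @export
bonded_energy <- function(model, frame) {
  cs <- as_compiled(model)
  X <- frame$coordinates
  e <- 0
  if (!is.null(cs$bonds)) {
    dv <- X[cs$bonds$i, , drop = FALSE] - X[cs$bonds$j, , drop = FALSE]
    b <- sqrt(rowSums(dv^2))
    if (isTRUE(cs$morse)) {
      a <- sqrt(cs$bonds$k / cs$morse_depth)
      e <- e + sum(cs$morse_depth * (1 - exp(-a * (b - cs$bonds$b0)))^2)
    } else {
      e <- e + sum(cs$bonds$k * (b - cs$bonds$b0)^2)
    }
  }
  if (!is.null(cs$angles)) {
    th <- angle_values(X, cs$angles)
    e <- e + sum(cs$angles$k * (th - cs$angles$th0)^2)
  }
  e
}

angle_values <- function(X, ang) {
  u <- X[ang$i, , drop = FALSE] - X[ang$j, , drop = FALSE]
  v <- X[ang$k_atom, , drop = FALSE] - X[ang$j, , drop = FALSE]
  cu <- sqrt(rowSums(u^2)); cv <- sqrt(rowSums(v^2))
  cth <- pmin(1, pmax(-1, rowSums(u * v) / (cu * cv)))
  acos(cth)
}

#' Switched Lennard-Jones energy
#'
#' Pairwise 12-6 Lennard-Jones energy with Lorentz-Berthelot combining
#' (`eps_ij = sqrt(eps_i eps_j)`, `rmin_ij = rmin_half_i + rmin_half_j`)
#' multiplied by the cubic switching function which is 1 up to `r_on`
#' and 0 beyond `r_off`.
#'
#' @inheritParams bonded_energy
#' @param settings a [nonbonded_settings()].
#' @param pairs which pair classes to include: any of `"ss"`, `"sv"`,
#'   `"vv"` (solute-solute, solute-solvent, solvent-solvent).
#' @return energy in kcal/mol.
#' @export
lj_energy <- function(model, frame, settings = nonbonded_settings(),
                      pairs = c("ss", "sv", "vv")) {
  cs <- as_compiled(model)
  sel <- cs$pair_class %in% pairs
  if (!any(sel)) return(0)
  i <- cs$pair_i[sel]; j <- cs$pair_j[sel]
  dv <- pair_dvec(frame$coordinates, i, j,
                  if (settings$use_min_image) cs$box_edge else NULL)
  r <- sqrt(rowSums(dv^2))
  check_no_overlap(r, "Lennard-Jones")
  eps <- sqrt(cs$eps[i] * cs$eps[j])
  rmin <- cs$rmh[i] + cs$rmh[j]
  live <- eps > 0 & r < settings$r_off
  if (!any(live)) return(0)
  x6 <- (rmin[live] / r[live])^6
  u <- eps[live] * (x6^2 - 2 * x6)
  sum(u * switch_fn(r[live], settings$r_on, settings$r_off))
}

#' Soft-core Lennard-Jones energy
#'
#' The separation-shifted soft-core form applied to the pairs being
#' annihilated (those involving at least one solute atom): with
#' `lambda = lambda_vdw`, `sigma = rmin / 2^(1/6)` and
#' `u = sigma^2 / (r^2 + delta * lambda * sigma^2)`, the pair energy is
#' `(1 - lambda) * 4 * eps * (u^6 - u^3)`, switched like [lj_energy()].
#' The form is finite at `r = 0` for `lambda > 0`, reduces to the plain
#' LJ energy at `lambda = 0`, and vanishes at `lambda = 1`.
#'
#' @inheritParams lj_energy
#' @param state an [alchemical_state()].
#' @return energy in kcal/mol.
#' @export
softcore_lj_energy <- function(model, frame, state,
                               settings = nonbonded_settings()) {
  cs <- as_compiled(model)
  lam <- state$lambda_vdw
  if (lam >= 1) return(0)
  sel <- cs$pair_class %in% c("ss", "sv")
  if (!any(sel)) return(0)
  i <- cs$pair_i[sel]; j <- cs$pair_j[sel]
  dv <- pair_dvec(frame$coordinates, i, j,
                  if (settings$use_min_image) cs$box_edge else NULL)
  r2 <- rowSums(dv^2)
  if (lam == 0) check_no_overlap(sqrt(r2), "Lennard-Jones")
  eps <- sqrt(cs$eps[i] * cs$eps[j])
  rmin <- cs$rmh[i] + cs$rmh[j]
  sig2 <- (rmin / 2^(1 / 6))^2
  u <- sig2 / (r2 + settings$softcore_delta * lam * sig2)
  e <- (1 - lam) * 4 * eps * (u^6 - u^3)
  live <- eps > 0 & sqrt(r2) < settings$r_off
  if (!any(live)) return(0)
  sum(e[live] * switch_fn(sqrt(r2[live]), settings$r_on, settings$r_off))
}

#' Coulomb energy
#'
#' `k_e q_i q_j / r_ij` over all non-excluded charge-site pairs (atom
#' cores and Drude particles), minimum-image when periodic, with no
#' switching.  Solute site charges are scaled by `(1 - lambda_elec)`.
#'
#' @inheritParams softcore_lj_energy
#' @return energy in kcal/mol.
#' @export
coulomb_energy <- function(model, frame, state = alchemical_state(),
                           settings = nonbonded_settings()) {
  cs <- as_compiled(model)
  if (!length(cs$cpair_i)) return(0)
  dv <- site_pair_dvec(cs, frame,
                       if (settings$use_min_image) cs$box_edge else NULL)
  r <- sqrt(rowSums(dv^2))
  check_no_overlap(r, "Coulomb")
  scale <- (1 - state$lambda_elec)^cs$c_scale_pow
  qq <- cs$cq_i * cs$cq_j * scale
  sum(K_COULOMB * qq / r)
}

# displacement vectors (site_i - site_j) for coulomb pairs; the periodic
# image is fixed by the core-core separation so the energy stays smooth
# in the Drude displacements
site_pair_dvec <- function(cs, frame, edge = NULL, sel = NULL) {
  X <- frame$coordinates; D <- frame$drude
  pi_ <- cs$cpair_i; pj_ <- cs$cpair_j
  di <- cs$cdr_i; dj <- cs$cdr_j
  if (!is.null(sel)) { pi_ <- pi_[sel]; pj_ <- pj_[sel]
                       di <- di[sel]; dj <- dj[sel] }
  dv <- X[pi_, , drop = FALSE] - X[pj_, , drop = FALSE]
  if (!is.null(edge)) dv <- min_image(dv, edge)
  if (any(di)) dv[di, ] <- dv[di, , drop = FALSE] + D[pi_[di], , drop = FALSE]
  if (any(dj)) dv[dj, ] <- dv[dj, , drop = FALSE] - D[pj_[dj], , drop = FALSE]
  dv
}

drude_spring_energy <- function(cs, frame) {
  if (!any(cs$pol)) return(0)
  d2 <- rowSums(frame$drude[cs$pol, , drop = FALSE]^2)
  sum(0.5 * cs$kd[cs$pol] * d2)
}

external_field_energy <- function(cs, frame, state, efield) {
  if (is.null(efield) || all(efield == 0)) return(0)
  # -sum_s q_s E . r_s over all charge sites
  X <- frame$coordinates
  scale <- ifelse(cs$is_solute, 1 - state$lambda_elec, 1)
  e <- -sum((cs$q_core * scale) * (X %*% efield))
  if (any(cs$pol)) {
    pos_d <- X[cs$pol, , drop = FALSE] + frame$drude[cs$pol, , drop = FALSE]
    e <- e - sum((cs$qd[cs$pol] * scale[cs$pol]) * (pos_d %*% efield))
  }
  e
}

#' Total potential energy
#'
#' Bonded terms, Drude spring self-energy, switched LJ on
#' solvent-solvent pairs, soft-core LJ on solute-involving pairs, and
#' Coulomb with solute charges scaled by `(1 - lambda_elec)`.  At the
#' fully coupled state this is the plain force-field energy.
#'
#' @inheritParams softcore_lj_energy
#' @param efield optional uniform external field, length-3 vector
#'   (kcal/mol/A/e).
#' @return energy in kcal/mol.
#' @export
total_energy <- function(model, frame, state = alchemical_state(),
                         settings = nonbonded_settings(), efield = NULL) {
  cs <- as_compiled(model)
  bonded_energy(cs, frame) +
    drude_spring_energy(cs, frame) +
    lj_energy(cs, frame, settings, pairs = "vv") +
    softcore_lj_energy(cs, frame, state, settings) +
    coulomb_energy(cs, frame, state, settings) +
    external_field_energy(cs, frame, state, efield)
}

#' Group-wise energy decomposition
#'
#' Splits the potential energy by pair-group membership: nonbonded
#' solute-solute, electrostatic and vdW solute-solvent, solvent-solvent
#' (including solvent bonded terms), bonded solute terms and Drude
#' spring energy.  The components sum to the total single-pass energy.
#'
#' @inheritParams total_energy
#' @return a one-row tibble (class `energy_breakdown`) with components
#'   and `total`, all in kcal/mol.
#' @export
decompose_energy <- function(model, frame, state = alchemical_state(),
                             settings = nonbonded_settings()) {
  cs <- as_compiled(model)
  # bonded terms split by the group of the first atom of each term
  bonded_by_group <- function(groups_wanted) {
    sub <- cs
    if (!is.null(sub$bonds)) {
      keep <- cs$is_solute[sub$bonds$i] == (groups_wanted == "solute")
      sub$bonds <- lapply(sub$bonds, `[`, keep)
      if (!length(sub$bonds$i)) sub$bonds <- NULL
    }
    if (!is.null(sub$angles)) {
      keep <- cs$is_solute[sub$angles$j] == (groups_wanted == "solute")
      sub$angles <- lapply(sub$angles, `[`, keep)
      if (!length(sub$angles$i)) sub$angles <- NULL
    }
    bonded_energy(sub, frame)
  }
  bonded_solute <- bonded_by_group("solute")
  bonded_solvent <- bonded_by_group("solvent")

  coulomb_by_class <- function(classes) {
    sub <- cs
    keep <- pair_site_class(cs) %in% classes
    for (fld in c("cpair_i", "cpair_j", "cdr_i", "cdr_j", "cq_i", "cq_j",
                  "c_scale_pow"))
      sub[[fld]] <- cs[[fld]][keep]
    coulomb_energy(sub, frame, state, settings)
  }
  ss_elec <- coulomb_by_class("ss")
  sv_elec <- coulomb_by_class("sv")
  vv_elec <- coulomb_by_class("vv")

  sc_by_class <- function(classes) {
    sub <- cs
    keep <- cs$pair_class %in% classes
    for (fld in c("pair_i", "pair_j", "pair_class"))
      sub[[fld]] <- cs[[fld]][keep]
    softcore_lj_energy(sub, frame, state, settings)
  }
  ss_vdw <- sc_by_class("ss")
  sv_vdw <- sc_by_class("sv")
  vv_vdw <- lj_energy(cs, frame, settings, pairs = "vv")
  drude <- drude_spring_energy(cs, frame)

  out <- tibble(
    solute_solute = ss_elec + ss_vdw,
    solute_solvent_elec = sv_elec,
    solute_solvent_vdw = sv_vdw,
    solvent_solvent = vv_elec + vv_vdw + bonded_solvent,
    bonded_solute = bonded_solute,
    drude_spring = drude)
  out$total <- rowSums(out)
  class(out) <- c("energy_breakdown", class(out))
  out
}

pair_site_class <- function(cs) {
  si <- cs$is_solute[cs$cpair_i]; sj <- cs$is_solute[cs$cpair_j]
  ifelse(si & sj, "ss", ifelse(si | sj, "sv", "vv"))
}

#' Bookend energy difference between two Hamiltonian levels
#'
#' Potential-energy difference `U_B - U_A` on one frame, using only the
#' components that do not cancel between levels sharing the same solvent
#' model: solute-solute nonbonded, solute bonded, and electrostatic
#' solute-solvent interactions.  Solvent-solvent terms and
#' solute-solvent vdW terms are identical at both levels and are
#' omitted.  Bookend evaluations use full minimum-image sums with no
#' cutoff.
#'
#' @param model_a,model_b [system_model()]s sharing a topology.
#' @param frame a [new_frame()].
#' @param state an [alchemical_state()] (physical end point by default).
#' @return `U_B - U_A` in kcal/mol.
#' @export
bookend_delta_u <- function(model_a, model_b, frame,
                            state = alchemical_state()) {
  if (inherits(model_a, "system_model") && inherits(model_b, "system_model") &&
      !identical(dim(model_a$topology$bonds), dim(model_b$topology$bonds)))
    abort("bookend levels must share a topology", class = "alchemr_validation")
  ca <- as_compiled(model_a)
  cb <- as_compiled(model_b)
  bookend_part_energy(cb, frame, state) - bookend_part_energy(ca, frame, state)
}

#' Recenter a periodic frame around the solute
#'
#' Translates the frame so the solute centroid sits at the box centre
#' and wraps each solvent molecule whole (by its first atom's image)
#' into the primary box.  Minimum-image energies are unchanged.  Gas
#' phase frames are returned unmodified.
#'
#' @param frame a [new_frame()].
#' @param model a periodic [system_model()].
#' @return a recentred `frame`.
#' @export
recenter <- function(frame, model) {
  if (is.null(model$box_edge)) return(frame)
  edge <- model$box_edge
  top <- model$topology
  X <- frame$coordinates
  sol <- which(top$atoms$group == "solute")
  if (!length(sol)) sol <- 1L
  shift <- rep(edge / 2, 3) - colMeans(X[sol, , drop = FALSE])
  X <- sweep(X, 2, shift, `+`)
  # wrap solvent molecules whole, keyed on each molecule's first atom
  solvent <- which(top$atoms$group == "solvent")
  if (length(solvent)) {
    mol_id <- cumsum(seq_along(solvent) %% 3 == 1)  # 3-site solvent
    for (m in unique(mol_id)) {
      rows <- solvent[mol_id == m]
      ref <- X[rows[1], ]
      wrap <- -edge * floor(ref / edge)
      X[rows, ] <- sweep(X[rows, , drop = FALSE], 2, wrap, `+`)
    }
  }
  new_frame(X, frame$drude, frame$replica_index, frame$step)
}
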